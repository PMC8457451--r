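# Synthetic H&E-like fixture generator. Nuclei are radially perturbed
# ellipses (harmonics 2-6 emulate membrane irregularity) with a radial
# intensity profile whose pale center emulates chromatin clearing, placed by
# a clustered point process on an eosin-pink background. The two class
# presets differ in size, boundary irregularity, and central clearing, the
# nuclear criteria that separate PTC-like from non-PTC-like nuclei. Every
# draw is governed by one seed, so a dataset is byte-reproducible.

#' Per-class nuclear presets of the synthetic generator
#'
#' PTC-like nuclei are larger (1.5x mean radius), more irregular in outline,
#' and show stronger central chromatin clearing than non-PTC-like nuclei;
#' these margins are the study conditions for the end-to-end recovery checks.
#'
#' @param class_label `"PTC"` or `"nonPTC"`.
#' @return Named list of nuclear parameters.
#' @export
class_preset <- function(class_label = c("PTC", "nonPTC")) {
  class_label <- match.arg(class_label)
  common <- list(
    base_color = c(88, 60, 130),   # hematoxylin purple
    noise_sd = 6,
    cluster_intensity = 0.6
  )
  if (class_label == "PTC") {
    c(list(radius_mean = 10.5, radius_sd = 1.5, axis_ratio = c(1.1, 1.6),
           boundary_irregularity = 0.22, center_clearing = 1.6), common)
  } else {
    c(list(radius_mean = 7, radius_sd = 1, axis_ratio = c(1.0, 1.3),
           boundary_irregularity = 0.05, center_clearing = 1.1), common)
  }
}

#' Generator configuration
#'
#' @param n_patients_per_class Patients per class.
#' @param images_per_patient Images per patient.
#' @param nuclei_per_image Integer range `c(min, max)` of nuclei per image.
#' @param image_size `c(H, W)` in pixels.
#' @param presets Named list with elements `PTC` and `nonPTC` (see
#'   [class_preset()]).
#' @param background_color Eosin-pink background RGB.
#' @param n_raters Panel size for the synthetic vote table.
#' @param vote_prob Probability that a rater votes the true class.
#' @param vote_concentration Beta-binomial concentration; large values make
#'   every panel split concentrate at `vote_prob`.
#' @param seed Seed governing all randomness of the generator.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients_per_class = 10,
                             images_per_patient = 2,
                             nuclei_per_image = c(12, 18),
                             image_size = c(128, 128),
                             presets = list(PTC = class_preset("PTC"),
                                            nonPTC = class_preset("nonPTC")),
                             background_color = c(235, 200, 215),
                             n_raters = 24,
                             vote_prob = 0.85,
                             vote_concentration = 30,
                             seed = 1) {
  stopifnot(n_patients_per_class >= 1, images_per_patient >= 1,
            length(nuclei_per_image) == 2, all(nuclei_per_image >= 1),
            all(image_size >= 16))
  structure(list(
    n_patients_per_class = as.integer(n_patients_per_class),
    images_per_patient = as.integer(images_per_patient),
    nuclei_per_image = as.integer(nuclei_per_image),
    image_size = as.integer(image_size),
    presets = presets,
    background_color = background_color,
    n_raters = as.integer(n_raters),
    vote_prob = vote_prob,
    vote_concentration = vote_concentration,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Rasterize one nucleus into img/lm (modified by reference-style return).
# Boundary: ellipse radius modulated by harmonics 2-6 with total amplitude
# `irregularity`; intensity: base color brightened toward the center by the
# clearing factor; later nuclei overwrite earlier ones on contested pixels.
draw_nucleus <- function(img, lm, center, label, preset) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r0 <- max(2, rnorm(1, preset$radius_mean, preset$radius_sd))
  q <- runif(1, preset$axis_ratio[1], preset$axis_ratio[2])
  a <- r0 * sqrt(q); b <- r0 / sqrt(q)      # area-preserving ellipse axes
  phi <- runif(1, 0, 2 * pi)
  nh <- 5
  amp <- preset$boundary_irregularity
  amps <- abs(rnorm(nh, 0, 1)); amps <- amps / max(1e-9, sum(amps)) * amp
  phases <- runif(nh, 0, 2 * pi)
  rmax <- max(a, b) * (1 + amp) + 1
  r1 <- max(1, floor(center[1] - rmax)); r2 <- min(h, ceiling(center[1] + rmax))
  c1 <- max(1, floor(center[2] - rmax)); c2 <- min(w, ceiling(center[2] + rmax))
  if (r1 > r2 || c1 > c2) return(list(img = img, lm = lm, drawn = FALSE))
  rr <- r1:r2; cc <- c1:c2
  dy <- outer(rr - center[1], rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - center[2])
  # rotate into the ellipse frame
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  theta <- atan2(v / b, u / a)
  base_r <- (a * b) / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  mod <- rep(1, length(theta))
  for (k in seq_len(nh)) {
    mod <- mod + amps[k] * cos((k + 1) * theta + phases[k])
  }
  bnd <- base_r * pmax(0.2, mod)
  d <- sqrt(dx^2 + dy^2)
  inside <- d <= bnd
  if (!any(inside)) return(list(img = img, lm = lm, drawn = FALSE))
  depth <- pmax(0, 1 - d / pmax(bnd, 1e-9))      # 1 at center, 0 at border
  gain <- 1 + (preset$center_clearing - 1) * depth
  idx <- which(inside)
  sub_lm <- lm[rr, cc, drop = FALSE]
  sub_lm[idx] <- label
  lm[rr, cc] <- sub_lm
  for (ch in 1:3) {
    sub <- img[rr, cc, ch]
    sub[idx] <- preset$base_color[ch] * gain[idx]
    img[rr, cc, ch] <- sub
  }
  list(img = img, lm = lm, drawn = TRUE)
}

# Clustered centroid placement: cluster centers uniform in the frame, each
# nucleus sits near a cluster with prob. cluster_intensity, else uniform.
place_centroids <- function(n, size, r_mean, cluster_intensity) {
  h <- size[1]; w <- size[2]
  margin <- r_mean + 2
  n_clusters <- max(1, round(n / 6))
  ctr <- cbind(runif(n_clusters, margin, h - margin),
               runif(n_clusters, margin, w - margin))
  out <- matrix(NA_real_, 0, 2)
  attempts <- 0
  while (nrow(out) < n && attempts < n * 30) {
    attempts <- attempts + 1
    if (runif(1) < cluster_intensity) {
      k <- sample.int(n_clusters, 1)
      p <- ctr[k, ] + rnorm(2, 0, 3 * r_mean)
    } else {
      p <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
    }
    if (p[1] < margin || p[1] > h - margin || p[2] < margin || p[2] > w - margin) next
    if (nrow(out) > 0 &&
        min(sqrt(rowSums(sweep(out, 2, p)^2))) < 1.9 * r_mean) next
    out <- rbind(out, p)
  }
  out
}

#' Generate a synthetic labeled dataset
#'
#' Produces, per patient, `images_per_patient` H&E-like tiles with
#' ground-truth instance label maps, a manifest tibble, a synthetic
#' pathologist vote table (beta-binomial panel splits whose mean tracks the
#' true class), and a generation log with the placed-nuclei bookkeeping.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return List of class `synthetic_dataset`: `manifest`, `images` (named
#'   list of H x W x 3 arrays), `labelmaps` (named list of label matrices),
#'   `votes` (tibble), `log` (tibble image_id / nuclei_requested /
#'   nuclei_placed).
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(derive_seed(cfg$seed, 1))
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  manifest <- list(); images <- list(); labelmaps <- list(); log <- list()
  classes <- c(rep("PTC", cfg$n_patients_per_class),
               rep("nonPTC", cfg$n_patients_per_class))
  ids <- sprintf("P%03d", seq_along(classes))
  for (i in seq_along(ids)) {
    preset <- cfg$presets[[classes[i]]]
    for (im in seq_len(cfg$images_per_patient)) {
      image_id <- sprintf("%s_img%02d", ids[i], im)
      n_req <- sample(cfg$nuclei_per_image[1]:cfg$nuclei_per_image[2], 1)
      img <- array(rep(cfg$background_color, each = h * w), dim = c(h, w, 3))
      lm <- matrix(0L, h, w)
      cen <- place_centroids(n_req, c(h, w), preset$radius_mean,
                             preset$cluster_intensity)
      if (nrow(cen) < n_req) {
        warn(sprintf("%s: placed %d of %d nuclei (packing limit)",
                     image_id, nrow(cen), n_req))
      }
      placed <- 0L
      for (k in seq_len(nrow(cen))) {
        res <- draw_nucleus(img, lm, cen[k, ], k, preset)
        img <- res$img; lm <- res$lm
        if (res$drawn) placed <- placed + 1L
      }
      img <- img + array(rnorm(h * w * 3, 0, preset$noise_sd), dim = dim(img))
      img <- round(pmax(pmin(img, 255), 0))
      images[[image_id]] <- img
      labelmaps[[image_id]] <- lm
      log[[image_id]] <- tibble::tibble(
        image_id = image_id, nuclei_requested = n_req,
        nuclei_placed = length(unique(lm[lm > 0]))
      )
      manifest[[image_id]] <- tibble::tibble(
        patient_id = ids[i], class_label = classes[i],
        image_path = paste0("images/", image_id, ".tif"),
        labelmap_path = paste0("labels/", image_id, ".tif"),
        resolution_um_per_px = 0.23, image_id = image_id
      )
    }
  }
  votes <- synthetic_votes(ids, classes, cfg)
  structure(list(
    manifest = dplyr::bind_rows(manifest),
    images = images, labelmaps = labelmaps,
    votes = votes, log = dplyr::bind_rows(log),
    config = cfg
  ), class = "synthetic_dataset")
}

# Beta-binomial panel splits: vote_prob is the per-rater probability of the
# true class; concentration -> Inf degenerates to a binomial at vote_prob.
synthetic_votes <- function(ids, classes, cfg) {
  k <- cfg$vote_concentration
  p0 <- cfg$vote_prob
  p_case <- rbeta(length(ids), p0 * k, (1 - p0) * k)
  ptc_votes <- rbinom(length(ids), cfg$n_raters,
                      ifelse(classes == "PTC", p_case, 1 - p_case))
  tibble::tibble(
    case_id = ids,
    votes_non_ptc = cfg$n_raters - ptc_votes,
    votes_ptc = ptc_votes,
    rereviewed = FALSE,
    rereview_ptc_count = NA_integer_
  )
}

#' Write a synthetic dataset to disk
#'
#' Writes `images/*.tif`, `labels/*.tif`, `manifest.csv`, `votes.csv`, and
#' `generation_log.csv` under `dir`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(ds$images)) {
    write_image(ds$images[[id]], file.path(dir, "images", paste0(id, ".tif")))
    write_labelmap(ds$labelmaps[[id]], file.path(dir, "labels", paste0(id, ".tif")))
  }
  write_manifest(ds$manifest, file.path(dir, "manifest.csv"))
  write_votes(ds$votes, file.path(dir, "votes.csv"))
  utils::write.csv(as.data.frame(ds$log), file.path(dir, "generation_log.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Corrupt a label map with merged and truncated instances
#'
#' Produces the two artifact types the median-area filter targets: randomly
#' merges pairs of adjacent instances into one label (merged nuclei) and
#' crops random instances to small fragments (nuclei insufficiently
#' represented in the image plane).
#'
#' @param lm Label matrix.
#' @param merge_rate Probability that an instance is merged into an adjacent
#'   neighbour.
#' @param drop_rate Probability that an instance is cropped to a fragment
#'   (about 30% of its pixels, top rows kept).
#' @param seed Seed.
#' @return Perturbed label matrix.
#' @export
perturb_labels <- function(lm, merge_rate = 0, drop_rate = 0, seed = 1) {
  assert_labelmap(lm)
  stopifnot(merge_rate >= 0, merge_rate <= 1, drop_rate >= 0, drop_rate <= 1)
  if (merge_rate == 0 && drop_rate == 0) return(lm)
  set.seed(derive_seed(seed, 9))
  labs <- sort(unique(lm[lm > 0]))
  if (length(labs) == 0) return(lm)
  # adjacency via 1-pixel dilation overlap
  if (merge_rate > 0 && length(labs) > 1) {
    for (id in labs) {
      if (runif(1) >= merge_rate) next
      mask <- lm == id
      dil <- EBImage::dilate(EBImage::Image(mask * 1),
                             EBImage::makeBrush(5, "diamond"))
      touching <- setdiff(unique(lm[as.matrix(dil) > 0.5 & lm > 0]), id)
      if (length(touching) == 0) next
      target <- touching[1]
      lm[lm == id] <- as.integer(target)
    }
  }
  if (drop_rate > 0) {
    labs2 <- sort(unique(lm[lm > 0]))
    for (id in labs2) {
      if (runif(1) >= drop_rate) next
      px <- which(lm == id, arr.ind = TRUE)
      keep_n <- max(1, floor(0.3 * nrow(px)))
      ord <- order(px[, 1], px[, 2])
      drop_px <- px[ord[-seq_len(keep_n)], , drop = FALSE]
      lm[drop_px] <- 0L
    }
  }
  lm
}
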