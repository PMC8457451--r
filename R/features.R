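# Per-nucleus morphometry: 23 color features (channel statistics, ring-zone
# color ratios, GLCM texture, Shannon entropy), 4 shape features, and 9
# spatial features (nuclear crowding at eight radii + nearest-neighbour
# distance). All features are computed per nucleus from its RGB crop, binary
# mask, and the image-level centroid configuration.

#' Canonical per-nucleus feature names
#'
#' The 36 feature columns in their fixed order: 23 color, 4 shape, 9 spatial.
#'
#' @param family Optionally restrict to one family.
#' @return Character vector of feature names.
#' @export
nucleus_feature_names <- function(family = c("all", "color", "shape", "spatial")) {
  family <- match.arg(family)
  color <- c(
    "mean_r", "mean_g", "mean_b", "mean_gray",
    "std_r", "std_g", "std_b", "std_gray",
    "ratio_border_middle_r", "ratio_border_middle_g",
    "ratio_border_middle_b", "ratio_border_middle_gray",
    "ratio_border_center_r", "ratio_border_center_g",
    "ratio_border_center_b", "ratio_border_center_gray",
    "glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity",
    "glcm_energy", "glcm_correlation", "glcm_asm",
    "shannon_entropy"
  )
  shape <- c("area", "perimeter", "eccentricity", "solidity")
  spatial <- c(paste0("crowd_x", c(3, 5, 7, 9, 15, 20, 25, 30)), "nn_distance")
  switch(family,
    all = c(color, shape, spatial),
    color = color, shape = shape, spatial = spatial
  )
}

#' Luminance grayscale conversion
#'
#' ITU-R 709 luminance: `0.2125 R + 0.7154 G + 0.0721 B`, kept real-valued
#' in \[0, 255\].
#'
#' @param img H x W x 3 RGB array (or an RGB crop).
#' @return H x W numeric matrix.
#' @export
to_grayscale <- function(img) {
  assert_rgb_image(img)
  0.2125 * img[, , 1] + 0.7154 * img[, , 2] + 0.0721 * img[, , 3]
}

#' Partition a nucleus mask into border / middle / center ring zones
#'
#' Divides the mask into three disjoint zones of equal pixel count (within
#' one pixel) ordered by depth: pixels are sorted by Euclidean distance to
#' the nucleus boundary (ties broken by row, then column); the shallowest
#' third is the border, the deepest third the center. Used for the
#' chromatin-clearing color ratios.
#'
#' @param mask Binary matrix (the nucleus support within its bounding box).
#' @return Integer matrix of the mask's shape: 0 outside, 1 border,
#'   2 middle, 3 center; or `NULL` when the mask has fewer than 3 pixels.
#' @export
ring_zones <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  if (n < 3) return(NULL)
  d <- padded_distmap(mask * 1)
  dv <- d[px]
  ord <- order(dv, px[, 1], px[, 2])
  base <- n %/% 3; rem <- n %% 3
  sizes <- c(base + (rem >= 1), base + (rem >= 2), base)
  zone_of <- rep.int(1:3, times = sizes)
  zones <- matrix(0L, nrow(mask), ncol(mask))
  zones[px[ord, , drop = FALSE]] <- zone_of
  zones
}

# Gray-level co-occurrence matrix properties, averaged over the four
# principal directions at distance 1, symmetric and normalized, 256 levels.
# Out-of-mask pixels never enter a pair. Returns the six properties;
# correlation of a single-valued crop is defined as 0.
glcm_props <- function(gray, mask, levels = 256) {
  g <- round(gray)
  g[!mask] <- NA
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  acc <- NULL
  h <- nrow(g); w <- ncol(g)
  counts_all <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    dr <- offsets[[k]][1]; dc <- offsets[[k]][2]
    r1 <- max(1, 1 - dr):min(h, h - dr)
    c1 <- max(1, 1 - dc):min(w, w - dc)
    a <- g[r1, c1, drop = FALSE]
    b <- g[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) { counts_all[[k]] <- NULL; next }
    ai <- a[ok]; bi <- b[ok]
    code <- c(ai * levels + bi, bi * levels + ai) + 1  # symmetric
    counts_all[[k]] <- tabulate(code, nbins = levels * levels)
  }
  props <- matrix(NA_real_, 0, 6)
  for (counts in counts_all) {
    if (is.null(counts)) next
    idx <- which(counts > 0)
    p <- counts[idx] / sum(counts[idx])
    i <- (idx - 1) %/% levels
    j <- (idx - 1) %% levels
    diffs <- i - j
    contrast <- sum(p * diffs^2)
    dissim <- sum(p * abs(diffs))
    homog <- sum(p / (1 + diffs^2))
    asm <- sum(p^2)
    mu_i <- sum(p * i); mu_j <- sum(p * j)
    s_i <- sqrt(sum(p * (i - mu_i)^2)); s_j <- sqrt(sum(p * (j - mu_j)^2))
    corr <- if (s_i < 1e-12 || s_j < 1e-12) 0 else {
      sum(p * (i - mu_i) * (j - mu_j)) / (s_i * s_j)
    }
    props <- rbind(props, c(contrast, dissim, homog, sqrt(asm), corr, asm))
  }
  if (nrow(props) == 0) return(rep(NA_real_, 6))
  colMeans(props)
}

# Shannon entropy (bits) of the 256-bin histogram of masked 8-bit values.
shannon_entropy <- function(gray, mask) {
  v <- round(gray[mask])
  if (length(v) == 0) return(NA_real_)
  p <- tabulate(v + 1, nbins = 256)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

#' Color features of one nucleus
#'
#' The 23 color features: mean and (population) standard deviation of the
#' red, green, blue, and luminance channels over the masked pixels (8);
#' mean-intensity ratios border/middle and border/center per channel from the
#' [ring_zones()] partition (8), capturing chromatin clearing and margination
#' to the nuclear membrane; six GLCM texture properties (contrast,
#' dissimilarity, homogeneity, energy, correlation, ASM) averaged over the
#' four principal directions at offset 1 on the 8-bit grayscale crop with
#' out-of-mask pixels excluded (6); and the Shannon entropy of the masked
#' grayscale histogram (1).
#'
#' @param crop RGB crop (bounding box of the nucleus).
#' @param mask Binary matrix of the same height/width.
#' @return Named numeric vector of length 23.
#' @export
color_features <- function(crop, mask) {
  assert_rgb_image(crop)
  if (!any(mask)) abort("mask is empty")
  gray <- to_grayscale(crop)
  chans <- list(r = crop[, , 1], g = crop[, , 2], b = crop[, , 3], gray = gray)
  means <- vapply(chans, function(ch) mean(ch[mask]), numeric(1))
  stds <- vapply(chans, function(ch) pop_sd(ch[mask]), numeric(1))
  zones <- ring_zones(mask)
  ratios_bm <- ratios_bc <- setNames(rep(NA_real_, 4), names(chans))
  if (!is.null(zones)) {
    for (nm in names(chans)) {
      ch <- chans[[nm]]
      mb <- mean(ch[zones == 1]); mm <- mean(ch[zones == 2]); mc <- mean(ch[zones == 3])
      ratios_bm[nm] <- if (is.na(mm) || mm == 0) NA_real_ else mb / mm
      ratios_bc[nm] <- if (is.na(mc) || mc == 0) NA_real_ else mb / mc
    }
  }
  gl <- glcm_props(gray, mask)
  ent <- shannon_entropy(gray, mask)
  out <- c(means, stds, ratios_bm, ratios_bc, gl, ent)
  setNames(out, nucleus_feature_names("color"))
}

# Contour-weighted perimeter (Benkrid & Crookes estimator): border pixels
# (4-connectivity erosion residue, image edge counts as background) coded by
# a 3x3 convolution; codes map to weights 1, sqrt(2), (1+sqrt(2))/2.
perimeter_estimate <- function(mask) {
  m <- mask * 1L
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  core <- pad[2:(h + 1), 2:(w + 1)]
  er <- core &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  border <- matrix(0L, h + 2, w + 2)
  border[2:(h + 1), 2:(w + 1)] <- (core == 1L) & !er
  b <- border
  code <- b[2:(h + 1), 2:(w + 1)] +
    2L * (b[1:h, 2:(w + 1)] + b[3:(h + 2), 2:(w + 1)] +
          b[2:(h + 1), 1:w] + b[2:(h + 1), 3:(w + 2)]) +
    10L * (b[1:h, 1:w] + b[1:h, 3:(w + 2)] +
           b[3:(h + 2), 1:w] + b[3:(h + 2), 3:(w + 2)])
  wts <- numeric(50)
  wts[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  wts[c(21, 33) + 1] <- sqrt(2)
  wts[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  sum(wts[code[border[2:(h + 1), 2:(w + 1)] == 1L] + 1])
}

#' Shape features of one nucleus
#'
#' Area (pixel count), contour-weighted perimeter estimate, eccentricity of
#' the ellipse with matched second central moments (0 = circle), and solidity
#' (pixel area over convex-hull pixel area; low solidity indicates an
#' irregular nuclear membrane).
#'
#' @param mask Binary matrix (4-connected nucleus support).
#' @return Named numeric vector `area, perimeter, eccentricity, solidity`.
#' @export
shape_features <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 0) abort("mask is empty")
  area <- n
  perim <- perimeter_estimate(mask)
  # moment-matched ellipse eccentricity
  r <- px[, 1]; cc <- px[, 2]
  mrr <- mean((r - mean(r))^2); mcc <- mean((cc - mean(cc))^2)
  mrc <- mean((r - mean(r)) * (cc - mean(cc)))
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + common) / 2
  l2 <- (mrr + mcc - common) / 2
  ecc <- if (l1 <= 1e-12) 0 else sqrt(max(0, 1 - l2 / l1))
  # solidity via convex hull of pixel centers
  solidity <- if (n < 3) 1 else {
    hull <- grDevices::chull(cc, r)
    if (length(hull) < 3) 1 else {
      hx <- cc[hull]; hy <- r[hull]
      allpx <- which(mask | TRUE, arr.ind = TRUE)  # every pixel of the bbox
      inside <- pracma::inpolygon(allpx[, 2], allpx[, 1], hx, hy,
                                  boundary = TRUE)
      hull_area <- sum(inside)
      if (hull_area == 0) 1 else min(1, area / hull_area)
    }
  }
  c(area = area, perimeter = perim, eccentricity = ecc, solidity = solidity)
}

#' Mean nucleus radius of an image
#'
#' The mean equivalent-disk radius over the image's (post-filter) nuclei:
#' `(1/n) * sum(sqrt(A_k / pi))`, where `A_k` is the pixel area of nucleus
#' `k`. This is the unit in which the crowding radii are expressed.
#'
#' @param areas Positive areas (px) of all nuclei of one image.
#' @return Mean radius in pixels; `NA` for an empty input.
#' @export
mean_radius <- function(areas) {
  if (length(areas) == 0) return(NA_real_)
  if (any(areas <= 0)) abort("areas must be positive")
  mean(sqrt(areas / pi))
}

#' Nuclear crowding counts
#'
#' For every nucleus and every multiplier `x` in {3, 5, 7, 9, 15, 20, 25, 30},
#' the number of other nuclei whose centroid lies within Euclidean distance
#' `x * r_mean` (inclusive). No correction is applied at image borders.
#'
#' @param centroids Two-column matrix or data frame of (row, col) centroids.
#' @param r_mean Mean nucleus radius of the same image (px), from
#'   [mean_radius()].
#' @param multipliers Radius multipliers.
#' @return Tibble with one row per nucleus and one `crowd_x*` column per
#'   multiplier.
#' @export
crowding <- function(centroids, r_mean,
                     multipliers = c(3, 5, 7, 9, 15, 20, 25, 30)) {
  cen <- as.matrix(centroids)
  if (nrow(cen) == 0) abort("need at least one centroid")
  if (!is.numeric(r_mean) || is.na(r_mean) || r_mean <= 0) {
    abort("r_mean must be positive")
  }
  dmat <- as.matrix(dist(cen))
  diag(dmat) <- Inf  # exclude self
  out <- lapply(multipliers, function(x) {
    as.integer(rowSums(dmat <= x * r_mean))
  })
  names(out) <- paste0("crowd_x", multipliers)
  tibble::as_tibble(out)
}

#' Nearest-neighbour centroid distance
#'
#' @param centroids Two-column matrix or data frame of (row, col) centroids.
#' @return Numeric vector: per-nucleus Euclidean distance to the nearest
#'   other nucleus; `NA` when the image holds a single nucleus.
#' @export
nn_distance <- function(centroids) {
  cen <- as.matrix(centroids)
  n <- nrow(cen)
  if (n == 0) return(numeric(0))
  if (n == 1) return(NA_real_)
  dmat <- as.matrix(dist(cen))
  diag(dmat) <- Inf
  unname(apply(dmat, 1, min))
}

#' Extract the 36 per-nucleus features of one image
#'
#' Combines [color_features()], [shape_features()], and the spatial features
#' ([crowding()] with the image's own mean radius, and [nn_distance()]) into
#' one row per nucleus, columns in the canonical order of
#' [nucleus_feature_names()]. Extraction is fully deterministic.
#'
#' @param seg A `segmentation_result` from [extract_nuclei()] (after size
#'   filtering).
#' @param img The source RGB image (only used for validation; crops are
#'   stored in `seg`).
#' @return Tibble: `nucleus_id` + 36 feature columns; zero rows when the
#'   image holds no nuclei.
#' @export
extract_features <- function(seg, img = NULL) {
  if (!inherits(seg, "segmentation_result")) {
    abort("seg must be a segmentation_result")
  }
  if (!is.null(img) && !all(dim(img)[1:2] == dim(seg$label_map))) {
    abort("image and segmentation dimensions differ")
  }
  nuc <- seg$nuclei
  empty <- tibble::as_tibble(
    c(list(nucleus_id = integer(0)),
      setNames(rep(list(numeric(0)), 36), nucleus_feature_names()))
  )
  if (length(nuc) == 0) return(empty)
  cen <- t(vapply(nuc, function(n) n$centroid, numeric(2)))
  areas <- vapply(nuc, function(n) n$area_px, numeric(1))
  r_mean <- mean_radius(areas)
  crowd <- crowding(cen, r_mean)
  nnd <- nn_distance(cen)
  rows <- purrr::map(seq_along(nuc), function(i) {
    n <- nuc[[i]]
    cf <- color_features(n$crop, n$mask)
    sf <- shape_features(n$mask)
    sp <- c(unlist(crowd[i, ]), nn_distance = unname(nnd[i]))
    tibble::as_tibble(as.list(c(nucleus_id = n$nucleus_id, cf, sf, sp)))
  })
  out <- dplyr::bind_rows(rows)
  out$nucleus_id <- as.integer(out$nucleus_id)
  out[, c("nucleus_id", nucleus_feature_names())]
}
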