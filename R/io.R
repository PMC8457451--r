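# Raster and manifest IO, plus resolution harmonization.
#
# Conventions used throughout the package:
#   * RGB images are H x W x 3 numeric arrays with intensities in [0, 255]
#     (8-bit color depth, channel order red, green, blue).
#   * Label maps are H x W integer matrices; 0 is background, positive
#     integers are nucleus instance ids (not necessarily consecutive).
#   * Pixel indices are row-major and 0-based in all reported coordinates
#     (centroids, bounding boxes), so a centroid of (0, 0) is the top-left
#     pixel center. Internally R's 1-based indexing is used and converted at
#     the boundary.

#' Read an RGB histology image
#'
#' Reads an 8-bit RGB TIFF or PNG into an H x W x 3 array of intensities in
#' \[0, 255\].
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return An H x W x 3 numeric array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  raw <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  round(raw * 255)
}

#' Write an RGB histology image
#'
#' @param img H x W x 3 array, intensities in \[0, 255\].
#' @param path Output path; format chosen from the extension (TIFF or PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_rgb_image(img)
  norm <- pmax(pmin(img, 255), 0) / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(norm, path)
  } else {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read an instance label map
#'
#' Reads a 16-bit single-channel TIFF or PNG instance segmentation into an
#' integer matrix. 0 is background; positive labels are nucleus ids and are
#' preserved exactly (no relabeling).
#'
#' @param path Path to the label map.
#' @return H x W integer matrix.
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path)) abort(paste0("label map not found: ", path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3) abort("label map must be single-channel")
    lm <- round(raw * 65535)
  } else {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(raw)) == 3) abort("label map must be single-channel")
    lm <- raw
  }
  storage.mode(lm) <- "integer"
  lm
}

#' Write an instance label map
#'
#' @param lm H x W integer matrix of labels; all labels must fit in 16 bits.
#' @param path Output path (TIFF).
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(lm, path) {
  assert_labelmap(lm)
  if (any(lm > 65535)) abort("labels exceed the 16-bit range")
  tiff::writeTIFF(lm / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Rescale an RGB image by spline interpolation
#'
#' Resamples each channel independently with separable interpolation, the way
#' a 20x acquisition is brought to a 40x working resolution (factor 2, spline
#' order 3). Output dimensions are `round(factor * dim)`; intensities are
#' clipped to \[0, 255\] and rounded back to 8-bit.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param factor Positive scale factor.
#' @param order Interpolation order: 0 (nearest), 1 (linear), or >= 2
#'   (cubic spline).
#' @return Rescaled H' x W' x 3 array.
#' @export
rescale_image <- function(img, factor, order = 3) {
  assert_rgb_image(img)
  if (!is.numeric(factor) || factor <= 0) abort("factor must be positive")
  if (order < 0 || order > 5) abort("order must be in [0, 5]")
  if (factor == 1) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  h2 <- max(1L, as.integer(round(factor * h)))
  w2 <- max(1L, as.integer(round(factor * w)))
  out <- array(0, dim = c(h2, w2, 3))
  # Output pixel centers map back into input coordinates area-consistently.
  src_r <- pmin(pmax((seq_len(h2) - 0.5) * h / h2 + 0.5, 1), h)
  src_c <- pmin(pmax((seq_len(w2) - 0.5) * w / w2 + 0.5, 1), w)
  interp1 <- function(y, xout) {
    n <- length(y)
    if (n == 1) return(rep(y, length(xout)))
    if (order == 0) return(y[pmin(pmax(round(xout), 1), n)])
    if (order == 1) return(approx(seq_len(n), y, xout = xout, rule = 2)$y)
    splinefun(seq_len(n), y, method = "natural")(xout)
  }
  for (ch in 1:3) {
    # along columns first: tmp[j, i] = channel at output col j, original row i
    tmp <- apply(img[, , ch, drop = FALSE][, , 1], 1, interp1, xout = src_c)
    tmp <- matrix(tmp, nrow = w2)
    # then along rows: result is h2 x w2
    out[, , ch] <- matrix(apply(tmp, 1, interp1, xout = src_r), nrow = h2)
  }
  round(pmax(pmin(out, 255), 0))
}

#' Rescale a label map by nearest-neighbour resampling
#'
#' Companion to [rescale_image()] for harmonizing ground-truth instance maps
#' to the working resolution; nearest-neighbour keeps labels integral.
#'
#' @param lm Integer label matrix.
#' @param factor Positive scale factor.
#' @return Rescaled integer label matrix.
#' @export
rescale_labelmap <- function(lm, factor) {
  assert_labelmap(lm)
  if (factor <= 0) abort("factor must be positive")
  if (factor == 1) return(lm)
  h <- nrow(lm); w <- ncol(lm)
  h2 <- max(1L, as.integer(round(factor * h)))
  w2 <- max(1L, as.integer(round(factor * w)))
  ri <- pmin(pmax(round((seq_len(h2) - 0.5) * h / h2 + 0.5), 1), h)
  ci <- pmin(pmax(round((seq_len(w2) - 0.5) * w / w2 + 0.5), 1), w)
  out <- lm[ri, ci, drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

# ---------------------------------------------------------------------------
# Dataset manifest

#' Read a dataset manifest
#'
#' The manifest is a CSV with one row per (patient, image):
#' `patient_id, class_label, image_path, labelmap_path, resolution_um_per_px`.
#' `class_label` is `"PTC"` / `"nonPTC"` (may be empty for unlabeled
#' inference data); `labelmap_path` may be empty when segmentation is to be
#' computed. All referenced files are checked for existence.
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that referenced image/label files exist.
#' @return A tibble of class `nucleo_manifest`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("patient_id", "class_label", "image_path", "labelmap_path",
                "resolution_um_per_px")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("manifest missing columns: ", paste(missing, collapse = ", ")))
  }
  df$resolution_um_per_px <- as.numeric(df$resolution_um_per_px)
  man <- tibble::as_tibble(df[required])
  base <- dirname(path)
  rel <- function(p) ifelse(p == "" | is.na(p) | grepl("^/", p), p, file.path(base, p))
  man$image_path <- rel(man$image_path)
  man$labelmap_path <- rel(man$labelmap_path)
  validate_manifest(man, check_files = check_files)
}

#' Validate a dataset manifest tibble
#'
#' @param man Tibble with the manifest columns (see [read_manifest()]).
#' @param check_files Verify referenced files exist.
#' @return The validated manifest with class `nucleo_manifest`.
#' @export
validate_manifest <- function(man, check_files = FALSE) {
  man <- tibble::as_tibble(man)
  if (nrow(man) == 0) abort("manifest is empty")
  if (any(is.na(man$resolution_um_per_px) | man$resolution_um_per_px <= 0)) {
    abort("resolution_um_per_px must be a positive real")
  }
  bad <- man$class_label[!man$class_label %in% c("PTC", "nonPTC", "", NA)]
  if (length(bad) > 0) {
    abort(paste0("unknown class label(s): ", paste(unique(bad), collapse = ", ")))
  }
  # one label per patient
  lab <- unique(man[, c("patient_id", "class_label")])
  if (anyDuplicated(lab$patient_id) > 0) {
    abort("a patient_id maps to more than one class_label")
  }
  if (anyDuplicated(man$image_path[man$image_path != ""]) > 0) {
    abort("duplicate image_path entries in manifest")
  }
  has_lm <- man$labelmap_path != "" & !is.na(man$labelmap_path)
  per_pat <- tapply(has_lm, man$patient_id, function(z) length(unique(z)))
  if (any(per_pat > 1)) {
    abort("each patient must have label maps for all images or for none")
  }
  if (check_files) {
    for (p in man$image_path) {
      if (!file.exists(p)) abort(paste0("manifest references missing image: ", p))
    }
    for (p in man$labelmap_path[has_lm]) {
      if (!file.exists(p)) abort(paste0("manifest references missing label map: ", p))
    }
  }
  class(man) <- c("nucleo_manifest", class(man))
  man
}

#' Write a dataset manifest
#'
#' @param man Manifest tibble.
#' @param path Output CSV path. Paths are written as given.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(man, path) {
  df <- as.data.frame(man)[, c("patient_id", "class_label", "image_path",
                               "labelmap_path", "resolution_um_per_px")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Harmonize a manifest's images to the working resolution
#'
#' Feature extraction must run at the resolution the segmentation operates at
#' (default 0.23 um/px, a 40x acquisition). Images declared at a coarser or
#' finer resolution are rescaled by the ratio with cubic-spline interpolation
#' (label maps by nearest neighbour) and written next to `out_dir`; the
#' returned manifest points at the harmonized copies.
#'
#' @param man Manifest tibble.
#' @param out_dir Directory for rescaled rasters.
#' @param working_res_um_per_px Target resolution (um per pixel).
#' @param tol Relative resolution mismatch tolerated without resampling.
#' @return Manifest tibble at the working resolution.
#' @export
harmonize_resolution <- function(man, out_dir,
                                 working_res_um_per_px = 0.23, tol = 0.01) {
  man <- validate_manifest(man)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- man
  for (i in seq_len(nrow(man))) {
    res <- man$resolution_um_per_px[i]
    factor <- res / working_res_um_per_px
    if (abs(factor - 1) <= tol) next
    img <- read_image(man$image_path[i])
    dst <- file.path(out_dir, basename(man$image_path[i]))
    write_image(rescale_image(img, factor, order = 3), dst)
    out$image_path[i] <- dst
    if (!is.na(man$labelmap_path[i]) && man$labelmap_path[i] != "") {
      lm <- read_labelmap(man$labelmap_path[i])
      dstl <- file.path(out_dir, basename(man$labelmap_path[i]))
      write_labelmap(rescale_labelmap(lm, factor), dstl)
      out$labelmap_path[i] <- dstl
    }
    out$resolution_um_per_px[i] <- working_res_um_per_px
  }
  out
}

# ---------------------------------------------------------------------------
# Feature and vote tables

#' Write a feature table to CSV
#'
#' Identifier columns come first, then features in the canonical order (the
#' per-nucleus 36 or the per-patient 72); non-finite values are written as the
#' literal `NA` token. Column order is deterministic so repeated writes are
#' byte-identical.
#'
#' @param rows Tibble of features keyed by patient/image/nucleus ids.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (anyDuplicated(names(rows)) > 0) abort("feature table column names must be unique")
  ids <- intersect(c("patient_id", "image_id", "nucleus_id", "class_label",
                     "n_nuclei"), names(rows))
  feats <- c(intersect(nucleus_feature_names(), names(rows)),
             intersect(patient_feature_names(), names(rows)))
  other <- setdiff(names(rows), c(ids, feats))
  df <- as.data.frame(rows[, c(ids, feats, other)])
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]][!is.finite(df[[j]])] <- NA
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(paste0("feature table not found: ", path))
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a pathologist vote table
#'
#' CSV columns: `case_id, votes_non_ptc, votes_ptc, rereviewed,
#' rereview_ptc_count` (the last may be empty for cases not re-reviewed).
#'
#' @param path CSV path.
#' @return A tibble with one row per case.
#' @export
read_votes <- function(path) {
  if (!file.exists(path)) abort(paste0("vote table not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "votes_non_ptc", "votes_ptc", "rereviewed")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("vote table missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!"rereview_ptc_count" %in% names(df)) df$rereview_ptc_count <- NA_integer_
  df$rereviewed <- as.logical(df$rereviewed)
  validate_votes(tibble::as_tibble(df[c(need, "rereview_ptc_count")]))
}

validate_votes <- function(votes) {
  if (any(votes$votes_non_ptc < 0 | votes$votes_ptc < 0)) {
    abort("vote counts must be non-negative")
  }
  if (any(votes$votes_non_ptc + votes$votes_ptc == 0)) {
    abort("each case needs at least one vote")
  }
  if (any(votes$rereviewed & is.na(votes$rereview_ptc_count))) {
    abort("re-reviewed cases need rereview_ptc_count")
  }
  votes
}

#' Write a pathologist vote table
#'
#' @param votes Vote tibble (see [read_votes()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_votes <- function(votes, path) {
  utils::write.csv(as.data.frame(votes), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
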