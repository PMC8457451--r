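# Nucleus instance masks: a classical baseline segmenter for synthetic
# fixtures, the per-image median-area post-processing filter, and extraction
# of per-nucleus records (crop + mask + geometry).

# distmap that treats the raster edge as background (EBImage::distmap does
# not: an all-foreground image would be all-Inf). Pads with a zero ring.
padded_distmap <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  d <- EBImage::distmap(pad)
  matrix(as.numeric(d), h + 2, w + 2)[2:(h + 1), 2:(w + 1)]
}

#' Baseline nucleus segmenter for synthetic fixtures
#'
#' Deterministic classical pipeline: luminance grayscale, global Otsu
#' threshold (nuclei are the dark hematoxylin phase), hole filling, removal
#' of sub-`min_area` specks, Euclidean distance transform and marker-based
#' watershed to split touching nuclei. It is a stand-in input source for the
#' feature stage, adequate for the bundled synthetic H&E-like images; it is
#' not claimed adequate for real histology.
#'
#' @param img H x W x 3 RGB array in \[0, 255\].
#' @param min_area Instances smaller than this many pixels are discarded as
#'   noise specks before the median-area filter runs.
#' @param watershed_tolerance Minimum object height in the distance map for
#'   the watershed to keep two maxima apart (px).
#' @return H x W integer label matrix (0 = background).
#' @export
segment_baseline <- function(img, min_area = 15, watershed_tolerance = 1) {
  assert_rgb_image(img)
  gray <- to_grayscale(img) / 255
  thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  mask <- gray < thr   # nuclei darker than eosin background
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dmap <- padded_distmap(matrix(as.numeric(mask), nrow(img), ncol(img)))
  ws <- EBImage::watershed(EBImage::Image(dmap), tolerance = watershed_tolerance)
  lm <- matrix(as.integer(EBImage::imageData(ws)), nrow(img), ncol(img))
  areas <- label_areas(lm)
  drop <- as.integer(names(areas)[areas < min_area])
  if (length(drop) > 0) lm[lm %in% drop] <- 0L
  lm
}

#' Remove merged and truncated nuclei by the per-image median-area rule
#'
#' Computes the median instance area once over all pre-filter instances of
#' the image, then removes every instance strictly larger than 200% of that
#' median (merged nuclei) or strictly smaller than 50% of it (nuclei
#' insufficiently represented in the image plane). Instances exactly at the
#' 50%/200% bounds survive. Surviving labels are left unchanged.
#'
#' @param lm Integer label matrix.
#' @param drop_border Also remove instances touching the image frame
#'   (off by default; the size rule is the canonical mechanism).
#' @return Filtered label matrix with the original surviving labels.
#' @export
filter_by_size <- function(lm, drop_border = FALSE) {
  assert_labelmap(lm)
  areas <- label_areas(lm)
  if (length(areas) == 0) return(lm)
  m <- median(as.numeric(areas))  # single pre-filter median for this image
  drop <- names(areas)[areas > 2 * m | areas < 0.5 * m]
  if (drop_border) {
    edge <- unique(c(lm[1, ], lm[nrow(lm), ], lm[, 1], lm[, ncol(lm)]))
    drop <- union(drop, as.character(edge[edge > 0]))
  }
  if (length(drop) > 0) lm[lm %in% as.integer(drop)] <- 0L
  lm
}

#' Extract per-nucleus records from an image and its label map
#'
#' One record per positive label: pixel-count area, real-valued centroid
#' (0-based row/col), bounding box, the instance's binary mask restricted to
#' the box, and the RGB crop of the box.
#'
#' @param img H x W x 3 RGB array.
#' @param lm Label matrix of the same height/width (typically the output of
#'   [filter_by_size()]).
#' @return A list of class `segmentation_result` with elements `label_map`,
#'   `nuclei` (list of records), and `median_area_px` (median of this map's
#'   instance areas).
#' @export
extract_nuclei <- function(img, lm) {
  assert_rgb_image(img)
  assert_labelmap(lm)
  if (!all(dim(img)[1:2] == dim(lm))) {
    abort("image and label map dimensions differ")
  }
  labs <- sort(unique(lm[lm > 0]))
  nuclei <- vector("list", length(labs))
  keep <- logical(length(labs))
  for (i in seq_along(labs)) {
    id <- labs[i]
    px <- which(lm == id, arr.ind = TRUE)
    if (nrow(px) == 0) {
      warn(paste0("label ", id, " has zero pixels; skipped"))
      next
    }
    keep[i] <- TRUE
    rmin <- min(px[, 1]); rmax <- max(px[, 1])
    cmin <- min(px[, 2]); cmax <- max(px[, 2])
    mask <- lm[rmin:rmax, cmin:cmax, drop = FALSE] == id
    nuclei[[i]] <- list(
      nucleus_id = as.integer(id),
      area_px = nrow(px),
      centroid = c(row = mean(px[, 1]) - 1, col = mean(px[, 2]) - 1),
      bbox = c(row_min = rmin - 1L, col_min = cmin - 1L,
               row_max = rmax - 1L, col_max = cmax - 1L),
      mask = mask,
      crop = img[rmin:rmax, cmin:cmax, , drop = FALSE]
    )
  }
  nuclei <- nuclei[keep]
  areas <- vapply(nuclei, function(n) n$area_px, numeric(1))
  structure(
    list(label_map = lm, nuclei = nuclei,
         median_area_px = if (length(areas)) median(areas) else NA_real_),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> ", length(x$nuclei), " nuclei, median area ",
      format(x$median_area_px), " px\n", sep = "")
  invisible(x)
}

#' Per-nucleus geometry summary of a segmentation
#'
#' @param seg A `segmentation_result`.
#' @return Tibble with `nucleus_id`, `area_px`, `centroid_row`, `centroid_col`.
#' @export
nucleus_summary <- function(seg) {
  tibble::tibble(
    nucleus_id = vapply(seg$nuclei, function(n) n$nucleus_id, integer(1)),
    area_px = vapply(seg$nuclei, function(n) n$area_px, numeric(1)),
    centroid_row = vapply(seg$nuclei, function(n) n$centroid[["row"]], numeric(1)),
    centroid_col = vapply(seg$nuclei, function(n) n$centroid[["col"]], numeric(1))
  )
}
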