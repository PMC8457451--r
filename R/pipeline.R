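# End-to-end orchestration: simulate (optional) -> segment -> size filter ->
# per-nucleus features -> patient aggregation -> nested CV, mirroring the
# three-stage feature-based pipeline.

#' Extract per-nucleus features for a whole dataset
#'
#' Runs segmentation (or takes ground-truth/precomputed label maps), the
#' median-area size filter, and feature extraction for every image of a
#' dataset, either an in-memory `synthetic_dataset` or a manifest whose
#' paths are read from disk.
#'
#' @param data A `synthetic_dataset` or a `nucleo_manifest` tibble.
#' @param segmenter `"precomputed"` uses the supplied label maps;
#'   `"baseline"` runs [segment_baseline()] on each image.
#' @param size_filter Apply [filter_by_size()] before feature extraction.
#' @return Tibble of per-nucleus rows: `patient_id`, `image_id`,
#'   `nucleus_id`, and the 36 features.
#' @export
extract_dataset_features <- function(data,
                                     segmenter = c("precomputed", "baseline"),
                                     size_filter = TRUE) {
  segmenter <- match.arg(segmenter)
  if (inherits(data, "synthetic_dataset")) {
    man <- data$manifest
    get_img <- function(i) data$images[[man$image_id[i]]]
    get_lm <- function(i) data$labelmaps[[man$image_id[i]]]
    image_ids <- man$image_id
  } else {
    man <- validate_manifest(data)
    get_img <- function(i) read_image(man$image_path[i])
    get_lm <- function(i) {
      if (man$labelmap_path[i] == "" || is.na(man$labelmap_path[i])) {
        abort("manifest lacks label maps; use segmenter = 'baseline'")
      }
      read_labelmap(man$labelmap_path[i])
    }
    image_ids <- if ("image_id" %in% names(man)) man$image_id else {
      tools::file_path_sans_ext(basename(man$image_path))
    }
  }
  rows <- lapply(seq_len(nrow(man)), function(i) {
    img <- get_img(i)
    lm <- if (segmenter == "baseline") segment_baseline(img) else get_lm(i)
    if (size_filter) lm <- filter_by_size(lm)
    seg <- extract_nuclei(img, lm)
    ft <- extract_features(seg)
    if (nrow(ft) == 0) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(patient_id = man$patient_id[i], image_id = image_ids[i]),
      ft
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the full study pipeline on a synthetic dataset
#'
#' Generates a dataset from `gen_cfg`, extracts and aggregates features, and
#' runs stratified nested cross-validation under `model_cfg`. The single
#' `seed` argument (when given) overrides both configs' seeds so one number
#' reproduces the whole run.
#'
#' @param gen_cfg A [generator_config()].
#' @param model_cfg A [pipeline_config()].
#' @param segmenter `"precomputed"` (ground-truth masks) or `"baseline"`.
#' @param seed Optional seed overriding both configs.
#' @return List of class `nucleo_study`: `dataset`, `nuclei` (per-nucleus
#'   tibble), `patients` (72-feature tibble), `cv` (a `nucleo_cv`), `votes`.
#' @export
run_study <- function(gen_cfg = generator_config(),
                      model_cfg = pipeline_config(),
                      segmenter = c("precomputed", "baseline"),
                      seed = NULL) {
  segmenter <- match.arg(segmenter)
  if (!is.null(seed)) {
    gen_cfg$seed <- as.integer(seed)
    model_cfg$seed <- as.integer(seed)
  }
  ds <- generate_dataset(gen_cfg)
  nuclei <- extract_dataset_features(ds, segmenter = segmenter)
  patients <- aggregate_patients(nuclei, ds$manifest)
  cv <- nested_cv(patients, model_cfg)
  structure(list(dataset = ds, nuclei = nuclei, patients = patients,
                 cv = cv, votes = ds$votes),
            class = "nucleo_study")
}

#' @export
print.nucleo_study <- function(x, ...) {
  cat("<nucleo_study> ", nrow(x$patients), " patients, ",
      nrow(x$nuclei), " nuclei\n", sep = "")
  print(x$cv)
  invisible(x)
}
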