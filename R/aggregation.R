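# Patient-level aggregation: nuclei are pooled across all images of a
# patient (never averaged per image first), then each of the 36 features is
# summarized by its mean and population standard deviation, giving 72
# features per patient.

#' Canonical per-patient feature names
#'
#' `mean_<f>` and `std_<f>` for each of the 36 per-nucleus features, in the
#' canonical nucleus-feature order (72 names).
#'
#' @return Character vector of length 72.
#' @export
patient_feature_names <- function() {
  as.vector(rbind(paste0("mean_", nucleus_feature_names()),
                  paste0("std_", nucleus_feature_names())))
}

#' Aggregate per-nucleus features to one row per patient
#'
#' Pools the nuclei of all images of a patient into one sample and summarizes
#' each feature by its mean and population standard deviation (divide by n,
#' so a single-nucleus patient gets std 0). `NA` feature values (e.g.
#' `nn_distance` on a single-nucleus image) are excluded from that feature's
#' aggregate; when every value is `NA` the aggregate is `NA` and a warning is
#' raised. Patients with zero nuclei are dropped with a warning.
#'
#' @param per_nucleus Tibble of per-nucleus features carrying a `patient_id`
#'   column (and optionally `image_id`).
#' @param manifest Optional manifest used to attach `class_label` and to
#'   verify that every nucleus belongs to a known patient.
#' @return Tibble: `patient_id`, `class_label` (if available), `n_nuclei`,
#'   then the 72 feature columns of [patient_feature_names()].
#' @export
aggregate_patients <- function(per_nucleus, manifest = NULL) {
  if (!"patient_id" %in% names(per_nucleus)) {
    abort("per_nucleus must carry a patient_id column")
  }
  feats <- nucleus_feature_names()
  missing <- setdiff(feats, names(per_nucleus))
  if (length(missing) > 0) {
    abort(paste0("missing feature columns: ", paste(missing, collapse = ", ")))
  }
  if (!is.null(manifest)) {
    unknown <- setdiff(unique(per_nucleus$patient_id), manifest$patient_id)
    if (length(unknown) > 0) {
      abort(paste0("nuclei reference patients absent from the manifest: ",
                   paste(unknown, collapse = ", ")))
    }
    empty <- setdiff(manifest$patient_id, unique(per_nucleus$patient_id))
    if (length(empty) > 0) {
      warn(paste0("patient(s) with zero nuclei dropped: ",
                  paste(empty, collapse = ", ")))
    }
  }
  agg_one <- function(x) {
    m <- mean(x, na.rm = TRUE)
    s <- pop_sd(x)
    if (all(is.na(x))) { m <- NA_real_; s <- NA_real_ }
    c(m, s)
  }
  out <- per_nucleus |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      vals <- unlist(lapply(feats, function(f) agg_one(df[[f]])))
      names(vals) <- as.vector(rbind(paste0("mean_", feats), paste0("std_", feats)))
      tibble::as_tibble(c(list(n_nuclei = nrow(df)), as.list(vals)))
    }) |>
    dplyr::ungroup()
  if (any(is.na(out[patient_feature_names()]))) {
    warn("some aggregated features are NA (all-NA nucleus values)")
  }
  if (!is.null(manifest)) {
    lab <- unique(tibble::as_tibble(manifest)[, c("patient_id", "class_label")])
    out <- dplyr::left_join(out, lab, by = "patient_id")
  }
  front <- intersect(c("patient_id", "class_label", "n_nuclei"), names(out))
  out[, c(front, patient_feature_names())]
}
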