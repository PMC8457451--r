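# Expert-panel analysis: the per-case mean pathologist rating, consensus
# label derivation with re-review thresholds and tie exclusion, and the
# agreement-threshold evaluation curves.

#' Mean expert pathologist rating of a case
#'
#' For a case graded by a panel, the rating is the majority fraction
#' `max(c_n, c_p) / (c_n + c_p)`, where `c_n` and `c_p` count the
#' pathologists grading the case non-PTC-like and PTC-like. It lies in
#' \[0.5, 1\]: 1 for unanimity, 0.5 for an exact split, and it is invariant
#' to swapping the two counts.
#'
#' @param votes_non_ptc,votes_ptc Non-negative vote counts (vectorized).
#' @return Numeric rating(s) in \[0.5, 1\]; `NA` when a case has no votes.
#' @export
expert_rating <- function(votes_non_ptc, votes_ptc) {
  total <- votes_non_ptc + votes_ptc
  out <- pmax(votes_non_ptc, votes_ptc) / total
  out[total == 0] <- NA_real_
  out
}

#' Derive consensus class labels from a pathologist vote table
#'
#' Cases that went through a re-review (where a nuclear score of 2-3 defines
#' PTC-like) are labeled by the re-review count: fewer than 13 of the raters
#' calling it PTC-like gives `nonPTC`, more than 15 gives `PTC`, and the
#' gray zone 13-15 is excluded. All other cases get the majority vote of the
#' panel; exact ties are excluded.
#'
#' @param votes Vote tibble (see [read_votes()]): `case_id`,
#'   `votes_non_ptc`, `votes_ptc`, `rereviewed`, `rereview_ptc_count`.
#' @return Tibble: `case_id`, `label` (`"PTC"`, `"nonPTC"`, `"excluded"`),
#'   and the rating `c_i` (`NA` for excluded ties).
#' @export
derive_labels <- function(votes) {
  votes <- validate_votes(tibble::as_tibble(votes))
  ci <- expert_rating(votes$votes_non_ptc, votes$votes_ptc)
  label <- character(nrow(votes))
  for (i in seq_len(nrow(votes))) {
    if (isTRUE(votes$rereviewed[i])) {
      rp <- votes$rereview_ptc_count[i]
      label[i] <- if (rp < 13) "nonPTC" else if (rp > 15) "PTC" else "excluded"
    } else if (votes$votes_ptc[i] > votes$votes_non_ptc[i]) {
      label[i] <- "PTC"
    } else if (votes$votes_ptc[i] < votes$votes_non_ptc[i]) {
      label[i] <- "nonPTC"
    } else {
      label[i] <- "excluded"
    }
  }
  ci[label == "excluded" & votes$votes_ptc == votes$votes_non_ptc] <- NA_real_
  tibble::tibble(case_id = votes$case_id, label = label, c_i = ci)
}

#' Mean expert rating over included cases
#'
#' @param cases Tibble with a `c_i` column (e.g. from [derive_labels()]);
#'   excluded cases (label `"excluded"`) are ignored if a `label` column is
#'   present.
#' @return Arithmetic mean of `c_i`; `NA` for an empty input.
#' @export
mean_expert_rating <- function(cases) {
  if ("label" %in% names(cases)) cases <- cases[cases$label != "excluded", ]
  ci <- cases$c_i[!is.na(cases$c_i)]
  if (length(ci) == 0) return(NA_real_)
  mean(ci)
}

#' Evaluation restricted to cases above an agreement threshold
#'
#' For each threshold `t` (the minimal pathologist agreement level), takes
#' the subset of cases with `c_i >= t` and reports the subset size, the
#' per-class composition, the mean rating, the classifier accuracy on the
#' subset (when predictions are supplied), and the distribution accuracy --
#' the accuracy achievable by always predicting the subset's majority class.
#'
#' @param cases Tibble with `case_id`, `label` (`PTC`/`nonPTC`), `c_i`.
#'   Excluded cases must already be removed.
#' @param predictions Optional tibble `case_id`, `predicted` aligned by
#'   `case_id`.
#' @param thresholds Numeric thresholds on `c_i` (inclusive comparison).
#' @return Tibble with one row per threshold: `threshold`, `n`, `n_ptc`,
#'   `n_non_ptc`, `ptc_fraction`, `mean_c_i`, `distribution_accuracy`, and
#'   `accuracy` when predictions were given. Empty subsets give `n = 0` and
#'   `NA` metrics.
#' @export
threshold_evaluation <- function(cases, predictions = NULL,
                                 thresholds = seq(0.5, 1, by = 0.02)) {
  cases <- tibble::as_tibble(cases)
  if ("label" %in% names(cases) && any(cases$label == "excluded")) {
    abort("remove excluded cases before threshold evaluation")
  }
  if (any(is.na(cases$c_i))) abort("every case needs a defined c_i")
  if (!is.null(predictions)) {
    predictions <- tibble::as_tibble(predictions)
    missing <- setdiff(cases$case_id, predictions$case_id)
    if (length(missing) > 0) {
      abort(paste0("no prediction for case(s): ", paste(missing, collapse = ", ")))
    }
    cases <- dplyr::left_join(cases,
                              predictions[, c("case_id", "predicted")],
                              by = "case_id")
  }
  rows <- lapply(thresholds, function(t) {
    sub <- cases[cases$c_i >= t, ]
    n <- nrow(sub)
    if (n == 0) {
      return(tibble::tibble(threshold = t, n = 0L, n_ptc = 0L, n_non_ptc = 0L,
                            ptc_fraction = NA_real_, mean_c_i = NA_real_,
                            distribution_accuracy = NA_real_,
                            accuracy = NA_real_))
    }
    n_ptc <- sum(sub$label == "PTC")
    n_non <- sum(sub$label == "nonPTC")
    acc <- if ("predicted" %in% names(sub)) {
      mean(sub$predicted == sub$label)
    } else NA_real_
    tibble::tibble(
      threshold = t, n = as.integer(n), n_ptc = as.integer(n_ptc),
      n_non_ptc = as.integer(n_non),
      ptc_fraction = n_ptc / n,
      mean_c_i = mean(sub$c_i),
      distribution_accuracy = max(n_ptc, n_non) / n,
      accuracy = acc
    )
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(predictions)) out$accuracy <- NULL
  out
}
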