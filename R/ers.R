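## Encoding-retrieval similarity (ERS).
##
## Pearson correlations between each retrieval trial's voxel pattern and the
## encoding patterns of the full ROI (no feature selection), Fisher
## transformed before any averaging. Three cells per retrieval trial:
## within-event (the trial's own encoding pattern), within-category (other
## same-category events, the same-event pair removed), and between-category.
## Comparison events are matched on associative retrieval success: hits are
## compared against events that went on to be hits, non-hits against events
## that went on to be non-hits.

.SUCCESS_STATES <- c(associative_hit = "success", associative_miss = "failure",
                     item_hit = "failure", item_miss = "failure")

#' Compute encoding-retrieval similarity records
#'
#' @param encoding,retrieval full-ROI [PatternMatrix-class] objects for one
#'   participant.
#' @param trials that participant's classified trial `data.frame`; encoding
#'   and retrieval rows are linked by `word`.
#' @param scale apply [scaleWithinRun()] to both phases before correlating
#'   (mirrors the classifier preprocessing; set `FALSE` for raw patterns).
#' @param exclude_same_run drop same-run pairs from the within/between
#'   category cells (guards against run-level similarity inflation; off by
#'   default).
#' @return `data.frame` with one row per studied retrieval trial carrying a
#'   success state: trial_id, condition, category, within_event_z,
#'   within_category_z, between_category_z, roi_mean_activity (mean pattern
#'   value over all voxels, a univariate nuisance covariate). Cells with no
#'   eligible comparison trials are `NA` (logged).
#' @export
computeERS <- function(encoding, retrieval, trials, scale = TRUE,
                       exclude_same_run = FALSE) {
  if (scale) {
    encoding <- scaleWithinRun(encoding)
    retrieval <- scaleWithinRun(retrieval)
  }
  enc <- patternValues(encoding)
  ret <- patternValues(retrieval)
  enc_tr <- trials[match(trialIds(encoding), trials$trial_id), , drop = FALSE]
  ret_tr <- trials[match(trialIds(retrieval), trials$trial_id), , drop = FALSE]
  if (anyNA(enc_tr$trial_id) || anyNA(ret_tr$trial_id))
    stop("pattern trial ids missing from the trial table")
  # retrieval outcome state of each encoding event, linked by word
  ret_state <- .SUCCESS_STATES[ret_tr$condition]
  enc_state <- ret_state[match(enc_tr$word, ret_tr$word)]

  probe <- which(!ret_tr$is_foil & !is.na(ret_state))
  if (!length(probe)) stop("no studied retrieval trials with a success state")
  cormat <- cor(t(ret[probe, , drop = FALSE]), t(enc))
  z <- atanh(pmin(pmax(cormat, -(1 - 1e-7)), 1 - 1e-7))

  n_missing <- 0L
  out <- lapply(seq_along(probe), function(ii) {
    t_ret <- probe[ii]
    own <- match(ret_tr$word[t_ret], enc_tr$word)
    state <- ret_state[t_ret]
    not_own <- if (is.na(own)) rep(TRUE, nrow(enc))
      else seq_len(nrow(enc)) != own
    eligible <- !is.na(enc_state) & enc_state == state & not_own
    if (exclude_same_run) eligible <- eligible & enc_tr$run != ret_tr$run[t_ret]
    same_cat <- eligible & enc_tr$category == ret_tr$category[t_ret]
    other_cat <- eligible & enc_tr$category != ret_tr$category[t_ret] &
      enc_tr$category %in% c("face", "place")
    wc <- if (any(same_cat)) mean(z[ii, same_cat]) else NA_real_
    bc <- if (any(other_cat)) mean(z[ii, other_cat]) else NA_real_
    if (is.na(wc) || is.na(bc)) n_missing <<- n_missing + 1L
    data.frame(trial_id = ret_tr$trial_id[t_ret],
               condition = ret_tr$condition[t_ret],
               category = ret_tr$category[t_ret],
               within_event_z = if (is.na(own)) NA_real_ else z[ii, own],
               within_category_z = wc, between_category_z = bc,
               roi_mean_activity = mean(ret[t_ret, ]),
               stringsAsFactors = FALSE)
  })
  if (n_missing > 0)
    message(n_missing, " ERS record(s) with an empty comparison cell")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Event-level reinstatement contrast
#'
#' Within-event minus within-category Fisher-z similarity: positive values
#' indicate reinstatement of trial-unique event detail over and above shared
#' category structure.
#'
#' @param ers an ERS record `data.frame` from [computeERS()].
#' @return numeric vector (NA where a component is missing).
#' @export
eventLevelContrast <- function(ers) {
  ers$within_event_z - ers$within_category_z
}

#' Category-level reinstatement contrast
#'
#' Within-category minus between-category Fisher-z similarity: positive
#' values indicate reinstatement of categorical (face vs place) structure.
#'
#' @inheritParams eventLevelContrast
#' @return numeric vector (NA where a component is missing).
#' @export
categoryLevelContrast <- function(ers) {
  ers$within_category_z - ers$between_category_z
}
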