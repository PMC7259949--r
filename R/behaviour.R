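## Behavioural scoring: the six-condition memory taxonomy, signal-detection
## d' indices, post-test exemplar scoring, and the delayed-recall composite.

#' Map a retrieval response onto the memory-condition taxonomy
#'
#' Deterministic, exhaustive and mutually exclusive mapping from
#' `(is_foil, category, response)` to the six memory conditions (plus
#' `unclassified` for absent responses):
#' studied + correct category = associative hit; studied + wrong category =
#' associative miss; studied + "Old" = item hit; studied + "New" = item miss;
#' foil + "New" = correct rejection; foil + "Old" = item false alarm;
#' foil + "Face"/"Place" = associative false alarm.
#'
#' @param is_foil logical; was the probe word unstudied?
#' @param category studied associate category (`"face"`, `"place"`; `"none"`
#'   for foils).
#' @param response the four-way memory response (`"Face"`, `"Place"`,
#'   `"Old"`, `"New"`; `"none"` if absent).
#' @return character vector of condition labels.
#' @export
conditionFromResponse <- function(is_foil, category, response) {
  n <- max(length(is_foil), length(category), length(response))
  is_foil <- rep_len(as.logical(is_foil), n)
  category <- rep_len(as.character(category), n)
  response <- rep_len(as.character(response), n)
  out <- rep("unclassified", n)
  assoc <- response %in% c("Face", "Place")
  correct <- (response == "Face" & category == "face") |
             (response == "Place" & category == "place")
  out[!is_foil & assoc & correct] <- "associative_hit"
  out[!is_foil & assoc & !correct] <- "associative_miss"
  out[!is_foil & response == "Old"] <- "item_hit"
  out[!is_foil & response == "New"] <- "item_miss"
  out[is_foil & response == "New"] <- "correct_rejection"
  out[is_foil & response == "Old"] <- "item_false_alarm"
  out[is_foil & assoc] <- "associative_false_alarm"
  out
}

#' Classify the retrieval trials of a trial table
#'
#' Fills the `condition` column for retrieval rows; encoding rows keep
#' `unclassified` (they carry no memory response).
#'
#' @param trials trial `data.frame` from [readTrialTable()] or
#'   [generateStudy()].
#' @return `trials` with `condition` populated.
#' @export
classifyResponses <- function(trials) {
  ret <- trials$phase == "retrieval"
  if (!any(ret)) stop("no retrieval-phase trials to classify")
  trials$condition[ret] <- conditionFromResponse(
    trials$is_foil[ret], trials$category[ret], trials$response[ret])
  trials
}

#' Signal-detection discriminability (d')
#'
#' \eqn{d' = \Phi^{-1}(\mathrm{hit\ rate}) - \Phi^{-1}(\mathrm{FA\ rate})}.
#' Perfect rates are undefined under the inverse normal CDF; the default
#' boundary rule replaces a rate of 0 with \eqn{1/(2N)} and 1 with
#' \eqn{1 - 1/(2N)} (N = that rate's trial count) before the transform.
#'
#' @param hit_count,hit_n hits and number of target trials.
#' @param fa_count,fa_n false alarms and number of foil trials.
#' @param boundary_rule `"half_count"` (the 1/(2N) correction) or `"none"`
#'   (raw rates; infinite at the boundary).
#' @return d' (numeric scalar).
#' @examples
#' computeDprime(96, 120, 6, 30)          # rates 0.8 vs 0.2 -> 1.6832
#' computeDprime(120, 120, 0, 30)         # perfect scores -> ~4.77
#' @export
computeDprime <- function(hit_count, hit_n, fa_count, fa_n,
                          boundary_rule = c("half_count", "none")) {
  boundary_rule <- match.arg(boundary_rule)
  if (hit_n <= 0 || fa_n <= 0) stop("trial counts must be positive")
  if (hit_count > hit_n || fa_count > fa_n)
    stop("counts cannot exceed their denominators")
  hr <- hit_count / hit_n
  far <- fa_count / fa_n
  if (boundary_rule == "half_count") {
    hr <- min(max(hr, 1 / (2 * hit_n)), 1 - 1 / (2 * hit_n))
    far <- min(max(far, 1 / (2 * fa_n)), 1 - 1 / (2 * fa_n))
  }
  qnorm(hr) - qnorm(far)
}

.normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- iconv(x, to = "ASCII//TRANSLIT", sub = "")
  x <- gsub("[[:punct:]]", " ", x)
  gsub("\\s+", " ", trimws(x))
}

#' Score post-test exemplar recall responses
#'
#' A typed response counts as correct when, after normalization (lowercase,
#' punctuation/diacritics stripped, whitespace collapsed), it contains the
#' full normalized target name as a substring. Non-matching non-empty
#' responses are routed to a review file for human rating, which is outside
#' this package.
#'
#' @param response_text typed recall responses.
#' @param target_name names of the studied images.
#' @param review_file optional path; non-matching, non-empty responses are
#'   appended there (TSV: response, target).
#' @return logical vector of exact-match correctness.
#' @export
scorePosttest <- function(response_text, target_name, review_file = NULL) {
  if (any(is.na(target_name) | !nzchar(target_name)))
    stop("target names must be non-empty")
  resp <- .normalize_text(response_text)
  resp[is.na(response_text)] <- ""
  targ <- .normalize_text(target_name)
  ok <- mapply(function(r, t) nzchar(r) && grepl(t, r, fixed = TRUE),
               resp, targ, USE.NAMES = FALSE)
  needs_review <- !ok & nzchar(resp)
  if (!is.null(review_file) && any(needs_review)) {
    write.table(
      data.frame(response = response_text[needs_review],
                 target = target_name[needs_review]),
      review_file, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = !file.exists(review_file), append = file.exists(review_file))
  }
  attr(ok, "needs_review") <- which(needs_review)
  ok
}

#' Delayed-recall composite score
#'
#' Mean of the three delayed-recall subtest z-scores (Logical Memory, HVLT-R,
#' BVMT-R); z-scoring across the sample is done upstream. Any missing subtest
#' yields a missing composite with a warning.
#'
#' @param lm_z,hvlt_z,bvmt_z subtest z-scores (vectors recycle together).
#' @return numeric composite z-score(s).
#' @export
delayedRecallComposite <- function(lm_z, hvlt_z, bvmt_z) {
  m <- cbind(lm_z, hvlt_z, bvmt_z)
  out <- rowMeans(m)
  if (anyNA(out)) warning(sum(is.na(out)), " composite(s) missing a subtest")
  unname(out)
}

#' Per-participant behavioural summary
#'
#' Computes, for each participant, old/new d' (any "old" response -- Face,
#' Place or Old -- to studied words vs the same responses to foils),
#' associative d' (correct-category responses to studied words vs any
#' Face/Place response to foils), and post-scan exemplar-specific recall
#' (post-test correct / studied words). Behavioural rates use all retrieval
#' trials by default; set `exclude_artifacts = TRUE` to restrict to
#' artifact-free trials.
#'
#' @param trials classified trial `data.frame` (see [classifyResponses()]).
#' @param exclude_artifacts drop artifact-flagged trials from the rates?
#' @return `data.frame` with one row per participant: d' measures, exemplar
#'   recall, and the underlying counts.
#' @export
summarizeBehaviour <- function(trials, exclude_artifacts = FALSE) {
  ret <- trials[trials$phase == "retrieval", , drop = FALSE]
  if (exclude_artifacts) ret <- ret[!ret$artifact, , drop = FALSE]
  if (all(ret$condition == "unclassified"))
    stop("conditions not classified; run classifyResponses() first")
  do.call(rbind, lapply(split(ret, ret$participant_id), function(d) {
    studied <- d[!d$is_foil, , drop = FALSE]
    foils <- d[d$is_foil, , drop = FALSE]
    if (nrow(studied) == 0) stop("participant with zero studied trials")
    old_resp <- c("Face", "Place", "Old")
    oldnew <- computeDprime(sum(studied$response %in% old_resp), nrow(studied),
                            sum(foils$response %in% old_resp), nrow(foils))
    assoc <- computeDprime(sum(studied$condition == "associative_hit"),
                           nrow(studied),
                           sum(foils$response %in% c("Face", "Place")),
                           nrow(foils))
    recall <- if (all(is.na(studied$posttest_correct))) NA_real_
      else mean(studied$posttest_correct, na.rm = TRUE)
    data.frame(participant_id = d$participant_id[1],
               oldnew_dprime = oldnew, associative_dprime = assoc,
               exemplar_recall = recall,
               n_studied = nrow(studied), n_foils = nrow(foils),
               n_associative_hits = sum(studied$condition == "associative_hit"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
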