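## Multivoxel pattern classification of face/place category evidence.
##
## Preprocessing scales every voxel to zero mean / unit variance within run;
## feature selection keeps the top-k voxels most selective for each category
## by a two-sample t contrast on encoding data; training subsamples to equal
## category counts; classification is L2-penalized logistic regression
## (inverse regularization C, fit with glmnet at the single equivalent
## lambda). Encoding decodability uses leave-one-run-out cross-validation;
## retrieval reinstatement evidence trains on all encoding data and tests on
## retrieval data, reporting the probability assigned to each trial's correct
## associate category as a signed log-odds. Significance comes from
## permutation of the training labels through the full pipeline.

#' Classifier specification
#'
#' @param inverse_regularization C of the L2 logistic loss (larger = weaker
#'   penalty).
#' @param n_subsamples balanced training subsamples whose predicted
#'   probabilities are averaged.
#' @param n_features_per_category voxels kept per category direction by
#'   feature selection (the union has at most twice this).
#' @param n_permutations label permutations for the null distribution.
#' @param clip probabilities are clipped to `[clip, 1 - clip]` before the
#'   log-odds transform.
#' @param selection_scope `"fold"` recomputes feature selection inside each
#'   training fold (no leakage); `"subject"` selects once on all encoding
#'   data.
#' @return `patcomp_classifier_spec` list.
#' @export
classifierSpec <- function(inverse_regularization = 1.0,
                           n_subsamples = 10L,
                           n_features_per_category = 250L,
                           n_permutations = 1000L,
                           clip = 1e-6,
                           selection_scope = c("fold", "subject")) {
  spec <- list(inverse_regularization = inverse_regularization,
               n_subsamples = as.integer(n_subsamples),
               n_features_per_category = as.integer(n_features_per_category),
               n_permutations = as.integer(n_permutations),
               clip = clip,
               selection_scope = match.arg(selection_scope))
  stopifnot(spec$inverse_regularization > 0, spec$n_subsamples >= 1,
            spec$n_features_per_category >= 1, spec$clip > 0)
  class(spec) <- "patcomp_classifier_spec"
  spec
}

#' Scale voxels to zero mean and unit variance within each run
#'
#' Uses the sample (n-1) SD. Voxels with zero variance inside a run are set
#' to zero there, with a warning. A run with a single trial cannot be scaled.
#'
#' @param pm a [PatternMatrix-class].
#' @return the scaled `PatternMatrix`.
#' @export
scaleWithinRun <- function(pm) {
  values <- patternValues(pm)
  runs <- runLabels(pm)
  degenerate <- FALSE
  for (r in unique(runs)) {
    i <- runs == r
    if (sum(i) < 2) stop("run ", r, " has fewer than 2 trials; cannot scale")
    m <- values[i, , drop = FALSE]
    mu <- colMeans(m)
    s <- apply(m, 2, sd)
    zero <- s == 0
    s[zero] <- 1
    if (any(zero)) degenerate <- TRUE
    values[i, ] <- sweep(sweep(m, 2, mu), 2, s, "/")
    values[i, zero] <- 0
  }
  if (degenerate)
    warning("zero-variance voxel(s) within a run set to 0 after scaling")
  patternMatrix(values, run_labels = runs, trial_ids = trialIds(pm),
                roi = roiName(pm), phase = phaseName(pm))
}

#' Select category-selective voxels
#'
#' Ranks voxels by the two-sample t statistic of face vs place encoding
#' trials and keeps the `k` most face-selective and `k` most place-selective
#' voxels (the selected set is symmetric under swapping the category
#' labels). When `2k` exceeds the voxel count, all voxels are returned with
#' a warning.
#'
#' @param values trials x voxels numeric matrix (encoding phase).
#' @param labels per-trial category labels ("face"/"place").
#' @param k voxels per category direction.
#' @return sorted integer vector of selected voxel indices.
#' @export
selectCategoryVoxels <- function(values, labels, k = 250L) {
  stopifnot(nrow(values) == length(labels))
  labels <- as.character(labels)
  if (!all(c("face", "place") %in% labels))
    stop("both categories must be present for feature selection")
  if (2L * k >= ncol(values)) {
    if (2L * k > ncol(values))
      warning("2k exceeds the voxel count; using all voxels")
    return(seq_len(ncol(values)))
  }
  f <- labels == "face"
  n1 <- sum(f); n2 <- sum(!f)
  m1 <- colMeans(values[f, , drop = FALSE])
  m2 <- colMeans(values[!f, , drop = FALSE])
  v1 <- apply(values[f, , drop = FALSE], 2, var)
  v2 <- apply(values[!f, , drop = FALSE], 2, var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)) *
    sqrt(1 / n1 + 1 / n2)
  tstat <- (m1 - m2) / ifelse(sp == 0, Inf, sp)
  face_sel <- order(tstat, decreasing = TRUE)[seq_len(k)]
  place_sel <- order(tstat)[seq_len(k)]
  sort(union(face_sel, place_sel))
}

.signed_logit <- function(p, clip) {
  p <- pmin(pmax(p, clip), 1 - clip)
  log(p / (1 - p))
}

## Balanced-subsample L2-logistic ensemble: average the face-probabilities of
## n_subsamples fits, each on an equal number of face and place trials.
.ensemble_p_face <- function(x_train, y_train, x_test, spec) {
  stopifnot(all(y_train %in% c("face", "place")))
  idx_f <- which(y_train == "face")
  idx_p <- which(y_train == "place")
  if (!length(idx_f) || !length(idx_p))
    stop("training fold is missing a category")
  n_bal <- min(length(idx_f), length(idx_p))
  p_sum <- numeric(nrow(x_test))
  for (s in seq_len(spec$n_subsamples)) {
    take <- c(if (length(idx_f) > n_bal) sample(idx_f, n_bal) else idx_f,
              if (length(idx_p) > n_bal) sample(idx_p, n_bal) else idx_p)
    yy <- y_train[take]
    stopifnot(sum(yy == "face") == sum(yy == "place"))  # balanced by design
    fit <- glmnet(x_train[take, , drop = FALSE],
                  factor(yy, levels = c("place", "face")),
                  family = "binomial", alpha = 0, standardize = FALSE,
                  lambda = 1 / (spec$inverse_regularization * length(take)))
    p_sum <- p_sum + as.numeric(predict(fit, x_test, type = "response"))
  }
  p_sum / spec$n_subsamples
}

#' Leave-one-run-out encoding classification
#'
#' For each held-out run, trains the balanced-subsample classifier ensemble
#' on the remaining runs (feature selection recomputed inside the training
#' folds by default) and scores the held-out trials. A trial is counted
#' correct when the averaged probability of its true category strictly
#' exceeds 0.5.
#'
#' @param pm encoding-phase [PatternMatrix-class].
#' @param labels category per encoding trial, aligned with `pm` rows.
#' @param spec a [classifierSpec()].
#' @param scale apply [scaleWithinRun()] first (default).
#' @return list with `records` (trial_id, run, p_correct, logit, accuracy),
#'   `mean_accuracy` (the participant's encoding accuracy) and `mean_logit`
#'   (encoding classifier strength).
#' @export
encodingCVAccuracy <- function(pm, labels, spec = classifierSpec(),
                               scale = TRUE) {
  if (scale) pm <- scaleWithinRun(pm)
  values <- patternValues(pm)
  runs <- runLabels(pm)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(values))
  if (length(unique(runs)) < 2) stop("need >= 2 runs for cross-validation")
  subject_sel <- if (spec$selection_scope == "subject")
    selectCategoryVoxels(values, labels, spec$n_features_per_category)
  recs <- lapply(sort(unique(runs)), function(held) {
    tr <- runs != held
    sel <- if (spec$selection_scope == "fold")
      selectCategoryVoxels(values[tr, , drop = FALSE], labels[tr],
                           spec$n_features_per_category) else subject_sel
    p_face <- .ensemble_p_face(values[tr, sel, drop = FALSE], labels[tr],
                               values[!tr, sel, drop = FALSE], spec)
    p_correct <- ifelse(labels[!tr] == "face", p_face, 1 - p_face)
    data.frame(trial_id = trialIds(pm)[!tr], run = held,
               p_correct = p_correct,
               logit = .signed_logit(p_correct, spec$clip),
               accuracy = p_correct > 0.5, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  records <- records[match(trialIds(pm), records$trial_id), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, mean_accuracy = mean(records$accuracy),
       mean_logit = mean(records$logit))
}

#' Retrieval-phase reinstatement evidence
#'
#' Trains the balanced-subsample ensemble on all encoding-phase data and
#' tests on retrieval-phase data. For each retrieval trial the averaged
#' probability assigned to the trial's correct associate category is clipped
#' and log-odds transformed, so positive evidence always means
#' correct-category reinstatement regardless of face/place. Trials without a
#' correct category (foils) are excluded.
#'
#' @param encoding,retrieval [PatternMatrix-class] objects sharing a voxel
#'   set.
#' @param encoding_labels category per encoding trial.
#' @param correct_category category per retrieval trial (`NA`/"none" for
#'   foils).
#' @param spec a [classifierSpec()].
#' @param scale apply [scaleWithinRun()] to both phases (default).
#' @return `data.frame` of evidence records: trial_id, category, p_correct,
#'   logit, accuracy, selected_voxel_activity (mean scaled activity over the
#'   selected voxels, a univariate nuisance covariate), n_subsamples.
#' @export
retrievalEvidence <- function(encoding, encoding_labels, retrieval,
                              correct_category, spec = classifierSpec(),
                              scale = TRUE) {
  if (scale) {
    encoding <- scaleWithinRun(encoding)
    retrieval <- scaleWithinRun(retrieval)
  }
  enc <- patternValues(encoding)
  ret <- patternValues(retrieval)
  stopifnot(ncol(enc) == ncol(ret))
  encoding_labels <- as.character(encoding_labels)
  correct_category <- as.character(correct_category)
  keep <- !is.na(correct_category) & correct_category %in% c("face", "place")
  if (any(!keep))
    message(sum(!keep), " retrieval trial(s) without a correct category ",
            "excluded from evidence")
  sel <- selectCategoryVoxels(enc, encoding_labels,
                              spec$n_features_per_category)
  p_face <- .ensemble_p_face(enc[, sel, drop = FALSE], encoding_labels,
                             ret[keep, sel, drop = FALSE], spec)
  p_correct <- ifelse(correct_category[keep] == "face", p_face, 1 - p_face)
  data.frame(trial_id = trialIds(retrieval)[keep],
             category = correct_category[keep],
             p_correct = p_correct,
             logit = .signed_logit(p_correct, spec$clip),
             accuracy = p_correct > 0.5,
             selected_voxel_activity = rowMeans(ret[keep, sel, drop = FALSE]),
             n_subsamples = spec$n_subsamples,
             stringsAsFactors = FALSE)
}

#' Permutation p value for classifier accuracy
#'
#' Re-runs the full train/test pipeline (feature selection, balanced
#' subsampling, fitting) with the encoding training labels shuffled, keeping
#' test labels fixed, `n_permutations` times for each subsampling iteration.
#' The p value is the fraction of permuted accuracies that meet or exceed the
#' observed accuracy, computed per subsample iteration and averaged.
#'
#' @param observed_accuracy the observed mean accuracy to calibrate.
#' @param encoding,encoding_labels,retrieval,correct_category,scale as in
#'   [retrievalEvidence()]; `retrieval` may be a condition subset.
#' @param spec a [classifierSpec()]; `n_permutations` below 100 triggers a
#'   warning (unstable p).
#' @param seed integer seed for the permutation stream.
#' @param refit_selection recompute feature selection per shuffle
#'   (full-pipeline null, default) or freeze the observed selection.
#' @return p value in [0, 1].
#' @export
permutationPValue <- function(observed_accuracy, encoding, encoding_labels,
                              retrieval, correct_category,
                              spec = classifierSpec(), seed = 1,
                              refit_selection = TRUE, scale = TRUE) {
  if (spec$n_permutations < 100)
    warning("fewer than 100 permutations; p value will be unstable")
  if (scale) {
    encoding <- scaleWithinRun(encoding)
    retrieval <- scaleWithinRun(retrieval)
  }
  enc <- patternValues(encoding)
  ret <- patternValues(retrieval)
  encoding_labels <- as.character(encoding_labels)
  correct_category <- as.character(correct_category)
  keep <- !is.na(correct_category) & correct_category %in% c("face", "place")
  ret <- ret[keep, , drop = FALSE]
  correct_category <- correct_category[keep]
  one_spec <- spec; one_spec$n_subsamples <- 1L
  frozen_sel <- selectCategoryVoxels(enc, encoding_labels,
                                     spec$n_features_per_category)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
    globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  # acc[s, b]: accuracy of subsample iteration s under permutation b
  acc <- matrix(NA_real_, spec$n_subsamples, spec$n_permutations)
  for (b in seq_len(spec$n_permutations)) {
    perm <- sample(encoding_labels)
    sel <- if (refit_selection)
      selectCategoryVoxels(enc, perm, spec$n_features_per_category)
      else frozen_sel
    for (s in seq_len(spec$n_subsamples)) {
      p_face <- .ensemble_p_face(enc[, sel, drop = FALSE], perm,
                                 ret[, sel, drop = FALSE], one_spec)
      p_correct <- ifelse(correct_category == "face", p_face, 1 - p_face)
      acc[s, b] <- mean(p_correct > 0.5)
    }
  }
  mean(rowMeans(acc >= observed_accuracy))
}
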