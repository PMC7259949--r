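## Individual-differences layer: per-participant neural aggregates,
## nuisance adjustment by residualization, age models, and hierarchical
## regression with model-comparison F tests.

#' Per-participant neural summary
#'
#' Aggregates trial-level neural measures over artifact-free trials:
#' hippocampal activity contrast (mean over associative hits minus mean over
#' correct rejections), mean signed reinstatement logit over associative
#' hits per ROI, mean event-level ERS contrast (within-event minus
#' within-category) over associative hits per ROI, and encoding classifier
#' strength (mean cross-validated encoding logit) per ROI. A participant
#' lacking associative hits or correct rejections (below `min_trials`) gets
#' missing aggregates, logged.
#'
#' @param trials classified trial `data.frame` with `hippo_activity`.
#' @param evidence named list (by ROI) of retrieval evidence `data.frame`s
#'   from [retrievalEvidence()].
#' @param encoding named list (by ROI) of per-participant encoding strength:
#'   a `data.frame` with `participant_id` and `mean_logit` (see
#'   [encodingCVAccuracy()]).
#' @param ers named list (by ROI) of ERS `data.frame`s from [computeERS()].
#' @param min_trials minimum trials per aggregate cell.
#' @return `data.frame`, one row per participant: `hippo_activity`,
#'   `mean_logit_<roi>`, `event_ers_<roi>`, `encoding_strength_<roi>`.
#' @export
summarizeNeural <- function(trials, evidence, ers = NULL, encoding = NULL,
                            min_trials = 1L) {
  ret <- trials[trials$phase == "retrieval" & !trials$artifact, , drop = FALSE]
  if (all(ret$condition == "unclassified"))
    stop("conditions not classified; run classifyResponses() first")
  rois <- names(evidence)
  by_part <- split(ret, ret$participant_id)
  n_dropped <- 0L
  out <- lapply(by_part, function(d) {
    hits <- d[d$condition == "associative_hit", , drop = FALSE]
    crs <- d[d$condition == "correct_rejection", , drop = FALSE]
    hippo <- if (nrow(hits) >= min_trials && nrow(crs) >= min_trials)
      mean(hits$hippo_activity) - mean(crs$hippo_activity) else {
        n_dropped <<- n_dropped + 1L; NA_real_ }
    row <- data.frame(participant_id = d$participant_id[1],
                      hippo_activity = hippo, stringsAsFactors = FALSE)
    for (roi in rois) {
      ev <- evidence[[roi]]
      ev_hit <- ev[ev$trial_id %in% hits$trial_id, , drop = FALSE]
      row[[paste0("mean_logit_", roi)]] <-
        if (nrow(ev_hit) >= min_trials) mean(ev_hit$logit) else NA_real_
      if (!is.null(ers)) {
        er <- ers[[roi]]
        er_hit <- er[er$trial_id %in% hits$trial_id, , drop = FALSE]
        contrast <- eventLevelContrast(er_hit)
        row[[paste0("event_ers_", roi)]] <-
          if (sum(!is.na(contrast)) >= min_trials)
            mean(contrast, na.rm = TRUE) else NA_real_
      }
      if (!is.null(encoding)) {
        es <- encoding[[roi]]
        row[[paste0("encoding_strength_", roi)]] <-
          es$mean_logit[match(d$participant_id[1], es$participant_id)]
      }
    }
    row
  })
  if (n_dropped)
    message(n_dropped, " participant(s) with missing hippocampal contrast")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Residualize a measure on nuisance covariates
#'
#' Returns the residuals of the least-squares regression of `values` on the
#' covariates, with the grand mean restored, so the adjusted variable keeps
#' its original location. Missing entries stay missing.
#'
#' @param values numeric vector (one value per participant).
#' @param covariates numeric vector, matrix, or `data.frame` of nuisance
#'   variables.
#' @return adjusted numeric vector.
#' @export
adjustByNuisance <- function(values, covariates) {
  X <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(X)) stop("covariates must be numeric")
  stopifnot(nrow(X) == length(values))
  ok <- complete.cases(cbind(values, X))
  Xd <- cbind(`(Intercept)` = 1, X[ok, , drop = FALSE])
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) {
    drop_cols <- colnames(Xd)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop("rank-deficient covariates: ", paste(drop_cols, collapse = ", "))
  }
  out <- rep(NA_real_, length(values))
  res <- qr.resid(qr_x, values[ok])
  out[ok] <- res + mean(values[ok])
  out
}

#' Standardized cross-participant regression
#'
#' Ordinary least squares after z-scoring all continuous variables across
#' participants, yielding standardized coefficients. Rows with missing
#' values are dropped listwise (count logged).
#'
#' @param data per-participant `data.frame`.
#' @param outcome outcome column.
#' @param predictors predictor columns (focal + covariates alike; all are
#'   reported).
#' @return `patcomp_regression` list: `coefficients` (standardized beta, se,
#'   t, p per term), `r2`, `adjusted_r2`, `n`, `model`.
#' @export
fitSubjectRegression <- function(data, outcome, predictors) {
  stopifnot(all(c(outcome, predictors) %in% colnames(data)))
  d <- data[, c(outcome, predictors), drop = FALSE]
  ok <- complete.cases(d)
  if (any(!ok)) message(sum(!ok), " row(s) dropped listwise")
  d <- d[ok, , drop = FALSE]
  if (nrow(d) <= length(predictors) + 2)
    stop("too few complete cases for the requested model")
  for (cn in colnames(d))
    if (is.numeric(d[[cn]])) d[[cn]] <- as.numeric(scale(d[[cn]]))
  fml <- as.formula(paste(outcome, "~", paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = d)
  sm <- summary(fit)
  cf <- sm$coefficients
  p_eff <- fit$rank - 1
  r2 <- sm$r.squared
  n <- nrow(d)
  structure(list(
    coefficients = data.frame(term = rownames(cf),
                              beta = unname(cf[, 1]), se = unname(cf[, 2]),
                              t = unname(cf[, 3]), p = unname(cf[, 4]),
                              stringsAsFactors = FALSE, row.names = NULL),
    r2 = r2,
    adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - p_eff - 1),
    n = n, model = fit), class = "patcomp_regression")
}

#' @export
print.patcomp_regression <- function(x, ...) {
  print(x$coefficients, digits = 3)
  cat(sprintf("R2 = %.3f, adjusted R2 = %.3f, n = %d\n", x$r2,
              x$adjusted_r2, x$n))
  invisible(x)
}

#' Hierarchical regression with model-comparison F tests
#'
#' Fits a nested sequence of standardized regressions on the common
#' complete-case sample and reports, per step, the change in explained
#' variance and its F ratio
#' \eqn{F = \frac{(R^2_{full} - R^2_{reduced})/\Delta p}
#'            {(1 - R^2_{full})/(n - p_{full} - 1)}},
#' plus each step's coefficients and adjusted R-squared.
#'
#' @param data per-participant `data.frame`.
#' @param outcome outcome column.
#' @param steps named list of predictor vectors; each step must contain the
#'   previous step's predictors.
#' @return list with `ladder` (`data.frame`: step, predictors added, r2,
#'   adjusted_r2, delta_r2, F, df1, df2, p) and `fits` (the per-step
#'   `patcomp_regression` objects).
#' @export
hierarchicalCompare <- function(data, outcome, steps) {
  stopifnot(is.list(steps), length(steps) >= 1)
  for (i in seq_along(steps)[-1])
    if (!all(steps[[i - 1]] %in% steps[[i]]))
      stop("step ", i, " does not nest step ", i - 1)
  all_vars <- unique(c(outcome, unlist(steps)))
  d <- data[complete.cases(data[, all_vars, drop = FALSE]), all_vars,
            drop = FALSE]
  n <- nrow(d)
  fits <- lapply(steps, function(p) fitSubjectRegression(d, outcome, p))
  ladder <- do.call(rbind, lapply(seq_along(steps), function(i) {
    r2f <- fits[[i]]$r2
    pf_ <- length(steps[[i]])
    if (i == 1) { r2r <- 0; pr <- 0 }
    else { r2r <- fits[[i - 1]]$r2; pr <- length(steps[[i - 1]]) }
    df1 <- pf_ - pr
    df2 <- n - pf_ - 1
    Fstat <- if (df1 == 0 || r2f <= r2r) 0
      else ((r2f - r2r) / df1) / ((1 - r2f) / df2)
    data.frame(step = names(steps)[i] %||% paste0("step", i),
               added = paste(setdiff(steps[[i]],
                                     if (i > 1) steps[[i - 1]] else NULL),
                             collapse = "+"),
               r2 = r2f, adjusted_r2 = fits[[i]]$adjusted_r2,
               delta_r2 = r2f - r2r, F = Fstat, df1 = max(df1, 1), df2 = df2,
               p = pf(if (df1 == 0) 0 else Fstat, max(df1, 1), df2,
                      lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(ladder) <- NULL
  list(ladder = ladder, fits = fits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Age, sex and education effects on participant-level measures
#'
#' Fits, for each measure, a standardized regression of the (optionally
#' nuisance-adjusted) measure on age plus any extra covariates, and reports
#' the age coefficient.
#'
#' @param summaries per-participant `data.frame` including `age`.
#' @param measures measure columns to model.
#' @param covariates additional covariate columns (e.g. `"sex_male"`).
#' @return `data.frame`: measure, age beta, se, p, n.
#' @export
ageModels <- function(summaries, measures, covariates = character()) {
  out <- lapply(measures, function(m) {
    fit <- fitSubjectRegression(summaries, m, c("age", covariates))
    cf <- fit$coefficients[fit$coefficients$term == "age", , drop = FALSE]
    data.frame(measure = m, beta_age = cf$beta, se = cf$se, p = cf$p,
               n = fit$n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
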