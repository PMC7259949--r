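## Trial-level inference: within-participant standardization, linear and
## logistic mixed-effects models with a participant random intercept and an
## uncorrelated random slope of the predictor of interest, likelihood-ratio
## tests of the focal fixed effect, age moderation, and bootstrap mediation
## of hippocampal activity through cortical reinstatement.

#' Standardize trial-level values within participant
#'
#' Centres and scales (sample SD) each participant's values across their own
#' trials. Participants with zero variance yield missing values with a
#' warning; fewer than two finite values is an error.
#'
#' @param values numeric vector.
#' @param participant_ids grouping vector of the same length.
#' @return standardized numeric vector.
#' @export
zscoreWithinParticipant <- function(values, participant_ids) {
  stopifnot(length(values) == length(participant_ids))
  out <- rep(NA_real_, length(values))
  warned <- FALSE
  for (p in unique(participant_ids)) {
    i <- which(participant_ids == p)
    v <- values[i]
    fin <- is.finite(v)
    if (sum(fin) < 2)
      stop("participant ", p, " has fewer than 2 finite values")
    s <- sd(v[fin])
    if (is.na(s) || s == 0) { warned <- TRUE; next }
    out[i] <- (v - mean(v[fin])) / s
  }
  if (warned) warning("zero within-participant variance; values set missing")
  out
}

#' Nuisance regressor set for a trial-wise analysis
#'
#' Encodes the covariate scheme of the trial-wise models: every model
#' controls stimulus category and age; models where classifier reinstatement
#' strength (logits) is a variable additionally control ROI encoding
#' classifier strength, and when it is the independent variable, univariate
#' activity in the selected voxels; ERS-as-predictor models control overall
#' ROI activity; event-level ERS models additionally control category-level
#' (within-category) ERS; hippocampal-activity models need no ROI terms.
#'
#' @param analysis_kind one of `"logit_iv"`, `"logit_dv"`, `"ers_iv"`,
#'   `"event_ers"`, `"hippo_iv"`.
#' @return character vector of regressor names.
#' @export
buildNuisanceSet <- function(analysis_kind) {
  switch(analysis_kind,
    logit_iv = c("category", "age", "encoding_strength",
                 "selected_voxel_activity"),
    logit_dv = c("category", "age", "encoding_strength"),
    ers_iv = c("category", "age", "roi_mean_activity"),
    event_ers = c("category", "age", "roi_mean_activity",
                  "within_category_z"),
    hippo_iv = c("category", "age"),
    stop("unknown analysis kind: ", analysis_kind))
}

.mixed_formula <- function(outcome, fixed, slope_of, pid, with_slope = TRUE) {
  rhs <- paste(c(fixed, sprintf("(1 | %s)", pid),
                 if (with_slope) sprintf("(0 + %s | %s)", slope_of, pid)),
               collapse = " + ")
  as.formula(paste(outcome, "~", rhs))
}

#' Fit a trial-wise mixed-effects model
#'
#' Fixed effects: the predictor of interest plus nuisance terms. Random
#' effects: a participant intercept and an uncorrelated random slope of the
#' predictor (fitted as separate terms, fixing their correlation at zero).
#' Linear models are fitted by maximum likelihood (not REML) so that
#' log-likelihoods are comparable across nested fixed-effect structures;
#' logistic models use the Laplace approximation. A singular random-slope
#' fit is refitted without the slope and flagged.
#'
#' @param data trial-level `data.frame`.
#' @param outcome,predictor column names (outcome 0/1 for logistic).
#' @param nuisance character vector of additional fixed-effect columns.
#' @param family `"linear"` or `"logistic"`.
#' @param participant_col grouping column.
#' @param random_slope fit the random slope of the predictor (default TRUE).
#' @param slope_of column receiving the random slope (defaults to the
#'   predictor of interest).
#' @return `patcomp_mixed` list: `coefficients` (estimate, se, z, p per
#'   term), `loglik`, `random_intercept_var`, `random_slope_var`, `n_obs`,
#'   `converged`, `singular`, `model` (the lme4 fit).
#' @export
fitMixedModel <- function(data, outcome, predictor, nuisance = character(),
                          family = c("linear", "logistic"),
                          participant_col = "participant_id",
                          random_slope = TRUE, slope_of = predictor) {
  family <- match.arg(family)
  stopifnot(all(c(outcome, predictor, nuisance, participant_col) %in%
                colnames(data)))
  data <- data[complete.cases(data[, c(outcome, predictor, nuisance),
                                   drop = FALSE]), , drop = FALSE]
  fixed <- c(predictor, nuisance)
  fit_one <- function(with_slope) {
    fml <- .mixed_formula(outcome, fixed, slope_of, participant_col,
                          with_slope)
    if (family == "linear")
      suppressMessages(lmer(fml, data = data, REML = FALSE,
        control = lmerControl(check.conv.singular = "ignore")))
    else
      suppressMessages(suppressWarnings(glmer(fml, data = data,
        family = binomial(),
        control = glmerControl(check.conv.singular = "ignore"))))
  }
  fit <- fit_one(random_slope)
  singular <- isSingular(fit)
  used_slope <- random_slope
  if (singular && random_slope) {
    fit <- fit_one(FALSE)
    used_slope <- FALSE
  }
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  z <- est / se
  coefs <- data.frame(term = rownames(sm), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = unname(2 * pnorm(-abs(z))),
                      stringsAsFactors = FALSE, row.names = NULL)
  vc <- as.data.frame(VarCorr(fit))
  ri <- vc$vcov[vc$grp != "Residual" & vc$var1 == "(Intercept)"]
  rs <- vc$vcov[vc$grp != "Residual" & !is.na(vc$var1) &
                vc$var1 == slope_of]
  conv <- is.null(fit@optinfo$conv$lme4$code)
  structure(list(coefficients = coefs, loglik = as.numeric(logLik(fit)),
                 random_intercept_var = if (length(ri)) ri[1] else 0,
                 random_slope_var = if (length(rs)) rs[1] else 0,
                 n_obs = nrow(data), converged = conv, singular = singular,
                 random_slope = used_slope, family = family,
                 outcome = outcome, predictor = predictor,
                 nuisance = nuisance, model = fit),
            class = "patcomp_mixed")
}

#' @export
print.patcomp_mixed <- function(x, ...) {
  cat(sprintf("Mixed %s model: %s ~ %s (+%d nuisance), n = %d\n", x$family,
              x$outcome, x$predictor, length(x$nuisance), x$n_obs))
  print(x$coefficients, digits = 3)
  cat(sprintf("logLik %.2f | var(intercept) %.3g | var(slope) %.3g%s\n",
              x$loglik, x$random_intercept_var, x$random_slope_var,
              if (x$singular) " [singular; slope dropped]" else ""))
  invisible(x)
}

#' Likelihood-ratio test of nested mixed models
#'
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})}, floored at zero (with a
#' warning when optimizer noise makes the full model fit worse), with
#' degrees of freedom equal to the difference in fixed-term count.
#'
#' @param full,reduced `patcomp_mixed` fits; the reduced model must nest the
#'   full model's fixed effects (same family and outcome).
#' @return list `chi2`, `df`, `p` (class `patcomp_lrt`).
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "patcomp_mixed"), inherits(reduced, "patcomp_mixed"))
  if (full$family != reduced$family || full$outcome != reduced$outcome)
    stop("models are not nested: different family or outcome")
  tf <- full$coefficients$term; tr <- reduced$coefficients$term
  if (!all(tr %in% tf) || length(tf) <= length(tr))
    stop("models are not nested: reduced terms must be a strict subset")
  chi2 <- 2 * (full$loglik - reduced$loglik)
  if (chi2 < 0) {
    warning("full model log-likelihood below reduced (optimizer noise); ",
            "chi-square floored at 0")
    chi2 <- 0
  }
  df <- length(tf) - length(tr)
  structure(list(chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE)),
            class = "patcomp_lrt")
}

#' @export
print.patcomp_lrt <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f, p = %.4g\n", x$df, x$chi2, x$p))
  invisible(x)
}

#' Likelihood-ratio test of a focal fixed effect
#'
#' Convenience wrapper: fits the full model and the reduced model with the
#' predictor's fixed effect dropped (the random slope of the predictor is
#' retained in both, so only the fixed effect is tested) and compares them.
#'
#' @inheritParams fitMixedModel
#' @return list with `full`, `reduced`, `lrt`.
#' @export
testFixedEffect <- function(data, outcome, predictor, nuisance = character(),
                            family = c("linear", "logistic"),
                            participant_col = "participant_id") {
  family <- match.arg(family)
  full <- fitMixedModel(data, outcome, predictor, nuisance, family,
                        participant_col)
  red <- .fit_reduced(data, outcome, predictor, nuisance, family,
                      participant_col, keep_slope = full$random_slope)
  list(full = full, reduced = red, lrt = lrt(full, red))
}

## reduced model: predictor removed from the fixed effects but (optionally)
## kept as an uncorrelated random slope
.fit_reduced <- function(data, outcome, predictor, nuisance, family,
                         participant_col, keep_slope = TRUE,
                         slope_of = predictor) {
  data <- data[complete.cases(data[, c(outcome, predictor, nuisance),
                                   drop = FALSE]), , drop = FALSE]
  fixed <- if (length(nuisance)) nuisance else "1"
  fml <- .mixed_formula(outcome, fixed, slope_of, participant_col,
                        keep_slope)
  fit <- if (family == "linear")
    suppressMessages(lmer(fml, data = data, REML = FALSE,
      control = lmerControl(check.conv.singular = "ignore")))
  else
    suppressMessages(suppressWarnings(glmer(fml, data = data,
      family = binomial(),
      control = glmerControl(check.conv.singular = "ignore"))))
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; z <- est / se
  structure(list(
    coefficients = data.frame(term = rownames(sm), estimate = unname(est),
                              se = unname(se), z = unname(z),
                              p = unname(2 * pnorm(-abs(z))),
                              stringsAsFactors = FALSE, row.names = NULL),
    loglik = as.numeric(logLik(fit)), n_obs = nrow(data),
    converged = is.null(fit@optinfo$conv$lme4$code),
    singular = isSingular(fit), random_slope = keep_slope, family = family,
    outcome = outcome, predictor = predictor, nuisance = nuisance,
    model = fit), class = "patcomp_mixed")
}

#' Age moderation of a trial-wise effect
#'
#' Tests the age-by-predictor interaction: compares a model whose fixed
#' effects include `predictor * age` against one with only the main effects,
#' by likelihood ratio (1 df). Age must vary across participants.
#'
#' @inheritParams fitMixedModel
#' @param age_col participant-level age column (z-scored across
#'   participants internally).
#' @return list with `full`, `reduced`, `lrt` (the interaction test).
#' @export
moderationByAge <- function(data, outcome, predictor, nuisance = character(),
                            family = c("linear", "logistic"),
                            age_col = "age",
                            participant_col = "participant_id") {
  family <- match.arg(family)
  page <- tapply(data[[age_col]], data[[participant_col]], mean)
  if (length(unique(page)) < 2 || sd(page) == 0)
    stop("age has zero variance across participants")
  az <- (data[[age_col]] - mean(page)) / sd(page)
  data$.age_z <- az
  data$.age_x_pred <- az * data[[predictor]]
  nuis <- unique(c(setdiff(nuisance, age_col), ".age_z"))
  full <- fitMixedModel(data, outcome, ".age_x_pred",
                        nuisance = c(predictor, nuis), family,
                        participant_col, slope_of = predictor)
  red <- .fit_reduced(data, outcome, ".age_x_pred",
                      nuisance = c(predictor, nuis), family,
                      participant_col, keep_slope = full$random_slope,
                      slope_of = predictor)
  list(full = full, reduced = red, lrt = lrt(full, red))
}
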