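## Bootstrap mediation: treatment -> mediator -> outcome.
##
## The a path is the treatment coefficient in a linear model of the
## mediator; the b path is the mediator coefficient in a logistic model of
## the outcome controlling the treatment; the indirect effect is a*b, with a
## percentile bootstrap confidence interval. The default bootstrap resamples
## participants (whole clusters) with replacement, preserving
## within-participant dependence; trial-level resampling is available. The
## path models are mixed models with the same random structure as the
## primary analyses, or pooled (single-level) regressions for speed inside
## bootstrap loops.

.dummy_matrix <- function(data, cols) {
  if (!length(cols)) return(NULL)
  mm <- model.matrix(as.formula(paste("~", paste(cols, collapse = "+"))),
                     data = data)
  mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
}

.pooled_paths <- function(y_med, y_out, treat, med, Za, Zb, rows) {
  Xa <- cbind(1, treat[rows], if (!is.null(Za)) Za[rows, , drop = FALSE])
  a <- tryCatch(qr.coef(qr(Xa), y_med[rows])[2], error = function(e) NA_real_)
  Xb <- cbind(1, med[rows], treat[rows],
              if (!is.null(Zb)) Zb[rows, , drop = FALSE])
  b <- tryCatch(
    glm.fit(Xb, y_out[rows], family = binomial())$coefficients[2],
    error = function(e) NA_real_)
  c(a = unname(a), b = unname(b))
}

#' Bootstrap mediation of an outcome through a mediator
#'
#' @param data trial-level `data.frame` (standardized variables).
#' @param treatment,mediator,outcome column names; the outcome is binary
#'   (associative success), the mediator continuous (reinstatement logit).
#' @param nuisance_mediator,nuisance_outcome nuisance regressor columns for
#'   the two path models (see [buildNuisanceSet()]).
#' @param n_boot bootstrap resamples (5000 for inference; reduce for speed).
#' @param seed RNG seed for the bootstrap.
#' @param engine `"mixed"` fits both paths as mixed models with participant
#'   intercept and uncorrelated treatment/mediator random slopes; `"pooled"`
#'   uses single-level regressions (recommended inside the bootstrap).
#' @param boot_engine engine for the bootstrap refits (defaults to
#'   `"pooled"`; `"mixed"` is exact but slow).
#' @param resample `"participant"` resamples whole participants;
#'   `"trial"` resamples rows.
#' @param participant_col grouping column.
#' @return `patcomp_mediation` list: `a_path`, `b_path`, `indirect`,
#'   `ci_low`, `ci_high`, `n_boot`, `significant`, `n_failed`, `boot`
#'   (the bootstrap indirect effects).
#' @export
mediate <- function(data, treatment = "hippo_activity", mediator = "logit",
                    outcome = "assoc_hit",
                    nuisance_mediator = character(),
                    nuisance_outcome = character(),
                    n_boot = 5000, seed = 1,
                    engine = c("mixed", "pooled"),
                    boot_engine = "pooled",
                    resample = c("participant", "trial"),
                    participant_col = "participant_id") {
  engine <- match.arg(engine)
  resample <- match.arg(resample)
  need <- unique(c(treatment, mediator, outcome, nuisance_mediator,
                   nuisance_outcome, participant_col))
  stopifnot(all(need %in% colnames(data)))
  data <- data[complete.cases(data[, need, drop = FALSE]), , drop = FALSE]

  point <- function(eng, d) {
    if (eng == "mixed") {
      am <- fitMixedModel(d, mediator, treatment, nuisance_mediator,
                          family = "linear",
                          participant_col = participant_col)
      bm <- fitMixedModel(d, outcome, mediator,
                          nuisance = c(treatment, nuisance_outcome),
                          family = "logistic",
                          participant_col = participant_col,
                          slope_of = mediator)
      c(a = am$coefficients$estimate[am$coefficients$term == treatment],
        b = bm$coefficients$estimate[bm$coefficients$term == mediator])
    } else {
      Za <- .dummy_matrix(d, nuisance_mediator)
      Zb <- .dummy_matrix(d, nuisance_outcome)
      .pooled_paths(d[[mediator]], d[[outcome]], d[[treatment]],
                    d[[mediator]], Za, Zb, seq_len(nrow(d)))
    }
  }
  ab <- point(engine, data)

  # bootstrap
  Za <- .dummy_matrix(data, nuisance_mediator)
  Zb <- .dummy_matrix(data, nuisance_outcome)
  pid <- data[[participant_col]]
  upid <- unique(pid)
  rows_of <- split(seq_len(nrow(data)), pid)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
    globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  boot <- numeric(n_boot)
  n_failed <- 0L
  for (i in seq_len(n_boot)) {
    if (resample == "participant") {
      sampled <- sample(length(upid), replace = TRUE)
      rows <- unlist(rows_of[sampled], use.names = FALSE)
      new_pid <- rep(seq_along(sampled), lengths(rows_of)[sampled])
    } else {
      rows <- sample(nrow(data), replace = TRUE)
      new_pid <- pid[rows]
    }
    ab_i <- if (boot_engine == "mixed") {
      d <- data[rows, , drop = FALSE]
      d[[participant_col]] <- new_pid   # duplicated clusters kept distinct
      tryCatch(point("mixed", d), error = function(e) c(a = NA_real_,
                                                        b = NA_real_))
    } else {
      .pooled_paths(data[[mediator]], data[[outcome]], data[[treatment]],
                    data[[mediator]], Za, Zb, rows)
    }
    boot[i] <- ab_i["a"] * ab_i["b"]
    if (anyNA(ab_i)) n_failed <- n_failed + 1L
  }
  if (n_failed > 0.05 * n_boot)
    warning("bootstrap failed in more than 5% of resamples; ",
            "interpret the interval with caution")
  ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(a_path = unname(ab["a"]), b_path = unname(ab["b"]),
                 indirect = unname(ab["a"] * ab["b"]),
                 ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
                 significant = !(ci[1] <= 0 && ci[2] >= 0),
                 n_failed = n_failed, boot = boot),
            class = "patcomp_mediation")
}

#' @export
print.patcomp_mediation <- function(x, ...) {
  cat(sprintf("Mediation: a = %.4f, b = %.4f, indirect a*b = %.4f\n",
              x$a_path, x$b_path, x$indirect))
  cat(sprintf("95%% bootstrap CI [%.4f, %.4f] (%d resamples)%s\n",
              x$ci_low, x$ci_high, x$n_boot,
              if (x$significant) " *" else ""))
  invisible(x)
}
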