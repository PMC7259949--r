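## Motion/intensity quality control.
##
## Volumes are flagged when framewise displacement exceeds 0.5 mm or whole
## brain intensity deviates from the run mean by more than five run SDs; runs
## are dropped when flags exceed 25% of timepoints or FD ever exceeds 2 mm
## (strict inequalities: "exceeds" means >). Any trial touching a flagged
## volume, or belonging to a dropped run, is excluded from analysis.

#' Flag artifact volumes within runs
#'
#' @param qc `data.frame` with columns `run`, `framewise_displacement` (mm)
#'   and `global_intensity` (one row per volume).
#' @param fd_threshold flag a volume when FD strictly exceeds this (mm).
#' @param intensity_sd_threshold flag when \eqn{|I - \bar I_{run}|} strictly
#'   exceeds this many run SDs.
#' @return logical vector, one flag per volume (row of `qc`).
#' @export
flagArtifactVolumes <- function(qc, fd_threshold = 0.5,
                                intensity_sd_threshold = 5) {
  stopifnot(is.data.frame(qc), nrow(qc) > 0,
            all(c("run", "framewise_displacement", "global_intensity") %in%
                colnames(qc)))
  if (any(qc$framewise_displacement < 0, na.rm = TRUE))
    stop("framewise displacement must be >= 0")
  flags <- qc$framewise_displacement > fd_threshold
  for (r in unique(qc$run)) {
    i <- qc$run == r
    mu <- mean(qc$global_intensity[i])
    s <- sd(qc$global_intensity[i])
    if (is.na(s) || s == 0) {
      warning("zero-variance intensity series in run ", r,
              "; intensity criterion skipped")
      next
    }
    flags[i] <- flags[i] |
      abs(qc$global_intensity[i] - mu) > intensity_sd_threshold * s
  }
  flags
}

#' Decide run-level exclusion
#'
#' A run is dropped when the flagged fraction of its volumes strictly exceeds
#' `artifact_fraction`, or its maximum framewise displacement strictly
#' exceeds `fd_run_max`. A run flagged on exactly the fraction boundary is
#' retained.
#'
#' @param flags logical per-volume flags from [flagArtifactVolumes()].
#' @param qc the matching QC `data.frame`.
#' @param artifact_fraction run-level flagged-volume fraction limit.
#' @param fd_run_max run-level maximum FD limit (mm).
#' @return named logical vector per run: `TRUE` = keep.
#' @export
applyRunExclusion <- function(flags, qc, artifact_fraction = 0.25,
                              fd_run_max = 2.0) {
  stopifnot(length(flags) == nrow(qc))
  runs <- sort(unique(qc$run))
  keep <- vapply(runs, function(r) {
    i <- qc$run == r
    frac <- mean(flags[i])
    frac <= artifact_fraction &&
      max(qc$framewise_displacement[i]) <= fd_run_max
  }, logical(1))
  names(keep) <- runs
  keep
}

#' Exclude trials touched by artifacts or dropped runs
#'
#' @param trials trial `data.frame` with `trial_id` and `run`.
#' @param flags per-volume flags.
#' @param qc the QC `data.frame` the flags refer to.
#' @param trial_volumes named list mapping `trial_id` to the integer row
#'   indices of `qc` covered by that trial.
#' @param run_keep named logical per run from [applyRunExclusion()]; computed
#'   from `flags`/`qc` at the defaults when omitted.
#' @return `trials` with its `artifact` column set (`TRUE` = excluded); an
#'   attribute `n_excluded` records the count.
#' @export
excludeArtifactTrials <- function(trials, flags, qc, trial_volumes,
                                  run_keep = NULL) {
  if (is.null(run_keep)) run_keep <- applyRunExclusion(flags, qc)
  missing_map <- setdiff(trials$trial_id, names(trial_volumes))
  if (length(missing_map))
    stop("trial(s) mapped to no volumes: ",
         paste(head(missing_map, 5L), collapse = ", "))
  hit <- vapply(trials$trial_id, function(id) {
    vols <- trial_volumes[[id]]
    if (!length(vols)) stop("trial mapped to no volumes: ", id)
    any(flags[vols])
  }, logical(1))
  dropped_run <- !run_keep[as.character(trials$run)]
  trials$artifact <- trials$artifact | hit | dropped_run
  attr(trials, "n_excluded") <- sum(hit | dropped_run)
  message(sum(hit | dropped_run), " trial(s) excluded by QC")
  trials
}
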