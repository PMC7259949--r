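#' PatternMatrix: trial-wise voxel activity patterns for one ROI and phase
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' trials-by-voxels activity matrix for a single region of interest and task
#' phase. Internally the assay is stored voxels x trials (features in rows,
#' samples in columns, the Bioconductor convention); user-facing accessors
#' return the trials-in-rows orientation that classification and similarity
#' code operates on. Column data carry the trial identifier and run label for
#' every trial.
#'
#' @slot roi character(1), region-of-interest name (e.g. "VTC", "ANG").
#' @slot phase character(1), "encoding" or "retrieval".
#'
#' @seealso [patternMatrix()] for construction, [patternValues()],
#'   [runLabels()], [trialIds()] for access, [scaleWithinRun()] for the
#'   classifier preprocessing step.
#' @export
setClass("PatternMatrix",
  contains = "SummarizedExperiment",
  slots = c(roi = "character", phase = "character")
)

setValidity("PatternMatrix", function(object) {
  msg <- character()
  if (length(object@roi) != 1L || !nzchar(object@roi))
    msg <- c(msg, "'roi' must be a single non-empty name")
  if (length(object@phase) != 1L || !object@phase %in% .PHASES)
    msg <- c(msg, "'phase' must be one of 'encoding', 'retrieval'")
  if (!"pattern" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'pattern' is missing")
  cd <- colData(object)
  if (!all(c("trial_id", "run") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'trial_id' and 'run'")
  else {
    if (anyDuplicated(cd$trial_id))
      msg <- c(msg, "trial_id values must be unique")
    if (!is.numeric(cd$run) || any(cd$run != as.integer(cd$run)))
      msg <- c(msg, "'run' labels must be integer-valued")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PatternMatrix
#'
#' @param values numeric matrix, trials in rows and voxels in columns.
#' @param run_labels integer vector, run label per trial (row).
#' @param trial_ids character vector of unique trial identifiers per row.
#' @param roi region-of-interest name.
#' @param phase "encoding" or "retrieval".
#' @return A [PatternMatrix-class] object.
#' @examples
#' pm <- patternMatrix(matrix(rnorm(20), 4, 5), run_labels = c(1, 1, 2, 2),
#'                     trial_ids = paste0("t", 1:4), roi = "VTC",
#'                     phase = "encoding")
#' dim(patternValues(pm))
#' @export
patternMatrix <- function(values, run_labels, trial_ids, roi, phase) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("'values' must be a numeric trials x voxels matrix")
  if (nrow(values) != length(run_labels) || nrow(values) != length(trial_ids))
    stop("'run_labels' and 'trial_ids' must have one entry per trial row")
  se <- SummarizedExperiment(
    assays = list(pattern = t(values)),
    colData = DataFrame(trial_id = as.character(trial_ids),
                        run = as.integer(run_labels))
  )
  new("PatternMatrix", se, roi = as.character(roi), phase = as.character(phase))
}

#' @describeIn patternMatrix trials x voxels numeric matrix.
#' @param x a `PatternMatrix`.
#' @export
patternValues <- function(x) {
  stopifnot(is(x, "PatternMatrix"))
  t(assay(x, "pattern"))
}

#' @describeIn patternMatrix integer run label per trial.
#' @export
runLabels <- function(x) {
  stopifnot(is(x, "PatternMatrix"))
  colData(x)$run
}

#' @describeIn patternMatrix character trial identifier per trial.
#' @export
trialIds <- function(x) {
  stopifnot(is(x, "PatternMatrix"))
  colData(x)$trial_id
}

#' @describeIn patternMatrix ROI name.
#' @export
roiName <- function(x) {
  stopifnot(is(x, "PatternMatrix"))
  x@roi
}

#' @describeIn patternMatrix task phase.
#' @export
phaseName <- function(x) {
  stopifnot(is(x, "PatternMatrix"))
  x@phase
}

setMethod("show", "PatternMatrix", function(object) {
  cat("PatternMatrix:", object@roi, "/", object@phase, "\n")
  cat("  ", ncol(object), "trials x", nrow(object), "voxels across",
      length(unique(colData(object)$run)), "run(s)\n")
})
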