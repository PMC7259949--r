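## Readers and writers for the tabular and pattern-matrix formats.
## Trial tables and covariates are TSV/CSV; pattern matrices are TSV with a
## trial_id and run column followed by one column per voxel, written at full
## double precision so that write-then-read round-trips exactly.

.read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

.match_enum <- function(x, levels, what, required = TRUE) {
  out <- levels[match(tolower(as.character(x)), tolower(levels))]
  bad <- which(is.na(out) & !is.na(x) & nzchar(as.character(x)))
  if (required && length(bad))
    stop("unparseable ", what, " token(s) at row(s) ",
         paste(head(bad, 5L), collapse = ", "), ": ",
         paste(unique(head(as.character(x)[bad], 5L)), collapse = ", "))
  out
}

.as_logical_col <- function(x, what) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  xs <- tolower(trimws(as.character(x)))
  out[xs %in% c("true", "t", "1", "yes")] <- TRUE
  out[xs %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(is.na(out) & !is.na(x) & nzchar(xs))
  if (length(bad))
    stop("unparseable logical '", what, "' at row(s) ",
         paste(head(bad, 5L), collapse = ", "))
  out
}

#' Read a trial table
#'
#' Parses a TSV/CSV table with one row per trial. Mandatory columns:
#' `participant_id`, `run`, `trial_index`, `phase`, `word`, `category`,
#' `is_foil`, `response`. Optional columns (`rt`, `artifact`,
#' `posttest_correct`, `condition`) are carried through when present and
#' filled with missing/default values otherwise. Enum tokens (phase,
#' category, response) are matched case-insensitively; unknown tokens are
#' errors, not silently coerced.
#'
#' Memory conditions are not derived here; run [classifyResponses()] after
#' reading. Row order is preserved.
#'
#' @param path path to a `.tsv`/`.csv` file.
#' @return A `data.frame` of trials with a `trial_id` key
#'   (`participant:run:index:phase`).
#' @export
readTrialTable <- function(path) {
  df <- .read_table_auto(path)
  mandatory <- c("participant_id", "run", "trial_index", "phase", "word",
                 "category", "is_foil", "response")
  missing_cols <- setdiff(mandatory, colnames(df))
  if (length(missing_cols))
    stop("trial table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    participant_id = as.character(df$participant_id),
    run = as.integer(df$run),
    trial_index = as.integer(df$trial_index),
    phase = .match_enum(df$phase, .PHASES, "phase"),
    word = as.character(df$word),
    category = .match_enum(df$category, .CATEGORIES, "category"),
    is_foil = .as_logical_col(df$is_foil, "is_foil"),
    response = .match_enum(df$response, .RESPONSES, "response"),
    stringsAsFactors = FALSE
  )
  out$rt <- if ("rt" %in% colnames(df)) as.numeric(df$rt) else NA_real_
  out$artifact <- if ("artifact" %in% colnames(df))
    .as_logical_col(df$artifact, "artifact") else FALSE
  out$posttest_correct <- if ("posttest_correct" %in% colnames(df))
    .as_logical_col(df$posttest_correct, "posttest_correct") else NA
  out$condition <- if ("condition" %in% colnames(df))
    .match_enum(df$condition, .CONDITIONS, "condition") else "unclassified"
  out$trial_id <- if ("trial_id" %in% colnames(df)) as.character(df$trial_id)
    else makeTrialIds(out)
  if (anyDuplicated(out$trial_id))
    stop("duplicated trial_id values in trial table")
  out
}

#' @describeIn readTrialTable canonical trial identifier
#'   (`participant:run:index:phase`) built from the key columns.
#' @param trials a trial `data.frame`.
#' @export
makeTrialIds <- function(trials) {
  paste(trials$participant_id, trials$run, trials$trial_index, trials$phase,
        sep = ":")
}

#' Write a trial table
#'
#' Inverse of [readTrialTable()]; tab-separated, one row per trial.
#'
#' @param trials trial `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrialTable <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pattern matrix aligned to a trial table
#'
#' Reads a delimited trials-by-voxels matrix (columns `trial_id`, `run`,
#' then voxels) and reorders its rows to follow the order of the matching
#' phase rows in `trials`. Every stored row must correspond to a trial in the
#' table and vice versa.
#'
#' @param path TSV file written by [writePatternMatrix()].
#' @param trials trial `data.frame` (the phase subset is selected
#'   automatically from the file's metadata columns).
#' @param roi,phase ROI name and phase recorded on the returned object.
#' @return A [PatternMatrix-class].
#' @export
readPatternMatrix <- function(path, trials, roi, phase) {
  df <- .read_table_auto(path)
  if (!all(c("trial_id", "run") %in% colnames(df)))
    stop("pattern matrix file must have 'trial_id' and 'run' columns")
  vox_cols <- setdiff(colnames(df), c("trial_id", "run"))
  values <- as.matrix(df[, vox_cols, drop = FALSE])
  storage.mode(values) <- "double"
  if (anyNA(values))
    stop("pattern matrix contains NaN/NA entries in row(s) ",
         paste(head(which(rowSums(is.na(values)) > 0), 5L), collapse = ", "))
  want <- trials[trials$phase == phase, , drop = FALSE]
  if (nrow(want) != nrow(df))
    stop("alignment error: ", nrow(df), " pattern rows but ", nrow(want),
         " ", phase, " trials in the table")
  idx <- match(want$trial_id, df$trial_id)
  if (anyNA(idx))
    stop("alignment error: trial id(s) absent from pattern file: ",
         paste(head(want$trial_id[is.na(idx)], 5L), collapse = ", "))
  patternMatrix(values[idx, , drop = FALSE], run_labels = df$run[idx],
                trial_ids = df$trial_id[idx], roi = roi, phase = phase)
}

#' Write a pattern matrix
#'
#' Serializes a [PatternMatrix-class] as TSV with full double precision
#' (`%.17g`), so a write/read cycle reproduces the values bit-exactly.
#'
#' @param pm a `PatternMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePatternMatrix <- function(pm, path) {
  values <- patternValues(pm)
  chr <- matrix(sprintf("%.17g", values), nrow = nrow(values))
  colnames(chr) <- if (!is.null(colnames(values))) colnames(values)
    else paste0("v", seq_len(ncol(values)))
  df <- data.frame(trial_id = trialIds(pm), run = runLabels(pm), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-participant covariate table
#'
#' TSV/CSV with one row per participant; requires `participant_id` and `age`,
#' and passes any additional columns (sex, education, mean_fd, delayed-recall
#' subtests, ...) through unchanged.
#'
#' @param path input file.
#' @return `data.frame` of covariates.
#' @export
readCovariates <- function(path) {
  df <- .read_table_auto(path)
  if (!all(c("participant_id", "age") %in% colnames(df)))
    stop("covariate table is missing mandatory column(s): ",
         paste(setdiff(c("participant_id", "age"), colnames(df)),
               collapse = ", "))
  df$participant_id <- as.character(df$participant_id)
  df
}
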