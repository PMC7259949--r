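# Shared fixtures, built in code. The memo cache keeps one small simulated
# study per configuration signature so several test files can reuse it.

.fixture_cache <- new.env(parent = emptyenv())

cached_study <- function(key, cfg) {
  if (!exists(key, .fixture_cache))
    assign(key, generateStudy(cfg), .fixture_cache)
  get(key, .fixture_cache)
}

# small cohort with the full per-run design, modest voxel count
small_study <- function() {
  cached_study("small", simulationConfig(
    n_participants = 8, n_voxels = 80, rois = c(VTC = 1, ANG = 0.8),
    seed = 424242))
}

small_analysis <- function() {
  if (!exists("small_an", .fixture_cache)) {
    an <- suppressMessages(analyzeStudy(
      small_study(),
      classifierSpec(n_features_per_category = 20, n_subsamples = 3)))
    assign("small_an", an, .fixture_cache)
  }
  get("small_an", .fixture_cache)
}

# noise-only pattern matrix
noise_pm <- function(n_trials, n_voxels, runs, phase = "encoding",
                     prefix = "t", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  patternMatrix(matrix(rnorm(n_trials * n_voxels), n_trials), runs,
                paste0(prefix, seq_len(n_trials)), "VTC", phase)
}

# minimal classified trial table for ERS tests: one participant, explicit
# words/categories/conditions
ers_trials <- function(words, categories, conditions, runs_enc = 1,
                       runs_ret = 1) {
  n <- length(words)
  enc <- data.frame(participant_id = "p1", run = runs_enc,
                    trial_index = seq_len(n), phase = "encoding",
                    word = words, category = categories, is_foil = FALSE,
                    response = "none", rt = NA_real_, artifact = FALSE,
                    posttest_correct = NA, condition = "unclassified",
                    stringsAsFactors = FALSE)
  ret <- enc
  ret$phase <- "retrieval"
  ret$run <- runs_ret
  ret$condition <- conditions
  ret$response <- ifelse(conditions == "associative_hit",
                         ifelse(categories == "face", "Face", "Place"),
                         "New")
  out <- rbind(enc, ret)
  out$trial_id <- makeTrialIds(out)
  out
}

# stub mixed-model results for exercising the likelihood-ratio arithmetic
mixed_stub <- function(terms, loglik, outcome = "y", family = "linear") {
  structure(list(
    coefficients = data.frame(term = terms, estimate = 0, se = 1, z = 0,
                              p = 1, stringsAsFactors = FALSE),
    loglik = loglik, family = family, outcome = outcome),
    class = "patcomp_mixed")
}
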