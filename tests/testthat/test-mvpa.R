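test_that("within-run scaling centres and scales each voxel, idempotently", {
  pm <- patternMatrix(cbind(c(1, 3, 0, 4), c(2, 2, 1, 5)),
                      run_labels = c(1, 1, 2, 2),
                      trial_ids = paste0("t", 1:4), "VTC", "encoding")
  expect_warning(sc <- scaleWithinRun(pm), "zero-variance")
  v <- patternValues(sc)
  # sample-SD convention: (1,3) -> +/- 1/sqrt(2)
  expect_equal(v[1:2, 1], c(-1, 1) / sqrt(2))
  # constant column within run 1 -> zeros
  expect_equal(v[1:2, 2], c(0, 0))
  # run means 0, sample variances 1 where defined
  expect_equal(mean(v[3:4, 2]), 0)
  expect_equal(var(v[3:4, 2]), 1)
  # idempotence on non-degenerate columns
  pm2 <- noise_pm(10, 6, rep(1:2, each = 5), seed = 3)
  once <- patternValues(scaleWithinRun(pm2))
  twice <- patternValues(scaleWithinRun(scaleWithinRun(pm2)))
  expect_equal(twice, once, tolerance = 1e-12)
  # a single-trial run cannot be scaled
  expect_error(scaleWithinRun(noise_pm(3, 4, c(1, 1, 2))), "fewer than 2")
})

test_that("feature selection recovers planted voxels and is label-symmetric", {
  set.seed(21)
  n <- 60; nv <- 600
  labels <- rep(c("face", "place"), n / 2)
  x <- matrix(rnorm(n * nv), n)
  x[labels == "face", 1:250] <- x[labels == "face", 1:250] + 2
  x[labels == "place", 251:500] <- x[labels == "place", 251:500] + 2
  sel <- selectCategoryVoxels(x, labels, k = 250)
  expect_gte(mean(sel %in% 1:500), 0.95)
  swapped <- ifelse(labels == "face", "place", "face")
  expect_identical(selectCategoryVoxels(x, swapped, k = 250), sel)
  # k at half the voxel count selects everything
  expect_identical(selectCategoryVoxels(x[, 1:20], labels, k = 10), 1:20)
  expect_warning(sel_all <- selectCategoryVoxels(x[, 1:10], labels, k = 10),
                 "all voxels")
  expect_identical(sel_all, 1:10)
  expect_error(selectCategoryVoxels(x, rep("face", n), k = 5),
               "both categories")
})

test_that("encoding CV is perfect on separable patterns, chance when shuffled", {
  set.seed(22)
  n <- 48; nv <- 20
  labels <- rep(c("face", "place"), n / 2)
  x <- matrix(rnorm(n * nv, 0, 0.05), n)
  x[labels == "face", 1:10] <- x[labels == "face", 1:10] + 2
  x[labels == "place", 11:20] <- x[labels == "place", 11:20] + 2
  pm <- patternMatrix(x, rep(1:3, each = n / 3), paste0("t", 1:n), "VTC",
                      "encoding")
  spec <- classifierSpec(n_features_per_category = 5, n_subsamples = 2)
  cv <- encodingCVAccuracy(pm, labels, spec)
  expect_equal(cv$mean_accuracy, 1)
  expect_gt(cv$mean_logit, 0)
  expect_identical(cv$records$accuracy, cv$records$logit > 0)

  accs <- vapply(1:5, function(i) {
    set.seed(100 + i)
    encodingCVAccuracy(pm, sample(labels), spec)$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / (5 * n)) + 0.05)
})

test_that("retrieval evidence is signed toward the correct associate", {
  st <- small_study()
  an <- small_analysis()
  ev <- an$evidence$VTC
  pc <- pmin(pmax(ev$p_correct, 1e-6), 1 - 1e-6)
  expect_equal(ev$logit, log(pc / (1 - pc)), tolerance = 1e-12)
  expect_identical(ev$accuracy, ev$logit > 0)
  expect_true(all(is.finite(ev$logit)))
  # evidence on associative hits exceeds evidence on associative misses
  # and both relate to the generative reinstatement latent
  tr <- classifyResponses(st$trials)
  m <- merge(ev, tr[, c("trial_id", "condition")], by = "trial_id")
  expect_gt(mean(m$logit[m$condition == "associative_hit"]), 0)
  expect_gt(mean(m$logit[m$condition == "associative_hit"]),
            mean(m$logit[m$condition == "associative_miss"]))
  truth <- st$truth$trial
  m2 <- merge(ev, truth, by = "trial_id")
  expect_gt(cor(m2$logit, pmax(m2$r, 0), use = "complete.obs"), 0.2)
})

test_that("evidence is invariant to voxel permutation and run relabeling", {
  set.seed(33)
  st <- small_study()
  tr <- st$trials[st$trials$participant_id == "sub003", ]
  enc <- st$patterns$sub003$VTC$encoding
  ret <- st$patterns$sub003$VTC$retrieval
  enc_labels <- tr$category[match(trialIds(enc), tr$trial_id)]
  ret_cat <- tr$category[match(trialIds(ret), tr$trial_id)]
  spec <- classifierSpec(n_features_per_category = 15, n_subsamples = 2)
  base <- local({set.seed(1); suppressMessages(
    retrievalEvidence(enc, enc_labels, ret, ret_cat, spec))})

  perm <- sample(ncol(patternValues(enc)))
  enc_p <- patternMatrix(patternValues(enc)[, perm], runLabels(enc),
                         trialIds(enc), "VTC", "encoding")
  ret_p <- patternMatrix(patternValues(ret)[, perm], runLabels(ret),
                         trialIds(ret), "VTC", "retrieval")
  permuted <- local({set.seed(1); suppressMessages(
    retrievalEvidence(enc_p, enc_labels, ret_p, ret_cat, spec))})
  expect_equal(permuted$logit, base$logit, tolerance = 1e-4)

  enc_r <- patternMatrix(patternValues(enc), runLabels(enc) + 7L,
                         trialIds(enc), "VTC", "encoding")
  ret_r <- patternMatrix(patternValues(ret), runLabels(ret) + 7L,
                         trialIds(ret), "VTC", "retrieval")
  relab <- local({set.seed(1); suppressMessages(
    retrievalEvidence(enc_r, enc_labels, ret_r, ret_cat, spec))})
  expect_equal(relab$logit, base$logit, tolerance = 1e-6)
})

test_that("permutation p values hit the boundary cases", {
  set.seed(44)
  n <- 40; nv <- 12
  labels <- rep(c("face", "place"), n / 2)
  x <- matrix(rnorm(n * nv), n)
  x[labels == "face", 1:6] <- x[labels == "face", 1:6] + 1.6
  x[labels == "place", 7:12] <- x[labels == "place", 7:12] + 1.6
  enc <- patternMatrix(x, rep(1:2, each = n / 2), paste0("e", 1:n), "VTC",
                       "encoding")
  y <- matrix(rnorm(n * nv), n)
  y[labels == "face", 1:6] <- y[labels == "face", 1:6] + 1.6
  y[labels == "place", 7:12] <- y[labels == "place", 7:12] + 1.6
  ret <- patternMatrix(y, rep(1:2, each = n / 2), paste0("r", 1:n), "VTC",
                       "retrieval")
  spec <- classifierSpec(n_features_per_category = 3, n_subsamples = 1,
                         n_permutations = 120)
  ev <- retrievalEvidence(enc, labels, ret, labels, spec)
  expect_gt(mean(ev$accuracy), 0.75)
  p <- permutationPValue(mean(ev$accuracy), enc, labels, ret, labels, spec,
                         seed = 9)
  expect_lt(p, 0.05)  # real signal: observed beats almost every shuffle
  # observed at floor: every permutation meets or exceeds it
  p1 <- permutationPValue(0, enc, labels, ret, labels, spec, seed = 9)
  expect_equal(p1, 1)
  expect_warning(
    permutationPValue(1, enc, labels, ret, labels,
                      classifierSpec(n_features_per_category = 3,
                                     n_subsamples = 1, n_permutations = 50),
                      seed = 9), "unstable")
})
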