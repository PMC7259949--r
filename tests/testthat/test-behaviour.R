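test_that("the memory-condition taxonomy is exhaustive and exclusive", {
  grid <- expand.grid(is_foil = c(FALSE, TRUE),
                      category = c("face", "place", "none"),
                      response = c("Face", "Place", "Old", "New", "none"),
                      stringsAsFactors = FALSE)
  cond <- conditionFromResponse(grid$is_foil, grid$category, grid$response)
  expect_true(all(cond %in% c("associative_hit", "associative_miss",
                              "item_hit", "item_miss", "item_false_alarm",
                              "associative_false_alarm", "correct_rejection",
                              "unclassified")))
  # every combination maps to exactly one condition (vector output, no NA)
  expect_false(anyNA(cond))
  # studied/correct category
  expect_equal(conditionFromResponse(FALSE, "face", "Face"),
               "associative_hit")
  expect_equal(conditionFromResponse(FALSE, "place", "Face"),
               "associative_miss")
  expect_equal(conditionFromResponse(FALSE, "face", "New"), "item_miss")
  expect_equal(conditionFromResponse(FALSE, "place", "Old"), "item_hit")
  # foils
  expect_equal(conditionFromResponse(TRUE, "none", "Place"),
               "associative_false_alarm")
  expect_equal(conditionFromResponse(TRUE, "none", "Old"),
               "item_false_alarm")
  expect_equal(conditionFromResponse(TRUE, "none", "New"),
               "correct_rejection")
  # only a response of "none" is unclassified
  expect_equal(sum(cond == "unclassified"), sum(grid$response == "none"))
})

test_that("d-prime equals the inverse-normal oracle and honours boundaries", {
  # grid of rate pairs against the closed-form oracle
  set.seed(11)
  for (i in 1:100) {
    hn <- sample(20:200, 1); fn <- sample(10:60, 1)
    hc <- sample(1:(hn - 1), 1); fc <- sample(1:(fn - 1), 1)
    expect_equal(computeDprime(hc, hn, fc, fn),
                 qnorm(hc / hn) - qnorm(fc / fn), tolerance = 1e-12)
  }
  expect_equal(computeDprime(96, 120, 6, 30), 1.6832, tolerance = 1e-4)
  # equal rates: zero by symmetry
  expect_equal(computeDprime(30, 100, 15, 50), 0)
  # antisymmetry under swapping hit and FA rates
  expect_equal(computeDprime(80, 100, 20, 100),
               -computeDprime(20, 100, 80, 100))
  # perfect performance under the 1/(2N) rule at the study's 120/30 design
  expect_equal(computeDprime(120, 120, 0, 30),
               qnorm(239 / 240) - qnorm(1 / 60), tolerance = 1e-12)
  expect_equal(computeDprime(120, 120, 0, 30), 4.766, tolerance = 1e-3)
  expect_error(computeDprime(1, 0, 1, 10), "positive")
  expect_error(computeDprime(5, 4, 1, 10), "exceed")
})

test_that("post-test scoring normalizes text and routes misses to review", {
  expect_true(scorePosttest("golden gate bridge", "Golden Gate Bridge"))
  expect_true(scorePosttest("I think it was the Golden-Gate Bridge!",
                            "Golden Gate Bridge"))
  expect_false(scorePosttest("", "Golden Gate Bridge"))
  expect_false(scorePosttest(NA_character_, "Golden Gate Bridge"))
  rf <- withr::local_tempfile(fileext = ".tsv")
  ok <- scorePosttest(c("a red bridge in SF", "niagara falls"),
                      c("Golden Gate Bridge", "Niagara Falls"),
                      review_file = rf)
  expect_equal(ok, c(FALSE, TRUE), ignore_attr = TRUE)
  review <- read.delim(rf)
  expect_equal(nrow(review), 1)
  expect_match(review$response, "red bridge")
})

test_that("the delayed-recall composite is a mean, order-invariant", {
  expect_equal(delayedRecallComposite(0, 0, 0), 0)
  expect_equal(delayedRecallComposite(1, -1, 0), 0)
  expect_equal(delayedRecallComposite(0.6, 0.3, 0.9), 0.6)
  expect_equal(delayedRecallComposite(0.3, 0.9, 0.6),
               delayedRecallComposite(0.9, 0.6, 0.3))
  expect_warning(out <- delayedRecallComposite(c(1, NA), c(0, 0), c(1, 1)),
                 "missing")
  expect_true(is.na(out[2]) && !is.na(out[1]))
})

test_that("behavioural summaries apply the printed rate definitions", {
  st <- small_study()
  trials <- classifyResponses(st$trials)
  beh <- summarizeBehaviour(trials)
  expect_equal(nrow(beh), 8)
  expect_equal(beh$n_studied, rep(120, 8))
  expect_equal(beh$n_foils, rep(30, 8))

  # recompute one participant by hand
  d <- trials[trials$participant_id == beh$participant_id[1] &
              trials$phase == "retrieval", ]
  stud <- d[!d$is_foil, ]; foil <- d[d$is_foil, ]
  old_resp <- c("Face", "Place", "Old")
  expect_equal(beh$oldnew_dprime[1],
               computeDprime(sum(stud$response %in% old_resp), nrow(stud),
                             sum(foil$response %in% old_resp), nrow(foil)))
  expect_equal(beh$associative_dprime[1],
               computeDprime(sum(stud$condition == "associative_hit"),
                             nrow(stud),
                             sum(foil$response %in% c("Face", "Place")),
                             nrow(foil)))
  expect_equal(beh$exemplar_recall[1], mean(stud$posttest_correct))

  # boundary: a participant answering New to everything still gets a d'
  all_new <- d
  all_new$response <- "New"
  all_new <- classifyResponses(all_new)
  one <- summarizeBehaviour(all_new)
  expect_true(is.finite(one$oldnew_dprime))
  expect_equal(one$oldnew_dprime, qnorm(1 / 240) - qnorm(1 / 60))
})

test_that("associative d-prime grows with the reinstatement-success link", {
  dp <- vapply(c(0, 1.6), function(br) {
    cfg <- simulationConfig(n_participants = 12, n_voxels = 2,
                            rois = c(VTC = 1),
                            behaviour_weights = c(-0.5, 0.4, br),
                            a_h = 0.4, seed = 909)
    st <- generateStudy(cfg)
    mean(summarizeBehaviour(classifyResponses(st$trials))$associative_dprime)
  }, numeric(1))
  expect_gt(dp[2], dp[1])
})
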