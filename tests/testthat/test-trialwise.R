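test_that("within-participant z-scoring is exact and idempotent", {
  expect_equal(zscoreWithinParticipant(c(2, 4), c("a", "a")),
               c(-1, 1) / sqrt(2))
  set.seed(61)
  v <- rnorm(40); id <- rep(c("a", "b"), each = 20)
  z <- zscoreWithinParticipant(v, id)
  expect_equal(zscoreWithinParticipant(z, id), z, tolerance = 1e-12)
  expect_equal(as.numeric(tapply(z, id, mean)), c(0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(tapply(z, id, sd)), c(1, 1), tolerance = 1e-12)
  expect_warning(out <- zscoreWithinParticipant(c(1, 1, 1, 2, 3),
                                                c("a", "a", "a", "b", "b")),
                 "zero")
  expect_true(all(is.na(out[1:3])) && !anyNA(out[4:5]))
  expect_error(zscoreWithinParticipant(c(1, 2, 3), c("a", "a", "b")),
               "fewer than 2")
})

test_that("nuisance sets encode the covariate scheme exactly", {
  expect_setequal(buildNuisanceSet("logit_iv"),
                  c("category", "age", "encoding_strength",
                    "selected_voxel_activity"))
  expect_setequal(buildNuisanceSet("logit_dv"),
                  c("category", "age", "encoding_strength"))
  expect_false("selected_voxel_activity" %in% buildNuisanceSet("logit_dv"))
  expect_setequal(buildNuisanceSet("ers_iv"),
                  c("category", "age", "roi_mean_activity"))
  expect_true("within_category_z" %in% buildNuisanceSet("event_ers"))
  expect_setequal(buildNuisanceSet("hippo_iv"), c("category", "age"))
  expect_error(buildNuisanceSet("banana"), "unknown")
})

test_that("mixed models collapse to pooled regressions without heterogeneity", {
  set.seed(62)
  np <- 20; nt <- 60
  d <- data.frame(participant_id = rep(seq_len(np), each = nt),
                  x = rnorm(np * nt))
  d$y <- 0.5 * d$x + rnorm(np * nt)
  d$yb <- rbinom(np * nt, 1, plogis(0.3 + 0.6 * d$x))
  fm <- fitMixedModel(d, "y", "x", family = "linear")
  expect_lt(abs(fm$coefficients$estimate[2] - coef(lm(y ~ x, d))[["x"]]),
            1e-3)
  gm <- fitMixedModel(d, "yb", "x", family = "logistic")
  pooled <- coef(glm(yb ~ x, d, family = binomial()))[["x"]]
  expect_lt(abs(gm$coefficients$estimate[2] - pooled), 1e-3)
  # Wald z is estimate over SE by construction
  expect_equal(fm$coefficients$z,
               fm$coefficients$estimate / fm$coefficients$se)
})

test_that("mixed models recover heterogeneous slopes and variances", {
  set.seed(63)
  np <- 30; nt <- 50
  d <- data.frame(participant_id = rep(seq_len(np), each = nt),
                  x = rnorm(np * nt))
  u <- rnorm(np, 0, 0.7); s <- rnorm(np, 0.5, 0.4)
  d$y <- u[d$participant_id] + s[d$participant_id] * d$x + rnorm(np * nt)
  fm <- fitMixedModel(d, "y", "x", family = "linear")
  expect_false(fm$singular)
  expect_equal(fm$coefficients$estimate[2], 0.5, tolerance = 0.35)
  expect_equal(fm$random_intercept_var, 0.49, tolerance = 0.5)
  expect_equal(fm$random_slope_var, 0.16, tolerance = 0.5)
  expect_true(fm$converged)
})

test_that("likelihood-ratio arithmetic follows the chi-square identity", {
  full <- mixed_stub(c("(Intercept)", "x", "z"), loglik = -100)
  red <- mixed_stub(c("(Intercept)", "z"), loglik = -102)
  out <- lrt(full, red)
  expect_equal(out$chi2, 4)
  expect_equal(out$df, 1)
  expect_equal(out$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(out$p, 0.0455, tolerance = 1e-4)
  # identical models: zero statistic, p = 1
  same <- lrt(full, mixed_stub(c("(Intercept)", "x"), loglik = -100))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # optimizer noise: floored at zero with a warning
  expect_warning(fl <- lrt(mixed_stub(c("(Intercept)", "x", "z"), -103),
                           red), "floored")
  expect_equal(fl$chi2, 0)
  # non-nested structures are rejected
  expect_error(lrt(full, mixed_stub(c("(Intercept)", "w"), -101)),
               "not nested")
  expect_error(lrt(full, mixed_stub(c("(Intercept)", "x"), -100,
                                    family = "logistic")), "not nested")
})

test_that("the focal-effect LRT is invariant to predictor rescaling and
           tracks the Wald statistic at large n", {
  set.seed(64)
  np <- 25; nt <- 80
  d <- data.frame(participant_id = rep(seq_len(np), each = nt),
                  x = rnorm(np * nt))
  u <- rnorm(np, 0, 0.4)
  d$y <- 0.2 * d$x + u[d$participant_id] + rnorm(np * nt)
  t1 <- testFixedEffect(d, "y", "x", family = "linear")
  d2 <- d; d2$x <- 10 * d2$x + 3
  t2 <- testFixedEffect(d2, "y", "x", family = "linear")
  expect_equal(t1$lrt$chi2, t2$lrt$chi2, tolerance = 1e-4)
  # Wald z^2 approximates the LRT chi-square (n = 2000 trials)
  z <- t1$full$coefficients$z[t1$full$coefficients$term == "x"]
  expect_lt(abs(z^2 - t1$lrt$chi2) / t1$lrt$chi2, 0.15)
})

test_that("age moderation flags only genuine interactions", {
  set.seed(65)
  np <- 40; nt <- 40
  age <- runif(np, 60, 82)
  mk <- function(decline) {
    d <- data.frame(participant_id = rep(seq_len(np), each = nt),
                    x = rnorm(np * nt))
    d$age <- age[d$participant_id]
    slope <- 0.6 - decline * (d$age - 60) / 22
    d$y <- slope * d$x + rnorm(np * nt)
    d
  }
  with_int <- moderationByAge(mk(0.6), "y", "x", family = "linear")
  expect_lt(with_int$lrt$p, 0.05)
  no_int <- moderationByAge(mk(0), "y", "x", family = "linear")
  expect_gt(no_int$lrt$p, 0.001)
  d_const <- mk(0); d_const$age <- 70
  expect_error(moderationByAge(d_const, "y", "x", family = "linear"),
               "zero variance")
})

test_that("mediation recovers its paths and is reproducible from the seed", {
  set.seed(66)
  np <- 30; nt <- 40
  d <- data.frame(participant_id = rep(seq_len(np), each = nt))
  d$h <- rnorm(np * nt)
  d$r <- 0.5 * d$h + sqrt(0.75) * rnorm(np * nt)
  d$success <- rbinom(np * nt, 1, plogis(0.2 + 0.4 * d$h + 0.8 * d$r))
  m <- mediate(d, "h", "r", "success", n_boot = 300, seed = 3,
               engine = "pooled")
  expect_equal(m$a_path, 0.5, tolerance = 0.1)
  expect_equal(m$b_path, 0.8, tolerance = 0.25)
  expect_equal(m$indirect, m$a_path * m$b_path)
  expect_true(m$significant)
  expect_true(m$ci_low <= m$indirect && m$indirect <= m$ci_high)
  m2 <- mediate(d, "h", "r", "success", n_boot = 300, seed = 3,
                engine = "pooled")
  expect_identical(m2$boot, m$boot)

  # severing the b path: interval straddles zero
  d0 <- d
  d0$success <- rbinom(np * nt, 1, plogis(0.2 + 0.4 * d0$h))
  m0 <- mediate(d0, "h", "r", "success", n_boot = 300, seed = 4,
                engine = "pooled")
  expect_false(m0$significant)

  # a pure-noise mediator centres the indirect effect on zero
  ests <- vapply(1:20, function(i) {
    set.seed(200 + i)
    dn <- d
    dn$r <- rnorm(np * nt)
    mediate(dn, "h", "r", "success", n_boot = 50, seed = i,
            engine = "pooled")$indirect
  }, numeric(1))
  expect_lt(abs(mean(ests)), 0.02)
})

test_that("the mixed-model mediation engine agrees with pooled paths when
           participants are exchangeable", {
  set.seed(67)
  np <- 15; nt <- 40
  d <- data.frame(participant_id = rep(seq_len(np), each = nt))
  d$h <- rnorm(np * nt)
  d$r <- 0.5 * d$h + sqrt(0.75) * rnorm(np * nt)
  d$success <- rbinom(np * nt, 1, plogis(0.2 + 0.4 * d$h + 0.8 * d$r))
  mm <- mediate(d, "h", "r", "success", n_boot = 50, seed = 5,
                engine = "mixed")
  mp <- mediate(d, "h", "r", "success", n_boot = 50, seed = 5,
                engine = "pooled")
  expect_equal(mm$a_path, mp$a_path, tolerance = 0.02)
  expect_equal(mm$b_path, mp$b_path, tolerance = 0.05)
})
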