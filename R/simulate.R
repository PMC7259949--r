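## Synthetic associative-memory fMRI studies with exported ground truth.
##
## The generator emulates the study design the analysis stages expect: five
## rounds of alternating encoding (24 word-picture pairs, 12 face / 12 place)
## and retrieval (the 24 studied words plus 6 foils, 4-way response) blocks,
## per-trial voxel patterns built from participant-specific unit-norm
## category templates and event vectors, a latent hippocampal drive h coupled
## to a latent reinstatement strength r, a logistic link from (h, r, ability)
## to associative success, RTs that shorten with reinstatement, a post-scan
## exemplar recall outcome, per-volume QC series, and an age-graded fidelity
## decline. Every latent is exported so downstream estimates can be checked
## against the generative truth.

#' Simulation configuration
#'
#' Returns a validated configuration list for [generateStudy()]. Defaults
#' encode the study conditions the pipeline targets: 100 participants aged
#' 60-82, 5 runs of 24 encoding trials (balanced face/place) and 30 retrieval
#' trials (6 foils), and effect sizes chosen to land cohort behaviour and
#' classifier performance in the empirically realistic regime (old/new d'
#' near 2, associative d' near 1.7, high encoding decodability, retrieval
#' decodability well above chance on associative hits only).
#'
#' @param n_participants cohort size.
#' @param n_runs,n_enc_trials_per_run,n_foils_per_run study design counts.
#' @param n_voxels voxels per ROI.
#' @param rois named numeric vector: ROI names with signal-gain multipliers.
#' @param template_gain,event_gain category- and event-specific signal
#'   amplitudes at encoding (arbitrary BOLD units).
#' @param noise_sd voxel noise SD (>0).
#' @param a_h hippocampus-to-reinstatement coupling in
#'   \eqn{r = a_h h + \sqrt{1-a_h^2}\,\eta}.
#' @param behaviour_weights `c(b0, b_h, b_r)` logistic weights from (1, h, r)
#'   to associative success.
#' @param ability_sd SD of the participant ability intercept.
#' @param cross_error_rate probability that a successful retrieval is
#'   reported as the wrong category (producing associative misses).
#' @param familiarity_params `c(item_hit_given_fail, foil_fa_rate,
#'   foil_assoc_frac)`: Old-response rate after failed retrieval, foil
#'   false-alarm rate, and the fraction of foil FAs that are associative.
#' @param rt_params `c(rt0, kappa, rt_sd)` seconds: baseline RT, reduction
#'   per unit positive reinstatement, residual SD (floored at 0.2 s).
#' @param age_range uniform age range (years).
#' @param age_slope fidelity decline per year past the range minimum;
#'   fidelity = max(0, 1 - age_slope * (age - min age)).
#' @param posttest_weights `c(w0, w_hit, w_r, w_ability)` logistic weights to
#'   post-test exemplar recall.
#' @param hippo_noise_sd measurement noise on the per-trial hippocampal
#'   activity readout of h.
#' @param foil_h_mean mean hippocampal drive on foil trials (baseline below
#'   the studied-trial mean of 0).
#' @param motion_params `c(meanlog, sdlog)` of the lognormal participant
#'   mean-FD distribution (mm).
#' @param encoding_gain_sd lognormal sdlog of the participant encoding gain.
#' @param volumes_per_trial fMRI volumes spanned by one trial (12 s at
#'   TR = 2 s).
#' @param artifact_rate per-volume probability of a motion spike above the
#'   0.5 mm flagging threshold.
#' @param seed master seed; every draw derives from it.
#' @return A `patcomp_sim_config` list.
#' @export
simulationConfig <- function(n_participants = 100,
                             n_runs = 5,
                             n_enc_trials_per_run = 24,
                             n_foils_per_run = 6,
                             n_voxels = 500,
                             rois = c(VTC = 1.0, ANG = 0.8),
                             template_gain = 3,
                             event_gain = 1.5,
                             noise_sd = 1,
                             a_h = 0.4,
                             behaviour_weights = c(b0 = 0.2, b_h = 0.4,
                                                   b_r = 0.8),
                             ability_sd = 0.5,
                             cross_error_rate = 0.08,
                             familiarity_params = c(item_hit_given_fail = 0.5,
                                                    foil_fa_rate = 0.10,
                                                    foil_assoc_frac = 0.5),
                             rt_params = c(rt0 = 1.8, kappa = 0.3,
                                           rt_sd = 0.4),
                             age_range = c(60, 82),
                             age_slope = 0.015,
                             posttest_weights = c(w0 = -2.2, w_hit = 1.5,
                                                  w_r = 0.5, w_ability = 0.8),
                             hippo_noise_sd = 0.5,
                             foil_h_mean = -0.5,
                             motion_params = c(meanlog = -1.6, sdlog = 0.4),
                             encoding_gain_sd = 0.2,
                             volumes_per_trial = 6,
                             artifact_rate = 0.015,
                             seed = 1) {
  cfg <- as.list(environment())
  if (cfg$noise_sd <= 0) stop("config error: noise_sd must be > 0")
  if (cfg$n_voxels < 2) stop("config error: n_voxels must be >= 2")
  if (cfg$n_enc_trials_per_run %% 2 != 0)
    stop("config error: encoding trials per run must be even (balanced)")
  if (abs(cfg$a_h) > 1) stop("config error: |a_h| must be <= 1")
  if (is.null(names(cfg$rois)) || any(!nzchar(names(cfg$rois))))
    stop("config error: rois must be a named gain vector")
  class(cfg) <- "patcomp_sim_config"
  cfg
}

.unit_vec <- function(n) {
  v <- rnorm(n)
  v / sqrt(sum(v^2))
}

.participant_seed <- function(master, i) {
  as.integer((as.numeric(master) * 100003 + 7919 * i) %% 2147483647)
}

#' Generate a complete synthetic study
#'
#' Draws a full multi-participant dataset: trial tables (with responses, RTs,
#' post-test outcomes and per-trial hippocampal activity), encoding and
#' retrieval [PatternMatrix-class] objects per ROI, per-volume QC series,
#' participant covariates, and the generative ground truth. One RNG stream is
#' derived per participant from the master seed, so regeneration from the
#' same `(config, seed)` is bit-identical and participant-level parallelism
#' cannot reorder draws.
#'
#' Generative model, per participant i with age \eqn{a_i \sim U(60, 82)} and
#' fidelity \eqn{f_i = \max(0, 1 - \delta (a_i - 60))}: encoding pattern of
#' trial t in category c is \eqn{g_i (\gamma_T T_c + \gamma_E E_t) + \epsilon}
#' with unit-norm participant-specific templates; trial latents
#' \eqn{h \sim N(0,1)}, \eqn{r = a_h h + \sqrt{1 - a_h^2}\,\eta}; retrieval
#' pattern \eqn{f_i \max(r, 0) (\gamma_T T_c + \gamma_E E_t) + \epsilon'}
#' (failed retrievals carry no signal); associative success is
#' Bernoulli-logistic in (h, r, ability); failures split Old/New by the
#' familiarity parameters, foils produce CR/FAs; RT decreases with positive
#' reinstatement; post-test recall is logistic in (success, r, ability);
#' hippocampal activity is h plus measurement noise.
#'
#' @param config a [simulationConfig()].
#' @param with_patterns generate voxel pattern matrices (default). Latent
#'   level simulation studies (behaviour, mixed models, mediation) can skip
#'   them; trial tables, covariates and ground truth are identical either
#'   way (QC draws follow the pattern draws in each participant stream, so
#'   QC series differ between the two settings).
#' @return list with `trials`, `patterns` (participant -> ROI -> phase ->
#'   `PatternMatrix`; `NULL` when skipped), `qc`, `trial_volumes`,
#'   `covariates`, `truth`, and the echoed `config`.
#' @export
generateStudy <- function(config = simulationConfig(), with_patterns = TRUE) {
  stopifnot(inherits(config, "patcomp_sim_config"))
  n_cat <- config$n_enc_trials_per_run / 2
  parts <- lapply(seq_len(config$n_participants), function(i) {
    pid <- sprintf("sub%03d", i)
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
      globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
      globalenv()), add = TRUE)
    set.seed(.participant_seed(config$seed, i))
    .simulate_participant(pid, config, n_cat, with_patterns)
  })
  trials <- do.call(rbind, lapply(parts, `[[`, "trials"))
  qc <- do.call(rbind, lapply(parts, `[[`, "qc"))
  covariates <- do.call(rbind, lapply(parts, `[[`, "covariates"))
  truth_trial <- do.call(rbind, lapply(parts, function(p) p$truth$trial))
  truth_part <- do.call(rbind, lapply(parts, function(p) p$truth$participant))
  patterns <- if (with_patterns)
    setNames(lapply(parts, `[[`, "patterns"),
             vapply(parts, function(p) p$covariates$participant_id,
                    character(1))) else NULL
  trial_volumes <- do.call(c, lapply(parts, `[[`, "trial_volumes"))
  rownames(trials) <- rownames(qc) <- rownames(covariates) <- NULL
  rownames(truth_trial) <- rownames(truth_part) <- NULL
  list(trials = trials, patterns = patterns, qc = qc,
       trial_volumes = trial_volumes, covariates = covariates,
       truth = list(trial = truth_trial, participant = truth_part,
                    config = config),
       config = config)
}

.simulate_participant <- function(pid, cfg, n_cat,
                                  with_patterns = TRUE) {
  w <- cfg$behaviour_weights; fam <- cfg$familiarity_params
  rtp <- cfg$rt_params; pw <- cfg$posttest_weights
  age <- runif(1, cfg$age_range[1], cfg$age_range[2])
  sex <- sample(c("F", "M"), 1, prob = c(0.61, 0.39))
  education <- sample(12:20, 1)
  ability <- rnorm(1, 0, cfg$ability_sd)
  enc_gain <- rlnorm(1, 0, cfg$encoding_gain_sd)
  mean_fd <- rlnorm(1, cfg$motion_params[1], cfg$motion_params[2])
  fidelity <- max(0, 1 - cfg$age_slope * (age - cfg$age_range[1]))
  # delayed-recall subtests share variance with ability
  ab_z <- if (cfg$ability_sd > 0) ability / cfg$ability_sd else 0
  dr <- function(mu, s) mu + s * (0.5 * ab_z + sqrt(0.75) * rnorm(1))
  n_events <- cfg$n_runs * cfg$n_enc_trials_per_run
  n_foils <- cfg$n_runs * cfg$n_foils_per_run

  # study list: event categories balanced within run, order shuffled
  ev <- do.call(rbind, lapply(seq_len(cfg$n_runs), function(run) {
    cats <- sample(rep(c("face", "place"), n_cat))
    data.frame(run = run, enc_index = seq_along(cats), category = cats,
               stringsAsFactors = FALSE)
  }))
  ev$event <- seq_len(n_events)
  ev$word <- sprintf("word_%s_%03d", pid, ev$event)

  # trial latents and behaviour for studied events
  h <- rnorm(n_events)
  eta <- rnorm(n_events)
  r <- cfg$a_h * h + sqrt(1 - cfg$a_h^2) * eta
  success <- rbinom(n_events, 1, plogis(w[1] + w[2] * h + w[3] * r + ability))
  cross_err <- rbinom(n_events, 1, cfg$cross_error_rate)
  other <- ifelse(ev$category == "face", "Place", "Face")
  correct <- ifelse(ev$category == "face", "Face", "Place")
  resp <- ifelse(success == 1, ifelse(cross_err == 1, other, correct),
                 ifelse(rbinom(n_events, 1, fam[1]) == 1, "Old", "New"))
  assoc_hit <- as.integer(resp == correct)
  rt_st <- pmax(0.2, rtp[1] - rtp[2] * pmax(r, 0) + rnorm(n_events, 0, rtp[3]))
  posttest <- rbinom(n_events, 1,
                     plogis(pw[1] + pw[2] * assoc_hit + pw[3] * r +
                            pw[4] * ability)) == 1
  hippo_st <- h + rnorm(n_events, 0, cfg$hippo_noise_sd)

  # foils
  h_f <- rnorm(n_foils, cfg$foil_h_mean, 1)
  fa <- rbinom(n_foils, 1, fam[2])
  fa_assoc <- rbinom(n_foils, 1, fam[3])
  resp_f <- ifelse(fa == 1,
                   ifelse(fa_assoc == 1,
                          ifelse(rbinom(n_foils, 1, 0.5) == 1, "Face",
                                 "Place"), "Old"), "New")
  rt_f <- pmax(0.2, rtp[1] + rnorm(n_foils, 0, rtp[3]))
  hippo_f <- h_f + rnorm(n_foils, 0, cfg$hippo_noise_sd)

  # assemble trial rows
  enc <- data.frame(participant_id = pid, run = ev$run,
                    trial_index = ev$enc_index, phase = "encoding",
                    word = ev$word, category = ev$category, is_foil = FALSE,
                    response = "none", rt = NA_real_, artifact = FALSE,
                    posttest_correct = NA, condition = "unclassified",
                    hippo_activity = NA_real_, event = ev$event,
                    stringsAsFactors = FALSE)
  enc$trial_id <- makeTrialIds(enc)
  ret_list <- lapply(seq_len(cfg$n_runs), function(run) {
    st <- which(ev$run == run)
    fo <- seq_len(cfg$n_foils_per_run) + (run - 1) * cfg$n_foils_per_run
    d <- data.frame(
      word = c(ev$word[st], sprintf("foil_%s_%03d", pid, fo)),
      category = c(ev$category[st], rep("none", length(fo))),
      is_foil = c(rep(FALSE, length(st)), rep(TRUE, length(fo))),
      response = c(resp[st], resp_f[fo]),
      rt = c(rt_st[st], rt_f[fo]),
      posttest_correct = c(posttest[st], rep(NA, length(fo))),
      hippo_activity = c(hippo_st[st], hippo_f[fo]),
      event = c(ev$event[st], rep(NA_integer_, length(fo))),
      h_lat = c(h[st], h_f[fo]),
      r_lat = c(r[st], rep(NA_real_, length(fo))),
      recollected = c(success[st] == 1, rep(NA, length(fo))),
      stringsAsFactors = FALSE)
    d <- d[sample(nrow(d)), , drop = FALSE]
    cbind(data.frame(participant_id = pid, run = run,
                     trial_index = seq_len(nrow(d)), phase = "retrieval",
                     stringsAsFactors = FALSE),
          d[, c("word", "category", "is_foil", "response")],
          rt = d$rt, artifact = FALSE, posttest_correct = d$posttest_correct,
          condition = "unclassified", hippo_activity = d$hippo_activity,
          event = d$event, h_lat = d$h_lat, r_lat = d$r_lat,
          recollected = d$recollected)
  })
  retfull <- do.call(rbind, ret_list)
  retfull$trial_id <- makeTrialIds(retfull)
  latent_cols <- c("h_lat", "r_lat", "recollected")
  trials <- rbind(enc[, setdiff(colnames(enc), "trial_id")],
                  retfull[, setdiff(colnames(retfull),
                                    c(latent_cols, "trial_id"))])
  trials$trial_id <- makeTrialIds(trials)

  # voxel patterns per ROI; cross-category errors are reports made without
  # category information, so their patterns carry no reinstatement signal
  # (keeps associative misses at chance decodability)
  ret <- trials[trials$phase == "retrieval", , drop = FALSE]
  sig_ret <- fidelity * pmax(r, 0) * ifelse(success == 1 & cross_err == 1,
                                            0, 1)   # indexed by event
  patterns <- if (!with_patterns) NULL else lapply(cfg$rois, function(gain) {
    Tf <- .unit_vec(cfg$n_voxels); Tp <- .unit_vec(cfg$n_voxels)
    E <- vapply(seq_len(n_events), function(e) .unit_vec(cfg$n_voxels),
                numeric(cfg$n_voxels))
    base <- function(cat, e)
      gain * (cfg$template_gain * (if (cat == "face") Tf else Tp) +
              cfg$event_gain * E[, e])
    enc_m <- t(vapply(seq_len(n_events), function(e)
      enc_gain * base(ev$category[e], e) + rnorm(cfg$n_voxels, 0,
                                                 cfg$noise_sd),
      numeric(cfg$n_voxels)))
    ret_m <- t(vapply(seq_len(nrow(ret)), function(k) {
      e <- ret$event[k]
      mu <- if (is.na(e)) 0 else sig_ret[e] * base(ret$category[k], e)
      mu + rnorm(cfg$n_voxels, 0, cfg$noise_sd)
    }, numeric(cfg$n_voxels)))
    list(
      encoding = patternMatrix(enc_m, run_labels = enc$run,
                               trial_ids = enc$trial_id,
                               roi = "roi", phase = "encoding"),
      retrieval = patternMatrix(ret_m, run_labels = ret$run,
                                trial_ids = ret$trial_id,
                                roi = "roi", phase = "retrieval"))
  })
  if (with_patterns) for (rn in names(patterns)) {
    patterns[[rn]]$encoding@roi <- rn
    patterns[[rn]]$retrieval@roi <- rn
  }

  # QC series and trial-to-volume map, one block per phase x run
  qc_list <- list(); trial_volumes <- list(); offset <- 0L
  for (ph in .PHASES) {
    for (run in seq_len(cfg$n_runs)) {
      tr <- trials[trials$phase == ph & trials$run == run, , drop = FALSE]
      tr <- tr[order(tr$trial_index), , drop = FALSE]
      nv <- nrow(tr) * cfg$volumes_per_trial
      fd <- rlnorm(nv, log(mean_fd), 0.35)
      spike <- rbinom(nv, 1, cfg$artifact_rate) == 1
      fd[spike] <- 0.5 + stats::rexp(sum(spike), 3)
      qc_list[[length(qc_list) + 1L]] <- data.frame(
        participant_id = pid, phase = ph, run = run, volume = seq_len(nv),
        framewise_displacement = fd,
        global_intensity = rnorm(nv, 1000, 10), stringsAsFactors = FALSE)
      for (k in seq_len(nrow(tr)))
        trial_volumes[[tr$trial_id[k]]] <-
          offset + ((k - 1L) * cfg$volumes_per_trial + 1L):
                   (k * cfg$volumes_per_trial)
      offset <- offset + nv
    }
  }

  covariates <- data.frame(
    participant_id = pid, age = age, sex = sex, education = education,
    mean_fd = mean_fd,
    lm_delayed = dr(32, 6), hvlt_delayed = dr(10.5, 1.7),
    bvmt_delayed = dr(9.8, 2.2), stringsAsFactors = FALSE)

  truth_trial <- data.frame(
    trial_id = retfull$trial_id, participant_id = pid,
    h = retfull$h_lat, r = retfull$r_lat,
    recollected = retfull$recollected, stringsAsFactors = FALSE)

  list(trials = trials, patterns = patterns,
       qc = do.call(rbind, qc_list), trial_volumes = trial_volumes,
       covariates = covariates,
       truth = list(trial = truth_trial,
                    participant = data.frame(
                      participant_id = pid, age = age, ability = ability,
                      fidelity = fidelity, encoding_gain = enc_gain,
                      stringsAsFactors = FALSE)))
}

#' Reference effect sizes implied by the generative configuration
#'
#' Returns the generative parameters in the estimand parameterization the
#' trial-wise models target: the a-path (slope of reinstatement strength r on
#' hippocampal drive h, equal to the coupling a_h because h has unit
#' variance), the b-path (the logistic slope of associative success on r
#' controlling h), and the full logistic behaviour slopes. These are
#' functions of the configuration alone and independent of the seed.
#'
#' @param truth the `truth` element of a [generateStudy()] result (or a
#'   `patcomp_sim_config`).
#' @return list with `a_path`, `b_path`, `indirect`, `logistic_slopes`.
#' @export
truthRegressionOracle <- function(truth) {
  cfg <- if (inherits(truth, "patcomp_sim_config")) truth else truth$config
  w <- cfg$behaviour_weights
  list(a_path = cfg$a_h, b_path = unname(w[3]),
       indirect = cfg$a_h * unname(w[3]),
       logistic_slopes = c(intercept = unname(w[1]), h = unname(w[2]),
                           r = unname(w[3])))
}
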