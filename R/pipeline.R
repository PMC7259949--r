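## End-to-end orchestration of the analysis stages on a study object (as
## returned by generateStudy(), or assembled from files with the readers).

#' Run classification and similarity stages for every participant and ROI
#'
#' Applies, per participant and ROI: within-run scaling, leave-one-run-out
#' encoding classification, train-encoding/test-retrieval reinstatement
#' evidence, and encoding-retrieval similarity. Conditions are classified
#' first if needed.
#'
#' @param study list with `trials` and `patterns` (participant -> ROI ->
#'   phase), as from [generateStudy()].
#' @param spec a [classifierSpec()].
#' @param rois ROI subset (default: all present).
#' @param compute_ers also run the ERS stage (default TRUE).
#' @return list: `trials` (classified), `evidence` (ROI -> `data.frame`
#'   across participants), `encoding` (ROI -> per-participant accuracy /
#'   strength table), `ers` (ROI -> `data.frame`).
#' @export
analyzeStudy <- function(study, spec = classifierSpec(), rois = NULL,
                         compute_ers = TRUE) {
  trials <- classifyResponses(study$trials)
  pids <- names(study$patterns)
  if (is.null(rois)) rois <- names(study$patterns[[1]])
  evidence <- list(); encoding <- list(); ers <- list()
  for (roi in rois) {
    ev_list <- list(); enc_list <- list(); ers_list <- list()
    for (pid in pids) {
      ptr <- trials[trials$participant_id == pid, , drop = FALSE]
      enc_pm <- study$patterns[[pid]][[roi]]$encoding
      ret_pm <- study$patterns[[pid]][[roi]]$retrieval
      keep_enc <- !ptr$artifact[match(trialIds(enc_pm), ptr$trial_id)]
      keep_ret <- !ptr$artifact[match(trialIds(ret_pm), ptr$trial_id)]
      enc_pm <- enc_pm[, keep_enc]
      ret_pm <- ret_pm[, keep_ret]
      enc_labels <- ptr$category[match(trialIds(enc_pm), ptr$trial_id)]
      ret_cat <- ptr$category[match(trialIds(ret_pm), ptr$trial_id)]
      cv <- encodingCVAccuracy(enc_pm, enc_labels, spec)
      enc_list[[pid]] <- data.frame(participant_id = pid,
                                    mean_accuracy = cv$mean_accuracy,
                                    mean_logit = cv$mean_logit,
                                    stringsAsFactors = FALSE)
      ev <- suppressMessages(
        retrievalEvidence(enc_pm, enc_labels, ret_pm, ret_cat, spec))
      ev$participant_id <- pid
      ev_list[[pid]] <- ev
      if (compute_ers) {
        er <- suppressMessages(computeERS(enc_pm, ret_pm, ptr))
        er$participant_id <- pid
        ers_list[[pid]] <- er
      }
    }
    evidence[[roi]] <- do.call(rbind, ev_list)
    encoding[[roi]] <- do.call(rbind, enc_list)
    if (compute_ers) ers[[roi]] <- do.call(rbind, ers_list)
    rownames(evidence[[roi]]) <- rownames(encoding[[roi]]) <- NULL
    if (compute_ers) rownames(ers[[roi]]) <- NULL
  }
  list(trials = trials, evidence = evidence, encoding = encoding,
       ers = if (compute_ers) ers else NULL)
}

#' Assemble the trial-level modelling table
#'
#' Merges behavioural outcomes with the neural evidence of one ROI for the
#' studied retrieval trials (artifact-free, false alarms excluded), applies
#' the within-participant z-scoring of continuous trial-level variables and
#' across-participant z-scoring of participant-level variables (age,
#' encoding strength), and adds the binary associative-hit and post-test
#' outcomes.
#'
#' @param analysis result of [analyzeStudy()].
#' @param covariates per-participant covariate `data.frame` with `age`.
#' @param roi which ROI's evidence/ERS to merge.
#' @param trial_filter `"all_studied"` (default), `"associative_hits_only"`,
#'   or `"excl_item_miss"`.
#' @return trial-level `data.frame` ready for [fitMixedModel()]: z-scored
#'   `logit`, `hippo_activity`, `rt`, `within_event_z`, `within_category_z`,
#'   `roi_mean_activity`, `selected_voxel_activity`, plus `assoc_hit`,
#'   `posttest`, `category`, `age`, `encoding_strength`.
#' @export
buildTrialData <- function(analysis, covariates, roi,
                           trial_filter = c("all_studied",
                                            "associative_hits_only",
                                            "excl_item_miss")) {
  trial_filter <- match.arg(trial_filter)
  trials <- analysis$trials
  ret <- trials[trials$phase == "retrieval" & !trials$artifact &
                !trials$is_foil &
                trials$condition %in% c("associative_hit", "associative_miss",
                                        "item_hit", "item_miss"), ,
                drop = FALSE]
  ev <- analysis$evidence[[roi]]
  d <- merge(ret, ev[, c("trial_id", "logit", "selected_voxel_activity")],
             by = "trial_id")
  if (!is.null(analysis$ers)) {
    er <- analysis$ers[[roi]]
    d <- merge(d, er[, c("trial_id", "within_event_z", "within_category_z",
                         "between_category_z", "roi_mean_activity")],
               by = "trial_id", all.x = TRUE)
  }
  d$assoc_hit <- as.integer(d$condition == "associative_hit")
  d$posttest <- as.integer(d$posttest_correct)
  if (trial_filter == "associative_hits_only")
    d <- d[d$assoc_hit == 1, , drop = FALSE]
  if (trial_filter == "excl_item_miss")
    d <- d[d$condition != "item_miss", , drop = FALSE]
  # trial-level continuous variables: z within participant
  for (v in intersect(c("logit", "hippo_activity", "rt",
                        "selected_voxel_activity", "within_event_z",
                        "within_category_z", "roi_mean_activity"),
                      colnames(d)))
    d[[v]] <- zscoreWithinParticipant(d[[v]], d$participant_id)
  # participant-level variables: z across participants
  enc <- analysis$encoding[[roi]]
  d$encoding_strength <- enc$mean_logit[match(d$participant_id,
                                              enc$participant_id)]
  d$age <- covariates$age[match(d$participant_id,
                                covariates$participant_id)]
  pz <- function(x) {
    pm <- tapply(x, d$participant_id, mean)
    (x - mean(pm)) / sd(pm)
  }
  d$encoding_strength <- pz(d$encoding_strength)
  d$age <- pz(d$age)
  d
}

#' Build the participant-level individual-differences table
#'
#' Joins behavioural summaries, neural aggregates, covariates and the
#' delayed-recall composite, then applies the nuisance adjustments used by
#' the cross-participant models: every neural measure is adjusted by head
#' motion (mean framewise displacement), and reinstatement measures are
#' further adjusted by the matching ROI's encoding classifier strength.
#'
#' @param analysis result of [analyzeStudy()].
#' @param covariates per-participant covariates (age, sex, mean_fd, the
#'   three delayed-recall subtests when available).
#' @return per-participant `data.frame` with raw and `_adj` measures.
#' @export
buildParticipantData <- function(analysis, covariates) {
  beh <- summarizeBehaviour(analysis$trials)
  neur <- summarizeNeural(analysis$trials, analysis$evidence,
                          ers = analysis$ers, encoding = analysis$encoding)
  d <- merge(beh, neur, by = "participant_id")
  d <- merge(d, covariates, by = "participant_id")
  if (all(c("lm_delayed", "hvlt_delayed", "bvmt_delayed") %in% colnames(d)))
    d$delayed_recall <- delayedRecallComposite(
      as.numeric(scale(d$lm_delayed)), as.numeric(scale(d$hvlt_delayed)),
      as.numeric(scale(d$bvmt_delayed)))
  rois <- sub("^mean_logit_", "",
              grep("^mean_logit_", colnames(d), value = TRUE))
  d$hippo_activity_adj <- adjustByNuisance(d$hippo_activity, d$mean_fd)
  for (roi in rois) {
    ml <- paste0("mean_logit_", roi)
    es <- paste0("encoding_strength_", roi)
    nuis <- if (es %in% colnames(d)) d[, c("mean_fd", es)] else d["mean_fd"]
    d[[paste0(ml, "_adj")]] <- adjustByNuisance(d[[ml]], nuis)
    ee <- paste0("event_ers_", roi)
    if (ee %in% colnames(d))
      d[[paste0(ee, "_adj")]] <- adjustByNuisance(d[[ee]], d["mean_fd"])
  }
  if ("sex" %in% colnames(d)) d$sex_male <- as.integer(d$sex == "M")
  d
}
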