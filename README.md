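# patcomp

Trial-wise and individual-differences analysis of **hippocampal pattern
completion** during associative cued recall with fMRI.

Episodic retrieval is hypothesized to begin with hippocampal pattern
completion — a partial cue reactivates a stored trace, driving *cortical
reinstatement* of the activity patterns present at encoding. `patcomp` turns
trial-level activity patterns, behavioural responses and QC series into the
standard quantitative assays of this process, for researchers studying
episodic memory and its variability (for example across healthy aging
cohorts):

* **Category-level reinstatement** — L2-logistic multivoxel classification
  (within-run scaling, per-category top-k feature selection, balanced
  subsampling, leave-one-run-out encoding cross-validation,
  train-encoding/test-retrieval), yielding per-trial signed log-odds
  evidence `logit p/(1-p)` for the correct associate category, with
  permutation-based significance.
* **Event-level reinstatement** — encoding-retrieval similarity (Pearson,
  Fisher-z before averaging) in within-event, within-category
  (diagonal-removed) and between-category cells, matched on retrieval
  success.
* **Behavioural scoring** — the six-condition memory taxonomy, signal
  detection indices `d' = Phi^-1(hit rate) - Phi^-1(FA rate)` with 1/(2N)
  boundary correction, post-test exemplar scoring, delayed-recall
  composite.
* **Trial-wise inference** — linear/logistic mixed models with participant
  random intercepts and uncorrelated random slopes, likelihood-ratio tests,
  age moderation, and cluster-bootstrap mediation of the indirect effect
  a x b (hippocampal activity -> reinstatement -> associative success).
* **Individual differences** — per-participant neural aggregates, motion
  and encoding-strength adjustment by residualization, standardized age
  models, and hierarchical regression with model-comparison F tests.
* **Synthetic studies** — `generateStudy()` simulates the full design
  (5 runs x 24 balanced encoding trials + 30 retrieval trials with 6
  foils, ages 60-82, age-graded pattern fidelity) with exported ground
  truth, so every estimator has a parameter-recovery test bed.

## Worked example

```r
library(patcomp)

cfg   <- simulationConfig(n_participants = 12, n_voxels = 120,
                          rois = c(VTC = 1, ANG = 0.8), seed = 7)
study <- generateStudy(cfg)
an    <- analyzeStudy(study, classifierSpec(n_features_per_category = 30,
                                            n_subsamples = 5))

beh <- summarizeBehaviour(an$trials)
mean(beh$oldnew_dprime)        # 2.27
mean(beh$associative_dprime)   # 1.82
mean(an$encoding$VTC$mean_accuracy)  # 0.925 encoding decodability

d  <- buildTrialData(an, study$covariates, "VTC")
tf <- testFixedEffect(d, "assoc_hit", "hippo_activity",
                      buildNuisanceSet("hippo_iv"), family = "logistic")
tf$lrt
#> chi2(1) = 20.196, p = 6.989e-06

mediate(d, treatment = "hippo_activity", mediator = "logit",
        outcome = "assoc_hit",
        nuisance_mediator = buildNuisanceSet("logit_dv"),
        nuisance_outcome = c("category", "age", "encoding_strength"),
        n_boot = 1000, seed = 11, engine = "pooled")
#> Mediation: a = 0.1299, b = 0.3630, indirect a*b = 0.0472
#> 95% bootstrap CI [0.0200, 0.0858] (1000 resamples) *
```

Reading the output: the behavioural indices say the simulated cohort
discriminates old from new words well (d' ~ 2.3) and recovers the associate
category above chance (d' ~ 1.8). The likelihood-ratio chi-square says
trial-wise hippocampal activity predicts associative success after
controlling category and age. The mediation line decomposes that effect: a
is the hippocampus -> reinstatement path, b the reinstatement -> success
path, and their product (CI excluding zero, starred) is the part of the
hippocampal effect carried through cortical reinstatement.

Retrieval-phase classification on this run is ~70% correct on associative
hits and near chance on associative misses — the qualitative signature of
reinstatement appearing only when associative retrieval succeeds.

## Scripted use

A thin CLI over the package functions lives at
`inst/scripts/patcomp-cli.R`:

```sh
Rscript inst/scripts/patcomp-cli.R simulate  --out study/ --seed 1 --participants 20
Rscript inst/scripts/patcomp-cli.R behaviour --in study/trials.tsv --out summary.tsv
Rscript inst/scripts/patcomp-cli.R qc        --in study/qc.tsv --out flags.tsv
```

Formats are plain TSV throughout (trial tables, covariates, QC series, and
full-precision pattern matrices that round-trip exactly); ground truth is
JSON. See the methods vignette
(`vignettes/pattern-completion-methods.Rmd`) for the statistical model, the
generator's assumptions, parameter defaults and design decisions.
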