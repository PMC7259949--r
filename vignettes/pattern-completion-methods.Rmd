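---
title: "Measuring hippocampal pattern completion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hippocampal pattern completion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patcomp)
```

# The scientific problem

Episodic retrieval is thought to begin with hippocampal *pattern
completion*: a partial cue (here, a studied word) reactivates a stored
memory trace, which drives *cortical reinstatement* — re-emergence of the
activity patterns that were present when the association (a famous face or
place paired with the word) was encoded. `patcomp` quantifies both sides of
this process from trial-level fMRI activity patterns and relates them to
behaviour, within participants (trial-wise mixed models, mediation) and
across participants (nuisance-adjusted regressions, hierarchical model
comparison).

The package assumes the associative cued-recall design it was built around:
five runs, each with 24 encoding trials (12 word-face, 12 word-place)
followed by a retrieval block probing those 24 words plus 6 novel foils with
a four-way response (Face / Place / Old / New), a post-scan test of
exemplar-specific recall, and a separate neuropsychological session
providing a delayed-recall composite.

# Quality control

Volumes are flagged when framewise displacement exceeds 0.5 mm or global
intensity deviates from the run mean by more than five run SDs; runs are
dropped when more than 25% of volumes are flagged or FD ever exceeds 2 mm.
All inequalities are strict ("exceeds"), so a run flagged on exactly a
quarter of its volumes is retained. Any trial overlapping a flagged volume,
or living in a dropped run, is excluded from all neural analyses.
Behavioural rates are computed on all trials by default
(`summarizeBehaviour(..., exclude_artifacts = FALSE)`), since button presses
are valid even when the concurrent image is not; the alternative is a flag.

# Behavioural scoring

Retrieval responses map deterministically onto six memory conditions
(associative hit/miss, item hit/miss, item and associative false alarms,
correct rejection). Two discrimination indices summarize performance:

* old/new d' = Phi^-1(P(Face, Place or Old | studied)) -
  Phi^-1(P(Face, Place or Old | foil))
* associative d' = Phi^-1(P(correct category | studied)) -
  Phi^-1(P(Face or Place | foil))

Perfect rates are replaced by 1/(2N) (or 1 - 1/(2N)) before the inverse
normal CDF. With 120 targets and 30 foils this bounds old/new d' at 4.77,
which is why that convention — rather than adding 0.5 to every cell — is the
package default. Post-test responses are scored as exemplar-correct when the
normalized response (lowercase, punctuation and diacritics stripped,
whitespace collapsed) contains the target name; everything else is routed to
a review file for human rating, which is out of scope here.

# Category-level reinstatement (classification)

Within each run, every voxel is scaled to zero mean and unit variance using
the sample (n-1) SD — the convention is stated so that tests can be exact.
Feature selection ranks voxels by a two-sample t contrast of face vs place
encoding trials and keeps the top `n_features_per_category` (default 250) in
each direction. Training subsamples to equal face/place counts,
`n_subsamples` (default 10) times; the predicted probabilities of the
subsample fits are averaged *on the probability scale* and only then
log-odds transformed, which keeps the pooled value inside (0, 1) before the
transform. Probabilities are clipped to [1e-6, 1 - 1e-6] so evidence is
finite. A trial counts as correctly classified only when the probability of
its true category strictly exceeds 0.5; an exact tie counts as incorrect
(conservative, and essentially measure-zero with continuous probabilities).

The classifier itself is L2-penalized logistic regression with inverse
regularization C = 1, fitted by `glmnet` at the single equivalent penalty
`lambda = 1/(C * n)` with `standardize = FALSE` (the data are already
scaled).

Two deployments:

* **Encoding decodability** — leave-one-run-out cross-validation on encoding
  data. Feature selection is recomputed inside each training fold by default
  to avoid selection leakage; a `selection_scope = "subject"` flag reproduces
  the single subject-level selection some pipelines use.
* **Retrieval reinstatement evidence** — train on all encoding data, test on
  all retrieval data. Evidence is *signed toward the correct associate*:
  positive log-odds always mean correct-category reinstatement, whether the
  associate was a face or a place. Foils have no correct category and are
  excluded.

Significance uses permutation: training labels are shuffled (test labels
fixed, a null of no learnable association), the full pipeline — including
feature selection, by default — is re-run per shuffle, and p is the fraction
of permuted accuracies meeting or exceeding the observed one, computed per
subsample iteration and averaged. `n_permutations` below 100 triggers an
instability warning.

# Event-level reinstatement (ERS)

Encoding-retrieval similarity correlates each retrieval trial's full-ROI
pattern (no feature selection) with encoding patterns, Fisher-transforms
every correlation (clipped at |r| = 1 - 1e-7) *before* any averaging, and
fills three cells per trial: within-event (the trial's own pair),
within-category (other same-category events, the same-event pair removed so
event-level similarity cannot leak into the category estimate), and
between-category. Comparison events are matched on associative retrieval
success, binarized as {associative hit} vs {associative miss, item hit, item
miss}. Cross-run pairs are allowed by default (`exclude_same_run = TRUE`
guards against run-level similarity inflation when wanted), and within-run
scaling is applied first by default, mirroring the classifier preprocessing
(`scale = FALSE` gives raw-pattern ERS; both orders are supported because
the right choice depends on the preprocessing already applied upstream).

# Trial-wise inference

Continuous trial-level variables are z-scored within participant;
participant-level variables (age, encoding classifier strength) are z-scored
across participants, since a within-participant z of a constant is
undefined. Models are linear or logistic mixed-effects fits with a
participant random intercept and an *uncorrelated* random slope of the
predictor of interest (fitted as separate terms, fixing the
intercept-slope correlation at zero to aid convergence). Linear models are
fitted by maximum likelihood so nested log-likelihoods are comparable.
Focal effects are tested by likelihood ratio (the reduced model drops the
fixed effect but keeps the random slope, so only the fixed effect is
tested); Wald z = estimate/SE is reported per coefficient. A singular
random-slope fit is refitted without the slope and flagged.

The nuisance scheme is encoded in `buildNuisanceSet()`: every model controls
stimulus category and age; reinstatement-strength models also control ROI
encoding classifier strength, plus selected-voxel univariate activity when
reinstatement is the predictor; ERS-as-predictor models control whole-ROI
activity; event-level ERS models additionally control within-category ERS;
hippocampal-activity models need no ROI terms.

Age moderation crosses the (participant-level, z-scored) age with the
trial-level predictor and LRT-tests the interaction (1 df), with the random
slope kept on the main predictor.

## Mediation

The indirect effect of hippocampal activity on associative success through
cortical reinstatement is a x b: a = treatment coefficient in the linear
mediator model, b = mediator coefficient in the logistic outcome model
controlling the treatment. The confidence interval is a percentile bootstrap
(default 5000 resamples); significance means zero lies outside the 95%
interval. The bootstrap resamples *participants* (whole clusters) with
replacement, preserving within-participant dependence — trial-level
resampling exists behind a flag but ignores clustering. Path models are
mixed models with the primary analyses' random structure by default; a
pooled single-level engine is provided for bootstrap loops, where refitting
thousands of mixed models is wasteful and the pooled a/b estimates agree
with the mixed ones whenever participants are exchangeable (a property the
test suite checks).

# Individual differences

Per participant, the neural aggregates are: hippocampal activity contrast
(mean over associative hits minus mean over correct rejections — correct
rejections are the baseline because they carry no retrieval signal), mean
signed logit over associative hits per ROI, mean event-level ERS contrast
over associative hits per ROI, and encoding classifier strength (mean
cross-validated encoding logit). Aggregates use artifact-free trials only;
participants lacking a cell are missing, not imputed.

Before cross-participant models, each neural measure is residualized on mean
framewise displacement, and reinstatement measures additionally on the
matching ROI's encoding strength, with the grand mean restored
(`adjustByNuisance()`). Regressions z-score all continuous variables across
participants, so coefficients are standardized; with a single predictor the
standardized coefficient equals the Pearson correlation, a property the
tests assert at 1e-10. Hierarchical model comparison reports, per step,
adjusted R-squared and the F ratio
((R2_full - R2_reduced)/dp) / ((1 - R2_full)/(n - p_full - 1)) on the common
complete-case sample. Missing outcomes are dropped listwise (the designed
use case: one participant without post-test data). Two-tailed alpha = 0.05
throughout, with no multiplicity correction — a deliberate
faithful-reproduction choice, stated rather than hidden. Education is not a
default covariate in the recall models (it nulls out in screening); sex is a
covariate in delayed-recall models.

# The synthetic-study generator

`generateStudy()` emulates the study's structure so every stage has a
parameter-recovery test bed. Per participant i: age ~ Uniform(60, 82);
pattern fidelity f_i = max(0, 1 - delta (age_i - 60)) with delta = 0.015/yr
by default (a ~33% fidelity loss across the sampled age range, enough to
produce the robust negative age gradient in reinstatement strength that a
100-participant cohort detects); an ability intercept (SD 0.5); an encoding
gain (lognormal, sdlog 0.2) deliberately independent of age, because
encoding decodability should not decline with age while retrieval
reinstatement does. Category templates and event vectors are unit-norm
random voxel patterns; encoding trials are
`g_i (3 T_c + 1.5 E_t) + N(0, 1)` per voxel, and retrieval trials are
`f_i max(r, 0) (3 T_c + 1.5 E_t) + N(0, 1)`, where the trial latents are
h ~ N(0,1) (hippocampal drive) and r = a_h h + sqrt(1 - a_h^2) eta
(reinstatement strength, coupling a_h = 0.4). Associative success is
Bernoulli-logistic in (h, r, ability) with weights (0.2, 0.4, 0.8); failures
split Old/New 50:50; foils false-alarm at 10%, half associatively. RT is
1.8 s minus 0.3 s per unit positive reinstatement plus N(0, 0.4), floored at
0.2 s. Post-test recall is logistic in (associative hit, r, ability).
Hippocampal "activity" is h plus measurement noise (SD 0.5), with foils
centred at -0.5 so correct rejections sit below studied trials. Mean FD is
lognormal(-1.6, 0.4) (~0.2 mm), and per-volume QC series include rare
(1.5%) motion spikes above the flagging threshold, matching the low
artifact rates typical of a well-behaved cohort. These defaults were chosen
once to land the cohort in the empirically realistic regime — old/new d'
near 2.2, associative d' near 1.8-1.9, exemplar recall near 0.25,
near-ceiling encoding decodability, retrieval decodability around 70% on
associative hits — and are not adjusted per analysis.

Two deliberate modelling choices:

* Reinstatement enters retrieval patterns through max(r, 0): failed
  retrievals carry no category signal, reproducing the qualitative
  signature that classification is at chance when associative retrieval
  fails.
* Cross-category errors (an associative miss after a successful latent
  retrieval, rate 0.08) are emitted as reports made *without* category
  information: their patterns carry no reinstatement signal. The
  alternative — letting them keep the correct-category signal — would make
  associative misses decodable above chance, contradicting the signature
  above. No empirical distribution of miss-trial evidence beyond "chance"
  is available to constrain this further, so it is a documented choice.

What the generator does **not** emulate: volumetric BOLD time series and
hemodynamics (trial patterns are emitted directly), spatial voxel
correlation, run effects or session drift, item-level difficulty (no
crossed random effects), and response-bias heterogeneity. Passing tests
therefore show that the estimators recover the generative quantities under
a clean, correctly specified world; they do not certify behaviour under
model misspecification found in real data.

Ground truth (per-trial h, r, success; per-participant ability, fidelity,
encoding gain) is exported with every dataset, and
`truthRegressionOracle()` returns the generative a-path, b-path and logistic
slopes in the estimand parameterization the trial-wise models target. One
RNG stream is derived per participant from the master seed, so regeneration
is bit-identical and participant order cannot change draws.

# Numerical choices and degenerate inputs

* Probability clipping 1e-6 before log-odds; correlation clipping 1e-7
  before Fisher z.
* Classification ties (p = 0.5) count as incorrect.
* Zero-variance voxels within a run scale to zero with a warning; a
  single-trial run is an error.
* LRT chi-square is floored at zero with a warning when optimizer noise
  makes the full model fit worse.
* Zero within-participant variance yields missing standardized values with
  a warning; fewer than two finite trials is an error.
* Rank-deficient nuisance matrices are an error naming the collinear
  columns; duplicated predictors in a hierarchical step yield delta R2 = 0
  and F = 0 rather than an error.
* Pattern matrices are stored as TSV at full double precision ("%.17g"),
  so a write/read cycle is bit-exact while staying human-inspectable; the
  same readers accept CSV.

# Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data.
The acceptance script simulates the full design (100 participants, 500
voxels, two cortical ROIs) and runs every stage at the default
specification. Statistical calibration checks use deliberately scaled-down
worlds chosen for validity of the property being measured, not for speed
alone: permutation calibration uses 199 permutations across 500 zero-signal
replicates of a 24-train/30-test problem; mediation coverage uses 200
replicates of 25-participant studies (a cluster bootstrap needs enough
clusters to attain nominal coverage) with 250 bootstrap resamples; LRT
size uses 200 replicates of 15 participants x 40 trials; the age-gradient
power check uses eight 100-participant cohorts at a reduced voxel count.

# Known limitations

* The pooled mediation engine ignores cluster-level random effects in the
  *point* models when selected; with substantial participant heterogeneity
  the mixed engine is the right default, at bootstrap cost.
* Logistic mixed models use the Laplace approximation (lme4 default);
  adaptive quadrature is not available with random slopes, and the
  contract is therefore calibration tolerances, not a specific algorithm.
* The permutation null shuffles training labels only; nulls that also
  shuffle test labels answer a different question and are not provided.
* Post-test scoring implements only the automated exact-match arm; the
  human-rater arm is out of scope, and review files exist to support it.
* Hippocampal subfield analyses require no new code: supply subfield
  activity/pattern inputs in place of whole-hippocampus ones.
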