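---
title: "Detecting sub-concussive impact effects in resting EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sub-concussive impact effects in resting EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Repetitive sub-concussive head impacts — for example soccer ball heading — may
alter brain physiology without producing clinical symptoms, and no routine
test exists to detect such changes. One candidate readout is resting-state
EEG: record a player before heading, again 1 h and 24 h after, extract
band-power features, and train a classifier to label a session as *baseline*
or *post-impact*. Because hyperparameter selection optimises over many
models, the selected cross-validated accuracy is optimistically biased; the
package therefore calibrates significance with a shuffled-label randomization
test — the entire model-selection process is re-run on permuted labels, and
the true and null score distributions are compared with Welch's t-test.

`impactEEG` implements that full pipeline — synthetic cohort generation,
preprocessing, Welch band-power features, subject-grouped gradient-boosted
classification with Tree-Parzen search, and randomization inference with
cross-lag transfer and subgroup analyses — as a seeded, testable whole. No
human recordings ship with the package; the cohort simulator is a first-class
module that realises the study's design with configurable ground truth.

## The synthetic cohort generator

The study design is fixed by `cohortConfig()` defaults: 36 subjects, half
assigned (by alternation) to a *kicking* group that exercises before its
baseline session; three sessions per subject (pre, 1 h post, 24 h post);
8 blocks of 2.5 min per session cycling twice through the four crossed
conditions (eyes open/closed × sitting/standing); 32 channels in a 10–10
montage at 512 Hz.

Each block is synthesised in the frequency domain. The target one-sided PSD
per channel is

\[ S(f) = c\,f^{-\beta} \;+\; A_\alpha w_\alpha(\text{ch})\,
  e^{-(f-10)^2/2\sigma_\alpha^2} \;+\; A_\beta w_\beta(\text{ch})\,
  e^{-(f-20)^2/2\sigma_\beta^2}, \]

a 1/f^β broadband floor (β = 1, c = 10 µV²/Hz) plus posterior-weighted alpha
and central beta oscillator bumps; eyes-closed blocks multiply the alpha bump
by 2. A complex-Gaussian spectrum with this expected magnitude is inverted by
FFT, so the expected Welch PSD of the generated block *equals* S(f) exactly —
multiplicative band/channel-group effect factors, per-subject lognormal band
offsets (sd 0.25 on the log scale), per-block broadband jitter (sd 0.05) and
the eyes-closed boost are all realised exactly in expectation. This is what
makes the generator a usable oracle: an injected alpha ×1.5 factor is
recovered as a ×1.5 ratio of mean band powers to Monte-Carlo error.

Artifacts are injected on top with known ground truth: blinks (Poisson,
default 8/min) as 300 ms half-cosine transients with a frontal-polar
topography; horizontal saccades (4/min) as ramped steps with a left/right
antisymmetric lateral-frontal topography; and per block one jump transient
(50–200 ms, 40× the channel SD) at a recorded channel and sample index. The
blink/saccade topographies are the same canonical templates the ICA step
matches against, which is deliberate: it makes ocular rejection testable
against ground truth.

Choices the study leaves open, decided once here: the real effect sizes are
unknown (and unknowable from the published summary statistics), so the
demonstration signature is occipital alpha ×1.5 plus frontal theta ×1.3 at
24 h, with an exercise effect of beta1/beta2 ×1.5 on all channels applied to
any session recorded within 1 h of an exercise bout. Under the design, the
kicking group exercises before *pre* and both groups head the ball before
*post1h*, so exercise cancels in the kicking group's 1 h contrast and
confounds the non-kicking group's — reproducing the study's subgroup logic.
Between-subject variability (sd 0.25 in log power, i.e. ~±28% per band) was
chosen as a realistic middle ground: large enough that classification is a
genuine across-subject generalisation problem, small enough that the
demonstration effects are detectable in a 12-subject cohort.

What the generator does **not** emulate: volume-conduction head modelling,
heartbeat/muscle artifacts, non-stationarity within blocks, electrode pops,
or any biophysical model of impact. Passing tests on this generator show the
*pipeline* behaves correctly under controlled ground truth — not that the
effect sizes resemble real post-impact EEG.

Seeding is counter-based (`deriveSeed()`): the master seed and integer keys
(subject, session, block, stage) are folded through a congruential mix, so
every block has an order-independent sub-seed and a fixed config reproduces a
cohort byte for byte.

## Preprocessing

The chain is fixed: band-pass → average reference → ICA ocular removal →
jump rejection, with every step and parameter recorded in the provenance.

**Band-pass 0.1–50 Hz.** A cascade of linear-phase Hamming-windowed FIR
filters applied with exact delay compensation (zero phase): a short low-pass
(10 Hz transition) followed by a long high-pass (0.1 Hz one-sided
transition, ~16.5 s kernel). The low-pass runs first so the high-pass
kernel's edge transient acts on a band-limited signal; blocks are padded by
even mirror reflection, which preserves the local mean (an odd/point
reflection puts a ~2·x(edge) pedestal under the long kernel and bleeds it
into the block). On blocks shorter than the high-pass kernel the kernel is
truncated with a warning and the low edge widens.

**ICA ocular removal.** FastICA (symmetric decorrelation, logcosh contrast)
with components equal to the post-reference rank (31 of 32). The unmixing
matrix is estimated on a decimated copy (~8000 samples) — topographies and
higher-order statistics are stable under modest downsampling — and sources
are extracted at full rate. Components whose mixing-column topography
correlates (absolutely) at ≥ 0.80 with the canonical vertical or horizontal
eye-movement template are zeroed before back-projection, at most 4 per
block, best matches first. Convergence is judged per component: a
near-Gaussian background subspace rotates freely under symmetric
orthogonalisation and never satisfies a strict global fixed-point criterion,
but the strongly non-Gaussian ocular components stabilise within tens of
iterations. Removal proceeds when every *matched* component's final update
step is < 0.05; otherwise the recording passes through unmodified and is
flagged.

**Jump rejection.** Per channel, the peak-to-trough amplitude in a sliding
0.5 s window (stride 1 sample) is compared to the channel's mean window
amplitude plus 15 standard deviations. The SD defaults to that of the
channel's *samples* (`population = "signal"`): a short transient inflates the
SD of the window-amplitude series it belongs to by far more than the sample
SD, so a threshold based on the window-series SD can sit *above* the very
spike it should catch (for a 200 ms, 50× spike in a 150 s block the
window-series threshold lands at ~57σ against a spike amplitude of ~55σ).
The window-series population remains available as `population = "windows"`.
Flagged windows are expanded to their samples, padded by 0.5 s each side and
unioned over channels; masked samples are *masked, not deleted* — downstream
Welch windows that touch a masked sample are skipped, avoiding splice
leakage. Zero-variance channels flag nothing, with a warning.

## Band-power features

Welch's method with NFFT = 512 (a 1 s window at 512 Hz, 1 Hz bin spacing),
0.5 s overlap, Hann taper (the taper is not dictated by the design; Hann at
50% overlap is the standard pairing). PSDs use the density convention
(µV²/Hz), and band power is the *mean density* over bins whose centres fall
in the half-open band intervals delta [1,4), theta [4,8), alpha [8,13),
beta1 [13,20), beta2 [20,30), gamma [30,50) — half-open so adjacent bands
never double-count a bin; the scaling convention is recorded in the output
metadata. Per session, band powers are averaged (unweighted) over the blocks
of each condition, giving 4 conditions × 32 channels × 6 bands = 768
features per subject-session; conditions with no surviving Welch window are
flagged missing. The feature table is a `SummarizedExperiment` subclass with
one column per subject × lag observation, labelled baseline vs post-impact.

## Classification

Gradient-boosted trees (xgboost) with the fixed settings: 100 estimators,
`gbtree`, `hist` split finding, binary logistic objective, log-loss metric,
gamma = 1, one thread. Cross-validation is 5-fold and *grouped by subject* —
subjects are shuffled by seed and dealt round-robin into folds, so both of a
subject's rows share a fold and scores estimate performance on a new
participant; class balance per fold is automatic (each subject contributes
one row per class). Inside every fold, features are ranked by the two-class
one-way ANOVA F statistic on training rows only and the top k enter the
model; a fold score is the balanced accuracy (with a single-class held-out
fold, possible under shuffled labels, the macro recall reduces to the recall
of the present class, matching common practice).

The search space: max depth U{2..8}, alpha regularisation log-U[1e-15, 1],
lambda log-U[1e-15, 100], row subsampling U[0.1, 1], column subsampling
U[0.2, 1], learning rate log-U[0.01, 1], and the number of selected features
U{10..nFeatures} with the upper bound resolved from the table width at
search start. The default optimiser is a Tree-Parzen estimator implemented
in-package: after prior-only startup trials, observed trials are split into
the top γ = 0.25 and the rest; per parameter, truncated-Gaussian Parzen
mixtures (plus a uniform prior component) model both sides on the
unit-transformed scale, candidates are drawn from the good-side density and
the draw maximising the density ratio is proposed. A random-search fallback
with identical distributions sits behind `strategy = "random"`. Trial i
derives its seed from (search seed, i), so trials are order-independent and
the whole search replays from one integer.

One behaviour of `hist` split finding matters for interpreting scores on
tiny cohorts: candidate cuts sit at training values, so on a strongly
separated two-cluster feature the chosen cut hugs the training positives'
minimum and each held-out positive undershoots it with probability
~1/(n+1) regardless of the cluster separation. With gamma = 1 the ensemble
is essentially a single split, so balanced accuracies on small separable
problems saturate near 1 − 1/(2(n+1)) rather than at 1.

## Randomization inference

`randomizationTest()` reruns the full model search `nSeeds` times with true
labels and `nSeeds` times with labels freshly permuted before each search
(uniformly over all rows; a within-subject swap variant exists for
sensitivity analysis), then compares the two best-score distributions with a
two-tailed Welch t-test (no multiplicity correction, α = 0.05). Shuffled
searches draw fresh sub-seeds rather than reusing the true-label seeds; this
is recorded in the result's config snapshot. Degenerate comparisons are
handled explicitly: identical constant score lists report t = 0, p = 1; zero
spread with unequal means reports a flagged NA.

One property of this comparison deserves emphasis: it is **conditional on the
dataset**. The true-label scores all share one fixed labeling, so the Welch
denominator quantifies seed-to-seed noise only; the cohort-level draw of
"how learnable this particular dataset's true labeling happens to be" enters
with n = 1 and is invisible to the test. In the package's null Monte-Carlo
(100 replicate null feature tables, 10 seeds, 4 trials) the cross-cohort
standard deviation of the true-minus-shuffled score gap is ~2.6× the
within-cohort Welch standard error, and the nominal 5% test rejects on ~47%
of null *cohorts* — while remaining a perfectly sensible description of how
far this dataset's true-label performance sits above its own shuffled-label
distribution relative to seed noise. Interpret p-values accordingly: they
calibrate seed noise given the data, not sampling of new cohorts, and small
gaps near the rejection boundary should not be read as evidence of an effect
in the population of cohorts. (This property is inherited from the published
procedure; the package reports it rather than silently replacing the test.)

`crossLagTransfer()` asks whether the 1 h and 24 h signatures are the same:
for each training lag, each seeded search's winning model is refit under
grouped CV and each fold's model predicts (a) its held-out post-impact rows
at the trained lag and (b) the *other* lag's post-impact rows restricted to
the same held-out subjects — the leakage guard; the same subjects appear at
both lags, so fold-wise restriction is the only leak-free protocol. Only
post-impact rows are scored at the other lag (the baseline rows are shared
between contrasts), so performance is reported as sensitivity, pooled over
folds per seed. `subgroupTest()` restricts the table to one exercise group
and reruns the randomization test with identical seed derivation, so the
`"all"` group reproduces `randomizationTest()` exactly.

## Problem sizes used by the test suite

The packaged checks run at a reduced scale chosen once: 12 subjects (16 for
the subgroup dissociation, so each 8-subject subgroup still supports 5-fold
grouped CV), 10–20 s blocks, 10 searches × 8 trials per condition, and
artifact-free cohorts with spectra computed directly on the simulated signal
for the statistical end-to-end checks (the synthetic background is already
zero-mean and band-limited; preprocessing has its own dedicated checks
against ground-truth artifacts). The suite also measures the rejection rate
over 20 replicate null cohorts against the exact binomial band at α = 0.05 —
a cross-cohort calibration the conditional Welch comparison does not possess
(see the inference section), so that check documents the property rather
than certifying calibration. `scripts/acceptance.R` re-runs the headline
analyses at the same scale from a single command-line seed.

## Known limitations

* Synthetic effect sizes are free parameters, not estimates of the real
  phenomenon; headline numbers from the human study (t ≈ 11, sensitivities
  0.49/0.29) are not reproducible from simulation and are not targeted.
* The generator's Gaussian, block-stationary background makes ICA's job
  easier than real EEG does; template thresholds that work here may need
  retuning on real recordings.
* EDF support covers the subset the package writes (16-bit, uniform rate,
  1 s records), not the full zoo of vendor EDF variants.
* The high-pass edge transient consumes ~8 s at each block edge at full
  scale; block-level features are barely affected, but very short blocks
  trigger kernel truncation and a widened low edge.
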