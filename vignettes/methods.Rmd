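---
title: "Models and methods behind infnirs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind infnirs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infnirs)
```

# Scope

`infnirs` implements a complete analysis chain for infant functional
near-infrared spectroscopy (fNIRS) block designs that contrast synchronous
audiovisual ("bimodal") speech with temporally alternating auditory and
visual ("alternating unimodal") speech: preprocessing with explicit channel,
trial and participant inclusion rules; channel-by-channel planned-contrast
statistics with super-/sub-additivity labelling; across-participant
multivariate decoding with permutation inference; and repeated-measures
power computations.  Because no infant recordings are distributed with the
package, a synthetic-cohort generator with fully known ground truth stands
in for the data; every downstream stage is exercised and calibrated against
it.

# The measurement model

A recording holds raw light intensities for 46 source-detector channels at
two wavelengths (780 and 850 nm), sampled at 10 Hz by default, in a
`NirsRecording` (a `SummarizedExperiment` with channels as rows, time as
columns and one assay per wavelength).  The montage covers frontal to
temporoparietal cortex bilaterally; channels 1-23 are left-hemisphere,
24-46 right.  The inferior frontal (3, 4 left; 24, 26 right) and superior
temporal (5, 15 left; 27, 28, 29, 31 right) region tags are a reconstruction
of the published array diagram: the exact boxed channel sets are not listed
in text anywhere, so the fixture freezes the sets that the reported effects
imply, and they should be treated as reconstructed rather than measured.
Channel adjacency is a simplified within-hemisphere chain; the analyses use
only its symmetry.

Intensity relates to haemoglobin concentration through the modified
Beer-Lambert law.  Optical density is `dOD(t) = -log10(I(t) / mean(I))`,
and per channel and sample the 2x2 linear system

```
dOD_lambda = (eps_HbO,lambda dHbO + eps_HbR,lambda dHbR) * d * DPF
```

is solved for the oxy- and deoxy-haemoglobin concentration changes, with
`d = 2` cm the source-detector separation, a differential pathway factor of
5.1 at both wavelengths, and standard compiled molar extinction
coefficients.  The simulator's forward model is the exact algebraic inverse
of this conversion, which is what makes the round-trip test meaningful: the
package recovers planted concentrations to floating-point precision (the
1e-9 uM tolerance in the tests is generous by five orders of magnitude).

# Preprocessing and the inclusion rules

Stages run in a fixed order: intensity pruning, optical density, motion
detection and correction, exclusion bookkeeping, band-pass filtering,
Beer-Lambert conversion, epoching, window means.  A guard test asserts that
swapping filtering ahead of motion correction changes the output on
artifact-bearing data, so the order is load-bearing, not cosmetic.

* **Pruning.** A channel is unusable when its mean raw intensity at either
  wavelength leaves `[0.001, 10]` (raw units; the bounds are applied to the
  channel-mean intensity).
* **Motion detection.** A sliding 1-s window flags stretches whose
  peak-to-peak amplitude exceeds 0.4 OD or whose standard deviation exceeds
  15x the series' median rolling SD; flags are padded by 1 s.  The
  published description fixes only the wavelet outlier factor, so the
  detection parameters are conventional defaults and are config-exposed.
* **Wavelet correction.** A periodic Daubechies-2 decomposition of each
  series (depth limited by sample-count divisibility, capped at 8 levels);
  detail coefficients farther than 0.8 interquartile ranges from their
  level median are zeroed.  No wavelet package is available in the target
  environment, so the transform is implemented in compiled code and checked
  against a pure-R reference and for perfect reconstruction.
* **Spline correction.** Within detected segments the series is replaced by
  its smoothing-spline detrended residual and re-levelled at the segment
  boundaries, which removes baseline steps.  Wavelet and spline stages are
  applied sequentially (wavelet globally, spline within detected segments).
* **Filtering.** A third-order Butterworth band-pass (0.03-0.50 Hz) applied
  as a zero-phase forward-backward cascade, realised by multiplying the
  spectrum with the filter's squared magnitude response under odd-symmetric
  reflection padding.  Gains are verified against oracle sinusoids
  (>= 0.9 at 0.12 Hz, <= 0.1 at 0.005 and 2 Hz).
* **Epoching.** 25-s epochs, -5 to +20 s around stimulation onsets,
  half-open windows; analysis windows are baseline (-5-0 s), W1 (5-10 s)
  and W2 (10-15 s).  The baseline window is a level of the time factor; no
  baseline subtraction is applied.
* **Inclusion rules.** A channel is excluded when artifacts intersect the
  guard-extended windows of more than 3 trials.  A trial is rejected when
  an artifact on any remaining usable channel intersects
  `[onset - 5 s, onset + 20 s]` (trial rejection is global, matching how
  stimulus blocks are discarded in practice; per-channel flags are kept for
  audit), when the infant looked at the screen less than 40% of the trial
  (ties at exactly 0.40 are kept), or when its epoch runs past the
  recording.  A participant is included iff at least 31 of 46 channels
  remain usable (exactly 31 passes) and at least 3 trials per condition
  survive.

# Channel-wise statistics

For each channel, chromophore and activation window, the per-participant
contrast score

```
d_i = (mean_window - mean_baseline)_bimodal - (mean_window - mean_baseline)_alternating
```

is tested against zero as a 1-df contrast F (the squared paired t), with
error df `n - 1` from the channel's complete cases — participants lacking a
channel are dropped for that channel only, which is why error dfs vary
across channels.  With both age groups, age enters as a between factor and
the age x contrast interaction is reported on `N - 2` df.  Partial eta
squared is computed as `F df1 / (F df1 + df2)`; the test suite verifies
this against the sum-of-squares computation on the same fit.  No
sphericity correction applies to 1-df contrasts (they are exact).

Post-hoc direction is the paired comparison of the two conditions' window
means; the direction is always recorded, and a zero-variance epsilon guard
keeps degenerate constructions finite.  False-discovery-rate control is
Benjamini-Hochberg step-up within each chromophore x window x age-group
family (all 46 channels); both uncorrected and corrected flags are carried.

A significant condition difference is interpreted through the chromophore:
a larger HbO increase to the bimodal condition is consistent with a
super-additive multisensory response and a larger HbO increase to the
alternating condition with a sub-additive one; for HbR the mapping inverts
(a larger HbR increase to bimodal is sub-additive, to alternating
super-additive).  Non-significant contrasts are labelled `none`.

# Across-participant decoding

One pattern per participant and condition (a single chromophore and
window), z-scored within channel across all patterns.  Missing channels
remain missing — never imputed.  Classification is leave-one-participant-out
with a soft-margin linear support-vector machine at fixed cost 1 (no
tuning, which would leak across folds).  Per fold, the feature space is the
held-out participant's available channels; by default it is further
intersected with the channels available for every training pattern, so the
fold trains on complete data (a `test`-only rule that instead drops
incomplete training participants is available, since the exact intersection
convention is not standard).

The solver is a small deterministic SMO (second-order working-set
selection) implemented in compiled code; the test suite cross-checks its
predictions against LIBSVM (via `e1071`) on random problems.  The reason
for an in-package solver is throughput: permutation inference refits the
classifier hundreds of thousands of times, and per-call overhead of the
external interface dominates at these problem sizes.

Permutation inference retrains the entire LOPO analysis 1000 times (200 in
the scaled-down calibration suites), independently keeping or exchanging
each participant's two condition labels with a fair coin — the
participant-level reading of "randomly maintaining or changing condition
labels", which preserves the balanced within-participant pairing.  The
inclusive estimator `p = (1 + #{permuted >= observed}) / (1 + n_perm)`
counts ties against the observed accuracy, so an unbeaten accuracy yields
exactly 1/1001.  Two properties of this scheme are worth knowing.  First,
the identity and all-flip permutations reproduce the observed labelling, so
in strongly decodable cohorts the attainable floor is governed by how often
those arise.  Second, LOPO accuracy lives on a grid of `1/(2N)`, and ties
make the inclusive estimator conservative; the null-calibration suite
therefore uses N = 20 participants (a 1/40 grid) and checks uniformity with
a Kolmogorov-Smirnov test at the 0.01 level, which accommodates the
residual discreteness.

The final "informative channels" model retrains on the two grand-average
condition patterns over channels available in at least 80% of participants;
informativeness is the product of weight and grand-average pattern value,
and the informative set is the most extreme 30% (ceiling; boundary ties are
all included).  Because z-scoring makes the class averages sign-symmetric,
the set for one class provably equals the set for the other; accuracy is
likewise invariant to channel order and to common affine rescaling before
normalization — both are asserted as properties.

Both accuracy counters are reported: proportion of correctly labelled
patterns (2N predictions) and proportion of participants with both patterns
correct; published accuracies that are not integer multiples of `1/(2N)`
leave the counting unit ambiguous, so the object carries both.

# Power

`rmWithinPower()` implements the repeated-measures within-factors
convention of the commonly used power program: noncentrality
`lambda = f^2 n m eps / (1 - rho)`, numerator df `(m - 1) eps`, denominator
df `(n - k)(m - 1) eps`, power from the noncentral F beyond the central
critical value.  Note that power *increases* with the repeated-measures
correlation `rho` under this convention.

The study being emulated reports achieved powers of 0.85, 0.89, 0.78 and
0.71 for medium effects (f = 0.25) at n = 20, 22, 17 and 15, but prints
neither the number of measurements nor the correlation or nonsphericity
entered.  The design has six cells (2 conditions x 3 windows), so m = 6;
a grid search over the unprinted parameters shows that `rho = 0.5, eps = 1`
(the program's defaults) yields 0.84/0.88/0.76/0.70 — close but not the
printed values — whereas `rho = 0.6, eps = 0.75` reproduces all four to two
decimals.  `studyPowerTable()` therefore fixes the calibrated
reconstruction m = 6, rho = 0.6, eps = 0.75 and documents it as a
reconstruction, not a reported setting.  An independent Monte-Carlo check
(compound-symmetry simulation of the within design) agrees with the
analytic formula to within 0.02.

# The synthetic cohort generator

The generator emulates the paradigm, signal and attrition structure:

* **Schedule.** 8-s stimulation trials, two conditions, baselines jittered
  uniformly on 9-12 s, exactly 3 trials per condition in every 120-s cycle,
  pseudo-random order with no condition three times in a row (enforced
  across cycle boundaries).  Because 6 x 8 + 6 x 12 = 120, a cycle always
  fits its window.  Sessions default to 240 s (6 trials per condition) —
  enough headroom over the 3-trial rule for attrition to act without
  dominating — and recordings carry a 20-s tail so the last epoch fits.
* **Haemodynamics.** The trial response is the analytic convolution of a
  gamma impulse response with the 8-s boxcar, parameterised by the latency
  of the *response* peak (9 s, the quantity actually measured in this
  paradigm) — the impulse-response peak is solved for internally.  Being
  closed-form (a difference of gamma CDFs), the simulated signal carries no
  discretisation error, which is what lets the window-mean quadrature
  oracle test demand 1e-6 agreement.  HbR is coupled to HbO by a factor of
  -0.3 with independent noise; only the sign of the coupling matters to any
  test.
* **Effects.** Per effect specification, the alternating condition responds
  with the given peak amplitude (uM) and the bimodal condition with 1.5x
  (super-additive), 0.5x (sub-additive), 1x (linear) or identically
  (none).  Amplitudes are free parameters — the study reports no uM
  scale — and the recovery suites use amplitude = 3x the white-noise SD.
* **Noise.** Sinusoids with per-channel random phase at 2.0 Hz (cardiac),
  0.6 Hz (respiratory) and 0.1 Hz (Mayer waves) — chosen to straddle the
  0.03-0.5 Hz passband so the filter is testable — plus a random-walk
  drift and white noise (SD 0.2 uM).
* **Artifacts and attrition.** Optical-density spikes (Gaussian bumps) and
  baseline shifts (steps) at configurable rates; per-channel dropout
  (dropped channels record a 5e-4 intensity and fail pruning); per-trial
  looking proportions from a Beta(8, 2) distribution, subjected to the 40%
  rule downstream.  Artifact onsets keep at least 3.5 s clearance from
  every epoch-rule boundary so that the 1-s detection padding cannot move
  an artifact across a rule edge — this is what makes the ground-truth
  exclusion audit exact rather than approximate.  The ground truth records,
  per participant, the planted effect map, artifact segments, dropped
  channels, looking values and the exclusion bookkeeping the preprocessing
  rules must reproduce.

`simulatePatternSet()` additionally generates activation patterns directly
at the window-means level.  The decoding stack consumes window means, so
its permutation-calibration suite (hundreds of cohorts) runs at this level;
the raw-signal stages are calibrated separately by the null-cohort contrast
suite.

What the generator does *not* emulate: optical photon transport, realistic
scalp coupling, spatially correlated physiology, age-dependent response
shapes, or gaze dynamics beyond one looking proportion per trial.  Passing
tests therefore certify the analysis logic — exclusion rules, estimator
calibration, label mappings, decoding inference — on data whose generative
structure matches the paradigm's timing and noise bands, not the full
richness of infant recordings.

# Problem sizes used by the verification suites

The calibration suites run at the study's scale where the property demands
it: 50 null cohorts of n = 20 for the contrast size check (observed
rejection rate 0.05 +/- 0.02 at alpha = .05), 200 pattern-level cohorts
with 200 permutations for p-uniformity, 20 replicates for effect recovery,
and 100 series for the Beer-Lambert round trip.  Monte-Carlo power checks
use 4000 replicates (standard error ~0.006 against a 0.02 tolerance).
Sessions are 240 s throughout; longer sessions change nothing but trial
counts.

# Known limitations

* Region tags and adjacency are reconstructions (see above); analyses that
  depend on exact anatomical boundaries should re-derive them.
* The HDF5-based interchange container for NIRS data is not read; the
  tabular dialect (long TSV + JSON sidecars) is the supported format.
* The omnibus three-level RM ANOVA is not exposed as a separate fit; the
  package reports the planned 1-df contrasts the analysis actually uses,
  plus the age interaction.  Published partial eta squared values that
  derive from an omnibus term can therefore differ slightly from the
  contrast-based values reported here.
* Real-data results of the emulated study (channel F values, decoding
  accuracies) are not reproducible without the unreleased recordings; the
  package's claims are calibration and recovery on synthetic cohorts.
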