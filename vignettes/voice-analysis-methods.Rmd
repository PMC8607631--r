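---
title: "Methods: sustained-vowel dysphonia analysis and the repeated stratified detection protocol"
author: "phonoPD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sustained-vowel dysphonia analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Parkinson's disease affects phonation early: glottal cycles become more
irregular in period (jitter) and amplitude (shimmer), turbulent noise rises
relative to the harmonic component, and the spectral and nonlinear structure
of the voice changes. phonoPD implements an analysis engine for detecting
these changes from short sustained /a/ phonations recorded on consumer
devices at 44.1 kHz: a 32-feature acoustic/nonlinear extractor operating on
one voiced second per recording, per-subject aggregation of recording
triplicates, and a repeated, stratified machine-learning protocol (feature
selection, hyperparameter tuning, holdout evaluation, cross-cohort
transfer). Because clinical voice recordings are access-restricted, the
package also contains a source-filter vowel synthesizer and a statistical
cohort simulator with exact ground truth, so every stage is testable without
any external data.

## Preprocessing

`readWav()` accepts RIFF/WAVE PCM (16/24/32-bit) and IEEE-float files,
averages multi-channel input to mono, and rejects rates other than 44.1 kHz
unless resampling is requested. `trimToVoicedSecond()` frames the signal
(25 ms frames, 10 ms hop), measures frame RMS relative to the loudest frame,
and keeps exactly one second starting at the first frame above a -40 dB
relative threshold. The threshold is relative, so trimming commutes with
gain; the *first* voiced second is kept to make the choice deterministic and
to avoid end-of-breath instability. Recordings with less than one second of
voiced material are rejected with the measured voiced duration in the error.

## Cycle detection

All perturbation measures need per-cycle periods and amplitudes
(`detectCycles()`). The mean period comes from the global normalized
autocorrelation peak in the 50-500 Hz band (signals whose peak correlation
is below 0.3 are declared unvoiced). Cycle marks are then placed by peak
picking constrained to +/- 30% of the running period, with parabolic
sub-sample refinement. Peaks are picked on the linear-prediction residual
(order 2 + fs/1000): its impulses mark glottal closure instants and are not
smeared by formant ringing, which matters because ringing from the previous
cycle otherwise biases both period and amplitude estimates by ~10%. A pure
tone leaves essentially no residual (the predictor is exact), so when the
residual is negligible or non-impulsive (kurtosis below 3.5) the detector
falls back to waveform peaks. Cycle marks therefore sit at a constant
intra-cycle phase offset from the nominal cycle onsets; every measure built
on them uses only differences, so the offset is immaterial.

## Acoustic features (9 + 13 MFCCs)

* **Jitter, shimmer** (`jitterLocal`, `shimmerLocal`): the local variants,
  `100 * mean(|x[i+1] - x[i]|) / mean(x)` over consecutive periods /
  peak amplitudes. The literature defines several variants (RAP, PPQ, APQ);
  the local one is the canonical single-number form and the one the
  synthesizer's ground-truth cycles calibrate directly.
* **HNR** (`hnrDb`): per 40 ms frame (10 ms hop), the correlation between
  the frame and its period-lagged self over their overlap; frame HNR is
  `10 log10(r / (1 - r))` with `r` clipped to [0.001, 0.999] (ceiling about
  30 dB), averaged over frames. The overlap-normalized correlation (rather
  than the biased ACF) is essential: the biased estimator caps `r` at
  `(n - lag) / n` and saturates near 6 dB.
* **CPP** (`cppDb`): per 40 ms Hamming frame (20 ms hop), the real cepstrum
  of the dB magnitude spectrum is searched in the 2-20 ms quefrency band;
  CPP is the peak's height in dB above a least-squares regression line over
  that band, averaged over frames. Gain changes move only the zero-quefrency
  bin, so CPP is gain invariant.
* **GNE** (`gne`): the signal is resampled to 10 kHz and inverse-filtered by
  frame-wise order-13 LPC (30 ms frames); Hilbert envelopes of the residual
  in 1 kHz-wide bands centered every 500 Hz from 500 to 4500 Hz are
  cross-correlated (lags +/- 0.3 ms) for band pairs more than 500 Hz apart;
  GNE is the maximum correlation, averaged over frames. A common glottal
  excitation drives all bands coherently (GNE near 1); aspiration noise
  decorrelates them.
* **ZCR** (`zcr`): sign changes per second, zeros attached to the preceding
  sign. The attachment convention makes the count exact for gain changes but
  can move a single crossing under polarity inversion.
* **Glottal quotients** (`glottalQuotients`): the glottal flow is estimated
  by two-pass iterative adaptive inverse filtering (source pre-whitening,
  vocal-tract LPC of order 2 + fs/1000, leaky-integrator lip-radiation
  inversion; the flow is lightly smoothed, 0.5 ms, so LPC ripple cannot
  split phase runs). Per cycle the open phase is the longest contiguous run
  where the flow exceeds 50% of its cycle range. The three dimensionless
  dispersion statistics are the 5th-95th percentile range of periods and the
  standard deviations of open/closed phase durations, all normalized by the
  mean period. If the open phase is empty in more than half the cycles the
  three phase statistics are flagged missing. These definitions are a
  reconstruction from the feature names in the dysphonia literature and are
  isolated behind this one function so they can be swapped.
* **MFCC 1-13** (`mfcc13`): 25 ms Hamming frames, 10 ms hop, 26 triangular
  mel filters to Nyquist, log energies, DCT-II, coefficients 1-13 averaged
  over frames. The gain-carrying 0th coefficient is excluded so the whole
  feature set is gain invariant; the energy floor is relative to the frame
  maximum for the same reason.

## Nonlinear features (10)

Embedding-based measures run at 22.05 kHz (one decimation stage) to bound
pairwise-distance costs; this has negligible effect on these measures for
voice.

* **RPDE** (`rpde`): time-delay embedding (m = 4, tau = 35 samples,
  radius 0.12 signal sd); for each base point the first return time to its
  epsilon-ball after leaving it is recorded and the normalized entropy
  `-sum p ln p / ln(Tmax)` of the return-time histogram returned. Base
  points are strided to at most 4000 and excursions longer than 4000 samples
  are censored, which bounds the cost at a fixed accuracy. At the default
  radius the recurrences of broadband noise are sparse and the finite-sample
  entropy is biased low (about 0.55-0.75 rather than the asymptotic ~1);
  the near-uniform-return-time regime used for validation is reached at
  radius 0.25 sd.
* **Correlation dimension** (`correlationDimension`):
  Grassberger-Procaccia with a Theiler window, least-squares slope of
  `log C(r)` over radii between the 10th and 50th percentile of pairwise
  distances. Over that region the correlation integral of an iid cloud
  saturates slightly, so embedded white noise reads ~2.9 rather than the
  embedding dimension 4; a sine reads 1.0.
* **PPE** (`ppe`): log-pitch relative to the median (transposition
  invariant), whitened by a least-squares AR(2) filter; normalized entropy
  of the residual histogram (30 bins over +/- 0.5).
* **Hurst exponent** (`hurstDfa`): order-1 DFA, scales 16 to n/8,
  non-overlapping windows from both series ends. Calibrated on white noise
  (H = 0.5) and Davies-Harte fractional Gaussian noise (exact spectrum).
* **LZ-2** (`lz2`): median binarization, LZ76 exhaustive-history word count
  `c(n)` (Kaspar-Schuster scan, verified exhaustively against a quadratic
  reference parser), normalized as `c(n) log2(n) / n`.
* **Permutation / Shannon entropy**: ordinal patterns (m = 3, tau = 1, ties
  to the earlier sample) normalized by `ln m!`; amplitude histogram over
  `[-max|x|, max|x|]` with 64 bins normalized by `log2` bins.
* **First AMI minimum** (`amiFirstMin`): histogram mutual information
  (32 x 32 bins) over lags to 20 ms; the first running minimum confirmed by
  a rise of 15% of the MI range. The prominence rule is what makes the
  estimator usable: histogram noise on a declining MI curve otherwise fakes
  minima at tiny lags, while a structureless (flat) profile still confirms
  its first dip immediately, giving the expected immediate minimum for iid
  noise and the quarter-period minimum for sinusoids.
* **First ACF zero** (`acfFirstZero`): first non-positive lag of the biased
  normalized ACF, linearly interpolated, in ms.
* **MFSW** (`mfsw`): multifractal DFA (order-1, q in -5..5 with the
  log-mean at q = 0, scales 16 to n/8); singularity strengths
  `alpha = h(q) + q h'(q)` by finite differences and width
  `max alpha - min alpha`. Calibrated on the binomial cascade, whose
  spectrum width is analytic (`log2(p/(1-p))`, 0.585 at p = 0.6). Scaling is
  declared degenerate (missing value) when the per-q regressions have
  R^2 < 0.9 for more than half the q values — which is the typical outcome
  for strongly periodic voiced audio, whose fluctuation functions have a
  crossover at the pitch period. MFSW is therefore frequently missing on
  clean synthetic vowels and is mean-imputed downstream; this is a known
  limitation of applying the estimator directly to voiced audio.

## The synthesizer and what it does (not) emulate

`synthVowel()` drives a cascade of two-pole formant resonators (default /a/:
700/1220/2600 Hz) with a Rosenberg glottal pulse train (open quotient 0.6,
speed quotient 2) followed by a first-difference lip-radiation stage. Cycle
`i` has period `T0 (1 + jitter/100 z_i)` and gain `1 + shimmer/100 z'_i`
(iid standard normal, clipped at +/- 3, so the perturbations match the
"local" jitter/shimmer definitions rather than a random walk). Onsets are
placed at integer samples by per-cycle rounding, and the recorded truth is
the realized integer-sample cycle sequence, so oracle comparisons are
self-consistent; at zero jitter all periods are exactly equal. The pulse
shape is sized from the nominal period and does not rescale per cycle:
period perturbations are absorbed by the closed phase, so glottal events
stay at a fixed phase offset from cycle onsets — the property that makes
cycle-mark-based jitter well defined. White Gaussian noise is passed through
the same resonators and scaled so the periodic-to-noise power ratio at the
filter output matches `hnrDb` (that is the ratio the HNR estimator sees).
Everything is determined by the seed.

The synthesizer emulates periodicity, perturbation and additive aspiration
noise. It does not emulate articulatory dynamics, soft phonation onsets,
diplophonia, tremor, room reverberation or device compression — so passing
recovery tests shows the estimators are correct for the stated signal model,
not that they are robust to every pathology or recording condition in real
cohorts.

`synthCohort()` generates class-conditional Gaussian feature tables: healthy
means 0, PD means equal to the chosen effect sizes on the informative
features, unit variances, optional equicorrelation within the informative
block, optional label noise. Its Bayes accuracy is known in closed form
(`pnorm(||d||/2)`), which anchors the recovery tests.
`applyCovariateShift()` produces the "second database" sibling by an affine
per-feature map. `synthAudioCohort()` synthesizes actual audio cohorts with
class-dependent dysphonia (PD voices drawn around jitter 1.2% / shimmer 5% /
HNR 14 dB, healthy around 0.5% / 2.5% / 21 dB, log-normal spread; f0 by
sex), which makes the end-to-end audio pipeline a meaningful classification
problem with overlap between classes.

## The detection protocol

All stages take the subject-level table (triplicates averaged
component-wise; the sex indicator is encoded male = 0 / female = 1 and
standardized like every other feature, since selection may legitimately pick
it).

* **Selection** (`rfecvSelect`): 100 iterations of stratified 5-fold CV;
  within each fold, features are recursively eliminated one at a time by
  weakest importance (absolute coefficients for linear families, impurity or
  gain for tree families) on the fold-standardized training data, and every
  subset size is scored on the held-out fold. An iteration's optimal count
  is the size with the best mean CV accuracy (smallest on ties); the final
  count is the first quartile of the 100 counts (linear-interpolation
  percentile, rounded half up, floored at 1); the selected set is the top of
  the mean-elimination-rank aggregate over all fold runs, ties alphabetical.
  Scaling is fitted per training fold here too, so selection is leakage-free
  by default.
* **Tuning** (`gridSearch`): exhaustive stratified 5-fold CV accuracy over
  small documented grids (`defaultHyperGrid()`); ties break by enumeration
  order, failures score 0 with a warning.
* **Evaluation** (`evaluate`): 1000 iterations; each draws a stratified
  75/25 split (largest-remainder per-class counts; for 30/30 cohorts every
  test set has 15 subjects, {7, 8} per class, the extra subject's class
  alternating with iteration parity), fits the scaler on the training split
  only, imputes missing features with training means, fits the classifier
  and scores the test split. Accuracy, sensitivity and specificity come from
  the confusion matrix with PD positive; AUC from the continuous score; the
  ROC is vertically averaged onto a 101-point FPR grid with a +/- 1 sd band.
  One master seed drives everything; iteration `i` derives its own seed, so
  reports are exactly reproducible.
* **Classifiers**: logistic regression (ridge-penalized IRLS, default
  penalty equivalent to the standard unit-strength L2 of common toolkits),
  random forest (ranger), averaged perceptron and PA-I passive-aggressive
  (compiled implementations), gradient boosting (xgboost) and SVM (e1071;
  linear kernel supplies coefficients when selection needs importances).
  Probabilistic families threshold at 0.5, margin families at 0.
* **Transfer** (`transferEvaluate`): the frozen feature subset and
  hyperparameters from a source-cohort experiment applied to a target
  cohort, with no re-selection or re-tuning, in two protocols. The default
  re-runs the holdout protocol on the target with the frozen choices
  (within-target performance of a frozen design). The `"frozen"` protocol
  trains on stratified source subsamples and scores stratified target
  subsamples, so the decision rule itself crosses cohorts. The distinction
  matters for covariate shift: a purely affine per-feature shift is exactly
  undone by train-split standardization, so only the frozen protocol can
  exhibit the degradation that motivates cross-cohort testing; the
  degradation analyses therefore use it.
* **Comparison** (`compareReports`): equal-variance two-sample t-tests per
  metric on the per-iteration samples (Welch optional), significance at
  0.05.

## Calibration subtleties worth knowing

Null cohorts (no class signal) do **not** sit exactly at accuracy 0.5 for a
*fixed* finite cohort: a classifier partially learns the cohort's realized
spurious feature-label association (pushing above 0.5), and anti-learns the
training split's noise direction, which mirrors into the complementary test
split (pushing below 0.5 at high dimension); the majority class of a 22/23
training split is also the minority of its 7/8 test split. At n = 60 and
33 features these effects give cohort-level accuracy/AUC fluctuations with
a standard deviation near 0.1 — properties of the protocol, not bugs, and
reproduced by the reference Python ML stack on the same design. Chance
calibration is therefore assessed with the standard permutation null:
labels are re-permuted before *every* holdout iteration, so each test split
is independent of the trained model, per-iteration accuracy is chance up to
binomial noise, and the 1000-iteration mean for every family sits within
+/- 0.05 of 0.5 with large margin.

## Problem sizes and determinism

The validation suite uses 1-second vowels at 44.1 kHz, 20 seeds per
perturbation level for recovery and monotonicity, 4096-sample series (20
seeds) for DFA calibrations, 2^14-sample cascades for MFSW, 60-subject
cohorts with 33 features for all pipeline experiments, 100-iteration RFECV,
and 1000 total holdout iterations per family (split over independent null
cohorts for calibration); the end-to-end audio run uses 60 subjects x 3
recordings. Every stochastic step is seeded; reports, selections and
synthesized audio are bit-reproducible for a fixed seed.

## Known limitations

* The glottal-quotient and MFSW estimators frequently flag missing values
  on clean strongly-periodic audio (degenerate inverse filtering or scaling
  crossover); the pipeline mean-imputes rather than dropping subjects.
* Shimmer estimates on noisy voices absorb additive-noise amplitude
  variation and read high, as amplitude-perturbation measures generally do;
  recovery is calibrated on clean signals.
* The cohort simulator's covariate shift is affine; real cross-database
  differences also change noise structure and effect sizes, which no test
  here exercises.
* Clinical validity is out of scope: all accuracy statements concern the
  synthetic generative models.
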