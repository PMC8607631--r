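# phonoPD

Voice-based screening support for Parkinson's disease (PD) from sustained
/a/ phonations. Parkinsonian voices show elevated cycle-to-cycle period
perturbation (jitter), amplitude perturbation (shimmer), reduced
harmonics-to-noise ratio, and altered cepstral/nonlinear structure. phonoPD
implements the full analysis engine a clinical study of smartphone
phonations needs, for researchers in biomedical speech analysis:

* **Feature extraction** — 32 acoustic and nonlinear features per one-second
  voiced segment: local jitter and shimmer

  `jitter% = 100 · mean|T(i+1) − T(i)| / mean T`,

  cepstral peak prominence (CPP), autocorrelation HNR
  (`10 log10(r/(1−r))`), glottal-to-noise excitation ratio (GNE),
  zero-crossing rate, three glottal-quotient dispersion statistics,
  MFCC 1–13, recurrence period density entropy (RPDE), correlation
  dimension D2, pitch period entropy (PPE), DFA Hurst exponent, LZ76
  complexity, permutation and Shannon entropy, first mutual-information
  minimum, first autocorrelation zero, and multifractal spectrum width
  (MFSW).
* **Detection protocol** — per-subject aggregation of recording triplicates,
  train-split standardization, recursive feature elimination with stratified
  5-fold cross-validation repeated 100 times and a first-quartile
  subset-size rule, grid-search tuning, a 1000-iteration stratified 75/25
  holdout evaluation (accuracy, sensitivity, specificity, AUC, averaged ROC
  with ±1 sd band), cross-cohort transfer with frozen features and
  hyperparameters, and Student's t comparisons between classifier reports.
  Six classifier families: logistic regression, random forest, perceptron,
  passive-aggressive, gradient boosting, SVM.
* **Synthetic ground truth** — a source-filter sustained-vowel synthesizer
  (Rosenberg pulses, formant resonators, controllable jitter/shimmer/HNR)
  that returns the exact glottal cycle sequence it rendered, plus Gaussian
  cohort simulators with known Bayes accuracy and controllable covariate
  shift. Every stage of the engine is validated against these oracles.

## Worked example

Synthesize a 60-subject cohort (30 PD / 30 healthy, three phonations each,
PD voices drawn with higher jitter/shimmer and lower HNR), extract all
features, aggregate to one row per subject, then select, tune and evaluate:

```r
library(phonoPD)

ft   <- synthAudioCohort(nPerClass = 30, recordingsPerSubject = 3, seed = 99)
subj <- aggregateBySubject(ft)          # 60 rows, 33 features incl. sex
res  <- runPipeline(subj, family = "logistic",
                    selectionIterations = 100, evalIterations = 1000,
                    seed = 99)

res$selection
#> SelectionResult (logistic): final count 1 (1st quartile of 100 iterations)
#>   selected: rpde

res$report
#> EvaluationReport (logistic): 1000 iterations
#>   accuracy    0.8749 +/- 0.0744
#>   sensitivity 0.9743 +/- 0.0642
#>   specificity 0.7768 +/- 0.1527
#>   auc         0.9446 +/- 0.0541
```

On this synthetic cohort the dominant class difference is aperiodicity, so
the first-quartile rule collapses the feature set all the way to a single
nonlinear measure (RPDE, the recurrence period density entropy) — in a
quarter of the repeated cross-validations one feature already gave the best
accuracy. The report gives the holdout mean ± sd over 1000 stratified 75/25
splits with PD as the positive class: mean sensitivity 0.974 means 97.4% of
held-out PD subjects are recognized, at a specificity of 0.777.
`plotRocBand(res$report)` draws the vertically averaged ROC with its ±1 sd
band.

Single recordings go through the same machinery:

```r
w <- readWav("phonation.wav")           # 44.1 kHz mono
extractFeatures(trimToVoicedSecond(w))  # named vector of 32 features
```

A thin command-line front end over these functions lives at
`inst/cli/phonopd.R` (`synth-audio`, `synth-cohort`, `extract`, `select`,
`tune`, `evaluate`, `transfer`, `compare`, `report`).

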