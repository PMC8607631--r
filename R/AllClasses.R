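#' @import methods
NULL

#' Mono audio waveform
#'
#' A uniformly sampled mono audio signal with its sample rate. Amplitudes are
#' dimensionless and expected to lie in \[-1, 1\]; the canonical rate for
#' phonation recordings handled by this package is 44100 Hz.
#'
#' @slot samples numeric vector of finite sample values.
#' @slot rateHz positive integer sample rate (samples/second).
#' @slot sourceId opaque identifier (file path, synthesis tag, ...).
#'
#' @seealso [readWav()], [trimToVoicedSecond()], [synthVowel()]
#' @export
setClass("Waveform",
  representation(samples = "numeric", rateHz = "integer", sourceId = "character"),
  prototype(samples = numeric(0), rateHz = 44100L, sourceId = NA_character_)
)

setValidity("Waveform", function(object) {
  if (length(object@samples) < 1L) return("waveform must contain at least one sample")
  if (!all(is.finite(object@samples))) return("waveform samples must all be finite")
  if (length(object@rateHz) != 1L || is.na(object@rateHz) || object@rateHz <= 0L)
    return("rateHz must be a single positive integer")
  TRUE
})

#' Glottal cycle sequence
#'
#' Per-cycle descriptors produced by [detectCycles()]: cycle onset positions
#' (in samples, possibly fractional after sub-sample refinement), per-cycle
#' periods and peak amplitudes, and — when glottal inverse filtering succeeds —
#' per-cycle open- and closed-phase durations.
#'
#' @slot onsets numeric, strictly increasing cycle onset positions (samples).
#' @slot periodsS numeric, per-cycle durations in seconds (length = cycles - 1
#'   relative to onsets, i.e. `diff(onsets)/rateHz`).
#' @slot peakAmps numeric, per-cycle absolute peak amplitudes (same length as
#'   `periodsS`).
#' @slot openS,closedS numeric, per-cycle open/closed phase durations in
#'   seconds, or length-0 when glottal analysis was not run or failed.
#' @slot rateHz integer sample rate of the analyzed waveform.
#' @export
setClass("CycleSeries",
  representation(onsets = "numeric", periodsS = "numeric", peakAmps = "numeric",
                 openS = "numeric", closedS = "numeric", rateHz = "integer")
)

setValidity("CycleSeries", function(object) {
  if (is.unsorted(object@onsets, strictly = TRUE)) return("onsets must be strictly increasing")
  if (length(object@periodsS) != length(object@peakAmps))
    return("periodsS and peakAmps must have equal length")
  if (any(object@periodsS <= 0)) return("periods must be positive")
  if (any(object@periodsS < 1 / 500 - 1e-9 | object@periodsS > 1 / 50 + 1e-9))
    return("periods must lie in the f0 search band [1/500, 1/50] s")
  TRUE
})

#' Synthesis ground truth
#'
#' The exact cycle-level ground truth of a synthesized vowel: the oracle that
#' perturbation extractors are validated against.
#'
#' @slot cycleOnsets integer sample indices (1-based) of each glottal cycle start.
#' @slot cyclePeriodsS numeric per-cycle durations (seconds) as realized in the
#'   rendered signal.
#' @slot cycleAmps numeric per-cycle source amplitudes (relative gains).
#' @slot voicedRange integer length-2, first and last voiced sample.
#' @slot noisePower numeric, power of the additive noise component (0 if none).
#' @export
setClass("SynthesisTruth",
  representation(cycleOnsets = "integer", cyclePeriodsS = "numeric",
                 cycleAmps = "numeric", voicedRange = "integer",
                 noisePower = "numeric")
)

setValidity("SynthesisTruth", function(object) {
  if (is.unsorted(object@cycleOnsets, strictly = TRUE))
    return("cycle onsets must be strictly increasing")
  if (any(object@cyclePeriodsS <= 0)) return("cycle periods must be positive")
  TRUE
})

#' Subject-by-feature table
#'
#' Rows of (subject, recording, label, sex, age) metadata plus named numeric
#' features; the container every selection/evaluation stage consumes. The sex
#' indicator may itself be listed among `featureNames` (encoded male = 0,
#' female = 1 when the feature matrix is materialized).
#'
#' @slot data data.frame with columns `subject_id`, `recording_id`, `label`
#'   (one of "PD", "healthy"), `sex` (one of "male", "female"), `age`, and one
#'   numeric column per non-sex feature. Missing features are `NA`.
#' @slot featureNames character, ordered feature names (possibly including
#'   `"sex"`).
#' @export
setClass("FeatureTable",
  representation(data = "data.frame", featureNames = "character")
)

setValidity("FeatureTable", function(object) {
  d <- object@data
  meta <- c("subject_id", "recording_id", "label", "sex", "age")
  if (!all(meta %in% names(d))) {
    return(paste("missing metadata columns:", paste(setdiff(meta, names(d)), collapse = ", ")))
  }
  fn <- setdiff(object@featureNames, "sex")
  if (!all(fn %in% names(d))) {
    return(paste("missing feature columns:", paste(setdiff(fn, names(d)), collapse = ", ")))
  }
  if (anyDuplicated(d[, c("subject_id", "recording_id")]))
    return("duplicated (subject_id, recording_id) keys")
  if (!all(d$label %in% c("PD", "healthy"))) return("labels must be 'PD' or 'healthy'")
  if (!all(d$sex %in% c("male", "female"))) return("sex must be 'male' or 'female'")
  for (f in fn) if (!is.numeric(d[[f]])) return(paste("feature column not numeric:", f))
  for (s in unique(d$subject_id)) {
    rows <- d[d$subject_id == s, ]
    if (length(unique(rows$label)) > 1L) return(paste("conflicting labels for subject", s))
    if (length(unique(rows$sex)) > 1L) return(paste("conflicting sex for subject", s))
  }
  TRUE
})

#' Standardization statistics
#'
#' Per-feature training-set mean and standard deviation, fitted by
#' [standardizeFit()] and applied with [standardizeApply()]. Constant columns
#' have their sd replaced by 1 so they map to zero rather than NaN.
#'
#' @slot center,scale named numeric vectors over the same feature names.
#' @export
setClass("Scaler", representation(center = "numeric", scale = "numeric"))

setValidity("Scaler", function(object) {
  if (!identical(names(object@center), names(object@scale)))
    return("center and scale must share names")
  if (any(object@scale <= 0)) return("scale entries must be positive")
  TRUE
})

#' Feature-selection result
#'
#' Output of [rfecvSelect()]: the per-iteration optimal subset sizes, the
#' aggregated elimination ranking, and the final subset chosen by the
#' first-quartile rule.
#'
#' @slot optimalCounts integer, one optimal feature count per iteration.
#' @slot ranking character, all features ordered best first (smallest mean
#'   elimination rank last removed first).
#' @slot finalCount integer, first quartile of `optimalCounts` (rounded half
#'   up, floored at 1).
#' @slot selectedFeatures character, the top `finalCount` of `ranking`.
#' @slot family character, classifier family used for elimination.
#' @slot elapsedS numeric, wall-clock seconds spent.
#' @export
setClass("SelectionResult",
  representation(optimalCounts = "integer", ranking = "character",
                 finalCount = "integer", selectedFeatures = "character",
                 family = "character", elapsedS = "numeric")
)

setValidity("SelectionResult", function(object) {
  if (object@finalCount < 1L || object@finalCount > length(object@ranking))
    return("finalCount out of range")
  if (!identical(object@selectedFeatures, object@ranking[seq_len(object@finalCount)]))
    return("selectedFeatures must be the top finalCount of ranking")
  TRUE
})

#' Repeated-holdout evaluation report
#'
#' Per-iteration accuracy, sensitivity, specificity and AUC of the repeated
#' stratified 75/25 holdout protocol, their means and standard deviations, an
#' averaged ROC curve with a +/- 1 sd band on a fixed FPR grid, and a
#' run-time breakdown.
#'
#' @slot metrics data.frame with one row per iteration and columns
#'   `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @slot rocFpr numeric FPR grid (101 points from 0 to 1).
#' @slot rocTprMean,rocTprSd numeric, vertically averaged TPR and its sd.
#' @slot family character classifier family.
#' @slot hyperparameters list of hyperparameter values used.
#' @slot timingsS named numeric: seconds for `selection`, `grid_search`,
#'   `classification` (NA when a stage was not run in this report).
#' @export
setClass("EvaluationReport",
  representation(metrics = "data.frame", rocFpr = "numeric",
                 rocTprMean = "numeric", rocTprSd = "numeric",
                 family = "character", hyperparameters = "list",
                 timingsS = "numeric")
)

setValidity("EvaluationReport", function(object) {
  need <- c("accuracy", "sensitivity", "specificity", "auc")
  if (!all(need %in% names(object@metrics))) return("metrics columns missing")
  vals <- unlist(object@metrics[need])
  if (any(vals < -1e-9 | vals > 1 + 1e-9, na.rm = TRUE)) return("metrics must lie in [0, 1]")
  if (length(object@rocTprMean) != length(object@rocFpr))
    return("ROC grid and mean TPR lengths differ")
  TRUE
})
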