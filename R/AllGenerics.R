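#' Accessors for phonoPD classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a phonoPD S4 object.
#' @return the accessed component; see the individual class pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("durationS", function(object) standardGeneric("durationS"))
#' @rdname accessors
#' @export
setGeneric("cycleOnsets", function(object) standardGeneric("cycleOnsets"))
#' @rdname accessors
#' @export
setGeneric("cyclePeriods", function(object) standardGeneric("cyclePeriods"))
#' @rdname accessors
#' @export
setGeneric("cycleAmps", function(object) standardGeneric("cycleAmps"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("subjectLabels", function(object) standardGeneric("subjectLabels"))
#' @rdname accessors
#' @export
setGeneric("tableData", function(object) standardGeneric("tableData"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("optimalCounts", function(object) standardGeneric("optimalCounts"))
#' @rdname accessors
#' @export
setGeneric("featureRanking", function(object) standardGeneric("featureRanking"))
#' @rdname accessors
#' @export
setGeneric("iterationMetrics", function(object) standardGeneric("iterationMetrics"))
#' @rdname accessors
#' @export
setGeneric("metricSummary", function(object) standardGeneric("metricSummary"))
#' @rdname accessors
#' @export
setGeneric("rocBand", function(object) standardGeneric("rocBand"))

#' @rdname accessors
setMethod("samples", "Waveform", function(object) object@samples)
#' @rdname accessors
setMethod("sampleRate", "Waveform", function(object) object@rateHz)
#' @rdname accessors
setMethod("sourceId", "Waveform", function(object) object@sourceId)
#' @rdname accessors
setMethod("durationS", "Waveform", function(object) length(object@samples) / object@rateHz)

#' @rdname accessors
setMethod("cycleOnsets", "CycleSeries", function(object) object@onsets)
#' @rdname accessors
setMethod("cyclePeriods", "CycleSeries", function(object) object@periodsS)
#' @rdname accessors
setMethod("cycleAmps", "CycleSeries", function(object) object@peakAmps)

#' @rdname accessors
setMethod("cycleOnsets", "SynthesisTruth", function(object) object@cycleOnsets)
#' @rdname accessors
setMethod("cyclePeriods", "SynthesisTruth", function(object) object@cyclePeriodsS)
#' @rdname accessors
setMethod("cycleAmps", "SynthesisTruth", function(object) object@cycleAmps)

#' @rdname accessors
setMethod("featureNames", "FeatureTable", function(object) object@featureNames)
#' @rdname accessors
setMethod("tableData", "FeatureTable", function(object) object@data)
#' @rdname accessors
setMethod("subjectLabels", "FeatureTable", function(object) object@data$label)

#' @describeIn accessors materialize the numeric feature matrix (rows =
#'   records, columns = `featureNames`); a `"sex"` feature is encoded
#'   male = 0, female = 1.
setMethod("featureMatrix", "FeatureTable", function(object) {
  d <- object@data
  cols <- lapply(object@featureNames, function(f) {
    if (f == "sex") ifelse(d$sex == "female", 1, 0) else d[[f]]
  })
  m <- do.call(cbind, cols)
  colnames(m) <- object@featureNames
  rownames(m) <- paste(d$subject_id, d$recording_id, sep = ":")
  m
})

#' @rdname accessors
setMethod("selectedFeatures", "SelectionResult", function(object) object@selectedFeatures)
#' @rdname accessors
setMethod("optimalCounts", "SelectionResult", function(object) object@optimalCounts)
#' @rdname accessors
setMethod("featureRanking", "SelectionResult", function(object) object@ranking)

#' @rdname accessors
setMethod("iterationMetrics", "EvaluationReport", function(object) object@metrics)

#' @describeIn accessors mean and sd of each metric over iterations.
setMethod("metricSummary", "EvaluationReport", function(object) {
  m <- object@metrics[, c("accuracy", "sensitivity", "specificity", "auc")]
  data.frame(metric = names(m), mean = vapply(m, mean, 0), sd = vapply(m, stats::sd, 0),
             row.names = NULL)
})

#' @describeIn accessors averaged ROC curve: data.frame with `fpr`,
#'   `tpr_mean`, `tpr_sd`.
setMethod("rocBand", "EvaluationReport", function(object) {
  data.frame(fpr = object@rocFpr, tpr_mean = object@rocTprMean, tpr_sd = object@rocTprSd)
})

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d samples @ %d Hz (%.3f s), source '%s'\n",
              length(object@samples), object@rateHz,
              length(object@samples) / object@rateHz, object@sourceId))
})

setMethod("show", "CycleSeries", function(object) {
  cat(sprintf("CycleSeries: %d cycles, mean f0 %.1f Hz, glottal phases %s\n",
              length(object@periodsS), 1 / mean(object@periodsS),
              if (length(object@openS)) "present" else "absent"))
})

setMethod("show", "FeatureTable", function(object) {
  d <- object@data
  cat(sprintf("FeatureTable: %d records, %d subjects (%d PD / %d healthy), %d features\n",
              nrow(d), length(unique(d$subject_id)),
              length(unique(d$subject_id[d$label == "PD"])),
              length(unique(d$subject_id[d$label == "healthy"])),
              length(object@featureNames)))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): final count %d (1st quartile of %d iterations)\n",
              object@family, object@finalCount, length(object@optimalCounts)))
  cat("  selected:", paste(object@selectedFeatures, collapse = ", "), "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  s <- metricSummary(object)
  cat(sprintf("EvaluationReport (%s): %d iterations\n", object@family, nrow(object@metrics)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
})

setMethod("show", "SynthesisTruth", function(object) {
  cat(sprintf("SynthesisTruth: %d cycles, noise power %.3g\n",
              length(object@cycleOnsets), object@noisePower))
})

setMethod("show", "Scaler", function(object) {
  cat(sprintf("Scaler over %d features\n", length(object@center)))
})
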