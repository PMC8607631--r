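# Per-subject table assembly, triplicate aggregation, standardization and
# CSV round-tripping.

#' Canonical feature names
#'
#' The 33 features of the detection pipeline in their documented CSV order:
#' the sex indicator followed by the 32 acoustic and nonlinear features.
#'
#' @param includeSex include the leading `"sex"` entry.
#' @return character vector of feature names.
#' @export
pdFeatureNames <- function(includeSex = TRUE) {
  nm <- c("jitter_pct", "shimmer_pct", "cpp_db", "hnr_db", "gne", "zcr_per_s",
          "gq_prc5_95", "gq_std_cycle_open", "gq_std_cycle_closed",
          paste0("mfcc_", 1:13),
          "rpde", "d2", "ppe", "hurst", "lz2", "perm_entropy",
          "shannon_entropy", "ami_first_min_ms", "mfsw", "acf_first_zero_ms")
  if (includeSex) c("sex", nm) else nm
}

#' Construct a FeatureTable
#'
#' @param data data.frame with the metadata columns `subject_id`,
#'   `recording_id`, `label`, `sex`, `age` and one numeric column per feature.
#' @param featureNames ordered feature names; defaults to every non-metadata
#'   column.
#' @return a [FeatureTable-class].
#' @export
FeatureTable <- function(data, featureNames = NULL) {
  meta <- c("subject_id", "recording_id", "label", "sex", "age")
  if (is.null(featureNames)) featureNames <- setdiff(names(data), meta)
  data$subject_id <- as.character(data$subject_id)
  data$recording_id <- as.character(data$recording_id)
  new("FeatureTable", data = data, featureNames = featureNames)
}

#' Extract the full 32-feature vector from a recording
#'
#' Convenience wrapper running [trimToVoicedSecond()] (unless the input is
#' already exactly one second), [extractAcousticFeatures()] and
#' [extractNonlinearFeatures()].
#'
#' @param w a [Waveform-class].
#' @return named numeric vector of the 32 non-sex features, in
#'   `pdFeatureNames(FALSE)` order.
#' @export
extractFeatures <- function(w) {
  if (length(samples(w)) != sampleRate(w)) w <- trimToVoicedSecond(w)
  cyc <- tryCatch(detectCycles(w), error = function(e) NULL)
  out <- c(extractAcousticFeatures(w), extractNonlinearFeatures(w, cycles = cyc))
  out[pdFeatureNames(includeSex = FALSE)]
}

#' Aggregate recordings to one row per subject
#'
#' Component-wise average of each subject's recordings (three per subject in
#' the reference protocol); missing values are excluded from each mean.
#' Labels and sex must be consistent within a subject.
#'
#' @param ft a [FeatureTable-class].
#' @return a [FeatureTable-class] with one row per subject
#'   (`recording_id = "mean"`).
#' @export
aggregateBySubject <- function(ft) {
  d <- tableData(ft)
  fn <- setdiff(featureNames(ft), "sex")
  subjects <- unique(d$subject_id)
  rows <- lapply(subjects, function(s) {
    sub <- d[d$subject_id == s, ]
    if (length(unique(sub$label)) > 1)
      .err("phonoPD_consistency_error", "conflicting labels for subject %s", s)
    if (length(unique(sub$sex)) > 1)
      .err("phonoPD_consistency_error", "conflicting sex for subject %s", s)
    out <- sub[1, c("subject_id", "label", "sex", "age"), drop = FALSE]
    out$recording_id <- "mean"
    for (f in fn) {
      v <- sub[[f]]
      out[[f]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    out
  })
  agg <- do.call(rbind, rows)
  agg <- agg[, c("subject_id", "recording_id", "label", "sex", "age", fn)]
  new("FeatureTable", data = agg, featureNames = featureNames(ft))
}

#' Fit / apply feature standardization
#'
#' `standardizeFit` computes per-feature means and standard deviations
#' (missing values excluded; constant columns get sd 1 so they map to zero);
#' `standardizeApply` transforms a table with a previously fitted scaler,
#' which is how test splits are scaled with training-set statistics only.
#'
#' @param ft a [FeatureTable-class] (>= 2 rows for fitting).
#' @return `standardizeFit`: a [Scaler-class].
#' @export
standardizeFit <- function(ft) {
  m <- featureMatrix(ft)
  if (nrow(m) < 2) .err("phonoPD_spec_error", "need >= 2 rows to fit a scaler")
  ctr <- colMeans(m, na.rm = TRUE)
  ctr[is.nan(ctr)] <- 0
  scl <- apply(m, 2, stats::sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl <= 0] <- 1
  new("Scaler", center = ctr, scale = scl)
}

#' @rdname standardizeFit
#' @param scaler a fitted [Scaler-class].
#' @return `standardizeApply`: the standardized [FeatureTable-class] (a
#'   `"sex"` feature becomes a numeric column `sex_std`; the categorical
#'   metadata column is preserved).
#' @export
standardizeApply <- function(scaler, ft) {
  if (!identical(sort(names(scaler@center)), sort(featureNames(ft))))
    .err("phonoPD_schema_error", "scaler and table feature names differ")
  d <- tableData(ft)
  m <- featureMatrix(ft)
  fn <- featureNames(ft)
  newNames <- ifelse(fn == "sex", "sex_std", fn)
  for (i in seq_along(fn)) {
    d[[newNames[i]]] <- (m[, fn[i]] - scaler@center[fn[i]]) / scaler@scale[fn[i]]
  }
  new("FeatureTable", data = d, featureNames = newNames)
}

#' Read / write a feature-table CSV
#'
#' Lossless CSV round-trip with the documented schema
#' `subject_id,recording_id,label,sex,age,<features>`; missing values are
#' empty cells. Duplicate keys, unknown metadata values and non-numeric
#' feature cells are parse errors reporting the offending row.
#'
#' @param path CSV file path.
#' @return `readFeatureTable`: a [FeatureTable-class].
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) .err("phonoPD_parse_error", "file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  meta <- c("subject_id", "recording_id", "label", "sex", "age")
  if (!all(meta %in% names(d)))
    .err("phonoPD_parse_error", "missing metadata columns: %s",
         paste(setdiff(meta, names(d)), collapse = ", "))
  fn <- setdiff(names(d), meta)
  dup <- which(duplicated(d[, c("subject_id", "recording_id")]))
  if (length(dup))
    .err("phonoPD_parse_error", "duplicated (subject, recording) key at row %d", dup[1])
  bad <- which(!d$label %in% c("PD", "healthy"))
  if (length(bad)) .err("phonoPD_parse_error", "unknown label at row %d", bad[1])
  bad <- which(!d$sex %in% c("male", "female"))
  if (length(bad)) .err("phonoPD_parse_error", "unknown sex at row %d", bad[1])
  d$age <- as.integer(d$age)
  for (f in fn) {
    raw <- d[[f]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !(is.na(raw) | raw == ""))
    if (length(bad))
      .err("phonoPD_parse_error", "non-numeric value '%s' in column %s at row %d",
           raw[bad[1]], f, bad[1])
    d[[f]] <- v
  }
  new("FeatureTable", data = d, featureNames = fn)
}

#' @rdname readFeatureTable
#' @param ft a [FeatureTable-class].
#' @return `writeFeatureTable`: `path`, invisibly.
#' @export
writeFeatureTable <- function(ft, path) {
  d <- tableData(ft)
  fn <- setdiff(featureNames(ft), "sex")
  d <- d[, c("subject_id", "recording_id", "label", "sex", "age", fn)]
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Synthesize an audio cohort with class-dependent dysphonia
#'
#' Generates `nPerClass` PD and `nPerClass` healthy subjects with
#' `recordingsPerSubject` sustained vowels each and extracts the full
#' feature table. PD voices are synthesized with elevated jitter and shimmer
#' and reduced harmonics-to-noise ratio relative to healthy voices, the
#' classic dysphonia profile of parkinsonian speech; per-subject values are
#' drawn around the class centers so the two classes overlap.
#'
#' @param nPerClass subjects per class.
#' @param recordingsPerSubject phonations per subject.
#' @param seed integer RNG seed.
#' @param durationS per-recording duration.
#' @return a [FeatureTable-class] with one row per recording and the 33
#'   canonical features.
#' @export
synthAudioCohort <- function(nPerClass = 30, recordingsPerSubject = 3, seed = 1L,
                             durationS = 1) {
  set.seed(as.integer(seed))
  n <- 2L * nPerClass
  label <- rep(c("PD", "healthy"), each = nPerClass)
  sex <- sample(rep_len(c("male", "female"), n))
  # class-conditional voice parameters: PD voices are more perturbed
  jit <- ifelse(label == "PD", stats::rlnorm(n, log(1.2), 0.4),
                stats::rlnorm(n, log(0.5), 0.4))
  shim <- ifelse(label == "PD", stats::rlnorm(n, log(5), 0.35),
                 stats::rlnorm(n, log(2.5), 0.35))
  hnr <- ifelse(label == "PD", stats::rnorm(n, 14, 3), stats::rnorm(n, 21, 3))
  f0 <- ifelse(sex == "female", stats::rnorm(n, 190, 20), stats::rnorm(n, 115, 15))
  age <- sample(51:87, n, replace = TRUE)
  rows <- list()
  for (i in seq_len(n)) {
    for (r in seq_len(recordingsPerSubject)) {
      sv <- synthVowel(f0Hz = max(80, min(300, f0[i] * stats::rnorm(1, 1, 0.02))),
                       durationS = durationS,
                       jitterPct = jit[i] * stats::rlnorm(1, 0, 0.1),
                       shimmerPct = shim[i] * stats::rlnorm(1, 0, 0.1),
                       hnrDb = hnr[i] + stats::rnorm(1, 0, 1),
                       seed = .iterSeed(seed, i * 101L + r))
      feats <- extractFeatures(sv$wave)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("S%03d", i), recording_id = sprintf("r%d", r),
        label = label[i], sex = sex[i], age = age[i],
        as.list(feats), stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  new("FeatureTable", data = d, featureNames = pdFeatureNames(TRUE))
}
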