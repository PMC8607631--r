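# Table assembly, triplicate aggregation, standardization and CSV round trip.

miniTable <- function() {
  d <- data.frame(
    subject_id = rep(c("S1", "S2"), each = 3),
    recording_id = rep(c("r1", "r2", "r3"), 2),
    label = rep(c("PD", "healthy"), each = 3),
    sex = rep(c("male", "female"), each = 3),
    age = rep(c(70, 65), each = 3),
    jitter = c(1, 2, 3, 4, 4, 4),
    hnr = c(10, 10, 10, 20, 21, 22),
    stringsAsFactors = FALSE)
  FeatureTable(d, c("sex", "jitter", "hnr"))
}

# lightweight metadata-only cohort (no audio) for structural tests
synthAudioMeta <- function(nSubj, nRec) {
  set.seed(1)
  d <- expand.grid(recording_id = paste0("r", seq_len(nRec)),
                   subject_id = sprintf("S%02d", seq_len(nSubj)),
                   stringsAsFactors = FALSE)
  d$label <- ifelse(as.integer(sub("S", "", d$subject_id)) <= nSubj / 2, "PD", "healthy")
  d$sex <- "male"; d$age <- 60L
  d$f01 <- rnorm(nrow(d))
  FeatureTable(d[, c("subject_id", "recording_id", "label", "sex", "age", "f01")])
}

test_that("aggregation averages a subject's recordings component-wise", {
  agg <- aggregateBySubject(miniTable())
  d <- tableData(agg)
  expect_equal(nrow(d), 2)
  expect_equal(d$jitter[d$subject_id == "S1"], 2)
  expect_equal(d$hnr[d$subject_id == "S2"], 21)
  expect_identical(d$label, c("PD", "healthy"))
  # idempotent on an aggregated table
  expect_equal(tableData(aggregateBySubject(agg))$jitter, d$jitter)
})

test_that("aggregation excludes missing values and keeps 60 x 3 -> 60", {
  ft <- miniTable()
  ft@data$jitter[2] <- NA
  agg <- aggregateBySubject(ft)
  expect_equal(tableData(agg)$jitter[1], 2)  # mean of 1, 3
  big <- synthAudioMeta(60, 3)
  expect_equal(nrow(tableData(aggregateBySubject(big))), 60)
})

test_that("conflicting labels within a subject raise a consistency error", {
  ft <- miniTable()
  ft@data$label[2] <- "healthy"
  expect_error(aggregateBySubject(ft), class = "phonoPD_consistency_error")
})

test_that("standardization gives zero mean unit sd and guards constants", {
  ft <- synthCohort(nPerClass = 10, nFeatures = 3, seed = 2)
  ft@data$f03 <- 5  # constant column
  sc <- standardizeFit(ft)
  z <- featureMatrix(standardizeApply(sc, ft))
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z[, 1:2], 2, sd) - 1)), 1e-9)
  expect_true(all(z[, "f03"] == 0))
})

test_that("test tables are scaled with training statistics only", {
  train <- synthCohort(nPerClass = 10, nFeatures = 2, seed = 3)
  test <- synthCohort(nPerClass = 5, nFeatures = 2, seed = 4)
  sc <- standardizeFit(train)
  test@data$f01[] <- sc@center["f01"]  # a test column at the train mean
  z <- featureMatrix(standardizeApply(sc, test))
  expect_true(all(abs(z[, "f01"]) < 1e-12))
})

test_that("standardization is affine-equivariant in the raw feature scale", {
  ft <- synthCohort(nPerClass = 10, nFeatures = 2, seed = 5)
  z1 <- featureMatrix(standardizeApply(standardizeFit(ft), ft))
  ft2 <- ft
  ft2@data$f01 <- 100 * ft2@data$f01 - 7
  z2 <- featureMatrix(standardizeApply(standardizeFit(ft2), ft2))
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("scaler/table schema mismatches are rejected", {
  a <- synthCohort(nPerClass = 5, nFeatures = 2, seed = 6)
  b <- synthCohort(nPerClass = 5, nFeatures = 3, seed = 6)
  expect_error(standardizeApply(standardizeFit(a), b), class = "phonoPD_schema_error")
})

test_that("CSV round trip is lossless including missing cells", {
  ft <- miniTable()
  ft@data$hnr[4] <- NA
  f <- tempfile(fileext = ".csv")
  writeFeatureTable(ft, f)
  back <- readFeatureTable(f)
  expect_equal(tableData(back)$jitter, tableData(ft)$jitter)
  expect_true(is.na(tableData(back)$hnr[4]))        # empty cell -> NA, not 0
  expect_identical(featureNames(back), c("jitter", "hnr"))
  unlink(f)
})

test_that("CSV parse errors carry the offending row", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,recording_id,label,sex,age,f01",
               "S1,r1,PD,male,70,1.5",
               "S1,r1,PD,male,70,2.0"), f)
  expect_error(readFeatureTable(f), "row 2", class = "phonoPD_parse_error")
  writeLines(c("subject_id,recording_id,label,sex,age,f01",
               "S1,r1,PD,male,70,abc"), f)
  expect_error(readFeatureTable(f), "row 1", class = "phonoPD_parse_error")
  writeLines(c("subject_id,recording_id,label,sex,age,f01",
               "S1,r1,sick,male,70,1"), f)
  expect_error(readFeatureTable(f), class = "phonoPD_parse_error")
  unlink(f)
})

test_that("the sex indicator is encoded male = 0 / female = 1 in the matrix", {
  m <- featureMatrix(miniTable())
  expect_identical(unname(m[, "sex"]), c(0, 0, 0, 1, 1, 1))
  expect_identical(colnames(m), c("sex", "jitter", "hnr"))
})

test_that("the canonical feature list has 33 names with sex leading", {
  expect_length(pdFeatureNames(), 33)
  expect_identical(pdFeatureNames()[1], "sex")
  expect_length(pdFeatureNames(includeSex = FALSE), 32)
  expect_true(all(c("rpde", "mfsw", "mfcc_13", "gq_prc5_95") %in% pdFeatureNames()))
})

test_that("duplicate keys are rejected at construction", {
  d <- tableData(miniTable())
  d$recording_id[2] <- "r1"
  expect_error(FeatureTable(d, c("sex", "jitter", "hnr")), "duplicated")
})
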