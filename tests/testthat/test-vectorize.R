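test_that("structured encoding follows the documented rules", {
  b <- encodeStructured(makeRecord(lymphatic_invasion = TRUE,
                                   pt_stage = "pT2", sex = "male"))
  v <- setNames(b@values, b@names)
  expect_equal(v[["lymphatic_invasion"]], 1)
  expect_equal(v[["pt_stage"]], 2)        # pT1 -> 1 ... pT4b -> 6
  expect_equal(v[["sex"]], 1)             # label, one-hot expanded later
  b2 <- encodeStructured(makeRecord(pt_stage = "pT4b", pn_stage = "pN2b",
                                    hpv_positive = NULL))
  v2 <- setNames(b2@values, b2@names)
  expect_equal(v2[["pt_stage"]], 6)
  expect_equal(v2[["pn_stage"]], 2)       # pN2a/b/c collapse
  expect_true(is.na(v2[["hpv_positive"]]))
  expect_error(
    encodeStructured(list(pt_stage = "pT9", patient_id = "001")),
    "decision table")
})

test_that("blood encoding passes hematology raw values and excludes the rest", {
  rec <- makeRecord(blood = list(
    hemoglobin = list(value = 14.1, unit = "g/dL", group = "hematology"),
    crp = list(value = 12, unit = "mg/L", group = "inflammation")))
  b <- encodeBlood(rec)
  v <- setNames(b@values, b@names)
  expect_equal(v[["blood.hemoglobin"]], 14.1)
  expect_false("blood.crp" %in% b@names)
  expect_true(all(is.na(v[setdiff(b@names, "blood.hemoglobin")])))
  empty <- encodeBlood(makeRecord(blood = list()))
  expect_true(all(is.na(empty@values)))
  expect_length(empty@values, 8)
})

test_that("ICD bag-of-words applies truncation and minimum support", {
  recs <- list(makeRecord("001", icd_codes = c("C32.0")),
               makeRecord("002", icd_codes = c("C32.0")),
               makeRecord("003", icd_codes = c("C32.0", "C10.8")),
               makeRecord("004", icd_codes = c("C10.8")))
  co <- newCohort(recs)
  enc <- encodeICD(co, minSupport = 3)
  expect_identical(enc$vocabulary, "C32.")
  expect_equal(unname(enc$counts[, "C32."]), c(1, 1, 1, 0))
  # empty code list -> zero vector; all codes below support -> zero width
  co2 <- newCohort(list(makeRecord("001", icd_codes = character(0)),
                        makeRecord("002", icd_codes = c("Z51.5"))))
  enc2 <- encodeICD(co2, minSupport = 3)
  expect_length(enc2$vocabulary, 0)
  expect_equal(ncol(enc2$counts), 0)
})

test_that("ICD vocabulary is invariant to patient ordering", {
  co <- cachedCohort(60, seed = 77)
  enc <- encodeICD(co)
  perm <- co[sample(patientIds(co))]  # subsetting re-sorts; same set
  enc2 <- encodeICD(perm)
  expect_identical(enc$vocabulary, enc2$vocabulary)
  expect_identical(enc$counts, enc2$counts)
})

test_that("TMA encoding is a fixed-order pass-through that rejects negatives", {
  b <- encodeTMA(makeRecord())
  expect_equal(unname(b@values), c(500, 300, 200, 100))
  allNA <- encodeTMA(makeRecord(tma_density = NULL))
  expect_true(all(is.na(allNA@values)))
  expect_length(allNA@values, 4)
  expect_error(encodeTMA(makeRecord(
    tma_density = list(CD3_tumor_center = -1))), "negative")
})

test_that("assembled vectors honor the normalization contract", {
  co <- cachedCohort(60, seed = 77)
  vs <- assembleVectors(co)
  m <- vectorMatrix(vs)
  scaled <- featureKind(vs) %in% c("ordinal", "numeric")
  nondeg <- scaled & apply(m, 2, function(x) length(unique(x)) > 1)
  expect_lt(max(abs(colMeans(m[, nondeg]))), 1e-9)
  expect_lt(max(abs(apply(m[, nondeg], 2, var) - 1)), 1e-9)
  # concatenated dimension = sum of block dimensions, fixed modality order
  expect_identical(unique(featureModality(vs)),
                   c("clinical_pathological", "blood", "icd", "tma"))
  expect_equal(nrow(vs), sum(table(featureModality(vs))))
})

test_that("one-hot expands to exactly the observed level count", {
  co <- newCohort(list(makeRecord("001", primary_site = "larynx"),
                       makeRecord("002", primary_site = "oropharynx"),
                       makeRecord("003", primary_site = "oral_cavity"),
                       makeRecord("004", primary_site = "larynx")))
  vs <- assembleVectors(co)
  siteCols <- SummarizedExperiment::rowData(vs)$sourceFeature == "primary_site"
  expect_equal(sum(siteCols), 3)  # 3 observed of 5 declared levels
})

test_that("completeness flags are decided before imputation and survive it", {
  co <- cachedCohort(60, seed = 77)
  broken <- injectMissingness(co, c(tma_density = 1), seed = 1)
  vs <- assembleVectors(broken)
  expect_false(any(isComplete(vs)))               # all TMA blocks blanked
  expect_true(all(is.finite(vectorMatrix(vs))))   # yet everything imputed
})

test_that("2-D projection is rescaled to [0,1], deterministic, needs n >= 3", {
  co <- cachedCohort(60, seed = 77)
  vs <- assembleVectors(co)
  p1 <- project2D(vs, seed = 4)
  expect_equal(unname(apply(p1, 2, min)), c(0, 0))
  expect_equal(unname(apply(p1, 2, max)), c(1, 1))
  expect_true(all(is.finite(p1)))
  expect_identical(p1, project2D(vs, seed = 4))
  expect_error(project2D(vectorMatrix(vs)[1:2, ]), "argument error")
  p3 <- project2D(matrix(rnorm(24), 3), seed = 1)
  expect_equal(dim(p3), c(3L, 2L))
})
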