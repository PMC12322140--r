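test_that("the generator is deterministic under a fixed seed", {
  c1 <- generateCohort(simConfig(nPatients = 30, seed = 11))
  c2 <- generateCohort(simConfig(nPatients = 30, seed = 11))
  expect_identical(records(c1), records(c2))
  c3 <- generateCohort(simConfig(nPatients = 30, seed = 12))
  expect_false(identical(records(c1), records(c3)))
})

test_that("generator output always passes record validation", {
  for (s in 1:3) {
    co <- generateCohort(simConfig(nPatients = 40, seed = 400 + s))
    expect_true(validObject(co))
  }
})

test_that("marginal demographics match their binomial targets at n = 2000", {
  co <- cachedCohort(2000, seed = 9)
  recs <- records(co)
  maleFrac <- mean(vapply(recs, function(r) r$sex == "male", logical(1)))
  sdMale <- sqrt(0.8 * 0.2 / 2000)
  expect_lt(abs(maleFrac - 0.80), 3 * sdMale)
  smokerFrac <- mean(vapply(recs, function(r) r$smoking_status != "never",
                            logical(1)))
  expect_lt(abs(smokerFrac - 0.72), 3 * sqrt(0.72 * 0.28 / 2000))
  ages <- vapply(recs, function(r) r$age_at_diagnosis, numeric(1))
  expect_lt(abs(median(ages) - 61), 2)
})

test_that("null effect sizes reduce outcomes to the base prevalence", {
  cfg <- simConfig(nPatients = 1500, seed = 21,
                   outcomeModel = list(stage = 0, blood = 0, immune = 0,
                                       icd = 0, frailty = 0, anomalyRisk = 0,
                                       recurrenceBase = -1.1, deathBase = -0.9),
                   siteConfounding = 0, atypicalFraction = 0)
  co <- generateCohort(cfg)
  hadRec <- vapply(records(co), function(r) !is.null(r$recurrence_days),
                   logical(1))
  # observed-within-followup rate underestimates the planted prevalence
  # slightly; compare against the planted plogis(-1.1) with 3 sigma slack
  p0 <- plogis(-1.1)
  expect_lt(abs(mean(hadRec) - p0), 3 * sqrt(p0 * (1 - p0) / 1500) + 0.02)
})

test_that("event days are consistent with status and follow-up", {
  co <- cachedCohort(200, seed = 5)
  for (r in records(co)) {
    if (!is.null(r$death_days)) {
      expect_identical(r$followup_days, r$death_days)
    }
    if (!is.null(r$recurrence_days)) {
      expect_lte(r$recurrence_days, r$followup_days)
    }
  }
})

test_that("injected missingness hits its configured rates", {
  co <- cachedCohort(400, seed = 23, missingRates = c(blood = 0))
  out <- injectMissingness(co, c(blood = 0.2), seed = 7)
  frac <- 1 - mean(vapply(records(out), function(r) length(r$blood),
                          numeric(1))) /
    mean(vapply(records(co), function(r) length(r$blood), numeric(1)))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / (400 * 12)))
  expect_identical(records(injectMissingness(co, c(blood = 0), seed = 1)),
                   records(co))
  allGone <- injectMissingness(co, c(tma_density = 1), seed = 1)
  dens <- unlist(lapply(records(allGone), function(r) r$tma_density))
  expect_null(dens)
  expect_error(injectMissingness(co, c(blood = 1.5)), "config error")
})

test_that("planted outliers are returned and geometrically extreme", {
  co <- cachedCohort(200, seed = 5)
  pl <- plantOutliers(co, k = 10, scale = 5, seed = 3)
  expect_length(pl$outlierIds, 10)
  m <- vectorMatrix(assembleVectors(pl$cohort))
  centroid <- colMeans(m)
  dCen <- apply(m, 1, function(x) cosineDistance(x, centroid))
  expect_gt(mean(dCen[pl$outlierIds]),
            mean(dCen[setdiff(rownames(m), pl$outlierIds)]))
  # degenerate arguments
  none <- plantOutliers(co, k = 0)
  expect_identical(records(none$cohort), records(co))
  expect_length(none$outlierIds, 0)
  all10 <- plantOutliers(co[1:10], k = 10, scale = 1, seed = 1)
  expect_setequal(all10$outlierIds, patientIds(co)[1:10])
  expect_error(plantOutliers(co, k = 500), "argument error")
})

test_that("site confounding shifts feature means under a site holdout", {
  co <- cachedCohort(200, seed = 5)  # siteConfounding = 1 by default
  vs <- assembleVectors(co)
  m <- vectorMatrix(vs)
  sp <- siteHoldoutSplit(co, "oropharynx")
  numc <- featureKind(vs) == "numeric"
  delta <- abs(colMeans(m[testIds(sp), numc, drop = FALSE]) -
               colMeans(m[trainIds(sp), numc, drop = FALSE]))
  expect_gt(max(delta), 0.3)  # a clear standardized mean shift somewhere
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nPatients = 0), "config error")
  expect_error(simConfig(maleFraction = 1.2), "config error")
  expect_error(simConfig(siteProbs = c(oral_cavity = 1)), "config error")
})
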