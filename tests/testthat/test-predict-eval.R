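test_that("recurrence labels implement the three-year class definitions", {
  co <- newCohort(list(
    makeRecord("001", recurrence_days = 400L),
    makeRecord("002", followup_days = 1500L),
    makeRecord("003", followup_days = 700L),
    makeRecord("004", recurrence_days = 1400L, followup_days = 2000L),
    makeRecord("005", death_days = 600L, followup_days = 600L,
               death_tumor_specific = TRUE)))
  st <- labelStatus(buildRecurrenceLabels(co))
  expect_equal(unname(as.character(st[c("001", "002", "003", "004", "005")])),
               c("positive", "negative", "excluded", "excluded", "excluded"))
})

test_that("survival labels exclude only non-tumor-specific deaths", {
  co <- newCohort(list(
    makeRecord("001", death_days = 900L, followup_days = 900L,
               death_tumor_specific = TRUE),
    makeRecord("002", death_days = 900L, followup_days = 900L,
               death_tumor_specific = NULL),   # unknown cause: kept
    makeRecord("003", death_days = 900L, followup_days = 900L,
               death_tumor_specific = FALSE),
    makeRecord("004", followup_days = 2000L)))
  st <- labelStatus(buildSurvivalLabels(co))
  expect_equal(unname(as.character(st)),
               c("positive", "positive", "excluded", "negative"))
})

test_that("SMOTE balances classes by interpolation and reduces k if needed", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(10, 5), 5))
  y <- c(rep(0, 20), rep(1, 5))
  bal <- smote(x, y, k = 5, seed = 2)
  expect_equal(sum(bal$y == 1), sum(bal$y == 0))
  # synthetic points lie within the minority convex region, far from majority
  synth <- bal$x[26:nrow(bal$x), , drop = FALSE]
  expect_true(all(rowMeans(synth) > 2))
  expect_message(smote(x[c(1:20, 21:22), ], c(rep(0, 20), 1, 1), k = 5,
                       seed = 1), "reducing neighbor count")
  expect_error(smote(x, rep(0, 25)), "both classes")
})

test_that("a linearly separable task reaches test AUC 1", {
  co <- cachedCohort(400, seed = 31)
  # label = high hemoglobin; separable through the blood block
  hb <- vapply(records(co), function(r) {
    v <- r$blood$hemoglobin$value
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  hb[is.na(hb)] <- median(hb, na.rm = TRUE)
  status <- factor(ifelse(hb > median(hb), "positive", "negative"),
                   levels = c("positive", "negative", "excluded"))
  labs <- new("OutcomeLabels", task = "recurrence",
              patientIds = patientIds(co), status = status,
              reason = rep("", 400))
  ids <- patientIds(co)
  set.seed(4)
  te <- sort(sample(ids, 80))
  sc <- fitPredict(co, setdiff(ids, te), te, labs, seed = 9)
  y <- as.numeric(labelStatus(labs)[names(sc)] == "positive")
  expect_equal(aucScore(sc, y), 1, tolerance = 1e-6)
})

test_that("randomly permuted labels give chance-level AUC", {
  co <- cachedCohort(200, seed = 5)
  labs <- buildRecurrenceLabels(co)
  st <- labelStatus(labs)
  ids <- patientIds(co)[st != "excluded"]
  aucs <- numeric(20)
  set.seed(77)
  for (r in 1:20) {
    perm <- new("OutcomeLabels", task = "recurrence",
                patientIds = patientIds(co),
                status = factor(
                  replace(as.character(st), match(ids, patientIds(co)),
                          sample(as.character(st[ids]))),
                  levels = c("positive", "negative", "excluded")),
                reason = rep("", length(st)))
    te <- sort(sample(ids, 60))
    tr <- setdiff(ids, te)
    sc <- fitPredict(co, tr, te, perm, seed = 1000 + r)
    aucs[r] <- aucScore(sc, as.numeric(labelStatus(perm)[names(sc)] ==
                                         "positive"))
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("no information from test patients enters the fitted pipeline", {
  co <- cachedCohort(200, seed = 5)
  labs <- buildRecurrenceLabels(co)
  st <- labelStatus(labs)
  ids <- patientIds(co)[st != "excluded"]
  set.seed(8)
  te <- sort(sample(ids, 40))
  tr <- setdiff(ids, te)
  sc1 <- fitPredict(co, tr, te, labs, seed = 3)
  # perturb one test patient's data wildly; other test scores must not move
  recs <- records(co)
  idx <- match(te[1], patientIds(co))
  recs[[idx]]$blood$hemoglobin$value <- 999
  recs[[idx]]$icd_codes <- c("Z99.9")
  co2 <- newCohort(recs)
  sc2 <- fitPredict(co2, tr, te, labs, seed = 3)
  expect_identical(sc1[te[-1]], sc2[te[-1]])
  # the training-side encoder is identical
  expect_identical(fitVectorizer(co[tr]), fitVectorizer(co2[tr]))
})

test_that("the site holdout is a clean partition by primary site", {
  co <- cachedCohort(200, seed = 5)
  sp <- siteHoldoutSplit(co, "oropharynx")
  sites <- vapply(records(co), function(r) r$primary_site, character(1))
  names(sites) <- patientIds(co)
  expect_true(all(sites[testIds(sp)] == "oropharynx"))
  expect_true(all(sites[trainIds(sp)] != "oropharynx"))
  expect_setequal(c(trainIds(sp), testIds(sp)), patientIds(co))
  expect_error(siteHoldoutSplit(co, "nasopharynx"), "unknown site")
  onlyLarynx <- co[sites == "larynx"]
  expect_error(siteHoldoutSplit(onlyLarynx, "oropharynx"), "no patients")
})

test_that("the evaluation protocol reports per-repeat AUCs deterministically", {
  co <- cachedCohort(200, seed = 5)
  ids <- patientIds(co)
  set.seed(10)
  te <- sort(sample(ids, 40))
  sp <- new("SplitResult", trainIds = setdiff(ids, te), testIds = te,
            bestFitness = NA_real_, trace = numeric(0), mode = "manual")
  ev <- evaluateProtocol(co, list(manual = sp), tasks = "recurrence",
                         repeats = 3, seed = 6)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$repeats, 3)
  expect_length(attr(ev, "aucs")[["manual.recurrence"]], 3)
  expect_true(all(ev$meanAUC >= 0 & ev$meanAUC <= 1))
  curves <- attr(ev, "curves")[["manual.recurrence"]]
  expect_equal(nrow(curves), 101)
  expect_true(all(diff(curves$tpr) >= -1e-9))
  ev2 <- evaluateProtocol(co, list(manual = sp), tasks = "recurrence",
                          repeats = 3, seed = 6)
  expect_identical(ev, ev2)
  bad <- new("SplitResult", trainIds = "zzz", testIds = te,
             bestFitness = NA_real_, trace = numeric(0), mode = "manual")
  expect_error(evaluateProtocol(co, list(bad = bad)), "validation error")
})

test_that("ROC points and AUC agree with the independent pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- rbinom(60, 1, 0.4)
  sc <- rnorm(60) + y
  expect_equal(aucScore(sc, y),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))),
               tolerance = 1e-10)
  roc <- rocCurve(sc, y)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1)
})

test_that("single-class training sets are rejected", {
  co <- cachedCohort(60, seed = 77)
  labs <- buildRecurrenceLabels(co)
  st <- labelStatus(labs)
  pos <- patientIds(co)[st == "positive"]
  neg <- patientIds(co)[st == "negative"]
  expect_error(fitPredict(co, pos, neg[1:5], labs, seed = 1),
               "single-class")
})
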