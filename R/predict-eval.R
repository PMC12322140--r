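# Outcome-label construction, SMOTE rebalancing, Random-Forest
# prediction, and the three-split ROC/AUC evaluation protocol.
#
# Three years are 1095 days (day-resolution timeline, no leap handling).
# All preprocessing that touches data (ICD vocabulary, categorical
# levels, imputation, z-scoring) is fit on training patients only inside
# fitPredict, so no information from test patients leaks into the model.

.THREE_YEARS <- 1095L

#' Build binary recurrence labels
#'
#' Positive: recurrence within three years of diagnosis. Negative: no
#' recurrence, alive beyond (or no death before) three years, and at
#' least three years of follow-up. Everything else is excluded with a
#' reason (insufficient follow-up, late recurrence, early death without
#' recurrence).
#'
#' @param cohort A [Cohort].
#' @return An [OutcomeLabels] object (task `recurrence`).
#' @export
buildRecurrenceLabels <- function(cohort) {
  stopifnot(is(cohort, "Cohort"))
  ids <- patientIds(cohort)
  status <- character(length(ids))
  reason <- character(length(ids))
  for (i in seq_along(ids)) {
    r <- records(cohort)[[i]]
    rec <- .fieldOrNA(r, "recurrence_days")
    death <- .fieldOrNA(r, "death_days")
    fup <- r$followup_days
    if (!is.na(rec) && rec <= .THREE_YEARS) {
      status[i] <- "positive"; reason[i] <- ""
    } else if (!is.na(rec)) {
      status[i] <- "excluded"; reason[i] <- "recurrence_after_3_years"
    } else if (!is.na(death) && death <= .THREE_YEARS) {
      status[i] <- "excluded"; reason[i] <- "death_within_3_years_without_recurrence"
    } else if (fup < .THREE_YEARS) {
      status[i] <- "excluded"; reason[i] <- "insufficient_followup"
    } else {
      status[i] <- "negative"; reason[i] <- ""
    }
  }
  new("OutcomeLabels", task = "recurrence", patientIds = ids,
      status = factor(status, levels = c("positive", "negative", "excluded")),
      reason = reason)
}

#' Build binary survival-status labels
#'
#' Positive ("deceased"): death with tumor-specific or unknown cause.
#' Negative ("living"): alive at end of follow-up. Excluded:
#' non-tumor-specific death.
#'
#' @param cohort A [Cohort].
#' @return An [OutcomeLabels] object (task `survival`).
#' @export
buildSurvivalLabels <- function(cohort) {
  stopifnot(is(cohort, "Cohort"))
  ids <- patientIds(cohort)
  status <- character(length(ids))
  reason <- character(length(ids))
  for (i in seq_along(ids)) {
    r <- records(cohort)[[i]]
    death <- .fieldOrNA(r, "death_days")
    dts <- .fieldOrNA(r, "death_tumor_specific")
    if (is.na(death)) {
      status[i] <- "negative"; reason[i] <- ""
    } else if (!is.na(dts) && !dts) {
      status[i] <- "excluded"; reason[i] <- "non_tumor_specific_death"
    } else {
      status[i] <- "positive"; reason[i] <- ""
    }
  }
  new("OutcomeLabels", task = "survival", patientIds = ids,
      status = factor(status, levels = c("positive", "negative", "excluded")),
      reason = reason)
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary training set by interpolating synthetic minority
#' samples between each drawn minority point and one of its `k` nearest
#' minority neighbors (Euclidean), until both classes have equal counts.
#' When the minority class has fewer than `k + 1` members, `k` is
#' reduced automatically (with a message); a singleton minority class is
#' duplicated.
#'
#' @param x Numeric matrix (samples x features), no missing values.
#' @param y Binary vector (0/1) of length `nrow(x)`.
#' @param k Number of nearest neighbors (default 5).
#' @param seed Integer seed.
#' @return `list(x = <matrix>, y = <numeric>)` with equal class counts.
#' @export
smote <- function(x, y, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("SMOTE needs both classes present")
  if (n1 == n0) return(list(x = x, y = y))
  minority <- if (n1 < n0) 1 else 0
  need <- abs(n0 - n1)
  xm <- x[y == minority, , drop = FALSE]
  nm <- nrow(xm)
  set.seed(seed)
  if (nm == 1L) {
    message("SMOTE: singleton minority class; duplicating")
    synth <- xm[rep(1L, need), , drop = FALSE]
  } else {
    kUse <- min(k, nm - 1L)
    if (kUse < k) message("SMOTE: reducing neighbor count to ", kUse)
    dd <- as.matrix(dist(xm))
    diag(dd) <- Inf
    nnIdx <- matrix(0L, nrow = nm, ncol = kUse)
    for (i in seq_len(nm)) nnIdx[i, ] <- order(dd[i, ])[seq_len(kUse)]
    base <- sample.int(nm, need, replace = TRUE)
    pick <- sample.int(kUse, need, replace = TRUE)
    u <- runif(need)
    neigh <- nnIdx[cbind(base, pick)]
    synth <- xm[base, , drop = FALSE] +
      u * (xm[neigh, , drop = FALSE] - xm[base, , drop = FALSE])
  }
  list(x = rbind(x, synth), y = c(y, rep(minority, need)))
}

#' Fit a Random Forest on training patients and score held-out patients
#'
#' Fits the full leakage-safe pipeline: the encoder (ICD vocabulary,
#' categorical levels, imputation, z-scoring) is fit on the training
#' patients only and applied to the test patients; SMOTE balances the
#' training classes; a probability Random Forest (500 trees,
#' sqrt-features) produces positive-class scores.
#'
#' @param cohort A [Cohort] containing both train and test patients.
#' @param trainIds,testIds Patient IDs (disjoint).
#' @param labels An [OutcomeLabels] object; excluded patients must not
#'   appear among `trainIds`.
#' @param schema Encoding schema.
#' @param modalities Optional subset of modalities
#'   (`clinical_pathological`, `blood`, `icd`, `tma`) to use; default all.
#' @param numTrees,mtry Random Forest hyperparameters (defaults: 500
#'   trees, sqrt of feature count).
#' @param smoteK SMOTE neighbor count (default 5).
#' @param seed Integer seed controlling SMOTE and the forest.
#' @return Named numeric vector of positive-class scores for `testIds`.
#' @export
fitPredict <- function(cohort, trainIds, testIds, labels,
                       schema = defaultSchema(), modalities = NULL,
                       numTrees = 500L, mtry = NULL, smoteK = 5L, seed = 1L) {
  stopifnot(is(cohort, "Cohort"), is(labels, "OutcomeLabels"))
  if (length(intersect(trainIds, testIds))) stop("train and test IDs overlap")
  # cohort subsetting returns records sorted by patient_id; keep the
  # label vector and the returned scores aligned with that order
  trainIds <- sort(as.character(trainIds))
  testIds <- sort(as.character(testIds))
  st <- labelStatus(labels)
  yTrain <- st[trainIds]
  if (any(is.na(yTrain)) || any(yTrain == "excluded")) {
    stop("training IDs must carry a positive or negative label")
  }
  y <- as.numeric(yTrain == "positive")
  if (length(unique(y)) < 2L) stop("single-class training set")

  vec <- fitVectorizer(cohort[trainIds], schema)
  trainPV <- applyVectorizer(vec, cohort[trainIds])
  xTrain <- vectorMatrix(trainPV)
  xTest <- vectorMatrix(applyVectorizer(vec, cohort[testIds]))
  if (!is.null(modalities)) {
    keep <- featureModality(trainPV) %in% modalities
    xTrain <- xTrain[, keep, drop = FALSE]
    xTest <- xTest[, keep, drop = FALSE]
  }
  if (ncol(xTrain) == 0L) stop("no features left after modality selection")

  bal <- smote(xTrain, y, k = smoteK, seed = .subSeed(seed, "smote"))
  df <- as.data.frame(bal$x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- factor(bal$y, levels = c(0, 1))
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = df, probability = TRUE,
    num.trees = numTrees,
    mtry = if (is.null(mtry)) max(1L, floor(sqrt(ncol(xTrain)))) else mtry,
    seed = .subSeed(seed, "ranger"), num.threads = 1L
  )
  dfTest <- as.data.frame(xTest)
  names(dfTest) <- paste0("f", seq_len(ncol(dfTest)))
  scores <- predict(rf, data = dfTest, num.threads = 1L)$predictions[, "1"]
  setNames(as.numeric(scores), testIds)
}

#' Hold out one primary site as the test set
#'
#' All patients whose primary site equals `site` form the test set; the
#' rest form the training set.
#'
#' @param cohort A [Cohort].
#' @param site One of the primary-site levels (e.g. `"oropharynx"`).
#' @return A [SplitResult] with mode `site_holdout`.
#' @export
siteHoldoutSplit <- function(cohort, site) {
  stopifnot(is(cohort, "Cohort"))
  if (!site %in% .SITE_LEVELS) stop("unknown site: ", site)
  ids <- patientIds(cohort)
  sites <- vapply(records(cohort), function(r) r$primary_site, character(1))
  test <- ids[sites == site]
  train <- ids[sites != site]
  if (length(test) == 0L) stop("no patients with primary site ", site)
  if (length(train) == 0L) stop("all patients share primary site ", site)
  new("SplitResult", trainIds = train, testIds = test,
      bestFitness = NA_real_, trace = numeric(0), mode = "site_holdout")
}

#' ROC curve points
#'
#' @param scores Numeric classifier scores.
#' @param y Binary labels (1 = positive).
#' @return Data frame with columns `fpr`, `tpr` (stepwise, including the
#'   (0,0) and (1,1) anchors).
#' @export
rocCurve <- function(scores, y) {
  y <- as.integer(y)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  tp <- cumsum(ys)
  fp <- cumsum(1L - ys)
  # collapse tied scores to one operating point
  keep <- c(diff(scores[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / max(1L, sum(y == 0L))),
             tpr = c(0, tp[keep] / max(1L, sum(y == 1L))))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling.
#'
#' @inheritParams rocCurve
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(scores, y) .aucRank(scores, y)

# Interpolate a ROC curve onto a fixed FPR grid (linear, as used for
# threshold-wise curve averaging across repeats).
.interpROC <- function(roc, grid) {
  approx(roc$fpr, roc$tpr, xout = grid, method = "linear",
         ties = max, yleft = 0, yright = 1)$y
}

#' Evaluate the multi-split, multi-task prediction protocol
#'
#' For each supplied split and task, runs [fitPredict()] `repeats` times
#' with distinct derived seeds, averages the ROC curves threshold-wise on
#' a fixed 101-point FPR grid, and reports mean and standard deviation of
#' the AUC. Patients whose label is `excluded` are dropped from both
#' train and test sets of every run.
#'
#' @param cohort A [Cohort].
#' @param splits Named list of [SplitResult] objects (e.g. `in_dist`,
#'   `out_dist`, `site_holdout`).
#' @param tasks Character vector among `"recurrence"`, `"survival"`.
#' @param repeats Number of train/evaluate repetitions (default 5).
#' @param seed Master seed; per-run seeds are derived from it.
#' @param schema Encoding schema.
#' @param modalities Optional modality subset passed to [fitPredict()].
#' @return A data frame with one row per (split, task): `meanAUC`,
#'   `sdAUC`, `repeats`, `nTrain`, `nTest`. Attribute `"aucs"` holds the
#'   per-repeat AUC matrix; attribute `"curves"` the mean ROC curves on
#'   the FPR grid.
#' @export
evaluateProtocol <- function(cohort, splits, tasks = c("recurrence", "survival"),
                             repeats = 5L, seed = 1L, schema = defaultSchema(),
                             modalities = NULL) {
  stopifnot(is(cohort, "Cohort"), length(splits) >= 1L)
  if (is.null(names(splits)) || any(names(splits) == "")) {
    stop("splits must be a named list")
  }
  allIds <- patientIds(cohort)
  grid <- seq(0, 1, length.out = 101L)
  rows <- list()
  aucsAll <- list()
  curves <- list()
  for (sName in names(splits)) {
    sp <- splits[[sName]]
    if (!all(c(trainIds(sp), testIds(sp)) %in% allIds)) {
      stop("validation error: split ", sName, " references unknown patient IDs")
    }
    for (task in tasks) {
      labels <- switch(task,
                       recurrence = buildRecurrenceLabels(cohort),
                       survival = buildSurvivalLabels(cohort),
                       stop("unknown task: ", task))
      st <- labelStatus(labels)
      tr <- trainIds(sp)[st[trainIds(sp)] != "excluded"]
      te <- testIds(sp)[st[testIds(sp)] != "excluded"]
      aucs <- numeric(repeats)
      tprMat <- matrix(NA_real_, nrow = repeats, ncol = length(grid))
      for (r in seq_len(repeats)) {
        runSeed <- .subSeed(seed, paste(sName, task, r, sep = "|"))
        scores <- fitPredict(cohort, tr, te, labels, schema = schema,
                             modalities = modalities, seed = runSeed)
        yTest <- as.numeric(st[names(scores)] == "positive")
        aucs[r] <- aucScore(scores, yTest)
        tprMat[r, ] <- .interpROC(rocCurve(scores, yTest), grid)
      }
      key <- paste(sName, task, sep = ".")
      aucsAll[[key]] <- aucs
      curves[[key]] <- data.frame(fpr = grid, tpr = colMeans(tprMat),
                                  sdTpr = apply(tprMat, 2, sd))
      rows[[key]] <- data.frame(split = sName, task = task,
                                meanAUC = mean(aucs), sdAUC = sd(aucs),
                                repeats = repeats, nTrain = length(tr),
                                nTest = length(te), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "aucs") <- aucsAll
  attr(out, "curves") <- curves
  out
}
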