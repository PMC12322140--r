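# Small bag sets keep these tests fast; the full-scale recovery runs in
# the acceptance suite.

tinyBags <- function(nBags = 24, seed = 1, d = 16, m = 12, shift = 3) {
  set.seed(seed)
  lapply(seq_len(nBags), function(i) {
    y <- as.numeric(i <= nBags / 2)
    H <- matrix(rnorm(m * d), m)
    if (y == 1) H[1:2, 1] <- H[1:2, 1] + shift
    new("Bag", patientId = sprintf("%03d", i), instances = H,
        sourceTags = rep("WSI", m), label = y)
  })
}

test_that("MIL survival labels implement removal and force-labeling", {
  co <- newCohort(list(
    makeRecord("001", death_days = 400L, followup_days = 400L),
    makeRecord("002", death_days = 2000L, followup_days = 2000L),
    makeRecord("003", followup_days = 800L),
    makeRecord("004", followup_days = 1200L)))
  st <- labelStatus(milSurvivalLabels(co))
  expect_equal(unname(as.character(st)),
               c("positive", "negative", "excluded", "negative"))
})

test_that("bag assembly follows the configured sizes and tags", {
  co <- cachedCohort(60, seed = 77)
  labs <- milSurvivalLabels(co)
  bags <- makeBags(co, labs, sources = c("WSI", "TMA:CD8"),
                   wsiInstances = 10, tmaTilesPerCore = 32,
                   coresPerStain = 2, embedDim = 8, seed = 2)
  b <- bags[[1]]
  expect_equal(nrow(b@instances), 10 + 32 * 2)
  expect_equal(sum(b@sourceTags == "TMA:CD8"), 64)
  expect_equal(ncol(b@instances), 8)
  onlyWSI <- makeBags(co, labs, sources = "WSI", wsiInstances = 6,
                      embedDim = 8, seed = 2)
  expect_true(all(vapply(onlyWSI, function(b)
    all(b@sourceTags == "WSI"), logical(1))))
  # excluded patients are skipped
  nLabeled <- sum(labelStatus(labs) != "excluded")
  expect_length(bags, nLabeled)
  expect_error(makeBags(co, labs, sources = "TMA:XYZ"), "unknown source")
})

test_that("bag assembly is deterministic under its seed", {
  co <- cachedCohort(60, seed = 77)
  labs <- milSurvivalLabels(co)
  b1 <- makeBags(co, labs, sources = "WSI", wsiInstances = 6, embedDim = 8,
                 seed = 5)
  b2 <- makeBags(co, labs, sources = "WSI", wsiInstances = 6, embedDim = 8,
                 seed = 5)
  expect_identical(lapply(b1, function(b) b@instances),
                   lapply(b2, function(b) b@instances))
})

test_that("training is reproducible and the loss trace decreases in trend", {
  bags <- tinyBags()
  par <- milParams(epochs = 12, restarts = 1, seed = 4)
  m1 <- trainMIL(bags, par)
  m2 <- trainMIL(bags, par)
  expect_identical(m1@weights, m2@weights)
  tr <- m1@lossTrace$bagLoss
  expect_lt(mean(tail(tr, 3)), mean(head(tr, 3)))
})

test_that("zero clustering weight removes the instance loss term", {
  bags <- tinyBags()
  m <- trainMIL(bags, milParams(epochs = 5, clusteringLossWeight = 0,
                                restarts = 1, seed = 4))
  expect_true(all(m@lossTrace$instanceLoss == 0))
  m2 <- trainMIL(bags, milParams(epochs = 5, clusteringLossWeight = 0.5,
                                 restarts = 1, seed = 4))
  expect_true(any(m2@lossTrace$instanceLoss > 0))
})

test_that("attention weights normalize, expose top instances, check dims", {
  bags <- tinyBags()
  m <- trainMIL(bags, milParams(epochs = 8, restarts = 1, seed = 4))
  att <- attend(m, bags[[1]])
  expect_equal(sum(att@instanceWeights), 1, tolerance = 1e-6)
  expect_true(all(att@instanceWeights >= 0))
  expect_length(topInstances(att, 3), 3)
  single <- new("Bag", patientId = "x",
                instances = matrix(rnorm(16), 1), sourceTags = "WSI",
                label = NA_real_)
  expect_equal(attend(m, single)@instanceWeights, 1)
  wrong <- new("Bag", patientId = "x", instances = matrix(rnorm(10), 2),
               sourceTags = c("WSI", "WSI"), label = NA_real_)
  expect_error(attend(m, wrong), "dimension mismatch")
})

test_that("attention is permutation-equivariant and scores are invariant", {
  bags <- tinyBags()
  m <- trainMIL(bags, milParams(epochs = 8, restarts = 1, seed = 4))
  b <- bags[[3]]
  set.seed(9)
  perm <- sample(nrow(b@instances))
  bp <- new("Bag", patientId = b@patientId,
            instances = b@instances[perm, ], sourceTags = b@sourceTags[perm],
            label = b@label)
  a1 <- attend(m, b)
  a2 <- attend(m, bp)
  expect_equal(a2@instanceWeights, a1@instanceWeights[perm],
               tolerance = 1e-12)
  expect_equal(a2@bagScore, a1@bagScore, tolerance = 1e-12)
})

test_that("per-source attention sums partition each bag's unit weight", {
  set.seed(3)
  bags <- lapply(1:8, function(i) {
    H <- matrix(rnorm(10 * 16), 10)
    new("Bag", patientId = sprintf("%03d", i), instances = H,
        sourceTags = rep(c("WSI", "TMA:CD8"), each = 5),
        label = as.numeric(i <= 4))
  })
  m <- trainMIL(bags, milParams(epochs = 5, restarts = 1, seed = 2))
  summ <- modalityAttentionSummary(m, bags)
  expect_setequal(summ$summary$source, c("WSI", "TMA:CD8"))
  expect_equal(sum(summ$summary$totalWeightShare), 1, tolerance = 1e-9)
  perBag <- attend(m, bags[[1]])
  expect_equal(sum(perBag@instanceWeights[perBag@sourceTags == "WSI"]) +
                 sum(perBag@instanceWeights[perBag@sourceTags == "TMA:CD8"]),
               1, tolerance = 1e-9)
})

test_that("degenerate training inputs are rejected", {
  bags <- tinyBags(8)
  oneClass <- bags[1:4]
  expect_error(trainMIL(oneClass, milParams(epochs = 2)), "two bags per class")
  noLabel <- bags
  noLabel[[1]]@label <- NA_real_
  expect_error(trainMIL(noLabel, milParams(epochs = 2)), "labels")
})
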