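test_that("cosine distance obeys its geometric anchors and conventions", {
  expect_equal(cosineDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosineDistance(c(1, 0), c(-1, 0)), 2)
  expect_equal(cosineDistance(c(1, 0), c(0, 1)), 1)
  expect_warning(d <- cosineDistance(c(0, 0), c(1, 1)), "zero-norm")
  expect_equal(d, 1)
})

test_that("balance penalty matches hand-computed values", {
  labs <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  # test fractions equal the overall fractions -> 0
  expect_equal(balancePenalty(c(TRUE, FALSE, FALSE, TRUE), labs, alpha = 1), 0)
  # all-positive test set, d_all = (0.5, 0.5), alpha = 1 -> 1.0
  expect_equal(balancePenalty(c(TRUE, FALSE, FALSE, FALSE), labs, alpha = 1), 1)
  # fractions differing from (0.25, 0.75), alpha = 2
  labs3 <- cbind(a = c(1, 0, 0, 0), b = c(1, 1, 1, 0))
  expect_equal(balancePenalty(c(TRUE, TRUE, TRUE, TRUE), labs3, alpha = 2),
               2 * (abs(0.25 - 0.25) + abs(0.75 - 0.75)))
  expect_equal(balancePenalty(c(TRUE, FALSE, TRUE, TRUE), labs3, alpha = 2),
               2 * (abs(1 / 3 - 0.25) + abs(2 / 3 - 0.75)))
  expect_error(balancePenalty(c(FALSE, FALSE), cbind(c(1, 0)), 1),
               "argument error")
})

test_that("fitness terms reproduce closed-form configurations", {
  # two orthogonal unit test points among three
  X <- rbind(c(1, 0), c(0, 1), c(1, 1))
  pr <- splitProblem(X, NULL, testFraction = 2 / 3, mode = "in_distribution")
  expect_equal(fitnessIn(c(TRUE, TRUE, FALSE), pr), 2)
  # identical test points -> 0
  X2 <- rbind(c(1, 1), c(1, 1), c(0, 1))
  pr2 <- splitProblem(X2, NULL, testFraction = 2 / 3,
                      mode = "in_distribution")
  expect_equal(fitnessIn(c(TRUE, TRUE, FALSE), pr2), 0)
  # one antipodal pair -> 2 in out-of-distribution mode
  X3 <- rbind(c(1, 0), c(-1, 0), c(0, 1))
  pr3 <- splitProblem(X3, NULL, testFraction = 2 / 3,
                      mode = "out_of_distribution")
  expect_equal(fitnessOut(c(TRUE, TRUE, FALSE), pr3), 2)
  expect_error(fitnessIn(c(TRUE, FALSE, FALSE), pr), "argument error")
})

test_that("fitness agrees with brute-force oracles on random instances", {
  set.seed(42)
  for (rep in 1:5) {
    X <- matrix(rnorm(8 * 5), 8)
    pr <- splitProblem(X, NULL, testFraction = 3 / 8,
                       mode = "in_distribution")
    mask <- logical(8)
    mask[sample(8, 3)] <- TRUE
    idx <- which(mask)
    # nearest-neighbor oracle by direct enumeration
    nnSum <- sum(vapply(idx, function(i) {
      min(vapply(setdiff(idx, i), function(j)
        cosineDistance(X[i, ], X[j, ]), numeric(1)))
    }, numeric(1)))
    expect_equal(fitnessIn(mask, pr), nnSum, tolerance = 1e-10)
    prO <- splitProblem(X, NULL, testFraction = 3 / 8,
                        mode = "out_of_distribution")
    pairSum <- sum(apply(combn(idx, 2), 2, function(p)
      cosineDistance(X[p[1], ], X[p[2], ])))
    expect_equal(fitnessOut(mask, prO), pairSum, tolerance = 1e-10)
  }
})

test_that("the exhaustive oracle finds planted optima and breaks ties", {
  # planted antipodal pair must be selected in out-of-distribution mode
  set.seed(7)
  X <- matrix(rnorm(6 * 4, sd = 0.1), 6) + 1
  X[5, ] <- c(3, 0, 0, 0)
  X[6, ] <- c(-3, 0, 0, 0)
  pr <- splitProblem(X, NULL, testFraction = 2 / 6,
                     mode = "out_of_distribution")
  orc <- exhaustiveSplitOracle(pr)
  expect_setequal(orc$testIds, c("5", "6"))
  # all-identical points: every mask ties; lexicographically smallest mask
  Xi <- matrix(1, 4, 3)
  pri <- splitProblem(Xi, NULL, testFraction = 0.5,
                      mode = "out_of_distribution")
  orci <- exhaustiveSplitOracle(pri)
  expect_identical(orci$testIds, c("3", "4"))  # mask (0,0,1,1) is smallest
  expect_error(exhaustiveSplitOracle(
    splitProblem(matrix(rnorm(60 * 2), 60), NULL, testFraction = 0.5,
                 mode = "in_distribution")), "too large")
})

test_that("the GA respects cardinality, partition, monotone trace and seeds", {
  co <- cachedCohort(60, seed = 77)
  vs <- assembleVectors(co)
  pr <- splitProblem(vs, labelMatrix(co), testFraction = 0.2,
                     mode = "in_distribution")
  par <- gaParams(populationSize = 60, stagnationLimit = 10,
                  maxGenerations = 60, seed = 3)
  res <- runGA(pr, par)
  expect_length(testIds(res), round(0.2 * 60))
  expect_setequal(c(trainIds(res), testIds(res)), patientIds(co))
  expect_length(intersect(trainIds(res), testIds(res)), 0)
  expect_true(all(diff(res@trace) >= 0))
  res2 <- runGA(pr, par)
  expect_identical(testIds(res2), testIds(res))
  expect_identical(res2@bestFitness, res@bestFitness)
})

test_that("ineligible patients are assigned to the training set", {
  co <- cachedCohort(60, seed = 77)
  vs <- assembleVectors(co)
  elig <- rep(TRUE, 60)
  elig[c(3, 10, 25)] <- FALSE
  pr <- splitProblem(vs, NULL, testFraction = 0.25,
                     mode = "in_distribution", eligible = elig)
  res <- runGA(pr, gaParams(populationSize = 40, stagnationLimit = 5,
                            maxGenerations = 20, seed = 1))
  expect_true(all(patientIds(co)[c(3, 10, 25)] %in% trainIds(res)))
  expect_false(any(patientIds(co)[c(3, 10, 25)] %in% testIds(res)))
})

test_that("oracle fitness bounds the GA on shared instances", {
  set.seed(13)
  X <- matrix(rnorm(10 * 6), 10)
  L <- cbind(rbinom(10, 1, 0.5))
  for (mode in c("in_distribution", "out_of_distribution")) {
    pr <- splitProblem(X, L, testFraction = 0.2, mode = mode)
    orc <- exhaustiveSplitOracle(pr)
    ga <- runGA(pr, gaParams(populationSize = 50, stagnationLimit = 10,
                             maxGenerations = 50, seed = 2))
    expect_lte(ga@bestFitness, orc$fitness + 1e-9)
  }
})

test_that("in-distribution test sets sit closer to the training data", {
  # compare on a cohort that actually contains distributional outliers:
  # the out-of-distribution objective pulls them into the test set, the
  # nearest-neighbor objective keeps the test set representative
  co <- cachedCohort(200, seed = 5)
  pl <- plantOutliers(co, k = 10, scale = 5, seed = 3)
  vs <- assembleVectors(pl$cohort)
  m <- vectorMatrix(vs)
  cs <- tcrossprod(m / sqrt(rowSums(m^2)))
  nnToTrain <- function(res) {
    mean(vapply(testIds(res), function(i)
      1 - max(cs[i, trainIds(res)]), numeric(1)))
  }
  par <- gaParams(populationSize = 150, stagnationLimit = 20,
                  maxGenerations = 300, seed = 2)
  dIn <- nnToTrain(runGA(splitProblem(vs, NULL,
                                      mode = "in_distribution"), par))
  dOut <- nnToTrain(runGA(splitProblem(vs, NULL,
                                       mode = "out_of_distribution"), par))
  expect_lt(dIn, dOut)
})
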