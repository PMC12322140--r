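# Evolutionary train/test splitting.
#
# A split is a binary mask over the eligible (complete-vector) patients
# with exactly N = round(testFraction * n) test bits. Fitness in
# in-distribution mode is the sum of cosine distances from each test
# point to its nearest neighboring test point (a space-filling, i.e.
# representative, selection); in out-of-distribution mode it is the sum
# of cosine distances over all test-point pairs (an extreme, mutually
# dissimilar selection). In both modes a class-balance penalty
# alpha * sum_k |d_k - d_k,all| is subtracted, where d_k is the positive
# fraction of target class k in the test set and d_k,all overall.
# The GA uses tournament selection with elitism, one-point crossover
# (followed by cardinality repair via random bit swaps) and inversion
# mutation (which preserves cardinality), stopping after a stagnation
# limit without improvement.

#' Construct a GA split problem
#'
#' @param vectors A [PatientVectors] object (imputed, encoded) or a
#'   numeric matrix (patients x features) with rownames as patient IDs.
#' @param labels Matrix or data.frame of binary targets (patients x C),
#'   e.g. recurrence and survival status; `NA` excludes a patient from
#'   the penalty of that class. May be `NULL` (no penalty).
#' @param testFraction Fraction of eligible patients assigned to test
#'   (default 0.20).
#' @param alpha Penalty weight; `"auto"` scales it to the magnitude of
#'   the distance sum: `N` for in-distribution, `N (N - 1) / 2` for
#'   out-of-distribution.
#' @param mode `"in_distribution"` or `"out_of_distribution"`.
#' @param eligible Logical mask of patients whose vectors are complete;
#'   defaults to [isComplete()] for PatientVectors input, all-`TRUE`
#'   otherwise. Ineligible patients are assigned to training.
#' @return A [SplitProblem].
#' @export
splitProblem <- function(vectors, labels = NULL, testFraction = 0.2,
                         alpha = "auto",
                         mode = c("in_distribution", "out_of_distribution"),
                         eligible = NULL) {
  mode <- match.arg(mode)
  if (is(vectors, "PatientVectors")) {
    x <- vectorMatrix(vectors)
    if (is.null(eligible)) eligible <- unname(isComplete(vectors))
  } else {
    x <- as.matrix(vectors)
    if (is.null(eligible)) eligible <- rep(TRUE, nrow(x))
  }
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (!all(is.finite(x))) stop("patient vectors must be finite (impute first)")
  if (testFraction <= 0 || testFraction >= 1) {
    stop("testFraction must lie strictly between 0 and 1")
  }
  ids <- rownames(x)
  elig <- which(eligible)
  nE <- length(elig)
  N <- as.integer(round(testFraction * nE))
  if (N < 2L || N >= nE) {
    stop("argument error: infeasible test-set size N = ", N,
         " for ", nE, " eligible patients")
  }
  if (is.null(labels)) {
    lab <- matrix(numeric(0), nrow = nE, ncol = 0)
  } else {
    lab <- as.matrix(labels)
    storage.mode(lab) <- "double"
    if (nrow(lab) != nrow(x)) stop("labels must have one row per patient")
    lab <- lab[elig, , drop = FALSE]
  }
  dAll <- if (ncol(lab)) colMeans(lab, na.rm = TRUE) else numeric(0)
  dAll[is.nan(dAll)] <- 0
  xe <- x[elig, , drop = FALSE]
  new("SplitProblem", X = xe, S = .cosineSimMatrix(xe), labels = lab,
      dAll = dAll, N = N,
      alpha = if (identical(alpha, "auto")) {
        if (mode == "in_distribution") N else N * (N - 1) / 2
      } else as.numeric(alpha),
      mode = mode, eligibleIds = ids[elig],
      ineligibleIds = ids[!eligible])
}

#' Class-balance penalty of a candidate test set
#'
#' `alpha * sum_k |d_k - d_k,all|` where `d_k` is the positive fraction
#' of class `k` among (labeled) test patients and `d_k,all` the overall
#' positive fraction. Patients with a missing label are excluded from
#' the penalty of that class.
#'
#' @param mask Logical vector over patients (TRUE = test) with at least
#'   one test patient.
#' @param labels Matrix of binary targets (patients x C), `NA` allowed.
#' @param alpha Penalty weight (>= 0).
#' @param dAll Optional precomputed overall positive fractions.
#' @return Non-negative penalty value.
#' @examples
#' labs <- cbind(rec = c(1, 1, 0, 0), surv = c(1, 0, 1, 0))
#' balancePenalty(c(TRUE, FALSE, TRUE, FALSE), labs, alpha = 1)  # 0
#' @export
balancePenalty <- function(mask, labels, alpha = 1, dAll = NULL) {
  mask <- as.logical(mask)
  if (sum(mask) < 1L) stop("argument error: empty test set")
  labels <- as.matrix(labels)
  if (ncol(labels) == 0L) return(0)
  if (is.null(dAll)) {
    dAll <- colMeans(labels, na.rm = TRUE)
    dAll[is.nan(dAll)] <- 0
  }
  dTest <- colMeans(labels[mask, , drop = FALSE], na.rm = TRUE)
  dTest[is.nan(dTest)] <- dAll[is.nan(dTest)]  # no labeled test patient
  alpha * sum(abs(dTest - dAll))
}

# Internal: fitness of a test index set, given the problem.
.fitnessOfIdx <- function(idx, problem) {
  sub <- problem@S[idx, idx, drop = FALSE]
  pen <- if (ncol(problem@labels)) {
    mask <- logical(nrow(problem@S))
    mask[idx] <- TRUE
    balancePenalty(mask, problem@labels, problem@alpha, problem@dAll)
  } else 0
  if (problem@mode == "in_distribution") {
    diag(sub) <- -Inf
    nnSim <- sub[cbind(seq_along(idx), max.col(sub, ties.method = "first"))]
    sum(1 - nnSim) - pen
  } else {
    (length(idx)^2 - sum(sub)) / 2 - pen
  }
}

#' In-distribution fitness of a split
#'
#' Sum of cosine distances from each test point to its nearest
#' neighboring test point (neighbors searched among the other test
#' points only; ties broken by lowest patient index), minus the
#' class-balance penalty.
#'
#' @param mask Logical vector over eligible patients (TRUE = test), at
#'   least two test patients.
#' @param problem A [SplitProblem].
#' @return Fitness value.
#' @export
fitnessIn <- function(mask, problem) {
  idx <- which(as.logical(mask))
  if (length(idx) < 2L) stop("argument error: need at least 2 test points")
  p <- problem
  p@mode <- "in_distribution"
  .fitnessOfIdx(idx, p)
}

#' Out-of-distribution fitness of a split
#'
#' Sum of cosine distances over all pairs of test points, minus the
#' class-balance penalty.
#'
#' @inheritParams fitnessIn
#' @return Fitness value.
#' @export
fitnessOut <- function(mask, problem) {
  idx <- which(as.logical(mask))
  if (length(idx) < 2L) stop("argument error: need at least 2 test points")
  p <- problem
  p@mode <- "out_of_distribution"
  .fitnessOfIdx(idx, p)
}

#' Genetic algorithm parameters
#'
#' @param populationSize Number of genomes (default 10,000).
#' @param stagnationLimit Stop after this many generations without
#'   improvement of the best fitness (default 50).
#' @param tournamentSize Tournament size for parent selection (default 3).
#' @param eliteCount Number of elites copied unchanged each generation
#'   (default 1% of the population, at least 1).
#' @param crossoverRate Probability of one-point crossover per child
#'   (default 0.9).
#' @param mutationRate Per-bit inversion-trigger rate; the number of
#'   segment-inversion events per genome is Binomial(n, rate). Default
#'   `1/n` (about one inversion per genome).
#' @param maxGenerations Hard cap on generations (default 2000).
#' @param greedyInit Seed the initial population with greedily
#'   constructed candidates for the mode's distance objective (plus
#'   mutated copies), a memetic warm start that speeds convergence on
#'   large cohorts; the balance penalty is then optimized by the GA
#'   (default `TRUE`).
#' @param seed Integer seed.
#' @return Parameter list of class `GAParams`.
#' @export
gaParams <- function(populationSize = 10000L, stagnationLimit = 50L,
                     tournamentSize = 3L, eliteCount = NULL,
                     crossoverRate = 0.9, mutationRate = NULL,
                     maxGenerations = 2000L, greedyInit = TRUE, seed = 1L) {
  if (populationSize < 2L) stop("populationSize must be >= 2")
  if (is.null(eliteCount)) eliteCount <- max(1L, round(0.01 * populationSize))
  p <- list(populationSize = as.integer(populationSize),
            stagnationLimit = as.integer(stagnationLimit),
            tournamentSize = as.integer(tournamentSize),
            eliteCount = as.integer(eliteCount),
            crossoverRate = crossoverRate, mutationRate = mutationRate,
            maxGenerations = as.integer(maxGenerations),
            greedyInit = isTRUE(greedyInit), seed = as.integer(seed))
  stopifnot(crossoverRate >= 0, crossoverRate <= 1)
  class(p) <- "GAParams"
  p
}

# Greedy construction of a test mask for the mode's distance objective
# (ignoring the balance penalty): start from the most distant pair, then
# iteratively add the point with the best marginal contribution.
.greedyMask <- function(problem) {
  S <- problem@S
  n <- nrow(S)
  N <- problem@N
  D <- 1 - S
  sel <- logical(n)
  start <- arrayInd(which.max(D), dim(D))
  sel[start] <- TRUE
  if (problem@mode == "out_of_distribution") {
    sumD <- rowSums(D[, sel, drop = FALSE])
    while (sum(sel) < N) {
      sumD[sel] <- -Inf
      add <- which.max(sumD)
      sel[add] <- TRUE
      sumD <- sumD + D[, add]
    }
  } else {
    # maximin spread: add the point farthest from the current set
    minD <- pmin(D[, start[1]], D[, start[2]])
    while (sum(sel) < N) {
      minD[sel] <- -Inf
      add <- which.max(minD)
      sel[add] <- TRUE
      minD <- pmin(minD, D[, add])
    }
  }
  sel
}

# Randomized improving-swap local search on the full fitness (distance
# objective minus balance penalty); used to refine greedy seed genomes.
.hillClimb <- function(mask, problem, iters) {
  fit <- .fitnessOfIdx(which(mask), problem)
  n <- length(mask)
  for (it in seq_len(iters)) {
    i <- sample(which(mask), 1L)
    j <- sample(which(!mask), 1L)
    cand <- mask
    cand[i] <- FALSE
    cand[j] <- TRUE
    f <- .fitnessOfIdx(which(cand), problem)
    if (f > fit) {
      fit <- f
      mask <- cand
    }
  }
  mask
}

# Repair a binary genome to exactly N ones via random bit swaps.
.repairMask <- function(mask, N) {
  k <- sum(mask)
  if (k > N) {
    drop <- sample(which(mask), k - N)
    mask[drop] <- FALSE
  } else if (k < N) {
    add <- sample(which(!mask), N - k)
    mask[add] <- TRUE
  }
  mask
}

#' Run the genetic algorithm split
#'
#' Maximizes the mode's fitness over fixed-cardinality binary masks.
#' Every genome in every generation carries exactly N test bits (repair
#' after crossover; inversion mutation preserves cardinality). The
#' best-so-far fitness trace is non-decreasing (elitism). Ineligible
#' (incomplete-vector) patients are appended to the training IDs.
#'
#' @param problem A [SplitProblem].
#' @param params A [gaParams()] list.
#' @return A [SplitResult] with `trainIds`, `testIds`, `bestFitness` and
#'   the per-generation fitness trace.
#' @export
runGA <- function(problem, params = gaParams()) {
  stopifnot(is(problem, "SplitProblem"), inherits(params, "GAParams"))
  n <- nrow(problem@S)
  N <- problem@N
  P <- params$populationSize
  mutRate <- if (is.null(params$mutationRate)) 1 / n else params$mutationRate
  set.seed(params$seed)

  pop <- matrix(FALSE, nrow = P, ncol = n)
  for (i in seq_len(P)) pop[i, sample(n, N)] <- TRUE
  if (params$greedyInit) {
    greedy <- .hillClimb(.greedyMask(problem), problem, iters = 8L * n)
    nSeeded <- min(P, max(2L, round(0.05 * P)))
    pop[1L, ] <- greedy
    for (i in seq_len(nSeeded - 1L)) {
      g <- greedy
      swap <- sample(which(g), min(sum(g), 1L + rpois(1L, 2)))
      g[swap] <- FALSE
      pop[i + 1L, ] <- .repairMask(g, N)
    }
  }
  fit <- apply(pop, 1L, function(m) .fitnessOfIdx(which(m), problem))

  bestFit <- -Inf
  bestMask <- pop[1L, ]
  trace <- numeric(0)
  stagnation <- 0L

  for (gen in seq_len(params$maxGenerations)) {
    gBest <- which.max(fit)
    if (fit[gBest] > bestFit + 1e-12) {
      bestFit <- fit[gBest]
      bestMask <- pop[gBest, ]
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
    }
    trace <- c(trace, bestFit)
    if (stagnation >= params$stagnationLimit) break

    eliteIdx <- order(fit, decreasing = TRUE)[seq_len(min(params$eliteCount, P))]
    nChildren <- P - length(eliteIdx)

    # vectorized tournament selection of 2 parents per child
    tIdx <- matrix(sample.int(P, nChildren * 2L * params$tournamentSize,
                              replace = TRUE),
                   nrow = nChildren * 2L)
    tFit <- matrix(fit[tIdx], nrow = nChildren * 2L)
    winners <- tIdx[cbind(seq_len(nChildren * 2L),
                          max.col(tFit, ties.method = "first"))]
    p1 <- winners[seq_len(nChildren)]
    p2 <- winners[nChildren + seq_len(nChildren)]

    children <- matrix(FALSE, nrow = nChildren, ncol = n)
    doCx <- runif(nChildren) < params$crossoverRate
    cxPoint <- sample.int(n - 1L, nChildren, replace = TRUE)
    nMut <- rbinom(nChildren, n, mutRate)
    for (i in seq_len(nChildren)) {
      child <- if (doCx[i]) {
        c(pop[p1[i], seq_len(cxPoint[i])], pop[p2[i], (cxPoint[i] + 1L):n])
      } else {
        pop[p1[i], ]
      }
      if (nMut[i] > 0L) {
        for (m in seq_len(nMut[i])) {
          pts <- sort(sample.int(n, 2L))
          child[pts[1L]:pts[2L]] <- rev(child[pts[1L]:pts[2L]])
        }
      }
      children[i, ] <- .repairMask(child, N)
    }
    childFit <- apply(children, 1L, function(m) .fitnessOfIdx(which(m), problem))
    pop <- rbind(pop[eliteIdx, , drop = FALSE], children)
    fit <- c(fit[eliteIdx], childFit)
  }

  testIdx <- which(bestMask)
  new("SplitResult",
      trainIds = c(problem@eligibleIds[-testIdx], problem@ineligibleIds),
      testIds = problem@eligibleIds[testIdx],
      bestFitness = bestFit, trace = trace, mode = problem@mode)
}

#' Exhaustive split oracle
#'
#' Brute-force enumeration of all `choose(n, N)` masks; returns the
#' global fitness optimum for the problem's mode. Ties are broken by the
#' lexicographically smallest 0/1 mask vector. Intended as an
#' independent optimum reference for small instances.
#'
#' @param problem A [SplitProblem].
#' @param N Test-set size (defaults to the problem's N).
#' @return `list(mask = <logical>, testIds = <character>, fitness = <numeric>)`.
#' @export
exhaustiveSplitOracle <- function(problem, N = problem@N) {
  n <- nrow(problem@S)
  if (choose(n, N) > 1e6) {
    stop("argument error: instance too large for exhaustive enumeration")
  }
  combos <- combn(n, N)
  best <- -Inf
  bestMask <- NULL
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    f <- .fitnessOfIdx(idx, problem)
    if (f > best + 1e-12) {
      best <- f
      bestMask <- idx
    } else if (f > best - 1e-12) {
      # tie: keep the lexicographically smallest 0/1 mask
      cur <- integer(n); cur[idx] <- 1L
      inc <- integer(n); inc[bestMask] <- 1L
      cmp <- which(cur != inc)
      if (length(cmp) && cur[cmp[1L]] < inc[cmp[1L]]) bestMask <- idx
    }
  }
  mask <- logical(n)
  mask[bestMask] <- TRUE
  list(mask = mask, testIds = problem@eligibleIds[bestMask], fitness = best)
}
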