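# Attention-based multiple instance learning over multimodal embedding
# bags.
#
# A bag is one patient's set of instance embeddings (tiles from a whole
# slide image and/or tissue-microarray cores in up to eight stains),
# labeled at the bag level. The model is a two-layer gated attention
# network, a_i = w' (tanh(V h_i) * sigmoid(U h_i)), with softmax
# attention pooling z = sum_i A_i h_i and a logistic bag classifier.
# Training minimizes the bag-level cross-entropy plus a clustering loss:
# binary cross-entropy of an instance-level head on the top-k / bottom-k
# attended instances, whose pseudo-labels derive from the attention
# ranking (top-k of a positive bag -> positive, its bottom-k and the
# top-k of negative bags -> negative). Gradients are computed
# analytically; optimization is Adam. Attention weights are the
# per-instance interpretability scores and can be aggregated per data
# source to attribute the decision to modalities.

.TMA_STAINS <- c("CD163", "CD3", "CD56", "CD68", "CD8", "HE", "MHC1", "PDL1")
.MIL_SOURCES <- c("WSI", paste0("TMA:", .TMA_STAINS))

#' Survival labels for multiple instance learning
#'
#' Deceased within three years: deceased class (positive). Deceased
#' after three years: force-labeled alive (the event can no longer be
#' tied to the data at the three-year horizon). Alive with at least
#' three years of observation: alive class. Alive with a shorter
#' observation period: excluded.
#'
#' @param cohort A [Cohort].
#' @return An [OutcomeLabels] object (task `mil_survival`).
#' @export
milSurvivalLabels <- function(cohort) {
  stopifnot(is(cohort, "Cohort"))
  ids <- patientIds(cohort)
  status <- character(length(ids))
  reason <- character(length(ids))
  for (i in seq_along(ids)) {
    r <- records(cohort)[[i]]
    death <- .fieldOrNA(r, "death_days")
    fup <- r$followup_days
    if (!is.na(death)) {
      if (death <= .THREE_YEARS) {
        status[i] <- "positive"; reason[i] <- ""
      } else {
        status[i] <- "negative"; reason[i] <- ""  # force-labeled alive
      }
    } else if (fup >= .THREE_YEARS) {
      status[i] <- "negative"; reason[i] <- ""
    } else {
      status[i] <- "excluded"; reason[i] <- "observation_shorter_than_3_years"
    }
  }
  new("OutcomeLabels", task = "mil_survival", patientIds = ids,
      status = factor(status, levels = c("positive", "negative", "excluded")),
      reason = reason)
}

#' Assemble per-patient multimodal embedding bags
#'
#' Builds one [Bag] per labeled patient from an embedding source. The
#' default synthetic source emulates encoder output: background
#' instances are standard Gaussian; bags of positive patients carry a
#' planted fraction of informative instances whose mean is shifted along
#' a fixed per-source direction. With `signalAssignment = "split"`, each
#' positive patient carries signal in only one (randomly chosen) of the
#' signal sources — complementary information across modalities.
#'
#' @param cohort A [Cohort].
#' @param labels An [OutcomeLabels] object (e.g. [milSurvivalLabels()]);
#'   excluded patients are skipped.
#' @param sources Sources to include: `"WSI"` and/or `"TMA:<stain>"`
#'   with stains CD163, CD3, CD56, CD68, CD8, HE, MHC1, PDL1.
#' @param wsiInstances Instances sampled per whole slide image
#'   (default 64; stands in for sparse patch sampling).
#' @param tmaTilesPerCore Tiles per TMA core (default 32).
#' @param coresPerStain TMA cores per stain (default 2: tumor center and
#'   invasion front).
#' @param embedDim Embedding dimension (default 64).
#' @param signalSources Sources that carry the planted signal (default:
#'   all requested sources).
#' @param signalFraction Fraction of informative instances in a positive
#'   patient's signal source (default 0.1).
#' @param signalShift Mean shift of informative instances along the
#'   source's signal direction (default 3).
#' @param signalAssignment `"all"` (signal in every signal source of a
#'   positive patient) or `"split"` (one randomly chosen signal source
#'   per positive patient).
#' @param embedSource Optional custom generator
#'   `function(patientId, label, source, n, d)` returning an `n x d`
#'   matrix; replaces the synthetic source.
#' @param seed Integer seed.
#' @return List of [Bag] objects.
#' @export
makeBags <- function(cohort, labels, sources = c("WSI", "TMA:CD8"),
                     wsiInstances = 64L, tmaTilesPerCore = 32L,
                     coresPerStain = 2L, embedDim = 64L,
                     signalSources = sources, signalFraction = 0.1,
                     signalShift = 3, signalAssignment = c("all", "split"),
                     embedSource = NULL, seed = 1L) {
  stopifnot(is(cohort, "Cohort"), is(labels, "OutcomeLabels"))
  signalAssignment <- match.arg(signalAssignment)
  if (!all(sources %in% .MIL_SOURCES)) {
    stop("unknown source(s): ",
         paste(setdiff(sources, .MIL_SOURCES), collapse = ", "))
  }
  set.seed(seed)
  # fixed unit signal direction per source
  dirs <- lapply(setNames(.MIL_SOURCES, .MIL_SOURCES), function(s) {
    v <- rnorm(embedDim)
    v / sqrt(sum(v^2))
  })
  st <- labelStatus(labels)
  ids <- patientIds(cohort)[st[patientIds(cohort)] != "excluded"]
  # draw per-patient signal-source assignments upfront so they are
  # identical across calls that include different source subsets
  assigned <- if (signalAssignment == "all") NULL
              else sample(signalSources, length(ids), replace = TRUE)
  bags <- vector("list", length(ids))
  nPerSource <- function(s) {
    if (s == "WSI") as.integer(wsiInstances)
    else as.integer(tmaTilesPerCore * coresPerStain)
  }
  for (b in seq_along(ids)) {
    id <- ids[b]
    y <- as.numeric(st[[id]] == "positive")
    carrySignal <- if (signalAssignment == "all") signalSources
                   else assigned[b]
    inst <- list()
    tags <- character(0)
    for (s in sources) {
      n <- nPerSource(s)
      if (n < 1L) {
        message("patient ", id, ": zero instances for source ", s, "; skipped")
        next
      }
      h <- if (is.null(embedSource)) {
        m <- matrix(rnorm(n * embedDim), nrow = n)
        if (y == 1 && s %in% carrySignal) {
          nSig <- max(1L, round(signalFraction * n))
          m[seq_len(nSig), ] <- m[seq_len(nSig), , drop = FALSE] +
            rep(signalShift * dirs[[s]], each = nSig)
        }
        m
      } else {
        embedSource(id, y, s, n, embedDim)
      }
      inst[[length(inst) + 1L]] <- h
      tags <- c(tags, rep(s, nrow(h)))
    }
    if (length(inst) == 0L) next
    bags[[b]] <- new("Bag", patientId = id,
                     instances = do.call(rbind, inst),
                     sourceTags = tags, label = y)
  }
  bags[!vapply(bags, is.null, logical(1))]
}

#' MIL training parameters
#'
#' @param epochs Training epochs (default 40).
#' @param lr Adam learning rate (default 0.002).
#' @param hidden Attention hidden size (default 32).
#' @param clusteringLossWeight Weight of the instance-level clustering
#'   loss (default 0.5; 0 reduces training to plain attention MIL).
#' @param topk Instances per bag used by the clustering loss (default 8).
#' @param weightDecay L2 regularization strength on all weights
#'   (default 0.03); counteracts bag memorization through the fixed
#'   random embedding directions.
#' @param balanceClasses Weight each bag's loss inversely to its class
#'   frequency (default `TRUE`), preventing collapse to the majority
#'   class on imbalanced cohorts.
#' @param restarts Number of random restarts (default 3); the model with
#'   the lowest final training loss (bag plus weighted instance loss) is
#'   kept. Restart seeds derive deterministically from `seed`.
#' @param seed Integer seed (initialization and bag order).
#' @return Parameter list of class `MILParams`.
#' @export
milParams <- function(epochs = 40L, lr = 0.002, hidden = 32L,
                      clusteringLossWeight = 0.5, topk = 8L,
                      weightDecay = 0.03, balanceClasses = TRUE,
                      restarts = 3L, seed = 1L) {
  p <- list(epochs = as.integer(epochs), lr = lr, hidden = as.integer(hidden),
            clusteringLossWeight = clusteringLossWeight,
            topk = as.integer(topk), weightDecay = weightDecay,
            balanceClasses = isTRUE(balanceClasses),
            restarts = as.integer(restarts), seed = as.integer(seed))
  class(p) <- "MILParams"
  p
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Forward pass for one bag; returns intermediates needed for backprop.
.milForward <- function(W, H) {
  Z1 <- H %*% t(W$V)            # m x hidden
  Tm <- tanh(Z1)
  Z2 <- H %*% t(W$U)
  Sg <- .sigmoid(Z2)
  G <- Tm * Sg                  # gated hidden, m x hidden
  a <- as.numeric(G %*% W$w)
  a <- a - max(a)
  A <- exp(a) / sum(exp(a))     # attention weights
  z <- as.numeric(crossprod(H, A))  # d
  s <- .sigmoid(sum(W$cls * z) + W$b)
  list(Tm = Tm, Sg = Sg, G = G, A = A, z = z, s = s)
}

# Instance selection for the clustering loss: indices and pseudo-labels.
.instanceTargets <- function(A, y, topk) {
  m <- length(A)
  k <- min(topk, floor(m / 2))
  if (k < 1L) return(NULL)
  ordIdx <- order(-A, seq_len(m))  # deterministic tie-break by index
  top <- ordIdx[seq_len(k)]
  if (y == 1) {
    bottom <- rev(ordIdx)[seq_len(k)]
    list(idx = c(top, bottom), y = c(rep(1, k), rep(0, k)))
  } else {
    list(idx = top, y = rep(0, k))
  }
}

#' Train a gated-attention MIL model
#'
#' Trains the attention network, bag classifier and instance head with
#' Adam on the bag-level binary cross-entropy plus
#' `clusteringLossWeight` times the instance-level clustering loss.
#' Requires at least two bags per class. Reproducible under
#' `params$seed`.
#'
#' @param bags List of [Bag] objects with 0/1 labels.
#' @param params A [milParams()] list.
#' @return A trained [MILModel].
#' @export
trainMIL <- function(bags, params = milParams()) {
  stopifnot(inherits(params, "MILParams"), length(bags) >= 2L)
  ylab <- vapply(bags, function(b) b@label, numeric(1))
  if (anyNA(ylab)) stop("all training bags need labels")
  if (min(table(ylab)) < 2L || length(unique(ylab)) < 2L) {
    stop("need at least two bags per class")
  }
  best <- NULL
  bestLoss <- Inf
  for (r in seq_len(max(1L, params$restarts))) {
    runSeed <- if (r == 1L) params$seed
               else .subSeed(params$seed, paste0("restart", r))
    fit <- .trainMILOnce(bags, ylab, params, runSeed)
    final <- fit@lossTrace[nrow(fit@lossTrace), ]
    loss <- final$bagLoss + params$clusteringLossWeight * final$instanceLoss
    if (loss < bestLoss) {
      bestLoss <- loss
      best <- fit
    }
  }
  best
}

.trainMILOnce <- function(bags, ylab, params, runSeed) {
  d <- ncol(bags[[1L]]@instances)
  hid <- params$hidden
  lambda <- params$clusteringLossWeight
  set.seed(runSeed)
  W <- list(V = matrix(rnorm(hid * d, 0, 0.1), hid, d),
            U = matrix(rnorm(hid * d, 0, 0.1), hid, d),
            w = rnorm(hid, 0, 0.1),
            cls = rnorm(d, 0, 0.1), b = 0,
            g = rnorm(hid, 0, 0.1), bg = 0)
  adamM <- lapply(W, function(p) p * 0)
  adamV <- lapply(W, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  tStep <- 0L
  lossTrace <- data.frame(epoch = integer(0), bagLoss = numeric(0),
                          instanceLoss = numeric(0))

  clsW <- if (isTRUE(params$balanceClasses)) {
    tab <- table(factor(ylab, levels = c(0, 1)))
    length(ylab) / (2 * pmax(tab, 1L))
  } else c("0" = 1, "1" = 1)

  for (epoch in seq_len(params$epochs)) {
    ord <- sample.int(length(bags))
    bagLossSum <- 0
    instLossSum <- 0
    for (bi in ord) {
      bag <- bags[[bi]]
      H <- bag@instances
      y <- bag@label
      m <- nrow(H)
      fw <- .milForward(W, H)
      cw <- clsW[[as.character(y)]]
      bagLossSum <- bagLossSum + cw * .bce(fw$s, y)

      ds <- cw * (fw$s - y)
      gradCls <- ds * fw$z
      gradB <- ds
      dz <- ds * W$cls
      dA <- as.numeric(H %*% dz)
      da <- fw$A * (dA - sum(fw$A * dA))
      dG <- outer(da, W$w)
      gradW <- as.numeric(crossprod(fw$G, da))
      gradG <- numeric(hid); gradBg <- 0

      if (lambda > 0) {
        sel <- .instanceTargets(fw$A, y, params$topk)
        if (!is.null(sel)) {
          Gsel <- fw$G[sel$idx, , drop = FALSE]
          p <- .sigmoid(as.numeric(Gsel %*% W$g) + W$bg)
          instLossSum <- instLossSum + .bce(p, sel$y)
          dp <- lambda * (p - sel$y) / length(sel$y)
          gradG <- as.numeric(crossprod(Gsel, dp))
          gradBg <- sum(dp)
          dG[sel$idx, ] <- dG[sel$idx, , drop = FALSE] + outer(dp, W$g)
        }
      }

      dZ1 <- dG * fw$Sg * (1 - fw$Tm^2)
      dZ2 <- dG * fw$Tm * fw$Sg * (1 - fw$Sg)
      grads <- list(V = crossprod(dZ1, H), U = crossprod(dZ2, H),
                    w = gradW, cls = gradCls, b = gradB,
                    g = gradG, bg = gradBg)

      tStep <- tStep + 1L
      wd <- params$weightDecay
      if (wd > 0) {
        # decay the attention backbone and bag classifier (an unbounded
        # bag head turns the model into plain mean pooling); the
        # instance head and biases are exempt
        for (nm in c("V", "U", "w", "cls")) {
          grads[[nm]] <- grads[[nm]] + wd * W[[nm]]
        }
      }
      for (nm in names(W)) {
        adamM[[nm]] <- beta1 * adamM[[nm]] + (1 - beta1) * grads[[nm]]
        adamV[[nm]] <- beta2 * adamV[[nm]] + (1 - beta2) * grads[[nm]]^2
        mHat <- adamM[[nm]] / (1 - beta1^tStep)
        vHat <- adamV[[nm]] / (1 - beta2^tStep)
        W[[nm]] <- W[[nm]] - params$lr * mHat / (sqrt(vHat) + eps)
      }
    }
    lossTrace <- rbind(lossTrace,
                       data.frame(epoch = epoch,
                                  bagLoss = bagLossSum / length(bags),
                                  instanceLoss = instLossSum / length(bags)))
  }
  new("MILModel", weights = W,
      params = unclass(params), lossTrace = lossTrace)
}

#' Attention weights and bag score for one bag
#'
#' @param model A trained [MILModel].
#' @param bag A [Bag] with matching embedding dimension.
#' @return An [AttentionResult]: normalized per-instance weights (sum to
#'   1), positive-class bag score in `[0, 1]`, source tags.
#' @export
attend <- function(model, bag) {
  stopifnot(is(model, "MILModel"), is(bag, "Bag"))
  if (ncol(bag@instances) != ncol(model@weights$V)) {
    stop("embedding dimension mismatch: bag has ", ncol(bag@instances),
         ", model expects ", ncol(model@weights$V))
  }
  fw <- .milForward(model@weights, bag@instances)
  new("AttentionResult", instanceWeights = fw$A, bagScore = fw$s,
      sourceTags = bag@sourceTags)
}

#' Bag-level scores for a list of bags
#'
#' @param model A trained [MILModel].
#' @param bags List of [Bag] objects.
#' @return Named numeric vector of positive-class scores.
#' @export
predictBags <- function(model, bags) {
  setNames(vapply(bags, function(b) attend(model, b)@bagScore, numeric(1)),
           vapply(bags, function(b) b@patientId, character(1)))
}

#' Top attended instances of an attention result
#'
#' @param result An [AttentionResult].
#' @param k Number of instances.
#' @return Integer indices of the k highest-attention instances,
#'   deterministic index tie-break.
#' @export
topInstances <- function(result, k) {
  ord <- order(-result@instanceWeights, seq_along(result@instanceWeights))
  ord[seq_len(min(k, length(ord)))]
}

#' Per-source attention attribution
#'
#' Aggregates attention weights (as produced, not renormalized per
#' source) over a set of bags by source tag: mean weight, total weight
#' share and the raw weight distributions for histograms.
#'
#' @param model A trained [MILModel].
#' @param bags List of (multi-source) [Bag] objects.
#' @return `list(summary = <data.frame>, weights = <named list>)`; the
#'   summary has one row per source with `meanWeight`, `totalWeightShare`
#'   and `nInstances`.
#' @export
modalityAttentionSummary <- function(model, bags) {
  weights <- list()
  for (bag in bags) {
    att <- attend(model, bag)
    for (s in unique(att@sourceTags)) {
      weights[[s]] <- c(weights[[s]], att@instanceWeights[att@sourceTags == s])
    }
  }
  total <- sum(unlist(weights))
  summary <- data.frame(
    source = names(weights),
    meanWeight = vapply(weights, mean, numeric(1)),
    totalWeightShare = vapply(weights, sum, numeric(1)) / total,
    nInstances = vapply(weights, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  summary <- summary[order(summary$source), , drop = FALSE]
  rownames(summary) <- NULL
  list(summary = summary, weights = weights)
}
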