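# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one user-facing seed, documented
# sub-streams per pipeline stage. Polynomial string hash folded with the
# master seed, kept strictly below 2^31 - 1.
.subSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647
  h <- as.double(seed) %% m
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Row-wise cosine similarity matrix. Zero-norm rows get similarity 0 to
# everything (cosine distance 1), matching the documented convention.
.cosineSimMatrix <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning("zero-norm vector(s) present; cosine distance to them is defined as 1")
    nrm[zero] <- 1
  }
  xs <- x / nrm
  s <- tcrossprod(xs)
  if (any(zero)) {
    s[zero, ] <- 0
    s[, zero] <- 0
  }
  # numerical safety: similarities live in [-1, 1]
  s[s > 1] <- 1
  s[s < -1] <- -1
  diag(s)[!zero] <- 1
  s
}

#' Cosine distance between two vectors
#'
#' Distance is `1 - cosine similarity`, taking values in `[0, 2]`. A
#' zero-norm vector has, by package convention, distance 1 to anything
#' (a warning is issued).
#'
#' @param u,v Finite numeric vectors of equal length.
#' @return A single number in `[0, 2]`.
#' @examples
#' cosineDistance(c(1, 0), c(0, 1))  # orthogonal: 1
#' cosineDistance(c(1, 1), c(-1, -1))  # antipodal: 2
#' @export
cosineDistance <- function(u, v) {
  stopifnot(length(u) == length(v), all(is.finite(u)), all(is.finite(v)))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("zero-norm vector; cosine distance defined as 1 by convention")
    return(1)
  }
  s <- sum(u * v) / (nu * nv)
  s <- max(-1, min(1, s))
  1 - s
}

# Most frequent value; deterministic tie-break by first-sorted value.
.modeValue <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA)
  tab <- table(x)
  best <- names(tab)[tab == max(tab)]
  val <- sort(best)[1L]
  if (is.numeric(x)) as.numeric(val) else val
}

.isScalarString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

.isScalarNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# NULL-safe field extraction from a record list; absent key == NULL == NA.
.fieldOrNA <- function(rec, name) {
  v <- rec[[name]]
  if (is.null(v) || length(v) == 0L || (length(v) == 1L && is.na(v))) NA else v
}

# Rank-based AUC of scores for binary labels (1 = positive), midrank ties.
.aucRank <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: one class is empty")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
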