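# Kaplan-Meier product-limit estimation with right-censoring and the
# Wilcoxon-Mann-Whitney two-sample comparison.

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival estimate
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), with
#' patients alive at the end of follow-up right-censored. Deaths precede
#' censorings at tied times (standard convention). The pointwise 95%
#' confidence band uses Greenwood's variance on the log scale.
#'
#' @param times Non-negative follow-up times in days, one per patient.
#' @param events Event indicators (1/TRUE = death observed,
#'   0/FALSE = censored).
#' @param confLevel Confidence level of the band (default 0.95).
#' @return A [KMCurve].
#' @examples
#' km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
#' survivalAt(km, 2.5)  # 0.5
#' @export
kmEstimate <- function(times, events, confLevel = 0.95) {
  times <- as.numeric(times)
  events <- as.integer(as.logical(events))
  if (length(times) != length(events) || length(times) < 1L) {
    stop("times and events must be equally long and non-empty")
  }
  if (any(times < 0)) stop("negative time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log", conf.int = confLevel)
  new("KMCurve", time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
      nEvent = fit$n.event, nCensor = fit$n.censor,
      lower = ifelse(is.na(fit$lower), 0, fit$lower),
      upper = ifelse(is.na(fit$upper), 1, fit$upper),
      maxTime = max(times))
}

#' Survival probability at a time point
#'
#' Right-continuous step-function lookup of a Kaplan-Meier curve.
#' Queries beyond the last observed time return the last value and are
#' flagged as extrapolated (warning plus `"extrapolated"` attribute).
#'
#' @param curve A [KMCurve].
#' @param t Time(s) in days, `>= 0`.
#' @return Survival probability (vectorized over `t`).
#' @export
survivalAt <- function(curve, t) {
  stopifnot(is(curve, "KMCurve"), all(t >= 0))
  idx <- findInterval(t, curve@time)
  out <- ifelse(idx == 0L, 1, curve@surv[pmax(idx, 1L)])
  extra <- t > curve@maxTime
  if (any(extra)) {
    warning("survival queried beyond the last observed time; ",
            "returning the last estimate (extrapolated)")
    attr(out, "extrapolated") <- extra
  }
  out
}

#' Wilcoxon-Mann-Whitney two-sample test
#'
#' U statistic with midrank tie handling. For small samples (total
#' n <= 12) the two-sided p-value is computed by exact enumeration of
#' all group assignments of the pooled (mid)ranks; otherwise by normal
#' approximation with tie correction and continuity correction.
#'
#' @param groupA,groupB Non-empty numeric vectors.
#' @return `list(U = <numeric>, p = <numeric>, method = <character>)`;
#'   `U` counts pairs in which a `groupA` value exceeds a `groupB` value
#'   (ties count one half).
#' @examples
#' mwuTest(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mwuTest <- function(groupA, groupB) {
  a <- as.numeric(groupA)
  b <- as.numeric(groupB)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (n <= 12L) {
    assigns <- combn(n, na)
    uAll <- apply(assigns, 2L, function(idx) {
      sum(r[idx]) - na * (na + 1) / 2
    })
    p <- mean(abs(uAll - mu) >= abs(U - mu) - 1e-9)
    method <- "exact_permutation"
  } else {
    ties <- table(r)
    tieCorr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tieCorr)
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * pnorm(z, lower.tail = FALSE)
    p <- min(1, p)
    method <- "normal_approximation"
  }
  list(U = U, p = p, method = method)
}

#' Compare TMA immune-cell densities between outcome groups
#'
#' Convenience wrapper: extracts one CD3/CD8 density from every patient,
#' groups patients by an outcome label, and runs [mwuTest()].
#'
#' @param cohort A [Cohort].
#' @param marker `"CD3"` or `"CD8"`.
#' @param region `"tumor_center"` or `"invasion_front"`.
#' @param labels An [OutcomeLabels] object defining the two groups
#'   (positive vs negative; excluded patients are dropped).
#' @return The [mwuTest()] result plus the group sizes.
#' @export
compareDensity <- function(cohort, marker = c("CD3", "CD8"),
                           region = c("tumor_center", "invasion_front"),
                           labels) {
  marker <- match.arg(marker)
  region <- match.arg(region)
  stopifnot(is(cohort, "Cohort"), is(labels, "OutcomeLabels"))
  key <- paste0(marker, "_", region)
  st <- labelStatus(labels)
  vals <- vapply(records(cohort), function(r) {
    v <- r$tma_density[[key]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  ids <- patientIds(cohort)
  ok <- !is.na(vals) & st[ids] != "excluded"
  grpPos <- vals[ok & st[ids] == "positive"]
  grpNeg <- vals[ok & st[ids] == "negative"]
  out <- mwuTest(grpPos, grpNeg)
  out$nPositive <- length(grpPos)
  out$nNegative <- length(grpNeg)
  out
}
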