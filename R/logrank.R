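#' Log-rank test for k survival groups
#'
#' Standard observed-minus-expected log-rank statistic. At each distinct
#' event time the expected events per group come from the hypergeometric
#' allocation of the total deaths over the risk set, with the matching
#' hypergeometric covariance; the chi-square statistic is the quadratic
#' form over the first k-1 groups, df = k-1, p from the chi-square upper
#' tail. Invariant to group relabeling and to any strictly increasing
#' transform of time.
#'
#' @param time non-negative follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group group labels; every level must be non-empty.
#' @return list with \code{chisq}, \code{df}, \code{p}, and the per-group
#'   \code{observed} and \code{expected} event totals.
#' @examples
#' logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 0), c("a", "a", "b", "b"))
#' @export
logrankTest <- function(time, event, group) {
  n <- length(time)
  if (length(event) != n || length(group) != n)
    stop("time, event and group lengths differ")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative")
  event <- as.integer(event)
  group <- as.factor(group)
  k <- nlevels(group)
  if (k < 2L) stop("need at least two groups")
  if (any(tabulate(group, k) == 0L)) stop("every group must be non-empty")

  eventTimes <- sort(unique(time[event == 1L]))
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k - 1L, k - 1L)
  gi <- as.integer(group)

  for (t in eventTimes) {
    atRisk <- time >= t
    nj <- sum(atRisk)
    dj <- sum(event == 1L & time == t)
    nij <- tabulate(gi[atRisk], k)
    dij <- tabulate(gi[event == 1L & time == t], k)
    O <- O + dij
    E <- E + dj * nij / nj
    if (nj > 1L) {
      # hypergeometric covariance of deaths over groups at this time
      f <- dj * (nj - dj) / (nj - 1) / nj^2
      p1 <- nij[-k] / nj
      V <- V + f * nj * (diag(p1 * nj, k - 1L, k - 1L) -
                           outer(nij[-k], nij[-k]) / nj)
    }
  }

  d <- (O - E)[-k]
  chisq <- if (all(abs(d) < 1e-12)) 0 else {
    sol <- tryCatch(solve(V, d), error = function(e) NULL)
    if (is.null(sol)) {
      # singular covariance: generalized inverse
      as.numeric(t(d) %*% MASS_ginv(V) %*% d)
    } else as.numeric(sum(d * sol))
  }
  chisq <- max(0, chisq)
  df <- k - 1L
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE),
       observed = as.numeric(O), expected = as.numeric(E))
}

# Moore-Penrose pseudoinverse via SVD (only needed for degenerate risk
# configurations in k > 2 group tests)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1L], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# fast vectorized two-group log-rank chi-square, used by the cutpoint
# scan (identical value to logrankTest with k = 2)
.logrank2 <- function(time, event, inHigh) {
  n <- length(time)
  ord <- order(time)
  ts <- time[ord]; es <- event[ord]; hi <- as.numeric(inHigh[ord])
  evTimes <- unique(ts[es == 1L])
  if (!length(evTimes)) return(0)
  first <- match(evTimes, ts)
  nj <- n - first + 1
  suffixHigh <- rev(cumsum(rev(hi)))
  n1 <- suffixHigh[first]
  dAll <- rowsum(es, ts)
  dHigh <- rowsum(es * hi, ts)
  # rowsum orders by sorted unique time; event rows align with evTimes
  dj <- dAll[dAll[, 1L] > 0, 1L]
  d1 <- dHigh[dAll[, 1L] > 0, 1L]
  U <- sum(d1 - dj * n1 / nj)
  ok <- nj > 1
  Vv <- sum((dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1))[ok])
  if (Vv <= 0) return(0)
  U^2 / Vv
}
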