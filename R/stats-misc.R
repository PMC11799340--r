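#' Classify recurrence timing
#'
#' Recurrence within the first 6 months of surgery is "very early",
#' between 6 and 12 months "early", and at 12 months or later "late";
#' patients without recurrence are "none".
#'
#' @param rfsMonths recurrence-free survival time in months (>= 0).
#' @param recurred logical/0-1 flag: did recurrence occur?
#' @param veryEarlyMax exclusive upper bound of very early recurrence.
#' @param lateMin inclusive lower bound of late recurrence.
#' @return character vector in \{very_early, early, late, none\}.
#' @examples
#' classifyRecurrenceTiming(c(5, 6, 12, 40), c(1, 1, 1, 0))
#' @export
classifyRecurrenceTiming <- function(rfsMonths, recurred,
                                     veryEarlyMax = 6, lateMin = 12) {
  if (veryEarlyMax >= lateMin)
    stop("veryEarlyMax must be smaller than lateMin")
  if (any(rfsMonths < 0)) stop("negative recurrence-free survival time")
  recurred <- as.logical(recurred)
  out <- rep("none", length(rfsMonths))
  out[recurred & rfsMonths < veryEarlyMax] <- "very_early"
  out[recurred & rfsMonths >= veryEarlyMax & rfsMonths < lateMin] <- "early"
  out[recurred & rfsMonths >= lateMin] <- "late"
  out
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic \eqn{\sum (O - E)^2 / E} on an r x c
#' contingency table, without continuity correction;
#' df = (r-1)(c-1), p from the chi-square upper tail.
#'
#' @param tab contingency matrix with non-negative cells and positive
#'   margins, at least 2 x 2.
#' @return list with \code{chisq}, \code{df}, \code{p}, \code{expected}.
#' @examples
#' chiSquareTest(matrix(c(50, 105, 5, 33), 2))
#' @export
chiSquareTest <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  if (any(tab < 0)) stop("cells must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin")
  E <- outer(rs, cs) / sum(tab)
  chisq <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE), expected = E)
}

#' Two-sample comparison of a continuous variable
#'
#' Welch's unequal-variance t test (default) or the Wilcoxon rank-sum
#' test with normal approximation and tie correction. Two-sided p-values.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param method \code{"t"} or \code{"wilcoxon"}.
#' @return list with \code{statistic}, \code{p}, and for the t test
#'   \code{df}.
#' @export
compareContinuous <- function(x, y, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  if (method == "t") {
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) stop("degenerate input: zero variance")
    nx <- length(x); ny <- length(y)
    se2 <- vx / nx + vy / ny
    stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    list(statistic = stat, df = df, p = 2 * pt(-abs(stat), df))
  } else {
    nx <- length(x); ny <- length(y)
    r <- rank(c(x, y))
    W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    ties <- table(r)
    tieAdj <- sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))
    sigma2 <- nx * ny / 12 * ((nx + ny + 1) - tieAdj)
    if (sigma2 <= 0) stop("degenerate input: all values tied")
    z <- (W - mu) / sqrt(sigma2)
    list(statistic = W, p = min(1, 2 * pnorm(-abs(z))))
  }
}
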