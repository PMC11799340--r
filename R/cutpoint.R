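#' Maximally selected log-rank cutpoint scan
#'
#' `scanCutpoints()` evaluates the two-group log-rank statistic at every
#' candidate dichotomization cutoff of a continuous marker (dosage).
#' Candidates are midpoints between consecutive distinct observed values,
#' restricted so both sides keep at least \code{minGroupSize} patients;
#' being rank-based, the selected partition is invariant to any strictly
#' increasing transform of the marker. `selectGlobal()` returns the
#' cutoff maximizing the statistic (ties toward the smaller cutoff);
#' `selectLocalMaxima()` returns up to k interior local maxima of the
#' statistic profile (plateaus merged, represented by their smallest
#' cutoff), for markers whose bimodal distribution supports two
#' clinically distinct thresholds.
#'
#' The per-cutoff p-values are naive chi-square(1) tail areas and do not
#' account for the maximal selection; with \code{nPerm > 0} a
#' permutation-calibrated p-value for the maximum statistic is computed
#' by permuting marker values against outcomes.
#'
#' @param dosages marker values; NA values are dropped with a warning.
#' @param time,event survival follow-up (months) and 0/1 event flags.
#' @param minGroupSize smallest group size allowed on either side.
#' @param mode \code{"global"} or \code{"local_maxima"}; controls which
#'   selector fills the \code{selected} slot.
#' @param k number of local maxima to keep in local-maxima mode.
#' @param nPerm permutations for the selection-corrected p (0 = off).
#' @return a [CutpointScan-class].
#' @examples
#' set.seed(1)
#' d <- runif(60)
#' tt <- rexp(60, 0.05 * ifelse(d > 0.5, 3, 1))
#' scanCutpoints(d, tt, rep(1, 60))
#' @export
scanCutpoints <- function(dosages, time, event, minGroupSize = 10L,
                          mode = c("global", "local_maxima"), k = 2L,
                          nPerm = 0L) {
  mode <- match.arg(mode)
  n0 <- length(dosages)
  if (length(time) != n0 || length(event) != n0)
    stop("dosages, time and event lengths differ")
  keep <- !is.na(dosages)
  if (any(!keep)) {
    warning(sum(!keep), " undefined dosage value(s) excluded from the scan")
    dosages <- dosages[keep]; time <- time[keep]; event <- event[keep]
  }
  n <- length(dosages)
  if (any(!is.finite(dosages))) stop("dosages must be finite")
  if (n < 2L * minGroupSize)
    stop("need at least 2 * minGroupSize patients with defined dosage")
  sorted <- sort(unique(dosages))
  if (length(sorted) < 2L) stop("all dosages identical: no valid cutoff")

  mids <- (sorted[-1] + sorted[-length(sorted)]) / 2
  nHigh <- vapply(mids, function(cc) sum(dosages > cc), numeric(1))
  ok <- nHigh >= minGroupSize & (n - nHigh) >= minGroupSize
  mids <- mids[ok]
  if (!length(mids))
    stop("no candidate cutoff satisfies the group-size constraint")

  chisq <- vapply(mids, function(cc) .logrank2(time, event, dosages > cc),
                  numeric(1))
  p <- pchisq(chisq, 1L, lower.tail = FALSE)

  permP <- NA_real_
  if (nPerm > 0L) {
    obsMax <- max(chisq)
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      dp <- sample(dosages)
      mx <- max(vapply(mids, function(cc) .logrank2(time, event, dp > cc),
                       numeric(1)))
      if (mx >= obsMax) exceed <- exceed + 1L
    }
    permP <- (exceed + 1L) / (nPerm + 1L)
  }

  scan <- new("CutpointScan", cutoffs = mids, chisq = chisq, p = p,
              selected = numeric(0), mode = mode,
              minGroupSize = as.integer(minGroupSize), permP = permP)
  scan@selected <- if (mode == "global") selectGlobal(scan)
                   else selectLocalMaxima(scan, k = k)
  validObject(scan)
  scan
}

#' @rdname scanCutpoints
#' @export
setMethod("selectGlobal", "CutpointScan", function(scan) {
  if (!length(scan@cutoffs)) stop("empty scan")
  scan@cutoffs[which.max(scan@chisq)]  # which.max takes the first = smaller
})

#' @rdname scanCutpoints
#' @export
setMethod("selectLocalMaxima", "CutpointScan", function(scan, k = 2L) {
  if (!length(scan@cutoffs)) stop("empty scan")
  # merge plateaus of equal statistic, keep each run's smallest cutoff
  r <- rle(scan@chisq)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  vals <- r$values
  m <- length(vals)
  isMax <- logical(m)
  if (m >= 3L)
    for (j in 2:(m - 1L))
      isMax[j] <- vals[j] > vals[j - 1L] && vals[j] > vals[j + 1L]
  cand <- which(isMax)
  if (!length(cand)) return(selectGlobal(scan))  # monotone profile
  top <- cand[order(vals[cand], decreasing = TRUE)][seq_len(min(k,
                                                                length(cand)))]
  sort(scan@cutoffs[starts[top]])
})

setMethod("show", "CutpointScan", function(object) {
  cat(sprintf("CutpointScan: %d candidates (min group %d), mode %s\n",
              length(object@cutoffs), object@minGroupSize, object@mode))
  best <- which.max(object@chisq)
  cat(sprintf("  max log-rank chi-square %.3f at cutoff %.4g (naive p=%.3g)\n",
              object@chisq[best], object@cutoffs[best], object@p[best]))
  cat("  selected:", paste(signif(object@selected, 4), collapse = ", "), "\n")
  if (!is.na(object@permP))
    cat(sprintf("  permutation-corrected max-statistic p: %.4g\n",
                object@permP))
})

#' Dichotomize a marker at a cutoff
#'
#' Values strictly greater than the cutoff are "high", values at or below
#' it are "low" (so the cutoff itself is low, matching a low group
#' defined by dosage below the threshold). Undefined markers yield NA
#' with a warning.
#'
#' @param dosages marker values.
#' @param cutoff finite threshold.
#' @return character vector in \{high, low\} (NA for undefined input).
#' @examples
#' dichotomize(c(0.195, 0.196), 0.195)  # low, high
#' @export
dichotomize <- function(dosages, cutoff) {
  stopifnot(is.finite(cutoff))
  if (!length(dosages)) return(character(0))
  out <- ifelse(dosages > cutoff, "high", "low")
  if (anyNA(dosages)) {
    warning(sum(is.na(dosages)), " undefined dosage value(s) left NA")
    out[is.na(dosages)] <- NA_character_
  }
  out
}

#' @rdname scanCutpoints
#' @param scan a [CutpointScan-class].
#' @return `scanAsTable()`: data.frame with cutoff, chi_square, p.
#' @export
scanAsTable <- function(scan) {
  data.frame(cutoff = scan@cutoffs, chi_square = scan@chisq, p = scan@p)
}
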