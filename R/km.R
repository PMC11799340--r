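#' Kaplan-Meier estimation and summaries
#'
#' `kmFit()` computes the product-limit estimator. At tied times,
#' censorings are processed after events (the standard convention), so a
#' subject censored at an event time is still in the risk set for that
#' event. `kmMedian()` returns the smallest time with S(t) <= 0.5, or NA
#' when the curve never reaches 0.5. `kmRateAt()` evaluates the
#' right-continuous step function S(t); 1-, 3- and 5-year survival rates
#' are S(12), S(36), S(60) on the month scale.
#'
#' @param time non-negative follow-up times (months).
#' @param event 1 = event occurred, 0 = censored.
#' @return `kmFit()`: a [KMCurve-class]; `kmMedian()`: months or
#'   `NA_real_`; `kmRateAt()`: S(t) in [0, 1].
#' @examples
#' curve <- kmFit(c(1, 2, 3), c(0, 1, 0))
#' kmRateAt(curve, 2)   # 0.5: at-risk 2 at t = 2
#' kmMedian(curve)
#' @export
kmFit <- function(time, event) {
  if (length(time) < 1L) stop("need at least one sample")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")

  ut <- sort(unique(time))
  nEvents <- as.integer(vapply(ut, function(t) sum(time == t & event == 1L),
                               numeric(1)))
  nCens <- as.integer(vapply(ut, function(t) sum(time == t & event == 0L),
                             numeric(1)))
  n <- length(time)
  atRisk <- as.integer(n - c(0L, cumsum(nEvents + nCens))[seq_along(ut)])
  surv <- cumprod(1 - nEvents / atRisk)
  new("KMCurve", time = ut, surv = surv, atRisk = atRisk,
      nEvents = nEvents, nCensored = nCens, n = as.integer(n))
}

#' @rdname kmFit
#' @export
setMethod("kmMedian", "KMCurve", function(curve) {
  hit <- which(curve@surv <= 0.5 + 1e-12)
  if (!length(hit)) return(NA_real_)
  curve@time[hit[1L]]
})

#' @rdname kmFit
#' @export
setMethod("kmRateAt", "KMCurve", function(curve, t) {
  stopifnot(t >= 0)
  vapply(t, function(tt) {
    idx <- which(curve@time <= tt)
    if (!length(idx)) 1 else curve@surv[max(idx)]
  }, numeric(1))
})

setMethod("show", "KMCurve", function(object) {
  cat(sprintf("KMCurve: n=%d, %d events over %d distinct times\n",
              object@n, sum(object@nEvents), length(object@time)))
  med <- kmMedian(object)
  cat(sprintf("  median: %s months\n",
              if (is.na(med)) "NA (not reached)" else format(med)))
})

#' Export a KM curve as a data.frame
#'
#' @param curve a [KMCurve-class].
#' @return data.frame with columns time, survival, at_risk, n_events.
#' @export
kmAsTable <- function(curve) {
  data.frame(time = curve@time, survival = curve@surv,
             at_risk = curve@atRisk, n_events = curve@nEvents)
}
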