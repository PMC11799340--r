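#' @import methods
#' @importFrom stats pchisq pnorm pt qbeta rbeta rbinom rexp rlnorm rmultinom
#'   runif setNames complete.cases
#' @importFrom utils read.csv read.delim write.table packageVersion
NULL

#' TargetLocus: a hotspot codon on the genome
#'
#' Describes one codon of interest by its three genomic coordinates, the
#' reference codon in genomic (plus-strand) orientation, the strand the gene
#' is transcribed from, and the genome build the coordinates refer to.
#' KRAS is on the minus strand, so the coding codon is the reverse
#' complement of \code{refCodon}.
#'
#' @slot chrom chromosome name.
#' @slot positions integer(3), consecutive ascending 1-based coordinates.
#' @slot refCodon three reference bases in genomic orientation.
#' @slot geneStrand \code{"+"} or \code{"-"}.
#' @slot build genome build tag, e.g. \code{"hg19"}.
#'
#' @seealso [krasLocus()] for the shipped G12/Q61 presets.
#' @export
setClass("TargetLocus",
  slots = c(
    chrom = "character",
    positions = "integer",
    refCodon = "character",
    geneStrand = "character",
    build = "character"
  )
)

setValidity("TargetLocus", function(object) {
  msg <- character()
  if (length(object@positions) != 3L)
    msg <- c(msg, "positions must have length 3")
  else if (!all(diff(object@positions) == 1L))
    msg <- c(msg, "codon positions must be consecutive ascending")
  if (length(object@refCodon) != 1L || nchar(object@refCodon) != 3L ||
      grepl("[^ACGT]", object@refCodon))
    msg <- c(msg, "refCodon must be three bases in ACGT")
  if (!object@geneStrand %in% c("+", "-"))
    msg <- c(msg, "geneStrand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' AlleleCounts: read counts at a hotspot codon
#'
#' Mutant / wild-type / other read counts for one sample, sequencing
#' modality and codon. "Mutant" means a non-synonymous substitution at the
#' codon, "other" collects reads that span the codon but cannot be
#' classified (indel-spanning, N bases, synonymous changes, quality
#' failures).
#'
#' @slot mutant,wildtype,other non-negative integer read counts.
#' @slot modality one of \code{"RNA"}, \code{"WES"}, \code{"TS"}.
#' @slot codon one of \code{"G12"}, \code{"Q61"}.
#' @export
setClass("AlleleCounts",
  slots = c(
    mutant = "integer",
    wildtype = "integer",
    other = "integer",
    modality = "character",
    codon = "character"
  )
)

setValidity("AlleleCounts", function(object) {
  msg <- character()
  for (s in c("mutant", "wildtype", "other")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0L)
      msg <- c(msg, sprintf("%s must be a single non-negative integer", s))
  }
  if (!object@modality %in% c("RNA", "WES", "TS"))
    msg <- c(msg, "modality must be RNA, WES or TS")
  if (!object@codon %in% c("G12", "Q61"))
    msg <- c(msg, "codon must be G12 or Q61")
  if (length(msg)) msg else TRUE
})

#' KMCurve: Kaplan-Meier product-limit estimate
#'
#' @slot time ascending distinct observed times (months).
#' @slot surv survival estimates S(t), non-increasing, within [0, 1].
#' @slot atRisk number at risk just before each time.
#' @slot nEvents events at each time.
#' @slot nCensored censorings at each time.
#' @slot n number of subjects the curve was fitted to.
#' @export
setClass("KMCurve",
  slots = c(
    time = "numeric",
    surv = "numeric",
    atRisk = "integer",
    nEvents = "integer",
    nCensored = "integer",
    n = "integer"
  )
)

setValidity("KMCurve", function(object) {
  msg <- character()
  k <- length(object@time)
  if (length(object@surv) != k || length(object@atRisk) != k ||
      length(object@nEvents) != k || length(object@nCensored) != k)
    msg <- c(msg, "all curve slots must have equal length")
  if (k && is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "time must be strictly ascending")
  if (any(object@surv < 0 | object@surv > 1))
    msg <- c(msg, "survival estimates must lie in [0, 1]")
  if (k > 1 && any(diff(object@surv) > 1e-12))
    msg <- c(msg, "survival must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' CutpointScan: log-rank profile over candidate dosage cutoffs
#'
#' Result of scanning candidate dichotomization cutoffs of a continuous
#' marker and computing the two-group log-rank statistic at each
#' (the maximally selected log-rank statistic).
#'
#' @slot cutoffs ascending candidate cutoffs (midpoints of distinct
#'   observed dosages satisfying the group-size constraint).
#' @slot chisq log-rank chi-square at each cutoff.
#' @slot p naive chi-square(1) upper-tail p at each cutoff. These do not
#'   account for the selection over cutoffs; see \code{permP}.
#' @slot selected the cutoff(s) chosen by [selectGlobal()] or
#'   [selectLocalMaxima()].
#' @slot mode \code{"global"} or \code{"local_maxima"}.
#' @slot minGroupSize the smaller-group floor used to restrict candidates.
#' @slot permP selection-corrected permutation p-value for the maximum
#'   statistic (NA unless requested).
#' @export
setClass("CutpointScan",
  slots = c(
    cutoffs = "numeric",
    chisq = "numeric",
    p = "numeric",
    selected = "numeric",
    mode = "character",
    minGroupSize = "integer",
    permP = "numeric"
  )
)

setValidity("CutpointScan", function(object) {
  msg <- character()
  k <- length(object@cutoffs)
  if (length(object@chisq) != k || length(object@p) != k)
    msg <- c(msg, "cutoffs, chisq and p must have equal length")
  if (k && is.unsorted(object@cutoffs, strictly = TRUE))
    msg <- c(msg, "cutoffs must be strictly ascending")
  if (any(object@chisq < 0)) msg <- c(msg, "chisq must be non-negative")
  if (any(object@p < 0 | object@p > 1)) msg <- c(msg, "p must lie in [0, 1]")
  if (length(object@selected) &&
      !all(object@selected %in% object@cutoffs))
    msg <- c(msg, "selected cutoffs must be members of cutoffs")
  if (length(msg)) msg else TRUE
})

#' CoxResult: proportional-hazards fit by Efron partial likelihood
#'
#' @slot coefficients data.frame with one row per covariate: \code{term},
#'   \code{coef}, \code{hr}, \code{se}, \code{z}, \code{p}, \code{ciLow},
#'   \code{ciHigh} (Wald 95\% CI on the hazard-ratio scale).
#' @slot logLik length-2 numeric: null and maximized log partial likelihood.
#' @slot scoreChisq score (log-rank-type) chi-square at the null.
#' @slot iter Newton-Raphson iterations used.
#' @slot converged logical convergence flag; FALSE signals monotone
#'   likelihood (e.g. perfect separation).
#' @slot n,nEvent subjects and events in the fit.
#' @export
setClass("CoxResult",
  slots = c(
    coefficients = "data.frame",
    logLik = "numeric",
    scoreChisq = "numeric",
    iter = "integer",
    converged = "logical",
    n = "integer",
    nEvent = "integer"
  )
)

setValidity("CoxResult", function(object) {
  msg <- character()
  cf <- object@coefficients
  need <- c("term", "coef", "hr", "se", "z", "p", "ciLow", "ciHigh")
  if (!all(need %in% names(cf)))
    msg <- c(msg, "coefficients must carry term/coef/hr/se/z/p/ciLow/ciHigh")
  else {
    ok <- complete.cases(cf[, c("hr", "ciLow", "ciHigh")])
    if (any(cf$hr[ok] <= 0)) msg <- c(msg, "hazard ratios must be positive")
    if (any(cf$ciLow[ok] > cf$hr[ok] | cf$ciHigh[ok] < cf$hr[ok]))
      msg <- c(msg, "Wald CI must contain the hazard ratio")
  }
  if (length(msg)) msg else TRUE
})

#' ScoreSummary: survival summaries stratified by prognostic score
#'
#' @slot summary long data.frame: one row per (endpoint, score stratum)
#'   with n, cohort share, KM median (NA when the curve never reaches 0.5),
#'   survival rates at 12/36/60 months, and the Cox hazard ratio versus the
#'   0-point stratum with 95\% CI and Wald p (HR fixed at 1 for the
#'   reference stratum).
#' @slot km named list (\code{os}, \code{rfs}) of per-stratum [KMCurve]s.
#' @slot cox named list (\code{os}, \code{rfs}) of [CoxResult]s, or empty
#'   when fewer than two strata are occupied.
#' @export
setClass("ScoreSummary",
  slots = c(summary = "data.frame", km = "list", cox = "list")
)

setValidity("ScoreSummary", function(object) {
  s <- object@summary
  msg <- character()
  for (ep in unique(s$endpoint)) {
    sh <- s$share[s$endpoint == ep]
    if (abs(sum(sh) - 1) > 1e-8)
      msg <- c(msg, "stratum shares must sum to 1 within each endpoint")
  }
  rates <- unlist(s[, intersect(c("rate12", "rate36", "rate60"), names(s))])
  rates <- rates[!is.na(rates)]
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
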