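## Synthetic-cohort generator: latent tumor biology -> read-level pileups ->
## clinical covariates -> proportional-hazards survival/recurrence outcomes.
## The defaults emulate a surgically resected PDAC cohort: low median tumor
## purity (~0.265, range clamped to [0.15, 1]), rare KRAS amplification
## (2.6%), rare subclonal Q61 co-mutation (7.3%), ultra-deep targeted
## sequencing (1e6x) vs. exome depth (300x), and RNA dosage inflated above
## the DNA VAF by a mutant-allele expression bias.

.distSample <- function(dist, n) {
  if (n == 0L) return(numeric(0))
  switch(dist$type,
    beta = {
      lo <- if (is.null(dist$lower)) 0 else dist$lower
      hi <- if (is.null(dist$upper)) 1 else dist$upper
      lo + (hi - lo) * rbeta(n, dist$shape1, dist$shape2)
    },
    mixture = {
      w <- dist$weights / sum(dist$weights)
      comp <- sample.int(length(w), n, replace = TRUE, prob = w)
      out <- numeric(n)
      for (j in seq_along(w)) {
        idx <- which(comp == j)
        if (length(idx)) out[idx] <- .distSample(dist$components[[j]],
                                                 length(idx))
      }
      out
    },
    lnorm = rlnorm(n, dist$meanlog, dist$sdlog),
    loguniform = exp(runif(n, log(dist$min), log(dist$max))),
    uniform = runif(n, dist$min, dist$max),
    fixed = rep(dist$value, n),
    stop("unknown distribution type: ", dist$type)
  )
}

#' Simulation configuration for synthetic cohorts
#'
#' Bundles every tunable of the synthetic-cohort generator and validates
#' ranges. Defaults target the cohort structure of resected pancreatic
#' ductal adenocarcinoma: tumor purity Beta(2, 11) rescaled to
#' [0.15, 1] (median about 0.265), KRAS amplification in 2.6\% of tumors
#' (amplified tumors carry 4 total copies with the mutant allele
#' amplified), a subclonal Q61 co-mutation in 7.3\%, targeted-sequencing
#' depth 1,000,000x, exome depth 300x, RNA depth log-uniform on
#' [20, 2000], a mutant-allele expression bias of 1.5 so RNA dosage runs
#' above the DNA VAF, and exponential baseline hazards whose rates put the
#' zero-risk-factor median OS near 97 months and median RFS near 58
#' months. Hazards multiply by \code{exp(log HR)} for each active risk
#' flag (dosage above threshold, tumor diameter > 20 mm,
#' CA 19-9 > 150 U/mL). Times are in months throughout.
#'
#' @param n_patients cohort size.
#' @param seed integer seed; all randomness in [generateCohort()] flows
#'   from it via per-patient L'Ecuyer-CMRG substreams.
#' @param purity_dist,subclonal_fraction_dist,depth_rna_dist,size_dist,ca199_dist
#'   distribution specs (lists with a \code{type} field understood by the
#'   internal sampler: beta, mixture, lnorm, loguniform, uniform, fixed).
#' @param amplification_prob probability of KRAS amplification.
#' @param amplified_copies total KRAS copies in amplified tumors (>= 3).
#' @param subclonal_q61_prob probability of a subclonal Q61 co-mutation
#'   (always on top of a clonal G12 mutation).
#' @param depth_ts,depth_wes sequencing depths at the hotspot codon.
#' @param rna_allelic_bias multiplicative mutant-allele expression factor.
#' @param sequencing_error per-read miscall probability.
#' @param baseline_hazard_os,baseline_hazard_rfs exponential event rates
#'   per month with no active risk flags.
#' @param log_hr_dosage,log_hr_size,log_hr_ca199 log hazard ratios of the
#'   three binarized risk factors.
#' @param censor_rate exponential censoring rate per month.
#' @param dosage_threshold truth-level dosage threshold that activates the
#'   dosage risk flag.
#' @param prob_local probability that an observed recurrence is local
#'   (rather than distant).
#' @return a validated list of class \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(n_patients = 50, seed = 1)
#' @export
simulationConfig <- function(
  n_patients = 193L,
  seed = 1L,
  purity_dist = list(type = "beta", shape1 = 2, shape2 = 11,
                     lower = 0.15, upper = 1),
  amplification_prob = 0.026,
  amplified_copies = 4L,
  subclonal_q61_prob = 0.073,
  subclonal_fraction_dist = list(type = "beta", shape1 = 2, shape2 = 2),
  depth_ts = 1000000L,
  depth_wes = 300L,
  depth_rna_dist = list(type = "loguniform", min = 20, max = 2000),
  rna_allelic_bias = 1.5,
  sequencing_error = 1e-3,
  baseline_hazard_os = log(2) / 97,
  baseline_hazard_rfs = log(2) / 58,
  log_hr_dosage = log(2),
  log_hr_size = log(1.7),
  log_hr_ca199 = log(1.7),
  censor_rate = 0.008,
  dosage_threshold = 0.195,
  prob_local = 0.22,
  size_dist = list(type = "lnorm", meanlog = log(28), sdlog = 0.45),
  ca199_dist = list(type = "lnorm", meanlog = log(140), sdlog = 1.5)
) {
  cfg <- as.list(environment())
  probs <- c(amplification_prob, subclonal_q61_prob, sequencing_error,
             prob_local)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (n_patients < 0) stop("n_patients must be non-negative")
  if (depth_ts < 1 || depth_wes < 1) stop("depths must be >= 1")
  if (amplified_copies < 3) stop("amplified_copies must be >= 3")
  rates <- c(baseline_hazard_os, baseline_hazard_rfs, censor_rate)
  if (any(rates <= 0)) stop("hazard and censoring rates must be > 0")
  if (rna_allelic_bias < 0) stop("rna_allelic_bias must be >= 0")
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "SimulationConfig")
}

#' Expected variant allele frequency under purity and copy number
#'
#' In a specimen with tumor-cell fraction \eqn{p} whose tumor cells carry
#' \eqn{c} total copies of the locus, \eqn{m} of them mutant, and whose
#' admixed normal cells carry two wild-type copies, the expected fraction
#' of mutant reads is
#' \deqn{v = p m / (p c + 2 (1 - p)).}
#' At copy-neutral heterozygosity (c = 2, m = 1) this reduces to p/2, so
#' dosage rises linearly with tumor purity.
#'
#' @param purity tumor-cell fraction in (0, 1].
#' @param totalCopies tumor locus copies, >= 1.
#' @param mutantCopies mutant copies, 0 <= m <= c.
#' @return expected VAF in [0, 1]. Vectorized over all arguments.
#' @examples
#' expectedVaf(1, 2, 1)      # 0.5: pure heterozygous tumor
#' expectedVaf(0.265, 2, 1)  # 0.1325: median-purity PDAC
#' @export
expectedVaf <- function(purity, totalCopies, mutantCopies) {
  if (any(purity <= 0 | purity > 1))
    stop("purity must lie in (0, 1]")
  if (any(totalCopies < 1)) stop("totalCopies must be >= 1")
  if (any(mutantCopies < 0 | mutantCopies > totalCopies))
    stop("mutantCopies must lie in [0, totalCopies]")
  purity * mutantCopies / (purity * totalCopies + 2 * (1 - purity))
}

# RNA-side dosage: mutant-allele expression multiplied by bias b
.expectedRnaDosage <- function(purity, totalCopies, mutantCopies, bias) {
  p <- purity; c <- totalCopies; m <- mutantCopies
  denom <- p * (m * bias + (c - m)) + 2 * (1 - p)
  ifelse(denom > 0, p * m * bias / denom, 0)
}

#' Draw the latent tumor state of one synthetic patient
#'
#' Draws purity, the copy state (amplified with
#' \code{amplification_prob}; amplified tumors carry the mutant allele on
#' all but one copy), and the subclonal Q61 indicator, then fills the
#' expected G12 VAF, expected Q61 VAF (cell fraction multiplying purity)
#' and expected RNA dosage (mutant-allele expression bias applied). Uses
#' the current RNG state; seed upstream for reproducibility.
#'
#' @param config a [simulationConfig()].
#' @return list with purity, total_copies, mutant_copies_g12,
#'   q61_cell_fraction, expected_vaf_g12, expected_vaf_q61,
#'   expected_rna_dosage.
#' @export
simulatePatient <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  purity <- min(max(.distSample(config$purity_dist, 1L), 0.15), 1)
  amplified <- runif(1) < config$amplification_prob
  totalCopies <- if (amplified) config$amplified_copies else 2L
  mutantCopies <- if (amplified) totalCopies - 1L else 1L
  q61 <- runif(1) < config$subclonal_q61_prob
  q61Frac <- if (q61) .distSample(config$subclonal_fraction_dist, 1L) else 0
  vafG12 <- expectedVaf(purity, totalCopies, mutantCopies)
  vafQ61 <- if (q61Frac > 0) expectedVaf(purity * q61Frac, 2L, 1L) else 0
  list(
    purity = purity,
    total_copies = totalCopies,
    mutant_copies_g12 = mutantCopies,
    q61_cell_fraction = q61Frac,
    expected_vaf_g12 = vafG12,
    expected_vaf_q61 = vafQ61,
    expected_rna_dosage = .expectedRnaDosage(purity, totalCopies,
                                             mutantCopies,
                                             config$rna_allelic_bias)
  )
}

#' Simulate a pileup at the hotspot codon
#'
#' Reads are drawn from the true allele mix and passed through a uniform
#' miscall channel: a read is miscalled with probability
#' \code{errorRate}, landing on each of the three non-true bases with
#' equal probability. Observed category probabilities are therefore
#' mutant \eqn{v(1-e) + (1-v)e/3}, wild-type \eqn{(1-v)(1-e) + v e/3},
#' other \eqn{2e/3}. Counts always sum to \code{depth}.
#'
#' @param expectedVaf true mutant-allele fraction in [0, 1].
#' @param depth number of reads (>= 0).
#' @param errorRate per-read miscall probability.
#' @param modality,codon labels attached to the result.
#' @return an [AlleleCounts-class].
#' @examples
#' set.seed(1)
#' simulatePileup(0.2, 1000, 1e-3)
#' @export
simulatePileup <- function(expectedVaf, depth, errorRate = 0,
                           modality = "TS", codon = "G12") {
  stopifnot(depth >= 0, expectedVaf >= 0, expectedVaf <= 1,
            errorRate >= 0, errorRate <= 1)
  if (depth == 0)
    return(AlleleCounts(0L, 0L, 0L, modality = modality, codon = codon))
  v <- expectedVaf; e <- errorRate
  pMut <- v * (1 - e) + (1 - v) * e / 3
  pWt <- (1 - v) * (1 - e) + v * e / 3
  pOther <- max(0, 1 - pMut - pWt)
  cnt <- rmultinom(1L, size = as.integer(depth), prob = c(pMut, pWt, pOther))
  AlleleCounts(cnt[1L], cnt[2L], cnt[3L], modality = modality, codon = codon)
}

#' Simulate survival and recurrence outcomes for one patient
#'
#' Death and recurrence times are exponential with rates
#' \code{baseline_hazard_os} and \code{baseline_hazard_rfs} multiplied by
#' \code{exp(sum of log HRs of active risk flags)}; censoring is an
#' independent exponential with \code{censor_rate}. RFS is the time to
#' the earlier of recurrence and death, so RFS <= OS by construction. A
#' recurrence pattern (local/distant) is drawn only when recurrence is
#' actually observed.
#'
#' @param riskFlags logical(3): dosage, size and CA 19-9 flags.
#' @param config a [simulationConfig()].
#' @return list with os_months, os_event, rfs_months, rfs_event,
#'   recurrence_pattern (\code{NA} when no recurrence was observed).
#' @export
simulateOutcomes <- function(riskFlags, config) {
  stopifnot(inherits(config, "SimulationConfig"), length(riskFlags) == 3L)
  lp <- sum(c(config$log_hr_dosage, config$log_hr_size,
              config$log_hr_ca199) * as.numeric(riskFlags))
  death <- rexp(1, config$baseline_hazard_os * exp(lp))
  recur <- rexp(1, config$baseline_hazard_rfs * exp(lp))
  cens <- rexp(1, config$censor_rate)
  osMonths <- min(death, cens)
  osEvent <- as.integer(death <= cens)
  rfsLatent <- min(recur, death)
  rfsMonths <- min(rfsLatent, cens)
  rfsEvent <- as.integer(rfsLatent <= cens)
  recurrenceObserved <- recur < death && recur <= cens
  pattern <- if (recurrenceObserved) {
    if (runif(1) < config$prob_local) "local" else "distant"
  } else NA_character_
  list(os_months = osMonths, os_event = osEvent,
       rfs_months = rfsMonths, rfs_event = rfsEvent,
       recurrence_pattern = pattern)
}

.emptyCohort <- function() {
  list(
    clinical = data.frame(
      patient_id = character(), age_years = numeric(), sex = character(),
      asa_class = character(), location = character(),
      tumor_diameter_mm = numeric(), ca19_9_u_ml = numeric(),
      stage = character(), margin = character(), adjuvant_ctx = character(),
      os_months = numeric(), os_event = integer(), rfs_months = numeric(),
      rfs_event = integer(), recurrence_pattern = character(),
      stringsAsFactors = FALSE),
    counts = data.frame(
      patient_id = character(), modality = character(), codon = character(),
      mutant_reads = integer(), wildtype_reads = integer(),
      other_reads = integer(), stringsAsFactors = FALSE),
    truth = data.frame(
      patient_id = character(), purity = numeric(), total_copies = integer(),
      mutant_copies_g12 = integer(), q61_cell_fraction = numeric(),
      expected_vaf_g12 = numeric(), expected_rna_dosage = numeric(),
      stringsAsFactors = FALSE)
  )
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generative model for \code{n_patients}: latent tumor
#' state, per-modality pileups at the G12 codon (plus the Q61 codon for
#' targeted sequencing), clinical covariates, and survival/recurrence
#' outcomes whose hazards depend on the truth-level risk flags. Every
#' patient gets an independent L'Ecuyer-CMRG substream spawned from
#' \code{config$seed}, so a cohort is reproducible and insensitive to
#' patient order.
#'
#' @param config a [simulationConfig()].
#' @return list of three linked data.frames keyed by \code{patient_id}:
#'   \code{clinical} (covariates and OS/RFS follow-up), \code{counts}
#'   (per-modality allele counts at the hotspot codons), and \code{truth}
#'   (latent purity, copy state and expected dosages, for recovery tests).
#' @examples
#' cohort <- generateCohort(simulationConfig(n_patients = 5, seed = 42))
#' cohort$clinical$os_months
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$n_patients
  if (n == 0L) return(.emptyCohort())

  oldKind <- RNGkind()
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
  on.exit({
    RNGkind(oldKind[1], oldKind[2], oldKind[3])
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(config$seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", globalenv())

  ids <- sprintf("P%04d", seq_len(n))
  clinical <- vector("list", n)
  countsRows <- vector("list", n)
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, globalenv())

    lat <- simulatePatient(config)

    depthRna <- max(1L, as.integer(round(.distSample(config$depth_rna_dist,
                                                     1L))))
    e <- config$sequencing_error
    acRna <- simulatePileup(lat$expected_rna_dosage, depthRna, e, "RNA")
    acWes <- simulatePileup(lat$expected_vaf_g12, config$depth_wes, e, "WES")
    acTs <- simulatePileup(lat$expected_vaf_g12, config$depth_ts, e, "TS")
    acQ61 <- simulatePileup(lat$expected_vaf_q61, config$depth_ts, e, "TS",
                            codon = "Q61")

    age <- min(max(stats::rnorm(1, 64.7, 10.2), 30), 92)
    sex <- if (runif(1) < 0.565) "male" else "female"
    asa <- if (runif(1) < 0.073) "III/IV" else "I/II"
    location <- sample(c("head", "body_tail", "diffuse"), 1L,
                       prob = c(0.565, 0.415, 0.020))
    stage <- sample(c("I", "II", "III"), 1L, prob = c(0.285, 0.503, 0.212))
    margin <- if (runif(1) < 0.171) "R1" else "R0"
    adjuvant <- if (runif(1) < 0.699) "Y" else "N"
    size <- .distSample(config$size_dist, 1L)
    ca199 <- .distSample(config$ca199_dist, 1L)

    flags <- c(lat$expected_vaf_g12 > config$dosage_threshold,
               size > 20, ca199 > 150)
    out <- simulateOutcomes(flags, config)

    clinical[[i]] <- data.frame(
      patient_id = ids[i], age_years = age, sex = sex, asa_class = asa,
      location = location, tumor_diameter_mm = size, ca19_9_u_ml = ca199,
      stage = stage, margin = margin, adjuvant_ctx = adjuvant,
      os_months = out$os_months, os_event = out$os_event,
      rfs_months = out$rfs_months, rfs_event = out$rfs_event,
      recurrence_pattern = out$recurrence_pattern, stringsAsFactors = FALSE)

    countsRows[[i]] <- data.frame(
      patient_id = ids[i],
      modality = c("RNA", "WES", "TS", "TS"),
      codon = c("G12", "G12", "G12", "Q61"),
      mutant_reads = c(acRna@mutant, acWes@mutant, acTs@mutant, acQ61@mutant),
      wildtype_reads = c(acRna@wildtype, acWes@wildtype, acTs@wildtype,
                         acQ61@wildtype),
      other_reads = c(acRna@other, acWes@other, acTs@other, acQ61@other),
      stringsAsFactors = FALSE)

    truth[[i]] <- data.frame(
      patient_id = ids[i], purity = lat$purity,
      total_copies = lat$total_copies,
      mutant_copies_g12 = lat$mutant_copies_g12,
      q61_cell_fraction = lat$q61_cell_fraction,
      expected_vaf_g12 = lat$expected_vaf_g12,
      expected_rna_dosage = lat$expected_rna_dosage,
      stringsAsFactors = FALSE)
  }

  list(clinical = do.call(rbind, clinical),
       counts = do.call(rbind, countsRows),
       truth = do.call(rbind, truth))
}
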