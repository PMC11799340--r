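test_that("expected VAF follows the purity/copy-number mixing model", {
  expect_equal(expectedVaf(1, 2, 1), 0.5)
  expect_equal(expectedVaf(0.265, 2, 1), 0.1325)
  expect_equal(expectedVaf(0.5, 4, 3), 0.5)  # 0.5*3 / (0.5*4 + 2*0.5)

  # strictly increasing in purity at copy-neutral heterozygosity
  p <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(expectedVaf(p, 2, 1)) > 0))

  expect_error(expectedVaf(0, 2, 1), "purity")
  expect_error(expectedVaf(0.5, 2, 3), "mutantCopies")
  expect_error(expectedVaf(0.5, 0, 0), "totalCopies")
})

test_that("latent patient states honor the configured copy and clone rates", {
  cfg0 <- simulationConfig(n_patients = 10, seed = 1, amplification_prob = 0)
  set.seed(5)
  states <- replicate(200, simulatePatient(cfg0), simplify = FALSE)
  expect_true(all(vapply(states, `[[`, numeric(1), "total_copies") == 2))

  # with unit allelic bias the RNA dosage is the DNA VAF (formula identity)
  cfgB <- simulationConfig(n_patients = 10, seed = 1, rna_allelic_bias = 1)
  set.seed(6)
  st <- replicate(200, simulatePatient(cfgB), simplify = FALSE)
  expect_equal(vapply(st, `[[`, numeric(1), "expected_rna_dosage"),
               vapply(st, `[[`, numeric(1), "expected_vaf_g12"))

  # default amplification rate recovered within a binomial 99% CI
  cfg <- simulationConfig(n_patients = 10, seed = 1)
  set.seed(7)
  amp <- replicate(10000,
                   simulatePatient(cfg)$total_copies > 2)
  ci <- 2.576 * sqrt(0.026 * 0.974 / 10000)
  expect_lt(abs(mean(amp) - 0.026), ci)

  # purity stays in [0.15, 1] with median near 0.265
  set.seed(8)
  pur <- replicate(5000, simulatePatient(cfg)$purity)
  expect_true(all(pur >= 0.15 & pur <= 1))
  expect_lt(abs(median(pur) - 0.265), 0.02)

  # a Q61 subclone always rides on a clonal G12 mutation
  set.seed(9)
  st2 <- replicate(500, simulatePatient(cfg), simplify = FALSE)
  q61 <- vapply(st2, `[[`, numeric(1), "q61_cell_fraction") > 0
  g12 <- vapply(st2, `[[`, numeric(1), "mutant_copies_g12") >= 1
  expect_true(all(g12[q61]))
})

test_that("pileups conserve depth, hit zero without signal, and replay", {
  set.seed(1)
  ac <- simulatePileup(0, 1000, 0)
  expect_identical(mutantReads(ac), 0L)
  expect_identical(totalReads(ac), 1000L)

  # counts conservation across random parameter draws
  set.seed(2)
  for (i in 1:25) {
    v <- runif(1); depth <- sample(0:5000, 1); e <- runif(1, 0, 0.01)
    acc <- simulatePileup(v, depth, e)
    expect_identical(totalReads(acc), as.integer(depth))
  }

  # ultra-deep dosage concentrates on the true VAF
  set.seed(3)
  deep <- simulatePileup(0.2, 1e6, 0)
  expect_lt(abs(computeDosage(deep) - 0.2), 0.002)

  # replaying the stream reproduces counts exactly
  set.seed(4); a <- simulatePileup(0.3, 500, 1e-3)
  set.seed(4); b <- simulatePileup(0.3, 500, 1e-3)
  expect_identical(mutantReads(a), mutantReads(b))
  expect_identical(wildtypeReads(a), wildtypeReads(b))

  # unbiasedness of the composed estimator up to the error channel
  set.seed(5)
  v <- 0.13; depth <- 2000
  reps <- replicate(1000, computeDosage(simulatePileup(v, depth, 0)))
  expect_lt(abs(mean(reps) - v), 3 * sqrt(v * (1 - v) / depth))
})

test_that("outcomes respect RFS <= OS and degenerate censoring", {
  cfg <- simulationConfig(n_patients = 10, seed = 1)
  set.seed(10)
  for (i in 1:200) {
    out <- simulateOutcomes(c(i %% 2 == 0, FALSE, TRUE), cfg)
    expect_lte(out$rfs_months, out$os_months)
    if (!is.na(out$recurrence_pattern))
      expect_true(out$recurrence_pattern %in% c("local", "distant"))
  }

  heavy <- simulationConfig(n_patients = 10, seed = 1, censor_rate = 1e6)
  set.seed(11)
  outs <- replicate(100, simulateOutcomes(c(FALSE, FALSE, FALSE), heavy),
                    simplify = FALSE)
  expect_true(all(vapply(outs, `[[`, numeric(1), "os_months") < 0.01))
  expect_true(mean(vapply(outs, `[[`, numeric(1), "os_event")) < 0.05)
})

test_that("cohorts are keyed, reproducible and structurally sound", {
  empty <- generateCohort(simulationConfig(n_patients = 0, seed = 1))
  expect_identical(nrow(empty$clinical), 0L)
  expect_true(all(c("patient_id", "os_months") %in% names(empty$clinical)))
  expect_true(all(c("modality", "mutant_reads") %in% names(empty$counts)))

  cfg <- simulationConfig(n_patients = 193, seed = 42)
  co <- generateCohort(cfg)
  expect_identical(nrow(co$clinical), 193L)
  expect_identical(nrow(co$truth), 193L)
  expect_identical(nrow(co$counts), 193L * 4L)  # RNA, WES, TS-G12, TS-Q61
  expect_false(anyDuplicated(co$clinical$patient_id) > 0)
  expect_true(all(co$clinical$rfs_months <= co$clinical$os_months + 1e-12))

  # determinism: the same config regenerates the same cohort
  co2 <- generateCohort(cfg)
  expect_identical(co, co2)
})

test_that("mean targeted dosage is non-decreasing across purity strata", {
  co <- sharedCohort()
  prof <- sharedProfiles()
  strata <- cut(co$truth$purity, quantile(co$truth$purity, 0:5 / 5),
                include.lowest = TRUE)
  means <- tapply(prof$dosage_ts, strata, mean)
  expect_true(all(diff(means) >= 0))
})

test_that("a bimodal purity mixture yields a bimodal targeted-dosage law", {
  cfg <- simulationConfig(
    n_patients = 400, seed = 7,
    purity_dist = list(
      type = "mixture", weights = c(0.5, 0.5),
      components = list(
        list(type = "beta", shape1 = 50, shape2 = 200,
             lower = 0.15, upper = 1),
        list(type = "beta", shape1 = 200, shape2 = 50,
             lower = 0.15, upper = 1))))
  prof <- buildDosageProfiles(generateCohort(cfg)$counts)
  dens <- stats::density(prof$dosage_ts, adjust = 2)
  nModes <- sum(diff(sign(diff(dens$y))) == -2)
  expect_identical(nModes, 2L)
})
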