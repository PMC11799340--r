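test_that("score points use strict thresholds and sum correctly", {
  expect_identical(assignScore(15, 100, 0.10)$total, 0L)
  expect_identical(assignScore(25, 200, 0.30)$total, 3L)
  expect_identical(assignScore(20, 150, 0.195)$total, 0L)  # boundaries

  expect_error(assignScore(25, 200, NA_real_), "undefined dosage")

  # monotonicity: crossing any single threshold never lowers the score
  set.seed(61)
  for (i in 1:50) {
    sz <- runif(1, 5, 60); ca <- runif(1, 10, 600); dd <- runif(1)
    base <- assignScore(sz, ca, dd)$total
    expect_gte(assignScore(max(sz, 20.01), ca, dd)$total, base)
    expect_gte(assignScore(sz, max(ca, 150.01), dd)$total, base)
    expect_gte(assignScore(sz, ca, max(dd, 0.1951))$total, base)
  }

  # alternative published threshold scores the 0.15 dosage differently
  alt <- scoreThresholds(dosage = 0.139)
  expect_identical(assignScore(15, 100, 0.15, alt)$total, 1L)
})

test_that("score strata reproduce their own KM and Cox summaries", {
  set.seed(62)
  n <- 400L
  scores <- sample(0:3, n, replace = TRUE)
  lp <- 0.5 * scores
  osT <- rexp(n, 0.01 * exp(lp)); rfsT <- pmin(osT, rexp(n, 0.02 * exp(lp)))
  cc <- rexp(n, 0.005)
  cohort <- data.frame(
    os_months = pmin(osT, cc), os_event = as.integer(osT <= cc),
    rfs_months = pmin(rfsT, cc), rfs_event = as.integer(rfsT <= cc))
  ss <- stratifyByScore(cohort, scores)
  s <- ss@summary

  expect_equal(sum(s$share[s$endpoint == "os"]), 1)
  expect_identical(sum(s$n[s$endpoint == "os"]), n)

  # reference stratum carries HR exactly 1
  expect_equal(s$hr[s$endpoint == "os" & s$score == 0], 1)

  # per-stratum medians equal kmMedian run standalone
  for (sc in 0:3) {
    idx <- scores == sc
    expect_equal(s$median[s$endpoint == "os" & s$score == sc],
                 kmMedian(kmFit(cohort$os_months[idx],
                                cohort$os_event[idx])))
  }

  # permutation equivariance: shuffling patients changes nothing
  set.seed(63)
  perm <- sample(n)
  ss2 <- stratifyByScore(cohort[perm, ], scores[perm])
  expect_equal(ss2@summary, s)

  # a single-stratum cohort yields KM output but no hazard ratios
  ss1 <- stratifyByScore(cohort, rep(0L, n))
  expect_true(all(is.na(ss1@summary$hr)))
  expect_length(ss1@cox, 0L)
  expect_error(stratifyByScore(cohort, rep(0L, n), requireCox = TRUE),
               "strata")
})

test_that("fitted hazard ratios increase with the planted per-point effect", {
  set.seed(64)
  hits <- 0L
  for (rep in 1:20) {
    n <- 600
    scores <- sample(0:3, n, replace = TRUE)
    osT <- rexp(n, 0.01 * exp(0.5 * scores))
    cohort <- data.frame(os_months = osT, os_event = 1L,
                         rfs_months = osT, rfs_event = 1L)
    s <- stratifyByScore(cohort, scores)@summary
    hr <- s$hr[s$endpoint == "os"][order(s$score[s$endpoint == "os"])]
    if (all(diff(hr) > 0)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("median survival is non-increasing in score under a positive effect", {
  set.seed(65)
  n <- 1200
  scores <- rep(0:3, each = n / 4)
  osT <- rexp(n, 0.015 * exp(0.5 * scores))
  cohort <- data.frame(os_months = osT, os_event = 1L,
                       rfs_months = osT, rfs_event = 1L)
  s <- stratifyByScore(cohort, scores)@summary
  med <- s$median[s$endpoint == "os"][order(s$score[s$endpoint == "os"])]
  expect_true(all(diff(med) <= 0))
})

test_that("group comparisons tabulate counts, percentages and tests", {
  # recurrence yes/no by dosage group, patient-level reconstruction
  cohort <- data.frame(
    recurred = rep(c("Y", "N", "Y", "N"), c(50, 5, 105, 33)),
    grp = rep(c("high", "low"), c(55, 138)))
  schema <- data.frame(variable = "recurred", type = "categorical")
  tab <- summarizeGroups(cohort, cohort$grp, schema)
  yes <- tab[tab$level == "Y", ]
  expect_equal(round(yes$pct_high, 1), 90.9)
  expect_equal(round(yes$pct_low, 1), 76.1)
  expect_lt(yes$p, 0.05)

  # timing among recurrers only (conditioned variable)
  timing <- data.frame(
    timing = c(rep(c("very_early", "early", "late"), c(25, 14, 11)),
               rep(c("very_early", "early", "late"), c(28, 30, 47))),
    rec = TRUE,
    grp = rep(c("high", "low"), c(50, 105)))
  schema2 <- data.frame(variable = "timing", type = "categorical",
                        condition = "rec")
  tab2 <- summarizeGroups(timing, timing$grp, schema2)
  expect_equal(round(tab2$pct_high[tab2$level == "very_early"], 1), 50.0)
  expect_equal(round(tab2$pct_low[tab2$level == "late"], 1), 44.8)

  # continuous variable: Welch comparison of means
  cont <- data.frame(age = c(rnorm(30, 64), rnorm(30, 66)),
                     grp = rep(c("high", "low"), each = 30))
  tab3 <- summarizeGroups(cont, cont$grp,
                          data.frame(variable = "age", type = "continuous"))
  expect_true(is.finite(tab3$p))
  expect_equal(tab3$mean_high, mean(cont$age[1:30]))

  expect_error(summarizeGroups(cohort, factor(cohort$grp,
                                              levels = c("high", "low",
                                                         "empty")),
                               schema), "at least one member")
  expect_error(summarizeGroups(cohort, cohort$grp,
                               data.frame(variable = "recurred",
                                          type = "fancy")), "unknown")
})
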