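test_that("candidate construction respects group sizes and degenerate input", {
  set.seed(41)
  d <- runif(40); tt <- rexp(40, 0.1); ev <- rep(1L, 40)
  scan <- scanCutpoints(d, tt, ev, minGroupSize = 10L)
  for (cc in scan@cutoffs) {
    expect_gte(sum(d > cc), 10L)
    expect_gte(sum(d <= cc), 10L)
  }
  expect_true(all(scan@selected %in% scan@cutoffs))

  # n = 2 * minGroupSize - 1 is too small
  expect_error(scanCutpoints(runif(19), rexp(19), rep(1, 19),
                             minGroupSize = 10L), "at least")
  expect_error(scanCutpoints(rep(0.3, 40), tt, ev), "identical")
})

test_that("the selected partition is invariant to monotone marker transforms", {
  set.seed(42)
  d <- runif(60); tt <- rexp(60, 0.05 * ifelse(d > 0.5, 3, 1))
  ev <- rep(1L, 60)
  s1 <- scanCutpoints(d, tt, ev)
  s2 <- scanCutpoints(exp(3 * d) + 7, tt, ev)   # strictly increasing map
  expect_equal(s1@chisq, s2@chisq)
  expect_identical(dichotomize(d, selectGlobal(s1)),
                   dichotomize(exp(3 * d) + 7, selectGlobal(s2)))
})

test_that("scan statistics are self-consistent with the log-rank test", {
  set.seed(43)
  d <- runif(80); tt <- rexp(80, 0.08); ev <- rbinom(80, 1, 0.8)
  scan <- scanCutpoints(d, tt, ev)
  sel <- selectGlobal(scan)
  recomputed <- logrankTest(tt, ev, dichotomize(d, sel))
  expect_equal(scan@chisq[match(sel, scan@cutoffs)], recomputed$chisq,
               tolerance = 1e-10)
})

test_that("global selection breaks ties toward the smaller cutoff", {
  mk <- function(chisq) new("CutpointScan",
                            cutoffs = seq_along(chisq) / 10, chisq = chisq,
                            p = pchisq(chisq, 1, lower.tail = FALSE),
                            selected = numeric(0), mode = "global",
                            minGroupSize = 1L, permP = NA_real_)
  expect_equal(selectGlobal(mk(5)), 0.1)                  # single candidate
  expect_equal(selectGlobal(mk(c(1, 4, 9, 4, 1))), 0.3)   # unimodal argmax
  expect_equal(selectGlobal(mk(c(2, 7, 1, 7, 2))), 0.2)   # tie -> smaller
})

test_that("local-maxima selection merges plateaus and handles monotone runs", {
  mk <- function(chisq) new("CutpointScan",
                            cutoffs = seq_along(chisq) / 10, chisq = chisq,
                            p = pchisq(chisq, 1, lower.tail = FALSE),
                            selected = numeric(0), mode = "local_maxima",
                            minGroupSize = 1L, permP = NA_real_)
  # interior peaks at the 5 and the 7
  expect_equal(selectLocalMaxima(mk(c(1, 5, 2, 7, 3))), c(0.2, 0.4))
  # monotone profile: only the boundary maximum exists
  expect_equal(selectLocalMaxima(mk(c(1, 2, 3, 4))), 0.4)
  # plateau is one maximum, represented by its smallest cutoff
  expect_equal(selectLocalMaxima(mk(c(1, 6, 6, 2, 8, 3))), c(0.2, 0.5))
  # k limits how many maxima come back, largest statistics win
  expect_equal(selectLocalMaxima(mk(c(1, 5, 2, 7, 3, 4, 1)), k = 1L), 0.4)
})

test_that("dichotomization keeps the threshold in the low group", {
  expect_identical(dichotomize(c(0.195, 0.196), 0.195), c("low", "high"))
  expect_identical(dichotomize(numeric(0), 0.5), character(0))
  expect_warning(out <- dichotomize(c(0.1, NA), 0.195), "undefined")
  expect_identical(out, c("low", NA))
})

test_that("permutation calibration exposes the selection effect", {
  # under the null the naive p of the maximal statistic is anti-conservative;
  # the permutation p upper-bounds it
  set.seed(44)
  n <- 30
  d <- runif(n); tt <- rexp(n, 0.1); ev <- rep(1L, n)
  scan <- scanCutpoints(d, tt, ev, minGroupSize = 5L, nPerm = 2000L)
  naiveMinP <- min(scan@p)
  expect_gte(scan@permP, naiveMinP)
})
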