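#' Thresholds of the three-factor preoperative prognostic score
#'
#' One point each for maximal tumor diameter strictly greater than 20 mm
#' at baseline CT, preoperative CA 19-9 strictly greater than 150 U/mL,
#' and a hotspot mutation dosage strictly greater than the dosage
#' threshold (0.195 by default; 0.139 is the published alternative for
#' targeted sequencing).
#'
#' @param size_mm tumor-diameter threshold in mm.
#' @param ca19_9 CA 19-9 threshold in U/mL.
#' @param dosage dosage threshold.
#' @param dosage_source which dosage column feeds the score.
#' @return a list of class \code{ScoreThresholds}.
#' @export
scoreThresholds <- function(size_mm = 20, ca19_9 = 150, dosage = 0.195,
                            dosage_source = c("dosage_ts",
                                              "adjusted_dosage_ts",
                                              "dosage_wes", "dosage_rna",
                                              "effective_dosage_ts")) {
  dosage_source <- match.arg(dosage_source)
  if (any(c(size_mm, ca19_9, dosage) <= 0))
    stop("all thresholds must be positive")
  structure(list(size_mm = size_mm, ca19_9 = ca19_9, dosage = dosage,
                 dosage_source = dosage_source),
            class = "ScoreThresholds")
}

#' Assign the 0-3 preoperative prognostic score
#'
#' Strict ">" comparisons: a value exactly at a threshold does not score.
#'
#' @param tumorDiameterMm maximal tumor diameter at baseline CT (mm).
#' @param ca199 preoperative CA 19-9 (U/mL).
#' @param dosage hotspot mutation dosage; must be defined (patients with
#'   undefined dosage are excluded from scoring upstream).
#' @param thresholds a [scoreThresholds()].
#' @return data.frame with size_point, ca199_point, dosage_point and
#'   total (0-3). Vectorized over patients.
#' @examples
#' assignScore(25, 200, 0.30)           # 3 points
#' assignScore(20, 150, 0.195)          # boundaries do not score
#' @export
assignScore <- function(tumorDiameterMm, ca199, dosage,
                        thresholds = scoreThresholds()) {
  if (anyNA(dosage))
    stop("undefined dosage: exclude these patients or impute before scoring")
  if (any(tumorDiameterMm < 0) || any(ca199 < 0) ||
      any(dosage < 0 | dosage > 1))
    stop("inputs out of range")
  sp <- as.integer(tumorDiameterMm > thresholds$size_mm)
  cp <- as.integer(ca199 > thresholds$ca19_9)
  dp <- as.integer(dosage > thresholds$dosage)
  data.frame(size_point = sp, ca199_point = cp, dosage_point = dp,
             total = sp + cp + dp)
}

#' Stratify survival by prognostic score
#'
#' Fits per-stratum Kaplan-Meier curves for OS and RFS, extracts the
#' median and the 12/36/60-month survival rates, and fits one
#' factor-coded Cox model per endpoint with the 0-point stratum as the
#' reference (HR fixed at 1.00). Empty strata are absent from the
#' output, not reported as zero. With fewer than two occupied strata the
#' Cox step is skipped (KM summaries are still produced) unless
#' \code{requireCox}.
#'
#' @param cohort data.frame with os_months, os_event, rfs_months,
#'   rfs_event.
#' @param scores integer scores (0-3), one per cohort row.
#' @param requireCox error (rather than skip) when the Cox model cannot
#'   be fitted.
#' @return a [ScoreSummary-class].
#' @export
stratifyByScore <- function(cohort, scores, requireCox = FALSE) {
  need <- c("os_months", "os_event", "rfs_months", "rfs_event")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  if (length(scores) != nrow(cohort))
    stop("scores and cohort lengths differ")
  if (anyNA(scores) || anyNA(cohort[need]))
    stop("every patient needs a score and complete OS/RFS follow-up")

  levelsPresent <- sort(unique(scores))
  n <- nrow(cohort)
  endpoints <- list(os = c("os_months", "os_event"),
                    rfs = c("rfs_months", "rfs_event"))

  coxes <- list()
  if (length(levelsPresent) >= 2L) {
    f <- factor(scores, levels = levelsPresent)
    dm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(dm) <- paste0("score", levelsPresent[-1L])
    for (ep in names(endpoints)) {
      coxes[[ep]] <- coxFit(dm, cohort[[endpoints[[ep]][1]]],
                            cohort[[endpoints[[ep]][2]]])
    }
  } else if (requireCox) {
    stop("fewer than two occupied score strata: Cox model undefined")
  }

  kms <- list(os = list(), rfs = list())
  rows <- list()
  for (ep in names(endpoints)) {
    tcol <- endpoints[[ep]][1]; ecol <- endpoints[[ep]][2]
    cox <- coxes[[ep]]
    for (s in levelsPresent) {
      idx <- scores == s
      curve <- kmFit(cohort[[tcol]][idx], cohort[[ecol]][idx])
      kms[[ep]][[as.character(s)]] <- curve
      if (!is.null(cox) && s != levelsPresent[1L]) {
        cf <- cox@coefficients
        row <- cf[cf$term == paste0("score", s), ]
        hr <- row$hr; lo <- row$ciLow; hi <- row$ciHigh; pv <- row$p
      } else if (!is.null(cox)) {
        hr <- 1; lo <- NA_real_; hi <- NA_real_; pv <- NA_real_
      } else {
        hr <- NA_real_; lo <- NA_real_; hi <- NA_real_; pv <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = ep, score = s, n = sum(idx), share = sum(idx) / n,
        median = kmMedian(curve),
        rate12 = kmRateAt(curve, 12), rate36 = kmRateAt(curve, 36),
        rate60 = kmRateAt(curve, 60),
        hr = hr, ciLow = lo, ciHigh = hi, p = pv,
        stringsAsFactors = FALSE)
    }
  }
  new("ScoreSummary", summary = do.call(rbind, rows), km = kms, cox = coxes)
}

setMethod("show", "ScoreSummary", function(object) {
  s <- object@summary
  cat("ScoreSummary over", length(unique(s$score)), "score strata\n")
  for (ep in unique(s$endpoint)) {
    cat(" ", toupper(ep), "\n")
    sub <- s[s$endpoint == ep, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf(
        "   %d pts (%.1f%%): n=%d median %s mo, 1/3/5-yr %.1f/%.1f/%.1f%%, HR %s\n",
        sub$score[i], 100 * sub$share[i], sub$n[i],
        ifelse(is.na(sub$median[i]), "NA", format(sub$median[i])),
        100 * sub$rate12[i], 100 * sub$rate36[i], 100 * sub$rate60[i],
        ifelse(is.na(sub$hr[i]), "NA",
               sprintf("%.2f", sub$hr[i]))))
  }
})

#' Compare clinical variables between groups
#'
#' Table-1/2-style group comparison: categorical variables get counts,
#' within-group percentages and a Pearson chi-square p; continuous
#' variables get mean (SD) per group and a Welch t-test p. A variable
#' may be conditioned on a logical column (e.g. recurrence-timing
#' variables are tabulated only among patients who recurred).
#'
#' @param cohort data.frame of patients.
#' @param groups group label per row; every group must be non-empty.
#' @param schema data.frame with columns \code{variable}, \code{type}
#'   ("categorical" or "continuous") and optionally \code{condition}
#'   (name of a logical/0-1 column restricting the rows used).
#' @return long data.frame: variable, level, one count and one percent
#'   column per group, statistic and p.
#' @export
summarizeGroups <- function(cohort, groups, schema) {
  if (length(groups) != nrow(cohort))
    stop("groups and cohort lengths differ")
  groups <- as.factor(groups)
  if (any(tabulate(groups, nlevels(groups)) == 0L))
    stop("every group must have at least one member")
  if (!all(c("variable", "type") %in% names(schema)))
    stop("schema needs 'variable' and 'type' columns")

  gl <- levels(groups)
  out <- list()
  for (i in seq_len(nrow(schema))) {
    v <- schema$variable[i]
    type <- schema$type[i]
    if (!v %in% names(cohort)) stop("unknown variable: ", v)
    keep <- rep(TRUE, nrow(cohort))
    if ("condition" %in% names(schema) && !is.na(schema$condition[i]) &&
        nzchar(schema$condition[i])) {
      cond <- cohort[[schema$condition[i]]]
      keep <- !is.na(cond) & as.logical(cond)
    }
    x <- cohort[[v]][keep]
    g <- droplevels(groups[keep])

    if (type == "categorical") {
      tab <- table(factor(x), g)
      test <- chiSquareTest(as.matrix(tab))
      for (lev in rownames(tab)) {
        row <- data.frame(variable = v, level = lev,
                          stringsAsFactors = FALSE)
        for (grp in gl) {
          cnt <- if (grp %in% colnames(tab)) tab[lev, grp] else NA_integer_
          tot <- if (grp %in% colnames(tab)) sum(tab[, grp]) else NA_integer_
          row[[paste0("n_", grp)]] <- cnt
          row[[paste0("pct_", grp)]] <- 100 * cnt / tot
        }
        row$statistic <- test$chisq
        row$p <- test$p
        out[[length(out) + 1L]] <- row
      }
    } else if (type == "continuous") {
      if (nlevels(g) != 2L)
        stop("continuous comparison requires exactly two groups")
      xs <- split(x, g)
      test <- compareContinuous(xs[[1L]], xs[[2L]], method = "t")
      row <- data.frame(variable = v, level = "mean_sd",
                        stringsAsFactors = FALSE)
      for (grp in gl) {
        row[[paste0("n_", grp)]] <- length(xs[[grp]])
        row[[paste0("pct_", grp)]] <- NA_real_
        row[[paste0("mean_", grp)]] <- mean(xs[[grp]])
        row[[paste0("sd_", grp)]] <- stats::sd(xs[[grp]])
      }
      row$statistic <- test$statistic
      row$p <- test$p
      out[[length(out) + 1L]] <- row
    } else {
      stop("unknown variable type in schema: ", type)
    }
  }
  merged <- Reduce(function(a, b) {
    for (cn in setdiff(names(b), names(a))) a[[cn]] <- NA
    for (cn in setdiff(names(a), names(b))) b[[cn]] <- NA
    rbind(a, b[names(a)])
  }, out)
  rownames(merged) <- NULL
  merged
}
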