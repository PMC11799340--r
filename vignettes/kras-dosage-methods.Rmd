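---
title: "Quantifying KRAS hotspot mutation dosage and building the preoperative prognostic score"
author: "krasdosage maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying KRAS hotspot mutation dosage and building the preoperative prognostic score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krasdosage)
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) is driven almost universally by
hotspot mutations in codon 12 of *KRAS*. Beyond the binary presence of a
G12 mutation, its **dosage** — the fraction of sequencing reads carrying
the mutant allele at the hotspot codon — carries prognostic information:
it rises with tumor purity and mutant copy number, and higher dosage
tracks earlier recurrence and shorter survival after pancreatectomy.
`krasdosage` implements the full analysis chain around that idea:

1. quantify the G12 (and Q61) dosage per patient and sequencing
   modality — RNA-seq, whole-exome sequencing (WES), and ultra-deep
   targeted amplicon sequencing (TS) — from allele-count tables, aligned
   reads, or VCF allelic depths;
2. pick survival-optimal dosage thresholds by scanning the two-group
   log-rank statistic over candidate cutoffs (the maximally selected
   log-rank statistic);
3. combine the dichotomized dosage with two preoperative clinical
   factors (tumor diameter > 20 mm, CA 19-9 > 150 U/mL) into a 0–3
   integer score and summarize survival and recurrence per stratum.

Because the cohorts such analyses run on are controlled-access, the
package carries a synthetic-cohort generator with the statistical
structure the pipeline assumes, and the whole chain is exercised and
tested against it.

## The dosage model

For a specimen with tumor-cell fraction (purity) $p$ whose tumor cells
carry $c$ total copies of the locus, $m$ of them mutant, with admixed
normal cells contributing two wild-type copies, the expected mutant read
fraction is

$$v = \frac{p\,m}{p\,c + 2(1-p)}.$$

At copy-neutral heterozygosity ($c=2$, $m=1$) this is $p/2$, so dosage
is a linear readout of purity; PDAC's typically low purity (median
around 0.265 in resected series) is why ultra-deep targeted sequencing,
not exome coverage, is the assay of record for dosage. `expectedVaf()`
implements the formula; `adjustForCnv()` inverts the copy-number part by
renormalizing an observed dosage to the two-copy scale
($d \cdot 2/c$, clamped to $[0,1]$). The exact renormalization used in
published analyses is rarely printed; the copy-neutral rule here is the
package's own choice and is deliberately the simplest one consistent
with the model above.

On the RNA side the dosage is a read fraction over *expressed* copies.
Mutant-allele expression bias $b$ inflates it to

$$v_{\mathrm{RNA}} = \frac{p\,m\,b}{p\,(m b + (c-m)) + 2(1-p)},$$

which reduces to the DNA VAF at $b = 1$ and exceeds it for $b > 1$. The
generator defaults to $b = 1.5$ so that cohort-median RNA dosage runs
above the DNA VAF, reproducing the direction consistently seen in
matched data. This is a modeling device: no mechanistic claim about
allele-specific expression is intended, and the tests only assert the
direction, never the magnitude.

## Counting reads at a codon

`countAllelesAtCodon()` classifies each read overlapping the hotspot
codon exactly once:

* reads under the mapping-quality floor (default 20) are excluded from
  the total entirely;
* a read must span **all three** codon positions with called bases; the
  codon's bases are taken in genomic orientation and compared against
  the reference codon (`krasLocus()` ships G12 and Q61 presets in hg19
  and hg38 coordinates; KRAS is on the minus strand, so the coding codon
  is the reverse complement);
* the reference codon counts as wild-type; any codon encoding a
  different amino acid counts as mutant — all G12 substitutions
  (G12D/V/R/C/A/S, …) are pooled, since the dosage is defined per codon,
  not per allele;
* everything else is "other": partial spans (avoids phasing ambiguity),
  indel-spanning reads, N bases, synonymous changes, and reads failing
  the base-quality floor (default 20) at any codon base. The
  base-quality rule — classify as other rather than drop — keeps the
  denominator an honest count of reads covering the codon; only mapping
  quality removes a read from the total.

`vafFromVcf()` is the analogous entry point for callers that emit VCFs:
it prefers the allelic-depth ratio $AD_{alt}/\sum AD$, falls back to the
AF genotype field, ignores non-PASS records, and **sums** the VAFs of
distinct alternate alleles that change the codon (a multi-allelic G12
record contributes one per-codon dosage). Indels and alleles that leave
the amino acid unchanged do not contribute.

## The synthetic cohort

`generateCohort()` draws, per patient: purity from a Beta(2, 11)
rescaled to $[0.15, 1]$ (median $\approx 0.265$ — the one printed purity
summary for this disease, and the only anchor we calibrate to);
amplification of the locus with probability 0.026 (amplified tumors get
4 total copies with the mutant allele on all but one, reflecting
oncogenic selection — allele-specific data being unavailable, this is a
design choice); a subclonal Q61 co-mutation with probability 0.073,
always on top of a clonal G12 mutation, with cell fraction drawn
Beta(2, 2) (unspecified by any source; chosen once so that occasional
high-VAF Q61 subclones occur). Read counts then come from
`simulatePileup()`: a multinomial over mutant/wild-type/other with a
uniform miscall channel at error rate $10^{-3}$ per read, at depth
1,000,000 for TS, 300 for WES, and log-uniform 20–2000 for RNA.

Clinical covariates are drawn to match the marginal frequencies of a
resected-PDAC cohort (56.5% male, 77.7% tumors > 20 mm via a log-normal
diameter with meanlog $\log 28$ and sdlog 0.45, 47.2% CA 19-9 > 150 via
meanlog $\log 140$, sdlog 1.5, and so on). Survival uses exponential
baseline hazards — $\log 2 / 97$ per month for OS and $\log 2 / 58$ for
RFS, putting the zero-risk-factor medians at the values reported for
0-point patients — multiplied by $\exp(\sum \text{log-HR})$ over the
three active risk flags (truth-level dosage > 0.195, diameter > 20 mm,
CA 19-9 > 150 U/mL; default log-HRs $\log 2$, $\log 1.7$, $\log 1.7$).
Censoring is an independent exponential (rate 0.008/month, a median
follow-up of roughly seven years). RFS is the time to the earlier of
recurrence and death, so RFS $\le$ OS holds by construction, and a
local/distant pattern is drawn only when recurrence is observed.

All randomness flows from the single config seed through per-patient
L'Ecuyer-CMRG substreams, so cohorts replay exactly and per-patient
draws are independent.

What the generator does **not** emulate: alignment artifacts, UMI or
duplicate structure, panel-specific error motifs, caller behavior,
informative censoring, or covariate correlations beyond those induced by
the risk flags. Passing tests therefore demonstrate that the estimators
recover the generative model's structure — not that any clinical claim
transfers to real data.

## Cutpoint selection

`scanCutpoints()` forms candidate cutoffs as midpoints between
consecutive distinct observed dosages, keeps those leaving at least
`minGroupSize` patients on each side (default 10, about 5% of a
~200-patient cohort; the constraint any given study used is typically
unstated), and computes the two-group log-rank chi-square at each.
Candidates being rank-based, any strictly increasing transform of the
marker leaves the selected partition unchanged.

Two selectors are offered. `selectGlobal()` takes the argmax (ties
toward the smaller cutoff). `selectLocalMaxima()` finds interior local
maxima of the statistic profile after merging plateaus (a plateau is one
maximum, represented by its smallest cutoff) and returns the top-k
(default 2) in ascending order — the mode intended for markers with a
bimodal distribution, where two clinically distinct thresholds can
coexist; published TS analyses of this kind report two such cutoffs,
0.139 and 0.195. Whether "two local maxima" should be read on the
log-rank profile or on the dosage density is ambiguous in such reports;
this package implements the log-rank-profile reading, and the density
reading can be emulated by scanning within density modes.

Per-cutoff p-values are naive $\chi^2_1$ tail areas, matching how
such log-rank p-values are conventionally reported. They ignore the
selection over cutoffs — the maximum of many correlated chi-squares is
not chi-square — so `nPerm > 0` adds a permutation-calibrated p-value
for the maximum statistic. The naive values are reported by default
because they are what published cutoff p-values correspond to; the
anti-conservatism is demonstrated, not hidden, in the test suite.

`dichotomize()` puts values strictly above the cutoff in the high group:
the threshold itself is low, consistent with defining the low-dosage
group as "dosage < threshold" and scoring a point only for dosage
strictly above it.

## Survival machinery

The survival layer is implemented from first principles (it is half the
point of the package) and cross-checked against independent oracles in
the tests, never delegated to them:

* **Kaplan–Meier** (`kmFit()`): product-limit estimator; at tied times
  censorings are processed after events. `kmMedian()` is the smallest
  time with $S(t) \le 0.5$ (NA when never reached, rendered "NA" in
  reports); `kmRateAt()` is the right-continuous step lookup, with the
  1/3/5-year rates read at exactly 12, 36 and 60 months.
* **Log-rank** (`logrankTest()`): observed-minus-expected with
  hypergeometric variance, any number of groups, df = k−1. The
  two-group kernel used by the cutpoint scan is the same statistic,
  vectorized.
* **Cox proportional hazards** (`coxFit()`): Newton–Raphson with step
  halving on the **Efron** partial likelihood (ties are unavoidable at
  month resolution, and Efron is the accurate default; times are
  accepted as floats). Convergence at max |score| < 1e-8 or relative
  log-likelihood change < 1e-10 within 50 iterations; monotone
  likelihoods (perfect separation) are flagged `converged = FALSE` with
  a warning rather than silently returning a huge coefficient. Wald 95%
  CIs are $\exp(\hat\beta \pm 1.96\,\mathrm{se})$; the score test at the
  null is exposed, and on tie-free data with one binary covariate it
  equals the log-rank chi-square to numerical precision — an identity
  the tests verify at 1e-8.
* **Categorical/continuous comparisons**: Pearson chi-square without
  continuity correction (published tables of this kind rarely
  disambiguate the variant; the uncorrected statistic is the one the
  scaling and hand-formula identities hold for), Welch t by default for
  continuous variables, Wilcoxon rank-sum with normal approximation and
  tie correction as the alternative. No multiplicity correction is
  applied anywhere, matching the raw-p-value reporting convention of
  clinical tables.
* **Recurrence timing** (`classifyRecurrenceTiming()`): very early
  (< 6 months), early (6 to < 12), late (≥ 12), none.

## Scoring and reporting

`assignScore()` applies the three strict thresholds and sums the points.
Patients with undefined dosage (no reads at the codon) cannot be scored;
`buildReport()` excludes them with a logged warning rather than imputing
— real cohorts may lack the targeted assay for some patients, and
imputation policy is a study-level decision the package refuses to make
silently.

`stratifyByScore()` fits per-stratum KM curves for both endpoints and
one factor-coded Cox model per endpoint with the 0-point stratum as
reference (HR exactly 1.00); a pairwise-model reading of published
score-vs-reference HRs is possible, but the single factor-coded model is
the default here, and empty strata are reported as absent rather than
zero. Percentages are rendered to one decimal in text output and stored
at full precision in JSON.

`runPipeline()` chains simulate → dosage → cutpoint → score → report,
logging per-stage row counts to stderr and writing the artifact bundle
(report.json with thresholds, seed and package version; KM tables;
Table-1/2-style comparisons; the scan profile). With a fixed seed the
bundle regenerates byte-identically.

## Numerical and design notes

* The Q61 "subclone" call in `buildDosageProfiles()` uses a noise floor
  (default Q61 dosage > 0.01): at depth $10^6$ and error $10^{-3}$ the
  error channel alone yields a mutant fraction around $3\times10^{-4}$
  at every codon, so an exact-zero rule would label every patient
  subclonal. The floor sits an order of magnitude above the error
  channel and two below real subclone dosages. `classifyClonality()`
  itself applies the literal "> 0" rule to whatever dosages it is given.
* The detection-sensitivity property ("deeper sequencing detects
  low-purity mutations more often") is asserted with a ≥ 20-mutant-read
  rule, a caller-like floor at which 300× exome coverage genuinely
  misses low-purity mutations while $10^6\times$ targeted depth does
  not. Only the ordering is asserted; printed per-modality detection
  rates arise from caller behavior outside this model.
* Problem sizes in the test suite (a shared 2,000-patient cohort for
  distribution-level properties, 100 seeds × n = 1000 for Cox recovery,
  50 replicates × n = 200 for change-point recovery, 1,000 simulations
  × n = 100 for null calibration, 5,000 permutations for the log-rank
  reference) were chosen so each check has comfortable statistical
  margin while the whole suite stays in the low minutes.
* Degenerate inputs fail loudly: all-identical dosages, cohorts smaller
  than twice the group floor, constant covariates, zero-margin tables,
  zero-variance t-tests, negative times.

## Limitations

The Cox layer has no time-varying covariates, stratification, frailty,
or competing-risks handling, and no proportional-hazards diagnostics;
the cutpoint scan implements no closed-form selection-bias correction
beyond the permutation option; the simulator's clinical covariates are
mutually independent given the risk flags, which understates real
confounding. CNV states and purities are *inputs* to the pipeline — the
package estimates neither.
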