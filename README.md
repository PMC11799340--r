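# krasdosage

Quantification of the *KRAS* hotspot (G12/Q61) **mutation dosage** — the
mutant read fraction at the hotspot codon — and the downstream survival
analysis that turns it into a preoperative prognostic score for resected
pancreatic ductal adenocarcinoma (PDAC).

For a tumor specimen with purity *p*, *c* total locus copies per tumor
cell and *m* mutant copies, the expected dosage is

    v = p·m / (p·c + 2·(1 − p))

(so *v = p/2* for a copy-neutral heterozygous mutation — dosage is a
linear readout of tumor purity). The package:

* computes dosage per patient and modality (RNA-seq, WES, ultra-deep
  targeted sequencing) from allele-count tables, indexed BAMs
  (`countAllelesAtCodon()`, with shipped hg19/hg38 presets for the G12
  and Q61 codons) or VCF allelic depths (`vafFromVcf()`), with
  copy-number renormalization (`adjustForCnv()`) and clonality
  classification (`classifyClonality()`);
* selects survival-optimal dosage thresholds by **maximally selected
  log-rank** scanning (`scanCutpoints()`), with a global-argmax mode and
  a local-maxima mode for bimodal markers;
* implements Kaplan–Meier, the k-group log-rank test and Cox
  proportional hazards (Efron ties, Newton–Raphson) from first
  principles (`kmFit()`, `logrankTest()`, `coxFit()`);
* assigns the 0–3 prognostic score — one point each for dosage > 0.195,
  tumor diameter > 20 mm, CA 19-9 > 150 U/mL, all strict — and produces
  score-stratified KM/Cox summaries and Table-1/2-style group
  comparisons (`assignScore()`, `stratifyByScore()`,
  `summarizeGroups()`, `buildReport()`);
* ships a synthetic-cohort generator (`generateCohort()`) that emulates
  the cohort structure the analysis assumes — low median purity
  (~0.265), rare *KRAS* amplification (2.6%), rare subclonal Q61
  co-mutation (7.3%), modality-specific depths, RNA dosage above the
  DNA VAF, proportional-hazards outcomes — so the entire pipeline is
  testable without controlled-access patient data.

See `vignettes/kras-dosage-methods.Rmd` for the model, the generator's
assumptions and the design decisions.

## Worked example

```r
library(krasdosage)

cfg      <- simulationConfig(n_patients = 193, seed = 7)
cohort   <- generateCohort(cfg)                  # clinical + counts + truth
profiles <- buildDosageProfiles(cohort$counts)   # one row per patient

scan <- scanCutpoints(profiles$dosage_ts, cohort$clinical$os_months,
                      cohort$clinical$os_event, minGroupSize = 10)
scan
#> CutpointScan: 174 candidates (min group 10), mode global
#>   max log-rank chi-square 5.178 at cutoff 0.12 (naive p=0.0229)
#>   selected: 0.12

scores <- assignScore(cohort$clinical$tumor_diameter_mm,
                      cohort$clinical$ca19_9_u_ml, profiles$dosage_ts)
stratifyByScore(cohort$clinical, scores$total)
#> ScoreSummary over 4 score strata
#>   OS
#>    0 pts (10.4%): n=20 median 59.56348 mo, 1/3/5-yr 89.7/73.5/45.4%, HR 1.00
#>    1 pts (47.2%): n=91 median 64.87527 mo, 1/3/5-yr 85.8/58.5/52.8%, HR 1.17
#>    2 pts (38.3%): n=74 median 36.20066 mo, 1/3/5-yr 80.3/50.4/33.7%, HR 1.89
#>    3 pts (4.1%): n=8 median 5.651683 mo, 1/3/5-yr 25.0/0.0/0.0%, HR 11.92
#>   RFS
#>    0 pts (10.4%): n=20 median 57.63652 mo, 1/3/5-yr 89.7/62.5/37.0%, HR 1.00
#>    1 pts (47.2%): n=91 median 24.38849 mo, 1/3/5-yr 65.6/30.4/19.3%, HR 2.21
#>    2 pts (38.3%): n=74 median 10.92777 mo, 1/3/5-yr 45.1/6.8/0.0%, HR 5.07
#>    3 pts (4.1%): n=8 median 4.846602 mo, 1/3/5-yr 25.0/0.0/0.0%, HR 10.95
```

The scan's cutoff is the dosage maximizing the survival separation
between high and low groups on this cohort; the score summary shows
survival worsening and hazard ratios rising with the score, with the
0-point stratum as the HR reference. The end-to-end run — including the
artifact bundle (report.json, KM tables, comparison tables) — is
`runPipeline()`, or from a shell:

```sh
Rscript inst/scripts/run_pipeline.R --out report/ --simulate --n 193 --seed 7
```

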