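Package: krasdosage
Title: KRAS G12 Mutation Dosage Quantification and Preoperative Prognostic
    Scoring for Pancreatic Cancer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the KRAS hotspot (G12/Q61) mutation dosage -- the
    mutant read fraction at the hotspot codon -- from allele-count tables,
    aligned reads, or VCF allelic depths across sequencing modalities
    (RNA-seq, whole-exome, ultra-deep targeted amplicon sequencing), with
    copy-number adjustment and clonality classification. Selects
    survival-optimal dosage cutoffs by maximally selected log-rank
    scanning, and builds a three-factor preoperative prognostic score
    (dosage, tumor diameter, CA 19-9) with stratified Kaplan-Meier and Cox
    proportional-hazards summaries. Includes a synthetic-cohort simulator
    (latent tumor purity and copy state, read-level pileups, clinical
    covariates, proportional-hazards survival and recurrence outcomes) so
    the full pipeline is testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    jsonlite,
    yaml,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    Rsamtools,
    GenomicAlignments,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
biocViews: Software, Sequencing, SomaticMutation, Survival, CopyNumberVariation
RoxygenNote: 7.3.3
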