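#' Count hotspot-codon alleles from aligned reads
#'
#' Walks the reads overlapping the hotspot codon in an indexed BAM and
#' classifies each read once: a read must span all three codon positions
#' with every base called (no N, no deletion) and every base quality at
#' or above \code{minBaseq} to be classified; the reference codon counts
#' as wild-type, any non-synonymous substitution codon counts as mutant
#' (all amino-acid changes at the codon are pooled), and everything else
#' (partial span, indel over the codon, N, synonymous change, base
#' quality failure) counts as other. Reads with mapping quality below
#' \code{minMapq} are excluded from the total entirely.
#'
#' @param bamFile path to a coordinate-sorted, indexed BAM.
#' @param locus a [TargetLocus-class] (see [krasLocus()]).
#' @param minMapq,minBaseq quality thresholds (>= 0).
#' @param modality label attached to the result.
#' @return an [AlleleCounts-class]; total 0 when no read passes.
#' @importFrom Rsamtools BamFile ScanBamParam scanBamHeader
#' @importFrom GenomicAlignments stackStringsFromBam
#' @export
countAllelesAtCodon <- function(bamFile, locus, minMapq = 20L,
                                minBaseq = 20L, modality = "TS") {
  stopifnot(is(locus, "TargetLocus"), minMapq >= 0L, minBaseq >= 0L)
  bf <- Rsamtools::BamFile(bamFile)
  contigs <- names(Rsamtools::scanBamHeader(bf)$targets)
  if (!locus@chrom %in% contigs)
    stop("locus contig ", locus@chrom, " absent from BAM header")

  region <- lociAsGRanges(locus)
  param <- Rsamtools::ScanBamParam(which = region, mapqFilter = minMapq)
  seqs <- GenomicAlignments::stackStringsFromBam(
    bf, param = param, what = "seq",
    Lpadding.letter = "+", Rpadding.letter = "+")
  quals <- GenomicAlignments::stackStringsFromBam(
    bf, param = param, what = "qual",
    Lpadding.letter = " ", Rpadding.letter = " ")

  mutant <- 0L; wildtype <- 0L; other <- 0L
  codonChars <- as.character(seqs)
  qualChars <- as.character(quals)
  for (i in seq_along(codonChars)) {
    codon <- toupper(codonChars[i])
    q <- utf8ToInt(qualChars[i]) - 33L       # Phred+33
    if (grepl("[^ACGT]", codon) || any(q < minBaseq)) {
      other <- other + 1L
      next
    }
    cls <- classifyCodon(codon, locus)
    if (cls == "mutant") mutant <- mutant + 1L
    else if (cls == "wildtype") wildtype <- wildtype + 1L
    else other <- other + 1L
  }
  refAA <- .codonAminoAcid(locus@refCodon, locus@geneStrand)
  AlleleCounts(mutant, wildtype, other, modality = modality,
               codon = if (identical(refAA, "Q")) "Q61" else "G12")
}

#' Variant allele frequency of hotspot-codon changes from a VCF
#'
#' Reads a VCF and returns the summed tumor variant allele frequency of
#' all alternate alleles that produce a non-synonymous change at the
#' hotspot codon. Per-allele VAFs prefer the allelic-depth ratio
#' AD_alt / sum(AD) and fall back to the AF field; filtered (non-PASS)
#' records are ignored. Undefined (NA) when no record carries a
#' codon-changing alternate allele.
#'
#' @param vcfPath path to a VCF (v4.x) with AD or AF in the genotype
#'   fields.
#' @param locus a [TargetLocus-class].
#' @param sample tumor sample name; default the first sample column.
#' @return summed VAF in [0, 1], or \code{NA_real_}.
#' @importFrom VariantAnnotation readVcf geno
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom GenomicRanges seqnames start
#' @export
vafFromVcf <- function(vcfPath, locus, sample = NULL) {
  stopifnot(is(locus, "TargetLocus"))
  vcf <- VariantAnnotation::readVcf(vcfPath)
  n <- nrow(vcf)
  if (n == 0L) return(NA_real_)
  if (is.null(sample)) sample <- colnames(vcf)[1L]

  rr <- SummarizedExperiment::rowRanges(vcf)
  filt <- rr$FILTER
  chromOk <- as.character(GenomicRanges::seqnames(rr)) == locus@chrom
  total <- NA_real_

  geno <- VariantAnnotation::geno(vcf)
  hasAD <- "AD" %in% names(geno)
  hasAF <- "AF" %in% names(geno)

  for (i in seq_len(n)) {
    if (!chromOk[i]) next
    if (!filt[i] %in% c("PASS", ".")) next
    pos <- GenomicRanges::start(rr)[i]
    refAllele <- as.character(rr$REF[i])
    alts <- as.character(rr$ALT[[i]])
    if (!length(alts)) next

    ad <- if (hasAD) unlist(geno$AD[i, sample]) else NULL
    af <- if (hasAF) unlist(geno$AF[i, sample]) else NULL

    for (j in seq_along(alts)) {
      altAllele <- alts[j]
      mutCodon <- .applySubstitution(locus, pos, refAllele, altAllele)
      if (is.na(mutCodon)) next
      if (classifyCodon(mutCodon, locus) != "mutant") next
      vaf <- if (!is.null(ad) && !anyNA(ad) && length(ad) >= j + 1L &&
                 sum(ad) > 0) {
        ad[j + 1L] / sum(ad)
      } else if (!is.null(af) && length(af) >= j) {
        af[j]
      } else NA_real_
      if (!is.na(vaf)) total <- sum(c(total, vaf), na.rm = TRUE)
    }
  }
  total
}

# mutated genomic-orientation codon after an equal-length substitution;
# NA when the variant is an indel or does not change a codon base
.applySubstitution <- function(locus, pos, refAllele, altAllele) {
  if (nchar(refAllele) != nchar(altAllele)) return(NA_character_)
  varPos <- pos + seq_len(nchar(refAllele)) - 1L
  hit <- varPos %in% locus@positions
  if (!any(hit)) return(NA_character_)
  codon <- strsplit(locus@refCodon, "")[[1]]
  altCh <- strsplit(altAllele, "")[[1]]
  for (k in which(hit)) {
    offset <- match(varPos[k], locus@positions)
    codon[offset] <- altCh[k]
  }
  out <- paste(codon, collapse = "")
  if (grepl("[^ACGT]", out)) NA_character_ else out
}

#' Copy-number adjustment of mutation dosage
#'
#' Renormalizes a dosage measured in a tumor carrying \code{totalCopies}
#' copies of the locus back to the copy-neutral two-copy scale:
#' \code{dosage * 2 / totalCopies}, clamped to [0, 1]. Identity at two
#' copies; halves the dosage at four copies.
#'
#' @param dosage fraction in [0, 1].
#' @param totalCopies tumor locus copy number (> 0).
#' @return adjusted dosage in [0, 1]. Vectorized.
#' @examples
#' adjustForCnv(0.4, 4)  # 0.2
#' @export
adjustForCnv <- function(dosage, totalCopies) {
  if (any(totalCopies <= 0, na.rm = TRUE)) stop("totalCopies must be > 0")
  if (any(dosage < 0 | dosage > 1, na.rm = TRUE))
    stop("dosage must lie in [0, 1]")
  pmin(1, pmax(0, dosage * 2 / totalCopies))
}

#' Classify mutation clonality from G12 and Q61 dosages
#'
#' A patient with no mutant reads at either codon is "none"; any Q61
#' dosage above zero on top of a G12 mutation marks the subclonal
#' G12+Q61 pattern, otherwise the mutation is clonal G12. When the
#' Q61-transition rule is enabled, the effective dosage used for
#' high/low grouping is the larger of the two codon dosages, so a
#' patient whose Q61 dosage exceeds the threshold transitions into the
#' high group even with a low G12 dosage.
#'
#' @param dosageG12 G12 dosage in [0, 1].
#' @param dosageQ61 Q61 dosage in [0, 1], or NA when unmeasured.
#' @param useQ61Transition apply the max(G12, Q61) grouping rule?
#' @return list with \code{clonality} (clonal_g12 / subclonal_g12_q61 /
#'   none) and \code{effectiveDosage}.
#' @examples
#' classifyClonality(0.05, 0.25)  # subclonal, effective 0.25
#' @export
classifyClonality <- function(dosageG12, dosageQ61 = NA_real_,
                              useQ61Transition = TRUE) {
  g <- dosageG12
  q <- if (is.na(dosageQ61)) 0 else dosageQ61
  stopifnot(is.na(g) || (g >= 0 && g <= 1), q >= 0, q <= 1)
  g0 <- if (is.na(g)) 0 else g
  clonality <- if (g0 == 0 && q == 0) "none"
    else if (q > 0) "subclonal_g12_q61"
    else "clonal_g12"
  effective <- if (useQ61Transition) max(g0, q) else g0
  list(clonality = clonality, effectiveDosage = effective)
}

#' Build per-patient dosage profiles
#'
#' Joins the long allele-count table (one row per patient, modality and
#' codon) into one profile per patient: raw dosages per modality,
#' CNV-adjusted targeted-sequencing dosage when a copy-number table is
#' supplied, Q61 dosage, clonality label and the effective dosage used
#' for grouping. Missing modalities yield NA dosages.
#'
#' @param countTable data.frame with columns patient_id, modality
#'   (RNA/WES/TS), codon (G12/Q61), mutant_reads, wildtype_reads,
#'   other_reads.
#' @param cnTable optional data.frame with patient_id, kras_total_copies.
#' @param q61NoiseFloor Q61 dosages at or below this fraction are treated
#'   as sequencing noise, not a subclone. At ultra-deep targeted depth
#'   the error channel alone produces a nonzero mutant fraction, so an
#'   exact-zero rule would label every patient subclonal.
#' @param useQ61Transition apply the max(G12, Q61) grouping rule (see
#'   [classifyClonality()]).
#' @return data.frame with one row per patient: patient_id, dosage_rna,
#'   dosage_wes, dosage_ts, adjusted_dosage_ts, dosage_q61_ts, clonality,
#'   effective_dosage_ts.
#' @export
buildDosageProfiles <- function(countTable, cnTable = NULL,
                                q61NoiseFloor = 0.01,
                                useQ61Transition = TRUE) {
  need <- c("patient_id", "modality", "codon", "mutant_reads",
            "wildtype_reads", "other_reads")
  missing <- setdiff(need, names(countTable))
  if (length(missing))
    stop("count table lacks column(s): ", paste(missing, collapse = ", "))
  key <- paste(countTable$patient_id, countTable$modality, countTable$codon)
  if (anyDuplicated(key))
    stop("duplicate (patient, modality, codon) rows in count table")

  tot <- countTable$mutant_reads + countTable$wildtype_reads +
    countTable$other_reads
  countTable$dosage <- ifelse(tot > 0, countTable$mutant_reads / tot,
                              NA_real_)

  ids <- unique(countTable$patient_id)
  pick <- function(id, mod, cod) {
    r <- countTable$dosage[countTable$patient_id == id &
                             countTable$modality == mod &
                             countTable$codon == cod]
    if (length(r)) r else NA_real_
  }
  prof <- do.call(rbind, lapply(ids, function(id) {
    dRna <- pick(id, "RNA", "G12")
    dWes <- pick(id, "WES", "G12")
    dTs <- pick(id, "TS", "G12")
    dQ61 <- pick(id, "TS", "Q61")
    q61Eff <- if (!is.na(dQ61) && dQ61 <= q61NoiseFloor) 0 else dQ61
    cl <- classifyClonality(dTs, q61Eff, useQ61Transition = useQ61Transition)
    data.frame(patient_id = id, dosage_rna = dRna, dosage_wes = dWes,
               dosage_ts = dTs, adjusted_dosage_ts = NA_real_,
               dosage_q61_ts = dQ61, clonality = cl$clonality,
               effective_dosage_ts = cl$effectiveDosage,
               stringsAsFactors = FALSE)
  }))

  if (!is.null(cnTable)) {
    if (!all(c("patient_id", "kras_total_copies") %in% names(cnTable)))
      stop("copy-number table needs patient_id and kras_total_copies")
    m <- match(prof$patient_id, cnTable$patient_id)
    cn <- cnTable$kras_total_copies[m]
    has <- !is.na(cn) & !is.na(prof$dosage_ts)
    prof$adjusted_dosage_ts[has] <- adjustForCnv(prof$dosage_ts[has],
                                                 cn[has])
  }
  rownames(prof) <- NULL
  prof
}
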