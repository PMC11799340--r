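test_that("codon-level allele counting classifies reads correctly", {
  # 7 wild-type (ACC), 3 G12D (plus-strand ATC), constructed in code
  lines <- c(
    vapply(1:7, function(i) codonRead(paste0("wt", i), "ACC"), character(1)),
    vapply(1:3, function(i) codonRead(paste0("mut", i), "ATC"), character(1)))
  bam <- makeBam(lines)
  ac <- countAllelesAtCodon(bam, G12_HG19)
  expect_identical(mutantReads(ac), 3L)
  expect_identical(wildtypeReads(ac), 7L)
  expect_identical(otherReads(ac), 0L)
  expect_identical(ac@codon, "G12")

  # counting is deterministic
  ac2 <- countAllelesAtCodon(bam, G12_HG19)
  expect_identical(mutantReads(ac2), mutantReads(ac))

  # all reads below the mapping-quality floor: nothing is counted
  low <- makeBam(vapply(1:5, function(i)
    codonRead(paste0("lq", i), "ATC", mapq = 5L), character(1)))
  expect_identical(totalReads(countAllelesAtCodon(low, G12_HG19,
                                                  minMapq = 20L)), 0L)

  # synonymous third-position change (GCC -> coding GGC, still Gly)
  syn <- makeBam(codonRead("syn1", "GCC"))
  acSyn <- countAllelesAtCodon(syn, G12_HG19)
  expect_identical(otherReads(acSyn), 1L)
  expect_identical(mutantReads(acSyn), 0L)

  # partial span and a deletion over the codon both land in "other"
  partial <- samRead("part1", G12_HG19@positions[1] - 10L,
                     paste0(strrep("G", 10), "AC"))  # stops mid-codon
  del <- samRead("del1", G12_HG19@positions[1] - 10L,
                 paste0(strrep("G", 10), "AC", strrep("T", 10)),
                 cigar = "11M1D11M")
  acOther <- countAllelesAtCodon(makeBam(c(partial, del)), G12_HG19)
  expect_identical(otherReads(acOther), 2L)

  # a base-quality failure inside the codon is unclassifiable
  lowq <- codonRead("bq1", "ATC",
                    qual = paste0(strrep("I", 10), "I#I", strrep("I", 10)))
  acBq <- countAllelesAtCodon(makeBam(lowq), G12_HG19, minBaseq = 20L)
  expect_identical(otherReads(acBq), 1L)

  # missing contig is an input error
  expect_error(
    countAllelesAtCodon(bam, TargetLocus("chrMissing", 100:102, "ACC")),
    "absent")
})

test_that("dosage is the mutant fraction of all covering reads", {
  expect_equal(computeDosage(AlleleCounts(0, 120)), 0)
  expect_equal(computeDosage(AlleleCounts(39, 161)), 0.195)
  expect_true(is.na(computeDosage(AlleleCounts(0, 0, 0))))
})

test_that("VCF dosage prefers allelic depths and honors filters", {
  loc <- G12_HG19
  # ref 80 / alt 20 at the middle codon base (C>T is G12D)
  v1 <- makeVcf("chr12\t25398284\t.\tC\tT\t.\tPASS\t.\tGT:AD\t0/1:80,20")
  expect_equal(vafFromVcf(v1, loc), 0.2)

  # non-PASS records are ignored entirely
  v2 <- makeVcf("chr12\t25398284\t.\tC\tT\t.\tartifact\tGT:AD\t0/1:80,20")
  expect_true(is.na(suppressWarnings(vafFromVcf(v2, loc))))

  # multi-allelic: both alts change the codon; dosages add per codon
  v3 <- makeVcf(
    "chr12\t25398284\t.\tC\tT,G\t.\tPASS\t.\tGT:AD\t0/1:85,10,5")
  expect_equal(vafFromVcf(v3, loc), 0.15)

  # synonymous alternate allele does not contribute
  v4 <- makeVcf("chr12\t25398283\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:90,10")
  expect_true(is.na(vafFromVcf(v4, loc)))

  # AF fallback when AD is absent
  v5 <- makeVcf("chr12\t25398284\t.\tC\tT\t.\tPASS\t.\tGT:AF\t0/1:0.25")
  expect_equal(vafFromVcf(v5, loc), 0.25)
})

test_that("copy-number adjustment renormalizes to the two-copy scale", {
  expect_equal(adjustForCnv(0.3, 2), 0.3)
  expect_equal(adjustForCnv(0.4, 4), 0.2)
  expect_equal(adjustForCnv(0.8, 1), 1)    # clamped
  expect_error(adjustForCnv(0.3, 0), "totalCopies")
})

test_that("clonality labels and effective dosage follow the Q61 rule", {
  r1 <- classifyClonality(0.3, NA)
  expect_identical(r1$clonality, "clonal_g12")
  expect_equal(r1$effectiveDosage, 0.3)

  # high-Q61 subclone transitions the patient into the high group
  r2 <- classifyClonality(0.05, 0.25)
  expect_identical(r2$clonality, "subclonal_g12_q61")
  expect_equal(r2$effectiveDosage, 0.25)
  expect_identical(dichotomize(r2$effectiveDosage, 0.195), "high")

  r3 <- classifyClonality(0, NA)
  expect_identical(r3$clonality, "none")

  r4 <- classifyClonality(0.05, 0.25, useQ61Transition = FALSE)
  expect_equal(r4$effectiveDosage, 0.05)
})

test_that("dosage profiles join modalities and recover the simulator truth", {
  tsOnly <- data.frame(patient_id = "A", modality = "TS", codon = "G12",
                       mutant_reads = 10L, wildtype_reads = 90L,
                       other_reads = 0L)
  p <- buildDosageProfiles(tsOnly)
  expect_true(is.na(p$dosage_rna) && is.na(p$dosage_wes))
  expect_equal(p$dosage_ts, 0.1)

  dup <- rbind(tsOnly, tsOnly)
  expect_error(buildDosageProfiles(dup), "duplicate")

  co <- sharedCohort()
  prof <- sharedProfiles()
  idx <- seq_len(500)
  m <- match(co$truth$patient_id[idx], prof$patient_id)
  # ultra-deep targeted dosage sits within +/-0.01 of the latent VAF
  expect_true(all(abs(prof$dosage_ts[m] -
                        co$truth$expected_vaf_g12[idx]) < 0.01))
  # dosage tracks tumor purity across the cohort
  expect_gt(cor(prof$dosage_ts, co$truth$purity, method = "spearman"), 0.5)

  # CNV adjustment flows through when a copy-number table is joined
  cn <- data.frame(patient_id = co$truth$patient_id,
                   kras_total_copies = co$truth$total_copies)
  profCn <- buildDosageProfiles(co$counts, cnTable = cn)
  expect_equal(profCn$adjusted_dosage_ts,
               pmin(1, profCn$dosage_ts * 2 / co$truth$total_copies[
                 match(profCn$patient_id, co$truth$patient_id)]))
})
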