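# Readers, writers, mutation filtering and sample harmonization.

writeMafFixture <- function(path, rows) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("MAF classes map onto the internal vocabulary, unknowns become other", {
  f <- tempfile(fileext = ".tsv")
  writeMafFixture(f, data.frame(
    Hugo_Symbol = "GATA3",
    Variant_Classification = c("Missense_Mutation", "Frame_Shift_Ins", "Silent"),
    Start_Position = c(100, 200, 300),
    Reference_Allele = c("A", "-", "G"),
    Tumor_Seq_Allele2 = c("T", "G", "A"),
    Tumor_Sample_Barcode = c("S1", "S2", "S3")))
  m <- readMutations(f, dialect = "maf")
  expect_equal(nrow(m), 3L)
  expect_equal(m$variant_class, c("missense", "frameshift_ins", "silent"))

  writeMafFixture(f, data.frame(
    Hugo_Symbol = "GATA3", Variant_Classification = "Targeted_Region",
    Start_Position = 1, Reference_Allele = "A", Tumor_Seq_Allele2 = "T",
    Tumor_Sample_Barcode = "S1"))
  expect_warning(m2 <- readMutations(f, dialect = "maf"), "other")
  expect_equal(m2$variant_class, "other")
})

test_that("header-only file gives an empty record set", {
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(c("Hugo_Symbol", "Variant_Classification", "Start_Position",
                     "Reference_Allele", "Tumor_Seq_Allele2",
                     "Tumor_Sample_Barcode"), collapse = "\t"), f)
  expect_equal(nrow(readMutations(f, "maf")), 0L)
})

test_that("format errors name the missing column; bad positions name the row", {
  f <- tempfile(fileext = ".tsv")
  writeMafFixture(f, data.frame(Hugo_Symbol = "X", Start_Position = 1,
                                Reference_Allele = "A", Tumor_Seq_Allele2 = "T",
                                Tumor_Sample_Barcode = "S1"))
  expect_error(readMutations(f, "maf"), "Variant_Classification")
  writeMafFixture(f, data.frame(
    Hugo_Symbol = "X", Variant_Classification = "Silent",
    Start_Position = "oops", Reference_Allele = "A", Tumor_Seq_Allele2 = "T",
    Tumor_Sample_Barcode = "S1"))
  expect_error(readMutations(f, "maf"), "row 1")
})

test_that("simulator output round-trips identically through both dialects", {
  sim <- simulateCohort(smallSimConfig(seed = 42, n_multi_mutant = 2L))
  recs <- mutations(cohort(sim))
  f1 <- tempfile(fileext = ".tsv")
  writeMutations(recs, f1, dialect = "simple_tsv")
  back <- readMutations(f1, dialect = "simple_tsv")
  expect_equal(back, recs, ignore_attr = TRUE)

  f2 <- tempfile(fileext = ".tsv")
  writeMutations(recs, f2, dialect = "maf")
  expect_no_warning(back2 <- readMutations(f2, dialect = "maf"))
  expect_equal(back2$sample_id, recs$sample_id)
  expect_equal(back2$variant_class, recs$variant_class)
  expect_equal(back2$cdna_position, recs$cdna_position)
  expect_equal(back2$genomic_position, recs$genomic_position)
})

test_that("readers tolerate gzip", {
  sim <- simulateCohort(smallSimConfig(seed = 5))
  recs <- mutations(cohort(sim))
  plain <- tempfile(fileext = ".tsv")
  writeMutations(recs, plain, dialect = "simple_tsv")
  gz <- paste0(plain, ".gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(plain), con)
  close(con)
  expect_equal(readMutations(gz, "simple_tsv"), readMutations(plain, "simple_tsv"))
})

test_that("class filtering drops exactly the requested classes, preserving order", {
  recs <- data.frame(sample_id = paste0("S", 1:5), gene = "G",
                     genomic_position = 1:5, cdna_position = NA_integer_,
                     variant_class = c("silent", "missense", "silent", "rna", "nonsense"),
                     ref_allele = "A", alt_allele = "T",
                     protein_change = NA_character_)
  expect_equal(filterMutations(recs, "silent")$sample_id, c("S2", "S4", "S5"))
  metab <- filterMutations(recs, c("silent", "rna"))
  expect_false(any(metab$variant_class %in% c("silent", "rna")))
  expect_equal(filterMutations(recs, character(0)), recs)
  # idempotence
  expect_equal(filterMutations(metab, c("silent", "rna")), metab)
})

test_that("single-mutation selection keeps exactly the singly mutated samples", {
  recs <- data.frame(sample_id = c("A", "B", "B", "C"), gene = "G",
                     genomic_position = c(10, 20, 30, 40),
                     cdna_position = NA_integer_, variant_class = "missense",
                     ref_allele = "A", alt_allele = "T",
                     protein_change = NA_character_)
  single <- singleMutationPatients(recs, "G")
  expect_setequal(single$sample_id, c("A", "C"))
  expect_equal(singleMutationPatients(single, "G"), single)  # idempotent

  multi <- recs[recs$sample_id == "B", ]
  expect_equal(nrow(singleMutationPatients(multi, "G")), 0L)
  expect_message(none <- singleMutationPatients(recs, "ABSENT"), "ABSENT")
  expect_equal(nrow(none), 0L)
})

test_that("single/multi/zero mutant counts partition the harmonized samples", {
  sim <- simulateCohort(smallSimConfig(seed = 9, n_multi_mutant = 3L))
  co <- harmonizeCohort(cohort(sim))
  recs <- mutations(co)
  nSamples <- ncol(expressionMatrix(co))
  single <- singleMutationPatients(recs, "GATA3")
  counts <- table(recs$sample_id[recs$gene == "GATA3"])
  nMulti <- sum(counts >= 2)
  nZero <- nSamples - length(counts)
  expect_equal(nrow(single), groundTruth(sim)$samples |> nrow())
  expect_equal(nrow(single) + nMulti + nZero, nSamples)
})

test_that("harmonization intersects ids, logs drops, and errors on zero overlap", {
  sim <- simulateCohort(smallSimConfig(seed = 2))
  co <- cohort(sim)
  expect_silent(h <- suppressMessages(harmonizeCohort(co)))
  expect_equal(nrow(mutations(h)), nrow(mutations(co)))

  # 2 of 10 mutation samples missing from expression
  recs <- mutations(co)[1:10, ]
  recs$sample_id[9:10] <- c("GHOST1", "GHOST2")
  co2 <- Cohort(recs, expressionMatrix(co), clinical(co))
  expect_message(h2 <- harmonizeCohort(co2), "dropped 2 mutation")
  expect_equal(nrow(mutations(h2)), 8L)

  recs$sample_id <- paste0("NOPE", seq_len(nrow(recs)))
  co3 <- Cohort(recs, expressionMatrix(co))
  expect_error(harmonizeCohort(co3), "no mutation sample ids overlap")
})

test_that("TCGA-style long barcodes match after 15-character truncation", {
  long <- c("TCGA-A1-A0SB-01A-11R-A144-07", "TCGA-A1-A0SD-01A-11R-A144-07")
  shortIds <- substr(long, 1, 15)
  recs <- data.frame(sample_id = long, gene = "G",
                     genomic_position = c(1, 2), cdna_position = NA_integer_,
                     variant_class = "missense", ref_allele = "A",
                     alt_allele = "T", protein_change = NA_character_)
  ex <- matrix(1, nrow = 2, ncol = 2,
               dimnames = list(c("G1", "G2"), paste0(shortIds, "X-extra")))
  h <- harmonizeCohort(Cohort(recs, ex), truncateBarcodes = 15L)
  expect_setequal(mutations(h)$sample_id, shortIds)
  expect_setequal(colnames(expressionMatrix(h)), shortIds)
})

test_that("expression and clinical readers validate their invariants", {
  f <- tempfile(fileext = ".tsv")
  writeExpression(matrix(c(1, 2, 3, 4), 2, 2,
                         dimnames = list(c("g1", "g2"), c("s1", "s2"))), f)
  m <- readExpression(f)
  expect_equal(m["g2", "s2"], 4)
  writeLines("gene_id\ts1\ng1\t-3", f)
  expect_error(readExpression(f), "non-negative")

  fc <- tempfile(fileext = ".tsv")
  writeClinical(data.frame(sample_id = "s1", dfs_months = 12.5, dfs_event = TRUE), fc)
  cl <- readClinical(fc)
  expect_equal(cl$dfs_months, 12.5)
  expect_true(cl$dfs_event)
})

test_that("transcript models survive a FASTA + sidecar round trip", {
  g <- gata3SyntheticTranscript()
  fa <- tempfile(fileext = ".fa"); sc <- tempfile(fileext = ".tsv")
  writeTranscriptModel(g, fa, sc)
  back <- readTranscriptModels(fa, sc)[[1]]
  expect_equal(as.character(back@cdna), as.character(g@cdna))
  expect_equal(back@cdsStart, g@cdsStart)
  expect_equal(back@exonEnds, g@exonEnds)
})
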