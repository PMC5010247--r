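# In-silico translation and frameshift classification.

test_that("net frame arithmetic follows (ins - del) mod 3", {
  expect_equal(netFrame(1, 0), 1L)    # single-base insertion -> +1 frame
  expect_equal(netFrame(0, 1), -1L)   # single-base deletion -> -1 frame
  expect_equal(netFrame(3, 0), 0L)
  expect_equal(netFrame(2, 0), -1L)
  expect_equal(netFrame(4, 1), 0L)
  expect_error(netFrame(-1, 0), "non-negative")
})

test_that("variant application edits the cDNA as specified", {
  t <- TranscriptModel("TOY", "T1", "ATGCAATAA", 1, 9, 9)
  expect_equal(substr(applyVariant(t, 4, "-", "G"), 1, 7), "ATGCGAA")
  expect_equal(applyVariant(t, 4, "C", "-"), "ATGAATAA")
  expect_equal(substr(applyVariant(t, 1, "A", "T"), 1, 6), "TTGCAA")
  expect_error(applyVariant(t, 4, "G", "-"), "expected 'G'.*has 'C'")
})

test_that("translation stops at the first stop codon and flags its absence", {
  expect_equal(translateCdna("ATGTAA")$protein, "M")
  expect_equal(translateCdna("ATGGAATGA")$protein, "ME")
  expect_true(translateCdna("ATGGAA")$noStop)
  expect_error(translateCdna("ATGNAA"), "offset 4")

  set.seed(31)
  for (r in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    got <- translateCdna(seq)
    ora <- oracleTranslate(seq)
    expect_identical(got$protein, ora$protein)
    expect_identical(got$noStop, ora$noStop)
  }
})

test_that("exon lookup is boundary-inclusive and matches a linear scan", {
  t <- TranscriptModel("TOY", "T1",
                       paste0("ATG", strrep("GCT", 131), "TAAA"), 1, 399,
                       exonEnds = c(100L, 250L, 400L))
  expect_equal(exonOf(t, 100), 1L)
  expect_equal(exonOf(t, 101), 2L)
  expect_error(exonOf(t, 0), "out of")
  set.seed(5)
  pos <- sample(400, 50)
  scan <- vapply(pos, function(p) which(p <= c(100L, 250L, 400L))[1], integer(1))
  expect_equal(exonOf(t, pos), scan)
})

test_that("classifier agrees with the whole-mRNA re-translation oracle on random indels", {
  set.seed(99)
  checked <- 0L
  for (r in 1:30) {
    toy <- makeToyTranscript(nCodons = sample(20:60, 1), utr3Len = 60L,
                             nVariants = 8L)
    t <- toy$transcript
    for (v in seq_len(nrow(toy$variants))) {
      pos <- toy$variants$cdna_position[v]
      ref <- toy$variants$ref_allele[v]
      alt <- toy$variants$alt_allele[v]
      got <- classifyConsequence(t, pos, ref, alt)
      ora <- oracleConsequence(t, pos, ref, alt)
      expect_identical(got@consequenceClass, ora$class,
                       label = sprintf("class at pos %d (%s>%s)", pos, ref, alt))
      expect_equal(got@firstAlteredResidue, ora$first_altered)
      expect_equal(got@mutantLength, ora$mutant_length)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 200L)
})

test_that("any in-CDS single-base insertion is +1 frame and never in-frame", {
  set.seed(17)
  toy <- makeToyTranscript(nCodons = 40, utr3Len = 60)
  t <- toy$transcript
  for (pos in sample(4:(40 * 3 - 6), 25)) {
    got <- classifyConsequence(t, pos, "-", sample(c("A", "C", "G", "T"), 1))
    expect_equal(got@frameShift, 1L)
    expect_false(got@consequenceClass %in% c("in_frame", "silent", "missense"))
  }
})

test_that("extension length bookkeeping is internally consistent", {
  g <- gata3SyntheticTranscript()
  W <- proteinLength(g)
  for (pos in c(1184L, 1224L, seq(1185L, 1329L, by = 24L))) {
    pc <- classifyConsequence(g, pos, "-", "G")
    expect_equal(pc@consequenceClass, "frameshift_extension")
    expect_equal(pc@novelCtermLength, pc@mutantLength - W)
    expect_gt(pc@mutantLength, W)
    expect_equal(pc@alteredOriginalResidues, W - pc@firstAlteredResidue + 1L)
  }
  tr <- classifyConsequence(g, 1006L, "-", "G")
  expect_lt(tr@mutantLength, W)
})

test_that("the synthetic GATA3 transcript reproduces the published worked values", {
  g <- gata3SyntheticTranscript()
  expect_equal(proteinLength(g), 444L)

  trunc <- classifyConsequence(g, 1006, "-", "G")
  expect_equal(trunc@consequenceClass, "frameshift_truncation")
  expect_equal(trunc@proteinChange, "p.G336fs")
  expect_equal(trunc@frameShift, 1L)

  ext <- classifyConsequence(g, 1224, "-", "G")
  expect_equal(ext@consequenceClass, "frameshift_extension")
  expect_equal(ext@proteinChange, "p.P409fs")
  expect_equal(ext@frameShift, 1L)
  expect_equal(ext@novelCtermLength, 63L)

  # extensions across the C-terminal window: labels span A395..G444, the
  # novel tail is shared, and at most 49 original residues are replaced
  window <- c(1184L, seq(1185L, 1329L, by = 3L))
  cons <- lapply(window, function(p) classifyConsequence(g, p, "-", "G"))
  expect_true(all(vapply(cons, function(x) x@consequenceClass, "") ==
                    "frameshift_extension"))
  expect_equal(unique(vapply(cons, function(x) x@novelCtermLength, 1L)), 63L)
  expect_equal(max(vapply(cons, function(x) x@alteredOriginalResidues, 1L)), 49L)
  expect_equal(cons[[1]]@proteinChange, "p.A395fs")

  # exon placement: the truncation hotspot sits in exon 5, the extension
  # hotspot in exon 6
  expect_equal(exonOf(g, cdsToTranscript(g, 1006)), 5L)
  expect_equal(exonOf(g, cdsToTranscript(g, 1224)), 6L)
})

test_that("substitution classes come out as silent/missense/nonsense", {
  g <- gata3SyntheticTranscript()
  # GCT -> GCC at codon 100: still Ala -> silent
  expect_equal(classifyConsequence(g, 300, "T", "C")@consequenceClass, "silent")
  # GCT -> ACT at codon 100 -> missense
  expect_equal(classifyConsequence(g, 298, "G", "A")@consequenceClass, "missense")
  # GCT -> TGA-forming change? engineer: codon GCT, change G->T gives TCT (Ser);
  # build a nonsense via GGA(336): G->T at first base gives TGA stop
  nonsense <- classifyConsequence(g, 1006, "G", "T")
  expect_equal(nonsense@consequenceClass, "nonsense")
  expect_equal(nonsense@frameShift, 0L)
  # positions outside the CDS are noncoding
  expect_equal(classifyConsequence(g, 1400, "C", "A")@consequenceClass, "noncoding")
})

test_that("class tallies partition the records and expose share helpers", {
  g <- gata3SyntheticTranscript()
  empty <- tallyClasses(data.frame(sample_id = character(0), gene = character(0),
                                   genomic_position = integer(0),
                                   cdna_position = integer(0),
                                   variant_class = character(0),
                                   ref_allele = character(0),
                                   alt_allele = character(0),
                                   protein_change = character(0)), g)
  expect_equal(empty$n, 0L)

  sim <- simulateCohort(smallSimConfig(seed = 21))
  recs <- mutations(cohort(sim))
  tl <- tallyClasses(recs, g)
  expect_equal(sum(tl$table$n), nrow(recs))
  truthClasses <- table(groundTruth(sim)$samples$class)
  got <- tapply(tl$table$n, tl$table$consequence_class, sum)
  for (cl in names(truthClasses))
    expect_equal(unname(got[[cl]]), unname(truthClasses[[cl]]))
  expect_true(tl$extension_share_of_frameshifts > 0 &&
                tl$extension_share_of_frameshifts < 1)
})
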