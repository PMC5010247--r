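## A fully synthetic GATA3-like transcript model.
##
## No reference sequence ships with (or is downloaded by) this package.
## Instead this constructor builds, in code, a 444-codon transcript whose
## local sequence around the two breast-cancer frameshift hotspots is
## engineered so that the published worked arithmetic of the GATA3
## frameshift classes holds exactly:
##
##   * cDNA:1006insG  -> p.G336fs, +1 frame, premature stop (truncation)
##   * cDNA:1224insG  -> p.P409fs, +1 frame, read-through into the 3'UTR,
##                       mutant length 507 = 444 + 63 novel residues
##   * every single-base insertion in the C-terminal extension window shares
##     the same shifted-frame stop, so all extensions append the same 63
##     novel residues; the earliest extension first alters residue 396,
##     i.e. at most 49 of the original C-terminal residues are replaced
##   * single-base deletions (-1 frame) upstream of codon 430 hit a planted
##     -1-frame stop and truncate at 429 residues
##
## Geometry of the construction (CDS positions, +1 = A of ATG):
##   codon 1 ATG; filler codons GCT (Ala) -- GCT repeats contain no stop in
##   any frame; codon 336 GGA (Gly); codons 340/370/394 AAT, each preceded
##   by a filler T, planting +1-frame TAA stops at 1017/1107/1179; codon 409
##   CCA (Pro); codons 430/431 GTA/ACT planting a -1-frame TAA at 1289;
##   codon 444 GGT (Gly); stop TAA. The 200-nt 3'UTR repeats CAG (stop-free
##   in all frames) with a +1-frame TAA planted at CDS positions 1521-1523
##   and a -1-frame TAA at 1526-1528.

# CDS coordinates of the planted shifted-frame stop codons (start position
# of each stop triplet). Used by the simulator's independent bookkeeping.
.GATA3_PLUS1_STOPS <- c(1017L, 1107L, 1179L, 1521L)
.GATA3_MINUS1_STOPS <- c(1289L, 1526L)

#' Synthetic GATA3-like transcript model
#'
#' Deterministically constructs the engineered 444-residue transcript
#' described in the package source (see `R/transcript-gata3.R`): a synthetic
#' stand-in for a GATA3 reference transcript that reproduces the worked
#' frameshift arithmetic of the breast-cancer GATA3 mutation classes
#' (G336fs truncation, P409fs +1-frame extension appending 63 novel
#' residues, at most 49 original C-terminal residues altered). It is *not*
#' the biological GATA3 sequence; outside the engineered positions the CDS
#' is filler.
#'
#' @return A [TranscriptModel-class] with a 30-nt 5'UTR, a 1335-nt CDS
#'   (444 codons + stop) and a 200-nt 3'UTR, split over 6 exons.
#' @examples
#' g <- gata3SyntheticTranscript()
#' classifyConsequence(g, 1224, "-", "G")
#' @export
gata3SyntheticTranscript <- function() {
  codons <- rep("GCT", 445L)
  codons[1L] <- "ATG"
  codons[336L] <- "GGA"   # Gly 336 (truncation hotspot codon)
  codons[340L] <- "AAT"   # +1-frame stop trap at 1017
  codons[370L] <- "AAT"   # +1-frame stop trap at 1107
  codons[394L] <- "AAT"   # +1-frame stop trap at 1179 (last before ext window)
  codons[409L] <- "CCA"   # Pro 409 (extension hotspot codon)
  codons[430L] <- "GTA"   # with codon 431, -1-frame stop at 1289
  codons[431L] <- "ACT"
  codons[444L] <- "GGT"   # Gly 444, last residue
  codons[445L] <- "TAA"   # stop
  cds <- paste(codons, collapse = "")

  utr3 <- strsplit(paste(rep("CAG", ceiling(200 / 3)), collapse = ""), "")[[1]][1:200]
  # planted shifted-frame stops in the 3'UTR (offsets from CDS end 1335)
  utr3[186:188] <- c("T", "A", "A")   # +1 frame: CDS positions 1521-1523
  utr3[191:193] <- c("T", "A", "A")   # -1 frame: CDS positions 1526-1528
  utr3 <- paste(utr3, collapse = "")

  utr5 <- paste(rep("CGA", 10L), collapse = "")

  TranscriptModel(gene = "GATA3",
                  transcriptId = "GATA3-SYNTH-444",
                  cdna = paste0(utr5, cds, utr3),
                  cdsStart = 31L, cdsEnd = 30L + 1335L,
                  exonEnds = c(150L, 420L, 800L, 1000L, 1240L, 1565L))
}
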