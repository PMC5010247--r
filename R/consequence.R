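## In-silico translation of coding variants: net frame, mutant cDNA
## construction, ORF translation, and truncation/extension classification.

#' Wild-type protein length of a transcript
#'
#' Residues encoded by the CDS, excluding the stop codon.
#' @param t a [TranscriptModel-class].
#' @return Integer protein length.
#' @export
proteinLength <- function(t) as.integer((t@cdsEnd - t@cdsStart + 1L) / 3L - 1L)

#' Convert a start-codon-anchored cDNA position to a transcript coordinate
#'
#' Variant cDNA positions are numbered with +1 at the A of the start codon;
#' transcript coordinates are 1-based on the full spliced cDNA.
#' @param t a [TranscriptModel-class].
#' @param cdnaPos integer position(s), +1 = A of ATG.
#' @return Integer transcript coordinate(s).
#' @export
cdsToTranscript <- function(t, cdnaPos) as.integer(t@cdsStart + cdnaPos - 1L)

#' Net reading-frame shift of an indel
#'
#' @param insertedLen,deletedLen non-negative integers.
#' @return `0` for in-frame changes, `1` for the +1 frame
#'   (`(ins - del) mod 3 == 1`, e.g. a single-base insertion), `-1` for the
#'   -1 frame (`mod 3 == 2`, e.g. a single-base deletion).
#' @examples
#' netFrame(1, 0)  # +1
#' netFrame(0, 1)  # -1
#' netFrame(3, 0)  # 0
#' @export
netFrame <- function(insertedLen, deletedLen) {
  if (insertedLen < 0 || deletedLen < 0)
    stop("netFrame: lengths must be non-negative")
  r <- (insertedLen - deletedLen) %% 3L
  if (r == 0) 0L else if (r == 1) 1L else -1L
}

#' Apply a substitution or indel to a transcript cDNA
#'
#' Positions are start-codon anchored (see [cdsToTranscript()]). Pure
#' insertions (`ref == "-"`) insert `alt` *after* `cdnaPos`; deletions
#' (`alt == "-"`) remove `nchar(ref)` bases starting at `cdnaPos`;
#' substitutions replace in place. The stated reference bases are checked
#' against the transcript.
#'
#' @param t a [TranscriptModel-class].
#' @param cdnaPos variant position (+1 = A of start codon).
#' @param ref,alt allele strings; `"-"` denotes absence (length 0).
#' @return Mutant cDNA as a character string (full transcript, UTRs
#'   included).
#' @export
applyVariant <- function(t, cdnaPos, ref, alt) {
  s <- as.character(t@cdna)
  p <- cdsToTranscript(t, cdnaPos)
  if (p < 1L || p > nchar(s)) stop("applyVariant: position outside transcript")
  if (ref == "-") {                      # pure insertion after p
    return(paste0(substr(s, 1L, p), alt, substr(s, p + 1L, nchar(s))))
  }
  found <- substr(s, p, p + nchar(ref) - 1L)
  if (found != ref)
    stop(sprintf("applyVariant: reference mismatch at cDNA %d: expected '%s', transcript has '%s'",
                 cdnaPos, ref, found))
  if (alt == "-") alt <- ""
  paste0(substr(s, 1L, p - 1L), alt, substr(s, p + nchar(ref), nchar(s)))
}

#' Translate a nucleotide sequence to its first stop codon
#'
#' Translation starts at position 1 (a codon boundary) with the standard
#' genetic code and stops at the first stop codon, which is excluded from
#' the returned peptide. A trailing partial codon is ignored.
#'
#' @param seq character nucleotide string (ACGT only).
#' @return List with `protein` (character) and `noStop` (logical, `TRUE`
#'   when no stop codon was encountered before the end of `seq`).
#' @examples
#' translateCdna("ATGTAA")$protein     # "M"
#' translateCdna("ATGGAATGA")$protein  # "ME"
#' @export
translateCdna <- function(seq) {
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0)
    stop(sprintf("translateCdna: non-ACGT character at offset %d", as.integer(bad)))
  nc <- 3L * (nchar(seq) %/% 3L)
  if (nc == 0L) return(list(protein = "", noStop = TRUE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, nc)), no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) list(protein = substr(aa, 1L, stop_at - 1L), noStop = FALSE)
  else list(protein = aa, noStop = TRUE)
}

#' Exon index of a transcript position
#'
#' @param t a [TranscriptModel-class].
#' @param pos transcript coordinate(s), `1 <= pos <= length(cdna)`; exon ends
#'   are inclusive.
#' @return Integer exon index (1-based), the smallest i with
#'   `pos <= exonEnds[i]`.
#' @export
exonOf <- function(t, pos) {
  n <- length(t@cdna)
  if (any(pos < 1L | pos > n)) stop("exonOf: position out of transcript range")
  findInterval(pos, t@exonEnds + 0.5) + 1L
}

#' Classify the protein consequence of a coding variant
#'
#' Builds the mutant cDNA, translates wild type and mutant from the start
#' codon (reading into the 3'UTR when a frameshift removes the wild-type
#' stop), and compares the two open reading frames. Frameshifts are classed
#' by mutant ORF length L against wild-type length W: truncation (L < W),
#' extension (L > W, with `novelCtermLength = L - W` and
#' `alteredOriginalResidues = W - firstAlteredResidue + 1`), or same length.
#' If no stop codon is reached before the end of the transcript, the class is
#' `no_stop` rather than a guessed length. Positions outside the CDS return
#' `noncoding`.
#'
#' @param t a [TranscriptModel-class].
#' @param cdnaPos variant position (+1 = A of start codon). For pure
#'   insertions the inserted bases follow this position.
#' @param ref,alt allele strings (`"-"` = absent).
#' @return A [ProteinConsequence-class] object.
#' @examples
#' g <- gata3SyntheticTranscript()
#' classifyConsequence(g, 1006, "-", "G")  # p.G336fs truncation
#' classifyConsequence(g, 1224, "-", "G")  # p.P409fs +1 extension
#' @export
classifyConsequence <- function(t, cdnaPos, ref, alt) {
  cdsLen <- t@cdsEnd - t@cdsStart + 1L
  insLen <- if (ref == "-") nchar(alt) else if (alt == "-") 0L else nchar(alt)
  delLen <- if (ref == "-") 0L else if (alt == "-") nchar(ref) else nchar(ref)
  if (cdnaPos < 1L || cdnaPos > cdsLen - 3L) {   # outside CDS (stop codon excluded)
    return(new("ProteinConsequence", frameShift = 0L,
               consequenceClass = "noncoding", firstAlteredResidue = NA_integer_,
               mutantLength = NA_integer_, novelCtermLength = NA_integer_,
               alteredOriginalResidues = NA_integer_,
               proteinChange = "p.?", wtLength = proteinLength(t)))
  }

  wtSeq <- substr(as.character(t@cdna), t@cdsStart, length(t@cdna))
  wt <- translateCdna(wtSeq)
  W <- nchar(wt$protein)
  mutFull <- applyVariant(t, cdnaPos, ref, alt)
  mutSeq <- substr(mutFull, t@cdsStart, nchar(mutFull))
  mut <- translateCdna(mutSeq)
  L <- nchar(mut$protein)

  frame <- if (insLen != delLen) netFrame(insLen, delLen) else 0L

  # first codon whose translation differs from wild type
  wtChars <- strsplit(wt$protein, "")[[1]]
  mutChars <- strsplit(mut$protein, "")[[1]]
  m <- min(W, L)
  firstAltered <- NA_integer_
  if (m > 0L) {
    diffs <- which(wtChars[seq_len(m)] != mutChars[seq_len(m)])
    if (length(diffs)) firstAltered <- diffs[1]
  }
  if (is.na(firstAltered) && L != W) firstAltered <- m + 1L

  # residue label: codon containing the first inserted / changed nucleotide
  changedNt <- if (ref == "-") cdnaPos + 1L else cdnaPos
  labelCodon <- as.integer(ceiling(changedNt / 3))
  wtRes <- if (labelCodon <= W) wtChars[labelCodon] else "*"

  novel <- NA_integer_
  alteredOrig <- NA_integer_
  if (frame != 0L) {
    if (mut$noStop) {
      cls <- "no_stop"
      L <- NA_integer_
    } else if (L < W) {
      cls <- "frameshift_truncation"
    } else if (L > W) {
      cls <- "frameshift_extension"
      novel <- L - W
      alteredOrig <- W - firstAltered + 1L
    } else cls <- "frameshift_same_length"
    pch <- sprintf("p.%s%dfs", wtRes, labelCodon)
  } else if (insLen != delLen) {
    cls <- "in_frame"
    pch <- sprintf("p.%s%ddelins", wtRes, labelCodon)
  } else {
    if (identical(wt$protein, mut$protein)) {
      cls <- "silent"
      pch <- sprintf("p.%s%d=", wtRes, labelCodon)
    } else if (!mut$noStop && L < W && is.na(match(FALSE, mutChars == wtChars[seq_len(L)]))) {
      cls <- "nonsense"
      firstAltered <- L + 1L
      pch <- sprintf("p.%s%d*", wtChars[firstAltered], firstAltered)
    } else {
      cls <- "missense"
      pch <- sprintf("p.%s%d%s", wtRes, labelCodon,
                     if (!is.na(firstAltered) && firstAltered <= L)
                       mutChars[firstAltered] else "?")
    }
  }

  new("ProteinConsequence", frameShift = as.integer(frame),
      consequenceClass = cls,
      firstAlteredResidue = as.integer(firstAltered),
      mutantLength = as.integer(L),
      novelCtermLength = as.integer(novel),
      alteredOriginalResidues = as.integer(alteredOrig),
      proteinChange = pch, wtLength = as.integer(W))
}

#' Classify all mutations of one gene against a transcript
#'
#' Vectorized wrapper around [classifyConsequence()]. In `"retranslate"`
#' mode (default) the protein-change label is regenerated from the
#' transcript; in `"annotation"` mode an existing `protein_change` column is
#' kept when present (consequence classes and lengths always come from
#' re-translation, since truncation-versus-extension cannot be read off an
#' fs label alone).
#'
#' @param t a [TranscriptModel-class].
#' @param records data.frame of mutation records (canonical columns) for
#'   `t@gene`; records without a `cdna_position` are classed `noncoding`.
#' @param mode `"retranslate"` or `"annotation"`.
#' @return data.frame with one row per record: sample_id, cdna_position,
#'   frame_shift, consequence_class, first_altered_residue, mutant_length,
#'   novel_cterm_length, altered_original_residues, protein_change, exon.
#' @export
classifyMutations <- function(t, records, mode = c("retranslate", "annotation")) {
  mode <- match.arg(mode)
  rows <- lapply(seq_len(nrow(records)), function(r) {
    pos <- records$cdna_position[r]
    if (is.na(pos)) {
      pc <- new("ProteinConsequence", frameShift = 0L,
                consequenceClass = "noncoding", firstAlteredResidue = NA_integer_,
                mutantLength = NA_integer_, novelCtermLength = NA_integer_,
                alteredOriginalResidues = NA_integer_, proteinChange = "p.?",
                wtLength = proteinLength(t))
      exon <- NA_integer_
    } else {
      pc <- classifyConsequence(t, pos, records$ref_allele[r], records$alt_allele[r])
      exon <- exonOf(t, cdsToTranscript(t, pos))
    }
    label <- pc@proteinChange
    if (mode == "annotation" && !is.null(records$protein_change) &&
        !is.na(records$protein_change[r]) && nzchar(records$protein_change[r]))
      label <- records$protein_change[r]
    data.frame(sample_id = records$sample_id[r],
               cdna_position = pos,
               frame_shift = pc@frameShift,
               consequence_class = pc@consequenceClass,
               first_altered_residue = pc@firstAlteredResidue,
               mutant_length = pc@mutantLength,
               novel_cterm_length = pc@novelCtermLength,
               altered_original_residues = pc@alteredOriginalResidues,
               protein_change = label,
               exon = exon,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(sample_id = character(0), cdna_position = integer(0),
                      frame_shift = integer(0), consequence_class = character(0),
                      first_altered_residue = integer(0), mutant_length = integer(0),
                      novel_cterm_length = integer(0),
                      altered_original_residues = integer(0),
                      protein_change = character(0), exon = integer(0)))
  do.call(rbind, rows)
}

#' Tally consequence classes by frame and exon
#'
#' Counts one gene's mutations by (consequence class, frame shift, exon);
#' the counts partition the records. Fraction helpers summarise the shares
#' the cohort figures report: extensions among frameshifts and the exon
#' distribution of extensions.
#'
#' @param records mutation records of one gene (canonical columns).
#' @param t the gene's [TranscriptModel-class].
#' @return List with `table` (counts by class/frame/exon), `n`,
#'   `extension_share_of_frameshifts`, and `extension_exon_share` (named
#'   fraction per exon among extensions).
#' @export
tallyClasses <- function(records, t) {
  cons <- classifyMutations(t, records)
  if (!nrow(cons))
    return(list(table = data.frame(consequence_class = character(0),
                                   frame_shift = integer(0), exon = integer(0),
                                   n = integer(0)),
                n = 0L, extension_share_of_frameshifts = NA_real_,
                extension_exon_share = numeric(0)))
  agg <- stats::aggregate(list(n = rep(1L, nrow(cons))),
                          by = list(consequence_class = cons$consequence_class,
                                    frame_shift = cons$frame_shift,
                                    exon = cons$exon), FUN = sum)
  isFs <- cons$consequence_class %in%
    c("frameshift_truncation", "frameshift_extension", "frameshift_same_length", "no_stop")
  isExt <- cons$consequence_class == "frameshift_extension"
  extShare <- if (any(isFs)) sum(isExt) / sum(isFs) else NA_real_
  exonShare <- if (any(isExt)) {
    tab <- table(cons$exon[isExt])
    setNames(as.numeric(tab) / sum(tab), names(tab))
  } else numeric(0)
  list(table = agg, n = nrow(cons),
       extension_share_of_frameshifts = extShare,
       extension_exon_share = exonShare)
}
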