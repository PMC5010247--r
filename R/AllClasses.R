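#' @import methods
#' @importFrom stats rnorm runif rexp median pchisq pnorm dnorm sd setNames
#' @importFrom utils read.delim write.table head
#' @useDynLib mutseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Recognised somatic variant classes
#'
#' Internal vocabulary for mutation classification. MAF
#' `Variant_Classification` strings are mapped onto these values on read;
#' unrecognised strings become `"other"` (with a warning) rather than being
#' dropped, so that filtering is always explicit.
#'
#' @format Character vector of the nine class labels.
#' @export
VARIANT_CLASSES <- c("silent", "missense", "nonsense", "frameshift_ins",
                     "frameshift_del", "inframe_indel", "splice", "rna", "other")

#' Protein-level consequence classes
#' @format Character vector of the recognised consequence labels.
#' @export
CONSEQUENCE_CLASSES <- c("in_frame", "frameshift_truncation", "frameshift_extension",
                         "frameshift_same_length", "nonsense", "missense", "silent",
                         "no_stop", "noncoding")

.MUTATION_COLUMNS <- c("sample_id", "gene", "genomic_position", "cdna_position",
                       "variant_class", "ref_allele", "alt_allele", "protein_change")

## ---------------------------------------------------------------------------
## TranscriptModel
## ---------------------------------------------------------------------------

#' Spliced transcript model for consequence prediction
#'
#' Holds a spliced cDNA (5'UTR + CDS + 3'UTR), the CDS bounds on that cDNA and
#' the cumulative exon ends. `cdsEnd` is the last base of the stop codon.
#' Variant cDNA coordinates used throughout the package are anchored at the
#' start codon (+1 = A of ATG); [cdsToTranscript()] converts them to transcript
#' coordinates.
#'
#' @slot gene HUGO symbol.
#' @slot transcriptId transcript accession or label.
#' @slot cdna a [Biostrings::DNAString] of the spliced transcript.
#' @slot cdsStart,cdsEnd integer, 1-based inclusive positions on `cdna`.
#' @slot exonEnds integer, strictly increasing 1-based transcript position of
#'   each exon's last base; the last entry equals `length(cdna)`.
#' @export
setClass("TranscriptModel",
  representation(gene = "character", transcriptId = "character",
                 cdna = "ANY", cdsStart = "integer", cdsEnd = "integer",
                 exonEnds = "integer"))

setValidity("TranscriptModel", function(object) {
  msgs <- character(0)
  s <- as.character(object@cdna)
  n <- nchar(s)
  cs <- object@cdsStart; ce <- object@cdsEnd
  if (length(cs) != 1L || length(ce) != 1L || cs < 1L || ce > n || cs >= ce)
    return("cdsStart/cdsEnd out of range")
  if ((ce - cs + 1L) %% 3L != 0L)
    msgs <- c(msgs, "CDS length not divisible by 3")
  if (substr(s, cs, cs + 2L) != "ATG")
    msgs <- c(msgs, "CDS does not begin with ATG")
  if (!substr(s, ce - 2L, ce) %in% c("TAA", "TAG", "TGA"))
    msgs <- c(msgs, "CDS does not end with a stop codon")
  ee <- object@exonEnds
  if (length(ee) == 0L || any(diff(ee) <= 0L) || ee[length(ee)] != n)
    msgs <- c(msgs, "exonEnds must be strictly increasing and end at length(cdna)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TranscriptModel
#'
#' @param gene,transcriptId character scalars.
#' @param cdna character or `DNAString` spliced transcript sequence.
#' @param cdsStart,cdsEnd 1-based inclusive CDS bounds on the transcript
#'   (`cdsEnd` = last base of the stop codon).
#' @param exonEnds integer vector of cumulative exon end positions.
#' @return A [TranscriptModel-class] object.
#' @examples
#' t <- TranscriptModel("TOY", "TOY-1", "ATGGAATGA", 1, 9, exonEnds = 9)
#' proteinLength(t)
#' @export
TranscriptModel <- function(gene, transcriptId, cdna, cdsStart, cdsEnd, exonEnds) {
  if (is.character(cdna)) cdna <- Biostrings::DNAString(cdna)
  new("TranscriptModel", gene = gene, transcriptId = transcriptId, cdna = cdna,
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd),
      exonEnds = as.integer(exonEnds))
}

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId, "(", object@gene, ")\n")
  cat("  cdna:", length(object@cdna), "nt; CDS", object@cdsStart, "-", object@cdsEnd,
      "(", proteinLength(object), "aa );", length(object@exonEnds), "exons\n")
})

## ---------------------------------------------------------------------------
## OrderedSeries
## ---------------------------------------------------------------------------

#' Expression series ordered by mutation position
#'
#' One gene's (mid)ranked expression values over the mutation-bearing
#' patients of a driver gene, ordered by the genomic position of each
#' patient's mutation. This is the object the segmentation engine operates on.
#'
#' @slot values numeric, the ordered (typically midranked) expression values.
#' @slot labels character sample ids, parallel to `values`.
#' @slot positions numeric ordering key (genomic mutation positions),
#'   non-decreasing.
#' @slot segmentable logical; `FALSE` when the series is too short to admit
#'   any split under the current minimum segment width.
#' @export
setClass("OrderedSeries",
  representation(values = "numeric", labels = "character",
                 positions = "numeric", segmentable = "logical"))

setValidity("OrderedSeries", function(object) {
  n <- length(object@values)
  if (length(object@labels) != n || length(object@positions) != n)
    return("values, labels, positions must have equal length")
  if (n > 1L && any(diff(object@positions) < 0))
    return("positions must be non-decreasing")
  if (any(!is.finite(object@values)))
    return("values must be finite")
  TRUE
})

#' Construct an OrderedSeries
#' @param values,labels,positions parallel vectors; see
#'   [OrderedSeries-class].
#' @param segmentable logical flag.
#' @return An [OrderedSeries-class] object.
#' @export
OrderedSeries <- function(values, labels = as.character(seq_along(values)),
                          positions = seq_along(values), segmentable = TRUE) {
  new("OrderedSeries", values = as.numeric(values), labels = as.character(labels),
      positions = as.numeric(positions), segmentable = segmentable)
}

setMethod("show", "OrderedSeries", function(object) {
  cat("OrderedSeries of length", length(object@values),
      if (!object@segmentable) "(flagged unsegmentable)" else "", "\n")
})

setMethod("length", "OrderedSeries", function(x) length(x@values))

## ---------------------------------------------------------------------------
## SegmentationParams
## ---------------------------------------------------------------------------

#' Parameters of the segmentation procedure
#'
#' @slot alpha split-acceptance threshold on the permutation p-value.
#' @slot nperm number of random permutations per tested split.
#' @slot minWidth strict minimum width of every piece produced by a split.
#' @slot seed integer seed governing the permutation stream.
#' @slot earlyStop logical; stop permuting once the exceedance count already
#'   guarantees p > alpha (accepted splits always complete the full `nperm`,
#'   so recorded split p-values are exact).
#' @export
setClass("SegmentationParams",
  representation(alpha = "numeric", nperm = "integer", minWidth = "integer",
                 seed = "integer", earlyStop = "logical"))

setValidity("SegmentationParams", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (object@nperm < 1L) return("nperm must be positive")
  if (object@alpha * (object@nperm + 1) < 1)
    return("alpha * (nperm + 1) must be >= 1 (p-value resolution)")
  if (object@minWidth < 1L) return("minWidth must be positive")
  TRUE
})

#' Construct segmentation parameters
#'
#' Defaults are the strict settings used for cohort-scale runs: a breakpoint
#' is only accepted when the permutation p-value of the split is at most
#' 0.005, assessed with 20000 permutations, and every resulting segment must
#' contain at least 5 samples.
#'
#' @param alpha split acceptance threshold (default 0.005).
#' @param nperm permutations per tested split (default 20000).
#' @param minWidth minimum segment width (default 5).
#' @param seed integer RNG seed.
#' @param earlyStop see [SegmentationParams-class].
#' @return A [SegmentationParams-class] object.
#' @export
SegmentationParams <- function(alpha = 0.005, nperm = 20000, minWidth = 5,
                               seed = 1, earlyStop = TRUE) {
  new("SegmentationParams", alpha = alpha, nperm = as.integer(nperm),
      minWidth = as.integer(minWidth), seed = as.integer(seed),
      earlyStop = earlyStop)
}

setMethod("show", "SegmentationParams", function(object) {
  cat(sprintf("SegmentationParams: alpha=%g nperm=%d minWidth=%d seed=%d earlyStop=%s\n",
              object@alpha, object@nperm, object@minWidth, object@seed,
              object@earlyStop))
})

## ---------------------------------------------------------------------------
## SegmentationResult
## ---------------------------------------------------------------------------

#' Result of segmenting an ordered series
#'
#' @slot segments data.frame with columns `start`, `end`, `mean`; the
#'   segments tile `1..n`.
#' @slot breakpoints sorted integer boundaries (a breakpoint after index k
#'   separates indices k and k+1).
#' @slot splitPvalues permutation p-values of the accepted splits, in the
#'   order the splits were accepted (top-level first).
#' @slot statistic the maximal arc statistic of the top-level scan.
#' @slot n series length.
#' @export
setClass("SegmentationResult",
  representation(segments = "data.frame", breakpoints = "integer",
                 splitPvalues = "numeric", statistic = "numeric", n = "integer"))

setValidity("SegmentationResult", function(object) {
  seg <- object@segments
  n <- object@n
  if (nrow(seg) == 0L) return("at least one segment required")
  if (seg$start[1] != 1L || seg$end[nrow(seg)] != n) return("segments must tile 1..n")
  if (nrow(seg) > 1L && any(seg$start[-1] != seg$end[-nrow(seg)] + 1L))
    return("segments must be contiguous")
  if (length(object@breakpoints) != nrow(seg) - 1L)
    return("number of breakpoints must equal number of segments - 1")
  if (length(object@breakpoints) > 1L && any(diff(object@breakpoints) <= 0L))
    return("breakpoints must be strictly increasing")
  TRUE
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult:", nrow(object@segments), "segment(s),",
      length(object@breakpoints), "breakpoint(s)\n")
  if (length(object@breakpoints))
    cat("  breakpoints after indices:", paste(object@breakpoints, collapse = ", "),
        "\n  split p-values:", paste(signif(object@splitPvalues, 3), collapse = ", "), "\n")
})

#' @describeIn SegmentationResult-class breakpoint indices of a result
#' @param x a `SegmentationResult`.
#' @export
breakpoints <- function(x) x@breakpoints

#' @describeIn SegmentationResult-class segment table of a result
#' @export
segmentTable <- function(x) x@segments

## ---------------------------------------------------------------------------
## Cohort
## ---------------------------------------------------------------------------

#' A harmonizable tumour cohort
#'
#' Bundles the three cohort tables: somatic mutations (long format, one row
#' per variant call), a normalized expression matrix held in a
#' [SummarizedExperiment::SummarizedExperiment], and a clinical table with
#' disease-free survival.
#'
#' @slot mutations data.frame with the canonical mutation columns
#'   (`sample_id`, `gene`, `genomic_position`, `cdna_position`,
#'   `variant_class`, `ref_allele`, `alt_allele`, `protein_change`).
#' @slot expression `SummarizedExperiment` with one assay `"expr"`.
#' @slot clinical data.frame with `sample_id`, `dfs_months`, `dfs_event`.
#' @export
setClass("Cohort",
  representation(mutations = "data.frame", expression = "ANY",
                 clinical = "data.frame"))

setValidity("Cohort", function(object) {
  m <- object@mutations
  miss <- setdiff(.MUTATION_COLUMNS, names(m))
  if (length(miss))
    return(paste("mutations missing columns:", paste(miss, collapse = ", ")))
  if (nrow(m) && any(!m$variant_class %in% VARIANT_CLASSES))
    return("unknown variant_class value in mutations")
  if (nrow(m) && any(m$genomic_position < 1, na.rm = TRUE))
    return("genomic_position must be >= 1")
  if (nrow(m) && any(m$ref_allele == "-" & m$alt_allele == "-"))
    return("ref and alt alleles must not both be '-'")
  ex <- object@expression
  if (!is(ex, "SummarizedExperiment")) return("expression must be a SummarizedExperiment")
  v <- SummarizedExperiment::assay(ex, "expr")
  if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
    return("duplicate gene or sample ids in expression")
  if (any(!is.finite(v)) || any(v < 0))
    return("expression values must be finite and non-negative")
  cl <- object@clinical
  if (nrow(cl)) {
    if (!all(c("sample_id", "dfs_months", "dfs_event") %in% names(cl)))
      return("clinical must have sample_id, dfs_months, dfs_event")
    if (any(cl$dfs_months < 0)) return("dfs_months must be >= 0")
  }
  TRUE
})

#' Construct a Cohort
#'
#' @param mutations data.frame of mutation records (canonical columns).
#' @param expression numeric matrix (genes x samples, dimnames required) or a
#'   `SummarizedExperiment` with assay `"expr"`.
#' @param clinical optional data.frame (`sample_id`, `dfs_months`,
#'   `dfs_event`).
#' @return A [Cohort-class] object.
#' @export
Cohort <- function(mutations, expression, clinical = NULL) {
  if (is.matrix(expression)) {
    expression <- SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = expression))
  }
  if (is.null(clinical))
    clinical <- data.frame(sample_id = character(0), dfs_months = numeric(0),
                           dfs_event = logical(0))
  new("Cohort", mutations = as.data.frame(mutations), expression = expression,
      clinical = as.data.frame(clinical))
}

setMethod("show", "Cohort", function(object) {
  v <- SummarizedExperiment::assay(object@expression, "expr")
  cat("Cohort:", nrow(object@mutations), "mutation records;",
      nrow(v), "genes x", ncol(v), "samples;",
      nrow(object@clinical), "clinical records\n")
})

#' @describeIn Cohort-class mutation table accessor
#' @param x a `Cohort`.
#' @export
mutations <- function(x) x@mutations

#' @describeIn Cohort-class expression matrix accessor (genes x samples)
#' @export
expressionMatrix <- function(x) SummarizedExperiment::assay(x@expression, "expr")

#' @describeIn Cohort-class clinical table accessor
#' @export
clinical <- function(x) x@clinical

## ---------------------------------------------------------------------------
## ProteinConsequence
## ---------------------------------------------------------------------------

#' Predicted protein-level consequence of a coding variant
#'
#' @slot frameShift integer 0, 1 (+1 frame) or -1.
#' @slot consequenceClass one of [CONSEQUENCE_CLASSES].
#' @slot firstAlteredResidue first codon whose translation differs from wild
#'   type (NA when not applicable).
#' @slot mutantLength mutant ORF length in residues (NA for noncoding /
#'   no-stop).
#' @slot novelCtermLength residues beyond the wild-type length (extensions).
#' @slot alteredOriginalResidues wild-type C-terminal residues replaced
#'   (extensions): `wtLength - firstAlteredResidue + 1`.
#' @slot proteinChange HGVS-like label, e.g. `"p.P409fs"`; for frameshifts the
#'   residue index is the codon containing the first inserted or shifted
#'   nucleotide, matching common annotation practice even when that codon's
#'   translation is coincidentally preserved.
#' @slot wtLength wild-type protein length.
#' @export
setClass("ProteinConsequence",
  representation(frameShift = "integer", consequenceClass = "character",
                 firstAlteredResidue = "integer", mutantLength = "integer",
                 novelCtermLength = "integer", alteredOriginalResidues = "integer",
                 proteinChange = "character", wtLength = "integer"))

setValidity("ProteinConsequence", function(object) {
  if (!object@consequenceClass %in% CONSEQUENCE_CLASSES)
    return("unknown consequence class")
  if (!object@frameShift %in% c(0L, 1L, -1L)) return("frameShift must be 0, 1 or -1")
  cl <- object@consequenceClass
  if (cl == "frameshift_extension") {
    if (!(object@mutantLength > object@wtLength))
      return("extension requires mutantLength > wtLength")
    if (object@novelCtermLength != object@mutantLength - object@wtLength)
      return("novelCtermLength inconsistent")
  }
  if (cl == "frameshift_truncation" && !(object@mutantLength < object@wtLength))
    return("truncation requires mutantLength < wtLength")
  if (cl %in% c("in_frame", "missense", "nonsense", "silent") && object@frameShift != 0L)
    return("frame must be 0 for in-frame classes")
  TRUE
})

setMethod("show", "ProteinConsequence", function(object) {
  cat(sprintf("ProteinConsequence %s: %s (frame %+d)\n", object@proteinChange,
              object@consequenceClass, object@frameShift))
  if (!is.na(object@mutantLength))
    cat(sprintf("  wt %d aa -> mutant %d aa", object@wtLength, object@mutantLength),
        if (!is.na(object@novelCtermLength))
          sprintf("(+%d novel C-terminal aa)", object@novelCtermLength) else "", "\n")
})

#' @describeIn ProteinConsequence-class consequence class accessor
#' @param x a `ProteinConsequence`.
#' @export
consequenceClass <- function(x) x@consequenceClass

## ---------------------------------------------------------------------------
## ResponseGeneScan
## ---------------------------------------------------------------------------

#' Result of a transcriptome-wide response-gene scan
#'
#' @slot table data.frame with one row per called response gene: `gene`,
#'   `n_breakpoints`, list-columns `breakpoint_indices` and
#'   `breakpoint_coords`, and `top_split_p`.
#' @slot driver driver gene scanned against.
#' @slot nTested,nCalled,nSkipped gene counts: segmented, called (>= 1
#'   breakpoint), skipped by the expressed filter.
#' @slot nSamples number of single-mutation patients used.
#' @slot params the [SegmentationParams-class] used.
#' @export
setClass("ResponseGeneScan",
  representation(table = "data.frame", driver = "character", nTested = "integer",
                 nCalled = "integer", nSkipped = "integer", nSamples = "integer",
                 params = "SegmentationParams"))

setMethod("show", "ResponseGeneScan", function(object) {
  cat("ResponseGeneScan for driver", object@driver, ":\n")
  cat(sprintf("  %d samples; %d genes segmented, %d skipped (expressed filter), %d response genes\n",
              object@nSamples, object@nTested, object@nSkipped, object@nCalled))
})

#' @describeIn ResponseGeneScan-class response-gene table accessor
#' @param x a `ResponseGeneScan`.
#' @export
responseGenes <- function(x) x@table

## ---------------------------------------------------------------------------
## SyntheticCohort
## ---------------------------------------------------------------------------

#' Simulated cohort with retained ground truth
#'
#' @slot cohort the emitted [Cohort-class].
#' @slot truth list of ground-truth tables (see [simulateCohort()]).
#' @slot config the generating configuration.
#' @export
setClass("SyntheticCohort",
  representation(cohort = "Cohort", truth = "list", config = "list"))

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort (seed", object@config$seed, ")\n  ")
  show(object@cohort)
  cat("  true boundary ordinal:", object@truth$boundary_ordinal, "; response genes:",
      sum(object@truth$genes$is_response), "\n")
})

#' @describeIn SyntheticCohort-class extract the emitted cohort
#' @param x a `SyntheticCohort`.
#' @export
cohort <- function(x) x@cohort

#' @describeIn SyntheticCohort-class extract the ground truth list
#' @export
groundTruth <- function(x) x@truth
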