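## Readers, writers and filtering rules for the three cohort tables and for
## transcript models. All readers tolerate gzip (connections are opened with
## gzfile, which reads plain text transparently).

.MAF_CLASS_MAP <- c(
  "Silent"             = "silent",
  "Missense_Mutation"  = "missense",
  "Nonsense_Mutation"  = "nonsense",
  "Frame_Shift_Ins"    = "frameshift_ins",
  "Frame_Shift_Del"    = "frameshift_del",
  "In_Frame_Ins"       = "inframe_indel",
  "In_Frame_Del"       = "inframe_indel",
  "Splice_Site"        = "splice",
  "Splice_Region"      = "splice",
  "RNA"                = "rna")

.MAF_CLASS_WRITE <- c(
  silent = "Silent", missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
  frameshift_ins = "Frame_Shift_Ins", frameshift_del = "Frame_Shift_Del",
  inframe_indel = "In_Frame_Ins", splice = "Splice_Site", rna = "RNA",
  other = "Unknown")

.readTsv <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  # gzfile() reads plain files transparently; read.delim closes it
  utils::read.delim(gzfile(path), stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# parse simple HGVS cDNA strings: c.1006insG / c.1005delG / c.1006G>A
.parseHgvsc <- function(x) {
  pos <- suppressWarnings(as.integer(sub("^c\\.(\\d+).*$", "\\1", x)))
  pos[!grepl("^c\\.\\d+", x)] <- NA_integer_
  pos
}

#' Read somatic mutation records
#'
#' Two dialects are supported. `"maf"` expects the TCGA MAF column names
#' (`Hugo_Symbol`, `Variant_Classification`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`, `Tumor_Sample_Barcode`, and
#' optionally `HGVSp_Short` and `HGVSc`); `"simple_tsv"` expects the
#' canonical internal columns directly. Variant classifications are mapped
#' onto the internal vocabulary; unknown classes are kept as `"other"` with
#' a warning, never silently dropped.
#'
#' @param path TSV file (optionally gzipped).
#' @param dialect `"maf"` or `"simple_tsv"`.
#' @return data.frame of mutation records with the canonical columns.
#' @export
readMutations <- function(path, dialect = c("maf", "simple_tsv")) {
  dialect <- match.arg(dialect)
  d <- .readTsv(path)
  if (dialect == "maf") {
    req <- c("Hugo_Symbol", "Variant_Classification", "Start_Position",
             "Reference_Allele", "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")
    miss <- setdiff(req, names(d))
    if (length(miss))
      stop(sprintf("mutation file format error: missing column(s) %s",
                   paste(miss, collapse = ", ")))
    pos <- suppressWarnings(as.integer(d$Start_Position))
    bad <- which(is.na(pos) & nzchar(as.character(d$Start_Position)))
    if (length(bad))
      stop(sprintf("unparseable Start_Position at row %d", bad[1]))
    vc <- unname(.MAF_CLASS_MAP[as.character(d$Variant_Classification)])
    unknown <- unique(d$Variant_Classification[is.na(vc)])
    if (length(unknown))
      warning(sprintf("unknown variant classification(s) mapped to 'other': %s",
                      paste(unknown, collapse = ", ")))
    vc[is.na(vc)] <- "other"
    out <- data.frame(
      sample_id = as.character(d$Tumor_Sample_Barcode),
      gene = as.character(d$Hugo_Symbol),
      genomic_position = pos,
      cdna_position = if ("HGVSc" %in% names(d)) .parseHgvsc(d$HGVSc)
                      else rep(NA_integer_, nrow(d)),
      variant_class = vc,
      ref_allele = as.character(d$Reference_Allele),
      alt_allele = as.character(d$Tumor_Seq_Allele2),
      protein_change = if ("HGVSp_Short" %in% names(d))
        as.character(d$HGVSp_Short) else rep(NA_character_, nrow(d)),
      stringsAsFactors = FALSE)
  } else {
    miss <- setdiff(.MUTATION_COLUMNS, names(d))
    if (length(miss))
      stop(sprintf("mutation file format error: missing column(s) %s",
                   paste(miss, collapse = ", ")))
    pos <- suppressWarnings(as.integer(d$genomic_position))
    bad <- which(is.na(pos) & nzchar(as.character(d$genomic_position)))
    if (length(bad))
      stop(sprintf("unparseable genomic_position at row %d", bad[1]))
    vc <- as.character(d$variant_class)
    unknown <- unique(vc[!vc %in% VARIANT_CLASSES])
    if (length(unknown)) {
      warning(sprintf("unknown variant class(es) mapped to 'other': %s",
                      paste(unknown, collapse = ", ")))
      vc[!vc %in% VARIANT_CLASSES] <- "other"
    }
    out <- data.frame(
      sample_id = as.character(d$sample_id),
      gene = as.character(d$gene),
      genomic_position = pos,
      cdna_position = suppressWarnings(as.integer(d$cdna_position)),
      variant_class = vc,
      ref_allele = as.character(d$ref_allele),
      alt_allele = as.character(d$alt_allele),
      protein_change = as.character(d$protein_change),
      stringsAsFactors = FALSE)
  }
  out
}

#' Write mutation records
#'
#' @param records canonical mutation data.frame.
#' @param path output TSV path.
#' @param dialect `"maf"` writes TCGA MAF column names (with `HGVSc` built
#'   from `cdna_position`, `ref_allele`, `alt_allele`); `"simple_tsv"`
#'   writes the canonical columns (lossless round trip through
#'   [readMutations()]).
#' @return `path`, invisibly.
#' @export
writeMutations <- function(records, path, dialect = c("maf", "simple_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "simple_tsv") {
    out <- records[, .MUTATION_COLUMNS]
  } else {
    hgvsc <- ifelse(is.na(records$cdna_position), "",
             ifelse(records$ref_allele == "-",
                    sprintf("c.%dins%s", records$cdna_position, records$alt_allele),
             ifelse(records$alt_allele == "-",
                    sprintf("c.%ddel%s", records$cdna_position, records$ref_allele),
                    sprintf("c.%d%s>%s", records$cdna_position,
                            records$ref_allele, records$alt_allele))))
    out <- data.frame(
      Hugo_Symbol = records$gene,
      Chromosome = "10",
      Start_Position = records$genomic_position,
      End_Position = records$genomic_position +
        ifelse(records$ref_allele == "-", 0L, nchar(records$ref_allele) - 1L),
      Variant_Classification = unname(.MAF_CLASS_WRITE[records$variant_class]),
      Reference_Allele = records$ref_allele,
      Tumor_Seq_Allele2 = records$alt_allele,
      Tumor_Sample_Barcode = records$sample_id,
      HGVSc = hgvsc,
      HGVSp_Short = ifelse(is.na(records$protein_change), "", records$protein_change),
      stringsAsFactors = FALSE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop mutation classes from a record set
#'
#' The cohort analyses remove silent mutations before any position/expression
#' pairing; for METABRIC-style cohorts noncoding substitution variants marked
#' as RNA are removed as well. Input order is preserved; an empty drop set is
#' the identity.
#'
#' @param records canonical mutation data.frame.
#' @param drop character vector of variant classes to remove (default
#'   `"silent"`; METABRIC mode uses `c("silent", "rna")`).
#' @return The records whose class is not in `drop`.
#' @export
filterMutations <- function(records, drop = "silent") {
  if (!length(drop)) return(records)
  bad <- setdiff(drop, VARIANT_CLASSES)
  if (length(bad)) stop(sprintf("unknown variant class in drop set: %s",
                                paste(bad, collapse = ", ")))
  records[!records$variant_class %in% drop, , drop = FALSE]
}

#' Patients with exactly one retained mutation in a gene
#'
#' Patients carrying more than one mutation in the gene of interest are
#' eliminated from the position/expression analysis; this returns the
#' remaining ones. Apply [filterMutations()] first so dropped classes do not
#' count.
#'
#' @param records canonical mutation data.frame (already class-filtered).
#' @param gene gene symbol.
#' @return data.frame of one record per retained sample (the sample's single
#'   mutation in `gene`); empty (with a message) when the gene is absent.
#' @export
singleMutationPatients <- function(records, gene) {
  g <- records[records$gene == gene, , drop = FALSE]
  if (!nrow(g)) {
    message(sprintf("singleMutationPatients: no mutations found for gene %s", gene))
    return(g)
  }
  counts <- table(g$sample_id)
  keep <- names(counts)[counts == 1L]
  g[g$sample_id %in% keep, , drop = FALSE]
}

#' Harmonize cohort sample identifiers
#'
#' Intersects mutation and clinical sample ids with the expression sample
#' ids, after an optional prefix-truncation rule for TCGA-style long
#' barcodes (default: first 15 characters, the sample-level prefix). Dropped
#' ids are reported via `message()`.
#'
#' @param x a [Cohort-class].
#' @param truncateBarcodes integer prefix length applied to all sample ids
#'   before matching, or `NULL` for exact matching. Default `15L`.
#' @return The harmonized [Cohort-class]; a hard error if no samples
#'   overlap.
#' @export
harmonizeCohort <- function(x, truncateBarcodes = 15L) {
  m <- x@mutations
  cl <- x@clinical
  ex <- expressionMatrix(x)
  trunc <- function(ids) if (is.null(truncateBarcodes)) ids
           else substr(ids, 1L, truncateBarcodes)
  exIds <- trunc(colnames(ex))
  keepCols <- !duplicated(exIds)
  ex <- ex[, keepCols, drop = FALSE]
  colnames(ex) <- exIds[keepCols]
  m$sample_id <- trunc(m$sample_id)
  if (nrow(cl)) cl$sample_id <- trunc(cl$sample_id)

  inExpr <- unique(m$sample_id) %in% colnames(ex)
  if (nrow(m) && !any(m$sample_id %in% colnames(ex)))
    stop("harmonizeCohort: no mutation sample ids overlap expression sample ids")
  dropM <- sum(!m$sample_id %in% colnames(ex))
  dropC <- if (nrow(cl)) sum(!cl$sample_id %in% colnames(ex)) else 0L
  if (dropM) message(sprintf("harmonizeCohort: dropped %d mutation record(s) without expression", dropM))
  if (dropC) message(sprintf("harmonizeCohort: dropped %d clinical record(s) without expression", dropC))
  m <- m[m$sample_id %in% colnames(ex), , drop = FALSE]
  if (nrow(cl)) cl <- cl[cl$sample_id %in% colnames(ex), , drop = FALSE]
  Cohort(m, ex, cl)
}

#' Read a normalized expression matrix
#'
#' First column gene id, header row of sample ids.
#' @param path TSV file (optionally gzipped).
#' @return Numeric matrix, genes x samples.
#' @export
readExpression <- function(path) {
  d <- .readTsv(path)
  genes <- as.character(d[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression file")
  v <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- genes
  if (anyDuplicated(colnames(v))) stop("duplicate sample ids in expression file")
  if (any(!is.finite(v)) || any(v < 0))
    stop("expression values must be finite and non-negative")
  v
}

#' Write an expression matrix
#' @param mat genes x samples matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(mat, path) {
  d <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table with disease-free survival
#'
#' Expects `sample_id`, `dfs_months` (alias `dfs_time` accepted) and
#' `dfs_event` (logical or 0/1).
#' @param path TSV file (optionally gzipped).
#' @return data.frame with sample_id, dfs_months, dfs_event.
#' @export
readClinical <- function(path) {
  d <- .readTsv(path)
  if (!"dfs_months" %in% names(d) && "dfs_time" %in% names(d))
    names(d)[names(d) == "dfs_time"] <- "dfs_months"
  miss <- setdiff(c("sample_id", "dfs_months", "dfs_event"), names(d))
  if (length(miss))
    stop(sprintf("clinical file format error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  out <- data.frame(sample_id = as.character(d$sample_id),
                    dfs_months = as.numeric(d$dfs_months),
                    dfs_event = as.logical(d$dfs_event),
                    stringsAsFactors = FALSE)
  if (any(out$dfs_months < 0, na.rm = TRUE)) stop("dfs_months must be >= 0")
  out
}

#' Write a clinical table
#' @param clin data.frame with sample_id, dfs_months, dfs_event.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(clin, path) {
  write.table(clin[, c("sample_id", "dfs_months", "dfs_event")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript models from FASTA plus a TSV sidecar
#'
#' The sidecar has columns `transcript_id`, `gene`, `cds_start`, `cds_end`,
#' `exon_ends` (comma-separated transcript positions); FASTA record names
#' must match `transcript_id`.
#'
#' @param fasta FASTA file of spliced cDNA sequences.
#' @param sidecar TSV sidecar path.
#' @return A list of [TranscriptModel-class] objects, named by transcript id.
#' @export
readTranscriptModels <- function(fasta, sidecar) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sc <- .readTsv(sidecar)
  miss <- setdiff(c("transcript_id", "gene", "cds_start", "cds_end", "exon_ends"),
                  names(sc))
  if (length(miss))
    stop(sprintf("transcript sidecar format error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  out <- lapply(seq_len(nrow(sc)), function(r) {
    id <- as.character(sc$transcript_id[r])
    if (!id %in% names(seqs))
      stop(sprintf("transcript %s not found in FASTA", id))
    TranscriptModel(gene = as.character(sc$gene[r]), transcriptId = id,
                    cdna = as.character(seqs[[id]]),
                    cdsStart = sc$cds_start[r], cdsEnd = sc$cds_end[r],
                    exonEnds = as.integer(strsplit(as.character(sc$exon_ends[r]),
                                                   ",")[[1]]))
  })
  names(out) <- as.character(sc$transcript_id)
  out
}

#' Write a transcript model to FASTA plus sidecar
#' @param t a [TranscriptModel-class].
#' @param fasta,sidecar output paths.
#' @return `fasta`, invisibly.
#' @export
writeTranscriptModel <- function(t, fasta, sidecar) {
  seq <- Biostrings::DNAStringSet(as.character(t@cdna))
  names(seq) <- t@transcriptId
  Biostrings::writeXStringSet(seq, fasta)
  write.table(data.frame(transcript_id = t@transcriptId, gene = t@gene,
                         cds_start = t@cdsStart, cds_end = t@cdsEnd,
                         exon_ends = paste(t@exonEnds, collapse = ",")),
              sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta)
}
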