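## Orchestration of the two cohort analyses (response-gene scan;
## extension-vs-other group analysis) plus simulation and per-mutation
## classification, each reading/writing plain TSV/JSON. A thin command-line
## wrapper over these functions ships in inst/scripts/mutseg-cli.R.

.pkgVersion <- function() as.character(utils::packageVersion("mutseg"))

.inputHashes <- function(paths) {
  paths <- as.character(unlist(paths))
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}

.writeRunSummary <- function(out, cmd, config, counts, seed) {
  summary <- list(tool = "mutseg", version = .pkgVersion(), command = cmd,
                  seed = seed, parameters = config, counts = counts,
                  input_md5 = .inputHashes(config[c("mutations", "expression",
                                                    "clinical", "transcript_fasta",
                                                    "transcript_tsv")]))
  jsonlite::write_json(summary, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.requireFile <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("%s file not found: %s", what,
                 if (is.null(path)) "(not set)" else path))
  path
}

# load + filter + harmonize a cohort per dialect
.loadCohort <- function(config) {
  dialect <- match.arg(config$dialect %||% "tcga", c("tcga", "metabric"))
  muts <- readMutations(.requireFile(config$mutations, "mutations"),
                        dialect = config$mutation_dialect %||% "maf")
  nRead <- nrow(muts)
  drop <- if (dialect == "metabric") c("silent", "rna") else "silent"
  muts <- filterMutations(muts, drop)
  message(sprintf("loaded %d mutation record(s); %d after dropping {%s}",
                  nRead, nrow(muts), paste(drop, collapse = ", ")))
  expr <- readExpression(.requireFile(config$expression, "expression"))
  clin <- if (!is.null(config$clinical)) readClinical(config$clinical) else NULL
  co <- harmonizeCohort(Cohort(muts, expr, clin),
                        truncateBarcodes = config$truncate_barcodes %||% 15L)
  list(cohort = co, n_read = nRead, n_filtered = nrow(muts), dropped_classes = drop)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.segParams <- function(config) {
  SegmentationParams(alpha = config$alpha %||% 0.005,
                     nperm = config$nperm %||% 20000,
                     minWidth = config$min_width %||% 5,
                     seed = config$seed %||% 1)
}

#' Run the response-gene scan
#'
#' Orchestrates cohort loading, mutation filtering (silent; plus RNA for
#' the METABRIC dialect), harmonization, the transcriptome scan and the
#' density summaries. Writes `response_genes.tsv`, `densities.tsv` and
#' `run_summary.json` into `config$out`.
#'
#' @param config named list: `mutations`, `expression`, optional `clinical`,
#'   `driver`, `dialect` ("tcga"/"metabric"), `alpha`, `nperm`, `min_width`,
#'   `seed`, `expressed_fraction`, optional `signature` (file with one gene
#'   per line), `out`.
#' @return The [ResponseGeneScan-class], invisibly.
#' @export
runScan <- function(config) {
  out <- config$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  loaded <- .loadCohort(config)
  co <- loaded$cohort
  params <- .segParams(config)
  scan <- scanTranscriptome(co, config$driver, params,
                            expressedFraction = config$expressed_fraction %||% 0.2)

  tab <- scan@table
  flat <- data.frame(gene = tab$gene, n_breakpoints = tab$n_breakpoints,
                     breakpoint_coords = vapply(tab$breakpoint_coords,
                                                function(v) paste(v, collapse = ","), character(1)),
                     top_split_p = tab$top_split_p, stringsAsFactors = FALSE)
  write.table(flat, file.path(out, "response_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  single <- singleMutationPatients(mutations(co), config$driver)
  span <- range(single$genomic_position)
  if (diff(span) == 0) span <- span + c(-1, 1)
  bd <- breakpointDensity(scan, span)
  md <- mutationDensity(single$genomic_position, span)
  write.table(data.frame(grid = bd$grid, density_single = bd$density_single,
                         density_multi = bd$density_multi,
                         density_mutations = md$density),
              file.path(out, "densities.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  sigRes <- NULL
  if (!is.null(config[["signature"]])) {
    sigGenes <- readLines(config[["signature"]])
    sigGenes <- sigGenes[nzchar(sigGenes)]
    sigRes <- signatureScan(co, config$driver, sigGenes, params,
                            expressedFraction = config$expressed_fraction %||% 0.2)
    write.table(sigRes$table, file.path(out, "signature_scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  counts <- list(mutations_read = loaded$n_read,
                 mutations_after_filter = loaded$n_filtered,
                 dropped_classes = loaded$dropped_classes,
                 single_mutation_patients = scan@nSamples,
                 genes_segmented = scan@nTested,
                 genes_skipped_expressed_filter = scan@nSkipped,
                 response_genes = scan@nCalled,
                 signature_called = if (!is.null(sigRes)) sigRes$n_called else NULL)
  .writeRunSummary(out, "scan", config, counts, params@seed)
  invisible(scan)
}

#' Run the mutation-class group analysis
#'
#' Classifies the driver's single-mutation patients by in-silico
#' translation, assigns mutation-class groups, computes extension-vs-other
#' differential statistics and a top-k signature, and compares disease-free
#' survival between the groups by the log-rank test. Writes `groups.tsv`,
#' `differential.tsv`, `signature.tsv`, `survival.json` and
#' `run_summary.json`.
#'
#' @param config named list as for [runScan()], plus optional
#'   `transcript_fasta`/`transcript_tsv` (default: the synthetic GATA3-like
#'   transcript), `signature_k` (default 50), `pseudocount` (default 0).
#' @return List with `groups`, `differential`, `signature`, `survival`,
#'   invisibly.
#' @export
runGroups <- function(config) {
  out <- config$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  loaded <- .loadCohort(config)
  co <- loaded$cohort
  tmod <- if (!is.null(config$transcript_fasta))
    readTranscriptModels(config$transcript_fasta,
                         .requireFile(config$transcript_tsv, "transcript sidecar"))[[1]]
  else gata3SyntheticTranscript()

  single <- singleMutationPatients(mutations(co), config$driver)
  if (!nrow(single))
    stop(sprintf("no single-mutation patients for driver %s", config$driver))
  cons <- classifyMutations(tmod, single,
                            mode = config$classify_mode %||% "retranslate")
  groups <- assignGroups(cons)
  write.table(merge(groups, cons, by = "sample_id"),
              file.path(out, "groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  caseIds <- groups$sample_id[groups$is_case]
  controlIds <- groups$sample_id[!groups$is_case]
  diffTab <- NULL
  sig <- NULL
  if (!length(caseIds)) {
    message("no extension-class (+1) patients: differential stage skipped")
  } else {
    diffTab <- differentialExpression(co, caseIds, controlIds,
                                      pseudocount = config$pseudocount %||% 0)
    write.table(diffTab, file.path(out, "differential.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sig <- deriveSignature(diffTab, k = config$signature_k %||% 50L,
                           sourceCohort = config$dialect %||% "tcga")
    write.table(sig, file.path(out, "signature.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  surv <- NULL
  clin <- clinical(co)
  if (nrow(clin) && length(caseIds) && length(controlIds)) {
    clin <- clin[clin$sample_id %in% groups$sample_id, ]
    grp <- ifelse(clin$sample_id %in% caseIds, "ext_plus1", "other")
    if (any(clin$dfs_event)) {
      surv <- logrankTest(clin$dfs_months, clin$dfs_event, grp)
      jsonlite::write_json(list(chisq = surv$chisq, p_value = surv$p.value,
                                n = surv$n, n_events = as.list(surv$n_events)),
                           file.path(out, "survival.json"), auto_unbox = TRUE,
                           digits = NA)
      kmFlat <- do.call(rbind, lapply(names(surv$km), function(g)
        data.frame(group = g, surv$km[[g]], stringsAsFactors = FALSE)))
      write.table(kmFlat, file.path(out, "km_curves.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    } else message("no events observed: survival stage skipped")
  }

  counts <- list(mutations_read = loaded$n_read,
                 mutations_after_filter = loaded$n_filtered,
                 dropped_classes = loaded$dropped_classes,
                 single_mutation_patients = nrow(single),
                 group_sizes = as.list(table(groups$label)),
                 differential_genes = if (!is.null(diffTab)) nrow(diffTab) else 0L,
                 signature_size = if (!is.null(sig)) nrow(sig) else 0L)
  .writeRunSummary(out, "groups", config, counts, config$seed %||% 1L)
  invisible(list(groups = groups, differential = diffTab, signature = sig,
                 survival = surv))
}

#' Run the per-mutation consequence classification
#'
#' Writes `consequences.tsv` (one row per mutation of the driver gene) and
#' `class_tallies.tsv` (counts by class, frame and exon).
#'
#' @param config named list as for [runGroups()] (expression/clinical not
#'   required; `mutations`, `driver`, `out`).
#' @return The consequence data.frame, invisibly.
#' @export
runClassify <- function(config) {
  out <- config$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  muts <- readMutations(.requireFile(config$mutations, "mutations"),
                        dialect = config$mutation_dialect %||% "maf")
  muts <- muts[muts$gene == config$driver, , drop = FALSE]
  tmod <- if (!is.null(config$transcript_fasta))
    readTranscriptModels(config$transcript_fasta,
                         .requireFile(config$transcript_tsv, "transcript sidecar"))[[1]]
  else gata3SyntheticTranscript()
  cons <- classifyMutations(tmod, muts,
                            mode = config$classify_mode %||% "retranslate")
  write.table(cons, file.path(out, "consequences.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tl <- tallyClasses(muts, tmod)
  write.table(tl$table, file.path(out, "class_tallies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeRunSummary(out, "classify", config,
                   list(mutations = nrow(muts),
                        extension_share_of_frameshifts =
                          tl$extension_share_of_frameshifts),
                   config$seed %||% 1L)
  invisible(cons)
}

#' Simulate a cohort and write it to disk
#'
#' @param config simulation settings understood by [simulationConfig()]
#'   (unknown entries rejected), plus `out` for the output directory.
#' @return The [SyntheticCohort-class], invisibly.
#' @export
runSimulate <- function(config) {
  out <- config$out %||% "."
  config$out <- NULL
  cfg <- do.call(simulationConfig, config)
  sim <- simulateCohort(cfg)
  writeCohort(sim, out)
  .writeRunSummary(out, "simulate", cfg,
                   list(patients = cfg$n_patients,
                        boundary_ordinal = sim@truth$boundary_ordinal,
                        response_genes = cfg$n_response_genes),
                   cfg$seed)
  invisible(sim)
}
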