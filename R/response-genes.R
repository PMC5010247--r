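## Transcriptome-wide response-gene scan: pair one driver gene's ranked
## mutation positions against every expressed gene's ranked expression,
## segment, and summarise breakpoints.

#' Build the ordered series for one (driver, gene) pair
#'
#' Takes the single-mutation patients of the driver, orders them by genomic
#' mutation position (ties broken by sample id, stable) and midranks the
#' gene's normalized expression over exactly those samples.
#'
#' @param x a harmonized [Cohort-class].
#' @param driver driver gene symbol (mutations assumed already
#'   class-filtered).
#' @param gene expression gene to pair against.
#' @param minWidth minimum segment width used only to flag series too short
#'   to segment.
#' @return An [OrderedSeries-class]; `@segmentable` is `FALSE` when fewer
#'   than `2 * minWidth` eligible samples exist.
#' @export
buildSeries <- function(x, driver, gene, minWidth = 5L) {
  single <- singleMutationPatients(mutations(x), driver)
  .buildSeriesFromMap(x, single, gene, minWidth)
}

# internal: series from a precomputed single-mutation record set
.buildSeriesFromMap <- function(x, single, gene, minWidth = 5L) {
  ex <- expressionMatrix(x)
  if (!gene %in% rownames(ex))
    stop(sprintf("gene %s not present in expression matrix", gene))
  ord <- order(single$genomic_position, single$sample_id)
  ids <- single$sample_id[ord]
  vals <- midrank(as.numeric(ex[gene, ids]))
  OrderedSeries(values = vals, labels = ids,
                positions = single$genomic_position[ord],
                segmentable = length(ids) >= 2L * minWidth)
}

#' Map a breakpoint index to a genomic coordinate
#'
#' The boundary after ordered sample k is placed at the midpoint of the
#' flanking mutation positions; for tied positions this is the shared
#' position itself.
#'
#' @param series an [OrderedSeries-class].
#' @param k breakpoint index, `1 <= k < length(series)` (may be a vector).
#' @return Numeric genomic coordinate(s).
#' @export
mapBreakpoint <- function(series, k) {
  n <- length(series@positions)
  if (any(k < 1L | k >= n)) stop("mapBreakpoint: k out of range")
  (series@positions[k] + series@positions[k + 1L]) / 2
}

#' Scan the transcriptome for response genes
#'
#' Segments every expressed gene's ordered series against the driver's
#' mutation positions; genes with at least one accepted breakpoint are
#' called response genes. The expressed-gene filter (configurable) requires
#' nonzero normalized expression in at least `expressedFraction` of the
#' mutation-bearing samples. Per-gene permutation seeds are derived
#' deterministically from `params@seed`, so results are reproducible
#' bit-for-bit.
#'
#' @param x a harmonized [Cohort-class] whose mutations are already
#'   class-filtered.
#' @param driver driver gene symbol.
#' @param params a [SegmentationParams-class].
#' @param genes genes to scan (default: all rows of the expression matrix).
#' @param expressedFraction expressed-gene filter threshold (default 0.2).
#' @return A [ResponseGeneScan-class].
#' @export
scanTranscriptome <- function(x, driver, params = SegmentationParams(),
                              genes = NULL, expressedFraction = 0.2) {
  single <- singleMutationPatients(mutations(x), driver)
  if (!nrow(single))
    stop(sprintf("scanTranscriptome: no eligible mutation-bearing samples for driver %s",
                 driver))
  ex <- expressionMatrix(x)
  if (is.null(genes)) genes <- rownames(ex)
  ids <- single$sample_id

  recs <- list()
  nTested <- 0L
  nSkipped <- 0L
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    v <- as.numeric(ex[g, ids])
    if (mean(v > 0) < expressedFraction) {
      nSkipped <- nSkipped + 1L
      next
    }
    nTested <- nTested + 1L
    series <- .buildSeriesFromMap(x, single, g, params@minWidth)
    if (!series@segmentable) next
    gp <- params
    gp@seed <- .stageSeed(params@seed, gi)
    res <- segmentSeries(series, gp)
    if (length(res@breakpoints)) {
      recs[[length(recs) + 1L]] <- data.frame(
        gene = g,
        n_breakpoints = length(res@breakpoints),
        breakpoint_indices = I(list(res@breakpoints)),
        breakpoint_coords = I(list(mapBreakpoint(series, res@breakpoints))),
        top_split_p = res@splitPvalues[1],
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(0), n_breakpoints = integer(0),
               breakpoint_indices = I(list()), breakpoint_coords = I(list()),
               top_split_p = numeric(0))
  new("ResponseGeneScan", table = tab, driver = driver,
      nTested = nTested, nCalled = nrow(tab), nSkipped = nSkipped,
      nSamples = nrow(single), params = params)
}

# direct Gaussian kernel density (no FFT binning), evaluated on a grid
.gaussKde <- function(x, grid, bw) {
  if (!length(x)) return(rep(0, length(grid)))
  rowMeans(dnorm(outer(grid, x, "-") / bw)) / bw
}

# Silverman bandwidth with a floor of `floorFrac` of the span
.kdeBandwidth <- function(x, span, floorFrac = 0.01) {
  floorBw <- floorFrac * diff(span)
  if (length(x) < 2L || sd(x) == 0) return(floorBw)
  max(stats::bw.nrd0(x), floorBw)
}

#' Breakpoint density along the driver gene
#'
#' Gaussian kernel density estimates of breakpoint genomic coordinates,
#' computed separately for single-breakpoint response genes and for genes
#' with two or more breakpoints (the two curves shown in the domain-analysis
#' density panels). A shared Silverman bandwidth (floored at `floorFrac` of
#' the gene span) is used for both.
#'
#' @param scan a [ResponseGeneScan-class] or its table.
#' @param geneSpan numeric `(start, end)` genomic span of the driver gene.
#' @param gridN grid resolution (default 512).
#' @param bw bandwidth in bp, or `NULL` for the Silverman rule.
#' @param floorFrac bandwidth floor as a fraction of the span.
#' @return List with `grid`, `density_single`, `density_multi`, `bandwidth`,
#'   and empty-source flags `empty_single`, `empty_multi` (empty sources
#'   yield zero densities).
#' @export
breakpointDensity <- function(scan, geneSpan, gridN = 512L, bw = NULL,
                              floorFrac = 0.01) {
  tab <- if (is(scan, "ResponseGeneScan")) scan@table else scan
  grid <- seq(geneSpan[1], geneSpan[2], length.out = gridN)
  singleC <- unlist(tab$breakpoint_coords[tab$n_breakpoints == 1L])
  multiC <- unlist(tab$breakpoint_coords[tab$n_breakpoints >= 2L])
  allC <- c(singleC, multiC)
  if (is.null(bw)) bw <- .kdeBandwidth(allC, geneSpan, floorFrac)
  list(grid = grid,
       density_single = .gaussKde(singleC, grid, bw),
       density_multi = .gaussKde(multiC, grid, bw),
       bandwidth = bw,
       empty_single = !length(singleC),
       empty_multi = !length(multiC))
}

#' Mutation-position density along the driver gene
#'
#' Kernel density of the mutation positions themselves, for comparison with
#' the breakpoint densities.
#'
#' @param positions numeric genomic mutation positions.
#' @param geneSpan numeric `(start, end)` span.
#' @param gridN,bw,floorFrac as in [breakpointDensity()].
#' @return List with `grid`, `density`, `bandwidth`, `empty`.
#' @export
mutationDensity <- function(positions, geneSpan, gridN = 512L, bw = NULL,
                            floorFrac = 0.01) {
  grid <- seq(geneSpan[1], geneSpan[2], length.out = gridN)
  if (is.null(bw)) bw <- .kdeBandwidth(positions, geneSpan, floorFrac)
  list(grid = grid, density = .gaussKde(positions, grid, bw),
       bandwidth = bw, empty = !length(positions))
}

#' Scan a gene signature for segmentation
#'
#' Runs the response-gene scan restricted to a supplied signature (for
#' cross-cohort checks of a derived signature). Signature genes absent from
#' the expression matrix are reported as unresolvable and excluded from the
#' denominator.
#'
#' @param x harmonized, class-filtered [Cohort-class].
#' @param driver driver gene symbol.
#' @param signature character vector of gene symbols.
#' @param params a [SegmentationParams-class].
#' @param expressedFraction expressed-gene filter threshold.
#' @return List with `table` (gene, resolvable, called, n_breakpoints),
#'   `n_resolvable`, `n_called`, `unresolved` (character).
#' @export
signatureScan <- function(x, driver, signature, params = SegmentationParams(),
                          expressedFraction = 0.2) {
  signature <- unique(signature)
  if (!length(signature))
    return(list(table = data.frame(gene = character(0), resolvable = logical(0),
                                   called = logical(0), n_breakpoints = integer(0)),
                n_resolvable = 0L, n_called = 0L, unresolved = character(0)))
  ex <- expressionMatrix(x)
  resolvable <- signature %in% rownames(ex)
  if (any(!resolvable))
    message(sprintf("signatureScan: %d/%d signature gene(s) not in expression matrix",
                    sum(!resolvable), length(signature)))
  scan <- scanTranscriptome(x, driver, params, genes = signature[resolvable],
                            expressedFraction = expressedFraction)
  called <- signature %in% scan@table$gene
  nbp <- integer(length(signature))
  m <- match(signature, scan@table$gene)
  nbp[!is.na(m)] <- scan@table$n_breakpoints[m[!is.na(m)]]
  list(table = data.frame(gene = signature, resolvable = resolvable,
                          called = called, n_breakpoints = nbp,
                          stringsAsFactors = FALSE),
       n_resolvable = sum(resolvable),
       n_called = sum(called),
       unresolved = signature[!resolvable])
}
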