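## Synthetic cohort generator. Emits the statistical structure the analysis
## assumes -- hotspot mutation positions with frame labels, step-shift
## response genes over the mutation-position ordering, null genes, and
## group-dependent exponential survival -- with full ground truth retained.
## Classes in the ground truth come from the generator's own stop-trap
## bookkeeping (see R/transcript-gata3.R), not from the consequence
## classifier, so the two can be compared as independent routes.

# first planted shifted-frame stop read by an insertion after CDS position p
.plus1StopAfter <- function(p) {
  s <- .GATA3_PLUS1_STOPS[.GATA3_PLUS1_STOPS >= p + 1L]
  if (!length(s)) NA_integer_ else s[1]
}
.minus1StopAfter <- function(p) {
  s <- .GATA3_MINUS1_STOPS[.GATA3_MINUS1_STOPS >= p + 1L]
  if (!length(s)) NA_integer_ else s[1]
}

# CDS position threshold separating the truncating region from the
# C-terminal extension window of the synthetic driver transcript
.EXT_RAW_MIN <- 1167L

# snap a raw extension-side position onto an allowed insertion point:
# 1184 (the A395-preserving insertion) or a codon boundary in [1185, 1329]
.snapExtPosition <- function(p) {
  if (p < 1186L) return(1184L)
  min(3L * (p %/% 3L), 1329L)
}

#' Configuration for the synthetic cohort simulator
#'
#' Defaults describe the cohort structure the analysis assumes at test
#' scale: 60 patients each carrying a single driver-gene mutation, hotspot
#' position mixtures anchored at the two frameshift hotspots of the
#' synthetic driver transcript (cDNA 1006, truncating; cDNA 1224, the
#' extension hotspot), 5 step-shift response genes among 100, a mean shift
#' of 2 pooled SD at the class boundary, and exponential disease-free
#' survival with a hazard ratio of 3 for the extension group.
#'
#' @param n_patients single-mutation patients to simulate.
#' @param driver driver gene symbol.
#' @param driver_span genomic `(start, end)` of the driver; cDNA positions
#'   map onto it affinely (the synthetic driver is treated as intronless on
#'   the genome).
#' @param hotspots list of `c(position, weight)` point masses on driver cDNA
#'   positions.
#' @param uniform_weight weight of the uniform position component.
#' @param uniform_range cDNA range of the uniform component.
#' @param frame_probs probabilities of frames `+1`, `-1`, `0` for mutations
#'   outside the extension window (the extension window itself carries
#'   +1-frame insertions by construction -- the selection signal under
#'   study).
#' @param true_breakpoint ordinal class boundary (number of non-extension
#'   samples), or `NULL` to let the mixture decide.
#' @param n_response_genes,n_null_genes gene counts.
#' @param effect_size mean shift of response genes in pooled-SD units.
#' @param noise_sd expression noise SD.
#' @param base_expression baseline expression level (kept well above 0 so
#'   the non-negativity of normalized expression is respected).
#' @param baseline_hazard exponential hazard per month for non-case samples.
#' @param hazard_ratio hazard multiplier for the extension (case) group.
#' @param censoring_rate approximate fraction censored (independent
#'   exponential censoring).
#' @param n_multi_mutant contaminant patients with two driver mutations
#'   (excluded by the single-mutation rule; useful for filter tests).
#' @param seed integer master seed.
#' @return Named list of validated settings.
#' @export
simulationConfig <- function(n_patients = 60L, driver = "GATA3",
                             driver_span = c(8096667, 8112317),
                             hotspots = list(c(position = 1006, weight = 0.20),
                                             c(position = 1224, weight = 0.30)),
                             uniform_weight = 0.50,
                             uniform_range = c(250L, 1330L),
                             frame_probs = c(`+1` = 0.60, `-1` = 0.05, `0` = 0.35),
                             true_breakpoint = NULL,
                             n_response_genes = 5L, n_null_genes = 95L,
                             effect_size = 2, noise_sd = 1, base_expression = 10,
                             baseline_hazard = 0.02, hazard_ratio = 3,
                             censoring_rate = 0.4, n_multi_mutant = 0L,
                             seed = 1L) {
  w <- sum(vapply(hotspots, function(h) h[["weight"]], numeric(1))) + uniform_weight
  if (abs(w - 1) > 1e-8) stop("hotspot weights plus uniform_weight must sum to 1")
  if (abs(sum(frame_probs) - 1) > 1e-8) stop("frame_probs must sum to 1")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (n_patients < 10L) stop("n_patients too small to segment")
  if (!is.null(true_breakpoint) &&
      (true_breakpoint < 1L || true_breakpoint >= n_patients))
    stop("true_breakpoint outside 1..(n_patients-1)")
  list(n_patients = as.integer(n_patients), driver = driver,
       driver_span = driver_span, hotspots = hotspots,
       uniform_weight = uniform_weight, uniform_range = uniform_range,
       frame_probs = frame_probs, true_breakpoint = true_breakpoint,
       n_response_genes = as.integer(n_response_genes),
       n_null_genes = as.integer(n_null_genes),
       effect_size = effect_size, noise_sd = noise_sd,
       base_expression = base_expression, baseline_hazard = baseline_hazard,
       hazard_ratio = hazard_ratio, censoring_rate = censoring_rate,
       n_multi_mutant = as.integer(n_multi_mutant), seed = as.integer(seed))
}

# draw one raw cDNA position from the hotspot/uniform mixture
.drawRawPosition <- function(cfg) {
  hw <- vapply(cfg$hotspots, function(h) h[["weight"]], numeric(1))
  comp <- sample.int(length(hw) + 1L, 1L, prob = c(hw, cfg$uniform_weight))
  if (comp <= length(hw)) as.integer(cfg$hotspots[[comp]][["position"]])
  else as.integer(round(runif(1, cfg$uniform_range[1], cfg$uniform_range[2])))
}

# build one mutation (position, alleles, frame, truth class) for a patient;
# side: NA = let the mixture decide, TRUE = extension side, FALSE = other
.drawMutation <- function(cfg, cds, wtProt, side = NA) {
  repeat {
    raw <- .drawRawPosition(cfg)
    isExt <- raw >= .EXT_RAW_MIN
    if (is.na(side) || isExt == side) break
  }
  W <- nchar(wtProt)
  if (isExt) {
    p <- .snapExtPosition(raw)
    frame <- 1L
    ref <- "-"; alt <- "G"
    s <- .plus1StopAfter(p)
    cls <- if (s / 3L > W) "frameshift_extension" else "frameshift_truncation"
    vclass <- "frameshift_ins"
    labCodon <- as.integer(ceiling((p + 1L) / 3))
    label <- sprintf("p.%s%dfs", substr(wtProt, labCodon, labCodon), labCodon)
  } else {
    p <- min(max(raw, 4L), 1166L)
    frame <- sample(c(1L, -1L, 0L), 1L, prob = cfg$frame_probs)
    if (frame == 1L) {
      ref <- "-"; alt <- "G"
      s <- .plus1StopAfter(p)
      cls <- if (s / 3L > W) "frameshift_extension" else "frameshift_truncation"
      vclass <- "frameshift_ins"
      labCodon <- as.integer(ceiling((p + 1L) / 3))
      label <- sprintf("p.%s%dfs", substr(wtProt, labCodon, labCodon), labCodon)
    } else if (frame == -1L) {
      ref <- substr(cds, p, p); alt <- "-"
      s <- .minus1StopAfter(p)
      cls <- if ((s + 1L) / 3L - 1L > W) "frameshift_extension" else "frameshift_truncation"
      vclass <- "frameshift_del"
      labCodon <- as.integer(ceiling(p / 3))
      label <- sprintf("p.%s%dfs", substr(wtProt, labCodon, labCodon), labCodon)
    } else {
      cdn <- as.integer(ceiling(p / 3))
      while (cdn %in% c(1L, 336L, 340L, 370L, 394L, 409L, 430L, 431L, 444L))
        cdn <- cdn + 1L
      p <- 3L * cdn - 2L
      ref <- "G"; alt <- "A"          # GCT -> ACT, always missense (Ala -> Thr)
      cls <- "missense"
      vclass <- "missense"
      label <- sprintf("p.%s%dT", substr(wtProt, cdn, cdn), cdn)
    }
  }
  list(cdna_position = p, frame = frame, class = cls, variant_class = vclass,
       ref = ref, alt = alt, protein_change = label)
}

#' Simulate a cohort with known ground truth
#'
#' Generates, reproducibly from `config$seed`: a mutation table (one
#' driver-gene mutation per patient, plus optional multi-mutant
#' contaminants), an expression matrix in which response genes carry a step
#' shift for extension-class samples (injected on the raw expression scale,
#' so the downstream rank machinery is genuinely exercised) and null genes
#' are pure noise, and a clinical table with exponential disease-free
#' survival scaled by the hazard ratio for the extension group.
#'
#' @param config list from [simulationConfig()].
#' @return A [SyntheticCohort-class]; `groundTruth(x)` holds per-sample
#'   positions/frames/classes/labels, per-gene response flags and
#'   directions, the ordinal class boundary and its genomic image.
#' @export
simulateCohort <- function(config = simulationConfig()) {
  set.seed(config$seed)
  tmod <- gata3SyntheticTranscript()
  cds <- substr(as.character(tmod@cdna), tmod@cdsStart, tmod@cdsEnd)
  wtProt <- translateCdna(cds)$protein
  n <- config$n_patients
  scale <- (config$driver_span[2] - config$driver_span[1]) / length(tmod@cdna)

  sides <- rep(NA, n)
  if (!is.null(config$true_breakpoint))
    sides <- c(rep(FALSE, config$true_breakpoint),
               rep(TRUE, n - config$true_breakpoint))
  muts <- lapply(seq_len(n), function(i) .drawMutation(config, cds, wtProt, sides[i]))

  ids <- sprintf("P%03d", seq_len(n))
  cdnaPos <- vapply(muts, `[[`, integer(1), "cdna_position")
  genomic <- as.integer(round(config$driver_span[1] +
                              (tmod@cdsStart + cdnaPos - 1L) * scale))
  classes <- vapply(muts, `[[`, character(1), "class")
  frames <- vapply(muts, `[[`, integer(1), "frame")
  isExt <- classes == "frameshift_extension" & frames == 1L

  mutTab <- data.frame(
    sample_id = ids, gene = config$driver, genomic_position = genomic,
    cdna_position = cdnaPos,
    variant_class = vapply(muts, `[[`, character(1), "variant_class"),
    ref_allele = vapply(muts, `[[`, character(1), "ref"),
    alt_allele = vapply(muts, `[[`, character(1), "alt"),
    protein_change = vapply(muts, `[[`, character(1), "protein_change"),
    stringsAsFactors = FALSE)

  # contaminant multi-mutant patients (two driver mutations each)
  if (config$n_multi_mutant > 0L) {
    for (j in seq_len(config$n_multi_mutant)) {
      mid <- sprintf("M%03d", j)
      for (r in 1:2) {
        mm <- .drawMutation(config, cds, wtProt)
        mutTab <- rbind(mutTab, data.frame(
          sample_id = mid, gene = config$driver,
          genomic_position = as.integer(round(config$driver_span[1] +
            (tmod@cdsStart + mm$cdna_position - 1L) * scale)),
          cdna_position = mm$cdna_position, variant_class = mm$variant_class,
          ref_allele = mm$ref, alt_allele = mm$alt,
          protein_change = mm$protein_change, stringsAsFactors = FALSE))
      }
    }
  }

  # ordinal ordering of the single-mutation patients and the class boundary
  ord <- order(genomic, ids)
  ordinal <- integer(n)
  ordinal[ord] <- seq_len(n)
  boundary <- sum(!isExt)
  boundaryGenomic <- if (boundary >= 1L && boundary < n) {
    gp <- genomic[ord]
    (gp[boundary] + gp[boundary + 1L]) / 2
  } else NA_real_

  # expression: response genes step-shift for samples past the boundary
  allIds <- unique(mutTab$sample_id)
  nr <- config$n_response_genes
  geneNames <- c(config$driver,
                 if (nr) sprintf("RESP%02d", seq_len(nr)),
                 if (config$n_null_genes) sprintf("NG%03d", seq_len(config$n_null_genes)))
  directions <- if (nr) ifelse(seq_len(nr) %% 2L == 1L, 1L, -1L) else integer(0)
  shift <- config$effect_size * config$noise_sd
  expr <- matrix(rnorm(length(geneNames) * length(allIds),
                       mean = config$base_expression, sd = config$noise_sd),
                 nrow = length(geneNames), ncol = length(allIds),
                 dimnames = list(geneNames, allIds))
  if (nr) {
    caseCols <- match(ids[isExt], allIds)
    for (j in seq_len(nr))
      expr[1L + j, caseCols] <- expr[1L + j, caseCols] + directions[j] * shift
  }
  if (any(expr < 0)) expr[expr < 0] <- 0   # respect non-negativity; vanishing odds at default scale

  # survival: exponential, hazard scaled for the extension group
  isCase <- allIds %in% ids[isExt]
  rate <- config$baseline_hazard * ifelse(isCase, config$hazard_ratio, 1)
  evTime <- rexp(length(allIds), rate)
  censTime <- if (config$censoring_rate <= 0) rep(Inf, length(allIds)) else
    rexp(length(allIds), config$baseline_hazard * config$censoring_rate /
           (1 - config$censoring_rate))
  clin <- data.frame(sample_id = allIds,
                     dfs_months = round(pmin(evTime, censTime), 3),
                     dfs_event = evTime <= censTime,
                     stringsAsFactors = FALSE)

  groupLabel <- ifelse(classes == "frameshift_extension" & frames == 1L, "ext_plus1",
                ifelse(classes == "frameshift_extension" & frames == -1L, "ext_minus1",
                ifelse(classes == "frameshift_truncation" & frames == 1L, "trunc_plus1",
                ifelse(classes == "frameshift_truncation" & frames == -1L, "trunc_minus1",
                       "other_mutant"))))

  truth <- list(
    samples = data.frame(sample_id = ids, cdna_position = cdnaPos,
                         genomic_position = genomic, frame = frames,
                         class = classes, group_label = groupLabel,
                         is_case = isExt, ordinal = ordinal,
                         stringsAsFactors = FALSE),
    genes = data.frame(gene = geneNames,
                       is_response = geneNames %in% geneNames[seq_len(nr) + 1L],
                       direction = c("none",
                                     if (nr) ifelse(directions > 0, "up", "down"),
                                     rep("none", config$n_null_genes)),
                       stringsAsFactors = FALSE),
    boundary_ordinal = boundary,
    boundary_genomic = boundaryGenomic,
    seed = config$seed)

  new("SyntheticCohort",
      cohort = Cohort(mutTab, expr, clin),
      truth = truth, config = config)
}

#' Write a synthetic cohort to disk
#'
#' Emits `mutations.maf.tsv` (MAF dialect), `expression.tsv`,
#' `clinical.tsv` and `truth.json` into `dir`.
#'
#' @param x a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  co <- x@cohort
  writeMutations(mutations(co), file.path(dir, "mutations.maf.tsv"), dialect = "maf")
  writeExpression(expressionMatrix(co), file.path(dir, "expression.tsv"))
  writeClinical(clinical(co), file.path(dir, "clinical.tsv"))
  jsonlite::write_json(x@truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a synthetic cohort directory back into a Cohort
#'
#' @param dir directory written by [writeCohort()].
#' @return A [Cohort-class].
#' @export
readCohortDir <- function(dir) {
  Cohort(readMutations(file.path(dir, "mutations.maf.tsv"), dialect = "maf"),
         readExpression(file.path(dir, "expression.tsv")),
         readClinical(file.path(dir, "clinical.tsv")))
}

## ---------------------------------------------------------------------------
## toy transcripts and the brute-force consequence oracle
## ---------------------------------------------------------------------------

#' Random toy transcript with planted variants
#'
#' Builds a random CDS (no internal stops) with a random 3'UTR into which
#' stop codons for both shifted reading frames are planted near the end, so
#' frameshift read-through always terminates. Plants a cycle of variant
#' types (1-bp insertion, 1-bp deletion, in-frame 3-bp insertion,
#' substitution) at random CDS positions.
#'
#' @param nCodons CDS length in residues (>= 5).
#' @param utr3Len 3'UTR length (>= 12).
#' @param nVariants number of planted variants.
#' @return List with `transcript` (a [TranscriptModel-class]) and
#'   `variants` (data.frame: cdna_position, ref_allele, alt_allele, type).
#' @export
makeToyTranscript <- function(nCodons = 60L, utr3Len = 60L, nVariants = 8L) {
  if (nCodons < 5L) stop("nCodons must be >= 5")
  if (utr3Len < 12L) stop("utr3Len must be >= 12")
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  allCodons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(allCodons, stops)
  codons <- c("ATG", sample(sense, nCodons - 1L, replace = TRUE),
              sample(stops, 1L))
  cds <- paste(codons, collapse = "")
  cdsLen <- nchar(cds)
  utr <- sample(bases, utr3Len, replace = TRUE)
  # plant a +1-frame stop (triplets start at full-sequence positions
  # congruent 0 mod 3) and a -1-frame stop (congruent 2 mod 3) near the end
  total <- cdsLen + utr3Len
  q1 <- 3L * ((total - 2L) %/% 3L)                  # largest start == 0 (mod 3)
  q2 <- q1 - 1L - ((q1 - 1L - 2L) %% 3L)            # largest start == 2 (mod 3) below q1
  if (q2 + 2L >= q1) q2 <- q2 - 3L
  utr[(q1 - cdsLen):(q1 - cdsLen + 2L)] <- c("T", "A", "A")
  utr[(q2 - cdsLen):(q2 - cdsLen + 2L)] <- c("T", "A", "A")
  utr <- paste(utr, collapse = "")
  tmod <- TranscriptModel("TOY", "TOY-1", paste0(cds, utr),
                          cdsStart = 1L, cdsEnd = cdsLen,
                          exonEnds = cdsLen + utr3Len)

  types <- rep(c("ins1", "del1", "ins3", "sub"), length.out = nVariants)
  variants <- do.call(rbind, lapply(types, function(ty) {
    p <- sample(4:(cdsLen - 6L), 1L)
    if (ty == "ins1") data.frame(cdna_position = p, ref_allele = "-",
                                 alt_allele = sample(bases, 1L), type = ty)
    else if (ty == "del1") data.frame(cdna_position = p,
                                      ref_allele = substr(cds, p, p),
                                      alt_allele = "-", type = ty)
    else if (ty == "ins3") data.frame(cdna_position = p, ref_allele = "-",
                                      alt_allele = paste(sample(bases, 3L, replace = TRUE),
                                                         collapse = ""), type = ty)
    else data.frame(cdna_position = p, ref_allele = substr(cds, p, p),
                    alt_allele = sample(setdiff(bases, substr(cds, p, p)), 1L),
                    type = ty)
  }))
  list(transcript = tmod, variants = variants)
}

#' Brute-force consequence reference by whole-mRNA re-translation
#'
#' Independent reference route for [classifyConsequence()]: mutates the
#' whole transcript by plain string surgery, translates wild type and
#' mutant from the start codon with a literal codon-table loop, and diffs
#' the proteins. Intended for validation; the classifier proper is
#' [classifyConsequence()].
#'
#' @param t a [TranscriptModel-class].
#' @param cdnaPos,ref,alt variant as in [classifyConsequence()].
#' @return List with `consequence_class`, `first_altered_residue`,
#'   `mutant_length`, `novel_cterm_length`, `wt_length`.
#' @export
naiveTranslateConsequence <- function(t, cdnaPos, ref, alt) {
  s <- as.character(t@cdna)
  p <- t@cdsStart + cdnaPos - 1L
  mut <- if (ref == "-") paste0(substr(s, 1L, p), alt, substr(s, p + 1L, nchar(s)))
         else paste0(substr(s, 1L, p - 1L), if (alt == "-") "" else alt,
                     substr(s, p + nchar(ref), nchar(s)))
  tr <- function(seq) {
    gc <- Biostrings::GENETIC_CODE
    out <- character(0)
    i <- 1L
    while (i + 2L <= nchar(seq)) {
      aa <- unname(gc[substr(seq, i, i + 2L)])
      if (aa == "*") return(list(protein = paste(out, collapse = ""), noStop = FALSE))
      out <- c(out, aa)
      i <- i + 3L
    }
    list(protein = paste(out, collapse = ""), noStop = TRUE)
  }
  wt <- tr(substr(s, t@cdsStart, nchar(s)))
  mu <- tr(substr(mut, t@cdsStart, nchar(mut)))
  W <- nchar(wt$protein); L <- nchar(mu$protein)
  m <- min(W, L)
  wtc <- strsplit(wt$protein, "")[[1]]; muc <- strsplit(mu$protein, "")[[1]]
  d <- which(wtc[seq_len(m)] != muc[seq_len(m)])
  firstAltered <- if (length(d)) d[1] else if (L != W) m + 1L else NA_integer_
  insLen <- if (ref == "-") nchar(alt) else if (alt == "-") 0L else nchar(alt)
  delLen <- if (ref == "-") 0L else if (alt == "-") nchar(ref) else nchar(ref)
  frame <- (insLen - delLen) %% 3L
  cls <- if (frame != 0L) {
    if (mu$noStop) "no_stop"
    else if (L < W) "frameshift_truncation"
    else if (L > W) "frameshift_extension"
    else "frameshift_same_length"
  } else if (insLen != delLen) "in_frame"
  else if (identical(wt$protein, mu$protein)) "silent"
  else if (L < W && !mu$noStop && all(muc == wtc[seq_len(L)])) "nonsense"
  else "missense"
  list(consequence_class = cls,
       first_altered_residue = as.integer(firstAltered),
       mutant_length = if (frame != 0L && mu$noStop) NA_integer_ else as.integer(L),
       novel_cterm_length = if (cls == "frameshift_extension") as.integer(L - W) else NA_integer_,
       wt_length = as.integer(W))
}
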