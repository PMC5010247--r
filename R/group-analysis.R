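## Mutation-class patient groups, extension-vs-other differential
## statistics, signature derivation/concordance, and the survival
## comparison.

#' Group labels used for the mutation-class comparison
#' @format Character vector of the five labels.
#' @export
GROUP_LABELS <- c("ext_plus1", "ext_minus1", "trunc_plus1", "trunc_minus1",
                  "other_mutant")

#' Assign patients to mutation-consequence groups
#'
#' Labels each single-mutation patient by consequence class and frame:
#' protein extensions in the +1 and -1 frames, truncations in the +1 and -1
#' frames, and all other mutations. The comparison of interest is the
#' dominant group (`ext_plus1`) against all other labels combined.
#'
#' @param consequences data.frame from [classifyMutations()] (one row per
#'   sample; multi-mutant samples excluded upstream).
#' @return data.frame with `sample_id`, `label`, `is_case` (`TRUE` for
#'   `ext_plus1`).
#' @export
assignGroups <- function(consequences) {
  lab <- with(consequences, ifelse(
    consequence_class == "frameshift_extension" & frame_shift == 1L, "ext_plus1",
    ifelse(consequence_class == "frameshift_extension" & frame_shift == -1L, "ext_minus1",
    ifelse(consequence_class == "frameshift_truncation" & frame_shift == 1L, "trunc_plus1",
    ifelse(consequence_class == "frameshift_truncation" & frame_shift == -1L, "trunc_minus1",
           "other_mutant")))))
  data.frame(sample_id = consequences$sample_id, label = lab,
             is_case = lab == "ext_plus1", stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most `exactMax`
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction. Symmetric in its arguments.
#'
#' @param x,y numeric vectors (non-empty).
#' @param exactMax combined-size threshold for the exact test (default 12).
#' @return List with `statistic` (the Mann-Whitney W for `x`) and `p.value`.
#' @examples
#' rankSumTest(c(1, 2), c(3, 4))$p.value  # exactly 1/3
#' @export
rankSumTest <- function(x, y, exactMax = 12L) {
  if (!length(x) || !length(y)) stop("rankSumTest: empty input")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= exactMax && !ties
  ht <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Median fold change between two groups
#'
#' @param x,y non-negative expression values (case, control).
#' @param pseudocount added to both medians before the ratio (default 0).
#' @return List with `fold_change`, `log2_fold_change`, `direction`
#'   (`"up"`/`"down"`/`"flat"`; flat iff the medians are equal). When both
#'   medians are zero and the pseudocount is zero the ratio is undefined:
#'   `fold_change` is `NA` and the direction is flat.
#' @export
medianFoldChange <- function(x, y, pseudocount = 0) {
  mx <- median(x)
  my <- median(y)
  dir <- if (mx > my) "up" else if (mx < my) "down" else "flat"
  if (mx + pseudocount == 0 && my + pseudocount == 0)
    return(list(fold_change = NA_real_, log2_fold_change = NA_real_,
                direction = "flat"))
  fc <- (mx + pseudocount) / (my + pseudocount)
  list(fold_change = fc, log2_fold_change = log2(fc), direction = dir)
}

#' Per-gene differential statistics between case and control samples
#'
#' For each gene, the median fold change (case over control) and a
#' two-sided Wilcoxon rank-sum p-value.
#'
#' @param x a [Cohort-class].
#' @param caseIds,controlIds sample id vectors.
#' @param genes genes to test (default all).
#' @param pseudocount see [medianFoldChange()].
#' @return data.frame: gene, median_case, median_control, fold_change,
#'   log2_fold_change, direction, p_value.
#' @export
differentialExpression <- function(x, caseIds, controlIds, genes = NULL,
                                   pseudocount = 0) {
  ex <- expressionMatrix(x)
  if (is.null(genes)) genes <- rownames(ex)
  if (!length(caseIds) || !length(controlIds))
    stop("differentialExpression: empty case or control set")
  rows <- lapply(genes, function(g) {
    xv <- as.numeric(ex[g, caseIds])
    yv <- as.numeric(ex[g, controlIds])
    fc <- medianFoldChange(xv, yv, pseudocount)
    ht <- rankSumTest(xv, yv)
    data.frame(gene = g, median_case = median(xv), median_control = median(yv),
               fold_change = fc$fold_change,
               log2_fold_change = fc$log2_fold_change,
               direction = fc$direction, p_value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Derive a top-k gene signature from differential results
#'
#' Ranks by ascending p-value, breaking ties by descending |log2 fold
#' change| and then gene id, and keeps the top k. Deterministic under
#' permutation of the input rows; duplicate genes are not possible.
#'
#' @param results data.frame from [differentialExpression()].
#' @param k signature size (default 50).
#' @param sourceCohort optional label recorded on the result.
#' @return data.frame: gene, direction, p_value, log2_fold_change; with
#'   attributes `k` and `source_cohort`.
#' @export
deriveSignature <- function(results, k = 50L, sourceCohort = NA_character_) {
  if (k <= 0) stop("deriveSignature: k must be positive")
  if (!nrow(results)) stop("deriveSignature: empty results")
  stopifnot(!anyDuplicated(results$gene))
  alfc <- abs(results$log2_fold_change)
  alfc[!is.finite(alfc)] <- 0
  ord <- order(results$p_value, -alfc, results$gene)
  sig <- results[head(ord, k), c("gene", "direction", "p_value", "log2_fold_change")]
  rownames(sig) <- NULL
  attr(sig, "k") <- as.integer(k)
  attr(sig, "source_cohort") <- sourceCohort
  sig
}

#' Sign concordance of differential directions across two cohorts
#'
#' Counts genes shared between two differential tables and, among those,
#' genes whose fold-change directions agree (a flat direction counts as
#' discordant unless flat in both).
#'
#' @param a,b data.frames with columns `gene` and `direction`.
#' @return List with `n_shared` and `n_concordant`.
#' @export
signConcordance <- function(a, b) {
  m <- merge(a[, c("gene", "direction")], b[, c("gene", "direction")],
             by = "gene", suffixes = c("_a", "_b"))
  list(n_shared = nrow(m),
       n_concordant = sum(m$direction_a == m$direction_b))
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Standard log-rank (Mantel-Cox): at each distinct event time the observed
#' events per group are compared with their hypergeometric expectation;
#' chi-square statistic with 1 df. Right censoring only; times in months.
#'
#' @param times non-negative survival/censoring times.
#' @param events logical (or 0/1) event indicators.
#' @param groups two-level factor/character, both levels non-empty.
#' @return List with `chisq`, `p.value`, `n`, `n_events` (per group) and
#'   `km` (per-group data.frames of `time`, `surv`, starting at 1.0).
#' @export
logrankTest <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L)
    stop("logrankTest: exactly two groups required")
  if (any(table(groups) == 0L))
    stop("logrankTest: a group has zero subjects")
  events <- as.logical(events)
  if (!any(events)) stop("logrankTest: at least one event required")
  sdf <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chisq <- unname(sdf$chisq)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  km <- lapply(levels(groups), function(lv) {
    sel <- groups == lv
    fit <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
    data.frame(time = c(0, fit$time), surv = c(1, fit$surv))
  })
  names(km) <- levels(groups)
  list(chisq = chisq, p.value = p,
       n = as.vector(table(groups)),
       n_events = setNames(as.numeric(sdf$obs), levels(groups)),
       km = km)
}
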