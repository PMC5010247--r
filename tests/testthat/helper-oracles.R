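# Independent reference implementations used to validate the package.
# Everything here is deliberately naive: plain loops, literal tables,
# no shared code paths with the implementations under test.

# ---- exhaustive arc-statistic search ---------------------------------------

# brute-force maximal |Z| over all admissible arcs, double loop, direct
# mean/sd arithmetic (no prefix sums)
bruteMaxStat <- function(y, mw) {
  n <- length(y)
  best <- list(i = -1L, j = -1L, statistic = 0)
  s <- stats::sd(y)
  if (n < 2 * mw || !is.finite(s) || s < 1e-12) return(best)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k == n) next
      if (i > 0 && j < n) {
        if (i < mw || k < mw || (n - j) < mw) next
      } else {
        if (k < mw || (n - k) < mw) next
      }
      arc <- y[(i + 1):j]
      comp <- y[setdiff(seq_len(n), (i + 1):j)]
      z <- abs((mean(arc) - mean(comp)) / (s * sqrt(1 / k + 1 / (n - k))))
      if (z > best$statistic + 1e-12) best <- list(i = i, j = j, statistic = z)
    }
  }
  best
}

# ---- naive translation ------------------------------------------------------

# literal standard genetic code
.ORACLE_CODONS <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracleTranslate <- function(seq) {
  aa <- character(0)
  i <- 1
  while (i + 2 <= nchar(seq)) {
    r <- .ORACLE_CODONS[[substr(seq, i, i + 2)]]
    if (r == "*") return(list(protein = paste(aa, collapse = ""), noStop = FALSE))
    aa <- c(aa, r)
    i <- i + 3
  }
  list(protein = paste(aa, collapse = ""), noStop = TRUE)
}

# full re-translation consequence oracle: mutate whole mRNA by string
# surgery, translate both from the start codon, diff proteins
oracleConsequence <- function(t, pos, ref, alt) {
  s <- as.character(t@cdna)
  p <- t@cdsStart + pos - 1
  mut <- if (ref == "-") paste0(substr(s, 1, p), alt, substr(s, p + 1, nchar(s)))
  else paste0(substr(s, 1, p - 1), if (alt == "-") "" else alt,
              substr(s, p + nchar(ref), nchar(s)))
  wt <- oracleTranslate(substr(s, t@cdsStart, nchar(s)))
  mu <- oracleTranslate(substr(mut, t@cdsStart, nchar(mut)))
  W <- nchar(wt$protein); L <- nchar(mu$protein)
  wtc <- strsplit(wt$protein, "")[[1]]
  muc <- strsplit(mu$protein, "")[[1]]
  m <- min(W, L)
  d <- which(wtc[seq_len(m)] != muc[seq_len(m)])
  fa <- if (length(d)) d[1] else if (L != W) m + 1L else NA_integer_
  insLen <- if (ref == "-") nchar(alt) else if (alt == "-") 0 else nchar(alt)
  delLen <- if (ref == "-") 0 else if (alt == "-") nchar(ref) else nchar(ref)
  shift <- (insLen - delLen) %% 3
  cls <- if (shift != 0) {
    if (mu$noStop) "no_stop"
    else if (L < W) "frameshift_truncation"
    else if (L > W) "frameshift_extension"
    else "frameshift_same_length"
  } else if (insLen != delLen) "in_frame"
  else if (wt$protein == mu$protein) "silent"
  else if (L < W && !mu$noStop && all(muc == wtc[seq_len(L)])) "nonsense"
  else "missense"
  list(class = cls, first_altered = fa,
       mutant_length = if (shift != 0 && mu$noStop) NA_integer_ else L,
       wt_length = W)
}

# ---- rank-sum enumeration ---------------------------------------------------

# exact two-sided rank-sum p by enumerating all group labelings
enumerateRankSumP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); m <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  combs <- utils::combn(n, m)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- m * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# ---- log-rank by explicit hypergeometric sums -------------------------------

oracleLogrank <- function(times, events, groups) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  ts <- sort(unique(times[events]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    atRisk <- times >= t
    n1 <- sum(atRisk & groups == lv[1])
    ntot <- sum(atRisk)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & groups == lv[1])
    O <- O + d1
    E <- E + d * n1 / ntot
    if (ntot > 1)
      V <- V + d * (n1 / ntot) * (1 - n1 / ntot) * (ntot - d) / (ntot - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# ---- direct kernel sums -----------------------------------------------------

oracleKdeAt <- function(grid, x, bw) {
  sapply(grid, function(g) mean(stats::dnorm((g - x) / bw)) / bw)
}

# ---- shared tiny fixtures ---------------------------------------------------

# small synthetic cohort used across files (fast settings)
smallSimConfig <- function(seed = 7, ...) {
  args <- list(n_patients = 60L, n_response_genes = 5L, n_null_genes = 20L,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulationConfig, args)
}

fastParams <- function(seed = 1, nperm = 2000) {
  SegmentationParams(alpha = 0.005, nperm = nperm, minWidth = 5, seed = seed)
}
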