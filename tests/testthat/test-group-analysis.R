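# Mutation-class groups, rank statistics, signatures, concordance,
# survival.

test_that("group labels follow consequence class and frame", {
  cons <- data.frame(
    sample_id = paste0("S", 1:6),
    consequence_class = c("frameshift_extension", "frameshift_extension",
                          "frameshift_truncation", "frameshift_truncation",
                          "missense", "no_stop"),
    frame_shift = c(1L, -1L, 1L, -1L, 0L, 1L))
  g <- assignGroups(cons)
  expect_equal(g$label, c("ext_plus1", "ext_minus1", "trunc_plus1",
                          "trunc_minus1", "other_mutant", "other_mutant"))
  expect_equal(g$is_case, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
})

test_that("group assignment of a simulated cohort matches the generator's labels", {
  sim <- simulateCohort(smallSimConfig(seed = 61))
  co <- harmonizeCohort(cohort(sim))
  single <- singleMutationPatients(mutations(co), "GATA3")
  cons <- classifyMutations(gata3SyntheticTranscript(), single)
  g <- assignGroups(cons)
  truth <- groundTruth(sim)$samples
  m <- merge(g, truth, by = "sample_id")
  expect_equal(m$label, m$group_label)
})

test_that("rank-sum p-values: exact enumeration, symmetry, identity case", {
  r <- rankSumTest(c(1, 2), c(3, 4))
  expect_equal(r$p.value, 1 / 3)
  expect_equal(enumerateRankSumP(c(1, 2), c(3, 4)), 1 / 3)

  expect_equal(rankSumTest(c(5, 7, 9), c(5, 7, 9))$p.value, 1)
  a <- rankSumTest(c(1, 5, 9, 12), c(2, 3, 4, 20))
  b <- rankSumTest(c(2, 3, 4, 20), c(1, 5, 9, 12))
  expect_equal(a$p.value, b$p.value)
})

test_that("the large-sample approximation tracks full enumeration", {
  set.seed(10)
  for (r in 1:5) {
    x <- round(rnorm(10, 0, 5), 3)
    y <- round(rnorm(10, 1, 5), 3)
    exact <- enumerateRankSumP(x, y)
    approx <- rankSumTest(x, y, exactMax = 0L)$p.value
    expect_lte(abs(approx - exact), 0.02)
  }
})

test_that("rank-sum p-values are uniform under label permutation of null data", {
  set.seed(20)
  pool <- rnorm(24)
  ps <- replicate(1000, {
    idx <- sample(24, 12)
    rankSumTest(pool[idx], pool[-idx])$p.value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("median fold change reports ratio and direction, handling zeros", {
  fc <- medianFoldChange(c(3, 4, 5), c(1, 2, 3))
  expect_equal(fc$fold_change, 2)
  expect_equal(fc$direction, "up")
  expect_equal(medianFoldChange(1:3, 1:3)$direction, "flat")
  expect_equal(medianFoldChange(1:3, 1:3)$fold_change, 1)
  z <- medianFoldChange(c(0, 0), c(0, 0), pseudocount = 0)
  expect_true(is.na(z$fold_change))
  expect_equal(z$direction, "flat")
})

test_that("fold change estimates a known median ratio in log-normal groups", {
  set.seed(30)
  x <- exp(rnorm(200, log(8), 0.4))
  y <- exp(rnorm(200, log(4), 0.4))
  fc <- medianFoldChange(x, y)
  expect_lt(abs(fc$fold_change - 2) / 2, 0.10)
})

test_that("signature derivation is deterministic, order-invariant and duplicate-free", {
  res <- data.frame(gene = c("g3", "g1", "g2", "g4"),
                    median_case = 1, median_control = 1,
                    fold_change = c(2, 4, 0.5, 1.2),
                    log2_fold_change = log2(c(2, 4, 0.5, 1.2)),
                    direction = c("up", "up", "down", "up"),
                    p_value = c(0.01, 0.001, 0.001, 0.2))
  sig <- deriveSignature(res, k = 3)
  expect_equal(sig$gene, c("g1", "g2", "g3"))  # p asc, then |lfc| desc
  expect_equal(deriveSignature(res[sample(4), ], k = 3)$gene, sig$gene)
  expect_equal(nrow(deriveSignature(res, k = 100)), 4L)
  expect_error(deriveSignature(res, k = 0), "positive")
  expect_false(anyDuplicated(sig$gene) > 0)
})

test_that("sign concordance counts shared genes with matching directions", {
  a <- data.frame(gene = c("g1", "g2", "g3"), direction = c("up", "down", "up"))
  b <- a
  expect_equal(signConcordance(a, b),
               list(n_shared = 3L, n_concordant = 3L))
  b$direction[2] <- "up"
  expect_equal(signConcordance(a, b)$n_concordant, 2L)
  b$direction[3] <- "flat"
  expect_equal(signConcordance(a, b)$n_concordant, 1L)
})

test_that("two independently simulated cohorts agree in planted effect signs", {
  co1 <- harmonizeCohort(cohort(simulateCohort(smallSimConfig(seed = 71))))
  co2 <- harmonizeCohort(cohort(simulateCohort(smallSimConfig(seed = 72))))
  diffOf <- function(co) {
    single <- singleMutationPatients(mutations(co), "GATA3")
    cons <- classifyMutations(gata3SyntheticTranscript(), single)
    g <- assignGroups(cons)
    differentialExpression(co, g$sample_id[g$is_case], g$sample_id[!g$is_case],
                           genes = sprintf("RESP%02d", 1:5))
  }
  d1 <- diffOf(co1); d2 <- diffOf(co2)
  conc <- signConcordance(d1, d2)
  expect_equal(conc$n_shared, 5L)
  expect_equal(conc$n_concordant, 5L)
})

test_that("log-rank: identical groups give chi2 = 0, p = 1", {
  t <- c(1, 2, 3, 4, 5, 6)
  e <- rep(TRUE, 6)
  g <- rep(c("a", "b"), each = 3)
  r <- logrankTest(c(t, t), c(e, e), rep(c("a", "b"), each = 6))
  expect_equal(r$chisq, 0, tolerance = 1e-12)
  expect_equal(r$p.value, 1)
  expect_error(logrankTest(t, e, rep("a", 6)), "two groups")
})

test_that("log-rank chi-square matches the hand hypergeometric oracle", {
  times <- c(1, 2, 3, 4, 5, 6)
  events <- rep(TRUE, 6)
  groups <- rep(c("A", "B"), each = 3)
  got <- logrankTest(times, events, groups)
  ora <- oracleLogrank(times, events, groups)
  expect_equal(got$chisq, ora$chisq, tolerance = 1e-9)
  expect_equal(got$p.value, ora$p, tolerance = 1e-9)

  set.seed(40)
  times2 <- round(rexp(30, 0.1), 2)
  events2 <- runif(30) < 0.7
  groups2 <- sample(c("A", "B"), 30, replace = TRUE)
  if (sum(events2) > 0 && length(unique(groups2)) == 2) {
    got2 <- logrankTest(times2, events2, groups2)
    ora2 <- oracleLogrank(times2, events2, groups2)
    expect_equal(got2$chisq, ora2$chisq, tolerance = 1e-8)
  }
})

test_that("without censoring the KM curve is the empirical survivor function", {
  times <- c(2, 4, 4, 7, 9)
  r <- logrankTest(c(times, 1, 2, 3, 4, 5), rep(TRUE, 10),
                   rep(c("x", "y"), each = 5))
  km <- r$km$x
  for (t in times)
    expect_equal(km$surv[findInterval(t, km$time)], mean(times > t))
})

test_that("log-rank keeps its nominal size under a unit hazard ratio", {
  set.seed(50)
  rej <- replicate(400, {
    t <- rexp(40, 0.1)
    cens <- rexp(40, 0.05)
    grp <- rep(c("a", "b"), each = 20)
    logrankTest(pmin(t, cens), t <= cens, grp)$p.value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("a strong extension-group hazard is detected with high power", {
  set.seed(60)
  hits <- replicate(25, {
    n <- 50
    tA <- rexp(n, 0.02 * 3); tB <- rexp(n, 0.02)
    cens <- rexp(2 * n, 0.02 * 2 / 3)
    times <- pmin(c(tA, tB), cens)
    events <- c(tA, tB) <= cens
    logrankTest(times, events, rep(c("ext", "other"), each = n))$p.value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
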