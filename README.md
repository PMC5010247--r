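# mutseg — mutation-position segmentation of tumour expression cohorts

Recurrently mutated cancer genes are usually analysed as on/off: a patient
carries a mutation in the gene or does not. mutseg asks a sharper question —
does *where* the mutation falls within the gene matter? In breast cancer,
*GATA3* frameshift indels split into premature truncations and +1-frame
C-terminal extensions with distinct downstream biology; mutseg provides the
machinery to discover and characterise such within-gene structure from
standard cohort exports (MAF mutations, normalized expression, clinical
disease-free survival). It is aimed at computational cancer-genomics
researchers working with TCGA/cBioPortal-style data.

## The method

For a driver gene *D*, keep the patients with exactly one non-silent
mutation in *D*, order them by the genomic position of that mutation, and
midrank every other gene's normalized expression over exactly those
patients. Each ordered series is segmented by circular binary segmentation:
the arc statistic

    Z(i,j) = (mean(y[arc]) − mean(y[complement])) / (s · sqrt(1/k + 1/(n−k))),  k = j − i

is maximised over all arcs whose induced pieces have at least `min_width`
observations, the split is accepted when its permutation p-value
`p = (1 + B)/(nperm + 1)` is at most `alpha` (defaults: `alpha = 0.005`,
`nperm = 20000`, `min_width = 5`), and the procedure recurses. Genes whose
series acquire at least one breakpoint are **response genes**; the border
between two segments is a **segmentation breakpoint**, mapped back to a
genomic coordinate between the flanking mutations.

Around the scan, the package provides:

* **Frameshift consequence prediction** by in-silico translation through
  the 3'UTR: truncation (mutant ORF shorter than wild type) versus
  extension (longer, with the novel C-terminal length and the number of
  replaced original residues reported).
* **Mutation-class group analysis**: `ext_plus1` (extensions in the +1
  frame) against all other mutant classes — median fold change, two-sided
  Wilcoxon rank-sum p-values, top-k signatures, cross-cohort sign
  concordance.
* **Survival**: two-group log-rank (Mantel–Cox) test with Kaplan–Meier
  curves on disease-free survival.
* **A synthetic cohort simulator** with hotspot position mixtures, planted
  step-shift response genes, null genes and group-dependent exponential
  survival, retaining full ground truth — this is what the test suite and
  the acceptance script run against.

## Worked example

```r
library(mutseg)

sim  <- simulateCohort(simulationConfig(seed = 777, true_breakpoint = 30L))
co   <- harmonizeCohort(cohort(sim))
scan <- scanTranscriptome(co, "GATA3", SegmentationParams(nperm = 2000, seed = 7))
scan
#> ResponseGeneScan for driver GATA3 :
#>   60 samples; 101 genes segmented, 0 skipped (expressed filter), 5 response genes
responseGenes(scan)[, c("gene", "n_breakpoints", "top_split_p")]
#>     gene n_breakpoints top_split_p
#> 1 RESP01             1       5e-04
#> 2 RESP02             1       5e-04
#> 3 RESP03             1       5e-04
#> 4 RESP04             1       5e-04
#> 5 RESP05             1       5e-04
```

The five planted response genes — and no null gene — are called; four of
the five breakpoints map to genomic coordinate 8108312, which is exactly
the simulator's true class boundary (`groundTruth(sim)$boundary_genomic`).
The consequence classifier reproduces the canonical *GATA3* arithmetic on
the packaged synthetic transcript:

```r
classifyConsequence(gata3SyntheticTranscript(), 1224, "-", "G")
#> ProteinConsequence p.P409fs: frameshift_extension (frame +1)
#>   wt 444 aa -> mutant 507 aa (+63 novel C-terminal aa)
```

Grouping patients by consequence and comparing disease-free survival:

```r
single <- singleMutationPatients(mutations(co), "GATA3")
grp    <- assignGroups(classifyMutations(gata3SyntheticTranscript(), single))
table(grp$label)
#>    ext_plus1 other_mutant trunc_minus1  trunc_plus1
#>           30           10            4           16
cl <- clinical(co)
lr <- logrankTest(cl$dfs_months, cl$dfs_event,
                  ifelse(cl$sample_id %in% grp$sample_id[grp$is_case],
                         "ext_plus1", "other"))
sprintf("log-rank chi2 = %.2f, p = %.4g", lr$chisq, lr$p.value)
#> "log-rank chi2 = 13.06, p = 0.0003016"
```

The extension group, simulated at a hazard ratio of 3, shows the expected
significantly shortened disease-free survival. `runSimulate()`,
`runScan()`, `runGroups()` and `runClassify()` wrap these stages with
TSV/JSON inputs and outputs (each run writes a `run_summary.json` with
version, seed, parameters, input hashes and stage-wise counts);
`inst/scripts/mutseg-cli.R` exposes them as shell subcommands.

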