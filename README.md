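# celldiv

Transcriptional diversity metrics across identified cell populations.

When many cell populations are profiled by RNA-seq (sorted pools, single-cell
clusters), the question is rarely just "which genes vary?" but *how* they
vary: a gene can differ between **many** pairs of populations, or it can
differ **cleanly** between the few pairs it separates. ANOVA-style screens
confound the two. `celldiv` separates them:

- **Differentiation Matrix (DM)** — per gene, a symmetric binary P × P
  matrix marking the population pairs the gene distinguishes
  (|log2 FC| > 2 and BH q < 0.05 from a moderated pairwise t-test; or
  |log2 FC| > 1 on cluster averages without replicates).
- **DEF** (differentially expressed fraction) — the fraction of the
  P(P−1)/2 pairs distinguished; on a partition into classes of sizes
  n_k it equals the Gini–Simpson index (P² − Σn_k²)/(P² − P).
- **FCR** (fold-change ratio) — mean |log2 FC| over distinguished pairs
  divided by the mean over undistinguished pairs: a signal-to-noise
  measure independent of how many pairs are distinguished.

Around this core the package provides: greedy combinatorial marker-code
search over combined DMs; gene-family analysis (hypergeometric
over-representation, OFF-state noise, expression-pattern orthogonality with
a randomized null, a seven-condition pan-neuronal filter); NNLS
decomposition of query profiles against reference cluster panels with
informative-gene selection, quantile normalization and purity scoring; a
calibrated Dirichlet-multinomial likelihood-ratio test for differential
splice-donor usage with PSI/ΔPSI and splice DEF; gene-length bias
summaries; and a fully seeded synthetic-data generator with ground truth so
the entire pipeline runs without external data.

## Worked example

Simulate a 12-population × 3-replicate study (1,000 genes: ON/OFF markers,
long graded effectors, housekeeping), build DMs, and score diversity:

```r
library(celldiv)
sim  <- simulate_expression(sim_config(seed = 1))
fpkm <- to_fpkm(sim$counts, sim$gene_table)
fit  <- fit_group_model(fpkm, max_replicates = 2)
dmc  <- build_dm(pairwise_contrasts(fit), lfc_thresh = 2, q_thresh = 0.05)
sc   <- diversity_scores(dmc)
head(sc[order(-sc$def), ], 3)
#>      gene       def      fcr n_distinguished n_pairs
#> 151 g0151 0.7272727 6.260954              48      66
#> 83  g0083 0.7121212 4.562627              47      66
#> 114 g0114 0.7121212 5.830802              47      66
```

The top DEF gene distinguishes 48 of the 66 population pairs (DEF 0.73)
with a modest FCR ≈ 6 — a graded, many-pair "effector" profile. Marker-like
genes show the opposite signature (few pairs, FCR in the hundreds or
infinite). A greedy search then finds a minimal combinatorial code:

```r
code <- greedy_code(dmc, threshold = 0.99)
code
#> code_result: 3 genes, combined DEF 1.0000 (threshold 0.99, achieved)
sim$truth$class[code$genes]
#>      g0151      g0083      g0100
#> "effector" "effector" "effector"
```

Three genes jointly distinguish all 66 pairs. Split-half cross-validated
decomposition confirms the populations are recoverable as nearly pure
mixtures of themselves:

```r
cv <- cross_validate(to_cpm(sim$counts, log = TRUE), n_genes = 300)
round(cv$mean_purity, 3)
#> [1] 0.954
```

For splicing, `simulate_junctions()` → `group_junctions_by_donor()` →
`splice_pairwise_tests()` → `splice_dm()` / `gene_splice_def()` runs the
Dirichlet-multinomial test over every donor unit and population pair and
combines donor-level DMs into per-gene splice DEF.

A thin command-line wrapper over these functions is installed at
`inst/scripts/celldiv.R` (subcommands `validate`, `simulate`, `dm`,
`diversity`, `code`, `noise`, `enrich`, `splice`, `lengthbias`).

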