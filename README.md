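# ifnkit

Downstream analysis of type I interferon (IFN) transcriptomics in mixed
immune-cell populations (PBMCs), for researchers who have bulk
differential-expression tables and labelled single-cell count matrices in
hand and want the IFN-specific analyses on top of them:

* **Promoter motif association** — assign each transcript group a 350 bp
  promoter (ENCODE-style promoter-like elements within 500 bp of the TSS,
  or imputed around the TSS), score promoters against a PWM library
  (max log-odds over both strands), Z-standardise against high-confidence
  reference promoters, aggregate into motif-cluster scores, and test
  per cluster and treatment whether high-scoring transcripts show different
  IFN-induced fold changes (Mann–Whitney U on a "likely regulated",
  z ≥ 2, versus "likely unregulated", z ≤ −1, partition; Benjamini–Hochberg
  across all cluster × treatment tests).
* **DET set algebra** — differentially expressed transcript sets at
  padj ≤ 0.05 and |log2FC| ≥ 0.585; universal, subtype-specific and
  lineage (Venn) sets.
* **Single-cell ISG analysis** — Seurat-style Wilcoxon differential
  expression (10% detection, 0.25 log-fold pre-filters, Bonferroni),
  core-ISG intersection across all eligible cell types and treatments,
  and per-cell ISG scores (sum of log-normalised expression over a gene
  set). The ten literature core ISGs ship as the constant `core_isgs`.
* **Non-coding RNA pairs** — divergent (head-to-head, ≤ 1 kb) and antisense
  (opposite-strand overlap) ncRNA/coding pairs, classified per contrast as
  co-regulated, anticorrelated, or unmatched.
* **A ground-truth synthetic generator** — a full simulated experiment
  (5 IFNs + mock, 3 donors, potency ordering, planted ISRE-like promoter
  motifs, shared/type-specific single-cell programs, heterogeneous genes,
  regulated ncRNA pairs) so every stage is testable end to end.

See `vignettes/ifnkit-methods.Rmd` for the full model description and the
design decisions.

## Worked example

```r
library(ifnkit)

sim <- simulate_ifn_experiment(sim_config(seed = 1))
res <- run_ifn_pipeline(sim)

dplyr::arrange(res$association, padj)[1:3, c(1, 2, 6, 7)]
#> # A tibble: 3 × 4
#>   cluster_id treatment        p         padj
#>   <chr>      <chr>        <dbl>        <dbl>
#> 1 C_ISRE     ifna1     8.83e-10 0.0000000133
#> 2 C_ISRE     ifnb      8.44e-10 0.0000000133
#> 3 C_ISRE     ifna10    1.45e- 9 0.0000000145
```

The ISRE-like motif cluster — the only cluster whose motif was planted into
ISG promoters — attains by far the smallest association p-value for every
IFN treatment, exactly the behaviour the association stage is meant to
detect. Decoy clusters stay near the null.

```r
length(res$universal_up)        # transcripts up-regulated by every IFN
#> [1] 226
setequal(res$core_set, ground_truth(sim)$core_ids)
#> [1] TRUE
```

`res$core_set` is the single-cell core-ISG intersection (significant in
every eligible cell type for every IFN); on synthetic data it recovers the
planted universal program exactly. `res$isg_scores` holds per-cell ISG
scores; `autoplot(res$association)` and `autoplot(res$isg_scores)` draw the
standard summaries.

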