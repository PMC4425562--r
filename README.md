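# sideroseq

Statistical machinery for integrative expression and targeted resequencing
studies of low-risk myelodysplastic syndromes (MDS), in particular
refractory anemia with ring sideroblasts (RARS) — the MDS subtype defined by
mitochondrial iron (ferritin) accumulation in erythroid precursors and
tightly associated with *SF3B1* spliceosome mutations. The package is aimed
at analysts who have preprocessed (e.g. RMA-summarized) log2 expression
matrices and single-nucleotide variant tables in hand and need the
statistics that tie such a study together, each piece testable against a
built-in synthetic cohort generator with known ground truth.

## What it implements

**SAM-style permutation differential expression** (`sam_analyze`). The
regularized statistic d = (x̄₂ − x̄₁)/(s + s₀) with a Welch (unequal
variance) standard error and a Tusher-style percentile search for the fudge
factor s₀; multiclass contrasts use an F-like form. The null is built by
relabeling samples (default 100 cycles); p-values pool permuted |d| across
genes, and q-values are empirical FDRs (π̂₀ = 1) made monotone in rank.
Genes are called at FDR < 0.05 by default, with fold changes reported as
"R fold" (2^Δmean).

**Empirical-Bayes moderated t** (`moderated_t`). Per-gene pooled variances
shrunk toward a prior fitted by closed-form moment matching on log s²;
t on d₀ + d_g degrees of freedom; forcing d₀ = 0 recovers the ordinary
pooled t exactly.

**Consensus signature selection** (`subsample_signature`). Repeated balanced
k-vs-k subsampling of two classes, per-subset moderated-t analysis, and
per-gene counting of significant contrasts; the signature is the top-N genes
by selection frequency. Presets `mut200` (7 vs 7, 10000 contrasts, q < 0.01,
top 200) and `rs75` (4 vs 4, 7425 contrasts, FDR < 0.10, top 75, ≥ 10
contrasts) mirror the mutation-split designs used in low-risk MDS studies.
A permutation global association test (`global_association_test`) checks
that a signature jointly predicts the class split.

**Contingency statistics** (`overlap_table`, `odds_ratio_ci`,
`fisher_exact`, `chi_square_2x2`, `enrich`). Gene-list overlap odds ratios
with Woolf intervals and Haldane–Anscombe zero-cell correction, exact
hypergeometric tests, classical chi-square, and hypergeometric / EASE
over-representation enrichment against an explicit gene universe.

**Variant triage** (`run_cascade`, `annotate_amino_acid_change`,
`call_haplotypes`, `compare_carrier_frequencies`). The capture-screen
cascade — known SNPs → non-coding → synonymous — with exact stage
accounting, strand-aware codon-level amino-acid annotation against spliced
CDS models, and two-SNP haplotype classification with case-control carrier
comparison.

**Synthetic cohorts** (`generate_expression_cohort`,
`generate_variant_cohort`, `generate_gene_sets`). Seeded generators that
emulate the study conditions (group sizes 30/39/31; mutation splits 22 vs 13
and 13 vs 6; ~1367 variants per sample with 56% known SNPs, 85% of the
remainder non-coding, ~58% of the coding remainder synonymous) and return
the planted truth for validation.

## Worked example

```r
library(sideroseq)

sim <- generate_expression_cohort(
  cohort_design(c(RARS = 30, CTRL = 31), n_genes = 2000, n_planted = 100,
                effect_log2 = 2, noise_sd = 0.7, seed = 1))
sim$cohort
#> expression_cohort: 2000 genes x 61 samples
#> groups: CTRL(31), RARS(30)

res <- sam_analyze(sim$cohort, sam_config(n_permutations = 100, seed = 2))
sum(res$called)                                        # genes at FDR < 0.05
#> [1] 106
sum(res$called & res$gene %in% sim$truth$planted_genes)
#> [1] 100
head(res[order(res$q, -abs(res$statistic)), ], 3)
#>        gene statistic    rfold     p q called
#> 60   g00060  6.408652 6.173535 5e-06 0   TRUE
#> 1929 g01929  6.148146 5.218754 5e-06 0   TRUE
#> 355  g00355  5.715726 4.954561 5e-06 0   TRUE
```

All 100 planted genes are recovered at FDR < 0.05 (106 calls total, i.e. a
handful of false positives at this threshold), and the top calls show
4–6-fold linear-scale up-regulation, consistent with the +2 log2 planted
shift.

The haplotype carrier comparison on a 12/100 vs 5/100 case-control split:

```r
cmp <- compare_carrier_frequencies(
  data.frame(sample = sprintf("rs%03d", 1:100),
             class = c(rep("variant", 12), rep("common", 88))),
  data.frame(sample = sprintf("ct%03d", 1:100),
             class = c(rep("variant", 5), rep("common", 95))))
cmp$table
#>      col1 col2
#> row1   12   88
#> row2    5   95
round(c(chisq = cmp$chisq, chisq_p = cmp$chisq_p,
        fisher_one_sided_p = cmp$fisher_one_sided_p), 4)
#>              chisq            chisq_p fisher_one_sided_p
#>             3.1501             0.0759             0.0631
```

Both tests land near p ≈ 0.07: a trend toward association, short of
significance at this sample size.

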