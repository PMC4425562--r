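---
title: "Methods: expression signatures and variant triage in low-risk MDS"
author: "sideroseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression signatures and variant triage in low-risk MDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sideroseq)
```

## Scope and scientific setting

Low-risk myelodysplastic syndromes (MDS) with ring sideroblasts — refractory
anemia with ring sideroblasts (RARS) in particular — are characterized by
mitochondrial iron accumulation in erythroid precursors and by recurrent
mutations in spliceosome genes such as *SF3B1* and *SRSF2*. Studies of these
diseases typically combine bulk microarray expression profiling of patient
bone marrow (RARS vs other low-risk MDS vs controls), consensus gene-signature
selection across mutation-defined subgroups, validation of signatures against
independent CD34+ cohorts, and targeted resequencing of iron/mitochondrial
gene panels with a triage of the called variants down to candidate missense
changes.

`sideroseq` implements the statistical machinery of such a study as reusable,
tested components. It deliberately starts *after* array preprocessing:
inputs are log2 expression matrices (e.g. RMA-summarized), phenotype labels,
gene-set collections, and single-nucleotide variant tables. Probe
summarization, normalization of raw intensity files, annotation-database
clients, and protein-level effect prediction are out of scope.

## Differential expression

### SAM-style permutation testing

For gene $g$ with two groups, the regularized statistic is Tusher-style

$$d_g = \frac{\bar x_{g2} - \bar x_{g1}}{s_g + s_0}, \qquad
s_g = \sqrt{\frac{s_{g1}^2}{n_1} + \frac{s_{g2}^2}{n_2}},$$

i.e. an unequal-variance (Welch) standard error — not a pooled one — plus a
fudge factor $s_0$. With more than two classes the statistic is F-like:
$\sqrt{c\,\mathrm{SSB}/(K-1)}$ over $\sqrt{c\,\mathrm{SSW}/(n-K)} + s_0$
with $c = \sum_k 1/n_k$, so that it reduces to $\sqrt F$ at $s_0 = 0$.

The fudge factor is chosen by the classical percentile search: candidates are
the 0, 5, …, 100 percentiles of the $s_g$ distribution, genes are binned by
deciles of $s_g$, and the candidate minimizing the coefficient of variation
of the per-bin median $|d|$ is selected. Ties resolve to the lowest
percentile, so a constant-spread input returns the 0th percentile candidate.
A fixed $s_0$ can be supplied instead.

The null is built by relabeling samples (default 100 cycles, the usual SAM
setting for cohorts of this size). Per-gene p-values pool the permuted
$|d|$ across genes and permutations; counting is inclusive ($\geq$) and the
p-value is floored at $1/(B \cdot G)$ so it is never zero. Q-values are
empirical FDRs: for gene $g$, the median across permutations of the count of
permuted $|d| \geq |d_g|$ (taking $\hat\pi_0 = 1$, a conservative choice),
divided by the number of observed $|d| \geq |d_g|$, capped at 1 and made
monotone from the top of the ranking down. This is simpler than the original
$\Delta$-table machinery but honors the same contract: genes flagged at
FDR < 0.05 (the default cutoff). If more permutations are requested than
distinct relabelings exist, the distinct relabelings are enumerated
exhaustively and a warning is issued.

Fold changes are reported as "R fold" — the anti-logged difference of group
means, $2^{\bar x_{case} - \bar x_{ref}}$ — following the SAM convention;
values below 1 indicate under-expression in the case group. For multiclass
runs the ratio of the largest to the smallest group mean is reported.

### Moderated t

The inner engine of the subsampling selector is an empirical-Bayes moderated
t. Per gene, the pooled two-group variance $s_g^2$ on $d_g = n_1 + n_2 - 2$
degrees of freedom is shrunk toward a prior scale:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and $\tilde t_g$ is referred to a t distribution on $d_0 + d_g$ degrees of
freedom. The hyperparameters $(d_0, s_0^2)$ are fitted by closed-form moment
matching on $\log s_g^2$ (mean and variance of the implied log-F
distribution, inverting the trigamma function by Newton iteration) — a
deterministic fit with no optimizer. When the observed spread of
$\log s_g^2$ is no larger than the sampling noise, $d_0 = \infty$ and all
variances collapse to $s_0^2$. Forcing $d_0 = 0$ recovers the ordinary
pooled-variance two-sample t exactly, which the tests exploit as a limit
oracle; `limma` serves as an independent cross-check of the fit in the test
suite, not as the implementation.

Benjamini–Hochberg adjustment is delegated to `stats::p.adjust` behind a
validating wrapper.

## The consensus-signature selector

The selector formalizes signature construction by repeated balanced
subsampling: draw $k$ samples per class without replacement, run the
moderated t on the subset, count the genes with $q$ below the per-contrast
cutoff, and repeat. Genes are ranked by selection frequency; the signature
is the top $N$. Two presets mirror the study designs this implements:

* `mut200` — 7 vs 7 subsets, 10000 contrasts, q < 0.01, top 200 (for a
  22-mutated vs 13-unmutated split);
* `rs75` — 4 vs 4 subsets, 7425 contrasts, FDR < 0.10, top 75 with a
  minimum of 10 significant contrasts (for a 13 vs 6 *SF3B1* split).

Design choices made where the procedure is genuinely open:

* Distinct contrasts may repeat subsets — with 10000 contrasts and
  $\binom{13}{7} = 1716$ subsets on one side, repetition is unavoidable — so
  no duplicate detection is attempted.
* The "recursive" description of such algorithms is interpreted as iterated
  subsampling and implemented iteratively.
* Ties at the signature boundary are broken by mean $|\tilde t|$ across
  contrasts (effect-size aware), then lexicographic gene ID, making the
  output fully deterministic given the seed.
* The minimum-contrast filter applies only when configured; the 200-gene
  preset leaves it unset.

As a joint check that a selected signature predicts the class split, a
permutation global association test is provided: with row-standardized
expression $x$ and centered labels $\tilde y$,
$Q = \sum_{g \in S} \left( \sum_s x_{gs} \tilde y_s \right)^2$, with the
p-value from random relabelings, $(1 + \#\{Q_b \geq Q\})/(1 + B)$ (default
$B = 9999$). Row standardization makes $Q$ scale-free; constant genes
contribute zero. This is a permutation re-implementation of the
"global test" idea — the asymptotic version is intentionally not provided.

## Contingency statistics

Gene-list overlap validation and functional enrichment both reduce to 2×2
tables over an explicit gene universe. The universe matters: enrichment
defaults to the measured array background (all genes in the expression
matrix), not the genome, since over-representation analyses are notoriously
background-sensitive.

* Odds ratios use $ad/bc$ with the Haldane–Anscombe +0.5 correction applied
  to all cells only when a zero cell occurs, and Woolf log-scale confidence
  intervals.
* `fisher_exact` computes exact hypergeometric tails by summing point
  masses; the two-sided p sums all tables whose probability does not exceed
  the observed one (with the standard 1e-7 tie slack). Fisher and chi-square
  always operate on raw, uncorrected counts.
* `chi_square_2x2` is the classical formula, optionally Yates-corrected;
  zero margins are an error rather than a silent NaN.
* `enrich` reports one-sided over-representation p-values per set, with the
  EASE variant decrementing the overlap by one (floored at zero) for
  conservatism, and BH adjustment across sets.

For the two-SNP haplotype case-control comparison the package reports the
uncorrected chi-square *and* both Fisher tails side by side: published
analyses of this kind often print a single unnamed p-value, and on the
canonical 12/100 vs 5/100 carrier split the uncorrected chi-square gives
p ≈ 0.076 while the one-sided Fisher gives p ≈ 0.063 — either rounds to the
customary "p = 0.07". No attempt is made to adjudicate which test such a
value came from.

## Variant triage

The cascade applies three filters in the order used by targeted-capture
screens: known SNPs (matched by `(chrom, pos, alt)` key *or* by ID, since
catalog builds differ), then non-coding positions (anything outside the CDS
intervals of the supplied transcript models; splice and UTR subcategories
are not modeled), then synonymous changes. Survivors are exactly the
missense / nonsense / start-loss variants. Every stage reports kept and
discarded counts, and kept + discarded equals the stage input by
construction.

Annotation is codon-level: the genomic position maps to a spliced CDS
offset (counted from the rightmost CDS base on the minus strand, with
alleles complemented), the affected codon is mutated, and both codons are
translated with the standard nuclear code (`Biostrings::GENETIC_CODE`).
A reference allele inconsistent with the CDS sequence is a hard error
naming the position — silent reference drift is the classic failure mode of
hand-maintained transcript models. Coordinates are 1-based inclusive
throughout, matching VCF convention. Only single-nucleotide substitutions
are handled; indels are rejected with a clear error, since every variant
this machinery targets is a substitution.

Haplotype classification at two linked sites is deliberately strict:
`variant` requires the variant allele at *both* sites, `common` at neither,
and anything discordant is `other`; samples with missing genotypes are
skipped with a warning and counted.

## The synthetic cohort generator

The generator exists so that every stage is testable with known ground
truth; it is an idealization, not a cohort model.

* Baseline per-gene means are Normal(7, 1.5) on the log2 scale — the rough
  location and spread of RMA-normalized arrays — with i.i.d. Normal residuals
  (default SD 0.7). Optionally, per-gene variances are drawn from a scaled
  inverse chi-square (e.g. $d_0 = 4$, $s_0^2 = 0.25$) to exercise the
  moderated-t hyperparameter fit.
* Default group sizes are 30/39/31 (case, other-MDS, control), the scale of
  a typical low-risk MDS profiling cohort; mutation splits of 22 vs 13 and
  13 vs 6 are built with `label_mutation_status()`.
* Planted genes (default 100 at +2 log2 units) are up-regulated in the case
  group only.
* The variant generator emulates a 6-sample capture screen: per-sample
  counts Poisson(1367), 56% of variants matching the known-SNP catalog, 15%
  coding, and 6.3% coding-and-non-synonymous — so the three cascade stages
  discard roughly 56%, 85% and 58%, the proportions seen in such screens.
  One pseudo-chromosome per transcript model, forward-strand CDS in
  generated fixtures (reverse-strand logic is exercised by dedicated unit
  fixtures), positions of coding variants drawn inside the CDS with
  rejection sampling to hit the requested consequence class.
* Seeds are explicit arguments everywhere; there is no hidden global
  random state, and equal seeds give byte-identical outputs.

What the generator does **not** emulate: probe-level artifacts, batch
effects, correlated gene modules, heavy-tailed intensity distributions,
linkage structure between variant sites, or sequencing error profiles.
Passing tests on this generator therefore demonstrate the *statistical
contracts* of the methods (calibration under the null, recovery of planted
effects, exact accounting), not their behavior on every pathology of real
data.

## Numerical choices and problem sizes

* Permutation p-values are inclusive-tied and floored away from zero;
  q-values are monotone-enforced from the top of the ranking.
* The trigamma inversion runs Newton to a 1e-10 relative tolerance.
* All-zero spreads in the fudge search return a small positive value with a
  warning rather than dividing by zero.
* The test suite and the acceptance script size their simulations to run on
  a single CPU in minutes: null calibration uses 2000-gene cohorts (plus 20
  seeds of 1000 genes for call-rate averaging), power checks use 2000 genes
  with 100 planted, the selector runs 1000 of the preset's 10000 contrasts
  (the full preset is a few minutes more), and the hyperparameter-recovery
  check uses 5000 genes. These sizes were chosen once as adequate for the
  properties being measured.

## Interface notes

File formats are the field's plain-text standards: expression and phenotype
TSV, GMT gene sets (read via `fgsea`), a VCF v4.2 subset with per-sample GT
(read via `vcfR`), transcript models as TSV plus a CDS FASTA (via
`Biostrings`). Writers can stamp the generating seed into a comment header
so that any output can be regenerated exactly. The exported functions are
the package's interface; `scripts/acceptance.R` in the source repository
shows an end-to-end run of every stage.

## Known limitations

* The SAM q-value is an empirical FDR with $\hat\pi_0 = 1$; it is
  conservative relative to estimators that fit $\pi_0$.
* The moderated-t engine covers two-group contrasts only — no multi-factor
  designs, covariates, or paired structure.
* The multiclass SAM statistic is one of several F-like variants in use;
  permutation calibration makes the choice immaterial for calling, but the
  statistic values themselves are not comparable across variants.
* `fisher_exact` enumerates the full support of the margin, which is exact
  but not the fastest route for very large tables (fine up to totals around
  1e6).
* The variant model is SNV-only, with a three-way coding classification;
  splice-site effects and indels require a richer transcript model than the
  cascade needs for its purpose.
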