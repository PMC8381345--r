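---
title: "Methods: integrative triage of a GWAS locus"
author: "locustriage"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(locustriage)
```

# The problem

A genome-wide significant GWAS locus typically spans many genes in strong
linkage disequilibrium (LD), and the association alone cannot say which
gene mediates risk. `locustriage` combines three independent lines of
evidence to triage the candidates:

1. **Functional evidence** — gene rankings from a pooled CRISPR
   loss-of-function screen of host factors (e.g. genes whose knockout
   protects cells from a viral infection);
2. **Aggregate genetic evidence** — whether GWAS association signal is
   inflated at the regulatory variants (lead cis-eQTLs) of the screen's
   top-ranked genes, indicating that the screen's biology is relevant to
   disease risk in humans;
3. **Locus-level genetic evidence** — Bayesian colocalization of the GWAS
   signal with each gene's cis-eQTL signal in each tissue or cell type,
   asking whether the two associations share one causal variant.

The outputs are integrated into a per-gene, per-dataset prioritization
table (`build_priority_table()`).

# Screen ranking

Guide read counts are normalized to counts per million (CPM) per sample
— the minimal depth correction; alternatives such as median-of-ratios
matter mostly when library composition shifts massively, which the
second-best statistic is already robust to. Replicates are averaged on
the normalized scale and the guide-level statistic is
`log2((infected + 1) / (control + 1))`; the pseudocount of 1 CPM keeps
dropout guides finite. Enrichment means *higher* abundance in infected
(surviving) cells: loss of a host-dependency gene protects the cell, so
its guides are over-represented among survivors.

Three gene statistics are computed (`screen_scores()`):

* **sbscore** — the second-highest guide fold-change. One spuriously
  enriched guide cannot carry a gene; two concordant guides can.
* **RRA rho** — with a gene's `k` guide ranks normalized by the total
  guide count and sorted, `rho = min_j P(Beta(j, k-j+1) <= r_(j))`, the
  most surprising order statistic under the uniform null. No p-value or
  FDR is attached to rho; it is used purely as a ranking statistic.
* **RIGER-style weighted sum** — `w * r_(1) + (1-w) * r_(2)` on the two
  best normalized ranks. The original software's weights are not
  published; the default `w = 0.25` leans toward the second-best rank
  (consistent with the sbscore philosophy) and is configurable.

Guide ranks are made a strict permutation by breaking fold-change ties on
guide id: RRA's order statistics require distinct ranks, and the
tie-break makes results deterministic. The screen's top-N union
(`top_ranked_union()`) takes the union of each method's top `n` genes,
optionally intersected with a protein-coding universe.

# Inflation of GWAS signal at lead cis-eQTLs

For a set of p-values, the quantile inflation statistic is

    lambda_q = Q_chisq1(1 - quantile_q(p)) / Q_chisq1(1 - q)

with `q = 0.1`: the chi-square(1) quantile implied by the 10% most
significant tests, relative to its null expectation. `lambda = 1` under
uniformity; `> 1` indicates excess association signal. The empirical
quantile uses R's default type-7 (linear interpolation) convention,
recorded in the result object, since the convention shifts lambda
slightly at small n.

Significance comes from a permutation null (`permutation_inflation_test()`):
`|target|` genes are drawn uniformly *without replacement* from the
background lead-eQTL set (a draw is a gene set, and the target is itself a
set of distinct genes) `k` times, each gene contributing the GWAS p-value
at its lead eQTL variant. Permuted lambdas are log-transformed, which
makes the null distribution approximately symmetric, and the two-sided
p-value is

    p = (1 + #{ |log(lambda_perm) - c| >= |log(lambda_obs) - c| }) / (k + 1)

The centering `c` of the extremity rule is not fully determined by the
verbal description "as extreme as or more extreme"; we default to the
permutation mean of `log(lambda)` (`center = "mean"`), with `center =
"zero"` available. The `+1` correction keeps p strictly positive, and the
whole procedure is bitwise reproducible under a fixed seed. A target
equal to the entire background is allowed as a degenerate self-comparison
(p near 1). Type-I error at the 5% level is calibrated to within two
points (checked over 500 null replicates in the test suite), and null
p-values are uniform by a Kolmogorov–Smirnov check.

# Colocalization

## Approximate Bayes factors

Per variant, with `z = beta/se`, `V = se^2` and prior effect variance
`W`, the log approximate Bayes factor against the null is

    labf = 0.5 * log(1 - r) + 0.5 * r * z^2,   r = W / (V + W).

Prior effect SDs default to the single-variant ABF conventions: `0.2` on
the log-odds scale for case-control traits and `0.15 * sdY` for
quantitative traits. Expression in the major eQTL resources is
rank-normalized, so `sdY = 1` is the default; `estimate_sdY()` (a
through-origin regression of `2 n maf (1-maf)` on `1/se^2`) is available
when the trait scale is unknown, and errors rather than returning a
nonsensical value when its slope is non-positive.

## Hypothesis posteriors

Under one causal variant per trait, five hypotheses are scored from the
per-variant log ABFs of the two traits on their shared, allele-harmonized
variant panel: H0 (no association), H1/H2 (one trait only), H3 (two
distinct causal variants), H4 (one shared causal variant). All hypothesis
sums are accumulated by log-sum-exp; the H3 term `sum_i sum_{j != i}` is
computed as a stable log-difference, with floating-point ties (relative
log-difference below 1e-9) clamped to zero mass rather than erroring — a
single-variant panel then yields exactly `PP3 = 0`. The test suite checks
the log-space computation against naive direct summation on panels of up
to 50 variants at 1e-10. Defaults follow the standard priors
`p1 = p2 = 1e-4`, `p12 = 5e-6`, and `PP4 > 0.5` is exposed as a
"suggestive colocalization" flag.

Analysis regions are built around the lead GWAS variant: genes are
eligible for testing when they have a cis-eQTL with nominal `P < 1e-4`
within 100 kb of the lead (closed window), and the analysis panel is the
+/- 500 kb region (positions are 1-based and all windows are closed
intervals — the conventions the window arithmetic depends on). Variants
are joined across datasets by the full `chrom:pos:ref:alt` identity;
rsIDs are never used for joining. When two datasets carry the same
position with swapped ref/alt, the record is aligned by flipping the
effect sign (and `eaf -> 1 - eaf`); strand-ambiguous A/T and C/G
mismatches are dropped with a logged count. This flip-and-drop rule is
the conservative standard for harmonizing summary statistics whose
allele orientation is not guaranteed consistent.

## Masking secondary signals

Allelic heterogeneity (several independent cis-eQTLs for one gene)
violates the single-causal-variant assumption and can dilute PP4.
`find_signals_masked()` selects up to 3 independent signals greedily:
take the smallest unmasked p-value, stop if it is not below `1e-4`, then
mask every variant with `r^2 > 0.01` to the selected lead. `coloc_masked()`
then runs one colocalization per signal on a panel purged of variants
linked to the *other* leads, reporting per-signal posteriors and the
maximum PP4; the GWAS side is treated as single-signal, and masking is
applied to the eQTL side only (the side whose LD reference is available
and whose secondary signals are the concern). Conditioning on genotype
dosages (an alternative to masking) is out of scope. With zero or one
signal the masked run reduces exactly to the single run.

LD `r^2` is the squared Pearson correlation of dosage vectors
(`ld_r2()`); monomorphic variants have undefined `r^2`, are flagged, and
are treated as unlinked during masking. `weighted_r2()` averages
per-population matrices elementwise with weights (e.g. ancestry counts)
normalized to one, excluding missing entries pairwise with weight
renormalization. Population subsetting of the reference panel is the
caller's responsibility via the dosage input.

# Prioritization table

Genes in the locus are scored per eQTL dataset by the nominal p-value of
the *lead GWAS variant* in that dataset (not each gene's own lead eQTL):
the question is which gene's expression the GWAS variant moves. Datasets
where any gene clears `P < 1e-4` are highlighted. `build_priority_table()`
performs a full outer join on (gene, dataset) with screen ranks attached,
a deterministic row order (the caller's gene order — typically genomic
position — then dataset id) and explicit `NA` for missing cells; ties in
p-value rankings break on gene id. Gene coordinates can be read from BED
(0-based half-open) and are converted to the package's 1-based closed
convention.

# Synthetic data

The generators produce data with the statistical structure the analysis
assumes, so the whole pipeline is testable offline:

* **Genotypes** (`simulate_genotypes()`): a latent Gaussian copula with
  AR(1) site correlation `rho^|i-j|`, thresholded per haplotype at each
  site's allele-frequency quantile; dosage = sum of two haplotypes. This
  gives analytically controllable LD decay without a coalescent
  simulator. Defaults (2,000 individuals, 200 variants, MAF uniform on
  \[0.05, 0.5\], `rho = 0.9`, ~500 kb span) emulate a dense common-variant
  panel over one LD block.
* **Marginal summary statistics** (`marginal_sumstats()`): closed-form
  simple linear regression for quantitative traits; for case-control, a
  score-test-based one-step approximation to logistic regression (exact
  `glm` fits available via `method = "glm"`, with agreement checked at
  n = 2,000 in the tests). Monomorphic variants yield flagged missing
  rows.
* **Trait pairs** (`simulate_trait_pair()`): disease liability
  `beta_gwas * dosage + N(0,1)` dichotomized at the empirical case
  fraction (default 0.5, a balanced design that maximizes power at fixed
  n); expression `beta_eqtl * dosage + N(0, 1)`. The shared / distinct /
  null regimes correspond to the H4 / H3 / H0-H2 colocalization truths.
  In the recovery checks, effect sizes are set to hit a target marginal
  z-score of about 8 at the causal variant — a strong but realistic
  lead-association strength — via
  `beta = z / sqrt(2 n maf (1-maf))` (times `1/sqrt(phi(1-phi))` on the
  liability scale).
* **Screen counts** (`simulate_screen_counts()`): negative binomial
  counts (dispersion 0.25, typical of pooled screens) at mean depth
  1,000 reads/guide for 1,000 genes x 6 guides; hit-gene guides are
  enriched `2^3`-fold in infected samples and totals are rescaled to a
  fixed sequencing depth. Defaults plant 20 hits.
* **Inflation backgrounds** (`simulate_inflation_background()`): uniform
  GWAS p-values for background lead eQTLs via the chi-square survival
  transform; target genes' chi-square draws are multiplied by the target
  inflation factor, so the realized `lambda_0.1` approximates the
  multiplier.

What the generators do **not** emulate: realistic demographic LD (no
recombination hotspots or allele-frequency/LD coupling), winner's-curse
selection of lead variants, sample overlap between GWAS and eQTL cohorts,
uncontrolled confounding, or sequencing-read-level artifacts in screens.
Passing the recovery checks therefore demonstrates correctness of the
statistical machinery under its own assumptions, not robustness to every
failure mode of real cohort data.

# Numerical and design choices

* Empirical quantiles: R type 7, recorded in results.
* Perfect-fit regressions clamp the residual variance at the smallest
  positive double, and p-values are floored at the same to stay in
  (0, 1].
* `exp` overflow is avoided everywhere in the colocalization engine via
  log-sum-exp; the direct-summation cross-checks are run in the regime
  where naive exponentials are representable.
* Tie-breaks (guide ranks, gene ranks, lead-variant selection) are
  deterministic and documented on the respective functions.
* Every generator and the permutation test are pure functions of their
  seed; the demo writes a manifest of md5 content hashes and two runs
  with the same seed are bitwise identical.
* Problem sizes in the shipped checks (e.g. 20-50 replicates of
  2,000 x 200 panels, 200-500 null replicates at k = 300-500 permutations,
  20-50 simulated screens) were chosen as the smallest sizes at which the
  Monte-Carlo error is comfortably below the margins being asserted.

# Limitations

* Single-causal-variant colocalization with masking only; no
  multi-signal fine-mapping (SuSiE-style) and no conditional analysis.
* The inflation test treats lead eQTLs as exchangeable across genes; no
  LD-aware pruning between lead variants of different genes.
* No genome-build liftover, no tabix random access; dosage input is TSV
  (VCF ingestion is not implemented).
* The exact centering of the two-sided permutation rule in prior work is
  underdetermined; results near the significance boundary can shift
  between `center = "mean"` and `center = "zero"`.
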