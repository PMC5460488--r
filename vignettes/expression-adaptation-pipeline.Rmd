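---
title: "Linking expression divergence to noncoding adaptation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking expression divergence to noncoding adaptation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcorr)
```

## The question the pipeline answers

When two closely related species — a human/chimpanzee comparison is the
motivating case — differ both in gene expression and in the amount of
adaptive change in noncoding, putatively regulatory DNA, are those two kinds
of divergence concentrated in the *same biological functions*? The unit of
inference here is not the gene but the gene set: the pipeline asks whether,
within a collection of functionally defined gene sets, the sets most
enriched with differentially expressed genes are also the sets most enriched
with genes near adaptively evolving noncoding regions.

`funcorr` implements that inference chain end to end:

1. **Differential-expression scoring** from a multi-tissue count matrix with
   a negative-binomial GLM (`fit_de_glm()`); the per-gene score is
   `-ln` of the BH-adjusted p-value of the species contrast.
2. **Tissue specificity** of divergence via squared-cosine scores
   (`specificity_scores()`).
3. **Gene-set enrichment** as a rank-biserial correlation between gene
   scores and set membership, with a bootstrap standard error
   (`rank_biserial()`, `bootstrap_se()`, `enrich_collection()`).
4. **Meta-analytic combination** of adaptation enrichments across several
   selection-scan studies with inverse-variance weights, Cochran's Q
   heterogeneity test and retention filters (`combine_studies()`).
5. **Functional correlation**: per collection, the Spearman correlation
   between the DE-enrichment profile and the meta-combined
   adaptation-enrichment profile, with an overlap-aware gene-level
   permutation p-value and BH q-values across collections
   (`overlap_aware_permutation_test()`).
6. A **synthetic-data generator** (`sim_config()`, `simulate_dataset()`)
   that produces all inputs with known ground truth, including a planted
   set-level coupling the pipeline must recover.

## Differential-expression model

For gene $g$ and sample $j$ the count model is

$$\log \mu_{gj} = o_j + \beta^{\text{tissue}}_{t(j)} +
\beta^{\text{species}}_{s(j)} + \beta^{\text{int}}_{t(j),s(j)},
\qquad y_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi_g),$$

with offsets $o_j = \log(\text{library size})$ (optionally with a
trimmed-mean-of-M-values composition adjustment, `tmm = TRUE`). The overall
species p-value is a likelihood-ratio test of the full model against the
model with every species-related coefficient (main effect and all
interactions) removed — analysing all tissues in one model rather than one
model per tissue maximises power and mirrors the motivating study design.
Per-tissue species contrasts are Wald tests of the within-tissue species
coefficient in the cell-means parameterisation; the tissue factor is tested
by dropping its main-effect columns.

**Dispersion.** $\phi_g$ is a method-of-moments estimate shrunk 50/50
toward the common dispersion, not an empirical-Bayes estimate: within each
species-by-tissue cell we compute $\sum_c (v_c - m_c) / \sum_c (m_c^2 -
v_c/n_c)$ (the denominator correction removes the upward bias of $m_c^2$ as
an estimate of $\mu^2$), and the common value is the unweighted mean of the
per-gene estimates. Two numerical points matter and were found the hard
way: (a) pooling the common dispersion as a ratio of sums weights each gene
by a quantity that shares sampling noise with the estimate itself and is
biased low, which makes every likelihood-ratio test anticonservative — the
unweighted mean across genes is nearly unbiased; (b) with the true
dispersion plugged in, the LRT p-values are uniform to KS distance ~0.02 at
this design size (40 samples), so residual miscalibration is attributable
to dispersion estimation, not to the $\chi^2$ asymptotics.

Genes with zero counts in every sample are excluded from testing and carry
`NA` p-values, as do the rare non-convergent fits — never a silent 0 or 1.
Adjusted values are Benjamini–Hochberg (a conservative, parameter-free
choice relative to smoothed q-value estimators), and scores clamp `q` at
`1e-300` before the logarithm so a zero cannot produce an infinite score.

## Rank-biserial enrichment and its bootstrap SE

For a set with membership indicator $m$ over the $N$ scored genes, with
midranks $R$,

$$r_{rb} = \frac{2\left(\bar R_{\text{in}} - \bar R_{\text{out}}\right)}{N}
= \frac{2U}{n_1 n_0} - 1,$$

where $U$ counts member-over-non-member wins with ties worth $\tfrac12$.
The identity between the two forms (and the midrank tie policy that keeps
it exact) is enforced by a property test against a brute-force pairwise
count. The SE is the standard deviation of $r_{rb}$ over bootstrap
resamples of the (score, membership) pairs; resampled duplicates are
genuine ties, and replicates that lose one class entirely are redrawn so
the SE is over exactly `B` valid replicates. Each set's resampling stream
is seeded from the master seed plus the set id, so results do not depend on
iteration order.

## Meta-analytic combination

Per-study enrichments $(r_i, s_i)$ for a set combine as
$\mathrm{WM} = \sum_i w_i r_i$ with $w_i \propto 1/s_i^2$ normalised to sum
to one. Heterogeneity uses Cochran's form $Q = \sum_i s_i^{-2}
(r_i - \mathrm{WM})^2 \sim \chi^2_{n-1}$; a `normalized` switch reuses the
normalised weights instead, but under that form $Q$ cannot have the stated
$\chi^2$ reference distribution, so Cochran's is the default. A set is
retained iff it appears in at least 2 studies, $Q$ is not significant at
0.05, and it averages at least 50 measured genes over the studies that
scored it. Bootstrap SEs of exactly zero (perfect separation in a small
universe) are floored at `1e-6` before weighting.

## The overlap-aware permutation test

Gene sets within a collection overlap, so their enrichment statistics are
correlated and a naive permutation of set-level values among sets
overstates significance. The null here is built at the gene level: each
replicate permutes the DE scores among the DE universe and each study's
adaptation scores among that study's covered genes (independently — the
stricter null for a correlation between the two sides), recomputes every
per-set $r_{rb}$ against the fixed memberships, recombines the study values
with the *frozen observed weights and retained-set lists*, and records the
replicate correlation. The one-tailed p is the fraction of replicates at or
above the observed correlation, reported as `"<1/B"` (with numeric
companion `1/B` for q-value computation) when no replicate reaches it.

Weights and retention are deliberately not recomputed per replicate:
re-estimating 10,000 bootstrap SEs inside each of 10,000 permutations is
computationally prohibitive, and freezing them conditions the test on the
observed precision structure. Replicates whose correlation is undefined
(a constant profile) count as non-exceedances. The naive set-level
permutation remains available (`permute = "sets"`) as a diagnostic.

A structural point uncovered during validation: overlap that is
*exchangeable* across sets — every pair sharing roughly equally in a pool
of popular genes — barely inflates the set-profile rank correlation,
because a common additive component moves all sets together and cancels in
ranks. What inflates it is *clustered* overlap: families of closely
related, partially redundant sets, which is exactly the structure of
curated collections. The generator therefore draws popularity orderings
per cluster of sets (`cluster_size`, default 6), and the anti-conservatism
of the naive test is asserted on pairs with observed correlation above
zero — the only regime in which a one-tailed test can claim significance;
below zero the comparison reverses sign by symmetry and a marginal test
cancels.

## The synthetic-data generator

`simulate_dataset()` emulates the study design the pipeline targets: two
species with `n_per_species = 4` individuals each across `n_tissues = 5`
tissues (one sample per individual per tissue), NB counts with dispersion
`0.1` (a typical biological CV for primate bulk RNA-Seq), log-normal
baseline intensities, per-gene per-tissue effects of scale 1 (making
tissue, not species, the dominant factor, as in real multi-tissue data),
planted species log-fold changes of half-normal scale 1 for ~30% of genes
(~a third tissue-confined), library sizes 0.8–1.2 million, three
adaptation studies each covering an independent 80% of genes with
between-study heterogeneity 0.25 and measurement noise 1, and three
collections of 60 sets of 100–250 genes.

**Coupling.** A latent nonnegative effect per set of the first collection
is added both to its member genes' DE propensity / effect magnitude and to
their adaptation propensity; `coupling` ($\kappa$, default 0.6) scales it.
At the defaults the truth-level Spearman correlation between per-set mean
planted DE effect and per-set mean adaptation propensity is ~0.6, the
gene-level score correlation stays weak (~0.05) — echoing the empirical
picture of near-zero genic correlation alongside clear set-level signal —
and the pipeline recovers the coupled collection at `p <= 0.01` in
essentially every dataset while uncoupled collections reject at the
nominal rate.

**Why uncoupled collections are drawn from genes outside the coupled
sets.** If all collections share one gene pool, any gene-level coupling
mechanism leaks: genes inside coupled sets also populate other
collections' sets, those sets genuinely co-enrich, and "uncoupled"
collections reject at 25–50%. That is a property of every generative model
in which coupling acts through genes, not a bug in the test. Since the
generator's purpose is validation — uncoupled collections must function as
a false-positive control — the remaining collections are drawn from the
genes outside the coupled collection, making their null exact. Real
collections do share genes; what passing tests show is that the test is
calibrated when no gene-level association exists, and powerful when a
set-level one does. They do not show the test separates *which* collection
carries a shared genome-wide signal, because no permutation test of this
null can.

One master seed streams to independent per-component sub-seeds
(`derive_seed()`), so counts, sets and scores can be regenerated
independently and identical seeds give bit-identical datasets.

## Problem sizes used in the validation suite

The test suite fixes its own simulation sizes: the calibration of the
overlap-aware test uses 200 datasets of 2,000 genes with 3 collections of
40 sets and 500 permutations; the power analysis uses 50 datasets at the
generator defaults; GLM calibration and ranking use 2,000-gene datasets;
the exhaustive permutation oracle uses a 5-gene, 2-set instance where all
$(5!)^2$ permutation pairs can be enumerated; the bootstrap oracle
enumerates all $4^4$ resamples of a 4-gene universe. Bootstrap SEs inside
the simulation studies use 60–200 replicates (they only set meta-analysis
weights there); the analysis scripts use 1,000 and the worked examples
10,000, matching the reporting convention of the motivating design.

## What the generator does not emulate

Read-level artifacts (mapping bias, GC effects), ortholog-definition error
between species, correlated expression between genes beyond set structure,
gene-length effects on counting, and real MSigDB content. Passing tests
demonstrate statistical correctness of the machinery under the stated
generative model, not robustness to those upstream artifacts.

## Known limitations

- The NB GLM uses plug-in dispersions; p-values are mildly liberal at the
  margins (null rejection ~6–7% at the 5% level on 2,000-gene datasets)
  though BH-level false discovery stays controlled. Empirical-Bayes
  moderation would tighten this at the cost of reimplementing a large
  machinery that exists elsewhere.
- The per-tissue species contrasts are Wald tests; at four samples per
  cell they are slightly less accurate than likelihood-ratio tests.
- "`<1/B`" p-values are a reporting floor, not an estimate; q-values
  computed from them inherit the floor.
- With `min_studies = 1` the heterogeneity filter is vacuous for
  single-study sets (`p_q` undefined, treated as passing); this is only
  intended for toy instances.
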