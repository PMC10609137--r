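---
title: "Methods and design of the mblink microbiome–lipidome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mblink microbiome-lipidome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mblink)
```

## What the pipeline computes

`mblink` analyzes a paired gut-microbiome / fecal-lipidome case–control
study of irritable bowel syndrome (IBS), with four groups (Control,
IBS-D, IBS-M, IBS-C), a monthly high-fructose corn syrup (HFCS)
consumption covariate in g/month, and socioeconomic covariates (income
bracket, marital status, alcohol, household occupants). Its stages:

1. **Rarefaction** of the ASV count table to an even depth.
2. **Alpha diversity** (Faith's phylogenetic diversity) with
   Kruskal–Wallis group tests and OLS regressions on socioeconomic
   covariates.
3. **Beta diversity**: unweighted UniFrac, principal coordinates
   analysis, and PERMANOVA by IBS status, subtype, income and marital
   status.
4. **Differential abundance**: rare-taxon filtering, centered log-ratio
   (CLR) transform, the ANCOM W statistic, and LEfSe effect sizes.
5. **Co-occurrence modules**: a taxon–lipid Pearson network, Louvain
   modules, and Kruskal–Wallis tests on summed module relative
   abundances.
6. **Phylogenetic balances**: one isometric log-ratio per internal tree
   node, with LASSO selection of the balances most associated with HFCS
   consumption and an unpenalized refit.
7. **Lipid panel statistics**: per-lipid Kruskal–Wallis (four groups),
   Mann–Whitney (Control vs IBS), log2 fold changes, Z-score profiles.
8. **PROTEST**: a Procrustes randomization test of microbiome–lipidome
   concordance on Bray–Curtis ordinations.

All of it is exercised end-to-end on synthetic paired data with planted,
recoverable structure (see below), since the package is a re-usable
method implementation, not a carrier of any particular dataset.

## Data model and conventions

Feature tables are integer matrices with samples as rows; readers
normalize orientation via a `transpose` flag. Trees are rooted, binary
`ape::phylo` objects; a multifurcating root in the input is resolved
with zero-length edges (and reported), because the balance builder needs
exactly two children per internal node. Lipid panels are samples ×
lipids concentration matrices in µg/g fecal dry mass; readings below the
lower limit of quantification are substituted with 0.001 (the sentinel
string and the substitution value are both configurable; the unit is
carried as metadata and never converted). Distance matrices must be
symmetric within 1e-12 with an exactly zero diagonal.

## Numerical and statistical choices

* **Rarefaction** samples reads *without replacement* (multivariate
  hypergeometric, drawn by sequential hypergeometric draws), so every
  retained row sums exactly to the depth; samples below depth are
  dropped, never up-sampled. Deterministic given a seed.
* **Unweighted UniFrac** uses presence/absence of the rarefied table:
  shared and unique branch lengths are accumulated per edge; floating
  point negatives in the unique-length difference are clamped at zero.
* **PCoA** eigendecomposes the double-centered squared-distance matrix;
  negative-eigenvalue axes are dropped (their count is reported) and
  proportions explained are relative to the positive-eigenvalue sum. No
  Lingoes/Cailliez correction is applied — the simplest defensible
  convention for these data.
* **PERMANOVA** is delegated to `vegan::adonis2` (999 permutations by
  default) and reported with the `(1 + count)/(1 + n_perm)` convention.
  For covariates that can have singleton levels (marital status), levels
  with fewer than two samples are excluded from that test.
* **HFCS by group** uses one-way ANOVA followed by Dunn's rank-based
  post hoc z tests with Bonferroni adjustment. The ANOVA-then-Dunn
  pairing is unconventional (Dunn's test normally follows
  Kruskal–Wallis) but is retained deliberately; both the F test and the
  pairwise results are reported.
* **Rare-taxon filter**: a taxon is removed only when its total count is
  below 500 *and* its mean count is below 3 — a conjunction, so either
  criterion alone keeps a taxon.
* **CLR / log-ratios** use pseudocount 1 throughout (configurable). CLR
  rows sum to zero by construction, and CLR is invariant to sample-wise
  count scaling when the pseudocount scales proportionally.
* **ANCOM**: for taxon *i*, W counts reference taxa *j* whose pairwise
  log-ratio differs across groups (Kruskal–Wallis; Benjamini–Hochberg
  within each taxon's m−1 tests, adjusted p < 0.05). The declaration
  cutoff defaults to the conventional 0.7·(m−1) but is a configuration
  knob, because published W values near 42/254 are sometimes described
  as differentially abundant even though no conventional cutoff would
  flag them; the package always reports the raw W values so readers can
  apply any cutoff.
* **LEfSe** here is the two-class reduction (no subclass stratification
  is available in this design): a Kruskal–Wallis screen at 0.05 on
  relative abundances scaled to a per-sample total of 10^6, then a
  bootstrapped (30 rounds, seeded) linear-discriminant effect size,
  reported as a log10 score signed toward the enriched class and
  thresholded at |score| ≥ 2.
* **Network**: taxa enter correlations as CLR values, lipids
  untransformed. Edges require Pearson r > 0.5 *and* p < 0.05 — strict
  inequalities, positive side only, with no multiple-testing correction
  on edge p-values (raw thresholds are part of the method definition).
  Modularity is maximized by Louvain on the *unweighted* graph
  (resolution 1) with 20 seeded random-vertex-order restarts, keeping
  the best-Q partition; module ids are renumbered by decreasing size so
  naming is reproducible. Module "relative abundances" sum taxon
  relative abundances only; lipid members are listed but excluded from
  the sums by default, since concentrations are not compositional — a
  flag exists to include them.
* **Balances**: one balance per internal node, numerator = first-parsed
  child subtree. The default transform follows the summed-reads wording:
  b = sqrt(rs/(r+s))·ln(Σ numerator/Σ denominator) on pseudocounted
  counts. The reference isometric construction with geometric means
  (`variant = "gmean"`) is also implemented; only the gmean variant is an
  isometry of CLR space, which the test suite verifies on 4-leaf trees.
* **LASSO** minimizes (1/(2n))·RSS + λ·‖β‖₁ by cyclic coordinate descent
  (soft-thresholding, coefficient-change tolerance 1e-8) on columns
  standardized to mean 0 and 1/n-variance 1, so λ has a fixed,
  documented meaning. λ defaults to 3000, which is interpretable here
  because the HFCS response is on the g/month scale (thousands); a
  published λ from other software can only be compared under a known
  standardization, so the value is a configuration default, not a
  reproduction claim. "Top 5" is implemented as a cap: the nonzero
  coefficients at λ, truncated to the 5 largest |standardized β|, then
  refit by ordinary least squares to report adjusted R², F and p.
* **Procrustes/PROTEST**: both coordinate sets are centered and scaled
  to unit sum of squares, zero-padded to a common axis count (all
  positive-eigenvalue axes by default; an `axes` cap exists), and the
  full orthogonal group (reflections included) with optimal scaling is
  used, giving Gower's m² in [0, 1] symmetrically. The null permutes the
  lipidome coordinate rows (either side is equivalent; one is fixed for
  determinism). Two p-values are reported: the *better-fit fraction* —
  the fraction of null m² values strictly lower than the observed, i.e.
  of random sample matchings fitting better, so an observed disparity
  lower than 99.8 % of nulls reads p = 0.002 — and the conventional
  permutation significance (1 + #{null ≤ observed})/(1 + n_perm). The
  two agree in magnitude for strong concordance but are not the same
  quantity; reporting both avoids silently reinterpreting either.
* **Lipid statistics** use uncorrected p-values at 0.05 by design (the
  per-lipid tests are descriptive); fold changes are
  log2(mean IBS/mean Control) with medians available as an option; the
  Mann–Whitney U is oriented as the number of (Control, IBS) pairs with
  the larger Control value; Z profiles standardize each lipid over all
  samples jointly before group means, so the group-size-weighted means
  are exactly zero.

## The synthetic-data generator

The generator emulates the study design: 45 samples (12 Control, 10
IBS-D, 13 IBS-M, 10 IBS-C), 255 ASVs on a random rooted binary tree
(sequential random joins, exponential(1) branch lengths), ~60,000 reads
per sample (jittered ±~10 %), and a 30-fatty-acid panel. Counts follow a
logistic-normal-multinomial: per-sample taxon log-abundances are a taxon
baseline (N(0, 2), wide enough that many taxa are conditionally absent
and presence/absence metrics carry signal) plus

* per-group log shifts (a module depleted in IBS, a module enriched in
  IBS-C, and two single-taxon shifts mirroring the kinds of single-taxon
  findings such analyses report),
* three disjoint planted 12-taxon modules driven by per-sample latent
  factors with loading 2,
* a planted balance at one internal node (both subtrees 4–16 leaves):
  ±slope/2 per SD of HFCS applied antisymmetrically to the
  numerator/denominator leaves, slope 1 by default,
* iid N(0, 0.5) noise,

then softmax and a multinomial draw. HFCS is log-normal (medians ~3,000
g/month for Control, ~8,000 for IBS, sdlog 0.6) — the higher-in-IBS
pattern the design emulates, on a g/month scale that also makes λ = 3000
meaningful. Lipids are log-normal with saturated species at higher
baselines, named group shifts (palmitic 16:0 up in IBS-C, margaric 17:0
up in IBS-M/C, γ-linolenic 18:3n6 strongly down in IBS — more than
2-fold higher in Control — and 18:2n6/18:3n3 down in IBS), and the
module latent factors loading into disjoint 5-lipid blocks with weight
`coupling_strength` (default 1), which is the single knob that creates
microbiome–lipidome Procrustes concordance. All randomness flows from
one root seed, split deterministically per stage.

Effect sizes are synthetic conventions chosen once so that planted
structure is recoverable at n = 45; no published effect estimates exist
to calibrate against, and none of these defaults should be read as
claims about real effect magnitudes. A `null_design()` zeroes every
group-linked effect (group shifts, balance slope, lipid shifts,
coupling) while keeping the latent co-occurrence structure — modules are
structure, not group effects — so group labels are exchangeable and
every downstream test can be checked for calibration.

What the generator does **not** emulate: realistic taxonomies, sequence
level error, thousands of sparse ASVs, background correlation outside
the planted modules (so real data yield far fewer singleton modules than
the synthetic graphs), overdispersion beyond the logistic-normal, batch
effects, or longitudinal sampling. Passing tests therefore demonstrate
correctness and calibration of the *methods*, not expected performance
on any particular real cohort.

## Validation strategy and problem sizes

The test suite validates the primitives against independent oracles —
Faith's PD and UniFrac against exhaustive path-enumeration on all
presence patterns of trees with up to 6 leaves; Louvain modularity
against the exhaustive-partition maximum on graphs of up to 10 nodes;
ANCOM W against a naive per-pair testing loop at m ≤ 20; the LASSO
against the orthonormal soft-threshold closed form and an independent
convex solver's objective (1e-6) — plus exact identities (CLR row sums,
zero balances for equal subtree sums, m² = 0 for transformed copies at
1e-12, exact rarefaction row sums, CLR-isometry of gmean balances at
1e-9).

Calibration runs the whole stack under `null_design()` (45 samples, 100
taxa, depth 5,000, 999 permutations) over 200 seeds, checking
Kolmogorov–Smirnov uniformity (p > 0.01) of PERMANOVA, module
Kruskal–Wallis, lipid Mann–Whitney and PROTEST p-values, and that ANCOM
flags at most 5 % of taxa at the 0.7 cutoff. Recovery runs the default
design (255 taxa) over 50 seeds, requiring adjusted Rand index ≥ 0.9
between the recovered and planted modules in at least 90 % of seeds,
the planted balance inside the top-5 LASSO selection in at least 90 %,
and PROTEST conventional p ≤ 0.01 in at least 90 %. These sizes are the
package's validation conditions, chosen to give stable checks at
interactive runtimes.

## A short example

```{r example, eval = FALSE}
design <- generator_design(n_taxa = 120, depth = 20000)
sim <- simulate_study(design, seed = 1, dir = "example_data")
cfg <- pipeline_config(rarefaction_depth = 10000,
                       protest_n_perm = 999, seed = 1)
report <- run_pipeline(list(counts = sim$counts, tree = sim$tree,
                            lipids = sim$lipids,
                            metadata = sim$metadata),
                       cfg, output_dir = "example_out")
str(report$summary)
```

## Known limitations

* The summed-reads balance variant is not an exact isometry of CLR
  space; it is the default because it is the stated construction for
  this analysis, with the isometric gmean variant one flag away.
* LEfSe's subclass (one-against-all) logic is not implemented; with no
  subclass variable in this design the screen reduces to the two-class
  Kruskal–Wallis.
* Unweighted UniFrac after deep rarefaction of a small, dense taxon set
  saturates presence and loses power; this is a property of the metric
  and of compact synthetic communities, not of the implementation.
* PERMANOVA assumes exchangeability under the null; with strongly
  unbalanced designs and heteroscedastic dispersion its pseudo-F
  conflates location and dispersion effects, as usual.
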