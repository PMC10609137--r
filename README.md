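# mblink — paired microbiome–lipidome analysis for IBS cohort studies

`mblink` is an R package for case–control studies that pair 16S
gut-microbiome profiles with targeted fecal fatty-acid (lipidome)
panels, as in irritable bowel syndrome (IBS) cohorts with diet
(high-fructose corn syrup, HFCS) and socioeconomic covariates. It is
aimed at microbiome bioinformaticians who want one tested, seedable
pipeline for the full analysis rather than a scatter of scripts.

## What it computes

For samples in four groups (Control, IBS-D, IBS-M, IBS-C):

* **Diversity** — rarefaction (multivariate hypergeometric), Faith's
  phylogenetic diversity `PD = Σ branch lengths spanning the observed
  taxa`, unweighted UniFrac
  `d(A,B) = unique branch length / union branch length`, PCoA, and
  PERMANOVA pseudo-F with permutation p-values.
* **Differential abundance** — rare-taxon filter (remove iff total <
  500 **and** mean < 3), CLR transform, ANCOM
  `W_i = #{ j : KW(log((x_i+1)/(x_j+1))) significant after BH }`,
  and two-class LEfSe scores (KW screen + bootstrapped LDA effect size,
  log10-scaled and signed toward the enriched class).
* **Co-occurrence modules** — taxon–lipid Pearson network (edges only
  for r > 0.5 and p < 0.05; taxa as CLR, lipids untransformed), Louvain
  modularity maximization with seeded restarts, and Kruskal–Wallis tests
  on summed module relative abundances (H(1) for Control vs IBS, H(3)
  across the four groups).
* **Phylogenetic balances** — one isometric log-ratio per internal tree
  node, `b = sqrt(rs/(r+s)) · ln(Σ numerator / Σ denominator)` (a
  geometric-mean variant is also provided), LASSO
  (`(1/2n)·RSS + λ‖β‖₁` by coordinate descent, λ = 3000 by default) to
  select the top 5 HFCS-associated balances, with an unpenalized refit
  reporting adjusted R², F and p.
* **Lipid statistics** — per-lipid Kruskal–Wallis and Mann–Whitney
  tests (uncorrected, by design), log2 fold changes IBS vs Control, and
  per-group mean Z-score profiles for the 30-fatty-acid panel.
* **PROTEST** — Procrustes superimposition of the Bray–Curtis PCoA
  ordinations of microbiome and lipidome (Gower's m²) with a
  row-permutation null, reporting both the "fraction of permutations
  fitting better" p and the conventional `(1+count)/(1+n_perm)` p.
* **Synthetic data** — a generator that emulates the study design
  (45 samples: 12/10/13/10; 255 taxa; ~60,000 reads; 30 lipids) with
  planted co-occurrence modules, a planted HFCS-associated balance, and
  a latent-factor microbiome–lipidome coupling, plus a machine-readable
  truth file so every stage can be scored on recovery.

## Worked example

```r
library(mblink)

design <- generator_design(n_taxa = 120, depth = 20000)
sim <- simulate_study(design, seed = 7)
cfg <- pipeline_config(rarefaction_depth = 10000,
                       protest_n_perm = 499, permanova_n_perm = 199,
                       seed = 3)
report <- run_pipeline(list(counts = sim$counts, tree = sim$tree,
                            lipids = sim$lipids,
                            metadata = sim$metadata),
                       cfg, output_dir = "run1")

report$summary[c("permanova_status_F", "hfcs_anova_F",
                 "lasso_selected", "lasso_adj_r2",
                 "protest_p_conventional")]
#> $permanova_status_F
#> [1] 1.761677
#> $hfcs_anova_F
#> [1] 3.37632
#> $lasso_selected
#> [1] "n92"
#> $lasso_adj_r2
#> [1] 0.9572404
#> $protest_p_conventional
#> [1] 0.002
```

Reading the output: the PERMANOVA pseudo-F tests whether community
composition differs by IBS status; the ANOVA F tests group differences
in monthly HFCS consumption; `lasso_selected` names the phylogenetic
balances associated with HFCS (here exactly the generator's planted
balance `n92`, with the refit explaining ~96 % of HFCS variance); and
the PROTEST p says the microbiome and lipidome ordinations fit together
better than 499 of 500 random sample matchings. `run1/` holds the
per-stage TSVs, a `summary.json` of every statistic, and a
`manifest.json` (config + per-stage seeds) sufficient to reproduce the
run bit-identically.

A thin command-line wrapper with `simulate` and `run` subcommands is
installed at `inst/scripts/mblink`.

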