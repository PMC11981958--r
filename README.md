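# riverfacets

Fish biodiversity in montane rivers, from eDNA metabarcoding tables to
cause–effect pathways.

`riverfacets` is an R package for surveys that sample a dendritic river
network with replicated water filters, sequence a 12S fragment, and want
three facets of fish biodiversity per site — taxonomic richness (TD),
convex-hull functional richness (FD) and per-order nucleotide diversity
(GD) — together with models of how elevation, human footprint and water
quality shape them. It covers:

* **Curation** — single-nucleotide (d = 1) single-linkage clustering of
  ASVs, the read/length/fish/abundance filter cascade (≥ 10 reads,
  160–200 bp, relative abundance ≥ 0.001), LULU-style merging of
  erroneous daughters by identity (≥ 0.84), co-occurrence (≥ 0.95) and
  abundance ratio (≥ 1), and a ≥ 2-of-3 replicate consensus.
* **Taxonomy** — in-silico PCR of reference barcodes (150–220 bp window,
  ≤ 3 mismatches per primer), then identity-banded assignment: native
  exact matches at species level, otherwise ≥ 0.98 species, 0.96–0.98
  genus, 0.90–0.96 family, < 0.90 order, with LCA on ties.
* **Facets** — TD as incidence row sums; FD as the convex-hull volume of
  a site's ASVs in the ≥ 95%-variance PCoA space of nine unitless
  morphological ratios, normalised by the pool hull; GD as the unweighted
  mean over orders of nucleotide diversity π; Chao2 incidence
  extrapolation (`S_asym = S_obs + ((T−1)/T)·Q1²/(2Q2)`).
* **Spatial structure** — Moran correlograms with permutation inference,
  distance-weighted autocovariates with the radius coupled to the first
  significant correlogram class, and the `AutoCor` residual covariate.
* **Model comparison** — per-facet Gaussian GLMs `mod0: facet ~ elevation
  + footprint + AutoCor + Type` versus `mod1` with an
  elevation × footprint term, compared by the BIC Bayes factor
  `bf01 = exp(0.5·(BIC(mod1) − BIC(mod0)))`; GAM trends with Pearson
  correlations for upstream–downstream gradients.
* **PLS path modeling** — a from-scratch PLS-SEM engine (Lohmöller
  iteration, centroid/factorial/path schemes, Mode A/B blocks) for the
  formative model

  ```
  elevation ─→ footprint ─→ water quality ─→ biodiversity
       └──────────┴──────────────┴───────────────↑
  ```

  with effect decomposition (indirect = sum of coefficient products over
  directed paths) and a 100-permutation test of each path.
* **Synthetic river surveys** — `simulate_study()` generates a dendritic
  network, covariate gradients, facets from the structural equations, and
  per-replicate ASV tables with planted errors and known truth, so every
  stage is testable end to end without any download.

## Worked example

```r
library(riverfacets)

study <- simulate_study(sim_config(seed = 3))  # 33 sites, 232-ASV regional pool
cur <- curate(study$asv$table,
              setNames(rep(TRUE, nrow(study$asv$table$counts)),
                       rownames(study$asv$table$counts)))
cur$table
#> ASV table: 214 ASVs x 99 samples ( 33 sites ), 7555730 reads

setequal(colnames(cur$incidence), study$asv$truth$pool$asv_id)
#> [1] TRUE

fit <- fit_plspm(sem_indicators(study), biodiversity_path_model())
fit
#> PLS path model ( centroid scheme ), 16 iterations, converged
#>            from            to estimate
#> 1     elevation     footprint -0.60024
#> 2     elevation water_quality  0.67578
#> 3     footprint water_quality  0.03337
#> 4     elevation  biodiversity -0.50935
#> 5     footprint  biodiversity -0.23059
#> 6 water_quality  biodiversity -0.21342
#> R2: footprint=0.36  water_quality=0.431  biodiversity=0.323
```

Curation returned exactly the 214 true ASVs that were actually sampled
somewhere in the basin (the 54 planted error daughters were absorbed by
`cluster_d1()` and `lulu_curate()`; 18 regional-pool members occurred at
no site and so cannot appear in a read table). The path coefficients
estimated from only 33 sites scatter around their generating values
(−0.5452, 0.4739, 0.5485, −0.7056, −0.1779, −0.0626); at n = 5000 sites
each is recovered within ±0.05. `effects_decomposition(fit)` splits
every latent pair into direct and indirect components, and
`run_pipeline(out_dir)` runs simulate → curate → facets → spatial → glm
→ sem in one call, writing each stage's tables and a reproducibility
manifest.

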