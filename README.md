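# metapart

Variation partitioning of pond metacommunities with generalized
additive models.

## The problem

Community ecologists routinely ask how much of the variation in
species occurrences across a landscape reflects local environmental
filtering (species sorting) and how much reflects spatial processes
such as dispersal limitation.  `metapart` implements a complete,
reproducible pipeline for answering that question from three plain
tables — a binary site-by-taxon matrix, a site-by-variable environment
table, and site coordinates:

1. **Latent-variable reduction** — binomial generalized linear latent
   variable models (GLLVM) fitted at candidate dimensions d = 0..3,
   the AIC winner's predicted probability matrix becoming the analysis
   response;
2. **Quasibinomial GAMs** — penalized thin-plate smooths (9 basis
   functions per variable, at most 3 variables) of the three leading
   environmental principal components and of the coordinates, pooled
   into a community adjusted R²;
3. **Forward selection** with the double-stopping criterion
   (significance *and* the global-model adjusted R² as a cap);
4. **Partition** of the joint adjusted R² into pure environment (E|S),
   spatially structured environment (E∩S), pure space (S|E) and
   residual, with a **Moran spectral randomization** correction of the
   environmental component:
   `R²_MSR(E) = 1 − (1 − R²(E)) / (1 − mean_r R²(E_r))`
   over surrogate environments that preserve each predictor's spatial
   power spectrum.

It also provides PERMDISP contrasts of multivariate environmental
heterogeneity between regions, the shoreline development index
`D_L = L / (2√(πA))` and land-cover Shannon diversity, haversine
site-distance utilities, and a fully seeded synthetic metacommunity
generator (`env_only`, `space_only`, `mixed`, `null` scenarios) with
which every stage is validated.

## Worked example

```r
library(metapart)

sim <- simulate_metacommunity("mixed", n_sites = 30, n_species = 20, seed = 42)
pcs <- reduce_environment(transform_variables(sim$environment))
data <- data.frame(pcs$scores, sim$landscape$coords)
names(data)[4:5] <- c("x", "y")

lv <- select_latent_dimension(sim$community, 0:3, seed = 42)
lv
#> Binomial GLLVM: d = 2, logLik = -317.76, AIC = 753.53 (converged)

P <- predicted_response(lv)
env_sel <- forward_select(P, data, c("PC1", "PC2", "PC3"),
                          coord_names = c("x", "y"))$selected
spa_sel <- forward_select(P, data, c("x", "y"),
                          coord_names = c("x", "y"))$selected
capped <- cap_selection(P, data, env_sel, spa_sel, coord_names = c("x", "y"))

partition_variation(P, data, capped$env_sel, capped$space_sel,
                    msr = msr_config(sim$landscape$mem_all, 99, seed = 42),
                    coord_names = c("x", "y"))
#> Partition: E|S = 0.140, EnS = 0.137, S|E = 0.458, residual = 0.264
#>   MSR-corrected env component: 0.186 (uncorrected 0.277)
```

Read: two latent dimensions carry the shared occurrence signal; after
the three-variable cap the model keeps PC2 plus the coordinate
surface; 73.6% of the latent-reduced community variation is explained
jointly (residual 0.264), pure space (0.458) exceeding pure
environment (0.140); of the environmental component 0.277, the
spectral correction attributes 0.186 to environment once its spatial
structure is discounted.  `run_pipeline()` chains these stages over
many groups with per-group error isolation and a run manifest, as in
`analysis/03_partition.R`.

The numbered scripts under `analysis/` narrate the full synthetic
study (simulate two regions → environmental characterization and
PERMDISP contrasts → partition all groups → MSR validation), writing
their tables under `results/`.

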