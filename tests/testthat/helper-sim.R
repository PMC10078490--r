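# Shared fixtures, all generated in code.

# binary matrix with known latent rank and strong loadings
sim_rank_matrix <- function(seed, n = 200, m = 12, d = 2, loading_sd = 2) {
  set.seed(seed)
  if (d == 0) {
    p <- matrix(runif(m, 0.2, 0.8), n, m, byrow = TRUE)
  } else {
    U <- matrix(rnorm(n * d), n, d)
    Lam <- matrix(rnorm(m * d, 0, loading_sd), m, d)
    p <- plogis(sweep(U %*% t(Lam), 2, rnorm(m, 0, 0.5), `+`))
  }
  matrix(rbinom(n * m, 1, p), n, m)
}

# one simulated scenario prepared for the GAM stage: PC scores +
# planar coordinates, plus the GLLVM-predicted response
prep_scenario <- function(scenario, seed, n_sites = 60, n_species = 12, ...) {
  sim <- simulate_metacommunity(scenario, n_sites = n_sites,
                                n_species = n_species, seed = seed, ...)
  envt <- transform_variables(sim$environment)
  pcs <- reduce_environment(envt)
  data <- data.frame(pcs$scores, sim$landscape$coords)
  names(data)[4:5] <- c("x", "y")
  sim$data <- data
  sim$coord_names <- c("x", "y")
  sim$env_labels <- colnames(pcs$scores)
  sim
}

# mgcv occasionally warns about smoothing-parameter step failures on
# near-degenerate responses; irrelevant to what the tests assert
quiet <- function(expr) suppressWarnings(expr)
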