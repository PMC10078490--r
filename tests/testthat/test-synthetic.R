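test_that("spatial environment variables are more autocorrelated than noise ones", {
  L <- simulate_landscape(30, seed = 3)
  truth <- make_truth("mixed", n_sites = 30, n_species = 5,
                      n_env_spatial = 10, n_env_nonspatial = 10, seed = 3)
  env <- simulate_environment(L, truth)
  vals <- as.matrix(env$values[, -1])
  # oracle: ape's Moran's I with the same binary connectivity weights
  I_obs <- apply(vals, 2, function(x)
    ape::Moran.I(x, L$weights)$observed)
  I_sp <- I_obs[env$meta$spatial]
  I_ns <- I_obs[!env$meta$spatial]
  expect_gt(min(I_sp), quantile(I_ns, 0.95))
  # standardized columns
  expect_lt(max(abs(colMeans(vals))), 1e-10)
  expect_equal(unname(apply(vals, 2, sd)), rep(1, 20))
})

test_that("noise-free spatial variables lie exactly in the MEM span", {
  L <- simulate_landscape(25, seed = 11)
  truth <- make_truth("mixed", n_sites = 25, n_species = 5,
                      n_env_spatial = 2, n_env_nonspatial = 1,
                      env_noise = 0, seed = 11)
  env <- simulate_environment(L, truth)
  for (v in env$meta$variable[env$meta$spatial]) {
    x <- env$values[[v]]
    fit <- lm(x ~ L$mem)
    expect_lt(sum(residuals(fit)^2) / sum((x - mean(x))^2), 1e-20)
  }
})

test_that("white-noise environment shows no spatial autocorrelation", {
  L <- simulate_landscape(30, seed = 5)
  truth <- make_truth("null", n_sites = 30, n_species = 5,
                      n_env_spatial = 0, n_env_nonspatial = 12, seed = 5)
  env <- simulate_environment(L, truth)
  I_obs <- apply(as.matrix(env$values[, -1]), 2, moran_i, W = L$weights)
  # expectation under no autocorrelation is -1/(n-1)
  expect_lt(abs(mean(I_obs) - (-1 / 29)), 0.1)
})

test_that("neutral community hits the prevalence target", {
  sim <- simulate_metacommunity("null", n_sites = 60, n_species = 40,
                                seed = 2, prevalence_target = 0.5)
  se <- sqrt(0.25 / (60 * 40))
  expect_lt(abs(mean(sim$community) - 0.5), 3 * se)
})

test_that("single-species logistic fit recovers the environmental effect sign", {
  sim <- simulate_metacommunity("env_only", n_sites = 150, n_species = 12,
                                seed = 4, beta_env = 2.5)
  G <- sim$environment$gradients
  drv <- attr(sim$community, "env_driver")
  truth <- sim$truth
  # oracle: per-species glm on the true generating gradient
  for (j in c(1, 5, 9)) {
    co <- coef(glm(sim$community[, j] ~ G[, drv[j]], family = binomial()))[2]
    expect_equal(sign(unname(co)), sign(truth$beta_env[j]))
  }
})

test_that("community generation is deterministic and flags degenerate taxa", {
  a <- simulate_metacommunity("mixed", n_sites = 30, n_species = 10, seed = 9)
  b <- simulate_metacommunity("mixed", n_sites = 30, n_species = 10, seed = 9)
  expect_identical(unclass(a$community), unclass(b$community))
  occ <- colMeans(a$community)
  expect_identical(unname(attr(a$community, "degenerate")),
                   unname(occ == 0 | occ == 1))
})

test_that("truth constructor validates its domain", {
  expect_error(make_truth("mixed", autocorr_scale = 0), "autocorr_scale")
  expect_error(make_truth("mixed", autocorr_scale = 1.2), "autocorr_scale")
  expect_error(make_truth("mixed", prevalence_target = 1), "prevalence_target")
})
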