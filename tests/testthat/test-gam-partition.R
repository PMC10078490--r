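planar_data <- function(n, seed) {
  set.seed(seed)
  data.frame(PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
             x = runif(n), y = runif(n))
}

test_that("constant responses explain nothing", {
  data <- planar_data(30, 1)
  P <- matrix(0.5, 30, 4)
  fit <- fit_gam_community(P, data, "PC1", coord_names = c("x", "y"))
  expect_equal(fit$r2, 0)
  expect_lte(fit$adj_r2, 0)
})

test_that("a smooth single-predictor signal is fitted almost perfectly", {
  set.seed(2)
  data <- planar_data(100, 2)
  f <- function(z) plogis(1.5 * sin(2 * z) - 0.5 * z)
  P <- cbind(f(data$PC1), plogis(0.8 * data$PC1^2 - 1))
  fit <- quiet(fit_gam_community(P, data, "PC1", coord_names = c("x", "y")))
  expect_gt(fit$r2, 0.95)
  expect_gt(fit$adj_r2, 0.9)
  expect_lte(fit$adj_r2, fit$r2)
})

test_that("saturated or invalid responses are rejected", {
  data <- planar_data(10, 3)
  P <- matrix(runif(40), 10, 4)
  expect_error(fit_gam_community(P, data, c("PC1", "PC2"),
                                 coord_names = c("x", "y")), "saturated")
  P_bad <- P; P_bad[1, 1] <- NA
  expect_error(fit_gam_community(P_bad, data, "PC1",
                                 coord_names = c("x", "y")), "non-finite")
  P_bad2 <- P; P_bad2[1, 1] <- 1.4
  expect_error(fit_gam_community(P_bad2, data, "PC1",
                                 coord_names = c("x", "y")), "lie in")
})

test_that("coordinate pairs become one bivariate surface, singles stay univariate", {
  expect_equal(smooth_terms(c("lon", "lat")), "s(lon, lat, bs = 'tp', k = 18)")
  expect_equal(smooth_terms("lat"), "s(lat, bs = 'tp', k = 9)")
  expect_equal(smooth_terms(c("PC1", "x", "y"), coord_names = c("x", "y")),
               "s(x, y, bs = 'tp', k = 18) + s(PC1, bs = 'tp', k = 9)")
  expect_equal(smooth_terms(character(0)), "1")
})

test_that("partition identity holds to machine precision and reduces when one side is empty", {
  for (seed in 1:3) {
    sim <- prep_scenario("mixed", seed, n_sites = 40, n_species = 6)
    P <- attr(sim$community, "prob")
    part <- quiet(partition_variation(P, sim$data, c("PC1", "PC2"),
                                      c("x", "y"),
                                      coord_names = sim$coord_names))
    expect_lt(abs(part$frac_pure_env + part$frac_shared +
                    part$frac_pure_space - part$adj_r2_ES), 1e-10)
    expect_equal(part$residual, 1 - part$adj_r2_ES, tolerance = 1e-12)
  }
  sim <- prep_scenario("env_only", 4, n_sites = 40, n_species = 6)
  P <- attr(sim$community, "prob")
  only_env <- quiet(partition_variation(P, sim$data, "PC1", character(0),
                                        coord_names = sim$coord_names))
  expect_equal(only_env$frac_pure_space, 0)
  expect_equal(only_env$frac_shared, 0)
  expect_equal(only_env$frac_pure_env, only_env$adj_r2_E)
  both_empty <- partition_variation(P, sim$data, character(0), character(0))
  expect_equal(both_empty$flag, "no predictors selected")
  expect_equal(both_empty$adj_r2_ES, 0)
})

test_that("joint fits are never much worse than nested fits", {
  for (seed in 5:7) {
    sim <- prep_scenario("mixed", seed, n_sites = 40, n_species = 6)
    P <- attr(sim$community, "prob")
    part <- quiet(partition_variation(P, sim$data, c("PC1", "PC2"),
                                      c("x", "y"),
                                      coord_names = sim$coord_names))
    expect_gte(part$adj_r2_ES,
               max(part$adj_r2_E, part$adj_r2_S) - 0.02)
  }
})

test_that("forward selection finds a constructed driver and respects empty input", {
  sim <- prep_scenario("env_only", 8, n_sites = 60, n_species = 10,
                       beta_env = 2.5)
  lv <- select_latent_dimension(sim$community, 0:2, seed = 8)
  P <- predicted_response(lv, allow_unconverged = TRUE)
  sel <- quiet(forward_select(P, sim$data, sim$env_labels,
                              coord_names = sim$coord_names))
  expect_gt(length(sel$selected), 0)
  expect_equal(sel$selected[1], sel$steps$candidate[which.max(
    sel$steps$adj_r2[sel$steps$step == 1])])
  empty <- forward_select(P, sim$data, character(0))
  expect_equal(empty$selected, character(0))
})

test_that("the selection cap drops the weakest variables down to three", {
  sim <- prep_scenario("mixed", 10, n_sites = 60, n_species = 8)
  P <- attr(sim$community, "prob")
  capped <- quiet(cap_selection(P, sim$data,
                                c("PC1", "PC2", "PC3"), c("x", "y"),
                                coord_names = sim$coord_names))
  expect_equal(length(capped$env_sel) + length(capped$space_sel), 3)
  # already-small selections pass through untouched
  same <- cap_selection(P, sim$data, "PC1", "x")
  expect_equal(same$env_sel, "PC1")
  expect_equal(same$space_sel, "x")
})

test_that("relative proportions floor negatives and renormalize", {
  expect_equal(relative_proportions(c(0.2, 0.1, 0.1)), c(0.5, 0.25, 0.25))
  out <- relative_proportions(c(0.3, -0.05, 0.05))
  expect_equal(out, c(0.857, 0, 0.143), tolerance = 1e-3)
  expect_equal(sum(out), 1)
  expect_true(all(is.na(relative_proportions(c(0, 0, 0)))))
  expect_true(all(is.na(relative_proportions(c(-0.1, -0.2, 0)))))
})

test_that("MSR surrogates preserve variance and spatial structure", {
  L <- simulate_landscape(40, seed = 12)
  x <- drop(L$mem[, 1:4] %*% c(2, 1, 0.5, 0.5)) + rnorm(40, 0, 0.2)
  set.seed(1)
  reps <- replicate(200, metapart:::msr_randomize(x, L$mem_all))
  expect_equal(apply(reps, 2, mean), rep(mean(x), 200), tolerance = 1e-8)
  expect_equal(unname(apply(reps, 2, var)), rep(var(x), 200),
               tolerance = 1e-8)
  I_obs <- moran_i(x, L$weights)
  I_null <- apply(reps, 2, moran_i, W = L$weights)
  expect_lt(abs(mean(I_null) - I_obs), 0.15)
})

test_that("the MSR null size precondition is enforced", {
  L <- simulate_landscape(20, seed = 13)
  expect_error(msr_config(L$mem_all, n_replicates = 10), "too small")
  expect_error(msr_config(L$mem_all, n_replicates = 18), "too small")
  expect_s3_class(msr_config(L$mem_all, n_replicates = 19), "mp_msr_config")
})
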