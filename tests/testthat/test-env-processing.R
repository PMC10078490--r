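make_env <- function(df, transform = NA_character_, percent = FALSE) {
  list(values = cbind(data.frame(site_id = paste0("s", seq_len(nrow(df)))),
                      df),
       meta = data.frame(variable = names(df), transform = transform,
                         percent = percent, stringsAsFactors = FALSE))
}

test_that("arcsine-square-root and log transforms follow their conventions", {
  env <- make_env(data.frame(p = c(0, 0.25, 1)), transform = "asin_sqrt")
  out <- transform_variables(env)
  expect_equal(out$values$p, c(0, asin(sqrt(0.25)), pi / 2))
  expect_equal(out$values$p[3], 1.5708, tolerance = 1e-4)

  env <- make_env(data.frame(pc = c(0, 25, 100)), transform = "asin_sqrt",
                  percent = TRUE)
  expect_equal(transform_variables(env)$values$pc, c(0, asin(sqrt(0.25)), pi / 2))

  # offset +1 only when zeros are present
  env <- make_env(data.frame(x = c(0, 9, 99)), transform = "log")
  expect_equal(transform_variables(env)$values$x, c(0, 1, 2))
  env <- make_env(data.frame(x = c(1, 10, 100)), transform = "log")
  expect_equal(transform_variables(env)$values$x, c(0, 1, 2))
})

test_that("transform domain violations error, including double application", {
  env <- make_env(data.frame(p = c(0.5, 1.2)), transform = "asin_sqrt")
  expect_error(transform_variables(env), "outside")
  env <- make_env(data.frame(x = c(-1, 2)), transform = "log")
  expect_error(transform_variables(env), "negative")
  # applying asin_sqrt twice leaves the domain: pi/2 > 1
  env <- make_env(data.frame(p = c(0.2, 0.9, 1)), transform = "asin_sqrt")
  once <- transform_variables(env)
  expect_error(transform_variables(once), "outside")
})

test_that("auto-assignment picks log for right-skewed data and reduces skewness", {
  set.seed(31)
  x <- rlnorm(200, 0, 1)
  env <- make_env(data.frame(x = x))
  out <- transform_variables(env, auto = TRUE)
  expect_equal(out$meta$transform, "log")
  sk <- function(z) mean((z - mean(z))^3) / mean((z - mean(z))^2)^1.5
  expect_lt(abs(sk(out$values$x)), abs(sk(x)))
  # proportions go to asin_sqrt; symmetric data stay untransformed
  env2 <- make_env(data.frame(p = runif(50), z = rnorm(50)))
  out2 <- transform_variables(env2, auto = TRUE)
  expect_equal(out2$meta$transform, c("asin_sqrt", "none"))
})

test_that("PCA matches an independent eigen-decomposition of the correlation matrix", {
  set.seed(17)
  df <- as.data.frame(matrix(rnorm(60), 10, 6))
  env <- make_env(df, transform = "none")
  pcs <- reduce_environment(env)
  ev <- eigen(cor(as.matrix(df)), symmetric = TRUE)$values
  expect_equal(unname(pcs$explained_all), ev / 6, tolerance = 1e-10)
  expect_equal(pcs$cumulative_explained, sum(ev[1:3]) / 6, tolerance = 1e-10)
  # orthogonal scores, sign convention, shape
  expect_lt(max(abs(crossprod(scale(pcs$scores, scale = FALSE)) -
                      diag(diag(crossprod(scale(pcs$scores, scale = FALSE)))))),
            1e-8)
  for (k in 1:3)
    expect_gt(pcs$loadings[which.max(abs(pcs$loadings[, k])), k], 0)
})

test_that("PCA is invariant to variable order and reconstructs the table", {
  set.seed(23)
  df <- as.data.frame(matrix(rnorm(12 * 5), 12, 5))
  p1 <- reduce_environment(make_env(df, "none"))
  p2 <- reduce_environment(make_env(df[, c(3, 1, 5, 2, 4)], "none"))
  expect_equal(p1$explained, p2$explained, tolerance = 1e-10)
  expect_equal(abs(p1$scores), abs(p2$scores), tolerance = 1e-8)
  # 3-component reconstruction leaves exactly the unexplained variance
  Xs <- scale(as.matrix(df))
  resid <- Xs - p1$scores %*% t(p1$loadings)
  expect_equal(sum(resid^2) / sum(Xs^2), 1 - p1$cumulative_explained,
               tolerance = 1e-8)
})

test_that("three uncorrelated variables are fully explained; degenerate input errors", {
  df <- data.frame(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0), c = c(0, 0, 1, 0))
  pcs <- reduce_environment(make_env(df, "none"))
  expect_equal(pcs$cumulative_explained, 1.0, tolerance = 1e-10)
  expect_warning(
    reduce_environment(make_env(cbind(df, data.frame(k = rep(1, 4))), "none")),
    "constant")
  expect_error(reduce_environment(make_env(df[, 1:2], "none")), "3")
})

test_that("shoreline development index is 1 for a circle and scales correctly", {
  r <- 3.7
  expect_equal(shoreline_development(2 * pi * r, pi * r^2), 1, tolerance = 1e-12)
  expect_equal(shoreline_development(4, 1), 4 / (2 * sqrt(pi)),
               tolerance = 1e-12)
  expect_equal(shoreline_development(4, 1), 1.1284, tolerance = 1e-4)
  expect_error(shoreline_development(0, 1), "positive")
  expect_error(shoreline_development(1, -2), "positive")
})

test_that("land-cover Shannon index follows the entropy formula", {
  expect_equal(landcover_shannon(c(1, 0, 0)), 0)
  expect_equal(landcover_shannon(rep(1, 4)), log(4), tolerance = 1e-12)
  expect_equal(landcover_shannon(c(0.5, 0.3, 0.2)), 1.0297, tolerance = 1e-4)
  # renormalization: percentages and proportions agree
  expect_equal(landcover_shannon(c(50, 30, 20)),
               landcover_shannon(c(0.5, 0.3, 0.2)))
  expect_error(landcover_shannon(c(0, 0)), "all-zero")
  expect_error(landcover_shannon(c(-0.1, 1)), "non-negative")
})
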