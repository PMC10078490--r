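#' Parameters of a synthetic metacommunity ("truth")
#'
#' Bundles the generative effect sizes against which the partitioning
#' pipeline is validated.  The scenario presets encode the processes the
#' partition fractions are meant to detect: `env_only` (species sorting
#' along environmental gradients), `space_only` (spatially structured
#' occurrence independent of the measured environment, as under
#' dispersal limitation), `mixed` (both, plus a latent site effect) and
#' `null` (no structure at all).
#'
#' Defaults emulate the structure of the field study the pipeline is
#' designed for: ~30 sites per region, 49 mixed-type environmental
#' variables of which roughly half are spatially autocorrelated, and
#' sparse presence-absence matrices (mean prevalence 0.3).
#'
#' @param scenario one of `"env_only"`, `"space_only"`, `"mixed"`,
#'   `"null"`.
#' @param n_sites,n_species community dimensions.
#' @param n_env_spatial,n_env_nonspatial counts of spatially structured
#'   and pure-noise environmental variables.
#' @param autocorr_scale fraction (0,1] of the low-order MEM spectrum
#'   used to build spatial structure; low order = broad scale.
#' @param env_noise measurement-level noise standard deviation of the
#'   observed environmental variables around their underlying gradient
#'   (1 makes roughly half of each variable's variance shared; 0 makes
#'   spatial variables lie exactly in the MEM span).
#' @param sigma_latent scale of latent site-effect loadings (creates
#'   between-species covariance unrelated to predictors).
#' @param prevalence_target mean occurrence probability in (0,1).
#' @param beta_env,beta_space absolute per-species effect sizes on the
#'   logit scale; scalars are expanded with random signs.
#' @param seed integer master seed for the generator.
#' @return Object of class `mp_truth` (a list of the above, with
#'   per-species effect vectors).
#' @export
make_truth <- function(scenario = c("mixed", "env_only", "space_only", "null"),
                       n_sites = 30, n_species = 40,
                       n_env_spatial = 25, n_env_nonspatial = 24,
                       autocorr_scale = 0.5, env_noise = 1,
                       sigma_latent = NULL, prevalence_target = 0.3,
                       beta_env = NULL, beta_space = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  if (autocorr_scale <= 0 || autocorr_scale > 1)
    stop("autocorr_scale must be in (0, 1]")
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence_target must be in (0, 1)")
  defaults <- switch(scenario,
    env_only   = list(be = 2,    bs = 0,    sl = 0),
    space_only = list(be = 0,    bs = 2,    sl = 0),
    mixed      = list(be = 1.25, bs = 1.25, sl = 0.5),
    null       = list(be = 0,    bs = 0,    sl = 0)
  )
  if (is.null(beta_env)) beta_env <- defaults$be
  if (is.null(beta_space)) beta_space <- defaults$bs
  if (is.null(sigma_latent)) sigma_latent <- defaults$sl
  set.seed(derive_seed(seed, "truth"))
  expand <- function(b) {
    if (length(b) == 1L)
      b * sample(c(-1, 1), n_species, replace = TRUE)
    else {
      stopifnot(length(b) == n_species)
      b
    }
  }
  structure(list(
    scenario = scenario,
    n_sites = n_sites, n_species = n_species,
    n_env_spatial = n_env_spatial, n_env_nonspatial = n_env_nonspatial,
    autocorr_scale = autocorr_scale, env_noise = env_noise,
    sigma_latent = sigma_latent, prevalence_target = prevalence_target,
    beta_env = expand(beta_env), beta_space = expand(beta_space),
    seed = seed
  ), class = "mp_truth")
}

#' Simulate an environment table over a landscape
#'
#' Mimics the collinear structure of field environmental tables: two
#' underlying gradients — one spatially autocorrelated (a linear
#' combination of the low-order, broad-scale dbMEM eigenvectors), one
#' pure noise — are each measured by a block of observed variables with
#' independent measurement-level noise (`env_noise`).  Spatially
#' structured variables manifest the spatial gradient; the rest manifest
#' the non-spatial one.  Every variable is standardized to zero mean and
#' unit variance, and its origin is kept in the metadata (spatial
#' variables are labelled `macroclimatic`, non-spatial ones
#' `limnological`, mirroring the scales those sets vary on in field
#' data).  The gradients themselves are returned so community
#' simulation can couple species to them.
#'
#' @param landscape an [simulate_landscape()] object.
#' @param truth an [make_truth()] object with matching `n_sites`.
#' @return List with `values` (data frame, `site_id` first column),
#'   `meta` (variable, transform, set, spatial flag, units) and
#'   `gradients` (site matrix, columns `spatial`/`nonspatial`).
#' @export
simulate_environment <- function(landscape, truth) {
  stopifnot(inherits(landscape, "mp_landscape"), inherits(truth, "mp_truth"))
  n <- length(landscape$site_id)
  if (n != truth$n_sites)
    stop("landscape and truth disagree on the number of sites")
  if (truth$autocorr_scale <= 0 || truth$autocorr_scale > 1)
    stop("autocorr_scale must be in (0, 1]")
  set.seed(derive_seed(truth$seed, "environment"))
  K <- ncol(landscape$mem)
  n_low <- max(1L, ceiling(truth$autocorr_scale * K))
  B <- landscape$mem[, seq_len(n_low), drop = FALSE]
  g_sp <- drop(B %*% stats::rnorm(n_low))
  g_sp <- g_sp / stats::sd(g_sp)
  g_ns <- stats::rnorm(n)
  g_ns <- (g_ns - mean(g_ns)) / stats::sd(g_ns)
  gradients <- cbind(spatial = g_sp, nonspatial = g_ns)
  vals <- matrix(NA_real_, n, truth$n_env_spatial + truth$n_env_nonspatial)
  spatial <- rep(c(TRUE, FALSE),
                 c(truth$n_env_spatial, truth$n_env_nonspatial))
  for (k in seq_len(ncol(vals))) {
    g <- if (spatial[k]) g_sp else g_ns
    vals[, k] <- g + stats::rnorm(n, 0, truth$env_noise)
  }
  vals <- scale(vals)
  colnames(vals) <- ifelse(spatial,
    sprintf("env_sp_%02d", cumsum(spatial)[spatial]),
    sprintf("env_ns_%02d", cumsum(!spatial)[!spatial]))
  list(
    values = data.frame(site_id = landscape$site_id, vals,
                        check.names = FALSE),
    meta = data.frame(
      variable = colnames(vals),
      transform = "none",
      set = ifelse(spatial, "macroclimatic", "limnological"),
      spatial = spatial,
      units = "z-score",
      stringsAsFactors = FALSE
    ),
    gradients = gradients
  )
}

#' Simulate a presence-absence metacommunity
#'
#' For site i and species j the occurrence probability is
#' `logit p_ij = alpha_j + beta_env_j * G[i, a_j] + beta_space_j *
#' MEM[i, s_j] + lambda_j * u_i`, with `u_i` standard-normal latent site
#' effects, `lambda_j ~ N(0, sigma_latent^2)` loadings, `G[, a_j]` the
#' species' environmental gradient (spatial or non-spatial, drawn at
#' random) and `s_j` a random broad-scale MEM column (one of the first
#' three, so the spatial signal is shared across species).  The
#' intercept `alpha_j` is solved so each species' mean probability
#' matches `prevalence_target`, and occurrences are Bernoulli draws.
#' Species that come out all-absent or all-present are retained and
#' flagged (attribute `degenerate`), matching real data where ubiquitous
#' taxa occur.
#'
#' @param landscape an [simulate_landscape()] object.
#' @param environment output of [simulate_environment()] (or any list
#'   with a `values` data frame whose first column is `site_id`).
#' @param truth an [make_truth()] object.
#' @return Binary site-by-species matrix with dimnames, and attributes
#'   `truth`, `degenerate` (logical per species), `env_driver`,
#'   `mem_driver`, `prob` (the generating probability matrix).
#' @export
simulate_community <- function(landscape, environment, truth) {
  stopifnot(inherits(landscape, "mp_landscape"), inherits(truth, "mp_truth"))
  n <- length(landscape$site_id)
  stopifnot(nrow(environment$values) == n, truth$n_sites == n)
  G <- environment$gradients
  if (is.null(G)) {
    # external environment table without generative gradients: species
    # track observed variables directly
    G <- as.matrix(environment$values[, -1, drop = FALSE])
  }
  m <- truth$n_species
  set.seed(derive_seed(truth$seed, "community"))
  K <- ncol(landscape$mem)
  n_low <- max(1L, ceiling(truth$autocorr_scale * K))
  n_broad <- min(3L, n_low)
  env_driver <- sample.int(ncol(G), m, replace = TRUE)
  mem_driver <- sample.int(n_broad, m, replace = TRUE)
  u <- stats::rnorm(n)
  lambda <- stats::rnorm(m, 0, truth$sigma_latent)
  # MEM columns are unit-norm; rescale to unit variance so beta_space is
  # on the same per-SD logit scale as beta_env
  mem_std <- scale(landscape$mem[, seq_len(n_broad), drop = FALSE])
  eta0 <- sapply(seq_len(m), function(j) {
    truth$beta_env[j] * G[, env_driver[j]] +
      truth$beta_space[j] * mem_std[, mem_driver[j]] +
      lambda[j] * u
  })
  alpha <- vapply(seq_len(m), function(j) {
    f <- function(a) mean(invlogit(a + eta0[, j])) - truth$prevalence_target
    stats::uniroot(f, c(-40, 40))$root
  }, numeric(1))
  prob <- invlogit(sweep(eta0, 2, alpha, `+`))
  Y <- matrix(stats::rbinom(n * m, 1, prob), n, m)
  dimnames(Y) <- list(landscape$site_id, sprintf("sp_%03d", seq_len(m)))
  dimnames(prob) <- dimnames(Y)
  occ <- colMeans(Y)
  structure(Y,
            truth = truth,
            degenerate = occ == 0 | occ == 1,
            env_driver = env_driver,
            mem_driver = mem_driver,
            prob = prob)
}

#' Simulate a full scenario (landscape + environment + community)
#'
#' Convenience wrapper chaining [simulate_landscape()],
#' [simulate_environment()] and [simulate_community()] under one seed.
#'
#' @inheritParams make_truth
#' @param extent landscape side length.
#' @param geographic use decimal-degree coordinates and haversine
#'   distances.
#' @param ... further arguments to [make_truth()].
#' @return List with `landscape`, `environment`, `community`, `truth`.
#' @export
simulate_metacommunity <- function(scenario = "mixed", n_sites = 30,
                                   n_species = 40, seed = 1, extent = 1,
                                   geographic = FALSE, ...) {
  truth <- make_truth(scenario = scenario, n_sites = n_sites,
                      n_species = n_species, seed = seed, ...)
  landscape <- simulate_landscape(n_sites, extent = extent, seed = seed,
                                  geographic = geographic)
  env <- simulate_environment(landscape, truth)
  comm <- simulate_community(landscape, env, truth)
  list(landscape = landscape, environment = env, community = comm,
       truth = truth)
}
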