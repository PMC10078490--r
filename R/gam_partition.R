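# Quasibinomial GAM variation partitioning.
#
# The community response is a site-by-taxon matrix of probabilities (or
# 0/1 occurrences).  Each taxon gets its own penalized thin-plate
# regression spline fit (mgcv, GCV smoothness selection, quasibinomial
# family with logit link), and fits are pooled into one community R^2 on
# the response scale, 1 - sum_j RSS_j / sum_j TSS_j, mirroring
# multivariate redundancy-style R^2.  The adjusted R^2 is Ezekiel-type
# with the average per-taxon effective degrees of freedom in place of a
# parameter count.

#' Build the smooth-term model formula
#'
#' Environmental predictors get univariate thin-plate smooths with
#' `k_uni` basis functions; when both coordinates are present they form
#' one two-dimensional thin-plate surface with `k_bi` basis functions
#' (single coordinates get univariate smooths).
#'
#' @param terms character vector of predictor labels (e.g. `"PC1"`,
#'   `"lon"`, `"lat"`).
#' @param k_uni,k_bi basis dimensions for univariate and bivariate
#'   smooths.
#' @param coord_names the two labels treated as coordinates.
#' @return A one-sided formula string for the right-hand side.
#' @export
smooth_terms <- function(terms, k_uni = 9, k_bi = 18,
                         coord_names = c("lon", "lat")) {
  if (!length(terms)) return("1")
  is_coord <- terms %in% coord_names
  out <- character(0)
  if (sum(is_coord) == 2L) {
    out <- c(out, sprintf("s(%s, %s, bs = 'tp', k = %d)",
                          coord_names[1], coord_names[2], k_bi))
  } else if (sum(is_coord) == 1L) {
    out <- c(out, sprintf("s(%s, bs = 'tp', k = %d)",
                          terms[is_coord], k_uni))
  }
  for (v in terms[!is_coord]) {
    out <- c(out, sprintf("s(%s, bs = 'tp', k = %d)", v, k_uni))
  }
  paste(out, collapse = " + ")
}

#' Fit a community of quasibinomial GAMs and pool the fit
#'
#' @param P site-by-taxon matrix of responses in [0, 1] (predicted
#'   probabilities or raw occurrences).
#' @param data data frame of predictors (one row per site).
#' @param terms character vector of predictor labels; empty for the
#'   intercept-only (null) model.
#' @param k_uni,k_bi smooth basis dimensions (defaults 9 per variable,
#'   18 for the coordinate surface).
#' @param coord_names labels treated as spatial coordinates.
#' @return Object of class `mp_gamfit`: pooled `r2`, `adj_r2`, mean and
#'   total effective degrees of freedom (`edf`, `edf_total`), summed
#'   `rss`/`tss`, `n`, `m_eff` (taxa with variation), `terms`,
#'   `dispersion` (per-taxon Pearson), `per_taxon` data frame.
#' @export
fit_gam_community <- function(P, data, terms, k_uni = 9, k_bi = 18,
                              coord_names = c("lon", "lat")) {
  P <- as.matrix(P)
  if (!all(is.finite(P))) stop("non-finite response")
  if (any(P < 0 | P > 1)) stop("response must lie in [0, 1]")
  n <- nrow(P)
  stopifnot(nrow(data) == n)
  variant <- apply(P, 2, function(y) stats::var(y) > 0)
  rhs <- smooth_terms(terms, k_uni, k_bi, coord_names)
  basis_dim <- if (length(terms)) {
    n_coord <- sum(terms %in% coord_names)
    (n_coord == 2) * (k_bi - 1) + (n_coord == 1) * (k_uni - 1) +
      sum(!(terms %in% coord_names)) * (k_uni - 1)
  } else 0
  if (basis_dim + 1 >= n) stop("model saturated: basis dimension >= n_sites")

  if (!any(variant) || !length(terms)) {
    ybar <- colMeans(P)
    tss <- sum(sweep(P, 2, ybar)^2)
    return(structure(list(
      r2 = 0, adj_r2 = 0, edf = 0, edf_total = 0,
      rss = tss, tss = tss, n = n, m_eff = sum(variant),
      terms = terms, dispersion = rep(NA_real_, ncol(P)),
      per_taxon = NULL
    ), class = "mp_gamfit"))
  }

  if (".mp_response" %in% names(data))
    stop("predictor name '.mp_response' is reserved")
  fml <- stats::as.formula(paste(".mp_response ~", rhs))
  rss <- tss <- edf_vec <- disp <- numeric(ncol(P))
  for (j in seq_len(ncol(P))) {
    y <- P[, j]
    tss[j] <- sum((y - mean(y))^2)
    if (!variant[j]) {
      rss[j] <- 0
      edf_vec[j] <- NA_real_
      disp[j] <- NA_real_
      next
    }
    df_j <- data
    df_j$.mp_response <- y
    fit <- mgcv::gam(fml, family = stats::quasibinomial(),
                     data = df_j, method = "GCV.Cp")
    mu <- stats::fitted(fit)
    rss[j] <- sum((y - mu)^2)
    edf_vec[j] <- sum(fit$edf) - 1  # smooth edf, intercept excluded
    disp[j] <- summary(fit)$dispersion
  }
  m_eff <- sum(variant)
  r2 <- 1 - sum(rss[variant]) / sum(tss[variant])
  edf_mean <- mean(edf_vec[variant])
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - edf_mean - 1)
  structure(list(
    r2 = r2, adj_r2 = adj_r2, edf = edf_mean,
    edf_total = sum(edf_vec[variant]),
    rss = sum(rss[variant]), tss = sum(tss[variant]),
    n = n, m_eff = m_eff, terms = terms, dispersion = disp,
    per_taxon = data.frame(
      taxon = if (is.null(colnames(P))) sprintf("t%03d", seq_len(ncol(P)))
              else colnames(P),
      rss = rss, tss = tss, edf = edf_vec, variant = variant)
  ), class = "mp_gamfit")
}

#' @export
print.mp_gamfit <- function(x, ...) {
  cat(sprintf("Community GAM [%s]: R2 = %.3f, adj R2 = %.3f, mean EDF = %.2f\n",
              if (length(x$terms)) paste(x$terms, collapse = ", ") else "null",
              x$r2, x$adj_r2, x$edf))
  invisible(x)
}

# pooled F-type test of a nested pair of community fits; degrees of
# freedom are summed per-taxon EDF differences
pooled_f_test <- function(fit0, fit1) {
  if (fit1$m_eff == 0) return(list(f = NA_real_, p = 1))
  df1 <- max(fit1$edf_total - fit0$edf_total, 0.5)
  df2 <- fit1$m_eff * (fit1$n - 1) - fit1$edf_total
  if (df2 <= 0) return(list(f = NA_real_, p = 1))
  drop_rss <- fit0$rss - fit1$rss
  if (drop_rss <= 0) return(list(f = 0, p = 1))
  f <- (drop_rss / df1) / (fit1$rss / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Forward selection with the double-stopping criterion
#'
#' Iteratively adds the candidate giving the largest adjusted-R^2 gain
#' whose addition is significant (pooled F-type test, p < `alpha`),
#' stopping when no candidate qualifies or when the cumulative adjusted
#' R^2 would exceed that of the global model containing all candidates.
#' If nothing survives both criteria, the single most significant
#' candidate is kept provided its p-value is below `alpha`.
#'
#' @param P response matrix as in [fit_gam_community()].
#' @param data predictor data frame.
#' @param candidates character vector of candidate labels (all
#'   environmental or all spatial; the two sets are selected
#'   separately).
#' @param alpha significance threshold for adding a term.
#' @param k_uni,k_bi,coord_names smooth settings, as in
#'   [fit_gam_community()].
#' @return List: `selected` labels, `global_adj_r2`, `fallback` flag,
#'   `steps` data frame of every candidate evaluation.
#' @export
forward_select <- function(P, data, candidates, alpha = 0.05,
                           k_uni = 9, k_bi = 18,
                           coord_names = c("lon", "lat")) {
  if (!length(candidates))
    return(list(selected = character(0), global_adj_r2 = NA_real_,
                fallback = FALSE, steps = NULL))
  P <- as.matrix(P)
  if (all(apply(P, 2, stats::var) == 0))
    return(list(selected = character(0), global_adj_r2 = 0,
                fallback = FALSE, steps = NULL))
  fit_terms <- function(terms) fit_gam_community(P, data, terms, k_uni,
                                                 k_bi, coord_names)
  global <- fit_terms(candidates)
  selected <- character(0)
  current <- fit_terms(character(0))
  steps <- list()
  first_round <- NULL
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    trial <- lapply(remaining, function(cand) {
      fit <- fit_terms(c(selected, cand))
      tst <- pooled_f_test(current, fit)
      list(cand = cand, adj_r2 = fit$adj_r2, p = tst$p, f = tst$f)
    })
    tab <- data.frame(
      step = length(selected) + 1L,
      candidate = vapply(trial, `[[`, character(1), "cand"),
      adj_r2 = vapply(trial, `[[`, numeric(1), "adj_r2"),
      p = vapply(trial, `[[`, numeric(1), "p")
    )
    steps[[length(steps) + 1L]] <- tab
    if (is.null(first_round)) first_round <- tab
    ok <- which(tab$p < alpha)
    if (!length(ok)) break
    best <- ok[which.max(tab$adj_r2[ok])]
    # double stop: selected-model adjusted R^2 must stay below the
    # global model's
    if (tab$adj_r2[best] > global$adj_r2) break
    selected <- c(selected, tab$candidate[best])
    current <- fit_terms(selected)
  }
  fallback <- FALSE
  if (!length(selected) && !is.null(first_round)) {
    best <- which.min(first_round$p)
    if (first_round$p[best] < alpha) {
      selected <- first_round$candidate[best]
      fallback <- TRUE
    }
  }
  list(selected = selected, global_adj_r2 = global$adj_r2,
       fallback = fallback, steps = do.call(rbind, steps))
}

#' Cap the combined selection at three variables
#'
#' When environmental and spatial selections together exceed three
#' variables, the lowest-contribution variables (adjusted R^2 of their
#' single-term model) are dropped until three remain.
#'
#' @inheritParams forward_select
#' @param env_sel,space_sel selected label vectors.
#' @param max_vars cap on the combined number of variables.
#' @return List with the capped `env_sel` and `space_sel`.
#' @export
cap_selection <- function(P, data, env_sel, space_sel, max_vars = 3,
                          k_uni = 9, k_bi = 18,
                          coord_names = c("lon", "lat")) {
  all_sel <- c(env_sel, space_sel)
  if (length(all_sel) <= max_vars)
    return(list(env_sel = env_sel, space_sel = space_sel))
  contrib <- vapply(all_sel, function(v)
    fit_gam_community(P, data, v, k_uni, k_bi, coord_names)$adj_r2,
    numeric(1))
  while (length(env_sel) + length(space_sel) > max_vars) {
    drop <- names(which.min(contrib[c(env_sel, space_sel)]))
    env_sel <- setdiff(env_sel, drop)
    space_sel <- setdiff(space_sel, drop)
  }
  list(env_sel = env_sel, space_sel = space_sel)
}

#' Partition community variation between environment and space
#'
#' Fits the environment-only, space-only and joint community GAMs and
#' decomposes the joint adjusted R^2 by the standard identity
#' `E|S = adjR2(ES) - adjR2(S)`, `S|E = adjR2(ES) - adjR2(E)`,
#' `E n S = adjR2(E) + adjR2(S) - adjR2(ES)`, residual
#' `= 1 - adjR2(ES)`.  An empty side contributes adjusted R^2 of zero,
#' so the whole explained fraction loads on the other pure component.
#' When an `msr` configuration is supplied, the environmental component
#' is corrected by Moran spectral randomization (see [msr_correct()])
#' and the shared fraction is recomputed from the corrected component.
#'
#' @inheritParams forward_select
#' @param env_sel,space_sel selected environmental / spatial labels (at
#'   least one may be empty).
#' @param msr optional list from [msr_config()].
#' @return Object of class `mp_partition` with the raw and corrected
#'   fractions, relative proportions and bookkeeping fields.
#' @export
partition_variation <- function(P, data, env_sel, space_sel, msr = NULL,
                                k_uni = 9, k_bi = 18,
                                coord_names = c("lon", "lat")) {
  empty_env <- !length(env_sel)
  empty_space <- !length(space_sel)
  if (empty_env && empty_space) {
    res <- list(
      adj_r2_E = 0, adj_r2_S = 0, adj_r2_ES = 0,
      frac_pure_env = 0, frac_shared = 0, frac_pure_space = 0,
      residual = 1,
      corrected_adj_r2_E = NA_real_, corrected_frac_pure_env = NA_real_,
      corrected_frac_shared = NA_real_,
      rel_pure_env = NA_real_, rel_shared = NA_real_,
      rel_pure_space = NA_real_,
      selected_env = character(0), selected_space = character(0),
      msr_replicates = 0L, seed = NA_integer_,
      flag = "no predictors selected"
    )
    return(structure(res, class = "mp_partition"))
  }
  fitE <- if (empty_env) NULL else
    fit_gam_community(P, data, env_sel, k_uni, k_bi, coord_names)
  fitS <- if (empty_space) NULL else
    fit_gam_community(P, data, space_sel, k_uni, k_bi, coord_names)
  fitES <- fit_gam_community(P, data, c(env_sel, space_sel), k_uni, k_bi,
                             coord_names)
  adjE <- if (empty_env) 0 else fitE$adj_r2
  adjS <- if (empty_space) 0 else fitS$adj_r2
  adjES <- fitES$adj_r2
  pure_env <- adjES - adjS
  pure_space <- adjES - adjE
  shared <- adjE + adjS - adjES
  residual <- 1 - adjES

  corr_E <- corr_shared <- corr_pure_env <- NA_real_
  msr_rep <- 0L
  msr_seed <- NA_integer_
  if (!is.null(msr) && !empty_env) {
    corr <- msr_correct(P, data, env_sel, msr, k_uni = k_uni, k_bi = k_bi,
                        coord_names = coord_names)
    corr_E <- corr$corrected_adj_r2_E
    corr_pure_env <- pure_env
    corr_shared <- corr_E - pure_env
    msr_rep <- corr$n_replicates
    msr_seed <- corr$seed
  }

  rel <- relative_proportions(c(pure_env, shared, pure_space))

  structure(list(
    adj_r2_E = adjE, adj_r2_S = adjS, adj_r2_ES = adjES,
    frac_pure_env = pure_env, frac_shared = shared,
    frac_pure_space = pure_space, residual = residual,
    corrected_adj_r2_E = corr_E, corrected_frac_pure_env = corr_pure_env,
    corrected_frac_shared = corr_shared,
    rel_pure_env = rel[1], rel_shared = rel[2], rel_pure_space = rel[3],
    selected_env = env_sel, selected_space = space_sel,
    msr_replicates = msr_rep, seed = msr_seed,
    flag = if (is.na(rel[1])) "no explained variation" else NA_character_
  ), class = "mp_partition")
}

#' @export
print.mp_partition <- function(x, ...) {
  cat(sprintf(
    "Partition: E|S = %.3f, EnS = %.3f, S|E = %.3f, residual = %.3f\n",
    x$frac_pure_env, x$frac_shared, x$frac_pure_space, x$residual))
  if (!is.na(x$corrected_adj_r2_E))
    cat(sprintf("  MSR-corrected env component: %.3f (uncorrected %.3f)\n",
                x$corrected_adj_r2_E, x$adj_r2_E))
  invisible(x)
}

#' Relative proportions of the explained fractions
#'
#' Negative fractions are floored at zero and each survivor is divided
#' by the post-floor sum, giving E|S/(E+S), EnS/(E+S), S|E/(E+S).  A
#' zero sum leaves all proportions undefined (NA).
#'
#' @param fractions numeric vector `(pure_env, shared, pure_space)`.
#' @return Numeric vector of three proportions summing to one (or NAs).
#' @export
relative_proportions <- function(fractions) {
  stopifnot(length(fractions) == 3)
  f <- pmax(fractions, 0)
  s <- sum(f)
  if (s <= 0) return(rep(NA_real_, 3))
  f / s
}

#' Moran spectral randomization configuration
#'
#' @param mem_basis complete orthonormal MEM eigenbasis of the site
#'   configuration (`mem_all` from [simulate_landscape()] /
#'   [build_mem()]).
#' @param n_replicates number of spectral randomizations (>= 19,
#'   default 199).
#' @param seed integer seed.
#' @return List of class `mp_msr_config`.
#' @export
msr_config <- function(mem_basis, n_replicates = 199, seed = 1) {
  if (n_replicates < 19) stop("null too small for correction")
  structure(list(mem_basis = as.matrix(mem_basis),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "mp_msr_config")
}

#' Moran spectral randomization of a variable
#'
#' Decomposes a centred variable on the orthonormal MEM basis,
#' multiplies each spectral coefficient by an independent standard
#' Gaussian (randomizing component signs and magnitudes), and rescales
#' the coefficient vector to its original norm, preserving the
#' variable's variance and, in expectation, its spatial power spectrum
#' (hence its Moran's I within Monte Carlo error).
#'
#' @param x numeric site vector.
#' @param B orthonormal MEM basis (sites x components).
#' @return Randomized vector with the same mean and variance.
#' @keywords internal
msr_randomize <- function(x, B) {
  mu <- mean(x)
  cf <- drop(crossprod(B, x - mu))
  g <- stats::rnorm(length(cf))
  cf_star <- cf * g
  nrm <- sqrt(sum(cf_star^2))
  if (nrm > 0) cf_star <- cf_star * sqrt(sum(cf^2)) / nrm
  mu + drop(B %*% cf_star)
}

#' MSR correction of the environmental component
#'
#' Implements a spectral-randomization adjustment of the environmental
#' R^2, transplanting the MSR-based correction for spatially
#' autocorrelated predictors from redundancy analysis to the community
#' GAM setting:
#' the selected environmental predictors are replaced by surrogates that
#' preserve their spatial autocorrelation structure, the
#' environment-only community R^2 is recomputed for each of
#' `n_replicates` surrogates, and the corrected adjusted environmental
#' component is `1 - (1 - R2(E)) / (1 - mean_r R2(E_r))`.
#'
#' @inheritParams forward_select
#' @param env_sel selected environmental labels (non-empty).
#' @param msr an [msr_config()] object.
#' @return List: `corrected_adj_r2_E`, observed `r2_E`, `mean_null_r2`,
#'   `null_r2` vector, `n_replicates`, `seed`.
#' @export
msr_correct <- function(P, data, env_sel, msr, k_uni = 9, k_bi = 18,
                        coord_names = c("lon", "lat")) {
  stopifnot(inherits(msr, "mp_msr_config"), length(env_sel) >= 1)
  if (msr$n_replicates < 19) stop("null too small for correction")
  B <- msr$mem_basis
  stopifnot(nrow(B) == nrow(data))
  fitE <- fit_gam_community(P, data, env_sel, k_uni, k_bi, coord_names)
  r2_obs <- fitE$r2
  set.seed(msr$seed)
  null_r2 <- vapply(seq_len(msr$n_replicates), function(r) {
    data_r <- data
    for (v in env_sel) data_r[[v]] <- msr_randomize(data[[v]], B)
    fit_gam_community(P, data_r, env_sel, k_uni, k_bi, coord_names)$r2
  }, numeric(1))
  mean_null <- mean(null_r2)
  corrected <- 1 - (1 - r2_obs) / (1 - mean_null)
  list(corrected_adj_r2_E = corrected, r2_E = r2_obs,
       mean_null_r2 = mean_null, null_r2 = null_r2,
       n_replicates = msr$n_replicates, seed = msr$seed)
}
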