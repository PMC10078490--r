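# Binomial generalized linear latent variable model (GLLVM).
#
# Marginal model: y_ij ~ Bernoulli(logit^-1(alpha_j + lambda_j' u_i)),
# u_i ~ N(0, I_d).  Estimation maximizes the joint penalized likelihood
# over (alpha, Lambda, U) by blockwise Newton updates (the u-block is the
# posterior mode; a standard-normal prior on the loadings keeps the
# binary-data likelihood bounded), and the reported log-likelihood is
# the Laplace approximation to the marginal evaluated at the optimum:
#   ll = sum_i [ l_i(u_i) - u_i'u_i/2 - log det(I + Lambda' W_i Lambda)/2 ]
# with W_i the Bernoulli variance weights.  Identifiability: Lambda is
# rotated post hoc to upper-triangular-zero form with positive diagonal.

bernoulli_ll <- function(y, eta) {
  # numerically stable sum of y*eta - log(1 + exp(eta))
  sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
}

# columns of the lower-triangular index pairs for d x d symmetric matrices
sym_pairs <- function(d) {
  idx <- which(lower.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

solve_batch3 <- function(H, G) {
  a <- H[, 1]; b <- H[, 2]; cc <- H[, 3]
  dd <- H[, 4]; e <- H[, 5]; f <- H[, 6]
  # H_i = [a b dd; b cc e; dd e f]
  A11 <- cc * f - e^2
  A12 <- dd * e - b * f
  A13 <- b * e - cc * dd
  A22 <- a * f - dd^2
  A23 <- b * dd - a * e
  A33 <- a * cc - b^2
  det <- a * A11 + b * A12 + dd * A13
  cbind((A11 * G[, 1] + A12 * G[, 2] + A13 * G[, 3]) / det,
        (A12 * G[, 1] + A22 * G[, 2] + A23 * G[, 3]) / det,
        (A13 * G[, 1] + A23 * G[, 2] + A33 * G[, 3]) / det)
}

# batch solve H_i step = g_i for n small SPD systems given stacked unique
# elements of H (n x d(d+1)/2, lower-tri order) and gradients (n x d)
solve_batch <- function(H, G, d) {
  if (d == 1L) {
    return(G / H)
  }
  if (d == 2L) {
    a <- H[, 1]; b <- H[, 2]; c <- H[, 3]
    det <- a * c - b^2
    cbind((c * G[, 1] - b * G[, 2]) / det,
          (a * G[, 2] - b * G[, 1]) / det)
  } else if (d == 3L) {
    solve_batch3(H, G)
  } else if (d == 4L) {
    # Schur complement on the leading 3x3 block
    A <- H[, 1:6, drop = FALSE]
    b <- H[, 7:9, drop = FALSE]
    c <- H[, 10]
    Ainv_g <- solve_batch3(A, G[, 1:3, drop = FALSE])
    Ainv_b <- solve_batch3(A, b)
    x4 <- (G[, 4] - rowSums(b * Ainv_g)) / (c - rowSums(b * Ainv_b))
    cbind(Ainv_g - Ainv_b * x4, x4)
  } else {
    t(vapply(seq_len(nrow(G)), function(i) {
      Hi <- matrix(0, d, d)
      Hi[lower.tri(Hi, diag = TRUE)] <- H[i, ]
      Hi <- Hi + t(Hi) - diag(diag(Hi))
      solve(Hi, G[i, ])
    }, numeric(d)))
  }
}

batch_logdet <- function(H, d) {
  if (d == 1L) return(log(H[, 1]))
  if (d == 2L) return(log(H[, 1] * H[, 3] - H[, 2]^2))
  if (d == 3L) {
    a <- H[, 1]; b <- H[, 2]; cc <- H[, 3]
    dd <- H[, 4]; e <- H[, 5]; f <- H[, 6]
    return(log(a * (cc * f - e^2) + b * (dd * e - b * f) +
                 dd * (b * e - cc * dd)))
  }
  vapply(seq_len(nrow(H)), function(i) {
    Hi <- matrix(0, d, d)
    Hi[lower.tri(Hi, diag = TRUE)] <- H[i, ]
    Hi <- Hi + t(Hi) - diag(diag(Hi))
    determinant(Hi, logarithm = TRUE)$modulus
  }, numeric(1))
}

# stacked unique elements of Lambda' diag(w_i) Lambda + I across sites
hess_cols <- function(Wmat, Lambda, pairs) {
  LL <- Lambda[, pairs[, 1], drop = FALSE] * Lambda[, pairs[, 2], drop = FALSE]
  H <- Wmat %*% LL
  diag_idx <- which(pairs[, 1] == pairs[, 2])
  H[, diag_idx] <- H[, diag_idx] + 1
  H
}

# Newton steps for the site-score block (posterior modes given params)
update_scores <- function(Yv, U, alpha, Lambda, pairs, n_steps = 3) {
  d <- ncol(Lambda)
  for (s in seq_len(n_steps)) {
    eta <- sweep(U %*% t(Lambda), 2, alpha, `+`)
    P <- invlogit(eta)
    G <- (Yv - P) %*% Lambda - U
    H <- hess_cols(P * (1 - P), Lambda, pairs)
    step <- solve_batch(H, G, d)
    nrm <- sqrt(rowSums(step^2))
    too_big <- nrm > 4
    if (any(too_big)) step[too_big, ] <- step[too_big, ] * (4 / nrm[too_big])
    U <- U + step
  }
  U
}

#' Fit a binomial GLLVM of fixed latent dimension
#'
#' Fits intercepts, loadings and latent site scores by blockwise Newton
#' maximization of the penalized joint likelihood, with a Laplace
#' approximation to the marginal log-likelihood at the optimum; several
#' seeded random restarts guard against local optima.  `d = 0` is the
#' exact intercept-only model (closed-form prevalences).  Species with
#' no variation (all absent or all present) keep their column but are
#' excluded from the latent structure; their predicted probability is
#' their (clamped) prevalence.
#'
#' @param Y binary site-by-taxon matrix.
#' @param d latent dimension (0 <= d < min(n_sites, n_taxa)).
#' @param seed integer seed controlling the restarts.
#' @param n_restarts random restarts for d >= 1 (best kept).
#' @param max_iter,tol outer-loop iteration cap and relative
#'   log-likelihood tolerance.
#' @param init optional warm start: list with `alpha`, `Lambda`
#'   (variant-taxa rows), `U`; evaluated as an extra candidate and used
#'   to seed one restart.  The zero-loadings point is always evaluated
#'   too, so the reported likelihood never falls below the d = 0 model
#'   (the models are nested).
#' @return Object of class `mp_gllvm`: `n_latent`, `intercepts`,
#'   `loadings` (taxon x d, zero rows for invariant taxa),
#'   `site_scores`, `log_likelihood` (Laplace), `n_params`, `aic`,
#'   `predicted` (probabilities clamped to [1e-6, 1 - 1e-6]),
#'   `converged`, `n_restarts_used`, `variant` flags.
#' @export
fit_binomial_gllvm <- function(Y, d, seed = 1, n_restarts = 3,
                               max_iter = 150, tol = 1e-6, init = NULL) {
  Y <- as.matrix(Y)
  if (!all(Y %in% c(0, 1))) stop("community matrix must be binary")
  n <- nrow(Y); m <- ncol(Y)
  if (n < 2 || m < 1) stop("need at least 2 sites and 1 taxon")
  if (d < 0) stop("d must be non-negative")
  if (d > 0 && d >= min(n, m)) stop("d must be smaller than min(n_sites, n_taxa)")
  prev <- colMeans(Y)
  variant <- prev > 0 & prev < 1
  # closed-form independent-taxon log-likelihood (0 log 0 := 0)
  ll0 <- sum(ifelse(prev %in% c(0, 1), 0,
                    n * (prev * log(prev) + (1 - prev) * log(1 - prev))))
  alpha_full <- stats::qlogis(clamp_prob(prev))
  if (d == 0L || !any(variant)) {
    predicted <- matrix(clamp_prob(prev), n, m, byrow = TRUE,
                        dimnames = dimnames(Y))
    n_params <- m
    return(structure(list(
      n_latent = 0L, intercepts = alpha_full,
      loadings = matrix(0, m, 0), site_scores = matrix(0, n, 0),
      log_likelihood = ll0, n_params = n_params,
      aic = 2 * n_params - 2 * ll0, predicted = predicted,
      converged = TRUE, n_restarts_used = 0L, variant = variant,
      seed = seed
    ), class = "mp_gllvm"))
  }

  Yv <- Y[, variant, drop = FALSE]
  mv <- ncol(Yv)
  d <- as.integer(d)
  pairs <- sym_pairs(d)
  # standard-normal prior on loadings (symmetric with the score prior):
  # regularizes the otherwise unbounded joint likelihood of binary data,
  # where perfect separation drives loadings to infinity
  ridge <- 1

  penalized_ll <- function(U, alpha, Lambda) {
    eta <- sweep(U %*% t(Lambda), 2, alpha, `+`)
    bernoulli_ll(Yv, eta) - 0.5 * sum(U^2) - 0.5 * ridge * sum(Lambda^2)
  }

  laplace_at <- function(alpha, Lambda, U) {
    U <- update_scores(Yv, U, alpha, Lambda, pairs, n_steps = 4)
    eta <- sweep(U %*% t(Lambda), 2, alpha, `+`)
    P <- invlogit(eta)
    H <- hess_cols(P * (1 - P), Lambda, pairs)
    ll <- bernoulli_ll(Yv, eta) - 0.5 * sum(U^2) -
      0.5 * sum(batch_logdet(H, d))
    list(ll = ll, alpha = alpha, Lambda = Lambda, U = U)
  }

  # nested-model floor: at Lambda = 0 the Laplace likelihood equals the
  # exact independent-taxon likelihood
  best <- list(ll = ll0,
               alpha = stats::qlogis(prev[variant]),
               Lambda = matrix(0, mv, d),
               U = matrix(0, n, d),
               converged = TRUE)
  if (!is.null(init)) {
    cand <- laplace_at(init$alpha, init$Lambda, init$U)
    if (cand$ll > best$ll) best <- c(cand, converged = TRUE)
  }
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, paste0("gllvm_restart_", r)))
    if (r == 1L && !is.null(init)) {
      Lambda <- init$Lambda + matrix(stats::rnorm(mv * d, 0, 0.02), mv, d)
      alpha <- init$alpha
      U <- init$U
    } else {
      Lambda <- matrix(stats::rnorm(mv * d, 0, 0.3), mv, d)
      alpha <- stats::qlogis(clamp_prob(prev[variant], 1e-3))
      U <- matrix(stats::rnorm(n * d, 0, 0.1), n, d)
    }
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      U <- update_scores(Yv, U, alpha, Lambda, pairs, n_steps = 2)
      X <- cbind(1, U)
      pairsB <- sym_pairs(d + 1L)
      XX <- X[, pairsB[, 1], drop = FALSE] * X[, pairsB[, 2], drop = FALSE]
      diag_idx <- which(pairsB[, 1] == pairsB[, 2])
      r_vec <- c(1e-6, rep(ridge, d))
      Beta <- rbind(alpha, t(Lambda))
      for (s in 1:2) {
        eta <- X %*% Beta
        Pm <- invlogit(eta)
        Wm <- pmax(Pm * (1 - Pm), 1e-8)
        Gr <- crossprod(X, Yv - Pm) - Beta * r_vec
        Hc <- crossprod(Wm, XX)
        Hc[, diag_idx] <- sweep(Hc[, diag_idx, drop = FALSE], 2, r_vec, `+`)
        step <- solve_batch(Hc, t(Gr), d + 1L)
        nrm <- sqrt(rowSums(step^2))
        too_big <- nrm > 5
        if (any(too_big))
          step[too_big, ] <- step[too_big, ] * (5 / nrm[too_big])
        Beta <- Beta + t(step)
      }
      alpha <- Beta[1, ]
      Lambda <- t(Beta[-1, , drop = FALSE])
      ll_new <- penalized_ll(U, alpha, Lambda)
      if (is.finite(ll_new) && abs(ll_new - ll_old) <
            tol * (abs(ll_old) + 1)) {
        converged <- TRUE
        break
      }
      ll_old <- ll_new
    }
    cand <- laplace_at(alpha, Lambda, U)
    if (cand$ll > best$ll) best <- c(cand, converged = converged)
  }

  # rotate to upper-triangular-zero loadings with positive diagonal
  alpha <- best$alpha; Lambda <- best$Lambda; U <- best$U
  if (d > 1L && mv >= d) {
    M <- Lambda[seq_len(d), , drop = FALSE]
    Q <- qr.Q(qr(t(M)))
    Lambda <- Lambda %*% Q
    U <- U %*% Q
    top <- Lambda[seq_len(d), , drop = FALSE]
    top[upper.tri(top)] <- 0  # exact zeros where rotation leaves noise
    Lambda[seq_len(d), ] <- top
  }
  for (k in seq_len(d)) {
    if (k <= mv && Lambda[k, k] < 0) {
      Lambda[, k] <- -Lambda[, k]
      U[, k] <- -U[, k]
    }
  }

  loadings <- matrix(0, m, d,
                     dimnames = list(colnames(Y), paste0("LV", seq_len(d))))
  loadings[variant, ] <- Lambda
  intercepts <- alpha_full
  intercepts[variant] <- alpha

  eta_full <- matrix(stats::qlogis(clamp_prob(prev)), n, m, byrow = TRUE)
  eta_full[, variant] <- sweep(U %*% t(Lambda), 2, alpha, `+`)
  predicted <- clamp_prob(invlogit(eta_full))
  dimnames(predicted) <- dimnames(Y)

  # invariant taxa contribute 0 to the exact likelihood
  ll <- best$ll
  n_params <- m + d * mv - d * (d - 1) / 2
  structure(list(
    n_latent = d, intercepts = intercepts, loadings = loadings,
    site_scores = U, log_likelihood = ll, n_params = n_params,
    aic = 2 * n_params - 2 * ll, predicted = predicted,
    converged = best$converged, n_restarts_used = n_restarts,
    variant = variant, seed = seed
  ), class = "mp_gllvm")
}

#' @export
print.mp_gllvm <- function(x, ...) {
  cat(sprintf(
    "Binomial GLLVM: d = %d, logLik = %.2f, AIC = %.2f (%sconverged)\n",
    x$n_latent, x$log_likelihood, x$aic, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Select the latent dimension by AIC
#'
#' Fits every candidate dimension and returns the fit with the lowest
#' AIC; ties break toward the smaller dimension.
#'
#' @inheritParams fit_binomial_gllvm
#' @param d_candidates integer vector of candidate dimensions.
#' @param ... passed to [fit_binomial_gllvm()].
#' @return The winning `mp_gllvm` fit, with an `aic_table` attribute
#'   (candidate d, AIC, convergence).
#' @export
select_latent_dimension <- function(Y, d_candidates = 0:3, seed = 1, ...) {
  if (!length(d_candidates)) stop("d_candidates must be non-empty")
  d_candidates <- sort(unique(as.integer(d_candidates)))
  fits <- vector("list", length(d_candidates))
  prev_fit <- NULL
  for (i in seq_along(d_candidates)) {
    d <- d_candidates[i]
    init <- NULL
    if (!is.null(prev_fit) && d > 0L && prev_fit$n_latent < d &&
          any(prev_fit$variant)) {
      # warm start: previous solution padded with zero columns, so the
      # likelihood chain stays monotone in d
      mv <- sum(prev_fit$variant)
      pad <- d - prev_fit$n_latent
      init <- list(
        alpha = prev_fit$intercepts[prev_fit$variant],
        Lambda = cbind(prev_fit$loadings[prev_fit$variant, , drop = FALSE],
                       matrix(0, mv, pad)),
        U = cbind(prev_fit$site_scores, matrix(0, nrow(Y), pad))
      )
    }
    fits[[i]] <- fit_binomial_gllvm(Y, d,
                                    seed = derive_seed(seed, paste0("d", d)),
                                    init = init, ...)
    prev_fit <- fits[[i]]
  }
  conv <- vapply(fits, `[[`, logical(1), "converged")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  if (!any(conv)) {
    stop("no candidate latent dimension converged; AICs: ",
         paste(sprintf("d=%d: %.1f", d_candidates, aics), collapse = ", "))
  }
  best <- which.min(aics)  # candidates sorted ascending: ties go to smaller d
  fit <- fits[[best]]
  attr(fit, "aic_table") <- data.frame(
    d = d_candidates, aic = aics, converged = conv,
    selected = seq_along(fits) == best)
  fit
}

#' Predicted occurrence probabilities from a GLLVM fit
#'
#' Inverse-logit of the fitted linear predictor, clamped to
#' [1e-6, 1 - 1e-6]; the response matrix handed to the GAM stage.
#'
#' @param fit an `mp_gllvm` object.
#' @param allow_unconverged return predictions even if the optimizer did
#'   not meet its tolerance.
#' @return Site-by-taxon probability matrix.
#' @export
predicted_response <- function(fit, allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "mp_gllvm"))
  if (!fit$converged && !allow_unconverged)
    stop("GLLVM fit did not converge; pass allow_unconverged = TRUE to override")
  fit$predicted
}
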