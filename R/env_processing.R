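#' Transform environmental variables
#'
#' Applies the per-variable transformation recorded in (or assigned to)
#' the metadata: `asin_sqrt` for proportion-type variables
#' (\eqn{y = \arcsin\sqrt p}, percentages divided by 100 first) and
#' `log` for right-skewed non-negative variables
#' (\eqn{y = \log_{10}(x + c)} with offset \eqn{c = 1} when zeros are
#' present, else 0).  When `auto = TRUE` and a variable's transform is
#' missing or `NA`, the rule is: values in [0,1] (or [0,100] with
#' `percent`) -> `asin_sqrt`; non-negative with sample skewness > 1 ->
#' `log`; otherwise `none`.
#'
#' @param env list with `values` (data frame, first column `site_id`)
#'   and `meta` (data frame with columns `variable`, `transform`, and
#'   optionally `percent` flags).
#' @param auto assign transforms automatically where missing.
#' @return The same structure with transformed `values` and the
#'   resolved `meta$transform`.
#' @export
transform_variables <- function(env, auto = FALSE) {
  vals <- env$values
  meta <- env$meta
  if (anyNA(vals$site_id) || any(vals$site_id == ""))
    stop("missing site_id in environment table")
  stopifnot(all(meta$variable %in% names(vals)))
  if (is.null(meta$percent)) meta$percent <- FALSE
  for (i in seq_len(nrow(meta))) {
    v <- meta$variable[i]
    x <- vals[[v]]
    tr <- meta$transform[i]
    if (auto && (is.na(tr) || tr == "")) {
      tr <- if (all(x >= 0 & x <= (if (meta$percent[i]) 100 else 1),
                    na.rm = TRUE)) {
        "asin_sqrt"
      } else if (all(x >= 0, na.rm = TRUE) &&
                 isTRUE(sample_skewness(x) > 1)) {
        "log"
      } else "none"
    }
    if (is.na(tr) || tr == "") tr <- "none"
    if (tr == "asin_sqrt") {
      p <- if (meta$percent[i]) x / 100 else x
      if (any(p < 0 | p > 1, na.rm = TRUE))
        stop(sprintf("variable '%s': arcsine-square-root input outside [0, 1]", v))
      vals[[v]] <- asin(sqrt(p))
    } else if (tr == "log") {
      if (any(x < 0, na.rm = TRUE))
        stop(sprintf("variable '%s': negative input to log transform", v))
      offset <- if (any(x == 0, na.rm = TRUE)) 1 else 0
      vals[[v]] <- log10(x + offset)
    } else if (tr != "none") {
      stop(sprintf("unknown transform '%s' for variable '%s'", tr, v))
    }
    meta$transform[i] <- tr
  }
  list(values = vals, meta = meta)
}

#' Reduce the environment to its first three principal components
#'
#' Correlation PCA (variables standardized to zero mean, unit variance)
#' by singular value decomposition; constant variables are dropped with
#' a warning.  The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making downstream forward
#' selection reproducible.
#'
#' @param env list with `values`/`meta` as in [transform_variables()]
#'   (transforms already applied).
#' @param n_comp number of components to keep (default 3).
#' @return Object of class `mp_pcscores`: `scores` (site x n_comp, named
#'   PC1..), `loadings`, `explained` (per-component variance
#'   proportions), `cumulative_explained`, `site_id`, `dropped`.
#' @export
reduce_environment <- function(env, n_comp = 3) {
  vals <- env$values
  X <- as.matrix(vals[, -1, drop = FALSE])
  if (nrow(X) < 4) stop("need at least 4 sites for PCA")
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("dropping constant variable(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  if (ncol(X) < 3) stop("need at least 3 (non-constant) variables for PCA")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  explained <- ev / sum(ev)
  n_comp <- min(n_comp, ncol(pc$rotation))
  scores <- pc$x[, seq_len(n_comp), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  for (k in seq_len(n_comp)) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_comp))
  structure(list(
    scores = scores,
    loadings = loadings,
    explained = explained[seq_len(n_comp)],
    explained_all = explained,
    cumulative_explained = sum(explained[seq_len(n_comp)]),
    site_id = vals$site_id,
    dropped = dropped
  ), class = "mp_pcscores")
}

#' @export
print.mp_pcscores <- function(x, ...) {
  cat(sprintf(
    "PCA reduction: %d components, %.2f%% of variance (%s)\n",
    ncol(x$scores), 100 * x$cumulative_explained,
    paste(sprintf("%.1f%%", 100 * x$explained), collapse = " + ")))
  invisible(x)
}

#' Shoreline development index
#'
#' \eqn{D_L = L / (2 \sqrt{\pi A})}: the ratio of a waterbody's
#' shoreline length to the circumference of a circle of equal area.
#' Equals 1 for a perfect circle and grows with shoreline complexity.
#'
#' @param perimeter shoreline length L (m), > 0.
#' @param area surface area A (m^2), > 0.
#' @return Scalar index (>= 1 for simply connected shapes).
#' @export
shoreline_development <- function(perimeter, area) {
  if (any(perimeter <= 0) || any(area <= 0))
    stop("perimeter and area must be positive")
  perimeter / (2 * sqrt(pi * area))
}

#' Shannon diversity of land-cover proportions
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over land-cover classes; input
#' proportions are renormalized to sum to one and zero classes
#' contribute nothing.
#'
#' @param proportions non-negative cover fractions, sum > 0.
#' @return Scalar Shannon index (natural log).
#' @export
landcover_shannon <- function(proportions) {
  if (any(proportions < 0)) stop("proportions must be non-negative")
  s <- sum(proportions)
  if (s <= 0) stop("all-zero cover vector")
  p <- proportions / s
  p <- p[p > 0]
  -sum(p * log(p)) + 0  # + 0 normalizes IEEE negative zero
}
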