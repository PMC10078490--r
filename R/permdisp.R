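#' PERMDISP: homogeneity of multivariate dispersion
#'
#' Distances of sites to their group centroid are computed in the
#' principal-coordinate embedding of the Euclidean distance matrix
#' (negative-eigenvalue axes contribute negatively,
#' \eqn{\sqrt{d^2_{real} - d^2_{imag}}}, floored at zero), via
#' [vegan::betadisper()].  The F statistic is the one-way ANOVA F on the
#' centroid distances, and its p-value comes from permuting group labels
#' of the distances, \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) /
#' (1 + n_{perm})}.
#'
#' Variables are jointly standardized (zero mean, unit variance across
#' all groups) before the distance computation unless
#' `standardize = FALSE`.
#'
#' @param X site-by-variable numeric matrix or data frame (transformed
#'   variables).
#' @param groups factor or character vector of group labels (>= 2
#'   groups with >= 2 sites each).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param standardize standardize variables jointly before computing
#'   distances.
#' @return Object of class `mp_permdisp`: `distances` (per site),
#'   `group_means`, `f_stat`, `p_perm`, `n_perm`, `seed`, `groups`.
#' @export
permdisp <- function(X, groups, n_perm = 999, seed = 1,
                     standardize = TRUE) {
  X <- as.matrix(X)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 sites")
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X[, sds > 0, drop = FALSE])
  }
  if (all(apply(X, 2, stats::sd) == 0)) stop("zero total variance")
  bd <- vegan::betadisper(stats::dist(X), groups, type = "centroid")
  z <- bd$distances
  f_obs <- anova_f(z, groups)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    f_b <- anova_f(z[sample.int(length(z))], groups)
    if (f_b >= f_obs) exceed <- exceed + 1L
  }
  structure(list(
    distances = z,
    group_means = tapply(z, groups, mean),
    f_stat = f_obs,
    p_perm = (1 + exceed) / (1 + n_perm),
    n_perm = n_perm,
    seed = seed,
    groups = groups
  ), class = "mp_permdisp")
}

# one-way ANOVA F statistic on a vector given group labels
anova_f <- function(z, groups) {
  g <- nlevels(groups)
  n <- length(z)
  gm <- tapply(z, groups, mean)
  ng <- tabulate(groups)
  ssb <- sum(ng * (gm - mean(z))^2)
  ssw <- sum((z - gm[as.integer(groups)])^2)
  if (ssw == 0) return(Inf)
  (ssb / (g - 1)) / (ssw / (n - g))
}

#' @export
print.mp_permdisp <- function(x, ...) {
  cat("PERMDISP: F =", format(x$f_stat, digits = 4),
      ", p =", format(x$p_perm, digits = 4),
      sprintf("(%d permutations)\n", x$n_perm))
  cat("Mean distance to centroid:\n")
  print(round(x$group_means, 4))
  invisible(x)
}
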