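#' Derive a stage seed from a master seed and a label
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from the master seed and a short label, so that
#' adding or reordering stages never silently changes the stream another
#' stage consumes.  Seeds stay below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param tag character label of the stage (e.g. `"gllvm_rotifera"`).
#' @return A single integer usable with [set.seed()].
#' @export
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1L, is.finite(master))
  m <- 2147483647
  h <- as.double(master) %% m
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + code) %% m
  }
  h <- (h * 48271 + 11) %% m
  as.integer(h)
}

#' @keywords internal
invlogit <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
clamp_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Sample skewness
#'
#' Third standardized moment, \eqn{m_3 / m_2^{3/2}} with biased (moment)
#' estimators; used by the automatic transformation rule.
#'
#' @param x numeric vector.
#' @return Scalar skewness (NA if fewer than 3 distinct values).
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(NA_real_)
  z <- x - mean(x)
  m2 <- mean(z^2)
  m3 <- mean(z^3)
  m3 / m2^1.5
}

#' Moran's I spatial autocorrelation statistic
#'
#' Definitional form \eqn{I = (n / S_0) \, z' W z / z'z} with
#' \eqn{z = x - \bar x} and \eqn{S_0 = \sum_{ij} w_{ij}}.
#'
#' @param x numeric vector of site values.
#' @param W square spatial weight matrix (zero diagonal).
#' @return Scalar Moran's I.
#' @export
moran_i <- function(x, W) {
  n <- length(x)
  stopifnot(nrow(W) == n, ncol(W) == n)
  z <- x - mean(x)
  s0 <- sum(W)
  if (s0 == 0 || sum(z^2) == 0) return(NA_real_)
  (n / s0) * drop(crossprod(z, W %*% z)) / sum(z^2)
}
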