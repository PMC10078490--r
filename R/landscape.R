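#' Build a distance-based Moran eigenvector map (dbMEM) basis
#'
#' Follows the standard dbMEM recipe: pairwise distances are truncated
#' at the longest edge of the minimum spanning tree, connectivity within
#' the truncation radius is binary, the connectivity matrix is doubly
#' centred, and its eigenvectors form the spatial basis.  Eigenvectors
#' with positive eigenvalues (positively autocorrelated patterns,
#' broadest scales first) are the usual spatial predictors; the complete
#' orthonormal basis of the centred space (n - 1 columns with their
#' eigenvalue spectrum) is retained as well because Moran spectral
#' randomization needs an exact decomposition of any centred variable.
#'
#' @param coords two-column matrix or data frame of site positions
#'   (`x`/`y` in planar units, or `lon`/`lat` in decimal degrees).
#' @param geographic if `TRUE`, distances are great-circle (haversine,
#'   Earth radius 6371 km); otherwise Euclidean.
#' @return List with elements `basis` (sites x positive eigenvectors),
#'   `eigenvalues`, `basis_all`, `eigenvalues_all`, `threshold` (MST
#'   truncation distance) and `weights` (the binary connectivity
#'   matrix).
#' @export
build_mem <- function(coords, geographic = FALSE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4L) stop("insufficient sites for spatial basis")
  D <- if (geographic) haversine_matrix_km(coords) else
    as.matrix(stats::dist(coords))
  mst <- vegan::spantree(stats::as.dist(D))
  threshold <- max(mst$dist)
  W <- (D > 0 & D <= threshold) * 1
  diag(W) <- 0
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% W %*% C
  G <- (G + t(G)) / 2
  # eigen-decompose on the orthogonal complement of the constant vector,
  # so the full basis always has exactly n - 1 centred orthonormal
  # columns even when the centred connectivity is rank deficient (MSR
  # needs an exact decomposition of any centred variable)
  Q <- qr.Q(qr(cbind(rep(1, n), diag(n))))[, 2:n, drop = FALSE]
  e <- eigen(crossprod(Q, G %*% Q), symmetric = TRUE)
  vectors <- Q %*% e$vectors
  values <- e$values
  tol <- 1e-8 * max(abs(values), 1)
  keep_pos <- values > tol
  list(
    basis = vectors[, keep_pos, drop = FALSE],
    eigenvalues = values[keep_pos],
    basis_all = vectors,
    eigenvalues_all = values,
    threshold = threshold,
    weights = W
  )
}

#' Simulate a pond landscape with its spatial basis
#'
#' Places `n_sites` sites uniformly at random over a square of side
#' `extent` and attaches the dbMEM basis built from the configuration.
#' With `geographic = TRUE` the coordinates are decimal degrees centred
#' on (`lon0`, `lat0`) and all distances are haversine.
#'
#' @param n_sites number of sites (>= 4).
#' @param extent side of the square (planar units, or degrees when
#'   geographic).
#' @param seed integer seed; the landscape is reproducible given it.
#' @param geographic flag switching coordinates to decimal degrees.
#' @param lon0,lat0 centre of the geographic square (ignored when
#'   planar).
#' @return Object of class `mp_landscape`: `site_id`, `coords` (data
#'   frame with `x`,`y` or `lon`,`lat`), `mem` (positive-eigenvalue
#'   basis), `mem_eigenvalues`, `mem_all`, `mem_eigenvalues_all`,
#'   `weights`, `geographic`, `seed`.
#' @export
simulate_landscape <- function(n_sites, extent = 1, seed = 1,
                               geographic = FALSE, lon0 = 0, lat0 = 40) {
  if (n_sites < 4L) stop("insufficient sites for spatial basis")
  set.seed(derive_seed(seed, "landscape"))
  x <- stats::runif(n_sites, 0, extent)
  y <- stats::runif(n_sites, 0, extent)
  if (geographic) {
    coords <- data.frame(lon = lon0 - extent / 2 + x,
                         lat = lat0 - extent / 2 + y)
  } else {
    coords <- data.frame(x = x, y = y)
  }
  mem <- build_mem(coords, geographic = geographic)
  structure(list(
    site_id = sprintf("site_%03d", seq_len(n_sites)),
    coords = coords,
    mem = mem$basis,
    mem_eigenvalues = mem$eigenvalues,
    mem_all = mem$basis_all,
    mem_eigenvalues_all = mem$eigenvalues_all,
    weights = mem$weights,
    threshold = mem$threshold,
    geographic = geographic,
    seed = seed
  ), class = "mp_landscape")
}

#' @export
print.mp_landscape <- function(x, ...) {
  cat("Landscape:", length(x$site_id), "sites,",
      ncol(x$mem), "positive MEM eigenvectors",
      if (x$geographic) "(geographic)" else "(planar)", "\n")
  invisible(x)
}
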