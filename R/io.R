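# CSV readers/writers and geodesic utilities.  All tables are plain CSV
# with a header row and site_id as the first column.

#' Read a binary community matrix from CSV
#'
#' @param path CSV file, header row, first column `site_id`, remaining
#'   columns binary occurrences.
#' @return Site-by-taxon binary matrix with site ids as rownames.
#' @export
read_community_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  validate_site_ids(df[[1]], path)
  Y <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(Y %in% c(0, 1)), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(Y))
    stop(sprintf(
      "non-binary entry '%s' in community file at row '%s', column '%s'",
      Y[bad[1]], df[[1]][rc[1]], colnames(Y)[rc[2]]))
  }
  storage.mode(Y) <- "integer"
  rownames(Y) <- df[[1]]
  Y
}

#' Read an environment table (values + optional metadata) from CSV
#'
#' @param path values CSV (`site_id` first column, numeric variables).
#' @param meta_path optional companion CSV with columns `variable`,
#'   `transform`, `set`, and optionally `units`/`percent`.
#' @return List with `values` and `meta` as used by
#'   [transform_variables()].
#' @export
read_environment_csv <- function(path, meta_path = NULL) {
  vals <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_site_ids(vals[[1]], path)
  names(vals)[1] <- "site_id"
  meta <- if (!is.null(meta_path)) {
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  } else {
    data.frame(variable = names(vals)[-1], transform = NA_character_,
               set = "other", units = "", stringsAsFactors = FALSE)
  }
  missing <- setdiff(meta$variable, names(vals)[-1])
  if (length(missing))
    stop("metadata names variables absent from the table: ",
         paste(missing, collapse = ", "))
  list(values = vals, meta = meta)
}

#' Read site coordinates from CSV
#'
#' @param path CSV with columns `site_id`, `lon`, `lat` (decimal
#'   degrees, WGS84) or `site_id`, `x`, `y` (planar).
#' @return Data frame with validated coordinates.
#' @export
read_coordinates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_site_ids(df[[1]], path)
  names(df)[1] <- "site_id"
  geo <- all(c("lon", "lat") %in% names(df))
  if (!geo && !all(c("x", "y") %in% names(df)))
    stop("coordinate file needs lon/lat or x/y columns")
  if (geo) {
    if (anyNA(df$lon) || anyNA(df$lat))
      stop("missing coordinate for site(s): ",
           paste(df$site_id[is.na(df$lon) | is.na(df$lat)], collapse = ", "))
    check_lonlat(df$lon, df$lat)
  }
  attr(df, "geographic") <- geo
  df
}

validate_site_ids <- function(ids, path) {
  if (anyNA(ids) || any(ids == ""))
    stop("missing site_id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated site_id in ", path, ": ", paste(dup, collapse = ", "))
  invisible(ids)
}

check_lonlat <- function(lon, lat) {
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("coordinate out of range (lat must be in [-90, 90], lon in [-180, 180])")
  invisible(NULL)
}

#' Check that community, environment and coordinate tables align
#'
#' @param communities named list of community matrices (rownames =
#'   site ids).
#' @param environment list with `values` (first column `site_id`).
#' @param coords coordinate data frame (`site_id` column).
#' @return Invisibly, the common site ids (in environment-table order);
#'   errors list every offending site.
#' @export
validate_tables <- function(communities, environment, coords) {
  env_ids <- environment$values$site_id
  coord_ids <- coords$site_id
  if (!setequal(env_ids, coord_ids))
    stop("site sets differ between environment and coordinates: ",
         paste(union(setdiff(env_ids, coord_ids),
                     setdiff(coord_ids, env_ids)), collapse = ", "))
  for (g in names(communities)) {
    ids <- rownames(communities[[g]])
    extra <- setdiff(ids, env_ids)
    miss <- setdiff(env_ids, ids)
    if (length(extra) || length(miss))
      stop(sprintf("community '%s' misaligned with environment; %s%s", g,
                   if (length(extra)) paste0("unknown sites: ",
                                             paste(extra, collapse = ", "))
                   else "",
                   if (length(miss)) paste0(" missing sites: ",
                                            paste(miss, collapse = ", "))
                   else ""))
  }
  invisible(env_ids)
}

#' Write a site-by-taxon (or site-by-variable) matrix as CSV
#'
#' @param M matrix with site ids as rownames (or data frame with
#'   `site_id` first column).
#' @param path output file.
#' @export
write_sites_csv <- function(M, path) {
  if (is.matrix(M)) {
    M <- data.frame(site_id = rownames(M), M, check.names = FALSE)
  }
  utils::write.csv(M, path, row.names = FALSE)
  invisible(path)
}

#' Maximum pairwise great-circle distance between sites
#'
#' Haversine distances with Earth radius 6371 km.
#'
#' @param coords data frame or matrix with `lon`, `lat` columns in
#'   decimal degrees.
#' @return Maximum over all site pairs, in km.
#' @export
max_pairwise_distance_km <- function(coords) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("lon", "lat") %in% names(coords)))
  if (nrow(coords) < 2) stop("need at least 2 sites")
  check_lonlat(coords$lon, coords$lat)
  D <- haversine_matrix_km(as.matrix(coords[, c("lon", "lat")]))
  max(D)
}

#' Haversine distance matrix (km)
#'
#' @param lonlat two-column matrix, longitude then latitude, decimal
#'   degrees.
#' @return Symmetric matrix of great-circle distances in km (Earth
#'   radius 6371 km).
#' @export
haversine_matrix_km <- function(lonlat) {
  lonlat <- as.matrix(lonlat)
  geosphere::distm(lonlat, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371))
}
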