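#' Pipeline configuration
#'
#' Collects every tunable of the partitioning chain.  Each stochastic
#' stage derives its own seed deterministically from `seed` and the
#' group label, so reruns are bit-identical and groups are independent
#' of each other's random streams.
#'
#' @param seed master integer seed.
#' @param d_candidates candidate GLLVM latent dimensions.
#' @param n_restarts GLLVM random restarts per candidate.
#' @param alpha forward-selection significance threshold.
#' @param n_pc number of environmental principal components.
#' @param k_uni,k_bi smooth basis dimensions (9 per variable; 18 for
#'   the coordinate surface).
#' @param max_vars cap on the combined number of selected variables.
#' @param msr_replicates spectral-randomization replicates for the
#'   environmental correction (0 disables the correction).
#' @param auto_transform auto-assign variable transforms where the
#'   metadata leaves them blank.
#' @return List of class `mp_config`.
#' @export
pipeline_config <- function(seed = 1, d_candidates = 0:3, n_restarts = 3,
                            alpha = 0.05, n_pc = 3, k_uni = 9, k_bi = 18,
                            max_vars = 3, msr_replicates = 199,
                            auto_transform = FALSE) {
  structure(list(seed = as.integer(seed), d_candidates = d_candidates,
                 n_restarts = n_restarts, alpha = alpha, n_pc = n_pc,
                 k_uni = k_uni, k_bi = k_bi, max_vars = max_vars,
                 msr_replicates = msr_replicates,
                 auto_transform = auto_transform),
            class = "mp_config")
}

#' Run the full partitioning pipeline over a set of community matrices
#'
#' For each group: transform environment -> PCA reduction -> binomial
#' GLLVM with AIC dimension selection -> forward selection (environment
#' and space separately, double-stopping criterion) -> cap at three
#' variables -> variation partitioning with MSR correction -> relative
#' proportions.  A failure in one group is caught and reported without
#' aborting the others.
#'
#' @param communities named list of binary site-by-taxon matrices
#'   (rownames are site ids).
#' @param environment list with `values`/`meta` (see
#'   [read_environment_csv()]).
#' @param coords coordinate data frame (`site_id`, then `lon`/`lat` or
#'   `x`/`y`).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for the summary CSV, per-group
#'   JSON and a run manifest.
#' @return Data frame with one row per group (fractions, corrected
#'   fractions, relative proportions, selections, seeds, status); the
#'   per-group fit objects are in `attr(, "details")`.
#' @export
run_pipeline <- function(communities, environment, coords,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "mp_config"))
  site_ids <- validate_tables(communities, environment, coords)
  env_t <- transform_variables(environment, auto = config$auto_transform)
  pcs <- reduce_environment(env_t, n_comp = config$n_pc)
  geographic <- isTRUE(attr(coords, "geographic")) ||
    all(c("lon", "lat") %in% names(coords))
  coord_names <- if (geographic) c("lon", "lat") else c("x", "y")
  ord <- match(site_ids, coords$site_id)
  xy <- coords[ord, coord_names]
  data <- data.frame(pcs$scores, xy, row.names = NULL)
  names(data) <- c(colnames(pcs$scores), coord_names)
  mem <- build_mem(xy, geographic = geographic)
  env_labels <- colnames(pcs$scores)

  rows <- list()
  details <- list()
  for (g in names(communities)) {
    seed_g <- derive_seed(config$seed, paste0("group_", g))
    res <- tryCatch({
      Y <- communities[[g]][site_ids, , drop = FALSE]
      lv <- select_latent_dimension(Y, d_candidates = config$d_candidates,
                                    seed = seed_g,
                                    n_restarts = config$n_restarts)
      P <- predicted_response(lv, allow_unconverged = TRUE)
      sel_env <- forward_select(P, data, env_labels, alpha = config$alpha,
                                k_uni = config$k_uni, k_bi = config$k_bi,
                                coord_names = coord_names)
      sel_spa <- forward_select(P, data, coord_names, alpha = config$alpha,
                                k_uni = config$k_uni, k_bi = config$k_bi,
                                coord_names = coord_names)
      capped <- cap_selection(P, data, sel_env$selected, sel_spa$selected,
                              max_vars = config$max_vars,
                              k_uni = config$k_uni, k_bi = config$k_bi,
                              coord_names = coord_names)
      msr <- if (config$msr_replicates >= 19 && length(capped$env_sel)) {
        msr_config(mem$basis_all, n_replicates = config$msr_replicates,
                   seed = derive_seed(seed_g, "msr"))
      } else NULL
      part <- partition_variation(P, data, capped$env_sel, capped$space_sel,
                                  msr = msr, k_uni = config$k_uni,
                                  k_bi = config$k_bi,
                                  coord_names = coord_names)
      details[[g]] <- list(gllvm = lv, env_selection = sel_env,
                           space_selection = sel_spa, partition = part)
      data.frame(
        group = g, n_taxa = ncol(Y), n_sites = nrow(Y),
        d_selected = lv$n_latent, gllvm_converged = lv$converged,
        selected_env = paste(part$selected_env, collapse = ";"),
        selected_space = paste(part$selected_space, collapse = ";"),
        adj_r2_E = part$adj_r2_E, adj_r2_S = part$adj_r2_S,
        adj_r2_ES = part$adj_r2_ES,
        frac_pure_env = part$frac_pure_env,
        frac_shared = part$frac_shared,
        frac_pure_space = part$frac_pure_space,
        residual = part$residual,
        corrected_adj_r2_E = part$corrected_adj_r2_E,
        corrected_frac_shared = part$corrected_frac_shared,
        rel_pure_env = part$rel_pure_env,
        rel_shared = part$rel_shared,
        rel_pure_space = part$rel_pure_space,
        seed = seed_g, status = "ok",
        message = if (is.na(part$flag)) "" else part$flag,
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(
        group = g, n_taxa = ncol(communities[[g]]),
        n_sites = nrow(communities[[g]]),
        d_selected = NA_integer_, gllvm_converged = NA,
        selected_env = "", selected_space = "",
        adj_r2_E = NA_real_, adj_r2_S = NA_real_, adj_r2_ES = NA_real_,
        frac_pure_env = NA_real_, frac_shared = NA_real_,
        frac_pure_space = NA_real_, residual = NA_real_,
        corrected_adj_r2_E = NA_real_, corrected_frac_shared = NA_real_,
        rel_pure_env = NA_real_, rel_shared = NA_real_,
        rel_pure_space = NA_real_,
        seed = seed_g, status = "failed",
        message = conditionMessage(e), stringsAsFactors = FALSE
      )
    })
    rows[[g]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  attr(out, "pca") <- pcs
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "partition_summary.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "metapart",
      version = as.character(utils::packageVersion("metapart")),
      r_version = R.version.string,
      seed = config$seed,
      config = unclass(config),
      groups = names(communities),
      cumulative_explained = pcs$cumulative_explained,
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(manifest,
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
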