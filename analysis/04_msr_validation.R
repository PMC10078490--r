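#!/usr/bin/env Rscript

# Demonstrates why the spectral-randomization correction matters: under
# a confounded null (spatially structured environment and spatially
# structured, environment-independent species) the uncorrected
# environmental component is systematically inflated, while the
# MSR-corrected component is centred on zero.  Writes
# results/msr_validation.csv.

suppressPackageStartupMessages(library(metapart))

seed <- 20220901
n_rep <- 25

rows <- lapply(seq_len(n_rep), function(r) {
  s <- derive_seed(seed, paste0("confound", r))
  sim <- simulate_metacommunity("space_only", n_sites = 40, n_species = 6,
                                seed = s, autocorr_scale = 0.2)
  pcs <- reduce_environment(transform_variables(sim$environment))
  data <- data.frame(pcs$scores, sim$landscape$coords)
  names(data)[4:5] <- c("x", "y")
  part <- suppressWarnings(partition_variation(
    attr(sim$community, "prob"), data, "PC1", c("x", "y"),
    msr = msr_config(sim$landscape$mem_all, 29,
                     seed = derive_seed(s, "msr")),
    coord_names = c("x", "y")))
  data.frame(replicate = r, uncorrected = part$adj_r2_E,
             corrected = part$corrected_adj_r2_E)
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, file.path("results", "msr_validation.csv"), row.names = FALSE)

cat(sprintf(
  "Confounded null, %d replicates:\n  uncorrected environmental component: mean %.3f\n  MSR-corrected environmental component: mean %.3f\n",
  n_rep, mean(tab$uncorrected), mean(tab$corrected)))
cat("The uncorrected component mistakes shared spatial structure for an\nenvironmental effect; the corrected one does not.\n")
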