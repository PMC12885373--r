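#!/usr/bin/env Rscript
# Worst-case differential-diversity analysis: search for the binary grouping
# of communities that maximizes the change in ANOVA / PERMANOVA R-squared
# between cycle-0 and cycle-35 conditions. Brute force is exact at this
# sample count; GA and PSO results are reported alongside it.

suppressMessages(library(pcrbias))
seed <- as.integer(Sys.getenv("PCRBIAS_SEED", "1"))

fit <- readRDS("results/fit.rds")
tree <- read_newick("results/tree.nwk")
comms <- fit$design$communities
psi <- fit$psi

comp_at <- function(x) lapply(comms, function(cm) {
  ab <- extract_alpha_beta(fit, cm)
  phi_inverse(colMeans(ab$alpha) + x * colMeans(ab$beta), psi)
})
comps0 <- comp_at(0); comps35 <- comp_at(35)

out <- list()
cat("metric            method       R2_0   R2_35  deltaR2\n")
for (m in c("shannon", "simpson", "gini", "aitchison_norm")) {
  v0 <- vapply(comps0, alpha_diversity, numeric(1), metric = m)
  v35 <- vapply(comps35, alpha_diversity, numeric(1), metric = m)
  for (meth in c("brute_force", "ga")) {
    g <- optimize_grouping(v0, v35, "anova", meth, seed = seed)
    out[[paste(m, meth)]] <- g
    cat(sprintf("%-17s %-12s %.3f  %.3f  %.3f\n", m, meth,
                g$r2_cycle0, g$r2_cyclex, g$delta_r2))
  }
}
for (m in c("bray_curtis", "weighted_unifrac", "aitchison_distance")) {
  tr <- if (m == "weighted_unifrac") tree else NULL
  d0 <- distance_matrix(comps0, m, tree = tr, ids = comms)
  d35 <- distance_matrix(comps35, m, tree = tr, ids = comms)
  for (meth in c("brute_force", "pso")) {
    g <- optimize_grouping(d0, d35, "permanova", meth, seed = seed)
    out[[paste(m, meth)]] <- g
    cat(sprintf("%-17s %-12s %.3f  %.3f  %.3f\n", m, meth,
                g$r2_cycle0, g$r2_cyclex, g$delta_r2))
  }
}

jsonlite::write_json(
  lapply(out, function(g) list(assignment = g$assignment,
                               r2_cycle0 = g$r2_cycle0,
                               r2_cyclex = g$r2_cyclex,
                               delta_r2 = g$delta_r2,
                               method = g$method, seed = g$seed)),
  "results/grouping.json", auto_unbox = TRUE, digits = NA)
cat("\nAitchison-distance delta-R2 is zero for every grouping searched:",
    "group comparisons under a perturbation-invariant metric cannot be",
    "distorted by amplification.\n")
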