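#!/usr/bin/env Rscript
# Propagate the joint posterior through every diversity metric: per-community
# alpha-diversity bias at 35 cycles, and per-pair beta-diversity bias.
# Writes results/alpha_bias.csv and results/beta_bias.csv and reports which
# estimands move and which are provably immune.

suppressMessages(library(pcrbias))

fit <- readRDS("results/fit.rds")
tree <- read_newick("results/tree.nwk")
comms <- fit$design$communities

alpha_res <- list()
for (cm in comms)
  for (m in c("shannon", "simpson", "gini", "aitchison_norm"))
    alpha_res[[paste(cm, m)]] <- posterior_bias(fit, cm, m, x = 35)
adf <- write_bias_summary(alpha_res, "results/alpha_bias.csv")

beta_res <- list()
for (pp in utils::combn(comms, 2, simplify = FALSE))
  for (m in c("bray_curtis", "weighted_unifrac", "aitchison_distance"))
    beta_res[[paste(paste(pp, collapse = ":"), m)]] <-
      posterior_bias(fit, pp, m, x = 35, tree = tree)
bdf <- write_bias_summary(beta_res, "results/beta_bias.csv")

cat("Alpha-diversity bias (posterior median, by metric):\n")
print(tapply(as.numeric(adf$median), adf$metric, function(v)
  round(range(v), 4)))
cat("\nBeta-diversity bias medians, largest |median| per metric:\n")
print(tapply(as.numeric(bdf$median), bdf$metric, function(v)
  round(max(abs(v)), 6)))
cat("\nAitchison distance bias is identically zero across all",
    sum(bdf$metric == "aitchison_distance"), "pairs: perturbation",
    "invariance holds draw by draw.\n")
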