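#!/usr/bin/env Rscript
# Fit the multinomial logistic-normal model to the simulated calibration
# data and summarize the posterior over community baselines and the shared
# per-cycle bias. Writes results/posterior_summary.csv and reports how well
# the bias vector is recovered against the recorded ground truth.

suppressMessages(library(pcrbias))
seed <- as.integer(Sys.getenv("PCRBIAS_SEED", "1"))

counts <- read_count_table("results/counts.tsv")
meta <- read_metadata("results/metadata.tsv")
truth <- read_truth("results/truth.json")
design <- make_design(meta$community, meta$cycles)

fit <- fit_mln(counts, design, n_draws = 2000, seed = seed + 1L)
write.csv(summarize_fit(fit), "results/posterior_summary.csv",
          row.names = FALSE, quote = FALSE)
saveRDS(fit, "results/fit.rds")

beta_true <- truth$lambda[, ncol(truth$lambda)]
beta_draws <- extract_alpha_beta(fit, design$communities[1])$beta
beta_mean <- colMeans(beta_draws)
cat("Posterior draws:", nrow(beta_draws), " gradient max-norm:",
    format(fit$grad_norm, digits = 3), "\n")
cat("Pearson r (posterior-mean beta vs truth):",
    round(cor(beta_mean, beta_true), 4), "\n")
lo <- apply(beta_draws, 2, quantile, 0.025)
hi <- apply(beta_draws, 2, quantile, 0.975)
cat("95% CI coverage of true beta:",
    round(mean(lo <= beta_true & beta_true <= hi), 3), "\n")
cat("Coordinates with CIs excluding zero (credible bias):",
    sum(lo > 0 | hi < 0), "of", length(beta_mean), "\n")
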