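test_that("the collapsed prior term matches brute-force marginalization", {
  # D=2, N=2, p=1: integrate the matrix-normal likelihood of eta over the
  # conjugate (Lambda, Sigma) prior by naive Monte Carlo and compare with
  # the analytic matrix-t density.
  X <- matrix(c(1, 1), 1, 2)
  prior <- prior_spec(D = 2, p = 1)
  eta <- matrix(c(0.4, -0.3), 1, 2)
  A <- diag(2) + t(X) %*% prior$gamma0 %*% X
  analytic <- as.numeric(pcrbias:::log_matrix_t(
    eta, prior$theta0 %*% X, prior$xi0, A, prior$upsilon0))

  set.seed(101)
  M <- 2e5
  sigma <- prior$xi0[1, 1] / rchisq(M, df = prior$upsilon0)
  lambda <- rnorm(M, prior$theta0[1, 1], sqrt(sigma * prior$gamma0[1, 1]))
  w <- dnorm(eta[1, 1], lambda * X[1, 1], sqrt(sigma)) *
       dnorm(eta[1, 2], lambda * X[1, 2], sqrt(sigma))
  mc <- log(mean(w))
  mc_se <- sd(w) / (mean(w) * sqrt(M))
  expect_lt(abs(mc - analytic), 3 * mc_se + 1e-4)
})

test_that("the likelihood term improves as eta approaches the count ratio", {
  psi <- make_contrast_matrix("alr", 2)
  Y <- matrix(c(70, 30), 2, 1)
  des <- make_design("C1", 0)
  prior <- prior_spec(2, 2)
  target <- log(70 / 30)
  grid <- target + seq(-3, 0, length.out = 25)
  lik <- vapply(grid, function(e) {
    eta <- matrix(e, 1, 1)
    full <- collapsed_log_posterior(eta, Y, des, prior, psi)
    A <- diag(1) + t(des$X) %*% prior$gamma0 %*% des$X
    full - as.numeric(pcrbias:::log_matrix_t(eta, prior$theta0 %*% des$X,
                                             prior$xi0, A, prior$upsilon0))
  }, numeric(1))
  expect_true(all(diff(lik) > 0))
})

test_that("the collapsed posterior is exchangeable over samples", {
  set.seed(5)
  sim <- simulate_mock_experiment(2, D = 4, n_communities = 2, depth = 500)
  prior <- prior_spec(4, nrow(sim$design$X))
  eta <- sim$psi %*% log(sim$counts + 0.5)
  perm <- sample(ncol(sim$counts))
  des_p <- sim$design
  des_p$X <- des_p$X[, perm]
  v1 <- collapsed_log_posterior(eta, sim$counts, sim$design, prior, sim$psi)
  v2 <- collapsed_log_posterior(eta[, perm], sim$counts[, perm], des_p,
                                prior, sim$psi)
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("the mode is independent of the number of posterior draws", {
  sim <- simulate_mock_experiment(4, D = 3, n_communities = 2, depth = 800)
  f1 <- fit_mln(sim$counts, sim$design, n_draws = 1, seed = 1)
  f2 <- fit_mln(sim$counts, sim$design, n_draws = 200, seed = 99)
  expect_equal(f1$eta_mode, f2$eta_mode, tolerance = 1e-10)
  expect_lt(f1$grad_norm, 1e-6)
})

test_that("laplace posterior means match a long metropolis run", {
  # D=3, N=6, p=2 toy: random-walk Metropolis on the same collapsed
  # posterior, Rao-Blackwellized Lambda means via the conjugate conditional
  set.seed(77)
  psi <- make_contrast_matrix("alr", 3)
  cycles <- c(0, 0, 14, 14, 35, 35)
  des <- make_design(rep("C1", 6), cycles)
  lam <- matrix(c(0.4, -0.2, 0.03, -0.02), 2, 2)
  tr <- simulation_truth(lam, 0.05 * diag(2), seed = 8, depths = 500)
  Y <- simulate_counts(tr, des, psi)
  prior <- prior_spec(3, 2)

  fit <- fit_mln(Y, des, prior, psi, n_draws = 4000, seed = 3)
  lap_mean <- apply(fit$lambda_draws, c(2, 3), mean)
  lap_se <- apply(fit$lambda_draws, c(2, 3), sd) / sqrt(dim(fit$lambda_draws)[1])

  ce <- pcrbias:::collapsed_env(Y, des, prior, psi)
  g0inv <- solve(prior$gamma0)
  GN <- solve(des$X %*% t(des$X) + g0inv)
  theta_of <- function(eta) (eta %*% t(des$X) + prior$theta0 %*% g0inv) %*% GN

  eta <- fit$eta_mode
  lp <- pcrbias:::collapsed_value(eta, ce)
  n_iter <- 60000L; burn <- 10000L; thin <- 10L
  kept <- matrix(NA_real_, (n_iter - burn) / thin, 4)
  k <- 0L; acc <- 0L
  for (it in seq_len(n_iter)) {
    prop <- eta + matrix(rnorm(12, sd = 0.06), 2, 6)
    lp_prop <- pcrbias:::collapsed_value(prop, ce)
    if (log(runif(1)) < lp_prop - lp) { eta <- prop; lp <- lp_prop; acc <- acc + 1L }
    if (it > burn && (it - burn) %% thin == 0) {
      k <- k + 1L
      kept[k, ] <- as.vector(theta_of(eta))
    }
  }
  expect_gt(acc / n_iter, 0.1)
  # batch-means MCSE
  nb <- 40L
  bsz <- nrow(kept) %/% nb
  bm <- sapply(seq_len(nb), function(b)
    colMeans(kept[((b - 1) * bsz + 1):(b * bsz), , drop = FALSE]))
  mc_mean <- matrix(rowMeans(bm), 2, 2)
  mc_se <- matrix(apply(bm, 1, sd) / sqrt(nb), 2, 2)
  tol <- 3 * sqrt(mc_se^2 + lap_se^2)
  expect_true(all(abs(lap_mean - mc_mean) < tol + 0.01))
})

test_that("the fitted model recovers simulated coefficients", {
  sim <- simulate_mock_experiment(11)
  fit <- fit_mln(sim$counts, sim$design, n_draws = 500, seed = 2)
  ab <- extract_alpha_beta(fit, "C1")
  expect_gt(cor(colMeans(ab$beta), sim$beta_true), 0.9)

  # noise-free, high-depth: baseline slices sit on the true log-ratios
  psi <- make_contrast_matrix("alr", 4)
  lam <- cbind(c(0.5, -0.3, 0.2), c(-0.4, 0.1, 0.6), c(0.02, -0.01, 0.015))
  des <- make_design(rep(c("C1", "C2"), each = 3), rep(c(0, 20, 35), 2))
  tr <- simulation_truth(lam, matrix(0, 3, 3), seed = 4, depths = 2e5)
  Y <- simulate_counts(tr, des, psi, noise_free = TRUE)
  # diffuse column covariance so few-replicate baselines are not shrunk
  wk <- prior_spec(4, 3, gamma0 = 100 * diag(3))
  f <- fit_mln(Y, des, prior = wk, psi = psi, n_draws = 200, seed = 5)
  for (ci in 1:2) {
    ab_i <- extract_alpha_beta(f, paste0("C", ci))
    expect_lt(max(abs(colMeans(ab_i$alpha) - lam[, ci])), 0.05)
  }
})

test_that("alpha/beta slices respect the coefficient layout", {
  sim <- simulate_mock_experiment(6, D = 4, n_communities = 3, depth = 500)
  fit <- fit_mln(sim$counts, sim$design, n_draws = 50, seed = 1)
  ab1 <- extract_alpha_beta(fit, "C1")
  ab2 <- extract_alpha_beta(fit, "C2")
  expect_identical(ab1$beta, ab2$beta)
  expect_gt(max(abs(ab1$alpha - ab2$alpha)), 0)
  # reassembling the slices reproduces the draws
  expect_equal(fit$lambda_draws[, , 1], ab1$alpha)
  expect_equal(fit$lambda_draws[, , fit$design$cycle_row], ab1$beta)
  expect_error(extract_alpha_beta(fit, "C9"), "unknown community")
})

test_that("credible intervals for a null bias cover zero", {
  # beta = 0 truth: the shared bias column should not exclude zero often
  psi <- make_contrast_matrix("alr", 3)
  des <- make_design(rep(c("C1", "C2"), each = 3), rep(c(20, 28, 35), 2))
  covered <- vapply(1:10, function(r) {
    set.seed(100 + r)
    lam <- cbind(matrix(rnorm(4, sd = 1), 2, 2), c(0, 0))
    tr <- simulation_truth(lam, 0.05 * diag(2), seed = 500 + r, depths = 5000)
    Y <- simulate_counts(tr, des, psi)
    f <- fit_mln(Y, des, psi = psi, n_draws = 400, seed = r)
    b <- extract_alpha_beta(f, "C1")$beta
    lo <- apply(b, 2, quantile, 0.025); hi <- apply(b, 2, quantile, 0.975)
    mean(lo <= 0 & hi >= 0)
  }, numeric(1))
  expect_gte(mean(covered), 0.85)
})

test_that("posterior uncertainty contracts with more data", {
  beta_sd <- function(seed, depth, reps) {
    psi <- make_contrast_matrix("alr", 4)
    cyc <- rep(c(20, 28, 35), reps)
    des <- make_design(rep("C1", length(cyc)), cyc)
    set.seed(seed)
    lam <- cbind(rnorm(3), c(0.03, -0.02, 0.01))
    tr <- simulation_truth(lam, 0.05 * diag(3), seed = seed, depths = depth)
    Y <- simulate_counts(tr, des, psi)
    f <- fit_mln(Y, des, psi = psi, n_draws = 400, seed = 1)
    mean(apply(extract_alpha_beta(f, "C1")$beta, 2, sd))
  }
  expect_lt(beta_sd(42, 8000, 4), beta_sd(42, 4000, 2))
})

test_that("degenerate inputs are rejected with diagnostics", {
  sim <- simulate_mock_experiment(3, D = 3, n_communities = 2, depth = 300)
  bad <- sim$counts; bad[, 2] <- 0L
  expect_error(fit_mln(bad, sim$design), "at least one read")
  des_bad <- sim$design
  des_bad$X <- rbind(des_bad$X, des_bad$X[1, ])
  expect_error(fit_mln(sim$counts, des_bad), "rank deficient")
  expect_error(prior_spec(3, 2, upsilon0 = 1), "upsilon0")
  expect_error(prior_spec(3, 2, gamma0 = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})
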