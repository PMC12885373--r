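#' Bayesian multinomial logistic-normal regression
#'
#' Model: Y_n ~ Multinomial(pi_n), pi_n = phi_inverse(eta_n),
#' eta_n ~ N(Lambda X_n, Sigma), with a conjugate matrix-normal prior on
#' Lambda (mean theta0, column covariance gamma0, row covariance Sigma) and
#' an inverse-Wishart prior on Sigma (scale xi0, dof upsilon0).
#'
#' Inference collapses (Lambda, Sigma) analytically — eta then follows a
#' matrix-t prior — approximates the posterior over eta by a Laplace
#' Gaussian at its mode, and uncollapses each eta draw through the conjugate
#' inverse-Wishart / matrix-normal conditionals to recover joint draws of
#' (Lambda, Sigma, eta).
#'
#' @name inference
#' @keywords internal
NULL

#' Prior specification for the multinomial logistic-normal model
#'
#' Defaults are weakly informative and centred on "no bias, no structure":
#' zero prior mean for all coefficients, column covariance `10 I`,
#' `upsilon0 = D + 3` degrees of freedom and `xi0 = (upsilon0 - D) I` so the
#' prior mean of Sigma is the identity on contrast coordinates. The column
#' covariance scale matters: a coefficient's prior variance is
#' `Sigma * gamma0[j, j]`, and community baselines in real data span
#' several natural-log units, so the scale must be large enough not to
#' shrink baselines fitted from a handful of replicates — in calibration
#' designs without cycle-0 samples, baseline shrinkage leaks directly into
#' the per-cycle bias estimate because the two covariates are collinear.
#'
#' @param D Number of taxa.
#' @param p Number of covariates (design rows).
#' @param theta0 `(D-1) x p` prior mean of the coefficient matrix.
#' @param gamma0 `p x p` SPD column covariance.
#' @param upsilon0 Inverse-Wishart degrees of freedom, `> D - 1`.
#' @param xi0 `(D-1) x (D-1)` SPD inverse-Wishart scale.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(D, p, theta0 = NULL, gamma0 = NULL,
                       upsilon0 = NULL, xi0 = NULL) {
  D <- as.integer(D); p <- as.integer(p)
  if (is.null(theta0)) theta0 <- matrix(0, D - 1L, p)
  if (is.null(gamma0)) gamma0 <- 10 * diag(p)
  if (is.null(upsilon0)) upsilon0 <- D + 3
  if (upsilon0 <= D - 1) stop("upsilon0 must exceed D - 1", call. = FALSE)
  if (is.null(xi0)) xi0 <- (upsilon0 - D) * diag(D - 1L)
  theta0 <- as.matrix(theta0); gamma0 <- as.matrix(gamma0); xi0 <- as.matrix(xi0)
  if (!all(dim(theta0) == c(D - 1L, p))) stop("theta0 must be (D-1) x p", call. = FALSE)
  check_spd <- function(m, nm) {
    if (max(abs(m - t(m))) > 1e-10 ||
        min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop(nm, " must be symmetric positive definite", call. = FALSE)
  }
  check_spd(gamma0, "gamma0"); check_spd(xi0, "xi0")
  structure(list(D = D, p = p, theta0 = theta0, gamma0 = gamma0,
                 upsilon0 = upsilon0, xi0 = xi0),
            class = "prior_spec")
}

# log of the multivariate gamma function Gamma_p(a)
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# Matrix-variate t log-density of the (D-1) x N matrix eta with location M,
# row scale Xi ((D-1) x (D-1)), column scale A (N x N), dof upsilon:
# the analytic marginal of eta over Lambda ~ MN(theta0, Sigma, gamma0) and
# Sigma ~ IW(xi0, upsilon0), with A = I_N + X' gamma0 X.
log_matrix_t <- function(eta, M, Xi, A, upsilon) {
  pr <- nrow(eta); N <- ncol(eta)
  E <- eta - M
  EAinv <- t(solve(A, t(E)))
  K <- Xi + EAinv %*% t(E)
  -pr * N / 2 * log(pi) - pr / 2 * determinant(A)$modulus +
    lmvgamma((upsilon + N) / 2, pr) - lmvgamma(upsilon / 2, pr) +
    upsilon / 2 * determinant(Xi)$modulus -
    (upsilon + N) / 2 * determinant(K)$modulus
}

# Precompute everything fixed during optimization.
collapsed_env <- function(counts, design, prior, psi) {
  Y <- counts; X <- design$X
  pr <- nrow(psi); D <- ncol(psi); N <- ncol(Y)
  stopifnot(nrow(Y) == D, ncol(X) == N, nrow(X) == prior$p)
  A <- diag(N) + t(X) %*% prior$gamma0 %*% X
  Ainv <- solve(A)
  list(
    Y = Y, X = X, depths = colSums(Y), P = psi_pinv(psi),
    M = prior$theta0 %*% X, Xi = prior$xi0, upsilon = prior$upsilon0,
    A = A, Ainv = Ainv, logdetA = as.numeric(determinant(A)$modulus),
    logdetXi = as.numeric(determinant(prior$xi0)$modulus),
    pr = pr, D = D, N = N,
    mult_const = sum(lgamma(colSums(Y) + 1)) - sum(lgamma(Y + 1))
  )
}

# pi columns from eta columns: softmax of the clr preimage.
eta_to_pi <- function(eta, P) {
  clrm <- P %*% eta
  clrm <- sweep(clrm, 2, apply(clrm, 2, max))
  w <- exp(clrm)
  sweep(w, 2, colSums(w), "/")
}

collapsed_value <- function(eta, ce) {
  Pi <- eta_to_pi(eta, ce$P)
  ll <- ce$mult_const + sum(ce$Y * log(Pi))
  E <- eta - ce$M
  K <- ce$Xi + (E %*% ce$Ainv) %*% t(E)
  lt <- -ce$pr * ce$N / 2 * log(pi) - ce$pr / 2 * ce$logdetA +
    lmvgamma((ce$upsilon + ce$N) / 2, ce$pr) - lmvgamma(ce$upsilon / 2, ce$pr) +
    ce$upsilon / 2 * ce$logdetXi -
    (ce$upsilon + ce$N) / 2 * as.numeric(determinant(K)$modulus)
  ll + lt
}

collapsed_grad <- function(eta, ce) {
  Pi <- eta_to_pi(eta, ce$P)
  g_mult <- t(ce$P) %*% (ce$Y - sweep(Pi, 2, ce$depths, "*"))
  E <- eta - ce$M
  EB <- E %*% ce$Ainv
  K <- ce$Xi + EB %*% t(E)
  g_t <- -(ce$upsilon + ce$N) * solve(K, EB)
  g_mult + g_t
}

#' Collapsed log-posterior of the latent log-ratio matrix
#'
#' The multinomial log-likelihood of the counts given
#' `phi_inverse(eta)` plus the matrix-t log-density of eta obtained by
#' analytically marginalizing the coefficient matrix and covariance under
#' their conjugate priors.
#'
#' @param eta `(D-1) x N` matrix of latent log-ratio coordinates.
#' @param counts `D x N` count matrix with positive column sums.
#' @param design A [make_design()] design.
#' @param prior A [prior_spec()].
#' @param psi Contrast matrix.
#' @return Scalar log-posterior (up to the constant marginal likelihood).
#' @export
collapsed_log_posterior <- function(eta, counts, design, prior, psi) {
  check_psi(psi)
  eta <- as.matrix(eta)
  ce <- collapsed_env(counts, design, prior, psi)
  if (nrow(eta) != ce$pr || ncol(eta) != ce$N)
    stop("eta must be (D-1) x N", call. = FALSE)
  collapsed_value(eta, ce)
}

# Dense Hessian by central finite differences of the analytic gradient.
collapsed_hessian <- function(eta, ce, h = 1e-5) {
  d <- length(eta)
  H <- matrix(0, d, d)
  for (j in seq_len(d)) {
    ep <- eta; ep[j] <- ep[j] + h
    em <- eta; em[j] <- em[j] - h
    H[, j] <- (as.vector(collapsed_grad(ep, ce)) -
               as.vector(collapsed_grad(em, ce))) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit the multinomial logistic-normal model
#'
#' Maximizes the collapsed log-posterior over the latent log-ratio matrix
#' (L-BFGS warm-started from pseudo-count log-ratios, polished by damped
#' Newton steps until the gradient max-norm passes `grad_tol`), forms the
#' Laplace Gaussian at the mode with covariance from the inverse Hessian,
#' draws `n_draws` eta samples from it, and uncollapses each through the
#' conjugate inverse-Wishart and matrix-normal conditionals. All draws are
#' index-aligned joint samples.
#'
#' @param counts `D x N` integer count matrix, positive column sums.
#' @param design A [make_design()] design (full row rank).
#' @param prior A [prior_spec()]; default [prior_spec()] for the data's
#'   dimensions.
#' @param psi Contrast matrix; default ALR for D taxa.
#' @param n_draws Number of joint posterior draws (default 2000).
#' @param seed Integer seed for the sampling stage (the mode search is
#'   deterministic).
#' @param grad_tol Gradient max-norm declaring convergence (default 1e-6).
#' @param max_newton Maximum Newton polish iterations (default 50).
#' @return An `mln_fit` list: `eta_mode`, `eta_draws` (S x (D-1) x N),
#'   `lambda_draws` (S x (D-1) x p), `sigma_draws` (S x (D-1) x (D-1)),
#'   `psi`, `design`, `prior`, `taxon_ids`, `sample_ids`, `grad_norm`,
#'   `seed`.
#' @export
fit_mln <- function(counts, design, prior = NULL, psi = NULL,
                    n_draws = 2000L, seed = 1L,
                    grad_tol = 1e-6, max_newton = 50L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(colSums(counts) <= 0))
    stop("every sample must have at least one read", call. = FALSE)
  D <- nrow(counts); N <- ncol(counts)
  X <- design$X
  if (qr(X)$rank < nrow(X))
    stop("design matrix is rank deficient", call. = FALSE)
  if (is.null(psi)) psi <- make_contrast_matrix("alr", D)
  if (is.null(prior)) prior <- prior_spec(D, nrow(X))
  ce <- collapsed_env(counts, design, prior, psi)

  # deterministic warm start: pseudo-count log-ratios of the observed counts
  eta0 <- psi %*% log(counts + 0.5)

  obj <- function(v) -collapsed_value(matrix(v, ce$pr, ce$N), ce)
  grd <- function(v) -as.vector(collapsed_grad(matrix(v, ce$pr, ce$N), ce))
  opt <- stats::optim(as.vector(eta0), obj, grd, method = "L-BFGS-B",
                      control = list(maxit = 10000L, factr = 1e7))
  eta_hat <- matrix(opt$par, ce$pr, ce$N)

  # Newton polish to the requested gradient tolerance; the Hessian is also
  # the Laplace curvature, so the final one is reused for sampling
  H <- NULL
  g <- collapsed_grad(eta_hat, ce)
  it <- 0L
  while (max(abs(g)) > grad_tol && it < max_newton) {
    it <- it + 1L
    H <- collapsed_hessian(eta_hat, ce)
    nH <- -H
    step <- tryCatch(solve(nH, as.vector(g)),
                     error = function(e) solve(nH + 1e-6 * diag(nrow(nH)),
                                               as.vector(g)))
    f0 <- collapsed_value(eta_hat, ce)
    sz <- 1
    repeat {
      eta_new <- eta_hat + sz * matrix(step, ce$pr, ce$N)
      if (collapsed_value(eta_new, ce) >= f0 - 1e-10) break
      sz <- sz / 2
      if (sz < 1e-8) break
    }
    eta_hat <- eta_hat + sz * matrix(step, ce$pr, ce$N)
    g <- collapsed_grad(eta_hat, ce)
  }
  if (max(abs(g)) > grad_tol * 100)
    stop("mode search did not converge: gradient max-norm ",
         format(max(abs(g))), " after L-BFGS (code ", opt$convergence,
         ") and ", it, " Newton steps", call. = FALSE)
  if (is.null(H)) H <- collapsed_hessian(eta_hat, ce)

  # Laplace covariance = inverse negative Hessian at the mode
  nH <- -H
  R <- tryCatch(chol(nH), error = function(e) {
    jit <- 1e-8 * max(diag(nH))
    chol(nH + jit * diag(nrow(nH)))
  })

  d <- ce$pr * ce$N
  S <- as.integer(n_draws)
  eta_draws <- array(NA_real_, c(S, ce$pr, ce$N))
  lambda_draws <- array(NA_real_, c(S, ce$pr, prior$p))
  sigma_draws <- array(NA_real_, c(S, ce$pr, ce$pr))

  g0inv <- solve(prior$gamma0)
  GN <- solve(X %*% t(X) + g0inv)
  GN <- (GN + t(GN)) / 2
  UG <- chol(GN)
  upsN <- prior$upsilon0 + N

  with_seed(seed, {
    Z <- matrix(rnorm(d * S), d, S)
    eta_flat <- as.vector(eta_hat) + backsolve(R, Z)
    for (s in seq_len(S)) {
      eta_s <- matrix(eta_flat[, s], ce$pr, ce$N)
      eta_draws[s, , ] <- eta_s
      ThetaN <- (eta_s %*% t(X) + prior$theta0 %*% g0inv) %*% GN
      Es <- eta_s - ThetaN %*% X
      Dth <- ThetaN - prior$theta0
      XiN <- prior$xi0 + Es %*% t(Es) + Dth %*% g0inv %*% t(Dth)
      XiN <- (XiN + t(XiN)) / 2
      W <- stats::rWishart(1, upsN, solve(XiN))[, , 1]
      Sigma_s <- solve(W)
      Sigma_s <- (Sigma_s + t(Sigma_s)) / 2
      sigma_draws[s, , ] <- Sigma_s
      Zl <- matrix(rnorm(ce$pr * prior$p), ce$pr, prior$p)
      lambda_draws[s, , ] <- ThetaN + t(chol(Sigma_s)) %*% Zl %*% UG
    }
  })

  structure(list(
    eta_mode = eta_hat, eta_draws = eta_draws,
    lambda_draws = lambda_draws, sigma_draws = sigma_draws,
    psi = psi, design = design, prior = prior,
    taxon_ids = rownames(counts), sample_ids = colnames(counts),
    grad_norm = max(abs(g)), newton_iters = it, seed = as.integer(seed)
  ), class = "mln_fit")
}

#' @export
print.mln_fit <- function(x, ...) {
  cat("<mln_fit>", dim(x$lambda_draws)[1], "joint draws,",
      dim(x$lambda_draws)[2] + 1L, "taxa,", dim(x$eta_draws)[3], "samples\n")
  cat("covariates:", paste(x$design$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Slice community baseline and shared bias draws from a fit
#'
#' @param fit An `mln_fit`.
#' @param community Community label present in the design.
#' @return List with `alpha` (S x (D-1) draws of the community's cycle-0
#'   log-ratio baseline) and `beta` (S x (D-1) draws of the shared per-cycle
#'   bias), index-aligned.
#' @export
extract_alpha_beta <- function(fit, community) {
  nms <- fit$design$covariate_names
  idx <- match(community, nms)
  if (is.na(idx) || idx == fit$design$cycle_row)
    stop("unknown community: ", community, call. = FALSE)
  list(alpha = fit$lambda_draws[, , idx, drop = TRUE],
       beta = fit$lambda_draws[, , fit$design$cycle_row, drop = TRUE])
}

#' Posterior coefficient summary
#'
#' @param fit An `mln_fit`.
#' @return Data frame with one row per (contrast coordinate, covariate):
#'   posterior mean, SD, and 2.5/97.5 percentiles.
#' @export
summarize_fit <- function(fit) {
  pr <- dim(fit$lambda_draws)[2]; p <- dim(fit$lambda_draws)[3]
  out <- expand.grid(coord = seq_len(pr),
                     covariate = fit$design$covariate_names,
                     stringsAsFactors = FALSE)
  stats_f <- function(v) c(mean(v), sd(v), quantile(v, c(0.025, 0.975)))
  m <- t(apply(out, 1, function(row) {
    j <- match(row[["covariate"]], fit$design$covariate_names)
    stats_f(fit$lambda_draws[, as.integer(row[["coord"]]), j])
  }))
  out$mean <- m[, 1]; out$sd <- m[, 2]; out$lo95 <- m[, 3]; out$hi95 <- m[, 4]
  out
}
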