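#' PCR-induced bias estimands
#'
#' Amplification acts on every sample as the same shift `x * beta` in
#' log-ratio space. For an alpha metric f the induced bias at x cycles is
#' `f(phi_inverse(alpha + x beta)) - f(phi_inverse(alpha))`; for a beta
#' metric g both communities receive the shift. Estimands unchanged by any
#' common log-ratio shift (perturbation-invariant estimands) have zero bias
#' for every composition and every bias vector; the rest are
#' perturbation-sensitive.
#'
#' @name bias_estimands
#' @keywords internal
NULL

#' Alpha-diversity bias induced by amplification
#'
#' @param alpha Log-ratio coordinates of the unamplified composition.
#' @param beta Per-cycle bias vector, same basis.
#' @param x Number of PCR cycles (default 35).
#' @param metric Alpha metric name or [metric_spec()].
#' @param psi Contrast matrix defining the basis.
#' @param relative Divide by the unamplified metric value (which must be
#'   nonzero).
#' @return Scalar bias (metric units, or dimensionless when `relative`).
#' @export
alpha_bias <- function(alpha, beta, x = 35, metric, psi, relative = FALSE) {
  if (length(alpha) != length(beta))
    stop("alpha and beta must share a basis (equal length)", call. = FALSE)
  if (x < 0) stop("cycle count must be >= 0", call. = FALSE)
  metric <- as_metric_spec(metric)
  f0 <- alpha_diversity(phi_inverse(alpha, psi), metric)
  fx <- alpha_diversity(phi_inverse(perturb(alpha, x * beta), psi), metric)
  b <- fx - f0
  if (!relative) return(b)
  if (abs(f0) < 1e-12)
    stop("relative bias undefined: unamplified ", metric$name, " is zero",
         call. = FALSE)
  b / f0
}

#' Beta-diversity bias induced by amplification
#'
#' Both communities are shifted by the same `x * beta`; the bias is the
#' change in their dissimilarity.
#'
#' @param alpha1,alpha2 Log-ratio coordinates of the two unamplified
#'   communities (same basis).
#' @param beta Per-cycle bias vector.
#' @param x Cycle count (default 35).
#' @param metric Beta metric name or [metric_spec()].
#' @param psi Contrast matrix.
#' @param tree Tree for `weighted_unifrac`.
#' @param relative Divide by the unamplified distance (error when that is
#'   below 1e-12).
#' @return Scalar bias.
#' @export
beta_bias <- function(alpha1, alpha2, beta, x = 35, metric, psi,
                      tree = NULL, relative = FALSE) {
  if (length(alpha1) != length(alpha2) || length(alpha1) != length(beta))
    stop("alpha1, alpha2 and beta must share a basis", call. = FALSE)
  if (x < 0) stop("cycle count must be >= 0", call. = FALSE)
  metric <- as_metric_spec(metric)
  g0 <- beta_diversity(phi_inverse(alpha1, psi), phi_inverse(alpha2, psi),
                       metric, tree = tree)
  gx <- beta_diversity(phi_inverse(perturb(alpha1, x * beta), psi),
                       phi_inverse(perturb(alpha2, x * beta), psi),
                       metric, tree = tree)
  b <- gx - g0
  if (!relative) return(b)
  if (abs(g0) < 1e-12)
    stop("relative bias undefined: unamplified distance is zero", call. = FALSE)
  b / g0
}

#' Posterior distribution of amplification bias
#'
#' Propagates joint posterior draws of (alpha, beta) from a fitted model
#' through [alpha_bias()] or [beta_bias()], one bias value per draw, so the
#' posterior correlation between baseline and bias is preserved.
#'
#' @param fit An `mln_fit`.
#' @param community One community label (alpha metric) or a length-2 vector
#'   of labels (beta metric).
#' @param metric Metric name or [metric_spec()].
#' @param x Cycle count (default 35).
#' @param tree Tree for `weighted_unifrac`.
#' @param relative Compute relative bias.
#' @return A `bias_result` list: `draws` (length S), `summary` (median,
#'   lo95, hi95), `metric`, `cycles`, `community`.
#' @export
posterior_bias <- function(fit, community, metric, x = 35, tree = NULL,
                           relative = FALSE) {
  metric <- as_metric_spec(metric)
  psi <- fit$psi
  if (metric$type == "alpha") {
    if (length(community) != 1L)
      stop("alpha metrics take a single community", call. = FALSE)
    ab <- extract_alpha_beta(fit, community)
    draws <- vapply(seq_len(nrow(ab$alpha)), function(s)
      alpha_bias(ab$alpha[s, ], ab$beta[s, ], x, metric, psi,
                 relative = relative), numeric(1))
  } else {
    if (length(community) != 2L)
      stop("beta metrics take a pair of communities", call. = FALSE)
    ab1 <- extract_alpha_beta(fit, community[1])
    ab2 <- extract_alpha_beta(fit, community[2])
    draws <- vapply(seq_len(nrow(ab1$alpha)), function(s)
      beta_bias(ab1$alpha[s, ], ab2$alpha[s, ], ab1$beta[s, ], x, metric, psi,
                tree = tree, relative = relative), numeric(1))
  }
  qs <- unname(quantile(draws, c(0.5, 0.025, 0.975)))
  structure(list(draws = draws,
                 summary = c(median = qs[1], lo95 = qs[2], hi95 = qs[3]),
                 metric = metric$name, cycles = x,
                 community = community, relative = relative),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat("<bias_result> ", x$metric, " at ", x$cycles, " cycles, ",
      paste(x$community, collapse = " vs "),
      if (x$relative) " (relative)", "\n", sep = "")
  print(signif(x$summary, 4))
  invisible(x)
}

#' Differential log-ratio between two conditions
#'
#' Mean of `log(pi_d1 / pi_d2)` over samples with `z == 1` minus the same
#' mean over `z == 0`: the relative log-fold-change estimand of
#' differential-abundance analysis. It depends only on within-sample
#' contrasts, so a common perturbation of all samples cancels exactly.
#'
#' @param comps List of compositions (named or indexed consistently).
#' @param z Binary condition labels (0/1, or logical), one per composition.
#' @param d1,d2 Taxon indices or names.
#' @return Scalar difference in mean log-ratio abundance.
#' @export
differential_log_ratio <- function(comps, z, d1, d2) {
  z <- as.integer(as.logical(z))
  if (length(z) != length(comps))
    stop("one condition label per composition required", call. = FALSE)
  if (length(unique(z)) < 2L)
    stop("both conditions must be present", call. = FALSE)
  lr <- vapply(comps, function(c) {
    p <- as_parts(c)
    v1 <- if (is.character(d1)) p[[d1]] else p[[as.integer(d1)]]
    v2 <- if (is.character(d2)) p[[d2]] else p[[as.integer(d2)]]
    log(v1 / v2)
  }, numeric(1))
  mean(lr[z == 1]) - mean(lr[z == 0])
}

#' Classify an estimand as perturbation invariant or sensitive
#'
#' Draws random log-ratio shift vectors gamma, applies the same shift to
#' every composition, and records the largest change in the estimand. An
#' estimand whose maximal change stays below `tol` is classified invariant;
#' by the invariance theorem such estimands are immune to amplification
#' bias of any magnitude.
#'
#' @param estimand Function taking a list of compositions and returning a
#'   scalar.
#' @param test_comps List of compositions (all of the same dimension D).
#' @param n_trials Number of random gamma draws (default 100).
#' @param seed Integer seed.
#' @param tol Absolute invariance tolerance (default 1e-9).
#' @param gamma_sd SD of the iid normal gamma coordinates (default 1).
#' @param psi Contrast matrix (default ALR for the compositions' D).
#' @param estimand_name Label for the report.
#' @return An `invariance_report` list: `estimand_name`,
#'   `max_abs_deviation`, `n_trials`, `verdict`.
#' @export
check_invariance <- function(estimand, test_comps, n_trials = 100L, seed = 1L,
                             tol = 1e-9, gamma_sd = 1, psi = NULL,
                             estimand_name = "estimand") {
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  D <- length(as_parts(test_comps[[1]]))
  if (is.null(psi)) psi <- make_contrast_matrix("alr", D)
  base_val <- estimand(test_comps)
  etas <- lapply(test_comps, phi, psi = psi)
  max_dev <- with_seed(seed, {
    devs <- vapply(seq_len(n_trials), function(i) {
      gamma <- rnorm(D - 1L, sd = gamma_sd)
      pert <- lapply(etas, function(e) phi_inverse(perturb(e, gamma), psi))
      val <- tryCatch(estimand(pert), error = function(e)
        stop("estimand failed on trial ", i, ": ", conditionMessage(e),
             call. = FALSE))
      abs(val - base_val)
    }, numeric(1))
    max(devs)
  })
  structure(list(estimand_name = estimand_name,
                 max_abs_deviation = max_dev,
                 n_trials = as.integer(n_trials),
                 tol = tol,
                 verdict = if (max_dev < tol) "invariant" else "sensitive"),
            class = "invariance_report")
}

#' @export
print.invariance_report <- function(x, ...) {
  cat("<invariance_report> ", x$estimand_name, ": ", x$verdict,
      " (max |delta| = ", format(x$max_abs_deviation, digits = 3),
      " over ", x$n_trials, " trials)\n", sep = "")
  invisible(x)
}
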