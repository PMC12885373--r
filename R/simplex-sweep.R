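#' Composition-dependent bias surfaces on the 3-part simplex
#'
#' Bias is not a single number: it depends on where the unamplified
#' community sits on the simplex. These sweeps evaluate a metric's bias at
#' every point of a lattice over the 3-taxon simplex, for rendering as
#' ternary heatmaps.
#'
#' @name simplex_sweep
#' @keywords internal
NULL

#' Lattice of interior compositions on the 3-part simplex
#'
#' All points `(i*step, j*step, 1 - (i+j)*step)` with every part at least
#' `floor`. The boundary is excluded because log-ratio metrics require
#' strictly positive parts.
#'
#' @param step Lattice spacing in `(0, 1)` (default 0.01).
#' @param floor Minimum part value (default 1e-6).
#' @return List of 3-part compositions.
#' @export
simplex_grid <- function(step = 0.01, floor = 1e-6) {
  if (step <= 0 || step >= 1) stop("step must be in (0, 1)", call. = FALSE)
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  kmax <- base::floor(1 / step)
  pts <- list()
  for (i in 0:kmax) {
    for (j in 0:(kmax - i)) {
      p <- c(i * step, j * step, 1 - (i + j) * step)
      if (all(p >= floor) && abs(sum(p) - 1) < 1e-9)
        pts[[length(pts) + 1L]] <- composition(p / sum(p), normalize = FALSE)
    }
  }
  pts
}

#' Alpha-diversity bias over the simplex
#'
#' Evaluates [alpha_bias()] at every grid point for a fixed per-cycle bias
#' vector.
#'
#' @param metric Alpha metric name or [metric_spec()].
#' @param beta Per-cycle bias vector of length 2 (3-taxon basis), or a
#'   3-part efficiency vector in `[1, 2]` converted via
#'   [efficiencies_to_beta()].
#' @param x Cycle count (default 35).
#' @param step,floor Grid parameters; see [simplex_grid()].
#' @param psi 3-taxon contrast matrix (default ALR).
#' @return A `bias_surface` list: `points`, `bias_values`, `metric`, `beta`,
#'   `cycles`, `reference = NULL`.
#' @export
sweep_alpha <- function(metric, beta, x = 35, step = 0.01, floor = 1e-6,
                        psi = make_contrast_matrix("alr", 3)) {
  metric <- as_metric_spec(metric)
  beta <- resolve_beta(beta, psi)
  pts <- simplex_grid(step, floor)
  vals <- vapply(pts, function(p)
    alpha_bias(phi(p, psi), beta, x, metric, psi), numeric(1))
  structure(list(points = pts, bias_values = vals, metric = metric$name,
                 beta = beta, cycles = x, reference = NULL),
            class = "bias_surface")
}

#' Beta-diversity bias over the simplex against a fixed reference
#'
#' Evaluates [beta_bias()] between a fixed reference community and every
#' grid point.
#'
#' @param metric Beta metric name or [metric_spec()].
#' @param reference 3-part composition held fixed.
#' @param beta Per-cycle bias vector (length 2) or 3-part efficiency vector.
#' @param x Cycle count (default 35).
#' @param step,floor Grid parameters.
#' @param tree Tree for `weighted_unifrac`.
#' @param psi 3-taxon contrast matrix (default ALR).
#' @return A `bias_surface` with `reference` set.
#' @export
sweep_beta <- function(metric, reference, beta, x = 35, step = 0.01,
                       floor = 1e-6, tree = NULL,
                       psi = make_contrast_matrix("alr", 3)) {
  metric <- as_metric_spec(metric)
  beta <- resolve_beta(beta, psi)
  ref_eta <- phi(reference, psi)
  pts <- simplex_grid(step, floor)
  vals <- vapply(pts, function(p)
    beta_bias(ref_eta, phi(p, psi), beta, x, metric, psi, tree = tree),
    numeric(1))
  structure(list(points = pts, bias_values = vals, metric = metric$name,
                 beta = beta, cycles = x,
                 reference = composition(as_parts(reference), normalize = FALSE)),
            class = "bias_surface")
}

# Accept a bias vector in basis coordinates (length D-1) or an efficiency
# vector (length D, values in [1,2]).
resolve_beta <- function(beta, psi) {
  if (length(beta) == nrow(psi)) return(as.numeric(beta))
  if (length(beta) == ncol(psi)) return(efficiencies_to_beta(beta, psi))
  stop("beta must have length D-1 (log-ratio) or D (efficiencies)",
       call. = FALSE)
}

#' Ternary plot coordinates of a 3-part composition
#'
#' Standard barycentric-to-Cartesian map onto the unit triangle:
#' `x = p2 + p3/2`, `y = sqrt(3)/2 * p3`.
#'
#' @param c A 3-part composition.
#' @return Named numeric vector `c(x, y)`.
#' @export
ternary_coords <- function(c) {
  p <- as_parts(c)
  if (length(p) != 3L) stop("ternary coordinates need exactly 3 parts",
                            call. = FALSE)
  c(x = p[2] + p[3] / 2, y = sqrt(3) / 2 * p[3])
}

#' Long-format data frame of a bias surface
#'
#' @param surface A `bias_surface`.
#' @return Data frame with columns p1, p2, p3, tern_x, tern_y, bias.
#' @export
surface_to_df <- function(surface) {
  m <- t(vapply(surface$points, as_parts, numeric(3)))
  tc <- t(vapply(surface$points, ternary_coords, numeric(2)))
  data.frame(p1 = m[, 1], p2 = m[, 2], p3 = m[, 3],
             tern_x = tc[, 1], tern_y = tc[, 2],
             bias = surface$bias_values)
}

#' @export
print.bias_surface <- function(x, ...) {
  cat("<bias_surface> ", x$metric, " at ", x$cycles, " cycles, ",
      length(x$points), " grid points",
      if (!is.null(x$reference)) " (vs fixed reference)", "\n", sep = "")
  cat("bias range: [", format(min(x$bias_values), digits = 4), ", ",
      format(max(x$bias_values), digits = 4), "]\n", sep = "")
  invisible(x)
}
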