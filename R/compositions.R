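#' Log-ratio geometry of the simplex
#'
#' A composition is a vector of strictly positive relative abundances that
#' sum to one: a point on the D-part simplex. All log-ratio machinery in
#' this package (contrast matrices, the phi transform and its inverse, the
#' centred log-ratio, and the perturbation operator) lives here. Natural
#' logarithms are used throughout.
#'
#' @name compositions
#' @keywords internal
NULL

.COMP_TOL <- 1e-12

#' Construct and validate a composition
#'
#' @param parts Numeric vector of D >= 2 strictly positive values. They are
#'   renormalised to sum to one unless they already do; `normalize = FALSE`
#'   requires an exact (1e-12) unit sum.
#' @param normalize Renormalise `parts` to unit sum (default `TRUE`).
#' @return Numeric vector of class `composition` summing to one.
#' @examples
#' composition(c(2, 1, 1))
#' @export
composition <- function(parts, normalize = TRUE) {
  nm <- names(parts)
  parts <- as.numeric(parts)
  names(parts) <- nm
  if (length(parts) < 2L)
    stop("a composition needs at least 2 parts", call. = FALSE)
  if (any(!is.finite(parts)))
    stop("composition parts must be finite", call. = FALSE)
  if (any(parts <= 0))
    stop("composition parts must be strictly positive", call. = FALSE)
  s <- sum(parts)
  if (normalize) {
    parts <- parts / s
  } else if (abs(s - 1) > .COMP_TOL) {
    stop("parts do not sum to 1 (got ", format(s), ")", call. = FALSE)
  }
  structure(parts, class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition,", length(x), "parts>\n")
  print(unclass(x), ...)
  invisible(x)
}

is_composition <- function(x) {
  is.numeric(x) && length(x) >= 2L && all(is.finite(x)) && all(x > 0) &&
    abs(sum(x) - 1) <= 1e-8
}

as_parts <- function(c) {
  if (inherits(c, "composition")) return(unclass(c))
  c <- as.numeric(c)
  if (!is_composition(c))
    stop("not a valid composition (strictly positive parts summing to 1)",
         call. = FALSE)
  c
}

#' Contrast matrix for a log-ratio basis
#'
#' Builds the (D-1) x D contrast matrix Psi whose rows sum to zero, have
#' entries in [-1, 1] and rank D-1. The additive-log-ratio (ALR) form is an
#' identity block with a final column of -1 (last part is the reference);
#' the isometric (ILR) form is the orthonormalised Helmert-style basis, in
#' which Euclidean norms of coordinates equal clr norms.
#'
#' @param kind `"alr"` or `"ilr"`.
#' @param D Number of parts (>= 2).
#' @return A `contrast_matrix`: numeric matrix with attribute `basis_kind`.
#' @examples
#' make_contrast_matrix("alr", 3)
#' @export
make_contrast_matrix <- function(kind = c("alr", "ilr"), D) {
  kind <- match.arg(kind)
  D <- as.integer(D)
  if (is.na(D) || D < 2L)
    stop("D must be an integer >= 2", call. = FALSE)
  if (kind == "alr") {
    psi <- cbind(diag(D - 1L), rep(-1, D - 1L))
  } else {
    # Helmert-style orthonormal rows: row i contrasts the first i parts
    # against part i+1; entries stay within [-1, 1].
    psi <- matrix(0, D - 1L, D)
    for (i in seq_len(D - 1L)) {
      psi[i, seq_len(i)] <- 1 / sqrt(i * (i + 1))
      psi[i, i + 1L] <- -i / sqrt(i * (i + 1))
    }
  }
  dimnames(psi) <- NULL
  structure(psi, basis_kind = kind, class = c("contrast_matrix", "matrix"))
}

psi_dim <- function(psi) ncol(psi)

check_psi <- function(psi) {
  if (!is.matrix(psi) || nrow(psi) != ncol(psi) - 1L)
    stop("contrast matrix must be (D-1) x D", call. = FALSE)
  if (max(abs(rowSums(psi))) > 1e-10)
    stop("contrast matrix rows must sum to zero", call. = FALSE)
  invisible(psi)
}

# Moore-Penrose-style right inverse restricted to the zero-sum hyperplane:
# clr(pi) = t(psi) %*% solve(psi %*% t(psi)) %*% eta. Exact because the row
# space of a rank-(D-1) zero-sum contrast matrix IS the hyperplane.
psi_pinv <- function(psi) {
  t(psi) %*% solve(psi %*% t(psi))
}

#' Log-ratio transform phi
#'
#' Maps a composition to its (D-1)-dimensional log-ratio coordinates
#' eta = Psi log(pi) (natural log).
#'
#' @param c A composition (or positive vector summing to 1).
#' @param psi Contrast matrix from [make_contrast_matrix()].
#' @return Numeric vector of length D-1.
#' @export
phi <- function(c, psi) {
  p <- as_parts(c)
  check_psi(psi)
  if (length(p) != ncol(psi))
    stop("composition has ", length(p), " parts but contrast matrix expects ",
         ncol(psi), call. = FALSE)
  drop(psi %*% log(p))
}

#' Inverse log-ratio transform
#'
#' Recovers the unique composition with the given log-ratio coordinates.
#' Works for any full-rank zero-sum contrast basis: the clr vector is the
#' row-space preimage of eta, and the composition is its softmax.
#'
#' @param eta Numeric vector of length D-1 (finite).
#' @param psi Contrast matrix.
#' @return A [composition()].
#' @export
phi_inverse <- function(eta, psi) {
  check_psi(psi)
  eta <- as.numeric(eta)
  if (length(eta) != nrow(psi))
    stop("eta has length ", length(eta), " but basis expects ", nrow(psi),
         call. = FALSE)
  if (any(!is.finite(eta)))
    stop("eta must be finite", call. = FALSE)
  clrv <- drop(psi_pinv(psi) %*% eta)
  w <- exp(clrv - max(clrv))
  composition(w / sum(w), normalize = FALSE)
}

#' Centred log-ratio transform
#'
#' @param c A composition.
#' @return Numeric vector of length D summing to zero: log(parts) minus its
#'   mean.
#' @export
clr <- function(c) {
  p <- as_parts(c)
  lp <- log(p)
  lp - mean(lp)
}

#' Perturbation in log-ratio coordinates
#'
#' The simplex group operation expressed on coordinates: componentwise sum
#' of two log-ratio vectors in the same basis. `perturb(eta, 0)` is the
#' identity and `-gamma` is the group inverse.
#'
#' @param eta,gamma Numeric vectors of equal length (same basis).
#' @return Numeric vector `eta + gamma`.
#' @export
perturb <- function(eta, gamma) {
  eta <- as.numeric(eta); gamma <- as.numeric(gamma)
  if (length(eta) != length(gamma))
    stop("perturbation requires log-ratio vectors of equal length ",
         "(same basis)", call. = FALSE)
  eta + gamma
}

#' Validate a vector of per-cycle amplification efficiencies
#'
#' Each efficiency is the per-cycle multiplicative growth factor of a
#' template: 1 means no amplification, 2 perfect doubling.
#'
#' @param b Numeric vector in `[1, 2]^D`.
#' @return `b`, invisibly validated.
#' @export
efficiency_vector <- function(b) {
  b <- as.numeric(b)
  if (length(b) < 2L || any(!is.finite(b)))
    stop("need at least 2 finite efficiencies", call. = FALSE)
  if (any(b < 1 - 1e-12) || any(b > 2 + 1e-12))
    stop("amplification efficiencies must lie in [1, 2]", call. = FALSE)
  pmin(pmax(b, 1), 2)
}
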