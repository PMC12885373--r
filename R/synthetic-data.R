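#' Synthetic calibration experiments
#'
#' Generates count tables with the exact statistical structure the analysis
#' assumes: each sample's log-ratio composition is a community baseline
#' shifted by cycle-number times a per-cycle bias vector (the log-ratio form
#' of exponential amplification), plus logistic-normal noise, observed
#' through multinomial sequencing at a fixed depth.
#'
#' @name synthetic_data
#' @keywords internal
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stream sub-seed: one stream per sample so partial
# re-simulation is stable. Lehmer-style mix kept below 2^31.
split_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483629)
}

#' Expected two-template ratio after amplification
#'
#' The exponential amplification model for two templates: starting ratio
#' `a1/a2`, per-cycle efficiencies `b1`, `b2` in `[1, 2]`, observed ratio
#' after `x` cycles is `(a1/a2) * (b1/b2)^x`.
#'
#' @param a1,a2 Positive starting template quantities.
#' @param b1,b2 Per-cycle amplification efficiencies in `[1, 2]`.
#' @param x Non-negative cycle count.
#' @return The expected observed ratio.
#' @examples
#' expected_ratio(1, 1, 1.05, 1, 10)  # 1.05^10
#' @export
expected_ratio <- function(a1, a2, b1, b2, x) {
  if (any(c(a1, a2, b1, b2) <= 0)) stop("inputs must be positive", call. = FALSE)
  efficiency_vector(c(b1, b2))
  if (x < 0) stop("cycle count must be >= 0", call. = FALSE)
  (a1 / a2) * (b1 / b2)^x
}

#' Per-cycle bias vector from amplification efficiencies
#'
#' beta = Psi log(b): the log-ratio coordinates of the efficiency vector.
#' Equal efficiencies carry no compositional information and map to zero.
#'
#' @param b Efficiency vector in `[1, 2]^D`.
#' @param psi Contrast matrix over the same D taxa.
#' @return Numeric vector of length D-1.
#' @export
efficiencies_to_beta <- function(b, psi) {
  b <- efficiency_vector(b)
  check_psi(psi)
  if (length(b) != ncol(psi))
    stop("efficiency vector length does not match contrast matrix",
         call. = FALSE)
  drop(psi %*% log(b))
}

#' Build a calibration design matrix
#'
#' One row per community (one-hot membership indicators) plus a final row
#' holding the PCR cycle number, so the coefficient matrix has one baseline
#' log-ratio column per community and a shared per-cycle bias column.
#'
#' @param communities Character/factor vector of community labels, one per
#'   sample.
#' @param cycles Non-negative integer cycle counts, one per sample.
#' @return A `design_matrix` list: `X` (p x N), `communities` (levels),
#'   `cycle_row`, `covariate_names`.
#' @export
make_design <- function(communities, cycles) {
  communities <- as.character(communities)
  n <- length(communities)
  if (n < 1L || length(cycles) != n)
    stop("communities and cycles must be non-empty and equal length",
         call. = FALSE)
  if (any(cycles < 0) || any(cycles != round(cycles)))
    stop("cycles must be non-negative integers", call. = FALSE)
  levs <- unique(communities)
  X <- rbind(
    vapply(communities, function(cm) as.numeric(levs == cm), numeric(length(levs))),
    as.numeric(cycles)
  )
  if (length(levs) == 1L) X <- matrix(X, nrow = 2L, ncol = n,
                                      byrow = FALSE)
  rownames(X) <- c(levs, "cycles")
  colnames(X) <- NULL
  structure(list(X = X, communities = levs,
                 cycle_row = length(levs) + 1L,
                 covariate_names = rownames(X)),
            class = "design_matrix")
}

#' Construct simulation ground truth
#'
#' @param lambda `(D-1) x p` coefficient matrix: one baseline column per
#'   community followed by the per-cycle bias column (log-ratio units).
#' @param sigma `(D-1) x (D-1)` symmetric PSD covariance of the
#'   logistic-normal noise.
#' @param seed Integer master seed.
#' @param depths Sequencing depth per sample (recycled to N at simulation).
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(lambda, sigma, seed, depths = 10000L) {
  lambda <- as.matrix(lambda)
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != nrow(lambda) || ncol(sigma) != nrow(lambda))
    stop("sigma must be (D-1) x (D-1) matching lambda's rows", call. = FALSE)
  if (max(abs(sigma - t(sigma))) > 1e-10)
    stop("sigma must be symmetric", call. = FALSE)
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("sigma must be positive semi-definite", call. = FALSE)
  if (any(depths < 1)) stop("depths must be >= 1", call. = FALSE)
  structure(list(lambda = lambda, sigma = sigma, seed = as.integer(seed),
                 depths = as.integer(depths)),
            class = "simulation_truth")
}

#' Noise-free expected log-ratio coordinates
#'
#' @param truth A [simulation_truth()].
#' @param design A [make_design()] design.
#' @return `(D-1) x N` matrix `Lambda %*% X`.
#' @export
expected_logratios <- function(truth, design) {
  if (ncol(truth$lambda) != nrow(design$X))
    stop("coefficient columns do not match design rows", call. = FALSE)
  truth$lambda %*% design$X
}

#' Simulate a count table under the amplification-bias model
#'
#' For each sample, draws log-ratio coordinates from
#' `N(Lambda X_n, Sigma)` (or uses the mean exactly when `noise_free`),
#' maps them to the simplex, and draws multinomial read counts at the
#' sample's depth. Column sums equal the requested depths exactly. One RNG
#' stream per sample, all derived from the truth's master seed.
#'
#' @param truth A [simulation_truth()].
#' @param design A [make_design()] design.
#' @param psi Contrast matrix (basis of `lambda`'s rows).
#' @param noise_free Skip the logistic-normal noise (default `FALSE`).
#' @param taxon_ids,sample_ids Optional dimnames.
#' @return Integer `D x N` count matrix.
#' @export
simulate_counts <- function(truth, design, psi, noise_free = FALSE,
                            taxon_ids = NULL, sample_ids = NULL) {
  check_psi(psi)
  if (nrow(psi) != nrow(truth$lambda))
    stop("contrast matrix does not match coefficient dimension", call. = FALSE)
  eta_mean <- expected_logratios(truth, design)
  N <- ncol(eta_mean); Dm1 <- nrow(eta_mean); D <- Dm1 + 1L
  depths <- rep_len(truth$depths, N)
  sig_chol <- if (!noise_free && any(truth$sigma != 0))
    chol(truth$sigma + 1e-12 * diag(Dm1)) else NULL
  Y <- matrix(0L, D, N)
  for (n in seq_len(N)) {
    Y[, n] <- with_seed(split_seed(truth$seed, n), {
      eta_n <- eta_mean[, n]
      if (!is.null(sig_chol)) eta_n <- eta_n + drop(t(sig_chol) %*% rnorm(Dm1))
      pi_n <- phi_inverse(eta_n, psi)
      as.integer(rmultinom(1, depths[n], unclass(pi_n)))
    })
  }
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(D))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(N))
  dimnames(Y) <- list(taxon_ids, sample_ids)
  Y
}

#' Draw per-taxon amplification efficiencies
#'
#' Uniform in `[2 - spread, 2]`, clipped to `[1, 2]`: efficiencies near
#' perfect doubling, so per-cycle log-ratio biases are small and distortion
#' accumulates over tens of cycles.
#'
#' @param D Number of taxa (>= 2).
#' @param seed Integer seed.
#' @param spread Width of the uniform draw, in `(0, 1]` (default 0.3).
#' @return Numeric vector in `[1, 2]^D`.
#' @export
simulate_efficiencies <- function(D, seed, spread = 0.3) {
  if (D < 2) stop("D must be >= 2", call. = FALSE)
  if (spread <= 0 || spread > 1) stop("spread must be in (0, 1]", call. = FALSE)
  with_seed(seed, efficiency_vector(pmin(pmax(runif(D, 2 - spread, 2), 1), 2)))
}

#' Simulate a random phylogeny over the study taxa
#'
#' Random rooted bifurcating topology with exponential branch lengths,
#' tips labelled by the taxon ids. A stand-in for the pruned reference
#' phylogeny a real study would use.
#'
#' @param taxon_ids Character vector of >= 2 unique taxon ids.
#' @param seed Integer seed.
#' @param rate Rate of the exponential branch-length distribution.
#' @return An `ape::phylo` tree.
#' @export
simulate_tree <- function(taxon_ids, seed, rate = 1) {
  D <- length(taxon_ids)
  if (D < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon ids", call. = FALSE)
  with_seed(seed, {
    tree <- ape::rtree(D, rooted = TRUE, br = stats::rexp, rate = rate)
    # rtree names tips tN in random order; relabel by position so the tip
    # set equals taxon_ids exactly
    tree$tip.label <- taxon_ids[order(as.integer(sub("^t", "", tree$tip.label)))]
    tree
  })
}

#' Simulate a full mock-community calibration experiment
#'
#' The package's default study conditions: `D` taxa, `n_communities`
#' communities each sequenced as one replicate per calibration cycle number,
#' multinomial depth per sample, community baselines drawn iid normal in
#' log-ratio coordinates, per-cycle bias derived from uniform efficiencies
#' near 2, and isotropic logistic-normal noise.
#'
#' @param seed Integer master seed driving every random component.
#' @param D Taxa (default 10).
#' @param n_communities Communities (default 10).
#' @param cycles Calibration cycle numbers, one replicate each per community
#'   (default `c(20, 28, 35)`).
#' @param depth Reads per sample (default 10000).
#' @param spread Efficiency spread (default 0.3); see
#'   [simulate_efficiencies()].
#' @param sigma_scale Isotropic noise variance on log-ratio coordinates
#'   (default 0.1).
#' @param alpha_sd SD of the iid normal community baselines (default 1).
#' @param basis Contrast basis kind (default `"alr"`).
#' @return List with `counts`, `metadata` (data.frame: sample_id, community,
#'   cycles), `design`, `truth`, `psi`, `efficiencies`, `beta_true`, `tree`,
#'   `taxon_ids`.
#' @export
simulate_mock_experiment <- function(seed, D = 10L, n_communities = 10L,
                                     cycles = c(20L, 28L, 35L),
                                     depth = 10000L, spread = 0.3,
                                     sigma_scale = 0.1, alpha_sd = 1,
                                     basis = "alr") {
  psi <- make_contrast_matrix(basis, D)
  taxon_ids <- paste0("taxon_", seq_len(D))
  comm_ids <- paste0("C", seq_len(n_communities))
  communities <- rep(comm_ids, each = length(cycles))
  cyc <- rep(as.integer(cycles), times = n_communities)
  design <- make_design(communities, cyc)
  b <- simulate_efficiencies(D, split_seed(seed, 1L), spread = spread)
  beta_true <- efficiencies_to_beta(b, psi)
  alpha <- with_seed(split_seed(seed, 2L),
                     matrix(rnorm((D - 1L) * n_communities, sd = alpha_sd),
                            D - 1L, n_communities))
  lambda <- cbind(alpha, beta_true)
  colnames(lambda) <- c(comm_ids, "cycles")
  truth <- simulation_truth(lambda, sigma_scale * diag(D - 1L),
                            seed = split_seed(seed, 3L), depths = depth)
  sample_ids <- paste0(communities, "_x", cyc)
  counts <- simulate_counts(truth, design, psi,
                            taxon_ids = taxon_ids, sample_ids = sample_ids)
  tree <- simulate_tree(taxon_ids, split_seed(seed, 4L))
  list(counts = counts,
       metadata = data.frame(sample_id = sample_ids, community = communities,
                             cycles = cyc, stringsAsFactors = FALSE),
       design = design, truth = truth, psi = psi,
       efficiencies = b, beta_true = beta_true, tree = tree,
       taxon_ids = taxon_ids)
}
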