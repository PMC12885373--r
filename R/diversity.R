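#' Diversity metrics
#'
#' Alpha metrics map one composition to a non-negative scalar; beta metrics
#' map a pair of compositions to a non-negative dissimilarity. These are the
#' estimands whose sensitivity to PCR amplification bias the rest of the
#' package quantifies.
#'
#' @name diversity
#' @keywords internal
NULL

.ALPHA_METRICS <- c("shannon", "simpson", "gini", "aitchison_norm")
.BETA_METRICS  <- c("bray_curtis", "weighted_unifrac", "aitchison_distance")

#' Specify a diversity metric
#'
#' @param name One of `shannon`, `simpson`, `gini`, `aitchison_norm` (alpha)
#'   or `bray_curtis`, `weighted_unifrac`, `aitchison_distance` (beta).
#' @param normalized For `weighted_unifrac` only: divide the branch-weighted
#'   abundance differences by the maximal attainable value so the distance
#'   lies in `[0, 1]` (default `TRUE`).
#' @return A `metric_spec` list with fields `name`, `type`, `options`.
#' @export
metric_spec <- function(name, normalized = TRUE) {
  name <- match.arg(name, c(.ALPHA_METRICS, .BETA_METRICS))
  type <- if (name %in% .ALPHA_METRICS) "alpha" else "beta"
  if (!identical(normalized, TRUE) && name != "weighted_unifrac")
    stop("`normalized` applies only to weighted_unifrac", call. = FALSE)
  structure(list(name = name, type = type,
                 options = list(normalized = isTRUE(normalized))),
            class = "metric_spec")
}

as_metric_spec <- function(metric) {
  if (inherits(metric, "metric_spec")) return(metric)
  if (is.character(metric) && length(metric) == 1L) return(metric_spec(metric))
  stop("metric must be a metric name or a metric_spec()", call. = FALSE)
}

#' Alpha diversity of a composition
#'
#' Shannon entropy (-sum p log p, natural log), Gini-Simpson index
#' (1 - sum p^2), Gini inequality coefficient
#' (sum_ij |p_i - p_j| / (2 D)), or the Aitchison norm (Euclidean norm of
#' the clr vector).
#'
#' @param c A composition.
#' @param metric Metric name or [metric_spec()] of type alpha.
#' @return Non-negative scalar.
#' @examples
#' alpha_diversity(composition(rep(1, 3)), "shannon")  # log(3)
#' @export
alpha_diversity <- function(c, metric) {
  metric <- as_metric_spec(metric)
  if (metric$type != "alpha")
    stop(metric$name, " is a beta metric, not an alpha metric", call. = FALSE)
  p <- as_parts(c)
  switch(metric$name,
    shannon = -sum(p * log(p)),
    simpson = 1 - sum(p^2),
    gini = sum(abs(outer(p, p, "-"))) / (2 * length(p)),
    aitchison_norm = sqrt(sum(clr(p)^2))
  )
}

#' Beta diversity between two compositions
#'
#' Bray-Curtis (half the L1 distance of relative abundances), normalized or
#' raw weighted UniFrac (branch lengths weighting the difference in
#' descendant mass, accumulated post-order), or the Aitchison distance
#' (Euclidean distance between clr vectors).
#'
#' @param c1,c2 Compositions over the same taxa.
#' @param metric Metric name or [metric_spec()] of type beta.
#' @param tree An `ape::phylo` tree; required for `weighted_unifrac`. Named
#'   compositions are matched to tip labels; unnamed ones must follow the
#'   tree's tip order.
#' @return Non-negative scalar.
#' @export
beta_diversity <- function(c1, c2, metric, tree = NULL) {
  metric <- as_metric_spec(metric)
  if (metric$type != "beta")
    stop(metric$name, " is an alpha metric, not a beta metric", call. = FALSE)
  p <- as_parts(c1); q <- as_parts(c2)
  if (length(p) != length(q))
    stop("compositions have different numbers of taxa", call. = FALSE)
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q)))
      stop("compositions are over different taxa", call. = FALSE)
    q <- q[names(p)]
  }
  switch(metric$name,
    bray_curtis = sum(abs(p - q)) / 2,
    aitchison_distance = sqrt(sum((clr(p) - clr(q))^2)),
    weighted_unifrac = {
      if (is.null(tree))
        stop("weighted_unifrac requires a phylogenetic tree", call. = FALSE)
      weighted_unifrac(p, q, tree, normalized = metric$options$normalized)
    }
  )
}

# Map a composition's parts onto the tree's tips.
match_tips <- function(p, tree) {
  tips <- tree$tip.label
  if (length(p) != length(tips))
    stop("composition has ", length(p), " taxa but tree has ", length(tips),
         " tips", call. = FALSE)
  if (!is.null(names(p))) {
    if (!setequal(names(p), tips))
      stop("composition taxa do not match tree tip labels", call. = FALSE)
    p <- p[tips]
  }
  unname(p)
}

# Weighted UniFrac by a single post-order pass: each edge contributes its
# length times |P_e - Q_e| where P_e, Q_e are the descendant tip masses.
# Normalized form divides by sum_tips d_tip * (p_tip + q_tip) with d_tip the
# root-to-tip path length (the maximum attainable raw value).
weighted_unifrac <- function(p, q, tree, normalized = TRUE) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  p <- match_tips(p, tree); q <- match_tips(q, tree)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  mass_p <- c(p, rep(0, nnode - ntip))
  mass_q <- c(q, rep(0, nnode - ntip))
  raw <- 0
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    raw <- raw + tree$edge.length[k] * abs(mass_p[ch] - mass_q[ch])
    mass_p[par] <- mass_p[par] + mass_p[ch]
    mass_q[par] <- mass_q[par] + mass_q[ch]
  }
  if (!normalized) return(raw)
  depth <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  denom <- sum(depth * (p + q))
  if (denom == 0) return(0)
  raw / denom
}

#' Pairwise distance matrix
#'
#' @param comps List of >= 2 compositions over the same taxa.
#' @param metric Beta metric name or [metric_spec()].
#' @param tree Tree for `weighted_unifrac`.
#' @param ids Optional sample ids for dimnames.
#' @return Symmetric N x N matrix with zero diagonal.
#' @export
distance_matrix <- function(comps, metric, tree = NULL, ids = NULL) {
  if (!is.list(comps) || length(comps) < 2L)
    stop("need a list of at least 2 compositions", call. = FALSE)
  n <- length(comps)
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dm[i, j] <- dm[j, i] <- beta_diversity(comps[[i]], comps[[j]], metric,
                                             tree = tree)
    }
  }
  if (!is.null(ids)) dimnames(dm) <- list(ids, ids)
  dm
}

#' Read a Newick tree
#'
#' Thin validating wrapper over `ape::read.tree`: duplicate tip labels are
#' an error, and missing branch lengths are set to zero with a warning.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("failed to parse Newick file: ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree: ", path, call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths; defaulting to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Write a Newick tree
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
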