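#' Worst-case differential-diversity analysis
#'
#' How much can amplification bias change the apparent separation of two
#' groups of samples? R-squared from ANOVA (scalar diversity values) or
#' PERMANOVA (distance matrices) is computed at cycle 0 and at the
#' evaluation cycle; the grouping search maximizes the absolute change
#' delta-R2 = |R2_x - R2_0| over binary sample partitions.
#'
#' @name group_optimization
#' @keywords internal
NULL

check_assignment <- function(assignment, n, min_size = 1L) {
  a <- as.integer(as.logical(assignment))
  if (length(a) != n) stop("assignment length mismatch", call. = FALSE)
  if (sum(a) < min_size || sum(1 - a) < min_size)
    stop("each group needs at least ", min_size, " samples", call. = FALSE)
  a
}

#' ANOVA R-squared of a binary grouping
#'
#' Between-group sum of squares over total sum of squares.
#'
#' @param values Numeric vector, one diversity value per sample.
#' @param assignment Binary group labels.
#' @return R-squared in `[0, 1]`; 0 (with a warning) when the values have
#'   zero total variance.
#' @export
anova_r2 <- function(values, assignment) {
  a <- check_assignment(assignment, length(values))
  sst <- sum((values - mean(values))^2)
  if (sst == 0) {
    warning("zero total variance; R2 defined as 0")
    return(0)
  }
  m0 <- mean(values[a == 0]); m1 <- mean(values[a == 1])
  ssb <- sum(a == 0) * (m0 - mean(values))^2 + sum(a == 1) * (m1 - mean(values))^2
  ssb / sst
}

permanova_ss <- function(d2, a) {
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in c(0L, 1L)) {
    idx <- which(a == g)
    sub <- d2[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(sst = sst, ssw = ssw)
}

#' PERMANOVA R-squared, pseudo-F and permutation p-value
#'
#' Distance-based partitioning of sums of squares:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` summed per group with its
#' own size, `R2 = 1 - SS_within / SS_total`, pseudo-F with (1, N-2)
#' degrees of freedom. The p-value counts permutations (plus the observed
#' labelling) with pseudo-F at least as large as observed.
#'
#' @param dm Symmetric N x N distance matrix with zero diagonal.
#' @param assignment Binary group labels, each group of size >= 2.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List with `r2`, `pseudo_f`, `p`.
#' @export
permanova_r2 <- function(dm, assignment, n_perm = 999L, seed = 1L) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (max(abs(dm - t(dm))) > 1e-8 || any(diag(dm) != 0))
    stop("dm must be symmetric with zero diagonal", call. = FALSE)
  a <- check_assignment(assignment, n, min_size = 2L)
  d2 <- dm^2
  ss <- permanova_ss(d2, a)
  ssb <- ss["sst"] - ss["ssw"]
  r2 <- unname(ssb / ss["sst"])
  f_obs <- unname((ssb / 1) / (ss["ssw"] / (n - 2)))
  p <- with_seed(seed, {
    exceed <- 1L  # the observed labelling counts
    for (i in seq_len(n_perm)) {
      ap <- sample(a)
      ssp <- permanova_ss(d2, ap)
      fp <- (ssp["sst"] - ssp["ssw"]) / (ssp["ssw"] / (n - 2))
      if (fp >= f_obs - 1e-12) exceed <- exceed + 1L
    }
    exceed / (n_perm + 1)
  })
  list(r2 = r2, pseudo_f = f_obs, p = unname(p))
}

#' Change in group-separation R-squared across cycle conditions
#'
#' @param at0,atx Diversity values (mode `"anova"`) or distance matrices
#'   (mode `"permanova"`) at cycle 0 and at the evaluation cycle.
#' @param assignment Binary group labels.
#' @param mode `"anova"` or `"permanova"`.
#' @return `|R2_x - R2_0|` in `[0, 1]`.
#' @export
delta_r2 <- function(at0, atx, assignment, mode = c("anova", "permanova")) {
  mode <- match.arg(mode)
  r2 <- function(obj) {
    if (mode == "anova") anova_r2(obj, assignment)
    else permanova_r2(obj, assignment, n_perm = 0L)$r2
  }
  abs(r2(atx) - r2(at0))
}

# enumerate all bipartitions (sample 1 fixed to group 0) meeting min size
all_bipartitions <- function(n, min_size) {
  masks <- seq_len(2^(n - 1L) - 1L)
  lapply(masks, function(m) {
    a <- as.integer(intToBits(m)[seq_len(n - 1L)] == 1)
    c(0L, a)
  })
}

#' Search for the grouping maximizing delta-R2
#'
#' `brute_force` enumerates all `2^(N-1) - 1` bipartitions meeting the
#' size constraint and is exact. `ga` is a seeded genetic algorithm
#' (population 50, 100 generations, tournament size 3, uniform crossover
#' 0.8, per-bit mutation 1/N, elitism 1). `pso` is particle swarm
#' optimization on `[0,1]^N` positions thresholded at 0.5 (40 particles,
#' 200 iterations, inertia 0.72, cognitive/social weights 1.49). Both
#' heuristics repair infeasible candidates by flipping random bits.
#'
#' @param at0,atx Values or distance matrices at the two cycle conditions.
#' @param mode `"anova"` or `"permanova"`.
#' @param method `"brute_force"`, `"ga"`, or `"pso"`.
#' @param min_size Minimum group size (default 2).
#' @param seed Integer seed (heuristics only).
#' @return A `grouping_result` list: `assignment`, `r2_cycle0`, `r2_cyclex`,
#'   `delta_r2`, `method`, `seed`.
#' @export
optimize_grouping <- function(at0, atx, mode = c("anova", "permanova"),
                              method = c("brute_force", "ga", "pso"),
                              min_size = 2L, seed = 1L) {
  mode <- match.arg(mode); method <- match.arg(method)
  n <- if (mode == "anova") length(at0) else nrow(as.matrix(at0))
  if (n < 2L * min_size)
    stop("need at least ", 2L * min_size, " samples for groups of size >= ",
         min_size, call. = FALSE)
  eff_min <- if (mode == "permanova") max(min_size, 2L) else min_size
  fitness <- function(a) {
    if (sum(a) < eff_min || sum(1 - a) < eff_min) return(-1)
    delta_r2(at0, atx, a, mode)
  }
  repair <- function(a) {
    while (sum(a) < eff_min) a[sample(which(a == 0L), 1L)] <- 1L
    while (sum(1 - a) < eff_min) a[sample(which(a == 1L), 1L)] <- 0L
    a
  }

  best <- switch(method,
    brute_force = {
      cands <- all_bipartitions(n, eff_min)
      fits <- vapply(cands, fitness, numeric(1))
      if (all(fits < 0)) stop("no feasible bipartition", call. = FALSE)
      cands[[which.max(fits)]]
    },
    ga = with_seed(seed, {
      pop_size <- 50L; n_gen <- 100L
      pop <- replicate(pop_size,
                       repair(sample(0:1, n, replace = TRUE)), simplify = FALSE)
      fits <- vapply(pop, fitness, numeric(1))
      for (g in seq_len(n_gen)) {
        elite <- pop[[which.max(fits)]]
        newpop <- vector("list", pop_size)
        newpop[[1L]] <- elite
        for (k in seq.int(2L, pop_size)) {
          pick <- function() {
            cand <- sample.int(pop_size, 3L)
            pop[[cand[which.max(fits[cand])]]]
          }
          p1 <- pick(); p2 <- pick()
          child <- if (runif(1) < 0.8) ifelse(runif(n) < 0.5, p1, p2) else p1
          flip <- runif(n) < 1 / n
          child[flip] <- 1L - child[flip]
          newpop[[k]] <- repair(child)
        }
        pop <- newpop
        fits <- vapply(pop, fitness, numeric(1))
      }
      pop[[which.max(fits)]]
    }),
    pso = with_seed(seed, {
      n_part <- 40L; n_iter <- 200L
      w <- 0.72; c1 <- 1.49; c2 <- 1.49
      pos <- matrix(runif(n_part * n), n_part, n)
      vel <- matrix(runif(n_part * n, -0.2, 0.2), n_part, n)
      decode <- function(x) repair(as.integer(x > 0.5))
      pfit <- apply(pos, 1, function(x) fitness(decode(x)))
      pbest <- pos; pbest_fit <- pfit
      gbest <- pos[which.max(pfit), ]; gbest_fit <- max(pfit)
      for (it in seq_len(n_iter)) {
        r1 <- matrix(runif(n_part * n), n_part, n)
        r2m <- matrix(runif(n_part * n), n_part, n)
        vel <- w * vel + c1 * r1 * (pbest - pos) +
          c2 * r2m * (matrix(gbest, n_part, n, byrow = TRUE) - pos)
        pos <- pmin(pmax(pos + vel, 0), 1)
        fit <- apply(pos, 1, function(x) fitness(decode(x)))
        upd <- fit > pbest_fit
        pbest[upd, ] <- pos[upd, ]; pbest_fit[upd] <- fit[upd]
        if (max(fit) > gbest_fit) {
          gbest <- pos[which.max(fit), ]; gbest_fit <- max(fit)
        }
      }
      decode(gbest)
    })
  )

  r2_of <- function(obj, a) {
    if (mode == "anova") anova_r2(obj, a)
    else permanova_r2(obj, a, n_perm = 0L)$r2
  }
  r0 <- r2_of(at0, best); rx <- r2_of(atx, best)
  structure(list(assignment = best, r2_cycle0 = r0, r2_cyclex = rx,
                 delta_r2 = abs(rx - r0), method = method,
                 seed = as.integer(seed)),
            class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  cat("<grouping_result> method=", x$method,
      " delta_r2=", signif(x$delta_r2, 4),
      " (R2_0=", signif(x$r2_cycle0, 4),
      ", R2_x=", signif(x$r2_cyclex, 4), ")\n", sep = "")
  cat("groups:", paste(x$assignment, collapse = ""), "\n")
  invisible(x)
}
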