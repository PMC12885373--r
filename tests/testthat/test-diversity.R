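test_that("alpha metrics match closed forms", {
  u3 <- composition(rep(1, 3))
  expect_equal(alpha_diversity(u3, "shannon"), log(3))
  expect_equal(alpha_diversity(u3, "simpson"), 2 / 3)
  expect_equal(alpha_diversity(u3, "gini"), 0)
  expect_equal(alpha_diversity(u3, "aitchison_norm"), 0)

  p <- composition(c(0.5, 0.25, 0.25), normalize = FALSE)
  expect_equal(alpha_diversity(p, "shannon"),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(alpha_diversity(composition(c(0.8, 0.2), normalize = FALSE),
                               "aitchison_norm"), log(4) / sqrt(2))
  # near-degenerate three-part composition approaches the (D-1)/D gini limit
  eps <- 1e-6
  expect_equal(alpha_diversity(composition(c(1 - 2 * eps, eps, eps),
                                           normalize = FALSE), "gini"),
               2 / 3, tolerance = 1e-5)
  expect_error(alpha_diversity(u3, "bray_curtis"), "beta metric")
})

test_that("shannon is maximized exactly at the uniform composition", {
  for (D in c(3, 6)) {
    expect_equal(alpha_diversity(composition(rep(1, D)), "shannon"), log(D))
    set.seed(13)
    vals <- replicate(100, alpha_diversity(rcomp(D), "shannon"))
    expect_true(all(vals < log(D)))
  }
})

test_that("beta metrics match closed forms", {
  p <- composition(c(0.2, 0.5, 0.3), normalize = FALSE)
  for (m in c("bray_curtis", "aitchison_distance"))
    expect_equal(beta_diversity(p, p, m), 0)
  tr <- tree3()
  expect_equal(beta_diversity(p, p, "weighted_unifrac", tree = tr), 0)

  eps <- 1e-9
  bc <- beta_diversity(composition(c(0.5, 0.5 - eps, eps), normalize = FALSE),
                       composition(c(eps, 0.5 - eps, 0.5), normalize = FALSE),
                       "bray_curtis")
  expect_equal(bc, 0.5, tolerance = 1e-6)

  expect_equal(beta_diversity(composition(c(0.8, 0.2), normalize = FALSE),
                              composition(c(0.2, 0.8), normalize = FALSE),
                              "aitchison_distance"), sqrt(2) * log(4))
})

test_that("weighted unifrac on a two-tip cherry hits its extremes", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  eps <- 1e-9
  p <- c(A = 1 - eps, B = eps); q <- c(A = eps, B = 1 - eps)
  raw <- beta_diversity(composition(p, normalize = FALSE),
                        composition(q, normalize = FALSE),
                        metric_spec("weighted_unifrac", normalized = FALSE),
                        tree = cherry)
  nrm <- beta_diversity(composition(p, normalize = FALSE),
                        composition(q, normalize = FALSE),
                        "weighted_unifrac", tree = cherry)
  expect_equal(raw, 2, tolerance = 1e-6)
  expect_equal(nrm, 1, tolerance = 1e-6)
  expect_error(beta_diversity(composition(p, normalize = FALSE),
                              composition(q, normalize = FALSE),
                              "weighted_unifrac"), "tree")
})

test_that("bray-curtis and unifrac agree with vegan and phyloseq", {
  skip_if_not_installed("vegan")
  skip_if_not_installed("phyloseq")
  set.seed(17)
  tr <- simulate_tree(paste0("taxon_", 1:6), 99)
  comps <- replicate(4, {
    x <- rgamma(6, 1); names(x) <- paste0("taxon_", 1:6); composition(x)
  }, simplify = FALSE)
  m <- t(vapply(comps, unclass, numeric(6)))
  colnames(m) <- paste0("taxon_", 1:6)

  bc_mine <- distance_matrix(comps, "bray_curtis")
  bc_vegan <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(unname(bc_mine), unname(bc_vegan), tolerance = 1e-12)

  otu <- phyloseq::otu_table(t(m), taxa_are_rows = TRUE)
  ps <- phyloseq::phyloseq(otu, phyloseq::phy_tree(tr))
  wu_ps <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  wu_mine <- distance_matrix(comps, "weighted_unifrac", tree = tr)
  expect_equal(unname(wu_mine), unname(wu_ps), tolerance = 1e-10)
  wu_ps_raw <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                           normalized = FALSE))
  wu_mine_raw <- distance_matrix(comps,
                                 metric_spec("weighted_unifrac",
                                             normalized = FALSE), tree = tr)
  expect_equal(unname(wu_mine_raw), unname(wu_ps_raw), tolerance = 1e-10)
})

test_that("bray-curtis is bounded and unifrac normalization stays in [0,1]", {
  set.seed(23)
  tr <- simulate_tree(paste0("taxon_", 1:5), 7)
  for (i in 1:50) {
    p <- rcomp(5); q <- rcomp(5)
    bc <- beta_diversity(p, q, "bray_curtis")
    expect_true(bc >= 0 && bc <= 1)
    expect_equal(bc, beta_diversity(q, p, "bray_curtis"))
    wu <- beta_diversity(p, q, "weighted_unifrac", tree = tr)
    expect_true(wu >= 0 && wu <= 1 + 1e-12)
    expect_equal(wu, beta_diversity(q, p, "weighted_unifrac", tree = tr))
  }
})

test_that("aitchison distance satisfies the metric axioms", {
  set.seed(29)
  for (i in 1:500) {
    a <- rcomp(4); b <- rcomp(4); c <- rcomp(4)
    dab <- beta_diversity(a, b, "aitchison_distance")
    dba <- beta_diversity(b, a, "aitchison_distance")
    dac <- beta_diversity(a, c, "aitchison_distance")
    dcb <- beta_diversity(c, b, "aitchison_distance")
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_lte(dab, dac + dcb + 1e-10)
  }
  a <- rcomp(4)
  expect_equal(beta_diversity(a, a, "aitchison_distance"), 0)
})

test_that("only the aitchison distance survives joint perturbation", {
  psi <- make_contrast_matrix("alr", 5)
  tr <- simulate_tree(paste0("taxon_", 1:5), 12)
  set.seed(31)
  devs <- replicate(1000, {
    e1 <- rnorm(4); e2 <- rnorm(4); g <- rnorm(4)
    p <- phi_inverse(e1, psi); q <- phi_inverse(e2, psi)
    pp <- phi_inverse(perturb(e1, g), psi); qp <- phi_inverse(perturb(e2, g), psi)
    c(ait = abs(beta_diversity(pp, qp, "aitchison_distance") -
                beta_diversity(p, q, "aitchison_distance")),
      bray = abs(beta_diversity(pp, qp, "bray_curtis") -
                 beta_diversity(p, q, "bray_curtis")),
      wu = abs(beta_diversity(pp, qp, "weighted_unifrac", tree = tr) -
               beta_diversity(p, q, "weighted_unifrac", tree = tr)))
  })
  expect_lt(max(devs["ait", ]), 1e-10)
  expect_gt(max(devs["bray", ]), 1e-3)
  expect_gt(max(devs["wu", ]), 1e-3)
})

test_that("distance matrices are symmetric and agree elementwise", {
  set.seed(37)
  comps <- replicate(10, rcomp(4), simplify = FALSE)
  dm <- distance_matrix(comps, "bray_curtis", ids = paste0("s", 1:10))
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  for (i in c(1, 4)) for (j in c(2, 9))
    expect_equal(dm[i, j], beta_diversity(comps[[i]], comps[[j]], "bray_curtis"))
  two <- distance_matrix(list(comps[[1]], comps[[1]]), "aitchison_distance")
  expect_equal(two, matrix(0, 2, 2))
})

test_that("newick reading validates and round-trips", {
  f <- tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  tr <- read_newick(f)
  expect_equal(ape::Ntip(tr), 2L)
  expect_setequal(tr$tip.label, c("A", "B"))

  writeLines("((A:1,B:2):0.5,C:3);", f)
  tr3 <- read_newick(f)
  expect_equal(ape::Ntip(tr3), 3L)
  expect_equal(sort(tr3$edge.length), c(0.5, 1, 2, 3))

  tr_rand <- simulate_tree(letters[1:8], 3)
  write_newick(tr_rand, f)
  back <- read_newick(f)
  expect_identical(ape::write.tree(back), ape::write.tree(tr_rand))
  expect_lt(max(abs(sort(back$edge.length) - sort(tr_rand$edge.length))), 1e-9)

  writeLines("(A:1,A:2);", f)
  expect_error(read_newick(f), "duplicate")
  writeLines("(A,B);", f)
  expect_warning(read_newick(f), "branch lengths")
})
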