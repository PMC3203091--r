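test_that("hybrid species tree validates and decomposes into parental trees", {
  expect_error(hybrid_species_tree("H", "H", "P2", "O"), "distinct")
  expect_error(hybrid_species_tree("H", "P1", "P2", "O", t = c(1, 1)), "three")
  expect_error(hybrid_species_tree("H", "P1", "P2", "O", t = c(-1, 1, 1)), "nonnegative")

  S <- hybrid_species_tree("H", "P1", "P2", "O", t = c(1, 1, 1))
  taus <- decompose_parental_trees(S)
  ## tau1 joins the hybrid with parent1 first; node heights 1, 2, 3
  d1 <- ape::node.depth.edgelength(taus$tau1)
  expect_equal(max(d1), 3)
  expect_true(ape::is.ultrametric(taus$tau1))
  mrca1 <- ape::getMRCA(taus$tau1, c("H", "P1"))
  expect_equal(max(d1) - d1[mrca1], 1)
  mrca2 <- ape::getMRCA(taus$tau2, c("H", "P2"))
  d2 <- ape::node.depth.edgelength(taus$tau2)
  expect_equal(max(d2) - d2[mrca2], 1)

  ## swapping the parent designation swaps the parental trees
  Ssw <- hybrid_species_tree("H", "P2", "P1", "O", t = c(1, 1, 1))
  tausw <- decompose_parental_trees(Ssw)
  expect_identical(hybcoal:::.canonical_topology_key(tausw$tau1),
                   hybcoal:::.canonical_topology_key(taus$tau2))

  ## degenerate zero intervals are accepted
  taus0 <- decompose_parental_trees(S, t = c(0, 0, 0))
  expect_equal(max(ape::node.depth.edgelength(taus0$tau1)), 0)

  ## non-uniform intervals place heights at the partial sums
  tausu <- decompose_parental_trees(S, t = c(0.2, 0.5, 1.3))
  du <- ape::node.depth.edgelength(tausu$tau1)
  expect_equal(max(du), 2)
  expect_equal(max(du) - du[ape::getMRCA(tausu$tau1, c("H", "P1"))], 0.2)
  expect_equal(max(du) - du[ape::getMRCA(tausu$tau1, c("H", "P2"))], 0.7)
})

test_that("mixture endpoints reduce to the component probabilities", {
  st <- study_setup(samples = c(H = 1, P1 = 1, P2 = 1, O = 1))
  g <- parse_newick("(((H_1,P1_1),P2_1),O_1);")
  taus <- decompose_parental_trees(st$S)
  p1 <- gene_tree_prob(g, taus$tau1, st$map)
  p2 <- gene_tree_prob(g, taus$tau2, st$map)
  expect_equal(per_gene_mixture_prob(g, 0, st$S$t, st$S, st$map), p2)
  expect_equal(per_gene_mixture_prob(g, 1, st$S$t, st$S, st$map), p1)
  expect_equal(per_gene_mixture_prob(g, 0.37, st$S$t, st$S, st$map),
               0.37 * p1 + 0.63 * p2, tolerance = 1e-12)
  ## a gene tree symmetric in the two parents: flat in gamma
  gs <- parse_newick("(((P1_1,P2_1),H_1),O_1);")
  q1 <- gene_tree_prob(gs, taus$tau1, st$map)
  q2 <- gene_tree_prob(gs, taus$tau2, st$map)
  expect_equal(q1, q2, tolerance = 1e-12)
  for (gam in c(0, 0.25, 0.8)) {
    expect_equal(per_gene_mixture_prob(gs, gam, st$S$t, st$S, st$map), q1,
                 tolerance = 1e-12)
  }
})

test_that("log-likelihood has product structure and parent-swap symmetry", {
  st <- study_setup(samples = c(H = 2, P1 = 1, P2 = 1, O = 1))
  g <- parse_newick("((((H_1,H_2),P1_1),P2_1),O_1);")
  single <- hyb_log_likelihood(0.4, c(1, 1, 1), list(g), st$S, st$map)
  ten <- hyb_log_likelihood(0.4, c(1, 1, 1), replicated_sample(write_newick(g), 10), st$S, st$map)
  expect_equal(ten, 10 * single, tolerance = 1e-9)

  ## L(gamma | P1,P2) == L(1-gamma | P2,P1) across randomized inputs
  Ssw <- hybrid_species_tree("H", "P2", "P1", "O")
  set.seed(99)
  taus <- decompose_parental_trees(st$S)
  for (r in 1:5) {
    D <- lapply(1:4, function(i) {
      simulate_gene_tree(if (i %% 2) taus$tau1 else taus$tau2, st$samples)
    })
    D <- lapply(D, function(tr) { tr$edge.length <- NULL; tr })
    gam <- runif(1)
    tt <- runif(3, 0.1, 2)
    expect_equal(hyb_log_likelihood(gam, tt, D, st$S, st$map),
                 hyb_log_likelihood(1 - gam, tt, D, Ssw, st$map),
                 tolerance = 1e-12)
  }

  expect_error(hyb_log_likelihood(0.5, c(1, 1, 1), list(), st$S, st$map), "empty")
})

test_that("a polytomous gene tree contributes the summed probability of its resolutions", {
  st <- study_setup(samples = c(H = 3, P1 = 1, P2 = 1, O = 1))
  poly <- parse_newick("((((H_1,H_2,H_3),P1_1),P2_1),O_1);")
  res <- resolve_polytomies(poly)
  expect_length(res, 3)
  taus <- decompose_parental_trees(st$S)
  for (tau in taus) {
    p_sum <- sum(vapply(res, gene_tree_prob, 0, species_tree = tau, map = st$map))
    ## likelihood endpoint recovers the summed component
    lnL <- hyb_log_likelihood(if (identical(tau, taus$tau1)) 1 else 0,
                              st$S$t, list(poly), st$S, st$map)
    expect_equal(exp(lnL), p_sum, tolerance = 1e-9)
  }
})

test_that("species tree spec files round-trip", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(hybrid = "H", parent1 = "P1", parent2 = "P2", outgroup = "O",
         t = c(0.5, 1, 1.5)),
    path, auto_unbox = TRUE
  )
  S <- read_species_tree_spec(path)
  expect_s3_class(S, "hyb_species_tree")
  expect_equal(S$t, c(0.5, 1, 1.5))
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(hybrid = "H"), bad, auto_unbox = TRUE)
  expect_error(read_species_tree_spec(bad), "missing fields")
})
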