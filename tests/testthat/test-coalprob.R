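three_taxon_setup <- function(T_int = 1) {
  list(
    sp = ape::read.tree(text = sprintf("((A:1,B:1):%.17g,C:%.17g);", T_int, 1 + T_int)),
    map = taxon_map(c("a", "b", "c"), c("A", "B", "C")),
    conc = parse_newick("((a,b),c);"),
    disc1 = parse_newick("((a,c),b);"),
    disc2 = parse_newick("((b,c),a);")
  )
}

test_that("Tavare lineage-count probabilities match closed forms and expm", {
  expect_equal(tavare_gij(1, 1, 0.3), 1)
  expect_equal(tavare_gij(1, 1, Inf), 1)
  expect_equal(tavare_gij(2, 2, 1), exp(-1), tolerance = 1e-12)
  expect_equal(tavare_gij(2, 1, 0.5), 1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(tavare_gij(5, 1, Inf), 1)
  expect_equal(tavare_gij(5, 3, Inf), 0)
  expect_error(tavare_gij(2, 3, 1), "j <= i")
  expect_error(tavare_gij(2, 1, -1), "T >= 0")

  ## normalization over j and agreement with the matrix-exponential oracle
  for (i in 2:6) {
    for (T in c(0.01, 0.1, 1, 4)) {
      gj <- vapply(1:i, function(j) tavare_gij(i, j, T), 0)
      expect_equal(sum(gj), 1, tolerance = 1e-9)
      for (j in 1:i) {
        expect_lt(abs(gj[j] - oracle_gij(i, j, T)), 1e-9)  # absolute scale
      }
    }
  }
  ## larger i, short T: numerically delicate corner stays sane
  g14 <- vapply(1:14, function(j) tavare_gij(14, j, 1e-4), 0)
  expect_true(all(g14 >= 0))
  expect_equal(sum(g14), 1, tolerance = 1e-8)
})

test_that("three-taxon gene-tree probabilities match the classical closed form", {
  for (T in c(0.2, 1, 3)) {
    s <- three_taxon_setup(T)
    expect_equal(gene_tree_prob(s$conc, s$sp, s$map), 1 - (2 / 3) * exp(-T),
                 tolerance = 1e-9)
    expect_equal(gene_tree_prob(s$disc1, s$sp, s$map), exp(-T) / 3,
                 tolerance = 1e-9)
    expect_equal(gene_tree_prob(s$disc2, s$sp, s$map), exp(-T) / 3,
                 tolerance = 1e-9)
  }
  ## asymptotics: a long internal branch forces concordance
  s <- three_taxon_setup(50)
  expect_equal(gene_tree_prob(s$conc, s$sp, s$map), 1, tolerance = 1e-9)
  ## monotonicity in the internal branch length
  probs <- vapply(seq(0.1, 3, by = 0.29), function(T) {
    s <- three_taxon_setup(T)
    gene_tree_prob(s$conc, s$sp, s$map)
  }, 0)
  expect_true(all(diff(probs) > 0))
})

test_that("history enumeration matches hand counts", {
  s <- three_taxon_setup()
  h_conc <- enumerate_histories(s$conc, s$sp, s$map)
  expect_equal(max(h_conc$history), 2)  # cherry on internal branch or at root
  h_disc <- enumerate_histories(s$disc1, s$sp, s$map)
  expect_equal(max(h_disc$history), 1)  # both coalescences in the root
  expect_true(all(h_disc$species_branch == "A+B+C"))

  one <- enumerate_histories(parse_newick("(x1,x2);"), "X",
                             taxon_map(c("x1", "x2"), c("X", "X")))
  expect_equal(max(one$history), 1)
})

test_that("kernel agrees with the brute-force history oracle", {
  set.seed(11)
  configs <- list(
    list(sp = "((A:0.8,B:0.8):0.6,C:1.4);",
         map = taxon_map(c("a1", "a2", "b1", "c1"), c("A", "A", "B", "C"))),
    list(sp = "((A:0.5,B:0.5):1.2,C:1.7);",
         map = taxon_map(c("a1", "b1", "b2", "c1", "c2"),
                         c("A", "B", "B", "C", "C"))),
    list(sp = "(((A:0.4,B:0.4):0.5,C:0.9):0.7,D:1.6);",
         map = taxon_map(c("a1", "a2", "b1", "c1", "d1"),
                         c("A", "A", "B", "C", "D")))
  )
  for (cf in configs) {
    sp <- ape::read.tree(text = cf$sp)
    inds <- cf$map$individual
    trees <- phangorn::allTrees(length(inds), rooted = TRUE, tip.label = inds)
    pick <- sample(length(trees), 6)
    tot <- 0
    for (k in pick) {
      p_fast <- gene_tree_prob(trees[[k]], sp, cf$map)
      p_slow <- oracle_gene_tree_prob(trees[[k]], sp, cf$map)
      expect_equal(p_fast, p_slow, tolerance = 1e-9)
    }
  }
})

test_that("topology probabilities are a distribution and respect symmetry", {
  s <- three_taxon_setup()
  ap3 <- all_topology_probs(s$sp, s$map)
  expect_equal(nrow(ap3), 3)
  expect_equal(sum(ap3$prob), 1, tolerance = 1e-9)

  sp2 <- ape::read.tree(text = "((A:0.9,B:0.9):0.8,C:1.7);")
  map4 <- taxon_map(c("a1", "b1", "c1", "c2"), c("A", "B", "C", "C"))
  ap4 <- all_topology_probs(sp2, map4)
  expect_equal(nrow(ap4), 15)
  expect_equal(sum(ap4$prob), 1, tolerance = 1e-9)

  ## exchangeable same-species samples: swapping c1/c2 leaves probs unchanged
  swapped <- vapply(ap4$topology, function(nwk) {
    s <- gsub("c1", "cX", nwk, fixed = TRUE)
    s <- gsub("c2", "c1", s, fixed = TRUE)
    s <- gsub("cX", "c2", s, fixed = TRUE)
    gene_tree_prob(parse_newick(s), sp2, map4)
  }, 0)
  expect_equal(unname(swapped), ap4$prob, tolerance = 1e-12)

  ## symmetric species tree + symmetric sampling: label symmetry of probs
  spS <- ape::read.tree(text = "(A:1.1,B:1.1);")
  mapS <- taxon_map(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  apS <- all_topology_probs(spS, mapS)
  expect_equal(sum(apS$prob), 1, tolerance = 1e-9)
  mirrored <- vapply(apS$topology, function(nwk) {
    tr <- parse_newick(chartr("ab", "ba", nwk))
    gene_tree_prob(tr, spS, mapS)
  }, 0)
  expect_equal(unname(mirrored), apS$prob, tolerance = 1e-12)

  expect_error(all_topology_probs(sp2, taxon_map(letters[1:8], rep("A", 8))),
               "max_tips")
})

test_that("changing branch lengths re-evaluates without re-enumeration", {
  coal_cache_clear()
  map <- taxon_map(c("a1", "a2", "b1", "c1"), c("A", "A", "B", "C"))
  g <- parse_newick("(((a1,a2),b1),c1);")
  sp1 <- ape::read.tree(text = "((A:0.8,B:0.8):0.6,C:1.4);")
  sp2 <- ape::read.tree(text = "((A:0.3,B:0.3):2.1,C:2.4);")
  p1 <- gene_tree_prob(g, sp1, map)
  builds_after_first <- coal_cache_stats()$builds
  p2 <- gene_tree_prob(g, sp2, map)
  expect_identical(coal_cache_stats()$builds, builds_after_first)
  expect_gt(coal_cache_stats()$hits, 0)
  expect_false(isTRUE(all.equal(p1, p2)))
})

test_that("kernel topology frequencies match simulation", {
  ## simulator as an independent check of the analytic kernel: 3 configs,
  ## one with several individuals per species
  set.seed(301)
  configs <- list(
    list(sp = "((A:1,B:1):1,C:2);", n = c(A = 1, B = 1, C = 1), reps = 8000),
    list(sp = "(A:0.6,B:0.6);", n = c(A = 2, B = 2), reps = 8000),
    list(sp = "((A:0.7,B:0.7):0.9,C:1.6);", n = c(A = 2, B = 1, C = 1), reps = 8000)
  )
  for (cf in configs) {
    sp <- ape::read.tree(text = cf$sp)
    map <- study_taxon_map_of(cf$n)
    probs <- all_topology_probs(sp, map)
    key_of <- setNames(seq_len(nrow(probs)),
                       vapply(probs$topology, function(x)
                         hybcoal:::.canonical_topology_key(parse_newick(x)), ""))
    counts <- numeric(nrow(probs))
    for (r in seq_len(cf$reps)) {
      tr <- simulate_gene_tree(sp, cf$n)
      k <- key_of[[hybcoal:::.canonical_topology_key(tr)]]
      counts[k] <- counts[k] + 1
    }
    freq <- counts / cf$reps
    se <- sqrt(probs$prob * (1 - probs$prob) / cf$reps)
    expect_true(all(abs(freq - probs$prob) <= 4 * se + 1e-12))
  }
})
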