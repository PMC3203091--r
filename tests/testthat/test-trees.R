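test_that("newick parsing returns topologies and validates input", {
  tr <- parse_newick("((a,b),c);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  expect_true(ape::is.rooted(tr))

  expect_message(
    tr2 <- parse_newick("((a:0.1,b:0.2):0.3,c:0.5);"),
    "discarded"
  )
  expect_null(tr2$edge.length)
  expect_identical(hybcoal:::.canonical_topology_key(tr2),
                   hybcoal:::.canonical_topology_key(tr))

  expect_error(parse_newick("((a,b),c;"), "unclosed")
  expect_error(parse_newick("((a,b)),c;"), "character")
  expect_error(parse_newick("((a,a),c);"), "duplicate")
})

test_that("parse/write round trip preserves topology for random trees", {
  set.seed(42)
  for (n in c(4, 8, 13, 20)) {
    tr <- ape::rtree(n, br = NULL)
    txt <- write_newick(tr)
    back <- parse_newick(txt)
    expect_setequal(
      vapply(hybcoal:::.clade_list(tr), paste, "", collapse = "|"),
      vapply(hybcoal:::.clade_list(back), paste, "", collapse = "|")
    )
  }
})

test_that("taxon maps deduplicate, reject conflicts, and read from TSV", {
  tm <- taxon_map(c("Sca151", "Scter16"), c("catenatus", "tergeminus"))
  expect_equal(nrow(tm), 2)
  tm2 <- taxon_map(c("x", "x", "y"), c("A", "A", "B"))
  expect_equal(nrow(tm2), 2)
  expect_error(taxon_map(c("x", "x"), c("A", "B")), "more than one species")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "ind1\tA", "ind2\tB", "ind2\tB"), path)
  tm3 <- read_taxon_map(path)
  expect_equal(nrow(tm3), 2)
  expect_equal(tm3$species[tm3$individual == "ind2"], "B")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# only a comment", empty)
  expect_error(read_taxon_map(empty), "empty")
})

test_that("semi-strict consensus keeps exactly the compatible clades", {
  t1 <- parse_newick("((a,b),(c,d));")
  expect_identical(
    hybcoal:::.canonical_topology_key(semi_strict_consensus(list(t1, t1))),
    hybcoal:::.canonical_topology_key(t1)
  )
  ## a resolved tree and a compatible partial resolution
  t2 <- parse_newick("((a,b),c,d);")
  cons <- semi_strict_consensus(list(t1, t2))
  expect_identical(hybcoal:::.canonical_topology_key(cons),
                   hybcoal:::.canonical_topology_key(t1))
  ## conflicting resolutions collapse to a star
  u1 <- parse_newick("((a,b),c);")
  u2 <- parse_newick("((a,c),b);")
  star <- semi_strict_consensus(list(u1, u2))
  expect_equal(star$Nnode, 1)
  expect_error(semi_strict_consensus(list(u1, t1)), "tip sets")
})

test_that("semi-strict consensus properties hold on random inputs", {
  set.seed(7)
  labs <- letters[1:6]
  for (rep in 1:10) {
    trees <- replicate(3, {
      tr <- ape::rtree(6, br = NULL)
      tr$tip.label <- sample(labs)
      tr
    }, simplify = FALSE)
    cons <- semi_strict_consensus(trees)
    ## consensus of the multiset equals consensus of the deduplicated set
    cons2 <- semi_strict_consensus(c(trees, trees[1]))
    expect_identical(hybcoal:::.canonical_topology_key(cons),
                     hybcoal:::.canonical_topology_key(cons2))
    ## every consensus clade is compatible with every input tree
    for (cl in hybcoal:::.clade_list(cons)) {
      for (tr in trees) {
        expect_true(hybcoal:::.clade_compatible(cl, hybcoal:::.clade_list(tr)))
      }
    }
  }
})

test_that("polytomy resolution enumerates the right number of binary trees", {
  bin <- parse_newick("((a,b),c);")
  expect_true(is_binary_tree(bin))
  expect_length(resolve_polytomies(bin), 1)

  tri <- parse_newick("(a,b,c);")
  expect_false(is_binary_tree(tri))
  res3 <- resolve_polytomies(tri)
  expect_length(res3, 3)
  expect_true(all(vapply(res3, is_binary_tree, TRUE)))

  quad <- parse_newick("(a,b,c,d);")
  res15 <- resolve_polytomies(quad)
  expect_length(res15, 15)
  expect_length(unique(vapply(res15, hybcoal:::.canonical_topology_key, "")), 15)

  expect_error(resolve_polytomies(quad, max_resolutions = 10), "cap")
})

test_that("resolution classes partition the labelled resolutions", {
  lk <- c(h1 = "H", h2 = "H", h3 = "H", h4 = "H", p = "P")
  poly <- parse_newick("((h1,h2,h3,h4),p);")
  cls <- hybcoal:::.resolution_classes(poly, lk)
  all_res <- resolve_polytomies(poly)
  expect_equal(sum(cls$counts), length(all_res))   # 15 labelled resolutions
  expect_length(cls$counts, 2)                     # caterpillar + balanced
  ## class keys match the species-canonical keys of the labelled resolutions
  keys <- vapply(all_res, hybcoal:::.species_canonical_key, "", lk = lk)
  expect_setequal(cls$keys, unique(keys))
  expect_equal(sort(as.integer(cls$counts)), sort(as.integer(table(keys))))
})

test_that("outgroup rooting recovers a rooted topology", {
  tm <- taxon_map(c("a1", "a2", "b1", "o1"), c("A", "A", "B", "O"))
  unr <- ape::unroot(parse_newick("(((a1,a2),b1),o1);"))
  rt <- root_with_outgroup(unr, tm, "O")
  expect_true(ape::is.rooted(rt))
  kids <- hybcoal:::.clade_list(rt)
  expect_true(any(vapply(kids, function(x) identical(x, c("a1", "a2")), TRUE)))
})
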