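#' Parse a newick tree
#'
#' Parses a single rooted newick statement into an `ape::phylo` object.
#' Branch lengths are not part of the gene-tree data model (only topologies
#' enter the likelihood), so lengths present in the input are discarded with
#' a notice unless `expect_branch_lengths = TRUE`.
#'
#' @param text A single well-formed newick statement (terminating `;`
#'   optional).
#' @param expect_branch_lengths Keep branch lengths if present?
#' @return A `phylo` object.
#' @export
#' @examples
#' parse_newick("((a,b),c);")
parse_newick <- function(text, expect_branch_lengths = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  .check_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = if (grepl(";", text, fixed = TRUE)) text else paste0(text, ";")),
    error = function(e) abort(paste0("malformed newick: ", conditionMessage(e)))
  )
  if (is.null(phy)) abort("malformed newick: could not be parsed")
  if (inherits(phy, "multiPhylo")) abort("expected a single newick statement")
  if (anyDuplicated(phy$tip.label)) {
    abort(paste0("duplicate tip labels: ",
                 paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", ")))
  }
  if (!is.null(phy$edge.length) && !expect_branch_lengths) {
    message("branch lengths present in newick input were discarded")
    phy$edge.length <- NULL
  }
  phy
}

## cheap structural pre-check so that unbalanced input reports an offset
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  closed <- FALSE
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      if (closed) abort(paste0("malformed newick: content after the outermost group at character ", k))
      depth <- depth + 1L
    }
    if (chars[k] == ",") {
      if (closed || depth == 0L) {
        abort(paste0("malformed newick: separator outside any group at character ", k))
      }
    }
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L) abort(paste0("malformed newick: unmatched ')' at character ", k))
      if (depth == 0L) closed <- TRUE
    }
  }
  if (depth != 0L) {
    abort(paste0("malformed newick: ", depth, " unclosed '(' at end of input (length ",
                 length(chars), ")"))
  }
  invisible(NULL)
}

#' Write a tree as newick
#'
#' @param phy A `phylo` object.
#' @param file Optional path; if omitted the newick string is returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_newick <- function(phy, file = NULL) {
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a multi-tree newick file
#'
#' Accepts one tree per line or several `;`-separated statements; branch
#' lengths are discarded (gene trees are used as topologies only).
#'
#' @param path Path to a newick file.
#' @return A `multiPhylo` list of rooted gene-tree topologies.
#' @export
read_gene_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  stmts <- unlist(strsplit(paste(lines, collapse = "\n"), ";", fixed = TRUE))
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  if (!length(stmts)) abort(paste0("no trees found in ", path))
  trees <- lapply(stmts, function(s) suppressMessages(parse_newick(paste0(s, ";"))))
  class(trees) <- "multiPhylo"
  trees
}

#' Construct or read a taxon map
#'
#' A taxon map assigns each sampled individual (a gene-tree tip label) to a
#' species (a species-tree tip label); it is the bridge that lets several
#' lineages per species enter the coalescent computation.
#'
#' `taxon_map()` builds one from vectors, `read_taxon_map()` from a
#' two-column TSV (`individual<TAB>species`, `#`-comments allowed).
#' Identical repeated rows are deduplicated; the same individual mapped to
#' two species is an error.
#'
#' @param individual,species Character vectors of equal length.
#' @return A tibble with columns `individual` and `species`.
#' @export
#' @examples
#' taxon_map(c("a1", "a2", "b1"), c("A", "A", "B"))
taxon_map <- function(individual, species) {
  stopifnot(length(individual) == length(species))
  if (!length(individual)) abort("taxon map is empty")
  tm <- tibble::tibble(individual = as.character(individual),
                       species = as.character(species))
  tm <- dplyr::distinct(tm)
  dup <- tm$individual[duplicated(tm$individual)]
  if (length(dup)) {
    abort(paste0("individual(s) mapped to more than one species: ",
                 paste(unique(dup), collapse = ", ")))
  }
  tm
}

#' @param path Path to a two-column TSV file.
#' @rdname taxon_map
#' @export
read_taxon_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) abort(paste0("taxon map file is empty: ", path))
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad)) abort(paste0("taxon map line ", bad[1], " does not have two columns"))
  taxon_map(vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2))
}

## named character vector species[individual]; accepts tibble or named vector
.map_lookup <- function(map) {
  if (is.character(map) && !is.null(names(map))) return(map)
  if (is.data.frame(map)) {
    stopifnot(all(c("individual", "species") %in% names(map)))
    return(setNames(as.character(map$species), map$individual))
  }
  abort("taxon map must be a taxon_map tibble or a named character vector")
}

#' Root a gene tree using an outgroup species
#'
#' Re-roots a tree on the edge separating the individuals of the named
#' outgroup species from everything else. If the outgroup individuals are
#' not monophyletic in the unrooted tree, the tree is rooted at the first
#' outgroup individual instead (with a warning), so that a rooted topology
#' is always returned.
#'
#' @param phy A `phylo` object.
#' @param map A taxon map (see [taxon_map()]).
#' @param outgroup_species Species label whose individuals root the tree.
#' @return A rooted `phylo` object.
#' @export
root_with_outgroup <- function(phy, map, outgroup_species) {
  lk <- .map_lookup(map)
  outs <- phy$tip.label[lk[phy$tip.label] %in% outgroup_species]
  if (!length(outs)) abort(paste0("no individuals of species ", outgroup_species, " in tree"))
  rooted <- tryCatch(
    ape::root(phy, outgroup = outs, resolve.root = TRUE),
    error = function(e) NULL
  )
  if (is.null(rooted) || !ape::is.rooted(rooted)) {
    warn(paste0("outgroup '", outgroup_species,
                "' not monophyletic; rooting at individual ", outs[1]))
    rooted <- ape::root(phy, outgroup = outs[1], resolve.root = TRUE)
  }
  rooted
}

#' Semi-strict (combinable-component) consensus
#'
#' Returns the consensus tree containing every clade that appears in at
#' least one input tree and is compatible with all of them. This is the
#' consensus used to summarise ties in maximum-likelihood gene-tree
#' estimation; it may contain polytomies.
#'
#' @param trees A list/`multiPhylo` of rooted trees on identical tip sets.
#' @return A rooted `phylo` topology.
#' @export
#' @examples
#' t1 <- parse_newick("((a,b),c);")
#' t2 <- parse_newick("((a,c),b);")
#' write_newick(semi_strict_consensus(list(t1, t2)))  # star
semi_strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) abort("need at least one tree")
  tipset <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), tipset)) abort("trees have differing tip sets")
  }
  clade_sets <- lapply(trees, .clade_list)
  cand <- unique(unlist(clade_sets, recursive = FALSE))
  keep <- cand[vapply(cand, function(cl) {
    all(vapply(clade_sets, function(cs) .clade_compatible(cl, cs), logical(1)))
  }, logical(1))]
  .tree_from_clades(tipset, keep)
}

## clades as sorted character vectors of tip labels, one per internal node
.clade_list <- function(phy) {
  nt <- ape::Ntip(phy)
  kids <- .children_list(phy)
  out <- vector("list", phy$Nnode)
  rec <- function(v) {
    if (v <= nt) return(phy$tip.label[v])
    tips <- sort(unlist(lapply(kids[[v]], rec)))
    out[[v - nt]] <<- tips
    tips
  }
  rec(nt + 1L)
  out
}

## clade (label vector) vs a tree's clade list: compatible iff for each
## clade X of the tree, intersect(C, X) is empty, C, or X
.clade_compatible <- function(cl, clade_set) {
  for (x in clade_set) {
    i <- length(intersect(cl, x))
    if (i > 0 && i < length(cl) && i < length(x)) return(FALSE)
  }
  TRUE
}

## build a rooted tree from a laminar family of clades over tipset
.tree_from_clades <- function(tipset, clades) {
  clades <- unique(c(clades, list(tipset)))
  clades <- clades[order(-lengths(clades))]
  expand <- function(cl) {
    if (length(cl) == 1) return(cl)
    inside <- clades[vapply(clades, function(x) {
      length(x) < length(cl) && all(x %in% cl)
    }, logical(1))]
    ## maximal proper sub-clades
    maximal <- inside[vapply(seq_along(inside), function(k) {
      !any(vapply(inside[-k], function(y) {
        length(y) > length(inside[[k]]) && all(inside[[k]] %in% y)
      }, logical(1)))
    }, logical(1))]
    maximal <- unique(maximal)
    covered <- unlist(maximal)
    singles <- setdiff(cl, covered)
    parts <- c(vapply(maximal, expand, ""), singles)
    paste0("(", paste(sort(parts), collapse = ","), ")")
  }
  txt <- expand(tipset)
  if (!grepl("^\\(", txt)) txt <- paste0("(", txt, ")")
  ape::read.tree(text = paste0(txt, ";"))
}

#' Test whether a rooted tree is fully bifurcating
#'
#' @param phy A `phylo` object.
#' @return Logical flag.
#' @export
is_binary_tree <- function(phy) {
  ## rooted reading: every internal node has exactly two children (ape's
  ## is.binary would accept a basal trifurcation as binary-unrooted)
  phy$Nnode == ape::Ntip(phy) - 1L &&
    all(tabulate(phy$edge[, 1], nbins = ape::Ntip(phy) + phy$Nnode) %in% c(0L, 2L))
}

#' Enumerate all binary resolutions of a (possibly multifurcating) tree
#'
#' Every polytomy is expanded into all of its rooted binary resolutions;
#' the resolutions of separate polytomies combine multiplicatively. A binary
#' input returns itself. Used when a consensus gene tree (from tied
#' maximum-likelihood estimates) must be consumed by the likelihood, which
#' is defined on binary topologies.
#'
#' @param phy A rooted `phylo` object.
#' @param max_resolutions Hard cap on the number of resolutions; exceeding
#'   it is an error (re-estimate the gene tree rather than enumerate).
#' @return A list of binary `phylo` topologies.
#' @export
#' @examples
#' length(resolve_polytomies(parse_newick("(a,b,c);")))  # 3
resolve_polytomies <- function(phy, max_resolutions = 1000) {
  nt <- ape::Ntip(phy)
  kids <- .children_list(phy)
  total <- 1
  for (v in (nt + 1L):(nt + phy$Nnode)) {
    k <- length(kids[[v]])
    if (k > 2) total <- total * .count_rooted_shapes(k)
    if (total > max_resolutions) {
      abort(paste0("polytomy resolution count exceeds cap (", max_resolutions,
                   "); re-estimate the gene tree instead"))
    }
  }
  rec <- function(v) {
    if (v <= nt) return(phy$tip.label[v])
    parts <- lapply(kids[[v]], rec)  # each: character vector of alternatives
    combos <- .cross_strings(parts)
    out <- character(0)
    for (cmb in combos) out <- c(out, .binary_joins(cmb))
    out
  }
  lapply(rec(nt + 1L), function(s) ape::read.tree(text = paste0(s, ";")))
}

.count_rooted_shapes <- function(k) {
  if (k <= 2) return(1)
  prod(seq(3, 2 * k - 3, by = 2))  # (2k-3)!!
}

## cartesian product of lists of strings, as list of character vectors
.cross_strings <- function(parts) {
  combos <- list(character(0))
  for (p in parts) {
    combos <- unlist(lapply(combos, function(c0) lapply(p, function(x) c(c0, x))),
                     recursive = FALSE)
  }
  combos
}

## all rooted binary joins of k subtree strings
.binary_joins <- function(items) {
  k <- length(items)
  if (k == 1) return(items)
  if (k == 2) return(paste0("(", items[1], ",", items[2], ")"))
  out <- character(0)
  idx <- seq_len(k)
  ## split: left part contains item 1 to avoid double counting
  for (sz in 1:(k - 1)) {
    lefts <- if (sz == 1) list(1L) else {
      cs <- combn(idx[-1], sz - 1)
      lapply(seq_len(ncol(cs)), function(j) c(1L, cs[, j]))
    }
    for (L in lefts) {
      lt <- .binary_joins(items[L])
      rt <- .binary_joins(items[-L])
      for (a in lt) for (b in rt) out <- c(out, paste0("(", a, ",", b, ")"))
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Resolution classes: distinct species-relabelled binary resolutions of a
## polytomous gene tree, with multiplicities. Since the coalescent topology
## probability is invariant under permuting same-species individuals, the
## likelihood needs one representative per class weighted by its count,
## not the full (often huge) set of labelled resolutions.

.resolution_classes <- function(phy, lk, max_classes = 1000) {
  nt <- ape::Ntip(phy)
  kids <- .children_list(phy)
  rec <- function(v) {
    if (v <= nt) {
      return(list(ind = phy$tip.label[v], sp = unname(lk[[phy$tip.label[v]]]), cnt = 1))
    }
    ch_classes <- lapply(kids[[v]], rec)
    combos <- list(list(ind = character(0), sp = character(0), cnt = 1))
    for (cc in ch_classes) {
      new <- vector("list", length(combos) * length(cc$ind))
      r <- 0L
      for (c0 in combos) {
        for (a in seq_along(cc$ind)) {
          r <- r + 1L
          new[[r]] <- list(ind = c(c0$ind, cc$ind[a]), sp = c(c0$sp, cc$sp[a]),
                           cnt = c0$cnt * cc$cnt[a])
        }
      }
      combos <- new
      if (length(combos) > 4 * max_classes) {
        abort("polytomy resolution classes exceed cap; re-estimate the gene tree")
      }
    }
    dict <- new.env(parent = emptyenv())
    a_ind <- character(0); a_sp <- character(0); a_cnt <- numeric(0)
    for (c0 in combos) {
      jc <- .join_classes(c0$ind, c0$sp, maxc = 4 * max_classes)
      for (a in seq_along(jc$ind)) {
        id <- dict[[jc$sp[a]]]
        if (is.null(id)) {
          a_ind <- c(a_ind, jc$ind[a]); a_sp <- c(a_sp, jc$sp[a])
          a_cnt <- c(a_cnt, 0); id <- length(a_cnt)
          assign(jc$sp[a], id, envir = dict)
        }
        a_cnt[id] <- a_cnt[id] + c0$cnt * jc$cnt[a]
      }
      if (length(a_ind) > max_classes) {
        abort("polytomy resolution classes exceed cap; re-estimate the gene tree")
      }
    }
    list(ind = a_ind, sp = a_sp, cnt = a_cnt)
  }
  top <- rec(nt + 1L)
  list(trees = lapply(top$ind, function(s) ape::read.tree(text = paste0(s, ";"))),
       counts = top$cnt, keys = paste0(top$sp, ";"))
}

## all rooted binary joins of k labelled subtrees, grouped by their
## species-canonical form. Subtrees with identical species form are
## interchangeable, so the enumeration runs over multisets of class counts
## (memoized), with multinomial factors counting the labelled assignments;
## a labelled representative is assembled afterwards from per-class pools.
.join_classes <- function(ind, sp, maxc = 10000) {
  k <- length(ind)
  cls <- unique(sp)
  if (length(cls) > 9) {
    abort("polytomy too heterogeneous to resolve; re-estimate the gene tree")
  }
  cid <- match(sp, cls)
  m0 <- tabulate(cid, nbins = length(cls))
  pools <- split(ind, cid)
  memo <- new.env(parent = emptyenv())

  rec <- function(m) {
    key <- paste(m, collapse = ",")
    out <- memo[[key]]
    if (!is.null(out)) return(out)
    if (sum(m) == 1) {
      c1 <- which(m == 1)
      out <- list(list(sp = cls[c1], node = c1, cnt = 1))
    } else {
      c0 <- which(m > 0)[1]
      dict <- new.env(parent = emptyenv())
      acc <- list()
      ## left sub-multisets containing one designated item of class c0
      subs <- .sub_multisets(m, c0)
      for (m1 in subs) {
        m2 <- m - m1
        if (sum(m2) == 0) next
        ways <- choose(m[c0] - 1, m1[c0] - 1)
        for (c in seq_along(m)) if (c != c0) ways <- ways * choose(m[c], m1[c])
        lcl <- rec(m1)
        rcl <- rec(m2)
        for (a in lcl) {
          for (b in rcl) {
            if (a$sp <= b$sp) {
              spk <- paste0("(", a$sp, ",", b$sp, ")")
              node <- list(a$node, b$node)
            } else {
              spk <- paste0("(", b$sp, ",", a$sp, ")")
              node <- list(b$node, a$node)
            }
            id <- dict[[spk]]
            if (is.null(id)) {
              acc[[length(acc) + 1]] <- list(sp = spk, node = node, cnt = 0)
              id <- length(acc)
              assign(spk, id, envir = dict)
            }
            acc[[id]]$cnt <- acc[[id]]$cnt + ways * a$cnt * b$cnt
          }
        }
        if (length(acc) > maxc) {
          abort("polytomy resolution classes exceed cap; re-estimate the gene tree")
        }
      }
      out <- acc
    }
    assign(key, out, envir = memo)
    out
  }

  classes <- rec(m0)
  ## build one labelled representative per class by assigning pool items
  build <- function(node, used) {
    if (!is.list(node)) {
      used[node] <- used[node] + 1L
      return(list(s = pools[[node]][used[node]], used = used))
    }
    l <- build(node[[1]], used)
    r <- build(node[[2]], l$used)
    list(s = paste0("(", l$s, ",", r$s, ")"), used = r$used)
  }
  ind_out <- character(length(classes))
  for (q in seq_along(classes)) {
    ind_out[q] <- build(classes[[q]]$node, integer(length(cls)))$s
  }
  list(ind = ind_out,
       sp = vapply(classes, function(x) x$sp, ""),
       cnt = vapply(classes, function(x) x$cnt, 0))
}

## sub-multisets m1 <= m with m1[c0] >= 1 (the designated item's class)
.sub_multisets <- function(m, c0) {
  ranges <- lapply(seq_along(m), function(c) if (c == c0) 1:m[c] else 0:m[c])
  grid <- do.call(expand.grid, ranges)
  lapply(seq_len(nrow(grid)), function(r) as.integer(grid[r, ]))
}
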