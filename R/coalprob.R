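#' Tavare's lineage-count probability
#'
#' Probability that `i` gene lineages entering a population are reduced to
#' exactly `j` lineages after time `T`, with time in coalescent units (2Ne
#' generations; each pair coalesces at rate 1 per unit). `T = Inf` gives 1
#' if `j == 1` and 0 otherwise, which is how the species-tree root branch is
#' handled.
#'
#' @param i Number of entering lineages (>= 1).
#' @param j Number of leaving lineages, in `[1, i]`.
#' @param T Nonnegative duration in coalescent units, possibly `Inf`.
#' @return The probability, a scalar in `[0, 1]`.
#' @export
#' @examples
#' tavare_gij(2, 2, 1)  # exp(-1)
tavare_gij <- function(i, j, T) {
  stopifnot(length(i) == 1, length(j) == 1, length(T) == 1)
  if (i < 1 || j < 1 || j > i) abort("need 1 <= j <= i")
  if (is.na(T) || T < 0) abort("need T >= 0")
  .gij_matrix(i, T)[i, j]
}

## Tavare (1984) spectral form: g_ij(T) = sum_k a_{ijk} exp(-k(k-1)T/2).
## Coefficients depend only on (i, j, k); cached as triplets up to the
## largest i requested so far, with a grouping index for fast rowsum.
.tavare_coef <- function(imax) {
  tc <- .hyb_cache$tavare
  if (!is.null(tc) && tc$imax >= imax) return(tc)
  ii <- integer(0); jj <- integer(0); kk <- integer(0); aa <- numeric(0)
  for (i in seq_len(imax)) {
    for (j in seq_len(i)) {
      for (k in j:i) {
        pr <- 1
        for (y in 0:(k - 1)) pr <- pr * (j + y) * (i - y) / (i + y)
        co <- (2 * k - 1) * (-1)^(k - j) /
          (factorial(j) * factorial(k - j) * (j + k - 1))
        ii <- c(ii, i); jj <- c(jj, j); kk <- c(kk, k); aa <- c(aa, co * pr)
      }
    }
  }
  grp <- (jj - 1L) * imax + ii  # column-major cell index in an imax x imax matrix
  tc <- list(imax = imax, i = ii, j = jj, k = kk, a = aa,
             grp = grp, rate = kk * (kk - 1) / 2)
  .hyb_cache$tavare <- tc
  tc
}

## full lower-triangular matrix G[i, j] = g_ij(T) for all i <= imax,
## memoized on (imax, T): the optimizer revisits durations constantly
.gij_matrix <- function(imax, T) {
  memo <- .hyb_cache$gij
  if (is.null(memo)) {
    memo <- new.env(parent = emptyenv())
    .hyb_cache$gij <- memo
    .hyb_cache$gij_n <- 0L
  }
  key <- sprintf("%d|%.17g", imax, T)
  G <- memo[[key]]
  if (!is.null(G)) return(G)
  G <- .gij_matrix_raw(imax, T)
  if (.hyb_cache$gij_n < 20000L) {
    assign(key, G, envir = memo)
    .hyb_cache$gij_n <- .hyb_cache$gij_n + 1L
  }
  G
}

.gij_matrix_raw <- function(imax, T) {
  tc <- .tavare_coef(max(imax, 2L))
  keep <- tc$i <= imax
  ek <- if (is.finite(T)) exp(-tc$rate[keep] * T) else as.numeric(tc$k[keep] == 1)
  vals <- tc$a[keep] * ek
  grp <- (tc$j[keep] - 1L) * imax + tc$i[keep]
  G <- matrix(0, imax, imax)
  agg <- rowsum(vals, grp)
  G[as.integer(rownames(agg))] <- agg
  G[G < 0] <- 0
  G[G > 1] <- 1
  G
}

## ---------------------------------------------------------------------------

## validate and prepare the (gene tree, species tree, map) triple
.coal_inputs <- function(g, species_tree, map) {
  lk <- .map_lookup(map)
  miss <- setdiff(g$tip.label, names(lk))
  if (length(miss)) {
    abort(paste0("individuals missing from taxon map: ", paste(miss, collapse = ", ")))
  }
  sp <- .prep_species(species_tree)
  spec <- lk[g$tip.label]
  bad <- setdiff(unique(spec), sp$labels)
  if (length(bad)) {
    abort(paste0("species not in species tree: ", paste(bad, collapse = ", ")))
  }
  list(lk = lk, sp = sp, tipspec = match(spec, sp$labels))
}

## cached transition structure for one (gene topology, species topology, map)
.gene_structure <- function(gphy, spphy, map) {
  lk <- .map_lookup(map)
  ## keyed on the species-relabelled canonical topology: permuting
  ## same-species individuals leaves the probability unchanged, so
  ## equivalent gene trees share one cached structure
  key <- paste0(.species_canonical_key(gphy, lk), "|", .canonical_topology_key(spphy))
  .cache_get_or_build(key, function() {
    inp <- .coal_inputs(gphy, spphy, map)
    gp <- .prep_gene(gphy)
    sp <- inp$sp
    skids <- lapply(sp$kids, function(k) if (is.null(k)) integer(0) else as.integer(k))
    coal_build_structure(gp$ntip, gp$nnode, gp$kids, gp$parent,
                         sp$ntip, skids, as.integer(sp$postorder),
                         as.integer(sp$root), as.integer(inp$tipspec))
  })
}

## evaluate a cached structure at the durations stored in spphy
.eval_structure_prob <- function(str, spphy) {
  sp <- .prep_species(spphy)
  imax <- max(2L, str$max_i)
  n <- sp$ntip + sp$nnode
  Gs <- vector("list", n)
  seen <- list()
  for (v in sp$postorder) {
    key <- sprintf("%.17g", sp$dur[v])
    if (is.null(seen[[key]])) seen[[key]] <- .gij_matrix(imax, sp$dur[v])
    Gs[[v]] <- seen[[key]]
  }
  skids <- lapply(sp$kids, function(k) if (is.null(k)) integer(0) else as.integer(k))
  p <- coal_eval_structure(str, Gs, skids)
  min(max(p, 0), 1)
}

#' Probability of a rooted gene-tree topology under the multispecies coalescent
#'
#' Computes `P(g | species tree)` for a rooted binary gene-tree topology on
#' sampled individuals, given a rooted species tree with branch lengths in
#' coalescent units and a taxon map, by summing over coalescent histories.
#' The history bookkeeping depends only on topologies and is cached, so
#' re-evaluation at different branch lengths is cheap (see
#' [coal_cache_stats()]).
#'
#' For the degenerate single-population case `species_tree` may be a single
#' species name; every lineage then coalesces in one population of infinite
#' duration and only the topological ordering probability remains.
#'
#' @param g A rooted binary `phylo` gene-tree topology.
#' @param species_tree A rooted binary `phylo` with branch lengths in
#'   coalescent units (the root branch is implicitly infinite), or a single
#'   species name.
#' @param map A taxon map (see [taxon_map()]).
#' @return The topology probability, in `[0, 1]`.
#' @export
#' @examples
#' sp <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' tm <- taxon_map(c("a", "b", "c"), c("A", "B", "C"))
#' gene_tree_prob(parse_newick("((a,b),c);"), sp, tm)  # 1 - 2/3 * exp(-1)
gene_tree_prob <- function(g, species_tree, map) {
  if (!ape::is.rooted(g)) abort("gene tree must be rooted")
  if (!is_binary_tree(g)) abort("gene tree must be binary; see resolve_polytomies()")
  if (is.character(species_tree) && length(species_tree) == 1) {
    return(.single_population_prob(g, species_tree, map))
  }
  str <- .gene_structure(g, species_tree, map)
  .eval_structure_prob(str, species_tree)
}

## all lineages in one population: P(topology) = (#orderings consistent with
## g) / (#sequences of n-1 coalescences) = linext(all nodes) / d(n, 1)
.single_population_prob <- function(g, species, map) {
  lk <- .map_lookup(map)
  spec <- lk[g$tip.label]
  if (any(is.na(spec)) || !all(spec == species)) {
    abort("all individuals must map to the single population's species")
  }
  gp <- .prep_gene(g)
  nodes <- gp$ntip + seq_len(gp$nnode)
  desc <- vapply(nodes, function(a) {
    sum(vapply(nodes, function(b) {
      x <- b
      repeat {
        if (x == a) return(TRUE)
        x <- gp$parent[x]
        if (x == 0) return(FALSE)
      }
    }, logical(1)))
  }, numeric(1))
  w <- factorial(gp$nnode) / prod(desc)
  d <- prod(choose(2:gp$ntip, 2))
  w / d
}

#' Enumerate coalescent histories
#'
#' A coalescent history assigns each gene-tree coalescence (internal node)
#' to the species-tree branch on which it occurs. Valid assignments place a
#' node at or above the species-tree population ancestral to all species of
#' its descendant individuals, and at or above the branches of its child
#' nodes. This direct enumeration is intended for inspection and for small
#' problems; [gene_tree_prob()] uses an equivalent but aggregated dynamic
#' program.
#'
#' @inheritParams gene_tree_prob
#' @param max_histories Error out if the enumeration would exceed this many
#'   histories.
#' @return A tibble with columns `history` (integer id), `gene_node` (the
#'   clade of individuals below the coalescence), and `species_branch` (the
#'   species clade labelling the branch the coalescence occurs on).
#' @export
enumerate_histories <- function(g, species_tree, map, max_histories = 100000) {
  if (!ape::is.rooted(g)) abort("gene tree must be rooted")
  if (!is_binary_tree(g)) abort("gene tree must be binary")
  single <- is.character(species_tree) && length(species_tree) == 1
  if (single) {
    gp <- .prep_gene(g)
    lab <- .gene_clade_labels(g)
    .single_population_prob(g, species_tree, map)  # validates the map
    return(tibble::tibble(
      history = 1L,
      gene_node = lab[gp$ntip + seq_len(gp$nnode)],
      species_branch = species_tree
    ))
  }
  inp <- .coal_inputs(g, species_tree, map)
  sp <- inp$sp
  gp <- .prep_gene(g)
  spar <- .parent_vector(species_tree)
  splab <- .species_clade_labels(sp)
  glab <- .gene_clade_labels(g)

  ## species composition below each gene node
  n_g <- gp$ntip + gp$nnode
  gspec <- vector("list", n_g)
  for (t in seq_len(gp$ntip)) gspec[[t]] <- inp$tipspec[t]
  ord <- .gene_postorder(gp)
  for (v in ord) {
    if (v > gp$ntip) {
      gspec[[v]] <- sort(unique(c(gspec[[gp$kids[v - gp$ntip, 1]]],
                                  gspec[[gp$kids[v - gp$ntip, 2]]])))
    }
  }
  ## species tips below each species node
  n_s <- sp$ntip + sp$nnode
  under <- vector("list", n_s)
  for (v in sp$postorder) {
    under[[v]] <- if (v <= sp$ntip) v else
      sort(unique(unlist(under[sp$kids[[v]]])))
  }
  ## minimal admissible species node per gene node, then its ancestor chain
  mrca_of <- function(specset) {
    best <- sp$root
    for (v in sp$postorder) {
      if (all(specset %in% under[[v]]) && length(under[[v]]) < length(under[[best]])) best <- v
    }
    best
  }
  chain_up <- function(v) {
    out <- v
    while (v != sp$root) { v <- spar[v]; out <- c(out, v) }
    out
  }
  inodes <- gp$ntip + seq_len(gp$nnode)
  allowed <- lapply(inodes, function(v) chain_up(mrca_of(gspec[[v]])))
  names(allowed) <- as.character(inodes)
  depth <- integer(n_s)   # root depth 0, increasing tip-ward
  calc_depth <- function(v, d) {
    depth[v] <<- d
    for (k in sp$kids[[v]]) calc_depth(k, d + 1L)
  }
  calc_depth(sp$root, 0L)

  ## DFS over gene internal nodes in postorder, child branches constrain parents
  ord_i <- ord[ord > gp$ntip]
  assign_now <- integer(n_g)
  results <- list()
  rec <- function(k) {
    if (length(results) > max_histories) abort("history count exceeds max_histories")
    if (k > length(ord_i)) {
      results[[length(results) + 1L]] <<- assign_now[ord_i]
      return(invisible(NULL))
    }
    v <- ord_i[k]
    ch <- gp$kids[v - gp$ntip, ]
    maxdepth <- n_s
    for (c in ch) {
      if (c > gp$ntip) maxdepth <- min(maxdepth, depth[assign_now[c]])
    }
    for (b in allowed[[as.character(v)]]) {
      if (depth[b] > maxdepth) next  # must be at or above children's branches
      ## also require b is an ancestor-or-equal of child branches, not a cousin
      ok <- TRUE
      for (c in ch) {
        if (c > gp$ntip) {
          x <- assign_now[c]
          anc <- FALSE
          while (TRUE) {
            if (x == b) { anc <- TRUE; break }
            if (x == sp$root) break
            x <- spar[x]
          }
          if (!anc) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assign_now[v] <<- b
      rec(k + 1L)
    }
  }
  rec(1L)
  if (!length(results)) abort("no valid coalescent history (inconsistent inputs)")
  purrr::map_dfr(seq_along(results), function(h) {
    tibble::tibble(history = h,
                   gene_node = glab[ord_i],
                   species_branch = splab[results[[h]]])
  })
}

.gene_postorder <- function(gp) {
  root <- gp$ntip + 1L
  stack <- root
  visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    if (v > gp$ntip) stack <- c(stack, gp$kids[v - gp$ntip, ])
  }
  rev(visit)
}

.gene_clade_labels <- function(phy) {
  nt <- ape::Ntip(phy)
  kids <- .children_list(phy)
  lab <- character(nt + phy$Nnode)
  rec <- function(v) {
    if (v <= nt) {
      lab[v] <<- phy$tip.label[v]
      return(phy$tip.label[v])
    }
    tips <- sort(unlist(lapply(kids[[v]], rec)))
    lab[v] <<- paste(tips, collapse = "+")
    tips
  }
  rec(nt + 1L)
  lab
}

#' Probabilities of all rooted gene-tree topologies
#'
#' Enumerates every rooted binary labelled topology on the sampled
#' individuals and computes each topology's probability; the probabilities
#' sum to one, which is the normalization check used throughout the test
#' suite.
#'
#' @inheritParams gene_tree_prob
#' @param max_tips Refuse configurations with more individuals than this
#'   (the number of topologies is (2n-3)!!).
#' @return A tibble with columns `topology` (newick) and `prob`, ordered as
#'   enumerated.
#' @export
all_topology_probs <- function(species_tree, map, max_tips = 7) {
  lk <- .map_lookup(map)
  inds <- names(lk)
  if (length(inds) > max_tips) {
    abort(paste0("configuration has ", length(inds), " individuals; max_tips = ", max_tips))
  }
  trees <- phangorn::allTrees(length(inds), rooted = TRUE, tip.label = inds)
  tibble::tibble(
    topology = vapply(trees, function(tr) ape::write.tree(tr), ""),
    prob = vapply(trees, function(tr) gene_tree_prob(tr, species_tree, lk), 0)
  )
}
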