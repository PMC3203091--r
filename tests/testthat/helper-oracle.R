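# Independent brute-force oracle for gene-tree topology probabilities.
# Deliberately shares no code path with the package kernel: histories are
# enumerated as raw assignments, within-branch ordering counts come from
# explicit permutation enumeration, and the lineage-count probabilities
# come from the matrix exponential of the pure-death coalescent generator.

# g_ij(T) via expm of the death chain on {i, i-1, ..., 1}
oracle_gij <- function(i, j, T) {
  if (i == j && !is.infinite(T)) return(exp(-choose(i, 2) * T))
  if (is.infinite(T)) return(as.numeric(j == 1))
  if (i == 1) return(as.numeric(j == 1))
  Q <- matrix(0, i, i)
  for (k in 2:i) {
    rate <- choose(k, 2)
    Q[k, k] <- -rate
    Q[k, k - 1] <- rate
  }
  P <- as.matrix(Matrix::expm(Q * T))
  P[i, j]
}

# number of orderings of the node set A (children before parents) by
# explicit permutation enumeration; |A| must be small
oracle_orderings <- function(A, parent) {
  if (length(A) <= 1) return(max(1, length(A)))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  cnt <- 0
  for (p in perms(A)) {
    ok <- TRUE
    for (pos in seq_along(p)) {
      anc <- parent[p[pos]]
      while (anc != 0) {
        if (anc %in% p[seq_len(pos - 1)]) { ok <- FALSE; break }
        anc <- parent[anc]
      }
      if (!ok) break
    }
    # children must come before parents: a node may not appear after any of
    # its ancestors... invert: check each node's ancestors appear later
    if (ok) cnt <- cnt + 1
  }
  cnt
}

# probability of one rooted binary gene tree by naive history enumeration
oracle_gene_tree_prob <- function(gphy, spphy, map) {
  lk <- if (is.data.frame(map)) setNames(map$species, map$individual) else map
  gnt <- ape::Ntip(gphy)
  gkids <- vector("list", gnt + gphy$Nnode)
  for (e in seq_len(nrow(gphy$edge))) {
    gkids[[gphy$edge[e, 1]]] <- c(gkids[[gphy$edge[e, 1]]], gphy$edge[e, 2])
  }
  gparent <- integer(gnt + gphy$Nnode)
  gparent[gphy$edge[, 2]] <- gphy$edge[, 1]

  snt <- ape::Ntip(spphy)
  skids <- vector("list", snt + spphy$Nnode)
  for (e in seq_len(nrow(spphy$edge))) {
    skids[[spphy$edge[e, 1]]] <- c(skids[[spphy$edge[e, 1]]], spphy$edge[e, 2])
  }
  sparent <- integer(snt + spphy$Nnode)
  sparent[spphy$edge[, 2]] <- spphy$edge[, 1]
  sdur <- rep(Inf, snt + spphy$Nnode)
  sdur[spphy$edge[, 2]] <- spphy$edge.length
  sroot <- snt + 1L

  # species tips below each species node
  under <- vector("list", snt + spphy$Nnode)
  fill_under <- function(v) {
    if (v <= snt) { under[[v]] <<- v; return(v) }
    u <- sort(unlist(lapply(skids[[v]], fill_under)))
    under[[v]] <<- u
    u
  }
  fill_under(sroot)

  # gene tip -> species tip id; gene node -> species set
  tipspec <- match(lk[gphy$tip.label], spphy$tip.label)
  gspec <- vector("list", gnt + gphy$Nnode)
  fill_gspec <- function(v) {
    if (v <= gnt) { gspec[[v]] <<- tipspec[v]; return(gspec[[v]]) }
    s <- sort(unique(unlist(lapply(gkids[[v]], fill_gspec))))
    gspec[[v]] <<- s
    s
  }
  fill_gspec(gnt + 1L)

  anc_chain <- function(v) {
    out <- v
    while (v != sroot) { v <- sparent[v]; out <- c(out, v) }
    out
  }
  is_anc_or_eq <- function(a, b) a %in% anc_chain(b)  # a at/above b

  gnodes <- (gnt + 1L):(gnt + gphy$Nnode)
  allowed <- lapply(gnodes, function(v) {
    cands <- Filter(function(s) all(gspec[[v]] %in% under[[s]]),
                    seq_len(snt + spphy$Nnode))
    # minimal admissible = species MRCA; allow it and its ancestors
    mr <- cands[which.min(lengths(under[cands]))]
    anc_chain(mr)
  })

  # species branch on which a gene TIP starts
  tip_branch <- tipspec

  total <- 0
  assign_vec <- integer(length(gnodes))
  rec <- function(k) {
    if (k > length(gnodes)) {
      total <<- total + oracle_history_prob(assign_vec, gnodes, gnt, gparent,
                                            gkids, tip_branch, skids, sparent,
                                            sdur, snt, sroot, anc_chain)
      return(invisible())
    }
    v <- gnodes[k]
    for (b in allowed[[k]]) {
      ok <- TRUE
      for (c in gkids[[v]]) {
        cb <- if (c <= gnt) tip_branch[c] else assign_vec[match(c, gnodes)]
        if (c > gnt && is.na(cb)) next
        if (!is_anc_or_eq(b, cb)) { ok <- FALSE; break }
      }
      if (ok) {
        assign_vec[match(v, gnodes)] <<- b
        rec(k + 1)
        assign_vec[match(v, gnodes)] <<- NA
      }
    }
  }
  # order gene nodes so children are assigned before parents (postorder)
  po <- integer(0)
  walk <- function(v) {
    if (v <= gnt) return(invisible())
    for (c in gkids[[v]]) walk(c)
    po <<- c(po, v)
  }
  walk(gnt + 1L)
  gnodes <- po
  allowed <- lapply(gnodes, function(v) {
    cands <- Filter(function(s) all(gspec[[v]] %in% under[[s]]),
                    seq_len(snt + spphy$Nnode))
    mr <- cands[which.min(lengths(under[cands]))]
    anc_chain(mr)
  })
  assign_vec <- rep(NA_integer_, length(gnodes))
  rec(1)
  total
}

oracle_history_prob <- function(assign_vec, gnodes, gnt, gparent, gkids,
                                tip_branch, skids, sparent, sdur, snt, sroot,
                                anc_chain) {
  # lineages entering each species branch: tips at their species branch,
  # then propagate uncoalesced lineages rootward
  branches <- seq_along(sdur)
  A <- split(gnodes, factor(assign_vec, levels = branches))
  # entering count per branch, by postorder accumulation
  po <- integer(0)
  walk <- function(v) {
    for (c in skids[[v]]) walk(c)
    po <<- c(po, v)
  }
  walk(sroot)
  enter <- integer(length(branches))
  leave <- integer(length(branches))
  for (v in po) {
    e <- sum(tip_branch == v & seq_along(tip_branch) <= gnt)
    if (length(skids[[v]])) e <- e + sum(leave[skids[[v]]])
    enter[v] <- e
    leave[v] <- e - length(A[[as.character(v)]])
  }
  p <- 1
  for (v in po) {
    i <- enter[v]
    if (i == 0) next
    j <- leave[v]
    nodes_here <- A[[as.character(v)]]
    d <- if (j >= i) 1 else prod(choose((j + 1):i, 2))
    w <- oracle_orderings(nodes_here, gparent)
    p <- p * oracle_gij(i, j, sdur[v]) * w / d
  }
  p
}
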