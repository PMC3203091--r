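## Internal tree bookkeeping shared by the coalescent kernel and the
## simulation pipeline. Node ids follow ape conventions: tips 1..ntip,
## internals ntip+1..ntip+Nnode with the root at ntip+1.

.children_list <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  kids <- vector("list", n)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1]
    kids[[a]] <- c(kids[[a]], phy$edge[e, 2])
  }
  kids
}

.parent_vector <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  par <- integer(n)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

## gene tree in kernel form; requires rooted binary
.prep_gene <- function(phy) {
  nt <- ape::Ntip(phy)
  nn <- phy$Nnode
  kids <- .children_list(phy)
  for (v in (nt + 1L):(nt + nn)) {
    if (length(kids[[v]]) != 2) {
      abort("gene tree must be binary; resolve polytomies first")
    }
  }
  kmat <- matrix(0L, nn, 2)
  for (v in (nt + 1L):(nt + nn)) kmat[v - nt, ] <- kids[[v]]
  list(ntip = nt, nnode = nn, kids = kmat, parent = .parent_vector(phy),
       labels = phy$tip.label)
}

## species tree in kernel form: edge lengths are branch durations in
## coalescent units; the root branch has infinite duration
.prep_species <- function(phy) {
  nt <- ape::Ntip(phy)
  nn <- phy$Nnode
  if (is.null(phy$edge.length)) abort("species tree needs branch lengths (coalescent units)")
  if (any(phy$edge.length < 0)) abort("species tree branch lengths must be nonnegative")
  kids <- .children_list(phy)
  n <- nt + nn
  dur <- rep(Inf, n)
  dur[phy$edge[, 2]] <- phy$edge.length
  ## postorder via reversed preorder stack walk
  root <- nt + 1L
  stack <- root
  visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    if (!is.null(kids[[v]])) stack <- c(stack, kids[[v]])
  }
  list(ntip = nt, nnode = nn, kids = kids, dur = dur,
       postorder = rev(visit), root = root, labels = phy$tip.label)
}

## canonical topology string: children sorted recursively by their own
## canonical form, so equal topologies map to equal keys
.canonical_topology_key <- function(phy) {
  nt <- ape::Ntip(phy)
  kids <- .children_list(phy)
  rec <- function(v) {
    if (v <= nt) return(phy$tip.label[v])
    parts <- sort(vapply(kids[[v]], rec, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(nt + 1L), ";")
}

## canonical key of the species-relabelled topology: the coalescent
## probability is invariant under permuting individuals within a species,
## so this key identifies probability-equivalent gene trees
.species_canonical_key <- function(phy, lk) {
  nt <- ape::Ntip(phy)
  kids <- .children_list(phy)
  rec <- function(v) {
    if (v <= nt) return(lk[[phy$tip.label[v]]])
    parts <- sort(vapply(kids[[v]], rec, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(nt + 1L), ";")
}

## species-under mask per species-tree node, and readable branch labels
.species_clade_labels <- function(sp) {
  n <- sp$ntip + sp$nnode
  lab <- character(n)
  rec <- function(v) {
    if (v <= sp$ntip) {
      lab[v] <<- sp$labels[v]
      return(sp$labels[v])
    }
    tips <- sort(unlist(lapply(sp$kids[[v]], rec)))
    lab[v] <<- paste(tips, collapse = "+")
    tips
  }
  rec(sp$root)
  lab
}
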