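#' Specify a hybrid species tree
#'
#' Encodes the four-taxon hybrid species phylogeny used throughout the
#' package: a putative hybrid species `H` whose genome is a mosaic of
#' contributions from two parental species `P1` and `P2`, plus an outgroup
#' `O`. The three interval parameters `t = (t1, t2, t3)`, in coalescent
#' units, are the times between successive events looking rootward: `t1`
#' from the present (tips) to the hybridization/first-divergence event,
#' `t2` from there to the divergence of the two parental lineages, and `t3`
#' from there to the outgroup divergence. Node heights are therefore
#' `t1`, `t1 + t2` and `t1 + t2 + t3`.
#'
#' The `t1`-most-recent labelling of the intervals is a convention of this
#' package (the likelihood is defined through the node heights, which are
#' what the intervals accumulate to).
#'
#' @param hybrid,parent1,parent2,outgroup Species labels (mutually
#'   distinct).
#' @param t Numeric vector `(t1, t2, t3)` of nonnegative interval lengths in
#'   coalescent units.
#' @return An object of class `hyb_species_tree`.
#' @export
#' @examples
#' hybrid_species_tree("H", "P1", "P2", "O", t = c(1, 1, 1))
hybrid_species_tree <- function(hybrid, parent1, parent2, outgroup, t = c(1, 1, 1)) {
  labs <- c(hybrid, parent1, parent2, outgroup)
  stopifnot(is.character(labs), length(labs) == 4)
  if (anyDuplicated(labs)) abort("hybrid, parent1, parent2 and outgroup must be distinct")
  if (length(t) != 3 || any(!is.finite(t)) || any(t < 0)) {
    abort("t must be three nonnegative finite interval lengths")
  }
  structure(
    list(hybrid = hybrid, parent1 = parent1, parent2 = parent2,
         outgroup = outgroup, t = as.numeric(t)),
    class = "hyb_species_tree"
  )
}

#' @export
print.hyb_species_tree <- function(x, ...) {
  cat("Hybrid species tree (4 taxa)\n")
  cat("  hybrid:  ", x$hybrid, "\n  parents: ", x$parent1, ", ", x$parent2,
      "\n  outgroup:", x$outgroup, "\n", sep = "")
  cat(sprintf("  intervals t = (%.4g, %.4g, %.4g) coalescent units\n",
              x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Read a hybrid species tree specification from JSON
#'
#' The file must contain fields `hybrid`, `parent1`, `parent2`, `outgroup`
#' and optionally `t` (three intervals, default `(1, 1, 1)`).
#'
#' @param path Path to a JSON file.
#' @return A `hyb_species_tree`.
#' @export
read_species_tree_spec <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("hybrid", "parent1", "parent2", "outgroup")
  miss <- setdiff(need, names(js))
  if (length(miss)) abort(paste0("species tree spec missing fields: ", paste(miss, collapse = ", ")))
  t <- if (!is.null(js$t)) as.numeric(js$t) else c(1, 1, 1)
  hybrid_species_tree(js$hybrid, js$parent1, js$parent2, js$outgroup, t = t)
}

#' Decompose a hybrid species tree into its two parental trees
#'
#' The hybrid species tree splits into two ordinary species trees: one in
#' which the hybrid first joins `parent1` and one in which it first joins
#' `parent2`. Both share the interval vector `t`; node heights are
#' `t1 < t1 + t2 < t1 + t2 + t3` in each.
#'
#' @param S A [hybrid_species_tree()].
#' @param t Optional interval vector overriding `S$t`.
#' @return A list with elements `tau1` and `tau2`, each an ultrametric
#'   `phylo` with branch lengths in coalescent units.
#' @export
decompose_parental_trees <- function(S, t = S$t) {
  stopifnot(inherits(S, "hyb_species_tree"))
  list(tau1 = .parental_tree(S$hybrid, S$parent1, S$parent2, S$outgroup, t),
       tau2 = .parental_tree(S$hybrid, S$parent2, S$parent1, S$outgroup, t))
}

## ladder tree (((H,Pa),Pb),O) with heights t1, t1+t2, t1+t2+t3
.parental_tree <- function(h, pa, pb, o, t) {
  txt <- sprintf("(((%s:%.17g,%s:%.17g):%.17g,%s:%.17g):%.17g,%s:%.17g);",
                 h, t[1], pa, t[1], t[2], pb, t[1] + t[2], t[3],
                 o, t[1] + t[2] + t[3])
  ape::read.tree(text = txt)
}

#' Per-gene mixture probability
#'
#' The probability of one gene-tree topology under the hybridization
#' mixture: with probability `gamma` the gene traces its history through
#' the parental tree joining the hybrid with `parent1`, with probability
#' `1 - gamma` through the one joining it with `parent2`.
#'
#' @param g A rooted binary gene-tree topology (`phylo`).
#' @param gamma Hybridization proportion in `[0, 1]`.
#' @param t Interval vector `(t1, t2, t3)`.
#' @param S A [hybrid_species_tree()].
#' @param map A taxon map.
#' @return `gamma * P(g | t, tau1) + (1 - gamma) * P(g | t, tau2)`.
#' @export
per_gene_mixture_prob <- function(g, gamma, t, S, map) {
  if (gamma < 0 || gamma > 1) abort("gamma must be in [0, 1]")
  taus <- decompose_parental_trees(S, t)
  gamma * gene_tree_prob(g, taus$tau1, map) +
    (1 - gamma) * gene_tree_prob(g, taus$tau2, map)
}

#' Mixture log-likelihood of a gene-tree sample
#'
#' Sum over loci of the log per-gene mixture probability; the loci are
#' assumed independent given the species tree. A gene tree containing
#' polytomies (a consensus of tied maximum-likelihood estimates) enters as
#' the sum of the probabilities of its binary resolutions.
#'
#' @param gamma Hybridization proportion in `[0, 1]`.
#' @param t Interval vector `(t1, t2, t3)`.
#' @param trees A list/`multiPhylo` of rooted gene-tree topologies, all on
#'   the identical individual set.
#' @param S A [hybrid_species_tree()].
#' @param map A taxon map.
#' @param max_resolutions Cap on binary resolutions per polytomous tree.
#' @return The log-likelihood; `-Inf` if any gene has probability zero
#'   under both parental trees.
#' @export
hyb_log_likelihood <- function(gamma, t, trees, S, map, max_resolutions = 1000) {
  eval_fn <- .prep_likelihood(trees, S, map, max_resolutions = max_resolutions)
  eval_fn(gamma, t)
}

## validate a gene tree sample: identical tip sets; trees are interpreted
## as rooted as written (a basal polytomy is a rooted topology whose root
## resolution is unresolved, e.g. from a consensus of tied estimates)
.check_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) abort("empty gene tree sample")
  tipset <- sort(trees[[1]]$tip.label)
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    if (!inherits(tr, "phylo")) abort("gene trees must be phylo objects")
    if (!identical(sort(tr$tip.label), tipset)) {
      abort(paste0("gene tree ", k, " has a different individual set; ",
                   "all loci must sample the identical individuals"))
    }
  }
  trees
}

## build a fast evaluator (gamma, t) -> lnL with structures cached up front
.prep_likelihood <- function(trees, S, map, max_resolutions = 1000) {
  trees <- .check_sample(trees)
  lk <- .map_lookup(map)
  taus0 <- decompose_parental_trees(S, c(1, 1, 1))  # topology carriers
  ## binary resolutions of each (possibly polytomous) gene tree, then
  ## deduplicated by species-relabelled canonical topology: resolutions
  ## differing only in which same-species individuals sit where have equal
  ## probability, so one representative per class carries a count weight
  res_sets <- vector("list", length(trees))
  res_wts <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    if (is_binary_tree(trees[[i]])) {
      res_sets[[i]] <- list(trees[[i]])
      res_wts[[i]] <- 1
    } else {
      cls <- .resolution_classes(trees[[i]], lk, max_classes = max_resolutions)
      res_sets[[i]] <- cls$trees
      res_wts[[i]] <- cls$counts
    }
  }
  str1 <- lapply(res_sets, function(rs) lapply(rs, .gene_structure, spphy = taus0$tau1, map = map))
  str2 <- lapply(res_sets, function(rs) lapply(rs, .gene_structure, spphy = taus0$tau2, map = map))
  sp <- .prep_species(taus0$tau1)
  skids <- lapply(sp$kids, function(k) if (is.null(k)) integer(0) else as.integer(k))
  imax <- max(2L,
              vapply(unlist(str1, recursive = FALSE), function(s) s$max_i, 0L),
              vapply(unlist(str2, recursive = FALSE), function(s) s$max_i, 0L))
  ## durations per species-tree node as linear combinations of the three
  ## intervals; tau1 and tau2 share the ladder shape, tip order and timing,
  ## so one duration vector serves both
  dmat <- vapply(1:3, function(k) {
    tk <- c(0, 0, 0)
    tk[k] <- 1
    d <- .prep_species(.parental_tree(S$hybrid, S$parent1, S$parent2, S$outgroup, tk))$dur
    d[!is.finite(d)] <- 0
    d
  }, numeric(sp$ntip + sp$nnode))

  ## flatten structures for batched evaluation
  n_genes <- length(trees)
  gene_of <- rep(seq_len(n_genes), lengths(str1))
  wts <- unlist(res_wts)
  flat1 <- unlist(str1, recursive = FALSE)
  flat2 <- unlist(str2, recursive = FALSE)

  ## per-gene component probabilities are memoized on t so the Brent pass
  ## over gamma (which leaves t untouched) re-evaluates only the mixture;
  ## the component not entering the mixture (gamma exactly 0 or 1) is
  ## skipped
  last_t <- NULL
  p1v <- NULL
  p2v <- NULL

  function(gamma, t) {
    if (is.null(last_t) || !identical(t, last_t)) {
      last_t <<- t
      p1v <<- NULL
      p2v <<- NULL
    }
    need1 <- gamma > 0 && is.null(p1v)
    need2 <- gamma < 1 && is.null(p2v)
    if (need1 || need2) {
      dur <- as.numeric(dmat %*% t)
      dur[sp$root] <- Inf
      seen <- new.env(parent = emptyenv())
      Gs <- vector("list", sp$ntip + sp$nnode)
      for (v in sp$postorder) {
        key <- sprintf("%.17g", dur[v])
        G <- seen[[key]]
        if (is.null(G)) {
          G <- .gij_matrix(imax, dur[v])
          assign(key, G, envir = seen)
        }
        Gs[[v]] <- G
      }
      if (need1) p1v <<- coal_eval_batch(flat1, gene_of, wts, Gs, skids, n_genes)
      if (need2) p2v <<- coal_eval_batch(flat2, gene_of, wts, Gs, skids, n_genes)
    }
    p <- if (gamma <= 0) p2v
    else if (gamma >= 1) p1v
    else gamma * p1v + (1 - gamma) * p2v
    if (any(p <= 0)) return(-Inf)
    sum(log(p))
  }
}

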