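#' Simulation study configuration
#'
#' Bundles the data-generation settings of the simulation study: loci are
#' assigned to the two parental trees by a Binomial draw with success
#' probability `gamma_true`; gene trees are simulated under the
#' multispecies coalescent on the assigned parental tree; sequences evolve
#' along each gene tree under Jukes-Cantor with coalescent-unit branch
#' lengths scaled to substitutions per site; gene trees are then
#' re-estimated from the sequences by maximum likelihood and fed to the
#' mixture model and likelihood-ratio test.
#'
#' The defaults are the study conditions: 10 loci, four individuals per
#' ingroup species and two outgroup individuals (14 tips), intervals
#' (1, 1, 1) coalescent units, a per-locus mutation parameter theta of 5.0
#' realized as a branch scale of 0.005 substitutions/site per coalescent
#' unit over 500 bp, and a test level of 0.05.
#'
#' @param gamma_true True hybridization proportion(s); a vector runs one
#'   study level per value.
#' @param n_loci Number of loci per replicate.
#' @param samples_per_species Named integer vector of individuals sampled
#'   per species (names are species labels; the first three are the
#'   ingroup in the order hybrid, parent1, parent2; the last the outgroup).
#' @param t_true True interval vector `(t1, t2, t3)` in coalescent units.
#' @param theta_locus Per-locus mutation parameter (4*Ne*mu). It enters the
#'   pipeline only through `branch_scale` (theta per site divided by two);
#'   both are kept so the configuration documents itself.
#' @param seq_length Sites per locus.
#' @param branch_scale Substitutions per site per coalescent unit.
#' @param n_replicates Replicates per `gamma_true` level.
#' @param alpha Level of the likelihood-ratio test.
#' @param seed Master seed; per-replicate streams are derived from it.
#' @param estimator Gene-tree estimation mode passed to
#'   [estimate_gene_tree()]: `"clock"` (default) or `"unrooted"`.
#' @param hybrid,parent1,parent2,outgroup Species labels.
#' @return A list of class `hyb_simulation_config`.
#' @export
simulation_config <- function(gamma_true = c(0, 0.1, 0.3, 0.5),
                              n_loci = 10,
                              samples_per_species = c(H = 4, P1 = 4, P2 = 4, O = 2),
                              t_true = c(1, 1, 1),
                              theta_locus = 5.0,
                              seq_length = 500,
                              branch_scale = 0.005,
                              n_replicates = 100,
                              alpha = 0.05,
                              seed = 1,
                              estimator = c("clock", "unrooted"),
                              hybrid = "H", parent1 = "P1", parent2 = "P2",
                              outgroup = "O") {
  estimator <- match.arg(estimator)
  stopifnot(all(gamma_true >= 0 & gamma_true <= 1), n_loci >= 1,
            all(samples_per_species >= 1), length(t_true) == 3, all(t_true >= 0),
            theta_locus > 0, seq_length >= 1, branch_scale >= 0,
            n_replicates >= 0, alpha > 0, alpha < 1)
  roles <- c(hybrid, parent1, parent2, outgroup)
  if (!setequal(names(samples_per_species), roles)) {
    abort("names(samples_per_species) must be the four species labels")
  }
  structure(
    list(gamma_true = gamma_true, n_loci = n_loci,
         samples_per_species = samples_per_species, t_true = t_true,
         theta_locus = theta_locus, seq_length = seq_length,
         branch_scale = branch_scale, n_replicates = n_replicates,
         alpha = alpha, seed = seed, estimator = estimator,
         hybrid = hybrid, parent1 = parent1, parent2 = parent2,
         outgroup = outgroup),
    class = "hyb_simulation_config"
  )
}

#' Binomial assignment of loci to parental trees
#'
#' @param n_loci Number of loci.
#' @param gamma_true Probability a locus derives from parental tree 1.
#' @return Integer count of loci assigned to parental tree 1 (the rest go
#'   to parental tree 2).
#' @export
draw_parental_assignments <- function(n_loci, gamma_true) {
  stopifnot(n_loci >= 0, gamma_true >= 0, gamma_true <= 1)
  rbinom(1, n_loci, gamma_true)
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Within each species-tree branch, `k` lineages coalesce at rate
#' `choose(k, 2)` per coalescent unit; lineages that fail to coalesce
#' before the branch ends enter the ancestral population, and everything
#' coalesces in the unbounded root branch. Sampled individuals are named
#' `<species>_<i>`.
#'
#' @param species_tree Rooted binary `phylo` with branch lengths in
#'   coalescent units.
#' @param samples Named integer vector: individuals sampled per species.
#' @return A rooted `phylo` with coalescent-unit branch lengths.
#' @export
simulate_gene_tree <- function(species_tree, samples) {
  ## single-species case: one population, unbounded
  if (is.character(species_tree) && length(species_tree) == 1) {
    return(.sim_one_population(species_tree, samples[[species_tree]]))
  }
  sp <- .prep_species(species_tree)
  if (!all(sp$labels %in% names(samples))) abort("samples must name every species")
  n_sp <- sp$ntip + sp$nnode
  hts <- numeric(n_sp)  # height of the bottom of each branch
  for (v in rev(sp$postorder)) {
    for (k in sp$kids[[v]]) hts[k] <- 0
  }
  for (v in sp$postorder) {
    if (v > sp$ntip) {
      c1 <- sp$kids[[v]][1]
      hts[v] <- hts[c1] + sp$dur[c1]
    }
  }
  m <- sum(samples[sp$labels])
  tip_label <- character(m)
  node_h <- numeric(2 * m - 1)
  merge_child <- matrix(0L, m - 1, 2)
  merge_h <- numeric(m - 1)
  n_merge <- 0L
  next_tip <- 1L
  active <- vector("list", n_sp)  # per species node: lineage ids at branch top

  for (v in sp$postorder) {
    if (v <= sp$ntip) {
      k <- samples[[sp$labels[v]]]
      ids <- seq.int(next_tip, next_tip + k - 1L)
      tip_label[ids] <- paste0(sp$labels[v], "_", seq_len(k))
      node_h[ids] <- 0
      next_tip <- next_tip + k
      cur <- ids
    } else {
      cur <- c(active[[sp$kids[[v]][1]]], active[[sp$kids[[v]][2]]])
    }
    t_now <- hts[v]
    top <- hts[v] + sp$dur[v]
    while (length(cur) > 1) {
      t_now <- t_now + rexp(1, choose(length(cur), 2))
      if (t_now > top) break
      pick <- sample.int(length(cur), 2)
      n_merge <- n_merge + 1L
      id <- m + n_merge
      merge_child[n_merge, ] <- cur[pick]
      merge_h[n_merge] <- t_now
      node_h[id] <- t_now
      cur <- c(cur[-pick], id)
    }
    active[[v]] <- cur
  }
  .merges_to_phylo(m, tip_label, node_h, merge_child, merge_h)
}

.sim_one_population <- function(species, k) {
  stopifnot(k >= 1)
  m <- k
  tip_label <- paste0(species, "_", seq_len(m))
  if (m == 1) {
    return(structure(list(edge = matrix(0L, 0, 2), tip.label = tip_label,
                          Nnode = 0L), class = "phylo"))
  }
  node_h <- numeric(2 * m - 1)
  merge_child <- matrix(0L, m - 1, 2)
  merge_h <- numeric(m - 1)
  cur <- seq_len(m)
  t_now <- 0
  n_merge <- 0L
  while (length(cur) > 1) {
    t_now <- t_now + rexp(1, choose(length(cur), 2))
    pick <- sample.int(length(cur), 2)
    n_merge <- n_merge + 1L
    id <- m + n_merge
    merge_child[n_merge, ] <- cur[pick]
    merge_h[n_merge] <- t_now
    node_h[id] <- t_now
    cur <- c(cur[-pick], id)
  }
  .merges_to_phylo(m, tip_label, node_h, merge_child, merge_h)
}

## assemble an ape phylo from recorded coalescences; internal nodes are
## renumbered by decreasing height so the root is ntip+1
.merges_to_phylo <- function(m, tip_label, node_h, merge_child, merge_h) {
  ord <- order(-merge_h)
  newid <- integer(2 * m - 1)
  newid[seq_len(m)] <- seq_len(m)
  newid[m + ord] <- m + seq_len(m - 1)
  edge <- matrix(0L, 2 * m - 2, 2)
  elen <- numeric(2 * m - 2)
  r <- 0L
  for (k in seq_len(m - 1)) {
    for (c in merge_child[k, ]) {
      r <- r + 1L
      edge[r, ] <- c(newid[m + k], newid[c])
      elen[r] <- merge_h[k] - node_h[c]
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = tip_label, Nnode = m - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate sequences under Jukes-Cantor
#'
#' Sites evolve independently down the gene tree from a uniform root base;
#' coalescent-unit branch lengths are converted to substitutions per site
#' by `branch_scale`.
#'
#' @param gene_tree Rooted `phylo` with coalescent-unit branch lengths.
#' @param seq_length Number of sites.
#' @param branch_scale Substitutions per site per coalescent unit.
#' @return A `phyDat` alignment.
#' @export
simulate_sequences_jc69 <- function(gene_tree, seq_length = 500, branch_scale = 0.005) {
  stopifnot(seq_length >= 1, branch_scale >= 0)
  tr <- gene_tree
  tr$edge.length <- tr$edge.length * branch_scale
  phangorn::simSeq(tr, l = seq_length, type = "DNA")
}

#' Estimate a gene-tree topology by maximum likelihood under Jukes-Cantor
#'
#' The default search assumes a molecular clock, matching the generating
#' model of the simulation pipeline (coalescent times times a constant
#' rate): a UPGMA starting tree followed by nearest-neighbor-interchange
#' hill climbing over rooted, clock-constrained Jukes-Cantor likelihoods.
#' Clock-based estimation roots the tree by itself; `outgroup_species` is
#' only used by the clock-free alternative (`method = "unrooted"`), which
#' searches unconstrained topologies from a random-order stepwise-addition
#' start and then roots on the outgroup.
#'
#' Internal branches whose fitted length is (numerically) zero mark sets
#' of topologies tied in likelihood; they are collapsed, so the returned
#' topology is the semi-strict consensus of the tied resolutions and may
#' contain polytomies. Where full tie enumeration would be intractable
#' downstream, the least-supported branches are collapsed first and the
#' remainder keep the search's own resolution (mirroring a heuristic
#' search that only reports the tied trees it visited).
#'
#' @param aln A `phyDat` alignment (or character matrix convertible to one)
#'   of at least three sequences.
#' @param map A taxon map.
#' @param outgroup_species Species label used to root the tree under
#'   `method = "unrooted"`.
#' @param tie_tol Branch length (substitutions/site) below which an
#'   internal branch is treated as a likelihood tie and collapsed.
#' @param method `"clock"` (default) or `"unrooted"`.
#' @return A rooted gene-tree topology (`phylo`, no branch lengths).
#' @export
estimate_gene_tree <- function(aln, map, outgroup_species, tie_tol = 1e-6,
                               method = c("clock", "unrooted")) {
  method <- match.arg(method)
  if (!inherits(aln, "phyDat")) aln <- phangorn::phyDat(as.matrix(aln), type = "DNA")
  if (attr(aln, "nr") < 1) abort("alignment must contain at least one site")
  if (length(aln) < 3) abort("need at least three sequences")
  if (method == "clock") {
    start <- phangorn::upgma(phangorn::dist.ml(aln))
    ## degenerate alignments (e.g. no variable site) can break the rooted
    ## optimizer; the clustering start tree is then already the ML tree
    rooted <- tryCatch({
      fit <- phangorn::pml(start, aln)
      fit <- phangorn::optim.pml(fit, optNni = TRUE, optRooted = TRUE,
                                 control = phangorn::pml.control(trace = 0,
                                                                 epsilon = 1e-7,
                                                                 maxit = 10))
      fit$tree
    }, error = function(e) start)
  } else {
    start <- phangorn::random.addition(aln)
    start$edge.length <- rep(0.05, nrow(start$edge))
    fit <- phangorn::pml(start, aln)
    fit <- phangorn::optim.pml(fit, optNni = TRUE,
                               control = phangorn::pml.control(trace = 0,
                                                               epsilon = 1e-8,
                                                               maxit = 25))
    rooted <- root_with_outgroup(fit$tree, map, outgroup_species)
    ## the rooting edge's length ends up on one side; split it evenly so a
    ## long rooting edge is not spuriously collapsed as a tie at the root
    rkids <- which(rooted$edge[, 1] == ape::Ntip(rooted) + 1L)
    if (length(rkids) == 2) {
      tot <- sum(rooted$edge.length[rkids])
      rooted$edge.length[rkids] <- tot / 2
    }
  }
  lk <- .map_lookup(map)
  for (max_degree in c(99L, 8L, 6L, 4L, 3L)) {
    out <- .collapse_ties(rooted, tie_tol, max_degree)
    n_cls <- .class_count(out, lk, cap = 16)
    if (is.finite(n_cls)) break
  }
  if (!is.finite(n_cls)) {
    out <- rooted
    out$edge.length <- NULL
  }
  out
}

## collapse internal branches shorter than tol (likelihood ties), smallest
## first, refusing any collapse that would push a polytomy past max_degree;
## returns a topology-only tree
.collapse_ties <- function(phy, tol, max_degree = 99L) {
  nt <- ape::Ntip(phy)
  n <- nt + phy$Nnode
  kids <- .children_list(phy)
  parent <- .parent_vector(phy)
  elen <- rep(NA_real_, n)
  elen[phy$edge[, 2]] <- phy$edge.length
  root <- nt + 1L
  cand <- setdiff(which(elen < tol), seq_len(nt))
  cand <- cand[cand != root]
  cand <- cand[order(elen[cand], cand)]
  alive <- rep(TRUE, n)
  for (u in cand) {
    p <- parent[u]
    while (!alive[p]) p <- parent[p]
    deg <- length(kids[[p]]) - 1L + length(kids[[u]])
    if (deg > max_degree) next
    kids[[p]] <- c(setdiff(kids[[p]], u), kids[[u]])
    for (c in kids[[u]]) parent[c] <- p
    alive[u] <- FALSE
    kids[u] <- list(NULL)
  }
  rec <- function(v) {
    if (v <= nt) return(phy$tip.label[v])
    paste0("(", paste(vapply(kids[[v]], rec, ""), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(rec(root), ";"))
}

## number of species-canonical resolution classes, or Inf if over cap
.class_count <- function(phy, lk, cap) {
  if (is_binary_tree(phy)) return(1)
  tryCatch(length(.resolution_classes(phy, lk, max_classes = cap)$counts),
           error = function(e) Inf)
}

#' Simulate one multi-locus dataset from the hybridization model
#'
#' Draws the Binomial locus assignment, simulates coalescent gene trees on
#' the assigned parental trees, evolves Jukes-Cantor sequences, and (by
#' default) re-estimates each gene tree from its alignment.
#'
#' @param cfg A [simulation_config()].
#' @param gamma_true True hybridization proportion for this dataset.
#' @param estimate Re-estimate gene trees from sequences? If `FALSE` the
#'   true simulated topologies are returned as the data.
#' @return A list: `S` (the model [hybrid_species_tree()]), `map`,
#'   `n_tau1` (loci from parental tree 1), `true_trees` (with branch
#'   lengths), `alignments`, and `trees` (the topologies to analyse).
#' @export
simulate_hybrid_dataset <- function(cfg, gamma_true = cfg$gamma_true[1], estimate = TRUE) {
  S <- hybrid_species_tree(cfg$hybrid, cfg$parent1, cfg$parent2, cfg$outgroup,
                           t = cfg$t_true)
  map <- study_taxon_map(cfg)
  taus <- decompose_parental_trees(S)
  n1 <- draw_parental_assignments(cfg$n_loci, gamma_true)
  true_trees <- vector("list", cfg$n_loci)
  for (l in seq_len(cfg$n_loci)) {
    tau <- if (l <= n1) taus$tau1 else taus$tau2
    true_trees[[l]] <- simulate_gene_tree(tau, cfg$samples_per_species)
  }
  alns <- lapply(true_trees, simulate_sequences_jc69,
                 seq_length = cfg$seq_length, branch_scale = cfg$branch_scale)
  trees <- if (estimate) {
    lapply(alns, estimate_gene_tree, map = map, outgroup_species = cfg$outgroup,
           method = cfg$estimator)
  } else {
    lapply(true_trees, function(tr) { tr$edge.length <- NULL; tr })
  }
  class(trees) <- "multiPhylo"
  class(true_trees) <- "multiPhylo"
  list(S = S, map = map, n_tau1 = n1, true_trees = true_trees,
       alignments = alns, trees = trees)
}

#' Taxon map implied by a simulation configuration
#'
#' @param cfg A [simulation_config()].
#' @return A [taxon_map()] tibble with individuals `<species>_<i>`.
#' @export
study_taxon_map <- function(cfg) {
  sps <- rep(names(cfg$samples_per_species), cfg$samples_per_species)
  inds <- unlist(lapply(names(cfg$samples_per_species), function(s) {
    paste0(s, "_", seq_len(cfg$samples_per_species[[s]]))
  }))
  taxon_map(inds, sps)
}

#' Run the simulation power study
#'
#' For each `gamma_true` level, simulates `n_replicates` full datasets
#' (Binomial locus assignment, coalescent gene trees, Jukes-Cantor
#' sequences, maximum-likelihood gene-tree re-estimation), fits the
#' mixture model with the interval upper bound of the supplied optimizer
#' configuration, performs the likelihood-ratio test at `cfg$alpha`, and
#' aggregates estimates, test rejections and boundary hits. Fully
#' reproducible from `cfg$seed`; per-replicate failures are recorded, not
#' dropped.
#'
#' @param cfg A [simulation_config()].
#' @param opt_config An [optimizer_config()] (upper interval bound 5.0 by
#'   default, as in the study).
#' @param progress Print a line per completed level?
#' @return An object of class `hyb_power_study`: `results` (per-replicate
#'   tibble), `summary` (per-level tibble), `failures`, and the
#'   configurations. `tidy()` returns the per-replicate results,
#'   `summary()`/`glance()` the per-level table, and `autoplot()` draws the
#'   estimate histograms.
#' @export
run_power_study <- function(cfg, opt_config = optimizer_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "hyb_simulation_config"))
  set.seed(cfg$seed)
  rows <- list()
  fails <- list()
  for (g in cfg$gamma_true) {
    seeds <- if (cfg$n_replicates > 0) sample.int(2147483646L, cfg$n_replicates) else integer(0)
    for (r in seq_len(cfg$n_replicates)) {
      out <- tryCatch(
        .study_replicate(cfg, g, seeds[r], opt_config),
        error = function(e) e
      )
      if (inherits(out, "error")) {
        fails[[length(fails) + 1]] <- tibble::tibble(
          gamma_true = g, replicate = r, seed = seeds[r],
          message = conditionMessage(out))
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          gamma_true = g, replicate = r, seed = seeds[r], n_tau1 = out$n_tau1,
          gamma_hat = out$gamma_hat, t1_hat = out$t[1], t2_hat = out$t[2],
          t3_hat = out$t[3], lnL = out$lnL, delta = out$delta,
          p_value = out$p_value, reject = out$p_value <= cfg$alpha,
          boundary_t1 = out$boundary[1], boundary_t2 = out$boundary[2],
          boundary_t3 = out$boundary[3], converged = out$converged)
      }
    }
    if (progress) {
      message(sprintf("gamma_true = %.2f: %d replicates done", g, cfg$n_replicates))
    }
  }
  results <- if (length(rows)) dplyr::bind_rows(rows) else .empty_results()
  failures <- if (length(fails)) dplyr::bind_rows(fails) else
    tibble::tibble(gamma_true = numeric(0), replicate = integer(0),
                   seed = integer(0), message = character(0))
  structure(
    list(results = results, summary = .summarize_study(results),
         failures = failures, config = cfg, opt_config = opt_config),
    class = "hyb_power_study"
  )
}

.study_replicate <- function(cfg, gamma_true, seed, opt_config) {
  set.seed(seed)
  ds <- suppressWarnings(simulate_hybrid_dataset(cfg, gamma_true, estimate = TRUE))
  lrt <- suppressWarnings(
    likelihood_ratio_test(ds$trees, ds$S, ds$map, opt_config)
  )
  fit <- lrt$fit_alt
  list(n_tau1 = ds$n_tau1, gamma_hat = fit$gamma, t = fit$t, lnL = fit$lnL,
       delta = lrt$delta, p_value = lrt$p_value,
       boundary = unname(fit$boundary[c("t1", "t2", "t3")]),
       converged = fit$converged)
}

.empty_results <- function() {
  tibble::tibble(
    gamma_true = numeric(0), replicate = integer(0), seed = integer(0),
    n_tau1 = integer(0), gamma_hat = numeric(0), t1_hat = numeric(0),
    t2_hat = numeric(0), t3_hat = numeric(0), lnL = numeric(0),
    delta = numeric(0), p_value = numeric(0), reject = logical(0),
    boundary_t1 = logical(0), boundary_t2 = logical(0),
    boundary_t3 = logical(0), converged = logical(0)
  )
}

.summarize_study <- function(results) {
  if (!nrow(results)) {
    return(tibble::tibble(
      gamma_true = numeric(0), n = integer(0),
      mean_gamma_hat = numeric(0), sd_gamma_hat = numeric(0),
      mean_t1 = numeric(0), sd_t1 = numeric(0),
      mean_t2 = numeric(0), sd_t2 = numeric(0),
      mean_t3 = numeric(0), sd_t3 = numeric(0),
      power = numeric(0),
      boundary_t1 = integer(0), boundary_t2 = integer(0), boundary_t3 = integer(0),
      mean_t1_interior = numeric(0), mean_t2_interior = numeric(0),
      mean_t3_interior = numeric(0)
    ))
  }
  dplyr::summarise(
    dplyr::group_by(results, .data$gamma_true),
    n = dplyr::n(),
    mean_gamma_hat = mean(.data$gamma_hat), sd_gamma_hat = stats::sd(.data$gamma_hat),
    mean_t1 = mean(.data$t1_hat), sd_t1 = stats::sd(.data$t1_hat),
    mean_t2 = mean(.data$t2_hat), sd_t2 = stats::sd(.data$t2_hat),
    mean_t3 = mean(.data$t3_hat), sd_t3 = stats::sd(.data$t3_hat),
    power = mean(.data$reject),
    boundary_t1 = sum(.data$boundary_t1),
    boundary_t2 = sum(.data$boundary_t2),
    boundary_t3 = sum(.data$boundary_t3),
    mean_t1_interior = mean(.data$t1_hat[!.data$boundary_t1]),
    mean_t2_interior = mean(.data$t2_hat[!.data$boundary_t2]),
    mean_t3_interior = mean(.data$t3_hat[!.data$boundary_t3]),
    .groups = "drop"
  )
}

#' @export
print.hyb_power_study <- function(x, ...) {
  cat("Hybridization power study:", nrow(x$results), "replicates across",
      length(unique(x$results$gamma_true)), "level(s) of gamma\n")
  if (nrow(x$failures)) cat(" ", nrow(x$failures), "replicate failure(s) recorded\n")
  print(x$summary)
  invisible(x)
}

#' @rdname run_power_study
#' @param x A `hyb_power_study`.
#' @param ... Unused.
#' @export
tidy.hyb_power_study <- function(x, ...) x$results

#' @rdname run_power_study
#' @export
glance.hyb_power_study <- function(x, ...) x$summary

#' @rdname run_power_study
#' @param object A `hyb_power_study`.
#' @export
summary.hyb_power_study <- function(object, ...) object$summary
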