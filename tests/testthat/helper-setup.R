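# shared fixtures built in code

# taxon map for individuals named <species>_<i>
study_taxon_map_of <- function(samples) {
  taxon_map(
    unlist(lapply(names(samples), function(s) paste0(s, "_", seq_len(samples[[s]])))),
    rep(names(samples), samples)
  )
}

# the four-taxon study tree and its map at given sample sizes
study_setup <- function(samples = c(H = 2, P1 = 2, P2 = 1, O = 1),
                        t = c(1, 1, 1)) {
  list(
    S = hybrid_species_tree("H", "P1", "P2", "O", t = t),
    map = study_taxon_map_of(samples),
    samples = samples
  )
}

# a sample of n identical copies of one topology
replicated_sample <- function(nwk, n) {
  trees <- replicate(n, parse_newick(nwk), simplify = FALSE)
  class(trees) <- "multiPhylo"
  trees
}
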