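# shared fixtures built in code

# Robinson-Foulds distance without ape's rooted-tree warnings
topo_dist <- function(a, b) {
  suppressWarnings(ape::dist.topo(a, b)[[1]])
}

random_chronogram <- function(n, depth = 1) {
  tr <- ape::rcoal(n)
  macroils::scale_root_height(tr, depth)
}

random_alignment <- function(n_taxa, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_sites, replace = TRUE),
              n_taxa, n_sites,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  macroils::alignment(m)
}

# simulate an alignment on a random coalescent tree of a given scale
sim_on_random_tree <- function(n_taxa, n_sites, model = subst_model("JC"),
                               scale = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, scale)
  list(tree = tr, aln = simulate_alignment(tr, model, n_sites))
}

# brute-force pruning oracle for 4 taxa: enumerate the two internal states
# of the unrooted quartet topology ((a,b),(c,d)) explicitly
quartet_lnl_oracle <- function(tree, aln, model) {
  stopifnot(length(tree$tip.label) == 4)
  k <- length(model$cat_rates)
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- 4L
  inner <- unique(tree$edge[, 1])  # two internal nodes (root has 3 children
                                   # in unrooted form -> handle generally)
  total <- 0
  for (site in seq_len(ncol(aln))) {
    obs <- match(unclass(aln)[tree$tip.label, site], c("A", "C", "G", "T"))
    Lcat <- numeric(k)
    for (cat in seq_len(k)) {
      r <- model$cat_rates[cat]
      P <- lapply(tree$edge.length * r, function(t) {
        macroils::transition_matrix(model, t)
      })
      states <- as.matrix(expand.grid(rep(list(1:4), length(inner))))
      s <- 0
      for (row in seq_len(nrow(states))) {
        assign_state <- function(node) {
          if (node <= ntip) obs[node] else states[row, match(node, inner)]
        }
        pr <- model$base_freqs[assign_state(inner[length(inner)])]
        for (e in seq_len(nrow(tree$edge))) {
          pa <- assign_state(tree$edge[e, 1])
          ch <- assign_state(tree$edge[e, 2])
          pr <- pr * P[[e]][pa, ch]
        }
        s <- s + pr
      }
      Lcat[cat] <- s
    }
    total <- total + log(mean(Lcat))
  }
  total
}

guide_trees_cached <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- macroils::study_guide_trees()
    val
  }
})
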