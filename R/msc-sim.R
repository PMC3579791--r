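#' Population parameters for the multispecies coalescent
#'
#' A single (diploid, nuclear-reference) effective population size applied to
#' every branch of the species tree, and a generation time used to convert
#' node ages in Ma to generations.
#'
#' @param Ne effective population size (diploid individuals, nuclear
#'   reference) (> 0).
#' @param generation_time years per generation (> 0); the macropodid average
#'   used throughout is 7 years.
#' @return list of class `pop_params`.
#' @export
pop_params <- function(Ne, generation_time = 7) {
  stopifnot(Ne > 0, generation_time > 0)
  structure(list(Ne = Ne, generation_time = generation_time),
            class = "pop_params")
}

#' Locus model: length, ploidy class and mutation rate
#'
#' @param name locus name.
#' @param length alignment length in bp (> 0).
#' @param ploidy_class `"nuclear_autosomal"` or `"mitochondrial"`. The
#'   mitochondrial effective size is one quarter of the nuclear reference
#'   (haploid, maternally inherited).
#' @param mu mutation rate in substitutions/site/generation (> 0).
#' @param model a [subst_model()] used when sequences are simulated on this
#'   locus's genealogies.
#' @return list of class `locus_model`.
#' @export
locus_model <- function(name, length, ploidy_class = c("nuclear_autosomal",
                                                       "mitochondrial"),
                        mu, model = subst_model("HKY")) {
  ploidy_class <- match.arg(ploidy_class)
  stopifnot(length > 0, mu > 0)
  structure(list(name = name, length = as.integer(length),
                 ploidy_class = ploidy_class, mu = mu, model = model),
            class = "locus_model")
}

#' Population mutation parameter theta for a locus
#'
#' Nuclear autosomal loci: `4 * Ne * mu`. Mitochondrial loci: `2 * (Ne/4) *
#' mu` — the mitochondrial effective size is one quarter of the nuclear value.
#'
#' @param params a [pop_params()].
#' @param locus a [locus_model()].
#' @return theta (> 0).
#' @export
effective_theta <- function(params, locus) {
  switch(locus$ploidy_class,
         nuclear_autosomal = 4 * params$Ne * locus$mu,
         mitochondrial     = 2 * (params$Ne / 4) * locus$mu)
}

# Pairwise coalescence rate per generation for a locus, consistent with the
# theta parameterization: theta = 2 * E[pairwise coalescence time] * mu, so
# nuclear theta = 4*Ne*mu gives rate 1/(2*Ne) and mitochondrial
# theta = 2*(Ne/4)*mu gives rate 1/(Ne/4) (haploid maternal, one quarter the
# nuclear effective size).
coal_rate <- function(params, locus) {
  switch(locus$ploidy_class,
         nuclear_autosomal = 1 / (2 * params$Ne),
         mitochondrial     = 1 / (params$Ne / 4))
}

#' Simulate a gene genealogy under the multispecies coalescent
#'
#' One sampled lineage per species (tip) by default. Within each species-tree
#' branch, lineage pairs coalesce at rate `1/(2 Ne)` per generation (nuclear)
#' or `1/(Ne/4)` (mitochondrial: haploid maternal, effective size one quarter
#' of the nuclear reference); lineages that fail to coalesce enter the parent
#' branch. Species-tree node ages in Ma are converted to generations at
#' `1e6 / generation_time` generations per Ma.
#'
#' @param tree an ultrametric species tree (`phylo`, heights in Ma).
#' @param params a [pop_params()].
#' @param locus a [locus_model()].
#' @param samples_per_species integer, lineages sampled per species.
#' @return list of class `genealogy` with elements `tree` (binary `phylo`,
#'   edge lengths in generations; tip labels are the species labels, suffixed
#'   `_1`, `_2`, ... when more than one lineage per species is sampled),
#'   `ages` (node times in generations), `mu`, and `tree_subs` (the same tree
#'   with edges scaled to expected substitutions/site).
#' @export
simulate_genealogy <- function(tree, params, locus, samples_per_species = 1L) {
  if (!is_chronogram(tree)) stop("species tree must be ultrametric")
  gens_per_ma <- 1e6 / params$generation_time
  rate <- coal_rate(params, locus)
  sp_ages <- node_ages(tree) * gens_per_ma
  ntip_sp <- length(tree$tip.label)
  root_sp <- ntip_sp + 1L

  k <- samples_per_species
  tip_labels <- if (k == 1L) tree$tip.label else
    as.vector(t(outer(tree$tip.label, seq_len(k), paste, sep = "_")))
  n_tips <- ntip_sp * k
  # gene-tree bookkeeping: nodes 1..n_tips are tips; internals appended
  g_time <- numeric(2 * n_tips - 1)
  g_left <- integer(2 * n_tips - 1)
  g_right <- integer(2 * n_tips - 1)
  next_node <- n_tips + 1L

  sp_parent <- integer(ntip_sp + tree$Nnode)
  sp_parent[tree$edge[, 2]] <- tree$edge[, 1]
  sp_children <- split(tree$edge[, 2], tree$edge[, 1])

  # lineages entering each species node's branch, filled tips-first
  pending <- vector("list", ntip_sp + tree$Nnode)
  for (s in seq_len(ntip_sp)) {
    pending[[s]] <- if (k == 1L) s else
      match(paste(tree$tip.label[s], seq_len(k), sep = "_"), tip_labels)
  }

  visit_order <- order(sp_ages[seq_len(ntip_sp + tree$Nnode)])
  done <- logical(ntip_sp + tree$Nnode)
  for (v in visit_order) {
    if (v > ntip_sp) {
      # merge surviving lineages from children
      for (ch in sp_children[[as.character(v)]]) {
        pending[[v]] <- c(pending[[v]], pending[[ch]])
      }
    }
    lineages <- pending[[v]]
    t_now <- sp_ages[v]
    t_end <- if (v == root_sp) Inf else sp_ages[sp_parent[v]]
    while (length(lineages) >= 2) {
      total <- choose(length(lineages), 2) * rate
      t_now <- t_now + stats::rexp(1, total)
      if (t_now >= t_end) break
      pair <- sample.int(length(lineages), 2)
      nd <- next_node; next_node <- nd + 1L
      g_time[nd] <- t_now
      g_left[nd] <- lineages[pair[1]]
      g_right[nd] <- lineages[pair[2]]
      lineages <- c(lineages[-pair], nd)
    }
    pending[[v]] <- lineages
    done[v] <- TRUE
  }
  stopifnot(length(pending[[root_sp]]) == 1L)

  # assemble phylo: internal gene nodes were created in increasing-time order
  n_int <- n_tips - 1L
  edge <- matrix(0L, 2L * n_int, 2L)
  el <- numeric(2L * n_int)
  # phylo requires root = n_tips+1; internal creation order is time-increasing,
  # so the last created node is the root: reverse the internal numbering
  remap <- integer(2 * n_tips - 1)
  remap[seq_len(n_tips)] <- seq_len(n_tips)
  internals <- (n_tips + 1L):(2L * n_tips - 1L)
  remap[internals] <- rev(internals)
  r <- 0L
  for (nd in internals) {
    for (ch in c(g_left[nd], g_right[nd])) {
      r <- r + 1L
      edge[r, ] <- c(remap[nd], remap[ch])
      el[r] <- g_time[nd] - g_time[ch]
    }
  }
  gt <- list(edge = edge, tip.label = tip_labels, Nnode = n_int,
             edge.length = el)
  class(gt) <- "phylo"
  gt <- ape::reorder.phylo(gt, "cladewise")
  ages <- numeric(2 * n_tips - 1)
  ages[remap] <- g_time
  ts <- gt
  ts$edge.length <- ts$edge.length * locus$mu
  structure(list(tree = gt, ages = ages, mu = locus$mu, tree_subs = ts),
            class = "genealogy")
}

#' Graft a new tip onto the stem of a clade at a given age
#'
#' @param tree an ultrametric `phylo` (heights in Ma).
#' @param taxon new tip label.
#' @param sibling_clade character vector: the clade onto whose stem lineage
#'   the tip is attached.
#' @param attach_age Ma; must lie strictly between the sibling clade's crown
#'   age and its parent node's age.
#' @return the enlarged ultrametric tree.
#' @export
graft_taxon <- function(tree, taxon, sibling_clade, attach_age) {
  if (taxon %in% tree$tip.label) stop("taxon already present: ", taxon)
  masks <- node_masks(tree)
  m <- mask_of(sibling_clade, tree$tip.label)
  node <- which(masks == m)
  if (!length(node)) stop("sibling clade not present in tree")
  ages <- node_ages(tree)
  crown <- ages[node]
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  if (!length(parent)) stop("cannot graft onto the root stem")
  stem_top <- ages[parent]
  if (attach_age <= crown || attach_age >= stem_top) {
    stop(sprintf("attach age %.4g outside the stem interval (%.4g, %.4g)",
                 attach_age, crown, stem_top))
  }
  newtip <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = taxon,
                 Nnode = 1L, edge.length = attach_age)
  class(newtip) <- "phylo"
  out <- ape::bind.tree(tree, newtip, where = node,
                        position = attach_age - crown)
  out
}

#' Rescale a chronogram to a target root height
#'
#' @param tree ultrametric `phylo`.
#' @param target new root height (same units).
#' @return rescaled tree.
#' @export
scale_root_height <- function(tree, target) {
  h <- max(node_ages(tree))
  if (h <= 0) stop("root height must be positive")
  tree$edge.length <- tree$edge.length * (target / h)
  tree
}
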