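# Species-tree inference by minimizing deep coalescences (MDC), with
# soft-polytomy gene trees scored as the minimum over their resolutions.
# Clades are integer bitmasks over the taxon universe (<= 31 taxa).

.int_masks <- function(tree, taxa) {
  m <- node_masks(tree, taxa)
  if (length(taxa) > 31) stop("MDC machinery limited to 31 taxa")
  as.integer(m)
}

# number of gene lineages exiting cluster mask C (an integer bitmask), under
# the best refinement of soft polytomies: at a polytomy, children lying fully
# inside C coalesce into a single exiting lineage.
.exits <- function(children, masks, node, C) {
  mn <- masks[node]
  i <- bitwAnd(mn, C)
  if (i == 0L) return(0L)
  if (i == mn) return(1L)
  kids <- children[[node]]
  full <- 0L; total <- 0L
  for (ch in kids) {
    mc <- masks[ch]
    j <- bitwAnd(mc, C)
    if (j == 0L) next
    if (j == mc) full <- 1L
    else total <- total + .exits(children, masks, ch, C)
  }
  total + full
}

.gene_data <- function(gene_tree, taxa) {
  masks <- .int_masks(gene_tree, taxa)
  nnode <- length(gene_tree$tip.label) + gene_tree$Nnode
  children <- vector("list", nnode)
  for (i in seq_len(nrow(gene_tree$edge))) {
    p <- gene_tree$edge[i, 1]
    children[[p]] <- c(children[[p]], gene_tree$edge[i, 2])
  }
  list(children = children, masks = masks,
       root = length(gene_tree$tip.label) + 1L)
}

# extra lineages contributed by one gene tree for one cluster mask
.xl_cluster <- function(gd, C) {
  k <- .exits(gd$children, gd$masks, gd$root, C)
  max(k - 1L, 0L)
}

#' Extra-lineage (deep coalescence) count
#'
#' For each species-tree edge, the number of gene lineages exiting that edge
#' minus one, summed over edges. Gene-tree polytomies are soft: the count is
#' the minimum over their resolutions. The gene tree's leaf set may be a
#' subset of the species tree's.
#'
#' @param species_tree rooted `phylo`.
#' @param gene_tree rooted `phylo` (may contain polytomies).
#' @return non-negative integer.
#' @export
count_extra_lineages <- function(species_tree, gene_tree) {
  extra <- setdiff(gene_tree$tip.label, species_tree$tip.label)
  if (length(extra)) stop("gene-tree taxa absent from species tree: ",
                          paste(extra, collapse = ", "))
  taxa <- species_tree$tip.label
  sp_masks <- .int_masks(species_tree, taxa)
  root <- length(taxa) + 1L
  clusters <- sp_masks[-root]      # every edge's cluster: tips + non-root internals
  gd <- .gene_data(gene_tree, taxa)
  sum(vapply(clusters, function(C) .xl_cluster(gd, C), integer(1)))
}

# all rooted topologies on a taxon set (recursive edge-insertion enumeration)
.all_rooted <- function(taxa) {
  n <- length(taxa)
  if (n > 8) stop("exhaustive enumeration limited to 8 taxa")
  trees <- phangorn::allTrees(n, rooted = TRUE, tip.label = taxa)
  trees
}

.dp_candidates <- function(gene_trees, taxa) {
  n <- length(taxa)
  cand <- c(as.integer(2^(seq_len(n) - 1)), as.integer(2^n - 1))
  for (g in gene_trees) cand <- c(cand, .int_masks(g, taxa))
  cand <- unique(cand[cand > 0L])
  base <- setdiff(cand, c(as.integer(2^(seq_len(n) - 1)),
                          as.integer(2^n - 1)))
  unions <- integer(0)
  if (length(base) >= 2) {
    for (i in seq_along(base)) {
      unions <- c(unions, bitwOr(base[i], base))
    }
  }
  sort(unique(c(cand, unions[unions < 2^n])))
}

# cluster-based DP over a candidate mask set; w(C) precomputed
.dp_solve <- function(cand, w, full) {
  cand <- sort(unique(c(cand, full)))
  size <- vapply(cand, function(m) sum(bitwAnd(m, 2^(0:30)) > 0), numeric(1))
  ord <- order(size)
  pos <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(cand)) assign(as.character(cand[i]), i, envir = pos)
  best <- rep(Inf, length(cand))
  split_l <- integer(length(cand)); split_r <- integer(length(cand))
  tie <- logical(length(cand))
  for (i in ord) {
    C <- cand[i]
    if (size[i] == 1) { best[i] <- w[i]; next }
    subs <- which(bitwAnd(cand, C) == cand & cand != C)
    bi <- Inf; bl <- 0L; br <- 0L; t <- FALSE
    for (j in subs) {
      A <- cand[j]; B <- bitwXor(C, A)
      if (A > B) next                      # each split once, lexicographic
      kj <- get0(as.character(B), envir = pos)
      if (is.null(kj)) next
      val <- best[j] + best[kj]
      if (val < bi - 1e-9) { bi <- val; bl <- j; br <- kj; t <- FALSE }
      else if (is.finite(val) && abs(val - bi) <= 1e-9 &&
               !(j == bl && kj == br)) t <- TRUE
    }
    cost_here <- if (C == full) 0 else w[i]
    best[i] <- bi + cost_here
    split_l[i] <- bl; split_r[i] <- br; tie[i] <- t
  }
  list(cand = cand, best = best, split_l = split_l, split_r = split_r,
       tie = tie, root = which(cand == full))
}

.dp_tree <- function(sol, taxa) {
  build <- function(i) {
    if (sol$split_l[i] == 0L) {
      idx <- which(bitwAnd(sol$cand[i], 2^(seq_along(taxa) - 1)) > 0)
      return(taxa[idx])
    }
    paste0("(", build(sol$split_l[i]), ",", build(sol$split_r[i]), ")")
  }
  tie_used <- function(i) {
    if (sol$split_l[i] == 0L) return(FALSE)
    sol$tie[i] || tie_used(sol$split_l[i]) || tie_used(sol$split_r[i])
  }
  list(tree = parse_newick(paste0(build(sol$root), ";")),
       tie = tie_used(sol$root))
}

#' Species tree by minimizing deep coalescences
#'
#' Gene trees with numeric support labels are first collapsed at
#' `collapse_threshold`; collapsed polytomies are soft (scored as the best
#' refinement). The optimum is found exactly by exhaustive enumeration of
#' rooted topologies (<= `exhaustive_max` taxa) or by cluster-based dynamic
#' programming; the DP is exact over the full power set up to 12 taxa and
#' restricted to gene-tree clusters, their pairwise unions and singletons
#' above that (a documented heuristic). Ties are broken deterministically
#' (lexicographic mask order) and flagged.
#'
#' @param gene_trees list/multiPhylo of rooted gene trees over a common taxon
#'   universe (subsets allowed).
#' @param collapse_threshold bootstrap percentage below which gene-tree edges
#'   are collapsed (applied only to trees carrying support labels);
#'   `NULL` disables collapsing.
#' @param method `"auto"`, `"exhaustive"` or `"dp"`.
#' @param exhaustive_max taxon cap for the exhaustive path in auto mode.
#' @return list of class `mdc_result`: `tree`, `total_xl`, `per_gene_xl`,
#'   `tie` (logical), and `optima` (all tied optimal trees, exhaustive mode
#'   only).
#' @export
mdc_infer <- function(gene_trees, collapse_threshold = 50,
                      method = c("auto", "exhaustive", "dp"),
                      exhaustive_max = 7) {
  method <- match.arg(method)
  if (!length(gene_trees)) stop("no gene trees supplied")
  gene_trees <- lapply(gene_trees, function(g) {
    if (!is.null(collapse_threshold) && !is.null(g$node.label) &&
        any(!is.na(suppressWarnings(as.numeric(g$node.label))))) {
      g <- collapse_low_support(g, collapse_threshold,
                                missing_support = "resolved")
    }
    g
  })
  taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  n <- length(taxa)
  if (method == "auto") {
    method <- if (n <= exhaustive_max) "exhaustive" else "dp"
  }
  gds <- lapply(gene_trees, .gene_data, taxa = taxa)
  root_id <- length(taxa) + 1L
  xl_total <- function(sp) {
    clusters <- .int_masks(sp, taxa)[-root_id]
    clusters <- clusters[bitwAnd(clusters, clusters - 1L) != 0L]  # skip tips
    tot <- 0L
    for (gd in gds) {
      for (C in clusters) tot <- tot + .xl_cluster(gd, C)
    }
    tot
  }
  if (method == "exhaustive") {
    trees <- .all_rooted(taxa)
    xls <- vapply(trees, xl_total, numeric(1))
    mn <- min(xls)
    opt <- which(xls == mn)
    best_tree <- trees[[opt[1]]]
    per_gene <- vapply(gene_trees, function(g) {
      count_extra_lineages(best_tree, g)
    }, integer(1))
    return(structure(list(tree = best_tree, total_xl = as.integer(mn),
                          per_gene_xl = per_gene, tie = length(opt) > 1,
                          optima = trees[opt]),
                     class = "mdc_result"))
  }
  full <- as.integer(2^n - 1)
  cand <- if (n <= 12) as.integer(seq_len(2^n - 1)) else
    .dp_candidates(gene_trees, taxa)
  w <- vapply(cand, function(C) {
    sum(vapply(gds, .xl_cluster, integer(1), C = C))
  }, numeric(1))
  sol <- .dp_solve(cand, w, full)
  if (!is.finite(sol$best[sol$root])) {
    stop("candidate cluster set admits no resolved species tree")
  }
  bt <- .dp_tree(sol, taxa)
  per_gene <- vapply(gene_trees, function(g) {
    count_extra_lineages(bt$tree, g)
  }, integer(1))
  structure(list(tree = bt$tree, total_xl = as.integer(sol$best[sol$root]),
                 per_gene_xl = per_gene, tie = bt$tie, optima = NULL),
            class = "mdc_result")
}
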