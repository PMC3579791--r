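# The headline analyses: clade-support scans over an Ne grid, placement
# frequency queries for the introgression diagnostic, and the gene-number
# power scan.

.substream_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.infer_tree <- function(aln, model, engine, n_starts = 2) {
  if (engine == "fasttree") {
    fasttree_tree(aln, model)
  } else {
    ml_search(aln, model, start = "stepwise", n_starts = n_starts)$tree
  }
}

#' Scan expected clade support across an effective-population-size grid
#'
#' For every Ne in the grid and every replicate: simulate one genealogy per
#' locus under the multispecies coalescent on the guide chronogram, evolve
#' sequences, estimate each locus's ML tree, and record which focal clades the
#' tree contains. A gene "supports" a clade when the clade is present in its
#' ML point-estimate tree. The full per-replicate table and the replicate
#' trees are retained so tallies can be audited without re-simulation.
#'
#' @param guide ultrametric guide tree (`phylo`, heights in Ma).
#' @param grid strictly increasing vector of (nuclear-reference) Ne values.
#' @param loci list of [locus_model()]s.
#' @param clades named list of focal clades (character vectors).
#' @param reps replicates per Ne (default 200).
#' @param seed integer; drives all simulation streams reproducibly.
#' @param generation_time years/generation.
#' @param engine `"fasttree"` (default) or `"nni"` (internal search).
#' @return list of class `ils_scan`: `table` (Ne, rep, locus, clade,
#'   contained), `trees` (Ne, rep, locus, newick), `clades`, `grid`, `reps`.
#' @export
run_ils_scan <- function(guide, grid, loci, clades, reps = 200, seed = 1,
                         generation_time = 7,
                         engine = c("fasttree", "nni")) {
  engine <- match.arg(engine)
  if (is.unsorted(grid, strictly = TRUE)) stop("Ne grid must be strictly increasing")
  tasks <- expand.grid(locus = seq_along(loci), rep = seq_len(reps),
                       ne = grid)
  seeds <- .substream_seeds(seed, nrow(tasks))
  rows <- vector("list", nrow(tasks))
  trees <- character(nrow(tasks))
  for (i in seq_len(nrow(tasks))) {
    set.seed(seeds[i])
    ne <- tasks$ne[i]; li <- tasks$locus[i]
    locus <- loci[[li]]
    params <- pop_params(ne, generation_time)
    gen <- simulate_genealogy(guide, params, locus)
    aln <- simulate_alignment(gen, locus$model, locus$length)
    tr <- .infer_tree(aln, locus$model, engine)
    trees[i] <- write_newick(tr)
    rows[[i]] <- data.frame(
      Ne = ne, rep = tasks$rep[i], locus = locus$name,
      clade = names(clades),
      contained = vapply(clades, tree_has_clade, logical(1), tree = tr),
      row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  tree_tab <- data.frame(Ne = tasks$ne, rep = tasks$rep,
                         locus = vapply(loci, `[[`, character(1),
                                        "name")[tasks$locus],
                         newick = trees)
  structure(list(table = tab, trees = tree_tab, clades = clades,
                 grid = grid, reps = reps, seed = seed, engine = engine),
            class = "ils_scan")
}

#' Expected (and observed) gene support per clade
#'
#' Summarizes an [run_ils_scan()] result: for each Ne and clade, the mean
#' number of loci whose ML tree contains the clade, over replicates.
#'
#' @param scan an `ils_scan`.
#' @param observed optional named integer vector: observed number of genes
#'   supporting each clade in the real data.
#' @return data.frame of class `support_profile`: `Ne`, `clade`, `expected`,
#'   and `observed` when supplied.
#' @export
support_profile <- function(scan, observed = NULL) {
  tab <- scan$table
  counts <- stats::aggregate(contained ~ Ne + rep + clade, tab, sum)
  prof <- stats::aggregate(contained ~ Ne + clade, counts, mean)
  names(prof)[names(prof) == "contained"] <- "expected"
  if (!is.null(observed)) {
    miss <- setdiff(prof$clade, names(observed))
    if (length(miss)) stop("observed counts missing for: ",
                           paste(miss, collapse = ", "))
    prof$observed <- as.numeric(observed[prof$clade])
  }
  class(prof) <- c("support_profile", class(prof))
  prof
}

#' Sum-of-squares fit between expected and observed clade support
#'
#' @param profile a [support_profile()] with an `observed` column.
#' @param ne the Ne value at which to evaluate the fit.
#' @return `sum((expected - observed)^2)` over clades.
#' @export
sum_of_squares <- function(profile, ne) {
  if (is.null(profile$observed)) stop("profile has no observed support")
  sub <- profile[profile$Ne == ne, ]
  if (!nrow(sub)) stop("Ne value not in profile: ", ne)
  sum((sub$expected - sub$observed)^2)
}

#' Placement queries over replicate trees
#'
#' Constructs a predicate to apply to inferred trees. Three forms:
#' `in_clade` (the focal taxon's sister group is exactly / within the given
#' clade -- i.e. the tree contains `c(focal, clade)` as a clade),
#' `monophyly` (the tree contains the taxon set as a clade), and
#' `attach_depth` (the focal taxon attaches as sister to a group whose crown
#' age on the guide tree is at most `max_age`, the group not intersecting
#' `exclude`; the guide tree supplies the age scale).
#'
#' @param type one of `"in_clade"`, `"monophyly"`, `"attach_depth"`.
#' @param focal focal taxon (for `in_clade` / `attach_depth`).
#' @param taxa taxon set (for `monophyly` / `in_clade`).
#' @param max_age crown-age ceiling in Ma (`attach_depth`).
#' @param exclude taxa the sister group must avoid (`attach_depth`).
#' @param guide guide chronogram including the focal taxon (`attach_depth`);
#'   ages are measured after dropping the focal tip.
#' @param outgroup tip(s) used to root inferred trees before sister-group
#'   queries.
#' @return function(tree) -> logical, class `placement_query`.
#' @export
placement_query <- function(type = c("in_clade", "monophyly", "attach_depth"),
                            focal = NULL, taxa = NULL, max_age = NULL,
                            exclude = NULL, guide = NULL,
                            outgroup = NULL) {
  type <- match.arg(type)
  if (type == "monophyly") {
    stopifnot(!is.null(taxa))
    f <- function(tree) tree_has_clade(tree, taxa)
  } else if (type == "in_clade") {
    stopifnot(!is.null(focal), !is.null(taxa))
    f <- function(tree) tree_has_clade(tree, union(focal, taxa))
  } else {
    stopifnot(!is.null(focal), !is.null(max_age), !is.null(guide),
              !is.null(outgroup))
    guide_wo <- ape::drop.tip(guide, focal)
    f <- function(tree) {
      rt <- root_on_outgroup(tree, outgroup)
      sis <- sister_group(rt, focal)
      if (!length(sis)) return(FALSE)
      if (!is.null(exclude) && length(intersect(sis, exclude))) return(FALSE)
      mrca_age(guide_wo, sis) <= max_age
    }
  }
  structure(f, class = c("placement_query", "function"))
}

#' Sister group of a tip in a rooted tree
#'
#' @param tree rooted `phylo`.
#' @param tip tip label.
#' @return character vector of the tip labels subtended by the tip's sibling
#'   edge(s); empty if the tip is attached at the root.
#' @export
sister_group <- function(tree, tip) {
  id <- match(tip, tree$tip.label)
  if (is.na(id)) stop("tip not in tree: ", tip)
  parent <- tree$edge[tree$edge[, 2] == id, 1]
  if (!length(parent)) return(character(0))
  masks <- node_masks(tree)
  sibs <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], id)
  idx <- unlist(lapply(sibs, function(s) {
    which(bitwAnd(as.integer(masks[s]), as.integer(2^(seq_along(tree$tip.label) - 1))) > 0)
  }))
  tree$tip.label[sort(unique(idx))]
}

#' Fraction of replicate trees satisfying a placement query
#'
#' @param trees list/multiPhylo of trees, or an `ils_scan` (optionally
#'   filtered with `locus` / `ne`).
#' @param query a [placement_query()].
#' @param locus,ne optional filters when `trees` is an `ils_scan`.
#' @return fraction in `[0, 1]`.
#' @export
placement_frequency <- function(trees, query, locus = NULL, ne = NULL) {
  if (inherits(trees, "ils_scan")) {
    tt <- trees$trees
    if (!is.null(locus)) tt <- tt[tt$locus %in% locus, ]
    if (!is.null(ne)) tt <- tt[tt$Ne %in% ne, ]
    trees <- lapply(tt$newick, parse_newick)
  }
  if (!length(trees)) stop("no replicate trees")
  mean(vapply(trees, function(tr) isTRUE(query(tr)), logical(1)))
}

# branch-length transfer between topologies sharing most splits
.transfer_el <- function(from, to, default = 0.01) {
  taxa <- sort(from$tip.label)
  full <- sum(2^(seq_along(taxa) - 1))
  canon <- function(m) pmin(m, full - m)
  mf <- canon(node_masks(from, taxa))
  mt <- canon(node_masks(to, taxa))
  lens <- stats::setNames(from$edge.length, mf[from$edge[, 2]])
  el <- lens[as.character(mt[to$edge[, 2]])]
  el[is.na(el)] <- default
  to$edge.length <- unname(el)
  to
}

#' Gene-number power scan for clade resolution
#'
#' Simulated genes (default 1,000 bp) are added in increments (default 5);
#' after each increment the genes simulated so far are concatenated, the ML
#' tree is estimated, and bootstrap support for each target clade is
#' computed. Each run continues until every target clade has reached
#' `target_bp` percent support (or `max_genes` is hit, recorded as censored).
#' Bootstrap support uses RELL resampling over the NNI envelope of the
#' concatenated ML tree by default (`boot_mode = "rell"`); `"full"` re-runs
#' the tree search per bootstrap replicate via FastTree.
#'
#' @param guide guide chronogram (Ma).
#' @param params a [pop_params()].
#' @param locus template [locus_model()] for the simulated genes (its length
#'   is the per-gene length).
#' @param clades named list of target clades.
#' @param increment genes added per step (default 5).
#' @param runs independent runs (default 10).
#' @param target_bp bootstrap percentage to reach (default 95).
#' @param max_genes cap per run (default 35).
#' @param boot_reps bootstrap replicates per increment (default 100).
#' @param boot_mode `"rell"` or `"full"`.
#' @param seed integer.
#' @param engine ML engine for the point-estimate tree.
#' @return list of class `power_scan`: `summary` (run, clade, genes_needed,
#'   censored), `trajectory` (run, genes, clade, support).
#' @export
power_scan <- function(guide, params, locus, clades, increment = 5,
                       runs = 10, target_bp = 95, max_genes = 35,
                       boot_reps = 100, boot_mode = c("rell", "full"),
                       seed = 1, engine = c("fasttree", "nni")) {
  boot_mode <- match.arg(boot_mode)
  engine <- match.arg(engine)
  run_seeds <- .substream_seeds(seed, runs)
  traj <- list(); summ <- list()
  for (r in seq_len(runs)) {
    set.seed(run_seeds[r])
    genes <- list()
    reached <- stats::setNames(rep(NA_integer_, length(clades)),
                               names(clades))
    g <- 0L
    while (g < max_genes && anyNA(reached)) {
      for (j in seq_len(increment)) {
        gen <- simulate_genealogy(guide, params, locus)
        genes[[length(genes) + 1L]] <-
          unclass(simulate_alignment(gen, locus$model, locus$length))
      }
      g <- g + increment
      concat <- alignment(do.call(cbind, genes))
      supp <- .concat_bootstrap_support(concat, locus$model, clades,
                                        boot_reps, boot_mode, engine)
      for (cl in names(clades)) {
        traj[[length(traj) + 1L]] <- data.frame(
          run = r, genes = g, clade = cl, support = supp[[cl]])
        if (is.na(reached[[cl]]) && supp[[cl]] >= target_bp) {
          reached[[cl]] <- g
        }
      }
    }
    for (cl in names(clades)) {
      summ[[length(summ) + 1L]] <- data.frame(
        run = r, clade = cl,
        genes_needed = if (is.na(reached[[cl]])) NA_integer_ else reached[[cl]],
        censored = is.na(reached[[cl]]))
    }
  }
  structure(list(summary = do.call(rbind, summ),
                 trajectory = do.call(rbind, traj),
                 target_bp = target_bp, boot_reps = boot_reps,
                 boot_mode = boot_mode),
            class = "power_scan")
}

# bootstrap support for clades on a concatenated alignment
.concat_bootstrap_support <- function(aln, model, clades, reps, mode,
                                      engine) {
  ml <- .infer_tree(aln, model, engine)
  ml <- ape::unroot(ml)
  if (mode == "full") {
    mats <- lapply(seq_len(reps), function(i) {
      unclass(aln)[, sample.int(ncol(aln), replace = TRUE), drop = FALSE]
    })
    trees <- .fasttree_many(mats, gtr = !identical(model$family, "JC"))
    return(vapply(clades, function(cl) {
      100 * mean(vapply(trees, tree_has_clade, logical(1), clade = cl))
    }, numeric(1)))
  }
  # RELL over the NNI envelope of the ML tree; one pattern compression and
  # one engine per candidate, site log-likelihoods read off the engine
  pd <- .pattern_data(unclass(aln))
  E <- .make_engine(ml, unclass(aln), model, pd = pd)
  .engine_optimize(E, tol = 1e-3, max_sweeps = 3)
  ml_fit <- .tree_with_el(E)
  site_lnl_of <- function(En) .pattern_lnl(En)[En$map]
  nbrs <- phangorn::nni(ml_fit)
  cands <- vector("list", length(nbrs) + 1L)
  cands[[1]] <- ml_fit
  L <- matrix(0, ncol(aln), length(cands))
  L[, 1] <- site_lnl_of(E)
  for (i in seq_along(nbrs)) {
    nb <- .transfer_el(ml_fit, nbrs[[i]])
    En <- .make_engine(nb, unclass(aln), model, pd = pd)
    # refresh only edges lacking a transferred length (the swap region)
    fresh <- which(abs(En$el - 0.01) < 1e-12)
    nodes <- unique(En$tree$edge[fresh, 2])
    .down_pass(En)
    if (length(nodes)) { .sweep_edges(En, nodes = nodes, brent_tol = 1e-5)
      .sweep_edges(En, nodes = nodes, brent_tol = 1e-5) }
    cands[[i + 1L]] <- .tree_with_el(En)
    L[, i + 1L] <- site_lnl_of(En)
  }
  winners <- .rell_winners(L, reps)
  vapply(clades, function(cl) {
    has <- vapply(cands, tree_has_clade, logical(1), clade = cl)
    100 * mean(has[winners])
  }, numeric(1))
}

.rell_winners <- function(L, reps) {
  nsite <- nrow(L)
  winners <- integer(reps)
  done <- 0L; block <- 2000L
  while (done < reps) {
    b <- min(block, reps - done)
    counts <- stats::rmultinom(b, nsite, rep(1 / nsite, nsite))
    R <- crossprod(counts, L)
    winners[done + seq_len(b)] <- max.col(R, ties.method = "first")
    done <- done + b
  }
  winners
}
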