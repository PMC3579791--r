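.as_phydat <- function(aln) {
  phangorn::phyDat(unclass(aln), type = "DNA")
}

.start_trees <- function(aln, start, n_starts) {
  taxa <- rownames(aln)
  if (inherits(start, "phylo")) return(list(ape::unroot(start)))
  if (inherits(start, "multiPhylo")) return(lapply(start, ape::unroot))
  if (identical(start, "nj")) {
    d <- ape::dist.dna(ape::as.DNAbin(tolower(unclass(aln))), model = "JC69",
                       pairwise.deletion = TRUE)
    d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 2
    return(list(ape::unroot(ape::nj(d))))
  }
  if (identical(start, "stepwise")) {
    pd <- .as_phydat(aln)
    return(lapply(seq_len(n_starts), function(i) {
      ape::unroot(phangorn::random.addition(pd))
    }))
  }
  stop("unknown start: supply a tree, \"nj\" or \"stepwise\"")
}

#' Maximum-likelihood tree search
#'
#' NNI hill-climbing from one or more start trees (random-addition-order
#' parsimony starts by default, 20 of them, or neighbor joining, or a supplied
#' tree), with branch lengths re-optimized at every step; the best tree over
#' all starts is returned. With `method = "exhaustive"` (<= 6 taxa) every
#' unrooted topology is scored instead. Ties among equal-likelihood neighbors
#' (|diff| < 1e-8) are broken first-found, so searches are reproducible under
#' a fixed seed.
#'
#' @inheritParams log_likelihood
#' @param start `"stepwise"`, `"nj"`, or a `phylo`/`multiPhylo` of start
#'   trees.
#' @param n_starts number of random-addition starts (default 20).
#' @param method `"nni"` or `"exhaustive"`.
#' @param tol lnL convergence tolerance.
#' @return `lik_result` list: `lnL`, `tree` (unrooted, optimized lengths),
#'   `multipliers`, plus `n_evaluated`.
#' @export
ml_search <- function(aln, models, scheme = NULL, start = "stepwise",
                      n_starts = 20, method = c("nni", "exhaustive"),
                      tol = 1e-4) {
  method <- match.arg(method)
  if (nrow(aln) < 4) stop("ML search requires at least 4 taxa")
  n_eval <- 0L
  fit_tree <- function(tr, sweeps = 30) {
    n_eval <<- n_eval + 1L
    optimize_branch_lengths(tr, aln, models, scheme, tol = tol,
                            max_sweeps = sweeps)
  }
  if (method == "exhaustive") {
    if (nrow(aln) > 6) stop("exhaustive search limited to 6 taxa")
    trees <- phangorn::allTrees(nrow(aln), rooted = FALSE,
                                tip.label = rownames(aln))
    fits <- lapply(trees, fit_tree)
    lnls <- vapply(fits, `[[`, numeric(1), "lnL")
    best <- fits[[which.max(lnls)]]
    best$n_evaluated <- n_eval
    return(best)
  }
  best <- NULL
  for (st in .start_trees(aln, start, n_starts)) {
    cur <- fit_tree(st)
    repeat {
      nbrs <- phangorn::nni(cur$tree)
      scores <- vapply(nbrs, function(nb) {
        nb$edge.length <- NULL
        fit_tree(nb, sweeps = 3)$lnL
      }, numeric(1))
      top <- which.max(scores)
      if (scores[top] > cur$lnL + 1e-8) {
        nb <- nbrs[[top]]; nb$edge.length <- NULL
        cur <- fit_tree(nb)
      } else break
    }
    if (is.null(best) || cur$lnL > best$lnL) best <- cur
  }
  best$n_evaluated <- n_eval
  best
}

#' Nonparametric bootstrap clade support
#'
#' `mode = "full"` re-runs the ML search on each site-resampled alignment;
#' `mode = "RELL"` resamples per-site log-likelihoods over a fixed candidate
#' tree set (each candidate's branch lengths optimized once on the original
#' data) and counts how often each candidate wins. Support for a clade is the
#' percentage of replicates whose (re-estimated or winning) tree contains it.
#'
#' @inheritParams ml_search
#' @param reps bootstrap replicates (default 500).
#' @param mode `"full"` or `"RELL"`.
#' @param candidates `multiPhylo` candidate set, required for RELL.
#' @param clades optional named list of clades (character vectors) to tally.
#' @param n_starts random-addition starts per full-bootstrap search.
#' @return list of class `bootstrap_support`: `trees` (multiPhylo of
#'   replicate trees), `reps`, `mode`, and `support` (named percentages, if
#'   `clades` given).
#' @export
bootstrap <- function(aln, models, scheme = NULL, reps = 500,
                      mode = c("full", "RELL"), candidates = NULL,
                      clades = NULL, n_starts = 1) {
  mode <- match.arg(mode)
  stopifnot(reps >= 1)
  nsite <- ncol(aln)
  if (mode == "full") {
    trees <- vector("list", reps)
    for (r in seq_len(reps)) {
      idx <- sample.int(nsite, replace = TRUE)
      sub <- alignment(unclass(aln)[, idx, drop = FALSE])
      trees[[r]] <- ml_search(sub, models, scheme = NULL,
                              n_starts = n_starts)$tree
    }
  } else {
    if (is.null(candidates) || length(candidates) < 2) {
      stop("RELL mode needs a candidate tree set (>= 2 trees)")
    }
    L <- vapply(candidates, function(tr) {
      site_log_likelihoods(tr, aln, models, scheme)$site_lnL
    }, numeric(nsite))                      # nsite x ntree
    winners <- .rell_winners(L, reps)
    trees <- lapply(winners, function(i) candidates[[i]])
  }
  class(trees) <- "multiPhylo"
  out <- list(trees = trees, reps = reps, mode = mode)
  if (!is.null(clades)) {
    out$support <- vapply(clades, function(cl) {
      100 * mean(vapply(trees, tree_has_clade, logical(1), clade = cl))
    }, numeric(1))
  }
  class(out) <- "bootstrap_support"
  out
}

#' Clade containment for possibly unrooted trees
#'
#' A clade query on an unrooted tree asks whether some split separates the
#' clade from all remaining taxa; for rooted trees this reduces to
#' [contains_clade()].
#'
#' @param tree `phylo`.
#' @param clade character vector of tip labels.
#' @return logical.
#' @export
tree_has_clade <- function(tree, clade) {
  clade <- unique(clade)
  if (!all(clade %in% tree$tip.label)) {
    stop("clade taxa missing from tree")
  }
  if (length(clade) <= 1) return(TRUE)
  if (length(clade) >= length(tree$tip.label) - 1) {
    return(length(clade) == length(tree$tip.label) - 1 ||
             length(clade) == length(tree$tip.label))
  }
  masks <- node_masks(tree)
  target <- mask_of(clade, tree$tip.label)
  full <- sum(2^(seq_along(tree$tip.label) - 1))
  any(masks == target) || any(masks == full - target)
}

#' KH and SH topology tests by RELL resampling
#'
#' Per-site log-likelihoods are computed for every candidate (branch lengths
#' optimized per tree), then resampled `reps` times. The SH test uses the
#' standard max-centering convention (each tree's resampled log-likelihoods
#' are centered at its own mean, the test statistic is the deficit from the
#' per-replicate maximum), so the ML tree gets the largest p-value. KH
#' p-values are one-sided pairwise comparisons against the ML tree.
#'
#' @inheritParams ml_search
#' @param candidate_trees `multiPhylo` (>= 2 trees).
#' @param reps RELL resampling replicates (default 1e5).
#' @return data.frame: `tree`, `lnL`, `delta` (lnL_best - lnL), `p_KH`,
#'   `p_SH`, `identical_sites` (flag: site-likelihood vector identical to the
#'   best tree's).
#' @export
kh_sh_test <- function(aln, candidate_trees, models, scheme = NULL,
                       reps = 1e5) {
  if (length(candidate_trees) < 2) stop("need >= 2 candidate trees")
  nsite <- ncol(aln)
  L <- vapply(candidate_trees, function(tr) {
    site_log_likelihoods(tr, aln, models, scheme)$site_lnL
  }, numeric(nsite))                        # nsite x m
  m <- ncol(L)
  lnl <- colSums(L)
  best <- which.max(lnl)
  delta <- lnl[best] - lnl
  ident <- vapply(seq_len(m), function(i) {
    max(abs(L[, i] - L[, best])) < 1e-12
  }, logical(1))
  # resampled, centered sums (chunked)
  p_sh_ge <- numeric(m); p_kh_ge <- numeric(m)
  centered <- sweep(L, 2, colMeans(L))      # site-wise centered lnL
  done <- 0L; block <- 2000L
  while (done < reps) {
    b <- min(block, reps - done)
    counts <- stats::rmultinom(b, nsite, rep(1 / nsite, nsite))
    S <- crossprod(counts, centered)        # b x m, centered resampled sums
    mx <- S[cbind(seq_len(b), max.col(S, ties.method = "first"))]
    for (i in seq_len(m)) {
      p_sh_ge[i] <- p_sh_ge[i] + sum((mx - S[, i]) >= delta[i])
      p_kh_ge[i] <- p_kh_ge[i] + sum((S[, best] - S[, i]) >= delta[i])
    }
    done <- done + b
  }
  p_sh <- p_sh_ge / reps
  p_kh <- p_kh_ge / reps
  p_kh[best] <- 1; p_sh[best] <- 1
  p_kh[ident] <- 1; p_sh[ident] <- 1
  data.frame(tree = seq_len(m), lnL = lnl, delta = delta,
             p_KH = p_kh, p_SH = p_sh, identical_sites = ident)
}

#' Fitch parsimony length
#'
#' Minimum number of state changes over all sites (unordered states, gaps and
#' ambiguities as missing), via `phangorn::fitch`.
#'
#' @param tree `phylo` over the alignment's taxa.
#' @param aln an [alignment()].
#' @return integer parsimony length.
#' @export
fitch_length <- function(tree, aln) {
  pd <- .as_phydat(aln)
  as.integer(phangorn::fitch(tree, pd))
}

# FastTree ---------------------------------------------------------------------

#' Is the FastTree binary available?
#' @return logical.
#' @export
fasttree_available <- function() nzchar(Sys.which("fasttree"))

#' Approximate-ML gene tree via FastTree
#'
#' Fast engine for large replicate scans: FastTree 2 (NNI+SPR search, CAT rate
#' approximation), GTR unless the model family is JC. Output is an unrooted
#' tree without support values. FastTree is deterministic for a fixed input.
#'
#' @param aln an [alignment()].
#' @param model a [subst_model()] (only the family is consulted).
#' @return unrooted `phylo`.
#' @export
fasttree_tree <- function(aln, model = subst_model("GTR")) {
  if (!fasttree_available()) stop("fasttree binary not found on PATH")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".tre")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(aln, fin)
  args <- c("-nt", "-quiet", "-nosupport")
  if (!identical(model$family, "JC")) args <- c(args, "-gtr")
  status <- system2("fasttree", c(args, fin), stdout = fout,
                    stderr = FALSE)
  if (status != 0) stop("fasttree failed with status ", status)
  tr <- ape::read.tree(fout)
  tr$tip.label <- trimws(tr$tip.label)
  tr
}

# Many alignments in one FastTree process (interleaved PHYLIP, repeated names,
# blank line between blocks -- the dialect FastTree's -n mode expects).
.fasttree_many <- function(mats, gtr = TRUE) {
  if (!fasttree_available()) stop("fasttree binary not found on PATH")
  fin <- tempfile(fileext = ".phy"); fout <- tempfile(fileext = ".tre")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  taxa <- rownames(mats[[1]])
  short <- paste0("t", seq_along(taxa))   # strict-PHYLIP-safe aliases
  con <- file(fin, "w")
  for (m in mats) {
    stopifnot(identical(rownames(m), taxa))
    nt <- nrow(m); ns <- ncol(m)
    writeLines(paste(nt, ns), con)
    starts <- seq(1, ns, by = 1000)
    for (b in starts) {
      cols <- b:min(b + 999, ns)
      for (i in seq_len(nt)) {
        writeLines(paste0(sprintf("%-10s", short[i]),
                          paste(m[i, cols], collapse = "")), con)
      }
      writeLines("", con)
    }
  }
  close(con)
  args <- c("-nt", "-quiet", "-nosupport", if (gtr) "-gtr",
            "-n", length(mats))
  status <- system2("fasttree", c(args, fin), stdout = fout, stderr = FALSE)
  if (status != 0) stop("fasttree failed with status ", status)
  trees <- ape::read.tree(fout)
  if (inherits(trees, "phylo")) trees <- c(trees)
  for (i in seq_along(trees)) {
    trees[[i]]$tip.label <- taxa[match(trimws(trees[[i]]$tip.label), short)]
  }
  trees
}
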