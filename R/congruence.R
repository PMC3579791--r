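# Incongruence and stationarity tests: ML parametric bootstrap homogeneity,
# ILD, and chi-squared base-composition homogeneity.

.common_taxa <- function(gene_alns) {
  taxa <- rownames(gene_alns[[1]])
  for (g in gene_alns[-1]) {
    if (!setequal(rownames(g), taxa)) {
      if (!length(intersect(rownames(g), taxa))) {
        stop("genes have disjoint taxon sets")
      }
      stop("genes must share a common taxon set")
    }
  }
  taxa
}

.gene_models <- function(models, n) {
  if (inherits(models, "subst_model")) models <- rep(list(models), n)
  if (length(models) != n) stop("need one model per gene (or a single model)")
  models
}

# best single topology for a set of genes: maximizes the sum of per-gene
# lnL (branch lengths and models per gene). Returns lnL sum, topology and the
# per-gene fitted trees.
.shared_fit <- function(gene_alns, models, exhaustive, n_starts, tol) {
  taxa <- rownames(gene_alns[[1]])
  score <- function(topo) {
    fits <- lapply(seq_along(gene_alns), function(i) {
      tr <- topo; tr$edge.length <- NULL
      optimize_branch_lengths(tr, gene_alns[[i]], models[[i]], tol = tol)
    })
    list(lnL = sum(vapply(fits, `[[`, numeric(1), "lnL")), fits = fits)
  }
  if (exhaustive) {
    topos <- phangorn::allTrees(length(taxa), rooted = FALSE,
                                tip.label = taxa)
    scored <- lapply(topos, score)
    lnls <- vapply(scored, `[[`, numeric(1), "lnL")
    best <- which.max(lnls)
    return(list(lnL = lnls[best], topology = topos[[best]],
                fits = scored[[best]]$fits))
  }
  # NNI hill-climb on the summed objective from a concatenated NJ start
  concat <- alignment(do.call(cbind, lapply(gene_alns, function(g) {
    unclass(g)[taxa, , drop = FALSE]
  })))
  cur_topo <- .start_trees(concat, "nj", 1)[[1]]
  cur <- score(cur_topo)
  repeat {
    nbrs <- phangorn::nni(cur_topo)
    sc <- lapply(nbrs, score)
    lnls <- vapply(sc, `[[`, numeric(1), "lnL")
    top <- which.max(lnls)
    if (lnls[top] > cur$lnL + 1e-8) {
      cur_topo <- nbrs[[top]]; cur <- sc[[top]]
    } else break
  }
  list(lnL = cur$lnL, topology = cur_topo, fits = cur$fits)
}

.free_fit <- function(gene_alns, models, exhaustive, n_starts, tol) {
  fits <- lapply(seq_along(gene_alns), function(i) {
    if (exhaustive) {
      ml_search(gene_alns[[i]], models[[i]], method = "exhaustive", tol = tol)
    } else {
      ml_search(gene_alns[[i]], models[[i]], start = "stepwise",
                n_starts = n_starts, tol = tol)
    }
  })
  list(lnL = sum(vapply(fits, `[[`, numeric(1), "lnL")), fits = fits)
}

#' Likelihood parametric-bootstrap test of topological homogeneity
#'
#' The statistic is the likelihood improvement of letting every gene have its
#' own topology over forcing one shared topology T* (branch lengths and
#' substitution models are per-gene in both fits). Its null distribution is
#' built by simulating `n_sims` multi-gene datasets on T* with each gene's
#' fitted branch lengths and model, and recomputing the statistic on each.
#' The Monte-Carlo p-value uses the (1 + exceedances)/(n + 1) convention.
#'
#' @param gene_alns list of [alignment()]s over a common taxon set.
#' @param models a [subst_model()] or list, one per gene.
#' @param n_sims simulated datasets for the null (default 200).
#' @param search `"auto"` (exhaustive when <= 6 taxa), `"exhaustive"`, or
#'   `"nni"`.
#' @param n_starts random-addition starts for NNI searches.
#' @param tol lnL tolerance passed to the optimizers.
#' @return list of class `homogeneity_result`: `delta` (observed statistic,
#'   >= 0), `null` (simulated statistics), `p_value`, `shared_topology`,
#'   `lnL_shared`, `lnL_free`.
#' @export
parametric_homogeneity_test <- function(gene_alns, models, n_sims = 200,
                                        search = c("auto", "exhaustive",
                                                   "nni"),
                                        n_starts = 2, tol = 1e-4) {
  search <- match.arg(search)
  if (length(gene_alns) < 2) stop("need >= 2 genes")
  taxa <- .common_taxa(gene_alns)
  models <- .gene_models(models, length(gene_alns))
  exhaustive <- switch(search, auto = length(taxa) <= 6,
                       exhaustive = TRUE, nni = FALSE)
  # exhaustive path: one per-(topology, gene) fit matrix serves both the
  # shared-topology and free-topology maximizations
  delta_exhaustive <- function(alns) {
    topos <- phangorn::allTrees(length(taxa), rooted = FALSE,
                                tip.label = taxa)
    fits <- lapply(topos, function(tp) {
      lapply(seq_along(alns), function(i) {
        tr <- tp; tr$edge.length <- NULL
        optimize_branch_lengths(tr, alns[[i]], models[[i]], tol = tol)
      })
    })
    M <- do.call(rbind, lapply(fits, function(row) {
      vapply(row, `[[`, numeric(1), "lnL")
    }))
    shared_row <- which.max(rowSums(M))
    lnl_shared <- sum(M[shared_row, ])
    lnl_free <- sum(apply(M, 2, max))
    list(delta = max(lnl_free - lnl_shared, 0),
         shared = list(lnL = lnl_shared, topology = topos[[shared_row]],
                       fits = fits[[shared_row]]),
         free = list(lnL = lnl_free))
  }
  delta_of <- function(alns) {
    if (exhaustive) return(delta_exhaustive(alns))
    sh <- .shared_fit(alns, models, exhaustive, n_starts, tol)
    fr <- .free_fit(alns, models, exhaustive, n_starts, tol)
    list(delta = max(fr$lnL - sh$lnL, 0), shared = sh, free = fr)
  }
  obs <- delta_of(gene_alns)
  null <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    sims <- lapply(seq_along(gene_alns), function(i) {
      simulate_alignment(obs$shared$fits[[i]]$tree, models[[i]],
                         ncol(gene_alns[[i]]))
    })
    null[s] <- delta_of(sims)$delta
  }
  p <- (1 + sum(null >= obs$delta - 1e-9)) / (n_sims + 1)
  structure(list(delta = obs$delta, null = null, p_value = p,
                 shared_topology = obs$shared$topology,
                 lnL_shared = obs$shared$lnL, lnL_free = obs$free$lnL),
            class = "homogeneity_result")
}

# sites with >= 2 states (unambiguous A/C/G/T only) each seen >= 2 times
parsimony_informative <- function(aln) {
  apply(unclass(aln), 2, function(col) {
    tab <- table(col[col %in% NUC])
    sum(tab >= 2) >= 2
  })
}

# minimum parsimony length: exhaustive for <= 6 taxa, heuristic NNI search
# from a random-addition start otherwise
.mp_length <- function(aln, exhaustive = nrow(aln) <= 6) {
  pd <- .as_phydat(aln)
  if (exhaustive) {
    trees <- phangorn::allTrees(nrow(aln), rooted = FALSE,
                                tip.label = rownames(aln))
    return(min(phangorn::fitch(trees, pd)))
  }
  start <- phangorn::random.addition(pd)
  fit <- phangorn::optim.parsimony(start, pd, method = "fitch",
                                   rearrangements = "NNI", trace = 0)
  as.integer(attr(fit, "pscore"))
}

#' Incongruence length difference (ILD) test
#'
#' Statistic: combined-data minimum parsimony length minus the sum of
#' per-gene minimum lengths. The null distribution re-partitions sites at
#' random into classes of the original gene sizes (sampling without
#' replacement) and recomputes the statistic `n_reps` times.
#'
#' @param gene_alns list of [alignment()]s over a common taxon set.
#' @param n_reps random re-partitions (default 1000).
#' @return list of class `ild_result`: `ild` (observed statistic), `null`,
#'   `p_value`, `lengths` (per-gene and combined MP lengths),
#'   `uninformative_partitions` (names of genes without parsimony-informative
#'   sites, flagged but not excluded).
#' @export
ild_test <- function(gene_alns, n_reps = 1000) {
  if (length(gene_alns) < 2) stop("need >= 2 genes")
  taxa <- .common_taxa(gene_alns)
  gene_alns <- lapply(gene_alns, function(g) {
    alignment(unclass(g)[taxa, , drop = FALSE])
  })
  sizes <- vapply(gene_alns, ncol, integer(1))
  has_pi <- vapply(gene_alns, function(g) any(parsimony_informative(g)),
                   logical(1))
  gene_ids <- names(gene_alns)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_along(gene_alns))
  flagged <- gene_ids[!has_pi]
  if (length(flagged)) {
    warning("partition(s) without parsimony-informative sites: ",
            paste(flagged, collapse = ", "))
  }
  combined <- do.call(cbind, lapply(gene_alns, unclass))
  l_comb <- .mp_length(alignment(combined))
  l_genes <- vapply(gene_alns, .mp_length, numeric(1))
  ild_obs <- l_comb - sum(l_genes)
  nsite <- ncol(combined)
  grp_end <- cumsum(sizes)
  null <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    perm <- sample.int(nsite)
    tot <- 0
    s0 <- 1L
    for (gi in seq_along(sizes)) {
      cols <- perm[s0:grp_end[gi]]
      tot <- tot + .mp_length(alignment(combined[, cols, drop = FALSE]))
      s0 <- grp_end[gi] + 1L
    }
    null[r] <- l_comb - tot
  }
  p <- (1 + sum(null >= ild_obs)) / (n_reps + 1)
  structure(list(ild = ild_obs, null = null, p_value = p,
                 lengths = c(combined = l_comb, stats::setNames(l_genes,
                   names(gene_alns))),
                 uninformative_partitions = flagged),
            class = "ild_result")
}

#' Chi-squared base-composition homogeneity test
#'
#' For each partition class, builds the taxa x {A,C,G,T} contingency table
#' (after the requested site exclusions) and tests homogeneity of base
#' composition across taxa with the chi-squared statistic on
#' `(n_taxa - 1) * 3` degrees of freedom.
#'
#' @param aln an [alignment()].
#' @param scheme optional [partition_scheme()]; default a single class.
#' @param exclude any of `"uninformative"` (parsimony-uninformative sites)
#'   and `"gapped"` (sites with any gap or missing character among the tested
#'   taxa); default both.
#' @param taxa_subset optional ingroup restriction (character vector).
#' @return data.frame: `class`, `n_sites`, `chi2`, `df`, `p`.
#' @export
chi2_composition_test <- function(aln, scheme = NULL,
                                  exclude = c("uninformative", "gapped"),
                                  taxa_subset = NULL) {
  m <- unclass(aln)
  if (!is.null(taxa_subset)) {
    missing <- setdiff(taxa_subset, rownames(m))
    if (length(missing)) stop("taxa_subset not in alignment: ",
                              paste(missing, collapse = ", "))
    m <- m[taxa_subset, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("need >= 2 taxa")
  sites <- if (is.null(scheme)) list(all = seq_len(ncol(m)))
           else scheme_sites(scheme, ncol(m))
  rows <- list()
  for (cl in names(sites)) {
    sub <- m[, sites[[cl]], drop = FALSE]
    keep <- rep(TRUE, ncol(sub))
    if ("gapped" %in% exclude) {
      keep <- keep & apply(sub, 2, function(col) all(col %in% NUC))
    }
    if ("uninformative" %in% exclude) {
      keep <- keep & parsimony_informative(alignment(sub))
    }
    sub <- sub[, keep, drop = FALSE]
    if (ncol(sub) == 0) {
      warning("class ", cl, " empty after filtering; skipped")
      next
    }
    counts <- t(apply(sub, 1, function(r) {
      tabulate(match(r, NUC), nbins = 4)
    }))
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    ok <- expected > 0
    chi2 <- sum((counts[ok] - expected[ok])^2 / expected[ok])
    df <- (nrow(m) - 1) * 3
    rows[[cl]] <- data.frame(class = cl, n_sites = ncol(sub), chi2 = chi2,
                             df = df, p = stats::pchisq(chi2, df,
                                                        lower.tail = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
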