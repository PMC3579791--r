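# Felsenstein pruning engine.
#
# Likelihoods are computed over compressed site patterns, per discrete-gamma
# category, with per-node max-scaling of partial likelihood vectors to prevent
# underflow (log scalers are accumulated per pattern and re-added at the
# root). Gaps, '?' and IUPAC ambiguities contribute a partial likelihood of 1
# over their compatible states.

# fast column sums of a 4-row matrix
.colsum4 <- function(m) m[1, ] + m[2, ] + m[3, ] + m[4, ]

# fast column maxima of a small-row matrix
.cmax <- function(m) {
  out <- m[1, ]
  nr <- nrow(m)
  if (nr > 1) for (i in 2:nr) out <- pmax.int(out, m[i, ])
  out
}

.pattern_data <- function(aln) {
  key <- apply(aln, 2, paste, collapse = "\r")
  pat <- match(key, unique(key))
  first <- !duplicated(key)
  cols <- which(first)
  w <- tabulate(pat, nbins = length(cols))
  tipP <- lapply(rownames(aln), function(tx) {
    t(IUPAC_PARTIALS[aln[tx, cols], , drop = FALSE])
  })
  names(tipP) <- rownames(aln)
  list(tipP = tipP, weights = w, map = pat, npat = length(cols))
}

# engine state: tree bookkeeping + tip partials, used by all likelihood ops;
# pass a precomputed .pattern_data() as `pd` when scoring many trees on one
# alignment
.make_engine <- function(tree, aln, model, pd = NULL) {
  if (!setequal(tree$tip.label, rownames(aln))) {
    only_t <- setdiff(tree$tip.label, rownames(aln))
    only_a <- setdiff(rownames(aln), tree$tip.label)
    stop("taxon mismatch between tree and alignment; only in tree: {",
         paste(only_t, collapse = ","), "}, only in alignment: {",
         paste(only_a, collapse = ","), "}")
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  if (is.null(pd)) pd <- .pattern_data(aln)
  parent <- integer(nnode); edge_id <- integer(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_id[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  children <- vector("list", nnode)
  for (i in seq_len(nrow(tree$edge))) {
    children[[tree$edge[i, 1]]] <- c(children[[tree$edge[i, 1]]],
                                     tree$edge[i, 2])
  }
  root <- ntip + 1L
  el <- tree$edge.length
  if (is.null(el)) el <- rep(0.1, nrow(tree$edge))
  el <- pmax(el, 1e-9)
  env <- new.env(parent = emptyenv())
  env$tree <- tree; env$ntip <- ntip; env$nnode <- nnode; env$root <- root
  env$parent <- parent; env$edge_id <- edge_id; env$children <- children
  env$el <- el; env$model <- model
  env$tipP <- pd$tipP[tree$tip.label]  # ordered by tip id
  env$w <- pd$weights; env$map <- pd$map; env$npat <- pd$npat
  env$k <- length(model$cat_rates)
  env$D <- NULL
  env
}

.pmat <- function(model, t) {
  P <- model$left %*% (exp(model$eigenvalues * t) * model$right)
  P[P < 0] <- 0
  P
}

# message arriving at `node`'s parent through the edge above `node`:
# P(t * r_cat) %*% D[[cat]][[node]]
.msg <- function(E, node, cat, t = E$el[E$edge_id[node]]) {
  r <- E$model$cat_rates[cat]
  .pmat(E$model, t * r) %*% E$D[[cat]][[node]]
}

# full postorder pass; fills E$D (per category, per node: 4 x npat) and
# E$logsc (per node: npat log scalers, shared across categories is NOT valid,
# so logsc is per category too)
.down_pass <- function(E) {
  k <- E$k
  E$D <- vector("list", k)
  E$logsc <- vector("list", k)
  for (cat in seq_len(k)) {
    D <- vector("list", E$nnode)
    logsc <- vector("list", E$nnode)
    for (tp in seq_len(E$ntip)) {
      D[[tp]] <- E$tipP[[tp]]
      logsc[[tp]] <- numeric(E$npat)
    }
    E$D[[cat]] <- D; E$logsc[[cat]] <- logsc
    ord <- unique(E$tree$edge[, 1])  # postorder parents
    for (v in ord) .refresh_node(E, v, cat)
  }
  invisible(E)
}

# recompute D at internal node v (children partials assumed valid)
.refresh_node <- function(E, v, cat) {
  prod <- NULL; logsc <- numeric(E$npat)
  for (ch in E$children[[v]]) {
    m <- .msg(E, ch, cat)
    prod <- if (is.null(prod)) m else prod * m
    logsc <- logsc + E$logsc[[cat]][[ch]]
  }
  s <- .cmax(prod)
  s[s <= 0] <- 1
  E$D[[cat]][[v]] <- prod / rep(s, each = 4)
  E$logsc[[cat]][[v]] <- logsc + log(s)
  invisible(E)
}

# per-pattern log-likelihood from valid D partials
.pattern_lnl <- function(E) {
  k <- E$k
  if (k == 1L) {
    rootL <- .colsum4(E$model$base_freqs * E$D[[1]][[E$root]])
    return(log(rootL) + E$logsc[[1]][[E$root]])
  }
  lc <- matrix(0, k, E$npat)
  for (cat in seq_len(k)) {
    rootL <- .colsum4(E$model$base_freqs * E$D[[cat]][[E$root]])
    lc[cat, ] <- log(rootL) + E$logsc[[cat]][[E$root]]
  }
  mx <- .cmax(lc)
  mx + log(colMeans(exp(lc - rep(mx, each = k))))
}

.engine_lnl <- function(E) {
  .down_pass(E)
  sum(E$w * .pattern_lnl(E))
}

# "flux" above node: F[x,p] per category, the partial likelihood of
# everything outside node's subtree, seen at node's parent, with the
# stationary frequencies folded in at the root. Walks root -> node.
.flux_above <- function(E, node, cat) {
  path <- integer(0); v <- node
  while (v != E$root) { v <- E$parent[v]; path <- c(v, path) }
  U <- matrix(E$model$base_freqs, 4, E$npat)
  logscU <- numeric(E$npat)
  for (i in seq_along(path)) {
    v <- path[i]
    nxt <- if (i < length(path)) path[i + 1L] else node
    for (s in E$children[[v]]) {
      if (s == nxt) next
      U <- U * .msg(E, s, cat)
      logscU <- logscU + E$logsc[[cat]][[s]]
    }
    if (nxt != node) {
      r <- E$model$cat_rates[cat]
      U <- crossprod(.pmat(E$model, E$el[E$edge_id[nxt]] * r), U)
    }
    sc <- .cmax(U); sc[sc <= 0] <- 1
    U <- U / rep(sc, each = 4)
    logscU <- logscU + log(sc)
  }
  list(U = U, logsc = logscU)
}

# log-likelihood as a function of one edge length (edge above `node`),
# given valid D partials; returns a closure
.edge_objective <- function(E, node) {
  k <- E$k
  flux <- lapply(seq_len(k), function(cat) .flux_above(E, node, cat))
  Dn <- lapply(seq_len(k), function(cat) E$D[[cat]][[node]])
  base <- lapply(seq_len(k), function(cat) {
    flux[[cat]]$logsc + E$logsc[[cat]][[node]]
  })
  if (k == 1L) {
    U1 <- flux[[1]]$U; D1 <- Dn[[1]]; b1 <- base[[1]]; w <- E$w
    mdl <- E$model
    return(function(t) {
      M <- .pmat(mdl, t) %*% D1
      sum(w * (log(pmax.int(.colsum4(U1 * M), 1e-300)) + b1))
    })
  }
  function(t) {
    lc <- matrix(0, k, E$npat)
    for (cat in seq_len(k)) {
      r <- E$model$cat_rates[cat]
      M <- .pmat(E$model, t * r) %*% Dn[[cat]]
      lc[cat, ] <- log(pmax.int(.colsum4(flux[[cat]]$U * M), 1e-300)) +
        base[[cat]]
    }
    mx <- .cmax(lc)
    sum(E$w * (mx + log(colMeans(exp(lc - rep(mx, each = k))))))
  }
}

# after changing the edge above `node`, refresh partials up to the root
.bubble_up <- function(E, node) {
  v <- E$parent[node]
  while (v != 0) {
    for (cat in seq_len(E$k)) .refresh_node(E, v, cat)
    v <- E$parent[v]
  }
  invisible(E)
}

# one Gauss-Seidel sweep of branch-length optimization over `nodes` (each
# identifying the edge above it); D partials must be valid on entry
.sweep_edges <- function(E, nodes = NULL, brent_tol = 1e-8) {
  if (is.null(nodes)) nodes <- E$tree$edge[, 2]
  for (node in nodes) {
    f <- .edge_objective(E, node)
    cur <- E$el[E$edge_id[node]]
    upper <- max(10, 3 * cur)
    opt <- stats::optimize(f, c(1e-9, upper), maximum = TRUE, tol = brent_tol)
    if (opt$objective >= f(cur)) {
      E$el[E$edge_id[node]] <- opt$maximum
      .bubble_up(E, node)
    }
  }
  invisible(E)
}

.engine_optimize <- function(E, tol = 1e-6, max_sweeps = 30,
                             nodes = NULL) {
  .down_pass(E)
  last <- sum(E$w * .pattern_lnl(E))
  brent_tol <- min(1e-4, max(1e-8, tol * 1e-2))
  for (i in seq_len(max_sweeps)) {
    .sweep_edges(E, nodes = nodes, brent_tol = brent_tol)
    cur <- sum(E$w * .pattern_lnl(E))
    if (cur - last < tol) { last <- max(cur, last); break }
    last <- cur
  }
  last
}

.tree_with_el <- function(E) {
  tr <- E$tree
  tr$edge.length <- E$el
  tr
}

.as_model_list <- function(models, classes) {
  if (inherits(models, "subst_model")) {
    models <- stats::setNames(rep(list(models), length(classes)), classes)
  }
  if (is.null(names(models))) names(models) <- classes
  missing <- setdiff(classes, names(models))
  if (length(missing)) stop("no model for partition class(es): ",
                            paste(missing, collapse = ", "))
  models[classes]
}

#' Phylogenetic log-likelihood (Felsenstein pruning)
#'
#' Computes the log-likelihood of an alignment on a tree under GTR-family
#' models with discrete-gamma rate heterogeneity. With a partition scheme,
#' each site class gets its own model and branch-length multiplier and the
#' per-class log-likelihoods are summed. Gaps and ambiguities are treated as
#' missing data. The likelihood is invariant to root placement (reversible
#' models).
#'
#' @param tree a `phylo` with branch lengths in substitutions/site.
#' @param aln an [alignment()].
#' @param models a [subst_model()] or a named list of them (one per class).
#' @param scheme optional [partition_scheme()].
#' @param multipliers optional named per-class branch-length multipliers
#'   (default 1).
#' @param by_site if TRUE, attach attribute `"site_lnL"` (per-site vector, in
#'   alignment column order).
#' @return the log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(tree, aln, models, scheme = NULL,
                           multipliers = NULL, by_site = FALSE) {
  if (is.null(scheme)) {
    classes <- "all"
    sites <- list(all = seq_len(ncol(aln)))
  } else {
    sites <- scheme_sites(scheme, ncol(aln))
    classes <- names(sites)
  }
  models <- .as_model_list(models, classes)
  if (is.null(multipliers)) {
    multipliers <- stats::setNames(rep(1, length(classes)), classes)
  }
  total <- 0
  site_lnl <- if (by_site) numeric(ncol(aln)) else NULL
  for (cl in classes) {
    sub <- unclass(aln)[, sites[[cl]], drop = FALSE]
    tr <- tree
    tr$edge.length <- tree$edge.length * multipliers[[cl]]
    E <- .make_engine(tr, sub, models[[cl]])
    .down_pass(E)
    pl <- .pattern_lnl(E)
    total <- total + sum(E$w * pl)
    if (by_site) site_lnl[sites[[cl]]] <- pl[E$map]
  }
  if (by_site) attr(total, "site_lnL") <- site_lnl
  total
}

#' Optimize branch lengths (and partition rate multipliers)
#'
#' Coordinate-wise Brent optimization of each branch length, swept until the
#' log-likelihood improves by less than `tol` over a full sweep. With a
#' partition scheme, per-class branch-length multipliers (first class fixed to
#' 1) are optimized alternately with the shared lengths.
#'
#' @inheritParams log_likelihood
#' @param tol convergence tolerance on lnL.
#' @param max_sweeps cap on optimization sweeps.
#' @return list of class `lik_result`: `lnL`, `tree` (optimized lengths),
#'   `multipliers`.
#' @export
optimize_branch_lengths <- function(tree, aln, models, scheme = NULL,
                                    multipliers = NULL, tol = 1e-6,
                                    max_sweeps = 30) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length <- pmax(tree$edge.length, 1e-9)
  if (is.null(scheme)) {
    sub <- unclass(aln)
    models1 <- .as_model_list(models, "all")[[1]]
    E <- .make_engine(tree, sub, models1)
    lnl <- .engine_optimize(E, tol = tol, max_sweeps = max_sweeps)
    out <- list(lnL = lnl, tree = .tree_with_el(E),
                multipliers = c(all = 1))
    class(out) <- "lik_result"
    return(out)
  }
  sites <- scheme_sites(scheme, ncol(aln))
  classes <- names(sites)
  models <- .as_model_list(models, classes)
  if (is.null(multipliers)) {
    multipliers <- stats::setNames(rep(1, length(classes)), classes)
  }
  cur_tree <- tree
  obj <- function(tr, mult) {
    log_likelihood(tr, aln, models, scheme, mult)
  }
  last <- obj(cur_tree, multipliers)
  for (sweep in seq_len(max_sweeps)) {
    before <- last
    # shared branch lengths, full-evaluation Brent per edge
    for (e in seq_len(nrow(cur_tree$edge))) {
      f <- function(t) {
        tr <- cur_tree; tr$edge.length[e] <- t
        obj(tr, multipliers)
      }
      cur <- cur_tree$edge.length[e]
      opt <- stats::optimize(f, c(1e-9, max(10, 3 * cur)), maximum = TRUE,
                             tol = 1e-7)
      if (opt$objective >= last) {
        cur_tree$edge.length[e] <- opt$maximum
        last <- opt$objective
      }
    }
    # multipliers (first class anchored at 1)
    for (cl in classes[-1]) {
      f <- function(m) {
        mu <- multipliers; mu[[cl]] <- m
        obj(cur_tree, mu)
      }
      opt <- stats::optimize(f, c(1e-4, 100), maximum = TRUE, tol = 1e-6)
      if (opt$objective >= last) {
        multipliers[[cl]] <- opt$maximum
        last <- opt$objective
      }
    }
    if (last - before < tol) break
  }
  out <- list(lnL = last, tree = cur_tree, multipliers = multipliers)
  class(out) <- "lik_result"
  out
}

#' Per-site log-likelihoods on a fixed tree
#'
#' Branch lengths are first optimized, then per-site log-likelihoods are
#' returned (the RELL ingredients).
#'
#' @inheritParams log_likelihood
#' @param optimize whether to optimize branch lengths first (default TRUE).
#' @param ... passed to [optimize_branch_lengths()].
#' @return list: `lnL`, `site_lnL`, `tree`.
#' @export
site_log_likelihoods <- function(tree, aln, models, scheme = NULL,
                                 optimize = TRUE, ...) {
  if (optimize) {
    fit <- optimize_branch_lengths(tree, aln, models, scheme, ...)
    tree <- fit$tree
    mult <- fit$multipliers
  } else {
    mult <- NULL
  }
  lnl <- log_likelihood(tree, aln, models, scheme, mult, by_site = TRUE)
  list(lnL = as.numeric(lnl), site_lnL = attr(lnl, "site_lnL"), tree = tree)
}
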