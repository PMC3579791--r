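NUC <- c("A", "C", "G", "T")

# IUPAC ambiguity -> state indicator rows used for tip partial likelihoods
IUPAC_PARTIALS <- local({
  m <- rbind(
    A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
    U = c(0, 0, 0, 1),
    R = c(1, 0, 1, 0), Y = c(0, 1, 0, 1), S = c(0, 1, 1, 0), W = c(1, 0, 0, 1),
    K = c(0, 0, 1, 1), M = c(1, 1, 0, 0),
    B = c(0, 1, 1, 1), D = c(1, 0, 1, 1), H = c(1, 1, 0, 1), V = c(1, 1, 1, 0),
    N = c(1, 1, 1, 1), `-` = c(1, 1, 1, 1), `?` = c(1, 1, 1, 1))
  colnames(m) <- NUC
  m
})

#' GTR-family substitution model with discrete-gamma rate heterogeneity
#'
#' The rate matrix is normalized so that the mean substitution rate at
#' stationarity is 1; branch lengths are then in expected substitutions/site.
#' Gamma rate heterogeneity uses k equal-probability categories represented by
#' their category means (mean relative rate 1), matching the Seq-Gen
#' convention; a proportion `p_invariant` of sites may be held invariant.
#'
#' @param family `"JC"`, `"K2P"`, `"HKY"` or `"GTR"`.
#' @param base_freqs stationary frequencies (A,C,G,T), summing to 1.
#' @param rates exchangeabilities in the order AC, AG, AT, CG, CT, GT; GT is
#'   fixed to 1 for identifiability. For JC all are 1; for K2P/HKY supply
#'   `kappa` instead.
#' @param kappa transition/transversion rate ratio for K2P/HKY.
#' @param gamma_shape alpha of the gamma distribution of site rates, or `NULL`
#'   for rate homogeneity.
#' @param n_rate_categories number of discrete gamma categories (default 4).
#' @param p_invariant proportion of invariant sites in `[0, 1)`.
#' @return list of class `subst_model`, carrying the normalized rate matrix
#'   `Q`, its eigendecomposition, and the per-category relative rates.
#' @export
subst_model <- function(family = c("JC", "K2P", "HKY", "GTR"),
                        base_freqs = rep(0.25, 4), rates = rep(1, 6),
                        kappa = 2, gamma_shape = NULL, n_rate_categories = 4L,
                        p_invariant = 0) {
  family <- match.arg(family)
  stopifnot(length(base_freqs) == 4, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-8,
            p_invariant >= 0, p_invariant < 1)
  if (family %in% c("JC", "K2P")) base_freqs <- rep(0.25, 4)
  if (family %in% c("K2P", "HKY")) rates <- c(1, kappa, 1, 1, kappa, 1)
  if (family == "JC") rates <- rep(1, 6)
  stopifnot(length(rates) == 6, all(rates >= 0))
  rates <- rates / rates[6]  # GT = 1
  R <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  R[1, 2] <- R[2, 1] <- rates[1]; R[1, 3] <- R[3, 1] <- rates[2]
  R[1, 4] <- R[4, 1] <- rates[3]; R[2, 3] <- R[3, 2] <- rates[4]
  R[2, 4] <- R[4, 2] <- rates[5]; R[3, 4] <- R[4, 3] <- rates[6]
  Q <- R %*% diag(base_freqs)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))
  Q <- Q / mu
  # symmetrize for a stable eigendecomposition:  B = D^1/2 Q D^-1/2
  sq <- sqrt(base_freqs)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  # P(t) = D^-1/2 V exp(L t) V' D^1/2
  left <- diag(1 / sq) %*% eig$vectors
  right <- t(eig$vectors) %*% diag(sq)
  cat_rates <- 1
  if (!is.null(gamma_shape)) {
    stopifnot(gamma_shape > 0, n_rate_categories >= 1)
    cat_rates <- discrete_gamma_rates(gamma_shape, n_rate_categories)
  }
  structure(list(family = family, base_freqs = base_freqs, rates = rates,
                 kappa = if (family %in% c("K2P", "HKY")) kappa else NA_real_,
                 gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories),
                 p_invariant = p_invariant, Q = Q,
                 eigenvalues = eig$values, left = left, right = right,
                 cat_rates = cat_rates),
            class = "subst_model")
}

#' Mean relative rates of k equal-probability discrete gamma categories
#'
#' @param alpha gamma shape (rate = shape, so the mean is 1).
#' @param k number of categories.
#' @return numeric vector of k category means averaging exactly 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # E[X ; a < X < b] = P(Gamma(alpha+1, alpha) in (a,b)) for mean-1 gamma
  p <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  k * diff(p)
}

#' Transition probability matrix P(t)
#'
#' @param model a [subst_model()].
#' @param t branch length in expected substitutions/site (>= 0).
#' @return 4x4 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) stop("branch length must be non-negative, got ", t)
  P <- model$left %*% (exp(model$eigenvalues * t) * model$right)
  P[P < 0] <- 0
  dimnames(P) <- list(NUC, NUC)
  P
}

#' Simulate an alignment on a gene genealogy
#'
#' Evolves nucleotide sequences site-independently along a tree whose branch
#' lengths are in expected substitutions/site. The root sequence is drawn from
#' the model's stationary frequencies; each site keeps a single gamma rate
#' category (and possibly invariant status) across the whole tree; no indels
#' are generated, so the output length equals `length` exactly.
#'
#' @param genealogy a `genealogy` (from [simulate_genealogy()]) or a `phylo`
#'   with branch lengths in substitutions/site.
#' @param model a [subst_model()].
#' @param length number of sites (> 0).
#' @return an [alignment()] matrix (tips x sites).
#' @export
simulate_alignment <- function(genealogy, model, length) {
  if (length <= 0) stop("alignment length must be positive")
  tree <- if (inherits(genealogy, "genealogy")) genealogy$tree_subs else genealogy
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  nsite <- as.integer(length)
  k <- length(model$cat_rates)
  site_rate <- model$cat_rates[sample.int(k, nsite, replace = TRUE)]
  if (model$p_invariant > 0) {
    inv <- stats::runif(nsite) < model$p_invariant
    site_rate[inv] <- 0
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  states <- matrix(0L, nnode, nsite)
  states[root, ] <- sample.int(4, nsite, replace = TRUE,
                               prob = model$base_freqs)
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  el <- ape::reorder.phylo(tree, "cladewise")$edge.length
  rate_groups <- split(seq_len(nsite), site_rate)
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    for (g in names(rate_groups)) {
      r <- as.numeric(g); sites <- rate_groups[[g]]
      if (r == 0) { states[ch, sites] <- states[p, sites]; next }
      P <- transition_matrix(model, el[i] * r)
      cum <- t(apply(P, 1, cumsum))
      u <- stats::runif(length(sites))
      ps <- states[p, sites]
      # vectorized categorical draw: count thresholds exceeded
      draws <- 1L + (u > cum[cbind(ps, 1L)]) + (u > cum[cbind(ps, 2L)]) +
        (u > cum[cbind(ps, 3L)])
      states[ch, sites] <- draws
    }
  }
  m <- matrix(NUC[states[seq_len(ntip), , drop = FALSE]], ntip, nsite)
  rownames(m) <- tree$tip.label
  alignment(m)
}
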