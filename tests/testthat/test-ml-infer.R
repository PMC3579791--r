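test_that("two identical sequences at zero distance give L*log(1/4)", {
  a <- alignment(matrix(rep(c("A", "C", "G", "T"), 2), 2, 4, byrow = TRUE,
                        dimnames = list(c("A", "B"), NULL)))
  tr <- parse_newick("(A:1e-9,B:1e-9);")
  expect_equal(log_likelihood(tr, a, subst_model("JC")), 4 * log(0.25),
               tolerance = 1e-6)
})

test_that("pruning likelihood equals the exhaustive enumeration oracle", {
  set.seed(10)
  for (m in list(subst_model("JC"),
                 subst_model("HKY", base_freqs = c(.3, .2, .2, .3), kappa = 3,
                             gamma_shape = 0.5))) {
    sim <- sim_on_random_tree(4, 30, model = m)
    mine <- log_likelihood(sim$tree, sim$aln, m)
    oracle <- quartet_lnl_oracle(sim$tree, sim$aln, m)
    expect_equal(as.numeric(mine), oracle, tolerance = 1e-8)
  }
})

test_that("likelihood agrees with phangorn on larger trees", {
  set.seed(11)
  m <- subst_model("GTR", base_freqs = c(.3, .2, .2, .3),
                   rates = c(2, 8, 1.5, 1.2, 10, 1), gamma_shape = 0.7)
  sim <- sim_on_random_tree(8, 400, model = m)
  mine <- log_likelihood(sim$tree, sim$aln, m)
  pd <- phangorn::phyDat(unclass(sim$aln), type = "DNA")
  ph <- phangorn::pml(sim$tree, pd, bf = m$base_freqs,
                      Q = m$rates, k = 4, shape = 0.7)
  expect_equal(as.numeric(mine), ph$logLik, tolerance = 1e-6)
})

test_that("very large gamma shape converges to the no-gamma likelihood", {
  set.seed(12)
  sim <- sim_on_random_tree(5, 200)
  flat <- subst_model("HKY", kappa = 2, gamma_shape = 1e6)
  none <- subst_model("HKY", kappa = 2)
  expect_equal(as.numeric(log_likelihood(sim$tree, sim$aln, flat)),
               as.numeric(log_likelihood(sim$tree, sim$aln, none)),
               tolerance = 1e-6)
})

test_that("likelihood is invariant under re-rooting", {
  set.seed(13)
  sim <- sim_on_random_tree(6, 300)
  m <- subst_model("HKY", kappa = 3)
  base <- log_likelihood(sim$tree, sim$aln, m)
  for (og in sim$tree$tip.label[1:3]) {
    rr <- ape::root(ape::unroot(sim$tree), outgroup = og,
                    resolve.root = TRUE)
    expect_equal(as.numeric(log_likelihood(rr, sim$aln, m)),
                 as.numeric(base), tolerance = 1e-8)
  }
})

test_that("taxon mismatches are reported with the symmetric difference", {
  a <- random_alignment(4, 20, seed = 1)
  tr <- parse_newick("((t1,t2),(t3,zzz));")
  expect_error(log_likelihood(tr, a, subst_model("JC")), "zzz")
  expect_error(log_likelihood(tr, a, subst_model("JC")), "t4")
})

test_that("gaps and ambiguities act as missing data", {
  m <- subst_model("JC")
  a1 <- alignment(matrix(c("A", "A"), 2, 1,
                         dimnames = list(c("A", "B"), NULL)))
  aq <- alignment(matrix(c("A", "?"), 2, 1,
                         dimnames = list(c("A", "B"), NULL)))
  tr <- parse_newick("(A:0.1,B:0.1);")
  # a '?' sums the partial over all states: site likelihood = pi_A
  expect_equal(as.numeric(log_likelihood(tr, aq, m)), log(0.25),
               tolerance = 1e-9)
  expect_gt(log_likelihood(tr, aq, m), log_likelihood(tr, a1, m))
})

test_that("2-taxon optimization recovers the closed-form JC distance", {
  set.seed(14)
  tr <- parse_newick("(A:0.12,B:0.12);")
  a <- simulate_alignment(tr, subst_model("JC"), 2000)
  p <- mean(unclass(a)["A", ] != unclass(a)["B", ])
  closed <- -(3 / 4) * log(1 - 4 * p / 3)
  fit <- optimize_branch_lengths(parse_newick("(A:0.05,B:0.05);"), a,
                                 subst_model("JC"))
  expect_equal(sum(fit$tree$edge.length), closed, tolerance = 1e-6)
  # idempotence
  fit2 <- optimize_branch_lengths(fit$tree, a, subst_model("JC"))
  expect_lt(abs(fit2$lnL - fit$lnL), 1e-6)
})

test_that("optimization recovers simulated branch lengths on 8 taxa", {
  set.seed(15)
  tr <- ape::rtree(8)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.3)
  tr <- ape::unroot(tr)
  m <- subst_model("HKY", kappa = 3)
  a <- simulate_alignment(tr, m, 20000)
  start <- tr; start$edge.length <- rep(0.1, nrow(tr$edge))
  fit <- optimize_branch_lengths(start, a, m, tol = 1e-5)
  # align edges by split before comparing (the optimizer reorders the tree)
  split_lens <- function(t) {
    taxa <- sort(t$tip.label)
    full <- sum(2^(seq_along(taxa) - 1))
    msk <- macroils:::node_masks(t, taxa)[t$edge[, 2]]
    stats::aggregate(len ~ split,
                     data.frame(split = pmin(msk, full - msk),
                                len = t$edge.length), sum)
  }
  mg <- merge(split_lens(tr), split_lens(fit$tree), by = "split")
  rel <- abs(mg$len.y - mg$len.x) / mg$len.x
  expect_lt(stats::median(rel), 0.05)
  expect_lt(max(rel), 0.15)
})

test_that("ml_search equals exhaustive scoring on 4 and 5 taxa", {
  set.seed(16)
  m <- subst_model("JC")
  for (n in c(4, 5)) {
    tr <- ape::rcoal(n); tr$edge.length <- tr$edge.length * 0.5
    a <- simulate_alignment(tr, m, 300)
    ex <- ml_search(a, m, method = "exhaustive")
    nn <- ml_search(a, m, start = "stepwise", n_starts = 3)
    expect_equal(nn$lnL, ex$lnL, tolerance = 1e-3)
    expect_equal(ape::dist.topo(ape::unroot(nn$tree),
                                ape::unroot(ex$tree))[[1]], 0)
  }
})

test_that("strong-signal search recovers the generating topology", {
  set.seed(17)
  m <- subst_model("JC")
  hits <- replicate(8, {
    tr <- ape::rtree(6)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.08, 0.25)
    a <- simulate_alignment(tr, m, 2000)
    fit <- ml_search(a, m, start = "nj", n_starts = 1)
    topo_dist(ape::unroot(fit$tree), ape::unroot(tr)) == 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("partition multipliers fixed at 1 reproduce the unpartitioned
          likelihood", {
  set.seed(18)
  sim <- sim_on_random_tree(5, 240)
  m <- subst_model("HKY", kappa = 2)
  sch <- partition_scheme(p1 = c(1, 120), p2 = c(121, 240))
  lp <- log_likelihood(sim$tree, sim$aln, m, scheme = sch,
                       multipliers = c(p1 = 1, p2 = 1))
  lu <- log_likelihood(sim$tree, sim$aln, m)
  expect_equal(as.numeric(lp), as.numeric(lu), tolerance = 1e-9)
})

test_that("fitch length matches hand counts and the exhaustive oracle", {
  a <- alignment(matrix(c("A", "A", "C", "C"), 4, 1,
                        dimnames = list(paste0("t", 1:4), NULL)))
  t12 <- parse_newick("((t1,t2),(t3,t4));")
  t13 <- parse_newick("((t1,t3),(t2,t4));")
  expect_equal(fitch_length(t12, a), 1L)
  expect_equal(fitch_length(t13, a), 2L)
  # invariant alignment
  const <- alignment(matrix("G", 4, 5, dimnames = list(paste0("t", 1:4),
                                                       NULL)))
  expect_equal(fitch_length(t12, const), 0L)
  # brute-force over all ancestral labelings on 5 taxa
  brute_fitch <- function(tree, aln) {
    tree <- ape::reorder.phylo(tree, "postorder")
    ntip <- length(tree$tip.label)
    internal <- unique(tree$edge[, 1])
    tot <- 0L
    for (s in seq_len(ncol(aln))) {
      obs <- match(unclass(aln)[tree$tip.label, s], c("A", "C", "G", "T"))
      combos <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
      best <- Inf
      for (rr in seq_len(nrow(combos))) {
        st <- function(nd) if (nd <= ntip) obs[nd] else
          combos[rr, match(nd, internal)]
        changes <- 0L
        for (e in seq_len(nrow(tree$edge))) {
          changes <- changes + (st(tree$edge[e, 1]) != st(tree$edge[e, 2]))
        }
        best <- min(best, changes)
      }
      tot <- tot + best
    }
    tot
  }
  set.seed(19)
  for (i in 1:3) {
    tr <- ape::rtree(5)
    a5 <- random_alignment(5, 6)
    expect_equal(fitch_length(tr, a5), brute_fitch(tr, a5))
  }
})

test_that("bootstrap saturates on strong signal and RELL tracks full", {
  set.seed(20)
  m <- subst_model("JC")
  tr <- ape::rtree(6)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.08, 0.25)
  a <- simulate_alignment(tr, m, 2500)
  pp <- ape::prop.part(tr)
  cherry <- NULL
  for (nd in seq_along(pp)) if (length(pp[[nd]]) == 2) cherry <- pp[[nd]]
  clades <- list(cherry = tr$tip.label[cherry])
  bs <- bootstrap(a, m, reps = 15, mode = "full", clades = clades,
                  n_starts = 1)
  expect_equal(as.numeric(bs$support["cherry"]), 100)

  # RELL against full bootstrap on a moderate-signal fixture
  set.seed(21)
  tr8 <- ape::rtree(8)
  tr8$edge.length <- stats::runif(nrow(tr8$edge), 0.03, 0.15)
  a8 <- simulate_alignment(tr8, m, 800)
  ml <- ml_search(a8, m, start = "nj", n_starts = 1)
  cands <- c(list(ml$tree), lapply(phangorn::nni(ml$tree), function(x) x))
  class(cands) <- "multiPhylo"
  pp8 <- ape::prop.part(tr8)
  cl8 <- list()
  for (nd in seq_along(pp8)) {
    if (length(pp8[[nd]]) %in% 2:4) {
      cl8[[paste0("c", nd)]] <- tr8$tip.label[pp8[[nd]]]
    }
  }
  full <- bootstrap(a8, m, reps = 50, mode = "full", clades = cl8,
                    n_starts = 1)
  rell <- bootstrap(a8, m, reps = 2000, mode = "RELL", candidates = cands,
                    clades = cl8)
  # MC error at 50 replicates is ~7 points; allow that plus a margin for the
  # restricted candidate set
  expect_lt(max(abs(full$support - rell$support)), 20)
  expect_error(bootstrap(a8, m, mode = "RELL"), "candidate")
})

test_that("KH/SH tests behave on duplicates and calibrate type-I error", {
  set.seed(22)
  tr <- ape::rcoal(5); tr$edge.length <- tr$edge.length * 0.6
  m <- subst_model("JC")
  a <- simulate_alignment(tr, m, 800)
  dup <- c(list(tr, tr))
  class(dup) <- "multiPhylo"
  res <- kh_sh_test(a, dup, m, reps = 2000)
  expect_equal(res$delta, c(0, 0))
  expect_equal(res$p_KH, c(1, 1))
  expect_equal(res$p_SH, c(1, 1))
  expect_true(all(res$identical_sites))

  # the ML tree always has delta 0 and the max p-value
  alt <- phangorn::nni(ape::unroot(tr))[[1]]
  pair <- c(list(ape::unroot(tr), alt)); class(pair) <- "multiPhylo"
  res2 <- kh_sh_test(a, pair, m, reps = 2000)
  best <- which.max(res2$lnL)
  expect_equal(res2$delta[best], 0)
  expect_equal(res2$p_KH[best], 1)

  # type-I calibration: simulate on T1, test T1 vs an NNI neighbour; reject
  # at most ~alpha + MC error when the data carry real signal for T1
  set.seed(23)
  rejections <- replicate(40, {
    a0 <- simulate_alignment(tr, m, 400)
    r <- kh_sh_test(a0, pair, m, reps = 500)
    true_row <- 1  # tr is the generating tree
    r$p_KH[true_row] < 0.05 && r$delta[true_row] > 0
  })
  expect_lte(mean(rejections), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})
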