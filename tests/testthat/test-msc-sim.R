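test_that("effective_theta follows the ploidy rules", {
  p <- pop_params(1e5, 7)
  expect_equal(effective_theta(p, locus_model("n", 10, "nuclear_autosomal",
                                              2.5e-9)), 1e-3)
  # mitochondrial: one quarter the nuclear size, haploid maternal
  expect_equal(effective_theta(p, locus_model("m", 10, "mitochondrial",
                                              1.0e-8)), 5e-4)
  expect_equal(effective_theta(pop_params(1e6), locus_model(
    "n", 10, "nuclear_autosomal", 2.5e-9)), 1e-2)
  expect_error(pop_params(-1), "Ne")
})

test_that("zero-coalescent-time limit reproduces the species topology", {
  guide <- guide_trees_cached()$combined
  loc <- locus_model("n", 10, "nuclear_autosomal", 1e-8)
  set.seed(1)
  ok <- replicate(50, {
    g <- simulate_genealogy(guide, pop_params(10), loc)
    topo_dist(g$tree, guide) == 0
  })
  expect_true(all(ok))
})

test_that("triplet concordance matches 1 - (2/3)exp(-T)", {
  loc <- locus_model("n", 10, "nuclear_autosomal", 1e-8)
  ne <- 10000; gen_time <- 1
  for (T in c(0.1, 0.5, 1, 2, 5)) {
    dur <- T * 2 * ne / 1e6          # coalescent units -> Ma at 1 yr/gen
    tr <- parse_newick(sprintf("((A:1,B:1):%.8f,C:%.8f);", dur, 1 + dur))
    set.seed(100 + round(10 * T))
    n <- 2000
    hits <- replicate(n, contains_clade(
      simulate_genealogy(tr, pop_params(ne, gen_time), loc)$tree, c("A", "B")))
    theo <- 1 - (2 / 3) * exp(-T)
    mc_se <- sqrt(theo * (1 - theo) / n)
    expect_lt(abs(mean(hits) - theo), 3 * mc_se + 1e-9)
  }
})

test_that("coalescence times never pre-date the species divergence", {
  guide <- guide_trees_cached()$nuclear_only
  loc <- locus_model("m", 10, "mitochondrial", 1e-8)
  gens_per_ma <- 1e6 / 7
  set.seed(2)
  for (i in 1:20) {
    g <- simulate_genealogy(guide, pop_params(1e6, 7), loc)
    ab_split_gen <- mrca_age(guide, c("W_bicolor", "M_eugenii")) * gens_per_ma
    gene_mrca <- mrca_age(g$tree, c("W_bicolor", "M_eugenii"))
    expect_gte(gene_mrca, ab_split_gen - 1e-6)
    # all internal times increase root-ward and the tree is binary
    expect_true(ape::is.binary(g$tree))
    expect_true(all(g$tree$edge.length > 0))
  }
})

test_that("mean pairwise coalescence times follow the theta timescale", {
  # near-zero species depth isolates the within-branch waiting time;
  # theta = 2*E[T2]*mu gives E[T2] = 2Ne (nuclear) and Ne/4 (mitochondrial)
  tr <- parse_newick("(A:0.000001,B:0.000001);")
  ne <- 10000
  set.seed(3)
  n <- 3000
  wait_n <- replicate(n, max(node_ages(simulate_genealogy(
    tr, pop_params(ne, 1), locus_model("n", 10, "nuclear_autosomal",
                                       1e-8))$tree)))
  wait_m <- replicate(n, max(node_ages(simulate_genealogy(
    tr, pop_params(ne, 1), locus_model("m", 10, "mitochondrial",
                                       1e-8))$tree)))
  expect_lt(abs(mean(wait_n) - 2 * ne) / (2 * ne), 3 / sqrt(n) + 0.02)
  expect_lt(abs(mean(wait_m) - ne / 4) / (ne / 4), 3 / sqrt(n) + 0.02)
})

test_that("4-taxon clade frequencies match an independent rejection
          simulator", {
  # independent oracle: an interval-by-interval exponential race on the
  # asymmetric species tree (((A,B),C),D), written without any of the
  # package's tree machinery
  ne <- 20000
  splits <- c(10000, 30000, 60000)     # generations
  rate <- 1 / (2 * ne)
  # track every group ever formed so clade presence can be judged afterwards
  naive_clades <- function() {
    formed <- list()
    race <- function(groups, t_now, t_end) {
      while (length(groups) >= 2) {
        t_now <- t_now + stats::rexp(1, choose(length(groups), 2) * rate)
        if (t_now >= t_end) break
        pr <- sample(length(groups), 2)
        merged <- sort(unlist(groups[pr]))
        formed[[length(formed) + 1]] <<- merged
        groups <- c(groups[-pr], list(merged))
      }
      groups
    }
    g <- race(list("A", "B"), splits[1], splits[2])
    g <- race(c(g, list("C")), splits[2], splits[3])
    race(c(g, list("D")), splits[3], Inf)
    c(ab = any(vapply(formed, identical, logical(1), y = c("A", "B"))),
      abc = any(vapply(formed, identical, logical(1),
                       y = c("A", "B", "C"))))
  }
  tr <- parse_newick(sprintf("(((A:%f,B:%f):%f,C:%f):%f,D:%f);",
                             splits[1] / 1e6, splits[1] / 1e6,
                             (splits[2] - splits[1]) / 1e6, splits[2] / 1e6,
                             (splits[3] - splits[2]) / 1e6, splits[3] / 1e6))
  loc <- locus_model("n", 10, "nuclear_autosomal", 1e-8)
  n <- 2500
  set.seed(4)
  pkg <- replicate(n, {
    g <- simulate_genealogy(tr, pop_params(ne, 1), loc)$tree
    c(ab = contains_clade(g, c("A", "B")),
      abc = contains_clade(g, c("A", "B", "C")))
  })
  set.seed(5)
  ora <- replicate(n, naive_clades())
  for (cl in c("ab", "abc")) {
    p1 <- mean(pkg[cl, ]); p2 <- mean(ora[cl, ])
    se <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
    expect_lt(abs(p1 - p2), 3.5 * se + 0.01)
  }
})

test_that("graft_taxon inserts a tip on the stem and preserves heights", {
  guide <- guide_trees_cached()$combined
  core <- macropodid_taxa()$core_notamacropus
  base <- ape::drop.tip(guide, "M_irma")
  out <- graft_taxon(base, "M_new", core, attach_age = 4.0)
  expect_true(is_chronogram(out))
  expect_equal(length(out$tip.label), length(base$tip.label) + 1)
  expect_equal(mrca_age(out, c("M_new", core)), 4.0)
  # prior node heights unchanged
  expect_equal(mrca_age(out, core), mrca_age(base, core))
  expect_equal(max(node_ages(out)), max(node_ages(base)))
  # outside the stem interval
  expect_error(graft_taxon(base, "M_x", core, attach_age = 6.0),
               "outside the stem")
  expect_error(graft_taxon(base, "M_x", core, attach_age = 2.0),
               "outside the stem")
})

test_that("scale_root_height rescales proportionally", {
  guide <- guide_trees_cached()$combined
  sc <- scale_root_height(guide, 21.3)
  expect_equal(max(node_ages(sc)), 21.3)
  ages <- node_ages(guide)
  r <- node_ages(sc)[ages > 1e-6] / ages[ages > 1e-6]
  expect_lt(diff(range(r)), 1e-9)
  # identity when scaling to the current height
  same <- scale_root_height(guide, 20)
  expect_equal(same$edge.length, guide$edge.length, tolerance = 1e-12)
})
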