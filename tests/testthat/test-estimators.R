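test_that("the MCC tree maximizes the clade credibility product over the sample", {
  s <- example_sample()
  tab <- tally(s)
  est <- mcc_tree(s, tab)
  expect_identical(est$tree$key, topo(fig_newick["t1"], s$taxa)$key)
  expect_equal(est$score, 9 / 49)
  # score matches recomputation from the table
  cred <- tab$clade_count / tab$k
  expect_equal(est$score,
               prod(cred[topology_clades(est$tree, trivial = FALSE)]),
               tolerance = 1e-12)
  # single-tree sample: that tree with credibility product one
  s1 <- parse_trees(rep("((A,B),(C,D));", 3), burnin_fraction = 0)
  est1 <- mcc_tree(s1)
  expect_equal(est1$score, 1)
  expect_identical(est1$tree$key, s1$topologies[[1]]$key)
})

test_that("MCC ties break toward the higher-multiplicity topology", {
  # f(AB) = f(CD) = f(AC) = f(BD) = 2 with k = 5, so the two balanced
  # trees tie at PrCC = 4/25; multiplicity 2 beats multiplicity 1
  s <- parse_trees(c("((A,B),(C,D));",
                     rep("((A,C),(B,D));", 2),
                     "(((A,B),C),D);",
                     "(((C,D),A),B);"),
                   burnin_fraction = 0)
  tab <- tally(s)
  est <- mcc_tree(s, tab)
  expect_equal(est$score, 4 / 25)
  expect_identical(est$tree$key, topo("((A,C),(B,D));", s$taxa)$key)
})

test_that("greedy consensus reproduces the worked example resolution", {
  tab <- tally(example_sample())
  est <- greedy_consensus(tab)
  expect_true(est$tree$resolved)
  expect_identical(est$tree$key, topo("((A,(B,C)),(D,E));", tab$taxa)$key)
  # accepted clades: ABC (7/7), BC (4/7), DE (3/7); score is their sum
  expect_equal(est$score, 1 + 4 / 7 + 3 / 7)
  expect_setequal(names(est$support),
                  c(ekey(c("A", "B", "C")), ekey(c("B", "C")), ekey(c("D", "E"))))
  # an all-identical sample returns its only topology
  s1 <- parse_trees(rep("(((A,B),C),(D,E));", 5), burnin_fraction = 0)
  expect_identical(greedy_consensus(tally(s1))$tree$key, s1$topologies[[1]]$key)
})

test_that("greedy consensus can return an unresolved tree under conflicting ties", {
  # hand-traced case: the 4-clade {t1,t2,t3,t4} is accepted, then {t2,t4}
  # (first size-2 clade in canonical order) blocks both of its resolvers
  taxa5 <- paste0("t", 1:5)
  s <- tree_sample(list(topo("((t4,t2),(t3,(t5,t1)));", taxa5),
                        topo("(t5,((t3,t2),(t4,t1)));", taxa5)))
  est <- greedy_consensus(tally(s))
  expect_false(est$tree$resolved)
  taxa <- s$taxa
  expect_setequal(
    names(est$support),
    c(clade_key(c("t1", "t2", "t3", "t4"), taxa), clade_key(c("t2", "t4"), taxa))
  )
  # the polytomy: {t2,t4}, t1, t3 below the accepted 4-clade
  expect_length(est$tree$children[[clade_key(c("t1", "t2", "t3", "t4"), taxa)]], 3L)
})

test_that("greedy consensus contains every majority clade", {
  set.seed(31)
  for (rep in 1:10) {
    s <- random_fixture_sample(sample(5:8, 1), pool = sample(2:5, 1))
    tab <- tally(s)
    est <- greedy_consensus(tab)
    cred <- clade_credibility(tab)
    majority <- names(cred)[cred > 0.5]
    expect_true(all(majority %in% topology_clades(est$tree, trivial = FALSE)))
    # accepted clades are pairwise compatible (laminar)
    acc <- names(est$support)
    for (i in seq_along(acc)) {
      for (j in seq_len(i - 1L)) {
        expect_true(ccdtree:::keys_compatible(acc[i], acc[j]))
      }
    }
  }
})

test_that("the CCD1-MAP tree is the most probable displayed tree", {
  tab <- tally(example_sample())
  ccd1 <- build_ccd1(tab)
  est <- map_tree(ccd1)
  expect_identical(est$tree$key, topo("((A,(B,C)),(D,E));", tab$taxa)$key)
  expect_equal(est$score, 12 / 49)
  expect_equal(tree_probability(ccd1, est$tree), est$score, tolerance = 1e-12)
  expect_true(est$tree$resolved)
  # MAP probability dominates every sampled topology's probability
  s <- example_sample()
  for (top in s$topologies) {
    expect_gte(est$score, tree_probability(ccd1, top) - 1e-12)
  }
})

test_that("MAP and MSCC trees match brute-force argmaxes on random fixtures", {
  set.seed(47)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    s <- random_fixture_sample(n, pool = sample(2:4, 1))
    tab <- tally(s)
    ccd0 <- build_ccd0(tab)
    ccd1 <- build_ccd1(tab)
    ccd2 <- build_ccd2(s)
    for (dist in list(ccd0, ccd1, ccd2)) {
      enum <- enumerate_trees(dist)
      est <- map_tree(dist, support = "none")
      expect_equal(est$score, max(enum$prob), tolerance = 1e-12)
      expect_equal(tree_probability(dist, est$tree), est$score, tolerance = 1e-12)
    }
    # MSCC: maximize the sum of clade credibilities over displayed trees
    enum0 <- enumerate_trees(ccd0)
    cred <- tab$clade_count / tab$k
    sums <- vapply(enum0$tree, function(t) {
      sum(cred[topology_clades(t, trivial = FALSE)])
    }, numeric(1))
    est <- mscc_tree(ccd0, support = "none")
    expect_equal(est$score, max(sums), tolerance = 1e-12)
    expect_true(est$tree$resolved)
  }
})

test_that("the worked-example MSCC tree attains clade credibility sum 2", {
  tab <- tally(example_sample())
  est <- mscc_tree(build_ccd0(tab))
  expect_identical(est$tree$key, topo("((A,(B,C)),(D,E));", tab$taxa)$key)
  expect_equal(est$score, 4 / 7 + 1 + 3 / 7)
  expect_error(mscc_tree(build_ccd1(tab)), "CCD0")
})

test_that("support annotations carry Monte Carlo or CCD clade probabilities", {
  s <- example_sample()
  tab <- tally(s)
  ccd1 <- build_ccd1(tab)
  est_mc <- map_tree(ccd1, support = "montecarlo")
  est_ccd <- map_tree(ccd1, support = "ccd")
  nt <- topology_clades(est_mc$tree, trivial = FALSE)
  # for a CCD1 both notions coincide with f(C)/k
  expect_equal(est_mc$support[nt], est_ccd$support[nt], tolerance = 1e-12)
  expect_equal(unname(est_mc$support[ekey(c("B", "C"))]), 4 / 7)
  # estimators are deterministic: repeated runs agree exactly
  expect_identical(write_tree(map_tree(ccd1)$tree), write_tree(map_tree(ccd1)$tree))
  expect_identical(glance(est_mc)$newick, write_tree(est_mc$tree))
})

test_that("tidiers expose estimates and graphs as tables", {
  tab <- tally(example_sample())
  ccd1 <- build_ccd1(tab)
  td <- tidy(ccd1)
  expect_true(all(c("parent", "left", "right", "prob", "count") %in% names(td)))
  expect_equal(sum(td$prob[td$parent == "A,B,C,D,E"]), 1)
  gl <- glance(ccd1)
  expect_identical(gl$n_trees, 6)
  expect_identical(gl$flavor, "ccd1")
  est <- mcc_tree(example_sample())
  expect_identical(nrow(tidy(est)), 3L)
  expect_identical(glance(est)$method, "mcc")
})
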