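test_that("tallies reproduce the worked-example frequencies and invariants", {
  tab <- tally(example_sample())
  expect_identical(tab$k, 7L)
  expect_identical(unname(tab$clade_count[ekey(c("A", "B", "C"))]), 7)
  expect_identical(unname(tab$clade_count[ekey(c("A", "B"))]), 3)
  sid <- function(a, b) ccdtree:::split_id(ekey(a), ekey(b))
  expect_identical(unname(tab$split_count[sid(c("A", "B", "C"), c("D", "E"))]), 3)
  expect_identical(unname(tab$split_count[sid(c("A", "B", "C", "D"), "E")]), 2)
  expect_identical(unname(tab$split_count[sid(c("A", "B", "C", "E"), "D")]), 2)
  expect_identical(unname(tab$split_count[sid(c("A", "B"), "C")]), 3)
  expect_identical(unname(tab$split_count[sid("A", c("B", "C"))]), 4)

  # f(S) <= f(C), split counts sum to f(C), trivial clades have f = k
  for (id in names(tab$split_count)) {
    parent <- tab$split_parent[[id]]
    expect_lte(tab$split_count[[id]], tab$clade_count[[parent]])
  }
  sums <- rowsum(unname(tab$split_count), unname(tab$split_parent))
  expect_equal(sums[, 1], tab$clade_count[rownames(sums)], ignore_attr = TRUE)
  n <- length(tab$taxa)
  triv <- names(tab$clade_count)[ccdtree:::key_size(names(tab$clade_count)) %in% c(1L, n)]
  expect_true(all(tab$clade_count[triv] == tab$k))
})

test_that("single-topology samples give count k everywhere", {
  s <- parse_trees(rep("(((A,B),C),(D,E));", 4), burnin_fraction = 0)
  tab <- tally(s)
  expect_true(all(tab$clade_count == 4))
  expect_true(all(tab$split_count == 4))
})

test_that("CCD1 conditional probabilities are observed split ratios", {
  tab <- tally(example_sample())
  ccd1 <- build_ccd1(tab)
  root <- ccd1$splits[[ekey(LETTERS[1:5])]]
  abc_de <- root$prob[root$left == ekey(c("D", "E")) | root$right == ekey(c("D", "E"))]
  expect_equal(abc_de, 3 / 7)
  abc <- ccd1$splits[[ekey(c("A", "B", "C"))]]
  a_bc <- abc$prob[abc$left == ekey("A") | abc$right == ekey("A")]
  expect_equal(a_bc, 4 / 7)
  # cherry clades have a single split of probability one
  expect_equal(ccd1$splits[[ekey(c("D", "E"))]]$prob, 1)
  # normalization at every clade
  for (d in ccd1$splits) expect_equal(sum(d$prob), 1, tolerance = 1e-12)
})

test_that("split expansion adds exactly the assemblable unobserved splits", {
  # divergence example: AB|CD assemblable from observed clades
  tab <- tally(split_expansion_sample())
  exp_df <- expand_splits(tab)
  taxa <- tab$taxa
  id <- ccdtree:::split_id(clade_key(c("A", "B"), taxa), clade_key(c("C", "D"), taxa))
  got <- paste(exp_df$left, exp_df$right, sep = "|")
  expect_true(id %in% got)
  expect_false(id %in% names(tab$split_count))
  expect_false(exp_df$observed[got == id])

  # the worked example expands to nothing new
  tab1 <- tally(example_sample())
  exp1 <- expand_splits(tab1)
  expect_setequal(paste(exp1$left, exp1$right, sep = "|"), names(tab1$split_count))

  # single-tree sample: expansion equals the tree's own splits
  tab2 <- tally(parse_trees("((((A,B),C),D),E);", burnin_fraction = 0))
  exp2 <- expand_splits(tab2)
  expect_setequal(paste(exp2$left, exp2$right, sep = "|"), names(tab2$split_count))
})

test_that("CCD0 probabilities equal the normalized clade-credibility product", {
  # brute-force oracle over all 105 five-taxon topologies
  samples <- list(example_sample(), split_expansion_sample())
  set.seed(7)
  for (n in c(4, 5)) samples <- c(samples, list(random_fixture_sample(n)))
  for (s in samples) {
    tab <- tally(s)
    ccd0 <- build_ccd0(tab)
    target <- ccd0_target_probs(tab, tab$taxa)
    got <- all_topology_probs(ccd0, tab$taxa)
    expect_equal(got, target[names(got)], tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("CCD1 displays a tree iff all its splits were observed", {
  tab <- tally(example_sample())
  ccd1 <- build_ccd1(tab)
  probs <- all_topology_probs(ccd1, tab$taxa)
  displayed <- names(probs)[probs > 0]
  expect_length(displayed, 6L)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  # hand-computed probabilities: sampled 9/49, 8/49, 8/49; unsampled 12/49, 6/49, 6/49
  key_of <- function(nw) topo(nw, taxa = tab$taxa)$key
  expect_equal(unname(probs[key_of("(((A,B),C),(D,E));")]), 9 / 49)
  expect_equal(unname(probs[key_of("(((A,(B,C)),D),E);")]), 8 / 49)
  expect_equal(unname(probs[key_of("(((A,(B,C)),E),D);")]), 8 / 49)
  expect_equal(unname(probs[key_of("((A,(B,C)),(D,E));")]), 12 / 49)
  expect_equal(unname(probs[key_of("((((A,B),C),D),E);")]), 6 / 49)
  expect_equal(unname(probs[key_of("((((A,B),C),E),D);")]), 6 / 49)
  # a tree with an unobserved clade gets zero
  expect_identical(
    tree_probability(ccd1, topo("((((A,C),B),D),E);", taxa = tab$taxa)), 0
  )
})

test_that("CCD2 conditions on the sibling clade and keeps only sampled trees here", {
  s <- example_sample()
  ccd2 <- build_ccd2(s)
  probs <- all_topology_probs(ccd2, s$taxa)
  displayed <- sort(names(probs)[probs > 0])
  expect_identical(displayed,
                   sort(vapply(s$topologies, function(t) t$key, character(1))))
  expect_equal(unname(probs[topo(fig_newick["t1"], s$taxa)$key]), 3 / 7)
  expect_equal(unname(probs[topo(fig_newick["t2"], s$taxa)$key]), 2 / 7)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_identical(count_trees(ccd2), 3)
})

test_that("sampling follows the distribution it was built from", {
  tab <- tally(example_sample())
  ccd1 <- build_ccd1(tab)
  enum <- enumerate_trees(ccd1)
  set.seed(11)
  draws <- sample_trees(ccd1, 5000)
  expect_identical(draws$k, 5000L)
  counts <- stats::setNames(numeric(nrow(enum)), enum$key)
  got <- vapply(draws$topologies, function(t) t$key, character(1))
  counts[got] <- draws$multiplicity
  # every draw is a displayed tree
  expect_true(all(got %in% enum$key))
  gof <- suppressWarnings(stats::chisq.test(counts, p = enum$prob))
  expect_gt(gof$p.value, 0.001)
  # U1 frequency within 3 standard errors of 12/49
  p <- 12 / 49
  se <- sqrt(p * (1 - p) / 5000)
  expect_lt(abs(counts[enum$key[1]] / 5000 - p), 3 * se)
  # deterministic under a fixed seed
  set.seed(11)
  again <- sample_trees(ccd1, 5000)
  expect_identical(vapply(again$topologies, function(t) t$key, character(1)), got)
})

test_that("tree counts, entropy and clade probabilities match enumeration", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    s <- random_fixture_sample(n, pool = sample(2:4, 1))
    tab <- tally(s)
    for (dist in list(build_ccd0(tab), build_ccd1(tab), build_ccd2(s))) {
      enum <- enumerate_trees(dist)
      expect_identical(count_trees(dist), as.numeric(nrow(enum)))
      expect_equal(sum(enum$prob), 1, tolerance = 1e-9)
      ent <- entropy(dist)
      expect_equal(unname(ent["H"]), -sum(enum$prob * log(enum$prob)),
                   tolerance = 1e-9)
      expect_equal(unname(ent["Ne"]), exp(unname(ent["H"])))
      # clade containment probabilities against enumeration weights
      for (key in sample(names(tab$clade_count), 4)) {
        direct <- clade_probability(dist, key)
        weighted <- sum(enum$prob[vapply(enum$tree, function(t) {
          key %in% topology_clades(t)
        }, logical(1))])
        expect_equal(direct, weighted, tolerance = 1e-9)
      }
    }
  }
})

test_that("entropy closed forms hold for degenerate and uniform graphs", {
  one <- build_ccd1(tally(parse_trees("((((A,B),C),D),E);", burnin_fraction = 0)))
  expect_equal(unname(entropy(one)), c(0, 1))
  expect_identical(count_trees(one), 1)
  expect_identical(enumerate_trees(one)$prob, 1)
  # uniform over m trees via an explicit sample distribution
  s <- tree_sample(all_topologies(LETTERS[1:4])[1:6])
  expect_equal(unname(entropy(s)["H"]), log(6), tolerance = 1e-12)
})

test_that("tree counts stay exact beyond double precision", {
  # two trees that chain m four-taxon blocks, each block resolved either
  # ((a,b),(c,d)) or ((a,c),(b,d)): the CCD1 displays exactly 2^m trees
  quad_chain <- function(m, variant) {
    blocks <- vapply(seq_len(m), function(i) {
      q <- paste0("t", 4 * (i - 1) + 1:4)
      if (variant == 1) {
        sprintf("((%s,%s),(%s,%s))", q[1], q[2], q[3], q[4])
      } else {
        sprintf("((%s,%s),(%s,%s))", q[1], q[3], q[2], q[4])
      }
    }, character(1))
    acc <- blocks[1]
    for (i in seq_len(m - 1)) acc <- sprintf("(%s,%s)", acc, blocks[i + 1])
    paste0(acc, ";")
  }
  m <- 54
  s <- parse_trees(c(quad_chain(m, 1), quad_chain(m, 2)), burnin_fraction = 0)
  cnt <- count_trees(build_ccd1(tally(s)))
  expect_true(is.character(cnt))
  expect_identical(cnt, "18014398509481984")  # 2^54, beyond exact doubles
  # and within double range the same construction stays numeric and exact
  s10 <- parse_trees(c(quad_chain(10, 1), quad_chain(10, 2)), burnin_fraction = 0)
  expect_identical(count_trees(build_ccd1(tally(s10))), 2^10)
})

test_that("outlier detection flags lone disjoint topologies only", {
  base <- rep("((((A,B),C),D),E);", 9)
  stray <- "((((E,D),C),B),A);"
  s <- parse_trees(c(base, stray), burnin_fraction = 0)
  rep_tab <- detect_outliers(s)
  flagged <- rep_tab[rep_tab$disjoint_outlier, ]
  expect_identical(nrow(flagged), 1L)
  expect_identical(flagged$multiplicity, 1L)
  # CCD1 still gives the stray tree probability 1/k
  ccd1 <- build_ccd1(tally(s))
  expect_equal(tree_probability(ccd1, topo(stray, s$taxa)), 1 / 10)
  # homogeneous sample: nothing flagged
  expect_false(any(detect_outliers(parse_trees(base, burnin_fraction = 0))$flagged))
  # worked example: no flags either
  expect_false(any(detect_outliers(example_sample())$flagged))
})

test_that("ccd graphs serialize to json-lines and back with validation", {
  tab <- tally(example_sample())
  for (ccd in list(build_ccd0(tab), build_ccd1(tab))) {
    f <- tempfile(fileext = ".jsonl")
    write_ccd(ccd, f)
    back <- read_ccd(f)
    expect_identical(back$flavor, ccd$flavor)
    expect_identical(back$clades, ccd$clades)
    for (p in names(ccd$splits)) {
      expect_identical(back$splits[[p]]$left, ccd$splits[[p]]$left)
      expect_identical(back$splits[[p]]$right, ccd$splits[[p]]$right)
      expect_equal(back$splits[[p]]$prob, ccd$splits[[p]]$prob)
    }
    # distributions agree
    expect_equal(enumerate_trees(back)$prob, enumerate_trees(ccd)$prob)
    unlink(f)
  }
  # corrupt probabilities are rejected on load
  f <- tempfile(fileext = ".jsonl")
  write_ccd(build_ccd1(tab), f)
  lines <- readLines(f)
  lines[2] <- sub("1(,|})", "0.5\\1", lines[2])
  bad <- tempfile(fileext = ".jsonl")
  writeLines(lines, bad)
  expect_error(read_ccd(bad), "sum to 1")
  unlink(c(f, bad))
})
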