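# Metrics for comparing estimated tree distributions against a reference
# ("golden") distribution, and point estimates against each other. All
# metrics treat distributions through the common query interface
# (tree_probability / enumerate_trees / clade probabilities), so samples
# and CCDs are interchangeable.

#' Credible set of a tree distribution
#'
#' Trees sorted by decreasing probability; the shortest prefix whose
#' probabilities sum to at least `level`. Probability ties are ordered by
#' topology key, so the set is deterministic.
#'
#' @param reference An enumerable distribution (`tree_sample`, `ccd_graph`,
#'   `ccd2_graph`).
#' @param level Fraction in `(0, 1]`.
#' @param cap Enumeration cap, see [enumerate_trees()].
#' @return A tibble (subset of `enumerate_trees(reference)` rows) with an
#'   extra `cumulative` column.
#' @export
credible_set <- function(reference, level = 0.95, cap = 1e6) {
  if (!is.numeric(level) || level <= 0 || level > 1) {
    stop("level must lie in (0, 1]")
  }
  enum <- enumerate_trees(reference, cap = cap)
  enum$cumulative <- cumsum(enum$prob)
  need <- which(enum$cumulative >= level - 1e-12)
  if (length(need) == 0L) need <- nrow(enum)
  enum[seq_len(need[1]), , drop = FALSE]
}

#' Mean absolute error of tree probabilities
#'
#' Average over the trees of the reference (golden) distribution of the
#' absolute difference between the probability under `estimate` and under
#' `reference`. High-probability reference trees dominate this metric.
#'
#' @param estimate Distribution under evaluation.
#' @param reference Enumerable golden distribution.
#' @param cap Enumeration cap for the reference support.
#' @return Non-negative number (at most 1).
#' @export
mae <- function(estimate, reference, cap = 1e6) {
  ref <- enumerate_trees(reference, cap = cap)
  if (nrow(ref) == 0L) stop("empty reference distribution")
  est_p <- vapply(ref$tree, function(t) tree_probability(estimate, t), numeric(1))
  mean(abs(est_p - ref$prob))
}

#' Mean relative error of tree or clade probabilities
#'
#' Mean of `|p_est - p_ref| / p_ref`. For tree probabilities the mean runs
#' over the reference trees inside the credible set at `subset` (a level in
#' `(0, 1]`); with `subset = "clades"` it runs over all nontrivial clades
#' of the reference distribution, comparing clade probabilities.
#'
#' @inheritParams mae
#' @param subset Credible level (e.g. `0.5`, `0.95`) or `"clades"`.
#' @return Non-negative number.
#' @export
mre <- function(estimate, reference, subset = 0.95, cap = 1e6) {
  if (identical(subset, "clades")) {
    ref_p <- dist_clade_probabilities(reference)
    ref_p <- ref_p[ref_p > 0]
    est_p <- vapply(names(ref_p), function(key) clade_probability(estimate, key),
                    numeric(1))
    return(mean(abs(est_p - ref_p) / ref_p))
  }
  cs <- credible_set(reference, level = subset, cap = cap)
  est_p <- vapply(cs$tree, function(t) tree_probability(estimate, t), numeric(1))
  mean(abs(est_p - cs$prob) / cs$prob)
}

# nontrivial clade -> containment probability, for any distribution type
dist_clade_probabilities <- function(dist) {
  if (inherits(dist, "ccd_graph")) {
    p <- ccd_clade_probabilities(dist)
  } else if (inherits(dist, "ccd2_graph")) {
    p <- ccd2_clade_probabilities(dist)
  } else if (inherits(dist, "tree_sample")) {
    tab <- tally(dist)
    p <- tab$clade_count / tab$k
  } else {
    stop("unsupported distribution type")
  }
  sz <- key_size(names(p))
  p[sz > 1L & sz < max(sz)]
}

#' Rank of the reference top tree under an estimate
#'
#' The 1-based position of the reference distribution's most probable tree
#' in the estimate's probability ordering (ties by topology key). If the
#' estimate's support is too large to enumerate, the rank is computed among
#' a candidate pool made of the reference support plus the estimate's MAP
#' tree, which lower-bounds the full-support rank.
#'
#' @inheritParams mae
#' @return Positive integer.
#' @export
top_tree_rank <- function(estimate, reference, cap = 1e6) {
  ref <- enumerate_trees(reference, cap = cap)
  top_key <- ref$key[1]
  top_tree <- ref$tree[[1]]
  enumerable <- inherits(estimate, "tree_sample") ||
    !is.character(count_trees(estimate)) && count_trees(estimate) <= cap
  if (enumerable) {
    est <- enumerate_trees(estimate, cap = cap)
    hit <- match(top_key, est$key)
    return(if (is.na(hit)) nrow(est) + 1L else hit)
  }
  pool_keys <- ref$key
  pool_p <- vapply(ref$tree, function(t) tree_probability(estimate, t), numeric(1))
  est_map <- map_tree(estimate, support = "none")
  if (!(est_map$tree$key %in% pool_keys)) {
    pool_keys <- c(pool_keys, est_map$tree$key)
    pool_p <- c(pool_p, est_map$score)
  }
  ord <- order(-pool_p, pool_keys)
  match(top_key, pool_keys[ord])
}

#' Mean absolute probability difference between two replicate distributions
#'
#' Computed over the union of the two supports: trees displayed by either
#' distribution. Identical distributions give 0; disjoint deterministic
#' ones give 1.
#'
#' @param est_a,est_b Enumerable distributions on the same taxa.
#' @param cap Enumeration cap per distribution.
#' @return Number in `[0, 1]` times at most 1 per tree.
#' @export
replicate_precision <- function(est_a, est_b, cap = 1e6) {
  ea <- enumerate_trees(est_a, cap = cap)
  eb <- enumerate_trees(est_b, cap = cap)
  keys <- union(ea$key, eb$key)
  pa <- stats::setNames(numeric(length(keys)), keys)
  pb <- pa
  pa[ea$key] <- ea$prob
  pb[eb$key] <- eb$prob
  mean(abs(pa - pb))
}

#' RF distance between two replicate point estimates
#'
#' Convenience wrapper around [rf_distance()] for `point_estimate` or
#' `tree_topology` inputs.
#'
#' @param est_a,est_b Point estimates (or topologies) from two replicate
#'   runs.
#' @return Non-negative half-integer.
#' @export
point_estimator_precision <- function(est_a, est_b) {
  tree_of <- function(x) if (inherits(x, "point_estimate")) x$tree else x
  rf_distance(tree_of(est_a), tree_of(est_b))
}
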