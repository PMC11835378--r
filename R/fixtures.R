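# Synthetic-data generators: random Yule topologies, random ground-truth
# CCDs, and replicate "posterior" samples drawn from them. These stand in
# for MCMC output in tests and simulation studies; everything is
# reproducible from R's global RNG (seed with set.seed()).

#' Random Yule tree topology
#'
#' Draws a rooted binary topology by repeatedly joining two uniformly
#' chosen lineages, which yields the topology distribution of the Yule
#' (pure birth) process on labelled trees. Divergence times are not
#' generated: every computation in this package is topology-level.
#'
#' @param n Number of taxa (at least 2), or give `taxa` directly.
#' @param taxa Optional character vector of taxon labels; defaults to
#'   `"t1" ... "tn"`.
#' @return A `tree_topology`.
#' @examples
#' set.seed(1)
#' yule_topology(5)
#' @export
yule_topology <- function(n, taxa = NULL) {
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  validate_taxa(taxa)
  n <- length(taxa)
  lineages <- as.list(singleton_keys(taxa))
  children <- list()
  while (length(lineages) > 1L) {
    pick <- sample.int(length(lineages), 2L)
    a <- lineages[[pick[1]]]
    b <- lineages[[pick[2]]]
    parent <- key_union(a, b)
    children[[parent]] <- sort(c(a, b))
    lineages[pick] <- NULL
    lineages <- c(lineages, parent)
  }
  new_topology(taxa, children)
}

#' Random nearest-neighbour interchange of a topology
#'
#' Picks a random internal clade with a non-leaf child and swaps one
#' grandchild subtree with its uncle subtree — the rooted
#' nearest-neighbour-interchange (NNI) move. Chains of NNI moves emulate
#' the local exploration of tree space that an MCMC sampler performs.
#'
#' @param tree A resolved `tree_topology` with at least 3 taxa.
#' @return A resolved `tree_topology` one NNI move away.
#' @export
nni_topology <- function(tree) {
  stopifnot(inherits(tree, "tree_topology"), tree$resolved,
            length(tree$taxa) >= 3L)
  ch <- tree$children
  cand <- names(ch)[vapply(ch, function(k) any(key_size(k) > 1L), logical(1))]
  parent <- if (length(cand) == 1L) cand else sample(cand, 1L)
  kids <- ch[[parent]]
  inner <- kids[key_size(kids) > 1L]
  pivot <- if (length(inner) == 1L) inner else sample(inner, 1L)
  uncle <- setdiff(kids, pivot)
  below <- ch[[pivot]]
  up <- sample(2L, 1L)
  keep <- below[up]          # promoted next to the new inner clade
  move <- below[-up]         # grouped with the former uncle
  fresh <- key_union(move, uncle)
  ch[[pivot]] <- NULL
  ch[[fresh]] <- sort(c(move, uncle))
  ch[[parent]] <- sort(c(keep, fresh))
  new_topology(tree$taxa, ch)
}

#' Random ground-truth CCD
#'
#' Builds a forest network from the clades and splits of a pool of related
#' random topologies — a Yule base tree followed by an NNI random walk, so
#' the pool shares structure the way consecutive MCMC samples do — and
#' assigns each clade's conditional split probabilities from a symmetric
#' Dirichlet. The result is a valid CCD graph usable as an exactly known
#' truth in parameter-recovery and benchmark experiments.
#'
#' @param n Number of taxa, or give `taxa`.
#' @param pool_size Number of pooled topologies whose splits form the
#'   graph (1 = a single Yule tree, deterministic distribution).
#' @param concentration Symmetric Dirichlet concentration for the split
#'   probabilities at each clade; large values approach equal
#'   probabilities, small values concentrate mass on few splits.
#' @param taxa Optional taxon labels.
#' @return A `ccd_graph` with `flavor = "random"`.
#' @export
random_ccd <- function(n, pool_size = 5L, concentration = 1, taxa = NULL) {
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  validate_taxa(taxa)
  stopifnot(pool_size >= 1L, concentration > 0)
  pool <- vector("list", pool_size)
  pool[[1]] <- yule_topology(taxa = taxa)
  for (i in seq_len(pool_size - 1L)) {
    pool[[i + 1L]] <- if (length(taxa) >= 3L) nni_topology(pool[[i]]) else pool[[i]]
  }
  splits_env <- new.env(parent = emptyenv())
  for (top in pool) {
    for (parent in names(top$children)) {
      kids <- top$children[[parent]]
      id <- split_id(kids[1], kids[2])
      cur <- splits_env[[parent]]
      if (is.null(cur) || !(id %in% cur)) {
        assign(parent, c(cur, id), envir = splits_env)
      }
    }
  }
  splits <- list()
  for (parent in sort(ls(splits_env))) {
    ids <- sort(splits_env[[parent]])
    sides <- split_sides(ids)
    w <- stats::rgamma(length(ids), shape = concentration)
    if (all(w == 0)) w <- rep(1, length(ids))
    d <- data.frame(
      left = vapply(sides, `[`, character(1), 1L),
      right = vapply(sides, `[`, character(1), 2L),
      prob = w / sum(w),
      count = NA_real_,
      stringsAsFactors = FALSE
    )
    splits[[parent]] <- d[order(d$left, d$right), , drop = FALSE]
  }
  validate_ccd(new_ccd_graph(taxa, "random", splits))
}

#' Replicate posterior-like samples from a truth distribution
#'
#' Draws i.i.d. topologies from `truth` and organizes them per replicate
#' and subsample size, with nested prefixes within one replicate (the
#' size-3 sample is the head of the size-10 sample, and so on), mirroring
#' how subsamples of a single MCMC chain relate to each other.
#'
#' @param truth A `ccd_graph` or `ccd2_graph` to sample from.
#' @param sizes Increasing integer vector of subsample sizes.
#' @param replicates Number of independent replicate chains.
#' @return A list of `replicates` elements, each a named list of
#'   `tree_sample` objects keyed by size.
#' @export
synth_posterior <- function(truth, sizes, replicates = 2L) {
  sizes <- sort(unique(as.integer(sizes)))
  stopifnot(all(sizes >= 1L), replicates >= 1L)
  lapply(seq_len(replicates), function(r) {
    draws <- sample_trees(truth, max(sizes))
    flat <- rep(draws$topologies, draws$multiplicity)
    # restore an arbitrary-but-seeded chain order
    flat <- flat[sample.int(length(flat))]
    out <- lapply(sizes, function(s) tree_sample(flat[seq_len(s)], taxa = truth$taxa))
    stats::setNames(out, as.character(sizes))
  })
}
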