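# Distribution queries shared by sample distributions and CCD graphs:
# tree probability, sampling, exact tree counts, entropy, and clade
# probabilities. All recursions are dynamic programs over the clade graph
# (or, for CCD2, over clade-in-context vertices).

#' Probability of a topology under a tree distribution
#'
#' For a CCD this is the product of conditional clade-split probabilities
#' along the tree (sibling-aware for CCD2), computed in log space; trees
#' requiring a clade or split absent from the graph have probability zero.
#' For a `tree_sample` it is the Monte Carlo frequency of the topology.
#'
#' @param dist A `ccd_graph`, `ccd2_graph`, or `tree_sample`.
#' @param tree A resolved `tree_topology` on the same taxa.
#' @return A probability.
#' @export
tree_probability <- function(dist, tree) UseMethod("tree_probability")

check_same_taxa <- function(dist, tree) {
  stopifnot(inherits(tree, "tree_topology"))
  if (!identical(dist$taxa, tree$taxa)) {
    if (!setequal(dist$taxa, tree$taxa)) stop("taxon sets differ")
    tree <- remap_topology(tree, dist$taxa)
  }
  if (!tree$resolved) stop("tree probabilities are defined for resolved topologies")
  tree
}

#' @export
tree_probability.ccd_graph <- function(dist, tree) {
  tree <- check_same_taxa(dist, tree)
  lp <- 0
  for (parent in names(tree$children)) {
    d <- dist$splits[[parent]]
    if (is.null(d)) return(0)
    kids <- tree$children[[parent]]
    hit <- which(d$left == kids[1] & d$right == kids[2])
    if (length(hit) == 0L || d$prob[hit] == 0) return(0)
    lp <- lp + log(d$prob[hit])
  }
  exp(lp)
}

#' @export
tree_probability.ccd2_graph <- function(dist, tree) {
  tree <- check_same_taxa(dist, tree)
  context <- stats::setNames("ROOT", root_key(dist$taxa))
  lp <- 0
  for (parent in names(tree$children)[order(-key_size(names(tree$children)))]) {
    kids <- tree$children[[parent]]
    d <- dist$splits[[ccd2_vertex(parent, context[[parent]])]]
    if (is.null(d)) return(0)
    hit <- which(d$left == kids[1] & d$right == kids[2])
    if (length(hit) == 0L || d$prob[hit] == 0) return(0)
    lp <- lp + log(d$prob[hit])
    context[kids[1]] <- kids[2]
    context[kids[2]] <- kids[1]
  }
  exp(lp)
}

#' @export
tree_probability.tree_sample <- function(dist, tree) {
  tree <- check_same_taxa(dist, tree)
  keys <- vapply(dist$topologies, function(t) t$key, character(1))
  hit <- match(tree$key, keys)
  if (is.na(hit)) 0 else dist$multiplicity[hit] / dist$k
}

#' Draw topologies from a tree distribution
#'
#' Sampling from a CCD walks the clade graph from the root, picking a clade
#' split at each clade according to its conditional probability, so the
#' sampling distribution equals [tree_probability()]. Uses R's global RNG;
#' seed with [set.seed()] for reproducibility.
#'
#' @param dist A `ccd_graph`, `ccd2_graph`, or `tree_sample`.
#' @param n Number of draws.
#' @return A `tree_sample` of the `n` draws (identical draws merged).
#' @export
sample_trees <- function(dist, n = 1L) UseMethod("sample_trees")

pick_row <- function(d) {
  if (nrow(d) == 1L) 1L else sample.int(nrow(d), 1L, prob = d$prob)
}

#' @export
sample_trees.ccd_graph <- function(dist, n = 1L) {
  draws <- replicate(n, {
    children <- list()
    expand <- root_key(dist$taxa)
    while (length(expand) > 0L) {
      clade <- expand[[1]]
      expand <- expand[-1]
      d <- dist$splits[[clade]]
      row <- pick_row(d)
      kids <- sort(c(d$left[row], d$right[row]))
      children[[clade]] <- kids
      expand <- c(expand, kids[!is_leaf_key(kids)])
    }
    new_topology(dist$taxa, children)
  }, simplify = FALSE)
  tree_sample(draws, taxa = dist$taxa)
}

#' @export
sample_trees.ccd2_graph <- function(dist, n = 1L) {
  draws <- replicate(n, {
    children <- list()
    expand <- list(c(root_key(dist$taxa), "ROOT"))
    while (length(expand) > 0L) {
      v <- expand[[1]]
      expand <- expand[-1]
      d <- dist$splits[[ccd2_vertex(v[1], v[2])]]
      row <- pick_row(d)
      l <- d$left[row]
      r <- d$right[row]
      children[[v[1]]] <- sort(c(l, r))
      if (!is_leaf_key(l)) expand <- c(expand, list(c(l, r)))
      if (!is_leaf_key(r)) expand <- c(expand, list(c(r, l)))
    }
    new_topology(dist$taxa, children)
  }, simplify = FALSE)
  tree_sample(draws, taxa = dist$taxa)
}

#' @export
sample_trees.tree_sample <- function(dist, n = 1L) {
  idx <- sample.int(length(dist$topologies), n, replace = TRUE,
                    prob = dist$multiplicity)
  tree_sample(dist$topologies[idx], taxa = dist$taxa)
}

#' Exact number of distinct topologies displayed by a distribution
#'
#' Bottom-up dynamic program `t(C) = sum over splits of t(C1) t(C2)` with
#' `t(leaf) = 1`; for CCD2 the recursion runs over clade-in-context
#' vertices. Counts are computed in exact arbitrary-precision arithmetic.
#'
#' @param dist A `ccd_graph`, `ccd2_graph`, or `tree_sample`.
#' @return The count as a numeric when it fits exactly in a double, else as
#'   a decimal digit string.
#' @export
count_trees <- function(dist) UseMethod("count_trees")

#' @export
count_trees.ccd_graph <- function(dist) {
  memo <- new.env(parent = emptyenv())
  count <- function(clade) {
    if (is_leaf_key(clade)) return(1)
    got <- memo[[clade]]
    if (!is.null(got)) return(got)
    d <- dist$splits[[clade]]
    acc <- 0
    for (i in seq_len(nrow(d))) {
      acc <- big_add(acc, big_mul(count(d$left[i]), count(d$right[i])))
    }
    assign(clade, acc, envir = memo)
    acc
  }
  big_value(count(root_key(dist$taxa)))
}

#' @export
count_trees.ccd2_graph <- function(dist) {
  memo <- new.env(parent = emptyenv())
  count <- function(clade, context) {
    if (is_leaf_key(clade)) return(1)
    vid <- ccd2_vertex(clade, context)
    got <- memo[[vid]]
    if (!is.null(got)) return(got)
    d <- dist$splits[[vid]]
    acc <- 0
    for (i in seq_len(nrow(d))) {
      acc <- big_add(acc, big_mul(count(d$left[i], d$right[i]),
                                  count(d$right[i], d$left[i])))
    }
    assign(vid, acc, envir = memo)
    acc
  }
  big_value(count(root_key(dist$taxa), "ROOT"))
}

#' @export
count_trees.tree_sample <- function(dist) as.numeric(length(dist$topologies))

#' Entropy and effective number of topologies
#'
#' Shannon entropy (natural log) of the tree distribution, computed for
#' CCDs by the per-clade recursion
#' `H*(C) = sum_S -Pr(S) (log Pr(S) - H*(C1) - H*(C2))` with `H*(leaf) = 0`.
#' The number equivalent `Ne = exp(H)` is the effective number of distinct
#' topologies.
#'
#' @param dist A `ccd_graph`, `ccd2_graph`, or `tree_sample`.
#' @return Named numeric vector with elements `H` (nats) and `Ne`.
#' @export
entropy <- function(dist) UseMethod("entropy")

entropy_from_splits <- function(children_of, root_id) {
  memo <- new.env(parent = emptyenv())
  hstar <- function(id) {
    node <- children_of(id)
    if (is.null(node)) return(0)  # leaf
    got <- memo[[id]]
    if (!is.null(got)) return(got)
    d <- node$table
    acc <- 0
    for (i in seq_len(nrow(d))) {
      p <- d$prob[i]
      if (p == 0) next
      acc <- acc - p * (log(p) - hstar(node$child_ids[[i]][1]) -
                          hstar(node$child_ids[[i]][2]))
    }
    assign(id, acc, envir = memo)
    acc
  }
  h <- hstar(root_id)
  c(H = h, Ne = exp(h))
}

#' @export
entropy.ccd_graph <- function(dist) {
  entropy_from_splits(function(id) {
    if (is_leaf_key(id)) return(NULL)
    d <- dist$splits[[id]]
    list(table = d, child_ids = Map(c, d$left, d$right))
  }, root_key(dist$taxa))
}

#' @export
entropy.ccd2_graph <- function(dist) {
  entropy_from_splits(function(id) {
    clade <- sub("@.*$", "", id)
    if (is_leaf_key(clade)) return(NULL)
    d <- dist$splits[[id]]
    list(
      table = d,
      child_ids = Map(function(l, r) c(ccd2_vertex(l, r), ccd2_vertex(r, l)),
                      d$left, d$right)
    )
  }, ccd2_root_vertex(dist))
}

#' @export
entropy.tree_sample <- function(dist) {
  p <- dist$multiplicity / dist$k
  h <- -sum(p * log(p))
  c(H = h, Ne = exp(h))
}

#' Probability that a drawn tree contains a clade
#'
#' Top-down recursion over the clade graph: the root has probability one
#' and each clade accumulates `Pr(parent) * Pr(S | parent)` over the split
#' instances pointing at it (within one tree these are disjoint events).
#' Clades absent from the graph have probability zero. For a CCD1 this
#' equals the Monte Carlo clade frequency `f(C)/k` of the sample it was
#' built from.
#'
#' @param dist A `ccd_graph`, `ccd2_graph`, or `tree_sample`.
#' @param clade Clade of interest: a character vector of taxon labels, or a
#'   single clade key string.
#' @return A probability.
#' @export
clade_probability <- function(dist, clade) UseMethod("clade_probability")

resolve_clade <- function(clade, taxa) {
  if (length(clade) == 1L && nchar(clade) == length(taxa) &&
      grepl("^[01]+$", clade)) {
    return(clade)
  }
  clade_key(clade, taxa)
}

ccd_clade_probabilities <- function(dist) {
  p <- stats::setNames(numeric(length(dist$clades)), dist$clades)
  p[root_key(dist$taxa)] <- 1
  for (parent in names(dist$splits)[order(-key_size(names(dist$splits)))]) {
    d <- dist$splits[[parent]]
    w <- p[parent] * d$prob
    for (i in seq_len(nrow(d))) {
      p[d$left[i]] <- p[d$left[i]] + w[i]
      p[d$right[i]] <- p[d$right[i]] + w[i]
    }
  }
  p
}

#' @export
clade_probability.ccd_graph <- function(dist, clade) {
  key <- resolve_clade(clade, dist$taxa)
  p <- ccd_clade_probabilities(dist)
  if (key %in% names(p)) unname(p[key]) else 0
}

#' @export
clade_probability.ccd2_graph <- function(dist, clade) {
  key <- resolve_clade(clade, dist$taxa)
  p <- ccd2_clade_probabilities(dist)
  if (key %in% names(p)) unname(p[key]) else 0
}

# containment probability per clade, summing over clade-in-context
# vertices (mutually exclusive within one tree)
ccd2_clade_probabilities <- function(dist) {
  vids <- names(dist$splits)
  p <- new.env(parent = emptyenv())
  assign(ccd2_root_vertex(dist), 1, envir = p)
  bump <- function(id, by) {
    assign(id, by + (if (is.null(p[[id]])) 0 else p[[id]]), envir = p)
  }
  clade_of <- sub("@.*$", "", vids)
  for (vid in vids[order(-key_size(clade_of))]) {
    d <- dist$splits[[vid]]
    base <- if (is.null(p[[vid]])) 0 else p[[vid]]
    for (i in seq_len(nrow(d))) {
      bump(ccd2_vertex(d$left[i], d$right[i]), base * d$prob[i])
      bump(ccd2_vertex(d$right[i], d$left[i]), base * d$prob[i])
    }
  }
  ids <- ls(p)
  vals <- vapply(ids, function(id) p[[id]], numeric(1))
  rowsum_keys <- sub("@.*$", "", ids)
  agg <- rowsum(vals, rowsum_keys)
  stats::setNames(agg[, 1], rownames(agg))
}

#' @export
clade_probability.tree_sample <- function(dist, clade) {
  key <- resolve_clade(clade, dist$taxa)
  hit <- vapply(dist$topologies, function(t) key %in% topology_clades(t),
                logical(1))
  sum(dist$multiplicity[hit]) / dist$k
}

#' Flag likely burn-in outliers in a tree sample
#'
#' A sampled topology whose nontrivial clades are all private to it (their
#' frequency equals the topology's own multiplicity) shares no structure
#' with the rest of the sample; under a CCD1/CCD2 such a tree keeps
#' probability `multiplicity/k`, which vastly overestimates a stray
#' burn-in state. Such topologies are flagged when they are the minority
#' side of the sample (multiplicity below half of `k`). Topologies
#' containing once-observed clades or splits are also reported. Advisory
#' only: nothing is removed.
#'
#' @param sample A `tree_sample` with `k >= 2`.
#' @param table Optional matching `clade_freq_table` (recomputed if
#'   missing).
#' @return A tibble with one row per distinct topology: `topology`
#'   (Newick), `multiplicity`, `disjoint_outlier`, `n_once_clades`,
#'   `n_once_splits`, and `flagged`.
#' @export
detect_outliers <- function(sample, table = NULL) {
  stopifnot(inherits(sample, "tree_sample"))
  if (sample$k < 2L) stop("outlier detection needs at least two trees")
  if (is.null(table)) table <- tally(sample)
  rows <- lapply(seq_along(sample$topologies), function(i) {
    top <- sample$topologies[[i]]
    m <- sample$multiplicity[i]
    nt <- topology_clades(top, trivial = FALSE)
    ids <- unname(topology_splits(top))
    # disjoint outlier: shares no nontrivial clade with the rest of the
    # sample and is the minority side of the sample
    disjoint <- length(nt) > 0L && all(table$clade_count[nt] == m) &&
      m < sample$k - m
    tibble::tibble(
      topology = write_tree(top),
      multiplicity = m,
      disjoint_outlier = disjoint,
      n_once_clades = sum(table$clade_count[nt] == 1),
      n_once_splits = sum(table$split_count[ids] == 1)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$flagged <- out$disjoint_outlier | out$n_once_clades > 0 | out$n_once_splits > 0
  out
}
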