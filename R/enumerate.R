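# Explicit enumeration of all topologies displayed by a distribution, with
# exact probabilities. Used as the independent cross-check for every
# dynamic program on the clade graph, and to evaluate credible sets; cost
# is linear in the number of displayed trees, so a cap guards against
# combinatorial blow-up.

#' Enumerate all displayed topologies with their probabilities
#'
#' Recursively expands the clade graph (clade-in-context vertices for CCD2)
#' into every displayed topology. Probabilities sum to one over the result.
#'
#' @param dist A `ccd_graph`, `ccd2_graph`, or `tree_sample`.
#' @param cap Refuse to enumerate more than this many topologies.
#' @return A tibble sorted by decreasing probability (ties by topology key)
#'   with columns `key`, `prob`, and a list-column `tree` of
#'   `tree_topology` objects.
#' @export
enumerate_trees <- function(dist, cap = 1e6) UseMethod("enumerate_trees")

check_cap <- function(dist, cap) {
  n <- count_trees(dist)
  if (is.character(n) || n > cap) {
    stop("distribution displays ", n, " trees, more than the cap of ", cap)
  }
  n
}

enum_finish <- function(taxa, frags) {
  trees <- lapply(frags, function(fr) new_topology(taxa, fr$children))
  keys <- vapply(trees, function(t) t$key, character(1))
  probs <- vapply(frags, function(fr) fr$prob, numeric(1))
  ord <- order(-probs, keys)
  tibble::tibble(key = keys[ord], prob = probs[ord], tree = trees[ord])
}

# fragments: list(children = named list, prob = numeric)
cross_fragments <- function(a, b, extra_parent, extra_kids, weight) {
  out <- vector("list", length(a) * length(b))
  pos <- 0L
  for (fa in a) {
    for (fb in b) {
      pos <- pos + 1L
      children <- c(fa$children, fb$children)
      children[[extra_parent]] <- extra_kids
      out[[pos]] <- list(children = children, prob = fa$prob * fb$prob * weight)
    }
  }
  out
}

leaf_fragment <- list(list(children = list(), prob = 1))

#' @export
enumerate_trees.ccd_graph <- function(dist, cap = 1e6) {
  check_cap(dist, cap)
  memo <- new.env(parent = emptyenv())
  expand <- function(clade) {
    if (is_leaf_key(clade)) return(leaf_fragment)
    got <- memo[[clade]]
    if (!is.null(got)) return(got)
    d <- dist$splits[[clade]]
    frags <- list()
    for (i in seq_len(nrow(d))) {
      if (d$prob[i] == 0) next
      frags <- c(frags, cross_fragments(
        expand(d$left[i]), expand(d$right[i]),
        clade, sort(c(d$left[i], d$right[i])), d$prob[i]
      ))
    }
    assign(clade, frags, envir = memo)
    frags
  }
  enum_finish(dist$taxa, expand(root_key(dist$taxa)))
}

#' @export
enumerate_trees.ccd2_graph <- function(dist, cap = 1e6) {
  check_cap(dist, cap)
  memo <- new.env(parent = emptyenv())
  expand <- function(clade, context) {
    if (is_leaf_key(clade)) return(leaf_fragment)
    vid <- ccd2_vertex(clade, context)
    got <- memo[[vid]]
    if (!is.null(got)) return(got)
    d <- dist$splits[[vid]]
    frags <- list()
    for (i in seq_len(nrow(d))) {
      if (d$prob[i] == 0) next
      frags <- c(frags, cross_fragments(
        expand(d$left[i], d$right[i]), expand(d$right[i], d$left[i]),
        clade, sort(c(d$left[i], d$right[i])), d$prob[i]
      ))
    }
    assign(vid, frags, envir = memo)
    frags
  }
  enum_finish(dist$taxa, expand(root_key(dist$taxa), "ROOT"))
}

#' @export
enumerate_trees.tree_sample <- function(dist, cap = 1e6) {
  keys <- vapply(dist$topologies, function(t) t$key, character(1))
  probs <- dist$multiplicity / dist$k
  ord <- order(-probs, keys)
  tibble::tibble(key = keys[ord], prob = probs[ord], tree = dist$topologies[ord])
}
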