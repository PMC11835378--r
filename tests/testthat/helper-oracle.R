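# Independent brute-force oracles: explicit recursion over *all* rooted
# binary topologies on a small taxon set, with probabilities computed from
# first principles (no clade-graph dynamic programming involved).

all_topologies <- function(taxa) {
  n <- length(taxa)
  build <- function(labels) {
    if (length(labels) == 1L) {
      return(list(list(children = list())))
    }
    first <- labels[1]
    rest <- labels[-1]
    out <- list()
    for (size_left in 0:(length(rest) - 1L)) {
      combos <- utils::combn(rest, size_left, simplify = FALSE)
      if (size_left == 0L) combos <- list(character(0))
      for (extra in combos) {
        left <- c(first, extra)
        right <- setdiff(labels, left)
        for (lt in build(left)) {
          for (rt in build(right)) {
            children <- c(lt$children, rt$children)
            children[[clade_key(labels, taxa)]] <-
              sort(c(clade_key(left, taxa), clade_key(right, taxa)))
            out[[length(out) + 1L]] <- list(children = children)
          }
        }
      }
    }
    out
  }
  lapply(build(taxa), function(x) {
    ccdtree:::new_topology(taxa, x$children)
  })
}

# probability of each topology under a fitted graph, evaluated over the
# complete topology space; returns named vector by topology key
all_topology_probs <- function(dist, taxa) {
  tops <- all_topologies(taxa)
  p <- vapply(tops, function(t) tree_probability(dist, t), numeric(1))
  stats::setNames(p, vapply(tops, function(t) t$key, character(1)))
}

# brute-force CCD0 target: mass proportional to prod f(C)/k over trees
# whose clades are all observed, normalized
ccd0_target_probs <- function(table, taxa) {
  tops <- all_topologies(taxa)
  observed <- names(table$clade_count)
  w <- vapply(tops, function(t) {
    cl <- topology_clades(t, trivial = FALSE)
    if (!all(cl %in% observed)) return(0)
    prod(table$clade_count[cl] / table$k)
  }, numeric(1))
  stats::setNames(w / sum(w), vapply(tops, function(t) t$key, character(1)))
}
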