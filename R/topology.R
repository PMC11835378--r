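# Rooted tree topologies as laminar families of clades. A topology stores,
# for every non-leaf clade, the keys of its child clades; binary nodes have
# exactly two children. Branch lengths and node labels play no role in
# identity: two topologies are equal iff their clade sets are equal.

new_topology <- function(taxa, children) {
  children <- children[order(names(children))]
  resolved <- all(lengths(children) == 2L)
  structure(
    list(
      taxa = taxa,
      children = children,
      resolved = resolved,
      key = topology_key_from_children(children, taxa)
    ),
    class = "tree_topology"
  )
}

topology_key_from_children <- function(children, taxa) {
  nt <- setdiff(names(children), root_key(taxa))
  paste(sort(nt), collapse = ";")
}

#' All clades of a topology
#'
#' @param tree A `tree_topology`.
#' @param trivial Include the root clade and the singleton leaf clades?
#' @return Character vector of clade keys.
#' @export
topology_clades <- function(tree, trivial = TRUE) {
  internal <- names(tree$children)
  if (trivial) {
    unique(c(internal, singleton_keys(tree$taxa)))
  } else {
    setdiff(internal, root_key(tree$taxa))
  }
}

# splits of a (binary part of a) topology as canonical "left|right" ids,
# named by parent clade key
topology_splits <- function(tree) {
  ch <- tree$children
  bin <- ch[lengths(ch) == 2L]
  ids <- vapply(bin, function(p) split_id(p[1], p[2]), character(1))
  names(ids) <- names(bin)
  ids
}

#' @export
print.tree_topology <- function(x, ...) {
  cat(
    "Rooted topology on", length(x$taxa), "taxa",
    if (x$resolved) "(resolved)" else "(unresolved)", "\n"
  )
  cat(" ", write_tree(x), "\n")
  invisible(x)
}

#' Convert an ape phylogeny to a topology
#'
#' Branch lengths, node labels and tip rotation are discarded; only the
#' clade structure is kept. The tree must be rooted, and its tips must match
#' `taxa` exactly.
#'
#' @param phy An [ape::read.tree()]-style `phylo` object.
#' @param taxa Ordered taxon labels defining the shared taxon set; defaults
#'   to the sorted tip labels of `phy`.
#' @param require_binary Reject multifurcating trees?
#' @return A `tree_topology`.
#' @export
as_topology <- function(phy, taxa = NULL, require_binary = TRUE) {
  if (inherits(phy, "tree_topology")) return(phy)
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' or 'tree_topology' object")
  if (is.null(taxa)) taxa <- sort(phy$tip.label)
  validate_taxa(taxa)
  if (length(phy$tip.label) != length(taxa) || !setequal(phy$tip.label, taxa)) {
    stop("tree tips do not match the taxon set")
  }
  if (!ape::is.rooted(phy)) stop("trees must be rooted")
  n <- length(taxa)
  idx <- match(phy$tip.label, taxa)
  nnode <- phy$Nnode
  edge <- phy$edge
  # member bit rows per node, filled tips-first in postorder
  memb <- matrix(FALSE, nrow = n + nnode, ncol = n)
  memb[cbind(seq_len(n), idx)] <- TRUE
  po <- ape::reorder.phylo(phy, "postorder")
  kids <- vector("list", n + nnode)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]
    ch <- po$edge[e, 2L]
    memb[p, ] <- memb[p, ] | memb[ch, ]
    kids[[p]] <- c(kids[[p]], ch)
  }
  keys <- apply(memb, 1L, function(row) paste(ifelse(row, "1", "0"), collapse = ""))
  internal <- which(lengths(kids) > 0L)
  if (require_binary && any(lengths(kids[internal]) != 2L)) {
    stop("trees must be binary (no polytomies)")
  }
  children <- lapply(internal, function(v) sort(keys[kids[[v]]]))
  names(children) <- keys[internal]
  if (anyDuplicated(names(children))) stop("invalid tree: duplicated clades")
  new_topology(taxa, children)
}

#' Write a topology as a Newick string
#'
#' Internal nodes can carry BEAST-style `[&support=...]` metadata, keyed by
#' clade. The output round-trips through [parse_trees()] up to clade-set
#' identity.
#'
#' @param tree A `tree_topology`.
#' @param annotations Optional named numeric vector of node annotations;
#'   names are clade keys (see [clade_key()]) of clades present in `tree`.
#' @param label Annotation label used inside the comment, default
#'   `"support"`.
#' @param file Optional path; when given the string is written to it.
#' @param digits Significant digits for annotation values.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_tree <- function(tree, annotations = NULL, label = "support",
                       file = NULL, digits = 6) {
  stopifnot(inherits(tree, "tree_topology"))
  if (!is.null(annotations)) {
    if (is.null(names(annotations)) ||
        !all(names(annotations) %in% topology_clades(tree))) {
      stop("annotations must be named by clade keys of clades in the tree")
    }
  }
  render <- function(key) {
    tag <- ""
    if (!is.null(annotations) && key %in% names(annotations)) {
      tag <- sprintf("[&%s=%s]", label,
                     format(unname(annotations[key]), digits = digits))
    }
    if (key_size(key) == 1L) {
      return(paste0(tree$taxa[key_indices(key)], tag))
    }
    kids <- tree$children[[key]]
    kids <- kids[order(vapply(kids, function(k) min(key_indices(k)), integer(1)))]
    parts <- vapply(kids, render, character(1))
    paste0("(", paste(parts, collapse = ","), ")", tag)
  }
  out <- paste0(render(root_key(tree$taxa)), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' @rdname write_tree
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = write_tree(tree))
}

#' Rooted Robinson-Foulds distance
#'
#' Half the size of the symmetric difference of the two topologies' clade
#' sets, taken over nontrivial clades (root and singletons excluded). On
#' resolved topologies this is a metric; comparing with an unresolved tree
#' can give half-integer values.
#'
#' @param t1,t2 `tree_topology` objects on the same taxon set.
#' @return Non-negative half-integer.
#' @examples
#' t1 <- parse_trees("(((A,B),C),(D,E));")$topologies[[1]]
#' t2 <- parse_trees("(((A,(B,C)),D),E);")$topologies[[1]]
#' rf_distance(t1, t2)
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "tree_topology"), inherits(t2, "tree_topology"))
  if (!identical(t1$taxa, t2$taxa)) {
    if (!setequal(t1$taxa, t2$taxa)) stop("trees are on different taxon sets")
    t2 <- remap_topology(t2, t1$taxa)
  }
  c1 <- topology_clades(t1, trivial = FALSE)
  c2 <- topology_clades(t2, trivial = FALSE)
  (length(setdiff(c1, c2)) + length(setdiff(c2, c1))) / 2
}

#' Relative Robinson-Foulds distance to a reference tree
#'
#' The fraction of the n - 2 nontrivial clades of a resolved reference tree
#' that the estimate gets wrong: `rf_distance / (n - 2)`.
#'
#' @param estimate A `tree_topology`.
#' @param truth A resolved `tree_topology` on the same taxa.
#' @return A fraction in `[0, 1]` (may exceed 1 only if `estimate` is
#'   unresolved in a way that cannot happen for resolved estimates).
#' @export
relative_rf <- function(estimate, truth) {
  stopifnot(inherits(truth, "tree_topology"))
  if (!truth$resolved) stop("the reference tree must be fully resolved")
  n <- length(truth$taxa)
  if (n < 3L) stop("relative RF distance needs at least 3 taxa")
  rf_distance(estimate, truth) / (n - 2)
}

# re-key a topology onto a different ordering of the same taxa
remap_topology <- function(tree, taxa) {
  remap <- function(key) clade_key(tree$taxa[key_indices(key)], taxa)
  children <- lapply(tree$children, function(kids) sort(vapply(kids, remap, character(1))))
  names(children) <- vapply(names(tree$children), remap, character(1))
  new_topology(taxa, children)
}
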