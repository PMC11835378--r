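# Reading and writing posterior tree samples. Parsing goes through ape
# (plain Newick and Nexus TREES blocks with optional TRANSLATE, the format
# BEAST writes); topology identity ignores branch lengths and metadata
# comments, and identical topologies are merged with multiplicities.

new_tree_sample <- function(taxa, topologies, multiplicity) {
  stopifnot(length(topologies) == length(multiplicity), length(topologies) > 0L)
  keys <- vapply(topologies, function(t) t$key, character(1))
  ord <- order(keys)
  structure(
    list(
      taxa = taxa,
      topologies = topologies[ord],
      multiplicity = as.integer(multiplicity[ord]),
      k = sum(as.integer(multiplicity))
    ),
    class = "tree_sample"
  )
}

#' Assemble a tree sample from topologies
#'
#' @param topologies List of `tree_topology` objects (or `phylo` objects, or
#'   Newick strings) on a common taxon set.
#' @param multiplicity Integer vector of per-topology counts, recycled from
#'   1. Duplicate topologies are merged.
#' @param taxa Optional explicit taxon ordering.
#' @return A `tree_sample` with elements `taxa`, `topologies`,
#'   `multiplicity`, and total size `k`.
#' @export
tree_sample <- function(topologies, multiplicity = 1L, taxa = NULL) {
  topologies <- lapply(topologies, function(t) {
    if (is.character(t)) t <- ape::read.tree(text = t)
    as_topology(t, taxa = taxa)
  })
  if (is.null(taxa)) taxa <- topologies[[1]]$taxa
  topologies <- lapply(topologies, function(t) {
    if (identical(t$taxa, taxa)) t else remap_topology(t, taxa)
  })
  multiplicity <- rep_len(as.integer(multiplicity), length(topologies))
  keys <- vapply(topologies, function(t) t$key, character(1))
  agg <- rowsum(multiplicity, keys)
  idx <- match(rownames(agg), keys)  # not name indexing: keys may be ""
  new_tree_sample(taxa, topologies[idx], agg[, 1])
}

#' Parse a posterior sample of rooted binary trees
#'
#' Reads trees from Newick text/files or Nexus files (TREES block, optional
#' TRANSLATE as written by BEAST), discards a leading burn-in fraction,
#' drops branch lengths and `[&...]` metadata, and merges identical
#' topologies. All trees must be rooted, binary, and on the same taxa; the
#' taxon order of the first retained tree defines the shared taxon set.
#'
#' @param source Path to a tree file, or a character vector of Newick text.
#' @param format `"newick"` or `"nexus"`. Guessed from the file when
#'   omitted.
#' @param burnin_fraction Fraction in `[0, 1)` of leading trees to discard
#'   (in file order, before merging).
#' @return A `tree_sample`.
#' @examples
#' s <- parse_trees(c("((A,B),C);", "((A,B),C);", "((A,C),B);"),
#'                  burnin_fraction = 0)
#' s$k
#' @export
parse_trees <- function(source, format = NULL, burnin_fraction = 0.1) {
  if (!is.numeric(burnin_fraction) || burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("burnin_fraction must lie in [0, 1)")
  }
  is_path <- length(source) == 1L && !grepl("[();]", source) && file.exists(source)
  if (is.null(format)) {
    format <- if (is_path && grepl("\\.(nex|nexus|trees|t)$", source, ignore.case = TRUE)) {
      "nexus"
    } else if (is_path && any(grepl("#NEXUS", toupper(readLines(source, n = 1L)), fixed = TRUE))) {
      "nexus"
    } else {
      "newick"
    }
  }
  format <- match.arg(format, c("newick", "nexus"))
  trees <- if (format == "nexus") {
    if (!is_path) {
      tf <- tempfile(fileext = ".nex")
      on.exit(unlink(tf), add = TRUE)
      writeLines(source, tf)
      source <- tf
    }
    ape::read.nexus(source)
  } else {
    txt <- if (is_path) readLines(source) else source
    txt <- strip_metadata_comments(txt)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) == 0L) stop("no trees found in input")
    ape::read.tree(text = txt)
  }
  if (is.null(trees)) stop("failed to parse trees from input")
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo") && !is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)
  }
  trees <- unclass(trees)
  n_in <- length(trees)
  drop <- floor(burnin_fraction * n_in)
  if (drop >= n_in) stop("no trees left after burn-in")
  trees <- trees[(drop + 1L):n_in]
  taxa <- trees[[1]]$tip.label
  validate_taxa(taxa)
  tops <- lapply(trees, as_topology, taxa = taxa)
  tree_sample(tops, taxa = taxa)
}

strip_metadata_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

#' Write a tree sample to a file
#'
#' @param sample A `tree_sample`.
#' @param file Output path.
#' @param format `"newick"` (one tree per line, repeated by multiplicity) or
#'   `"nexus"` (TREES block with TRANSLATE, via [ape::write.nexus()]).
#' @return `file`, invisibly.
#' @export
write_sample <- function(sample, file, format = c("newick", "nexus")) {
  stopifnot(inherits(sample, "tree_sample"))
  format <- match.arg(format)
  lines <- rep(
    vapply(sample$topologies, write_tree, character(1)),
    sample$multiplicity
  )
  if (format == "newick") {
    writeLines(lines, file)
  } else {
    phy <- lapply(lines, function(x) ape::read.tree(text = x))
    class(phy) <- "multiPhylo"
    ape::write.nexus(phy, file = file, translate = TRUE)
  }
  invisible(file)
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample: k =", x$k, "trees,",
      length(x$topologies), "distinct topologies on",
      length(x$taxa), "taxa\n")
  show <- utils::head(order(-x$multiplicity), 5L)
  for (i in show) {
    cat(sprintf("  %4d x %s\n", x$multiplicity[i], write_tree(x$topologies[[i]])))
  }
  if (length(x$topologies) > 5L) cat("  ...\n")
  invisible(x)
}
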