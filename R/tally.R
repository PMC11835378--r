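# Clade and clade-split frequency tables: the sufficient statistics from
# which all CCD parametrizations are built.

#' Tally clade and clade-split frequencies of a tree sample
#'
#' Counts, over the `k` trees of the sample, how often each clade `C` and
#' each clade split `S = C1 | C2` occurs. By construction `f(S) <= f(C)`
#' for every split of `C`, the split counts of each non-leaf observed clade
#' sum to `f(C)`, and the root and every singleton have frequency `k`.
#'
#' @param sample A `tree_sample`.
#' @return A `clade_freq_table` with fields `taxa`, `k`, `clade_count`
#'   (named by clade key), `split_count` (named by canonical
#'   `"left|right"` split id), and `split_parent` (split id to parent clade
#'   key).
#' @examples
#' s <- parse_trees(c("((A,B),C);", "((A,C),B);"), burnin_fraction = 0)
#' tally(s)$clade_count
#' @export
tally <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  taxa <- sample$taxa
  clade_env <- new.env(parent = emptyenv())
  split_env <- new.env(parent = emptyenv())
  parent_env <- new.env(parent = emptyenv())
  bump <- function(env, key, by) {
    assign(key, by + (if (is.null(env[[key]])) 0 else env[[key]]), envir = env)
  }
  for (i in seq_along(sample$topologies)) {
    top <- sample$topologies[[i]]
    m <- sample$multiplicity[i]
    for (parent in names(top$children)) {
      bump(clade_env, parent, m)
      kids <- top$children[[parent]]
      sid <- split_id(kids[1], kids[2])
      bump(split_env, sid, m)
      assign(sid, parent, envir = parent_env)
    }
    for (leaf in singleton_keys(taxa)) bump(clade_env, leaf, m)
  }
  as_named <- function(env) {
    keys <- sort(ls(env))
    stats::setNames(vapply(keys, function(k) env[[k]], numeric(1)), keys)
  }
  structure(
    list(
      taxa = taxa,
      k = sample$k,
      clade_count = as_named(clade_env),
      split_count = as_named(split_env),
      split_parent = {
        keys <- sort(ls(parent_env))
        stats::setNames(vapply(keys, function(k) parent_env[[k]], character(1)), keys)
      }
    ),
    class = "clade_freq_table"
  )
}

#' @export
print.clade_freq_table <- function(x, ...) {
  nt <- names(x$clade_count)[key_size(names(x$clade_count)) > 1L]
  cat("Clade frequency table: k =", x$k, "trees,",
      length(x$clade_count), "clades,",
      length(x$split_count), "observed splits\n")
  invisible(x)
}

#' Tidy view of a frequency table
#'
#' @param x A `clade_freq_table`.
#' @param ... Unused.
#' @return A tibble with one row per observed clade split: parent clade,
#'   both sides (as comma-joined member labels), and the counts `f(S)` and
#'   `f(C)`.
#' @method tidy clade_freq_table
#' @export
tidy.clade_freq_table <- function(x, ...) {
  ids <- names(x$split_count)
  sides <- split_sides(ids)
  lab <- function(key) paste(clade_members(key, x$taxa), collapse = ",")
  tibble::tibble(
    parent = vapply(x$split_parent[ids], lab, character(1)),
    left = vapply(sides, function(s) lab(s[1]), character(1)),
    right = vapply(sides, function(s) lab(s[2]), character(1)),
    f_split = unname(x$split_count[ids]),
    f_parent = unname(x$clade_count[x$split_parent[ids]]),
    k = x$k
  )
}

#' Monte Carlo clade credibilities f(C)/k
#'
#' @param table A `clade_freq_table`.
#' @param trivial Include root and singleton clades (which always have
#'   credibility 1)?
#' @return Named numeric vector of `f(C)/k` by clade key.
#' @export
clade_credibility <- function(table, trivial = FALSE) {
  stopifnot(inherits(table, "clade_freq_table"))
  cc <- table$clade_count / table$k
  if (!trivial) {
    sz <- key_size(names(cc))
    cc <- cc[sz > 1L & sz < length(table$taxa)]
  }
  cc
}
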