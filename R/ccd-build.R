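# Construction of conditional clade distributions. A ccd_graph is a forest
# network (bipartite clade / clade-split graph) with conditional
# probabilities Pr(S | C) on each clade's splits summing to one; the
# distribution over displayed trees is the product of the conditional split
# probabilities along a tree. CCD1 sets Pr(S | C) = f(S)/f(C) from observed
# split frequencies; CCD0 uses only observed clade frequencies, adds every
# split that can be assembled from observed clades, and normalizes so that
# a displayed tree's probability is proportional to the product of its
# clades' Monte Carlo probabilities f(C)/k.

new_ccd_graph <- function(taxa, flavor, splits, k = NA_real_, cred = NULL) {
  splits <- splits[order(names(splits))]
  structure(
    list(
      taxa = taxa,
      flavor = flavor,
      splits = splits,       # parent key -> data.frame(left, right, prob, count)
      clades = sort(unique(c(
        names(splits), singleton_keys(taxa),
        unlist(lapply(splits, function(d) c(d$left, d$right)), use.names = FALSE)
      ))),
      k = k,
      cred = cred            # f(C)/k per clade, kept for CCD0 scoring
    ),
    class = "ccd_graph"
  )
}

#' Build a CCD1 from observed clade-split frequencies
#'
#' The conditional probability of split `S` at clade `C` is `f(S)/f(C)`;
#' the graph contains exactly the observed clades and splits.
#'
#' @param table A `clade_freq_table` from [tally()].
#' @return A `ccd_graph` with `flavor = "ccd1"`.
#' @examples
#' s <- parse_trees(c("((A,B),C);", "((A,C),B);"), burnin_fraction = 0)
#' ccd1 <- build_ccd1(tally(s))
#' tidy(ccd1)
#' @export
build_ccd1 <- function(table) {
  stopifnot(inherits(table, "clade_freq_table"))
  ids <- names(table$split_count)
  parents <- table$split_parent[ids]
  sides <- split_sides(ids)
  df <- data.frame(
    parent = unname(parents),
    left = vapply(sides, `[`, character(1), 1L),
    right = vapply(sides, `[`, character(1), 2L),
    count = unname(table$split_count[ids]),
    stringsAsFactors = FALSE
  )
  df$prob <- df$count / unname(table$clade_count[df$parent])
  splits <- split(df[c("left", "right", "prob", "count")], df$parent)
  splits <- lapply(splits, function(d) d[order(d$left, d$right), , drop = FALSE])
  new_ccd_graph(table$taxa, "ccd1", splits, k = table$k,
                cred = table$clade_count / table$k)
}

#' Expand observed clades into all assemblable clade splits
#'
#' Returns every split `{C1, C2}` such that `C1`, `C2`, and `C1 U C2` are
#' all observed clades — a superset of the observed splits. For each parent
#' clade, each observed proper subset is tried as one side and the
#' complement is looked up by key, so the cost is quadratic in the number of
#' observed clades.
#'
#' @param table A `clade_freq_table`.
#' @return A data frame with columns `parent`, `left`, `right` (clade keys,
#'   canonical order within a split) and `observed` (was the split in the
#'   sample?).
#' @export
expand_splits <- function(table) {
  stopifnot(inherits(table, "clade_freq_table"))
  keys <- names(table$clade_count)
  sizes <- key_size(keys)
  observed <- new.env(parent = emptyenv())
  for (key in keys) assign(key, TRUE, envir = observed)
  out_parent <- character(0)
  out_left <- character(0)
  out_right <- character(0)
  nontriv_or_leaf <- keys[sizes < length(table$taxa)]
  for (parent in keys[sizes > 1L]) {
    psize <- sizes[match(parent, keys)]
    cand <- nontriv_or_leaf[key_size(nontriv_or_leaf) < psize]
    for (child in cand) {
      if (child >= key_diff(parent, child)) next  # canonical side order, dedup
      if (!key_subset(child, parent)) next
      comp <- key_diff(parent, child)
      if (!isTRUE(observed[[comp]])) next
      out_parent <- c(out_parent, parent)
      out_left <- c(out_left, child)
      out_right <- c(out_right, comp)
    }
  }
  ids <- paste(out_left, out_right, sep = "|")
  data.frame(
    parent = out_parent, left = out_left, right = out_right,
    observed = ids %in% names(table$split_count),
    stringsAsFactors = FALSE
  )
}

#' Build a CCD0 from observed clade frequencies
#'
#' The split set is the expansion of [expand_splits()]; conditional split
#' probabilities are then set so that every displayed tree `T` has
#' probability proportional to `prod_{C in C(T)} f(C)/k`, with total mass
#' one. This is done with one bottom-up pass computing per-clade subtree
#' sums `z`: `z(leaf) = 1`, `z(C) = (f(C)/k) * sum_{S in S(C)}
#' z(C1) z(C2)`, and `Pr({C1,C2} | C) = z(C1) z(C2) / sum_S z(C1') z(C2')`.
#'
#' @param table A `clade_freq_table`.
#' @return A `ccd_graph` with `flavor = "ccd0"`.
#' @export
build_ccd0 <- function(table) {
  stopifnot(inherits(table, "clade_freq_table"))
  exp_df <- expand_splits(table)
  cred <- table$clade_count / table$k
  z <- stats::setNames(rep(NA_real_, length(cred)), names(cred))
  z[key_size(names(z)) == 1L] <- 1
  ord <- names(sort(stats::setNames(key_size(names(cred)), names(cred))))
  splits <- list()
  for (parent in ord[key_size(ord) > 1L]) {
    rows <- exp_df[exp_df$parent == parent, , drop = FALSE]
    if (nrow(rows) == 0L) stop("observed clade without any split: ", parent)
    w <- z[rows$left] * z[rows$right]
    total <- sum(w)
    rows$prob <- as.numeric(w / total)
    rows$count <- NA_real_
    rows <- rows[order(rows$left, rows$right), , drop = FALSE]
    splits[[parent]] <- rows[c("left", "right", "prob", "count")]
    z[parent] <- unname(cred[parent]) * total
  }
  new_ccd_graph(table$taxa, "ccd0", splits, k = table$k, cred = cred)
}

#' Build a CCD2 (sibling-conditioned CCD) from a tree sample
#'
#' The extended CCD graph distinguishes each clade by the sibling clade next
#' to which it occurs (the root clade has a unique ROOT context). The
#' conditional probability of a split at a clade-in-context vertex is its
#' count divided by the vertex count, so the model matches the core of a
#' subsplit DAG populated by sample frequencies.
#'
#' @param sample A `tree_sample`.
#' @return A `ccd2_graph` with per-vertex split tables; vertex ids are
#'   `"<clade>@<sibling>"` with `"ROOT"` as the root context.
#' @export
build_ccd2 <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  taxa <- sample$taxa
  vcount <- new.env(parent = emptyenv())
  scount <- new.env(parent = emptyenv())
  bump <- function(env, key, by) {
    assign(key, by + (if (is.null(env[[key]])) 0 else env[[key]]), envir = env)
  }
  rk <- root_key(taxa)
  for (i in seq_along(sample$topologies)) {
    top <- sample$topologies[[i]]
    m <- sample$multiplicity[i]
    context <- stats::setNames("ROOT", rk)
    # walk top-down so each child knows its sibling
    for (parent in names(top$children)[order(-key_size(names(top$children)))]) {
      kids <- top$children[[parent]]
      ctx <- context[[parent]]
      vid <- paste(parent, ctx, sep = "@")
      bump(vcount, vid, m)
      bump(scount, paste(vid, split_id(kids[1], kids[2]), sep = " "), m)
      context[kids[1]] <- kids[2]
      context[kids[2]] <- kids[1]
    }
  }
  skeys <- sort(ls(scount))
  parts <- strsplit(skeys, " ", fixed = TRUE)
  vid <- vapply(parts, `[`, character(1), 1L)
  sides <- split_sides(vapply(parts, `[`, character(1), 2L))
  df <- data.frame(
    vertex = vid,
    left = vapply(sides, `[`, character(1), 1L),
    right = vapply(sides, `[`, character(1), 2L),
    count = vapply(skeys, function(k) scount[[k]], numeric(1)),
    stringsAsFactors = FALSE
  )
  df$prob <- df$count / vapply(df$vertex, function(v) vcount[[v]], numeric(1))
  splits <- split(df[c("left", "right", "prob", "count")], df$vertex)
  splits <- lapply(splits, function(d) d[order(d$left, d$right), , drop = FALSE])
  structure(
    list(
      taxa = taxa,
      flavor = "ccd2",
      splits = splits[order(names(splits))],
      vertex_count = stats::setNames(
        vapply(sort(ls(vcount)), function(v) vcount[[v]], numeric(1)),
        sort(ls(vcount))
      ),
      k = sample$k
    ),
    class = "ccd2_graph"
  )
}

ccd2_vertex <- function(clade, context) paste(clade, context, sep = "@")

ccd2_root_vertex <- function(ccd) ccd2_vertex(root_key(ccd$taxa), "ROOT")

is_leaf_key <- function(key) key_size(key) == 1L

#' @export
print.ccd_graph <- function(x, ...) {
  cat(sprintf(
    "%s graph on %d taxa: %d clades, %d splits%s\n",
    toupper(x$flavor), length(x$taxa), length(x$clades),
    sum(vapply(x$splits, nrow, integer(1))),
    if (is.na(x$k)) "" else sprintf(" (from k = %d trees)", as.integer(x$k))
  ))
  invisible(x)
}

#' @export
print.ccd2_graph <- function(x, ...) {
  cat(sprintf(
    "CCD2 (extended) graph on %d taxa: %d clade-context vertices, %d splits (from k = %d trees)\n",
    length(x$taxa), length(x$vertex_count),
    sum(vapply(x$splits, nrow, integer(1))), as.integer(x$k)
  ))
  invisible(x)
}

validate_ccd <- function(ccd, tol = 1e-12) {
  for (parent in names(ccd$splits)) {
    d <- ccd$splits[[parent]]
    if (nrow(d) < 1L) stop("non-leaf clade without splits: ", parent)
    if (any(d$prob < -tol | d$prob > 1 + tol)) stop("split probability outside [0, 1]")
    if (abs(sum(d$prob) - 1) > 1e-9) {
      stop("split probabilities at ", parent, " do not sum to 1")
    }
  }
  # every non-root clade reachable from the root
  if (inherits(ccd, "ccd_graph")) {
    kids <- unique(unlist(lapply(ccd$splits, function(d) c(d$left, d$right)),
                          use.names = FALSE))
    rk <- root_key(ccd$taxa)
    orphan <- setdiff(setdiff(ccd$clades, rk), kids)
    if (length(orphan) > 0L) stop("clades without a parent: ",
                                  paste(orphan, collapse = ", "))
  }
  invisible(ccd)
}
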