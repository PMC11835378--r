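# Point estimators of the posterior topology: the maximum clade
# credibility (MCC) tree restricted to the sample, the greedy majority-rule
# consensus, and the CCD-based MAP and MSCC trees obtained by dynamic
# programming over the clade graph. All tie-breaks are deterministic
# (documented per estimator) so repeated runs agree.

new_point_estimate <- function(tree, method, score, support = NULL) {
  structure(
    list(tree = tree, method = method, score = score, support = support),
    class = "point_estimate"
  )
}

#' @export
print.point_estimate <- function(x, ...) {
  cat(sprintf("%s point estimate (score = %.6g, %s)\n", x$method, x$score,
              if (x$tree$resolved) "resolved" else "unresolved"))
  cat(" ", write_tree(x$tree), "\n")
  invisible(x)
}

#' Maximum clade credibility (MCC) tree
#'
#' The sampled topology maximizing the product of Monte Carlo clade
#' credibilities `f(C)/k` over its nontrivial clades. Ties are broken
#' toward higher multiplicity, then by canonical clade-set order.
#'
#' @param sample A `tree_sample`.
#' @param table Optional matching `clade_freq_table` (recomputed if
#'   missing).
#' @return A `point_estimate` whose `score` is the clade credibility
#'   product and whose `support` holds `f(C)/k` for the tree's nontrivial
#'   clades.
#' @export
mcc_tree <- function(sample, table = NULL) {
  stopifnot(inherits(sample, "tree_sample"))
  if (is.null(table)) table <- tally(sample)
  cred <- table$clade_count / table$k
  scores <- vapply(sample$topologies, function(top) {
    sum(log(cred[topology_clades(top, trivial = FALSE)]))
  }, numeric(1))
  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  if (length(cand) > 1L) {
    mult <- sample$multiplicity[cand]
    cand <- cand[mult == max(mult)]
    if (length(cand) > 1L) {
      keys <- vapply(sample$topologies[cand], function(t) t$key, character(1))
      cand <- cand[order(keys)[1]]
    }
  }
  top <- sample$topologies[cand[1]][[1]]
  nt <- topology_clades(top, trivial = FALSE)
  new_point_estimate(top, "mcc", exp(scores[cand[1]]),
                     support = stats::setNames(unname(cred[nt]), nt))
}

#' Greedy majority-rule consensus tree
#'
#' Processes the observed nontrivial clades in decreasing frequency and
#' accepts each clade compatible (nested or disjoint) with everything
#' accepted so far, refining a star tree. Frequency ties are broken by
#' decreasing clade size, then by canonical clade key order, as a
#' deterministic stand-in for an arbitrary tie-break; the result may be
#' unresolved.
#'
#' @param table A `clade_freq_table`.
#' @return A `point_estimate`; `score` is the sum of accepted clade
#'   credibilities and `support` holds `f(C)/k` for the accepted clades.
#' @export
greedy_consensus <- function(table) {
  stopifnot(inherits(table, "clade_freq_table"))
  taxa <- table$taxa
  cred <- clade_credibility(table, trivial = FALSE)
  keys <- names(cred)
  ord <- order(-cred, -key_size(keys), keys)
  accepted <- character(0)
  for (key in keys[ord]) {
    ok <- all(vapply(accepted, keys_compatible, logical(1), b = key))
    if (ok) accepted <- c(accepted, key)
  }
  family <- c(root_key(taxa), accepted, singleton_keys(taxa))
  sizes <- key_size(family)
  children <- stats::setNames(
    rep(list(character(0)), sum(sizes > 1L)),
    family[sizes > 1L]
  )
  for (v in family[-1]) {
    sup <- family[sizes > key_size(v)]
    sup <- sup[vapply(sup, function(s) key_subset(v, s), logical(1))]
    parent <- sup[which.min(key_size(sup))]
    children[[parent]] <- sort(c(children[[parent]], v))
  }
  tree <- new_topology(taxa, children)
  new_point_estimate(tree, "greedy-consensus", sum(cred[accepted]),
                     support = cred[sort(accepted)])
}

#' CCD-MAP tree
#'
#' The topology of maximum probability under a CCD, found by the dynamic
#' program `Pr*(C) = max over splits of Pr(S | C) Pr*(C1) Pr*(C2)` (run in
#' log space; clade-in-context vertices for CCD2) and backtracking. Ties
#' are broken toward the canonical split order. The result need not be a
#' sampled topology and is always fully resolved.
#'
#' @param ccd A `ccd_graph` or `ccd2_graph`.
#' @param support Clade support to annotate the result with: `"ccd"` for
#'   clade probabilities under `ccd`, `"montecarlo"` for sample
#'   frequencies `f(C)/k` (where available), `"none"` to skip.
#' @return A `point_estimate` whose `score` equals
#'   `tree_probability(ccd, tree)`.
#' @export
map_tree <- function(ccd, support = c("ccd", "montecarlo", "none")) {
  UseMethod("map_tree")
}

map_backtrack <- function(taxa, choice, root_id, id_clade, id_children) {
  children <- list()
  walk <- function(id) {
    clade <- id_clade(id)
    if (is_leaf_key(clade)) return(invisible())
    kids <- choice[[id]]
    children[[clade]] <<- sort(c(id_clade(kids[1]), id_clade(kids[2])))
    walk(kids[1])
    walk(kids[2])
  }
  walk(root_id)
  new_topology(taxa, children)
}

map_dp <- function(taxa, root_id, node_table, id_clade) {
  memo <- new.env(parent = emptyenv())
  choice <- new.env(parent = emptyenv())
  best <- function(id) {
    if (is_leaf_key(id_clade(id))) return(0)
    got <- memo[[id]]
    if (!is.null(got)) return(got)
    node <- node_table(id)
    d <- node$table
    scores <- vapply(seq_len(nrow(d)), function(i) {
      log(d$prob[i]) + best(node$child_ids[[i]][1]) + best(node$child_ids[[i]][2])
    }, numeric(1))
    pick <- which.max(scores)  # table rows are in canonical order
    assign(id, node$child_ids[[pick]], envir = choice)
    assign(id, scores[pick], envir = memo)
    scores[pick]
  }
  lp <- best(root_id)
  tree <- map_backtrack(taxa, choice, root_id, id_clade, NULL)
  list(tree = tree, prob = exp(lp))
}

#' @export
map_tree.ccd_graph <- function(ccd, support = c("ccd", "montecarlo", "none")) {
  support <- match.arg(support)
  res <- map_dp(
    ccd$taxa, root_key(ccd$taxa),
    function(id) {
      d <- ccd$splits[[id]]
      list(table = d, child_ids = Map(c, d$left, d$right))
    },
    function(id) id
  )
  est <- new_point_estimate(res$tree, paste0(ccd$flavor, "-map"), res$prob)
  est$support <- estimate_support(est$tree, ccd, support)
  est
}

#' @export
map_tree.ccd2_graph <- function(ccd, support = c("ccd", "montecarlo", "none")) {
  support <- match.arg(support)
  res <- map_dp(
    ccd$taxa, ccd2_root_vertex(ccd),
    function(id) {
      d <- ccd$splits[[id]]
      list(
        table = d,
        child_ids = Map(function(l, r) c(ccd2_vertex(l, r), ccd2_vertex(r, l)),
                        d$left, d$right)
      )
    },
    function(id) sub("@.*$", "", id)
  )
  est <- new_point_estimate(res$tree, "ccd2-map", res$prob)
  est$support <- estimate_support(est$tree, ccd, support)
  est
}

#' CCD0-MSCC tree
#'
#' The tree in a CCD0 maximizing the sum of clade credibilities `f(C)/k`
#' over its nontrivial clades, via the dynamic program `S*(leaf) = 0`,
#' `S*(C) = f(C)/k + max over splits of S*(C1) + S*(C2)` (the root clade,
#' being trivial, contributes nothing). Ties break toward canonical split
#' order; the result is always fully resolved.
#'
#' @param ccd0 A `ccd_graph` with `flavor = "ccd0"`.
#' @inheritParams map_tree
#' @return A `point_estimate` whose `score` is the clade credibility sum.
#' @export
mscc_tree <- function(ccd0, support = c("ccd", "montecarlo", "none")) {
  support <- match.arg(support)
  stopifnot(inherits(ccd0, "ccd_graph"))
  if (!identical(ccd0$flavor, "ccd0")) {
    stop("the MSCC tree is defined for CCD0 graphs")
  }
  rk <- root_key(ccd0$taxa)
  memo <- new.env(parent = emptyenv())
  choice <- new.env(parent = emptyenv())
  best <- function(clade) {
    if (is_leaf_key(clade)) return(0)
    got <- memo[[clade]]
    if (!is.null(got)) return(got)
    d <- ccd0$splits[[clade]]
    scores <- vapply(seq_len(nrow(d)), function(i) {
      best(d$left[i]) + best(d$right[i])
    }, numeric(1))
    pick <- which.max(scores)
    own <- if (clade == rk) 0 else unname(ccd0$cred[clade])
    assign(clade, c(d$left[pick], d$right[pick]), envir = choice)
    assign(clade, own + scores[pick], envir = memo)
    own + scores[pick]
  }
  total <- best(rk)
  tree <- map_backtrack(ccd0$taxa, choice, rk, function(id) id, NULL)
  est <- new_point_estimate(tree, "ccd0-mscc", total)
  est$support <- estimate_support(tree, ccd0, support)
  est
}

# clade support annotations for an estimated tree
estimate_support <- function(tree, ccd, source) {
  if (source == "none") return(NULL)
  nt <- topology_clades(tree, trivial = FALSE)
  if (source == "montecarlo") {
    if (is.null(ccd$cred)) stop("no sample frequencies available on this graph")
    vals <- ifelse(nt %in% names(ccd$cred), ccd$cred[nt], 0)
    return(stats::setNames(as.numeric(vals), nt))
  }
  if (inherits(ccd, "ccd_graph")) {
    p <- ccd_clade_probabilities(ccd)
    vals <- ifelse(nt %in% names(p), p[nt], 0)
    stats::setNames(as.numeric(vals), nt)
  } else {
    stats::setNames(vapply(nt, function(key) clade_probability(ccd, key),
                           numeric(1)), nt)
  }
}

#' Highest sampled-density topology (pass-through estimator)
#'
#' Picks the topology of the sample state with maximum per-sample posterior
#' density. Only available when densities accompany the sample; kept for
#' comparison purposes, not recommended.
#'
#' @param sample A `tree_sample`.
#' @param densities Numeric vector of per-tree (post burn-in, pre-merging
#'   order is not needed: one value per distinct topology) posterior
#'   densities, aligned with `sample$topologies`.
#' @return A `point_estimate` with the chosen sampled topology.
#' @export
max_density_tree <- function(sample, densities) {
  stopifnot(inherits(sample, "tree_sample"),
            length(densities) == length(sample$topologies))
  pick <- which.max(densities)
  new_point_estimate(sample$topologies[[pick]], "max-sampled-density",
                     densities[pick])
}
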