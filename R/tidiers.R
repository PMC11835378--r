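# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the split table of a CCD graph
#'
#' @param x A `ccd_graph`.
#' @param ... Unused.
#' @return A tibble with one row per clade split: `parent`, `left`,
#'   `right` (comma-joined member labels), conditional probability `prob`,
#'   and observed `count` (NA for expansion-only CCD0 splits).
#' @method tidy ccd_graph
#' @export
tidy.ccd_graph <- function(x, ...) {
  lab <- function(key) paste(clade_members(key, x$taxa), collapse = ",")
  rows <- lapply(names(x$splits), function(parent) {
    d <- x$splits[[parent]]
    tibble::tibble(
      parent = lab(parent),
      left = vapply(d$left, lab, character(1)),
      right = vapply(d$right, lab, character(1)),
      prob = d$prob,
      count = d$count
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.ccd_graph
#' @method tidy ccd2_graph
#' @export
tidy.ccd2_graph <- function(x, ...) {
  lab <- function(key) {
    if (key == "ROOT") "ROOT" else paste(clade_members(key, x$taxa), collapse = ",")
  }
  rows <- lapply(names(x$splits), function(vid) {
    parts <- strsplit(vid, "@", fixed = TRUE)[[1]]
    d <- x$splits[[vid]]
    tibble::tibble(
      clade = lab(parts[1]),
      context = lab(parts[2]),
      left = vapply(d$left, lab, character(1)),
      right = vapply(d$right, lab, character(1)),
      prob = d$prob,
      count = d$count
    )
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a CCD
#'
#' @param x A `ccd_graph` or `ccd2_graph`.
#' @param ... Unused.
#' @return A tibble with the flavor, taxon and sample counts, graph sizes,
#'   the number of displayed topologies (NA when beyond double precision),
#'   entropy `H` (nats) and number equivalent `Ne`.
#' @method glance ccd_graph
#' @export
glance.ccd_graph <- function(x, ...) {
  ent <- entropy(x)
  n_trees <- count_trees(x)
  tibble::tibble(
    flavor = x$flavor,
    n_taxa = length(x$taxa),
    k = x$k,
    n_clades = length(x$clades),
    n_splits = sum(vapply(x$splits, nrow, integer(1))),
    n_trees = if (is.character(n_trees)) NA_real_ else n_trees,
    n_trees_exact = as.character(n_trees),
    H = unname(ent["H"]),
    Ne = unname(ent["Ne"])
  )
}

#' @rdname glance.ccd_graph
#' @method glance ccd2_graph
#' @export
glance.ccd2_graph <- glance.ccd_graph

#' Tidy the clade support of a point estimate
#'
#' @param x A `point_estimate`.
#' @param ... Unused.
#' @return A tibble with one row per annotated clade: members and support.
#' @method tidy point_estimate
#' @export
tidy.point_estimate <- function(x, ...) {
  if (is.null(x$support)) {
    return(tibble::tibble(clade = character(0), support = numeric(0)))
  }
  tibble::tibble(
    clade = vapply(names(x$support), function(key) {
      paste(clade_members(key, x$tree$taxa), collapse = ",")
    }, character(1)),
    support = unname(x$support)
  )
}

#' @rdname tidy.point_estimate
#' @method glance point_estimate
#' @export
glance.point_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    score = x$score,
    resolved = x$tree$resolved,
    n_taxa = length(x$tree$taxa),
    newick = write_tree(x$tree)
  )
}

#' Plot a benchmark report
#'
#' Mean metric value against subsample size (log scale), one line per
#' distribution type, facetted by metric.
#'
#' @param object A `ccd_benchmark` tibble from [run_benchmark()].
#' @param metrics Metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ccd_benchmark
#' @export
autoplot.ccd_benchmark <- function(object, metrics = c("mae", "precision"), ...) {
  keep <- metrics
  df <- dplyr::filter(object, .data$metric %in% keep)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$size, .data$label, .data$metric),
    value = mean(.data$value), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$value,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "subsample size", y = "mean value",
                  colour = "distribution")
}

#' Plot a point-estimate topology
#'
#' Draws the summary tree with ape, labelling internal nodes with their
#' clade support when available.
#'
#' @param x A `point_estimate`.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.point_estimate <- function(x, ...) {
  phy <- as_phylo(x$tree)
  ape::plot.phylo(phy, ...)
  if (!is.null(x$support)) {
    labs <- tidy(x)
    ape::nodelabels(text = sprintf("%.2f", x$support[order(names(x$support))]),
                    node = match_support_nodes(phy, x), frame = "none",
                    adj = c(1.1, -0.4), cex = 0.7)
  }
  invisible(x)
}

# internal: ape node numbers for annotated clades (sorted by clade key)
match_support_nodes <- function(phy, est) {
  taxa <- est$tree$taxa
  keys <- sort(names(est$support))
  vapply(keys, function(key) {
    tips <- match(clade_members(key, taxa), phy$tip.label)
    ape::getMRCA(phy, tips)
  }, numeric(1))
}
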