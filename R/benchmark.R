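# Desk-scale simulation harness comparing the sample distribution and the
# three CCD parametrizations against an exactly known generating ("golden")
# distribution, across subsample sizes and replicates.

#' Benchmark configuration
#'
#' @param n_taxa Taxon counts, recycled across datasets.
#' @param n_datasets Number of simulated truth distributions.
#' @param sizes Subsample size grid (nested within a replicate).
#' @param replicates Replicate chains per dataset.
#' @param pool_size,concentration Passed to [random_ccd()] per dataset.
#' @param seed Seed driving all randomness of the run.
#' @param entropy_bins Number of equal-count entropy bins used when
#'   tallying wins.
#' @param cap Enumeration cap for golden supports.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_taxa = 8, n_datasets = 10, sizes = c(3, 10, 30),
                             replicates = 2, pool_size = 5, concentration = 1,
                             seed = 1, entropy_bins = 3, cap = 1e6) {
  cfg <- list(
    n_taxa = as.integer(n_taxa), n_datasets = as.integer(n_datasets),
    sizes = sort(as.integer(sizes)), replicates = as.integer(replicates),
    pool_size = as.integer(pool_size), concentration = as.numeric(concentration),
    seed = as.integer(seed), entropy_bins = as.integer(entropy_bins),
    cap = as.numeric(cap)
  )
  if (any(cfg$sizes < 1L) || cfg$n_datasets < 1L || cfg$replicates < 1L) {
    stop("invalid benchmark grid")
  }
  structure(cfg, class = "benchmark_config")
}

#' Read a benchmark configuration from a flat key-value file
#'
#' Lines of the form `key = value` (comma-separated lists allowed, `#`
#' comments ignored) with the keys of [benchmark_config()].
#'
#' @param path File path.
#' @return A `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- lapply(kv, function(p) as.numeric(strsplit(trimws(p[2]), ",")[[1]]))
  names(args) <- vapply(kv, function(p) trimws(p[1]), character(1))
  known <- names(formals(benchmark_config))
  bad <- setdiff(names(args), known)
  if (length(bad) > 0L) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(benchmark_config, args)
}

#' Run the distribution-accuracy benchmark
#'
#' For each simulated dataset a random ground-truth CCD is the golden
#' distribution. Per replicate and subsample size, a sample distribution
#' and CCD0/CCD1/CCD2 are built from draws out of the truth and scored
#' against it: MAE of tree probabilities, MRE within the 50% and 95%
#' credible sets and over clades, and the rank of the golden top tree.
#' Replicate pairs additionally get a precision row (mean absolute
#' probability difference between replicates). Deterministic given the
#' config seed.
#'
#' @param config A `benchmark_config` (or arguments for one, via `...`).
#' @param ... Used to build a config when `config` is missing.
#' @return A `ccd_benchmark` tibble with columns `dataset`, `n_taxa`,
#'   `entropy`, `entropy_bin`, `size`, `replicate`, `label`, `metric`,
#'   `value`.
#' @export
run_benchmark <- function(config = NULL, ...) {
  if (is.null(config)) config <- benchmark_config(...)
  stopifnot(inherits(config, "benchmark_config"))
  set.seed(config$seed)
  n_taxa <- rep_len(config$n_taxa, config$n_datasets)
  rows <- list()
  entropies <- numeric(config$n_datasets)
  for (ds in seq_len(config$n_datasets)) {
    truth <- random_ccd(n_taxa[ds], pool_size = config$pool_size,
                        concentration = config$concentration)
    entropies[ds] <- unname(entropy(truth)["H"])
    reps <- synth_posterior(truth, sizes = config$sizes,
                            replicates = config$replicates)
    dists <- rep(list(list()), config$replicates)
    for (r in seq_len(config$replicates)) {
      for (s in as.character(config$sizes)) {
        smp <- reps[[r]][[s]]
        tab <- tally(smp)
        dists[[r]] <- c(dists[[r]], stats::setNames(list(list(
          Sample = smp,
          CCD0 = build_ccd0(tab),
          CCD1 = build_ccd1(tab),
          CCD2 = build_ccd2(smp)
        )), s))
        for (label in c("Sample", "CCD0", "CCD1", "CCD2")) {
          d <- dists[[r]][[s]][[label]]
          vals <- c(
            mae = mae(d, truth, cap = config$cap),
            mre_50 = mre(d, truth, subset = 0.5, cap = config$cap),
            mre_95 = mre(d, truth, subset = 0.95, cap = config$cap),
            mre_clades = mre(d, truth, subset = "clades", cap = config$cap),
            top_rank = top_tree_rank(d, truth, cap = config$cap)
          )
          rows[[length(rows) + 1L]] <- tibble::tibble(
            dataset = ds, n_taxa = n_taxa[ds], entropy = entropies[ds],
            size = as.integer(s), replicate = r, label = label,
            metric = names(vals), value = unname(vals)
          )
        }
      }
    }
    if (config$replicates >= 2L) {
      for (s in as.character(config$sizes)) {
        for (label in c("Sample", "CCD0", "CCD1", "CCD2")) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            dataset = ds, n_taxa = n_taxa[ds], entropy = entropies[ds],
            size = as.integer(s), replicate = NA_integer_, label = label,
            metric = "precision",
            value = replicate_precision(dists[[1]][[s]][[label]],
                                        dists[[2]][[s]][[label]],
                                        cap = config$cap)
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  breaks <- unique(stats::quantile(entropies,
                                   probs = seq(0, 1, length.out = config$entropy_bins + 1L)))
  out$entropy_bin <- if (length(breaks) > 1L) {
    as.integer(cut(out$entropy, breaks = breaks, include.lowest = TRUE))
  } else {
    1L
  }
  out <- out[c("dataset", "n_taxa", "entropy", "entropy_bin", "size",
               "replicate", "label", "metric", "value")]
  class(out) <- c("ccd_benchmark", class(out))
  attr(out, "config") <- config
  out
}

#' Tally benchmark wins
#'
#' Counts, per entropy bin and subsample size, how often each distribution
#' type achieved the lowest value of a metric (averaged over replicates
#' within a dataset first). Ties award the win to every tied label.
#'
#' @param report A `ccd_benchmark` tibble from [run_benchmark()].
#' @param metric Metric name to rank on (default `"mae"`).
#' @return A tibble with `entropy_bin`, `size`, `label`, `wins`.
#' @export
benchmark_wins <- function(report, metric = "mae") {
  metric_name <- metric
  df <- dplyr::filter(report, .data$metric == metric_name)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$dataset, .data$entropy_bin, .data$size, .data$label),
    value = mean(.data$value), .groups = "drop"
  )
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$dataset, .data$size),
    win = .data$value <= min(.data$value) + 1e-15
  )
  df <- dplyr::ungroup(df)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$entropy_bin, .data$size, .data$label),
    wins = sum(.data$win), .groups = "drop"
  )
  dplyr::arrange(out, .data$entropy_bin, .data$size, dplyr::desc(.data$wins))
}

#' Write a benchmark report as tab-separated values
#'
#' @param report A `ccd_benchmark` tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_benchmark <- function(report, file) {
  utils::write.table(report, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @importFrom rlang %||% .data
NULL
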