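# CCD graph serialization: a JSON-lines format for caching and external
# inspection. Line 1 is a header object (format tag, flavor, taxa, k);
# every further line is one clade with its splits and conditional
# probabilities. Clades are hexadecimal bitmasks of the taxon indices
# (taxon i = bit i-1, least significant bit first).

key_to_hex <- function(key) {
  bits <- rev(strsplit(key, "", fixed = TRUE)[[1]] == "1")
  pad <- (4 - length(bits) %% 4) %% 4
  bits <- c(rep(FALSE, pad), bits)
  nib <- vapply(seq_len(length(bits) / 4), function(i) {
    sum(bits[(4 * i - 3):(4 * i)] * c(8, 4, 2, 1))
  }, numeric(1))
  paste0("0x", paste(sprintf("%x", nib), collapse = ""))
}

hex_to_key <- function(hex, n) {
  nib <- strtoi(strsplit(sub("^0x", "", hex), "", fixed = TRUE)[[1]], base = 16L)
  bits <- unlist(lapply(nib, function(v) as.logical(bitwAnd(v, c(8, 4, 2, 1)))))
  bits <- rev(bits)
  if (length(bits) < n) bits <- c(bits, rep(FALSE, n - length(bits)))
  if (length(bits) > n && any(bits[(n + 1):length(bits)])) {
    stop("bitmask wider than the taxon set: ", hex)
  }
  paste(ifelse(bits[seq_len(n)], "1", "0"), collapse = "")
}

#' Write a CCD graph to a JSON-lines file
#'
#' @param ccd A `ccd_graph`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @seealso [read_ccd()]
#' @export
write_ccd <- function(ccd, file) {
  stopifnot(inherits(ccd, "ccd_graph"))
  header <- list(
    format = "ccd-graph", version = 1L, flavor = ccd$flavor,
    n_taxa = length(ccd$taxa), taxa = ccd$taxa,
    k = if (is.na(ccd$k)) NULL else ccd$k
  )
  lines <- jsonlite::toJSON(header, auto_unbox = TRUE, null = "null", digits = NA)
  for (parent in names(ccd$splits)) {
    d <- ccd$splits[[parent]]
    rec <- list(
      clade = key_to_hex(parent),
      cred = if (!is.null(ccd$cred) && parent %in% names(ccd$cred)) {
        unname(ccd$cred[parent])
      } else {
        NULL
      },
      splits = lapply(seq_len(nrow(d)), function(i) {
        list(left = key_to_hex(d$left[i]), right = key_to_hex(d$right[i]),
             prob = d$prob[i],
             count = if (is.na(d$count[i])) NULL else d$count[i])
      })
    )
    lines <- c(lines, jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                       digits = NA))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a CCD graph from a JSON-lines file
#'
#' Validates all structural invariants on load: split probabilities in
#' `[0, 1]` summing to one per clade, split sides disjoint and uniting to
#' the parent, every clade reachable from the root.
#'
#' @param file Path written by [write_ccd()].
#' @return A `ccd_graph`.
#' @export
read_ccd <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 2L) stop("not a ccd-graph file: ", file)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$format, "ccd-graph")) {
    stop("not a ccd-graph file: ", file)
  }
  taxa <- validate_taxa(as.character(header$taxa))
  n <- length(taxa)
  splits <- list()
  cred <- stats::setNames(numeric(0), character(0))
  for (line in lines[-1]) {
    rec <- jsonlite::fromJSON(line, simplifyDataFrame = FALSE)
    parent <- hex_to_key(rec$clade, n)
    d <- do.call(rbind, lapply(rec$splits, function(s) {
      data.frame(left = hex_to_key(s$left, n), right = hex_to_key(s$right, n),
                 prob = as.numeric(s$prob),
                 count = if (is.null(s$count)) NA_real_ else as.numeric(s$count),
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_len(nrow(d))) {
      if (!keys_disjoint(d$left[i], d$right[i]) ||
          key_union(d$left[i], d$right[i]) != parent) {
        stop("invalid split under clade ", rec$clade)
      }
      if (d$left[i] > d$right[i]) {
        tmp <- d$left[i]; d$left[i] <- d$right[i]; d$right[i] <- tmp
      }
    }
    splits[[parent]] <- d[order(d$left, d$right), , drop = FALSE]
    if (!is.null(rec$cred)) cred[parent] <- as.numeric(rec$cred)
  }
  ccd <- new_ccd_graph(taxa, header$flavor %||% "custom", splits,
                       k = if (is.null(header$k)) NA_real_ else header$k,
                       cred = if (length(cred) > 0L) cred else NULL)
  validate_ccd(ccd)
}
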