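# Clades are subsets of an ordered taxon set, stored as bit-vector keys:
# character strings of 0/1 with position i corresponding to taxon i.
# String comparison on keys equals lexicographic comparison of bit vectors,
# which gives the canonical order used for split sides and tie-breaking.

#' Build a clade key from taxon members
#'
#' A clade over an ordered taxon set is encoded as a bit string ("01100"
#' means the clade contains the second and third taxon). All clade-level
#' bookkeeping in the package (tallies, graphs, distances) is keyed by these
#' strings, so two clades are equal iff their keys are equal.
#'
#' @param members Taxon names (character) or positions (integer) of the
#'   clade members.
#' @param taxa Ordered character vector of all taxon labels.
#' @return A single clade key string.
#' @examples
#' clade_key(c("A", "B"), taxa = c("A", "B", "C"))
#' @export
clade_key <- function(members, taxa) {
  n <- length(taxa)
  if (is.character(members)) {
    idx <- match(members, taxa)
    if (anyNA(idx)) {
      stop("unknown taxa in clade: ", paste(members[is.na(idx)], collapse = ", "))
    }
  } else {
    idx <- as.integer(members)
    if (any(idx < 1L | idx > n)) stop("clade member index out of range")
  }
  if (length(idx) == 0L) stop("a clade must be nonempty")
  bits <- rep.int("0", n)
  bits[idx] <- "1"
  paste(bits, collapse = "")
}

#' Recover clade members from a key
#'
#' @param key Clade key string (see [clade_key()]).
#' @param taxa Ordered taxon labels the key refers to.
#' @return Character vector of member taxon labels.
#' @export
clade_members <- function(key, taxa) {
  taxa[key_indices(key)]
}

# integer member positions of a key
key_indices <- function(key) {
  which(strsplit(key, "", fixed = TRUE)[[1]] == "1")
}

key_size <- function(key) {
  # number of 1-bits; vectorized over keys
  nchar(gsub("0", "", key, fixed = TRUE))
}

key_union <- function(a, b) {
  ab <- charToRaw(a)
  bb <- charToRaw(b)
  one <- charToRaw("1")[1]
  ab[bb == one] <- one
  rawToChar(ab)
}

keys_disjoint <- function(a, b) {
  one <- charToRaw("1")[1]
  !any(charToRaw(a) == one & charToRaw(b) == one)
}

key_subset <- function(a, b) {
  # is clade a contained in clade b?
  one <- charToRaw("1")[1]
  !any(charToRaw(a) == one & charToRaw(b) != one)
}

key_diff <- function(a, b) {
  # members of a not in b
  ab <- charToRaw(a)
  one <- charToRaw("1")[1]
  ab[charToRaw(b) == one] <- charToRaw("0")[1]
  rawToChar(ab)
}

# are two clades compatible (nested or disjoint)?
keys_compatible <- function(a, b) {
  one <- charToRaw("1")[1]
  av <- charToRaw(a) == one
  bv <- charToRaw(b) == one
  both <- any(av & bv)
  !both || !any(av & !bv) || !any(bv & !av)
}

root_key <- function(taxa) strrep("1", length(taxa))

singleton_keys <- function(taxa) {
  n <- length(taxa)
  vapply(seq_len(n), function(i) clade_key(i, taxa), character(1))
}

# canonical split id: the lexicographically smaller child key first
split_id <- function(left, right) {
  swap <- left > right
  l <- ifelse(swap, right, left)
  r <- ifelse(swap, left, right)
  paste(l, r, sep = "|")
}

split_sides <- function(id) strsplit(id, "|", fixed = TRUE)

validate_taxa <- function(taxa) {
  if (!is.character(taxa) || length(taxa) < 2L) {
    stop("a taxon set needs at least two character labels")
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon labels are not allowed")
  if (any(!nzchar(taxa))) stop("taxon labels must be non-empty")
  taxa
}
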