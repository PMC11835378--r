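# Minimal exact non-negative integer arithmetic for tree counts, which can
# exceed the range where doubles are exact. Numbers are numeric vectors of
# base-1e7 digits, little-endian; sums and products of digits stay far
# below 2^53 so double arithmetic on digits is exact.

BIG_BASE <- 1e7

big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x))
  if (x == 0) return(0)
  digits <- numeric(0)
  while (x > 0) {
    digits <- c(digits, x %% BIG_BASE)
    x <- x %/% BIG_BASE
  }
  digits
}

big_carry <- function(d) {
  i <- 1L
  while (i <= length(d)) {
    if (d[i] >= BIG_BASE) {
      carry <- d[i] %/% BIG_BASE
      d[i] <- d[i] %% BIG_BASE
      if (i == length(d)) d <- c(d, 0)
      d[i + 1L] <- d[i + 1L] + carry
    }
    i <- i + 1L
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  d
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_carry(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

big_mul <- function(a, b) {
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
    out <- big_carry(out)
  }
  big_carry(out)
}

big_to_string <- function(d) {
  top <- format(d[length(d)], scientific = FALSE)
  rest <- if (length(d) > 1L) {
    sprintf("%07d", rev(d[-length(d)]))
  } else {
    character(0)
  }
  paste0(top, paste(rest, collapse = ""))
}

big_value <- function(d) {
  # numeric when exactly representable, otherwise a digit string
  x <- sum(d * BIG_BASE^(seq_along(d) - 1L))
  if (x <= 2^53) x else big_to_string(d)
}
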