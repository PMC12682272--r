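# Minimal arbitrary-precision non-negative integers.
#
# Distinct-subsequence counts grow roughly exponentially with the number of
# spells, overflowing doubles near 2^1024, while the turbulence statistic
# needs log2 of the exact count. Only four operations are required by the
# counting recurrence (construct from a small integer, double, subtract,
# take log2), so the representation is deliberately small: a little-endian
# integer vector of base-1e6 limbs, class "kf_bigint". Values are always
# non-negative; subtraction asserts a >= b (the recurrence guarantees it).

BIG_BASE <- 1000000L

big_from_int <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  limbs <- integer(0)
  repeat {
    limbs <- c(limbs, as.integer(x %% BIG_BASE))
    x <- floor(x / BIG_BASE)
    if (x == 0) break
  }
  structure(limbs, class = "kf_bigint")
}

big_normalize <- function(limbs) {
  n <- length(limbs)
  while (n > 1L && limbs[n] == 0L) n <- n - 1L
  structure(limbs[seq_len(n)], class = "kf_bigint")
}

big_double <- function(a) {
  limbs <- unclass(a) * 2L
  carry <- 0L
  for (i in seq_along(limbs)) {
    v <- limbs[i] + carry
    carry <- v %/% BIG_BASE
    limbs[i] <- v %% BIG_BASE
  }
  if (carry > 0L) limbs <- c(limbs, carry)
  big_normalize(limbs)
}

big_add <- function(a, b) {
  la <- unclass(a); lb <- unclass(b)
  n <- max(length(la), length(lb))
  la <- c(la, integer(n - length(la)))
  lb <- c(lb, integer(n - length(lb)))
  limbs <- la + lb
  carry <- 0L
  for (i in seq_len(n)) {
    v <- limbs[i] + carry
    carry <- v %/% BIG_BASE
    limbs[i] <- v %% BIG_BASE
  }
  if (carry > 0L) limbs <- c(limbs, carry)
  big_normalize(limbs)
}

# a - b, requiring a >= b
big_sub <- function(a, b) {
  la <- unclass(a); lb <- unclass(b)
  if (big_cmp(a, b) < 0) stop("bigint subtraction would be negative")
  lb <- c(lb, integer(length(la) - length(lb)))
  limbs <- la - lb
  for (i in seq_along(limbs)) {
    if (limbs[i] < 0L) {
      limbs[i] <- limbs[i] + BIG_BASE
      limbs[i + 1L] <- limbs[i + 1L] - 1L
    }
  }
  big_normalize(limbs)
}

big_cmp <- function(a, b) {
  la <- big_normalize(unclass(a)); lb <- big_normalize(unclass(b))
  if (length(la) != length(lb)) return(sign(length(la) - length(lb)))
  for (i in rev(seq_along(la))) {
    if (la[i] != lb[i]) return(sign(la[i] - lb[i]))
  }
  0L
}

# Exact when the value fits in a double (< 2^53); used by tests on small
# cases and by show methods.
big_as_numeric <- function(a) {
  limbs <- as.numeric(unclass(a))
  sum(limbs * BIG_BASE^(seq_along(limbs) - 1))
}

# log2 of the exact integer: mantissa from the top limbs (more than enough
# for double precision), exponent from the limb count.
big_log2 <- function(a) {
  limbs <- unclass(big_normalize(unclass(a)))
  n <- length(limbs)
  if (n == 1L && limbs[1] == 0L) return(-Inf)
  k <- min(n, 4L)
  top <- limbs[seq.int(n, n - k + 1L)]
  mant <- sum(as.numeric(top) * BIG_BASE^(seq.int(k - 1L, 0L)))
  log2(mant) + (n - k) * log2(BIG_BASE)
}

#' @export
format.kf_bigint <- function(x, ...) {
  v <- big_as_numeric(x)
  if (v < 2^53) format(v, scientific = FALSE)
  else sprintf("~2^%.2f", big_log2(x))
}

#' @export
print.kf_bigint <- function(x, ...) {
  cat("<bigint> ", format(x), "\n", sep = "")
  invisible(x)
}
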