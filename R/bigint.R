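# Internal exact arbitrary-precision integer arithmetic.
#
# Nonnegative integers are stored as numeric vectors of limbs in base 2^24,
# little-endian ("bi" scalars), or as 3-dimensional arrays (nrow x ncol x K)
# holding one limb plane per power of the base ("bm" matrices).  All limbs are
# integral doubles; every operation keeps intermediate values below 2^53 so
# that double arithmetic is exact.  Only nonnegative values are supported:
# the joint-distribution recursion never subtracts below zero.

.BI_BASE <- 16777216  # 2^24
.BI_SMALL_MAX <- 2^26 # scalar multipliers/divisors guaranteed overflow-safe

## ---- scalar big integers -------------------------------------------------

bi_trim <- function(a) {
  n <- length(a)
  while (n > 1L && a[n] == 0) n <- n - 1L
  if (n == length(a)) a else a[seq_len(n)]
}

# carry-propagate a vector whose entries may be any nonneg integers < 2^53
bi_norm <- function(a) {
  repeat {
    carry <- a %/% .BI_BASE
    if (!any(carry > 0)) break
    a <- a - carry * .BI_BASE
    a <- c(a, 0)
    idx <- seq_along(carry) + 1L
    a[idx] <- a[idx] + carry
  }
  bi_trim(a)
}

bi_new <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x), x >= 0, x < 2^53, x == floor(x))
  bi_norm(x)
}

bi_is_zero <- function(a) all(a == 0)

bi_cmp <- function(a, b) {
  a <- bi_trim(a); b <- bi_trim(b)
  if (length(a) != length(b)) return(if (length(a) > length(b)) 1L else -1L)
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(if (a[i] > b[i]) 1L else -1L)
  }
  0L
}

bi_eq <- function(a, b) bi_cmp(a, b) == 0L

bi_add <- function(a, b) {
  if (length(a) < length(b)) { tmp <- a; a <- b; b <- tmp }
  a[seq_along(b)] <- a[seq_along(b)] + b
  bi_norm(a)
}

# a - b, requires a >= b
bi_sub <- function(a, b) {
  stopifnot(bi_cmp(a, b) >= 0L)
  a <- bi_trim(a); b <- bi_trim(b)
  r <- a
  r[seq_along(b)] <- r[seq_along(b)] - b
  # borrow propagation
  for (i in seq_along(r)) {
    if (r[i] < 0) {
      borrow <- ceiling(-r[i] / .BI_BASE)
      r[i] <- r[i] + borrow * .BI_BASE
      r[i + 1L] <- r[i + 1L] - borrow
    }
  }
  bi_trim(r)
}

bi_mul_small <- function(a, s) {
  stopifnot(length(s) == 1L, s >= 0, s == floor(s))
  if (s == 0) return(0)
  if (s == 1) return(bi_trim(a))
  if (s >= .BI_SMALL_MAX) return(bi_mul(a, bi_new(s)))
  bi_norm(a * s)
}

bi_mul <- function(a, b) {
  a <- bi_trim(a); b <- bi_trim(b)
  if (bi_is_zero(a) || bi_is_zero(b)) return(0)
  if (length(b) > length(a)) { tmp <- a; a <- b; b <- tmp }
  la <- length(a)
  acc <- numeric(la + length(b) + 1L)
  pending <- 0L
  for (j in seq_along(b)) {
    if (b[j] > 0) {
      idx <- j:(j + la - 1L)
      acc[idx] <- acc[idx] + a * b[j]
      pending <- pending + 1L
      if (pending == 16L) {  # keep partial sums below 16 * 2^48 < 2^53
        acc <- .bi_renorm_keep(acc)
        pending <- 0L
      }
    }
  }
  bi_norm(acc)
}

# normalize but keep (at least) the original length, for in-place accumulation
.bi_renorm_keep <- function(a) {
  n <- length(a)
  a <- bi_norm(a)
  if (length(a) < n) a <- c(a, numeric(n - length(a)))
  a
}

bi_pow <- function(base, exp) {
  stopifnot(exp >= 0, exp == floor(exp))
  b <- if (length(base) == 1L) bi_new(base) else bi_trim(base)
  r <- 1
  while (exp > 0) {
    if (exp %% 2 == 1) r <- bi_mul(r, b)
    exp <- exp %/% 2
    if (exp > 0) b <- bi_mul(b, b)
  }
  r
}

bi_prod <- function(v) {
  r <- 1
  for (x in v) r <- if (length(x) == 1L) bi_mul_small(r, x) else bi_mul(r, x)
  r
}

# quotient and small remainder for a small divisor d (1 <= d < 2^26)
bi_divmod_small <- function(a, d) {
  stopifnot(d >= 1, d < .BI_SMALL_MAX, d == floor(d))
  a <- bi_trim(a)
  q <- numeric(length(a))
  r <- 0
  for (i in rev(seq_along(a))) {
    cur <- r * .BI_BASE + a[i]
    q[i] <- cur %/% d
    r <- cur - q[i] * d
  }
  list(q = bi_trim(q), r = r)
}

# divide by a product of small factors; returns big quotient and big remainder
# so that a = q * prod(factors) + r with 0 <= r < prod(factors)
bi_divmod_factored <- function(a, factors) {
  q <- bi_trim(a)
  rem <- 0
  lead <- 1  # product of the factors consumed so far
  for (d in factors) {
    if (d == 1) next
    qr <- bi_divmod_small(q, d)
    rem <- bi_add(rem, bi_mul_small(lead, qr$r))
    lead <- bi_mul_small(lead, d)
    q <- qr$q
  }
  list(q = q, r = rem)
}

bi_to_double <- function(a) {
  a <- bi_trim(a)
  x <- 0
  for (i in rev(seq_along(a))) x <- x * .BI_BASE + a[i]
  x
}

bi_to_string <- function(a) {
  a <- bi_trim(a)
  if (bi_is_zero(a)) return("0")
  chunks <- character(0)
  while (!bi_is_zero(a)) {
    qr <- bi_divmod_small(a, 1e7)
    chunks <- c(chunks, formatC(qr$r, width = 7, flag = "0", format = "d"))
    a <- qr$q
  }
  out <- paste(rev(chunks), collapse = "")
  sub("^0+(?=.)", "", out, perl = TRUE)
}

bi_from_string <- function(s) {
  s <- gsub("[ ,]", "", s)
  stopifnot(grepl("^[0-9]+$", s))
  acc <- 0
  # consume 7 decimal digits at a time
  pos <- 1L
  nch <- nchar(s)
  lead <- nch %% 7L
  if (lead > 0L) {
    acc <- bi_new(as.numeric(substr(s, 1L, lead)))
    pos <- lead + 1L
  }
  while (pos <= nch) {
    acc <- bi_add(bi_mul_small(acc, 1e7), bi_new(as.numeric(substr(s, pos, pos + 6L))))
    pos <- pos + 7L
  }
  acc
}

## ---- matrices of big integers ---------------------------------------------

.limbs_for_bits <- function(bits) max(1L, as.integer(ceiling(bits / 24)) + 1L)

bm_zero <- function(nr, nc, K = 1L) array(0, c(nr, nc, K))

# carry-propagate every cell of a limb array (entries nonneg < 2^53)
bm_norm <- function(a) {
  d <- dim(a)
  repeat {
    carry <- a %/% .BI_BASE
    if (!any(carry > 0)) break
    a <- a - carry * .BI_BASE
    K <- d[3L]
    if (any(carry[, , K] > 0)) {
      a <- array(c(a, numeric(d[1L] * d[2L])), c(d[1L], d[2L], K + 1L))
      d <- dim(a)
      K <- K + 1L
    }
    a[, , 2:K] <- a[, , 2:K, drop = FALSE] + carry[, , 1:(K - 1L), drop = FALSE]
  }
  a
}

# drop all-zero leading (most significant) limb planes, keeping at least one
bm_trim <- function(a) {
  d <- dim(a)
  K <- d[3L]
  while (K > 1L && all(a[, , K] == 0)) K <- K - 1L
  if (K == d[3L]) a else a[, , seq_len(K), drop = FALSE]
}

# exact conversion of a numeric matrix of integers < 2^53 into a limb array
bm_from_matrix <- function(m) {
  stopifnot(all(m >= 0), all(m == floor(m)), all(m < 2^53))
  a <- array(0, c(nrow(m), ncol(m), 3L))
  t1 <- m %/% .BI_BASE
  a[, , 1L] <- m - t1 * .BI_BASE
  t2 <- t1 %/% .BI_BASE
  a[, , 2L] <- t1 - t2 * .BI_BASE
  a[, , 3L] <- t2
  bm_trim(a)
}

# per-cell conversion to doubles (exact below 2^53, correctly rounded above)
bm_to_double <- function(a) {
  d <- dim(a)
  W <- matrix(0, d[1L], d[2L])
  for (k in rev(seq_len(d[3L]))) W <- W * .BI_BASE + a[, , k]
  W
}

bm_cell <- function(a, i, j) bi_trim(a[i, j, ])

# multiply every cell (normalized limbs) by a scalar big integer
bm_mul_bi <- function(a, s) {
  s <- bi_trim(s)
  if (length(s) == 1L && s == 1) return(a)
  d <- dim(a)
  K <- d[3L]
  out <- array(0, c(d[1L], d[2L], K + length(s)))
  pending <- 0L
  for (j in seq_along(s)) {
    if (s[j] > 0) {
      idx <- j:(j + K - 1L)
      out[, , idx] <- out[, , idx, drop = FALSE] + a * s[j]
      pending <- pending + 1L
      if (pending == 16L) {
        out <- bm_norm(out)
        pending <- 0L
      }
    }
  }
  bm_trim(bm_norm(out))
}

# total mass: sum of all cells as a big integer
bm_total <- function(a) {
  d <- dim(a)
  bi_norm(colSums(matrix(a, d[1L] * d[2L], d[3L])))
}

# cumulative sums along the column (l) dimension, normalized
bm_cumsum_cols <- function(a) {
  d <- dim(a)
  out <- a
  if (d[2L] > 1L) {
    for (l in 2:d[2L]) {
      out[, l, ] <- out[, l - 1L, , drop = FALSE] + out[, l, , drop = FALSE]
    }
  }
  bm_norm(out)
}

# add a (trimmed, normalized) piece into a rectangular slice of acc
bm_add_slice <- function(acc, piece, rows, cols) {
  Kp <- dim(piece)[3L]
  stopifnot(Kp <= dim(acc)[3L])
  acc[rows, cols, 1:Kp] <- acc[rows, cols, 1:Kp, drop = FALSE] + piece
  acc
}

## ---- exact rational formatting ---------------------------------------------

# number of decimals after which num/prod(factors) terminates, NA if it never does
.dec_digits_needed <- function(factors) {
  a <- 0L; b <- 0L
  for (d in factors) {
    dd <- d
    while (dd %% 2 == 0) { dd <- dd / 2; a <- a + 1L }
    while (dd %% 5 == 0) { dd <- dd / 5; b <- b + 1L }
    if (dd != 1) return(NA_integer_)
  }
  max(a, b)
}

# exact decimal string of v / prod(factors), rounded half-away-from-zero to
# `digits` decimals; factors are the small integers whose product is the
# denominator, den the same denominator as a big integer
.rat_round_string <- function(v, factors, den, digits) {
  t <- if (digits > 0) bi_mul(v, bi_pow(10, digits)) else bi_trim(v)
  qr <- bi_divmod_factored(t, factors)
  q <- qr$q
  if (bi_cmp(bi_mul_small(qr$r, 2), den) >= 0L) q <- bi_add(q, 1)
  s <- bi_to_string(q)
  if (digits == 0) return(s)
  if (nchar(s) <= digits) s <- paste0(strrep("0", digits - nchar(s) + 1L), s)
  paste0(substr(s, 1L, nchar(s) - digits), ".",
         substr(s, nchar(s) - digits + 1L, nchar(s)))
}

# exact representation of v / prod(factors): a terminating decimal when the
# denominator is of the form 2^a * 5^b, otherwise a fraction "num/den"
.rat_exact_string <- function(v, factors, den, dmax = .dec_digits_needed(factors)) {
  if (is.na(dmax)) {
    return(paste0(bi_to_string(v), "/", bi_to_string(den)))
  }
  if (dmax == 0L) return(bi_to_string(v))
  s <- .rat_round_string(v, factors, den, dmax)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}
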