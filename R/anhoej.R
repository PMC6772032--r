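# Anhoej run-chart rules: shift rule (unusually long run) and crossings rule
# (unusually few crossings), with exact specificities and sensitivities
# computed from the joint distribution of (C, L).

# round half away from zero (nonnegative arguments)
.half_away <- function(x) floor(x + 0.5)

#' Shift-rule limit
#'
#' The largest non-signalling run length: round(log2(n) + 3) to the nearest
#' integer (half away from zero).  A chart signals on the shift rule when a
#' run is strictly longer.
#'
#' @param n number of useful observations (>= 1)
#' @return an integer
#' @examples
#' shiftLimit(16)  # 7
#' shiftLimit(45)  # 8
#' @export
shiftLimit <- function(n) {
  stopifnot(all(n >= 1), all(n == floor(n)))
  as.integer(.half_away(log2(n) + 3))
}

#' Crossings-rule limit
#'
#' The smallest non-signalling number of crossings: the lower 5th percentile
#' of the Binomial(n-1, 1/2) distribution, i.e. the smallest k with
#' P(Binom(n-1, 1/2) <= k) >= 0.05.  A chart signals on the crossings rule
#' when C is strictly below this limit.  The quantile is determined by exact
#' integer comparison of 20 * cumulative binomial coefficients against
#' 2^(n-1), so no floating-point CDF is involved.
#'
#' @param n number of useful observations (>= 2)
#' @return an integer
#' @examples
#' crossingsLimit(16)  # 4
#' crossingsLimit(2)   # 0
#' @export
crossingsLimit <- function(n) {
  stopifnot(all(n >= 2), all(n == floor(n)))
  vapply(as.integer(n), function(nn) {
    row <- .pascal_row(nn - 1L)
    total <- bi_pow(2, nn - 1L)
    cum <- 0
    for (k in 0:(nn - 1L)) {
      cum <- bi_add(cum, row[[k + 1L]])
      if (bi_cmp(bi_mul_small(cum, 20), total) >= 0L) return(k)
    }
    nn - 1L
  }, integer(1L))
}

#' Combined Anhoej rule limits
#'
#' @param n number of useful observations (>= 2)
#' @return a [RuleLimits-class] object
#' @export
ruleLimits <- function(n) {
  stopifnot(length(n) == 1L, n >= 2, n == floor(n))
  new("RuleLimits", n = as.integer(n),
      longestRunLimit = shiftLimit(n), crossingsLimit = crossingsLimit(n))
}

#' Apply the Anhoej rules to observed statistics
#'
#' @param c number of crossings (0..n-1); vectorized
#' @param l longest run length (1..n); vectorized
#' @param limits a [RuleLimits-class], e.g. from [ruleLimits()]
#' @return logical: `TRUE` when the chart signals (l exceeds the run limit or
#'   c falls below the crossings limit)
#' @examples
#' applyRules(10, 5, ruleLimits(16))  # FALSE: random-looking
#' applyRules(0, 16, ruleLimits(16))  # TRUE: one constant run
#' @export
applyRules <- function(c, l, limits) {
  stopifnot(is(limits, "RuleLimits"))
  n <- limits@n
  if (any(c < 0 | c > n - 1L)) stop("c must be in 0..n-1")
  if (any(l < 1 | l > n)) stop("l must be in 1..n")
  l > limits@longestRunLimit | c < limits@crossingsLimit
}

# exact specificity numerator (times scale, integer) and denominator 2^(n-1)
.spec_parts <- function(n) {
  lim <- ruleLimits(n)
  la <- min(lim@longestRunLimit, n)
  ca <- lim@crossingsLimit
  .sym_extend(n)
  Tn <- .cr_cache$symT[[n]]
  S <- bm_total(Tn[(ca + 1L):n, 1:la, , drop = FALSE])
  list(S = S, la = la, ca = ca)
}

#' Exact specificity of the Anhoej rules
#'
#' The probability that a random (p = 1/2) chart with n useful observations
#' does not signal on either rule, computed exactly as the mass of the
#' no-signal box {C >= crossingsLimit, L <= longestRunLimit} in the symmetric
#' joint distribution.
#'
#' @param n number of useful observations (>= 2)
#' @param digits if non-`NULL`, round the exact rational half-away-from-zero
#'   to this many decimals (3 reproduces the published table values)
#' @return a numeric probability
#' @examples
#' specificity(16, digits = 3)
#' @export
specificity <- function(n, digits = NULL) {
  stopifnot(length(n) == 1L, n >= 2, n == floor(n))
  parts <- .spec_parts(as.integer(n))
  den <- bi_pow(2, n - 1L)
  if (is.null(digits)) {
    bi_to_double(parts$S) / bi_to_double(den)
  } else {
    as.numeric(.rat_round_string(parts$S, rep(2, n - 1L), den, digits))
  }
}

#' Exact sensitivity of the Anhoej rules
#'
#' The probability that a chart with success probability p signals on at
#' least one rule: one minus the no-signal box mass of the unconditional
#' joint distribution at p.  At p = 1/2 this equals 1 - specificity(n).
#'
#' @param n number of useful observations (>= 2)
#' @param p success probability (anything [bernoulliSpec()] accepts)
#' @param digits if non-`NULL`, round the exact rational to this many decimals
#' @return a numeric probability
#' @export
sensitivity <- function(n, p, digits = NULL) {
  stopifnot(length(n) == 1L, n >= 2, n == floor(n))
  spec <- bernoulliSpec(p)
  lim <- ruleLimits(n)
  la <- min(lim@longestRunLimit, n)
  u <- combineUnconditional(jointConditional(n, spec))
  # exact complement: numerator of the signal mass is den - no-signal sum
  S <- bm_total(u@num[(lim@crossingsLimit + 1L):n, 1:la, , drop = FALSE])
  sig <- bi_sub(u@den, S)
  if (is.null(digits)) {
    bi_to_double(sig) / bi_to_double(u@den)
  } else {
    as.numeric(.rat_round_string(sig, u@denFactors, u@den, digits))
  }
}

#' Anhoej rule limits and exact specificities over a range of n
#'
#' Computes, for every n in `nMin..nMax`, the shift and crossings limits and
#' the exact specificity of the combined rules.  The symmetric joint
#' distributions are built once, iteratively, and shared across all n.
#'
#' @param nMin,nMax range of numbers of useful observations (nMin >= 2)
#' @param digits decimals for the exactly rounded specificity (`NULL` for
#'   full double precision)
#' @return a data.frame with columns n, longestRunLimit, crossingsLimit,
#'   specificity
#' @examples
#' anhoejSpecificities(10, 12)
#' @export
anhoejSpecificities <- function(nMin = 10L, nMax = 100L, digits = 3L) {
  stopifnot(nMin >= 2, nMax >= nMin)
  .sym_extend(as.integer(nMax))
  ns <- as.integer(nMin):as.integer(nMax)
  out <- data.frame(n = ns, longestRunLimit = NA_integer_,
                    crossingsLimit = NA_integer_, specificity = NA_real_)
  for (i in seq_along(ns)) {
    n <- ns[i]
    parts <- .spec_parts(n)
    out$longestRunLimit[i] <- parts$la
    out$crossingsLimit[i] <- parts$ca
    out$specificity[i] <- if (is.null(digits)) {
      bi_to_double(parts$S) / 2^(n - 1)
    } else {
      as.numeric(.rat_round_string(parts$S, rep(2, n - 1L), bi_pow(2, n - 1L),
                                   digits))
    }
  }
  out
}
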