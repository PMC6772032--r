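#' @import methods
NULL

## ---- BernoulliSpec ---------------------------------------------------------

#' Exact Bernoulli success probability
#'
#' Stores a success probability as an exact rational number pNum/pDen.  All
#' joint-distribution computations in this package are carried out in exact
#' integer arithmetic on these rationals, so the choice of representation
#' matters: a numeric input is interpreted through its (shortest) decimal
#' representation, e.g. `0.6` becomes 3/5 exactly.  Probabilities that have
#' no terminating decimal expansion (1/3, say) must be given as fraction
#' strings, e.g. `"1/3"`.
#'
#' @slot pNum numerator of p (integral double)
#' @slot pDen denominator of p (integral double); q = (pDen - pNum)/pDen
#' @export
setClass("BernoulliSpec", representation(pNum = "numeric", pDen = "numeric"),
         validity = function(object) {
           if (length(object@pNum) != 1L || length(object@pDen) != 1L)
             return("pNum and pDen must be scalars")
           if (object@pNum != floor(object@pNum) || object@pDen != floor(object@pDen))
             return("pNum and pDen must be integers")
           if (!(object@pNum > 0 && object@pNum < object@pDen))
             return("p must satisfy 0 < p < 1")
           TRUE
         })

.gcd <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

# parse one probability into c(num, den), reduced
.parse_prob <- function(x) {
  if (is(x, "BernoulliSpec")) return(c(x@pNum, x@pDen))
  if (is.numeric(x)) {
    stopifnot(length(x) == 1L, is.finite(x), x > 0, x < 1)
    x <- format(x, digits = 15, scientific = FALSE)
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("/", x, fixed = TRUE)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
    stopifnot(length(parts) == 2L)
    num <- as.numeric(parts[1L]); den <- as.numeric(parts[2L])
  } else {
    stopifnot(grepl("^[0-9]*\\.?[0-9]+$", x))
    parts <- strsplit(x, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) { num <- as.numeric(parts); den <- 1 }
    else {
      dec <- parts[2L]
      stopifnot(nchar(dec) <= 15)
      den <- 10^nchar(dec)
      num <- as.numeric(parts[1L]) * den + as.numeric(dec)
    }
  }
  stopifnot(is.finite(num), is.finite(den), num > 0, den > num, den < 2^53)
  g <- .gcd(num, den)
  c(num / g, den / g)
}

#' Construct an exact Bernoulli success probability
#'
#' @param p a probability in (0,1): numeric (read via its decimal
#'   representation), a decimal string such as `"0.6"`, or a fraction string
#'   such as `"3/5"`.
#' @return a [BernoulliSpec-class] object
#' @examples
#' bernoulliSpec(0.6)     # 3/5
#' bernoulliSpec("1/3")   # exact third
#' @export
bernoulliSpec <- function(p) {
  r <- .parse_prob(p)
  new("BernoulliSpec", pNum = r[1L], pDen = r[2L])
}

#' @describeIn bernoulliSpec numeric value of p
#' @param spec a BernoulliSpec
#' @export
probValue <- function(spec) spec@pNum / spec@pDen

setMethod("show", "BernoulliSpec", function(object) {
  cat(sprintf("BernoulliSpec: p = %s/%s (%.6g), q = %s/%s\n",
              format(object@pNum), format(object@pDen), probValue(object),
              format(object@pDen - object@pNum), format(object@pDen)))
})

## ---- ProbabilityVector -----------------------------------------------------

#' Per-observation success probabilities
#'
#' A sequence of exact rational success probabilities, one per observation
#' position, for independent but non-identically distributed Bernoulli
#' observations.
#'
#' @slot pNum numerators (integral doubles), one per position
#' @slot pDen denominators (integral doubles), one per position
#' @export
setClass("ProbabilityVector", representation(pNum = "numeric", pDen = "numeric"),
         validity = function(object) {
           if (length(object@pNum) != length(object@pDen))
             return("pNum and pDen must have equal length")
           if (length(object@pNum) < 1L) return("at least one probability required")
           if (any(object@pNum <= 0) || any(object@pNum >= object@pDen))
             return("all probabilities must be strictly in (0,1)")
           TRUE
         })

#' Construct a vector of exact per-position probabilities
#'
#' @param p numeric or character vector of probabilities in (0,1); each entry
#'   is parsed as in [bernoulliSpec()]
#' @return a [ProbabilityVector-class] object
#' @export
probabilityVector <- function(p) {
  stopifnot(length(p) >= 1L)
  r <- vapply(seq_along(p), function(i) .parse_prob(p[[i]]), numeric(2L))
  new("ProbabilityVector", pNum = r[1L, ], pDen = r[2L, ])
}

#' @describeIn probabilityVector numeric values of the probabilities
#' @param probs a ProbabilityVector
#' @export
probValues <- function(probs) probs@pNum / probs@pDen

setMethod("show", "ProbabilityVector", function(object) {
  cat(sprintf("ProbabilityVector of length %d: %s\n", length(object@pNum),
              paste(sprintf("%g/%g", object@pNum, object@pDen), collapse = ", ")))
})

setMethod("length", "ProbabilityVector", function(x) length(x@pNum))

## ---- JointPMF --------------------------------------------------------------

#' Exact joint distribution of crossings and longest run
#'
#' An n-by-n matrix of exact nonnegative rational weights indexed by the number
#' of crossings C (rows, c = 0..n-1) and the longest run length L (columns,
#' l = 1..n).  Weights are stored as arbitrary-precision integer numerators
#' (limb arrays) over a common denominator, so all values are exact.
#'
#' The `scale` slot controls presentation only: under `"probability"` the
#' weights are the joint probabilities (total mass 1); under `"times"` every
#' weight is multiplied by m^(n-1) (the "times" representation, in which the
#' symmetric p = 1/2, m = 2 case consists of exact integers summing to
#' 2^(n-1)).  [rescale()] switches between the two without any loss.
#'
#' @slot n sequence length
#' @slot scale `"probability"` or `"times"`
#' @slot m times-representation multiplier (default 2)
#' @slot conditioning `"success"`, `"failure"` (side of the first observation)
#'   or `"unconditional"`
#' @slot num n x n x K limb array of exact integer numerators
#' @slot den common denominator as a limb vector
#' @slot denFactors small integer factors whose product is `den` (used for
#'   exact division and decimal rounding)
#' @slot params free-form list recording the generating probabilities
#' @export
setClass("JointPMF", representation(
  n = "integer", scale = "character", m = "integer", conditioning = "character",
  num = "array", den = "numeric", denFactors = "numeric", params = "list"))

setValidity("JointPMF", function(object) {
  n <- object@n
  d <- dim(object@num)
  if (length(d) != 3L || d[1L] != n || d[2L] != n)
    return("num must be an n x n x K limb array")
  if (!object@scale %in% c("probability", "times"))
    return("scale must be 'probability' or 'times'")
  if (!object@conditioning %in% c("success", "failure", "unconditional"))
    return("conditioning must be 'success', 'failure' or 'unconditional'")
  if (object@m < 1L) return("m must be a positive integer")
  if (any(object@num < 0)) return("all weights must be nonnegative")
  if (!bi_eq(bi_prod(object@denFactors), object@den))
    return("denFactors do not multiply to den")
  # exact normalization: numerators must sum to the denominator
  if (!bi_eq(bm_total(object@num), object@den))
    return("weights do not sum to the total mass (1, resp. m^(n-1))")
  # support: weight(c,l) = 0 unless ceiling(n/(c+1)) <= l <= n-c
  nz <- matrix(rowSums(matrix(object@num != 0, n * n, d[3L])) > 0, n, n)
  cs <- matrix(0:(n - 1L), n, n)
  ls <- matrix(1:n, n, n, byrow = TRUE)
  bad <- nz & !(ls >= ceiling(n / (cs + 1)) & ls <= n - cs)
  if (any(bad)) return("nonzero weight outside the feasible (c,l) support band")
  TRUE
})

## ---- ConditionalPair --------------------------------------------------------

#' Pair of joint distributions conditional on the first observation
#'
#' The unit propagated by the iterative recursion: the joint distribution of
#' (C, L) conditional on the first observation being a success, and the same
#' conditional on a failure.
#'
#' @slot givenSuccess [JointPMF-class] with conditioning `"success"`
#' @slot givenFailure [JointPMF-class] with conditioning `"failure"`
#' @export
setClass("ConditionalPair",
         representation(givenSuccess = "JointPMF", givenFailure = "JointPMF"),
         validity = function(object) {
           s1 <- object@givenSuccess; s0 <- object@givenFailure
           if (s1@n != s0@n) return("members must share n")
           if (s1@scale != s0@scale || s1@m != s0@m)
             return("members must share scale")
           if (s1@conditioning != "success" || s0@conditioning != "failure")
             return("member conditioning labels are wrong")
           TRUE
         })

#' @describeIn ConditionalPair-class the member conditional on a success start
#' @param pair a ConditionalPair
#' @export
givenSuccess <- function(pair) pair@givenSuccess

#' @describeIn ConditionalPair-class the member conditional on a failure start
#' @export
givenFailure <- function(pair) pair@givenFailure

setMethod("show", "ConditionalPair", function(object) {
  cat(sprintf("ConditionalPair (n = %d, scale = %s)\n", object@givenSuccess@n,
              object@givenSuccess@scale))
  cat("$givenSuccess:\n"); show(object@givenSuccess)
  cat("$givenFailure:\n"); show(object@givenFailure)
})

## ---- RuleLimits --------------------------------------------------------------

#' Anhoej run-chart rule limits
#'
#' For n useful observations the shift rule signals when the longest run
#' exceeds `longestRunLimit` = round(log2(n) + 3), and the crossings rule
#' signals when the number of crossings falls below `crossingsLimit`, the
#' lower 5th percentile of Binomial(n-1, 1/2).
#'
#' @slot n number of useful observations
#' @slot longestRunLimit largest non-signalling run length
#' @slot crossingsLimit smallest non-signalling number of crossings
#' @export
setClass("RuleLimits", representation(
  n = "integer", longestRunLimit = "integer", crossingsLimit = "integer"))

setMethod("show", "RuleLimits", function(object) {
  cat(sprintf(
    "Anhoej rule limits for n = %d: signal if L > %d or C < %d\n",
    object@n, object@longestRunLimit, object@crossingsLimit))
})

## ---- SequenceStats -----------------------------------------------------------

#' Crossings and longest run of an observed binary sequence
#'
#' @slot n sequence length
#' @slot crossings number of adjacent unequal pairs
#' @slot longestRun length of the longest constant stretch
#' @export
setClass("SequenceStats", representation(
  n = "integer", crossings = "integer", longestRun = "integer"))

setMethod("show", "SequenceStats", function(object) {
  cat(sprintf("SequenceStats: n = %d, C = %d, L = %d\n",
              object@n, object@crossings, object@longestRun))
})
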