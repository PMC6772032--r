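# Accessors and operations on JointPMF objects.

# scale multiplier m^(n-1) as a big integer (1 on the probability scale)
.scale_mult <- function(pmf) {
  if (pmf@scale == "times") bi_pow(pmf@m, pmf@n - 1L) else 1
}

#' @describeIn symmetricJoint sequence length of a pmf
#' @param pmf a [JointPMF-class]
#' @export
seqLength <- function(pmf) pmf@n

#' Numeric matrix of joint weights
#'
#' Returns the weights of a [JointPMF-class] as a plain numeric matrix on the
#' object's presentation scale, rows c = 0..n-1 and columns l = 1..n.  The
#' conversion from the exact internal representation is correctly rounded to
#' double precision; use [jointWeightStrings()] for exact values.
#'
#' @param pmf a [JointPMF-class]
#' @return an n x n numeric matrix with dimnames `c=...` / `l=...`
#' @export
jointWeights <- function(pmf) {
  W <- bm_to_double(pmf@num) / bi_to_double(pmf@den)
  if (pmf@scale == "times") W <- W * bi_to_double(.scale_mult(pmf))
  dimnames(W) <- list(paste0("c=", 0:(pmf@n - 1L)), paste0("l=", 1:pmf@n))
  W
}

# exact value strings for a limb array over the pmf's denominator, on the
# pmf's scale; digits = NULL gives exact representations
.value_strings <- function(pmf, arr, digits = NULL) {
  mult <- .scale_mult(pmf)
  d <- dim(arr)
  dmax <- .dec_digits_needed(pmf@denFactors)
  out <- matrix("", d[1L], d[2L])
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      v <- bi_trim(arr[i, j, ])
      if (!(length(mult) == 1L && mult == 1)) v <- bi_mul(v, mult)
      out[i, j] <- if (is.null(digits)) {
        .rat_exact_string(v, pmf@denFactors, pmf@den, dmax)
      } else {
        .rat_round_string(v, pmf@denFactors, pmf@den, digits)
      }
    }
  }
  out
}

#' Exact joint weights as decimal strings
#'
#' Formats the weights exactly: with `digits = NULL`, values whose denominator
#' is of the form 2^a 5^b are written as terminating decimals and all others
#' as fractions `"num/den"`; with an integer `digits`, every value is rounded
#' half-away-from-zero to that many decimals (the rounding used when
#' comparing against published tables).
#'
#' @param pmf a [JointPMF-class]
#' @param digits number of decimals, or `NULL` for exact representation
#' @return an n x n character matrix with dimnames as in [jointWeights()]
#' @export
jointWeightStrings <- function(pmf, digits = NULL) {
  out <- .value_strings(pmf, pmf@num, digits)
  dimnames(out) <- list(paste0("c=", 0:(pmf@n - 1L)), paste0("l=", 1:pmf@n))
  out
}

#' Total mass of a joint distribution
#'
#' Exactly 1 on the probability scale and m^(n-1) on the times scale; the
#' exact identity is enforced by the class validity, so this accessor mainly
#' serves reporting.
#'
#' @param pmf a [JointPMF-class]
#' @return a numeric value
#' @export
totalMass <- function(pmf) {
  bi_to_double(bm_total(pmf@num)) / bi_to_double(pmf@den) *
    bi_to_double(.scale_mult(pmf))
}

#' Switch between probability and times scales
#'
#' The internal representation stores exact probability-scale rationals, so
#' rescaling only changes the presentation scale; a round trip is exactly the
#' identity.
#'
#' @param pmf a [JointPMF-class]
#' @param scale `"probability"` or `"times"`
#' @return a [JointPMF-class]
#' @export
rescale <- function(pmf, scale = c("probability", "times")) {
  scale <- match.arg(scale)
  if (scale == pmf@scale) return(pmf)
  initialize(pmf, scale = scale)
}

#' Marginal distribution of the number of crossings
#'
#' Row sums of the joint matrix over l.  For the symmetric times-scale
#' distribution the entries are exactly the binomial coefficients
#' choose(n-1, c).
#'
#' @param pmf a [JointPMF-class]
#' @param exact if `TRUE`, return exact value strings instead of doubles
#' @return named numeric (or character) vector indexed by c = 0..n-1
#' @export
marginalCrossings <- function(pmf, exact = FALSE) {
  n <- pmf@n
  if (!exact) {
    out <- rowSums(jointWeights(pmf))
  } else {
    rs <- apply(pmf@num, c(1L, 3L), sum)           # n x K, entries < 2^53
    arr <- bm_norm(array(rs, c(n, 1L, dim(pmf@num)[3L])))
    out <- as.vector(.value_strings(pmf, arr))
  }
  names(out) <- paste0("c=", 0:(n - 1L))
  out
}

#' Marginal distribution of the longest run
#'
#' Column sums of the joint matrix over c.
#'
#' @inheritParams marginalCrossings
#' @return named numeric (or character) vector indexed by l = 1..n
#' @export
marginalLongestRun <- function(pmf, exact = FALSE) {
  n <- pmf@n
  if (!exact) {
    out <- colSums(jointWeights(pmf))
  } else {
    cs <- apply(pmf@num, c(2L, 3L), sum)           # n x K, entries < 2^53
    arr <- bm_norm(array(cs, c(n, 1L, dim(pmf@num)[3L])))
    out <- as.vector(.value_strings(pmf, arr))
  }
  names(out) <- paste0("l=", 1:n)
  out
}

#' Mass of a box {C >= cMin, L <= lMax}
#'
#' Sums the joint weights over all cells with at least `cMin` crossings and
#' longest run at most `lMax` -- the shape needed for run-chart rule
#' specificities (the no-signal region of the Anhoej rules is exactly such a
#' box).  The sum is carried out exactly.
#'
#' @param pmf a [JointPMF-class]
#' @param cMin smallest number of crossings included (0..n-1)
#' @param lMax largest longest-run length included (1..n)
#' @param digits if non-`NULL`, round the exact value half-away-from-zero to
#'   this many decimals before returning
#' @return a numeric value on the pmf's scale
#' @export
boxMass <- function(pmf, cMin, lMax, digits = NULL) {
  n <- pmf@n
  if (cMin < 0 || cMin > n - 1L) stop("cMin must be in 0..n-1")
  if (lMax < 1 || lMax > n) stop("lMax must be in 1..n")
  sub <- pmf@num[(cMin + 1L):n, 1:lMax, , drop = FALSE]
  S <- bm_total(sub)
  mult <- .scale_mult(pmf)
  if (is.null(digits)) {
    bi_to_double(S) / bi_to_double(pmf@den) * bi_to_double(mult)
  } else {
    if (!(length(mult) == 1L && mult == 1)) S <- bi_mul(S, mult)
    as.numeric(.rat_round_string(S, pmf@denFactors, pmf@den, digits))
  }
}

#' Expected product of crossings and longest run
#'
#' E(C * L) under the joint distribution (independent of the presentation
#' scale).  Used as a demanding scalar summary for cross-checking the exact
#' computation against simulation.
#'
#' @param pmf a [JointPMF-class]
#' @return a numeric value
#' @export
expectedCL <- function(pmf) {
  W <- bm_to_double(pmf@num) / bi_to_double(pmf@den)
  n <- pmf@n
  as.numeric((0:(n - 1L)) %*% W %*% (1:n))
}

#' Exact equality of two joint distributions
#'
#' Compares the underlying probability-scale weights cell for cell as exact
#' rationals (cross-multiplying the two denominators), independently of the
#' presentation scale.
#'
#' @param a,b [JointPMF-class] objects
#' @return `TRUE` or `FALSE`
#' @export
jointEqual <- function(a, b) {
  if (a@n != b@n) return(FALSE)
  if (bi_eq(a@den, b@den)) {
    return(identical(bm_trim(bm_norm(a@num)), bm_trim(bm_norm(b@num))))
  }
  x <- bm_mul_bi(a@num, b@den)
  y <- bm_mul_bi(b@num, a@den)
  identical(bm_trim(x), bm_trim(y))
}

#' Exact binomial coefficients
#'
#' choose(n, 0..n) computed exactly by Pascal's triangle in arbitrary
#' precision, returned as decimal strings.  Serves as the independent
#' reference for the crossings marginal of the symmetric joint distribution.
#'
#' @param n a nonnegative integer
#' @return character vector of length n + 1
#' @examples
#' exactChoose(4)  # "1" "4" "6" "4" "1"
#' @export
exactChoose <- function(n) {
  stopifnot(length(n) == 1L, n >= 0, n == floor(n))
  row <- .pascal_row(as.integer(n))
  vapply(row, bi_to_string, character(1L))
}

# cached Pascal rows as lists of big integers
.pascal_row <- function(n) {
  rows <- .cr_cache$pascal
  if (is.null(rows)) rows <- list(list(1))
  from <- length(rows)
  if (from < n + 1L) {
    for (k in from:n) {
      prev <- rows[[k]]
      cur <- vector("list", k + 1L)
      cur[[1L]] <- 1; cur[[k + 1L]] <- 1
      if (k > 1L) {
        for (j in 2:k) cur[[j]] <- bi_add(prev[[j - 1L]], prev[[j]])
      }
      rows[[k + 1L]] <- cur
    }
    .cr_cache$pascal <- rows
  }
  rows[[n + 1L]]
}

setMethod("show", "JointPMF", function(object) {
  cat(sprintf(
    "JointPMF: n = %d, scale = %s%s, conditioning = %s, total mass = %g\n",
    object@n, object@scale,
    if (object@scale == "times") sprintf(" (m = %d)", object@m) else "",
    object@conditioning, totalMass(object)))
  W <- jointWeights(object)
  top <- order(W, decreasing = TRUE)[seq_len(min(3L, sum(W > 0)))]
  ij <- arrayInd(top, dim(W))
  cat("highest cells:",
      paste(sprintf("(c=%d, l=%d): %.4g", ij[, 1L] - 1L, ij[, 2L], W[top]),
            collapse = ", "), "\n")
})
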