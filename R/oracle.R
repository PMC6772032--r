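# Ground truth by brute force: statistics of a concrete 0/1 sequence, and
# exact enumeration of all 2^n binary sequences.  These are deliberately
# independent of the iterative recursion and serve as its oracle in tests.

#' Crossings and longest run of a binary sequence
#'
#' Counts the crossings (adjacent unequal pairs) and the longest run (longest
#' constant stretch) of an observed 0/1 sequence.
#'
#' @param x a vector of 0/1 values (numeric, integer or logical), length >= 1
#' @return a [SequenceStats-class] object
#' @examples
#' sequenceStats(c(1, 1, 0, 0, 0, 1))  # C = 2, L = 3
#' @export
sequenceStats <- function(x) {
  if (is.logical(x)) x <- as.integer(x)
  if (length(x) < 1L) stop("x must have length >= 1")
  if (!is.numeric(x) || any(is.na(x)) || !all(x %in% c(0, 1)))
    stop("x must contain only 0/1 values")
  new("SequenceStats", n = length(x),
      crossings = as.integer(sum(x[-1L] != x[-length(x)])),
      longestRun = as.integer(max(rle(x)$lengths)))
}

# normalize a probability argument into exact numerator/denominator vectors
.probs_vectors <- function(probs, n) {
  if (is(probs, "BernoulliSpec")) {
    list(pa = rep(probs@pNum, n), pb = rep(probs@pDen, n))
  } else if (is(probs, "ProbabilityVector")) {
    stopifnot(length(probs) == n)
    list(pa = probs@pNum, pb = probs@pDen)
  } else if (length(probs) == 1L) {
    s <- bernoulliSpec(probs)
    list(pa = rep(s@pNum, n), pb = rep(s@pDen, n))
  } else {
    v <- probabilityVector(probs)
    stopifnot(length(v) == n)
    list(pa = v@pNum, pb = v@pDen)
  }
}

#' Exact joint distribution by exhaustive enumeration
#'
#' Iterates over every binary sequence of length n (fixing the first value
#' when conditioning on the start side), accumulating the exact
#' product-of-probabilities weight of each (C, L) cell.  This is the
#' brute-force oracle against which the iterative recursion is validated; its
#' cost is O(2^n), so n is capped.
#'
#' @param n sequence length (n <= cap)
#' @param probs success probability or per-position probabilities (anything
#'   [bernoulliSpec()] or [probabilityVector()] accepts)
#' @param conditioning `"unconditional"`, `"success"` or `"failure"`
#' @param cap safety cap on n (default 16, i.e. 65536 sequences)
#' @return a [JointPMF-class] on the probability scale
#' @export
enumerateJoint <- function(n, probs,
                           conditioning = c("unconditional", "success", "failure"),
                           cap = 16L) {
  conditioning <- match.arg(conditioning)
  stopifnot(length(n) == 1L, n >= 1, n == floor(n))
  if (n > cap) {
    stop("n = ", n, " exceeds the enumeration cap (", cap,
         "): 2^n sequences would be enumerated; use the recursion ",
         "(jointConditional) for longer sequences or raise `cap` explicitly")
  }
  n <- as.integer(n)
  pv <- .probs_vectors(probs, n)
  pa <- pv$pa; pb <- pv$pb; qa <- pb - pa
  first <- switch(conditioning, success = 1L, failure = 0L, unconditional = NA)
  free <- if (is.na(first)) n else n - 1L
  denF <- if (is.na(first)) pb else if (n > 1L) pb[2:n] else numeric(0)
  if (prod(denF) >= 2^53) {
    stop("probability denominators too large for exact enumeration at this n; ",
         "use probabilities with smaller denominators or a smaller n")
  }
  seqs <- if (free == 0L) {
    matrix(first, 1L, 1L)
  } else {
    g <- as.matrix(expand.grid(rep(list(0:1), free), KEEP.OUT.ATTRS = FALSE))
    if (is.na(first)) g else cbind(first, g)
  }
  nseq <- nrow(seqs)
  w <- rep(1, nseq)
  from <- if (is.na(first)) 1L else 2L
  if (n >= from) {
    for (i in from:n) w <- w * ifelse(seqs[, i] == 1L, pa[i], qa[i])
  }
  C <- if (n > 1L) rowSums(seqs[, -1L, drop = FALSE] != seqs[, -n, drop = FALSE])
       else rep(0L, nseq)
  L <- apply(seqs, 1L, function(r) max(rle(r)$lengths))
  acc <- matrix(0, n, n)
  agg <- rowsum(w, group = C * n + L)
  idx <- as.integer(rownames(agg))
  # decode group id g = C*n + L back to (row = C + 1, col = L)
  Cg <- (idx - 1L) %/% n
  Lg <- idx - Cg * n
  acc[cbind(Cg + 1L, Lg)] <- agg[, 1L]
  .new_joint(n, bm_from_matrix(acc), denF, "probability", 2L, conditioning,
             list(pNum = pa, pDen = pb))
}
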