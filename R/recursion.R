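# The iterative recursion for the joint distribution of the number of
# crossings C and the longest run L, conditional on the side S of the first
# observation.  The sequence is partitioned by the end position F of the first
# crossing: given S and F = f (f >= 2) the initial run has length f - 1 and
# the remaining n + 1 - f observations form the same kind of chart, one step
# shorter and starting on the opposite side.  Two cases arise:
#
#   Case 1 (f - 1 >= n + 1 - f): the initial run is longest, so all mass of
#     the shorter chart collapses onto the column l = f - 1 (its crossings
#     marginal), with c shifted by +1 for the first crossing.
#   Case 2 (f - 1 < n + 1 - f): mass of the shorter chart with longest run
#     <= f - 1 lands at l = f - 1; mass with longest run l in f..(n + 1 - f)
#     stays at l; c again shifts by +1.
#
# All arithmetic is exact: weights are integer numerators over the common
# denominator prod(per-trial probability denominators).

# package-level cache (symmetric tables, Pascal rows)
.cr_cache <- new.env(parent = emptyenv())

# finish one conditional member: normalized numerators + cumulative-l sums
.member_finish <- function(num) {
  num <- bm_norm(num)
  list(num = num, cum = bm_cumsum_cols(num))
}

# Build conditional pairs for every suffix of the probability sequence
# paV/pbV (exact rationals pa_i/pb_i, i = 1..n).  pairs[[k]] holds the pair
# for the suffix starting at position k (length n - k + 1), with numerators
# over prod_{i > k} pb_i.  For constant probabilities this is exactly the
# iterative build over lengths 1..n.
.build_pair_tables <- function(paV, pbV) {
  n <- length(paV)
  qaV <- pbV - paV
  lb <- log2(pbV)
  bitsAfter <- rev(cumsum(rev(lb))) - lb  # sum_{i > k} log2(pb_i)
  pairs <- vector("list", n)
  for (k in n:1) {
    len <- n - k + 1L
    K <- .limbs_for_bits(bitsAfter[k])
    if (len == 1L) {
      num <- array(0, c(1L, 1L, K)); num[1L, 1L, 1L] <- 1
      m1 <- .member_finish(num)
      pairs[[k]] <- list(s1 = m1, s0 = m1)
      next
    }
    out <- vector("list", 2L)
    names(out) <- c("s1", "s0")
    for (side in c("s1", "s0")) {
      w <- if (side == "s1") paV else qaV  # stay-on-side numerators
      o <- pbV - w                          # cross-to-other-side numerators
      acc <- array(0, c(len, len, K))
      # F = 1 (no crossing): one run of length len
      nc <- bi_prod(w[(k + 1L):n])
      acc[1L, len, seq_along(nc)] <- nc
      run <- 1  # prod_{i = k+1}^{t-1} w_i, exact
      for (t in (k + 1L):n) {
        f <- t - k + 1L        # first-crossing index within the suffix
        n1 <- n - t + 1L       # length of the remainder, starting at t
        Mt <- bi_mul(run, bi_new(o[t]))
        sh <- pairs[[t]][[if (side == "s1") "s0" else "s1"]]
        if (f - 1L >= n1) {
          marg <- array(sh$cum[, n1, ], c(n1, 1L, dim(sh$cum)[3L]))
          acc <- bm_add_slice(acc, bm_mul_bi(marg, Mt), 2:(n1 + 1L), f - 1L)
        } else {
          head <- sh$cum[, f - 1L, , drop = FALSE]
          acc <- bm_add_slice(acc, bm_mul_bi(head, Mt), 2:(n1 + 1L), f - 1L)
          tail <- sh$num[, f:n1, , drop = FALSE]
          acc <- bm_add_slice(acc, bm_mul_bi(tail, Mt), 2:(n1 + 1L), f:n1)
        }
        run <- bi_mul(run, bi_new(w[t]))
      }
      out[[side]] <- .member_finish(acc)
    }
    pairs[[k]] <- out
  }
  pairs
}

# Extend the cached symmetric (p = 1/2, m = 2) times-representation tables up
# to nmax.  In that case every first-crossing weight equals 1 on the times
# scale, both conditional members coincide, and the recursion consists of
# integer additions only; entry (c+1, l) of T[[n]] is 2^(n-1) * P_n(C=c, L=l).
.sym_extend <- function(nmax) {
  T <- .cr_cache$symT
  cums <- .cr_cache$symCum
  if (is.null(T)) { T <- list(); cums <- list() }
  from <- length(T) + 1L
  if (from > nmax) return(invisible(T))
  for (nn in from:nmax) {
    K <- .limbs_for_bits(nn - 1)
    acc <- array(0, c(nn, nn, K))
    if (nn == 1L) {
      acc[1L, 1L, 1L] <- 1
    } else {
      acc[1L, nn, 1L] <- 1  # no crossing
      # slice additions are written out in place (no helper call) so that the
      # accumulator keeps a single reference and R does not copy it each step
      for (f in 2:nn) {
        n1 <- nn + 1L - f
        cum <- cums[[n1]]
        rows <- 2:(n1 + 1L)
        Kc <- dim(cum)[3L]
        if (f - 1L >= n1) {
          acc[rows, f - 1L, 1:Kc] <- acc[rows, f - 1L, 1:Kc] + cum[, n1, ]
        } else {
          acc[rows, f - 1L, 1:Kc] <- acc[rows, f - 1L, 1:Kc] + cum[, f - 1L, ]
          Kt <- dim(T[[n1]])[3L]
          acc[rows, f:n1, 1:Kt] <- acc[rows, f:n1, 1:Kt, drop = FALSE] +
            T[[n1]][, f:n1, , drop = FALSE]
        }
      }
      acc <- bm_norm(acc)
    }
    T[[nn]] <- acc
    cums[[nn]] <- bm_cumsum_cols(acc)
  }
  .cr_cache$symT <- T
  .cr_cache$symCum <- cums
  invisible(T)
}

.new_joint <- function(n, num, denFactors, scale, m, conditioning, params = list()) {
  new("JointPMF", n = as.integer(n), scale = scale, m = as.integer(m),
      conditioning = conditioning, num = bm_trim(num),
      den = bi_prod(denFactors), denFactors = as.numeric(denFactors),
      params = params)
}

#' Conditional joint distributions at n = 1
#'
#' The starting point of the iterative recursion: with a single observation
#' the joint distribution of (C, L) is degenerate at (0, 1) on either side,
#' so both conditional members carry weight 1 there (also on the times scale,
#' since m^0 = 1).
#'
#' @param scale `"probability"` or `"times"`
#' @param m times-representation multiplier
#' @return a [ConditionalPair-class] for n = 1
#' @export
baseCase <- function(scale = c("probability", "times"), m = 2L) {
  scale <- match.arg(scale)
  num <- array(0, c(1L, 1L, 1L)); num[1L, 1L, 1L] <- 1
  mk <- function(cond) .new_joint(1L, num, numeric(0), scale, m, cond)
  new("ConditionalPair", givenSuccess = mk("success"), givenFailure = mk("failure"))
}

#' Distribution of the first crossing position
#'
#' Probability that the first crossing ends at position f, conditional on the
#' side of the first observation.  By convention f = 1 means no crossing at
#' all, with probability p^(n-1) given a success start; for f in 2..n the
#' start is followed by f-2 further same-side observations and one crossing,
#' giving p^(f-2) q.  Conditional on a failure start, p and q swap roles.
#'
#' @param n sequence length (>= 1)
#' @param f first-crossing end position, in 1..n
#' @param spec success probability ([bernoulliSpec()] or anything it accepts)
#' @param side side of the first observation, `"success"` or `"failure"`
#' @return the probability as a numeric value
#' @examples
#' firstCrossingWeight(3, 1, 0.6)  # 0.36
#' firstCrossingWeight(3, 2, 0.6)  # 0.4
#' @export
firstCrossingWeight <- function(n, f, spec, side = c("success", "failure")) {
  side <- match.arg(side)
  stopifnot(n >= 1, n == floor(n))
  if (length(f) != 1L || f != floor(f) || f < 1 || f > n)
    stop("f must be an integer in 1..n")
  spec <- bernoulliSpec(spec)
  p <- probValue(spec)
  if (side == "failure") p <- 1 - p
  q <- 1 - p
  if (f == 1) p^(n - 1) else p^(f - 2) * q
}

#' Conditional joint distributions of crossings and longest run
#'
#' Computes, by the exact iterative recursion, the joint distribution of the
#' number of crossings C and the longest run L in n independent Bernoulli(p)
#' observations, conditional on the first observation being a success and a
#' failure.  All arithmetic is exact rational.
#'
#' @param n sequence length (>= 1)
#' @param spec success probability ([bernoulliSpec()] or anything it accepts)
#' @param scale `"probability"` or `"times"` (presentation scale, see
#'   [JointPMF-class])
#' @param m times-representation multiplier (default 2)
#' @return a [ConditionalPair-class]
#' @examples
#' pair <- jointConditional(2, 0.6)
#' jointWeights(givenSuccess(pair))  # mass p at (0,2), q at (1,1)
#' @export
jointConditional <- function(n, spec, scale = c("probability", "times"), m = 2L) {
  scale <- match.arg(scale)
  stopifnot(length(n) == 1L, n >= 1, n == floor(n))
  spec <- bernoulliSpec(spec)
  if (n > 200) warning("n > 200: exact computation may be slow and memory-hungry")
  pairs <- .build_pair_tables(rep(spec@pNum, n), rep(spec@pDen, n))
  denF <- rep(spec@pDen, n - 1L)
  params <- list(pNum = spec@pNum, pDen = spec@pDen)
  new("ConditionalPair",
      givenSuccess = .new_joint(n, pairs[[1L]]$s1$num, denF, scale, m,
                                "success", params),
      givenFailure = .new_joint(n, pairs[[1L]]$s0$num, denF, scale, m,
                                "failure", params))
}

#' Conditional joint distributions with per-observation probabilities
#'
#' Generalizes [jointConditional()] to independent observations whose success
#' probability varies by position.  The recursion runs over suffixes of the
#' probability sequence: conditional on the side of the first observation of
#' the current suffix, a first crossing ending at absolute position t carries
#' weight (prod of stay-side probabilities over the positions in between)
#' times the cross-over probability at t, and the remainder is the suffix
#' starting at t with the opposite start side.  With constant probabilities
#' the result reduces exactly to [jointConditional()].
#'
#' @param probs a [probabilityVector()] or numeric/character vector accepted
#'   by it
#' @inheritParams jointConditional
#' @return a [ConditionalPair-class]
#' @export
jointConditionalVarying <- function(probs, scale = c("probability", "times"),
                                    m = 2L) {
  scale <- match.arg(scale)
  if (!is(probs, "ProbabilityVector")) probs <- probabilityVector(probs)
  n <- length(probs)
  pairs <- .build_pair_tables(probs@pNum, probs@pDen)
  denF <- if (n > 1L) probs@pDen[2:n] else numeric(0)
  params <- list(pNum = probs@pNum, pDen = probs@pDen)
  new("ConditionalPair",
      givenSuccess = .new_joint(n, pairs[[1L]]$s1$num, denF, scale, m,
                                "success", params),
      givenFailure = .new_joint(n, pairs[[1L]]$s0$num, denF, scale, m,
                                "failure", params))
}

#' Unconditional joint distribution
#'
#' Mixes the two conditional members with the probability of the first
#' observation: P(L, C) = P(L, C | S=1) p + P(L, C | S=0) q.  On the times
#' scale the result is m^(n-1) times the unconditional probabilities.
#'
#' @param pair a [ConditionalPair-class]
#' @param spec probability of a success at the first position; defaults to
#'   the probability stored when the pair was built
#' @return a [JointPMF-class] with conditioning `"unconditional"`
#' @export
combineUnconditional <- function(pair, spec = NULL) {
  s1 <- pair@givenSuccess; s0 <- pair@givenFailure
  if (is.null(spec)) {
    pr <- s1@params
    if (is.null(pr$pNum)) stop("pair carries no probabilities; supply `spec`")
    pa <- pr$pNum[1L]; pb <- pr$pDen[1L]
  } else {
    spec <- bernoulliSpec(spec)
    pa <- spec@pNum; pb <- spec@pDen
  }
  qa <- pb - pa
  if (pa == qa && identical(s1@num, s0@num)) {
    # symmetric: the mixture equals either member; keep the denominator
    return(.new_joint(s1@n, s1@num, s1@denFactors, s1@scale, s1@m,
                      "unconditional", s1@params))
  }
  a <- bm_mul_bi(s1@num, bi_new(pa))
  b <- bm_mul_bi(s0@num, bi_new(qa))
  Ka <- dim(a)[3L]; Kb <- dim(b)[3L]; K <- max(Ka, Kb) + 1L
  acc <- array(0, c(s1@n, s1@n, K))
  acc <- bm_add_slice(acc, a, seq_len(s1@n), seq_len(s1@n))
  acc <- bm_add_slice(acc, b, seq_len(s1@n), seq_len(s1@n))
  .new_joint(s1@n, bm_norm(acc), c(s1@denFactors, pb), s1@scale, s1@m,
             "unconditional", s1@params)
}

#' Symmetric joint distribution in the times representation
#'
#' The p = 1/2, m = 2 joint distribution of (C, L), computed without
#' conditioning on the start side: in the symmetric case both conditional
#' members coincide and every first-crossing weight equals 1 on the times
#' scale, so the recursion reduces to integer additions.  All weights are
#' exact integers summing to 2^(n-1); dividing by 2^(n-1) gives the joint
#' probabilities.  Results for lengths up to n are cached and reused.
#'
#' @param n sequence length (>= 1)
#' @return a [JointPMF-class], times scale, unconditional
#' @examples
#' jointWeights(symmetricJoint(4))
#' @export
symmetricJoint <- function(n) {
  stopifnot(length(n) == 1L, n >= 1, n == floor(n))
  n <- as.integer(n)
  .sym_extend(n)
  .new_joint(n, .cr_cache$symT[[n]], rep(2, n - 1L), "times", 2L,
             "unconditional", list(pNum = 1, pDen = 2))
}
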