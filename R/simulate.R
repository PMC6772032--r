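# Monte-Carlo simulation of run charts, for stochastic cross-checks of the
# exact joint distribution (notably the mean of C*L at large n).

#' Simulate the joint distribution of crossings and longest run
#'
#' Generates `reps` independent Bernoulli(p) sequences of length n and
#' tabulates the empirical joint frequencies of (C, L) together with the
#' sample mean and standard error of C * L.  A seed is mandatory so that
#' every simulation is reproducible; it is recorded in the result.
#'
#' @param n sequence length (>= 1)
#' @param p success probability (numeric or anything [bernoulliSpec()]
#'   accepts)
#' @param reps number of simulated sequences (>= 1)
#' @param seed integer seed for the random number generator (required)
#' @return a list of class `"crossingsSimulation"` with elements `n`, `p`,
#'   `reps`, `seed`, `freq` (n x n matrix of empirical joint relative
#'   frequencies, rows c = 0..n-1, columns l = 1..n), `meanCL` and `seCL`
#' @examples
#' sim <- simulateJoint(16, 0.5, reps = 1000, seed = 42)
#' sim$meanCL
#' @export
simulateJoint <- function(n, p, reps, seed) {
  stopifnot(length(n) == 1L, n >= 1, n == floor(n), reps >= 1, reps == floor(reps))
  if (missing(seed)) stop("an explicit `seed` is required for reproducibility")
  pNum <- probValue(bernoulliSpec(p))
  n <- as.integer(n); reps <- as.integer(reps)
  set.seed(seed)
  x <- matrix(stats::runif(reps * n) < pNum, reps, n)
  C <- if (n > 1L) rowSums(x[, -1L, drop = FALSE] != x[, -n, drop = FALSE])
       else rep(0L, reps)
  L <- apply(x, 1L, function(r) max(rle(r)$lengths))
  freq <- matrix(0, n, n,
                 dimnames = list(paste0("c=", 0:(n - 1L)), paste0("l=", 1:n)))
  counts <- rowsum(rep(1, reps), group = C * n + L)
  idx <- as.integer(rownames(counts))
  Cg <- (idx - 1L) %/% n
  freq[cbind(Cg + 1L, idx - Cg * n)] <- counts[, 1L] / reps
  cl <- C * L
  structure(list(n = n, p = pNum, reps = reps, seed = seed, freq = freq,
                 meanCL = mean(cl), seCL = stats::sd(cl) / sqrt(reps)),
            class = "crossingsSimulation")
}

#' @export
print.crossingsSimulation <- function(x, ...) {
  cat(sprintf(
    "Simulated joint (C, L) distribution: n = %d, p = %g, reps = %d, seed = %s\n",
    x$n, x$p, x$reps, format(x$seed)))
  cat(sprintf("mean(C*L) = %.4f (SE %.4f)\n", x$meanCL, x$seCL))
  invisible(x)
}
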