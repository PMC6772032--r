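# Brute-force oracle and Monte-Carlo simulator.

test_that("sequence statistics count crossings and longest runs", {
  s <- sequenceStats(c(1, 1, 0, 0, 0, 1))
  expect_identical(c(s@crossings, s@longestRun), c(2L, 3L))
  s <- sequenceStats(rep(1, 9))
  expect_identical(c(s@crossings, s@longestRun), c(0L, 9L))
  s <- sequenceStats(rep(c(0, 1), 5))
  expect_identical(c(s@crossings, s@longestRun), c(9L, 1L))
  expect_identical(sequenceStats(c(TRUE, FALSE))@crossings, 1L)
  expect_error(sequenceStats(numeric(0)))
  expect_error(sequenceStats(c(0, 2)), "0/1")
})

test_that("every binary sequence satisfies the (c, l) support bounds", {
  for (n in c(1, 5, 10)) {
    seqs <- as.matrix(expand.grid(rep(list(0:1), n)))
    for (i in seq_len(nrow(seqs))) {
      s <- sequenceStats(seqs[i, ])
      cc <- s@crossings; ll <- s@longestRun
      expect_true(cc >= 0 && cc <= n - 1)
      expect_true(ll >= ceiling(n / (cc + 1)) && ll <= n - cc)
    }
  }
})

test_that("enumeration is normalized and capped", {
  for (probs in list("0.5", "0.3")) {
    o <- enumerateJoint(7, probs)
    expect_equal(totalMass(o), 1)
  }
  expect_error(enumerateJoint(17, 0.5), "cap")
  expect_silent(enumerateJoint(5, 0.5, cap = 5))
})

test_that("symmetric enumeration reproduces the published integer table", {
  o <- enumerateJoint(16, "1/2", "unconditional")
  expect_equal(unname(jointWeights(o) * 2^15), unname(table1_n16()))
})

test_that("simulation is seed-reproducible and demands a seed", {
  a <- simulateJoint(30, 0.4, 500, seed = 11)
  b <- simulateJoint(30, 0.4, 500, seed = 11)
  expect_identical(a, b)
  c <- simulateJoint(30, 0.4, 500, seed = 12)
  expect_false(identical(a$freq, c$freq))
  expect_error(simulateJoint(30, 0.4, 500), "seed")
  one <- simulateJoint(10, 0.5, 1, seed = 3)
  expect_equal(sum(one$freq == 1), 1)  # a point mass
  expect_equal(sum(one$freq), 1)
})

test_that("empirical frequencies approach the exact joint distribution", {
  reps <- 1e5
  sim <- simulateJoint(16, 0.6, reps, seed = 160)
  exact <- jointWeights(
    rescale(combineUnconditional(jointConditional(16, 0.6)), "probability"))
  # the published high-mass cell (c=7, l=4): empirical within 4 SE
  p74 <- exact[8, 4]
  se <- sqrt(p74 * (1 - p74) / reps)
  expect_lt(abs(sim$freq[8, 4] - p74), 4 * se)
  expect_equal(sum(sim$freq), 1)
})
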