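# The exact recursion for constant success probability.

test_that("the single-observation base case is degenerate at (0, 1)", {
  for (scale in c("probability", "times")) {
    pair <- baseCase(scale)
    for (pmf in list(givenSuccess(pair), givenFailure(pair))) {
      W <- jointWeights(pmf)
      expect_equal(unname(W), matrix(1, 1, 1))
      expect_equal(totalMass(pmf), 1)
    }
  }
})

test_that("first-crossing probabilities follow the geometric pattern", {
  expect_equal(firstCrossingWeight(3, 1, 0.6), 0.36)
  expect_equal(firstCrossingWeight(3, 2, 0.6), 0.4)
  expect_equal(firstCrossingWeight(3, 2, 0.6, side = "failure"), 0.6)
  # F partitions the sample space: weights sum to one
  for (n in c(1, 2, 7, 20)) {
    for (p in c(0.2, 0.5, 0.9)) {
      for (side in c("success", "failure")) {
        tot <- sum(vapply(1:n, firstCrossingWeight, numeric(1L),
                          n = n, spec = p, side = side))
        expect_equal(tot, 1)
      }
    }
  }
  expect_error(firstCrossingWeight(3, 0, 0.5), "1..n")
  expect_error(firstCrossingWeight(3, 4, 0.5), "1..n")
  expect_error(jointConditional(0, 0.5))
})

test_that("two observations give mass p at (0,2) and q at (1,1)", {
  for (p in c(0.25, 0.6)) {
    W <- jointWeights(givenSuccess(jointConditional(2, p)))
    expect_equal(unname(W), matrix(c(0, 1 - p, p, 0), 2, 2))
    W0 <- jointWeights(givenFailure(jointConditional(2, p)))
    expect_equal(unname(W0), matrix(c(0, p, 1 - p, 0), 2, 2))
  }
})

test_that("recursion equals exhaustive enumeration cell for cell", {
  for (p in c("0.3", "0.5", "0.8")) {
    for (n in c(1, 3, 6, 10)) {
      pair <- jointConditional(n, p)
      expect_true(jointEqual(givenSuccess(pair),
                             enumerateJoint(n, p, "success")))
      expect_true(jointEqual(givenFailure(pair),
                             enumerateJoint(n, p, "failure")))
      expect_true(jointEqual(combineUnconditional(pair),
                             enumerateJoint(n, p, "unconditional")))
    }
  }
})

test_that("swapping p and q exchanges the conditional members", {
  for (n in c(2, 5, 9)) {
    a <- jointConditional(n, "3/10")
    b <- jointConditional(n, "7/10")
    expect_true(jointEqual(givenSuccess(a), givenFailure(b)))
    expect_true(jointEqual(givenFailure(a), givenSuccess(b)))
  }
})

test_that("closed-form corner cells match", {
  for (p in c(0.3, 0.6)) {
    q <- 1 - p
    for (n in c(4, 7, 11)) {
      u <- combineUnconditional(jointConditional(n, p))
      W <- jointWeights(u)
      expect_equal(W[1, n], p^n + q^n)  # no crossing: one constant run
      # strict alternation: c = n-1, l = 1, both start sides
      expect_equal(W[n, 1],
                   p^ceiling(n / 2) * q^floor(n / 2) +
                   p^floor(n / 2) * q^ceiling(n / 2))
    }
  }
})

test_that("marginals sum the joint correctly", {
  u <- combineUnconditional(jointConditional(2, 0.7))
  ml <- marginalLongestRun(u)
  expect_equal(unname(ml), c(2 * 0.7 * 0.3, 0.7^2 + 0.3^2))
  mc <- marginalCrossings(u)
  expect_equal(sum(ml), sum(mc))
  u5 <- combineUnconditional(jointConditional(9, 0.4))
  expect_equal(sum(marginalCrossings(u5)), 1)
  expect_equal(unname(marginalCrossings(u5)),
               unname(rowSums(jointWeights(u5))))
})

test_that("box masses accumulate the requested corner", {
  u <- combineUnconditional(jointConditional(8, 0.35))
  expect_equal(boxMass(u, 0, 8), 1)
  p <- 0.35; q <- 0.65
  expect_equal(boxMass(u, 7, 1), p^4 * q^4 + p^4 * q^4)
  expect_equal(boxMass(u, 3, 5),
               sum(jointWeights(u)[4:8, 1:5]))
  expect_error(boxMass(u, 8, 1), "cMin")
  expect_error(boxMass(u, 0, 9), "lMax")
})

test_that("times and probability scales are exact rescalings", {
  pair <- jointConditional(9, 0.6, scale = "times")
  s1 <- givenSuccess(pair)
  expect_equal(totalMass(s1), 2^8)
  back <- rescale(rescale(s1, "probability"), "times")
  expect_identical(back@num, s1@num)
  expect_identical(back@den, s1@den)
  expect_identical(back@scale, "times")
  expect_equal(totalMass(rescale(s1, "probability")), 1)
  # times weights are m^(n-1) times the probabilities
  expect_equal(jointWeights(s1), jointWeights(rescale(s1, "probability")) * 2^8)
})

test_that("normalization holds exactly across n and p", {
  for (p in c("1/5", "0.5", "0.6", "0.8")) {
    for (n in c(13, 40)) {
      pair <- jointConditional(n, p, scale = "times")
      expect_equal(totalMass(givenSuccess(pair)), 2^(n - 1))
      expect_equal(totalMass(givenFailure(pair)), 2^(n - 1))
      expect_equal(totalMass(combineUnconditional(pair)), 2^(n - 1))
    }
  }
})
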