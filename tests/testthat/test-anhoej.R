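# Anhoej run-chart rules: limits, specificity, sensitivity.

test_that("shift-rule limits round log2(n) + 3 to the nearest integer", {
  expect_identical(shiftLimit(16), 7L)   # log2(16) + 3 = 7 exactly
  expect_identical(shiftLimit(20), 7L)   # 7.32 rounds down
  expect_identical(shiftLimit(45), 8L)   # 8.49 rounds down
  expect_identical(shiftLimit(91), 10L)  # 9.51 rounds up
  expect_identical(shiftLimit(c(10, 100)), c(6L, 10L))
})

test_that("crossings limits are the exact lower 5th binomial percentile", {
  expect_identical(crossingsLimit(16), 4L)
  expect_identical(crossingsLimit(2), 0L)  # CDF(0; 1, 1/2) = 0.5 >= 0.05
  # cross-check the exact integer quantile against the standard quantile
  ns <- 2:100
  expect_identical(crossingsLimit(ns),
                   as.integer(qbinom(0.05, ns - 1L, 0.5)))
})

test_that("rule application flags long runs or few crossings", {
  lim <- ruleLimits(16)
  expect_false(applyRules(10, 5, lim))
  expect_true(applyRules(0, 16, lim))    # one constant run
  expect_false(applyRules(15, 1, lim))   # perfect alternation
  expect_true(applyRules(3, 5, lim))     # too few crossings
  expect_true(applyRules(10, 8, lim))    # run longer than 7
  expect_identical(applyRules(c(3, 10), c(5, 5), lim), c(TRUE, FALSE))
  expect_error(applyRules(16, 1, lim), "0..n-1")
  expect_error(applyRules(1, 17, lim), "1..n")
})

test_that("specificities reproduce the published three-decimal values", {
  expect_equal(specificity(10, digits = 3), 0.955)
  expect_equal(specificity(45, digits = 3), 0.897)
  expect_equal(specificity(46, digits = 3), 0.936)
  tab <- anhoejSpecificities(10, 20)
  ref <- table3_specificities()
  expect_equal(tab$specificity, ref$specificity[ref$n %in% 10:20])
})

test_that("specificity agrees with brute-force enumeration", {
  for (n in c(10, 12)) {
    lim <- ruleLimits(n)
    o <- enumerateJoint(n, "1/2", "unconditional")
    byOracle <- boxMass(o, lim@crossingsLimit, min(lim@longestRunLimit, n))
    expect_equal(specificity(n), byOracle, tolerance = 1e-12)
  }
})

test_that("sensitivity complements the no-signal mass", {
  expect_equal(sensitivity(16, 0.5), 1 - specificity(16), tolerance = 1e-12)
  # a strong shift makes a signal near-certain
  expect_gt(sensitivity(16, 0.99), 0.98)
  # exact complement identity at any p
  n <- 12; p <- 0.7
  lim <- ruleLimits(n)
  u <- combineUnconditional(jointConditional(n, p))
  expect_equal(sensitivity(n, p) +
                 boxMass(u, lim@crossingsLimit, min(lim@longestRunLimit, n)),
               1, tolerance = 1e-12)
})

test_that("the signal region mass matches the published p = 0.6 table", {
  # summing the published times-representation cells over the signal region
  # (c < 4 or l > 7) and dividing by 2^15 gives the n = 16 sensitivity
  ref <- as.numeric(table2_n16_p06())
  sig <- outer(0:15, 1:16, function(c, l) c < 4 | l > 7)
  fromTable <- sum(ref[sig]) / 2^15
  expect_equal(sensitivity(16, 0.6), fromTable, tolerance = 1e-3)
})
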