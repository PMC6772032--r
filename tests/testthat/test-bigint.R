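# The limb-based exact integer arithmetic underlying every computation.
# Reference values for the large-number cases were computed independently
# with arbitrary-precision integer arithmetic and frozen here.

bi_new <- CrossingRuns:::bi_new
bi_add <- CrossingRuns:::bi_add
bi_sub <- CrossingRuns:::bi_sub
bi_mul <- CrossingRuns:::bi_mul
bi_mul_small <- CrossingRuns:::bi_mul_small
bi_pow <- CrossingRuns:::bi_pow
bi_prod <- CrossingRuns:::bi_prod
bi_cmp <- CrossingRuns:::bi_cmp
bi_divmod_small <- CrossingRuns:::bi_divmod_small
bi_divmod_factored <- CrossingRuns:::bi_divmod_factored
bi_to_string <- CrossingRuns:::bi_to_string
bi_from_string <- CrossingRuns:::bi_from_string
bi_to_double <- CrossingRuns:::bi_to_double

test_that("large powers and factorials match independent references", {
  expect_identical(bi_to_string(bi_pow(2, 100)),
                   "1267650600228229401496703205376")
  expect_identical(bi_to_string(bi_pow(3, 50)), "717897987691852588770249")
  expect_identical(bi_to_string(bi_prod(1:25)), "15511210043330985984000000")
  expect_identical(bi_to_string(bi_pow(5, 15)), "30517578125")
})

test_that("add, multiply and divide agree with frozen references", {
  a <- bi_from_string("123456789123456789123456789")
  b <- bi_from_string("987654321987654321")
  expect_identical(bi_to_string(bi_add(a, b)), "123456790111111111111111110")
  expect_identical(bi_to_string(bi_mul(a, b)),
                   "121932631356500531469135800347203169112635269")
  qr <- bi_divmod_factored(a, rep(3, 38))  # 3^38 < b-scale divisor chain
  recon <- bi_add(bi_mul(qr$q, bi_pow(3, 38)), qr$r)
  expect_identical(bi_to_string(recon), bi_to_string(a))
})

test_that("arithmetic matches doubles on randomly drawn safe-range values", {
  set.seed(42)
  for (rep in 1:50) {
    x <- floor(runif(1, 0, 2^40))
    y <- floor(runif(1, 0, 2^26))
    expect_equal(bi_to_double(bi_add(bi_new(x), bi_new(y))), x + y)
    expect_equal(bi_to_double(bi_mul(bi_new(x), bi_new(y))), x * y)
    expect_equal(bi_to_double(bi_sub(bi_new(x + y), bi_new(y))), x)
    qr <- bi_divmod_small(bi_new(x), max(1, y))
    expect_equal(bi_to_double(qr$q) * max(1, y) + qr$r, x)
  }
})

test_that("string conversion round-trips and compares correctly", {
  s <- "99999999999999999999999999999999000000001"
  expect_identical(bi_to_string(bi_from_string(s)), s)
  expect_identical(bi_cmp(bi_from_string(s), bi_add(bi_from_string(s), 1)), -1L)
  expect_identical(bi_cmp(bi_from_string(s), bi_from_string(s)), 0L)
  expect_identical(bi_to_string(bi_new(0)), "0")
})

test_that("limb matrices mirror per-cell scalar arithmetic", {
  bm_from_matrix <- CrossingRuns:::bm_from_matrix
  bm_to_double <- CrossingRuns:::bm_to_double
  bm_mul_bi <- CrossingRuns:::bm_mul_bi
  bm_total <- CrossingRuns:::bm_total
  bm_cell <- CrossingRuns:::bm_cell
  set.seed(7)
  m <- matrix(floor(runif(12, 0, 2^40)), 3, 4)
  arr <- bm_from_matrix(m)
  expect_equal(bm_to_double(arr), m)
  s <- bi_pow(7, 30)
  prod <- bm_mul_bi(arr, s)
  for (i in 1:3) for (j in 1:4) {
    expect_identical(bi_to_string(bm_cell(prod, i, j)),
                     bi_to_string(bi_mul(bi_new(m[i, j]), s)))
  }
  expect_equal(bi_to_double(bm_total(arr)), sum(m))
})

test_that("exact decimal rounding is half-away-from-zero", {
  rat <- CrossingRuns:::.rat_round_string
  # 25/1000 = 0.025 -> 0.03 (exact tie rounds away); 24/1000 -> 0.02
  expect_identical(rat(bi_new(25), c(10, 10, 10), bi_new(1000), 2L), "0.03")
  expect_identical(rat(bi_new(24), c(10, 10, 10), bi_new(1000), 2L), "0.02")
  exact <- CrossingRuns:::.rat_exact_string
  expect_identical(exact(bi_new(3), c(2, 2, 2), bi_new(8)), "0.375")
  expect_identical(exact(bi_new(1), c(3), bi_new(3)), "1/3")
})
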