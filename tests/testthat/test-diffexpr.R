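test_that("exact test reproduces its closed forms", {
  # x=0, y=10, equal sizes: one tail is a geometric series, sum 2^-10
  expect_equal(exact_count_test(0, 1e6, 10, 1e6), 2^-9)
  # y=0: P_low = p(0|5) = 2^-6, doubled
  expect_equal(exact_count_test(5, 1e6, 0, 1e6), 0.03125)
  # symmetric counts: both tails >= 0.5, doubled then clipped
  expect_equal(exact_count_test(3, 1e6, 3, 1e6), 1)
})

test_that("exact test agrees with direct pmf summation", {
  cases <- expand.grid(x = c(0, 1, 5, 40, 300),
                       y = c(0, 3, 17, 120),
                       r = c(1, 0.5, 2.7))
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; y <- cases$y[i]
    n1 <- 1e6; n2 <- 1e6 * cases$r[i]
    expect_equal(exact_count_test(x, n1, y, n2),
                 ac_two_sided_oracle(x, n1, y, n2), tolerance = 1e-9)
  }
})

test_that("conditional pmf mass and swap symmetry hold", {
  for (x in c(0, 2, 25, 400)) {
    for (r in c(1, 3)) {
      Y <- ceiling(x * r + 50 * sqrt(x + 1) + 50)
      total <- sum(ac_pmf_oracle(0:Y, x, 1e6, r * 1e6))
      expect_gte(total, 1 - 1e-10)
    }
  }
  # The doubled-tail convention includes the observed point in both tails,
  # so the two argument orders can differ -- but by no more than twice the
  # conditional point mass at the observation (exact for x = y at equal
  # sizes, where both orders give the same clipped value).
  set.seed(5)
  for (i in 1:50) {
    x <- rpois(1, 60); y <- rpois(1, 40)
    n1 <- runif(1, 5e5, 5e6); n2 <- runif(1, 5e5, 5e6)
    pt <- max(ac_pmf_oracle(y, x, n1, n2), ac_pmf_oracle(x, y, n2, n1))
    expect_lte(abs(exact_count_test(x, n1, y, n2) -
                   exact_count_test(y, n2, x, n1)), 2 * pt + 1e-12)
  }
  expect_equal(exact_count_test(9, 2e6, 9, 2e6),
               exact_count_test(9, 2e6, 9, 2e6))
})

test_that("bh_adjust matches definition, p.adjust and stays monotone", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:60, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("log2_fold_change closed forms and antisymmetry", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(31, 7, 1), 2)
  expect_equal(log2_fold_change(7, 31, 1), -2)
})

test_that("call_de flags the planted gene and respects the strict gate", {
  n <- 100
  m <- matrix(rep(c(50, 50), each = n), n, 2)
  m[1, ] <- c(1000, 10)
  ct <- make_ct(m, samples = c("P1", "P2"), lib = c(1e6, 1e6))
  de <- call_de(ct, c("P1", "P2"), alpha = 0.001, fc = 2)
  # oracle route: direct-summation p-values through the definition of BH
  p_or <- vapply(seq_len(n), function(i)
    ac_two_sided_oracle(m[i, 1], 1e6, m[i, 2], 1e6), 0)
  q_or <- bh_oracle(p_or)
  expect_equal(de$q, q_or, tolerance = 1e-9)
  expect_identical(de$direction[1], "UP")
  expect_identical(unique(de$direction[-1]), "NS")

  # fold change exactly 2 (log2fc = 1) fails the strict > gate even when
  # overwhelmingly significant
  m2 <- matrix(rep(c(3000, 3000), each = n), n, 2)
  m2[1, ] <- c(2047, 1023)
  ct2 <- make_ct(m2, samples = c("P1", "P2"), lib = c(1e6, 1e6))
  de2 <- call_de(ct2, c("P1", "P2"), alpha = 0.001, fc = 2)
  expect_equal(de2$log2fc[1], 1)
  expect_lte(de2$q[1], 0.001)
  expect_identical(de2$direction[1], "NS")

  # x=y at equal sizes is NS
  expect_identical(de$direction[2], "NS")
})

test_that("null type-I fraction is controlled (small-n version)", {
  set.seed(23)
  n <- 2000
  x <- rpois(n, 100); y <- rpois(n, 100)
  p <- exact_count_test(x, 1e6, y, 1e6)
  frac <- mean(p <= 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(frac, 0.05 + 3 * se)
})
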