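test_that("Fisher enrichment reproduces hand-computed tables", {
  # symmetric table: no association
  res <- fisher_enrichment(1, 2, 2, 4)
  expect_equal(res$p_value, 1)
  expect_equal(res$odds_ratio, 1)
  # complete association on a 5/5 split: two-sided p = 2/choose(10,5) = 1/126
  res2 <- fisher_enrichment(5, 5, 5, 10)
  expect_equal(res2$p_value, 1 / 126, tolerance = 1e-9)
  expect_error(fisher_enrichment(5, 4, 5, 10), "inconsistent")
})

test_that("Fisher enrichment matches hypergeometric enumeration on random tables", {
  withr::local_seed(19)
  for (case in 1:150) {
    n <- sample(4:30, 1)
    k <- sample(1:(n - 1), 1)
    m <- sample(1:(n - 1), 1)
    a <- sample(max(0, k + m - n):min(k, m), 1)
    res <- fisher_enrichment(a, k, m, n)
    expect_equal(res$p_value,
                 oracle_fisher_p(a, k - a, m - a, n - k - m + a),
                 tolerance = 1e-9)
  }
})

test_that("rank-sum test is exact for small samples, approximate beyond", {
  # identical multisets: every assignment is as extreme -> p = 1
  expect_equal(rank_sum_test(c(2, 5, 5), c(2, 5, 5))$p_value, 1)
  # complete separation of 3 vs 3: 2 of 20 assignments are as extreme
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 0)
  expect_identical(res$method, "exact")
  expect_identical(rank_sum_test(rnorm(8), rnorm(8))$method,
                   "normal approximation")
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("the normal approximation tracks exact enumeration at n = 6 + 6", {
  # at this sample size the continuity-corrected normal approximation sits
  # within 0.05 of the exact tail probability (worst case near mid-range p)
  withr::local_seed(23)
  devs <- numeric(100)
  for (case in 1:100) {
    a <- round(rnorm(6, 10, 3), 1)
    b <- round(rnorm(6, 10 + runif(1, 0, 4), 3), 1)
    p_exact <- rank_sum_test(a, b)$p_value
    p_approx <- rank_sum_test(a, b, exact_limit = 0)$p_value
    devs[case] <- abs(p_exact - p_approx)
  }
  expect_lt(max(devs), 0.05)
  expect_lt(mean(devs), 0.02)
})

test_that("BH control matches the brute-force step-up rule", {
  res <- benjamini_hochberg(c(0.01, 0.02, 0.03), q = 0.05)
  expect_true(all(res$rejected)) # max k with p_(k) <= k q / m is 3
  res1 <- benjamini_hochberg(rep(1, 5), q = 0.1)
  expect_false(any(res1$rejected))
  expect_equal(res1$p_adjusted, rep(1, 5))
  withr::local_seed(29)
  for (case in 1:150) {
    m <- sample(1:20, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    res <- benjamini_hochberg(p, q)
    expect_identical(res$rejected, oracle_bh_reject(p, q))
    expect_true(all(diff(sort(res$p_adjusted)) >= -1e-12))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})
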