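make_signature <- function(seed = 5, k = 20) {
  co <- simulate_cohort(cohort_config(n_noncancer = 2, n_cancer = 2,
                                      n_background_genes = 1, seed = seed))
  select_signature_genes(co$tissue_reference, k = k)
}

as_expr_tbl <- function(sig, y, sample = "s1") {
  out <- tibble::tibble(gene = rownames(sig$X))
  out[[sample]] <- y
  out
}

frac_matrix <- function(d, sig) unname(as.matrix(d[1, sig$tissues]))[1, ]

# KKT residual of min ||Xb - y||^2 s.t. b >= 0, sum(b) <= 1 at the point b.
kkt_residual <- function(X, y, b, tol = 1e-6) {
  g <- as.vector(2 * crossprod(X, X %*% b - y)) # objective gradient
  active_sum <- sum(b) >= 1 - tol
  free <- b > tol
  lambda <- if (active_sum && any(free)) mean(-g[free]) else 0
  lambda <- max(lambda, 0)
  viol <- c(
    max(0, -min(b)),                         # primal: b >= 0
    max(0, sum(b) - 1),                      # primal: sum <= 1
    if (any(free)) max(abs(g[free] + lambda)) else 0, # stationarity, free coords
    max(0, max(-(g[!free] + lambda), 0))     # dual feasibility at bounds
  )
  max(viol)
}

test_that("deconvolution recovers exact mixtures and handles degenerate input", {
  sig <- make_signature()
  p <- length(sig$tissues)
  # y = one signature column -> unit fraction vector
  y <- as.vector(sig$X[, 2])
  d <- deconvolve(as_expr_tbl(sig, y), sig)
  b <- frac_matrix(d, sig)
  expect_equal(b, c(0, 1, 0, 0, 0), tolerance = 1e-6)
  expect_lt(abs(d$remainder[1]), 1e-6)
  # y = 0 -> beta = 0, remainder 1
  d0 <- deconvolve(as_expr_tbl(sig, rep(0, nrow(sig$X))), sig)
  expect_equal(frac_matrix(d0, sig), rep(0, p))
  expect_equal(d0$remainder[1], 1)
  # all-zero signature errors
  sig0 <- sig
  sig0$X[] <- 0
  expect_error(deconvolve(as_expr_tbl(sig, y), sig0), "all zero")
})

test_that("the QP solution beats a dense simplex grid on a planted mixture", {
  sig <- make_signature()
  y <- as.vector(sig$X %*% c(0.4, 0.5, 0, 0, 0))
  d <- deconvolve(as_expr_tbl(sig, y), sig)
  b <- frac_matrix(d, sig)
  expect_equal(b, c(0.4, 0.5, 0, 0, 0), tolerance = 1e-6)
  expect_equal(d$remainder[1], 0.1, tolerance = 1e-6)
  # independent oracle: dense grid at 0.01 over the two active coordinates
  grid <- expand.grid(b1 = seq(0, 1, 0.01), b2 = seq(0, 1, 0.01))
  grid <- grid[grid$b1 + grid$b2 <= 1, ]
  obj <- apply(grid, 1, function(g) {
    sum((sig$X %*% c(g[1], g[2], 0, 0, 0) - y)^2)
  })
  expect_lte(sum((sig$X %*% b - y)^2), min(obj) + 1e-9)
})

test_that("solutions satisfy the KKT conditions and dominate random feasible points", {
  sig <- make_signature()
  withr::local_seed(17)
  p <- length(sig$tissues)
  scale <- mean(sig$X[sig$X > 0])^2
  for (case in 1:10) {
    # noisy, sometimes super-unit mixtures force active constraints
    b_true <- rgamma(p, 0.6)
    b_true <- b_true / sum(b_true) * runif(1, 0.3, 1.6)
    y <- pmax(as.vector(sig$X %*% b_true) + rnorm(nrow(sig$X), 0, 5), 0)
    d <- deconvolve(as_expr_tbl(sig, y), sig)
    b <- frac_matrix(d, sig)
    expect_lt(kkt_residual(sig$X, y, b) / scale, 1e-6)
    obj_hat <- sum((sig$X %*% b - y)^2)
    for (r in 1:100) {
      br <- rgamma(p, 1)
      br <- br / sum(br) * runif(1)
      expect_lte(obj_hat, sum((sig$X %*% br - y)^2) + 1e-8)
    }
  }
})

test_that("noise-free generator mixtures are recovered within 1e-4", {
  sig <- make_signature(seed = 9)
  withr::local_seed(31)
  for (case in 1:5) {
    b_true <- rgamma(length(sig$tissues), 1)
    b_true <- b_true / sum(b_true) * runif(1, 0.4, 0.99)
    y <- simulate_tissue_mixture(sig, b_true, noise_sd = 0)
    d <- deconvolve(as_expr_tbl(sig, y$rpm), sig)
    expect_lt(max(abs(frac_matrix(d, sig) - b_true)), 1e-4)
  }
})

test_that("scaling y scales the recovered fractions while feasible", {
  sig <- make_signature()
  b_true <- c(0.2, 0.3, 0.1, 0.05, 0.15)
  y <- as.vector(sig$X %*% b_true)
  for (cc in c(0.25, 0.6, 1)) {
    d <- deconvolve(as_expr_tbl(sig, cc * y), sig)
    expect_equal(frac_matrix(d, sig), cc * b_true, tolerance = 1e-5)
  }
})

test_that("signature genes missing from the sample are dropped with a warning", {
  sig <- make_signature()
  y <- as.vector(sig$X %*% c(0.5, 0.2, 0, 0, 0))
  expr <- as_expr_tbl(sig, y)[-(1:5), ]
  expect_warning(d <- deconvolve(expr, sig), "dropped")
  expect_equal(frac_matrix(d, sig), c(0.5, 0.2, 0, 0, 0), tolerance = 1e-5)
})
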