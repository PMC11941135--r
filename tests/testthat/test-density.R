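test_that("marginal KDE reproduces the standard normal density and cdf", {
  x <- withr::with_seed(1, rnorm(10000))
  m <- fit_marginal(x)
  expect_lt(abs(marginal_pdf(m, 0) - dnorm(0)), 0.02)
  expect_lt(abs(marginal_cdf(m, median(x)) - 0.5), 0.02)
  expect_true(all(m$pdf >= 0))
})

test_that("marginal pdf integrates to one over its padded support", {
  x <- withr::with_seed(2, rexp(5000))
  m <- fit_marginal(x)
  dx <- diff(m$grid[1:2])
  expect_lt(abs(sum(m$pdf) * dx - 1), 1e-3)
  # and the stored cdf is the integral of the pdf (trapezoid + left tail)
  trapz <- m$cdf[1] + c(0, cumsum((m$pdf[-1] + m$pdf[-length(m$pdf)]) / 2) * dx)
  expect_lt(max(abs(trapz - m$cdf)), 2e-3)
})

test_that("marginal cdf is strictly increasing across the data range", {
  x <- withr::with_seed(3, c(rnorm(500), rnorm(500, 6)))
  m <- fit_marginal(x)
  g <- seq(min(x), max(x), length.out = 1000)
  expect_true(all(diff(marginal_cdf(m, g)) > 0))
})

test_that("degenerate and short samples are rejected", {
  expect_error(fit_marginal(rep(1, 100)), "jitter")
  expect_error(fit_marginal(rnorm(10)), "at least 50")
})

test_that("copula correlations recover independence and comonotonicity", {
  n <- 10000
  Z <- withr::with_seed(4, matrix(rnorm(3 * n), ncol = 3))
  ind <- fit_copula(Z)
  off <- ind$R[upper.tri(ind$R)]
  expect_lt(max(abs(off)), 3 / sqrt(n))

  x <- withr::with_seed(5, rexp(n))
  como <- fit_copula(cbind(x, 2 * x + 1))
  expect_gt(como$R[1, 2], 0.99)
})

test_that("normal-scores correlation matches Pearson for Gaussian pairs", {
  n <- 10000
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  Z <- withr::with_seed(6, matrix(rnorm(2 * n), ncol = 2) %*% chol(S))
  cd <- fit_copula(Z)
  expect_lt(abs(cd$R[1, 2] - 0.6), 0.03)
})

test_that("identity copula reduces the joint log-density to the marginals", {
  X <- withr::with_seed(7, matrix(rnorm(2 * 500), ncol = 2))
  cd <- fit_copula(X)
  cd$R <- diag(2); cd$R_inv <- diag(2); cd$log_det <- 0
  pts <- withr::with_seed(8, matrix(rnorm(20), ncol = 2))
  got <- log_density(cd, pts)
  manual <- log(marginal_pdf(cd$marginals[[1]], pts[, 1])) +
    log(marginal_pdf(cd$marginals[[2]], pts[, 2]))
  expect_equal(as.numeric(got), manual, tolerance = 1e-12)
})

test_that("fitted density matches a known bivariate Gaussian at its center", {
  n <- 10000
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  X <- withr::with_seed(9, matrix(rnorm(2 * n), ncol = 2) %*% chol(S))
  cd <- fit_copula(X)
  truth <- -log(2 * pi) - 0.5 * log(det(S))  # log N(0; 0, S)
  got <- log_density(cd, colMeans(X))
  expect_lt(abs(as.numeric(got) - truth), 0.05)
})

test_that("the fitted 2-D density integrates to one", {
  X <- withr::with_seed(10, cbind(rnorm(2000), rexp(2000)))
  cd <- fit_copula(X)
  g1 <- seq(min(X[, 1]) - 1, max(X[, 1]) + 1, length.out = 120)
  g2 <- seq(min(X[, 2]) - 1, max(X[, 2]) + 1, length.out = 120)
  grid <- as.matrix(expand.grid(g1, g2))
  dens <- exp(log_density(cd, grid))
  integral <- sum(dens) * diff(g1[1:2]) * diff(g2[1:2])
  expect_lt(abs(integral - 1), 0.02)
})

test_that("log-density never returns non-finite values", {
  X <- withr::with_seed(11, matrix(rexp(600), ncol = 2))
  cd <- fit_copula(X)
  extreme <- rbind(c(-1e6, 0.5), c(1e6, 1e6), c(0.5, -3))
  ld <- log_density(cd, extreme)
  expect_true(all(is.finite(ld)))
  expect_gt(attr(ld, "floor_events"), 0)
})

test_that("copula fitting is invariant to cell order", {
  X <- withr::with_seed(12, cbind(rnorm(300), rexp(300)))
  a <- fit_copula(X)
  b <- fit_copula(X[sample(300), ])
  expect_equal(a$R, b$R)
  expect_equal(a$marginals[[1]]$pdf, b$marginals[[1]]$pdf)
})

test_that("ace of a single cell is exactly its negative log-density", {
  X <- withr::with_seed(13, matrix(rnorm(400), ncol = 2))
  cd <- fit_copula(X)
  y1 <- X[7, , drop = FALSE]
  expect_equal(as.numeric(ace(cd, y1)), -as.numeric(log_density(cd, y1)))
})

test_that("regularization keeps near-degenerate correlation matrices usable", {
  x <- withr::with_seed(14, rnorm(2000))
  # three almost perfectly dependent columns
  X <- cbind(x, x + rnorm(2000, sd = 1e-8), -x + rnorm(2000, sd = 1e-8))
  cd <- fit_copula(X)
  ev <- eigen(cd$R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_true(all(is.finite(log_density(cd, X[1:5, ]))))
})
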