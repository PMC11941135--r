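test_that("initial log-abundances have the configured means and variances", {
  n <- 8000
  x <- sample_initial(n, seed = 101)
  lg <- log(as.matrix(x))
  mu <- c(5.25, 7.60, 5.25, 7.60, 5.25, 5.25)
  s2 <- c(0.15, 0.06, 0.15, 0.06, 0.15, 0.15)
  for (j in 1:6) {
    expect_lt(abs(mean(lg[, j]) - mu[j]), 3 * sqrt(s2[j] / n))
    # sample variance of a normal: var ~ 2 sigma^4 / n
    expect_lt(abs(var(lg[, j]) - s2[j]), 3 * sqrt(2 * s2[j]^2 / n))
  }
})

test_that("initial log-abundance columns are uncorrelated", {
  n <- 4000
  lg <- log(as.matrix(sample_initial(n, seed = 202)))
  C <- cor(lg)
  # 15 pairwise correlations, each ~ N(0, 1/n): bound the max at 4 sigma
  expect_lt(max(abs(C[upper.tri(C)])), 4 / sqrt(n))
})

test_that("sampling is bit-reproducible from the seed", {
  expect_identical(sample_initial(100, seed = 7), sample_initial(100, seed = 7))
  expect_false(identical(sample_initial(100, seed = 7),
                         sample_initial(100, seed = 8)))
})

test_that("invalid variance parameters are rejected", {
  expect_error(sample_initial(10, sigma2 = c(0.1, -1, 0.1, 0.1, 0.1, 0.1)),
               "positive")
  expect_error(sample_initial(0), "at least 1")
})

test_that("generate_tss splits cells into disjoint snapshots of n_cells each", {
  tss <- generate_tss("MEDIUM", n_cells = 400, time = 1.5, seed = 5)
  expect_equal(nrow(tss$t0), 400)
  expect_equal(nrow(tss$yt), 400)
  expect_equal(attr(tss$yt, "time"), 1.5)
  expect_equal(tss$meta$theta,
               c(theta1 = 0.10, theta2 = 0.90, theta3 = 0.18))
  # end-to-end determinism
  tss2 <- generate_tss("MEDIUM", n_cells = 400, time = 1.5, seed = 5)
  expect_identical(as.matrix(tss$yt), as.matrix(tss2$yt))
})

test_that("at time zero the two halves are exchangeable samples", {
  tss <- generate_tss("SMALL", n_cells = 3000, time = 0, seed = 9)
  m0 <- colMeans(as.matrix(tss$t0))
  m1 <- colMeans(as.matrix(tss$yt))
  se <- sqrt(apply(as.matrix(tss$t0), 2, var) / 3000 +
               apply(as.matrix(tss$yt), 2, var) / 3000)
  expect_true(all(abs(m0 - m1) < 3.5 * se))
})

test_that("evolved snapshot means match the RK4 oracle", {
  tss <- generate_tss("LARGE", n_cells = 250, time = 1.5, seed = 33)
  # recover the evolved half's initial cells by rerunning the generator's
  # sampling stages
  x_all <- sample_initial(500, seed = child_seed(33, 1L))
  idx <- withr::with_seed(child_seed(33, 2L), sample.int(500, 250))
  x_evolved_half <- as.matrix(x_all[-idx, ])
  oracle <- rk4_evolve(x_evolved_half, nk_network(),
                       nk_theta(0.10, 0.95, 0.18), 1.5, h = 5e-4)
  expect_lt(rel_err(as.matrix(tss$yt), oracle), 1e-5)
})

test_that("scenario truths match the study conditions", {
  sc <- tss_scenarios()
  expect_equal(sc$theta2[sc$scenario == "LARGE"], 0.95)
  expect_equal(sc$theta3[sc$scenario == "MEDIUM"], 0.18)
  # SMALL sits inside the one-parameter family
  small <- sc[sc$scenario == "SMALL", ]
  expect_equal(small$theta2, 9 * small$theta1)
  expect_equal(small$theta3, 2 * small$theta1)
  expect_error(generate_tss("HUGE", 10, 1, 1), "unknown scenario")
})

test_that("child seeds are deterministic, distinct, and in integer range", {
  s <- vapply(0:1000, function(i) child_seed(123, i), integer(1))
  expect_false(any(duplicated(s)))
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_identical(child_seed(5, 7), child_seed(5, 7))
})
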