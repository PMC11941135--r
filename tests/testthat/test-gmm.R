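test_that("cost is exactly zero when the data are the model's own output", {
  cands <- nk_candidates()
  x0 <- sample_initial(300, seed = 4)
  y <- evolve_cells(x0, nk_network(), nk_theta(), 1.5, 1e-6, 1e-6)
  cost <- gmm_cost(c(0.1, 0.18), cands$h2, x0, y, 1.5)
  expect_equal(cost, 0)
})

test_that("cost equals the quadratic form d' W d for arbitrary weights", {
  cands <- nk_candidates()
  x0 <- sample_initial(200, seed = 5)
  tss <- small_tss(n = 200, seed = 6)
  y <- tss$yt
  # compute d independently from moment_vector + evolve_cells
  pred <- evolve_cells(x0, nk_network(), expand_theta(cands$h2, c(0.11, 0.2)),
                       1.5, 1e-6, 1e-6)
  d <- moment_vector(pred, "marginal")$value - moment_vector(y, "marginal")$value
  w <- seq(0.5, 3, length.out = length(d))
  expect_equal(gmm_cost(c(0.11, 0.2), cands$h2, x0, y, 1.5, weighting = w),
               sum(w * d^2), tolerance = 1e-8)
  W <- diag(w)
  expect_equal(gmm_cost(c(0.11, 0.2), cands$h2, x0, y, 1.5, weighting = W),
               sum(w * d^2), tolerance = 1e-8)
})

test_that("cost is invariant to permuting cells in either snapshot", {
  cands <- nk_candidates()
  tss <- small_tss(n = 150, seed = 7)
  c0 <- gmm_cost(0.1, cands$h1, tss$t0, tss$yt, 1.5)
  c1 <- gmm_cost(0.1, cands$h1, tss$t0[sample(150), ], tss$yt[sample(150), ], 1.5)
  expect_equal(c0, c1)
})

test_that("optimizer attains at least the best of a coarse parameter grid", {
  cands <- nk_candidates()
  tss <- small_tss(n = 400, seed = 8)
  fit <- fit_gmm(cands$h1, tss$t0, tss$yt, 1.5, starts = 2, seed = 1)
  grid <- exp(seq(log(0.02), log(0.5), length.out = 20))
  grid_costs <- vapply(grid, function(g) {
    gmm_cost(g, cands$h1, tss$t0, tss$yt, 1.5)
  }, numeric(1))
  expect_lte(fit$cost, min(grid_costs) + 1e-10)
})

test_that("the generating parameters are recovered on medium-size data", {
  cands <- nk_candidates()
  tss <- small_tss("MEDIUM", n = 1600, seed = 9)
  fit <- fit_gmm(cands$h2, tss$t0, tss$yt, 1.5, starts = 2, seed = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$theta[["theta1"]] - 0.10), 0.02)
  expect_lt(abs(fit$theta[["theta3"]] - 0.18), 0.03)
  td <- tidy(fit)
  expect_equal(td$term[td$free], c("theta1", "theta3"))
  expect_equal(glance(fit)$k_free, 2)
})

test_that("estimator spread shrinks with sample size", {
  cands <- nk_candidates()
  ns <- c(400, 3600)
  spread <- vapply(ns, function(n) {
    est <- vapply(1:5, function(r) {
      tss <- small_tss("MEDIUM", n = n, seed = 1000 * n + r)
      fit_gmm(cands$h1, tss$t0, tss$yt, 1.5, starts = 1)$theta[["theta1"]]
    }, numeric(1))
    sd(est)
  }, numeric(1))
  # 9x the cells: spread should drop roughly 3x; wide slack for 6 reps
  expect_lt(spread[2], 0.75 * spread[1])
})

test_that("nested candidates order their attained costs", {
  cands <- nk_candidates()
  tss <- small_tss("MEDIUM", n = 1500, seed = 10)
  costs <- vapply(cands, function(cm) {
    fit_gmm(cm, tss$t0, tss$yt, 1.5, starts = 3, seed = 3)$cost
  }, numeric(1))
  expect_lte(costs[["h3"]], costs[["h2"]] * (1 + 1e-6))
  expect_lte(costs[["h2"]], costs[["h1"]] * (1 + 1e-6))
})

test_that("frozen-Jacobian refits agree with full refits near the optimum", {
  cands <- nk_candidates()
  tss <- small_tss("MEDIUM", n = 1200, seed = 12)
  full <- fit_gmm(cands$h2, tss$t0, tss$yt, 1.5, starts = 2, seed = 4,
                  return_jacobian = TRUE)
  # perturbed data: a resample of the same cells
  idx <- withr::with_seed(5, sample.int(1200, 1200, replace = TRUE))
  idy <- withr::with_seed(6, sample.int(1200, 1200, replace = TRUE))
  lm_fit <- fit_gmm(cands$h2, tss$t0[idx, ], tss$yt[idy, ], 1.5, starts = 1,
                    init = full$theta_free)
  gn_fit <- fit_gmm(cands$h2, tss$t0[idx, ], tss$yt[idy, ], 1.5,
                    init = full$theta_free, frozen_jacobian = full$jacobian)
  expect_lt(max(abs(log(gn_fit$theta_free) - log(lm_fit$theta_free))), 0.02)
})

test_that("weighting validation rejects bad inputs", {
  cands <- nk_candidates()
  tss <- small_tss(n = 120, seed = 13)
  expect_error(gmm_cost(0.1, cands$h1, tss$t0, tss$yt, 1.5,
                        weighting = rep(-1, 12)), "positive")
  bad <- matrix(rnorm(144), 12, 12)  # not symmetric
  expect_error(gmm_cost(0.1, cands$h1, tss$t0, tss$yt, 1.5, weighting = bad),
               "symmetric")
})
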