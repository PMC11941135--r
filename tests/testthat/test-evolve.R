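test_that("zero-time evolution returns the input unchanged", {
  x0 <- sample_initial(20, seed = 1)
  y <- evolve_cells(x0, nk_network(), nk_theta(), time = 0)
  expect_equal(as.matrix(y), as.matrix(x0))
})

test_that("adaptive solution matches a fine fixed-step RK4 oracle", {
  net <- nk_network()
  th <- nk_theta(0.10, 0.90, 0.18)
  # single cell at the log-scale median abundances
  x0 <- matrix(exp(c(5.25, 7.60, 5.25, 7.60, 5.25, 5.25)), nrow = 1,
               dimnames = list(NULL, net$species))
  oracle <- rk4_evolve(x0, net, th, 1.5, h = 1e-4)
  got <- evolve_cells(as.data.frame(x0), net, th, 1.5, rtol = 1e-9, atol = 1e-9)
  expect_lt(rel_err(as.matrix(got), oracle), 1e-6)
})

test_that("twenty random cells agree with the RK4 oracle to 1e-6 relative", {
  net <- nk_network()
  th <- nk_theta()
  x0 <- sample_initial(20, seed = 3)
  oracle <- rk4_evolve(as.matrix(x0), net, th, 1.5, h = 2e-4)
  for (m in c("dopri5", "dopri5_cell", "rosenbrock")) {
    got <- evolve_cells(x0, net, th, 1.5, rtol = 1e-9, atol = 1e-9, method = m)
    expect_lt(rel_err(as.matrix(got), oracle), 1e-6)
  }
})

test_that("evolution agrees with an independent stiff solver (deSolve)", {
  skip_if_not_installed("deSolve")
  net <- nk_network()
  th <- nk_theta(0.2, 1.1, 0.35)
  k <- bind_rates(net, th)
  x0 <- sample_initial(5, seed = 11)
  ref <- t(apply(as.matrix(x0), 1, function(x) {
    out <- deSolve::lsoda(
      y = x, times = c(0, 1.5),
      func = function(t, y, p) {
        list(as.numeric(mass_action_rhs(y, net, th)))
      },
      rtol = 1e-10, atol = 1e-10
    )
    out[2, -1]
  }))
  got <- evolve_cells(x0, net, th, 1.5, rtol = 1e-9, atol = 1e-9)
  expect_lt(rel_err(as.matrix(got), ref), 1e-6)
})

test_that("evolution composes over time (autonomous semigroup property)", {
  x0 <- sample_initial(10, seed = 5)
  net <- nk_network()
  th <- nk_theta()
  oneshot <- evolve_cells(x0, net, th, 1.5)
  twostep <- evolve_cells(evolve_cells(x0, net, th, 0.6), net, th, 0.9)
  expect_lt(rel_err(as.matrix(twostep), as.matrix(oneshot)), 1e-6)
})

test_that("per-cell conservation totals hold to 1e-6 relative", {
  net <- nk_network()
  V <- conservation_laws(net)
  x0 <- sample_initial(50, seed = 9)
  for (t in c(0.3, 1.5, 4.5)) {
    y <- evolve_cells(x0, net, nk_theta(), t)
    before <- as.matrix(x0) %*% t(V)
    after <- as.matrix(y) %*% t(V)
    expect_lt(max(abs(after - before) / pmax(abs(before), 1)), 1e-6)
  }
})

test_that("no species dips meaningfully below zero", {
  x0 <- sample_initial(200, seed = 13)
  y <- evolve_cells(x0, nk_network(), nk_theta(), 1.5)
  totals <- rowSums(as.matrix(x0))
  expect_true(all(as.matrix(y) > -1e-9 * totals))
})

test_that("outputs depend smoothly on the rates", {
  x0 <- sample_initial(20, seed = 17)
  net <- nk_network()
  base <- as.matrix(evolve_cells(x0, net, nk_theta(), 1.5, 1e-10, 1e-10))
  bump <- as.matrix(evolve_cells(x0, net, nk_theta(0.1 * (1 + 1e-6)), 1.5,
                                 1e-10, 1e-10))
  expect_lt(rel_err(bump, base), 1e-4)
  expect_gt(rel_err(bump, base), 0)  # not bitwise identical either
})

test_that("hopeless rate sets fail with an informative error", {
  x0 <- sample_initial(3, seed = 1)
  expect_error(
    evolve_cells(x0, nk_network(), nk_theta(t1 = 1e12), 1.5,
                 method = "dopri5_cell"),
    "cell"
  )
})

test_that("column order is taken from names, not position", {
  net <- nk_network()
  x0 <- sample_initial(10, seed = 21)
  shuffled <- x0[, rev(names(x0))]
  expect_equal(as.matrix(evolve_cells(shuffled, net, nk_theta(), 1)),
               as.matrix(evolve_cells(x0, net, nk_theta(), 1)))
  expect_error(evolve_cells(x0[, 1:5], net, nk_theta(), 1), "SHP1.pVav1")
})
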