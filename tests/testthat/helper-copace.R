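# Report every failure: the end-to-end study checks are allowed to flag
# several conditions without aborting the run of the remaining files.
options(testthat.progress.max_fails = 1000)

# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data.

nk_theta <- function(t1 = 0.1, t2 = 0.9, t3 = 0.18) {
  c(theta1 = t1, theta2 = t2, theta3 = t3)
}

# A two-species toy: A + A -> B at rate k1, B -> A + A at rate k2.
# Hand-expanded mass action: dA/dt = -2 k1 A^2 + 2 k2 B, dB/dt = k1 A^2 - k2 B.
toy_network <- function() {
  reaction_network(
    species = c("A", "B"),
    reactions = list(
      list(reactants = c("A", "A"), products = "B", rate = "theta1"),
      list(reactants = "B", products = c("A", "A"), rate = 0.3)
    )
  )
}

# Independent fixed-step classical RK4 oracle, vectorized over cells.
# Never calls the package's compiled solver.
rk4_evolve <- function(X, network, theta, tfinal, h = 1e-4) {
  k <- copace::bind_rates(network, theta)
  A <- network$reactant_order
  S <- network$net_stoich
  f <- function(M) {
    rates <- sapply(seq_len(nrow(A)), function(j) {
      r <- rep(k[j], nrow(M))
      for (i in which(A[j, ] > 0)) r <- r * M[, i]^A[j, i]
      r
    })
    if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1)
    rates %*% S
  }
  X <- as.matrix(X)
  nstep <- ceiling(tfinal / h)
  h <- tfinal / nstep
  for (s in seq_len(nstep)) {
    k1 <- f(X)
    k2 <- f(X + h / 2 * k1)
    k3 <- f(X + h / 2 * k2)
    k4 <- f(X + h * k3)
    X <- X + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  X
}

# Small TSS dataset for pipeline tests (kept little for speed).
small_tss <- function(scenario = "MEDIUM", n = 1000, time = 1.5, seed = 42) {
  generate_tss(scenario, n_cells = n, time = time, seed = seed)
}

rel_err <- function(a, b) {
  max(abs(a - b) / pmax(abs(b), 1e-12))
}
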