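test_that("split_cells partitions both snapshots at the requested fraction", {
  tss <- small_tss(n = 500, seed = 20)
  sp <- split_cells(tss$t0, tss$yt, est_frac = 0.2, seed = 1)
  expect_equal(nrow(sp$x0_est), 100)
  expect_equal(nrow(sp$x0_sel), 400)
  expect_equal(nrow(sp$y_est), 100)
  expect_equal(nrow(sp$y_sel), 400)
  # partition property: estimation + selection = all rows, no duplicates
  recon <- rbind(as.matrix(sp$x0_est), as.matrix(sp$x0_sel))
  expect_equal(recon[order(recon[, 1]), ],
               as.matrix(tss$t0)[order(as.matrix(tss$t0)[, 1]), ])
  expect_false(any(duplicated(sp$idx_x0)))
  # reproducible from the seed; sensitive to it
  sp2 <- split_cells(tss$t0, tss$yt, est_frac = 0.2, seed = 1)
  expect_identical(sp$idx_x0, sp2$idx_x0)
  expect_false(identical(sp$idx_x0,
                         split_cells(tss$t0, tss$yt, 0.2, seed = 2)$idx_x0))
})

test_that("halving ten cells gives five and five", {
  t0 <- sample_initial(10, seed = 1)
  yt <- sample_initial(10, seed = 2)
  expect_warning(sp <- split_cells(t0, yt, est_frac = 0.5, seed = 3),
                 "smaller than 100")
  expect_equal(nrow(sp$x0_est), 5)
  expect_equal(nrow(sp$x0_sel), 5)
})

test_that("too-small estimation splits error; fractions are validated", {
  t0 <- sample_initial(30, seed = 1)
  expect_error(split_cells(t0, t0, est_frac = 0.1, seed = 1), "5 cells")
  expect_error(split_cells(t0, t0, est_frac = 0, seed = 1), "between 0 and 1")
})

test_that("AICc penalty arithmetic is exact", {
  tss <- small_tss(n = 200, seed = 21)
  pred <- evolve_cells(tss$t0, nk_network(), nk_theta(), 1.5, 1e-6, 1e-6)
  raw <- aicc_mean_diff(tss$yt, pred, k_free = 3, penalty = "none")
  aic <- aicc_mean_diff(tss$yt, pred, k_free = 3, penalty = "aic")
  full <- aicc_mean_diff(tss$yt, pred, k_free = 3, penalty = "aicc")
  expect_equal(aic - raw, 6)                      # 2k
  expect_equal(full - raw, 6 + 2 * 3 * 4 / (6 - 3 - 1))  # 2k + 2k(k+1)/(n-k-1)
})

test_that("AICc log-likelihood matches a hand-computed toy", {
  y <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 2, 4, 4))
  x <- tibble::tibble(a = c(2, 3), b = c(1, 5))
  got <- aicc_mean_diff(y, x, k_free = 1, penalty = "none")
  d <- colMeans(y) - colMeans(x)          # (0, 0)
  v <- apply(y, 2, var) / 4 + apply(x, 2, var) / 2
  manual <- -2 * sum(dnorm(d, 0, sqrt(v), log = TRUE))
  expect_equal(got, manual)
  expect_equal(unname(d), c(0, 0))        # the toy is centred by construction
})

test_that("AICc refuses more free parameters than proteins allow", {
  tss <- small_tss(n = 120, seed = 22)
  expect_error(aicc_mean_diff(tss$yt, tss$t0, k_free = 5), "more proteins")
})

test_that("run_selection reports each candidate and the criterion minima", {
  tss <- small_tss("MEDIUM", n = 1000, seed = 23)
  cfg <- selection_config(starts = 2)
  rep <- run_selection(tss$t0, tss$yt, time = 1.5, seed = 3, config = cfg)
  td <- tidy(rep)
  expect_equal(td$candidate, c("h1", "h2", "h3"))
  expect_true(all(is.finite(td$ace)))
  expect_equal(rep$selected_by_ace, td$candidate[which.min(td$ace)])
  expect_equal(rep$selected_by_aicc, td$candidate[which.min(td$aicc)])
  g <- glance(rep)
  expect_equal(g$min_ace, min(td$ace))
  expect_equal(g$n_failed, 0)
})

test_that("duplicate candidates tie and break by free-parameter count then order", {
  tss <- small_tss("MEDIUM", n = 800, seed = 24)
  cands <- nk_candidates()
  dup <- list(h2 = cands$h2, h2_again = cands$h2, h3 = cands$h3)
  cfg <- selection_config(starts = 2)
  rep <- run_selection(tss$t0, tss$yt, candidates = dup, time = 1.5,
                       seed = 4, config = cfg)
  td <- tidy(rep)
  expect_equal(td$ace[td$candidate == "h2"], td$ace[td$candidate == "h2_again"])
  # exact tie between h2 and h2_again: registry order wins
  if (min(td$ace) == td$ace[1]) expect_equal(rep$selected_by_ace, "h2")
})

test_that("selection needs at least two candidates", {
  tss <- small_tss(n = 300, seed = 25)
  expect_error(run_selection(tss$t0, tss$yt,
                             candidates = nk_candidates()["h1"], time = 1.5),
               "at least 2")
})

test_that("bootstrap probabilities are frequencies that sum to one", {
  tss <- small_tss("MEDIUM", n = 700, seed = 26)
  cfg <- selection_config(starts = 2)
  bs <- bootstrap_selection(tss$t0, tss$yt, time = 1.5, B = 5, seed = 6,
                            config = cfg)
  expect_equal(sum(bs$probs$p_ace), 1, tolerance = 1e-12)
  expect_equal(sum(bs$probs$p_aicc), 1, tolerance = 1e-12)
  counts <- table(factor(bs$per_replicate$ace, levels = bs$probs$candidate))
  expect_equal(as.numeric(counts) / 5, bs$probs$p_ace)
  # deterministic given the seed
  bs2 <- bootstrap_selection(tss$t0, tss$yt, time = 1.5, B = 5, seed = 6,
                             config = cfg)
  expect_identical(bs$per_replicate$ace, bs2$per_replicate$ace)
})

test_that("a single bootstrap replicate yields a degenerate distribution", {
  tss <- small_tss("MEDIUM", n = 600, seed = 27)
  cfg <- selection_config(starts = 2)
  bs <- bootstrap_selection(tss$t0, tss$yt, time = 1.5, B = 1, seed = 7,
                            config = cfg)
  expect_equal(unname(sort(bs$probs$p_ace, decreasing = TRUE)), c(1, 0, 0))
  expect_equal(glance(bs)$B, 1)
})
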