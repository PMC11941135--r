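#' Split both snapshots into estimation and selection sets
#'
#' Partitions the rows of each snapshot independently into a small
#' estimation fraction (used to fit candidate rates by GMM) and the
#' complementary selection fraction (used to build and score the candidate
#' densities). The split-sample design avoids the optimism bias of selecting
#' on the same cells the parameters were tuned to.
#'
#' @param t0 Time-0 snapshot (cells x species).
#' @param yt Observed snapshot at the later time.
#' @param est_frac Estimation fraction in (0, 1); the study design uses 0.2.
#' @param seed Integer seed; the partition is reproducible from it.
#' @return List with `x0_est`, `x0_sel`, `y_est`, `y_sel` (tibbles) and the
#'   index vectors `idx_x0`, `idx_y` of the estimation rows.
#' @export
split_cells <- function(t0, yt, est_frac = 0.2, seed = 1L) {
  if (!is.numeric(est_frac) || est_frac <= 0 || est_frac >= 1) {
    abort("`est_frac` must be strictly between 0 and 1")
  }
  n0 <- nrow(t0)
  n1 <- nrow(yt)
  ne0 <- round(est_frac * n0)
  ne1 <- round(est_frac * n1)
  if (min(ne0, ne1) < 5) {
    abort("estimation split smaller than 5 cells; provide more data")
  }
  if (min(ne0, ne1) < 100) {
    warn("estimation split smaller than 100 cells; GMM moments will be noisy")
  }
  idx <- withr::with_seed(as.integer(seed), {
    list(x0 = sample.int(n0, ne0), y = sample.int(n1, ne1))
  })
  list(
    x0_est = as_tibble(t0[idx$x0, , drop = FALSE]),
    x0_sel = as_tibble(t0[-idx$x0, , drop = FALSE]),
    y_est = as_tibble(yt[idx$y, , drop = FALSE]),
    y_sel = as_tibble(yt[-idx$y, , drop = FALSE]),
    idx_x0 = idx$x0,
    idx_y = idx$y
  )
}

#' AICc from differences in snapshot means
#'
#' A complementary, likelihood-based criterion: the difference between the
#' observed and predicted mean abundance of each protein is treated as
#' normal with mean zero and variance `var(y_j)/N_y + var(x_j)/N_x`
#' (the variance of a difference of independent sample means, plugged in and
#' treated as known, independent across proteins). With `n` proteins and
#' `k` free rates, `AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)`. The sample
#' size in the correction is `n` = the number of mean differences (6 here),
#' so `k` must stay below `n - 1`.
#'
#' @param observed_y Observed selection-split cells at time t.
#' @param predicted_x Model-predicted cells at time t (evolved initial
#'   cells).
#' @param k_free Number of freely varying rates of the candidate.
#' @param penalty `"aicc"` (default), `"aic"` (no small-sample correction),
#'   or `"none"` (raw -2 logL).
#' @return Single number (smaller is better).
#' @export
aicc_mean_diff <- function(observed_y, predicted_x, k_free,
                           penalty = c("aicc", "aic", "none")) {
  penalty <- match.arg(penalty)
  Y <- as.matrix(as.data.frame(observed_y))
  X <- as.matrix(as.data.frame(predicted_x))
  if (nrow(Y) < 2 || nrow(X) < 2) abort("both datasets need at least 2 cells")
  if (ncol(Y) != ncol(X)) abort("observed and predicted column mismatch")
  n <- ncol(Y)
  if (penalty == "aicc" && n - k_free - 1 <= 0) {
    abort(sprintf(paste0(
      "AICc correction undefined: need more proteins than free parameters ",
      "plus one (n = %d proteins, k = %d free rates)"), n, k_free))
  }
  d <- colMeans(Y) - colMeans(X)
  v <- apply(Y, 2, var) / nrow(Y) + apply(X, 2, var) / nrow(X)
  log_lik <- sum(dnorm(d, 0, sqrt(v), log = TRUE))
  pen <- switch(penalty,
    aicc = 2 * k_free + 2 * k_free * (k_free + 1) / (n - k_free - 1),
    aic = 2 * k_free,
    none = 0
  )
  -2 * log_lik + pen
}

#' Run the full model-selection pipeline on one TSS dataset
#'
#' For every candidate: (1) estimate its rates by GMM on the estimation
#' split; (2) evolve the selection-split initial cells under the fitted
#' rates; (3) fit the kernel-marginal Gaussian-copula density to those
#' predictions; (4) score the approximate cross-entropy (ACE) of the
#' held-out observed cells and the mean-difference AICc. The selected model
#' minimizes each criterion; ties go to the candidate with fewer free
#' parameters, then registry order.
#'
#' @param t0,yt Time-0 and time-t snapshots (cells x species).
#' @param candidates Named list of [candidate_model()]s (>= 2).
#' @param time Observation time of `yt`, seconds.
#' @param seed Seed for the estimation/selection split.
#' @param config A [selection_config()].
#' @param warm Optional named list mapping candidate ids to free-parameter
#'   warm starts (bootstrap replicates pass the base fit).
#' @return Object of class `selection_report`: `results` (one tibble row
#'   per candidate: rates, cost, ace, aicc, diagnostics), `selected_by_ace`,
#'   `selected_by_aicc`, `split_seed`. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
run_selection <- function(t0, yt, candidates = nk_candidates(), time = 1.5,
                          seed = 1L, config = selection_config(),
                          warm = NULL) {
  if (length(candidates) < 2) abort("need at least 2 candidate models")
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, function(c) c$id, character(1))
  }
  sp <- split_cells(t0, yt, est_frac = config$est_frac,
                    seed = child_seed(seed, 101L))

  rows <- purrr::imap(candidates, function(cand, id) {
    w <- warm[[id]]
    res <- tryCatch({
      fit <- fit_gmm(
        cand, sp$x0_est, sp$y_est, time,
        weighting = config$weighting, moment_set = config$moment_set,
        starts = if (is.null(w)) config$starts else config$warm_starts,
        seed = child_seed(seed, 202L),
        init = if (is.list(w)) w$init else w,
        frozen_jacobian = if (is.list(w)) w$jac else NULL,
        rtol = config$ode_rtol, atol = config$ode_atol,
        max_iter = config$max_iter,
        return_jacobian = is.null(w) && config$refit == "frozen"
      )
      x0_dens <- if (config$density_split == "selection") sp$x0_sel else sp$x0_est
      pred <- evolve_unique(as_species_matrix(x0_dens, cand$network$species),
                            cand$network, bind_rates(cand$network, fit$theta),
                            time, config$ode_rtol, config$ode_atol)
      dens <- fit_copula(pred, bw_mult = config$bw_mult, ngrid = config$ngrid,
                         shrink = config$shrink, eig_floor = config$eig_floor)
      a <- ace(dens, sp$y_sel)
      list(
        fit = fit,
        ace = as.numeric(a),
        floor_events = attr(a, "floor_events"),
        aicc = aicc_mean_diff(sp$y_sel, pred, length(cand$free),
                              penalty = config$aicc_penalty)
      )
    }, error = function(e) e)

    if (inherits(res, "error")) {
      warn(sprintf("candidate %s failed: %s", id, conditionMessage(res)))
      return(tibble(candidate = id, k_free = length(cand$free),
                    failed = TRUE, theta = list(NULL), cost = NA_real_,
                    converged = NA, ace = NA_real_, aicc = NA_real_,
                    floor_events = NA_integer_, jacobian = list(NULL)))
    }
    tibble(
      candidate = id,
      k_free = length(cand$free),
      failed = FALSE,
      theta = list(res$fit$theta),
      cost = res$fit$cost,
      converged = res$fit$converged,
      ace = res$ace,
      aicc = res$aicc,
      floor_events = res$floor_events,
      jacobian = list(res$fit$jacobian)
    )
  })
  results <- list_rbind(rows)

  ok <- results[!results$failed, ]
  if (nrow(ok) < 2) abort("fewer than 2 candidates completed; cannot select")

  pick <- function(crit) {
    v <- ok[[crit]]
    best <- which(v <= min(v) + 0)
    if (length(best) > 1) best <- best[order(ok$k_free[best])]
    ok$candidate[best[1]]
  }

  structure(
    list(
      results = results,
      selected_by_ace = pick("ace"),
      selected_by_aicc = pick("aicc"),
      split_seed = as.integer(seed),
      time = time,
      config = config
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> ACE selects %s; AICc selects %s\n",
              x$selected_by_ace, x$selected_by_aicc))
  print(tidy(x))
  invisible(x)
}

#' @rdname run_selection
#' @param x A `selection_report`.
#' @param ... Unused.
#' @export
tidy.selection_report <- function(x, ...) {
  res <- x$results
  th <- purrr::map(res$theta, function(t) {
    if (is.null(t)) {
      tibble(theta1 = NA_real_, theta2 = NA_real_, theta3 = NA_real_)
    } else {
      as_tibble(as.list(t))
    }
  })
  dplyr::bind_cols(
    res[, c("candidate", "k_free")],
    list_rbind(th),
    res[, c("cost", "ace", "aicc", "converged")]
  )
}

#' @rdname run_selection
#' @export
glance.selection_report <- function(x, ...) {
  ok <- x$results[!x$results$failed, ]
  tibble(
    selected_by_ace = x$selected_by_ace,
    selected_by_aicc = x$selected_by_aicc,
    min_ace = min(ok$ace),
    min_aicc = min(ok$aicc),
    n_candidates = nrow(x$results),
    n_failed = sum(x$results$failed),
    split_seed = x$split_seed
  )
}
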