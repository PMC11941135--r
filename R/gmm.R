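#' Weighted moment-matching (GMM) cost
#'
#' The generalized-method-of-moments cost for a candidate model: the
#' quadratic form `d' W d`, where `d` is the difference between the moment
#' vector of the observed time-`time` snapshot and the moment vector of the
#' model's prediction (the time-0 cells evolved under
#' `expand_theta(candidate, theta_free)`).
#'
#' `W` defaults to diagonal inverse-variance weighting: each moment is
#' divided by the per-cell standard deviation of its moment function,
#' estimated once from the observed snapshot. This is the diagonal
#' approximation to the efficient GMM weighting; it keeps near-zero, heavily
#' skewed abundances (free Syk and free SHP1 at later times) from dominating
#' the fit through their noisy second moments, which is exactly the failure
#' mode of naive relative weighting on this system.
#'
#' @param theta_free Free-parameter values for `candidate`.
#' @param candidate A [candidate_model()].
#' @param x0 Time-0 snapshot (cells x species data frame).
#' @param y Observed snapshot at `time`.
#' @param time Observation time, seconds.
#' @param weighting `"variance"` (default), `"relative"`, `"identity"`, or a
#'   positive-definite weight matrix / positive diagonal vector matching the
#'   moment set.
#' @param moment_set `"marginal"` (12 moments: means and per-protein raw
#'   second moments, the default) or `"full"` (adds cross moments).
#' @param rtol,atol Integration tolerances used inside the cost.
#' @return A single non-negative number.
#' @export
gmm_cost <- function(theta_free, candidate, x0, y, time,
                     weighting = "variance", moment_set = "marginal",
                     rtol = 1e-6, atol = 1e-6) {
  ctx <- gmm_context(candidate, x0, y, weighting, moment_set, time,
                     rtol, atol)
  sum(ctx$residuals(log(as.numeric(theta_free)))^2)
}

# Shared setup for gmm_cost / fit_gmm: precomputes observed moments, weights
# (as sqrt-weight residual scaling), and a residual closure over log-theta.
gmm_context <- function(candidate, x0, y, weighting, moment_set, time,
                        rtol, atol) {
  stopifnot(inherits(candidate, "candidate_model"))
  net <- candidate$network
  X0 <- as_species_matrix(x0, net$species)
  Y <- as_species_matrix(y, net$species)
  obs <- moment_vector(as.data.frame(Y), set = moment_set, network = net)
  pairs <- if (moment_set == "closure") reactant_pairs(net)

  if (is.character(weighting)) {
    w <- moment_weights(obs, weighting)
    sqw <- sqrt(w)
    to_res <- function(d) sqw * d
  } else if (is.matrix(weighting)) {
    if (!isTRUE(all.equal(weighting, t(weighting)))) {
      abort("weight matrix must be symmetric positive definite")
    }
    L <- tryCatch(chol(weighting),
                  error = function(e) abort("weight matrix must be symmetric positive definite"))
    to_res <- function(d) L %*% d
  } else {
    w <- as.numeric(weighting)
    if (length(w) != nrow(obs) || any(w <= 0)) {
      abort(sprintf("diagonal weights must be %d positive values", nrow(obs)))
    }
    sqw <- sqrt(w)
    to_res <- function(d) sqw * d
  }

  # unique initial rows: bootstrap resamples repeat cells, and the moment
  # average over repeats equals the count-weighted average over uniques
  key0 <- do.call(paste, c(as.data.frame(X0), sep = "\r"))
  ui <- which(!duplicated(key0))
  X0u <- X0[ui, , drop = FALSE]
  cnt <- tabulate(match(key0, key0[ui]), nbins = length(ui))
  pred <- function(log_theta) {
    th <- expand_theta(candidate, exp(log_theta))
    k <- bind_rates(net, th)
    # cap integrator effort: optimizer proposals at extreme rates would
    # otherwise crawl through stiff regimes; a capped failure is caught and
    # backtracked by the optimizer
    P <- evolve_cells_cpp(X0u, net$reactant_order, net$net_stoich, k,
                          time, rtol, atol, "dopri5", 8000)
    as.numeric(crossprod(cnt, moment_functions(P, moment_set, pairs))) /
      nrow(X0)
  }
  residuals <- function(log_theta) {
    p <- tryCatch(pred(log_theta), error = function(e) NULL)
    if (is.null(p)) {
      # capped/failed integration at an extreme proposal: return a large
      # finite residual so the optimizer retreats instead of aborting
      return(rep(1e6, nrow(obs)))
    }
    as.numeric(to_res(p - obs$value))
  }
  list(residuals = residuals, pred = pred, to_res = to_res, obs = obs,
       k_free = length(candidate$free))
}

# Forward-difference Jacobian of the unweighted predicted moments with
# respect to log-theta (columns = free parameters).
moment_jacobian <- function(ctx, log_theta, delta = 1e-3) {
  p0 <- ctx$pred(log_theta)
  J <- vapply(seq_along(log_theta), function(i) {
    lt <- log_theta
    lt[i] <- lt[i] + delta
    (ctx$pred(lt) - p0) / delta
  }, numeric(length(p0)))
  list(jac = matrix(J, ncol = length(log_theta)), pred0 = p0)
}

# Damped Gauss-Newton refit with a frozen moment Jacobian: used for
# bootstrap replicate refits, where the optimizer starts at the base-data
# estimate and the Jacobian changes negligibly between replicates. Each
# iteration costs a single ensemble evolution.
fit_gmm_frozen <- function(ctx, init_log, jac, max_iter = 3, tol = 1e-4) {
  Jw <- apply(jac, 2, function(col) as.numeric(ctx$to_res(col)))
  Jw <- matrix(Jw, ncol = ncol(jac))
  JtJ <- crossprod(Jw)
  damp <- diag(1e-8 * pmax(diag(JtJ), 1e-12), nrow(JtJ))
  lt <- init_log
  r <- ctx$residuals(lt)
  it <- 0L
  for (it in seq_len(max_iter)) {
    step <- as.numeric(solve(JtJ + damp, -crossprod(Jw, r)))
    # cap the log-rate move per iteration; the cost surface has flat ridges
    # along which an unclamped Gauss-Newton step can jump to absurd rates
    # (which also grind the integrator: stiffness scales with the rates)
    big <- max(abs(step))
    if (big > 0.5) step <- step * (0.5 / big)
    ok <- FALSE
    for (half in 1:4) {
      cand <- pmin(pmax(lt + step, log(1e-3)), log(10))
      r_new <- tryCatch(ctx$residuals(cand), error = function(e) NULL)
      if (!is.null(r_new) && sum(r_new^2) <= sum(r^2) * (1 + 1e-9)) {
        ok <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok) break
    lt <- cand
    r <- r_new
    if (max(abs(step)) < tol) break
  }
  list(par = lt, cost = sum(r^2), iter = it)
}

#' Fit a candidate model by the generalized method of moments
#'
#' Minimizes the weighted moment-matching cost over the candidate's free
#' rates with multi-start Levenberg-Marquardt in log-parameter space (which
#' enforces positivity). Start 1 is the log-box center (0.1/s for every free
#' rate); further starts are log-uniform draws from `start_box`.
#'
#' @inheritParams gmm_cost
#' @param starts Number of optimizer starts (>= 1).
#' @param seed Seed for the random starts.
#' @param start_box Positive length-2 vector: the log-uniform start range in
#'   1/s.
#' @param init Optional warm-start value for the free parameters (used as
#'   start 1 instead of the box center; bootstrap refits pass the base-data
#'   estimate here).
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @param frozen_jacobian Optional moment Jacobian (from a previous
#'   `return_jacobian = TRUE` fit on near-identical data). Together with
#'   `init` this switches to damped Gauss-Newton refitting with the frozen
#'   Jacobian -- the iterated one-step refit used inside bootstrap
#'   replicates, where each iteration costs one ensemble evolution.
#' @param return_jacobian If `TRUE`, attach the finite-difference Jacobian
#'   of the predicted moments at the optimum (`$jacobian`), for reuse as
#'   `frozen_jacobian`.
#' @return An object of class `gmm_fit`: estimates (free and expanded),
#'   attained cost, convergence flag, per-start diagnostics. Has [tidy()]
#'   and [glance()] methods.
#' @examples
#' \donttest{
#' tss <- generate_tss("MEDIUM", n_cells = 1000, time = 1.5, seed = 1)
#' fit <- fit_gmm(nk_candidates()$h2, tss$t0, tss$yt, time = 1.5, starts = 2)
#' tidy(fit)
#' }
#' @export
fit_gmm <- function(candidate, x0, y, time,
                    weighting = "variance", moment_set = "marginal",
                    starts = 3, seed = 1L, start_box = c(1e-3, 10),
                    init = NULL, rtol = 1e-6, atol = 1e-6,
                    max_iter = 40, frozen_jacobian = NULL,
                    return_jacobian = FALSE) {
  if (starts < 1) abort("`starts` must be at least 1")
  ctx <- gmm_context(candidate, x0, y, weighting, moment_set, time,
                     rtol, atol)
  kf <- ctx$k_free

  if (!is.null(frozen_jacobian)) {
    if (is.null(init)) abort("`frozen_jacobian` requires an `init` value")
    gn <- fit_gmm_frozen(ctx, log(as.numeric(init)), frozen_jacobian)
    theta_free <- setNames(exp(gn$par), candidate$free)
    return(structure(
      list(candidate_id = candidate$id, theta_free = theta_free,
           theta = expand_theta(candidate, theta_free), cost = gn$cost,
           converged = TRUE, n_starts_used = 1L, n_starts_failed = 0L,
           weighting = if (is.character(weighting)) weighting else "custom",
           moment_set = moment_set, time = time,
           starts = list(list(ok = TRUE, cost = gn$cost,
                              message = sprintf("frozen-Jacobian refit, %d iteration(s)",
                                                gn$iter)))),
      class = "gmm_fit"
    ))
  }

  start_mat <- withr::with_seed(as.integer(seed), {
    rand <- matrix(runif((starts - 1) * kf, log(start_box[1]),
                         log(start_box[2])), ncol = kf)
    first <- if (is.null(init)) rep(log(0.1), kf) else log(as.numeric(init))
    rbind(matrix(first, nrow = 1), rand)
  })

  ctrl <- minpack.lm::nls.lm.control(
    ftol = 1e-9, ptol = 1e-9, epsfcn = 1e-6, maxiter = max_iter)
  runs <- purrr::map(seq_len(starts), function(s) {
    tryCatch({
      f <- minpack.lm::nls.lm(par = start_mat[s, ], fn = ctx$residuals,
                              lower = rep(log(1e-4), kf),
                              upper = rep(log(30), kf),
                              control = ctrl)
      list(ok = TRUE, par = f$par, cost = f$deviance, info = f$info,
           message = f$message, niter = f$niter)
    }, error = function(e) list(ok = FALSE, message = conditionMessage(e)))
  })

  ok <- vapply(runs, function(r) isTRUE(r$ok), logical(1))
  if (!any(ok)) {
    msgs <- vapply(seq_along(runs), function(i) {
      sprintf("start %d: %s", i, runs[[i]]$message)
    }, character(1))
    abort(c("all optimizer starts failed", msgs))
  }
  costs <- vapply(runs, function(r) if (isTRUE(r$ok)) r$cost else Inf,
                  numeric(1))
  # tie-break: lowest cost, then lowest theta1
  best_cost <- min(costs)
  cand_idx <- which(costs <= best_cost * (1 + 1e-12))
  if (length(cand_idx) > 1) {
    th1 <- vapply(cand_idx, function(i) runs[[i]]$par[1], numeric(1))
    cand_idx <- cand_idx[order(th1)]
  }
  best <- runs[[cand_idx[1]]]

  theta_free <- setNames(exp(best$par), candidate$free)
  jac <- if (return_jacobian) moment_jacobian(ctx, best$par)$jac else NULL
  structure(
    list(
      candidate_id = candidate$id,
      theta_free = theta_free,
      theta = expand_theta(candidate, theta_free),
      cost = best$cost,
      converged = best$info %in% 1:4,
      n_starts_used = starts,
      n_starts_failed = sum(!ok),
      weighting = if (is.character(weighting)) weighting else "custom",
      moment_set = moment_set,
      time = time,
      jacobian = jac,
      starts = purrr::map(runs, function(r) r[c("ok", "cost", "message")])
    ),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> candidate %s  cost %.5g  (%s weighting%s)\n",
              x$candidate_id, x$cost, x$weighting,
              if (x$converged) "" else ", NOT converged"))
  cat("  theta:", paste(sprintf("%s=%.4g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_gmm
#' @param x A `gmm_fit`.
#' @param ... Unused.
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble(
    candidate = x$candidate_id,
    term = names(x$theta),
    estimate = unname(x$theta),
    free = names(x$theta) %in% names(x$theta_free)
  )
}

#' @rdname fit_gmm
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(
    candidate = x$candidate_id,
    cost = x$cost,
    k_free = length(x$theta_free),
    converged = x$converged,
    n_starts_used = x$n_starts_used
  )
}
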