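#' First and raw second moments of a snapshot
#'
#' The moment vector stacks the 6 column means and the 21 distinct raw
#' second moments `E[x_j x_k]` (upper triangle, row-major: (1,1), (1,2),
#' ..., (1,6), (2,2), ..., (6,6)). Cross-moments are included because the
#' multivariate density comparison downstream benefits from dependence
#' information, not just marginals; `set = "marginal"` restricts to means
#' plus the 6 squared-abundance moments.
#'
#' @param data Cells-by-species data frame with at least 2 rows.
#' @param set `"full"` (27 moments, default), `"marginal"` (12 moments), or
#'   `"closure"` (marginal plus the reactant-pair cross moments of
#'   `network`, i.e. the moment functions appearing in the expected
#'   mass-action rate equations).
#' @param network A [reaction_network()], required for `set = "closure"`.
#' @return Tibble with columns `moment` (label), `value`, and `sd_cell`
#'   (per-cell standard deviation of the moment function, the basis for
#'   inverse-variance weighting).
#' @examples
#' moment_vector(tibble::tibble(a = c(1, 3)), set = "marginal")
#' @export
moment_vector <- function(data, set = c("full", "marginal", "closure"),
                          network = NULL) {
  set <- match.arg(set)
  X <- as.matrix(as.data.frame(data))
  if (nrow(X) < 2) abort("moment estimation needs at least 2 cells")
  storage.mode(X) <- "double"
  pairs <- if (set == "closure") {
    if (is.null(network)) abort("`closure` moments need a `network`")
    reactant_pairs(network)
  }
  Phi <- moment_functions(X, set, pairs)
  tibble(
    moment = colnames(Phi),
    value = unname(colMeans(Phi)),
    sd_cell = unname(apply(Phi, 2, sd))
  )
}

# Per-cell moment functions: columns x_j then distinct products x_j x_k.
# "closure" takes the self-products plus the supplied reactant pairs: the
# cross moments that actually enter the expected mass-action dynamics.
moment_functions <- function(X, set = "full", pairs_extra = NULL) {
  ns <- ncol(X)
  nms <- colnames(X) %||% paste0("x", seq_len(ns))
  pairs <- switch(set,
    full = which(upper.tri(diag(ns), diag = TRUE), arr.ind = TRUE),
    marginal = cbind(seq_len(ns), seq_len(ns)),
    closure = rbind(cbind(seq_len(ns), seq_len(ns)), pairs_extra),
    abort(sprintf("unknown moment set '%s'", set))
  )
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  P <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  colnames(P) <- paste0("m2_", nms[pairs[, 1]], ".", nms[pairs[, 2]])
  Phi <- cbind(X, P)
  colnames(Phi) <- c(paste0("m1_", nms), colnames(P))
  Phi
}

# Distinct reactant pairs (i < j) of the network's bimolecular reactions:
# the cross moments whose expectations drive the mean mass-action dynamics.
reactant_pairs <- function(network) {
  A <- network$reactant_order
  out <- NULL
  for (r in seq_len(nrow(A))) {
    idx <- which(A[r, ] > 0)
    if (length(idx) == 2) out <- rbind(out, sort(idx))
  }
  if (is.null(out)) return(NULL)
  unique(out)
}

# Diagonal GMM weights from the observed estimation snapshot.
# "variance": 1 / per-cell variance of each moment function (default;
#   diagonal approximation to the efficient weighting),
# "relative": 1 / observed moment^2,
# "identity": all ones.
moment_weights <- function(obs, weighting = c("variance", "relative", "identity")) {
  weighting <- match.arg(weighting)
  if (weighting == "variance" && any(obs$sd_cell <= 0)) {
    abort(sprintf("moment '%s' has zero spread across cells; cannot use inverse-variance weights",
                  obs$moment[which(obs$sd_cell <= 0)[1]]))
  }
  w <- switch(weighting,
    variance = 1 / pmax(obs$sd_cell^2, 1e-300),
    relative = 1 / pmax(obs$value^2, 1e-300),
    identity = rep(1, nrow(obs))
  )
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort("weights must be positive and finite; a moment has zero spread")
  }
  w
}
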