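#' Candidate model: a network plus rate constraints
#'
#' A candidate model fixes which of the symbolic rates vary freely and how
#' the constrained rates derive from the free ones. Estimation happens in
#' the free-parameter space; [expand_theta()] maps free values to the full
#' rate vector.
#'
#' @param id Candidate identifier (e.g. `"h2"`).
#' @param free Character vector of freely varying rate symbols.
#' @param constraints Named list mapping each constrained symbol to a
#'   function of the named free-parameter vector, e.g.
#'   `list(theta2 = function(th) 9 * th[["theta1"]])`.
#' @param network A [reaction_network()].
#' @return An object of class `candidate_model`.
#' @export
candidate_model <- function(id, free, constraints = list(),
                            network = nk_network()) {
  stopifnot(inherits(network, "reaction_network"))
  syms <- unique(stats::na.omit(network$rate_symbols))
  if (!all(free %in% syms)) {
    abort(sprintf("free parameters must be among network rate symbols: %s",
                  paste(syms, collapse = ", ")))
  }
  uncovered <- setdiff(syms, c(free, names(constraints)))
  if (length(uncovered) > 0) {
    abort(sprintf("rate symbol(s) neither free nor constrained: %s",
                  paste(uncovered, collapse = ", ")))
  }
  structure(
    list(id = id, free = free, constraints = constraints, network = network),
    class = "candidate_model"
  )
}

#' @export
print.candidate_model <- function(x, ...) {
  cat(sprintf("<candidate_model> %s: free (%s), %d constraint(s)\n",
              x$id, paste(x$free, collapse = ", "), length(x$constraints)))
  invisible(x)
}

#' Expand free parameters to the full rate vector
#'
#' @param candidate A [candidate_model()].
#' @param theta_free Numeric vector of free parameter values, in
#'   `candidate$free` order (names optional).
#' @return Named numeric vector covering every rate symbol of the network.
#' @export
expand_theta <- function(candidate, theta_free) {
  stopifnot(inherits(candidate, "candidate_model"))
  if (length(theta_free) != length(candidate$free)) {
    abort(sprintf("candidate %s has %d free parameter(s), got %d values",
                  candidate$id, length(candidate$free), length(theta_free)))
  }
  th <- setNames(as.numeric(theta_free), candidate$free)
  for (sym in names(candidate$constraints)) {
    th[[sym]] <- candidate$constraints[[sym]](th)
  }
  th
}

#' The nested candidate registry h1, h2, h3
#'
#' Three nested parameterizations of the same network:
#' \describe{
#'   \item{h1}{only `theta1` free; `theta2 = 9 * theta1`, `theta3 = 2 * theta1`.}
#'   \item{h2}{`theta1`, `theta3` free; `theta2 = 9 * theta1`.}
#'   \item{h3}{all of `theta1`, `theta2`, `theta3` free.}
#' }
#' Nesting (h1 within h2 within h3) means the attained moment-matching cost
#' can only decrease with complexity; the selection criteria are what
#' penalize the extra freedom.
#'
#' @param network A [reaction_network()] shared by all three candidates.
#' @return Named list of [candidate_model()] objects.
#' @export
nk_candidates <- function(network = nk_network()) {
  list(
    h1 = candidate_model(
      "h1", free = "theta1",
      constraints = list(
        theta2 = function(th) 9 * th[["theta1"]],
        theta3 = function(th) 2 * th[["theta1"]]
      ),
      network = network
    ),
    h2 = candidate_model(
      "h2", free = c("theta1", "theta3"),
      constraints = list(theta2 = function(th) 9 * th[["theta1"]]),
      network = network
    ),
    h3 = candidate_model(
      "h3", free = c("theta1", "theta2", "theta3"),
      network = network
    )
  )
}
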