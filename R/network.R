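#' Declare a mass-action reaction network
#'
#' A reaction network is a declarative object: a species vector plus a table
#' of reactions, each given by reactant and product multisets and either a
#' fixed rate constant or a rate symbol (`theta1`, `theta2`, ...) to be bound
#' at simulation/fitting time. Propensities follow deterministic mass-action
#' kinetics on copy numbers: rate times the product of reactant abundances
#' (no volume factor; all rates are in 1/s).
#'
#' @param species Character vector of species names (canonical column order
#'   for all snapshot data).
#' @param reactions A list of reactions. Each reaction is a list with
#'   elements `reactants` and `products` (character vectors, possibly with
#'   repeats, naming species) and `rate` (a single number for a fixed rate,
#'   or a character symbol such as `"theta1"` for a free/constrained rate).
#'
#' @return An object of class `reaction_network` with elements `species`,
#'   `reactions` (tibble), `reactant_order` and `net_stoich` (reaction-by-
#'   species integer matrices), and `rate_symbols`.
#' @seealso [nk_network()] for the built-in six-species network,
#'   [read_network()] / [write_network()] for the YAML representation.
#' @export
reaction_network <- function(species, reactions) {
  if (length(species) < 1 || anyDuplicated(species) > 0) {
    abort("`species` must be a non-empty vector of unique names")
  }
  rows <- purrr::imap(reactions, function(rx, j) {
    for (side in c("reactants", "products")) {
      bad <- setdiff(rx[[side]], species)
      if (length(bad) > 0) {
        abort(sprintf("reaction %d names unknown species: %s",
                      j, paste(bad, collapse = ", ")))
      }
    }
    tibble(
      reaction  = j,
      reactants = list(as.character(rx$reactants)),
      products  = list(as.character(rx$products)),
      rate      = list(rx$rate)
    )
  })
  reactions_tbl <- list_rbind(rows)

  nr <- nrow(reactions_tbl)
  ns <- length(species)
  A <- matrix(0L, nr, ns, dimnames = list(NULL, species))
  S <- matrix(0, nr, ns, dimnames = list(NULL, species))
  for (j in seq_len(nr)) {
    rt <- table(factor(reactions_tbl$reactants[[j]], levels = species))
    pt <- table(factor(reactions_tbl$products[[j]], levels = species))
    A[j, ] <- as.integer(rt)
    S[j, ] <- as.numeric(pt) - as.numeric(rt)
    if (any(A[j, ] > 2L)) {
      abort(sprintf("reaction %d has an order-3+ reactant; mass action here supports order <= 2", j))
    }
  }
  syms <- vapply(reactions_tbl$rate, function(r) {
    if (is.character(r)) r else NA_character_
  }, character(1))

  structure(
    list(
      species = as.character(species),
      reactions = reactions_tbl,
      reactant_order = A,
      net_stoich = S,
      rate_symbols = syms
    ),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions\n",
              length(x$species), nrow(x$reactions)))
  cat("species:", paste(x$species, collapse = ", "), "\n")
  for (j in seq_len(nrow(x$reactions))) {
    r <- x$reactions[j, ]
    rate <- r$rate[[1]]
    cat(sprintf("  R%d: %s -> %s  @ %s\n", j,
                paste(r$reactants[[1]], collapse = " + "),
                paste(r$products[[1]], collapse = " + "),
                if (is.character(rate)) rate else format(rate)))
  }
  invisible(x)
}

#' The six-species NK-cell signaling network
#'
#' The default network couples Syk-mediated phosphorylation of Vav1 with
#' SHP1-mediated dephosphorylation:
#' \describe{
#'   \item{R1}{Syk + Vav1 -> Syk.Vav1, rate `theta1` (binding)}
#'   \item{R2}{Syk.Vav1 -> Syk + Vav1, fixed 0.12/s (unbinding)}
#'   \item{R3}{Syk.Vav1 -> Syk + pVav1, rate `theta2` (phosphorylation)}
#'   \item{R4}{SHP1 + pVav1 -> SHP1.pVav1, rate `theta3` (binding)}
#'   \item{R5}{SHP1.pVav1 -> SHP1 + pVav1, fixed 0.14/s (unbinding)}
#'   \item{R6}{SHP1.pVav1 -> SHP1 + Vav1, fixed 0.05/s (dephosphorylation)}
#' }
#'
#' The published description of this system is a network diagram that names
#' the species and the three fixed rates (0.12, 0.14, 0.05 per second) but
#' not the reaction list; the wiring above is this package's reconstruction
#' of the canonical kinase/phosphatase motif for those species, and it is
#' deliberately a data object: pass a different [reaction_network()] anywhere
#' this one is accepted to swap the topology without touching code.
#'
#' Species order (canonical column order for all datasets):
#' Syk, Vav1, Syk.Vav1, pVav1, SHP1, SHP1.pVav1.
#'
#' @return A [reaction_network()].
#' @export
nk_network <- function() {
  reaction_network(
    species = c("Syk", "Vav1", "Syk.Vav1", "pVav1", "SHP1", "SHP1.pVav1"),
    reactions = list(
      list(reactants = c("Syk", "Vav1"), products = "Syk.Vav1", rate = "theta1"),
      list(reactants = "Syk.Vav1", products = c("Syk", "Vav1"), rate = 0.12),
      list(reactants = "Syk.Vav1", products = c("Syk", "pVav1"), rate = "theta2"),
      list(reactants = c("SHP1", "pVav1"), products = "SHP1.pVav1", rate = "theta3"),
      list(reactants = "SHP1.pVav1", products = c("SHP1", "pVav1"), rate = 0.14),
      list(reactants = "SHP1.pVav1", products = c("SHP1", "Vav1"), rate = 0.05)
    )
  )
}

#' Bind numeric rates to a network's rate symbols
#'
#' @param network A [reaction_network()].
#' @param theta Named numeric vector supplying every rate symbol used by the
#'   network (e.g. `c(theta1 = 0.1, theta2 = 0.9, theta3 = 0.18)`).
#' @return Numeric vector of per-reaction rate constants.
#' @export
bind_rates <- function(network, theta) {
  stopifnot(inherits(network, "reaction_network"))
  syms <- network$rate_symbols
  k <- numeric(length(syms))
  for (j in seq_along(syms)) {
    if (is.na(syms[j])) {
      k[j] <- network$reactions$rate[[j]]
    } else {
      if (!syms[j] %in% names(theta)) {
        abort(sprintf("rate symbol '%s' (reaction %d) is not bound by `theta`",
                      syms[j], j))
      }
      k[j] <- theta[[syms[j]]]
    }
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    abort("all reaction rates must be finite and > 0")
  }
  k
}

#' Mass-action time derivatives
#'
#' Evaluates the deterministic mass-action right-hand side for one state
#' vector. Mainly useful for inspection and testing; bulk integration goes
#' through [evolve_cells()].
#'
#' @param state Numeric vector of species abundances, in network species
#'   order.
#' @inheritParams bind_rates
#' @return Named numeric vector of time derivatives (copies per second).
#' @export
mass_action_rhs <- function(state, network, theta) {
  stopifnot(inherits(network, "reaction_network"))
  if (length(state) != length(network$species)) {
    abort(sprintf("state has %d entries but the network defines %d species",
                  length(state), length(network$species)))
  }
  k <- bind_rates(network, theta)
  out <- mass_action_rhs_cpp(as.numeric(state), network$reactant_order,
                             network$net_stoich, k)
  setNames(out, network$species)
}

#' Conservation laws of a network
#'
#' Returns a basis for the left null space of the stoichiometry matrix:
#' vectors `v` such that `v %*% d(state)/dt == 0` along every trajectory.
#' For the built-in NK network these are the total Syk, total Vav1, and total
#' SHP1 pools.
#'
#' @inheritParams bind_rates
#' @return A matrix with one row per conservation law and one column per
#'   species (possibly zero rows).
#' @export
conservation_laws <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  S <- network$net_stoich # reactions x species; want v with S %*% v = 0
  ns <- ncol(S)
  qr_S <- qr(t(S))
  rank <- qr_S$rank
  if (rank == ns) {
    return(matrix(0, 0, ns, dimnames = list(NULL, network$species)))
  }
  # null space of t(v) S^T = 0  <=>  columns rank+1..ns of Q
  Q <- qr.Q(qr_S, complete = TRUE)
  V <- t(Q[, (rank + 1):ns, drop = FALSE])
  colnames(V) <- network$species
  # tidy up: scale so the largest entry is 1 and near-zeros vanish
  V <- t(apply(V, 1, function(v) {
    v[abs(v) < 1e-10] <- 0
    v / v[which.max(abs(v))]
  }))
  colnames(V) <- network$species
  V
}

#' Read / write a reaction network as YAML
#'
#' The YAML layout mirrors [reaction_network()]: a `species` list and a
#' `reactions` list whose entries have `reactants`, `products`, and `rate`
#' (number = fixed, string = rate symbol).
#'
#' @param path File path.
#' @return `read_network()` returns a [reaction_network()];
#'   `write_network()` invisibly returns `path`.
#' @export
read_network <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$species) || is.null(doc$reactions)) {
    abort("network YAML needs top-level 'species' and 'reactions'")
  }
  reactions <- purrr::map(doc$reactions, function(rx) {
    list(
      reactants = unlist(rx$reactants) %||% character(),
      products = unlist(rx$products) %||% character(),
      rate = if (is.character(rx$rate)) rx$rate else as.numeric(rx$rate)
    )
  })
  reaction_network(unlist(doc$species), reactions)
}

#' @rdname read_network
#' @param network A [reaction_network()].
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  doc <- list(
    species = as.list(network$species),
    reactions = purrr::map(seq_len(nrow(network$reactions)), function(j) {
      list(
        reactants = as.list(network$reactions$reactants[[j]]),
        products = as.list(network$reactions$products[[j]]),
        rate = network$reactions$rate[[j]]
      )
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
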