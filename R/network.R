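#' Mass-action reaction networks
#'
#' A `reaction_network` bundles a species list, a set of elementary
#' reactions with mass-action rate laws, the rate-constant values, and the
#' conservation (moiety) structure of the system. Concentrations are in nM
#' and time in minutes throughout.
#'
#' Boundary species (e.g. an extracellular ligand bath) are integrated with
#' a clamped concentration: they enter rate laws normally but their own
#' time derivative is fixed at zero, and they take part in no conservation
#' group.
#'
#' @param species character vector of unique species names.
#' @param reactions list of reactions built with [reaction()].
#' @param params named numeric vector of non-negative rate constants.
#' @param boundary character vector of clamped (boundary) species.
#' @param conservation named list of conservation groups; each group is a
#'   named numeric vector of stoichiometric weights over species, whose
#'   weighted net stoichiometry must be zero in every reaction.
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, params,
                             boundary = character(),
                             conservation = list()) {
  if (anyDuplicated(species)) {
    stop("species names must be unique: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  if (any(params < 0)) {
    stop("negative rate constant: ",
         paste(names(params)[params < 0], collapse = ", "))
  }
  if (!all(boundary %in% species)) {
    stop("boundary species not declared: ",
         paste(setdiff(boundary, species), collapse = ", "))
  }
  for (rx in reactions) {
    bad <- setdiff(c(names(rx$reactants), names(rx$products)), species)
    if (length(bad)) {
      stop("reaction '", rx$name, "' references undeclared species: ",
           paste(bad, collapse = ", "))
    }
    if (!rx$rate %in% names(params)) {
      stop("reaction '", rx$name, "' references missing rate constant '",
           rx$rate, "'")
    }
  }
  net <- structure(
    list(species = species, reactions = reactions, params = params,
         boundary = boundary, conservation = conservation),
    class = "reaction_network")
  net$stoichiometry <- stoichiometry_matrix(net)
  attr(net, "rate_fun") <- compile_rates(net)
  for (grp in names(conservation)) {
    w <- rep(0, length(species))
    names(w) <- species
    w[names(conservation[[grp]])] <- conservation[[grp]]
    resid <- as.numeric(w %*% net$stoichiometry)
    if (any(resid != 0)) {
      stop("conservation group '", grp, "' is not closed (reaction ",
           paste(which(resid != 0), collapse = ","), ")")
    }
  }
  net
}

#' Declare a single mass-action reaction
#'
#' Reactants and products are named numeric vectors of stoichiometric
#' coefficients. The rate law is k * prod(conc^coef) over the reactants;
#' catalysts are written on both sides so that their net stoichiometry is
#' zero.
#'
#' @param name reaction label used in error messages.
#' @param reactants,products named numeric stoichiometry vectors.
#' @param rate name of the rate constant in the network's parameter set.
#' @export
reaction <- function(name, reactants, products, rate) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(reactants) && is.null(names(reactants))) {
    stop("reactants must be named")
  }
  if (length(products) && is.null(names(products))) {
    stop("products must be named")
  }
  list(name = name, reactants = reactants, products = products, rate = rate)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", length(x$species), "species,",
      length(x$reactions), "reactions,",
      length(x$conservation), "conservation groups\n")
  invisible(x)
}

# species x reaction matrix of net stoichiometric change
stoichiometry_matrix <- function(net) {
  S <- matrix(0, length(net$species), length(net$reactions),
              dimnames = list(net$species,
                              vapply(net$reactions, `[[`, "", "name")))
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    S[names(rx$reactants), j] <- S[names(rx$reactants), j] - rx$reactants
    S[names(rx$products), j] <- S[names(rx$products), j] + rx$products
  }
  S
}

# mass-action rate of every reaction at a state
rate_vector <- function(net, state) {
  f <- attr(net, "rate_fun")
  if (is.null(f)) f <- compile_rates(net)
  f(state[net$species])
}

# Precompute an index-based evaluator for the rate-law vector. Reactions of
# total order <= 2 (the mass-action cases used here) are evaluated with two
# vectorised index lookups; anything else falls back to a per-reaction
# product.
compile_rates <- function(net) {
  k <- vapply(net$reactions, function(rx) net$params[[rx$rate]], numeric(1))
  n <- length(net$reactions)
  i1 <- rep(NA_integer_, n)
  i2 <- rep(NA_integer_, n)
  general <- integer()
  for (j in seq_len(n)) {
    rx <- net$reactions[[j]]
    coef <- rx$reactants
    if (length(coef) && (any(coef != round(coef)) || sum(coef) > 2)) {
      general <- c(general, j)
      next
    }
    idx <- rep(match(names(coef), net$species), times = coef)
    if (length(idx) >= 1) i1[j] <- idx[1]
    if (length(idx) == 2) i2[j] <- idx[2]
  }
  reactions <- net$reactions
  species <- net$species
  function(y) {
    v <- k
    has1 <- !is.na(i1)
    v[has1] <- v[has1] * y[i1[has1]]
    has2 <- !is.na(i2)
    v[has2] <- v[has2] * y[i2[has2]]
    for (j in general) {
      coef <- reactions[[j]]$reactants
      v[j] <- k[j] * prod(y[match(names(coef), species)]^coef)
    }
    v
  }
}

#' Time derivative of every species under mass-action kinetics
#'
#' Computes the stoichiometry matrix times the mass-action rate-law vector.
#' Boundary (clamped) species get derivative zero.
#'
#' @param network a [reaction_network()].
#' @param state named numeric vector of concentrations (nM) covering all
#'   network species.
#' @return named numeric vector of rates of change (nM/min).
#' @export
derivatives <- function(network, state) {
  missing <- setdiff(network$species, names(state))
  if (length(missing)) {
    stop("state is missing species: ", paste(missing, collapse = ", "))
  }
  state <- state[network$species]
  dx <- as.numeric(network$stoichiometry %*% rate_vector(network, state))
  names(dx) <- network$species
  dx[network$boundary] <- 0
  dx
}

#' Totals of every conservation group at a state
#' @keywords internal
moiety_totals <- function(network, state) {
  vapply(network$conservation, function(w) {
    sum(w * state[names(w)])
  }, numeric(1))
}

#' Integrate a reaction network
#'
#' Stiff integration (deSolve's lsoda) of the network ODEs over a strictly
#' increasing time grid. After integration every conservation group is
#' checked against its initial total at a relative tolerance of 1e-6, and
#' small negative excursions (above -1e-9 nM) are clipped to zero; larger
#' negatives are an error.
#'
#' @param network a [reaction_network()].
#' @param init named non-negative initial state covering all species (nM).
#' @param t_grid strictly increasing numeric time grid (min) starting at
#'   the initial time.
#' @param rtol,atol solver tolerances.
#' @return a `trajectory`: list with `time` and a time x species
#'   concentration matrix `conc`; attribute `conserved` reports the worst
#'   relative drift per moiety, and `flags` any tolerance breach.
#' @export
simulate <- function(network, init, t_grid, rtol = 1e-8, atol = 1e-10) {
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  missing <- setdiff(network$species, names(init))
  if (length(missing)) {
    stop("initial state is missing species: ",
         paste(missing, collapse = ", "))
  }
  if (any(init < 0)) {
    stop("negative initial concentration: ",
         paste(names(init)[init < 0], collapse = ", "))
  }
  y0 <- init[network$species]
  S <- network$stoichiometry
  rate_fun <- attr(network, "rate_fun")
  if (is.null(rate_fun)) rate_fun <- compile_rates(network)
  bidx <- match(network$boundary, network$species)
  rhs <- function(t, y, p) {
    dx <- as.numeric(S %*% rate_fun(y))
    if (length(bidx)) dx[bidx] <- 0
    list(dx)
  }
  sol <- deSolve::lsoda(y = y0, times = t_grid, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop("integration failed (lsoda istate ", diagn[1], ")")
  }
  conc <- unname(sol[, -1, drop = FALSE])
  dimnames(conc) <- list(NULL, network$species)
  neg <- conc < 0
  if (any(conc[neg] < -1e-9)) {
    stop("negative concentration beyond tolerance: min = ",
         format(min(conc)))
  }
  conc[neg] <- 0

  drift <- 0
  flags <- character()
  if (length(network$conservation)) {
    tot0 <- moiety_totals(network, conc[1, ])
    totF <- moiety_totals(network, conc[nrow(conc), ])
    rel <- abs(totF - tot0) / pmax(abs(tot0), 1e-8)
    drift <- max(rel)
    if (drift > 1e-6) {
      flags <- c(flags, paste0("conservation drift ", format(drift), " in ",
                               names(which.max(rel))))
      warning(flags[length(flags)])
    }
  }
  structure(list(time = as.numeric(t_grid), conc = conc),
            class = "trajectory",
            network = network, conserved = drift, flags = flags)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$time), "time points x",
      ncol(x$conc), "species, t in [", x$time[1], ",",
      x$time[length(x$time)], "] min\n")
  invisible(x)
}

#' Extract pathway readouts from a trajectory
#'
#' The policy is either a fixed time on the grid (`list(type = "time",
#' t = 60)`, or just the number) or steady state (`list(type =
#' "steady_state")`), which returns values at the first stored time where
#' the largest relative derivative falls below `tol`.
#'
#' @param traj a trajectory from [simulate()].
#' @param policy readout time in minutes, or a policy list.
#' @param tol relative-derivative threshold declaring steady state.
#' @return a `signal_readout` with pAKT, pERK, total phospho-homodimer
#'   (pHER2) and total phospho-heterodimer concentrations, and the readout
#'   time; for generic networks, species absent from the trajectory are
#'   reported as NA.
#' @export
readout <- function(traj, policy = 60, tol = 1e-8) {
  if (is.numeric(policy)) policy <- list(type = "time", t = policy)
  if (identical(policy$type, "time")) {
    i <- which(abs(traj$time - policy$t) < 1e-9)
    if (!length(i)) stop("readout time ", policy$t, " is not on the grid")
    i <- i[1]
  } else if (identical(policy$type, "steady_state")) {
    net <- attr(traj, "network")
    i <- NA_integer_
    for (k in seq_along(traj$time)) {
      dx <- derivatives(net, traj$conc[k, ])
      rel <- max(abs(dx) / pmax(abs(traj$conc[k, ]), 1e-6))
      if (rel < tol) { i <- k; break }
    }
    if (is.na(i)) {
      stop("steady state not reached within the simulated horizon")
    }
  } else {
    stop("unknown readout policy type: ", policy$type)
  }
  state <- traj$conc[i, ]
  pick <- function(nm) if (nm %in% names(state)) unname(state[nm]) else NA_real_
  homo <- grep("^p\\(HER2", names(state), value = TRUE)
  het <- grep("^pHER3:", names(state), value = TRUE)
  structure(list(
    pAKT = pick("pAKT"),
    pERK = pick("pERK"),
    pHER2_homodimer = if (length(homo)) sum(state[homo]) else NA_real_,
    pHER3_heterodimer = if (length(het)) sum(state[het]) else NA_real_,
    time = traj$time[i], state = state), class = "signal_readout")
}

#' @export
print.signal_readout <- function(x, ...) {
  cat(sprintf("signal readout at t = %g min: pAKT = %.4g nM, pERK = %.4g nM\n",
              x$time, x$pAKT, x$pERK))
  invisible(x)
}
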