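# shared fixtures: parameter set, small toy networks, cached simulations

default_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- kinetic_parameters()
    cache
  }
})

# A + B <-> C, C -> D with hand-picked rates
toy_network <- function(k1 = 2, k2 = 0.5, k3 = 0.25) {
  reaction_network(
    species = c("A", "B", "C", "D"),
    reactions = list(
      reaction("bind", c(A = 1, B = 1), c(C = 1), "k1"),
      reaction("unbind", c(C = 1), c(A = 1, B = 1), "k2"),
      reaction("convert", c(C = 1), c(D = 1), "k3")),
    params = c(k1 = k1, k2 = k2, k3 = k3),
    conservation = list(A = c(A = 1, C = 1, D = 1),
                        B = c(B = 1, C = 1, D = 1)))
}

# independent brute-force derivative oracle: per-species summation over
# reactions, written without the stoichiometry matrix
oracle_derivatives <- function(net, state) {
  out <- stats::setNames(rep(0, length(net$species)), net$species)
  for (rx in net$reactions) {
    v <- net$params[[rx$rate]]
    for (i in seq_along(rx$reactants)) {
      v <- v * state[[names(rx$reactants)[i]]]^rx$reactants[[i]]
    }
    for (i in seq_along(rx$reactants)) {
      nm <- names(rx$reactants)[i]
      out[nm] <- out[nm] - rx$reactants[[i]] * v
    }
    for (i in seq_along(rx$products)) {
      nm <- names(rx$products)[i]
      out[nm] <- out[nm] + rx$products[[i]] * v
    }
  }
  out[net$boundary] <- 0
  out
}

# random mass-action network on <= 6 species
random_network <- function(n_species = sample(3:6, 1),
                           n_reactions = sample(2:6, 1)) {
  sp <- LETTERS[seq_len(n_species)]
  rxs <- lapply(seq_len(n_reactions), function(j) {
    nr <- sample(1:2, 1)
    np <- sample(1:2, 1)
    reaction(paste0("r", j),
             stats::setNames(rep(1, nr), sample(sp, nr)),
             stats::setNames(rep(1, np), sample(sp, np)),
             paste0("k", j))
  })
  # duplicate species within a side are collapsed by summing
  rxs <- lapply(rxs, function(rx) {
    rx$reactants <- tapply(rx$reactants, names(rx$reactants), sum)
    rx$products <- tapply(rx$products, names(rx$products), sum)
    rx
  })
  reaction_network(sp, rxs,
                   stats::setNames(stats::runif(n_reactions, 0.1, 3),
                                   paste0("k", seq_len(n_reactions))))
}

skov3 <- function(...) model_config(her2_total = 50, ratio = 0.5, ...)
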