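# Small networks and oracles shared across tests.

toy_ab_network <- function(kf = 1, kr = 1, a0 = 2, b0 = 0) {
  reaction_network(
    list(species("A", "internal", a0), species("B", "internal", b0)),
    list(reaction("R1", c(A = 1), c(B = 1), kf, kr)))
}

chain_network <- function() {
  reaction_network(
    list(species("A", "internal", 5), species("B", "internal", 0),
         species("C", "internal", 0)),
    list(reaction("R1", c(A = 1), c(B = 1), 0.7),
         reaction("R2", c(B = 1), c(C = 1), 0.3)))
}

# Independent evaluation of the mass-action rate law, term by term.
oracle_flux <- function(reaction, state, parameters = NULL) {
  getk <- function(k) {
    if (is.character(k)) parameters[[k]] else if (is.na(k)) 0 else k
  }
  fwd <- getk(reaction$kf)
  for (i in seq_along(reaction$reactants)) {
    fwd <- fwd * state[[names(reaction$reactants)[i]]] ^ reaction$reactants[[i]]
  }
  rev <- getk(reaction$kr)
  for (i in seq_along(reaction$products)) {
    rev <- rev * state[[names(reaction$products)[i]]] ^ reaction$products[[i]]
  }
  fwd - rev
}

# Hand-expanded derivative oracle: sum signed fluxes per species.
oracle_rhs <- function(network, state) {
  dy <- setNames(numeric(length(network$species)), species_names(network))
  for (r in network$reactions) {
    v <- oracle_flux(r, state, network$parameters)
    for (i in seq_along(r$reactants)) {
      nm <- names(r$reactants)[i]
      dy[[nm]] <- dy[[nm]] - r$reactants[[i]] * v
    }
    for (i in seq_along(r$products)) {
      nm <- names(r$products)[i]
      dy[[nm]] <- dy[[nm]] + r$products[[i]] * v
    }
  }
  for (i in seq_along(network$species)) {
    if (network$species[[i]]$clamped) dy[[network$species[[i]]$name]] <- 0
  }
  dy
}

random_small_network <- function(seed) {
  set.seed(seed)
  ns <- sample(3:5, 1)
  nr <- sample(2:5, 1)
  sp <- lapply(seq_len(ns), function(i) {
    species(paste0("S", i), "internal", runif(1, 0, 10),
            clamped = i == 1 && runif(1) < 0.3)
  })
  rx <- lapply(seq_len(nr), function(j) {
    k <- sample(ns, 2)
    reaction(paste0("R", j),
             setNames(sample(1:2, 1), paste0("S", k[1])),
             setNames(sample(1:2, 1), paste0("S", k[2])),
             kf = runif(1, 0, 2),
             kr = if (runif(1) < 0.5) runif(1, 0, 2) else NA)
  })
  reaction_network(sp, rx)
}

random_state <- function(network, seed) {
  set.seed(seed)
  setNames(runif(length(network$species), 0, 10), species_names(network))
}
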