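# Generic mass-action reaction networks and ODE right-hand sides.
#
# Conventions: cell-associated species are amounts in molecules/cell,
# extracellular ligands are concentrations in nM and are clamped by default
# (their derivative is forced to zero during integration). Rate constants for
# reactions consuming a clamped ligand are expressed per nM so that fluxes are
# uniformly molecules/cell/min.

#' Define a species
#'
#' @param name Unique species identifier.
#' @param compartment One of `"extracellular"`, `"surface"`, `"internal"`,
#'   `"degraded_pool"`. Cytosolic proteins live in `"internal"`; internalized
#'   receptor pools also use `"internal"` (their names carry an `_i` suffix).
#' @param initial_amount Non-negative initial amount (molecules/cell, or nM for
#'   extracellular ligands).
#' @param clamped If `TRUE` the species is held constant during integration
#'   (used for ligands supplied from a large media reservoir).
#' @param composition Optional named integer vector giving the number of copies
#'   of each elementary protein contained in the species (e.g. a receptor dimer
#'   has `FGFR1 = 2`). Used for moiety bookkeeping and readout checks.
#' @return An object of class `ma_species`.
#' @export
species <- function(name,
                    compartment = c("internal", "surface", "extracellular",
                                    "degraded_pool"),
                    initial_amount = 0, clamped = FALSE, composition = NULL) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(initial_amount) || length(initial_amount) != 1L ||
      is.na(initial_amount) || initial_amount < 0) {
    stop("initial_amount must be a single non-negative number (species '",
         name, "')")
  }
  if (!is.null(composition)) {
    if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
      stop("composition must be a named vector")
    }
    composition <- composition[composition != 0]
  }
  structure(list(name = name, compartment = compartment,
                 initial_amount = as.numeric(initial_amount),
                 clamped = isTRUE(clamped), composition = composition),
            class = "ma_species")
}

#' Define a mass-action reaction
#'
#' Reversible reactions are stored as a single reaction with forward and
#' reverse rate constants; `kr = NA` (or 0) marks an irreversible reaction.
#' Rate constants may be given as numbers or as names referring to entries of
#' the network's parameter table, which allows several reactions to share one
#' rate constant.
#'
#' @param label Reaction identifier (`"R1"` ... style).
#' @param reactants,products Named numeric vectors mapping species names to
#'   positive integer stoichiometric coefficients. Either side may be empty.
#' @param kf,kr Forward/reverse rate constant: a non-negative number or the
#'   name of a network parameter. `kr = NA` means irreversible.
#' @return An object of class `ma_reaction`.
#' @export
reaction <- function(label, reactants, products, kf, kr = NA) {
  chk_side <- function(x, what) {
    if (length(x) == 0L) return(numeric(0))
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("reaction ", label, ": ", what, " must be a named vector")
    }
    if (any(x <= 0) || any(x != round(x))) {
      stop("reaction ", label, ": stoichiometric coefficients must be ",
           "positive integers")
    }
    x
  }
  chk_rate <- function(k, what) {
    if (length(k) != 1L) stop("reaction ", label, ": ", what, " must be scalar")
    if (is.character(k)) return(k)
    if (is.na(k)) return(NA_real_)
    if (!is.numeric(k) || k < 0) {
      stop("reaction ", label, ": ", what, " must be non-negative or a ",
           "parameter name")
    }
    as.numeric(k)
  }
  structure(list(label = label,
                 reactants = chk_side(reactants, "reactants"),
                 products = chk_side(products, "products"),
                 kf = chk_rate(kf, "kf"), kr = chk_rate(kr, "kr")),
            class = "ma_reaction")
}

#' Assemble a reaction network
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param parameters Named numeric vector of rate constants referenced by name
#'   from the reactions.
#' @return A validated object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, parameters = numeric(0)) {
  net <- structure(list(species = species, reactions = reactions,
                        parameters = unlist(parameters)),
                   class = "reaction_network")
  validate_network(net)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", length(x$species), "species,",
      length(x$reactions), "reactions,", length(x$parameters),
      "parameters\n")
  invisible(x)
}

#' Species names of a network
#' @param network A `reaction_network`.
#' @return Character vector of species names in network order.
#' @export
species_names <- function(network) {
  vapply(network$species, function(s) s$name, character(1))
}

#' Validate a reaction network
#'
#' Checks name uniqueness, non-negative initial amounts, positive integer
#' stoichiometry, resolvable rate constants and non-negative rates.
#'
#' @param network A `reaction_network`.
#' @return The network, invisibly; stops with a configuration error otherwise.
#' @export
validate_network <- function(network) {
  sn <- species_names(network)
  if (anyDuplicated(sn)) {
    stop("duplicate species names: ",
         paste(unique(sn[duplicated(sn)]), collapse = ", "))
  }
  pn <- names(network$parameters)
  if (length(network$parameters) && anyDuplicated(pn)) {
    stop("duplicate parameter names")
  }
  labels <- vapply(network$reactions, function(r) r$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate reaction labels")
  for (r in network$reactions) {
    refs <- c(names(r$reactants), names(r$products))
    bad <- setdiff(refs, sn)
    if (length(bad)) {
      stop("reaction ", r$label, " references unknown species: ",
           paste(bad, collapse = ", "))
    }
    for (k in list(r$kf, r$kr)) {
      if (is.character(k) && !k %in% pn) {
        stop("reaction ", r$label, " references unknown parameter '", k, "'")
      }
    }
  }
  invisible(network)
}

resolve_rate <- function(k, parameters) {
  if (is.character(k)) return(unname(parameters[[k]]))
  if (is.na(k)) return(0)
  k
}

#' Resolved forward/reverse rate constants
#' @param network A `reaction_network`.
#' @param parameters Optional named vector overriding network parameters.
#' @return List with numeric vectors `kf` and `kr` (one entry per reaction).
#' @export
reaction_rates <- function(network, parameters = NULL) {
  p <- network$parameters
  if (!is.null(parameters)) p[names(parameters)] <- parameters
  kf <- vapply(network$reactions, function(r) resolve_rate(r$kf, p), numeric(1))
  kr <- vapply(network$reactions, function(r) resolve_rate(r$kr, p), numeric(1))
  if (any(kf < 0) || any(kr < 0)) stop("negative rate constant")
  list(kf = kf, kr = kr)
}

#' Mass-action flux of a single reaction
#'
#' Returns `kf * prod(state[reactants]^coef) - kr * prod(state[products]^coef)`.
#'
#' @param reaction A [reaction()].
#' @param state Named non-negative vector with one entry per species involved
#'   (extra entries are ignored).
#' @param parameters Named vector used to resolve rate-constant names.
#' @return The net flux (amount per minute).
#' @export
mass_action_rate <- function(reaction, state, parameters = NULL) {
  refs <- c(names(reaction$reactants), names(reaction$products))
  missing <- setdiff(refs, names(state))
  if (length(missing)) {
    stop("state lacks species: ", paste(missing, collapse = ", "))
  }
  kf <- resolve_rate(reaction$kf, parameters)
  kr <- resolve_rate(reaction$kr, parameters)
  fwd <- kf * prod(state[names(reaction$reactants)] ^ reaction$reactants)
  rev <- kr * prod(state[names(reaction$products)] ^ reaction$products)
  unname(fwd - rev)
}

# Sparse (CSR-like) encoding of reactant/product incidence used by the
# compiled RHS.
network_sparse <- function(network) {
  sn <- species_names(network)
  side <- function(get) {
    idx <- integer(0); coef <- numeric(0); ptr <- integer(length(network$reactions) + 1L)
    for (i in seq_along(network$reactions)) {
      s <- get(network$reactions[[i]])
      ptr[i + 1L] <- ptr[i] + length(s)
      idx <- c(idx, match(names(s), sn) - 1L)
      coef <- c(coef, unname(s))
    }
    list(ptr = ptr, idx = idx, coef = coef)
  }
  list(r = side(function(x) x$reactants), p = side(function(x) x$products),
       clamped = vapply(network$species, function(s) s$clamped, logical(1)))
}

#' Stoichiometry matrix
#' @param network A `reaction_network`.
#' @return Matrix (species x reactions) of net stoichiometric coefficients.
#' @export
stoichiometry_matrix <- function(network) {
  sn <- species_names(network)
  S <- matrix(0, length(sn), length(network$reactions),
              dimnames = list(sn, vapply(network$reactions,
                                         function(r) r$label, character(1))))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (k in seq_along(r$reactants)) {
      S[names(r$reactants)[k], j] <- S[names(r$reactants)[k], j] - r$reactants[k]
    }
    for (k in seq_along(r$products)) {
      S[names(r$products)[k], j] <- S[names(r$products)[k], j] + r$products[k]
    }
  }
  S
}

#' Build the ODE right-hand side of a network
#'
#' Returns a derivative function in the signature expected by
#' [deSolve::lsoda()]: `function(t, y, parms)` returning `list(dy)`. Clamped
#' species have derivative zero. The `"compiled"` backend evaluates the
#' mass-action fluxes in C++; the `"R"` backend is a plain-R evaluation of the
#' same rate law kept for cross-checking.
#'
#' @param network A validated `reaction_network`.
#' @param parameters Optional named vector overriding network parameters.
#' @param backend `"compiled"` or `"R"`.
#' @return Function `(t, y, parms) -> list(dy)`.
#' @export
assemble_rhs <- function(network, parameters = NULL,
                         backend = c("compiled", "R")) {
  backend <- match.arg(backend)
  validate_network(network)
  rates <- reaction_rates(network, parameters)
  sp <- network_sparse(network)
  if (backend == "compiled") {
    function(t, y, parms = NULL) {
      list(rhs_mass_action_cpp(y, rates$kf, rates$kr,
                               sp$r$ptr, sp$r$idx, sp$r$coef,
                               sp$p$ptr, sp$p$idx, sp$p$coef, sp$clamped))
    }
  } else {
    S <- stoichiometry_matrix(network)
    nr <- length(network$reactions)
    function(t, y, parms = NULL) {
      v <- numeric(nr)
      for (j in seq_len(nr)) {
        fwd <- rates$kf[j]
        for (k in seq.int(sp$r$ptr[j] + 1L, length.out = sp$r$ptr[j + 1L] - sp$r$ptr[j])) {
          fwd <- fwd * y[sp$r$idx[k] + 1L] ^ sp$r$coef[k]
        }
        rev <- rates$kr[j]
        for (k in seq.int(sp$p$ptr[j] + 1L, length.out = sp$p$ptr[j + 1L] - sp$p$ptr[j])) {
          rev <- rev * y[sp$p$idx[k] + 1L] ^ sp$p$coef[k]
        }
        v[j] <- fwd - rev
      }
      dy <- as.numeric(S %*% v)
      dy[sp$clamped] <- 0
      list(dy)
    }
  }
}

#' Build the analytic Jacobian of the mass-action RHS
#'
#' Returns `function(t, y, parms)` giving the dense Jacobian matrix
#' `d(dy)/dy`, evaluated in C++. Supplying it to the stiff solver avoids
#' costly finite-difference Jacobians (one RHS call per state variable).
#'
#' @param network A validated `reaction_network`.
#' @param parameters Optional named vector overriding network parameters.
#' @return Function `(t, y, parms) -> matrix`.
#' @export
assemble_jacobian <- function(network, parameters = NULL) {
  validate_network(network)
  rates <- reaction_rates(network, parameters)
  sp <- network_sparse(network)
  function(t, y, parms = NULL) {
    jac_mass_action_cpp(y, rates$kf, rates$kr,
                        sp$r$ptr, sp$r$idx, sp$r$coef,
                        sp$p$ptr, sp$p$idx, sp$p$coef, sp$clamped)
  }
}

#' Conserved moieties of a network
#'
#' Computes an (orthonormal) basis of the left null space of the stoichiometry
#' matrix restricted to non-clamped species: weight vectors `w` with
#' `t(w) %*% S = 0`, so `sum(w * state)` is constant along any trajectory.
#' Clamped species are excluded because holding a species constant breaks the
#' corresponding balance.
#'
#' @param network A `reaction_network`.
#' @param tol Singular-value tolerance for the rank decision.
#' @return Matrix whose columns are conservation weight vectors; rownames are
#'   the non-clamped species names. Zero columns if no moiety exists.
#' @export
conserved_moieties <- function(network, tol = 1e-10) {
  S <- stoichiometry_matrix(network)
  clamped <- vapply(network$species, function(s) s$clamped, logical(1))
  S <- S[!clamped, , drop = FALSE]
  if (nrow(S) == 0L) return(matrix(numeric(0), 0, 0))
  sv <- svd(S, nu = nrow(S), nv = 0)
  d <- c(sv$d, rep(0, nrow(S) - length(sv$d)))
  keep <- d < tol * max(d, 1)
  W <- sv$u[, keep, drop = FALSE]
  rownames(W) <- rownames(S)
  W
}

#' Test membership of a weight vector in the conserved-moiety space
#'
#' @param network A `reaction_network`.
#' @param w Named weight vector over (a subset of) non-clamped species.
#' @param tol Relative tolerance.
#' @return `TRUE` if `t(w) %*% S = 0` over the non-clamped species.
#' @export
is_conserved <- function(network, w, tol = 1e-8) {
  S <- stoichiometry_matrix(network)
  clamped <- vapply(network$species, function(s) s$clamped, logical(1))
  S <- S[!clamped, , drop = FALSE]
  full <- setNames(numeric(nrow(S)), rownames(S))
  unknown <- setdiff(names(w), names(full))
  if (length(unknown)) {
    stop("weights refer to unknown or clamped species: ",
         paste(unknown, collapse = ", "))
  }
  full[names(w)] <- w
  max(abs(drop(full %*% S))) <= tol * max(abs(w), 1)
}
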