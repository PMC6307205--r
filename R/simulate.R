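# Stimulation protocols and stiff ODE simulation.

#' Define a stimulation protocol
#'
#' @param fgf_nM,vegf_nM Ligand concentrations (nM), held constant (clamped)
#'   over the simulation.
#' @param heparin_ug_per_ml Soluble heparin dose (ug/ml); requires a model
#'   built with [build_heparin_extension()] when non-zero.
#' @param horizon_min Simulated time window (minutes). The model is validated
#'   for responses within two hours; longer horizons require
#'   `allow_long = TRUE`.
#' @param output_grid_min Strictly increasing output grid starting at 0;
#'   default 0.5-min spacing so a time-to-peak of a few minutes is resolved.
#' @param allow_long Permit `horizon_min > 120`.
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(fgf_nM = 0, vegf_nM = 0, heparin_ug_per_ml = 0,
                              horizon_min = 120,
                              output_grid_min = NULL, allow_long = FALSE) {
  stopifnot(fgf_nM >= 0, vegf_nM >= 0, heparin_ug_per_ml >= 0,
            horizon_min > 0)
  if (horizon_min > 120 && !allow_long) {
    stop("horizon exceeds the 2-hour validity window; set allow_long = TRUE ",
         "to override")
  }
  if (is.null(output_grid_min)) {
    output_grid_min <- seq(0, horizon_min, by = 0.5)
  }
  if (output_grid_min[1] != 0 || any(diff(output_grid_min) <= 0)) {
    stop("output grid must start at 0 and be strictly increasing")
  }
  if (max(output_grid_min) > horizon_min) {
    stop("output grid extends beyond the horizon")
  }
  structure(list(fgf_nM = fgf_nM, vegf_nM = vegf_nM,
                 heparin_ug_per_ml = heparin_ug_per_ml,
                 horizon_min = horizon_min,
                 output_grid_min = output_grid_min),
            class = "stimulus_protocol")
}

as_param_values <- function(params) {
  if (is.null(params)) return(NULL)
  if (inherits(params, "parameter_set")) return(params$values)
  if (is.list(params) && !is.null(params$values)) return(unlist(params$values))
  unlist(params)
}

# Split a named vector of overrides into rate-constant and initial-amount
# parts, by name.
split_overrides <- function(values, network) {
  if (is.null(values)) return(list(pars = NULL, init = NULL))
  pn <- names(network$parameters)
  sn <- species_names(network)
  unknown <- setdiff(names(values), c(pn, sn))
  if (length(unknown)) {
    stop("unknown parameter/species names: ", paste(unknown, collapse = ", "))
  }
  list(pars = values[names(values) %in% pn],
       init = values[names(values) %in% sn])
}

#' Simulate a stimulation protocol
#'
#' Integrates the mass-action ODE system with a stiff solver
#' ([deSolve::lsoda()]), ligands clamped at the protocol doses. For a
#' heparin-extended model the solution-phase FGF/heparin binding is applied as
#' a pre-equilibrium: free FGF is clamped at `fgf/(1 + hep/Kd_hep)` with
#' `Kd_hep = koff_FGF_HEP/kon_FGF_HEP`, and the FGF:heparin complex at the
#' remainder (the media reservoir is large, so both are effectively constant
#' within two hours). Negative excursions beyond the error-control scale abort
#' with a diagnostic error rather than being clipped.
#'
#' @param model A `signaling_model`.
#' @param params Optional named overrides (rate constants and/or initial
#'   amounts), a `parameter_set`, or `NULL` for the baseline.
#' @param protocol A [stimulus_protocol()].
#' @param parameter_set_id Identifier attached to the trajectory.
#' @param rtol,atol Solver tolerances (relative / absolute, molecules per
#'   cell).
#' @param maxsteps Solver step budget between output points (lower it inside
#'   optimization loops so pathological parameter sets fail fast).
#' @param backend RHS backend passed to [assemble_rhs()].
#' @return Object of class `trajectory`: `times`, `amounts` (time x species
#'   matrix), `protocol`, `parameter_set_id`.
#' @export
simulate <- function(model, params = NULL, protocol = stimulus_protocol(),
                     parameter_set_id = "baseline",
                     rtol = 1e-8, atol = 1e-6, backend = "compiled",
                     maxsteps = 50000) {
  stopifnot(inherits(model, "signaling_model"),
            inherits(protocol, "stimulus_protocol"))
  net <- model$network
  ov <- split_overrides(as_param_values(params), net)
  pars <- net$parameters
  if (length(ov$pars)) pars[names(ov$pars)] <- ov$pars

  y0 <- vapply(net$species, function(s) s$initial_amount, numeric(1))
  names(y0) <- species_names(net)
  if (length(ov$init)) y0[names(ov$init)] <- ov$init
  y0[["FGF"]] <- protocol$fgf_nM
  y0[["VEGF"]] <- protocol$vegf_nM

  if (protocol$heparin_ug_per_ml > 0 && !identical(model$kind, "heparin")) {
    stop("protocol includes heparin but the model has no heparin extension; ",
         "use build_heparin_extension()")
  }
  if (identical(model$kind, "heparin")) {
    hep_nM <- ligand_unit_convert(protocol$heparin_ug_per_ml, "ug_per_ml",
                                  "heparin")
    kd_hep <- pars[["koff_FGF_HEP"]] / pars[["kon_FGF_HEP"]]
    fgf_free <- protocol$fgf_nM / (1 + hep_nM / kd_hep)
    y0[["FGF"]] <- fgf_free
    y0[["FGF_HEP"]] <- protocol$fgf_nM - fgf_free
    y0[["HEP"]] <- hep_nM
  }

  rhs <- assemble_rhs(net, parameters = pars, backend = backend)
  jac <- if (identical(backend, "compiled")) {
    assemble_jacobian(net, parameters = pars)
  }
  out <- try(
    if (is.null(jac)) {
      deSolve::lsoda(y = y0, times = protocol$output_grid_min, func = rhs,
                     parms = NULL, rtol = rtol, atol = atol, maxsteps = maxsteps)
    } else {
      deSolve::lsoda(y = y0, times = protocol$output_grid_min, func = rhs,
                     parms = NULL, jacfunc = jac, jactype = "fullusr",
                     rtol = rtol, atol = atol, maxsteps = maxsteps)
    },
    silent = TRUE)
  fail <- function(msg) {
    stop("simulation failed [parameter_set_id=", parameter_set_id,
         ", fgf=", protocol$fgf_nM, " nM, vegf=", protocol$vegf_nM,
         " nM, heparin=", protocol$heparin_ug_per_ml, " ug/ml]: ", msg,
         call. = FALSE)
  }
  if (inherits(out, "try-error")) fail(attr(out, "condition")$message)
  if (nrow(out) < length(protocol$output_grid_min)) {
    fail("integrator stopped early")
  }
  amounts <- unclass(out)[, -1, drop = FALSE]
  if (any(!is.finite(amounts))) fail("non-finite state")
  neg_tol <- max(atol, rtol * max(abs(amounts)))
  if (min(amounts) < -neg_tol) {
    fail(sprintf("negative excursion %.3g beyond tolerance %.3g",
                 min(amounts), neg_tol))
  }
  structure(list(times = protocol$output_grid_min, amounts = amounts,
                 protocol = protocol, parameter_set_id = parameter_set_id),
            class = "trajectory")
}

#' Simulate an ensemble of parameter sets
#'
#' One trajectory per parameter set, in input order. Per-set failures are
#' captured and returned as error entries without aborting the remaining sets.
#'
#' @param model A `signaling_model`.
#' @param param_sets List of parameter sets (named vectors or
#'   `parameter_set` objects).
#' @param protocol A [stimulus_protocol()].
#' @param ... Passed to [simulate()].
#' @return List of `trajectory` objects (or `simulation_error` entries),
#'   named by parameter-set id.
#' @export
ensemble_simulate <- function(model, param_sets, protocol, ...) {
  if (length(param_sets) < 1L) stop("need at least one parameter set")
  ids <- names(param_sets)
  if (is.null(ids)) ids <- paste0("set", seq_along(param_sets))
  out <- vector("list", length(param_sets))
  names(out) <- ids
  for (i in seq_along(param_sets)) {
    out[[i]] <- tryCatch(
      simulate(model, params = param_sets[[i]], protocol = protocol,
               parameter_set_id = ids[i], ...),
      error = function(e) structure(list(parameter_set_id = ids[i],
                                         message = conditionMessage(e)),
                                    class = "simulation_error"))
  }
  out
}

#' Ensemble readout matrix and summaries
#'
#' @param trajectories Result of [ensemble_simulate()] (failed entries are
#'   dropped with a warning).
#' @param name Readout name.
#' @param model The `signaling_model`.
#' @return List: `times`, `values` (time x set matrix), `mean`, `sd`.
#' @export
ensemble_readout <- function(trajectories, name, model) {
  ok <- !vapply(trajectories, inherits, logical(1), "simulation_error")
  if (!all(ok)) {
    warning(sum(!ok), " trajectories failed and were dropped")
  }
  trajectories <- trajectories[ok]
  if (!length(trajectories)) stop("no successful trajectories")
  vals <- vapply(trajectories, function(tr) readout(tr, name, model)$value,
                 numeric(length(trajectories[[1]]$times)))
  vals <- matrix(vals, ncol = length(trajectories),
                 dimnames = list(NULL, names(trajectories)))
  list(times = trajectories[[1]]$times, values = vals,
       mean = rowMeans(vals), sd = apply(vals, 1, stats::sd))
}

#' Tidy data frame of a trajectory (long format)
#'
#' @param x A `trajectory`.
#' @param species Optional subset of species columns.
#' @param ... Unused.
#' @return `data.frame(time_min, species, amount, parameter_set_id, fgf_nM,
#'   vegf_nM, heparin_ug_per_ml)`.
#' @export
as.data.frame.trajectory <- function(x, species = NULL, ...) {
  cols <- species %||% colnames(x$amounts)
  data.frame(
    time_min = rep(x$times, length(cols)),
    species = rep(cols, each = length(x$times)),
    amount = as.vector(x$amounts[, cols]),
    parameter_set_id = x$parameter_set_id,
    fgf_nM = x$protocol$fgf_nM,
    vegf_nM = x$protocol$vegf_nM,
    heparin_ug_per_ml = x$protocol$heparin_ug_per_ml,
    stringsAsFactors = FALSE)
}

#' Write a trajectory to a tidy CSV file
#' @param trajectory A `trajectory`.
#' @param path Output path.
#' @param species Optional subset of species.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, species = NULL) {
  utils::write.csv(as.data.frame(trajectory, species = species), path,
                   row.names = FALSE)
  invisible(path)
}
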