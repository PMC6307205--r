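# Calibration: weighted SSR objective, prediction normalization, particle
# swarm optimization, and selection of the best parameter sets.

#' Parameter set
#'
#' The unit of fitting: named positive values for the free rate constants and
#' fitted initial amounts, with optional box bounds.
#'
#' @param values Named numeric vector.
#' @param bounds Optional named list of `c(lower, upper)` per value.
#' @param id Identifier.
#' @param wssr_train Training error, if known.
#' @return Object of class `parameter_set`.
#' @export
parameter_set <- function(values, bounds = NULL, id = "set1",
                          wssr_train = NA_real_) {
  values <- unlist(values)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("values must be named")
  }
  if (!is.null(bounds)) {
    for (nm in names(values)) {
      b <- bounds[[nm]]
      if (!is.null(b) && (values[[nm]] < b[1] || values[[nm]] > b[2])) {
        stop("value '", nm, "' outside its bounds")
      }
    }
  }
  structure(list(values = values, bounds = bounds, id = id,
                 wssr_train = wssr_train),
            class = "parameter_set")
}

#' Fitting bounds for the free quantities
#'
#' One order of magnitude above and below the baseline values.
#'
#' @param model A `signaling_model`.
#' @param fold Half-width as fold change (default 10).
#' @return `data.frame(name, baseline, lower, upper)`.
#' @export
free_parameter_bounds <- function(model, fold = 10) {
  base <- c(model$network$parameters,
            stats::setNames(
              vapply(model$network$species, function(s) s$initial_amount,
                     numeric(1)),
              species_names(model$network)))
  b <- base[model$free_names]
  data.frame(name = model$free_names, baseline = unname(b),
             lower = unname(b) / fold, upper = unname(b) * fold,
             stringsAsFactors = FALSE)
}

#' Weighted sum of squared residuals
#'
#' `sum(((pred - obs) / obs)^2)`; each observation must be positive because it
#' weights its own residual.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
wssr <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length")
  }
  zero <- which(observed <= 0)
  if (length(zero)) {
    stop("observed values must be positive (zero at index ",
         paste(utils::head(zero, 5), collapse = ", "), ")")
  }
  sum(((predicted - observed) / observed)^2)
}

#' Training/validation dataset container
#'
#' @param name Identifier.
#' @param readout Model readout the dataset measures (`"pERK_total"` or
#'   `"pR2_total"`).
#' @param scheme Normalization scheme: `"panel_max"` (all conditions share the
#'   single maximum across the panel, the FGF dose-panel convention) or
#'   `"per_condition"` (each curve divided by its own 2-hour maximum).
#' @param data `data.frame(condition_id, fgf_nM, vegf_nM, heparin_ug_per_ml,
#'   time_min, value)` with `value` in (0, 1].
#' @return Object of class `training_dataset`.
#' @export
training_dataset <- function(name, readout, scheme = c("per_condition",
                                                       "panel_max"), data) {
  scheme <- match.arg(scheme)
  need <- c("condition_id", "fgf_nM", "vegf_nM", "heparin_ug_per_ml",
            "time_min", "value")
  stopifnot(all(need %in% names(data)))
  if (any(data$value <= 0)) {
    stop("observed values must be positive (the WSSR weights by them); drop ",
         "pre-stimulation zeros")
  }
  if (max(data$value) > 1 + 1e-9) stop("normalized values must be <= 1")
  structure(list(name = name, readout = readout, scheme = scheme,
                 data = data), class = "training_dataset")
}

#' Simulate all conditions of a dataset
#'
#' Runs one simulation per unique condition of the dataset and extracts its
#' readout as a full curve over the 2-hour window.
#'
#' @param model A `signaling_model`.
#' @param params Parameter overrides.
#' @param dataset A [training_dataset()].
#' @param grid_step Output spacing (minutes).
#' @param ... Passed to [simulate()].
#' @return Named list (by condition id) of readout data frames.
#' @export
simulate_dataset_curves <- function(model, params, dataset, grid_step = 0.5,
                                    ...) {
  conds <- unique(dataset$data[, c("condition_id", "fgf_nM", "vegf_nM",
                                   "heparin_ug_per_ml")])
  # the output grid always contains the dataset's time points, so sampled
  # predictions are solver output, not interpolants, at any grid_step
  grid <- sort(unique(c(seq(0, 120, by = grid_step), dataset$data$time_min)))
  curves <- list()
  for (i in seq_len(nrow(conds))) {
    pr <- stimulus_protocol(fgf_nM = conds$fgf_nM[i],
                            vegf_nM = conds$vegf_nM[i],
                            heparin_ug_per_ml = conds$heparin_ug_per_ml[i],
                            output_grid_min = grid)
    tr <- simulate(model, params = params, protocol = pr, ...)
    curves[[as.character(conds$condition_id[i])]] <-
      readout(tr, dataset$readout, model)
  }
  curves
}

#' Normalize simulated curves to a dataset's convention
#'
#' Predictions are interpolated to the dataset's sampling times and the
#' normalizer is taken over those sampled values - the same operation applied
#' to the measured data. Under `"panel_max"` all conditions share the single
#' maximum across the panel's sampled points; under `"per_condition"` each
#' condition is divided by its own sampled maximum. Using sampled (not
#' full-curve) normalizers makes noise-free synthetic data reproduce the
#' model's own normalized output exactly, so the calibration objective
#' vanishes at the generating truth.
#'
#' @param curves Named list (by condition id) of `data.frame(time_min,
#'   value)` simulated curves covering the dataset's time points.
#' @param dataset A [training_dataset()].
#' @return Numeric vector of normalized predictions aligned to
#'   `dataset$data` rows.
#' @export
normalize_prediction <- function(curves, dataset) {
  data <- dataset$data
  pred <- numeric(nrow(data))
  for (cid in names(curves)) {
    rows <- which(data$condition_id == cid)
    cv <- curves[[cid]]
    pred[rows] <- stats::approx(cv$time_min, cv$value,
                                xout = data$time_min[rows])$y
  }
  if (identical(dataset$scheme, "panel_max")) {
    norm <- max(pred)
    if (norm <= 0) stop("degenerate simulation: zero normalizer for ",
                        "dataset '", dataset$name, "'")
    pred <- pred / norm
  } else {
    for (cid in unique(data$condition_id)) {
      rows <- data$condition_id == cid
      norm <- max(pred[rows])
      if (norm <= 0) stop("degenerate simulation: zero normalizer for ",
                          "condition '", cid, "' of dataset '",
                          dataset$name, "'")
      pred[rows] <- pred[rows] / norm
    }
  }
  pred
}

#' Calibration objective: summed WSSR over datasets
#'
#' Simulates each dataset's conditions under `theta`, normalizes per the
#' dataset's scheme and accumulates the weighted SSR. A simulation failure
#' contributes a large finite penalty (1e6) so the swarm can move away from
#' pathological regions.
#'
#' @param theta Named vector of free-quantity values (or a `parameter_set`).
#' @param model A `signaling_model`.
#' @param datasets List of [training_dataset()]s.
#' @param grid_step Simulation output spacing (minutes).
#' @param ... Passed to [simulate()].
#' @return Non-negative scalar.
#' @export
training_objective <- function(theta, model, datasets, grid_step = 0.5, ...) {
  theta <- as_param_values(theta)
  total <- 0
  for (ds in datasets) {
    res <- tryCatch({
      curves <- simulate_dataset_curves(model, theta, ds,
                                        grid_step = grid_step, ...)
      pred <- normalize_prediction(curves, ds)
      wssr(pred, ds$data$value)
    }, error = function(e) 1e6)
    total <- total + res
  }
  total
}

#' Particle swarm optimization over a box
#'
#' Constriction-coefficient PSO (inertia 0.729, cognitive/social 1.49445)
#' with reflecting boundaries; seeded and fully reproducible.
#'
#' @param objective Function of a numeric vector.
#' @param lower,upper Bound vectors.
#' @param n_particles Swarm size.
#' @param n_iter Iterations.
#' @param seed RNG seed.
#' @param inertia,c1,c2 PSO coefficients.
#' @param init Optional matrix (or vector) of starting positions injected
#'   into the initial swarm, e.g. a literature baseline.
#' @return Object of class `fit_result`: `par`, `value`, `trace` (global best
#'   per iteration, non-increasing), `seed`, `n_evals`.
#' @export
pso_minimize <- function(objective, lower, upper, n_particles = 40,
                         n_iter = 300, seed = 1, inertia = 0.729,
                         c1 = 1.49445, c2 = 1.49445, init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper))
  withr_seed(seed, {
    span <- upper - lower
    X <- matrix(stats::runif(n_particles * d), n_particles, d)
    X <- sweep(sweep(X, 2, span, "*"), 2, lower, "+")
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      k <- min(nrow(init), n_particles)
      X[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                   rep(lower, each = k)),
                              rep(upper, each = k))
    }
    V <- matrix(stats::runif(n_particles * d, -1, 1), n_particles, d)
    V <- sweep(V, 2, span / 10, "*")
    pbest <- X
    pval <- apply(X, 1, objective)
    g <- which.min(pval)
    gbest <- X[g, ]
    gval <- pval[g]
    trace <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
      r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
      V <- inertia * (V + c1 * r1 * (pbest - X) +
                        c2 * r2 * sweep(X, 2, gbest, function(x, g) g - x))
      X <- X + V
      # reflect at the box boundary (preserves swarm diversity near bounds)
      for (j in seq_len(d)) {
        lo <- X[, j] < lower[j]
        X[lo, j] <- pmin(upper[j], 2 * lower[j] - X[lo, j])
        V[lo, j] <- -V[lo, j]
        hi <- X[, j] > upper[j]
        X[hi, j] <- pmax(lower[j], 2 * upper[j] - X[hi, j])
        V[hi, j] <- -V[hi, j]
      }
      val <- apply(X, 1, objective)
      better <- val < pval
      pbest[better, ] <- X[better, , drop = FALSE]
      pval[better] <- val[better]
      g <- which.min(pval)
      if (pval[g] < gval) {
        gval <- pval[g]
        gbest <- pbest[g, ]
      }
      trace[it] <- gval
    }
    structure(list(par = gbest, value = gval, trace = trace, seed = seed,
                   n_evals = n_particles * (n_iter + 1L)),
              class = "fit_result")
  })
}

#' Fit the model's free quantities to datasets
#'
#' Optimizes the 39 free quantities in log10 space over the two-decade
#' fitting box using [pso_minimize()].
#'
#' @param model A `signaling_model`.
#' @param datasets List of [training_dataset()]s.
#' @param n_particles,n_iter,seed PSO settings.
#' @param fold Bound fold change (default 10).
#' @param grid_step Simulation output spacing for the objective.
#' @param warm_start Include the baseline values in the initial swarm
#'   (the bounds are centered on the baseline, which is the natural start).
#' @param ... Passed to [simulate()] via the objective.
#' @return `fit_result` with an added `parameter_set` element.
#' @export
fit_model <- function(model, datasets, n_particles = 40, n_iter = 300,
                      seed = 1, fold = 10, grid_step = 0.5,
                      warm_start = TRUE, ...) {
  bounds <- free_parameter_bounds(model, fold = fold)
  obj <- function(theta_log) {
    theta <- stats::setNames(10^theta_log, bounds$name)
    training_objective(theta, model, datasets, grid_step = grid_step, ...)
  }
  fit <- pso_minimize(obj, log10(bounds$lower), log10(bounds$upper),
                      n_particles = n_particles, n_iter = n_iter, seed = seed,
                      init = if (warm_start) log10(bounds$baseline))
  values <- stats::setNames(10^fit$par, bounds$name)
  fit$parameter_set <- parameter_set(
    values,
    bounds = stats::setNames(
      lapply(seq_len(nrow(bounds)), function(i) c(bounds$lower[i],
                                                  bounds$upper[i])),
      bounds$name),
    id = paste0("fit_seed", seed), wssr_train = fit$value)
  fit
}

#' Validation score of a parameter set
#'
#' Summed WSSR over the quantitative validation datasets plus, when a heparin
#' sign table is supplied, the number of time/dose points at which the
#' predicted pERK difference (with minus without heparin) disagrees in sign
#' with the expected pattern.
#'
#' @param theta Named free-quantity values.
#' @param model Main `signaling_model`.
#' @param val_datasets List of [training_dataset()]s (validation-shaped).
#' @param heparin_signs Optional `data.frame(fgf_nM, time_min, sign)`.
#' @param heparin_model Heparin-extended model (built if needed).
#' @param heparin_dose Heparin dose for the sign check (ug/ml).
#' @param grid_step Simulation output spacing.
#' @return Non-negative scalar.
#' @export
validation_score <- function(theta, model, val_datasets,
                             heparin_signs = NULL, heparin_model = NULL,
                             heparin_dose = 500, grid_step = 0.5) {
  score <- training_objective(theta, model, val_datasets,
                              grid_step = grid_step)
  if (!is.null(heparin_signs)) {
    if (is.null(heparin_model)) {
      heparin_model <- build_heparin_extension(model, heparin_dose)
    }
    delta <- tryCatch({
      doses <- unique(heparin_signs$fgf_nM)
      d <- numeric(nrow(heparin_signs))
      for (f in doses) {
        grid <- seq(0, 120, by = grid_step)
        with_h <- readout(simulate(heparin_model, theta,
                                   stimulus_protocol(fgf_nM = f,
                                                     heparin_ug_per_ml = heparin_dose,
                                                     output_grid_min = grid)),
                          "pERK_total", heparin_model)
        no_h <- readout(simulate(heparin_model, theta,
                                 stimulus_protocol(fgf_nM = f,
                                                   output_grid_min = grid)),
                        "pERK_total", heparin_model)
        rows <- which(heparin_signs$fgf_nM == f)
        d[rows] <- stats::approx(grid, with_h$value - no_h$value,
                                 xout = heparin_signs$time_min[rows])$y
      }
      d
    }, error = function(e) rep(NA_real_, nrow(heparin_signs)))
    mismatch <- sum(is.na(delta) | sign(delta) != heparin_signs$sign)
    score <- score + mismatch
  }
  score
}

#' Select the best parameter sets by training plus validation error
#'
#' Ranks fits by combined error (training WSSR + validation score) and
#' returns the top `k`; ties are broken by training WSSR and then by id.
#'
#' @param fits List of `fit_result`s (each with a `parameter_set`).
#' @param validation_scores Numeric vector aligned with `fits` (0 if omitted).
#' @param k Number of sets to keep (default 16).
#' @return List of `parameter_set`s of length `min(k, length(fits))` (with a
#'   warning when fewer than `k` fits are supplied).
#' @export
select_best <- function(fits, validation_scores = NULL, k = 16) {
  if (!length(fits)) stop("no fits supplied")
  train <- vapply(fits, function(f) f$value, numeric(1))
  if (is.null(validation_scores)) validation_scores <- rep(0, length(fits))
  stopifnot(length(validation_scores) == length(fits))
  ids <- vapply(fits, function(f) f$parameter_set$id, character(1))
  combined <- train + validation_scores
  ord <- order(combined, train, ids)
  if (length(fits) < k) {
    warning("fewer than ", k, " fits; returning all ", length(fits))
    k <- length(fits)
  }
  sel <- lapply(fits[ord[seq_len(k)]], function(f) f$parameter_set)
  attr(sel, "combined_error") <- combined[ord[seq_len(k)]]
  sel
}

#' Load the packaged best-fit parameter ensemble
#'
#' The 16 best parameter sets from the package's own PSO calibration against
#' synthetic training data (see the data generator). These stand in for the
#' study's fitted ensemble, which is not redistributable; the fixture is
#' synthetic and carries the training WSSR of each set.
#'
#' @return Named list of `parameter_set` objects.
#' @export
packaged_best_fits <- function() {
  path <- system.file("extdata", "best_fits_synthetic.csv",
                      package = "mapkcross", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  sets <- lapply(seq_len(nrow(df)), function(i) {
    vals <- unlist(df[i, setdiff(names(df), c("id", "wssr_train"))])
    parameter_set(vals, id = df$id[i], wssr_train = df$wssr_train[i])
  })
  stats::setNames(sets, df$id)
}

#' Write training/validation datasets to a tidy CSV file
#' @param datasets List of [training_dataset()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_datasets_csv <- function(datasets, path) {
  rows <- do.call(rbind, lapply(datasets, function(ds) {
    cbind(dataset = ds$name, readout = ds$readout, scheme = ds$scheme,
          ds$data)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read datasets written by [write_datasets_csv()]
#' @param path CSV path.
#' @return List of [training_dataset()]s.
#' @export
read_datasets_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$dataset), function(d) {
    training_dataset(d$dataset[1], d$readout[1], d$scheme[1],
                     d[, c("condition_id", "fgf_nM", "vegf_nM",
                           "heparin_ug_per_ml", "time_min", "value")])
  })
}
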