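# Synthetic data with the structure and noise character of the study's
# training and validation datasets, plus parameter-recovery experiments.

#' Apply multiplicative lognormal measurement noise
#'
#' Densitometry-style noise: each value is multiplied by a lognormal factor
#' with unit mean and coefficient of variation `cv` (so noisy values stay
#' strictly positive and the weighted-SSR division contract is never
#' violated).
#'
#' @param values Non-negative numeric vector.
#' @param cv Coefficient of variation (>= 0; 0 returns the input unchanged).
#' @param seed Optional seed (the caller may instead manage RNG state).
#' @return Noisy vector of the same length.
#' @export
apply_lognormal_noise <- function(values, cv, seed = NULL) {
  stopifnot(cv >= 0)
  if (cv == 0) return(values)
  draw <- function() {
    sdlog <- sqrt(log(1 + cv^2))
    values * stats::rlnorm(length(values), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Default sparse sampling grid of the synthetic datasets
#' @return Time points in minutes (about 8 points over 2 h, mimicking figure
#'   sampling; 0 is excluded because normalized observations must be
#'   positive).
#' @export
synthetic_time_grid <- function() c(5, 10, 15, 30, 45, 60, 90, 120)

#' FGF dose panel of the training data
#' @return Doses in ng/ml.
#' @export
fgf_training_doses_ng_ml <- function() c(0.16, 0.8, 4, 20, 100, 500)

#' Generate training- and validation-shaped synthetic datasets
#'
#' Simulates the three training conditions from a known truth - the
#' normalized pERK panel over six FGF doses (panel-max normalization), the
#' normalized pR2 time course at 5 ng/ml VEGF, and the normalized pERK time
#' course at 50 ng/ml VEGF - applies multiplicative lognormal noise before
#' normalization, and emits validation-shaped tables from the same truth
#' (pERK at 10 ng/ml FGF, pR2 at 80 ng/ml VEGF, and the sign pattern of the
#' heparin pERK difference at four time points across the FGF panel).
#'
#' @param model Main `signaling_model`.
#' @param true_params Named truth values for (a subset of) the free
#'   quantities; `NULL` uses the baseline.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed RNG seed; identical seeds reproduce identical tables.
#' @param time_grid Sampling times (minutes).
#' @param heparin_times Four time points of the heparin difference table.
#' @return Object of class `synthetic_study`: `true_parameters`, `datasets`
#'   (3 training sets), `validation` (2 quantitative sets),
#'   `heparin_signs`, `noise_cv`, `seed`.
#' @export
generate_training_like <- function(model, true_params = NULL, noise_cv = 0.1,
                                   seed = 1, time_grid = synthetic_time_grid(),
                                   heparin_times = c(30, 60, 90, 120)) {
  withr_seed(seed, {
    make_ds <- function(name, readout, scheme, conds) {
      rows <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
        data.frame(condition_id = conds$condition_id[i],
                   fgf_nM = conds$fgf_nM[i], vegf_nM = conds$vegf_nM[i],
                   heparin_ug_per_ml = 0, time_min = time_grid)
      }))
      ds_shape <- training_dataset(name, readout, scheme,
                                   cbind(rows, value = 1))
      curves <- simulate_dataset_curves(model, true_params, ds_shape)
      # noise acts on the raw (unnormalized) signal, then the dataset's
      # normalization is applied to the noisy values
      raw <- numeric(nrow(rows))
      norm_global <- 0
      norms <- list()
      for (cid in names(curves)) {
        sel <- which(rows$condition_id == cid)
        cv <- curves[[cid]]
        raw[sel] <- stats::approx(cv$time_min, cv$value,
                                  xout = rows$time_min[sel])$y
      }
      noisy <- apply_lognormal_noise(raw, noise_cv)
      if (scheme == "panel_max") {
        noisy <- noisy / max(noisy)
      } else {
        for (cid in unique(rows$condition_id)) {
          sel <- rows$condition_id == cid
          noisy[sel] <- noisy[sel] / max(noisy[sel])
        }
      }
      keep <- noisy > 0
      training_dataset(name, readout, scheme,
                       cbind(rows[keep, ], value = noisy[keep]))
    }
    fgf_doses <- ligand_unit_convert(fgf_training_doses_ng_ml(),
                                     "ng_per_ml", "FGF")
    train <- list(
      make_ds("fgf_panel_pERK", "pERK_total", "panel_max",
              data.frame(condition_id = paste0("fgf_",
                                               fgf_training_doses_ng_ml()),
                         fgf_nM = fgf_doses, vegf_nM = 0)),
      make_ds("vegf5_pR2", "pR2_total", "per_condition",
              data.frame(condition_id = "vegf_5",
                         fgf_nM = 0,
                         vegf_nM = ligand_unit_convert(5, "ng_per_ml",
                                                       "VEGF"))),
      make_ds("vegf50_pERK", "pERK_total", "per_condition",
              data.frame(condition_id = "vegf_50",
                         fgf_nM = 0,
                         vegf_nM = ligand_unit_convert(50, "ng_per_ml",
                                                       "VEGF"))))
    validation <- list(
      make_ds("fgf10_pERK", "pERK_total", "per_condition",
              data.frame(condition_id = "fgf_10",
                         fgf_nM = ligand_unit_convert(10, "ng_per_ml", "FGF"),
                         vegf_nM = 0)),
      make_ds("vegf80_pR2", "pR2_total", "per_condition",
              data.frame(condition_id = "vegf_80",
                         fgf_nM = 0,
                         vegf_nM = ligand_unit_convert(80, "ng_per_ml",
                                                       "VEGF"))))
    hep_model <- build_heparin_extension(model)
    hs <- expand.grid(fgf_nM = fgf_doses, time_min = heparin_times)
    delta <- numeric(nrow(hs))
    grid <- seq(0, 120, by = 0.5)
    for (f in fgf_doses) {
      with_h <- readout(simulate(hep_model, true_params,
                                 stimulus_protocol(fgf_nM = f,
                                                   heparin_ug_per_ml = 500,
                                                   output_grid_min = grid)),
                        "pERK_total", hep_model)
      no_h <- readout(simulate(hep_model, true_params,
                               stimulus_protocol(fgf_nM = f,
                                                 output_grid_min = grid)),
                      "pERK_total", hep_model)
      rows <- which(hs$fgf_nM == f)
      delta[rows] <- stats::approx(grid, with_h$value - no_h$value,
                                   xout = hs$time_min[rows])$y
    }
    hs$delta <- delta
    hs$sign <- sign(delta)
    structure(list(true_parameters = true_params, datasets = train,
                   validation = validation, heparin_signs = hs,
                   noise_cv = noise_cv, seed = seed),
              class = "synthetic_study")
  })
}

#' Parameter-recovery experiment on synthetic data
#'
#' Draws a truth by perturbing the baseline free quantities within the
#' fitting box, generates a synthetic study from it, runs multi-start PSO,
#' and reports per-quantity log10 errors, the objective gap, and which of the
#' designated influential quantities were recovered within the given fold.
#'
#' @param model Main `signaling_model`.
#' @param seed Master seed.
#' @param noise_cv Noise level of the generated data.
#' @param budget List: `n_starts`, `n_particles`, `n_iter`, and optionally
#'   `polish_iters` (Nelder-Mead refinement of the swarm optimum in log10
#'   space, default 400 evaluations).
#' @param perturb_sd_log10 SD (decades) of the lognormal truth perturbation.
#' @param influential Names scored for recovery (default: the sensitive
#'   initial amounts and MEK-phosphatase/trafficking rates identified by the
#'   sensitivity module).
#' @param recovery_fold Fold tolerance counted as recovered (default 2).
#' @param grid_step Simulation output spacing inside the objective.
#' @return Object of class `recovery_report`: data.frame `table` (name,
#'   true, estimate, log10_error, recovered), `objective_gap`, `best_wssr`,
#'   `truth_wssr`, `recovery_rate_influential`, `recovery_rate_other`.
#' @export
recovery_experiment <- function(model, seed = 1, noise_cv = 0,
                                budget = list(n_starts = 2, n_particles = 24,
                                              n_iter = 55,
                                              polish_iters = 400),
                                perturb_sd_log10 = 0.25,
                                influential = default_influential(),
                                recovery_fold = 2, grid_step = 2) {
  bounds <- free_parameter_bounds(model)
  truth <- withr_seed(seed, {
    f <- 10^stats::rnorm(nrow(bounds), 0, perturb_sd_log10)
    pmin(pmax(bounds$baseline * f, bounds$lower), bounds$upper)
  })
  names(truth) <- bounds$name
  study <- generate_training_like(model, truth, noise_cv = noise_cv,
                                  seed = seed)
  # fail-fast solver settings inside the swarm (coarser error control and a
  # small step budget); the reported objectives use the same settings so the
  # gap comparison is internally consistent
  sim_args <- list(rtol = 1e-6, atol = 1e-2, maxsteps = 5000)
  fits <- lapply(seq_len(budget$n_starts), function(i) {
    do.call(fit_model,
            c(list(model, study$datasets, n_particles = budget$n_particles,
                   n_iter = budget$n_iter, seed = seed * 1000L + i,
                   grid_step = grid_step), sim_args))
  })
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  polish_iters <- budget$polish_iters %||% 400
  if (polish_iters > 0) {
    obj_log <- function(theta_log) {
      theta_log <- pmin(pmax(theta_log, log10(bounds$lower)),
                        log10(bounds$upper))
      th <- stats::setNames(10^theta_log, bounds$name)
      do.call(training_objective,
              c(list(th, model, study$datasets, grid_step = grid_step),
                sim_args))
    }
    pol <- stats::optim(log10(best$parameter_set$values[bounds$name]),
                        obj_log, method = "Nelder-Mead",
                        control = list(maxit = polish_iters))
    if (pol$value < best$value) {
      best$value <- pol$value
      best$parameter_set$values[bounds$name] <-
        stats::setNames(pmin(pmax(10^pol$par, bounds$lower), bounds$upper),
                        bounds$name)
    }
  }
  est <- best$parameter_set$values[bounds$name]
  log10_err <- log10(est) - log10(truth)
  recovered <- abs(log10_err) <= log10(recovery_fold)
  truth_wssr <- do.call(training_objective,
                        c(list(truth, model, study$datasets,
                               grid_step = grid_step), sim_args))
  infl <- bounds$name %in% influential
  structure(list(
    table = data.frame(name = bounds$name, true = unname(truth),
                       estimate = unname(est),
                       log10_error = unname(log10_err),
                       influential = infl, recovered = unname(recovered),
                       stringsAsFactors = FALSE),
    best_wssr = best$value, truth_wssr = truth_wssr,
    objective_gap = best$value - truth_wssr,
    recovery_rate_influential = mean(recovered[infl]),
    recovery_rate_other = mean(recovered[!infl]),
    seed = seed, noise_cv = noise_cv, budget = budget),
    class = "recovery_report")
}

#' Designated influential quantities
#'
#' The free quantities flagged as influential by the global sensitivity
#' analysis of the baseline model: the initial amounts of FRS2, Ptase2, Ras,
#' MEK and Raf, the Ptase2-MEK rates (`k_dpMEK_p`, `ked2`) and the bound
#' VEGFR2 trafficking rates.
#'
#' @return Character vector.
#' @export
default_influential <- function() {
  c("FRS2", "Ptase2", "Ras", "MEK", "Raf",
    "k_dpMEK_p", "ked2", "k_intb", "k_recb", "k_degb")
}
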