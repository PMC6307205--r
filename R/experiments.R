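# Drivers for the in-silico perturbation experiments run over the best-fit
# ensemble: mono/combination dose grids, VEGFR2 density scan, trafficking
# swaps and the heparin difference.

metrics_row <- function(rec, id, fgf, vegf, extra = NULL) {
  df <- data.frame(parameter_set_id = id, fgf_nM = fgf, vegf_nM = vegf,
                   max_pERK = rec$max_pERK, T1 = rec$T1, T2 = rec$T2,
                   boundary_max = rec$boundary_max,
                   stringsAsFactors = FALSE)
  if (is.null(extra)) df else cbind(df, as.data.frame(extra))
}

ensemble_values <- function(param_sets) {
  ids <- names(param_sets)
  if (is.null(ids)) ids <- paste0("set", seq_along(param_sets))
  stats::setNames(lapply(param_sets, as_param_values), ids)
}

#' Combination dose grid of maximum pERK and ratio R
#'
#' For every (FGF, VEGF) dose pair - including the mono-stimulations obtained
#' by pairing each dose with 0 - computes per-parameter-set response metrics
#' and, for pairs with both doses positive, the combination ratio R.
#' Per-cell simulation errors are recorded without aborting the grid.
#'
#' @param model A `signaling_model`.
#' @param param_sets Ensemble (list of `parameter_set`s or named vectors).
#' @param fgf_doses_nM,vegf_doses_nM Dose grids (0 is added automatically).
#' @param horizon_min Metrics window.
#' @return List of data.frames: `metrics` (per set x cell), `ratios`
#'   (per set x combination cell), `errors`.
#' @export
run_combination_grid <- function(model, param_sets,
                                 fgf_doses_nM = c(0.01, 0.05, 0.1, 0.5, 1, 2),
                                 vegf_doses_nM = c(0.01, 0.05, 0.1, 0.5, 1, 2),
                                 horizon_min = 120) {
  sets <- ensemble_values(param_sets)
  fgf <- sort(unique(c(0, fgf_doses_nM)))
  vegf <- sort(unique(c(0, vegf_doses_nM)))
  cells <- expand.grid(fgf_nM = fgf, vegf_nM = vegf)
  cells <- cells[cells$fgf_nM > 0 | cells$vegf_nM > 0, ]
  metrics <- list(); errors <- list()
  maxes <- array(NA_real_, dim = c(length(fgf), length(vegf), length(sets)),
                 dimnames = list(as.character(fgf), as.character(vegf),
                                 names(sets)))
  for (id in names(sets)) {
    for (i in seq_len(nrow(cells))) {
      f <- cells$fgf_nM[i]; v <- cells$vegf_nM[i]
      rec <- tryCatch(
        perk_metrics(model, sets[[id]],
                     stimulus_protocol(fgf_nM = f, vegf_nM = v,
                                       horizon_min = horizon_min)),
        error = function(e) e)
      if (inherits(rec, "error")) {
        errors[[length(errors) + 1L]] <-
          data.frame(parameter_set_id = id, fgf_nM = f, vegf_nM = v,
                     message = conditionMessage(rec))
        next
      }
      metrics[[length(metrics) + 1L]] <- metrics_row(rec, id, f, v)
      maxes[as.character(f), as.character(v), id] <- rec$max_pERK
    }
  }
  ratios <- list()
  for (id in names(sets)) {
    for (f in setdiff(fgf, 0)) for (v in setdiff(vegf, 0)) {
      combo <- maxes[as.character(f), as.character(v), id]
      mf <- maxes[as.character(f), "0", id]
      mv <- maxes["0", as.character(v), id]
      if (any(is.na(c(combo, mf, mv))) || mf + mv <= 0) next
      ratios[[length(ratios) + 1L]] <-
        data.frame(parameter_set_id = id, fgf_nM = f, vegf_nM = v,
                   R = combo / (mf + mv), max_combo = combo,
                   max_fgf_alone = mf, max_vegf_alone = mv)
    }
  }
  list(metrics = do.call(rbind, metrics),
       ratios = do.call(rbind, ratios),
       errors = if (length(errors)) do.call(rbind, errors))
}

#' VEGFR2 density scan
#'
#' Scales the initial VEGFR2 surface density by each factor and computes
#' mono- and co-stimulation metrics plus the combination ratio.
#'
#' @param model A `signaling_model`.
#' @param param_sets Ensemble.
#' @param factors Density scale factors (default within the ten-fold range
#'   around the 1000 molecules/cell baseline).
#' @param fgf_nM,vegf_nM Doses used for the scan.
#' @return data.frame with one row per set x factor x condition
#'   (`fgf`, `vegf`, `combo`), columns `max_pERK`, `T1`, `T2`, `R` (combo
#'   rows).
#' @export
run_vegfr2_density_scan <- function(model, param_sets,
                                    factors = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                                    fgf_nM = 0.5, vegf_nM = 0.5) {
  stopifnot(all(factors > 0))
  sets <- ensemble_values(param_sets)
  base_r2 <- default_initial_amounts()[["VEGFR2"]]
  out <- list()
  for (id in names(sets)) {
    vals <- sets[[id]]
    for (fac in factors) {
      vals2 <- c(vals[setdiff(names(vals), "VEGFR2")], VEGFR2 = base_r2 * fac)
      recs <- list(
        fgf = perk_metrics(model, vals2, stimulus_protocol(fgf_nM = fgf_nM)),
        vegf = perk_metrics(model, vals2, stimulus_protocol(vegf_nM = vegf_nM)),
        combo = perk_metrics(model, vals2,
                             stimulus_protocol(fgf_nM = fgf_nM,
                                               vegf_nM = vegf_nM)))
      denom <- recs$fgf$max_pERK + recs$vegf$max_pERK
      for (cond in names(recs)) {
        out[[length(out) + 1L]] <- metrics_row(
          recs[[cond]], id, if (cond == "vegf") 0 else fgf_nM,
          if (cond == "fgf") 0 else vegf_nM,
          extra = list(factor = fac, condition = cond,
                       R = if (cond == "combo" && denom > 0) {
                         recs$combo$max_pERK / denom
                       } else NA_real_))
      }
    }
  }
  do.call(rbind, out)
}

#' VEGFR2-to-FGFR1 trafficking parameter swaps
#'
#' Replaces selected VEGFR2 trafficking rates with the corresponding FGFR1
#' values (`"all"` swaps all six) and computes the 0.5 nM VEGF response, with
#' the fitted-parameter VEGF and FGF references.
#'
#' @param model A `signaling_model`.
#' @param param_sets Ensemble.
#' @param selections Character vector of conditions drawn from `"fitted"`,
#'   `"all"`, `"k_int"`, `"k_rec"`, `"k_deg"`, `"k_intf"`, `"k_intb"`,
#'   `"k_recf"`, `"k_recb"`, `"k_degf"`, `"k_degb"`.
#' @param vegf_nM,fgf_ref_nM Doses of the scan and of the FGF reference.
#' @return data.frame with one row per set x condition.
#' @export
run_trafficking_swap <- function(model, param_sets,
                                 selections = c("fitted", "all", "k_intf",
                                                "k_intb", "k_int", "k_recf",
                                                "k_recb", "k_rec", "k_degf",
                                                "k_degb", "k_deg"),
                                 vegf_nM = 0.5, fgf_ref_nM = 0.5) {
  pair_map <- c(k_intf = "k_intf_R1", k_intb = "k_intb_R1",
                k_recf = "k_recf_R1", k_recb = "k_recb_R1",
                k_degf = "k_degf_R1", k_degb = "k_degb_R1")
  expand_sel <- function(sel) {
    switch(sel,
           fitted = character(0),
           all = names(pair_map),
           k_int = c("k_intf", "k_intb"),
           k_rec = c("k_recf", "k_recb"),
           k_deg = c("k_degf", "k_degb"),
           {
             if (!sel %in% names(pair_map)) {
               stop("unknown trafficking selection '", sel, "'")
             }
             sel
           })
  }
  sets <- ensemble_values(param_sets)
  base_pars <- model$network$parameters
  out <- list()
  for (id in names(sets)) {
    vals <- sets[[id]]
    fgfr_rates <- base_pars[pair_map]
    names(fgfr_rates) <- names(pair_map)
    present <- intersect(names(pair_map), names(vals))
    # FGFR1 rates are fixed quantities; the VEGFR2 rates being swapped may be
    # fitted, so the swap overrides the set's own values
    for (sel in selections) {
      swap <- expand_sel(sel)
      vals2 <- vals
      vals2[swap] <- unname(base_pars[pair_map[swap]])
      rec <- perk_metrics(model, vals2, stimulus_protocol(vegf_nM = vegf_nM))
      out[[length(out) + 1L]] <- metrics_row(rec, id, 0, vegf_nM,
                                             extra = list(condition = sel))
    }
    ref <- perk_metrics(model, vals, stimulus_protocol(fgf_nM = fgf_ref_nM))
    out[[length(out) + 1L]] <- metrics_row(ref, id, fgf_ref_nM, 0,
                                           extra = list(condition = "fgf_ref"))
  }
  do.call(rbind, out)
}

#' Heparin pERK difference table
#'
#' `delta = pERK(FGF + heparin) - pERK(FGF)` for each FGF dose, time point
#' and parameter set.
#'
#' @param model Main `signaling_model` (the heparin extension is built
#'   internally) or an already-extended model.
#' @param param_sets Ensemble.
#' @param fgf_doses_ng_ml FGF dose panel (default: the training panel).
#' @param times_min Four evaluation time points within 2 h.
#' @param heparin_ug_per_ml Heparin dose.
#' @return data.frame(parameter_set_id, fgf_ng_ml, fgf_nM, time_min, delta).
#' @export
run_heparin_difference <- function(model, param_sets,
                                   fgf_doses_ng_ml = fgf_training_doses_ng_ml(),
                                   times_min = c(30, 60, 90, 120),
                                   heparin_ug_per_ml = 500) {
  hep_model <- if (identical(model$kind, "heparin")) model else
    build_heparin_extension(model, heparin_ug_per_ml)
  sets <- ensemble_values(param_sets)
  grid <- seq(0, 120, by = 0.5)
  out <- list()
  for (id in names(sets)) {
    for (dose in fgf_doses_ng_ml) {
      f <- ligand_unit_convert(dose, "ng_per_ml", "FGF")
      with_h <- readout(simulate(hep_model, sets[[id]],
                                 stimulus_protocol(fgf_nM = f,
                                                   heparin_ug_per_ml = heparin_ug_per_ml,
                                                   output_grid_min = grid),
                                 parameter_set_id = id),
                        "pERK_total", hep_model)
      no_h <- readout(simulate(hep_model, sets[[id]],
                               stimulus_protocol(fgf_nM = f,
                                                 output_grid_min = grid),
                               parameter_set_id = id),
                      "pERK_total", hep_model)
      d <- stats::approx(grid, with_h$value - no_h$value, xout = times_min)$y
      out[[length(out) + 1L]] <-
        data.frame(parameter_set_id = id, fgf_ng_ml = dose, fgf_nM = f,
                   time_min = times_min, delta = d)
    }
  }
  do.call(rbind, out)
}
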