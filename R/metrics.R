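# Scalar descriptors of the pERK response: maximum, T1 (time to peak),
# T2 (duration above half-maximum), and the combination ratio R.

#' Compute response metrics of a readout series
#'
#' `max` is the window maximum of the series; `T1` the first time attaining
#' it; `T2` the total measure of the super-half-maximum set
#' `{t : series(t) > max/2}`, with linear interpolation at the crossings (this
#' is robust to multi-modal responses). An identically-zero series returns
#' `max = T1 = T2 = 0` by convention. If the maximum is only attained at the
#' window boundary the record is flagged (`boundary_max`), since the response
#' has then not peaked within the window.
#'
#' @param series A `readout_series` or `data.frame(time_min, value)`.
#' @param horizon_min Evaluation window (default: last time point).
#' @param parameter_set_id,protocol Optional metadata carried through.
#' @return Object of class `metrics_record`: list with `max_pERK`, `T1`,
#'   `T2`, `boundary_max`, plus metadata.
#' @export
compute_metrics <- function(series, horizon_min = NULL,
                            parameter_set_id = NA_character_,
                            protocol = NULL) {
  t <- series$time_min
  v <- series$value
  if (length(t) < 2L) stop("series must have at least two points")
  if (is.null(horizon_min)) horizon_min <- max(t)
  keep <- t <= horizon_min + 1e-9
  t <- t[keep]; v <- v[keep]
  vmax <- max(v)
  if (vmax <= 0) {
    rec <- list(max_pERK = 0, T1 = 0, T2 = 0, boundary_max = FALSE)
  } else {
    i1 <- which(v >= vmax * (1 - 1e-12))[1]
    half <- vmax / 2
    above <- v > half
    dur <- 0
    for (k in seq_len(length(t) - 1L)) {
      dt <- t[k + 1L] - t[k]
      if (above[k] && above[k + 1L]) {
        dur <- dur + dt
      } else if (above[k] != above[k + 1L]) {
        # linear interpolation of the crossing point
        frac <- (half - v[k]) / (v[k + 1L] - v[k])
        dur <- dur + if (above[k]) frac * dt else (1 - frac) * dt
      }
    }
    rec <- list(max_pERK = vmax, T1 = t[i1], T2 = dur,
                boundary_max = i1 == length(t))
  }
  rec$horizon_min <- horizon_min
  rec$parameter_set_id <- parameter_set_id
  rec$protocol <- protocol
  class(rec) <- "metrics_record"
  rec
}

#' pERK metrics for one protocol and parameter set
#'
#' Convenience wrapper: simulate, extract `pERK_total`, compute metrics.
#'
#' @param model A `signaling_model`.
#' @param params Parameter overrides (see [simulate()]).
#' @param protocol A [stimulus_protocol()].
#' @param readout_name Readout to score (default `pERK_total`).
#' @param ... Passed to [simulate()].
#' @return A `metrics_record`.
#' @export
perk_metrics <- function(model, params = NULL,
                         protocol = stimulus_protocol(),
                         readout_name = "pERK_total", ...) {
  tr <- simulate(model, params = params, protocol = protocol, ...)
  compute_metrics(readout(tr, readout_name, model),
                  horizon_min = protocol$horizon_min,
                  parameter_set_id = tr$parameter_set_id,
                  protocol = protocol)
}

#' Combination ratio R of co-stimulation versus summed mono-stimulations
#'
#' `R = max pERK(FGF and VEGF) / (max pERK(FGF) + max pERK(VEGF))`, from
#' three simulations under identical settings. `R > 1` indicates a
#' supra-additive combination, `R = 1` additivity, `R < 1` antagonism.
#'
#' @param model A `signaling_model`.
#' @param params Parameter overrides.
#' @param fgf_nM,vegf_nM Doses (at least one must be positive).
#' @param horizon_min Evaluation window.
#' @param ... Passed to [simulate()].
#' @return Object of class `ratio_record`: `R` plus the three component
#'   maxima.
#' @export
combination_ratio <- function(model, params = NULL, fgf_nM, vegf_nM,
                              horizon_min = 120, ...) {
  if (fgf_nM <= 0 && vegf_nM <= 0) stop("at least one dose must be positive")
  m <- function(f, v) {
    perk_metrics(model, params,
                 stimulus_protocol(fgf_nM = f, vegf_nM = v,
                                   horizon_min = horizon_min), ...)$max_pERK
  }
  combo <- m(fgf_nM, vegf_nM)
  fgf_alone <- m(fgf_nM, 0)
  vegf_alone <- m(0, vegf_nM)
  denom <- fgf_alone + vegf_alone
  if (denom <= 0) stop("undefined ratio: both mono-stimulation maxima are 0")
  structure(list(R = combo / denom, max_combo = combo,
                 max_fgf_alone = fgf_alone, max_vegf_alone = vegf_alone,
                 fgf_nM = fgf_nM, vegf_nM = vegf_nM),
            class = "ratio_record")
}

#' Summarize an ensemble of scalar metric values
#'
#' Median with a seeded percentile-bootstrap confidence interval for the
#' median, the per-fit values, and an optional one-sample Wilcoxon
#' signed-rank test against a reference value (the rank-based stand-in used
#' for significance marks).
#'
#' @param values Numeric vector (one value per parameter set), or a list of
#'   `metrics_record`/`ratio_record` objects plus `field`.
#' @param field Field to extract when `values` is a list of records.
#' @param conf Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Bootstrap seed.
#' @param test_against Optional reference value for the Wilcoxon test.
#' @return List: `median`, `ci` (length 2), `values`, and optionally
#'   `p_value`.
#' @export
ensemble_summary <- function(values, field = NULL, conf = 0.95,
                             n_boot = 10000, seed = 1, test_against = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    if (is.null(field)) {
      field <- if (inherits(values[[1]], "ratio_record")) "R" else "max_pERK"
    }
    values <- vapply(values, function(r) r[[field]], numeric(1))
  }
  if (!length(values)) stop("need at least one record")
  med <- stats::median(values)
  if (length(unique(values)) == 1L) {
    ci <- c(med, med)
  } else {
    boot <- withr_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        stats::median(sample(values, replace = TRUE))
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  }
  out <- list(median = med, ci = ci, values = values)
  if (!is.null(test_against)) {
    if (length(unique(values)) == 1L && values[1] == test_against) {
      out$p_value <- 1
    } else {
      out$p_value <- suppressWarnings(
        stats::wilcox.test(values, mu = test_against)$p.value)
    }
  }
  out
}

# Run code under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  code
}
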