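# Extended Fourier Amplitude Sensitivity Test (eFAST).
#
# Follows the resampling recipe standard in systems biology (Marino et al.,
# J. Theor. Biol. 2008): the input of interest is driven at the maximum
# interference-free frequency, the complementary set at low frequencies,
# with NR random-phase search curves and harmonics up to order M. First-order
# indices come from the power at the driving frequency's harmonics, total-order
# indices from one minus the complementary-frequency share of variance. A
# dummy (inert) input is appended to give a significance floor.

#' Construct an eFAST sampling design
#'
#' Each input is varied over `[lower, upper]` along sinusoidal search curves
#' `x = lb + (ub - lb) * (1/2 + (1/pi) * asin(sin(w*s + phi)))`; inputs with
#' `scale = "log"` are varied log-uniformly (the natural metric for
#' multiplicative, order-of-magnitude bounds).
#'
#' @param inputs `data.frame(name, lower, upper)` with optional `scale`
#'   column (`"log"` or `"linear"`, default `"log"`).
#' @param n_samples_per_curve Samples per search curve (NS); must satisfy the
#'   Nyquist constraint `NS >= 4*M^2 + 1` so the driving frequency keeps `M`
#'   interference-free harmonics.
#' @param n_resample_curves Number of random-phase curves (NR).
#' @param seed RNG seed for the phases.
#' @param M Number of harmonics retained.
#' @param add_dummy Append an inert dummy input (significance floor).
#' @return Object of class `efast_design`; element `samples` is the stacked
#'   sample matrix (one block per input-of-interest x curve) whose rows are
#'   model-input vectors.
#' @export
efast_design <- function(inputs, n_samples_per_curve = 65,
                         n_resample_curves = 5, seed = 1, M = 4,
                         add_dummy = TRUE) {
  stopifnot(is.data.frame(inputs), all(c("name", "lower", "upper") %in%
                                         names(inputs)))
  if (nrow(inputs) < 2L) stop("need at least two inputs")
  if (is.null(inputs$scale)) inputs$scale <- "log"
  if (add_dummy) {
    inputs <- rbind(inputs, data.frame(name = "_dummy_", lower = 0.5,
                                       upper = 1.5, scale = "linear"))
  }
  with(inputs, stopifnot(all(is.finite(lower)), all(is.finite(upper)),
                         all(lower < upper)))
  if (any(inputs$scale == "log" & inputs$lower <= 0)) {
    stop("log-scaled inputs need positive bounds")
  }
  k <- nrow(inputs)
  NS <- as.integer(n_samples_per_curve)
  if (NS %% 2L == 0L) NS <- NS + 1L
  w_max <- floor((NS - 1) / (2 * M))
  w_cmax <- floor(w_max / (2 * M))
  if (w_cmax < 1) {
    stop("sample budget below the Nyquist bound: need n_samples_per_curve >= ",
         4 * M^2 + 1)
  }
  s <- 2 * pi * (seq_len(NS) - 1) / NS - pi
  freqs_comp <- rep(seq_len(w_cmax), length.out = k - 1L)
  blocks <- list()
  meta <- list()
  phases <- withr_seed(seed, {
    array(stats::runif(k * k * n_resample_curves, 0, 2 * pi),
          dim = c(k, k, n_resample_curves))
  })
  lo <- ifelse(inputs$scale == "log", log10(inputs$lower), inputs$lower)
  hi <- ifelse(inputs$scale == "log", log10(inputs$upper), inputs$upper)
  for (i in seq_len(k)) {
    w <- numeric(k)
    w[i] <- w_max
    w[-i] <- freqs_comp
    for (r in seq_len(n_resample_curves)) {
      X <- matrix(NA_real_, NS, k, dimnames = list(NULL, inputs$name))
      for (j in seq_len(k)) {
        g <- 0.5 + (1 / pi) * asin(sin(w[j] * s + phases[j, i, r]))
        x <- lo[j] + (hi[j] - lo[j]) * g
        X[, j] <- if (inputs$scale[j] == "log") 10^x else x
      }
      blocks[[length(blocks) + 1L]] <- X
      meta[[length(meta) + 1L]] <- c(input = i, curve = r)
    }
  }
  structure(list(inputs = inputs, samples = do.call(rbind, blocks),
                 block_meta = do.call(rbind, meta), NS = NS,
                 M = M, w_max = w_max, n_resample_curves = n_resample_curves,
                 seed = seed, s = s),
            class = "efast_design")
}

#' Compute eFAST sensitivity indices
#'
#' Spectral variance decomposition of the model outputs evaluated at the
#' design samples: `S_i` is the variance share at the driving frequency and
#' its `M` harmonics, `S_ti = 1 - V_complementary/V` where the complementary
#' variance is the power below `w_max/2`. Point estimates pool the variance
#' components over the resample curves (ratio of summed variances) - the
#' per-curve ratio fluctuates with the random relative phases of main-effect
#' and interaction harmonics, and those coherence terms cancel in the pooled
#' sums; per-curve ratios are retained for the spread estimates. Non-finite
#' outputs are replaced by the per-curve median (count reported), since
#' dropping samples would corrupt the spectrum.
#'
#' @param design An [efast_design()].
#' @param outputs Numeric vector, one value per row of `design$samples`.
#' @return Object of class `sensitivity_result`: data.frame with `name`,
#'   `S_i`, `S_ti`, `S_ti_sd`, attributes `dummy_S_ti`, `n_imputed`,
#'   `degenerate`.
#' @export
efast_indices <- function(design, outputs) {
  stopifnot(inherits(design, "efast_design"),
            length(outputs) == nrow(design$samples))
  k <- nrow(design$inputs)
  NS <- design$NS
  M <- design$M
  w_max <- design$w_max
  nr <- design$n_resample_curves
  n_imputed <- 0L
  Si <- Sti <- matrix(NA_real_, k, nr)
  sumV <- sumVi <- sumVc <- numeric(k)
  degenerate <- FALSE
  for (b in seq_len(nrow(design$block_meta))) {
    i <- design$block_meta[b, "input"]
    r <- design$block_meta[b, "curve"]
    y <- outputs[((b - 1L) * NS + 1L):(b * NS)]
    bad <- !is.finite(y)
    if (any(bad)) {
      y[bad] <- stats::median(y[!bad])
      n_imputed <- n_imputed + sum(bad)
    }
    y <- y - mean(y)
    co <- stats::fft(y) / NS
    # one-sided spectrum: power at frequency j (j = 1..(NS-1)/2)
    P <- 2 * Mod(co[2:((NS - 1) / 2 + 1)])^2
    V <- sum(P)
    if (V <= .Machine$double.eps * 100) {
      Si[i, r] <- 0; Sti[i, r] <- 0
      degenerate <- TRUE
      next
    }
    Vi <- sum(P[seq_len(M) * w_max])
    Vci <- sum(P[seq_len(max(1, floor(w_max / 2)))])
    Si[i, r] <- Vi / V
    Sti[i, r] <- 1 - Vci / V
    sumV[i] <- sumV[i] + V
    sumVi[i] <- sumVi[i] + Vi
    sumVc[i] <- sumVc[i] + Vci
  }
  ok <- sumV > 0
  S_i_hat <- ifelse(ok, sumVi / pmax(sumV, .Machine$double.xmin), 0)
  S_ti_hat <- ifelse(ok, 1 - sumVc / pmax(sumV, .Machine$double.xmin), 0)
  res <- data.frame(name = design$inputs$name,
                    S_i = S_i_hat, S_ti = S_ti_hat,
                    S_i_sd = apply(Si, 1, stats::sd),
                    S_ti_sd = apply(Sti, 1, stats::sd),
                    stringsAsFactors = FALSE)
  is_dummy <- res$name == "_dummy_"
  structure(res, class = c("sensitivity_result", "data.frame"),
            dummy_S_ti = if (any(is_dummy)) res$S_ti[is_dummy] else NA_real_,
            dummy_S_ti_sd = if (any(is_dummy)) res$S_ti_sd[is_dummy] else NA_real_,
            per_curve_S_ti = Sti,
            n_imputed = n_imputed, degenerate = degenerate)
}

#' Rank inputs whose total-order index exceeds the dummy floor
#'
#' @param result A [efast_indices()] result computed with a dummy input.
#' @param n_sd How many dummy standard deviations above the dummy mean an
#'   input must lie to count as influential.
#' @return `data.frame(name, S_ti)` of significant inputs, ranked descending;
#'   zero rows if none.
#' @export
rank_influential <- function(result, n_sd = 2) {
  stopifnot(inherits(result, "sensitivity_result"))
  dummy <- attr(result, "dummy_S_ti")
  if (is.na(dummy)) stop("result was computed without a dummy input")
  floor_val <- dummy + n_sd * max(attr(result, "dummy_S_ti_sd"), 1e-12)
  df <- result[result$name != "_dummy_" & result$S_ti > floor_val,
               c("name", "S_ti")]
  df[order(-df$S_ti), , drop = FALSE]
}

#' eFAST analysis of the signaling model
#'
#' Varies the chosen rate constants / initial amounts ten-fold above and below
#' their baseline values (log-uniform) and decomposes the 2-hour maximum of
#' `pERK_total` under a fixed stimulus.
#'
#' @param model A `signaling_model`.
#' @param input_names Parameter and/or initial-amount names to vary.
#' @param stimulus `"fgf"` or `"vegf"`.
#' @param dose_nM Stimulus dose.
#' @param n_samples_per_curve,n_resample_curves,seed,M See [efast_design()].
#' @param fold Bound half-width as a fold change (default 10).
#' @param grid_step Output grid spacing in minutes for the underlying
#'   simulations (coarser than the default to keep large designs fast).
#' @return A `sensitivity_result` (attribute `design` holds the design).
#' @export
efast_model_sensitivity <- function(model, input_names,
                                    stimulus = c("fgf", "vegf"),
                                    dose_nM = 0.5,
                                    n_samples_per_curve = 65,
                                    n_resample_curves = 5, seed = 1, M = 4,
                                    fold = 10, grid_step = 2) {
  stimulus <- match.arg(stimulus)
  base <- c(model$network$parameters,
            stats::setNames(
              vapply(model$network$species, function(s) s$initial_amount,
                     numeric(1)),
              species_names(model$network)))
  missing <- setdiff(input_names, names(base))
  if (length(missing)) {
    stop("unknown inputs: ", paste(missing, collapse = ", "))
  }
  b <- base[input_names]
  if (any(b <= 0)) stop("baseline values of varied inputs must be positive")
  inputs <- data.frame(name = input_names, lower = b / fold, upper = b * fold,
                       scale = "log", stringsAsFactors = FALSE)
  design <- efast_design(inputs, n_samples_per_curve, n_resample_curves,
                         seed = seed, M = M)
  protocol <- stimulus_protocol(
    fgf_nM = if (stimulus == "fgf") dose_nM else 0,
    vegf_nM = if (stimulus == "vegf") dose_nM else 0,
    output_grid_min = seq(0, 120, by = grid_step))
  outputs <- apply(design$samples, 1, function(row) {
    ov <- row[names(row) != "_dummy_"]
    tryCatch(perk_metrics(model, params = ov, protocol = protocol)$max_pERK,
             error = function(e) NA_real_)
  })
  res <- efast_indices(design, outputs)
  attr(res, "design") <- design
  attr(res, "stimulus") <- stimulus
  res
}
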