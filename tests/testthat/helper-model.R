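# Memoized model builders (construction is cheap but repeated everywhere).

.model_cache <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.model_cache$main)) .model_cache$main <- build_main_network()
  .model_cache$main
}

test_heparin_model <- function() {
  if (is.null(.model_cache$hep)) {
    .model_cache$hep <- build_heparin_extension(test_model())
  }
  .model_cache$hep
}

test_best_fits <- function() {
  if (is.null(.model_cache$fits)) .model_cache$fits <- packaged_best_fits()
  .model_cache$fits
}

# coarse grid keeps multi-simulation tests fast
coarse_protocol <- function(fgf = 0, vegf = 0, hep = 0, step = 1) {
  stimulus_protocol(fgf_nM = fgf, vegf_nM = vegf, heparin_ug_per_ml = hep,
                    output_grid_min = seq(0, 120, by = step))
}
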