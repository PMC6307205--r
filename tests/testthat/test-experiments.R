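two_sets <- function() {
  b <- setNames(free_parameter_bounds(test_model())$baseline,
                free_parameter_bounds(test_model())$name)
  list(s1 = b, s2 = b * c(rep(1, 38), 1.2))  # second set: 20% more Raf
}

test_that("combination grid has the right shape and mono cells match re-runs", {
  m <- test_model()
  sets <- two_sets()[1]
  res <- run_combination_grid(m, sets, fgf_doses_nM = c(0.1, 0.5),
                              vegf_doses_nM = c(0.5))
  # cells: all (fgf, vegf) pairs minus the (0,0) corner
  expect_equal(nrow(res$metrics), (2 + 1) * (1 + 1) - 1)
  expect_equal(nrow(res$ratios), 2 * 1)
  expect_null(res$errors)
  # mono-stimulation cell equals an independent single run
  solo <- perk_metrics(m, sets$s1, stimulus_protocol(fgf_nM = 0.5))
  cell <- res$metrics[res$metrics$fgf_nM == 0.5 & res$metrics$vegf_nM == 0, ]
  expect_equal(cell$max_pERK, solo$max_pERK, tolerance = 1e-10)
  # ratio columns are consistent
  r <- res$ratios[1, ]
  expect_equal(r$R, r$max_combo / (r$max_fgf_alone + r$max_vegf_alone))
})

test_that("density scan: factor 1 is a no-op; metrics respond to density", {
  m <- test_model()
  sets <- two_sets()[1]
  res <- run_vegfr2_density_scan(m, sets, factors = c(1, 5))
  base_combo <- res[res$factor == 1 & res$condition == "combo", ]
  ref <- perk_metrics(m, sets$s1,
                      stimulus_protocol(fgf_nM = 0.5, vegf_nM = 0.5))
  expect_equal(base_combo$max_pERK, ref$max_pERK, tolerance = 1e-10)
  hi <- res[res$factor == 5 & res$condition == "vegf", ]
  lo <- res[res$factor == 1 & res$condition == "vegf", ]
  expect_gt(hi$max_pERK, lo$max_pERK)
  expect_error(run_vegfr2_density_scan(m, sets, factors = c(-1)), "factors")
})

test_that("trafficking swap: swapping to identical values is a no-op", {
  m <- test_model()
  # a set whose VEGFR2 rates already equal the FGFR1 rates
  pars <- m$network$parameters
  vals <- c(k_intf = unname(pars[["k_intf_R1"]]),
            k_recf = unname(pars[["k_recf_R1"]]),
            k_degf = unname(pars[["k_degf_R1"]]),
            k_intb = unname(pars[["k_intb_R1"]]),
            k_recb = unname(pars[["k_recb_R1"]]),
            k_degb = unname(pars[["k_degb_R1"]]))
  res <- run_trafficking_swap(m, list(s = vals),
                              selections = c("fitted", "all"))
  fitted <- res[res$condition == "fitted", "max_pERK"]
  all_sw <- res[res$condition == "all", "max_pERK"]
  expect_equal(fitted, all_sw, tolerance = 1e-10)
  expect_error(run_trafficking_swap(m, list(s = vals),
                                    selections = "k_bogus"),
               "unknown trafficking selection")
})

test_that("swapping VEGFR2 trafficking to FGFR1 rates changes the VEGF response", {
  m <- test_model()
  sets <- two_sets()[1]
  res <- run_trafficking_swap(m, sets, selections = c("fitted", "all", "k_int"))
  fitted <- res[res$condition == "fitted", "max_pERK"]
  all_sw <- res[res$condition == "all", "max_pERK"]
  expect_false(isTRUE(all.equal(fitted, all_sw)))
})

test_that("heparin difference: zero dose gives identically zero deltas", {
  h <- test_heparin_model()
  sets <- two_sets()[1]
  res <- run_heparin_difference(h, sets, fgf_doses_ng_ml = c(4),
                                times_min = c(30, 120),
                                heparin_ug_per_ml = 0)
  expect_true(all(abs(res$delta) < 1e-6))
})

test_that("heparin difference matches two independent single runs", {
  h <- test_heparin_model()
  sets <- two_sets()[1]
  res <- run_heparin_difference(h, sets, fgf_doses_ng_ml = c(20),
                                times_min = c(60))
  grid <- seq(0, 120, 0.5)
  f <- ligand_unit_convert(20, "ng_per_ml", "FGF")
  with_h <- readout(simulate(h, sets$s1,
                             stimulus_protocol(fgf_nM = f,
                                               heparin_ug_per_ml = 500,
                                               output_grid_min = grid)),
                    "pERK_total", h)
  no_h <- readout(simulate(h, sets$s1,
                           stimulus_protocol(fgf_nM = f,
                                             output_grid_min = grid)),
                  "pERK_total", h)
  manual <- with_h$value[grid == 60] - no_h$value[grid == 60]
  expect_equal(res$delta, manual, tolerance = 1e-9)
})

test_that("experiments do not mutate the packaged model or baseline", {
  m <- test_model()
  before <- m$network$parameters
  init_before <- vapply(m$network$species, function(s) s$initial_amount,
                        numeric(1))
  invisible(run_vegfr2_density_scan(m, two_sets()[1], factors = c(5)))
  expect_identical(m$network$parameters, before)
  expect_identical(vapply(m$network$species, function(s) s$initial_amount,
                          numeric(1)), init_before)
})

test_that("heparin dose 0 reproduces the main model exactly", {
  m <- test_model()
  h <- test_heparin_model()
  pr_main <- coarse_protocol(fgf = 0.8, step = 5)
  pr_hep <- coarse_protocol(fgf = 0.8, hep = 0, step = 5)
  a <- readout(simulate(m, NULL, pr_main), "pERK_total", m)
  b <- readout(simulate(h, NULL, pr_hep), "pERK_total", h)
  expect_equal(a$value, b$value, tolerance = 1e-8)
})

test_that("heparin shifts the pERK response up at high FGF and down at low FGF", {
  h <- test_heparin_model()
  res <- run_heparin_difference(h, list(s = NULL),
                                fgf_doses_ng_ml = c(0.16, 500),
                                times_min = c(30, 60, 90))
  lo <- res[res$fgf_ng_ml == 0.16, "delta"]
  hi <- res[res$fgf_ng_ml == 500, "delta"]
  expect_true(all(lo < 0))
  expect_true(all(hi > 0))
})
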