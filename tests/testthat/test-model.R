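test_that("main model has the declared structural counts", {
  m <- test_model()
  expect_length(m$network$reactions, 70)
  expect_length(m$network$species, 72)
  expect_length(m$network$parameters, 75)
  expect_length(m$free_names, 39)
})

test_that("heparin extension adds exactly 26 reactions, 25 species, 3 parameters", {
  m <- test_model()
  h <- test_heparin_model()
  expect_equal(length(h$network$reactions) - length(m$network$reactions), 26L)
  expect_equal(length(h$network$species) - length(m$network$species), 25L)
  expect_equal(length(h$network$parameters) - length(m$network$parameters), 3L)
  expect_error(build_heparin_extension(m, -1), "non-negative")
})

test_that("default receptor and co-receptor densities match the reported levels", {
  init <- default_initial_amounts()
  expect_equal(init[["FGFR1"]], 20000)
  expect_equal(init[["VEGFR2"]], 1000)
  expect_equal(init[["HSGAG"]], 1e5)
})

test_that("every reaction balances each protein moiety", {
  # check_model_integrity() stops on imbalance; also spot-check via the
  # stoichiometry matrix against composition weight vectors
  for (model in list(test_model(), test_heparin_model())) {
    expect_silent(check_model_integrity(model))
    S <- stoichiometry_matrix(model$network)
    for (w in moiety_weights(model, c("FGFR1", "VEGFR2", "ERK", "MEK"))) {
      full <- setNames(numeric(nrow(S)), rownames(S))
      full[names(w)] <- w
      expect_lt(max(abs(drop(full %*% S))), 1e-12)
    }
  }
})

test_that("ligand unit conversion honours the reported dose pairings", {
  expect_equal(ligand_unit_convert(100, "ng_per_ml", "FGF"), 4)
  expect_equal(ligand_unit_convert(50, "ng_per_ml", "VEGF"), 1.1)
  expect_equal(ligand_unit_convert(0, "ng_per_ml", "FGF"), 0)
  expect_equal(ligand_unit_convert(0, "ng_per_ml", "VEGF"), 0)
  # round trip
  expect_equal(ligand_unit_convert(ligand_unit_convert(7, "ng_per_ml", "FGF"),
                                   "nM", "FGF"), 7)
  expect_error(ligand_unit_convert(-1, "ng_per_ml", "FGF"), "non-negative")
})

test_that("readouts sum exactly their member species", {
  m <- test_model()
  tr <- simulate(m, NULL, coarse_protocol(fgf = 0.5, step = 5))
  for (nm in c("pERK_total", "pR2_total", "ppMEK")) {
    members <- m$readout_defs[[nm]]
    manual <- rowSums(sapply(members, function(s) tr$amounts[, s]))
    expect_equal(readout(tr, nm, m)$value, manual, ignore_attr = TRUE)
  }
  expect_error(readout(tr, "nonsense", m), "unknown readout")
})

test_that("pR2_total excludes the degraded pool", {
  m <- test_model()
  expect_false("pR2_deg" %in% m$readout_defs$pR2_total)
  expect_true("pR2_i" %in% m$readout_defs$pR2_total)
})

test_that("zero stimulus leaves ERK unphosphorylated", {
  m <- test_model()
  tr <- simulate(m, NULL, coarse_protocol(step = 5))
  expect_true(all(abs(readout(tr, "pERK_total", m)$value) < 1e-6))
})

test_that("receptor, MAPK and phosphatase moieties are conserved on trajectories", {
  m <- test_model()
  tr <- simulate(m, NULL, coarse_protocol(fgf = 0.5, vegf = 0.5, step = 5))
  for (w in moiety_weights(m, c("FGFR1", "VEGFR2", "FRS2", "ERK", "MEK",
                                "Ras", "Raf", "Ptase2"))) {
    tot <- as.vector(tr$amounts[, names(w), drop = FALSE] %*% w)
    expect_equal(tot, rep(tot[1], length(tot)), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("FGF dose response across the training panel is biphasic", {
  m <- test_model()
  doses <- ligand_unit_convert(fgf_training_doses_ng_ml(), "ng_per_ml", "FGF")
  mx <- vapply(doses, function(d) {
    compute_metrics(readout(simulate(m, NULL, coarse_protocol(fgf = d)),
                            "pERK_total", m))$max_pERK
  }, numeric(1))
  peak <- which.max(mx)
  expect_gt(peak, 1)
  expect_lt(peak, length(mx))
  expect_gt(mx[peak] / mx[1], 1.1)
  expect_gt(mx[peak] / mx[length(mx)], 1.02)
})

test_that("FRS2 is rapidly depleted even at 0.01 nM FGF", {
  m <- test_model()
  tr <- simulate(m, NULL, coarse_protocol(fgf = 0.01))
  fr <- readout(tr, "FRS2_free", m)$value
  expect_lt(min(fr) / fr[1], 0.15)
})

test_that("packaged model fixtures match the in-code builders", {
  main_path <- system.file("extdata", "model_main.yaml", package = "mapkcross")
  hep_path <- system.file("extdata", "model_heparin.yaml",
                          package = "mapkcross")
  m <- test_model()$network
  f <- read_network_yaml(main_path)
  expect_equal(species_names(f), species_names(m))
  expect_equal(f$parameters[names(m$parameters)], m$parameters)
  expect_equal(stoichiometry_matrix(f), stoichiometry_matrix(m))
  h <- read_network_yaml(hep_path)
  expect_length(h$reactions, 96)
})
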