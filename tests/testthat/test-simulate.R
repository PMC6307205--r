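test_that("protocol validation enforces the grid and horizon contracts", {
  expect_error(stimulus_protocol(fgf_nM = -1), "fgf_nM")
  expect_error(stimulus_protocol(horizon_min = 200), "2-hour")
  expect_s3_class(stimulus_protocol(horizon_min = 200, allow_long = TRUE),
                  "stimulus_protocol")
  expect_error(stimulus_protocol(output_grid_min = c(1, 2)), "start at 0")
  expect_error(stimulus_protocol(output_grid_min = c(0, 2, 2)),
               "strictly increasing")
})

test_that("identical inputs give bit-identical trajectories", {
  m <- test_model()
  t1 <- simulate(m, NULL, coarse_protocol(fgf = 0.5, step = 5))
  t2 <- simulate(m, NULL, coarse_protocol(fgf = 0.5, step = 5))
  expect_identical(t1$amounts, t2$amounts)
})

test_that("tightening solver tolerances barely changes the solution", {
  m <- test_model()
  pr <- coarse_protocol(fgf = 0.5, step = 2)
  a <- readout(simulate(m, NULL, pr, rtol = 1e-8, atol = 1e-6),
               "pERK_total", m)$value
  b <- readout(simulate(m, NULL, pr, rtol = 1e-10, atol = 1e-8),
               "pERK_total", m)$value
  scale <- max(b)
  expect_lt(max(abs(a - b)) / scale, 1e-3)
})

test_that("trajectories stay non-negative within solver tolerance", {
  m <- test_model()
  tr <- simulate(m, NULL, coarse_protocol(fgf = 2, vegf = 2, step = 2))
  expect_gt(min(tr$amounts), -1e-2)
})

test_that("parameter and initial-amount overrides are applied by name", {
  m <- test_model()
  tr <- simulate(m, c(FRS2 = 500), coarse_protocol(step = 10))
  expect_equal(tr$amounts[1, "FRS2"], 500, ignore_attr = TRUE)
  expect_error(simulate(m, c(bogus = 1), coarse_protocol(step = 10)),
               "unknown parameter")
})

test_that("heparin protocols require the extended model", {
  m <- test_model()
  expect_error(simulate(m, NULL, coarse_protocol(fgf = 0.5, hep = 500)),
               "heparin")
})

test_that("maximum pERK is monotone non-decreasing in VEGF dose", {
  m <- test_model()
  doses <- c(0.01, 0.1, 0.5, 1, 2)
  mx <- vapply(doses, function(v) {
    compute_metrics(readout(simulate(m, NULL, coarse_protocol(vegf = v)),
                            "pERK_total", m))$max_pERK
  }, numeric(1))
  expect_true(all(diff(mx) > -1e-9 * max(mx)))
})

test_that("ensemble simulation preserves order, tags failures, averages correctly", {
  m <- test_model()
  sets <- list(a = c(FRS2 = 12000), b = c(FRS2 = 6000), c = c(FRS2 = 3000))
  trs <- ensemble_simulate(m, sets, coarse_protocol(fgf = 0.1, step = 5))
  expect_named(trs, c("a", "b", "c"))
  er <- ensemble_readout(trs, "pERK_total", m)
  # independent element-wise averaging oracle
  manual <- (readout(trs$a, "pERK_total", m)$value +
               readout(trs$b, "pERK_total", m)$value +
               readout(trs$c, "pERK_total", m)$value) / 3
  expect_equal(er$mean, manual)
  # identical sets -> zero ensemble sd
  trs2 <- ensemble_simulate(m, list(x = NULL, y = NULL),
                            coarse_protocol(fgf = 0.1, step = 10))
  er2 <- ensemble_readout(trs2, "pERK_total", m)
  expect_true(all(er2$sd == 0))
  # failures are tagged without aborting the rest
  bad <- list(ok = NULL, broken = c(nonexistent_param = 1))
  trs3 <- ensemble_simulate(m, bad, coarse_protocol(step = 10))
  expect_s3_class(trs3$broken, "simulation_error")
  expect_s3_class(trs3$ok, "trajectory")
})

test_that("tidy export contains the protocol fields", {
  m <- test_model()
  tr <- simulate(m, NULL, coarse_protocol(fgf = 0.25, step = 30))
  df <- as.data.frame(tr, species = c("FGFR1", "pERK"))
  expect_setequal(unique(df$species), c("FGFR1", "pERK"))
  expect_true(all(df$fgf_nM == 0.25))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path, species = "pERK")
  expect_true(file.exists(path))
  expect_equal(nrow(utils::read.csv(path)), length(tr$times))
})
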