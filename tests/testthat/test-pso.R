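test_that("weighted SSR matches element-wise accumulation", {
  expect_equal(wssr(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wssr(2, 1), 1)
  set.seed(5)
  p <- runif(20, 0.5, 2); o <- runif(20, 0.5, 2)
  acc <- 0
  for (i in 1:20) acc <- acc + ((p[i] - o[i]) / o[i])^2
  expect_equal(wssr(p, o), acc)
  expect_error(wssr(c(1, 2), c(1, 0)), "positive")
  expect_error(wssr(1:3, 1:2), "equal length")
})

test_that("normalization schemes: per-condition max 1; panel shares one max", {
  curves <- list(
    lo = data.frame(time_min = 0:4, value = c(0, 1, 2, 1, 0)),
    hi = data.frame(time_min = 0:4, value = c(0, 2, 8, 4, 0)))
  data <- data.frame(condition_id = rep(c("lo", "hi"), each = 3),
                     fgf_nM = 0, vegf_nM = 0, heparin_ug_per_ml = 0,
                     time_min = rep(1:3, 2),
                     value = rep(0.5, 6))
  ds_pc <- training_dataset("d", "pERK_total", "per_condition", data)
  pred <- normalize_prediction(curves, ds_pc)
  expect_equal(max(pred[1:3]), 1)   # lo curve peaks at its own max
  expect_equal(max(pred[4:6]), 1)
  ds_pm <- training_dataset("d", "pERK_total", "panel_max", data)
  pred2 <- normalize_prediction(curves, ds_pm)
  expect_equal(max(pred2), 1)
  expect_equal(max(pred2[1:3]), 2 / 8)  # lo curve normalized by global max
  # brute-force two-pass oracle
  gmax <- max(sapply(curves, function(cv) max(cv$value)))
  expect_equal(pred2[4:6], curves$hi$value[2:4] / gmax)
})

test_that("PSO finds the sphere optimum and the trace is monotone", {
  sphere <- function(x) sum(x^2)
  fit <- pso_minimize(sphere, rep(-5, 5), rep(5, 5),
                      n_particles = 30, n_iter = 150, seed = 3)
  expect_lt(fit$value, 1e-6)
  expect_true(all(abs(fit$par) < 1e-3))
  expect_true(all(diff(fit$trace) <= 0))
  # determinism
  fit2 <- pso_minimize(sphere, rep(-5, 5), rep(5, 5),
                       n_particles = 30, n_iter = 150, seed = 3)
  expect_identical(fit$par, fit2$par)
  # a non-trivial box (Rosenbrock in 2D) stays within bounds
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  fit3 <- pso_minimize(rosen, c(-2, -2), c(2, 2), n_particles = 30,
                       n_iter = 200, seed = 8)
  expect_lt(fit3$value, 1e-3)
})

test_that("training objective is zero on self-generated noise-free data", {
  m <- test_model()
  study <- generate_training_like(m, noise_cv = 0, seed = 2)
  obj <- training_objective(NULL, m, study$datasets, grid_step = 0.5)
  expect_lt(obj, 1e-6)
  # dataset order does not matter
  obj2 <- training_objective(NULL, m, rev(study$datasets), grid_step = 0.5)
  expect_equal(obj, obj2)
})

test_that("objective is deterministic given theta", {
  m <- test_model()
  study <- generate_training_like(m, noise_cv = 0.1, seed = 3)
  th <- setNames(free_parameter_bounds(m)$baseline, free_parameter_bounds(m)$name)
  o1 <- training_objective(th, m, study$datasets, grid_step = 2)
  o2 <- training_objective(th, m, study$datasets, grid_step = 2)
  expect_identical(o1, o2)
})

test_that("select_best returns the top 16 by combined error with tie-breaks", {
  mk_fit <- function(id, train) {
    structure(list(value = train, trace = train, seed = 1,
                   parameter_set = parameter_set(c(k = 1), id = id)),
              class = "fit_result")
  }
  set.seed(11)
  train <- runif(72, 10, 30)
  val <- runif(72, 0, 5)
  fits <- lapply(seq_len(72), function(i) mk_fit(sprintf("f%02d", i), train[i]))
  sel <- select_best(fits, validation_scores = val, k = 16)
  expect_length(sel, 16)
  # brute-force full sort oracle: every selected error <= every non-selected
  combined <- train + val
  sel_ids <- vapply(sel, function(p) p$id, character(1))
  sel_idx <- match(sel_ids, sprintf("f%02d", seq_len(72)))
  expect_lte(max(combined[sel_idx]), min(combined[-sel_idx]))
  # identical fits: first 16 by id
  fits_eq <- lapply(seq_len(20), function(i) mk_fit(sprintf("f%02d", i), 1))
  sel_eq <- select_best(fits_eq, k = 16)
  expect_equal(vapply(sel_eq, function(p) p$id, character(1)),
               sprintf("f%02d", 1:16))
  expect_warning(select_best(fits_eq[1:3], k = 16), "fewer")
})

test_that("free-parameter bounds span one order of magnitude around baseline", {
  m <- test_model()
  b <- free_parameter_bounds(m)
  expect_equal(nrow(b), 39)
  expect_equal(b$upper / b$baseline, rep(10, 39))
  expect_equal(b$baseline / b$lower, rep(10, 39))
})

test_that("parameter sets validate bounds and dataset CSV round-trips", {
  expect_error(parameter_set(c(k = 5), bounds = list(k = c(0, 1))), "bounds")
  m <- test_model()
  study <- generate_training_like(m, noise_cv = 0.05, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_datasets_csv(study$datasets, path)
  back <- read_datasets_csv(path)
  expect_length(back, 3)
  orig <- study$datasets[[1]]
  rt <- back[[orig$name]]
  expect_equal(rt$data$value, orig$data$value, tolerance = 1e-12)
  expect_equal(rt$scheme, orig$scheme)
})
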