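linear_inputs <- data.frame(name = c("x1", "x2", "x3"),
                            lower = 0, upper = 1, scale = "linear")

test_that("design samples stay within bounds and respect the seed", {
  d1 <- efast_design(linear_inputs, 65, 2, seed = 4)
  expect_true(all(d1$samples >= 0 & d1$samples <= 1.5))
  for (nm in c("x1", "x2", "x3")) {
    expect_true(all(d1$samples[, nm] >= 0 & d1$samples[, nm] <= 1))
  }
  d2 <- efast_design(linear_inputs, 65, 2, seed = 4)
  expect_identical(d1$samples, d2$samples)
  d3 <- efast_design(linear_inputs, 65, 2, seed = 5)
  expect_false(identical(d1$samples, d3$samples))
})

test_that("sample budget below the Nyquist bound errors", {
  expect_error(efast_design(linear_inputs, n_samples_per_curve = 30),
               "Nyquist")
})

test_that("each input's samples are near-uniform over its range", {
  d <- efast_design(linear_inputs, 257, 1, seed = 2)
  blk <- d$samples[seq_len(d$NS), ]  # first curve
  for (nm in c("x1", "x2", "x3")) {
    ks <- suppressWarnings(ks.test(blk[, nm], "punif"))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("additive linear model: indices match the analytic variance shares", {
  a <- c(4, 2, 1)
  d <- efast_design(linear_inputs, 129, 5, seed = 9)
  y <- as.vector(d$samples[, 1:3] %*% a)
  res <- efast_indices(d, y)
  shares <- a^2 / sum(a^2)  # equal uniform variances
  got <- res$S_ti[match(c("x1", "x2", "x3"), res$name)]
  expect_equal(got, shares, tolerance = 0.06)
  # first-order equals total-order for an additive model
  expect_equal(res$S_i[match(c("x1", "x2", "x3"), res$name)], got,
               tolerance = 0.06)
  expect_lte(sum(res$S_i), 1.1)
})

test_that("Ishigami total-order indices match the closed form", {
  # y = sin(x1) + a sin(x2)^2 + b x3^4 sin(x1), a = 7, b = 0.1, x ~ U(-pi,pi)
  a <- 7; b <- 0.1
  inputs <- data.frame(name = c("x1", "x2", "x3"), lower = -pi, upper = pi,
                       scale = "linear")
  d <- efast_design(inputs, 513, 15, seed = 12)
  X <- d$samples
  y <- sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
  res <- efast_indices(d, y)
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  ST <- c(0.5 * (1 + b * pi^4 / 5)^2 + 8 * b^2 * pi^8 / 225,
          a^2 / 8,
          8 * b^2 * pi^8 / 225) / V
  got <- res$S_ti[match(c("x1", "x2", "x3"), res$name)]
  expect_equal(got, ST, tolerance = 0.05)
  # dummy index is statistically indistinguishable from zero
  expect_lt(attr(res, "dummy_S_ti"), 0.05)
})

test_that("permuting input order permutes but does not change indices", {
  inputs <- data.frame(name = c("x1", "x2", "x3"), lower = -pi, upper = pi,
                       scale = "linear")
  f <- function(X) sin(X[, "x1"]) + 7 * sin(X[, "x2"])^2 +
    0.1 * X[, "x3"]^4 * sin(X[, "x1"])
  d1 <- efast_design(inputs, 257, 9, seed = 3)
  r1 <- efast_indices(d1, f(d1$samples))
  d2 <- efast_design(inputs[c(2, 3, 1), ], 257, 9, seed = 3)
  r2 <- efast_indices(d2, f(d2$samples))
  for (nm in c("x1", "x2", "x3")) {
    expect_equal(r2$S_ti[r2$name == nm], r1$S_ti[r1$name == nm],
                 tolerance = 0.1)
  }
})

test_that("S_i <= S_ti within estimator noise", {
  inputs <- data.frame(name = c("x1", "x2", "x3"), lower = -pi, upper = pi,
                       scale = "linear")
  d <- efast_design(inputs, 129, 5, seed = 21)
  X <- d$samples
  y <- sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
  res <- efast_indices(d, y)
  expect_true(all(res$S_i <= res$S_ti + 0.05))
})

test_that("zero-variance output yields zero indices with a degenerate flag", {
  d <- efast_design(linear_inputs, 65, 2, seed = 1)
  res <- efast_indices(d, rep(3, nrow(d$samples)))
  expect_true(all(res$S_ti == 0))
  expect_true(attr(res, "degenerate"))
  expect_equal(nrow(rank_influential(res)), 0L)
})

test_that("rank_influential separates active inputs from the dummy floor", {
  d <- efast_design(linear_inputs, 129, 5, seed = 6)
  y <- as.vector(d$samples[, 1:3] %*% c(4, 2, 1))
  rk <- rank_influential(efast_indices(d, y))
  expect_equal(rk$name[1], "x1")
  expect_true(all(c("x1", "x2") %in% rk$name))
  expect_false("_dummy_" %in% rk$name)
  expect_true(all(diff(rk$S_ti) <= 0))
})
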