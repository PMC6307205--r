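test_that("mass-action rate law matches direct substitution", {
  # one-step receptor phosphorylation with explicit numbers
  r <- reaction("R1", c(VEGF = 1, VEGFR2 = 1), c(pVEGFR2 = 1), kf = 3, kr = 5)
  expect_equal(mass_action_rate(r, c(VEGF = 1, VEGFR2 = 2, pVEGFR2 = 0)), 6)
  expect_equal(mass_action_rate(r, c(VEGF = 0, VEGFR2 = 0, pVEGFR2 = 0)), 0)
  # rate-constant sharing by parameter name
  r2 <- reaction("R2", c(A = 2), c(B = 1), kf = "k", kr = "k")
  expect_equal(mass_action_rate(r2, c(A = 3, B = 4), parameters = c(k = 0.5)),
               0.5 * 9 - 0.5 * 4)
  expect_error(mass_action_rate(r, c(VEGF = 1)), "lacks species")
})

test_that("flux agrees with an independent product-of-powers oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    r <- reaction("Rx",
                  setNames(sample(1:3, 2), c("X", "Y")),
                  setNames(sample(1:2, 1), "Z"),
                  kf = runif(1, 0, 5), kr = runif(1, 0, 5))
    st <- c(X = runif(1, 0, 4), Y = runif(1, 0, 4), Z = runif(1, 0, 4))
    expect_equal(mass_action_rate(r, st), oracle_flux(r, st), tolerance = 1e-12)
  }
})

test_that("network validation catches configuration errors", {
  sp <- list(species("A", "internal", 1), species("B", "internal", 0))
  expect_error(reaction_network(sp, list(reaction("R1", c(A = 1), c(Q = 1), 1))),
               "unknown species")
  expect_error(reaction_network(sp, list(reaction("R1", c(A = 1), c(B = 1), "k"))),
               "unknown parameter")
  expect_error(species("A", initial_amount = -1), "non-negative")
  expect_error(reaction("R1", c(A = 1.5), c(B = 1), 1), "positive integers")
  expect_error(reaction("R1", c(A = 1), c(B = 1), -2), "non-negative")
})

test_that("assembled RHS reproduces the analytic solution of A <-> B", {
  net <- toy_ab_network(kf = 1, kr = 1, a0 = 2, b0 = 0)
  rhs <- assemble_rhs(net)
  times <- seq(0, 6, by = 0.1)
  out <- deSolve::lsoda(c(A = 2, B = 0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(out[, "A"], 1 + exp(-2 * times), tolerance = 1e-7,
               ignore_attr = TRUE)
  # equilibrium is A = B = 1
  expect_equal(unname(out[nrow(out), "A"]), 1, tolerance = 1e-4)
})

test_that("compiled RHS agrees with a hand-expanded oracle on random networks", {
  for (seed in 1:25) {
    net <- random_small_network(seed)
    st <- random_state(net, seed + 1000)
    rhs <- assemble_rhs(net, backend = "compiled")
    got <- rhs(0, st, NULL)[[1]]
    want <- oracle_rhs(net, st)
    expect_equal(got, unname(want), tolerance = 1e-12)
    # plain-R backend agrees too
    rhs_r <- assemble_rhs(net, backend = "R")
    expect_equal(rhs_r(0, st, NULL)[[1]], unname(want), tolerance = 1e-12)
  }
})

test_that("clamped species have zero derivative regardless of fluxes", {
  net <- reaction_network(
    list(species("L", "extracellular", 5, clamped = TRUE),
         species("R", "surface", 3), species("C", "surface", 0)),
    list(reaction("R1", c(L = 1, R = 1), c(C = 1), 2, 1)))
  rhs <- assemble_rhs(net)
  dy <- rhs(0, c(L = 5, R = 3, C = 0.5), NULL)[[1]]
  expect_identical(dy[1], 0)
  expect_equal(dy[2], -(2 * 5 * 3 - 1 * 0.5))
})

test_that("conserved moieties: chain total is conserved, clamp breaks it", {
  net <- chain_network()
  W <- conserved_moieties(net)
  expect_equal(ncol(W), 1L)
  expect_true(is_conserved(net, c(A = 1, B = 1, C = 1)))
  # the (1,1,1) direction spans the null space
  w <- W[, 1]
  expect_equal(abs(sum(w * c(1, 1, 1))) / sqrt(3), 1, tolerance = 1e-10)

  # clamped source feeding synthesis is excluded from moieties
  net2 <- reaction_network(
    list(species("S", "extracellular", 1, clamped = TRUE),
         species("A", "internal", 0)),
    list(reaction("R1", c(S = 1), c(A = 1), 1)))
  W2 <- conserved_moieties(net2)
  expect_false("S" %in% rownames(W2))
  expect_equal(ncol(W2), 0L)
})

test_that("moieties are constant along simulated trajectories", {
  net <- chain_network()
  rhs <- assemble_rhs(net)
  out <- deSolve::lsoda(c(A = 5, B = 0, C = 0), seq(0, 10, 0.5), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  total <- rowSums(out[, c("A", "B", "C")])
  expect_equal(total, rep(5, length(total)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("YAML serialization round-trips losslessly", {
  net <- random_small_network(42)
  path <- tempfile(fileext = ".yaml")
  write_network_yaml(net, path)
  net2 <- read_network_yaml(path)
  expect_equal(species_names(net2), species_names(net))
  expect_equal(stoichiometry_matrix(net2), stoichiometry_matrix(net))
  expect_equal(reaction_rates(net2), reaction_rates(net))
  st <- random_state(net, 99)
  expect_equal(assemble_rhs(net2)(0, st, NULL)[[1]],
               assemble_rhs(net)(0, st, NULL)[[1]])
})

test_that("SBML export is well-formed and complete", {
  net <- toy_ab_network()
  path <- tempfile(fileext = ".xml")
  export_sbml(net, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  expect_equal(length(xml2::xml_find_all(doc, "//s:species", ns)), 2L)
  expect_equal(length(xml2::xml_find_all(doc, "//s:reaction", ns)), 1L)
  expect_equal(length(xml2::xml_find_all(doc, "//s:kineticLaw", ns)), 1L)
})
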