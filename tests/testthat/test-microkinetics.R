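test_that("Eyring rates match closed-form arithmetic", {
  expect_equal(eyring_rate(0, 333.15), 6.94172e12, tolerance = 1e-5)
  # adding RT ln 10 to the barrier divides the rate by exactly 10
  rt_ln10 <- 8.314462618 * 333.15 * log(10) / 1000
  expect_equal(eyring_rate(50 + rt_ln10, 333.15), eyring_rate(50, 333.15) / 10,
               tolerance = 1e-12)
  # huge barriers underflow smoothly
  expect_equal(eyring_rate(500, 333.15), 0, tolerance = 1e-60)
  expect_gt(eyring_rate(500, 333.15), 0)
  expect_error(eyring_rate(-1), "non-negative")
  expect_error(eyring_rate(10, -300), "positive")
})

test_that("rate models satisfy detailed balance", {
  net <- make_chain_network(c(0, -8.314462618 * 333.15 * log(2) / 1000))
  rm <- build_rate_model(net)
  # thermoneutral would give k_fwd = k_bwd; here dG = -RT ln 2 so the ratio is 2
  expect_equal(rm$steps$k_fwd / rm$steps$k_bwd, 2, tolerance = 1e-9)

  net2 <- make_chain_network(c(0, 0))
  rm2 <- build_rate_model(net2)
  expect_equal(rm2$steps$k_fwd, rm2$steps$k_bwd, tolerance = 1e-12)

  # the paper fixture builds without error and balances every step
  rmx <- build_rate_model(fixture_net())
  g <- rmx$g_formation
  rt <- 8.314462618 * rmx$temperature / 1000
  for (i in seq_len(nrow(rmx$steps))) {
    s <- rmx$steps[i, ]
    dg <- g[[s$to]] - g[[s$from]]
    expect_equal(s$k_fwd / s$k_bwd, exp(-dg / rt), tolerance = 1e-9)
  }

  # a step lacking both g_a and the equilibrated flag is rejected
  bad <- make_chain_network(c(0, -5))
  bad$steps[[1]]$g_a <- NA_real_
  expect_error(build_rate_model(bad), "equilibrated")
})

test_that("simulated kinetics reproduce closed forms", {
  # A -> B irreversible: A(t) = exp(-k t)
  sp <- list(species("A", "sugar_tautomer", 0L, c(1, 0, 0, 0), g_formation = 0),
             species("B", "monoacetal", 0L, c(1, 0, 0, 0), g_formation = -40),
             species("HCHO", "reference", 0L, c(0, 1, 0, 0), g_formation = 0),
             species("H2O", "reference", 0L, c(0, 0, 1, 0), g_formation = 0),
             species("H3O+", "reference", 1L, c(0, 0, 0, 1), g_formation = 0))
  st <- list(elementary_step("ab", "A", "B", delta_g = -40, g_a = 70, reversible = FALSE))
  net <- reaction_network(sp, st, references = c("A", "HCHO", "H2O", "H3O+"))
  rm <- build_rate_model(net)
  k_min <- rm$steps$k_fwd * 60
  tr <- simulate_kinetics(rm, c(A = 1), t_end = 3 / k_min, n_points = 31)
  expect_equal(tr$A, exp(-k_min * tr$time_min), tolerance = 1e-6)

  # thermoneutral A <-> B relaxes to 50/50
  net2 <- make_chain_network(c(0, 0))
  rm2 <- build_rate_model(net2)
  k2 <- rm2$steps$k_fwd * 60
  tr2 <- simulate_kinetics(rm2, c(X1 = 1), t_end = 20 / k2, n_points = 11)
  expect_equal(unlist(tr2[nrow(tr2), c("X1", "X2")]), c(X1 = 0.5, X2 = 0.5),
               tolerance = 1e-6)

  # A -> I -> P with k1 > k2: Bateman solution, intermediate unimodal
  g3 <- c(0, -30, -120)
  net3 <- make_chain_network(g3)
  net3$steps[[1]]$g_a <- 60
  net3$steps[[2]]$g_a <- 95   # slower second step
  net3$steps[[1]]$reversible <- net3$steps[[2]]$reversible <- FALSE
  rm3 <- build_rate_model(net3)
  k1 <- rm3$steps$k_fwd[1] * 60; k2b <- rm3$steps$k_fwd[2] * 60
  tr3 <- simulate_kinetics(rm3, c(X1 = 1), t_end = 5 / k2b, n_points = 101)
  bateman <- k1 / (k2b - k1) * (exp(-k1 * tr3$time_min) - exp(-k2b * tr3$time_min))
  expect_equal(tr3$X2, bateman, tolerance = 1e-5)
  expect_true(is_unimodal(tr3$X2))

  expect_error(simulate_kinetics(rm2, c(X1 = 0.7), t_end = 1), "sum to 1")
  expect_error(simulate_kinetics(rm2, c(nope = 1), t_end = 1), "named")
})

test_that("squaring propagation agrees with the stiff integrator on a mild network", {
  net <- gen_toy_network(5, seed = 11)
  rm <- build_rate_model(net)
  tr_a <- simulate_kinetics(rm, c(S1 = 1), t_end = 0.01, n_points = 21)
  tr_b <- simulate_kinetics(rm, c(S1 = 1), t_end = 0.01, n_points = 21,
                            method = "squaring")
  expect_equal(as.matrix(tr_b[, -1]), as.matrix(tr_a[, -1]), tolerance = 1e-6)
})

test_that("mass is conserved and closed networks reach Boltzmann populations", {
  for (seed in c(3, 17)) {
    net <- gen_toy_network(6, seed = seed, g_range = c(-25, 10))
    rm <- build_rate_model(net)
    tr <- simulate_kinetics(rm, c(S1 = 1), t_end = 60, n_points = 41)
    frac <- as.matrix(tr[, -1])
    expect_lt(max(abs(rowSums(frac) - 1)), 1e-6)
    expect_true(all(frac > -1e-12))

    eq <- equilibrium_fractions(rm)
    tr_long <- simulate_kinetics(rm, c(S1 = 1), t_end = 1e5, n_points = 5,
                                 method = "squaring")
    final <- unlist(tr_long[nrow(tr_long), -1])
    expect_equal(final / eq[names(final)], rep(1, length(final)),
                 ignore_attr = TRUE, tolerance = 1e-4)
  }
})

test_that("fixture dynamics mirror the operando phenomenology", {
  net <- fixture_net()
  rm <- build_rate_model(net)
  tr <- simulate_kinetics(rm, c(alpha_xylopyranose = 1), t_end = 1e16,
                          n_points = 201, log_time = TRUE, t_first = 1e-12,
                          method = "squaring")
  expect_lt(max(abs(rowSums(as.matrix(tr[, -1])) - 1)), 1e-6)
  pools <- pool_traces(tr)
  # pyranose-monoacetal pools rise and then decay
  for (nm in c("Int1", "Int2", "Int3")) {
    expect_true(is_unimodal(pools[[nm]]))
    expect_gt(max(pools[[nm]]), 0.05)
    expect_lt(pools[[nm]][nrow(pools)], 1e-4)
  }
  # the furanose diacetal is non-decreasing and dominates at long time
  expect_true(all(diff(pools$diacetal) > -1e-9))
  expect_gt(pools$diacetal[nrow(pools)], 0.9)
})

test_that("deepening the diacetal well never lowers its long-time fraction", {
  net <- fixture_net()
  frac_dfx <- function(extra) {
    n2 <- net
    n2$species$DFX$g_formation <- n2$species$DFX$g_formation - extra
    n2$species$DFX$energy_terms$E <- n2$species$DFX$energy_terms$E - extra
    equilibrium_fractions(build_rate_model(n2))[["DFX"]]
  }
  f <- vapply(c(0, 10, 25, 60), frac_dfx, numeric(1))
  expect_true(all(diff(f) >= 0))
})

test_that("pyranose selectivity is a percentage with an undefined flag", {
  expect_equal(pyranose_selectivity(0, 3), 0)
  expect_equal(pyranose_selectivity(2, 2), 50)
  expect_equal(pyranose_selectivity(30, 70), 30)
  expect_true(is.na(pyranose_selectivity(0, 0)))
  expect_error(pyranose_selectivity(-1, 2), "non-negative")
})
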