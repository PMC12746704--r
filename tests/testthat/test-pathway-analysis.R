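test_that("profiles accumulate step energies and insert transition states", {
  net <- make_chain_network(c(0, -10), g_a_offset = 0)
  net$steps[[1]]$g_a <- 15
  pr <- build_profile(net, c("X1", "X2"))
  expect_equal(pr$g_cum, c(0, 15, -10))
  expect_equal(pr$kind, c("intermediate", "transition_state", "intermediate"))

  # cumulative-sum oracle: (-100, ga 30) then (+20, ga 110)
  net2 <- make_chain_network(c(0, -100, -80))
  net2$steps[[1]]$g_a <- 30
  net2$steps[[2]]$g_a <- 110
  pr2 <- build_profile(net2, c("X1", "X2", "X3"))
  expect_equal(pr2$g_cum, c(0, 30, -100, 10, -80))

  # barrierless and uncomputed steps contribute no TS state
  net3 <- make_chain_network(c(0, -5), g_a_offset = 0)
  expect_equal(nrow(build_profile(net3, c("X1", "X2"))), 2)
  net4 <- make_chain_network(c(0, -5), equilibrated = TRUE)
  expect_equal(nrow(build_profile(net4, c("X1", "X2"))), 2)

  expect_error(build_profile(net3, c("X1", "nope")), "undeclared|connect")
  expect_error(build_profile(make_chain_network(c(0, 1, 2)), c("X1", "X3")),
               "no elementary step")
})

test_that("profiles can traverse reversible steps against their direction", {
  net <- make_chain_network(c(0, -10), g_a_offset = 0)
  net$steps[[1]]$g_a <- 15
  pr <- build_profile(net, c("X2", "X1"))
  expect_equal(pr$g_cum, c(0, 25, 10))  # shared TS sits g_a - dG above X2
})

test_that("apparent barrier matches the exhaustive pairwise oracle", {
  # frozen examples
  p <- structure(data.frame(label = c("a", "ts", "b"),
                            kind = c("intermediate", "transition_state", "intermediate"),
                            g_cum = c(0, 50, -10)),
                 class = c("pathway_profile", "data.frame"))
  sr <- apparent_barrier(p)
  expect_equal(sr$span, 50)
  expect_equal(c(sr$low_state, sr$high_state), c("a", "ts"))

  p2 <- structure(data.frame(label = paste0("s", 1:5),
                             kind = c("intermediate", "transition_state", "intermediate",
                                      "transition_state", "intermediate"),
                             g_cum = c(0, 30, -100, 10, -150)),
                  class = c("pathway_profile", "data.frame"))
  sr2 <- apparent_barrier(p2)
  expect_equal(sr2$span, 110)
  expect_equal(c(sr2$low_state, sr2$high_state), c("s3", "s4"))

  # monotone downhill profile has zero span at the first state
  down <- structure(data.frame(label = c("a", "b", "c"),
                               kind = rep("intermediate", 3),
                               g_cum = c(0, -5, -60)),
                    class = c("pathway_profile", "data.frame"))
  sd <- apparent_barrier(down)
  expect_equal(sd$span, 0)
  expect_equal(sd$low_state, sd$high_state)

  # property: oracle equivalence on random profiles
  set.seed(42)
  for (i in 1:300) {
    pr <- random_profile(sample(2:12, 1))
    expect_equal(apparent_barrier(pr)$span, span_oracle(pr))
  }
})

test_that("span is shift-invariant, bounds single-step barriers, and reverses predictably", {
  set.seed(7)
  for (i in 1:50) {
    pr <- random_profile(sample(3:12, 1))
    shifted <- pr
    shifted$g_cum <- shifted$g_cum + 37.5
    expect_equal(apparent_barrier(shifted)$span, apparent_barrier(pr)$span)

    # reversal relation: span(rev) - span(pr) is bounded by the net drop;
    # check the exact antisymmetry of climbs on all-intermediate profiles
    pr$kind[] <- "intermediate"
    rev <- pr
    rev$g_cum <- rev(pr$g_cum) - pr$g_cum[nrow(pr)]
    # max climb of reversed profile equals max drop of the original
    drop_max <- max(0, max(outer(pr$g_cum, pr$g_cum, function(a, b) a - b)[
      upper.tri(matrix(0, nrow(pr), nrow(pr)))]))
    expect_equal(apparent_barrier(rev)$span, drop_max)
  }

  net <- make_chain_network(c(0, -40, -30, -90))
  pr <- build_profile(net, paste0("X", 1:4))
  max_ga <- max(vapply(net$steps, `[[`, 0, "g_a"))
  expect_gte(apparent_barrier(pr)$span + 1e-9, max_ga)
})

test_that("pathway enumeration ranks deterministically by span", {
  # one-route network: the unique path's span equals its profile span
  net <- make_chain_network(c(0, -20, 10, -60))
  r <- enumerate_pathways(net, "X1", "X4")
  expect_equal(nrow(r), 1)
  expect_equal(r$span, apparent_barrier(build_profile(net, paste0("X", 1:4)))$span)

  # two-branch toy: branch with span 40 ranked before span 60
  sp <- c(lapply(c("S", "T"), function(id)
    species(id, "sugar_tautomer", 0L, c(1, 0, 0, 0), g_formation = 0)),
    lapply(c("A", "B"), function(id)
      species(id, "monoacetal", 0L, c(1, 0, 0, 0), g_formation = -5)),
    list(species("HCHO", "reference", 0L, c(0, 1, 0, 0), g_formation = 0),
         species("H2O", "reference", 0L, c(0, 0, 1, 0), g_formation = 0),
         species("H3O+", "reference", 1L, c(0, 0, 0, 1), g_formation = 0)))
  st <- list(elementary_step("sa", "S", "A", delta_g = -5, g_a = 40),
             elementary_step("at", "A", "T", delta_g = 5, g_a = 20),
             elementary_step("sb", "S", "B", delta_g = -5, g_a = 60),
             elementary_step("bt", "B", "T", delta_g = 5, g_a = 20))
  net2 <- reaction_network(sp, st, references = c("S", "HCHO", "H2O", "H3O+"))
  r2 <- enumerate_pathways(net2, "S", "T")
  expect_equal(r2$span[1], 40)
  expect_match(r2$path[1], "-> A ->")
  # deterministic under re-evaluation
  expect_identical(r2, enumerate_pathways(net2, "S", "T"))

  expect_equal(nrow(enumerate_pathways(net, "X4", "X1", max_states = 1)), 0)
})

test_that("anomer route comparison reproduces the fixture preference order", {
  net <- fixture_net()
  tab <- compare_anomer_routes(net, c("Int4_alpha", "Int4_beta", "Int5_alpha"))
  expect_equal(tab$target, c("Int5_alpha", "Int4_alpha", "Int4_beta"))
  expect_equal(tab$span, c(145.0, 152.5, 186.2), tolerance = 1e-6)
  expect_equal(tab$low_state, c("14b", "18a", "M12b"))

  # a missing target is recorded as absent, not an error
  tab2 <- compare_anomer_routes(net, c("Int5_alpha", "Int9_gamma"))
  expect_true(is.na(tab2$span[tab2$target == "Int9_gamma"]))

  # an out-of-reach target ranks last
  sp_extra <- c(net$species, list(far = species("far", "monoacetal", 0L,
                                                c(1, 0, 0, 0), g_formation = 0)))
  names(sp_extra)[length(sp_extra)] <- "far"
  net3 <- net
  net3$species <- sp_extra
  net3$steps <- c(net3$steps, list(
    elementary_step("huge", "alpha_xylopyranose", "far", delta_g = 0, g_a = 999)))
  tab3 <- compare_anomer_routes(net3, c("Int5_alpha", "far"))
  expect_equal(tab3$target[nrow(tab3)], "far")
  expect_equal(tab3$span[2], 999)
})
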