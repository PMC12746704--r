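test_that("an empty reference-only network loads with defaults", {
  f <- withr::local_tempfile(fileext = ".json")
  refs <- list(
    list(id = "alpha_xylopyranose", role = "sugar_tautomer", charge = 0,
         stoich = c(1, 0, 0, 0), g_formation = 0),
    list(id = "HCHO", role = "reference", charge = 0, stoich = c(0, 1, 0, 0), g_formation = 0),
    list(id = "H2O", role = "reference", charge = 0, stoich = c(0, 0, 1, 0), g_formation = 0),
    list(id = "H3O+", role = "reference", charge = 1, stoich = c(0, 0, 0, 1), g_formation = 0)
  )
  jsonlite::write_json(list(units = "kJ/mol", temperature_K = 333.15,
                            references = c("alpha_xylopyranose", "HCHO", "H2O", "H3O+"),
                            species = refs, steps = list()),
                       f, auto_unbox = TRUE, digits = NA)
  net <- load_network(f)
  expect_length(net$species, 4)
  expect_length(net$steps, 0)
  expect_equal(net$temperature, 333.15)
})

test_that("the packaged pathway-2 fixture carries the near-barrierless proton transfer", {
  p2 <- load_network(system.file("extdata", "pathway2.json", package = "acetalnet"))
  hit <- Filter(function(s) s$from == "16a" && s$to == "18a", p2$steps)
  expect_length(hit, 1)
  expect_equal(hit[[1]]$g_a, 1)
  expect_equal(nrow(validate_network(p2)), 0)
})

test_that("loading fails loudly on malformed files", {
  net <- make_chain_network(c(0, -10))
  f <- withr::local_tempfile(fileext = ".json")
  save_network(net, f)
  raw <- jsonlite::fromJSON(f, simplifyVector = FALSE)

  bad <- raw
  bad$steps[[1]]$to <- "M99x"
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE, digits = NA)
  expect_error(load_network(f2), "M99x")

  bad <- raw
  bad$units <- NULL
  jsonlite::write_json(bad, f2, auto_unbox = TRUE, digits = NA)
  expect_error(load_network(f2), "units")

  bad <- raw
  bad$species <- c(bad$species, bad$species[1])
  jsonlite::write_json(bad, f2, auto_unbox = TRUE, digits = NA)
  expect_error(load_network(f2), "duplicate")
})

test_that("energies declared in eV are converted to kJ/mol on load", {
  net <- make_chain_network(c(0, -96.4853))
  f <- withr::local_tempfile(fileext = ".json")
  save_network(net, f)
  raw <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  raw$units <- "eV"
  for (i in seq_along(raw$species)) {
    if (!is.null(raw$species[[i]]$g_formation))
      raw$species[[i]]$g_formation <- raw$species[[i]]$g_formation / 96.4853
  }
  for (i in seq_along(raw$steps)) {
    raw$steps[[i]]$delta_g <- raw$steps[[i]]$delta_g / 96.4853
    if (!is.null(raw$steps[[i]]$g_a)) raw$steps[[i]]$g_a <- raw$steps[[i]]$g_a / 96.4853
  }
  jsonlite::write_json(raw, f, auto_unbox = TRUE, digits = NA, null = "null")
  ev <- load_network(f)
  expect_equal(ev$species$X2$g_formation, -96.4853, tolerance = 1e-12)
  expect_equal(ev$steps[[1]]$delta_g, -96.4853, tolerance = 1e-12)
})

test_that("save/load round trip preserves every numeric field", {
  net <- xylose_fa_network()
  f <- withr::local_tempfile(fileext = ".json")
  save_network(net, f)
  back <- load_network(f)
  expect_identical(names(back$species), names(net$species))
  for (id in names(net$species)) {
    a <- net$species[[id]]; b <- back$species[[id]]
    expect_equal(b$g_formation, a$g_formation, tolerance = 1e-9)
    expect_equal(b$stoich, a$stoich)
    if (!is.null(a$energy_terms)) expect_equal(b$energy_terms, a$energy_terms, tolerance = 1e-9)
  }
  for (id in names(net$steps)) {
    expect_equal(back$steps[[id]]$delta_g, net$steps[[id]]$delta_g, tolerance = 1e-9)
    expect_equal(back$steps[[id]]$g_a, net$steps[[id]]$g_a, tolerance = 1e-9)
  }
})

test_that("validate_network reports violations as data", {
  ok <- make_chain_network(c(0, -20, -5))
  expect_equal(nrow(validate_network(ok)), 0)

  # proton-addition step with consistent stoichiometry is clean
  sp <- list(
    species("A", "sugar_tautomer", 0L, c(1, 0, 0, 0), g_formation = 0),
    species("B", "protonated_intermediate", 1L, c(1, 0, -1, 1), g_formation = -30),
    species("HCHO", "reference", 0L, c(0, 1, 0, 0), g_formation = 0),
    species("H2O", "reference", 0L, c(0, 0, 1, 0), g_formation = 0),
    species("H3O+", "reference", 1L, c(0, 0, 0, 1), g_formation = 0)
  )
  st <- list(elementary_step("p1", "A", "B", delta_g = -30, g_a = 5,
                             consumes = c(`H3O+` = 1), releases = c(H2O = 1)))
  net <- reaction_network(sp, st, references = c("A", "HCHO", "H2O", "H3O+"))
  expect_equal(nrow(validate_network(net)), 0)

  # negative activation energy
  bad <- net
  bad$steps[[1]]$g_a <- -5
  v <- validate_network(bad)
  expect_match(v$rule, "negative activation", all = FALSE)

  # imbalanced proton bookkeeping
  bad <- net
  bad$steps[[1]]$releases[] <- 0
  v <- validate_network(bad)
  expect_true(any(grepl("imbalance", v$rule)))

  # inconsistent explicit reverse pair: 10 vs -9.5
  st2 <- list(elementary_step("f", "A", "B", delta_g = 10, g_a = 15,
                              consumes = c(`H3O+` = 1), releases = c(H2O = 1)),
              elementary_step("r", "B", "A", delta_g = -9.5, g_a = 5,
                              consumes = c(H2O = 1), releases = c(`H3O+` = 1)))
  net2 <- reaction_network(sp, st2, references = c("A", "HCHO", "H2O", "H3O+"))
  v <- validate_network(net2)
  expect_true(any(grepl("reverse mismatch 0.5", v$rule)))
})

test_that("reverse_step performs single-TS diagram arithmetic", {
  s <- elementary_step("s", "A", "B", delta_g = -10, g_a = 15)
  r <- reverse_step(s)
  expect_equal(r$delta_g, 10)
  expect_equal(r$g_a, 25)
  expect_equal(r$from, "B")

  sym <- elementary_step("s", "A", "B", delta_g = 0, g_a = 7)
  expect_equal(reverse_step(sym)$g_a, 7)

  unphys <- elementary_step("s", "A", "B", delta_g = 20, g_a = 5)
  expect_error(reverse_step(unphys), "inconsistent")

  # involution restores all fields exactly
  s2 <- elementary_step("s2", "A", "B", delta_g = -33.25, g_a = 41.5,
                        consumes = c(HCHO = 1, `H3O+` = 1), releases = c(H2O = 1),
                        tags = c("1", "side"))
  expect_identical(reverse_step(reverse_step(s2)), s2)
})

test_that("the packaged network fixture is clean and large enough", {
  net <- fixture_net()
  expect_equal(nrow(validate_network(net)), 0)
  expect_gte(length(net$steps), 140)
})
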