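# shared in-code fixtures for the test suite

# minimal network: the four references plus a chain of states built from
# explicit potentials; every step reversible with g_a = max(0, dG) + offset
make_chain_network <- function(g, g_a_offset = 10, temperature = 333.15,
                               equilibrated = FALSE) {
  n <- length(g)
  ids <- paste0("X", seq_len(n))
  sp <- c(
    lapply(seq_len(n), function(i)
      species(ids[i], if (i == 1) "sugar_tautomer" else "monoacetal",
              charge = 0L, stoich = c(1, 0, 0, 0), g_formation = g[i] - g[1])),
    list(species("HCHO", "reference", 0L, c(0, 1, 0, 0), g_formation = 0),
         species("H2O", "reference", 0L, c(0, 0, 1, 0), g_formation = 0),
         species("H3O+", "reference", 1L, c(0, 0, 0, 1), g_formation = 0))
  )
  steps <- lapply(seq_len(n - 1), function(i) {
    dg <- g[i + 1] - g[i]
    elementary_step(sprintf("c%02d", i), ids[i], ids[i + 1], delta_g = dg,
                    g_a = if (equilibrated) NA_real_ else max(0, dg) + g_a_offset,
                    equilibrated = equilibrated, tags = "side")
  })
  reaction_network(sp, steps, references = c("X1", "HCHO", "H2O", "H3O+"),
                   temperature = temperature)
}

# random free-energy profile for span property tests
random_profile <- function(n) {
  kind <- c("intermediate",
            sample(c("intermediate", "transition_state"), n - 1, replace = TRUE))
  g <- c(0, round(stats::runif(n - 1, -120, 120), 3))
  structure(data.frame(label = paste0("s", seq_len(n)), kind = kind, g_cum = g),
            class = c("pathway_profile", "data.frame"), pathway_id = NA_character_)
}

# exhaustive-pair oracle for the energetic span
span_oracle <- function(profile) {
  g <- profile$g_cum
  best <- 0
  for (i in seq_along(g)) {
    if (profile$kind[i] != "intermediate") next
    for (j in seq_along(g)) {
      if (j > i) best <- max(best, g[j] - g[i])
    }
  }
  best
}

# single maximum then non-increasing, within numerical tolerance
is_unimodal <- function(x, tol = 1e-6) {
  i <- which.max(x)
  all(diff(x[seq_len(i)]) > -tol) && all(diff(x[i:length(x)]) < tol)
}

fixture_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- xylose_fa_network()
    net
  }
})
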