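#' Generate a synthetic van't Hoff equilibrium series
#'
#' Emulates the tautomer-ratio measurement protocol: equilibrium constants
#' on a 20-140 C grid in 10 C increments (13 points), generated from
#' K(T) = exp(-dH/(R T) + dS/R) with multiplicative lognormal noise on K
#' (peak-area ratios are ratio data, so the noise is multiplicative). The
#' default truth parameters are the measured apparent enthalpy and entropy
#' of the xylopyranose -> xylofuranose conversion, dH = 11.3 kJ/mol and
#' dS = 13.6 J/(K mol).
#'
#' @param dH truth enthalpy, kJ/mol.
#' @param dS truth entropy, J/(K mol).
#' @param temps_c temperature grid in degrees C.
#' @param sigma_lnK standard deviation of the lognormal noise on K
#'   (sigma of ln K); must be >= 0. Default 0.02.
#' @param seed integer seed; fixed seed gives identical output.
#' @param pair pair label.
#' @param path optional TSV output path (columns `temperature_C`, `K` with a
#'   `# pair:` header); written when non-`NULL`.
#' @return an [equilibrium_series()] (invisibly returns `path` unchanged in
#'   the attribute `"path"` when written).
#' @export
gen_vant_hoff <- function(dH = 11.3, dS = 13.6, temps_c = seq(20, 140, by = 10),
                          sigma_lnK = 0.02, seed = 1, pair = "pyranose->furanose",
                          path = NULL) {
  if (sigma_lnK < 0) stop("sigma_lnK must be non-negative", call. = FALSE)
  t_k <- temps_c + 273.15
  k_true <- exp(-dH * 1000 / (.R_GAS * t_k) + dS / .R_GAS)
  noise <- withr_seed(seed, stats::rnorm(length(t_k), 0, sigma_lnK))
  series <- equilibrium_series(t_k, k_true * exp(noise), pair = pair)
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(c(paste0("# pair: ", pair), "temperature_C\tK"), con)
    utils::write.table(data.frame(temperature_C = temps_c, K = series$K), con,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    close(con)
  }
  series
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate noisy kinetic observations from a network
#'
#' Simulates the microkinetic model and emulates the operando sampling:
#' one observation every `cadence` minutes (default 6 min, over 10 h),
#' additive truncated-at-zero Gaussian noise on the mole fractions
#' (integration noise), renormalized per time point so the sugar-derived
#' fractions still sum to 1.
#'
#' @param net a [reaction_network()].
#' @param init named initial mole fractions (default: all sugar in the first
#'   reference species).
#' @param t_end end time, minutes (default 600 = 10 h).
#' @param cadence observation spacing, minutes.
#' @param sigma additive noise s.d. on fractions; >= 0.
#' @param seed integer seed.
#' @param temperature K; defaults to the network temperature.
#' @param method integration method passed to [simulate_kinetics()].
#' @param path optional CSV output path (`time_min`, one column per species).
#' @return a `"kinetic_trace"` data frame.
#' @export
gen_kinetic_observations <- function(net, init = NULL, t_end = 600, cadence = 6,
                                     sigma = 0.01, seed = 1,
                                     temperature = net$temperature,
                                     method = "lsoda", path = NULL) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  model <- build_rate_model(net, temperature)
  if (is.null(init)) init <- stats::setNames(1, net$references[1])
  n_points <- floor(t_end / cadence) + 1
  tr <- simulate_kinetics(model, init, t_end = t_end, n_points = n_points,
                          method = method)
  frac <- as.matrix(tr[, -1, drop = FALSE])
  if (sigma > 0) {
    noise <- withr_seed(seed, matrix(stats::rnorm(length(frac), 0, sigma),
                                     nrow = nrow(frac)))
    frac <- pmax(frac + noise, 0)
    frac <- frac / rowSums(frac)
  }
  out <- cbind(tr[, 1, drop = FALSE], as.data.frame(frac))
  class(out) <- c("kinetic_trace", "data.frame")
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Generate a synthetic aldehyde descriptor table
#'
#' Builds `n` synthetic aldehydes whose frontier-orbital energies are chosen
#' so the computed carbonyl electrophilicities span both sides of the
#' 28-29 kcal/mol pyranose-acetal threshold band, and which are internally
#' consistent (EI is recomputable from the orbital energies to machine
#' precision).
#'
#' @param n number of aldehydes (>= 2).
#' @param ei_cho_range kcal/mol range spanned by the EI_CHO targets; must
#'   straddle the threshold band.
#' @param seed integer seed.
#' @param path optional CSV output path.
#' @return data frame in the format of [compute_descriptors()] input.
#' @export
gen_descriptor_table <- function(n = 8, ei_cho_range = c(18, 40), seed = 1,
                                 path = NULL) {
  stopifnot(n >= 2, ei_cho_range[1] < 28, ei_cho_range[2] > 29)
  tab <- withr_seed(seed, {
    targets <- seq(ei_cho_range[1], ei_cho_range[2], length.out = n)
    spin <- stats::runif(n, 0.45, 0.85)
    eta_ev <- stats::runif(n, 2.6, 4.2)
    ei_ev <- convert_energy(targets / spin, "kcal/mol", "eV")
    mu <- -sqrt(2 * eta_ev * ei_ev)
    q_neutral <- round(stats::runif(n, 0.05, 0.20), 4)
    fukui <- round(0.10 + 0.005 * targets + stats::rnorm(n, 0, 0.01), 4)
    data.frame(name = sprintf("ALD%02d", seq_len(n)),
               e_homo = mu - eta_ev, e_lumo = mu + eta_ev,
               unit = "eV",
               spin_density_C = round(spin, 4),
               q_neutral = q_neutral,
               q_radical = q_neutral + fukui)
  })
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' Generate a random, thermodynamically consistent toy network
#'
#' Builds a connected isomerization network over `n` states from latent
#' per-state potentials: reaction free energies are potential differences
#' (so every loop closes exactly and forward/reverse pairs are consistent by
#' construction) and each barrier is `max(0, delta_g)` plus a positive
#' offset. The first state is the sugar reference at potential zero. All
#' generated networks pass [validate_network()] with an empty report.
#'
#' @param n_intermediates number of states (>= 2).
#' @param seed integer seed.
#' @param g_range potential range (kJ/mol) the non-reference states are
#'   drawn from.
#' @param extra_edges number of random extra connections beyond the spanning
#'   chain.
#' @return a [reaction_network()].
#' @export
gen_toy_network <- function(n_intermediates, seed = 1, g_range = c(-40, 15),
                            extra_edges = max(0, n_intermediates - 2)) {
  stopifnot(n_intermediates >= 2)
  withr_seed(seed, {
    ids <- paste0("S", seq_len(n_intermediates))
    g <- c(0, stats::runif(n_intermediates - 1, g_range[1], g_range[2]))
    sp <- c(
      lapply(seq_along(ids), function(i)
        species(ids[i], if (i == 1) "sugar_tautomer" else "monoacetal",
                charge = 0L, stoich = c(1, 0, 0, 0), g_formation = g[i])),
      list(species("HCHO", "reference", 0L, c(0, 1, 0, 0), g_formation = 0),
           species("H2O", "reference", 0L, c(0, 0, 1, 0), g_formation = 0),
           species("H3O+", "reference", 1L, c(0, 0, 0, 1), g_formation = 0))
    )
    pairs <- cbind(seq_len(n_intermediates - 1), seq_len(n_intermediates - 1) + 1)
    if (extra_edges > 0 && n_intermediates > 2) {
      for (k in seq_len(extra_edges)) {
        ij <- sort(sample(n_intermediates, 2))
        if (!any(pairs[, 1] == ij[1] & pairs[, 2] == ij[2]))
          pairs <- rbind(pairs, ij)
      }
    }
    steps <- lapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      dg <- g[j] - g[i]
      elementary_step(sprintf("e%02d", k), ids[i], ids[j], delta_g = dg,
                      g_a = max(0, dg) + stats::runif(1, 2, 30),
                      reversible = TRUE, tags = "side")
    })
    reaction_network(sp, steps, references = c("S1", "HCHO", "H2O", "H3O+"))
  })
}
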