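#' Temperature series of equilibrium constants
#'
#' Container for a tautomer-pair equilibrium series K(T) = C_i / C_j, e.g.
#' the aggregate pyranose -> furanose conversion of D-xylose measured by
#' quantitative NMR between 20 and 140 C.
#'
#' @param temperature temperatures; strictly increasing.
#' @param K dimensionless equilibrium constants, all positive.
#' @param pair label of the tautomer pair, e.g. `"pyranose->furanose"`.
#' @param celsius if `TRUE`, `temperature` is in degrees C and converted to K.
#' @return an object of class `"equilibrium_series"` (data frame with
#'   columns `temperature_K` and `K`).
#' @export
equilibrium_series <- function(temperature, K, pair = "pyranose->furanose",
                               celsius = FALSE) {
  t_k <- if (celsius) temperature + 273.15 else temperature
  if (any(diff(t_k) <= 0)) stop("temperatures must be strictly increasing", call. = FALSE)
  if (any(K <= 0)) stop("equilibrium constants must be positive", call. = FALSE)
  if (length(t_k) != length(K)) stop("temperature and K lengths differ", call. = FALSE)
  structure(data.frame(temperature_K = t_k, K = K),
            class = c("equilibrium_series", "data.frame"), pair = pair)
}

#' Read an equilibrium series from TSV
#'
#' Accepts the pair form (columns `temperature_C` or `temperature_K`, and
#' `K`) written by [gen_vant_hoff()].
#'
#' @param path TSV path.
#' @param pair pair label (defaults to a `# pair:` header comment if present).
#' @return an [equilibrium_series()].
#' @export
read_equilibrium_series <- function(path, pair = NULL) {
  header <- readLines(path, n = 5)
  if (is.null(pair)) {
    m <- grep("^# pair:", header, value = TRUE)
    pair <- if (length(m)) trimws(sub("^# pair:", "", m[1])) else "pyranose->furanose"
  }
  df <- utils::read.delim(path, comment.char = "#")
  if ("temperature_C" %in% names(df)) {
    equilibrium_series(df$temperature_C, df$K, pair = pair, celsius = TRUE)
  } else {
    equilibrium_series(df$temperature_K, df$K, pair = pair)
  }
}

#' Van't Hoff regression of an equilibrium series
#'
#' Ordinary least squares of ln K on 1/T: the slope is -dH/R and the
#' intercept dS/R, giving the apparent standard reaction enthalpy and
#' entropy with standard errors propagated from the regression. The fit is
#' unweighted.
#'
#' @param series an [equilibrium_series()] with at least 3 points.
#' @return an object of class `"vant_hoff_fit"`: list with `dH` (kJ/mol),
#'   `dS` (J/(K mol)), `se_dH`, `se_dS`, `r_squared`, `n` and `pair`.
#' @export
vant_hoff_fit <- function(series) {
  if (nrow(series) < 3)
    stop("need at least 3 temperatures to fit (use vant_hoff_solve for 2 points)",
         call. = FALSE)
  if (any(series$K <= 0)) stop("equilibrium constants must be positive", call. = FALSE)
  x <- 1 / series$temperature_K
  y <- log(series$K)
  fit <- stats::lm(y ~ x)
  # noiseless series trigger a benign "essentially perfect fit" note
  smry <- suppressWarnings(summary(fit))
  cf <- stats::coef(smry)
  structure(list(dH = -cf["x", "Estimate"] * .R_GAS / 1000,
                 dS = cf["(Intercept)", "Estimate"] * .R_GAS,
                 se_dH = cf["x", "Std. Error"] * .R_GAS / 1000,
                 se_dS = cf["(Intercept)", "Std. Error"] * .R_GAS,
                 r_squared = smry$r.squared,
                 n = nrow(series), pair = attr(series, "pair")),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff fit (%s, n = %d):\n", x$pair, x$n))
  cat(sprintf("  dH = %.2f +/- %.2f kJ/mol\n", x$dH, x$se_dH))
  cat(sprintf("  dS = %.2f +/- %.2f J/(K mol)\n", x$dS, x$se_dS))
  cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' Exact two-point van't Hoff solution
#'
#' Solves the 2x2 linear system through two (T, K) points; no uncertainty is
#' available. [vant_hoff_fit()] refuses 2-point input, this helper handles it.
#'
#' @param temperature length-2 temperatures, K.
#' @param K length-2 equilibrium constants.
#' @return list with `dH` (kJ/mol) and `dS` (J/(K mol)).
#' @export
vant_hoff_solve <- function(temperature, K) {
  stopifnot(length(temperature) == 2, length(K) == 2)
  if (any(K <= 0)) stop("equilibrium constants must be positive", call. = FALSE)
  x <- 1 / temperature; y <- log(K)
  slope <- diff(y) / diff(x)
  intercept <- y[1] - slope * x[1]
  list(dH = -slope * .R_GAS / 1000, dS = intercept * .R_GAS)
}

#' Standard reaction free energy at a temperature
#'
#' dG(T) = dH - T dS (units reconciled: dH in kJ/mol, dS in J/(K mol)).
#'
#' @param dH kJ/mol, or a `"vant_hoff_fit"` object (then `dS` is ignored).
#' @param dS J/(K mol).
#' @param temperature K.
#' @return dG in kJ/mol.
#' @examples
#' delta_g_at(11.3, 13.6, 333.15)  # 6.77 -> prints as 6.8 at one decimal
#' @export
delta_g_at <- function(dH, dS = NULL, temperature = .T_DEFAULT) {
  if (inherits(dH, "vant_hoff_fit")) { dS <- dH$dS; dH <- dH$dH }
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  dH - temperature * dS / 1000
}

#' Boltzmann tautomer fractions from relative free energies
#'
#' fraction_i = exp(-dG_i / R T) / sum_j exp(-dG_j / R T). The reference
#' tautomer carries dG = 0.
#'
#' @param dG numeric vector of per-tautomer free energies (kJ/mol) relative
#'   to the reference tautomer; names are carried through.
#' @param temperature K.
#' @return numeric vector of fractions summing to 1.
#' @export
tautomer_fractions <- function(dG, temperature = .T_DEFAULT) {
  if (!length(dG)) stop("empty free-energy list", call. = FALSE)
  rt <- .R_GAS * temperature / 1000
  w <- exp(-(dG - min(dG)) / rt)
  w / sum(w)
}

#' Equilibrium constants from per-tautomer peak areas
#'
#' Turns a long-form table of integrated NMR peak areas (one row per
#' temperature and tautomer) into an equilibrium series
#' K(T) = sum(numerator areas) / sum(denominator areas). Temperatures where
#' either side is entirely zero are dropped with a warning; a temperature
#' where all areas are zero is an error.
#'
#' @param areas data frame with columns `temperature_C` (or `temperature_K`),
#'   `tautomer`, `peak_area` (non-negative).
#' @param numerator,denominator character vectors of tautomer names, e.g.
#'   `c("alpha_furanose", "beta_furanose")` over
#'   `c("alpha_pyranose", "beta_pyranose")`. The open-chain form belongs to
#'   neither side of the aggregate pyranose -> furanose constant.
#' @param pair label for the resulting series.
#' @return an [equilibrium_series()].
#' @export
ratios_from_peak_areas <- function(areas,
                                   numerator = c("alpha_furanose", "beta_furanose"),
                                   denominator = c("alpha_pyranose", "beta_pyranose"),
                                   pair = "pyranose->furanose") {
  if (any(areas$peak_area < 0)) stop("peak areas must be non-negative", call. = FALSE)
  tcol <- if ("temperature_C" %in% names(areas)) "temperature_C" else "temperature_K"
  temps <- sort(unique(areas[[tcol]]))
  num <- den <- numeric(0); keep <- numeric(0)
  for (tt in temps) {
    sub <- areas[areas[[tcol]] == tt, ]
    if (all(sub$peak_area == 0))
      stop("all peak areas are zero at temperature ", tt, call. = FALSE)
    a_num <- sum(sub$peak_area[sub$tautomer %in% numerator])
    a_den <- sum(sub$peak_area[sub$tautomer %in% denominator])
    if (a_num == 0 || a_den == 0) {
      warning("dropping temperature ", tt, ": zero total area on one side")
      next
    }
    num <- c(num, a_num); den <- c(den, a_den); keep <- c(keep, tt)
  }
  equilibrium_series(keep, num / den, pair = pair,
                     celsius = tcol == "temperature_C")
}
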