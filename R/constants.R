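#' Physical constants and unit conversions
#'
#' The package works internally in kJ/mol. `convert_energy()` performs exact
#' linear conversions between the energy units that appear in quantum-chemistry
#' output and thermochemistry tables.
#'
#' Fixed constants:
#' * gas constant R = 8.314462618 J/(mol K)
#' * Boltzmann constant k_B = 1.380649e-23 J/K
#' * Planck constant h = 6.62607015e-34 J s
#' * 1 eV = 96.4853 kJ/mol, 1 kcal = 4.184 kJ, 1 Hartree = 2625.499639 kJ/mol
#'
#' @param value numeric vector of energies.
#' @param from,to one of `"kJ/mol"`, `"kcal/mol"`, `"eV"`, `"Hartree"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_energy(1, "eV", "kJ/mol")     # 96.4853
#' convert_energy(28, "kcal/mol", "kJ/mol") # 117.152
#' @export
convert_energy <- function(value, from, to) {
  stopifnot(is.numeric(value))
  f <- .unit_to_kj(from)
  t <- .unit_to_kj(to)
  value * (f / t)
}

# kJ/mol per one unit of each accepted energy unit
.energy_units <- c(
  "kJ/mol"   = 1,
  "kcal/mol" = 4.184,
  "eV"       = 96.4853,
  "Hartree"  = 2625.499639
)

.unit_to_kj <- function(unit) {
  if (!is.character(unit) || length(unit) != 1 || !unit %in% names(.energy_units)) {
    stop("unknown energy unit: ", deparse(unit),
         " (expected one of ", paste(names(.energy_units), collapse = ", "), ")",
         call. = FALSE)
  }
  .energy_units[[unit]]
}

.R_GAS  <- 8.314462618    # J/(mol K)
.K_BOLTZ <- 1.380649e-23  # J/K
.H_PLANCK <- 6.62607015e-34 # J s

# default analysis temperature: 60 C, the reaction temperature
.T_DEFAULT <- 333.15

# tolerance (kJ/mol) used when checking g_a >= max(0, delta_g):
# printed free energies are rounded to 0.1 kJ/mol
.GA_TOL <- 0.5

.SMALL_MOLECULES <- c("HCHO", "H2O", "H3O+")
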