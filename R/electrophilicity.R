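#' Conceptual-DFT descriptors from frontier-orbital energies
#'
#' From the HOMO and LUMO energies of a closed-shell molecule:
#' electronegativity mu = (e_HOMO + e_LUMO)/2, chemical hardness
#' eta = (e_LUMO - e_HOMO)/2, and the Parr electrophilicity index
#' EI = mu^2 / (2 eta). The returned values carry the unit of the input
#' energies (commonly eV or Hartree).
#'
#' @param e_homo,e_lumo frontier-orbital energies (vectorized); requires
#'   `e_lumo > e_homo` so the hardness is positive.
#' @return data frame with columns `mu`, `eta`, `ei`.
#' @examples
#' conceptual_dft(-7, -1)  # mu = -4, eta = 3, ei = 8/3
#' @export
conceptual_dft <- function(e_homo, e_lumo) {
  if (any(e_lumo <= e_homo))
    stop("e_lumo must exceed e_homo (zero or negative hardness)", call. = FALSE)
  mu <- (e_homo + e_lumo) / 2
  eta <- (e_lumo - e_homo) / 2
  data.frame(mu = mu, eta = eta, ei = mu^2 / (2 * eta))
}

#' Carbonyl-carbon electrophilicity index
#'
#' Localizes a molecule's electrophilicity index to the -CHO carbon by
#' weighting with the Mulliken spin density of that carbon in the radical
#' state: EI_CHO = EI * rho_spin. The unit follows `ei`.
#'
#' @param ei electrophilicity index (vectorized).
#' @param spin_density_C Mulliken spin density at the carbonyl carbon of the
#'   radical state; non-negative (populations may slightly exceed 1).
#' @return EI_CHO in the unit of `ei`.
#' @export
ei_cho <- function(ei, spin_density_C) {
  if (any(spin_density_C < 0)) stop("spin density must be non-negative", call. = FALSE)
  ei * spin_density_C
}

#' Condensed Fukui index of the carbonyl carbon
#'
#' Difference of the Mulliken charges on the -CHO carbon between the radical
#' and the neutral aldehyde.
#'
#' @param q_radical,q_neutral Mulliken charges (vectorized).
#' @return unitless Fukui index.
#' @export
fukui_index <- function(q_radical, q_neutral) q_radical - q_neutral

#' Classify the acetal scope of an aldehyde by EI_CHO
#'
#' Empirically, pyranose monoacetals form only for aldehydes whose
#' carbonyl-carbon electrophilicity exceeds a threshold band of
#' 28-29 kcal/mol; weaker aldehydes give furanose acetals only, because the
#' higher ring strain of trans-fused pyranose acetals is not compensated.
#' The band is inclusive on both ends.
#'
#' @param ei_cho_kcal EI_CHO in kcal/mol (vectorized).
#' @param threshold_band numeric length-2 band, default `c(28, 29)` kcal/mol.
#' @return character vector over `"furanose_only"`, `"boundary"`,
#'   `"pyranose_and_furanose"`.
#' @export
classify_acetal_scope <- function(ei_cho_kcal, threshold_band = c(28, 29)) {
  stopifnot(length(threshold_band) == 2, threshold_band[1] <= threshold_band[2])
  ifelse(ei_cho_kcal > threshold_band[2], "pyranose_and_furanose",
         ifelse(ei_cho_kcal < threshold_band[1], "furanose_only", "boundary"))
}

#' Compute the full descriptor pipeline for an aldehyde table
#'
#' Takes a flat table of electronic-structure descriptors (one aldehyde per
#' row) and appends mu, eta, EI, EI in kcal/mol, EI_CHO (kcal/mol), the
#' Fukui index, and the acetal-scope class.
#'
#' @param table data frame with columns `name`, `e_homo`, `e_lumo`, `unit`
#'   (energy unit of the orbital energies), `spin_density_C`, `q_neutral`,
#'   `q_radical`.
#' @return the input with descriptor columns appended.
#' @export
compute_descriptors <- function(table) {
  need <- c("name", "e_homo", "e_lumo", "unit", "spin_density_C", "q_neutral", "q_radical")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("descriptor table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cd <- conceptual_dft(table$e_homo, table$e_lumo)
  ei_kcal <- mapply(function(e, u) convert_energy(e, u, "kcal/mol"), cd$ei, table$unit)
  out <- cbind(table, cd)
  out$ei_kcal <- ei_kcal
  out$ei_cho_kcal <- ei_cho(ei_kcal, table$spin_density_C)
  out$fukui_C <- fukui_index(table$q_radical, table$q_neutral)
  out$acetal_scope <- classify_acetal_scope(out$ei_cho_kcal)
  out
}

#' Rank aldehydes by carbonyl electrophilicity
#'
#' Descending by `ei_cho_kcal`, with a deterministic alphabetical tie-break
#' on `name`. On the packaged descriptor table this reproduces the ordering
#' formaldehyde > propionaldehyde > dodecanal, with the aromatic aldehydes
#' below the saturated ones.
#'
#' @param table a data frame with at least `name` and `ei_cho_kcal` (e.g.
#'   from [compute_descriptors()]); at least one row.
#' @return the table ordered by rank, with a `rank` column prepended.
#' @export
rank_aldehydes <- function(table) {
  stopifnot(nrow(table) >= 1)
  ord <- order(-table$ei_cho_kcal, table$name)
  out <- cbind(rank = seq_len(nrow(table)), table[ord, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Read an aldehyde descriptor table from CSV
#'
#' @param path CSV with the columns documented in [compute_descriptors()].
#' @return data frame.
#' @export
read_descriptor_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged synthetic aldehyde descriptor table
#'
#' A small synthetic table of frontier-orbital and population descriptors
#' for the five aldehydes studied experimentally (formaldehyde FA,
#' propionaldehyde PA, dodecanal DA, benzaldehyde BnA,
#' 2-fluorobenzaldehyde FBnA). The numeric values are constructed, not
#' computed from wavefunctions; they are chosen to reproduce the qualitative
#' ordering of carbonyl electrophilicities (FA > PA > DA; aromatic below
#' saturated) and to straddle the 28-29 kcal/mol pyranose-acetal threshold.
#'
#' @return data frame as in [read_descriptor_table()].
#' @export
aldehyde_descriptor_table <- function() {
  read_descriptor_table(system.file("extdata", "aldehyde_descriptors_synthetic.csv",
                                    package = "acetalnet"))
}
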