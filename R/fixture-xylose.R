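#' The packaged xylose / formaldehyde acetalization network
#'
#' Loads the network describing acid-catalysed formylation of
#' alpha-D-xylopyranose to diformylxylose (DFX): the three parallel
#' conversion pathways (via the pyranose 1,2-O-monoacetal Int 3; via
#' anomerization/tautomerization to the furanose and Int 4; via the furanose
#' 3,5-O-monoacetal Int 5), the side branches to the pyranose monoacetals
#' Int 1 / Int 2 and to the beta-anomer acetals, ring-opened intermediates,
#' and the formylation chemistry considered at the remaining hydroxyl
#' positions — over 140 elementary steps in total.
#'
#' Free energies of states and steps reported in the literature for this
#' system are encoded at their reported values (kJ/mol, vacuum, 333.15 K,
#' referenced to isolated alpha-D-xylopyranose, HCHO, H2O and H3O+). The
#' remaining species and steps carry synthetic values built from per-species
#' potentials, so all thermodynamic-consistency invariants hold exactly;
#' hence the `_synthetic` fixture filename.
#'
#' @return a [reaction_network()].
#' @examples
#' net <- xylose_fa_network()
#' summary(net)
#' @export
xylose_fa_network <- function() {
  load_network(system.file("extdata", "xylose_fa_network_synthetic.json",
                           package = "acetalnet"))
}

#' Canonical state sequences of the three DFX-forming pathways
#'
#' Pathway 1 runs through the pyranose monoacetal Int 3-alpha; Pathway 2
#' through anomerization and tautomerization to alpha-xylofuranose and the
#' 1,2-O-furanose monoacetal Int 4-alpha; Pathway 3 through the 3,5-O
#' furanose monoacetal Int 5. By default the sequences stop at the
#' pathway-defining monoacetal (where the apparent barriers are compared);
#' with `to_dfx = TRUE` they continue to the diacetal product.
#'
#' @param pathway `"1"`, `"2"` or `"3"`.
#' @param to_dfx extend the sequence to DFX?
#' @return character vector of species ids, usable with [build_profile()].
#' @export
pathway_states <- function(pathway = c("1", "2", "3"), to_dfx = FALSE) {
  pathway <- match.arg(pathway)
  seqs <- list(
    "1" = c("alpha_xylopyranose", "6a", "8a", "M5a", "Int3_alpha",
            "RO3_alpha", "M17a", "Int4_alpha"),
    "2" = c("alpha_xylopyranose", "beta_xylopyranose", "beta_xylofuranose",
            "alpha_xylofuranose", "16a", "18a", "M11a", "Int4_alpha"),
    "3" = c("alpha_xylopyranose", "beta_xylopyranose", "beta_xylofuranose",
            "13b", "14b", "M8b", "Int5_beta", "Int5_alpha")
  )
  tails <- list(
    "1" = c("25a", "26a", "M15a", "DFX"),
    "2" = c("25a", "26a", "M15a", "DFX"),
    "3" = c("23a", "24a", "M14a", "DFX")
  )
  out <- seqs[[pathway]]
  if (to_dfx) out <- c(out, tails[[pathway]])
  out
}

#' Observable compound pools of the xylose / formaldehyde network
#'
#' Operando NMR resolves compounds, not microstates: each observed compound
#' corresponds in the model to its neutral form plus the protonated adducts
#' and ring-opened forms along its formation chemistry, which are
#' spectroscopically indistinguishable contributors on the common sugar
#' moiety. This helper returns that grouping so simulated traces can be
#' compared with the experimental phenomenology via [pool_traces()].
#'
#' @return named list mapping observable labels (`"xylose"`, `"Int1"`,
#'   `"Int2"`, `"Int3"`, `"Int4"`, `"Int5"`, `"diacetal"`) to species-id
#'   vectors.
#' @export
xylose_observable_pools <- function() {
  list(
    xylose = c("alpha_xylopyranose", "beta_xylopyranose", "alpha_xylofuranose",
               "beta_xylofuranose", "open_xylose",
               "RO_apyr", "RO_bpyr", "RO_afur", "RO_bfur"),
    Int1 = c("M1a", "M2a", "M3a", "Int1_alpha", "RO1_alpha",
             "M1b", "M2b", "M3b", "Int1_beta", "RO1_beta"),
    Int2 = c("M6a", "M7a", "M9a", "Int2_alpha", "RO2_alpha",
             "M6b", "M7b", "M9b", "Int2_beta", "RO2_beta"),
    Int3 = c("6a", "8a", "M5a", "Int3_alpha", "RO3_alpha",
             "6b", "8b", "M5b", "Int3_beta", "RO3_beta"),
    Int4 = c("M17a", "M16b", "16a", "18a", "M11a", "Int4_alpha",
             "16b", "17b", "M12b", "Int4_beta", "25a", "26a", "Int6a"),
    Int5 = c("13b", "14b", "M8b", "Int5_beta", "Int5_alpha", "23a", "24a"),
    diacetal = c("M15a", "M14a", "DFX")
  )
}

#' Sum kinetic-trace columns over compound pools
#'
#' @param trace a `"kinetic_trace"` from [simulate_kinetics()].
#' @param pools named list of species-id vectors, e.g.
#'   [xylose_observable_pools()]. Ids absent from the trace are ignored.
#' @return data frame with `time_min` and one column per pool.
#' @export
pool_traces <- function(trace, pools = xylose_observable_pools()) {
  out <- data.frame(time_min = trace$time_min)
  for (nm in names(pools)) {
    cols <- intersect(pools[[nm]], names(trace))
    out[[nm]] <- if (length(cols)) rowSums(trace[, cols, drop = FALSE]) else 0
  }
  out
}
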