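#' Construct a network species
#'
#' A species is a labelled thermodynamic state of the reaction network: a
#' sugar tautomer, a (possibly protonated) acetalization intermediate, an
#' acetal product, or one of the four reference molecules. Its composition is
#' tracked as stoichiometric counts `(a, b, c, d)` of the reference set
#' (alpha-D-xylopyranose, HCHO, H2O, H3O+), so that formation free energies of
#' all states share one zero. No molecular structure is stored.
#'
#' @param id short label, e.g. `"6a"`, `"Int3_alpha"`, `"DFX"`.
#' @param role one of `"reference"`, `"sugar_tautomer"`, `"open_intermediate"`,
#'   `"protonated_intermediate"`, `"monoacetal"`, `"diacetal"`,
#'   `"transition_state"`, `"small_molecule"`.
#' @param charge integer elementary charge; must equal the H3O+ count `d`.
#' @param stoich integer vector `(a, b, c, d)`: counts of the sugar reference,
#'   HCHO, H2O and H3O+ composing this state. Entries may be negative (e.g.
#'   condensations that release water).
#' @param energy_terms optional named list with `E` (electronic energy,
#'   kJ/mol), `ZPE` (kJ/mol) and `S` (entropy, J/(K mol)).
#' @param g_formation optional formation free energy in kJ/mol.
#' @param note optional free-text annotation (e.g. label aliases).
#' @return an object of class `"acetal_species"` (a named list).
#' @seealso [elementary_step()], [reaction_network()]
#' @export
species <- function(id, role, charge = 0L, stoich = c(0L, 0L, 0L, 0L),
                    energy_terms = NULL, g_formation = NA_real_, note = NA_character_) {
  roles <- c("reference", "sugar_tautomer", "open_intermediate",
             "protonated_intermediate", "monoacetal", "diacetal",
             "transition_state", "small_molecule")
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (!role %in% roles) stop("unknown species role: ", role, call. = FALSE)
  if (length(stoich) != 4) stop("stoich must have 4 entries (a, b, c, d)", call. = FALSE)
  if (any(stoich != round(stoich))) stop("stoich entries must be integers", call. = FALSE)
  if (!is.null(energy_terms)) {
    if (!all(c("E", "ZPE", "S") %in% names(energy_terms)))
      stop("energy_terms needs fields E, ZPE, S", call. = FALSE)
  }
  structure(list(id = id, role = role, charge = as.integer(charge),
                 stoich = as.numeric(stoich), energy_terms = energy_terms,
                 g_formation = as.numeric(g_formation), note = note),
            class = "acetal_species")
}

#' Construct an elementary step
#'
#' A directed edge of the reaction network carrying a reaction free energy
#' and, when a transition state was located, an activation free energy. Small
#' molecules consumed or released by the step (HCHO, H2O, H3O+) are recorded
#' as multisets so stoichiometric and charge balance can be validated.
#'
#' `g_a = 0` means an explicitly barrierless step; `g_a = NA` means no
#' transition state was computed. The distinction matters both for profile
#' construction (neither inserts a TS state) and for rate models (a step
#' without `g_a` must be flagged `equilibrated`).
#'
#' @param id step label.
#' @param from,to reactant- and product-state species ids.
#' @param delta_g reaction free energy, kJ/mol.
#' @param g_a optional activation free energy of the forward direction, kJ/mol.
#' @param ts_id optional transition-state label (e.g. `"TS_2c"`).
#' @param consumes,releases named integer vectors over `"HCHO"`, `"H2O"`,
#'   `"H3O+"`.
#' @param reversible logical; whether the step is treated as reversible.
#' @param equilibrated logical; fast low-barrier step lacking a computed
#'   `g_a` (e.g. anomerizations), treated as equilibrated by rate models.
#' @param tags character vector of pathway tags from
#'   `c("1", "2", "3", "side")`.
#' @return an object of class `"acetal_step"` (a named list).
#' @export
elementary_step <- function(id, from, to, delta_g, g_a = NA_real_, ts_id = NA_character_,
                            consumes = NULL, releases = NULL,
                            reversible = TRUE, equilibrated = FALSE,
                            tags = character()) {
  stopifnot(is.character(id), length(id) == 1)
  cons <- .as_multiset(consumes)
  rel <- .as_multiset(releases)
  structure(list(id = id, from = from, to = to,
                 delta_g = as.numeric(delta_g), g_a = as.numeric(g_a),
                 ts_id = ts_id, consumes = cons, releases = rel,
                 reversible = isTRUE(reversible), equilibrated = isTRUE(equilibrated),
                 tags = as.character(tags)),
            class = "acetal_step")
}

.as_multiset <- function(x) {
  out <- stats::setNames(numeric(3), .SMALL_MOLECULES)
  if (is.null(x) || length(x) == 0) return(out)
  if (is.null(names(x)) || !all(names(x) %in% .SMALL_MOLECULES))
    stop("consumes/releases must be named over ", paste(.SMALL_MOLECULES, collapse = ", "),
         call. = FALSE)
  out[names(x)] <- as.numeric(x)
  out
}

#' Assemble a reaction network
#'
#' @param species list of [species()] objects.
#' @param steps list of [elementary_step()] objects.
#' @param references character vector of the four reference ids, in the order
#'   (sugar reference, HCHO, H2O, H3O+).
#' @param temperature temperature in K (default 333.15 K, i.e. 60 C).
#' @return an object of class `"reaction_network"`.
#' @export
reaction_network <- function(species, steps, references, temperature = .T_DEFAULT) {
  stopifnot(length(references) == 4)
  ids <- vapply(species, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate species ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "),
                               call. = FALSE)
  sids <- vapply(steps, `[[`, "", "id")
  if (length(sids) && anyDuplicated(sids))
    stop("duplicate step ids: ", paste(unique(sids[duplicated(sids)]), collapse = ", "),
         call. = FALSE)
  missing_refs <- setdiff(references, ids)
  if (length(missing_refs))
    stop("reference species not declared: ", paste(missing_refs, collapse = ", "),
         call. = FALSE)
  endpoints <- unique(unlist(lapply(steps, function(s) c(s$from, s$to))))
  unresolved <- setdiff(endpoints, ids)
  if (length(unresolved))
    stop("step endpoints reference undeclared species: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  structure(list(species = stats::setNames(species, ids),
                 steps = stats::setNames(steps, sids),
                 references = references,
                 temperature = as.numeric(temperature)),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      length(x$steps), " elementary steps, T = ", x$temperature, " K\n", sep = "")
  cat("references:", paste(x$references, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a network by role and pathway tag
#'
#' @param object a [reaction_network()].
#' @param ... unused.
#' @return a list with species counts by role and step counts by pathway tag.
#' @export
summary.reaction_network <- function(object, ...) {
  roles <- table(vapply(object$species, `[[`, "", "role"))
  tags <- unlist(lapply(object$steps, `[[`, "tags"))
  out <- list(n_species = length(object$species),
              n_steps = length(object$steps),
              species_by_role = roles,
              steps_by_tag = if (length(tags)) table(tags) else table(character()))
  class(out) <- "summary.reaction_network"
  out
}

#' @export
print.summary.reaction_network <- function(x, ...) {
  cat("species:", x$n_species, " steps:", x$n_steps, "\n")
  print(x$species_by_role)
  print(x$steps_by_tag)
  invisible(x)
}

#' Look up a species or a step by id
#'
#' @param net a [reaction_network()].
#' @param id species or step id.
#' @return the `"acetal_species"` / `"acetal_step"` object.
#' @export
get_species <- function(net, id) {
  sp <- net$species[[id]]
  if (is.null(sp)) stop("no species with id ", id, call. = FALSE)
  sp
}

#' @rdname get_species
#' @export
get_step <- function(net, id) {
  st <- net$steps[[id]]
  if (is.null(st)) stop("no step with id ", id, call. = FALSE)
  st
}

#' Load a reaction network from a JSON file
#'
#' The on-disk format is JSON with top-level keys `units`
#' (`"kJ/mol"` or `"eV"`), `temperature_K`, `references` (four ids),
#' `species` and `steps`; see the schema shipped at
#' `system.file("extdata", "network-schema.json", package = "acetalnet")`.
#' All energies (`E`, `ZPE`, `g_formation`, `delta_g`, `g_a`) are converted
#' to kJ/mol internally; entropies are always J/(K mol).
#'
#' @param path path to a network JSON file.
#' @return a [reaction_network()].
#' @examples
#' p2 <- load_network(system.file("extdata", "pathway2.json", package = "acetalnet"))
#' summary(p2)
#' @export
load_network <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("units", "temperature_K", "references", "species", "steps")) {
    if (is.null(raw[[key]])) stop("network file missing field '", key, "'", call. = FALSE)
  }
  if (!raw$units %in% c("kJ/mol", "eV"))
    stop("network units must be 'kJ/mol' or 'eV', got '", raw$units, "'", call. = FALSE)
  conv <- function(x) if (is.null(x)) NA_real_ else convert_energy(as.numeric(x), raw$units, "kJ/mol")
  sp <- lapply(raw$species, function(s) {
    et <- NULL
    if (!is.null(s$energy_terms)) {
      et <- list(E = conv(s$energy_terms$E), ZPE = conv(s$energy_terms$ZPE),
                 S = as.numeric(s$energy_terms$S))
    }
    species(id = s$id, role = s$role,
            charge = if (is.null(s$charge)) 0L else s$charge,
            stoich = unlist(s$stoich),
            energy_terms = et,
            g_formation = conv(s$g_formation),
            note = if (is.null(s$note)) NA_character_ else s$note)
  })
  st <- lapply(raw$steps, function(s) {
    elementary_step(id = s$id, from = s$from, to = s$to,
                    delta_g = conv(s$delta_g),
                    g_a = conv(s$g_a),
                    ts_id = if (is.null(s$ts_id)) NA_character_ else s$ts_id,
                    consumes = unlist(s$consumes), releases = unlist(s$releases),
                    reversible = if (is.null(s$reversible)) TRUE else s$reversible,
                    equilibrated = if (is.null(s$equilibrated)) FALSE else s$equilibrated,
                    tags = unlist(s$tags))
  })
  net <- reaction_network(sp, st, references = unlist(raw$references),
                          temperature = as.numeric(raw$temperature_K))
  missing_energy <- vapply(net$species, function(s)
    is.null(s$energy_terms) && is.na(s$g_formation), logical(1))
  if (any(missing_energy))
    stop("species without energy_terms or g_formation: ",
         paste(names(net$species)[missing_energy], collapse = ", "), call. = FALSE)
  net
}

#' Write a reaction network to a JSON file
#'
#' Always writes kJ/mol at full double precision, so `load_network()` round
#' trips every numeric field.
#'
#' @param net a [reaction_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  drop_na <- function(x) if (length(x) == 1 && is.na(x)) NULL else x
  sp <- lapply(unname(net$species), function(s) {
    out <- list(id = s$id, role = s$role, charge = s$charge, stoich = s$stoich)
    if (!is.null(s$energy_terms)) out$energy_terms <- s$energy_terms
    out$g_formation <- drop_na(s$g_formation)
    out$note <- drop_na(s$note)
    out
  })
  st <- lapply(unname(net$steps), function(s) {
    list(id = s$id, from = s$from, to = s$to, delta_g = s$delta_g,
         g_a = drop_na(s$g_a), ts_id = drop_na(s$ts_id),
         consumes = as.list(s$consumes[s$consumes != 0]),
         releases = as.list(s$releases[s$releases != 0]),
         reversible = s$reversible, equilibrated = s$equilibrated,
         tags = as.list(s$tags))
  })
  obj <- list(schema_version = "1.0", units = "kJ/mol",
              temperature_K = net$temperature,
              references = as.list(net$references),
              species = sp, steps = st)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Validate a reaction network
#'
#' Checks every type invariant of the data model and returns the violations
#' as data, not exceptions: charge equals the H3O+ count `d`; reference
#' species sit at formation free energy zero; activation free energies are
#' non-negative and at least `max(0, delta_g)` within 0.5 kJ/mol (printed
#' values are rounded to 0.1); each step balances reference-species
#' stoichiometry and charge (`reactant + consumed = product + released`);
#' and explicit forward/reverse step pairs have `delta_g` summing to zero
#' within 1e-6 kJ/mol.
#'
#' @param net a [reaction_network()].
#' @return a data frame with columns `where` (species/step id) and `rule`;
#'   zero rows iff the network is clean.
#' @export
validate_network <- function(net) {
  bad <- list()
  flag <- function(where, rule) bad[[length(bad) + 1]] <<- data.frame(where = where, rule = rule)

  for (s in net$species) {
    if (s$charge != s$stoich[4])
      flag(s$id, sprintf("charge %d does not equal H3O+ count d = %g", s$charge, s$stoich[4]))
    if (s$id %in% net$references && !is.na(s$g_formation) && abs(s$g_formation) > 1e-9)
      flag(s$id, "reference species must have formation free energy 0")
  }
  ids <- names(net$species)
  for (st in net$steps) {
    if (!st$from %in% ids || !st$to %in% ids) {
      flag(st$id, "unresolved endpoint")
      next
    }
    if (!is.na(st$g_a)) {
      if (st$g_a < 0)
        flag(st$id, "negative activation free energy")
      else if (st$g_a < max(0, st$delta_g) - .GA_TOL)
        flag(st$id, sprintf("activation free energy %.3f below reaction free energy %.3f",
                            st$g_a, st$delta_g))
    }
    sf <- get_species(net, st$from); sp <- get_species(net, st$to)
    # stoichiometry balance over (HCHO, H2O, H3O+): reactant + consumed = product + released
    lhs <- sf$stoich[2:4] + st$consumes
    rhs <- sp$stoich[2:4] + st$releases
    if (any(abs(lhs - rhs) > 1e-9))
      flag(st$id, sprintf("stoichiometry imbalance (%s)",
                          paste(.SMALL_MOLECULES[abs(lhs - rhs) > 1e-9], collapse = ", ")))
    if (abs(sf$stoich[1] - sp$stoich[1]) > 1e-9)
      flag(st$id, "sugar moiety not conserved")
    chg_lhs <- sf$charge + st$consumes[["H3O+"]]
    chg_rhs <- sp$charge + st$releases[["H3O+"]]
    if (abs(chg_lhs - chg_rhs) > 1e-9)
      flag(st$id, "charge imbalance")
  }
  # explicit reverse pairs must be antisymmetric in delta_g
  key <- vapply(net$steps, function(s) paste(s$from, s$to, sep = "->"), "")
  for (st in net$steps) {
    rev_idx <- which(key == paste(st$to, st$from, sep = "->"))
    for (i in rev_idx) {
      other <- net$steps[[i]]
      mism <- abs(st$delta_g + other$delta_g)
      if (mism > 1e-6 && st$id < other$id)
        flag(st$id, sprintf("reverse mismatch %.6g kJ/mol with step %s", mism, other$id))
    }
  }
  if (!length(bad)) return(data.frame(where = character(), rule = character()))
  do.call(rbind, bad)
}

#' Reverse an elementary step
#'
#' Both directions share one transition state, so the reversed step has
#' `delta_g' = -delta_g` and, when a barrier is present,
#' `g_a' = g_a - delta_g`. A forward step with `g_a < delta_g` is
#' energetically inconsistent and raises an error.
#'
#' @param step an [elementary_step()].
#' @return the reversed `"acetal_step"`.
#' @examples
#' s <- elementary_step("s1", "A", "B", delta_g = -10, g_a = 15)
#' reverse_step(s)$g_a  # 25
#' @export
reverse_step <- function(step) {
  stopifnot(inherits(step, "acetal_step"))
  g_a_rev <- NA_real_
  if (!is.na(step$g_a)) {
    g_a_rev <- step$g_a - step$delta_g
    if (g_a_rev < -.GA_TOL)
      stop("inconsistent energetics: reversed activation free energy ",
           format(g_a_rev), " kJ/mol is negative (g_a < delta_g)", call. = FALSE)
    g_a_rev <- max(g_a_rev, 0)
  }
  rid <- if (endsWith(step$id, "_rev")) sub("_rev$", "", step$id) else paste0(step$id, "_rev")
  elementary_step(id = rid, from = step$to, to = step$from,
                  delta_g = -step$delta_g, g_a = g_a_rev, ts_id = step$ts_id,
                  consumes = step$releases[step$releases != 0],
                  releases = step$consumes[step$consumes != 0],
                  reversible = step$reversible, equilibrated = step$equilibrated,
                  tags = step$tags)
}
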