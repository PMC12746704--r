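#' Build a cumulative free-energy profile along a state sequence
#'
#' Walks the given species ids in order, accumulating reaction free energies.
#' After each intermediate at cumulative energy G, the outgoing transition
#' state (when the step carries a positive activation free energy) is
#' inserted at G + g_a. Steps whose `g_a` is absent or exactly 0 contribute
#' no TS state. A consecutive pair not connected by a stored step is an
#' error; stored steps may be traversed against their direction when marked
#' reversible (the shared TS then sits at `g_a - delta_g` above the new
#' initial state).
#'
#' @param net a [reaction_network()].
#' @param state_sequence character vector of species ids.
#' @param pathway_id optional label attached to the profile.
#' @return an object of class `"pathway_profile"`: a data frame with columns
#'   `label`, `kind` (`"intermediate"`/`"transition_state"`) and `g_cum`
#'   (kJ/mol relative to the first state).
#' @examples
#' # see enumerate_pathways() for profiles over a whole network
#' @export
build_profile <- function(net, state_sequence, pathway_id = NA_character_) {
  stopifnot(length(state_sequence) >= 1)
  edges <- .directed_edges(net)
  labels <- state_sequence[1]
  kinds <- "intermediate"
  g <- 0
  g_cum <- 0
  for (i in seq_len(length(state_sequence) - 1)) {
    from <- state_sequence[i]; to <- state_sequence[i + 1]
    hit <- edges[edges$from == from & edges$to == to, , drop = FALSE]
    if (!nrow(hit))
      stop("no elementary step connects ", from, " -> ", to, call. = FALSE)
    # prefer the lowest-barrier connection if several steps exist
    hit <- hit[order(ifelse(is.na(hit$g_a), -Inf, hit$g_a)), , drop = FALSE][1, ]
    if (!is.na(hit$g_a) && hit$g_a > 0) {
      labels <- c(labels, if (is.na(hit$ts_id)) paste0("TS(", from, "->", to, ")") else hit$ts_id)
      kinds <- c(kinds, "transition_state")
      g_cum <- c(g_cum, g + hit$g_a)
    }
    g <- g + hit$delta_g
    labels <- c(labels, to)
    kinds <- c(kinds, "intermediate")
    g_cum <- c(g_cum, g)
  }
  out <- data.frame(label = labels, kind = kinds, g_cum = g_cum)
  structure(out, class = c("pathway_profile", "data.frame"), pathway_id = pathway_id)
}

# all traversable directed edges: stored steps plus reverses of reversible ones
.directed_edges <- function(net) {
  rows <- lapply(net$steps, function(s) {
    fwd <- data.frame(from = s$from, to = s$to, delta_g = s$delta_g,
                      g_a = s$g_a, ts_id = s$ts_id, step_id = s$id,
                      equilibrated = s$equilibrated,
                      stringsAsFactors = FALSE)
    if (!s$reversible) return(fwd)
    rev <- reverse_step(s)
    rbind(fwd, data.frame(from = rev$from, to = rev$to, delta_g = rev$delta_g,
                          g_a = rev$g_a, ts_id = rev$ts_id, step_id = rev$id,
                          equilibrated = rev$equilibrated,
                          stringsAsFactors = FALSE))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Apparent barrier (energetic span) of a profile
#'
#' The apparent barrier is the largest free-energy climb on the profile: the
#' maximum of `G_cum(state_j) - G_cum(state_i)` over ordered pairs with
#' `state_i` restricted to intermediates and `state_j` any later state. It is
#' the free-energy difference between the lowest state and the highest state
#' that follows it, and sets the pathway's effective kinetics. A monotone
#' downhill profile has span 0 (low and high state both the first state, by
#' convention).
#'
#' @param profile a [build_profile()] result.
#' @return an object of class `"span_result"`: list with `span` (kJ/mol),
#'   `low_state`, `high_state` and `pathway_id`.
#' @export
apparent_barrier <- function(profile) {
  stopifnot(nrow(profile) >= 1)
  g <- profile$g_cum
  kind <- profile$kind
  best <- 0; lo <- 1L; hi <- 1L
  min_i <- NA_integer_
  for (j in seq_along(g)) {
    if (!is.na(min_i)) {
      climb <- g[j] - g[min_i]
      if (climb > best) { best <- climb; lo <- min_i; hi <- j }
    }
    if (kind[j] == "intermediate" && (is.na(min_i) || g[j] < g[min_i])) min_i <- j
  }
  structure(list(span = best,
                 low_state = profile$label[lo],
                 high_state = profile$label[hi],
                 pathway_id = attr(profile, "pathway_id")),
            class = "span_result")
}

#' @export
print.span_result <- function(x, ...) {
  cat(sprintf("apparent barrier %.1f kJ/mol (%s -> %s)%s\n", x$span,
              x$low_state, x$high_state,
              if (is.na(x$pathway_id)) "" else paste0(" [", x$pathway_id, "]")))
  invisible(x)
}

#' Enumerate and rank simple pathways by apparent barrier
#'
#' Finds every simple path (no repeated states) from `source` to `sink` of at
#' most `max_states` states, builds its free-energy profile, and ranks the
#' paths by ascending apparent barrier. Ties are broken by shorter path, then
#' lexicographically on the state labels, so the output is deterministic.
#'
#' @param net a [reaction_network()].
#' @param source,sink species ids.
#' @param max_states maximum number of states in a path (default 25).
#' @return data frame with one row per path: `rank`, `span`, `low_state`,
#'   `high_state`, `n_states` and `path` (states joined by `" -> "`), ordered
#'   by rank. Zero rows if the sink is unreachable.
#' @export
enumerate_pathways <- function(net, source, sink, max_states = 25) {
  stopifnot(source %in% names(net$species), sink %in% names(net$species))
  edges <- .directed_edges(net)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = TRUE,
                                     vertices = data.frame(name = names(net$species)))
  paths <- igraph::all_simple_paths(g, from = source, to = sink,
                                    mode = "out", cutoff = max_states - 1)
  if (!length(paths)) {
    return(data.frame(rank = integer(), span = numeric(), low_state = character(),
                      high_state = character(), n_states = integer(), path = character()))
  }
  rows <- lapply(paths, function(p) {
    ids <- names(p)
    sr <- apparent_barrier(build_profile(net, ids))
    data.frame(span = sr$span, low_state = sr$low_state, high_state = sr$high_state,
               n_states = length(ids), path = paste(ids, collapse = " -> "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$span, out$n_states, out$path)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Minimal apparent barrier towards each of several target intermediates
#'
#' For each target, enumerates routes from `source` and reports the smallest
#' apparent barrier and its realizing segment. A target with no route is
#' recorded as absent (`NA` span), not an error. On the packaged xylose /
#' formaldehyde network this reproduces the anomer preference
#' Int5_alpha < Int4_alpha < Int4_beta.
#'
#' @param net a [reaction_network()].
#' @param targets character vector of target species ids.
#' @param source starting species id (default `"alpha_xylopyranose"`).
#' @param max_states passed to [enumerate_pathways()].
#' @return data frame with one row per target (`target`, `span`, `low_state`,
#'   `high_state`, `path`), ordered by ascending span with absent targets last.
#' @export
compare_anomer_routes <- function(net, targets, source = "alpha_xylopyranose",
                                  max_states = 25) {
  rows <- lapply(targets, function(tg) {
    if (!tg %in% names(net$species)) {
      return(data.frame(target = tg, span = NA_real_, low_state = NA_character_,
                        high_state = NA_character_, path = NA_character_))
    }
    ranked <- enumerate_pathways(net, source, tg, max_states = max_states)
    if (!nrow(ranked)) {
      return(data.frame(target = tg, span = NA_real_, low_state = NA_character_,
                        high_state = NA_character_, path = NA_character_))
    }
    data.frame(target = tg, span = ranked$span[1], low_state = ranked$low_state[1],
               high_state = ranked$high_state[1], path = ranked$path[1])
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$span), out$span, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
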