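# Reaction-network assembly and thermodynamic route analysis: minimax
# (bottleneck) routes from seed species to targets over a hypergraph of
# elementary reactions, and energetic-span effective barriers over
# free-energy profiles.

#' Construct an elementary reaction record
#'
#' @param id Reaction identifier (unique within a network), e.g. "R1".
#' @param reactants,products Character vectors of species names (multisets:
#'   repeats allowed); both non-empty.
#' @param catalysts Character vector of catalyst/spectator species: required
#'   for the reaction to fire but not consumed.
#' @param g_a Activation free energy (kcal/mol, >= 0); for barriers quoted as
#'   a range this is the conservative upper bound used in route search.
#' @param g_a_lower Optional lower bound of a ranged barrier (kcal/mol).
#' @param dg Optional reaction free energy (kcal/mol).
#' @param note Optional free-text description.
#' @return An object of class `rtip_reaction`.
#' @export
elementary_reaction <- function(id, reactants, products,
                                catalysts = character(0),
                                g_a = NA_real_, g_a_lower = NA_real_,
                                dg = NA_real_, note = "") {
  reactants <- as.character(reactants); products <- as.character(products)
  catalysts <- as.character(catalysts)
  if (length(reactants) < 1L || length(products) < 1L) {
    stop("reactant and product multisets must be non-empty", call. = FALSE)
  }
  if (!is.na(g_a) && g_a < 0) stop("g_a must be non-negative", call. = FALSE)
  structure(list(id = as.character(id), reactants = reactants,
                 products = products, catalysts = catalysts,
                 g_a = g_a, g_a_lower = g_a_lower, dg = dg, note = note),
            class = "rtip_reaction")
}

#' @export
print.rtip_reaction <- function(x, ...) {
  cat(sprintf("%s: %s -> %s%s  [G_a = %s kcal/mol]\n", x$id,
              paste(x$reactants, collapse = " + "),
              paste(x$products, collapse = " + "),
              if (length(x$catalysts))
                paste0("  (cat: ", paste(x$catalysts, collapse = " + "), ")")
              else "",
              if (is.na(x$g_a)) "?" else format(x$g_a)))
  invisible(x)
}

#' Assemble a reaction network
#'
#' @param reactions List of [elementary_reaction()] records (unique ids).
#' @param seeds Character vector of seed species.
#' @return An object of class `rtip_network` with deduplicated species set.
#' @export
build_network <- function(reactions, seeds) {
  if (inherits(reactions, "rtip_reaction")) reactions <- list(reactions)
  stopifnot(is.list(reactions))
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  species <- unique(c(as.character(seeds),
                      unlist(lapply(reactions, function(r) {
                        c(r$reactants, r$products, r$catalysts)
                      }))))
  structure(list(species = species, reactions = reactions,
                 seeds = unique(as.character(seeds))),
            class = "rtip_network")
}

#' @export
print.rtip_network <- function(x, ...) {
  cat(sprintf("<rtip_network> %d species, %d reactions, seeds: %s\n",
              length(x$species), length(x$reactions),
              paste(x$seeds, collapse = ", ")))
  invisible(x)
}

# hypergraph reachability: a reaction fires only when all its reactants AND
# catalysts are already reachable. Returns reachable species and, per fired
# reaction, the firing round (reactions scanned in list order within rounds).
.reachability <- function(network, g_max = Inf, excluded = character(0)) {
  have <- network$seeds
  # a reaction with an unknown barrier is usable only under an infinite ceiling
  usable <- vapply(network$reactions, function(r) {
    !(r$id %in% excluded) &&
      (if (is.na(r$g_a)) is.infinite(g_max) else r$g_a <= g_max)
  }, TRUE)
  fired_round <- setNames(rep(NA_integer_, length(network$reactions)),
                          vapply(network$reactions, `[[`, "", "id"))
  round <- 0L
  repeat {
    round <- round + 1L
    new_any <- FALSE
    for (i in seq_along(network$reactions)) {
      if (!usable[i] || !is.na(fired_round[i])) next
      r <- network$reactions[[i]]
      if (all(c(r$reactants, r$catalysts) %in% have)) {
        fired_round[i] <- round
        have <- unique(c(have, r$products))
        new_any <- TRUE
      }
    }
    if (!new_any) break
  }
  list(species = have, fired_round = fired_round)
}

#' Reachable species of a network
#'
#' @param network An `rtip_network`.
#' @param g_max Barrier ceiling: only reactions with `g_a <= g_max` may fire.
#' @param excluded Reaction ids excluded from firing.
#' @return Character vector of reachable species (seeds included).
#' @export
reachable_species <- function(network, g_max = Inf, excluded = character(0)) {
  .reachability(network, g_max, excluded)$species
}

# backward-chain a supporting route for `target` from a reachability result
.extract_route <- function(network, reach, target) {
  ids <- vapply(network$reactions, `[[`, "", "id")
  producer_of <- function(sp) {
    cand <- which(!is.na(reach$fired_round) &
                    vapply(network$reactions,
                           function(r) sp %in% r$products, TRUE))
    if (!length(cand)) return(NA_integer_)
    cand[order(reach$fired_round[cand], ids[cand])][1L]
  }
  needed <- target
  used <- integer(0)
  while (length(needed)) {
    sp <- needed[1L]; needed <- needed[-1L]
    if (sp %in% network$seeds) next
    i <- producer_of(sp)
    if (is.na(i)) return(NULL)
    if (i %in% used) next
    used <- c(used, i)
    r <- network$reactions[[i]]
    needed <- unique(c(needed,
                       setdiff(c(r$reactants, r$catalysts),
                               network$seeds)))
  }
  used[order(reach$fired_round[used], ids[used])]
}

#' Minimax (bottleneck) route to a target species
#'
#' Among all reaction subsets that make `target` reachable from the seeds
#' (a reaction fires only when all its reactants and catalysts are already
#' reachable), finds one minimizing the largest activation free energy used.
#' Exact: binary search over the sorted barrier values with
#' hypergraph-reachability checks, followed by backward chaining of a
#' supporting route.
#'
#' @param network An `rtip_network`.
#' @param target Species name (must be in the network's species set).
#' @param excluded Reaction ids barred from use.
#' @return `NULL` if unreachable; otherwise a list with `route` (ordered
#'   character vector of reaction ids), `bottleneck` (kcal/mol) and
#'   `bottleneck_id`. A target that is itself a seed gives an empty route
#'   with bottleneck 0.
#' @export
minimax_route <- function(network, target, excluded = character(0)) {
  stopifnot(inherits(network, "rtip_network"))
  if (!target %in% network$species) {
    stop("target species '", target, "' not in the network", call. = FALSE)
  }
  if (target %in% network$seeds) {
    return(list(route = character(0), bottleneck = 0, bottleneck_id = NA_character_))
  }
  if (!target %in% .reachability(network, Inf, excluded)$species) return(NULL)
  barriers <- sort(unique(vapply(network$reactions, function(r) {
    if (is.na(r$g_a)) Inf else r$g_a
  }, 0.0)))
  lo <- 1L; hi <- length(barriers)
  while (lo < hi) {  # smallest ceiling that keeps the target reachable
    mid <- (lo + hi) %/% 2L
    if (target %in% .reachability(network, barriers[mid], excluded)$species) {
      hi <- mid
    } else lo <- mid + 1L
  }
  g_star <- barriers[lo]
  reach <- .reachability(network, g_star, excluded)
  used <- .extract_route(network, reach, target)
  ids <- vapply(network$reactions, `[[`, "", "id")
  g_used <- vapply(network$reactions[used], `[[`, 0.0, "g_a")
  g_used[is.na(g_used)] <- Inf
  bmax <- max(g_used)
  cand <- used[g_used == bmax]
  list(route = ids[used], bottleneck = bmax,
       bottleneck_id = sort(ids[cand])[1L])
}

#' Rank alternative routes by bottleneck barrier
#'
#' Iterated minimax: the best route is found, its bottleneck reaction is
#' excluded, and the search repeats, giving up to `k` routes with distinct
#' reaction sets, sorted by bottleneck (ties broken by id-lexicographic order
#' of the bottleneck reaction).
#'
#' @inheritParams minimax_route
#' @param k Maximum number of routes (>= 1).
#' @return List of route records as in [minimax_route()]; fewer than `k` if
#'   the target becomes unreachable.
#' @export
rank_alternatives <- function(network, target, k = 1L) {
  stopifnot(k >= 1L)
  out <- list()
  excluded <- character(0)
  for (i in seq_len(k)) {
    r <- minimax_route(network, target, excluded = excluded)
    if (is.null(r)) break
    out[[length(out) + 1L]] <- r
    if (is.na(r$bottleneck_id)) break  # target is a seed
    excluded <- c(excluded, r$bottleneck_id)
  }
  out
}

#' Assemble a free-energy profile
#'
#' @param states Data frame with columns `label`, `kind` (each `intermediate`
#'   or `TS`, strictly alternating, starting and ending with an
#'   intermediate) and `g` (kcal/mol, any common reference).
#' @return An object of class `rtip_profile`; energies are re-referenced so
#'   the first intermediate is 0.
#' @export
assemble_profile <- function(states) {
  stopifnot(is.data.frame(states),
            all(c("label", "kind", "g") %in% names(states)))
  kind <- as.character(states$kind)
  if (!all(kind %in% c("intermediate", "TS"))) {
    stop("kind must be 'intermediate' or 'TS'", call. = FALSE)
  }
  n <- nrow(states)
  if (n < 1L || kind[1L] != "intermediate" || kind[n] != "intermediate") {
    stop("profile must start and end with an intermediate", call. = FALSE)
  }
  if (n > 1L && any(kind[-1L] == kind[-n])) {
    stop("profile kinds must strictly alternate", call. = FALSE)
  }
  out <- data.frame(label = as.character(states$label), kind = kind,
                    g = as.numeric(states$g) - as.numeric(states$g)[1L],
                    stringsAsFactors = FALSE)
  structure(out, class = c("rtip_profile", "data.frame"))
}

#' Energetic span of a free-energy profile
#'
#' The effective barrier of a profile: the largest difference between a
#' transition-state energy and the lowest intermediate preceding it,
#' `span = max_j [ G(TS_j) - min_{i <= j} G(I_i) ]` -- the barrier "with
#' respect to the most stable intermediate state along the pathway". Ties are
#' broken towards the later transition state. Invariant under a constant
#' shift of all energies.
#'
#' @param profile An `rtip_profile`.
#' @return List with `span` (kcal/mol), `determining_ts` (label, or `NA` when
#'   the profile has no TS) and `reference_intermediate` (label or `NA`).
#' @export
effective_barrier <- function(profile) {
  stopifnot(inherits(profile, "rtip_profile"))
  is_ts <- profile$kind == "TS"
  if (!any(is_ts)) {
    return(list(span = 0, determining_ts = NA_character_,
                reference_intermediate = NA_character_))
  }
  span <- -Inf; dts <- NA_character_; ref <- NA_character_
  for (j in which(is_ts)) {
    ints <- which(!is_ts & seq_len(nrow(profile)) < j)
    i_min <- ints[which.min(profile$g[ints])]
    s <- profile$g[j] - profile$g[i_min]
    if (s >= span) {  # >= : ties go to the later TS
      span <- s; dts <- profile$label[j]; ref <- profile$label[i_min]
    }
  }
  list(span = span, determining_ts = dts, reference_intermediate = ref)
}
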