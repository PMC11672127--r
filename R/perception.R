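# Bond perception, molecular-graph canonicalization and reaction extraction.
# Graphs are element-labelled and distance-perceived: an edge exists iff the
# interatomic distance is below scale * (R_i + R_j) with covalent radii R.
# Bond orders are not perceived; species are distinguished by composition and
# connectivity, which suffices for the closed-shell C/H/N/O species handled
# here.

#' Perceive bonds from interatomic distances
#'
#' @param config An `rtip_config`; all elements must appear in
#'   [covalent_radii()].
#' @param scale Detection-band scale factor (default 1.2); atoms i, j are
#'   bonded iff `dist(i, j) < scale * (R_i + R_j)`.
#' @return An object of class `rtip_molgraph`: a list with `symbols`, `edges`
#'   (two-column matrix of atom indices, zero rows if none) and `graph`
#'   (an igraph object with a `symbol` vertex attribute).
#' @export
perceive_bonds <- function(config, scale = 1.2) {
  stopifnot(inherits(config, "rtip_config"), scale > 0)
  radii <- .radius_of(config$symbols)
  n <- n_atoms(config)
  edges <- matrix(0L, 0L, 2L)
  if (n >= 2L) {
    dm <- as.matrix(stats::dist(config$coords))
    cut <- scale * outer(radii, radii, `+`)
    hit <- which(dm < cut & upper.tri(dm), arr.ind = TRUE)
    if (nrow(hit) > 0L) edges <- unname(hit[, c(1L, 2L), drop = FALSE])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$symbol <- config$symbols
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  structure(list(symbols = config$symbols, edges = edges, graph = g),
            class = "rtip_molgraph")
}

#' @export
print.rtip_molgraph <- function(x, ...) {
  cat(sprintf("<rtip_molgraph> %d atoms, %d bonds, %d component(s)\n",
              length(x$symbols), nrow(x$edges),
              igraph::components(x$graph)$no))
  invisible(x)
}

# Hill-order composition string (C first, H second, rest alphabetical)
.composition <- function(symbols) {
  tab <- table(symbols)
  els <- names(tab)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (tab[[e]] == 1L) e else paste0(e, tab[[e]])
  }, ""), collapse = "")
}

#' Canonical key of a molecular graph
#'
#' A string that is identical for element-preservingly isomorphic graphs and
#' distinct otherwise. The graph is canonically relabelled with an
#' element-coloured canonical-form search (BLISS, via igraph), and the key is
#' the composition string plus the canonical edge list and colour sequence,
#' so cross-composition collisions are impossible by construction.
#'
#' @param graph An `rtip_molgraph` (or an igraph object with a `symbol`
#'   vertex attribute).
#' @return A character key.
#' @export
canonical_key <- function(graph) {
  g <- if (inherits(graph, "rtip_molgraph")) graph$graph else graph
  symbols <- igraph::V(g)$symbol
  if (length(symbols) == 0L) stop("empty graph", call. = FALSE)
  colors <- match(symbols, sort(unique(symbols)))
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  gc <- igraph::permute(g, perm)
  el <- igraph::as_edgelist(gc, names = FALSE)
  if (nrow(el) > 0L) {
    el <- t(apply(el, 1L, sort))
    el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  }
  sym_canon <- character(length(symbols))
  sym_canon[perm] <- symbols
  paste0(.composition(symbols), "|",
         paste(sym_canon, collapse = ""), "|",
         paste(el[, 1L], el[, 2L], sep = "-", collapse = ","))
}

#' Split a molecular graph into connected components
#'
#' @param graph An `rtip_molgraph`.
#' @return A list of `rtip_molgraph` objects, one per connected component,
#'   ordered by their canonical keys.
#' @export
split_components <- function(graph) {
  stopifnot(inherits(graph, "rtip_molgraph"))
  comp <- igraph::components(graph$graph)
  out <- lapply(seq_len(comp$no), function(ci) {
    sel <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(graph$graph, sel)
    el <- igraph::as_edgelist(sub, names = FALSE)
    structure(list(symbols = igraph::V(sub)$symbol,
                   edges = matrix(as.integer(el), ncol = 2L), graph = sub),
              class = "rtip_molgraph")
  })
  keys <- vapply(out, canonical_key, "")
  out[order(keys)]
}

# multiset of component species keys for one configuration
.species_multiset <- function(config, scale = 1.2) {
  comps <- split_components(perceive_bonds(config, scale = scale))
  sort(vapply(comps, canonical_key, ""))
}

#' Species registry: canonical keys of the packaged reference molecules
#'
#' Maps the canonical graph keys of the packaged small-molecule geometries
#' (see [reference_molecules()]) to human-readable species names, so that
#' extracted reactions can be reported in chemical vocabulary.
#'
#' @return A data frame with columns `key`, `name`, `formula`.
#' @export
species_registry <- function() {
  mols <- reference_molecules()
  data.frame(
    key = vapply(mols, function(m) canonical_key(perceive_bonds(m)), ""),
    name = names(mols),
    formula = vapply(mols, function(m) .composition(m$symbols), ""),
    stringsAsFactors = FALSE
  )
}

#' Read / write a species registry as JSON
#'
#' Serializes the key-to-name mapping (one object per species with `key`,
#' `name`, `formula`); the packaged registry pre-seeds the names of the
#' reference molecules.
#'
#' @param registry Data frame as returned by [species_registry()].
#' @param path File path.
#' @return `read_species_registry`: the registry data frame;
#'   `write_species_registry`: `path`, invisibly.
#' @export
write_species_registry <- function(registry, path) {
  rownames(registry) <- NULL
  jsonlite::write_json(registry, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_species_registry
#' @export
read_species_registry <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("key", "name") %in% names(df)))
  df
}

.name_species <- function(keys, registry = NULL) {
  if (is.null(registry)) registry <- species_registry()
  i <- match(keys, registry$key)
  out <- registry$name[i]
  out[is.na(i)] <- vapply(strsplit(keys[is.na(i)], "|", fixed = TRUE),
                          `[[`, "", 1L)
  out
}

#' Extract an elementary reaction from endpoint configurations
#'
#' Perceives bonds at both endpoints, splits them into species, and compares
#' the canonical-key multisets. Identical multisets mean no reaction
#' (a conformational event); otherwise the changed species become reactants
#' and products, and species present unchanged on both sides are flagged as
#' catalysts/spectators.
#'
#' @param reactant_config,product_config `rtip_config` objects with the same
#'   atom multiset (both assumed stationary on the PES; that is the caller's
#'   duty).
#' @param id Reaction identifier for the record.
#' @param e_reactant,e_product Optional endpoint energies (kcal/mol); their
#'   difference is stored as the raw reaction energy `dg`.
#' @param scale Bond-perception scale.
#' @return An [elementary_reaction()] (species given registry names where
#'   known), or `NULL` if the endpoints are the same species multiset.
#' @export
extract_reaction <- function(reactant_config, product_config, id = "R?",
                             e_reactant = NA_real_, e_product = NA_real_,
                             scale = 1.2) {
  if (!identical(sort(reactant_config$symbols), sort(product_config$symbols))) {
    stop("endpoints must share the same atom multiset", call. = FALSE)
  }
  kr <- .species_multiset(reactant_config, scale)
  kp <- .species_multiset(product_config, scale)
  if (identical(kr, kp)) return(NULL)
  # multiset differences / intersection
  all_keys <- unique(c(kr, kp))
  nr <- vapply(all_keys, function(k) sum(kr == k), 0L)
  np <- vapply(all_keys, function(k) sum(kp == k), 0L)
  reg <- species_registry()
  expand <- function(counts) {
    keys <- rep(all_keys, counts)
    .name_species(keys, reg)
  }
  elementary_reaction(
    id = id,
    reactants = expand(pmax(nr - np, 0L)),
    products = expand(pmax(np - nr, 0L)),
    catalysts = expand(pmin(nr, np)),
    g_a = NA_real_,
    dg = if (is.na(e_reactant) || is.na(e_product)) NA_real_
         else e_product - e_reactant
  )
}
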