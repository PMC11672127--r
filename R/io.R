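# File formats: XYZ / extended-XYZ, reaction tables (CSV/JSON), flat
# sectioned key=value run configuration, DOT network export.

.parse_xyz_comment <- function(comment) {
  out <- list(comment = comment)
  toks <- regmatches(comment,
                     gregexpr("[A-Za-z_][A-Za-z0-9_]*=[^ \t]+", comment))[[1L]]
  for (tk in toks) {
    kv <- strsplit(tk, "=", fixed = TRUE)[[1L]]
    val <- suppressWarnings(as.numeric(kv[2L]))
    out[[kv[1L]]] <- if (is.na(val)) kv[2L] else val
  }
  out
}

#' Read XYZ / extended-XYZ files
#'
#' Standard layout: an atom-count line, a comment line (extended-XYZ
#' `key=value` tokens such as `energy=-12.3 step=4` are parsed into
#' attributes), then one `Symbol x y z` record per atom (A). `read_xyz`
#' returns the first frame; `read_xyz_frames` returns all frames of a
#' trajectory as a list.
#'
#' @param path File path.
#' @return `read_xyz`: an `rtip_config` with attribute `info` (named list of
#'   parsed comment fields); `read_xyz_frames`: a list of such objects.
#' @export
read_xyz <- function(path) {
  read_xyz_frames(path)[[1L]]
}

#' @rdname read_xyz
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop("XYZ parse error at line ", i, ": invalid atom count '",
           lines[i], "'", call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop("XYZ parse error at line ", length(lines) + 1L,
           ": expected ", n, " atom records, file ends early", call. = FALSE)
    }
    info <- .parse_xyz_comment(lines[i + 1L])
    symbols <- character(n); coords <- matrix(0.0, n, 3L)
    for (a in seq_len(n)) {
      ln <- i + 1L + a
      toks <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
      vals <- suppressWarnings(as.numeric(toks[2:4]))
      if (length(toks) < 4L || anyNA(vals)) {
        stop("XYZ parse error at line ", ln, ": '", lines[ln], "'",
             call. = FALSE)
      }
      symbols[a] <- toks[1L]
      coords[a, ] <- vals
    }
    cfg <- configuration(symbols, coords)
    attr(cfg, "info") <- info
    frames[[length(frames) + 1L]] <- cfg
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no XYZ frames in ", path, call. = FALSE)
  frames
}

#' Write XYZ / extended-XYZ files
#'
#' @param config An `rtip_config`, or a list of them (a trajectory; one frame
#'   per configuration).
#' @param path Output path.
#' @param fields Named list (or list of named lists, one per frame) of
#'   extended-XYZ `key=value` comment fields, e.g.
#'   `list(energy = -12.3, step = 4)`.
#' @return `path`, invisibly. Coordinates are written with 8 decimals.
#' @export
write_xyz <- function(config, path, fields = NULL) {
  frames <- if (inherits(config, "rtip_config")) list(config) else config
  if (!is.null(fields) && !is.null(names(fields))) fields <- list(fields)
  lines <- character(0)
  for (fi in seq_along(frames)) {
    cfg <- frames[[fi]]
    stopifnot(inherits(cfg, "rtip_config"))
    fl <- if (is.null(fields)) NULL else fields[[min(fi, length(fields))]]
    comment <- if (is.null(fl)) "" else {
      paste(vapply(names(fl), function(k) {
        v <- fl[[k]]
        paste0(k, "=", if (is.numeric(v)) format(v, digits = 12) else v)
      }, ""), collapse = " ")
    }
    lines <- c(lines, as.character(n_atoms(cfg)), comment,
               sprintf("%-3s %16.8f %16.8f %16.8f", cfg$symbols,
                       cfg$coords[, 1L], cfg$coords[, 2L], cfg$coords[, 3L]))
  }
  writeLines(lines, path)
  invisible(path)
}

.split_species <- function(s) {
  s <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
  s[nzchar(s)]
}

#' Read / write reaction tables
#'
#' CSV columns: `id`, `reactants`, `products`, `catalysts` (species separated
#' by `+`), `g_a`, `g_a_lower`, `dg`, `note`. JSON uses one object per
#' reaction with species arrays.
#'
#' @param path File path.
#' @return `read_reactions_*`: a list of [elementary_reaction()] records.
#' @export
read_reactions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "reactants", "products", "g_a")
  if (!all(need %in% names(df))) {
    stop("reaction CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    elementary_reaction(
      id = df$id[i],
      reactants = .split_species(df$reactants[i]),
      products = .split_species(df$products[i]),
      catalysts = if ("catalysts" %in% names(df) && nzchar(df$catalysts[i]))
        .split_species(df$catalysts[i]) else character(0),
      g_a = as.numeric(df$g_a[i]),
      g_a_lower = if ("g_a_lower" %in% names(df)) as.numeric(df$g_a_lower[i])
                  else NA_real_,
      dg = if ("dg" %in% names(df)) as.numeric(df$dg[i]) else NA_real_,
      note = if ("note" %in% names(df)) as.character(df$note[i]) else ""
    )
  })
}

#' @rdname read_reactions_csv
#' @param reactions List of [elementary_reaction()] records.
#' @export
write_reactions_csv <- function(reactions, path) {
  df <- data.frame(
    id = vapply(reactions, `[[`, "", "id"),
    reactants = vapply(reactions, function(r) paste(r$reactants, collapse = " + "), ""),
    products = vapply(reactions, function(r) paste(r$products, collapse = " + "), ""),
    catalysts = vapply(reactions, function(r) paste(r$catalysts, collapse = " + "), ""),
    g_a = vapply(reactions, `[[`, 0.0, "g_a"),
    g_a_lower = vapply(reactions, `[[`, 0.0, "g_a_lower"),
    dg = vapply(reactions, `[[`, 0.0, "dg"),
    note = vapply(reactions, `[[`, "", "note"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_reactions_csv
#' @export
read_reactions_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(lst, function(r) {
    elementary_reaction(
      id = r$id,
      reactants = unlist(r$reactants),
      products = unlist(r$products),
      catalysts = if (is.null(r$catalysts)) character(0) else unlist(r$catalysts),
      g_a = if (is.null(r$g_a)) NA_real_ else as.numeric(r$g_a),
      g_a_lower = if (is.null(r$g_a_lower)) NA_real_ else as.numeric(r$g_a_lower),
      dg = if (is.null(r$dg)) NA_real_ else as.numeric(r$dg),
      note = if (is.null(r$note)) "" else r$note
    )
  })
}

#' @rdname read_reactions_csv
#' @export
write_reactions_json <- function(reactions, path) {
  jsonlite::write_json(lapply(reactions, unclass), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Export a reaction network in DOT format
#'
#' Species become nodes; each reaction becomes a labelled box node with edges
#' from its reactants (and dashed edges from catalysts) and to its products.
#'
#' @param network An `rtip_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_dot <- function(network, path) {
  q <- function(s) paste0('"', gsub('"', "'", s), '"')
  lines <- c("digraph reaction_network {", "  rankdir=LR;")
  for (sp in network$species) {
    shape <- if (sp %in% network$seeds) "doublecircle" else "ellipse"
    lines <- c(lines, sprintf("  %s [shape=%s];", q(sp), shape))
  }
  for (r in network$reactions) {
    rid <- q(r$id)
    label <- if (is.na(r$g_a)) r$id else sprintf("%s (%.1f)", r$id, r$g_a)
    lines <- c(lines, sprintf("  %s [shape=box,label=%s];", rid, q(label)))
    for (sp in unique(r$reactants)) {
      lines <- c(lines, sprintf("  %s -> %s;", q(sp), rid))
    }
    for (sp in unique(r$catalysts)) {
      lines <- c(lines, sprintf("  %s -> %s [style=dashed];", q(sp), rid))
    }
    for (sp in unique(r$products)) {
      lines <- c(lines, sprintf("  %s -> %s;", rid, q(sp)))
    }
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

# ---- flat sectioned key=value run configuration -----------------------------

#' Default run configuration
#'
#' Sections `bias`, `sampler` and `pes`; every field has a default. `NA`
#' means "resolve automatically" (see [bias_params()]).
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    bias = list(depth_increment = 1.0, width = NA_real_,
                temperature = NA_real_, max_modes = 4L),
    sampler = list(e_climb = 115, e_drop = 12.5, placement_radius = 5,
                   max_steps = 500L, micro_iters = 20L,
                   max_displacement = 0.1, gain = 0.02, seed = 1L,
                   n_samplings = 32L, relax_initial = TRUE),
    pes = list(file = "", name = "toy")
  )
}

#' Read / write a run configuration file
#'
#' Flat `key = value` pairs under `[section]` headers; a single, diff-friendly
#' dialect used for both user configs and run-provenance echoes. Unknown keys
#' are an error; missing keys take their defaults. Parsed configs round-trip
#' to an identical serialized form.
#'
#' @param path File path.
#' @return `read_run_config`: nested named list as in [default_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  lines <- readLines(path, warn = FALSE)
  section <- NA_character_
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(cfg)) {
        stop("config parse error at line ", i, ": unknown section [",
             section, "]", call. = FALSE)
      }
      next
    }
    if (is.na(section) || !grepl("=", ln, fixed = TRUE)) {
      stop("config parse error at line ", i, ": '", lines[i], "'",
           call. = FALSE)
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
    if (!key %in% names(cfg[[section]])) {
      stop("config parse error at line ", i, ": unknown key '", key,
           "' in [", section, "]", call. = FALSE)
    }
    old <- cfg[[section]][[key]]
    cfg[[section]][[key]] <- if (is.logical(old)) as.logical(val)
      else if (is.integer(old)) suppressWarnings(as.integer(val))
      else if (is.numeric(old)) suppressWarnings(as.numeric(val))
      else val
  }
  cfg
}

#' @rdname read_run_config
#' @param config Nested named list as returned by [default_run_config()].
#' @export
write_run_config <- function(config, path) {
  lines <- character(0)
  for (section in names(config)) {
    lines <- c(lines, paste0("[", section, "]"))
    for (key in names(config[[section]])) {
      v <- config[[section]][[key]]
      lines <- c(lines, paste0(key, " = ",
                               if (is.na(v)) "NA" else format(v, digits = 12)))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
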