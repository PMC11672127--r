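# Real-PES contract and built-in toy reactive pair potentials.
#
# The sampler only needs two callables from a potential-energy surface:
# energy(config) in kcal/mol and gradient(config) in kcal/(mol A). The
# built-in toy surfaces are pairwise: reactive element pairs carry a Morse
# well plus a Gaussian barrier bump, non-reactive pairs a soft exponential
# repulsion. Bond formation then emerges purely from geometry, which is what
# the sampler's energy-drop detection relies on.

#' Generic PES energy / gradient
#'
#' @param pes A PES backend (e.g. from [toy_pes()] or [external_pes()]).
#' @param config An `rtip_config`.
#' @return `pes_energy`: scalar energy (kcal/mol); `pes_gradient`: n x 3
#'   gradient matrix (kcal/(mol A)).
#' @export
pes_energy <- function(pes, config) UseMethod("pes_energy")

#' @rdname pes_energy
#' @export
pes_gradient <- function(pes, config) UseMethod("pes_gradient")

#' Define a reactive pair rule for a toy surface
#'
#' @param el1,el2 Element symbols (unordered pair).
#' @param D Morse well depth (kcal/mol).
#' @param alpha Morse range parameter (1/A).
#' @param r_e Morse equilibrium distance (A).
#' @param h Barrier-bump height (kcal/mol); 0 gives a pure Morse well.
#' @param r_b Bump centre (A).
#' @param w Bump width (A).
#' @return A one-row data frame; rows are collected by [toy_pes()].
#' @export
pair_rule <- function(el1, el2, D, alpha, r_e, h = 0, r_b = 2.5, w = 0.3) {
  stopifnot(D > 0, alpha > 0, r_e > 0, h >= 0, r_b > 0, w > 0)
  data.frame(el1 = el1, el2 = el2, reactive = TRUE,
             D = D, alpha = alpha, r_e = r_e, h = h, r_b = r_b, w = w,
             A = NA_real_, rho = NA_real_, stringsAsFactors = FALSE)
}

#' Define a non-reactive (purely repulsive) pair rule
#'
#' @inheritParams pair_rule
#' @param A Repulsion prefactor (kcal/mol).
#' @param rho Repulsion decay length (A).
#' @return A one-row data frame; rows are collected by [toy_pes()].
#' @export
repulsive_rule <- function(el1, el2, A = 100, rho = 0.5) {
  stopifnot(A > 0, rho > 0)
  data.frame(el1 = el1, el2 = el2, reactive = FALSE,
             D = NA_real_, alpha = NA_real_, r_e = NA_real_, h = NA_real_,
             r_b = NA_real_, w = NA_real_, A = A, rho = rho,
             stringsAsFactors = FALSE)
}

#' Build a toy reactive potential-energy surface
#'
#' @param rules Data frame of pair rules from [pair_rule()] /
#'   [repulsive_rule()] (rbind them).
#' @param name Backend name.
#' @return An object of classes `rtip_toy_pes`, `rtip_pes`.
#' @export
toy_pes <- function(rules, name = "toy") {
  stopifnot(is.data.frame(rules), nrow(rules) >= 1L)
  key <- apply(rules[, c("el1", "el2")], 1L, function(e) paste(sort(e), collapse = "-"))
  if (anyDuplicated(key)) stop("duplicate pair rule", call. = FALSE)
  rules$key <- key
  # plain-list lookup: data-frame row extraction is too slow for the
  # sampler's inner loop
  lookup <- lapply(seq_len(nrow(rules)), function(i) as.list(rules[i, ]))
  names(lookup) <- key
  structure(list(rules = rules, lookup = lookup, name = name),
            class = c("rtip_toy_pes", "rtip_pes"))
}

#' @export
print.rtip_toy_pes <- function(x, ...) {
  cat(sprintf("<rtip_toy_pes '%s'> %d pair rule(s)\n", x$name, nrow(x$rules)))
  invisible(x)
}

.pair_rule_for <- function(pes, e1, e2) {
  k <- if (e1 <= e2) paste0(e1, "-", e2) else paste0(e2, "-", e1)
  rule <- pes$lookup[[k]]
  if (is.null(rule)) stop("no pair rule for elements ", k, call. = FALSE)
  rule
}

# precomputed per-configuration pair list (indices + rules), reused by both
# energy and gradient
.pair_table <- function(pes, config) {
  n <- n_atoms(config)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    out[[length(out) + 1L]] <-
      list(i = i, j = j,
           rule = .pair_rule_for(pes, config$symbols[i], config$symbols[j]))
  }
  out
}

# scalar pair energy and its radial derivative
.pair_ev <- function(rule, r) {
  if (rule$reactive) {
    ex <- exp(-rule$alpha * (r - rule$r_e))
    e <- rule$D * ((1 - ex)^2 - 1)
    de <- 2 * rule$D * rule$alpha * ex * (1 - ex)
    if (rule$h > 0) {
      gb <- rule$h * exp(-(r - rule$r_b)^2 / (2 * rule$w^2))
      e <- e + gb
      de <- de - gb * (r - rule$r_b) / rule$w^2
    }
  } else {
    e <- rule$A * exp(-r / rule$rho)
    de <- -e / rule$rho
  }
  c(e, de)
}

#' Pair interaction profile of a toy surface
#'
#' @param pes An `rtip_toy_pes`.
#' @param pair Character vector of two element symbols.
#' @param r Vector of distances (A).
#' @return Numeric vector of pair energies (kcal/mol).
#' @export
toy_pair_energy <- function(pes, pair, r) {
  rule <- .pair_rule_for(pes, pair[1L], pair[2L])
  vapply(r, function(ri) .pair_ev(rule, ri)[1L], 0.0)
}

#' @export
pes_energy.rtip_toy_pes <- function(pes, config) {
  n <- n_atoms(config)
  if (n < 2L) return(0.0)
  xyz <- config$coords
  e <- 0.0
  for (p in .pair_table(pes, config)) {
    r <- sqrt(sum((xyz[p$i, ] - xyz[p$j, ])^2))
    e <- e + .pair_ev(p$rule, r)[1L]
  }
  e
}

#' @export
pes_gradient.rtip_toy_pes <- function(pes, config) {
  n <- n_atoms(config)
  grad <- matrix(0.0, n, 3L)
  if (n < 2L) return(grad)
  xyz <- config$coords
  for (p in .pair_table(pes, config)) {
    dv <- xyz[p$i, ] - xyz[p$j, ]
    r <- sqrt(sum(dv^2))
    de <- .pair_ev(p$rule, r)[2L]
    g <- (de / r) * dv
    grad[p$i, ] <- grad[p$i, ] + g
    grad[p$j, ] <- grad[p$j, ] - g
  }
  grad
}

#' Toy-surface energy of a configuration
#'
#' Convenience wrapper around [pes_energy()] for toy surfaces.
#' @param config An `rtip_config`.
#' @param pes An `rtip_toy_pes`.
#' @return Energy in kcal/mol.
#' @export
toy_energy <- function(config, pes) pes_energy(pes, config)

#' Dense 1-D association scan of a reactive pair (independent barrier oracle)
#'
#' Scans the pair interaction on a dense grid, takes the barrier as the scan
#' maximum minus the approach-side plateau (the energy at `r_max`), refines
#' the interior maximum and the global minimum by golden-section search to
#' ~1e-6 kcal/mol, and reports the well depth as plateau minus global minimum.
#'
#' @param pes An `rtip_toy_pes`.
#' @param pair Character vector of two element symbols.
#' @param r_min,r_max Scan range (A); must bracket the bump centre.
#' @param n_points Number of grid points (>= 1000).
#' @return List with `barrier_height` (kcal/mol; 0 if no interior maximum),
#'   `r_ts` (A, or NA), `well_depth` (kcal/mol), `r_min_energy` (A).
#' @export
scan_barrier <- function(pes, pair, r_min = 0.6, r_max = 12, n_points = 100000L) {
  stopifnot(n_points >= 1000L, r_min < r_max)
  rule <- .pair_rule_for(pes, pair[1L], pair[2L])
  if (rule$reactive && !(r_min < rule$r_b && rule$r_b < r_max)) {
    stop("scan range must bracket the bump centre", call. = FALSE)
  }
  r <- seq(r_min, r_max, length.out = n_points)
  e <- toy_pair_energy(pes, pair, r)
  f <- function(ri) toy_pair_energy(pes, pair, ri)
  plateau <- e[n_points]
  i_min <- which.min(e)
  # association barrier: the interior maximum between the well and the plateau
  # (the short-range repulsive wall is excluded)
  barrier <- 0.0; r_ts <- NA_real_
  if (i_min < n_points - 1L) {
    seg <- seq.int(i_min, n_points)
    i_max <- seg[which.max(e[seg])]
    if (i_max > i_min && i_max < n_points && e[i_max] > plateau) {
      opt <- stats::optimize(f, lower = r[i_max - 1L], upper = r[i_max + 1L],
                             maximum = TRUE, tol = 1e-9)
      barrier <- opt$objective - plateau
      r_ts <- opt$maximum
    }
  }
  lo <- max(1L, i_min - 1L); hi <- min(n_points, i_min + 1L)
  optm <- stats::optimize(f, lower = r[lo], upper = r[hi], tol = 1e-9)
  list(barrier_height = barrier, r_ts = r_ts,
       well_depth = plateau - optm$objective, r_min_energy = optm$minimum)
}

#' Wrap an external energy/gradient engine as a PES backend
#'
#' The command template must contain `{xyz_in}` and `{out}` placeholders. For
#' every evaluation the configuration is written as XYZ to `{xyz_in}`, the
#' command is run, and `{out}` is parsed: line 1 the energy in kcal/mol, then
#' one `gx gy gz` line per atom (kcal/(mol A)).
#'
#' @param command_template Shell command with `{xyz_in}` / `{out}`
#'   placeholders; the first token must resolve to an available executable.
#' @param name Backend name.
#' @return An object of classes `rtip_external_pes`, `rtip_pes`.
#' @export
external_pes <- function(command_template, name = "external") {
  exe <- strsplit(trimws(command_template), "[[:space:]]+")[[1L]][1L]
  if (!file.exists(exe) && Sys.which(exe) == "") {
    stop("external PES backend unavailable: executable '", exe, "' not found",
         call. = FALSE)
  }
  structure(list(command_template = command_template, name = name),
            class = c("rtip_external_pes", "rtip_pes"))
}

.external_eval <- function(pes, config) {
  xyz <- tempfile(fileext = ".xyz")
  out <- tempfile(fileext = ".out")
  on.exit(unlink(c(xyz, out)))
  write_xyz(config, xyz)
  cmd <- gsub("{out}", out, gsub("{xyz_in}", xyz, pes$command_template,
                                 fixed = TRUE), fixed = TRUE)
  status <- system(cmd, ignore.stdout = TRUE, ignore.stderr = TRUE)
  if (status != 0L) stop("external PES command failed (exit ", status, ")",
                         call. = FALSE)
  lines <- readLines(out, warn = FALSE)
  n <- n_atoms(config)
  if (length(lines) < n + 1L) {
    stop("external PES output too short: expected ", n + 1L, " lines, got ",
         length(lines), call. = FALSE)
  }
  e <- suppressWarnings(as.numeric(trimws(lines[1L])))
  if (is.na(e)) stop("external PES output parse error at line 1: '",
                     lines[1L], "'", call. = FALSE)
  grad <- matrix(0.0, n, 3L)
  for (i in seq_len(n)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 1L]),
                                                 "[[:space:]]+")[[1L]]))
    if (length(vals) != 3L || anyNA(vals)) {
      stop("external PES output parse error at line ", i + 1L, ": '",
           lines[i + 1L], "'", call. = FALSE)
    }
    grad[i, ] <- vals
  }
  list(energy = e, gradient = grad)
}

#' @export
pes_energy.rtip_external_pes <- function(pes, config) {
  .external_eval(pes, config)$energy
}

#' @export
pes_gradient.rtip_external_pes <- function(pes, config) {
  .external_eval(pes, config)$gradient
}

#' Read / write toy-surface parameter files
#'
#' CSV of pair rules (columns `el1`, `el2`, `reactive`, `D`, `alpha`, `r_e`,
#' `h`, `r_b`, `w`, `A`, `rho`) with a leading `# name=` comment line.
#'
#' @param pes An `rtip_toy_pes`.
#' @param path File path.
#' @return `read_toy_pes`: an `rtip_toy_pes`; `write_toy_pes`: `path`,
#'   invisibly.
#' @export
write_toy_pes <- function(pes, path) {
  stopifnot(inherits(pes, "rtip_toy_pes"))
  cols <- c("el1", "el2", "reactive", "D", "alpha", "r_e", "h", "r_b", "w",
            "A", "rho")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# name=", pes$name), con)
  utils::write.csv(pes$rules[, cols], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_toy_pes
#' @export
read_toy_pes <- function(path) {
  first <- readLines(path, n = 1L)
  name <- if (grepl("^# name=", first)) sub("^# name=", "", first) else "toy"
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  toy_pes(df, name = name)
}
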