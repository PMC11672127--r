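# Independent oracles and generators used across the suite. These never call
# the implementation paths they check.

random_config <- function(n, symbols = NULL, spread = 2) {
  if (is.null(symbols)) symbols <- sample(c("C", "H", "N", "O"), n, replace = TRUE)
  configuration(symbols, matrix(stats::rnorm(n * 3, sd = spread), n, 3))
}

euler_rotation <- function(a, b, c) {
  # z-y-z convention
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# brute-force minimum superposition distance: dense Euler grid followed by
# Nelder-Mead refinement of the direct Frobenius norm
grid_align_min <- function(p1, p2, n_alpha = 24, n_beta = 13) {
  x <- sweep(p1$coords, 2, colMeans(p1$coords))
  y <- sweep(p2$coords, 2, colMeans(p2$coords))
  dist_at <- function(ang) {
    r <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(sum((x - y %*% t(r))^2))
  }
  best <- Inf; best_ang <- c(0, 0, 0)
  alphas <- seq(0, 2 * pi, length.out = n_alpha + 1)[-(n_alpha + 1)]
  betas <- seq(0, pi, length.out = n_beta)
  for (a in alphas) for (b in betas) for (c in alphas) {
    d <- dist_at(c(a, b, c))
    if (d < best) { best <- d; best_ang <- c(a, b, c) }
  }
  opt <- stats::optim(best_ang, dist_at, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best, opt$value)
}

so3_generators <- function() {
  list(matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE),
       matrix(c(0, 0, 1, 0, 0, 0, -1, 0, 0), 3, 3, byrow = TRUE),
       matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE))
}

# canonical string by explicit minimisation over all vertex permutations
brute_canonical <- function(symbols, edges) {
  n <- length(symbols)
  perms <- if (n == 1) list(1L) else asplit(.permutations(n), 1)
  best <- NULL
  for (p in perms) {
    sym_p <- symbols[order(p)]
    if (nrow(edges) > 0) {
      e <- cbind(p[edges[, 1]], p[edges[, 2]])
      e <- t(apply(e, 1, sort))
      e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
      es <- paste(e[, 1], e[, 2], sep = "-", collapse = ",")
    } else es <- ""
    s <- paste(paste(sym_p, collapse = ""), es, sep = "|")
    if (is.null(best) || s < best) best <- s
  }
  best
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# exhaustive minimax oracle: enumerate reaction subsets (<= 14 reactions)
oracle_minimax <- function(network, target) {
  if (target %in% network$seeds) return(0)
  m <- length(network$reactions)
  stopifnot(m <= 14)
  reaches <- function(idx) {
    have <- network$seeds
    rs <- network$reactions[idx]
    repeat {
      fired <- FALSE
      for (r in rs) {
        if (all(c(r$reactants, r$catalysts) %in% have) &&
            !all(r$products %in% have)) {
          have <- unique(c(have, r$products)); fired <- TRUE
        }
      }
      if (!fired) break
    }
    target %in% have
  }
  best <- Inf
  for (mask in seq_len(2^m) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    if (!length(idx)) next
    g <- vapply(network$reactions[idx], function(r) {
      if (is.na(r$g_a)) Inf else r$g_a
    }, 0)
    if (max(g) >= best) next
    if (reaches(idx)) best <- max(g)
  }
  if (is.infinite(best) && !reaches(seq_len(m))) NA_real_ else best
}

# threshold-sweep minimax oracle for larger networks: independent naive
# fixpoint reachability per ascending barrier ceiling
oracle_minimax_sweep <- function(network, target) {
  if (target %in% network$seeds) return(0)
  g_all <- vapply(network$reactions, function(r) {
    if (is.na(r$g_a)) Inf else r$g_a
  }, 0)
  closure <- function(ceiling) {
    have <- network$seeds
    repeat {
      added <- FALSE
      for (i in seq_along(network$reactions)) {
        if (g_all[i] > ceiling) next
        r <- network$reactions[[i]]
        if (all(c(r$reactants, r$catalysts) %in% have) &&
            !all(r$products %in% have)) {
          have <- unique(c(have, r$products)); added <- TRUE
        }
      }
      if (!added) break
    }
    have
  }
  for (g in sort(unique(g_all))) {
    if (target %in% closure(g)) return(g)
  }
  NA_real_
}

# brute-force energetic span: double loop over (TS, preceding intermediate)
oracle_span <- function(profile) {
  ts <- which(profile$kind == "TS")
  if (!length(ts)) return(0)
  best <- -Inf
  for (j in ts) {
    for (i in seq_len(j - 1)) {
      if (profile$kind[i] != "intermediate") next
      best <- max(best, profile$g[j] - profile$g[i])
    }
  }
  best
}

random_profile <- function(n_steps) {
  k <- 2 * n_steps + 1
  kind <- rep(c("intermediate", "TS"), length.out = k)
  data.frame(label = paste0("S", seq_len(k)), kind = kind,
             g = cumsum(stats::rnorm(k, sd = 8)))
}

random_small_network <- function(n_species = 6, n_reactions = 8) {
  species <- paste0("S", seq_len(n_species))
  seeds <- species[1:2]
  reactions <- lapply(seq_len(n_reactions), function(i) {
    nr <- sample(1:2, 1); np <- sample(1:2, 1)
    elementary_reaction(
      id = sprintf("T%02d", i),
      reactants = sample(species, nr, replace = TRUE),
      products = sample(species, np, replace = TRUE),
      catalysts = if (stats::runif(1) < 0.3) sample(species, 1) else character(0),
      g_a = round(stats::runif(1, 1, 60), 1)
    )
  })
  build_network(reactions, seeds)
}

# degeneracy path: configurations engineered so the two lowest key-matrix
# eigenvalues cross exactly at t = 0 (singular values 3, 1+t, 1-t with a
# reflection-like correspondence)
crossing_pair <- function(t) {
  y <- rbind(diag(3), -diag(3))
  m <- diag(c(3, 1 + t, -(1 - t)))
  list(p1 = configuration(rep("C", 6), y %*% t(m)),
       p2 = configuration(rep("C", 6), y))
}
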