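# RTIP pathway-sampling driver: reactant placement, coincided-centroid
# destination, biased relaxation with a step-growing Gaussian bias, and
# climb/drop termination monitoring.

#' Sampler parameters
#'
#' @param e_climb Failure threshold (kcal/mol): the sampling aborts when the
#'   real energy rises more than this above the initial energy. Default 115.
#' @param e_drop Success threshold (kcal/mol): a drop of more than this from
#'   the running maximum of the real energy signals bond formation.
#'   Default 12.5.
#' @param placement_radius Distance of each molecular centroid from the
#'   global centroid at placement (A). Default 5.
#' @param max_steps Maximum number of outer bias steps. Default 500.
#' @param micro_iters Damped-descent iterations per bias step. Default 20.
#' @param max_displacement Per-atom displacement cap per iteration (A).
#'   Default 0.1.
#' @param gain Initial descent gain (A^2 mol/kcal). Default 0.02.
#' @param seed Integer RNG seed for placement.
#' @param n_samplings Parallel attempts per reactant set. Default 32.
#' @param relax_initial Relax the placement on the real PES before sampling
#'   (the energy reference E_ini is taken after this relaxation). Default TRUE.
#' @return An object of class `rtip_sampler_params`.
#' @export
sampler_params <- function(e_climb = 115, e_drop = 12.5, placement_radius = 5,
                           max_steps = 500L, micro_iters = 20L,
                           max_displacement = 0.1, gain = 0.02, seed = 1L,
                           n_samplings = 32L, relax_initial = TRUE) {
  stopifnot(e_climb > e_drop, e_drop > 0, placement_radius > 0,
            max_steps >= 1L, micro_iters >= 1L, max_displacement > 0,
            gain > 0, n_samplings >= 1L)
  structure(list(e_climb = e_climb, e_drop = e_drop,
                 placement_radius = placement_radius,
                 max_steps = as.integer(max_steps),
                 micro_iters = as.integer(micro_iters),
                 max_displacement = max_displacement, gain = gain,
                 seed = as.integer(seed),
                 n_samplings = as.integer(n_samplings),
                 relax_initial = relax_initial),
            class = "rtip_sampler_params")
}

# centroid directions: antipodal for 2 molecules, trigonal for 3 --
# the molecular centroids then average exactly to the global centroid
.placement_directions <- function(k) {
  frame <- random_rotation()
  if (k == 2L) {
    u <- frame[, 1L]
    list(u, -u)
  } else {
    phi0 <- stats::runif(1L, 0, 2 * pi)
    lapply(seq_len(3L), function(j) {
      th <- phi0 + (j - 1L) * 2 * pi / 3
      cos(th) * frame[, 1L] + sin(th) * frame[, 2L]
    })
  }
}

.min_intermolecular_distance <- function(coords, mol_id) {
  dm <- as.matrix(stats::dist(coords))
  same <- outer(mol_id, mol_id, `==`)
  min(dm[!same])
}

#' Randomly place reactant molecules around a common centroid
#'
#' Each molecule is randomly oriented (uniform over SO(3) via seeded unit
#' quaternions) and rigidly moved so that its centroid sits at
#' `radius` from the global centroid (the mean of the molecular centroids):
#' antipodal directions for two molecules, trigonal at 120 degrees in a random
#' plane for three. Placements with any intermolecular atom pair closer than
#' `min_separation` are redrawn (up to 100 times).
#'
#' @param molecules List of 2 or 3 `rtip_config` objects (repetition allowed).
#' @param radius Placement radius (A).
#' @param seed Integer seed; placements are deterministic given the seed.
#' @param min_separation Clash floor between molecules (A). Default 2.
#' @return An `rtip_config` with `molecule_id` labels assigned.
#' @export
place_reactants <- function(molecules, radius = 5, seed = 1L,
                            min_separation = 2) {
  if (!is.list(molecules) || length(molecules) < 2L || length(molecules) > 3L) {
    stop("place_reactants requires 2 or 3 molecules", call. = FALSE)
  }
  stopifnot(radius > 0)
  k <- length(molecules)
  .with_seed(seed, {
    for (attempt in seq_len(100L)) {
      dirs <- .placement_directions(k)
      pieces <- vector("list", k)
      for (j in seq_len(k)) {
        cen <- center_configuration(molecules[[j]])$config
        rot <- random_rotation()
        coords <- cen$coords %*% t(rot) +
          matrix(radius * dirs[[j]], n_atoms(cen), 3L, byrow = TRUE)
        pieces[[j]] <- list(symbols = cen$symbols, coords = coords)
      }
      symbols <- unlist(lapply(pieces, `[[`, "symbols"))
      coords <- do.call(rbind, lapply(pieces, `[[`, "coords"))
      mol_id <- rep(seq_len(k), vapply(pieces, function(p) length(p$symbols), 0L))
      if (.min_intermolecular_distance(coords, mol_id) >= min_separation) {
        return(configuration(symbols, coords, molecule_id = mol_id))
      }
    }
    stop("could not satisfy the ", min_separation,
         " A clash criterion in 100 placement draws", call. = FALSE)
  })
}

#' Build the coincided-centroid destination configuration
#'
#' Each molecule is translated -- without rotation or internal distortion --
#' so that all molecular centroids coincide with the global centroid. This
#' virtual structure is the attractor of the Gaussian bias; the real PES
#' decides what actually happens on the way there.
#'
#' @param p_ini An `rtip_config` with `molecule_id` labels.
#' @return The destination `rtip_config` (same atom order and labels).
#' @export
build_destination <- function(p_ini) {
  stopifnot(inherits(p_ini, "rtip_config"))
  if (is.null(p_ini$molecule_id)) {
    stop("build_destination requires molecule_id labels", call. = FALSE)
  }
  ids <- unique(p_ini$molecule_id)
  cents <- t(vapply(ids, function(i) {
    colMeans(p_ini$coords[p_ini$molecule_id == i, , drop = FALSE])
  }, numeric(3L)))
  global <- colMeans(cents)
  out <- p_ini
  for (j in seq_along(ids)) {
    sel <- p_ini$molecule_id == ids[j]
    shift <- global - cents[j, ]
    out$coords[sel, ] <- sweep(p_ini$coords[sel, , drop = FALSE], 2L, -shift)
  }
  out
}

# damped steepest descent with backtracking on `energy_fn`; per-atom step
# capped at `cap` A. Deterministic. Returns list(config, energy, gain,
# converged, n_eval).
.descend <- function(config, energy_fn, grad_fn, iters, cap, gain,
                     grad_tol = 0) {
  e <- energy_fn(config)
  converged <- FALSE
  for (it in seq_len(iters)) {
    g <- grad_fn(config)
    if (!all(is.finite(g)) || !is.finite(e)) {
      return(list(config = config, energy = e, gain = gain,
                  converged = FALSE, failed = TRUE))
    }
    # rotation-invariant convergence test: the largest per-atom gradient norm
    # (a max-component test would depend on the molecular orientation)
    if (grad_tol > 0 && max(sqrt(rowSums(g * g))) <= grad_tol) {
      converged <- TRUE
      break
    }
    accepted <- FALSE
    for (bt in seq_len(30L)) {
      step <- -gain * g
      norms <- sqrt(rowSums(step^2))
      over <- norms > cap
      if (any(over)) step[over, ] <- step[over, , drop = FALSE] * (cap / norms[over])
      trial <- config
      trial$coords <- config$coords + step
      et <- energy_fn(trial)
      if (is.finite(et) && et <= e) {
        config <- trial; e <- et; accepted <- TRUE
        gain <- gain * 1.2
        break
      }
      gain <- gain / 2
    }
    if (!accepted) {
      g_now <- grad_fn(config)
      converged <- grad_tol > 0 && max(sqrt(rowSums(g_now * g_now))) <= grad_tol
      break
    }
  }
  list(config = config, energy = e, gain = gain, converged = converged,
       failed = FALSE)
}

#' Local optimization on the real PES
#'
#' Damped steepest descent with backtracking line search and a per-atom
#' displacement cap. Energy is non-increasing across accepted steps.
#'
#' @param p An `rtip_config`.
#' @param pes A PES backend.
#' @param grad_tol Convergence threshold on the largest per-atom gradient
#'   norm (kcal/(mol A)); rotation-invariant, and stricter than the same
#'   bound on the largest component. Default 1e-4.
#' @param max_iter Iteration cap. Default 10000.
#' @param max_displacement Per-atom step cap (A). Default 0.1.
#' @param gain Initial gain. Default 0.02.
#' @return The optimized `rtip_config`, with attribute `converged` (logical)
#'   and `energy` (kcal/mol).
#' @export
local_optimize <- function(p, pes, grad_tol = 1e-4, max_iter = 10000L,
                           max_displacement = 0.1, gain = 0.02) {
  res <- .descend(p,
                  function(cfg) pes_energy(pes, cfg),
                  function(cfg) pes_gradient(pes, cfg),
                  iters = max_iter, cap = max_displacement, gain = gain,
                  grad_tol = grad_tol)
  if (isTRUE(res$failed)) stop("non-finite energy/gradient in local_optimize",
                               call. = FALSE)
  out <- res$config
  attr(out, "converged") <- res$converged
  attr(out, "energy") <- res$energy
  out
}

#' Run one RTIP pathway sampling
#'
#' Starting from a placed configuration, superimposes the step-growing
#' Gaussian bias towards the coincided-centroid destination onto the real PES
#' and relaxes. Per outer step n the biased surface is relaxed for up to
#' `micro_iters` damped-descent iterations, and the real energy and both
#' termination thresholds are monitored at every iteration: if
#' `E_real - E_ini > e_climb` the sampling fails (`climb_exceeded`); if the
#' drop from the running maximum exceeds `e_drop` the bias is removed, the
#' configuration is locally optimized on the real PES and the sampling
#' succeeds (`reaction_found`); otherwise it continues up to `max_steps`.
#' The running maximum `e_max` is likewise tracked at iteration granularity,
#' so the recorded maximum brackets the crossed barrier tightly; the returned
#' trajectory is sampled once per outer step.
#'
#' @param p_ini Placed `rtip_config` (with `molecule_id` labels for the
#'   destination construction).
#' @param pes A PES backend.
#' @param bias An [bias_params()] object; an `NA` width is frozen at start to
#'   `max(1, d_1(P_ini, P_des)/3)`.
#' @param params An [sampler_params()] object.
#' @return An object of class `rtip_pathway` with fields `status`
#'   (`reaction_found`, `climb_exceeded`, `max_steps_reached` or
#'   `numerical_failure`), `trajectory` (data frame: step, e_real, e_bias,
#'   d1 -- the metric to the destination),
#'   `configurations` (list of per-step configurations), `e_ini`, `e_max`,
#'   `step_of_max`, `step_of_detection`, `p_max`, `p_pro`, `p_des`,
#'   `bias_width`.
#' @export
run_sampling <- function(p_ini, pes, bias = bias_params(),
                         params = sampler_params()) {
  stopifnot(inherits(p_ini, "rtip_config"))
  p_des <- build_destination(p_ini)
  p_cur <- p_ini
  if (params$relax_initial) {
    p_cur <- local_optimize(p_ini, pes, max_iter = 2000L,
                            max_displacement = params$max_displacement,
                            gain = params$gain)
  }
  e_ini <- pes_energy(pes, p_cur)
  if (is.na(bias$width)) {
    bias$width <- max(1, rtip_metric(p_cur, p_des) / 3)
  }
  e_max <- e_ini
  p_max <- p_cur
  step_of_max <- 0L
  step_of_detection <- NA_integer_
  status <- "max_steps_reached"
  steps <- integer(0); e_reals <- numeric(0); e_biases <- numeric(0)
  d1s <- numeric(0)
  configs <- list()
  gain <- params$gain
  p_pro <- NULL

  e_real <- e_ini
  e_bias <- 0.0
  cap <- params$max_displacement
  terminal <- FALSE
  for (n in seq_len(params$max_steps)) {
    failed <- FALSE
    # relax the biased surface; both thresholds are monitored at every
    # iteration, not just at the end of the outer step
    for (k in seq_len(params$micro_iters)) {
      be <- .bias_eval(p_cur, p_des, n, bias, gradient = TRUE)
      e_bias <- be$energy
      g <- pes_gradient(pes, p_cur) + be$gradient
      if (!all(is.finite(g)) || !is.finite(e_real)) { failed <- TRUE; break }
      if (max(sqrt(rowSums(g * g))) < 1e-5) break  # minimum of this surface
      e_tot <- e_real + e_bias
      accepted <- FALSE
      for (bt in seq_len(12L)) {
        step <- -gain * g
        norms <- sqrt(rowSums(step * step))
        over <- norms > cap
        if (any(over)) {
          step[over, ] <- step[over, , drop = FALSE] * (cap / norms[over])
        }
        trial <- p_cur
        trial$coords <- p_cur$coords + step
        e_real_t <- pes_energy(pes, trial)
        e_bias_t <- .bias_eval(trial, p_des, n, bias, gradient = FALSE)$energy
        if (is.finite(e_real_t) && e_real_t + e_bias_t <= e_tot) {
          p_cur <- trial; e_real <- e_real_t; e_bias <- e_bias_t
          gain <- gain * 1.2
          accepted <- TRUE
          break
        }
        gain <- gain / 2
      }
      if (!accepted) { gain <- params$gain; break }  # biased minimum reached
      if (e_real > e_max) { e_max <- e_real; p_max <- p_cur; step_of_max <- n }
      if (e_real - e_ini > params$e_climb) {
        status <- "climb_exceeded"; terminal <- TRUE; break
      }
      if (e_max - e_real > params$e_drop) {
        status <- "reaction_found"; terminal <- TRUE
        step_of_detection <- n
        break
      }
    }
    steps <- c(steps, n); e_reals <- c(e_reals, e_real)
    e_biases <- c(e_biases, e_bias)
    d1s <- c(d1s, rtip_metric(p_cur, p_des))
    configs[[length(configs) + 1L]] <- p_cur
    if (failed || !is.finite(e_real)) { status <- "numerical_failure"; break }
    if (terminal) {
      if (status == "reaction_found") {
        p_pro <- local_optimize(p_cur, pes,
                                max_displacement = params$max_displacement,
                                gain = params$gain)
      }
      break
    }
  }
  structure(list(status = status,
                 trajectory = data.frame(step = steps, e_real = e_reals,
                                         e_bias = e_biases, d1 = d1s),
                 configurations = configs,
                 e_ini = e_ini, e_max = e_max, step_of_max = step_of_max,
                 step_of_detection = step_of_detection,
                 p_max = p_max, p_pro = p_pro, p_des = p_des,
                 bias_width = bias$width),
            class = "rtip_pathway")
}

#' @export
print.rtip_pathway <- function(x, ...) {
  cat(sprintf("<rtip_pathway> status=%s steps=%d E_ini=%.3f E_max=%.3f\n",
              x$status, nrow(x$trajectory), x$e_ini, x$e_max))
  invisible(x)
}

#' Run a batch of independent pathway samplings
#'
#' Runs `params$n_samplings` attempts; attempt i places the reactants with
#' seed `params$seed + i - 1`, so results are a pure function of
#' (seed, inputs) and the batch is embarrassingly parallel in principle
#' (executed sequentially here).
#'
#' @param molecules List of 2-3 `rtip_config` molecules (repetition allowed).
#' @param pes A PES backend.
#' @param bias An [bias_params()] object.
#' @param params An [sampler_params()] object.
#' @return A list of `rtip_pathway` results of length `n_samplings`.
#' @export
run_sampling_batch <- function(molecules, pes, bias = bias_params(),
                               params = sampler_params()) {
  lapply(seq_len(params$n_samplings), function(i) {
    p_ini <- place_reactants(molecules, radius = params$placement_radius,
                             seed = params$seed + i - 1L)
    run_sampling(p_ini, pes, bias, params)
  })
}
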