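# Reactant placement, destination construction, biased sampling driver.

test_that("two single atoms are placed antipodally at the requested radius", {
  a <- configuration("A", matrix(0, 1, 3))
  x <- configuration("X", matrix(0, 1, 3))
  p <- place_reactants(list(a, x), radius = 5, seed = 7)
  expect_equal(unname(c(stats::dist(p$coords))), 10, tolerance = 1e-9)
  expect_identical(p$molecule_id, c(1L, 2L))
  # determinism: same seed, same coordinates
  p2 <- place_reactants(list(a, x), radius = 5, seed = 7)
  expect_identical(p$coords, p2$coords)
  p3 <- place_reactants(list(a, x), radius = 5, seed = 8)
  expect_false(identical(p$coords, p3$coords))
})

test_that("three molecules sit at the radius around their common centroid", {
  w <- reference_molecules()$H2O
  for (seed in 1:10) {
    p <- place_reactants(list(w, w, w), radius = 5, seed = seed)
    cents <- t(vapply(1:3, function(i) {
      colMeans(p$coords[p$molecule_id == i, , drop = FALSE])
    }, numeric(3)))
    global <- colMeans(cents)
    d <- sqrt(rowSums(sweep(cents, 2, global)^2))
    expect_equal(d, rep(5, 3), tolerance = 1e-9)
    # clash floor between different molecules
    dm <- as.matrix(stats::dist(p$coords))
    inter <- dm[outer(p$molecule_id, p$molecule_id, `!=`)]
    expect_gte(min(inter), 2)
    # internal geometry preserved
    for (i in 1:3) {
      sub <- p$coords[p$molecule_id == i, ]
      expect_equal(c(stats::dist(sub)), c(stats::dist(w$coords)),
                   tolerance = 1e-9)
    }
  }
  expect_error(place_reactants(list(w), radius = 5), "2 or 3")
  # an impossible clash constraint is reported after the draw budget
  expect_error(place_reactants(list(w, w), radius = 0.1, seed = 1),
               "clash criterion")
})

test_that("build_destination collapses molecular centroids without distortion", {
  a <- configuration("A", matrix(0, 1, 3))
  x <- configuration("X", matrix(0, 1, 3))
  p <- place_reactants(list(a, x), radius = 5, seed = 3)
  d <- build_destination(p)
  expect_equal(d$coords[1, ], d$coords[2, ], tolerance = 1e-12)

  w <- reference_molecules()$H2O
  p2 <- place_reactants(list(w, w), radius = 5, seed = 3)
  d2 <- build_destination(p2)
  cents <- t(vapply(1:2, function(i) {
    colMeans(d2$coords[d2$molecule_id == i, , drop = FALSE])
  }, numeric(3)))
  expect_equal(cents[1, ], cents[2, ], tolerance = 1e-12)
  for (i in 1:2) {
    sel <- d2$molecule_id == i
    expect_equal(c(stats::dist(d2$coords[sel, ])),
                 c(stats::dist(p2$coords[sel, ])), tolerance = 1e-12)
  }
  # single molecule: geometry unchanged up to translation
  one <- w; one$molecule_id <- rep(1L, 3)
  d3 <- build_destination(one)
  expect_equal(c(stats::dist(d3$coords)), c(stats::dist(w$coords)),
               tolerance = 1e-12)
  expect_error(build_destination(w), "molecule_id")
})

test_that("local_optimize finds the Morse minimum and honours monotonicity", {
  pes <- toy_pes(pair_rule("A", "X", D = 20, alpha = 1.5, r_e = 1.2, h = 0))
  start <- configuration(c("A", "X"), rbind(c(0, 0, 0), c(1.32, 0, 0)))
  opt <- local_optimize(start, pes)
  expect_true(attr(opt, "converged"))
  expect_equal(unname(c(stats::dist(opt$coords))), 1.2, tolerance = 1e-3)
  expect_equal(attr(opt, "energy"), -20, tolerance = 1e-6)
  # an already-stationary input is returned unchanged within tolerance
  opt2 <- local_optimize(opt, pes)
  expect_lt(max(abs(opt2$coords - opt$coords)), 1e-3)
  # started beyond the bump on the shallow outer slope: relaxes outward,
  # never back over the barrier
  bumpy <- toy_diatomic_pes()
  sc <- scan_barrier(bumpy, c("A", "X"))
  outside <- configuration(c("A", "X"), rbind(c(0, 0, 0), c(3.2, 0, 0)))
  opt3 <- local_optimize(outside, bumpy)
  expect_gt(unname(c(stats::dist(opt3$coords))), sc$r_ts)
})

test_that("a sub-threshold barrier yields reaction_found at the Morse bond length", {
  pes <- toy_diatomic_pes()
  sc <- scan_barrier(pes, c("A", "X"))
  a <- configuration("A", matrix(0, 1, 3))
  x <- configuration("X", matrix(0, 1, 3))
  p_ini <- place_reactants(list(a, x), radius = 5, seed = 7)
  res <- run_sampling(p_ini, pes, bias_params(), sampler_params(seed = 7))
  expect_identical(res$status, "reaction_found")
  expect_false(is.na(res$step_of_detection))
  expect_equal(unname(c(stats::dist(res$p_pro$coords))), sc$r_min_energy,
               tolerance = 0.01)
  # the recorded maximum brackets the scan barrier
  expect_gte(res$e_max - res$e_ini, sc$barrier_height - 2)
  expect_lte(res$e_max - res$e_ini, sc$barrier_height + 2)
  # product is a stationary point of the real PES
  expect_lt(max(abs(pes_gradient(pes, res$p_pro))), 1e-4)
  # energy bookkeeping: e_max dominates the per-step records and the
  # detection-step inequality holds as recorded
  expect_gte(res$e_max, max(res$trajectory$e_real))
  e_det <- res$trajectory$e_real[res$trajectory$step == res$step_of_detection]
  expect_gt(res$e_max - e_det, 12.5)
})

test_that("sampling is deterministic given seed and parameters", {
  pes <- toy_diatomic_pes()
  a <- configuration("A", matrix(0, 1, 3))
  x <- configuration("X", matrix(0, 1, 3))
  p_ini <- place_reactants(list(a, x), radius = 5, seed = 11)
  r1 <- run_sampling(p_ini, pes, bias_params(), sampler_params(seed = 11))
  r2 <- run_sampling(p_ini, pes, bias_params(), sampler_params(seed = 11))
  expect_identical(r1$status, r2$status)
  expect_equal(r1$trajectory$e_real, r2$trajectory$e_real, tolerance = 1e-10)
  expect_equal(r1$p_pro$coords, r2$p_pro$coords, tolerance = 1e-10)
})

test_that("a super-threshold barrier yields climb_exceeded bounded by the barrier", {
  pes <- toy_diatomic_pes(h = 135)
  sc <- scan_barrier(pes, c("A", "X"))
  expect_gt(sc$barrier_height, 115)
  a <- configuration("A", matrix(0, 1, 3))
  x <- configuration("X", matrix(0, 1, 3))
  p_ini <- place_reactants(list(a, x), radius = 5, seed = 7)
  res <- run_sampling(p_ini, pes, bias_params(),
                      sampler_params(seed = 7, max_steps = 2000L))
  expect_identical(res$status, "climb_exceeded")
  expect_gt(res$e_max - res$e_ini, 115)
  # the absolute recorded maximum can never exceed the 1-D surface maximum
  # (e_ini sits slightly below zero in the pre-barrier encounter complex)
  expect_lte(res$e_max, sc$barrier_height + 1e-6)
  expect_null(res$p_pro)
})

test_that("mutually repulsive atoms never produce a reaction", {
  pes <- toy_pes(rbind(repulsive_rule("A", "X"),
                       repulsive_rule("A", "A"), repulsive_rule("X", "X")))
  a <- configuration("A", matrix(0, 1, 3))
  x <- configuration("X", matrix(0, 1, 3))
  p_ini <- place_reactants(list(a, x), radius = 5, seed = 5)
  res <- run_sampling(p_ini, pes, bias_params(),
                      sampler_params(seed = 5, max_steps = 300L))
  expect_true(res$status %in% c("climb_exceeded", "max_steps_reached"))
})

test_that("threshold semantics flip the outcome as the spec's inequalities say", {
  pes <- toy_diatomic_pes()
  sc <- scan_barrier(pes, c("A", "X"))
  a <- configuration("A", matrix(0, 1, 3))
  x <- configuration("X", matrix(0, 1, 3))
  p_ini <- place_reactants(list(a, x), radius = 5, seed = 7)
  # lowering e_climb below the oracle barrier turns the reacting case into
  # a failed climb
  res_lo <- run_sampling(p_ini, pes, bias_params(),
                         sampler_params(e_climb = sc$barrier_height - 5,
                                        seed = 7))
  expect_identical(res_lo$status, "climb_exceeded")
  # raising e_drop above the full release (barrier + well depth) prevents
  # detection: the drop is measured from the running maximum
  res_hi <- run_sampling(p_ini, pes, bias_params(),
                         sampler_params(e_drop = sc$barrier_height +
                                          sc$well_depth + 5,
                                        e_climb = 200, seed = 7,
                                        max_steps = 400L))
  expect_false(identical(res_hi$status, "reaction_found"))
})

test_that("batches are pure functions of their seeds", {
  pes <- toy_diatomic_pes()
  a <- configuration("A", matrix(0, 1, 3))
  x <- configuration("X", matrix(0, 1, 3))
  b1 <- run_sampling_batch(list(a, x), pes, bias_params(),
                           sampler_params(seed = 40, n_samplings = 3L))
  b2 <- run_sampling_batch(list(a, x), pes, bias_params(),
                           sampler_params(seed = 40, n_samplings = 3L))
  expect_identical(vapply(b1, `[[`, "", "status"),
                   vapply(b2, `[[`, "", "status"))
  for (i in seq_along(b1)) {
    expect_equal(b1[[i]]$trajectory$e_real, b2[[i]]$trajectory$e_real,
                 tolerance = 1e-12)
  }
  # attempt i reproduces an independent run with seed + i - 1
  solo <- run_sampling(place_reactants(list(a, x), radius = 5, seed = 41L),
                       pes, bias_params(), sampler_params(seed = 41L))
  expect_equal(b1[[2]]$trajectory$e_real, solo$trajectory$e_real,
               tolerance = 1e-12)
})
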