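# Reaction-network assembly, minimax routing, energetic spans.

test_that("network assembly deduplicates species and rejects duplicate ids", {
  empty <- build_network(list(), c("CO", "H2"))
  expect_identical(empty$species, c("CO", "H2"))
  r1 <- elementary_reaction("R1", "A0", "B0", g_a = 10)
  expect_error(build_network(list(r1, r1), "A0"), "duplicate reaction id")
  expect_error(elementary_reaction("R1", character(0), "B0", g_a = 1),
               "non-empty")
  expect_error(elementary_reaction("R1", "A0", "B0", g_a = -2),
               "non-negative")
})

test_that("a reaction whose catalyst is never reachable never fires", {
  rs <- list(elementary_reaction("R1", "S", "P1", catalysts = "ghost", g_a = 5),
             elementary_reaction("R2", "S", "P2", g_a = 50))
  net <- build_network(rs, "S")
  expect_false("P1" %in% reachable_species(net))
  expect_true("P2" %in% reachable_species(net))
  expect_null(minimax_route(net, "P1"))
  expect_equal(minimax_route(net, "P2")$bottleneck, 50)
})

test_that("minimax_route solves the hand-enumerable chain/shortcut network", {
  rs <- list(elementary_reaction("Rab", "Aq", "Bq", g_a = 10),
             elementary_reaction("Rbc", "Bq", "Cq", g_a = 20),
             elementary_reaction("Rac", "Aq", "Cq", g_a = 25))
  net <- build_network(rs, "Aq")
  # target in seeds: empty route, zero bottleneck
  r0 <- minimax_route(net, "Aq")
  expect_identical(r0$route, character(0))
  expect_identical(r0$bottleneck, 0)
  r <- minimax_route(net, "Cq")
  expect_identical(sort(r$route), c("Rab", "Rbc"))
  expect_equal(r$bottleneck, 20)
  expect_identical(r$bottleneck_id, "Rbc")
  ranked <- rank_alternatives(net, "Cq", k = 2)
  expect_length(ranked, 2)
  expect_equal(ranked[[1]]$bottleneck, 20)
  expect_identical(ranked[[2]]$route, "Rac")
  expect_equal(ranked[[2]]$bottleneck, 25)
  # k = 1 coincides with minimax_route
  expect_identical(rank_alternatives(net, "Cq", k = 1)[[1]], r)
})

test_that("minimax agrees with exhaustive subset enumeration on small networks", {
  set.seed(51)
  checked <- 0
  for (rep in 1:30) {
    net <- random_small_network(n_species = sample(4:6, 1),
                                n_reactions = sample(4:10, 1))
    for (target in setdiff(net$species, net$seeds)) {
      want <- oracle_minimax(net, target)
      got <- minimax_route(net, target)
      if (is.na(want)) {
        expect_null(got)
      } else {
        expect_equal(got$bottleneck, want)
        # the returned route really attains the bottleneck: every used
        # reaction is at or below it and the target is reached
        sub <- net$reactions[vapply(net$reactions, `[[`, "", "id") %in% got$route]
        subnet <- build_network(sub, net$seeds)
        expect_true(target %in% reachable_species(subnet))
        expect_equal(max(vapply(sub, `[[`, 0, "g_a")), want)
      }
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("removing a reaction never lowers a target's bottleneck", {
  set.seed(52)
  for (rep in 1:10) {
    net <- random_small_network(n_species = 5, n_reactions = 8)
    for (target in setdiff(net$species, net$seeds)) {
      full <- minimax_route(net, target)
      if (is.null(full)) next
      for (drop_id in vapply(net$reactions, `[[`, "", "id")) {
        reduced <- minimax_route(net, target, excluded = drop_id)
        if (!is.null(reduced)) expect_gte(reduced$bottleneck, full$bottleneck)
      }
    }
  }
})

test_that("the prebiotic fixture reproduces the printed route structure", {
  net <- build_network(prebiotic_reactions(), primordial_seeds())
  expect_true(all(c("glycine", "serine", "alanine", "formaldimine", "HCN")
                  %in% net$species))
  gly <- minimax_route(net, "glycine")
  expect_identical(gly$bottleneck_id, "R1")
  expect_equal(gly$bottleneck, 45.5)
  # independent threshold-sweep oracle agrees on the fixture
  expect_equal(gly$bottleneck, oracle_minimax_sweep(net, "glycine"))
  expect_equal(minimax_route(net, "serine")$bottleneck,
               oracle_minimax_sweep(net, "serine"))
  expect_equal(minimax_route(net, "alanine")$bottleneck,
               oracle_minimax_sweep(net, "alanine"))
  # iterated exclusion agrees with an oracle-driven reimplementation
  ranked <- rank_alternatives(net, "serine", k = 3)
  excluded <- character(0)
  for (r in ranked) {
    net_x <- build_network(net$reactions[!vapply(net$reactions, `[[`, "", "id")
                                         %in% excluded], net$seeds)
    expect_equal(r$bottleneck, oracle_minimax_sweep(net_x, "serine"))
    excluded <- c(excluded, r$bottleneck_id)
  }
  # marking R1's catalyst unreachable removes every glycine route:
  # without ammonia no formic acid can form
  no_nh3 <- build_network(net$reactions, setdiff(net$seeds, "NH3"))
  expect_null(minimax_route(no_nh3, "glycine"))
})

test_that("profiles validate alternation and reference invariance", {
  ok <- assemble_profile(data.frame(label = c("R", "TS1", "P"),
                                    kind = c("intermediate", "TS", "intermediate"),
                                    g = c(0, 10, -5)))
  expect_s3_class(ok, "rtip_profile")
  expect_equal(ok$g, c(0, 10, -5))
  expect_error(assemble_profile(data.frame(label = c("R", "T1", "T2", "P"),
                                           kind = c("intermediate", "TS", "TS",
                                                    "intermediate"),
                                           g = 1:4)),
               "alternate")
  expect_error(assemble_profile(data.frame(label = c("T", "P"),
                                           kind = c("TS", "intermediate"),
                                           g = c(1, 0))),
               "start and end")
  # shifting every energy leaves the effective barrier unchanged
  base <- data.frame(label = paste0("S", 1:5),
                     kind = c("intermediate", "TS", "intermediate", "TS",
                              "intermediate"),
                     g = c(0, 10, -5, 30, -20))
  e1 <- effective_barrier(assemble_profile(base))
  shifted <- base; shifted$g <- shifted$g + 7
  e2 <- effective_barrier(assemble_profile(shifted))
  expect_equal(e1, e2)
})

test_that("energetic span matches hand values and the brute-force double loop", {
  prof <- assemble_profile(data.frame(
    label = c("I1", "TS1", "I2", "TS2", "I3"),
    kind = c("intermediate", "TS", "intermediate", "TS", "intermediate"),
    g = c(0, 10, -5, 30, -20)
  ))
  eb <- effective_barrier(prof)
  expect_equal(eb$span, 35)
  expect_identical(eb$determining_ts, "TS2")
  expect_identical(eb$reference_intermediate, "I2")
  # descending profile with a TS below the start
  desc <- assemble_profile(data.frame(
    label = c("I1", "TS1", "I2"),
    kind = c("intermediate", "TS", "intermediate"),
    g = c(0, -3, -12)
  ))
  expect_equal(effective_barrier(desc)$span, -3)
  # no TS at all
  flat <- assemble_profile(data.frame(label = "I1", kind = "intermediate",
                                      g = 0))
  expect_equal(effective_barrier(flat)$span, 0)
  # randomized sweep against the double-loop oracle
  set.seed(53)
  for (rep in 1:300) {
    prof <- assemble_profile(random_profile(sample(1:6, 1)))
    expect_equal(effective_barrier(prof)$span, oracle_span(prof))
  }
  # span dominates every single-step barrier
  set.seed(54)
  for (rep in 1:20) {
    prof <- assemble_profile(random_profile(4))
    steps <- which(prof$kind == "TS")
    single <- prof$g[steps] - prof$g[steps - 1]
    expect_gte(effective_barrier(prof)$span + 1e-12, max(single))
  }
})

test_that("reaction tables round-trip through CSV and JSON", {
  rs <- prebiotic_reactions()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_reactions_csv(rs, csv)
  back <- read_reactions_csv(csv)
  expect_length(back, length(rs))
  for (i in seq_along(rs)) {
    expect_identical(back[[i]]$id, rs[[i]]$id)
    expect_identical(back[[i]]$reactants, rs[[i]]$reactants)
    expect_identical(back[[i]]$products, rs[[i]]$products)
    expect_identical(back[[i]]$catalysts, rs[[i]]$catalysts)
    expect_equal(back[[i]]$g_a, rs[[i]]$g_a)
  }
  js <- withr::local_tempfile(fileext = ".json")
  write_reactions_json(rs, js)
  back2 <- read_reactions_json(js)
  expect_length(back2, length(rs))
  expect_identical(back2[[7]]$reactants, rs[[7]]$reactants)
  expect_equal(back2[[7]]$g_a, rs[[7]]$g_a)
  # ranged barriers carry their bounds
  r25 <- back[[which(vapply(back, `[[`, "", "id") == "R25")]]
  expect_equal(r25$g_a, 49.6)
  expect_equal(r25$g_a_lower, 44.6)
})
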