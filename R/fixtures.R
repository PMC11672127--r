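# Packaged fixtures: reference small-molecule geometries, toy reactive
# surfaces with scan-verifiable barriers, and the prebiotic reaction table
# of elementary activation free energies used by the network analysis.

.mol <- function(symbols, coords) configuration(symbols, matrix(coords, ncol = 3L, byrow = TRUE))

#' Reference small-molecule geometries
#'
#' Ten closed-shell C/H/N/O molecules at standard experimental gas-phase
#' geometries (A): CO, H2, H2O, NH3, formaldehyde, HCN, formic acid,
#' formaldimine, methanol and CO2. Used to seed the species registry and as
#' the bond-perception stability-band fixture.
#'
#' @return Named list of `rtip_config` objects.
#' @export
reference_molecules <- function() {
  list(
    CO = .mol(c("C", "O"), c(0, 0, 0,
                             0, 0, 1.128)),
    H2 = .mol(c("H", "H"), c(0, 0, 0,
                             0, 0, 0.741)),
    H2O = .mol(c("O", "H", "H"), c(0, 0, 0,
                                   0.7572, 0.5865, 0,
                                   -0.7572, 0.5865, 0)),
    NH3 = .mol(c("N", "H", "H", "H"), c(0, 0, 0,
                                        0.9376, 0, -0.3809,
                                        -0.4688, 0.8120, -0.3809,
                                        -0.4688, -0.8120, -0.3809)),
    CH2O = .mol(c("C", "O", "H", "H"), c(0, 0, 0,
                                         0, 0, 1.205,
                                         0.9429, 0, -0.5870,
                                         -0.9429, 0, -0.5870)),
    HCN = .mol(c("H", "C", "N"), c(0, 0, -1.065,
                                   0, 0, 0,
                                   0, 0, 1.153)),
    HCOOH = .mol(c("C", "O", "O", "H", "H"), c(0, 0, 0,
                                               1.202, 0, 0,
                                               -0.7688, 1.1015, 0,
                                               -0.5975, -0.9200, 0,
                                               -0.1598, 1.8591, 0)),
    formaldimine = .mol(c("C", "N", "H", "H", "H"), c(0, 0, 0,
                                                      1.273, 0, 0,
                                                      1.629, 0.957, 0,
                                                      -0.625, 0.893, 0,
                                                      -0.625, -0.893, 0)),
    CH3OH = .mol(c("C", "O", "H", "H", "H", "H"), c(0, 0, 0,
                                                    0, 0, 1.43,
                                                    0.9105, 0, 1.7345,
                                                    0.5138, 0.8899, -0.3638,
                                                    -1.0276, 0, -0.3638,
                                                    0.5138, -0.8899, -0.3638)),
    CO2 = .mol(c("O", "C", "O"), c(0, 0, -1.16,
                                   0, 0, 0,
                                   0, 0, 1.16))
  )
}

#' Built-in toy reactive surfaces
#'
#' `toy_diatomic_pes(h)` defines one reactive pair A-X: a Morse well
#' (D = 20 kcal/mol, alpha = 1.5 1/A, r_e = 1.2 A) plus a Gaussian barrier
#' bump of height `h` at 2.5 A (width 0.3 A); A-A and X-X are softly
#' repulsive. The default bump `h = 24` gives an association barrier of about
#' 18.8 kcal/mol (verify with [scan_barrier()]); `h = 135` raises it to about
#' 130 kcal/mol, above the default climb threshold.
#'
#' `toy_termolecular_pes()` adds a weakly binding X-X well so that a third
#' particle can accompany an A-X association -- a pairwise stand-in for a
#' catalyst-stabilised encounter complex.
#'
#' @param h Bump height for the A-X pair (kcal/mol).
#' @return An `rtip_toy_pes`.
#' @export
toy_diatomic_pes <- function(h = 24) {
  toy_pes(rbind(
    pair_rule("A", "X", D = 20, alpha = 1.5, r_e = 1.2, h = h, r_b = 2.5, w = 0.3),
    repulsive_rule("A", "A", A = 100, rho = 0.5),
    repulsive_rule("X", "X", A = 100, rho = 0.5)
  ), name = if (h > 100) "toy_diatomic_high" else "toy_diatomic")
}

#' @rdname toy_diatomic_pes
#' @export
toy_termolecular_pes <- function() {
  toy_pes(rbind(
    pair_rule("A", "X", D = 20, alpha = 1.5, r_e = 1.2, h = 24, r_b = 2.5, w = 0.3),
    pair_rule("X", "X", D = 4, alpha = 1.2, r_e = 1.6, h = 0),
    repulsive_rule("A", "A", A = 100, rho = 0.5)
  ), name = "toy_termolecular")
}

#' Prebiotic elementary-reaction table
#'
#' Elementary reactions among C/H/N/O species with their activation free
#' energies (kcal/mol; gas phase, 298 K, 1 atm reference thermochemistry).
#' Barriers quoted only as a range carry the conservative upper bound in
#' `g_a` and the lower bound in `g_a_lower`. Catalysts (proton shuttles and
#' two-hydrogen-transfer mediators) are required but not consumed. Reactions
#' whose donor/acceptor partner is not fully specified in the source data
#' carry a note saying the assignment is inferred; R38's barrier is not
#' available and is stored as `NA`.
#'
#' @return A list of [elementary_reaction()] records.
#' @export
prebiotic_reactions <- function() {
  list(
    elementary_reaction("R1", c("CO", "H2O"), "HCOOH", "NH3", 45.5,
                        dg = -1.4,
                        note = "ammonia-catalysed synthesis of formic acid from CO and water"),
    elementary_reaction("R2", c("CO", "NH3"), "HCONH2", "H2O", 49.5,
                        note = "water-catalysed synthesis of formamide from CO and ammonia"),
    elementary_reaction("R3", c("HCOOH", "NH3"), c("HCONH2", "H2O"), "H2O", 36.2,
                        note = "water-catalysed amino-for-hydroxyl substitution on formic acid; 41.8 when referenced to the preceding complex"),
    elementary_reaction("R4", c("HCOOH", "HCOOH"), c("methanediol", "CO2"),
                        g_a = 42.6,
                        note = "two-hydrogen-transfer hydrogenation of formic acid (donor: formic acid)"),
    elementary_reaction("R5", c("HCONH2", "HCOOH"), c("aminomethanol", "CO2"),
                        g_a = 41.7,
                        note = "two-hydrogen-transfer hydrogenation of formamide (donor: formic acid)"),
    elementary_reaction("R6", "methanediol", c("CH2O", "H2O"), "HCOOH", 9.3,
                        note = "formic-acid-catalysed dehydration of methanediol to formaldehyde"),
    elementary_reaction("R7", "aminomethanol", c("CH2O", "NH3"), "HCOOH", 4.0,
                        note = "formic-acid-catalysed deamination of aminomethanol to formaldehyde"),
    elementary_reaction("R8", c("CO", "HCOOH"), c("CH2O", "CO2"), g_a = 52.0,
                        note = "two-hydrogen-transfer CO/formaldehyde interconversion (donor: formic acid)"),
    elementary_reaction("R10", c("HCOOH", "HCOOH"), c("CH2O", "H2O", "CO2"),
                        g_a = 42.1,
                        note = "two-hydrogen transfer linking water, formaldehyde and formic acid (donor: formic acid)"),
    elementary_reaction("R11", c("HCONH2", "HCOOH"), c("CH2O", "NH3", "CO2"),
                        g_a = 36.8,
                        note = "two-hydrogen transfer linking ammonia, formaldehyde and formamide (donor: formic acid)"),
    elementary_reaction("R12", c("CO2", "HCOOH"), c("HCOOH", "CO2"),
                        g_a = 31.4,
                        note = "degenerate two-hydrogen exchange between formic acid and CO2"),
    elementary_reaction("R13", c("HCONH2", "CO2"), c("HNCO", "HCOOH"),
                        g_a = 40.7,
                        note = "two-hydrogen-transfer dehydrogenation of formamide to isocyanic acid; acceptor assignment inferred"),
    elementary_reaction("R14", c("CO2", "H2O"), "carbonic-acid", "HCOOH", 24.6,
                        note = "formic-acid-catalysed hydration of CO2; endothermic product; barrier assignment from the catalysed-hydration comparison is approximate"),
    elementary_reaction("R17", c("formaldimine", "H2O"), "aminomethanol",
                        "HCOOH", 13.3,
                        note = "formic-acid-catalysed hydration of formaldimine (28.7 with water as the shuttle)"),
    elementary_reaction("R18", "HNCO", "NCOH", "HCOOH", 3.3,
                        note = "formic-acid-catalysed isomerisation of isocyanic to cyanic acid; endothermic product"),
    elementary_reaction("R19", c("formaldimine", "CO2"), c("HCN", "HCOOH"),
                        g_a = 29.9,
                        note = "two-hydrogen-transfer dehydrogenation of formaldimine to hydrogen cyanide; acceptor assignment inferred"),
    elementary_reaction("R21", c("CH3OH", "HCOOH"), c("CH4", "H2O", "CO2"),
                        g_a = 67.3,
                        note = "formic-acid-mediated conversion of methanol to methane"),
    elementary_reaction("R22", "aminomethanol", c("formaldimine", "H2O"),
                        "HCOOH", 19.1, dg = 5.8,
                        note = "formic-acid-catalysed dehydration of aminomethanol to formaldimine; endothermic by 5.8"),
    elementary_reaction("R25", c("formaldimine", "CO", "H2"),
                        "2-aminoacetaldehyde", g_a = 49.6, g_a_lower = 44.6,
                        note = "coupling of formaldimine with CO and H2; barrier quoted as a range"),
    elementary_reaction("R26", c("formaldimine", "H2", "CH2O"),
                        "ethanolamine", g_a = 49.6, g_a_lower = 44.6,
                        note = "coupling of formaldimine with H2 and formaldehyde; barrier quoted as a range"),
    elementary_reaction("R27", c("formaldimine", "formaldimine", "H2"),
                        "ethylenediamine", g_a = 49.6, g_a_lower = 44.6,
                        note = "coupling of two formaldimine molecules with H2; barrier quoted as a range"),
    elementary_reaction("R28", c("HCN", "CO", "H2"), "aminoketene",
                        g_a = 55.0, g_a_lower = 50.8,
                        note = "coupling of hydrogen cyanide with CO and H2; barrier quoted as a range"),
    elementary_reaction("R29", c("HCN", "H2", "CH2O"), "iminoethanol",
                        g_a = 55.0, g_a_lower = 50.8,
                        note = "coupling of hydrogen cyanide with H2 and formaldehyde; barrier quoted as a range"),
    elementary_reaction("R30", c("HCN", "CO", "H2O"), "iminoglycine",
                        g_a = 55.0, g_a_lower = 50.8,
                        note = "coupling of hydrogen cyanide with CO and water; barrier quoted as a range"),
    elementary_reaction("R31", c("aminoketene", "HCOOH"),
                        c("2-aminoacetaldehyde", "CO2"),
                        g_a = 33.8, g_a_lower = 27.8,
                        note = "two-hydrogen-transfer hydrogenation of aminoketene; group barrier range"),
    elementary_reaction("R32", c("iminoethanol", "HCOOH"),
                        c("ethanolamine", "CO2"),
                        g_a = 33.8, g_a_lower = 27.8,
                        note = "two-hydrogen-transfer hydrogenation of iminoethanol; group barrier range"),
    elementary_reaction("R33", c("2-aminoacetaldehyde", "HCOOH"),
                        c("ethanolamine", "CO2"), g_a = 39.5,
                        note = "two-hydrogen-transfer hydrogenation of 2-aminoacetaldehyde (explicit value; group quoted as 27.8-33.8)"),
    elementary_reaction("R34", c("2-aminovinyl-alcohol", "HCOOH"),
                        c("ethanolamine", "CO2"),
                        g_a = 33.8, g_a_lower = 27.8,
                        note = "two-hydrogen-transfer hydrogenation of 2-aminovinyl alcohol; group barrier range; donor assignment inferred"),
    elementary_reaction("R35", "iminoethanol", "2-aminovinyl-alcohol",
                        g_a = 29.2,
                        note = "isomerisation of iminoethanol to 2-aminovinyl alcohol"),
    elementary_reaction("R36", c("aminoketene", "formaldimine"),
                        c("2-aminoacetaldehyde", "HCN"),
                        g_a = 33.8, g_a_lower = 27.8,
                        note = "two-hydrogen-transfer hydrogenation of aminoketene by formaldimine; group barrier range; donor assignment inferred"),
    elementary_reaction("R37", "ethanolamine", c("vinylamine", "H2O"),
                        "HCOOH", 55.4,
                        note = "formic-acid-catalysed dehydration of ethanolamine to vinylamine"),
    elementary_reaction("R38", "ethylenediamine", c("vinylamine", "NH3"),
                        "HCOOH", NA_real_,
                        note = "formic-acid-catalysed deamination of ethylenediamine to vinylamine; barrier not available"),
    elementary_reaction("R39", "vinylamine", "ethanimine", "CH2O", 26.5,
                        note = "isomerisation of vinylamine to ethanimine accompanying formaldehyde amination; 34.7 when referenced to the preceding complex"),
    elementary_reaction("R40", c("formaldimine", "HCOOH"), "glycine",
                        "HCOOH", 41.9,
                        note = "formic-acid-catalysed coupling of formaldimine and formic acid to glycine"),
    elementary_reaction("R41", c("iminoglycine", "HCOOH"),
                        c("glycine", "CO2"), g_a = 27.7,
                        note = "two-hydrogen-transfer hydrogenation of iminoglycine to glycine"),
    elementary_reaction("R42", c("glycine", "CH2O"), "serine", "HCOOH", 47.9,
                        note = "formic-acid-catalysed coupling of glycine and formaldehyde to serine"),
    elementary_reaction("R43", c("iminoglycine", "H2", "CH2O"), "serine",
                        g_a = 47.9,
                        note = "direct coupling of iminoglycine, H2 and formaldehyde to serine"),
    elementary_reaction("R44", c("iminoethanol", "HCOOH"), "serine",
                        "HCOOH", 40.9,
                        note = "formic-acid-catalysed coupling of iminoethanol and formic acid to serine"),
    elementary_reaction("R45", c("2-aminovinyl-alcohol", "CO", "H2O"),
                        "serine", g_a = 60.0,
                        note = "direct coupling of 2-aminovinyl alcohol, CO and water to serine"),
    elementary_reaction("R46", c("ethanimine", "HCOOH"), "alanine",
                        "HCOOH", 40.8,
                        note = "formic-acid-catalysed coupling of ethanimine and formic acid to alanine"),
    elementary_reaction("R47", c("vinylamine", "CO", "H2O"), "alanine",
                        g_a = 54.1,
                        note = "direct coupling of vinylamine, CO and water to alanine"),
    elementary_reaction("R4p", c("HCOOH", "H2"), "methanediol", "NH3", 45.5,
                        note = "ammonia-catalysed hydrogenation of formic acid by H2 (alternative to R4)"),
    elementary_reaction("R5p", c("HCONH2", "H2"), "aminomethanol", "NH3", 49.7,
                        note = "ammonia-catalysed hydrogenation of formamide by H2 (alternative to R5); 69.9 uncatalysed"),
    elementary_reaction("R6p", "methanediol", c("CH2O", "H2O"), "H2O", 23.2,
                        note = "water-catalysed dehydration of methanediol (alternative to R6)"),
    elementary_reaction("R7p", c("CH2O", "NH3"), "aminomethanol", "NH3", 21.7,
                        note = "ammonia-catalysed amination of formaldehyde (alternative shuttle to R7's reverse)"),
    elementary_reaction("R40p", c("formaldimine", "CO", "H2O"), "glycine",
                        "H2O", 47.0,
                        note = "water-catalysed four-body coupling of formaldimine, CO and water to glycine (alternative to R40)")
  )
}

#' Primordial seed species
#'
#' The four primordial molecules from which the reaction network is grown.
#' @return Character vector.
#' @export
primordial_seeds <- function() c("CO", "H2", "H2O", "NH3")

#' Endpoint pair encoding an extracted catalysed reaction
#'
#' A synthetic stationary-endpoint pair for [extract_reaction()]: the
#' reactant side holds separated CO, H2O and NH3; the product side holds
#' formic acid and (unchanged) NH3 -- the ammonia-catalysed hydration of CO.
#' Both sides share one atom multiset; molecules are placed far apart so the
#' perceived components are unambiguous.
#'
#' @return List with `reactant` and `product` `rtip_config` objects.
#' @export
reaction_endpoint_fixture <- function() {
  mols <- reference_molecules()
  shift <- function(cfg, dx) {
    cfg$coords <- cfg$coords + matrix(c(dx, 0, 0), n_atoms(cfg), 3L, byrow = TRUE)
    cfg
  }
  cat2 <- function(a, b, c) {
    configuration(c(a$symbols, b$symbols, c$symbols),
                  rbind(a$coords, b$coords, c$coords))
  }
  reactant <- cat2(shift(mols$CO, -8), shift(mols$H2O, 0), shift(mols$NH3, 8))
  product <- configuration(
    c(mols$HCOOH$symbols, mols$NH3$symbols),
    rbind(mols$HCOOH$coords, shift(mols$NH3, 8)$coords)
  )
  # reactant atoms: C,O | O,H,H | N,H,H,H ; product: C,O,O,H,H | N,H,H,H
  list(reactant = reactant, product = product)
}

#' Generate packaged fixtures on disk
#'
#' Writes the named fixture into `out_dir`: `toy_diatomic` (A.xyz, X.xyz,
#' toy_diatomic.pes and the high-bump variant), `toy_termolecular` (A.xyz,
#' X.xyz, toy_termolecular.pes), `small_molecules_10` (ten XYZ files) or
#' `paper_barriers` (prebiotic_reactions.csv). Generation is deterministic
#' given `seed` (the geometries and tables are themselves fixed; the seed is
#' recorded in the provenance comment lines).
#'
#' @param name One of `toy_diatomic`, `toy_termolecular`,
#'   `small_molecules_10`, `paper_barriers`.
#' @param seed Integer seed recorded with the fixture.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
fixture_generator <- function(name, seed = 1L, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put_xyz <- function(cfg, file, label) {
    p <- file.path(out_dir, file)
    write_xyz(cfg, p, fields = list(name = label, seed = seed))
    written <<- c(written, p)
  }
  if (name == "toy_diatomic") {
    put_xyz(configuration("A", matrix(0, 1, 3)), "A.xyz", "A")
    put_xyz(configuration("X", matrix(0, 1, 3)), "X.xyz", "X")
    p1 <- file.path(out_dir, "toy_diatomic.pes")
    write_toy_pes(toy_diatomic_pes(), p1)
    p2 <- file.path(out_dir, "toy_diatomic_high.pes")
    write_toy_pes(toy_diatomic_pes(h = 135), p2)
    written <- c(written, p1, p2)
  } else if (name == "toy_termolecular") {
    put_xyz(configuration("A", matrix(0, 1, 3)), "A.xyz", "A")
    put_xyz(configuration("X", matrix(0, 1, 3)), "X.xyz", "X")
    p1 <- file.path(out_dir, "toy_termolecular.pes")
    write_toy_pes(toy_termolecular_pes(), p1)
    written <- c(written, p1)
  } else if (name == "small_molecules_10") {
    mols <- reference_molecules()
    for (nm in names(mols)) put_xyz(mols[[nm]], paste0(nm, ".xyz"), nm)
  } else if (name == "paper_barriers") {
    p <- file.path(out_dir, "prebiotic_reactions.csv")
    write_reactions_csv(prebiotic_reactions(), p)
    p2 <- file.path(out_dir, "species_registry.json")
    write_species_registry(species_registry(), p2)
    written <- c(written, p, p2)
  } else {
    stop("unknown fixture name '", name, "'", call. = FALSE)
  }
  invisible(written)
}
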