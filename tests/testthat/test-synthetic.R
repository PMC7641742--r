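test_that("idealized Form 1 coordinates satisfy their own restraint set", {
  fx <- form1_reference()
  ref <- fx$ref; t1 <- fx$topology
  hb <- hbond_restraints(t1)
  expect_equal(violation_count(ref, hb, 0.2), 0L)
  # planarity energy per tetrad below 1 kcal/mol at unit force constant
  e <- restraint_energy(ref, list(planarity = planarity_restraints(t1)),
                        kset = list(k_nonexch = 16, k_exch = 8,
                                    k_dihedral = 50, k_planarity = 1))
  expect_lt(e$components[["planarity"]] / 3, 1)
  # chi windows satisfied (small residual tolerated from regularization)
  e2 <- restraint_energy(ref, list(dihedral = dihedral_restraints(t1)))
  expect_lt(e2$components[["dihedral"]], 0.5)
  # backbone is closed
  xyz <- conf_xyz(ref)
  for (r in seq_len(max(ref$resno) - 1)) {
    d <- sqrt(sum((xyz[atom_index(ref, r, "O3'"), ] -
                   xyz[atom_index(ref, r + 1, "P"), ])^2))
    expect_lt(abs(d - 1.61), 0.1)
  }
})

test_that("idealized Form 2 coordinates satisfy hydrogen bonds and chi", {
  t2 <- form2_topology()
  ref <- build_idealized_coords(t2)
  expect_equal(violation_count(ref, hbond_restraints(t2), 0.2), 0L)
  e <- restraint_energy(ref, list(dihedral = dihedral_restraints(t2)))
  expect_lt(e$components[["dihedral"]], 0.5)
})

test_that("idealized construction is deterministic", {
  t <- toy_topology()
  a <- build_idealized_coords(t)
  b <- build_idealized_coords(t)
  expect_identical(conf_xyz(a), conf_xyz(b))
})

test_that("unchainable topologies are rejected", {
  # two pairs with no sequential adjacency and an unplaced residue
  t <- qdh_topology("broken", "GCAAAGC",
                    pairs = data.frame(g = c(1L, 6L), c = c(2L, 7L),
                                       role = "stem"))
  expect_error(build_idealized_coords(t), "chain")
})

test_that("NOE simulation quantizes distances into the stated classes", {
  # two protons at 2.5 A, boundaries (3.0, 4.5) -> strong
  pk <- simulate_noe_peaks(two_proton_conformer(2.5), max_distance = 6,
                           noise = noise_model())
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$class, "strong")
  expect_equal(pk$exchangeable, 0L)
  pk <- simulate_noe_peaks(two_proton_conformer(3.7))
  expect_equal(pk$class, "medium")
  pk <- simulate_noe_peaks(two_proton_conformer(5.2))
  expect_equal(pk$class, "weak")
  # beyond max_distance -> absent; below min_distance -> absent
  expect_equal(nrow(simulate_noe_peaks(two_proton_conformer(6.5))), 0L)
  expect_equal(nrow(simulate_noe_peaks(two_proton_conformer(1.5))), 0L)
})

test_that("simulated peaks round-trip through classification at zero jitter", {
  fx <- form1_reference()
  peaks <- fx$peaks
  noe <- noe_restraints(peaks)
  # for non-methyl peaks the restraint window contains the true distance
  plain <- !as.logical(peaks$methyl)
  lo <- noe$target - noe$minus
  up <- noe$target + noe$plus
  expect_true(all(peaks$distance[plain] >= lo[plain] - 1e-9))
  expect_true(all(peaks$distance[plain] <= up[plain] + 1e-9))
  # methyl peaks are carried by the methyl carbon with loosened windows
  if (any(peaks$methyl == 1)) {
    me <- noe[as.logical(peaks$methyl), ]
    expect_true(all(me$atom_a == "C7" | me$atom_b == "C7"))
  }
  # exchangeable flags follow the proton identity
  exch_named <- peaks$atom_a %in% qdhfold:::.exchangeable_protons |
    peaks$atom_b %in% qdhfold:::.exchangeable_protons
  expect_equal(as.logical(peaks$exchangeable), exch_named)
})

test_that("NOE simulation is seeded and supports false negatives", {
  fx <- form1_reference()
  ref <- fx$ref
  a <- simulate_noe_peaks(ref, 6, noise_model(jitter_sd = 0.2, seed = 5))
  b <- simulate_noe_peaks(ref, 6, noise_model(jitter_sd = 0.2, seed = 5))
  expect_identical(a, b)
  dropped <- simulate_noe_peaks(ref, 6,
                                noise_model(false_negative_rate = 0.5,
                                            seed = 5))
  full <- simulate_noe_peaks(ref, 6, noise_model(seed = 5))
  expect_lt(nrow(dropped), nrow(full))
})

test_that("CD mixture simulation inverts exactly and is seeded", {
  c1 <- cd_component_spectrum("hybrid")
  c2 <- cd_component_spectrum("antiparallel")
  expect_equal(simulate_cd_mixture(1, c1, c2)$ellipticity,
               c1$ellipticity)
  mix <- simulate_cd_mixture(0.81, c1, c2, noise_sd = 0)
  expect_equal(decompose_two_state(mix, c1, c2)$w1, 0.81,
               tolerance = 1e-12)
  a <- simulate_cd_mixture(0.5, c1, c2, 0.01, seed = 3)
  b <- simulate_cd_mixture(0.5, c1, c2, 0.01, seed = 3)
  expect_identical(a$ellipticity, b$ellipticity)
  c2short <- cd_component_spectrum("antiparallel", grid = seq(230, 310, 1))
  expect_error(simulate_cd_mixture(0.5, c1, c2short), "common")
})

test_that("melting-curve generator: theta(Tm)=0.5, dH sharpens transition", {
  grid <- seq(15, 95, 1)
  curve <- simulate_melting_curve(65, dH = 50, grid = grid)
  expect_equal(curve$ellipticity[grid == 65], 0.5, tolerance = 1e-9)
  width <- function(dH) {
    y <- simulate_melting_curve(55, dH = dH, grid = seq(15, 95, 0.1))
    tt <- y$temperature
    diff(range(tt[y$ellipticity > 0.1 & y$ellipticity < 0.9]))
  }
  expect_lt(width(100), width(30))
  # round trip through the extraction machinery
  bl <- fit_baselines(curve, c(15, 25), c(85, 95))
  expect_lt(abs(melt_tm(curve, bl)$tm - 65), 1)
})
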