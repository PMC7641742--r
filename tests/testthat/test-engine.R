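test_that("extended chain builder produces ideal covalent geometry", {
  conf <- build_chain("GACT")
  sys <- build_system(conf)
  dev <- geometry_deviations(conf, sys)
  expect_lt(dev["bonds"], 1e-6)
  expect_lt(dev["angles"], 1e-6)
  expect_lt(dev["impropers"], 1e-6)
  # single nucleotide carries the full template atom set
  g <- build_chain("G")
  expect_true(all(c("C1'", "O4'", "N9", "C8", "O6", "H1", "H21", "HO3'")
                  %in% g$atom))
  expect_error(build_chain("GX"), "unknown base")
  expect_error(build_chain(""), "non-empty")
})

test_that("chain building is deterministic", {
  expect_identical(build_chain("GCGT"), build_chain("GCGT"))
})

test_that("distance bounds honour covalent and restraint windows", {
  conf <- build_chain("GC")
  sys <- build_system(conf)
  r <- classify_noe("medium", FALSE, FALSE, 1, "H8", 2, "H5")
  b <- build_bounds(conf, r, system = sys)
  expect_true(all(b$lower <= b$upper + 1e-9))
  expect_equal(diag(b$lower), rep(0, sys$n))
  i <- atom_index(conf, 1, "H8"); j <- atom_index(conf, 2, "H5")
  expect_lte(b$upper[i, j], 4.7)
  expect_gte(b$lower[i, j], 2.9)
  # 1-2 distances pinned at the ideal bond length
  bd <- sys$bonds + 1
  for (k in sample(nrow(bd), 10)) {
    expect_equal(b$lower[bd[k, 1], bd[k, 2]], sys$bond_r0[k],
                 tolerance = 1e-9)
    expect_equal(b$upper[bd[k, 1], bd[k, 2]], sys$bond_r0[k],
                 tolerance = 1e-9)
  }
})

test_that("triangle smoothing enforces the hand-computed toy bound", {
  # 3-atom chain, bonds at 1.5, one loose pair bound of 5:
  # smoothed u(1,3) = min(5, 1.5 + 1.5) = 3
  L <- matrix(0, 3, 3)
  U <- matrix(c(0, 1.5, 5, 1.5, 0, 1.5, 5, 1.5, 0), 3, 3)
  sm <- qdhfold:::qdh_smooth_bounds(L, U)
  expect_equal(sm$upper[1, 3], 3.0)
  expect_true(all(sm$upper <= U + 1e-12))
})

test_that("embedding reproduces an exact tetrahedron up to rigid motion", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
             c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  D <- as.matrix(dist(P))
  b <- structure(list(lower = D, upper = D), class = "qdh_bounds")
  as_conf <- function(X) conformer(data.frame(
    resno = 1L, resname = "DG", atom = paste0("C", 1:4), element = "C",
    x = X[, 1], y = X[, 2], z = X[, 3]))
  ca <- as_conf(P)
  for (seed in c(3, 17)) {
    X <- embed_coords(b, seed = seed)
    Xm <- X; Xm[, 1] <- -Xm[, 1]
    rmsd <- min(kabsch_rmsd(ca, as_conf(X)), kabsch_rmsd(ca, as_conf(Xm)))
    expect_lt(rmsd, 1e-4)
  }
  # determinism
  expect_identical(embed_coords(b, seed = 5), embed_coords(b, seed = 5))
  # degenerate bounds rejected
  bad <- structure(list(lower = D + 1, upper = D), class = "qdh_bounds")
  expect_error(embed_coords(bad, seed = 1), "degenerate")
})

test_that("restraint energy is flat inside the window, quadratic outside", {
  conf <- two_proton_conformer(3.5)
  r <- data.frame(res_a = 1L, atom_a = "H8", res_b = 1L, atom_b = "H1'",
                  target = 3.8, minus = 0.9, plus = 0.9, class = "medium",
                  exchangeable = FALSE, origin = "intra-residue")
  e <- restraint_energy(conf, list(dist = r))
  expect_equal(e$energy, 0)
  # 0.5 A above the upper bound at k = 2 -> 2 * 0.25 = 0.5
  conf2 <- two_proton_conformer(4.7 + 0.5)
  e2 <- restraint_energy(conf2, list(dist = r),
                         kset = list(k_nonexch = 2, k_exch = 2,
                                     k_dihedral = 50, k_planarity = 1))
  expect_equal(e2$energy, 0.5, tolerance = 1e-12)
  expect_gte(e2$energy, 0)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  conf <- build_chain("GC")
  sys <- build_system(conf)
  dd <- data.frame(res_a = 1L, atom_a = "H8", res_b = 2L, atom_b = "H5",
                   target = 3.0, minus = 2.0, plus = 0.1, class = "medium",
                   exchangeable = FALSE, origin = "inter-residue")
  dih <- dihedral_restraints(qdh_topology(
    "t", "GC", pairs = data.frame(g = 1L, c = 2L, role = "stem"),
    syn = 1L))
  dih$halfwidth <- 1  # make the dihedral term active
  pl <- list(list(label = "p", members = c(1L, 2L)))
  ir <- qdhfold:::index_restraints(conf, dd, dih, pl)
  x0 <- conf_xyz(conf) + matrix(rnorm(nrow(conf) * 3, 0, 0.15), ncol = 3)
  g <- qdhfold:::qdh_energy_grad(x0, sys, ir, 16, 8, 50, 1, TRUE, TRUE)
  h <- 1e-5
  idx <- sample(length(x0), 60)
  for (i in idx) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    ep <- qdhfold:::qdh_energy_grad(xp, sys, ir, 16, 8, 50, 1, TRUE,
                                    TRUE)$energy
    em <- qdhfold:::qdh_energy_grad(xm, sys, ir, 16, 8, 50, 1, TRUE,
                                    TRUE)$energy
    expect_lt(abs((ep - em) / (2 * h) - g$grad[i]), 1e-5)
  }
})

test_that("minimization restores a stretched bond and never raises energy", {
  conf <- build_chain("GAT")
  x <- conf_xyz(conf)
  i_h <- which(conf$atom == "HO3'")
  i_o <- which(conf$atom == "O3'" & conf$resno == 3)
  x[i_h, ] <- x[i_h, ] + c(0.4, 0, 0)
  stretched <- set_conf_xyz(conf, x)
  e0 <- qdhfold:::qdh_energy_grad(
    x, build_system(conf), qdhfold:::index_restraints(conf),
    16, 8, 50, 1, TRUE, TRUE)$energy
  mn <- minimize_conformer(stretched, min_gradient = 0.05, max_iter = 8000)
  expect_true(attr(mn, "converged"))
  expect_lte(attr(mn, "energy"), e0)
  xm <- conf_xyz(mn)
  d <- sqrt(sum((xm[i_h, ] - xm[i_o, ])^2))
  sys <- build_system(conf)
  ideal <- sys$bond_r0[apply(sys$bonds + 1, 1, function(r)
    setequal(r, c(i_h, i_o)))]
  expect_equal(d, ideal, tolerance = 1e-3)
  # re-minimizing an already-minimal conformer does not raise the energy
  mn2 <- minimize_conformer(mn, min_gradient = 0.05, max_iter = 2000)
  expect_lte(attr(mn2, "energy"), attr(mn, "energy") + 1e-6)
  expect_lt(max(abs(conf_xyz(mn2) - conf_xyz(mn))), 0.3)
})

test_that("annealing schedule exposes the staged protocol", {
  st <- schedule_stages(anneal_schedule())
  expect_equal(st$duration_ps, c(14, 6, 20, 50, 42, 18))
  expect_equal(st$T_start[1], 300)
  expect_equal(st$T_end[1], 1000)
  expect_equal(st$T_end[5], 300)
  expect_equal(st$k_ne_end[3], 16)
  expect_equal(st$k_e_end[3], 8)
  s <- anneal_schedule()
  expect_equal(s$save_window_ps, 10)
  expect_equal(s$save_interval_ps, 0.5)
  expect_equal(s$k_dihedral, 50)
  expect_equal(s$k_planarity, 1)
  expect_equal(s$min_gradient, 0.1)
  expect_error(anneal_schedule(scale_factor = 0), "scale_factor")
})

test_that("zero-restraint dynamics at 0 K leaves an ideal chain in place", {
  conf <- build_chain("G")
  sched <- anneal_schedule(heat_start_K = 0, heat_end_K = 0,
                           scale_factor = 0.01)
  out <- sa_anneal(conf, list(dist = NULL, dihedral = NULL,
                              planarity = NULL),
                   schedule = sched, seed = 1)
  expect_lt(max(abs(conf_xyz(out) - conf_xyz(conf))), 1e-8)
})

test_that("annealing with identical seeds is bit-identical", {
  t <- toy_topology()
  rs <- qdh_restraints(t)
  conf <- build_chain(t$sequence)
  sched <- anneal_schedule(scale_factor = 0.02)
  a <- sa_anneal(conf, rs, schedule = sched, seed = 9)
  b <- sa_anneal(conf, rs, schedule = sched, seed = 9)
  expect_identical(conf_xyz(a), conf_xyz(b))
  c <- sa_anneal(conf, rs, schedule = sched, seed = 10)
  expect_false(identical(conf_xyz(a), conf_xyz(c)))
})

test_that("annealing lowers the restraint energy of a perturbed start", {
  t <- toy_topology()
  rs <- qdh_restraints(t)
  conf <- build_chain(t$sequence)
  kset <- qdhfold:::.kset_default()
  e0 <- restraint_energy(conf, rs, kset)$energy
  sched <- anneal_schedule(scale_factor = 0.05)
  ann <- sa_anneal(conf, rs, schedule = sched, seed = 3)
  mn <- minimize_conformer(ann, rs, kset, min_gradient = 0.2,
                           max_iter = 600)
  e1 <- restraint_energy(mn, rs, kset)$energy
  expect_lt(e1, e0)
})

test_that("pipeline flags exactly the lowest-energy structures", {
  t <- toy_topology()
  ens <- run_pipeline(t, n_structures = 6, n_select = 3,
                      schedule = anneal_schedule(scale_factor = 0.02),
                      seed = 4)
  expect_length(ens$flagged, 3L)
  expect_true(all(ens$energies[ens$flagged] <=
                    max(ens$energies[ens$flagged])))
  worst_flagged <- max(ens$energies[ens$flagged])
  unflagged <- setdiff(seq_along(ens$energies), ens$flagged)
  expect_true(all(ens$energies[unflagged] >= worst_flagged))
  # n_select = n_structures flags everything
  ens2 <- run_pipeline(t, n_structures = 2, n_select = 2,
                       schedule = anneal_schedule(scale_factor = 0.02),
                       seed = 4)
  expect_length(ens2$flagged, 2L)
  expect_error(run_pipeline(t, n_structures = 2, n_select = 3), "n_select")
})

test_that("pipelines with identical seeds give identical ensembles", {
  t <- toy_topology()
  sched <- anneal_schedule(scale_factor = 0.02)
  e1 <- run_pipeline(t, n_structures = 2, n_select = 1, schedule = sched,
                     seed = 21)
  e2 <- run_pipeline(t, n_structures = 2, n_select = 1, schedule = sched,
                     seed = 21)
  expect_identical(e1$energies, e2$energies)
  expect_identical(conf_xyz(e1$conformers[[1]]),
                   conf_xyz(e2$conformers[[1]]))
})
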