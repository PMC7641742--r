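test_that("Kabsch RMSD: identity, rigid invariance, translation toy", {
  conf <- build_chain("GAT")
  expect_equal(kabsch_rmsd(conf, conf), 0, tolerance = 1e-10)
  # rigid rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  moved <- set_conf_xyz(conf, conf_xyz(conf) %*% t(R) +
                          matrix(c(5, -2, 1), nrow(conf), 3, byrow = TRUE))
  expect_lt(kabsch_rmsd(conf, moved), 1e-8)
  # unit triangle translated by (1,1,1) -> 0
  tri <- conformer(data.frame(resno = 1L, resname = "DG",
                              atom = c("C1'", "C2'", "C3'"), element = "C",
                              x = c(0, 1, 0), y = c(0, 0, 1), z = 0))
  tri2 <- set_conf_xyz(tri, conf_xyz(tri) + 1)
  expect_lt(kabsch_rmsd(tri, tri2), 1e-10)
  # symmetry
  set.seed(1)
  pert <- set_conf_xyz(conf, conf_xyz(conf) + rnorm(nrow(conf) * 3, 0, 0.3))
  expect_equal(kabsch_rmsd(conf, pert), kabsch_rmsd(pert, conf),
               tolerance = 1e-10)
  expect_gt(kabsch_rmsd(conf, pert), 0)
})

test_that("Kabsch RMSD agrees with the bio3d superposition oracle", {
  skip_if_not_installed("bio3d")
  set.seed(11)
  conf <- build_chain("GCA")
  pert <- set_conf_xyz(conf, conf_xyz(conf) + rnorm(nrow(conf) * 3, 0, 0.5))
  ours <- kabsch_rmsd(conf, pert)
  theirs <- bio3d::rmsd(as.numeric(t(conf_xyz(conf))),
                        as.numeric(t(conf_xyz(pert))), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("selections pick the intended atom sets", {
  t1 <- form1_topology()
  conf <- build_chain(t1$sequence)
  heavy <- sel_all_heavy()(conf)
  expect_true(all(conf$element[heavy] != "H"))
  core <- sel_tetrad_core(t1)(conf)
  core_res <- unique(conf$resno[core])
  expect_setequal(core_res, c(3, 25, 22, 7, 4, 8, 21, 26, 5, 9, 20, 27))
  expect_true(all(conf$element[core] != "H"))
  some <- sel_residues(c(1, 2))(conf)
  expect_setequal(unique(conf$resno[some]), c(1, 2))
})

test_that("mismatched selections raise an error", {
  a <- build_chain("GAT")
  b <- build_chain("GA")
  expect_error(kabsch_rmsd(a, b, sel_residues(3)), "fewer than 3|match")
})

test_that("pairwise RMSD matches brute-force enumeration", {
  conf <- build_chain("GAT")
  set.seed(5)
  confs <- lapply(1:3, function(i)
    set_conf_xyz(conf, conf_xyz(conf) + rnorm(nrow(conf) * 3, 0, 0.2 * i)))
  e <- list(conformers = confs, energies = 1:3, flagged = 1:3)
  got <- pairwise_rmsd(e)
  # independent enumeration of the three unordered pairs
  vals <- c(kabsch_rmsd(confs[[1]], confs[[2]]),
            kabsch_rmsd(confs[[1]], confs[[3]]),
            kabsch_rmsd(confs[[2]], confs[[3]]))
  expect_equal(unname(got["mean"]), mean(vals), tolerance = 1e-12)
  expect_equal(unname(got["sd"]), sqrt(mean((vals - mean(vals))^2)),
               tolerance = 1e-12)
  expect_equal(unname(got["n_pairs"]), 3)
  # identical conformers -> 0 +/- 0; two conformers -> sd 0
  same <- list(conformers = list(conf, conf, conf), energies = 1:3,
               flagged = 1:3)
  expect_equal(unname(pairwise_rmsd(same)["mean"]), 0, tolerance = 1e-8)
  expect_equal(unname(pairwise_rmsd(same)["sd"]), 0, tolerance = 1e-8)
  two <- list(conformers = confs[1:2], energies = 1:2, flagged = 1:2)
  expect_equal(unname(pairwise_rmsd(two)["sd"]), 0)
  one <- list(conformers = confs[1], energies = 1, flagged = 1)
  expect_error(pairwise_rmsd(one), "at least 2")
})

test_that("violation counting uses a strict threshold", {
  conf <- two_proton_conformer(3.0)
  mk <- function(target, minus, plus)
    data.frame(res_a = 1L, atom_a = "H8", res_b = 1L, atom_b = "H1'",
               target = target, minus = minus, plus = plus,
               class = "medium", exchangeable = FALSE, origin = "x")
  # distance 3.0, window [1, 2.79] -> violation 0.21 -> counts
  expect_equal(violation_count(conf, mk(1.895, 0.895, 0.895)), 1L)
  # violation exactly 0.20 -> does not count
  expect_equal(violation_count(conf, mk(1.9, 0.9, 0.9)), 0L)
  # inside the window -> no violation
  expect_equal(violation_count(conf, mk(3.0, 0.5, 0.5)), 0L)
  # below the lower bound by 0.21
  expect_equal(violation_count(conf, mk(4.11, 0.9, 0.9)), 1L)
  expect_equal(violation_count(conf, NULL), 0L)
})

test_that("geometry deviations: ideal chain zero, closed form for one bond", {
  conf <- build_chain("GC")
  sys <- build_system(conf)
  dev0 <- geometry_deviations(conf, sys)
  expect_true(all(dev0 < 1e-6))
  # stretch the terminal hydroxyl bond (HO3' has a single bond) by 0.1 A
  x <- conf_xyz(conf)
  i_h <- which(conf$atom == "HO3'")
  i_o <- which(conf$atom == "O3'" & conf$resno == 2)
  u <- (x[i_h, ] - x[i_o, ]); u <- u / sqrt(sum(u^2))
  x[i_h, ] <- x[i_h, ] + 0.1 * u
  dev <- geometry_deviations(set_conf_xyz(conf, x), sys)
  expect_equal(unname(dev["bonds"]), 0.1 / sqrt(nrow(sys$bonds)),
               tolerance = 1e-6)
  expect_true(all(dev >= 0))
})

test_that("stat report aggregates the ensemble statistics", {
  t <- toy_topology()
  rs <- qdh_restraints(t)
  conf <- build_chain(t$sequence)
  set.seed(8)
  confs <- lapply(1:3, function(i)
    set_conf_xyz(conf, conf_xyz(conf) + rnorm(nrow(conf) * 3, 0, 0.05)))
  e <- list(conformers = confs, energies = 1:3, flagged = 1:3)
  # toy has no G-tetrad: core selection must fail loudly
  expect_error(stat_report(e, t, rs$dist))
  # with Form 1 selections on a fake ensemble of ideal chains
  t1 <- form1_topology()
  conf1 <- build_chain(t1$sequence)
  e1 <- list(conformers = list(conf1, conf1), energies = c(1, 2),
             flagged = 1:2)
  rep <- stat_report(e1, t1, hbond_restraints(t1))
  expect_s3_class(rep, "qdh_stat_report")
  expect_equal(rep$mean[rep$statistic == "rmsd_core_A"], 0,
               tolerance = 1e-8)
  expect_true(all(rep$sd >= 0))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_stat_report(rep, p)
  expect_equal(nrow(utils::read.delim(p)), 6L)
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_stat_report(rep, p2, format = "text")
  expect_true(any(grepl("Pairwise RMSD", readLines(p2))))
})
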