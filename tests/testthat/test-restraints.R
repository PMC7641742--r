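test_that("NOE classification reproduces the calibration windows", {
  # non-exchangeable strong / medium / weak
  r <- classify_noe("strong", FALSE, FALSE, 1, "H8", 2, "H1'")
  expect_equal(unlist(r[, c("target", "minus", "plus")], use.names = FALSE),
               c(2.7, 0.8, 0.8))
  r <- classify_noe("medium", FALSE, FALSE, 1, "H8", 2, "H1'")
  expect_equal(c(r$target - r$minus, r$target + r$plus), c(2.9, 4.7))
  r <- classify_noe("weak", FALSE, FALSE, 1, "H8", 2, "H1'")
  expect_equal(unlist(r[, c("target", "minus", "plus")], use.names = FALSE),
               c(5.5, 1.7, 1.7))
  # exchangeable classes
  r <- classify_noe("strong", TRUE, FALSE, 1, "H1", 2, "H8")
  expect_equal(c(r$target - r$minus, r$target + r$plus), c(3.0, 5.0))
  r <- classify_noe("medium", TRUE, FALSE, 1, "H1", 2, "H8")
  expect_equal(unlist(r[, c("target", "minus", "plus")], use.names = FALSE),
               c(4.8, 1.4, 1.4))
  r <- classify_noe("weak", TRUE, FALSE, 1, "H1", 2, "H8")
  expect_equal(unlist(r[, c("target", "minus", "plus")], use.names = FALSE),
               c(5.5, 1.7, 1.7))
})

test_that("thymine methyl peaks move to the carbon with a 0.5 A loosening", {
  r <- classify_noe("weak", FALSE, TRUE, 23, "H71", 25, "H1'")
  expect_equal(r$atom_a, "C7")
  expect_equal(r$atom_b, "H1'")
  expect_equal(c(r$target - r$minus, r$target + r$plus), c(3.3, 7.7))
})

test_that("unknown intensity class raises an error", {
  expect_error(classify_noe("faint", FALSE, FALSE, 1, "H8", 2, "H1'"),
               "unknown NOE intensity class")
})

test_that("hydrogen-bond restraint counts reproduce the bookkeeping table", {
  hb1 <- hbond_restraints(form1_topology())
  hb2 <- hbond_restraints(form2_topology())
  expect_equal(nrow(hb1), 66L)  # 3 tetrads x 16 + 3 pairs x 6
  expect_equal(nrow(hb2), 56L)  # 2 tetrads x 16 + 4 pairs x 6
  # distances exactly as prescribed
  expect_setequal(unique(hb1$target), c(2.0, 2.9))
  expect_equal(unique(hb1$minus[hb1$target == 2.0]), 0.2)
  expect_equal(unique(hb1$minus[hb1$target == 2.9]), 0.3)
  # single pair, no tetrads
  single <- qdh_topology("p", "GC",
                         pairs = data.frame(g = 1L, c = 2L, role = "stem"))
  expect_equal(nrow(hbond_restraints(single)), 6L)
})

test_that("hbond count follows the closed form 16 per tetrad + 6 per pair", {
  set.seed(7)
  for (rep in 1:5) {
    n_tet <- sample(0:3, 1)
    n_pair <- sample(0:4, 1)
    # synthetic sequence: guanine blocks for tetrads, then GC pairs
    seq <- paste(c(rep("G", 4 * n_tet), rep(c("G", "C"), n_pair)),
                 collapse = "")
    if (!nchar(seq)) next
    tetrads <- lapply(seq_len(n_tet), function(i)
      list(members = (4 * (i - 1) + 1):(4 * i), kind = "G"))
    pairs <- if (n_pair) data.frame(
      g = 4 * n_tet + 2 * seq_len(n_pair) - 1,
      c = 4 * n_tet + 2 * seq_len(n_pair), role = "stem")
    else data.frame(g = integer(), c = integer(), role = character())
    t <- qdh_topology("rand", seq, tetrads = tetrads, pairs = pairs)
    expect_length(validate_topology(t), 0)
    expect_equal(nrow(hbond_restraints(t)), 16 * n_tet + 6 * n_pair)
  }
})

test_that("Hoogsteen restraints follow the cyclic donor order", {
  t1 <- form1_topology()
  hb <- hbond_restraints(t1)
  h1 <- hb[hb$atom_a == "H1" & hb$res_a == 3, ]
  expect_equal(h1$res_b, 25L)  # G3 donates to G25, the next member
  expect_equal(h1$atom_b, "O6")
})

test_that("chi dihedral restraints cover tetrad/pair members plus syn extras", {
  d1 <- dihedral_restraints(form1_topology())
  d2 <- dihedral_restraints(form2_topology())
  expect_equal(nrow(d1), 19L)
  expect_equal(nrow(d2), 16L)
  expect_true(1L %in% d1$residue)  # syn 5'-terminal G1
  # atom quartets by base
  expect_true(all(d1$atoms[d1$base == "G"] == "O4'-C1'-N9-C4"))
  expect_true(all(d1$atoms[d1$base == "C"] == "O4'-C1'-N1-C2"))
  # syn center 60, anti center 240, default halfwidth 70
  g1 <- d1[d1$residue == 1, ]
  expect_equal(c(g1$center, g1$halfwidth), c(60, 70))
  expect_equal(c(g1$center - g1$halfwidth, g1$center + g1$halfwidth),
               c(-10, 130))
  anti <- d1[d1$glycosidic == "anti", ]
  expect_true(all(anti$center == 240))
  tight <- dihedral_restraints(form1_topology(), tight = TRUE)
  expect_true(all(tight$halfwidth == 40))
  override <- dihedral_restraints(form1_topology(), tight_residues = 3L)
  expect_equal(override$halfwidth[override$residue == 3], 40)
  expect_equal(override$halfwidth[override$residue == 4], 70)
})

test_that("chi restraints on a non-G/C residue raise an error", {
  bad <- qdh_topology("bad", "GAC",
                      pairs = data.frame(g = 1L, c = 3L, role = "stem"),
                      syn = 2L)  # syn A2 cannot carry a G/C chi restraint
  expect_error(dihedral_restraints(bad), "G/C residues only")
})

test_that("planarity units: one per tetrad plus non-junction pairs", {
  expect_length(planarity_restraints(form1_topology()), 6L)
  expect_length(planarity_restraints(form2_topology()), 5L)
  expect_length(planarity_restraints(qdh_topology("e", "GCGC")), 0L)
  # Form 2: the GCGC unit has 4 members, junction pairs are not duplicated
  u2 <- planarity_restraints(form2_topology())
  sizes <- vapply(u2, function(u) length(u$members), 1L)
  expect_equal(sort(sizes), c(2L, 2L, 4L, 4L, 4L))
})

test_that("restraint summary partitions counts as in a statistics table", {
  t1 <- form1_topology()
  peaks <- data.frame(
    res_a = c(1L, 1L, 2L), atom_a = c("H8", "H8", "H1"),
    res_b = c(1L, 2L, 3L), atom_b = c("H1'", "H1'", "H8"),
    class = c("strong", "medium", "weak"),
    exchangeable = c(0L, 0L, 1L), methyl = 0L)
  noe <- noe_restraints(peaks)
  s <- restraint_summary(noe, hbond_restraints(t1),
                         dihedral_restraints(t1),
                         planarity_restraints(t1))
  expect_equal(unname(s[c("intra_residue_D2O", "inter_residue_D2O",
                          "inter_residue_H2O")]), c(1L, 1L, 1L))
  expect_equal(unname(s[c("hydrogen_bond", "dihedral_angle", "planarity")]),
               c(66L, 19L, 6L))
  s2 <- restraint_summary(NULL, hbond_restraints(form2_topology()),
                          dihedral_restraints(form2_topology()),
                          planarity_restraints(form2_topology()))
  expect_equal(unname(s2[c("hydrogen_bond", "dihedral_angle", "planarity")]),
               c(56L, 16L, 5L))
  expect_true(all(restraint_summary() == 0))
})

test_that("restraint generation is deterministic and serializes stably", {
  t1 <- form1_topology()
  a <- hbond_restraints(t1); b <- hbond_restraints(t1)
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_restraints_tsv(a, p1); write_restraints_tsv(b, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_restraints_tsv(p1)
  expect_equal(back$target, a$target)
  expect_equal(back$atom_a, a$atom_a)
})

test_that("every distance restraint window is positive and ordered", {
  t1 <- form1_topology()
  ref_peaks <- data.frame(res_a = 1L, atom_a = "H8", res_b = 2L,
                          atom_b = "H5", class = "strong",
                          exchangeable = 0L, methyl = 0L)
  all_r <- rbind(noe_restraints(ref_peaks), hbond_restraints(t1))
  expect_true(all(all_r$target - all_r$minus > 0))
  expect_true(all(all_r$minus + all_r$plus > 0))
})

test_that("XPLOR-style writer emits one assign statement per restraint", {
  hb <- hbond_restraints(form1_topology())
  p <- withr::local_tempfile(fileext = ".tbl")
  write_restraints_xplor(hb, p)
  lines <- readLines(p)
  expect_length(lines, 66L)
  expect_true(all(grepl("^assign \\(resid", lines)))
})

test_that("peak-list TSV reader applies the classification per row", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("res_a\tatom_a\tres_b\tatom_b\tclass\texchangeable\tmethyl",
               "1\tH8\t2\tH1'\tmedium\t0\t0",
               "3\tH1\t4\tH8\tstrong\t1\t0"), p)
  r <- read_noe_peaks(p)
  expect_equal(nrow(r), 2L)
  expect_equal(r$target, c(3.8, 4.0))
  expect_equal(r$exchangeable, c(FALSE, TRUE))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb", bad)
  expect_error(read_noe_peaks(bad), "columns")
})
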