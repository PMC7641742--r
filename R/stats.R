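## Ensemble statistics: Kabsch superposition RMSD over atom selections,
## restraint-violation counts and covalent-geometry deviations, summarized
## the way NMR structure tables report them.

#' Atom selections
#'
#' Selections are predicate functions mapping a [conformer()] to a logical
#' vector over its atoms. `sel_all_heavy()` selects every non-hydrogen
#' atom; `sel_tetrad_core(t)` selects the heavy atoms of all G-tetrad
#' member residues of a topology (G.C.G.C tetrads excluded), the
#' conventional "G-tetrad core" superposition set; `sel_residues(r)`
#' selects heavy atoms of an explicit residue set.
#'
#' @param t A [qdh_topology()].
#' @param residues Integer vector of residue numbers.
#' @return A predicate `function(conf) -> logical`.
#' @export
sel_all_heavy <- function() {
  function(conf) conf$element != "H"
}

#' @rdname sel_all_heavy
#' @export
sel_tetrad_core <- function(t) {
  core <- unique(unlist(lapply(t$tetrads,
                               function(x) if (x$kind == "G") x$members)))
  function(conf) conf$element != "H" & conf$resno %in% core
}

#' @rdname sel_all_heavy
#' @export
sel_residues <- function(residues) {
  function(conf) conf$element != "H" & conf$resno %in% residues
}

.matched_coords <- function(a, b, selection = NULL) {
  if (is.null(selection)) selection <- function(conf) rep(TRUE, nrow(conf))
  sa <- a[selection(a), ]; sb <- b[selection(b), ]
  ka <- paste(sa$resno, sa$atom); kb <- paste(sb$resno, sb$atom)
  common <- intersect(ka, kb)
  if (length(common) < 3)
    stop("selection yields fewer than 3 matched atoms")
  if (length(common) != length(ka) || length(common) != length(kb))
    if (length(ka) != length(kb) || !setequal(ka, kb))
      stop("selections do not match between the two conformers")
  list(a = conf_xyz(sa)[match(common, ka), , drop = FALSE],
       b = conf_xyz(sb)[match(common, kb), , drop = FALSE])
}

.kabsch <- function(A, B) {
  # optimal rotation (no reflection) superposing B onto A after centering
  ca <- colMeans(A); cb <- colMeans(B)
  A <- sweep(A, 2, ca); B <- sweep(B, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bp <- B %*% t(R)
  sqrt(mean(rowSums((A - Bp)^2)))
}

#' Minimal RMSD after optimal rigid superposition (Kabsch)
#'
#' Superposes the matched atoms of two conformers by the optimal rotation
#' and translation (no reflection) and returns the root-mean-square
#' deviation in Angstrom. Atoms are matched by residue number and atom
#' name within the selection.
#'
#' @param a,b [conformer()] objects.
#' @param selection Atom predicate (see [sel_all_heavy()]); `NULL` uses
#'   all atoms.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, selection = NULL) {
  m <- .matched_coords(a, b, selection)
  .kabsch(m$a, m$b)
}

#' Pairwise ensemble RMSD over a selection
#'
#' Mean and standard deviation of [kabsch_rmsd()] over all unordered pairs
#' of the flagged (selected) conformers of an ensemble, as reported for
#' "G-tetrad core" and "all heavy atom" selections in structure
#' statistics tables. The population standard deviation (n divisor) is
#' used.
#'
#' @param e A `qdh_ensemble` from [run_pipeline()] (or any list with
#'   `conformers` and `flagged`).
#' @param selection Atom predicate.
#' @return Named numeric vector `c(mean, sd, n_pairs)`.
#' @export
pairwise_rmsd <- function(e, selection = NULL) {
  confs <- e$conformers[e$flagged]
  if (length(confs) < 2)
    stop("pairwise RMSD requires at least 2 flagged conformers")
  pairs <- utils::combn(length(confs), 2)
  vals <- apply(pairs, 2, function(p)
    kabsch_rmsd(confs[[p[1]]], confs[[p[2]]], selection))
  c(mean = mean(vals), sd = .pop_sd(vals), n_pairs = length(vals))
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Count distance-restraint violations beyond a threshold
#'
#' Number of distance restraints whose measured distance exceeds the upper
#' bound, or falls below the lower bound, by strictly more than
#' `threshold` Angstrom (a violation of exactly the threshold does not
#' count).
#'
#' @param conf A [conformer()].
#' @param dist Data frame of distance restraints.
#' @param threshold Violation threshold in Angstrom.
#' @return Integer count.
#' @export
violation_count <- function(conf, dist, threshold = 0.2) {
  if (is.null(dist) || !nrow(dist)) return(0L)
  ia <- atom_index(conf, dist$res_a, dist$atom_a)
  ib <- atom_index(conf, dist$res_b, dist$atom_b)
  xyz <- conf_xyz(conf)
  d <- sqrt(rowSums((xyz[ia, , drop = FALSE] - xyz[ib, , drop = FALSE])^2))
  lo <- dist$target - dist$minus
  up <- dist$target + dist$plus
  sum(d > up + threshold | d < lo - threshold)
}

#' Deviations from ideal covalent geometry
#'
#' Root-mean-square deviations of bond lengths (Angstrom), bond angles
#' (degrees) and improper torsions (degrees) from their template ideals.
#'
#' @param conf A [conformer()].
#' @param system Optional prebuilt [build_system()] output.
#' @return Named numeric vector `c(bonds, angles, impropers)`.
#' @export
geometry_deviations <- function(conf, system = NULL) {
  if (is.null(system)) system <- build_system(conf)
  xyz <- conf_xyz(conf)
  b <- system$bonds + 1L
  dbond <- sqrt(rowSums((xyz[b[, 1], , drop = FALSE] -
                         xyz[b[, 2], , drop = FALSE])^2)) - system$bond_r0
  a <- system$angles + 1L
  dang <- vapply(seq_len(nrow(a)), function(k)
    .vec_angle(xyz[a[k, 1], ], xyz[a[k, 2], ], xyz[a[k, 3], ]) -
      system$angle_th0[k], 0)
  im <- system$impropers + 1L
  dimp <- vapply(seq_len(nrow(im)), function(k) {
    phi <- .vec_torsion(xyz[im[k, 1], ], xyz[im[k, 2], ],
                        xyz[im[k, 3], ], xyz[im[k, 4], ])
    d <- phi - system$improper_phi0[k]
    atan2(sin(d), cos(d))
  }, 0)
  c(bonds = sqrt(mean(dbond^2)),
    angles = sqrt(mean(dang^2)) * 180 / pi,
    impropers = sqrt(mean(dimp^2)) * 180 / pi)
}

#' Structure-statistics report for an ensemble
#'
#' Computes, over the flagged conformers, the categories of an NMR
#' structure statistics table: mean +/- sd of the number of distance
#' restraints violated by more than 0.2 Angstrom, mean +/- sd of the
#' bond / angle / improper RMS deviations from ideal geometry, and
#' pairwise heavy-atom RMSD over the G-tetrad core and all-heavy-atom
#' selections. Standard deviations are population (n divisor).
#'
#' @param e A `qdh_ensemble`.
#' @param topology The [qdh_topology()] the ensemble was computed for.
#' @param dist Data frame of distance restraints used in the calculation.
#' @param threshold Violation threshold (Angstrom).
#' @return A data frame with columns `statistic`, `mean`, `sd`, of class
#'   `qdh_stat_report`.
#' @export
stat_report <- function(e, topology, dist, threshold = 0.2) {
  confs <- e$conformers[e$flagged]
  sys <- build_system(confs[[1]])
  viol <- vapply(confs, violation_count, 0L, dist = dist,
                 threshold = threshold)
  geo <- vapply(confs, geometry_deviations, c(bonds = 0, angles = 0,
                                              impropers = 0), system = sys)
  core <- pairwise_rmsd(e, sel_tetrad_core(topology))
  heavy <- pairwise_rmsd(e, sel_all_heavy())
  out <- data.frame(
    statistic = c("noe_violations_gt_threshold", "bond_dev_A",
                  "angle_dev_deg", "improper_dev_deg", "rmsd_core_A",
                  "rmsd_all_heavy_A"),
    mean = c(mean(viol), mean(geo["bonds", ]), mean(geo["angles", ]),
             mean(geo["impropers", ]), core["mean"], heavy["mean"]),
    sd = c(.pop_sd(viol), .pop_sd(geo["bonds", ]), .pop_sd(geo["angles", ]),
           .pop_sd(geo["impropers", ]), core["sd"], heavy["sd"])
  )
  class(out) <- c("qdh_stat_report", "data.frame")
  out
}

#' Write a structure-statistics report
#'
#' Emits the report as TSV, or as human-readable text mirroring the usual
#' table row labels when `format = "text"`.
#'
#' @param report A [stat_report()] result.
#' @param path Output path.
#' @param format `"tsv"` or `"text"`.
#' @export
write_stat_report <- function(report, path, format = c("tsv", "text")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    labels <- c(noe_violations_gt_threshold = "NOE violations, number (>0.2 A)",
                bond_dev_A = "Bond lengths (A)",
                angle_dev_deg = "Bond angles (deg)",
                improper_dev_deg = "Impropers (deg)",
                rmsd_core_A = "Pairwise RMSD, G-tetrad core (A)",
                rmsd_all_heavy_A = "Pairwise RMSD, all heavy atom (A)")
    writeLines(sprintf("%-40s %.3f +/- %.3f",
                       labels[report$statistic], report$mean, report$sd),
               path)
  }
  invisible(path)
}
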