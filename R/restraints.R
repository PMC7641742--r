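## Flat-bottom restraint generation.
##
## Distance restraints are tabular (one row per restraint) with a target and
## an asymmetric window [target - minus, target + plus]; the engine applies
## no penalty inside the window and a quadratic penalty outside.

# NOE class windows (Angstrom): target, minus, plus
.noe_windows <- list(
  nonexchangeable = list(strong = c(2.7, 0.8, 0.8),
                         medium = c(3.8, 0.9, 0.9),
                         weak   = c(5.5, 1.7, 1.7)),
  exchangeable    = list(strong = c(4.0, 1.0, 1.0),
                         medium = c(4.8, 1.4, 1.4),
                         weak   = c(5.5, 1.7, 1.7))
)

.distance_restraint <- function(res_a, atom_a, res_b, atom_b, target, minus,
                                plus, class_label, exchangeable, origin) {
  stopifnot(target - minus > 0, minus >= 0, plus >= 0)
  data.frame(res_a = as.integer(res_a), atom_a = atom_a,
             res_b = as.integer(res_b), atom_b = atom_b,
             target = target, minus = minus, plus = plus,
             class = class_label, exchangeable = as.logical(exchangeable),
             origin = origin, stringsAsFactors = FALSE)
}

#' Convert a classed NOE peak into a flat-bottom distance restraint
#'
#' Applies the standard intensity-to-distance calibration for classed NOESY
#' cross-peaks: non-exchangeable strong/medium/weak peaks become windows of
#' 2.7 +/- 0.8, 3.8 +/- 0.9 and 5.5 +/- 1.7 Angstrom; peaks involving
#' exchangeable protons (recorded in H2O) become 4.0 +/- 1.0, 4.8 +/- 1.4
#' and 5.5 +/- 1.7 Angstrom. For peaks involving a thymine methyl group the
#' proton selector on the methyl side is redirected to the methyl carbon
#' (C7) and both window edges are loosened by 0.5 Angstrom in compensation.
#'
#' @param intensity One of `"strong"`, `"medium"`, `"weak"`.
#' @param exchangeable Logical; does the peak involve an exchangeable
#'   (imino/amino) proton?
#' @param methyl Logical; does the peak involve thymine methyl protons?
#' @param res_a,atom_a,res_b,atom_b Residue index and atom name of the two
#'   proton selectors.
#' @return One-row data frame (a distance restraint).
#' @export
classify_noe <- function(intensity, exchangeable = FALSE, methyl = FALSE,
                         res_a, atom_a, res_b, atom_b) {
  kind <- if (isTRUE(exchangeable)) "exchangeable" else "nonexchangeable"
  w <- .noe_windows[[kind]][[intensity]]
  if (is.null(w))
    stop("unknown NOE intensity class: ", intensity)
  target <- w[1]; minus <- w[2]; plus <- w[3]
  if (isTRUE(methyl)) {
    if (grepl("^H7", atom_a)) atom_a <- "C7"
    if (grepl("^H7", atom_b)) atom_b <- "C7"
    minus <- minus + 0.5
    plus <- plus + 0.5
  }
  .distance_restraint(res_a, atom_a, res_b, atom_b, target, minus, plus,
                      intensity, exchangeable,
                      if (res_a == res_b) "intra-residue" else "inter-residue")
}

#' Read a classed NOE peak list and convert it to distance restraints
#'
#' The peak-list dialect is tab-separated with a header row and columns
#' `res_a, atom_a, res_b, atom_b, class, exchangeable, methyl`
#' (`class` in strong/medium/weak; the last two are 0/1 flags). Each row is
#' passed through [classify_noe()].
#'
#' @param path Path to a peak-list TSV.
#' @return Data frame of distance restraints.
#' @export
read_noe_peaks <- function(path) {
  pk <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("res_a", "atom_a", "res_b", "atom_b", "class",
            "exchangeable", "methyl")
  if (!all(need %in% names(pk)))
    stop("peak list must have columns: ", paste(need, collapse = ", "))
  noe_restraints(pk)
}

#' @rdname read_noe_peaks
#' @param peaks Data frame of classed peaks (same columns as the TSV).
#' @export
noe_restraints <- function(peaks) {
  if (!nrow(peaks)) return(.distance_restraint(1, "H1'", 1, "H8",
                                               3.8, 0.9, 0.9, "medium",
                                               FALSE, "intra-residue")[0, ])
  rows <- lapply(seq_len(nrow(peaks)), function(i)
    classify_noe(peaks$class[i], as.logical(peaks$exchangeable[i]),
                 as.logical(peaks$methyl[i]),
                 peaks$res_a[i], peaks$atom_a[i],
                 peaks$res_b[i], peaks$atom_b[i]))
  do.call(rbind, rows)
}

#' Hydrogen-bond distance restraints for a QDH topology
#'
#' Emits the fixed hydrogen-bond distance set used in quadruplex structure
#' calculation. Each cyclic Hoogsteen G-to-G edge of a G-tetrad (donor
#' residue i to acceptor residue i+1 in member order) contributes four
#' restraints: H21-N7 and H1-O6 at 2.0 +/- 0.2 Angstrom, N2-N7 and N1-O6 at
#' 2.9 +/- 0.3 Angstrom. Each Watson-Crick G.C pair (including the two
#' pairs inside a G.C.G.C tetrad) contributes six: H21-O2, H1-N3 and
#' O6-H41 at 2.0 +/- 0.2, and N2-O2, N1-N3 and O6-N4 at 2.9 +/- 0.3.
#' A valid topology therefore yields 16 restraints per G-tetrad plus 6 per
#' pair: 66 for the built-in Form 1 and 56 for Form 2.
#'
#' @param t A valid [qdh_topology()].
#' @return Data frame of distance restraints (origin `"hydrogen-bond"`).
#' @export
hbond_restraints <- function(t) {
  bases <- t$residues$base
  rows <- list()
  for (tet in t$tetrads) {
    if (tet$kind != "G") next
    m <- tet$members
    if (any(bases[m] != "G"))
      stop("G-tetrad contains a non-G member: ",
           paste0(bases[m], m, collapse = ","))
    for (i in 1:4) {
      don <- m[i]; acc <- m[if (i == 4) 1 else i + 1]
      rows <- c(rows, list(
        .distance_restraint(don, "H21", acc, "N7", 2.0, 0.2, 0.2, "hbond",
                            TRUE, "hydrogen-bond"),
        .distance_restraint(don, "N2", acc, "N7", 2.9, 0.3, 0.3, "hbond",
                            TRUE, "hydrogen-bond"),
        .distance_restraint(don, "H1", acc, "O6", 2.0, 0.2, 0.2, "hbond",
                            TRUE, "hydrogen-bond"),
        .distance_restraint(don, "N1", acc, "O6", 2.9, 0.3, 0.3, "hbond",
                            TRUE, "hydrogen-bond")))
    }
  }
  if (nrow(t$pairs)) for (k in seq_len(nrow(t$pairs))) {
    g <- t$pairs$g[k]; cc <- t$pairs$c[k]
    rows <- c(rows, list(
      .distance_restraint(g, "H21", cc, "O2", 2.0, 0.2, 0.2, "hbond",
                          TRUE, "hydrogen-bond"),
      .distance_restraint(g, "H1", cc, "N3", 2.0, 0.2, 0.2, "hbond",
                          TRUE, "hydrogen-bond"),
      .distance_restraint(g, "O6", cc, "H41", 2.0, 0.2, 0.2, "hbond",
                          TRUE, "hydrogen-bond"),
      .distance_restraint(g, "N2", cc, "O2", 2.9, 0.3, 0.3, "hbond",
                          TRUE, "hydrogen-bond"),
      .distance_restraint(g, "N1", cc, "N3", 2.9, 0.3, 0.3, "hbond",
                          TRUE, "hydrogen-bond"),
      .distance_restraint(g, "O6", cc, "N4", 2.9, 0.3, 0.3, "hbond",
                          TRUE, "hydrogen-bond")))
  }
  if (!length(rows)) return(noe_restraints(data.frame()))
  do.call(rbind, rows)
}

#' Glycosidic (chi) dihedral restraints for a QDH topology
#'
#' One chi restraint is applied per guanine or cytosine residue that is a
#' member of any tetrad or Watson-Crick pair, plus any residue explicitly
#' marked syn in the topology (which covers Form 1's 5'-terminal syn G1).
#' The restrained dihedral is O4'-C1'-N9-C4 for guanines and O4'-C1'-N1-C2
#' for cytosines; syn residues are centered at 60 degrees and anti residues
#' at 240 degrees, with a halfwidth of 70 degrees by default or 40 degrees
#' when `tight = TRUE` (per-residue tightening via `tight_residues`).
#'
#' @param t A valid [qdh_topology()].
#' @param tight Logical; use the +/- 40 degree halfwidth for all residues.
#' @param tight_residues Integer vector of residues restrained at +/- 40
#'   degrees when `tight = FALSE` (position-dependent tightening).
#' @return Data frame with columns `residue, base, glycosidic, atoms,
#'   center, halfwidth`.
#' @export
dihedral_restraints <- function(t, tight = FALSE, tight_residues = integer()) {
  bases <- t$residues$base
  members <- unique(c(unlist(lapply(t$tetrads, `[[`, "members")),
                      t$pairs$g, t$pairs$c, t$syn))
  members <- sort(members)
  if (!length(members)) {
    return(data.frame(residue = integer(), base = character(),
                      glycosidic = character(), atoms = character(),
                      center = numeric(), halfwidth = numeric()))
  }
  b <- bases[members]
  if (any(!b %in% c("G", "C")))
    stop("chi restraints are defined for G/C residues only; got ",
         paste0(b[!b %in% c("G", "C")], members[!b %in% c("G", "C")],
                collapse = ","))
  syn <- members %in% t$syn
  hw <- ifelse(tight | members %in% tight_residues, 40, 70)
  data.frame(
    residue = members,
    base = b,
    glycosidic = ifelse(syn, "syn", "anti"),
    atoms = ifelse(b == "G", "O4'-C1'-N9-C4", "O4'-C1'-N1-C2"),
    center = ifelse(syn, 60, 240),
    halfwidth = hw,
    stringsAsFactors = FALSE
  )
}

#' Base-plane planarity restraint units for a QDH topology
#'
#' One planarity unit is created per G-tetrad, per G.C.G.C tetrad, and per
#' Watson-Crick pair that is not already inside a G.C.G.C tetrad. Each
#' unit lists its member residues; the engine restrains the ring heavy
#' atoms of all members to their common best-fit plane. The built-in folds
#' give 6 units for Form 1 (3 tetrads + 3 pairs) and 5 for Form 2
#' (2 G-tetrads + 1 G.C.G.C tetrad + 2 stem pairs).
#'
#' @param t A valid [qdh_topology()].
#' @return List of units, each a list with `label` and `members`.
#' @export
planarity_restraints <- function(t) {
  bases <- t$residues$base
  units <- list()
  gcgc_members <- integer()
  for (tet in t$tetrads) {
    lab <- paste0(bases[tet$members], tet$members, collapse = ".")
    units <- c(units, list(list(label = lab, members = tet$members)))
    if (tet$kind == "GCGC") gcgc_members <- c(gcgc_members, tet$members)
  }
  if (nrow(t$pairs)) for (k in seq_len(nrow(t$pairs))) {
    g <- t$pairs$g[k]; cc <- t$pairs$c[k]
    if (g %in% gcgc_members && cc %in% gcgc_members) next
    units <- c(units, list(list(label = sprintf("G%d.C%d", g, cc),
                                members = c(g, cc))))
  }
  units
}

#' Restraint bookkeeping summary
#'
#' Partitions a full restraint set into the categories of a structure
#' statistics table: intra- and inter-residue NOE distance restraints split
#' by solvent (D2O for non-exchangeable peaks, H2O for exchangeable ones),
#' hydrogen-bond restraints, dihedral restraints and planarity units.
#'
#' @param noe Data frame of NOE distance restraints.
#' @param hbond Data frame of hydrogen-bond restraints.
#' @param dihedral Data frame of dihedral restraints.
#' @param planarity List of planarity units.
#' @return Named integer vector of counts.
#' @export
restraint_summary <- function(noe = NULL, hbond = NULL, dihedral = NULL,
                              planarity = NULL) {
  n_intra_d2o <- n_inter_d2o <- n_intra_h2o <- n_inter_h2o <- 0L
  if (!is.null(noe) && nrow(noe)) {
    intra <- noe$res_a == noe$res_b
    exch <- noe$exchangeable
    n_intra_d2o <- sum(intra & !exch)
    n_inter_d2o <- sum(!intra & !exch)
    n_intra_h2o <- sum(intra & exch)
    n_inter_h2o <- sum(!intra & exch)
  }
  c(intra_residue_D2O = n_intra_d2o,
    intra_residue_H2O = n_intra_h2o,
    inter_residue_D2O = n_inter_d2o,
    inter_residue_H2O = n_inter_h2o,
    hydrogen_bond = if (is.null(hbond)) 0L else nrow(hbond),
    dihedral_angle = if (is.null(dihedral)) 0L else nrow(dihedral),
    planarity = length(planarity))
}

#' Write / read distance restraints as TSV
#'
#' The canonical on-disk dialect for distance restraints is a tab-separated
#' table with one restraint per line and a single header row; it
#' round-trips byte-identically for a given restraint set.
#'
#' @param r Data frame of distance restraints.
#' @param path File path.
#' @export
write_restraints_tsv <- function(r, path) {
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_restraints_tsv
#' @export
read_restraints_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write distance restraints in an XPLOR-assign-like text format
#'
#' Interoperability writer: one `assign` statement per restraint with the
#' target and minus/plus window. The TSV dialect remains canonical.
#'
#' @param r Data frame of distance restraints.
#' @param path File path.
#' @export
write_restraints_xplor <- function(r, path) {
  lines <- sprintf(
    "assign (resid %d and name %s) (resid %d and name %s) %.2f %.2f %.2f",
    r$res_a, r$atom_a, r$res_b, r$atom_b, r$target, r$minus, r$plus)
  writeLines(lines, path)
  invisible(path)
}
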