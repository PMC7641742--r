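## Molecular templates: idealized deoxyribonucleotide geometry with PDB v3
## atom naming (residues DA/DC/DG/DT), shipped as plain-text tables under
## extdata. Ideal bond lengths, angles and impropers are derived from the
## template coordinates themselves, so the covalent force field is exactly
## consistent with the geometry used to build chains.

.qdh_cache <- new.env(parent = emptyenv())

.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)
.element_vdw  <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, P = 1.80)

#' Load the deoxyribonucleotide molecular template
#'
#' Returns the idealized per-residue-type geometry used throughout the
#' package: atom inventories with coordinates (standard residue geometry,
#' wwPDB atom naming) and covalent bond lists for DA, DC, DG and DT. The
#' free-nucleotide templates carry a 5'-phosphate (with the capping OP3
#' oxygen marking where the preceding residue's O3' attaches); the chain
#' builder trims terminal atoms as appropriate.
#'
#' @return A list with elements `atoms` (data frame: resname, atom,
#'   element, x, y, z) and `bonds` (data frame: resname, atom_a, atom_b).
#' @export
molecular_template <- function() {
  if (!is.null(.qdh_cache$template)) return(.qdh_cache$template)
  atoms <- utils::read.delim(system.file("extdata", "nucleotide_atoms.tsv",
                                         package = "qdhfold"),
                             stringsAsFactors = FALSE)
  bonds <- utils::read.delim(system.file("extdata", "nucleotide_bonds.tsv",
                                         package = "qdhfold"),
                             stringsAsFactors = FALSE)
  tpl <- list(atoms = atoms, bonds = bonds)
  .qdh_cache$template <- tpl
  tpl
}

.base_to_resname <- c(A = "DA", C = "DC", G = "DG", T = "DT")

# Atoms present only in the free-nucleotide form, never in a chain.
.always_drop <- c("OP3", "HOP3", "HOP2")
# 5'-terminal residues carry no phosphate.
.five_prime_drop <- c("P", "OP1", "OP2")

.residue_template <- function(resname, five_prime = FALSE,
                              three_prime = FALSE) {
  tpl <- molecular_template()
  at <- tpl$atoms[tpl$atoms$resname == resname, ]
  bd <- tpl$bonds[tpl$bonds$resname == resname, ]
  drop <- .always_drop
  if (five_prime) drop <- c(drop, .five_prime_drop)
  if (!three_prime) drop <- c(drop, "HO3'")
  at <- at[!at$atom %in% drop, ]
  bd <- bd[!(bd$atom_a %in% drop | bd$atom_b %in% drop), ]
  list(atoms = at, bonds = bd)
}

.rotation_onto <- function(v, target) {
  # rotation matrix taking unit vector v onto unit vector target
  v <- v / sqrt(sum(v^2)); target <- target / sqrt(sum(target^2))
  c_ <- sum(v * target)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to v
    p <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * v) * v; ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  ax <- c(v[2] * target[3] - v[3] * target[2],
          v[3] * target[1] - v[1] * target[3],
          v[1] * target[2] - v[2] * target[1])
  s <- sqrt(sum(ax^2)); ax <- ax / s
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' Conformer: an all-atom DNA chain with Cartesian coordinates
#'
#' A conformer is a data frame with one row per atom and columns
#' `resno` (1-based residue number), `resname` (DA/DC/DG/DT), `atom`
#' (wwPDB atom name), `element` and `x, y, z` (Angstrom), carrying class
#' `conformer` and optionally an `energy` attribute (kcal/mol) once
#' scored.
#'
#' @param df Atom table as described above.
#' @param energy Optional energy to attach.
#' @return The conformer object.
#' @export
conformer <- function(df, energy = NULL) {
  stopifnot(all(c("resno", "resname", "atom", "element", "x", "y", "z")
                %in% names(df)))
  if (anyDuplicated(paste(df$resno, df$atom)))
    stop("atom names must be unique within a residue")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("conformer coordinates must be finite")
  class(df) <- c("conformer", "data.frame")
  if (!is.null(energy)) attr(df, "energy") <- energy
  df
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("conformer: %d atoms, %d residues (%s)\n",
              nrow(x), length(unique(x$resno)),
              paste(x$resname[!duplicated(x$resno)], collapse = "")))
  if (!is.null(attr(x, "energy")))
    cat(sprintf("  energy: %.3f kcal/mol\n", attr(x, "energy")))
  invisible(x)
}

#' Extract / replace conformer coordinates as an n x 3 matrix
#' @param conf A [conformer()].
#' @return `conf_xyz` returns an n x 3 numeric matrix.
#' @export
conf_xyz <- function(conf) {
  cbind(x = conf$x, y = conf$y, z = conf$z)
}

#' @rdname conf_xyz
#' @param xyz New n x 3 coordinate matrix.
#' @export
set_conf_xyz <- function(conf, xyz) {
  conf$x <- xyz[, 1]; conf$y <- xyz[, 2]; conf$z <- xyz[, 3]
  conf
}

#' Row indices of named atoms in a conformer
#'
#' @param conf A [conformer()].
#' @param resno,atom Parallel vectors of residue numbers and atom names.
#' @param strict Error if an atom is missing (otherwise NA).
#' @return Integer vector of row indices.
#' @export
atom_index <- function(conf, resno, atom, strict = TRUE) {
  key <- paste(conf$resno, conf$atom)
  idx <- match(paste(resno, atom), key)
  if (strict && anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("atom %s of residue %d not found in conformer",
                 atom[bad], resno[bad]))
  }
  idx
}

.rodrigues <- function(pts, u, phi) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
  pts %*% t(R)
}

#' Build an extended all-atom chain from a DNA sequence
#'
#' Places one idealized nucleotide per sequence position, extending along
#' the x axis. Each residue after the first is positioned by exact
#' superposition of its template's 5'-cap oxygen onto the preceding O3',
#' with the phosphodiester direction chosen to give the ideal C3'-O3'-P
#' angle and the free spin chosen to maximize chain extension; all bonded
#' distances, angles and impropers therefore equal their template ideals.
#' The 5'-terminal residue carries no phosphate and the 3'-terminal O3' is
#' protonated (HO3'). The construction is deterministic.
#'
#' @param sequence DNA sequence string (A/C/G/T).
#' @return A [conformer()].
#' @export
build_chain <- function(sequence) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (!length(bases)) stop("sequence must be non-empty")
  if (any(!bases %in% names(.base_to_resname)))
    stop("unknown base in sequence: ",
         paste(unique(bases[!bases %in% names(.base_to_resname)]),
               collapse = ", "))
  n <- length(bases)
  xhat <- c(1, 0, 0)
  chunks <- vector("list", n)
  prev_o3 <- prev_c3 <- NULL
  for (i in seq_len(n)) {
    rn <- .base_to_resname[bases[i]]
    rt <- .residue_template(rn, five_prime = i == 1L, three_prime = i == n)
    full <- .template_geom(rn)$xyz   # includes the OP3 cap
    if (i == 1L) {
      hp <- full["O5'", ]; tp <- full["O3'", ]
      R <- .rotation_onto(tp - hp, xhat)
      placed <- sweep(full, 2, hp) %*% t(R)
    } else {
      a <- prev_c3 - prev_o3             # O3' -> C3' direction
      w <- c(a[2] * xhat[3] - a[3] * xhat[2],
             a[3] * xhat[1] - a[1] * xhat[3],
             a[1] * xhat[2] - a[2] * xhat[1])
      if (sqrt(sum(w^2)) < 1e-8) w <- c(0, 0, 1)
      phat <- as.numeric(.rodrigues(matrix(a / sqrt(sum(a^2)), 1), w,
                                    119.7 * pi / 180))
      # superpose the OP3 cap on prev O3' and align the P along phat
      loc <- sweep(full, 2, full["OP3", ])
      R <- .rotation_onto(loc["P", ], phat)
      loc <- loc %*% t(R)
      # free spin about the bond axis: maximize extension along +x
      cpar <- sum(loc["O3'", ] * phat) * phat
      cperp <- loc["O3'", ] - cpar
      pxc <- c(phat[2] * cperp[3] - phat[3] * cperp[2],
               phat[3] * cperp[1] - phat[1] * cperp[3],
               phat[1] * cperp[2] - phat[2] * cperp[1])
      spin <- atan2(pxc[1], cperp[1])
      loc <- .rodrigues(loc, phat, spin)
      placed <- sweep(loc, 2, prev_o3, `+`)
    }
    prev_o3 <- placed["O3'", ]; prev_c3 <- placed["C3'", ]
    xyz <- placed[rt$atoms$atom, , drop = FALSE]
    chunks[[i]] <- data.frame(resno = i, resname = rn,
                              atom = rt$atoms$atom, element = rt$atoms$element,
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  conformer(out)
}
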