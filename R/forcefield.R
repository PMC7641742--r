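## Covalent force-field construction. Bond / angle / improper ideals are
## measured on the idealized residue templates, so a freshly built chain has
## zero covalent energy (inter-residue phosphodiester angles use the
## template's OP3 cap as the stand-in for the preceding O3'). The nonbonded
## term is a purely repulsive soft sphere with 1-2/1-3/1-4 exclusions; no
## electrostatics, as is standard for restraint-driven NMR annealing.

.vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

.vec_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Base heavy atoms restrained by planarity units (ring + exocyclic).
.base_plane_atoms <- list(
  DG = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  DA = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  DC = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  DT = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")
)

# Default covalent / nonbonded force constants (kcal/mol/A^2 or rad^2).
# k_ring optionally biases the deoxyribose ring toward the template pucker;
# it is off by default (stiff rings make the annealing landscape rugged and
# hurt convergence at desk scale).
.ff_defaults <- list(k_bond = 200, k_angle = 50, k_improper = 30,
                     k_ring = 0, k_rep = 4, rep_scale = 0.80)

.template_geom <- function(resname) {
  key <- paste0("geom_", resname)
  if (!is.null(.qdh_cache[[key]])) return(.qdh_cache[[key]])
  tpl <- molecular_template()
  at <- tpl$atoms[tpl$atoms$resname == resname, ]
  bd <- tpl$bonds[tpl$bonds$resname == resname, ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rownames(xyz) <- at$atom
  nb <- lapply(at$atom, function(a)
    sort(c(bd$atom_b[bd$atom_a == a], bd$atom_a[bd$atom_b == a])))
  names(nb) <- at$atom
  g <- list(xyz = xyz, neighbors = nb, atoms = at$atom)
  .qdh_cache[[key]] <- g
  g
}

#' Build the covalent system description for a conformer
#'
#' Enumerates bonds, angles and impropers over the chain with ideal values
#' measured on the residue templates, plus per-atom masses, van der Waals
#' radii and the nonbonded exclusion list. The result is the fixed system
#' description consumed by the compiled energy/dynamics kernels.
#'
#' @param conf A [conformer()] as produced by [build_chain()] (atom
#'   inventory determines the terms; coordinates are not used).
#' @param constants Optional overrides for the covalent force constants
#'   (`k_bond`, `k_angle`, `k_improper`, `k_rep`, `rep_scale`).
#' @return A list of term tables (0-based atom indices, ready for the
#'   compiled kernels).
#' @export
build_system <- function(conf, constants = list()) {
  kk <- utils::modifyList(.ff_defaults, constants)
  n <- nrow(conf)
  key <- paste(conf$resno, conf$atom)
  idx_of <- function(res, at) match(paste(res, at), key)

  bonds <- list(); b_r0 <- numeric()
  angles <- list(); a_th0 <- numeric()
  imps <- list(); i_phi0 <- numeric(); i_k <- numeric()

  resnos <- unique(conf$resno)
  for (r in resnos) {
    rn <- conf$resname[conf$resno == r][1]
    g <- .template_geom(rn)
    present <- conf$atom[conf$resno == r]
    # intra-residue bonds
    tplb <- molecular_template()$bonds
    tplb <- tplb[tplb$resname == rn, ]
    keep <- tplb$atom_a %in% present & tplb$atom_b %in% present
    for (k in which(keep)) {
      a <- tplb$atom_a[k]; b <- tplb$atom_b[k]
      bonds[[length(bonds) + 1]] <- c(idx_of(r, a), idx_of(r, b))
      b_r0 <- c(b_r0, sqrt(sum((g$xyz[a, ] - g$xyz[b, ])^2)))
    }
    # intra-residue angles: every pair of surviving neighbors of each atom
    for (a in present) {
      nbr <- intersect(g$neighbors[[a]], present)
      if (length(nbr) < 2) next
      cmb <- utils::combn(nbr, 2)
      for (k in seq_len(ncol(cmb))) {
        angles[[length(angles) + 1]] <-
          c(idx_of(r, cmb[1, k]), idx_of(r, a), idx_of(r, cmb[2, k]))
        a_th0 <- c(a_th0, .vec_angle(g$xyz[cmb[1, k], ], g$xyz[a, ],
                                     g$xyz[cmb[2, k], ]))
      }
      # one improper per >=3-coordinate center keeps planarity/chirality
      if (length(nbr) >= 3) {
        tr <- nbr[1:3]
        imps[[length(imps) + 1]] <-
          c(idx_of(r, tr[1]), idx_of(r, a), idx_of(r, tr[2]), idx_of(r, tr[3]))
        i_phi0 <- c(i_phi0, .vec_torsion(g$xyz[tr[1], ], g$xyz[a, ],
                                         g$xyz[tr[2], ], g$xyz[tr[3], ]))
        i_k <- c(i_k, kk$k_improper)
      }
    }
    # optional sugar-ring torsions biasing the ring toward the template
    # pucker (k_ring = 0 disables them)
    ring <- if (kk$k_ring > 0) c("O4'", "C1'", "C2'", "C3'", "C4'")
      else character()
    for (k in seq_along(ring)) {
      quad <- ring[(seq(k, k + 3) - 1) %% 5 + 1]
      imps[[length(imps) + 1]] <- c(idx_of(r, quad[1]), idx_of(r, quad[2]),
                                    idx_of(r, quad[3]), idx_of(r, quad[4]))
      i_phi0 <- c(i_phi0, .vec_torsion(g$xyz[quad[1], ], g$xyz[quad[2], ],
                                       g$xyz[quad[3], ], g$xyz[quad[4], ]))
      i_k <- c(i_k, kk$k_ring)
    }
    # phosphodiester junction to the previous residue
    if (r > resnos[1]) {
      prev <- r - 1L
      o3 <- idx_of(prev, "O3'"); p <- idx_of(r, "P")
      bonds[[length(bonds) + 1]] <- c(o3, p)
      b_r0 <- c(b_r0, sqrt(sum((g$xyz["OP3", ] - g$xyz["P", ])^2)))
      angles[[length(angles) + 1]] <- c(idx_of(prev, "C3'"), o3, p)
      a_th0 <- c(a_th0, 119.7 * pi / 180)
      for (x in c("OP1", "OP2", "O5'")) {
        angles[[length(angles) + 1]] <- c(o3, p, idx_of(r, x))
        a_th0 <- c(a_th0, .vec_angle(g$xyz["OP3", ], g$xyz["P", ],
                                     g$xyz[x, ]))
      }
    }
  }

  bonds <- if (length(bonds)) do.call(rbind, bonds)
    else matrix(integer(), 0, 2)
  angles <- if (length(angles)) do.call(rbind, angles)
    else matrix(integer(), 0, 3)
  imps <- if (length(imps)) do.call(rbind, imps)
    else matrix(integer(), 0, 4)

  # 1-2 / 1-3 / 1-4 nonbonded exclusions from the bond graph
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- new.env(hash = TRUE, parent = emptyenv())
  add_ex <- function(i, j) {
    if (i == j) return()
    kk2 <- if (i < j) paste(i, j) else paste(j, i)
    assign(kk2, TRUE, envir = excl)
  }
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      add_ex(i, j)
      for (k in adj[[j]]) {
        add_ex(i, k)
        for (l in adj[[k]]) add_ex(i, l)
      }
    }
  }
  ex_pairs <- do.call(rbind, lapply(ls(excl), function(s)
    as.integer(strsplit(s, " ")[[1]])))
  if (is.null(ex_pairs)) ex_pairs <- matrix(integer(), 0, 2)

  list(
    n = n,
    mass = unname(.element_mass[conf$element]),
    vdw = unname(.element_vdw[conf$element]),
    bonds = bonds - 1L, bond_r0 = b_r0,
    angles = angles - 1L, angle_th0 = a_th0,
    impropers = imps - 1L,
    improper_phi0 = i_phi0, improper_k = i_k,
    excl = ex_pairs - 1L,
    k_bond = kk$k_bond, k_angle = kk$k_angle, k_improper = kk$k_improper,
    k_rep = kk$k_rep, rep_scale = kk$rep_scale
  )
}

#' Resolve restraint tables to atom indices of a conformer
#'
#' Maps distance restraints, chi dihedral restraints and planarity units
#' onto atom row indices of a specific conformer, producing the indexed
#' restraint set consumed by the compiled kernels. Distance restraints keep
#' their exchangeable flag so annealing can scale the two force-constant
#' classes independently.
#'
#' @param conf A [conformer()].
#' @param dist Data frame of distance restraints (see [classify_noe()]).
#' @param dihedral Data frame from [dihedral_restraints()].
#' @param planarity List of units from [planarity_restraints()].
#' @return List with indexed components `dist`, `dih`, `plan`.
#' @export
index_restraints <- function(conf, dist = NULL, dihedral = NULL,
                             planarity = NULL) {
  out <- list(
    dist = list(i = integer(), j = integer(), lo = numeric(),
                up = numeric(), exch = integer()),
    dih = list(i = integer(), j = integer(), k = integer(), l = integer(),
               center = numeric(), halfwidth = numeric()),
    plan = list()
  )
  if (!is.null(dist) && nrow(dist)) {
    ia <- atom_index(conf, dist$res_a, dist$atom_a)
    ib <- atom_index(conf, dist$res_b, dist$atom_b)
    out$dist <- list(i = ia - 1L, j = ib - 1L,
                     lo = dist$target - dist$minus,
                     up = dist$target + dist$plus,
                     exch = as.integer(dist$exchangeable))
  }
  if (!is.null(dihedral) && nrow(dihedral)) {
    quart <- strsplit(dihedral$atoms, "-", fixed = TRUE)
    i1 <- atom_index(conf, dihedral$residue, vapply(quart, `[`, "", 1))
    i2 <- atom_index(conf, dihedral$residue, vapply(quart, `[`, "", 2))
    i3 <- atom_index(conf, dihedral$residue, vapply(quart, `[`, "", 3))
    i4 <- atom_index(conf, dihedral$residue, vapply(quart, `[`, "", 4))
    out$dih <- list(i = i1 - 1L, j = i2 - 1L, k = i3 - 1L, l = i4 - 1L,
                    center = dihedral$center * pi / 180,
                    halfwidth = dihedral$halfwidth * pi / 180)
  }
  if (!is.null(planarity) && length(planarity)) {
    out$plan <- lapply(planarity, function(u) {
      idx <- integer()
      for (m in u$members) {
        rn <- conf$resname[conf$resno == m][1]
        if (is.na(rn)) stop("planarity unit references missing residue ", m)
        nm <- .base_plane_atoms[[rn]]
        idx <- c(idx, atom_index(conf, rep(m, length(nm)), nm))
      }
      idx - 1L
    })
  }
  out
}
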