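## Synthetic ground-truth generators: idealized QDH coordinates assembled
## from the declarative topology, classed NOE peak lists simulated from
## coordinates, CD mixtures and two-state melting curves. Every generator is
## a seeded deterministic function of its arguments.

#' Parameters of the idealized QDH geometry builder
#'
#' @param rise Inter-layer stacking rise in Angstrom.
#' @param tetrad_twist Helical twist between stacked tetrad layers
#'   (degrees).
#' @param duplex_twist Twist between stacked Watson-Crick stem pairs
#'   (degrees, B-form-like).
#' @param c1_half_diagonal Initial guess for the distance from the helix
#'   axis to a tetrad guanine base centroid (Angstrom).
#' @param loop_bulge Radial outward displacement of interpolated loop
#'   residues (Angstrom).
#' @param seed Integer seed (the construction itself is deterministic; the
#'   seed is recorded for provenance).
#' @return List of class `ideal_geometry_params`.
#' @export
ideal_geometry_params <- function(rise = 3.4, tetrad_twist = 25,
                                  duplex_twist = 36,
                                  c1_half_diagonal = 6.8, loop_bulge = 6,
                                  seed = 1) {
  stopifnot(rise > 0)
  structure(list(rise = rise, tetrad_twist = tetrad_twist,
                 duplex_twist = duplex_twist,
                 c1_half_diagonal = c1_half_diagonal,
                 loop_bulge = loop_bulge, seed = seed),
            class = "ideal_geometry_params")
}

.rz <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
.flip_x <- diag(c(1, -1, -1))  # rotation by pi about the local x axis

.glyc_n <- function(rn) if (rn %in% c("DA", "DG")) "N9" else "N1"

# Whole-nucleotide coordinates in a base-centered frame: origin at the base
# heavy-atom centroid, z along the base-plane normal, x from the glycosidic
# nitrogen through the centroid.
.base_local <- function(rn) {
  key <- paste0("baselocal_", rn)
  if (!is.null(.qdh_cache[[key]])) return(.qdh_cache[[key]])
  g <- .template_geom(rn)
  plane <- .base_plane_atoms[[rn]]
  P <- g$xyz[plane, , drop = FALSE]
  cen <- colMeans(P)
  sv <- svd(sweep(P, 2, cen))
  ez <- sv$v[, 3]
  exd <- cen - g$xyz[.glyc_n(rn), ]
  exd <- exd - sum(exd * ez) * ez
  ex <- exd / sqrt(sum(exd^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[1], ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  R <- cbind(ex, ey, ez)
  local <- sweep(g$xyz, 2, cen) %*% R
  rownames(local) <- rownames(g$xyz)
  .qdh_cache[[key]] <- local
  local
}

# placement: p_global = Rz(theta) %*% F %*% p_local + pos
.place_pt <- function(local_pt, pl) {
  F <- if (pl$flip) .flip_x else diag(3)
  as.numeric(.rz(pl$theta) %*% F %*% local_pt + pl$pos)
}

.place_all <- function(local, pl) {
  F <- if (pl$flip) .flip_x else diag(3)
  out <- local %*% t(F) %*% t(.rz(pl$theta))
  sweep(out, 2, pl$pos, `+`)
}

# Fit the in-plane rigid transform of a canonical G-tetrad member so that
# the C4 copies satisfy the Hoogsteen distance targets. sigma = +1 places
# the donor's acceptor at +90 degrees (face-up bases); sigma = -1 is the
# mirror arrangement (flipped bases).
.fit_g_tetrad <- function(sigma) {
  key <- paste0("tetradfit_", sigma)
  if (!is.null(.qdh_cache[[key]])) return(.qdh_cache[[key]])
  local <- .base_local("DG")
  flip <- sigma < 0
  targets <- rbind(c("H21", "N7", 2.0), c("N2", "N7", 2.9),
                   c("H1", "O6", 2.0), c("N1", "O6", 2.9))
  obj <- function(par) {
    pl0 <- list(theta = par[1], flip = flip, pos = c(par[2], par[3], 0))
    Racc <- .rz(sigma * pi / 2)
    s <- 0
    for (k in 1:4) {
      d <- .place_pt(local[targets[k, 1], ], pl0)
      a <- as.numeric(Racc %*% .place_pt(local[targets[k, 2], ], pl0))
      s <- s + (sqrt(sum((d - a)^2)) - as.numeric(targets[k, 3]))^2
    }
    s
  }
  best <- NULL
  for (a0 in seq(0, 2 * pi, length.out = 13)[-13])
    for (r0 in c(2.5, 4, 5.5, 7)) for (y0 in c(-2, 0, 2)) {
      o <- stats::optim(c(a0, r0, y0), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
  fit <- list(theta = best$par[1], flip = flip,
              pos = c(best$par[2], best$par[3], 0), rss = best$value)
  .qdh_cache[[key]] <- fit
  fit
}

# Fit the cytosine placement of a canonical Watson-Crick G.C pair (guanine
# base frame at the origin) against the six hydrogen-bond targets.
.fit_wc_pair <- function() {
  if (!is.null(.qdh_cache$wcfit)) return(.qdh_cache$wcfit)
  lg <- .base_local("DG"); lc <- .base_local("DC")
  targets <- rbind(c("H21", "O2", 2.0), c("H1", "N3", 2.0),
                   c("O6", "H41", 2.0), c("N2", "O2", 2.9),
                   c("N1", "N3", 2.9), c("O6", "N4", 2.9))
  plg <- list(theta = 0, flip = FALSE, pos = c(0, 0, 0))
  fit1 <- function(flip) {
    obj <- function(par) {
      plc <- list(theta = par[1], flip = flip, pos = c(par[2], par[3], 0))
      s <- 0
      for (k in 1:6) {
        d <- .place_pt(lg[targets[k, 1], ], plg)
        a <- .place_pt(lc[targets[k, 2], ], plc)
        s <- s + (sqrt(sum((d - a)^2)) - as.numeric(targets[k, 3]))^2
      }
      s
    }
    best <- NULL
    for (a0 in seq(0, 2 * pi, length.out = 13)[-13])
      for (r0 in c(4, 6, 8, 10)) for (y0 in c(-3, 0, 3)) {
        o <- stats::optim(c(a0, r0, y0), obj, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14))
        if (is.null(best) || o$value < best$value) best <- o
      }
    list(theta = best$par[1], flip = flip,
         pos = c(best$par[2], best$par[3], 0), rss = best$value)
  }
  fa <- fit1(FALSE); fb <- fit1(TRUE)
  fit <- if (fa$rss <= fb$rss) fa else fb
  .qdh_cache$wcfit <- fit
  fit
}

# in-plane rigid registration (rotation about z + xy translation) taking
# source points onto target points, least squares
.register_2d <- function(S, T) {
  cs <- colMeans(S); ct <- colMeans(T)
  Sx <- sweep(S, 2, cs); Tx <- sweep(T, 2, ct)
  num <- sum(Sx[, 1] * Tx[, 2] - Sx[, 2] * Tx[, 1])
  den <- sum(Sx[, 1] * Tx[, 1] + Sx[, 2] * Tx[, 2])
  theta <- atan2(num, den)
  list(theta = theta, cs = c(cs[1:2], 0), ct = c(ct[1:2], 0))
}

.apply_registration <- function(pl, reg, z_shift = 0) {
  pos <- as.numeric(.rz(reg$theta) %*% (pl$pos - reg$cs)) + reg$ct
  pos[3] <- pl$pos[3] + z_shift
  list(theta = pl$theta + reg$theta, flip = pl$flip, pos = pos)
}

.rotate_about_axis <- function(pts, origin, u, phi) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
  sweep(sweep(pts, 2, origin) %*% t(R), 2, origin, `+`)
}

.base_side_atoms <- list(
  DG = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4",
         "H8", "H1", "H21", "H22"),
  DA = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4",
         "H8", "H2", "H61", "H62"),
  DC = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6",
         "H41", "H42", "H5", "H6"),
  DT = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6",
         "H3", "H71", "H72", "H73", "H6")
)

# rotate the sugar/backbone side about the glycosidic bond so that chi
# (O4'-C1'-N9-C4 or O4'-C1'-N1-C2) equals the target, degrees
.set_chi <- function(xyz, atoms, rn, chi_deg) {
  glyN <- .glyc_n(rn)
  cref <- if (rn %in% c("DA", "DG")) "C4" else "C2"
  i_o4 <- match("O4'", atoms); i_c1 <- match("C1'", atoms)
  i_n <- match(glyN, atoms); i_c <- match(cref, atoms)
  chi_now <- .vec_torsion(xyz[i_o4, ], xyz[i_c1, ], xyz[i_n, ], xyz[i_c, ])
  target <- chi_deg * pi / 180
  sugar <- which(!(atoms %in% .base_side_atoms[[rn]]) & atoms != "C1'")
  sugar <- c(sugar, match("H1'", atoms))
  sugar <- unique(sugar[!is.na(sugar)])
  axis_u <- xyz[i_n, ] - xyz[i_c1, ]
  for (phi in c(target - chi_now, chi_now - target)) {
    cand <- xyz
    cand[sugar, ] <- .rotate_about_axis(xyz[sugar, , drop = FALSE],
                                        xyz[i_c1, ], axis_u, phi)
    chi2 <- .vec_torsion(cand[i_o4, ], cand[i_c1, ], cand[i_n, ],
                         cand[i_c, ])
    if (abs(atan2(sin(chi2 - target), cos(chi2 - target))) < 1e-6)
      return(cand)
  }
  stop("failed to set glycosidic torsion")  # nocov
}

# Partition the topology's tetrads and pairs into stacked layers and order
# them by sequential-residue adjacency into a single coaxial stack.
.layer_chain <- function(t) {
  layers <- list()
  gcgc_members <- unlist(lapply(t$tetrads,
                                function(x) if (x$kind == "GCGC") x$members))
  for (tet in t$tetrads)
    layers <- c(layers, list(list(type = if (tet$kind == "G") "tetrad"
                                  else "gcgc",
                                  members = tet$members, tet = tet)))
  if (nrow(t$pairs)) for (k in seq_len(nrow(t$pairs))) {
    g <- t$pairs$g[k]; cc <- t$pairs$c[k]
    if (g %in% gcgc_members && cc %in% gcgc_members) next
    layers <- c(layers, list(list(type = "pair", members = c(g, cc),
                                  pair = c(g, cc))))
  }
  n <- length(layers)
  if (n == 0) stop("topology has no tetrads or pairs to place")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- outer(layers[[i]]$members, layers[[j]]$members,
               function(a, b) abs(a - b))
    adj[i, j] <- any(d == 1)
  }
  deg <- rowSums(adj)
  if (n > 1 && (any(deg == 0) || sum(deg == 1) != 2))
    stop("layer connectivity cannot be chained into a single stack")
  start <- if (n == 1) 1L else {
    ends <- which(deg == 1)
    tet_ends <- ends[vapply(ends, function(e)
      layers[[e]]$type == "tetrad", TRUE)]
    if (length(tet_ends)) tet_ends[1] else ends[1]
  }
  order <- start
  while (length(order) < n) {
    nxt <- setdiff(which(adj[order[length(order)], ]), order)
    if (!length(nxt))
      stop("layer connectivity cannot be chained into a single stack")
    order <- c(order, nxt[1])
  }
  layers[order]
}

#' Idealized all-atom coordinates for a QDH topology
#'
#' Deterministically assembles an all-atom reference model from the
#' declarative topology: G-tetrad guanines are placed on C4-symmetric
#' planar squares whose in-plane geometry is fitted to the Hoogsteen
#' hydrogen-bond targets; Watson-Crick pairs (stem and G.C.G.C members)
#' use a fitted ideal pair geometry; layers are stacked coaxially at the
#' stated rise and twist with inter-layer registry chosen by rigid
#' in-plane registration of sequential residues; glycosidic torsions are
#' set to 60 degrees (syn) or 240 degrees (anti); loop and terminal
#' residues are placed by geometric interpolation between their anchors.
#' Because bases are placed rigidly, the raw assembly leaves the
#' phosphodiester backbone unclosed; a deterministic restrained
#' regularization (L-BFGS minimization of the covalent + soft-sphere
#' potential with strong hydrogen-bond, dihedral and planarity restraints)
#' closes the chain while holding the base arrangement, so the returned
#' model satisfies every hydrogen-bond restraint window of
#' [hbond_restraints()] and the chi dihedral windows, and is the
#' ground-truth reference for pipeline recovery experiments.
#'
#' @param t A valid [qdh_topology()].
#' @param params An [ideal_geometry_params()].
#' @param regularize Run the deterministic restrained regularization
#'   (default); `FALSE` returns the raw rigid-base assembly.
#' @return A [conformer()] with the same atom inventory as
#'   `build_chain(t$sequence)`.
#' @export
build_idealized_coords <- function(t, params = ideal_geometry_params(),
                                   regularize = TRUE) {
  msgs <- validate_topology(t)
  if (length(msgs))
    stop("invalid topology: ", paste(msgs, collapse = "; "))
  n <- nchar(t$sequence)
  bases <- t$residues$base
  chain <- .layer_chain(t)
  placements <- vector("list", n)
  wc <- .fit_wc_pair()

  layer_twist <- function(layer)
    if (layer$type == "tetrad") params$tetrad_twist * pi / 180
    else params$duplex_twist * pi / 180

  glyN_global <- function(res) {
    rn <- .base_to_resname[bases[res]]
    .place_pt(.base_local(rn)[.glyc_n(rn), ], placements[[res]])
  }

  place_tetrad <- function(layer, z, targets = NULL) {
    m <- layer$members
    cands <- list()
    sigmas <- if (is.null(targets)) {
      dir <- layer$tet$direction
      if (identical(dir, "clockwise")) -1 else 1
    } else c(1, -1)
    for (s in sigmas) for (o in 0:3) {
      fit <- .fit_g_tetrad(s)
      pls <- lapply(0:3, function(k) {
        q <- (s * k + o) %% 4
        rot <- .rz(pi / 2 * q)
        list(theta = fit$theta + pi / 2 * q, flip = fit$flip,
             pos = as.numeric(rot %*% fit$pos) + c(0, 0, z))
      })
      names(pls) <- as.character(m)
      if (is.null(targets)) return(pls)
      S <- do.call(rbind, lapply(names(targets), function(r) {
        rn <- .base_to_resname[bases[as.integer(r)]]
        .place_pt(.base_local(rn)[.glyc_n(rn), ], pls[[r]])
      }))
      T <- do.call(rbind, targets)
      reg <- .register_2d(S, T)
      S2 <- sweep(sweep(S, 2, reg$cs) %*% t(.rz(reg$theta)), 2, reg$ct, `+`)
      rss <- sum((S2[, 1:2] - T[, 1:2])^2)
      cands[[length(cands) + 1]] <- list(pls = pls, reg = reg, rss = rss)
    }
    best <- cands[[which.min(vapply(cands, `[[`, 0, "rss"))]]
    lapply(best$pls, .apply_registration, reg = best$reg)
  }

  place_pair <- function(g, cc, z, targets) {
    # canonical pair: G base at origin, C from the fitted WC transform
    plg <- list(theta = 0, flip = FALSE, pos = c(0, 0, z))
    plc <- list(theta = wc$theta, flip = wc$flip,
                pos = wc$pos + c(0, 0, z))
    pls <- list(plg, plc); names(pls) <- as.character(c(g, cc))
    if (!length(targets)) return(pls)
    S <- do.call(rbind, lapply(names(targets), function(r) {
      rn <- .base_to_resname[bases[as.integer(r)]]
      .place_pt(.base_local(rn)[.glyc_n(rn), ], pls[[r]])
    }))
    T <- do.call(rbind, targets)
    reg <- .register_2d(S, T)
    lapply(pls, .apply_registration, reg = reg)
  }

  z <- 0
  prev_layer <- NULL
  for (li in seq_along(chain)) {
    layer <- chain[[li]]
    if (li > 1) z <- z - params$rise
    targets <- NULL
    if (!is.null(prev_layer)) {
      tw <- layer_twist(layer)
      targets <- list()
      for (r in layer$members) {
        nb <- intersect(c(r - 1, r + 1), prev_layer$members)
        if (!length(nb)) next
        p <- glyN_global(nb[1])
        p <- as.numeric(.rz(tw) %*% c(p[1], p[2], 0))
        targets[[as.character(r)]] <- c(p[1], p[2], z)
      }
    }
    if (layer$type == "tetrad") {
      placements[layer$members] <- place_tetrad(layer, z, targets)
    } else if (layer$type == "pair") {
      pls <- place_pair(layer$pair[1], layer$pair[2], z, targets)
      placements[layer$members] <- pls
    } else { # gcgc: place its two Watson-Crick pairs independently
      pr <- t$pairs[t$pairs$role == "junction", ]
      for (k in seq_len(nrow(pr))) {
        g <- pr$g[k]; cc <- pr$c[k]
        tk <- targets[as.character(c(g, cc))]
        tk <- tk[!vapply(tk, is.null, TRUE)]
        placements[c(g, cc)] <- place_pair(g, cc, z, tk)
      }
    }
    prev_layer <- layer
  }

  # dangling termini: stack on the adjacent placed residue
  for (r in seq(n, 1)) {
    if (!is.null(placements[[r]]) || r == n) next
    if (!is.null(placements[[r + 1]]) && !.in_loop(t, r)) {
      pl <- placements[[r + 1]]
      top <- pl$pos[3] >= -1e-9
      placements[[r]] <- list(theta = pl$theta +
                                params$duplex_twist * pi / 180,
                              flip = pl$flip,
                              pos = pl$pos + c(0, 0, if (top) params$rise
                                               else -params$rise))
    }
  }
  for (r in seq_len(n)) {
    if (!is.null(placements[[r]]) || r == 1) next
    if (!is.null(placements[[r - 1]]) && !.in_loop(t, r)) {
      pl <- placements[[r - 1]]
      top <- pl$pos[3] >= -1e-9
      placements[[r]] <- list(theta = pl$theta +
                                params$duplex_twist * pi / 180,
                              flip = pl$flip,
                              pos = pl$pos + c(0, 0, if (top) params$rise
                                               else -params$rise))
    }
  }

  # loops: geometric interpolation between anchors, bulged radially outward
  for (lp in t$loops) {
    run <- lp$from:lp$to
    if (all(!vapply(placements[run], is.null, TRUE))) next
    a <- lp$from - 1L; b <- lp$to + 1L
    if (a < 1 || b > n || is.null(placements[[a]]) ||
        is.null(placements[[b]]))
      stop(sprintf("loop %d-%d has no placed anchors on both sides",
                   lp$from, lp$to))
    A <- glyN_global(a); B <- glyN_global(b)
    mid <- (A + B) / 2
    u <- c(mid[1], mid[2], 0)
    if (sqrt(sum(u^2)) < 1e-6) u <- c(1, 0, 0)
    u <- u / sqrt(sum(u^2))
    L <- length(run)
    for (i in seq_along(run)) {
      s <- i / (L + 1)
      P <- (1 - s) * A + s * B + params$loop_bulge * sin(pi * s) * u
      theta <- atan2(P[2], P[1])
      rn <- .base_to_resname[bases[run[i]]]
      pl <- list(theta = theta, flip = FALSE, pos = c(0, 0, 0))
      gly <- .place_pt(.base_local(rn)[.glyc_n(rn), ], pl)
      placements[[run[i]]] <- list(theta = theta, flip = FALSE,
                                   pos = P - gly)
    }
  }

  unplaced <- which(vapply(placements, is.null, TRUE))
  if (length(unplaced))
    stop("residues cannot be chained (not in any tetrad, pair, loop or ",
         "terminus): ", paste(unplaced, collapse = ", "))

  chunks <- vector("list", n)
  for (r in seq_len(n)) {
    rn <- .base_to_resname[bases[r]]
    rt <- .residue_template(rn, five_prime = r == 1L, three_prime = r == n)
    local <- .base_local(rn)[rt$atoms$atom, , drop = FALSE]
    xyz <- .place_all(local, placements[[r]])
    chi <- if (r %in% t$syn) 60 else 240
    xyz <- .set_chi(xyz, rt$atoms$atom, rn, chi)
    chunks[[r]] <- data.frame(resno = r, resname = rn, atom = rt$atoms$atom,
                              element = rt$atoms$element, x = xyz[, 1],
                              y = xyz[, 2], z = xyz[, 3],
                              stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  conf <- conformer(out)
  if (regularize) {
    rs <- qdh_restraints(t)
    sys <- build_system(conf)
    ir <- index_restraints(conf, rs$dist, rs$dihedral, rs$planarity)
    kset <- list(k_nonexch = 100, k_exch = 100, k_dihedral = 400,
                 k_planarity = 10)
    # close the backbone first without sterics, then relax contacts
    m <- .minimize_xyz(conf_xyz(conf), sys, ir, kset, nonbonded = FALSE,
                       min_gradient = 0.2, max_iter = 2500)
    x <- .repair_prochiral(conf, m$xyz, sys)
    m <- .minimize_xyz(x, sys, ir, kset, nonbonded = TRUE,
                       min_gradient = 0.1, max_iter = 2500)
    conf <- set_conf_xyz(conf, m$xyz)
  }
  conf
}

.in_loop <- function(t, r) {
  any(vapply(t$loops, function(lp) r >= lp$from && r <= lp$to, TRUE))
}

#' Noise model for simulated NOE peak lists
#'
#' @param jitter_sd Gaussian jitter applied to true distances (Angstrom).
#' @param class_bounds Two class-boundary distances (Angstrom) separating
#'   strong/medium and medium/weak for non-exchangeable pairs.
#' @param class_bounds_exch Boundaries for exchangeable pairs (chosen so
#'   each class window contains its distance range).
#' @param min_distance,min_distance_exch Pairs closer than this are not
#'   emitted (below the classification range).
#' @param false_negative_rate Fraction of peaks dropped at random.
#' @param seed Integer seed.
#' @return List of class `noe_noise_model`.
#' @export
noise_model <- function(jitter_sd = 0, class_bounds = c(3.0, 4.5),
                        class_bounds_exch = c(4.2, 5.5),
                        min_distance = 2.0, min_distance_exch = 3.0,
                        false_negative_rate = 0, seed = 1) {
  stopifnot(false_negative_rate >= 0, false_negative_rate <= 1)
  structure(list(jitter_sd = jitter_sd, class_bounds = class_bounds,
                 class_bounds_exch = class_bounds_exch,
                 min_distance = min_distance,
                 min_distance_exch = min_distance_exch,
                 false_negative_rate = false_negative_rate, seed = seed),
            class = "noe_noise_model")
}

.exchangeable_protons <- c("H1", "H21", "H22", "H41", "H42", "H61", "H62",
                           "H3", "HO3'", "HO5'")

#' Simulate a classed NOE peak list from coordinates
#'
#' Emits every inter-proton pair within `max_distance`, with the true
#' distance jittered (seeded Gaussian) and quantized into
#' strong/medium/weak by the class-boundary distances. Pairs involving an
#' exchangeable (imino/amino) proton are flagged and use the exchangeable
#' boundaries; thymine methyl protons are represented by their methyl
#' carbon (C7) distance with the methyl flag set. A false-negative
#' fraction of peaks is dropped at random. At zero jitter and default
#' boundaries, feeding each emitted peak through [classify_noe()] gives a
#' window containing the true (represented-atom) distance.
#'
#' @param conf A [conformer()] with hydrogens.
#' @param max_distance Maximum emitted distance (Angstrom).
#' @param noise A [noise_model()].
#' @return Data frame of classed peaks (the peak-list TSV dialect).
#' @export
simulate_noe_peaks <- function(conf, max_distance = 6.0,
                               noise = noise_model()) {
  set.seed(noise$seed)
  is_methyl <- conf$resname == "DT" & grepl("^H7", conf$atom)
  sel <- which(conf$element == "H" & !is_methyl)
  # one representative per methyl group: the carbon C7
  me <- which(conf$resname == "DT" & conf$atom == "C7")
  rows <- c(sel, me)
  methyl_flag <- c(rep(FALSE, length(sel)), rep(TRUE, length(me)))
  xyz <- conf_xyz(conf)[rows, , drop = FALSE]
  nn <- length(rows)
  exch <- conf$atom[rows] %in% .exchangeable_protons
  D <- as.matrix(stats::dist(xyz))
  out <- list()
  for (i in seq_len(nn - 1)) for (j in seq((i + 1), nn)) {
    d0 <- D[i, j]
    if (d0 > max_distance + 2) next
    d <- d0 + if (noise$jitter_sd > 0) stats::rnorm(1, 0, noise$jitter_sd)
      else 0
    pe <- exch[i] || exch[j]
    minb <- if (pe) noise$min_distance_exch else noise$min_distance
    cb <- if (pe) noise$class_bounds_exch else noise$class_bounds
    if (d < minb || d > max_distance) next
    if (noise$false_negative_rate > 0 &&
        stats::runif(1) < noise$false_negative_rate) next
    cls <- if (d < cb[1]) "strong" else if (d < cb[2]) "medium" else "weak"
    ri <- rows[i]; rj <- rows[j]
    out[[length(out) + 1]] <- data.frame(
      res_a = conf$resno[ri], atom_a = conf$atom[ri],
      res_b = conf$resno[rj], atom_b = conf$atom[rj],
      class = cls, exchangeable = as.integer(pe),
      methyl = as.integer(methyl_flag[i] || methyl_flag[j]),
      distance = round(d0, 3), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(res_a = integer(), atom_a = character(),
                      res_b = integer(), atom_b = character(),
                      class = character(), exchangeable = integer(),
                      methyl = integer(), distance = numeric()))
  do.call(rbind, out)
}

#' Write a simulated peak list in the canonical TSV dialect
#' @param peaks Data frame from [simulate_noe_peaks()].
#' @param path File path.
#' @export
write_noe_peaks <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parametric component CD spectra
#'
#' Gaussian-band mock-ups of the two pure-form CD profiles: the hybrid
#' (3+1) form with a positive peak near 265 nm, a positive shoulder near
#' 290 nm and a negative band near 245 nm; the antiparallel form with a
#' positive maximum near 290 nm and a negative minimum near 255 nm. Only
#' their linear independence matters for decomposition experiments.
#'
#' @param form `"hybrid"` or `"antiparallel"`.
#' @param grid Wavelength grid (nm).
#' @return A [cd_spectrum()].
#' @export
cd_component_spectrum <- function(form = c("hybrid", "antiparallel"),
                                  grid = seq(220, 320, by = 1)) {
  form <- match.arg(form)
  band <- function(center, amp, width) amp * exp(-(grid - center)^2 /
                                                   (2 * width^2))
  y <- if (form == "hybrid")
    band(265, 10, 9) + band(290, 4, 8) + band(245, -6, 8)
  else
    band(290, 10, 10) + band(255, -8, 9)
  cd_spectrum(grid, y)
}

#' Simulate a two-component CD mixture spectrum
#'
#' `w1 * comp1 + (1 - w1) * comp2` plus seeded Gaussian noise, either
#' additive (sd in ellipticity units) or multiplicative (relative sd, e.g.
#' 0.01 for 1 percent).
#'
#' @param w1 Weight of the first component, in `[0, 1]`.
#' @param comp1,comp2 [cd_spectrum()] objects on a common grid.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @param type `"multiplicative"` or `"additive"`.
#' @return A [cd_spectrum()].
#' @export
simulate_cd_mixture <- function(w1, comp1, comp2, noise_sd = 0, seed = 1,
                                type = c("multiplicative", "additive")) {
  type <- match.arg(type)
  stopifnot(w1 >= 0, w1 <= 1)
  if (length(comp1$wavelength) != length(comp2$wavelength) ||
      any(comp1$wavelength != comp2$wavelength))
    stop("component spectra must share a common wavelength grid")
  set.seed(seed)
  y <- w1 * comp1$ellipticity + (1 - w1) * comp2$ellipticity
  if (noise_sd > 0) {
    z <- stats::rnorm(length(y))
    y <- if (type == "multiplicative") y * (1 + noise_sd * z)
      else y + noise_sd * z
  }
  cd_spectrum(comp1$wavelength, y)
}

#' Simulate a two-state melting curve
#'
#' Generates the folded fraction from the two-state van't Hoff relation
#' `theta(T) = 1 / (1 + exp((dH/R) (1/Tm - 1/T)))` (temperatures in
#' Kelvin; theta(Tm) = 0.5 exactly) and mixes the folded and unfolded
#' linear baselines accordingly, plus seeded Gaussian noise. Larger
#' unfolding enthalpy gives a sharper transition.
#'
#' @param tm Melting temperature (deg C), within the grid.
#' @param dH Van't Hoff unfolding enthalpy (kcal/mol).
#' @param baseline_folded,baseline_unfolded `c(intercept, slope)` of the
#'   two state baselines (ellipticity vs deg C).
#' @param grid Temperature grid (deg C).
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @return A [melt_curve()].
#' @export
simulate_melting_curve <- function(tm, dH = 70,
                                   baseline_folded = c(1, 0),
                                   baseline_unfolded = c(0, 0),
                                   grid = seq(15, 95, by = 1),
                                   noise_sd = 0, seed = 1) {
  stopifnot(tm >= min(grid), tm <= max(grid))
  set.seed(seed)
  R <- 0.0019872041
  TK <- grid + 273.15; tmK <- tm + 273.15
  theta <- 1 / (1 + exp((dH / R) * (1 / tmK - 1 / TK)))
  yf <- baseline_folded[1] + baseline_folded[2] * grid
  yu <- baseline_unfolded[1] + baseline_unfolded[2] * grid
  y <- theta * yf + (1 - theta) * yu
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  melt_curve(grid, y)
}
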