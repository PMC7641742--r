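## Distance-geometry embedding + restrained simulated annealing.

.KB <- 0.0019872041  # kcal/mol/K

#' Annealing schedule for restrained molecular-dynamics refinement
#'
#' Encodes the staged refinement protocol: heat from 300 to 1000 K over
#' 14 ps and equilibrate 6 ps with distance-restraint force constants at
#' 2 kcal/mol/A^2; ramp the constants to 16 (non-exchangeable) and
#' 8 (exchangeable) kcal/mol/A^2 over 20 ps; equilibrate 50 ps at 1000 K;
#' cool to 300 K over 42 ps; equilibrate 18 ps, saving coordinates every
#' 0.5 ps over the final 10 ps for averaging. Dihedral (50 kcal/mol/rad^2)
#' and planarity (1 kcal/mol/A^2) constants are held throughout, and the
#' averaged structure is minimized to a residual gradient of 0.1 kcal/mol.
#' `scale_factor` multiplies every stage duration uniformly for desk-scale
#' runs (0.1 turns the 150 ps protocol into 15 ps).
#'
#' @param heat_start_K,heat_end_K Temperature ramp endpoints (K).
#' @param heat_ps,equil1_ps,ramp_ps,equil2_ps,cool_ps,equil3_ps Stage
#'   durations (ps).
#' @param save_window_ps,save_interval_ps Coordinate-averaging window and
#'   sampling interval at the end of the final equilibration (ps).
#' @param k_init,k_nonexch,k_exch Distance-restraint force constants
#'   (kcal/mol/A^2): initial, and final values for the two proton classes.
#' @param k_dihedral Dihedral restraint constant (kcal/mol/rad^2).
#' @param k_planarity Planarity restraint constant (kcal/mol/A^2).
#' @param min_gradient Minimization stop criterion on the RMS energy
#'   gradient (kcal/mol/A).
#' @param timestep_fs Integration timestep (fs).
#' @param rep_soft,rep_full Soft-sphere radius scale during the
#'   high-temperature stages and after cooling. Setting `rep_soft` below
#'   `rep_full` shrinks the repulsive radii while hot (letting chains
#'   thread past each other) and ramps them back during cooling; the
#'   default keeps full radii throughout.
#' @param scale_factor Uniform multiplier on all stage durations, in
#'   (0, 1].
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(heat_start_K = 300, heat_end_K = 1000,
                            heat_ps = 14, equil1_ps = 6, ramp_ps = 20,
                            equil2_ps = 50, cool_ps = 42, equil3_ps = 18,
                            save_window_ps = 10, save_interval_ps = 0.5,
                            k_init = 2, k_nonexch = 16, k_exch = 8,
                            k_dihedral = 50, k_planarity = 1,
                            min_gradient = 0.1, timestep_fs = 2,
                            rep_soft = 0.8, rep_full = 0.8,
                            scale_factor = 1) {
  stopifnot(heat_ps > 0, equil1_ps > 0, ramp_ps > 0, equil2_ps > 0,
            cool_ps > 0, equil3_ps > 0, save_window_ps > 0,
            save_interval_ps > 0, timestep_fs > 0,
            scale_factor > 0, scale_factor <= 1)
  structure(as.list(environment()), class = "anneal_schedule")
}

#' Stage ledger of an annealing schedule
#'
#' @param schedule An [anneal_schedule()].
#' @return Data frame with one row per dynamics stage: name, duration (ps,
#'   unscaled), temperature endpoints and distance force-constant
#'   endpoints for the two proton classes.
#' @export
schedule_stages <- function(schedule) {
  s <- schedule
  data.frame(
    stage = c("heat", "equil1", "ramp", "equil2", "cool", "equil3"),
    duration_ps = c(s$heat_ps, s$equil1_ps, s$ramp_ps, s$equil2_ps,
                    s$cool_ps, s$equil3_ps),
    T_start = c(s$heat_start_K, s$heat_end_K, s$heat_end_K, s$heat_end_K,
                s$heat_end_K, s$heat_start_K),
    T_end = c(s$heat_end_K, s$heat_end_K, s$heat_end_K, s$heat_end_K,
              s$heat_start_K, s$heat_start_K),
    k_ne_start = c(s$k_init, s$k_init, s$k_init, s$k_nonexch, s$k_nonexch,
                   s$k_nonexch),
    k_ne_end = c(s$k_init, s$k_init, s$k_nonexch, s$k_nonexch, s$k_nonexch,
                 s$k_nonexch),
    k_e_start = c(s$k_init, s$k_init, s$k_init, s$k_exch, s$k_exch, s$k_exch),
    k_e_end = c(s$k_init, s$k_init, s$k_exch, s$k_exch, s$k_exch, s$k_exch),
    rep_start = c(s$rep_soft, s$rep_soft, s$rep_soft, s$rep_soft,
                  s$rep_soft, s$rep_full),
    rep_end = c(s$rep_soft, s$rep_soft, s$rep_soft, s$rep_soft,
                s$rep_full, s$rep_full)
  )
}

#' @export
print.anneal_schedule <- function(x, ...) {
  st <- schedule_stages(x)
  cat(sprintf("annealing schedule (scale %.3g, dt %.3g fs):\n",
              x$scale_factor, x$timestep_fs))
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-7s %5.1f ps  T %4.0f->%4.0f K  k_dist %g->%g / %g->%g\n",
                st$stage[i], st$duration_ps[i], st$T_start[i], st$T_end[i],
                st$k_ne_start[i], st$k_ne_end[i], st$k_e_start[i],
                st$k_e_end[i]))
  invisible(x)
}

#' Generate the full restraint set for a topology
#'
#' Convenience bundler: hydrogen-bond restraints, chi dihedral restraints
#' and planarity units from the topology, merged with an optional NOE
#' distance-restraint table (as produced by [noe_restraints()] or
#' [read_noe_peaks()]).
#'
#' @param t A valid [qdh_topology()].
#' @param noe Optional data frame of NOE distance restraints.
#' @param tight Passed to [dihedral_restraints()].
#' @return List with elements `dist` (NOE + hydrogen bond), `dihedral`,
#'   `planarity`.
#' @export
qdh_restraints <- function(t, noe = NULL, tight = FALSE) {
  hb <- hbond_restraints(t)
  dist <- if (is.null(noe) || !nrow(noe)) hb else rbind(noe, hb)
  list(dist = dist,
       dihedral = dihedral_restraints(t, tight = tight),
       planarity = planarity_restraints(t))
}

#' Distance bounds matrix for metric-matrix embedding
#'
#' Builds symmetric lower/upper inter-atomic distance bounds: covalent 1-2
#' and 1-3 distances are fixed at their template ideals, restrained pairs
#' take their flat-bottom windows, all other pairs default to a scaled
#' van der Waals contact floor and a global upper bound. Upper bounds are
#' then triangle-smoothed (Floyd-style) and lower bounds tightened by one
#' inverse-triangle pass.
#'
#' @param conf A [conformer()] defining the atom inventory.
#' @param dist Data frame of distance restraints (NOE + hydrogen bond).
#' @param system Optional prebuilt [build_system()] output.
#' @param max_upper Default upper bound (A); defaults to 6 A per residue
#'   plus 20 A.
#' @return List of class `qdh_bounds` with `lower` and `upper` matrices.
#' @export
build_bounds <- function(conf, dist = NULL, system = NULL,
                         max_upper = NULL) {
  if (is.null(system)) system <- build_system(conf)
  n <- system$n
  if (is.null(max_upper)) max_upper <- 6 * length(unique(conf$resno)) + 20
  vdw <- system$vdw
  L <- 0.8 * outer(vdw, vdw, `+`)
  U <- matrix(max_upper, n, n)
  diag(L) <- 0; diag(U) <- 0

  bond_key <- new.env(hash = TRUE, parent = emptyenv())
  b <- system$bonds + 1L
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]; r0 <- system$bond_r0[k]
    L[i, j] <- L[j, i] <- U[i, j] <- U[j, i] <- r0
    assign(paste(min(i, j), max(i, j)), r0, envir = bond_key)
  }
  a <- system$angles + 1L
  for (k in seq_len(nrow(a))) {
    i <- a[k, 1]; j <- a[k, 2]; l <- a[k, 3]
    r1 <- get(paste(min(i, j), max(i, j)), envir = bond_key)
    r2 <- get(paste(min(j, l), max(j, l)), envir = bond_key)
    d <- sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(system$angle_th0[k]))
    L[i, l] <- L[l, i] <- U[i, l] <- U[l, i] <- d
  }
  if (!is.null(dist) && nrow(dist)) {
    ia <- atom_index(conf, dist$res_a, dist$atom_a)
    ib <- atom_index(conf, dist$res_b, dist$atom_b)
    for (k in seq_along(ia)) {
      i <- ia[k]; j <- ib[k]
      lo <- dist$target[k] - dist$minus[k]
      up <- dist$target[k] + dist$plus[k]
      U[i, j] <- U[j, i] <- min(U[i, j], up)
      L[i, j] <- L[j, i] <- max(L[i, j], lo)
    }
  }
  sm <- qdh_smooth_bounds(L, U)
  if (any(sm$upper < sm$lower - 1e-6))
    stop("degenerate bounds: smoothed upper bound fell below lower bound")
  structure(list(lower = sm$lower, upper = sm$upper), class = "qdh_bounds")
}

.embed_xyz <- function(bounds) {
  # uses the current RNG state
  n <- nrow(bounds$lower)
  D <- bounds$lower + matrix(stats::runif(n * n), n, n) *
    (bounds$upper - bounds$lower)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  diag(D) <- 0
  D2 <- D^2
  rm2 <- rowMeans(D2)
  d0 <- rm2 - sum(D2) / (2 * n^2)   # squared distances to the centroid
  G <- 0.5 * (outer(d0, rep(1, n)) + outer(rep(1, n), d0) - D2)
  e <- eigen(G, symmetric = TRUE)
  lam <- pmax(e$values[1:3], 0)
  xyz <- e$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(lam), 3)
  xyz
}

#' Metric-matrix distance-geometry embedding
#'
#' Draws one random distance matrix between the smoothed bounds (seeded),
#' double-centers its squared distances into a Gram matrix and projects
#' onto the three dominant eigenvectors. Handedness is not resolved here
#' (the embedding is defined up to reflection); [fix_chirality()] resolves
#' it downstream.
#'
#' @param bounds A [build_bounds()] result.
#' @param seed Integer seed for the distance sample.
#' @return An n x 3 coordinate matrix.
#' @export
embed_coords <- function(bounds, seed = 1) {
  if (any(bounds$upper < bounds$lower))
    stop("degenerate bounds: upper < lower")
  set.seed(seed)
  .embed_xyz(bounds)
}

#' Resolve the handedness of embedded coordinates
#'
#' Metric-matrix embedding determines a structure only up to reflection.
#' This checks the signs of the chiral (sugar-center) improper torsions
#' against their template ideals and mirrors the coordinates when the
#' majority is inverted.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param system A [build_system()] output for the same atom inventory.
#' @return Coordinate matrix with majority-correct chirality.
#' @export
fix_chirality <- function(xyz, system) {
  imp <- system$impropers + 1L
  phi0 <- system$improper_phi0
  chiral <- which(abs(abs(phi0) - pi) > 0.35 & abs(phi0) > 0.35)
  if (!length(chiral)) return(xyz)
  score <- function(x) {
    s <- 0
    for (k in chiral) {
      phi <- .vec_torsion(x[imp[k, 1], ], x[imp[k, 2], ],
                          x[imp[k, 3], ], x[imp[k, 4], ])
      if (sign(phi) == sign(phi0[k])) s <- s + 1
    }
    s
  }
  mirrored <- xyz; mirrored[, 1] <- -mirrored[, 1]
  if (score(mirrored) > score(xyz)) mirrored else xyz
}

.prochiral_pairs <- list(c("H5'", "H5''"), c("H2'", "H2''"),
                         c("OP1", "OP2"))

# Swap chemically equivalent prochiral substituents (H5'/H5'', H2'/H2'',
# OP1/OP2) wherever the swap improves the local improper agreement with the
# template; annealing can deposit these pairs in exchanged positions, which
# a gradient minimizer cannot undo.
.repair_prochiral <- function(conf, xyz, system) {
  imp <- system$impropers + 1L
  ctr_key <- paste(conf$resno[imp[, 2]], conf$atom[imp[, 2]])
  for (r in unique(conf$resno)) {
    for (pp in .prochiral_pairs) {
      i1 <- atom_index(conf, r, pp[1], strict = FALSE)
      i2 <- atom_index(conf, r, pp[2], strict = FALSE)
      if (is.na(i1) || is.na(i2)) next
      ctr <- switch(pp[1], "H5'" = "C5'", "H2'" = "C2'", "OP1" = "P")
      k <- which(ctr_key == paste(r, ctr))
      if (!length(k)) next
      dev_of <- function(x) {
        s <- 0
        for (kk in k) {
          phi <- .vec_torsion(x[imp[kk, 1], ], x[imp[kk, 2], ],
                              x[imp[kk, 3], ], x[imp[kk, 4], ])
          d <- phi - system$improper_phi0[kk]
          s <- s + abs(atan2(sin(d), cos(d)))
        }
        s
      }
      alt <- xyz
      alt[c(i1, i2), ] <- alt[c(i2, i1), ]
      if (dev_of(alt) < dev_of(xyz) - 1e-9) xyz <- alt
    }
  }
  xyz
}

.kset_default <- function(schedule = anneal_schedule()) {
  list(k_nonexch = schedule$k_nonexch, k_exch = schedule$k_exch,
       k_dihedral = schedule$k_dihedral, k_planarity = schedule$k_planarity)
}

# Violation-annealed final refinement: after the protocol minimization,
# re-minimize with stiffened distance constants, then iteratively shrink
# the windows of still-violated restraints (escalating their pull) until no
# restraint is violated beyond `threshold` or the round cap is reached.
# Structures far from satisfiable (misfolded runs) are left as-is.
.violation_polish <- function(x, conf0, sys, restraints, kset,
                              threshold = 0.2, max_rounds = 8,
                              hopeless = 40) {
  d <- restraints$dist
  if (is.null(d) || !nrow(d)) return(x)
  ia <- atom_index(conf0, d$res_a, d$atom_a)
  ib <- atom_index(conf0, d$res_b, d$atom_b)
  lo <- d$target - d$minus; up <- d$target + d$plus
  viol_of <- function(xx) {
    dd <- sqrt(rowSums((xx[ia, , drop = FALSE] - xx[ib, , drop = FALSE])^2))
    pmax(dd - up, lo - dd, 0)
  }
  ir <- index_restraints(conf0, d, restraints$dihedral,
                         restraints$planarity)
  kq <- utils::modifyList(kset, list(k_nonexch = 4 * kset$k_nonexch,
                                     k_exch = 4 * kset$k_exch))
  x <- .minimize_xyz(x, sys, ir, kq, min_gradient = 0.1,
                     max_iter = 1500)$xyz
  if (sum(viol_of(x) > threshold) > hopeless) return(x)
  for (round in seq_len(max_rounds)) {
    v <- viol_of(x)
    if (!sum(v > threshold)) break
    bad <- which(v > threshold / 4)
    d2 <- d
    d2$minus[bad] <- pmax(0.02, d$minus[bad] - (v[bad] + 0.35))
    d2$plus[bad] <- pmax(0.02, d$plus[bad] - (v[bad] + 0.35))
    ir2 <- index_restraints(conf0, d2, restraints$dihedral,
                            restraints$planarity)
    kq <- list(k_nonexch = min(512, kq$k_nonexch * 1.5),
               k_exch = min(256, kq$k_exch * 1.5),
               k_dihedral = kset$k_dihedral,
               k_planarity = kset$k_planarity)
    x <- .minimize_xyz(x, sys, ir2, kq, min_gradient = 0.2,
                       max_iter = 600)$xyz
  }
  x
}

#' Restraint energy and analytic gradient of a conformer
#'
#' Evaluates the pure restraint potential (no covalent or nonbonded
#' terms): flat-bottom quadratics on restrained distances, square-well
#' quadratics on chi dihedrals beyond their halfwidth, and the planarity
#' term (sum of squared distances of unit members from their best-fit
#' plane). The gradient is analytic and matches central finite differences
#' component-wise.
#'
#' @param conf A [conformer()].
#' @param restraints List with `dist`, `dihedral`, `planarity` (see
#'   [qdh_restraints()]).
#' @param kset Force constants: `k_nonexch`, `k_exch` (kcal/mol/A^2),
#'   `k_dihedral` (kcal/mol/rad^2), `k_planarity` (kcal/mol/A^2).
#' @return List with `energy` (kcal/mol, non-negative), `grad` (n x 3)
#'   and per-term `components`.
#' @export
restraint_energy <- function(conf, restraints, kset = .kset_default()) {
  sys <- build_system(conf)
  ir <- index_restraints(conf, restraints$dist, restraints$dihedral,
                         restraints$planarity)
  res <- qdh_energy_grad(conf_xyz(conf), sys, ir, kset$k_nonexch,
                         kset$k_exch, kset$k_dihedral, kset$k_planarity,
                         FALSE, FALSE)
  res
}

.minimize_xyz <- function(xyz, sys, ir, kset, covalent = TRUE,
                          nonbonded = TRUE, min_gradient = 0.1,
                          max_iter = 2000) {
  o <- qdh_minimize(xyz, sys, ir, kset$k_nonexch, kset$k_exch,
                    kset$k_dihedral, kset$k_planarity, covalent, nonbonded,
                    min_gradient, max_iter, 10L)
  list(xyz = o$xyz, energy = o$energy, converged = o$converged,
       iterations = o$iterations)
}

#' Energy minimization of a conformer
#'
#' Gradient-based (L-BFGS) minimization of the full potential (covalent +
#' soft-sphere nonbonded + restraints) until the RMS energy gradient falls
#' below `min_gradient` (0.1 kcal/mol by default) or the iteration cap is
#' reached, in which case a warning status is recorded (attribute
#' `converged`), not an error. Energy is non-increasing across accepted
#' steps.
#'
#' @inheritParams restraint_energy
#' @param min_gradient RMS-gradient stop criterion.
#' @param max_iter Iteration cap.
#' @param system Optional prebuilt system.
#' @return The minimized [conformer()] with attributes `energy`,
#'   `converged` and `iterations`.
#' @export
minimize_conformer <- function(conf, restraints = NULL,
                               kset = .kset_default(), min_gradient = 0.1,
                               max_iter = 2000, system = NULL) {
  if (is.null(system)) system <- build_system(conf)
  ir <- index_restraints(conf, restraints$dist, restraints$dihedral,
                         restraints$planarity)
  m <- .minimize_xyz(conf_xyz(conf), system, ir, kset,
                     min_gradient = min_gradient, max_iter = max_iter)
  out <- set_conf_xyz(conf, m$xyz)
  attr(out, "energy") <- m$energy
  attr(out, "converged") <- m$converged
  attr(out, "iterations") <- m$iterations
  out
}

.init_velocities <- function(n, mass, temp_K) {
  v <- matrix(stats::rnorm(n * 3), n, 3)
  v * sqrt(.KB * temp_K / mass)
}

.run_stages <- function(xyz, sys, ir, schedule, seed) {
  set.seed(seed)
  dt <- schedule$timestep_fs
  sc <- schedule$scale_factor
  st <- schedule_stages(schedule)
  vel <- .init_velocities(sys$n, sys$mass, schedule$heat_start_K)
  saved_sum <- NULL; n_saved <- 0
  for (i in seq_len(nrow(st))) {
    nsteps <- max(1L, as.integer(round(st$duration_ps[i] * 1000 * sc / dt)))
    save_every <- 0L; save_start <- 0L
    if (st$stage[i] == "equil3") {
      save_every <- max(1L, as.integer(round(
        schedule$save_interval_ps * 1000 * sc / dt)))
      win_steps <- max(save_every, as.integer(round(
        schedule$save_window_ps * 1000 * sc / dt)))
      save_start <- max(0L, nsteps - win_steps)
    }
    res <- qdh_md_stage(xyz, vel, sys, ir, nsteps, dt,
                        st$T_start[i], st$T_end[i],
                        st$k_ne_start[i], st$k_ne_end[i],
                        st$k_e_start[i], st$k_e_end[i],
                        schedule$k_dihedral, schedule$k_planarity,
                        rescale_every = 5L, nb_every = 10L,
                        save_every = save_every, save_start = save_start,
                        rep_start = st$rep_start[i], rep_end = st$rep_end[i])
    if (!isTRUE(res$ok))
      stop(sprintf("dynamics diverged (non-finite coordinates) in stage '%s' at step %d",
                   st$stage[i], res$step))
    xyz <- res$xyz; vel <- res$vel
    if (st$stage[i] == "equil3" && res$n_saved > 0) {
      saved_sum <- res$saved_sum; n_saved <- res$n_saved
    }
  }
  avg <- if (n_saved > 0) saved_sum / n_saved else xyz
  list(final = xyz, averaged = avg, n_saved = n_saved)
}

#' Restrained simulated-annealing refinement of one conformer
#'
#' Runs velocity-Verlet dynamics with a velocity-rescaling thermostat
#' through the staged protocol of the [anneal_schedule()]: heat, first
#' equilibration, force-constant ramp, high-temperature equilibration,
#' cooling and final equilibration, with coordinates saved at fixed
#' intervals over the final window and averaged. Dihedral and planarity
#' constants are held throughout. The returned conformer holds the
#' averaged coordinates (re-minimize with [minimize_conformer()] before
#' reporting).
#'
#' @inheritParams restraint_energy
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed (initial velocities).
#' @param system Optional prebuilt system.
#' @return The refined [conformer()], with attribute `n_saved` (number of
#'   averaged frames).
#' @export
sa_anneal <- function(conf, restraints, schedule = anneal_schedule(),
                      seed = 1, system = NULL) {
  if (is.null(system)) system <- build_system(conf)
  ir <- index_restraints(conf, restraints$dist, restraints$dihedral,
                         restraints$planarity)
  out <- .run_stages(conf_xyz(conf), system, ir, schedule, seed)
  res <- set_conf_xyz(conf, out$averaged)
  attr(res, "n_saved") <- out$n_saved
  res
}

#' Structure-calculation pipeline: embed, anneal, minimize, select
#'
#' Runs `n_structures` independent structure calculations (seeded as
#' `seed + run index`): metric-matrix embedding of the restraint-derived
#' bounds, chirality fix, restraint-guided regularization, simulated
#' annealing through the schedule, and final minimization. All successful
#' conformers are returned with their energies; the `n_select`
#' lowest-energy structures are flagged. A failing run is excluded and
#' logged; an error is raised only if every run fails.
#'
#' @param topology A valid [qdh_topology()].
#' @param restraints List with `dist`, `dihedral`, `planarity` (see
#'   [qdh_restraints()]); defaults to the topology-derived set.
#' @param n_structures Number of independent runs.
#' @param n_select Number of lowest-energy structures to flag.
#' @param schedule An [anneal_schedule()].
#' @param seed Base integer seed.
#' @param verbose Print per-run progress.
#' @return A `qdh_ensemble`: list with `conformers`, `energies`, `flagged`
#'   (indices of the selected structures) and `failed` (run indices).
#' @export
run_pipeline <- function(topology, restraints = NULL, n_structures = 100,
                         n_select = 10, schedule = anneal_schedule(),
                         seed = 1, verbose = FALSE) {
  stopifnot(n_select <= n_structures)
  msgs <- validate_topology(topology)
  if (length(msgs))
    stop("invalid topology: ", paste(msgs, collapse = "; "))
  if (is.null(restraints)) restraints <- qdh_restraints(topology)
  conf0 <- build_chain(topology$sequence)
  sys <- build_system(conf0)
  ir <- index_restraints(conf0, restraints$dist, restraints$dihedral,
                         restraints$planarity)
  bounds <- build_bounds(conf0, restraints$dist, system = sys)
  kset <- .kset_default(schedule)
  conformers <- list(); energies <- numeric(); failed <- integer()
  for (run in seq_len(n_structures)) {
    res <- tryCatch({
      run_seed <- seed + run
      xyz <- embed_coords(bounds, seed = run_seed)
      xyz <- fix_chirality(xyz, sys)
      reg <- .minimize_xyz(xyz, sys, ir,
                           list(k_nonexch = schedule$k_init,
                                k_exch = schedule$k_init,
                                k_dihedral = kset$k_dihedral,
                                k_planarity = kset$k_planarity),
                           nonbonded = FALSE, min_gradient = 0.5,
                           max_iter = 500)
      ann <- .run_stages(reg$xyz, sys, ir, schedule, run_seed)
      repaired <- .repair_prochiral(conf0, ann$averaged, sys)
      fin <- .minimize_xyz(repaired, sys, ir, kset,
                           min_gradient = schedule$min_gradient,
                           max_iter = 1500)
      x <- .violation_polish(fin$xyz, conf0, sys, restraints, kset)
      energy <- qdh_energy_grad(x, sys, ir, kset$k_nonexch, kset$k_exch,
                                kset$k_dihedral, kset$k_planarity,
                                TRUE, TRUE)$energy
      conf <- set_conf_xyz(conf0, x)
      attr(conf, "energy") <- energy
      attr(conf, "converged") <- fin$converged
      conf
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, run)
      if (verbose) message(sprintf("run %d failed: %s", run,
                                   conditionMessage(res)))
      next
    }
    conformers[[length(conformers) + 1]] <- res
    energies <- c(energies, attr(res, "energy"))
    if (verbose) message(sprintf("run %d: energy %.2f kcal/mol", run,
                                 attr(res, "energy")))
  }
  if (!length(conformers))
    stop("all structure-calculation runs failed")
  flagged <- order(energies)[seq_len(min(n_select, length(energies)))]
  structure(list(conformers = conformers, energies = energies,
                 flagged = sort(flagged), failed = failed,
                 topology = topology$name),
            class = "qdh_ensemble")
}

#' @export
print.qdh_ensemble <- function(x, ...) {
  cat(sprintf("ensemble of %d conformers (%d flagged, %d failed runs)\n",
              length(x$conformers), length(x$flagged), length(x$failed)))
  cat(sprintf("  energies: %.2f .. %.2f kcal/mol\n",
              min(x$energies), max(x$energies)))
  invisible(x)
}
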