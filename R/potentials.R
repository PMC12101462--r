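#' Evaluate a potential on a configuration
#'
#' The universal contract every potential honours: given an [atoms]
#' object, return the total energy (kJ/mol), the forces (kJ/mol/A, N x 3)
#' and, where defined, the 3 x 3 virial tensor W = sum over pairs of
#' r_ij (x) F_ij (kJ/mol).  The instantaneous pressure used throughout
#' the package is P = (N_dof kB T_inst / 3 + tr(W) / 3) / V.
#'
#' Everything downstream (relaxation, phonons, MD, PIMD, the sampler) is
#' generic over this contract, so user potentials plug in by providing an
#' `evaluate` method or via [as_potential].
#'
#' @param potential a potential object.
#' @param config an [atoms] object.
#' @param cache optional pair-list cache from a previous call at nearby
#'   positions; pass the returned `cache` element back in tight loops.
#' @return list with `energy`, `forces`, `virial` (or NULL), `cache`.
#' @export
evaluate <- function(potential, config, cache = NULL) {
  UseMethod("evaluate")
}

#' Wrap a plain function as a potential
#'
#' @param fun function(config) returning list(energy, forces, virial).
#' @param name label for reports.
#' @return a potential object of class `potential_function`.
#' @export
as_potential <- function(fun, name = "user") {
  structure(list(fun = fun, name = name),
            class = c("potential_function", "potential"))
}

#' @export
evaluate.potential_function <- function(potential, config, cache = NULL) {
  out <- potential$fun(config)
  if (!all(c("energy", "forces") %in% names(out)))
    stop("user potential must return energy and forces")
  out$virial <- out$virial %||% NULL
  out$cache <- cache
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Harmonic crystal: pair springs on a reference structure.  Exactly
# quadratic in the displacements, hence an analytic oracle for phonon and
# path-integral results.

#' Harmonic crystal potential from pair springs
#'
#' Builds harmonic springs between every pair of atoms (periodic images
#' included) closer than `cutoff` in the reference structure.  Each
#' spring resists bond stretching with constant k and relative motion
#' perpendicular to the bond with constant `transverse * k`, i.e.
#' E = 1/2 sum_b [ k_b p^2 + kt_b (|du|^2 - p^2) ] with
#' p = (u_j - u_i) . d_hat and u = r - r_ref.  The force-constant matrix
#' automatically satisfies the acoustic sum rule and is positive
#' semidefinite with exactly three zero (translation) modes; the
#' transverse term (absent in a purely central network) removes the
#' soft rotation-like modes a projection-only spring system would have.
#'
#' @param reference periodic or gas-phase [atoms] object; the minimum.
#' @param cutoff spring cutoff (Angstrom).
#' @param k spring constant (kJ/mol/A^2), or a function(d) of the
#'   reference pair distance returning per-pair constants.
#' @param transverse perpendicular stiffness as a fraction of k.
#' @return potential of class `harmonic_crystal`.
#' @export
make_harmonic_crystal <- function(reference, cutoff, k, transverse = 0.3) {
  pl <- pair_list(reference, cutoff)
  if (length(pl$i) == 0) stop("no pairs within cutoff")
  dvec <- pair_vectors(pl, reference$positions)
  d <- sqrt(rowSums(dvec^2))
  uhat <- dvec / d
  kb <- if (is.function(k)) k(d) else rep(k, length(d))
  structure(list(reference = reference, pairs = pl, uhat = uhat,
                 kb = kb, kt = transverse * kb, cutoff = cutoff,
                 name = "harmonic_crystal"),
            class = c("harmonic_crystal", "potential"))
}

#' @export
evaluate.harmonic_crystal <- function(potential, config, cache = NULL) {
  if (n_atoms(config) != n_atoms(potential$reference))
    stop("atom count does not match the harmonic reference")
  u <- config$positions - potential$reference$positions
  pl <- potential$pairs
  du <- u[pl$j, , drop = FALSE] - u[pl$i, , drop = FALSE]
  proj <- rowSums(du * potential$uhat)           # bond elongation
  energy <- 0.5 * sum(potential$kb * proj^2) +
    0.5 * sum(potential$kt * (rowSums(du^2) - proj^2))
  # force on i: k p d_hat + kt (du - p d_hat)
  fpair <- (potential$kb - potential$kt) * proj * potential$uhat +
    potential$kt * du
  forces <- accumulate_pair_forces(n_atoms(config), pl, fpair)
  # the springs reference absolute positions, so the strain derivative is
  # -dE/deps_ab = sum_i F_ia x_ib (translation invariant because sum F = 0)
  virial <- if (config$pbc) crossprod(forces, config$positions) else NULL
  list(energy = energy, forces = forces, virial = virial, cache = cache)
}

#' Force-constant matrix of a harmonic crystal potential
#'
#' Assembles the exact 3N x 3N second-derivative matrix Phi of the spring
#' network (kJ/mol/A^2), the analytic reference for the small-displacement
#' method.
#'
#' @param potential a `harmonic_crystal` potential.
#' @return symmetric 3N x 3N matrix.
#' @export
harmonic_phi_matrix <- function(potential) {
  n <- n_atoms(potential$reference)
  phi <- matrix(0, 3 * n, 3 * n)
  pl <- potential$pairs
  for (b in seq_along(pl$i)) {
    blk <- (potential$kb[b] - potential$kt[b]) *
      tcrossprod(potential$uhat[b, ]) + potential$kt[b] * diag(3)
    ii <- (pl$i[b] - 1) * 3 + 1:3
    jj <- (pl$j[b] - 1) * 3 + 1:3
    phi[ii, ii] <- phi[ii, ii] + blk
    phi[jj, jj] <- phi[jj, jj] + blk
    phi[ii, jj] <- phi[ii, jj] - blk
    phi[jj, ii] <- phi[jj, ii] - blk
  }
  phi
}

# ---------------------------------------------------------------------------
# Lennard-Jones with energy-shifted truncation.

#' Lennard-Jones potential
#'
#' 4 eps [(sigma/r)^12 - (sigma/r)^6], truncated at `cutoff` and shifted
#' so the energy is continuous there; no tail correction.  Periodic
#' systems interact with all images within the cutoff.
#'
#' @param epsilon well depth (kJ/mol).
#' @param sigma LJ diameter (Angstrom).
#' @param cutoff truncation radius (Angstrom), default 3 sigma.
#' @param skin pair-list margin (Angstrom) for reuse across MD steps.
#' @return potential of class `lj`.
#' @export
potential_lj <- function(epsilon = 1, sigma = 3, cutoff = 3 * sigma,
                         skin = 0.6) {
  structure(list(epsilon = epsilon, sigma = sigma, cutoff = cutoff,
                 skin = skin,
                 eshift = 4 * epsilon * ((sigma / cutoff)^12 -
                                           (sigma / cutoff)^6),
                 name = "lj"),
            class = c("lj", "potential"))
}

lj_pair_terms <- function(potential, r2) {
  s2 <- potential$sigma^2 / r2
  s6 <- s2^3
  e <- 4 * potential$epsilon * (s6^2 - s6) - potential$eshift
  # dphi/dr / r  (so force on i = -(dphi/dr/r) * (-pv) ... assembled below)
  dphi_over_r <- 24 * potential$epsilon * (s6 - 2 * s6^2) / r2
  list(e = e, dphi_over_r = dphi_over_r)
}

#' @export
evaluate.lj <- function(potential, config, cache = NULL) {
  pos <- config$positions
  if (is.null(cache) ||
      pair_list_stale(cache, pos, potential$cutoff, potential$skin))
    cache <- pair_list(config, potential$cutoff, potential$skin)
  pv <- pair_vectors(cache, pos)
  r2 <- rowSums(pv^2)
  keep <- r2 < potential$cutoff^2
  pl <- list(i = cache$i[keep], j = cache$j[keep],
             shift = cache$shift[keep, , drop = FALSE])
  pv <- pv[keep, , drop = FALSE]
  r2 <- r2[keep]
  t <- lj_pair_terms(potential, r2)
  # force on atom i from the pair: F_i = phi'(r) * pv/r = (phi'/r) * pv
  fpair <- t$dphi_over_r * pv
  forces <- accumulate_pair_forces(nrow(pos), pl, fpair)
  # virial W = sum r_ij (x) F_ij with r_ij = -pv, F_ij = fpair
  virial <- -crossprod(pv, fpair)
  list(energy = sum(t$e), forces = forces, virial = virial, cache = cache)
}

# ---------------------------------------------------------------------------
# Toy molecular crystal: harmonic intramolecular terms + intermolecular LJ.

#' Toy molecular-crystal potential
#'
#' A minimal emulation of a hydrogen-bonded / dispersion-bound organic
#' crystal: molecules held together by harmonic bonds (and optionally
#' harmonic angles), interacting between molecules through truncated,
#' shifted Lennard-Jones sites on every atom.
#'
#' @param topo a [topology] giving molecule membership and bond/angle lists.
#' @param bond_k,bond_r0 spring constant (kJ/mol/A^2) and rest length
#'   (Angstrom) per bond (recycled).
#' @param angle_k,angle_theta0 angle constant (kJ/mol/rad^2) and rest
#'   angle (rad) per angle triplet (recycled); only used if the topology
#'   has angles.
#' @param epsilon,sigma,cutoff intermolecular LJ parameters.
#' @param skin pair-list margin.
#' @return potential of class `toy_molecular_crystal`.
#' @export
potential_toy_molecular_crystal <- function(topo, bond_k = 2000,
                                            bond_r0 = 1.1,
                                            angle_k = 200,
                                            angle_theta0 = 1.91,
                                            epsilon = 1, sigma = 3,
                                            cutoff = 3 * sigma,
                                            skin = 0.6) {
  nb <- if (is.null(topo$bonds)) 0 else nrow(topo$bonds)
  structure(list(topo = topo,
                 bond_k = rep_len(bond_k, nb),
                 bond_r0 = rep_len(bond_r0, nb),
                 angle_k = angle_k, angle_theta0 = angle_theta0,
                 lj = potential_lj(epsilon, sigma, cutoff, skin),
                 name = "toy_molecular_crystal"),
            class = c("toy_molecular_crystal", "potential"))
}

#' @export
evaluate.toy_molecular_crystal <- function(potential, config, cache = NULL) {
  topo <- potential$topo
  if (length(topo$molecule) != n_atoms(config))
    stop("topology does not match configuration atom count")
  pos <- config$positions
  n <- nrow(pos)
  lj <- potential$lj
  if (is.null(cache) || pair_list_stale(cache, pos, lj$cutoff, lj$skin)) {
    cache <- pair_list(config, lj$cutoff, lj$skin)
    # drop intramolecular pairs once at build time (same molecule, zero shift)
    intra <- topo$molecule[cache$i] == topo$molecule[cache$j] &
      rowSums(cache$shift^2) == 0
    cache$i <- cache$i[!intra]; cache$j <- cache$j[!intra]
    cache$shift <- cache$shift[!intra, , drop = FALSE]
  }
  pv <- pair_vectors(cache, pos)
  r2 <- rowSums(pv^2)
  keep <- r2 < lj$cutoff^2
  pl <- list(i = cache$i[keep], j = cache$j[keep],
             shift = cache$shift[keep, , drop = FALSE])
  pv <- pv[keep, , drop = FALSE]
  t <- lj_pair_terms(lj, r2[keep])
  fpair <- t$dphi_over_r * pv
  forces <- accumulate_pair_forces(n, pl, fpair)
  energy <- sum(t$e)
  virial <- -crossprod(pv, fpair)

  # harmonic bonds (minimum image so cells can shrink in NPT)
  if (!is.null(topo$bonds) && nrow(topo$bonds)) {
    b <- topo$bonds
    dr <- minimum_image(pos[b[, 2], , drop = FALSE] -
                          pos[b[, 1], , drop = FALSE],
                        if (config$pbc) config$cell else NULL)
    d <- sqrt(rowSums(dr^2))
    stretch <- d - potential$bond_r0
    energy <- energy + 0.5 * sum(potential$bond_k * stretch^2)
    fb <- (potential$bond_k * stretch / d) * dr   # force on atom b[,1]
    for (dd in 1:3) {
      forces[, dd] <- forces[, dd] +
        tabulate_sum(b[, 1], fb[, dd], n) - tabulate_sum(b[, 2], fb[, dd], n)
    }
    virial <- virial - crossprod(dr, fb)
  }

  # harmonic angles
  if (!is.null(topo$angles) && nrow(topo$angles)) {
    for (r in seq_len(nrow(topo$angles))) {
      tri <- topo$angles[r, ]
      cellq <- if (config$pbc) config$cell else NULL
      rij <- as.numeric(minimum_image(pos[tri[1], ] - pos[tri[2], ], cellq))
      rkj <- as.numeric(minimum_image(pos[tri[3], ] - pos[tri[2], ], cellq))
      nij <- sqrt(sum(rij^2)); nkj <- sqrt(sum(rkj^2))
      cth <- sum(rij * rkj) / (nij * nkj)
      cth <- min(1 - 1e-12, max(-1 + 1e-12, cth))
      th <- acos(cth)
      dth <- th - potential$angle_theta0
      energy <- energy + 0.5 * potential$angle_k * dth^2
      # standard angle force: dE/dtheta times dtheta/dr
      sth <- sqrt(1 - cth^2)
      dEdth <- potential$angle_k * dth
      fi <- dEdth / (nij * sth) * (rkj / nkj - cth * rij / nij)
      fk <- dEdth / (nkj * sth) * (rij / nij - cth * rkj / nkj)
      forces[tri[1], ] <- forces[tri[1], ] + fi
      forces[tri[3], ] <- forces[tri[3], ] + fk
      forces[tri[2], ] <- forces[tri[2], ] - fi - fk
      virial <- virial - outer(rij, fi) - outer(rkj, fk)
    }
  }
  list(energy = energy, forces = forces,
       virial = if (config$pbc) virial else NULL, cache = cache)
}

# ---------------------------------------------------------------------------
# Double-well hydrogen-bond toy (O - H - O along x).

#' Double-well hydrogen-bond potential
#'
#' A three-atom donor-proton-acceptor model (O, H, O along the x axis)
#' with a quartic double well in the proton-transfer coordinate
#' s = x_H - (x_O1 + x_O3)/2, a harmonic restraint on the donor-acceptor
#' separation R = x_O3 - x_O1, and a coupling s^2 (R - R0) that shortens
#' the O-O distance when the proton localises in either well:
#'
#'   V = barrier * ((s/s0)^2 - 1)^2 + coupling * s^2 (R - R0)
#'       + k_oo/2 (R - R0)^2 + transverse and centre-of-mass tethers.
#'
#' With a light proton the ground state delocalises over the barrier
#' (small <s^2>) while the heavier deuteron localises in the wells
#' (larger <s^2>), so the coupling term produces a longer O-O distance
#' for H than for D - the conventional Ubbelohde effect.  The model is
#' exactly solvable by 2-dof grid diagonalisation (see
#' [hbond_oracle_thermal_oo]).
#'
#' The default parameters (barrier 6 kJ/mol, wells 0.6 A apart, O-O
#' stiffness 100 kJ/mol/A^2, coupling 270 kJ/mol/A^3) put the proton
#' zero-point energy just above the barrier for H and just below it for
#' D, and give a donor-acceptor elongation of ~0.03 A for the light
#' isotope at 300 K that a 32-bead simulation of a few tens of ps can
#' resolve against its own statistical error.
#'
#' @param barrier well-to-barrier height (kJ/mol).
#' @param well_sep distance between the two well minima (Angstrom); the
#'   minima sit at s = +/- well_sep/2.
#' @param k_oo O-O restraint stiffness (kJ/mol/A^2).
#' @param coupling proton-localisation / O-O coupling (kJ/mol/A^3).
#' @param r0 rest O-O separation (Angstrom).
#' @param k_t transverse (y, z) tether stiffness (kJ/mol/A^2).
#' @param k_com tether on the x centre of mass (kJ/mol/A^2).
#' @return potential of class `double_well_hbond`.
#' @export
potential_double_well_hbond <- function(barrier = 6, well_sep = 0.6,
                                        k_oo = 100, coupling = 270,
                                        r0 = 2.5, k_t = 200, k_com = 50) {
  structure(list(barrier = barrier, s0 = well_sep / 2, k_oo = k_oo,
                 coupling = coupling, r0 = r0, k_t = k_t, k_com = k_com,
                 name = "double_well_hbond"),
            class = c("double_well_hbond", "potential"))
}

# internal potential on the two collective coordinates (s, R)
hbond_vsr <- function(pot, s, R) {
  pot$barrier * ((s / pot$s0)^2 - 1)^2 +
    pot$coupling * s^2 * (R - pot$r0) +
    0.5 * pot$k_oo * (R - pot$r0)^2
}

#' @export
evaluate.double_well_hbond <- function(potential, config, cache = NULL) {
  if (n_atoms(config) != 3)
    stop("double-well H-bond potential expects exactly 3 atoms (O, H, O)")
  if (config$pbc) stop("double-well H-bond model is gas phase only")
  p <- config$positions
  m <- config$masses
  x <- p[, 1]
  s <- x[2] - (x[1] + x[3]) / 2
  R <- x[3] - x[1]
  pot <- potential
  dVds <- 4 * pot$barrier * s * (s^2 / pot$s0^2 - 1) / pot$s0^2 +
    2 * pot$coupling * s * (R - pot$r0)
  dVdR <- pot$coupling * s^2 + pot$k_oo * (R - pot$r0)
  energy <- hbond_vsr(pot, s, R)
  forces <- matrix(0, 3, 3)
  forces[1, 1] <- -(-0.5 * dVds - dVdR)
  forces[2, 1] <- -dVds
  forces[3, 1] <- -(-0.5 * dVds + dVdR)
  # transverse tethers
  energy <- energy + 0.5 * pot$k_t * sum(p[, 2:3]^2)
  forces[, 2:3] <- forces[, 2:3] - pot$k_t * p[, 2:3]
  # x centre-of-mass tether
  xcom <- sum(m * x) / sum(m)
  energy <- energy + 0.5 * pot$k_com * xcom^2
  forces[, 1] <- forces[, 1] - pot$k_com * xcom * m / sum(m)
  list(energy = energy, forces = forces, virial = NULL, cache = cache)
}

# ---------------------------------------------------------------------------
# Consistency diagnostics.

#' Check analytic forces against central differences
#'
#' @param potential potential object.
#' @param config configuration to probe.
#' @param h finite-difference step (Angstrom), in (1e-6, 1e-2).
#' @return maximum over atoms and components of
#'   |F_analytic - F_numeric| / scale, scale = max(1, max |F_numeric|).
#' @export
check_force_consistency <- function(potential, config, h = 1e-4) {
  stopifnot(h > 1e-6, h < 1e-2)
  ref <- evaluate(potential, config)
  n <- n_atoms(config)
  fnum <- matrix(0, n, 3)
  for (a in seq_len(n)) for (d in 1:3) {
    cp <- config; cp$positions[a, d] <- cp$positions[a, d] + h
    cm <- config; cm$positions[a, d] <- cm$positions[a, d] - h
    fnum[a, d] <- -(evaluate(potential, cp)$energy -
                      evaluate(potential, cm)$energy) / (2 * h)
  }
  scale <- max(1, max(abs(fnum)))
  max(abs(ref$forces - fnum)) / scale
}

#' Check the virial against a numerical strain derivative
#'
#' Applies symmetric strains eps to positions and cell, r -> (1 + eps) r,
#' and compares -dE/deps with the analytic virial tensor.
#'
#' @param potential potential object (must supply a virial).
#' @param config periodic configuration.
#' @param h strain step.
#' @return max relative deviation over tensor components,
#'   |W - W_num| / max(1, max |W_num|).
#' @export
check_virial_consistency <- function(potential, config, h = 1e-6) {
  ref <- evaluate(potential, config)
  if (is.null(ref$virial)) stop("potential supplies no virial")
  wnum <- matrix(0, 3, 3)
  strain_energy <- function(eps) {
    cfg <- config
    def <- diag(3) + eps
    cfg$positions <- config$positions %*% def
    cfg$cell <- config$cell %*% def
    evaluate(potential, cfg)$energy
  }
  for (a in 1:3) for (b in a:3) {
    eps <- matrix(0, 3, 3)
    eps[a, b] <- eps[a, b] + h / 2
    eps[b, a] <- eps[b, a] + h / 2
    dE <- (strain_energy(eps) - strain_energy(-eps)) / (2 * h)
    wnum[a, b] <- wnum[b, a] <- -dE
  }
  wsym <- (ref$virial + t(ref$virial)) / 2
  max(abs(wsym - wnum)) / max(1, max(abs(wnum)))
}
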