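#' Force constants by the small-displacement method
#'
#' Central finite differences of the analytic forces: each atom is
#' displaced by +/- `displacement` along each Cartesian axis and the
#' force response of all atoms gives one column of the 3N x 3N
#' force-constant matrix Phi.  Phi is then symmetrised and the acoustic
#' sum rule is enforced on the diagonal 3 x 3 blocks, so that uniform
#' translations cost exactly nothing.
#'
#' @param potential potential object.
#' @param config configuration at (or very near) a minimum.
#' @param displacement finite-displacement amplitude (Angstrom),
#'   default 0.01.
#' @param force_tol largest residual force accepted before the
#'   quadratic expansion is considered meaningless (kJ/mol/A).
#' @return symmetric 3N x 3N matrix (kJ/mol/A^2); atom a, axis d maps to
#'   row/column 3(a-1)+d.
#' @export
compute_force_constants <- function(potential, config, displacement = 0.01,
                                    force_tol = 1e-3) {
  stopifnot(displacement > 0)
  ref <- evaluate(potential, config)
  if (max(abs(ref$forces)) > force_tol)
    stop("not at minimum: residual force ",
         format(max(abs(ref$forces))), " exceeds ", force_tol)
  n <- n_atoms(config)
  phi <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) for (d in 1:3) {
    cp <- config; cp$positions[a, d] <- cp$positions[a, d] + displacement
    cm <- config; cm$positions[a, d] <- cm$positions[a, d] - displacement
    dF <- evaluate(potential, cp)$forces - evaluate(potential, cm)$forces
    phi[, 3 * (a - 1) + d] <- -as.vector(t(dF)) / (2 * displacement)
  }
  phi <- (phi + t(phi)) / 2
  enforce_acoustic_sum_rule(phi, n)
}

# diagonal-block correction: Phi(i,i) <- -sum_{j != i} Phi(i,j)
enforce_acoustic_sum_rule <- function(phi, n) {
  for (a in seq_len(n)) {
    ii <- 3 * (a - 1) + 1:3
    blk <- matrix(0, 3, 3)
    for (b in seq_len(n)) {
      if (b == a) next
      blk <- blk + phi[ii, 3 * (b - 1) + 1:3]
    }
    phi[ii, ii] <- -blk
  }
  phi
}

#' Phonon spectrum on a q-point grid
#'
#' Builds the dynamical matrix at each q point from supercell force
#' constants and diagonalises it.  The supercell must come from
#' [build_supercell] so that the mapping of every atom to (unit-cell
#' atom, lattice translation) is available.  Force constants whose range
#' exceeds the supercell are folded, as usual for the small-displacement
#' method, so grids should be converged by enlarging the supercell.
#'
#' Frequencies are angular, rad/ps; modes with omega^2 < -omega_tol^2
#' are stored as negative numbers (imaginary modes) and are never
#' silently dropped.
#'
#' @param phi supercell force-constant matrix from
#'   [compute_force_constants].
#' @param supercell the supercell `atoms` object (with mapping info).
#' @param qpoints matrix (nq x 3) of fractional q vectors of the unit
#'   cell, or the result of [monkhorst_pack].
#' @param weights q-point weights, summing to 1 (default uniform).
#' @param n_molecules molecules per unit cell (for per-molecule
#'   energies).
#' @return object of class `phonon_spectrum`: frequencies (nq x 3Nb),
#'   qpoints, weights, volume per molecule.
#' @export
phonon_spectrum <- function(phi, supercell, qpoints,
                            weights = NULL, n_molecules = 1) {
  map <- supercell$info$unit_cell_atoms
  trans <- supercell$info$lattice_translations
  if (is.null(map) || is.null(trans))
    stop("supercell must carry the build_supercell mapping info")
  qpoints <- matrix(qpoints, ncol = 3)
  nq <- nrow(qpoints)
  if (is.null(weights)) weights <- rep(1 / nq, nq)
  if (abs(sum(weights) - 1) > 1e-10) stop("q weights must sum to 1")
  nb <- max(map)                        # atoms in the unit cell
  masses_b <- supercell$masses[seq_len(nb)]
  first_cell <- which(rowSums(abs(trans)) == 0)[seq_len(nb)]
  freq <- matrix(0, nq, 3 * nb)
  for (iq in seq_len(nq)) {
    q <- qpoints[iq, ]
    D <- matrix(0 + 0i, 3 * nb, 3 * nb)
    phase <- exp(2i * pi * as.numeric(trans %*% q))
    for (k in seq_len(nb)) {
      rows <- 3 * (first_cell[k] - 1) + 1:3
      drows <- 3 * (k - 1) + 1:3
      for (Jat in seq_along(map)) {
        kp <- map[Jat]
        cols <- 3 * (Jat - 1) + 1:3
        dcols <- 3 * (kp - 1) + 1:3
        D[drows, dcols] <- D[drows, dcols] +
          phi[rows, cols] * phase[Jat] /
          sqrt(masses_b[k] * masses_b[kp])
      }
    }
    ev <- eigen((D + Conj(t(D))) / 2, symmetric = TRUE, only.values = TRUE)
    lam <- rev(ev$values) * units_xt$mass_freq2   # ascending, rad^2/ps^2
    freq[iq, ] <- sign(lam) * sqrt(abs(lam))
  }
  structure(list(frequencies = freq, qpoints = qpoints, weights = weights,
                 n_molecules = n_molecules,
                 volume_per_molecule = det(supercell$cell) /
                   ((length(map) / nb) * n_molecules)),
            class = "phonon_spectrum")
}

#' Uniform Monkhorst-Pack-style q grid including Gamma
#'
#' @param n integer vector (n1, n2, n3) of grid divisions.
#' @return list with `qpoints` (fractional) and uniform `weights`.
#' @export
monkhorst_pack <- function(n) {
  n <- rep_len(as.integer(n), 3)
  g <- expand.grid(q1 = (0:(n[1] - 1)) / n[1],
                   q2 = (0:(n[2] - 1)) / n[2],
                   q3 = (0:(n[3] - 1)) / n[3])
  list(qpoints = as.matrix(g), weights = rep(1 / prod(n), prod(n)))
}

#' Quantum-harmonic internal energy per mode
#'
#' hbar w / 2 + hbar w / (exp(hbar w / kB T) - 1) per mode, the scalar
#' building block of all quasi-harmonic energies; modes with |omega|
#' below `omega_tol` (acoustic at Gamma) contribute zero.
#'
#' @param omega angular frequencies (rad/ps); vectorised.
#' @param T temperature (K), >= 0.
#' @param omega_tol acoustic tolerance (rad/ps).
#' @return per-mode energies (kJ/mol).
#' @export
harmonic_mode_energy <- function(omega, T, omega_tol = 1e-4) {
  e <- numeric(length(omega))
  live <- omega > omega_tol
  hw <- units_xt$hbar * omega[live]
  e[live] <- hw / 2
  if (T > 0) {
    x <- hw / (units_xt$kB * T)
    bose <- ifelse(x > 500, 0, hw / expm1(x))
    e[live] <- e[live] + bose
  }
  e
}

#' Quasi-harmonic vibrational energy of the solid
#'
#' Per-molecule quantum-harmonic internal energy: the weighted q-sum over
#' all phonon branches of hbar w/2 + hbar w/(exp(hbar w/kB T)-1), divided
#' by the number of molecules in the unit cell.  The three acoustic
#' modes at Gamma (|w| below tolerance) contribute zero; imaginary modes
#' above tolerance are a hard error, because the quasi-harmonic
#' expressions presume a dynamically stable crystal.
#'
#' @param spectrum a `phonon_spectrum`.
#' @param T temperature (K), >= 0.
#' @param omega_tol acoustic/imaginary tolerance (rad/ps).
#' @return vibrational energy in kJ/mol per molecule.
#' @export
qha_vib_energy_solid <- function(spectrum, T, omega_tol = 1e-4) {
  stopifnot(T >= 0)
  bad <- which(spectrum$frequencies < -omega_tol, arr.ind = TRUE)
  if (nrow(bad))
    stop("imaginary modes present at (q, branch): ",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
  e_q <- vapply(seq_len(nrow(spectrum$frequencies)), function(iq)
    sum(harmonic_mode_energy(spectrum$frequencies[iq, ], T, omega_tol)),
    0)
  sum(spectrum$weights * e_q) / spectrum$n_molecules
}

#' Vibrational frequencies of an isolated molecule
#'
#' Numerical mass-weighted Hessian with rigid translations (3) and
#' rotations (3, or 2 for a linear molecule) projected out before
#' diagonalisation.  The null-space dimension found in the raw Hessian
#' is compared against the linearity flag and a mismatch is an error.
#'
#' @param potential potential object.
#' @param molecule gas-phase `atoms` object at a minimum.
#' @param linear is the molecule linear?
#' @param displacement finite-difference amplitude (Angstrom).
#' @param omega_tol frequencies below this (rad/ps) count as null modes.
#'   The default (5 rad/ps, about 27 cm^-1) leaves room for the O(u^2)
#'   contamination that finite displacements induce in the rotational
#'   curvatures while staying far below genuine vibrations.
#' @return object of class `gas_modes`: `omega` (rad/ps, length 3N-6 or
#'   3N-5), `dof`, `linear`.
#' @export
gas_frequencies <- function(potential, molecule, linear = FALSE,
                            displacement = 0.01, omega_tol = 5) {
  if (molecule$pbc) stop("gas_frequencies expects an aperiodic molecule")
  n <- n_atoms(molecule)
  phi <- compute_force_constants(potential, molecule, displacement)
  m3 <- rep(molecule$masses, each = 3)
  dm <- phi / sqrt(outer(m3, m3)) * units_xt$mass_freq2
  # null-space basis: translations and rotations about the centre of mass
  com <- colSums(molecule$positions * molecule$masses) /
    sum(molecule$masses)
  rel <- sweep(molecule$positions, 2, com)
  basis <- matrix(0, 3 * n, 6)
  sq <- sqrt(molecule$masses)
  for (d in 1:3) basis[seq(d, 3 * n, 3), d] <- sq
  ax <- diag(3)
  for (d in 1:3) {
    rot <- t(vapply(seq_len(n), function(a)
      crossing(ax[d, ], rel[a, ]) * sq[a], numeric(3)))
    basis[, 3 + d] <- as.vector(t(rot))
  }
  qr_b <- qr(basis)
  rank <- qr_b$rank                      # 6 non-linear, 5 linear
  expected <- if (linear) 5L else 6L
  # count null modes of the raw mass-weighted Hessian
  lam <- eigen(dm, symmetric = TRUE, only.values = TRUE)$values
  nnull <- sum(abs(lam) < omega_tol^2)
  if (rank != expected || nnull != expected)
    stop("linearity mismatch: expected ", expected,
         " null modes, rotation/translation space has rank ", rank,
         " and the Hessian has ", nnull, " null eigenvalues")
  Q <- qr.Q(qr_b)[, seq_len(rank), drop = FALSE]
  P <- diag(3 * n) - tcrossprod(Q)
  dmp <- P %*% dm %*% P
  lam2 <- sort(eigen((dmp + t(dmp)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
  dof <- vibrational_dof(n, linear)
  lam2 <- lam2[seq_len(dof)]
  if (any(lam2 < -omega_tol^2))
    stop("imaginary gas-phase modes: molecule is not at a minimum")
  structure(list(omega = sqrt(pmax(lam2, 0)), dof = dof, linear = linear),
            class = "gas_modes")
}

# cross product of two 3-vectors
crossing <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Quasi-harmonic vibrational energy of a gas molecule
#'
#' Sum of per-mode quantum-harmonic internal energies over the 3N-6 (or
#' 3N-5) vibrational modes.
#'
#' @param modes a `gas_modes` object (or any list with `omega`).
#' @param T temperature (K), >= 0.
#' @return energy in kJ/mol.
#' @export
qha_vib_energy_gas <- function(modes, T) {
  stopifnot(T >= 0)
  if (any(modes$omega <= 0)) stop("non-positive gas-phase frequency")
  sum(harmonic_mode_energy(modes$omega, T, omega_tol = 0))
}
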