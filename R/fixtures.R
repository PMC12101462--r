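#' Packaged toy systems
#'
#' Deterministic builders for the desk-scale model systems used by the
#' tests, the vignette and the acceptance analysis.  Each returns the
#' structure plus the matching potential (and topology where relevant),
#' so every stage of the pipeline can be exercised without any external
#' input.
#'
#' @name toy_systems
NULL

#' @describeIn toy_systems One water-like 3-atom molecule (O, H, H) per
#'   cubic unit cell with stiff intramolecular and soft intermolecular
#'   springs.  The spring constants are chosen so that the highest
#'   phonon has hbar omega / kB T <= 4 at 300 K, the regime where
#'   moderate bead counts converge path-integral averages.
#' @param a lattice constant (Angstrom).
#' @param k_intra,k_inter spring constants (kJ/mol/A^2).
#' @param reps supercell replication.
#' @export
toy_harmonic_crystal <- function(a = 4, k_intra = 40, k_inter = 15,
                                 reps = c(2, 2, 2)) {
  unit <- atoms(species = c("O", "H", "H"),
                positions = rbind(c(0, 0, 0),
                                  c(1.1, 0.15, 0),
                                  c(0.15, 1.1, 0.1)),
                cell = diag(3) * a)
  crystal <- build_supercell(unit, reps)
  kfun <- function(d) ifelse(d < 2, k_intra, k_inter)
  pot <- make_harmonic_crystal(crystal, cutoff = 1.05 * a, k = kfun)
  list(unit = unit, crystal = crystal, potential = pot,
       n_molecules = prod(reps), atoms_per_molecule = 3L,
       make_potential = function(cfg)
         make_harmonic_crystal(cfg, cutoff = 1.05 * a, k = kfun))
}

#' @describeIn toy_systems Lennard-Jones fcc crystal (argon-like), 4
#'   atoms in the conventional cubic cell.
#' @param epsilon,sigma LJ parameters.
#' @export
toy_lj_crystal <- function(a = 4.62, epsilon = 8, sigma = 3,
                           reps = c(1, 1, 1)) {
  unit <- atoms(species = rep("Ar", 4),
                positions = a * rbind(c(0, 0, 0), c(0.5, 0.5, 0),
                                      c(0.5, 0, 0.5), c(0, 0.5, 0.5)),
                cell = diag(3) * a)
  crystal <- build_supercell(unit, reps)   # also attaches the
  # unit-cell mapping that the phonon machinery expects
  list(unit = unit, crystal = crystal,
       potential = potential_lj(epsilon, sigma),
       n_molecules = 4 * prod(reps))
}

#' @describeIn toy_systems Diatomic molecular crystal: one harmonic
#'   dimer per cell, LJ between molecules.
#' @param bond_k,bond_r0 intramolecular spring.
#' @export
toy_molecular_crystal <- function(a = 3.8, bond_k = 1000, bond_r0 = 1.1,
                                  epsilon = 0.8, sigma = 3,
                                  reps = c(2, 2, 2)) {
  unit <- atoms(species = c("C", "H"),
                positions = rbind(c(0, 0, 0), c(bond_r0, 0, 0)),
                cell = diag(3) * a)
  crystal <- build_supercell(unit, reps)
  nmol <- prod(reps)
  topo <- topology(molecule = rep(seq_len(nmol), each = 2),
                   bonds = cbind(seq(1, 2 * nmol, 2), seq(2, 2 * nmol, 2)))
  pot <- potential_toy_molecular_crystal(topo, bond_k, bond_r0,
                                         epsilon = epsilon, sigma = sigma)
  list(unit = unit, crystal = crystal, potential = pot, topo = topo,
       n_molecules = nmol)
}

#' @describeIn toy_systems Gas-phase harmonic diatomic (linear molecule).
#' @param species two element symbols.
#' @export
toy_diatomic_gas <- function(bond_k = 500, bond_r0 = 1.1,
                             species = c("H", "H")) {
  mol <- atoms(species, rbind(c(0, 0, 0), c(bond_r0, 0, 0)))
  topo <- topology(c(1L, 1L), bonds = cbind(1L, 2L), linear = TRUE)
  pot <- potential_toy_molecular_crystal(topo, bond_k, bond_r0)
  list(molecule = mol, potential = pot, topo = topo)
}

#' @describeIn toy_systems Gas-phase bent triatomic (water-like,
#'   non-linear).
#' @param angle_k,theta0 harmonic bending term.
#' @export
toy_bent_triatomic <- function(bond_k = 800, bond_r0 = 0.96,
                               angle_k = 120, theta0 = 1.824) {
  p2 <- bond_r0 * c(1, 0, 0)
  p3 <- bond_r0 * c(cos(theta0), sin(theta0), 0)
  mol <- atoms(c("O", "H", "H"), rbind(c(0, 0, 0), p2, p3))
  topo <- topology(c(1L, 1L, 1L), bonds = rbind(c(1L, 2L), c(1L, 3L)),
                   angles = rbind(c(2L, 1L, 3L)), linear = FALSE)
  pot <- potential_toy_molecular_crystal(topo, bond_k, bond_r0,
                                         angle_k = angle_k,
                                         angle_theta0 = theta0)
  list(molecule = mol, potential = pot, topo = topo)
}

#' @describeIn toy_systems Collinear O-H-O double-well hydrogen-bond
#'   system (see [potential_double_well_hbond]).
#' @param deuterated use the deuteron mass on the central atom.
#' @param ... passed to [potential_double_well_hbond].
#' @export
toy_hbond <- function(deuterated = FALSE, ...) {
  pot <- potential_double_well_hbond(...)
  mol <- atoms(c("O", "H", "O"),
               rbind(c(-pot$r0 / 2, 0, 0),
                     c(pot$s0, 0, 0),
                     c(pot$r0 / 2, 0, 0)))
  if (deuterated) mol <- substitute_isotope(mol, "H", atomic_masses[["D"]])
  list(molecule = mol, potential = pot)
}

#' Synthetic Birch-Murnaghan energy-volume data
#'
#' Samples E(V) from an exact 3rd-order Birch-Murnaghan curve at the
#' volumes where its pressure equals the requested external pressures,
#' optionally with Gaussian noise - the self-consistency oracle for the
#' EOS fit.
#'
#' @param V0,E0,B0_GPa,B0p generator parameters (B0 in GPa).
#' @param pressures external pressures (bar).
#' @param noise Gaussian noise sd on E (kJ/mol).
#' @param seed RNG seed used when noise > 0.
#' @return data.frame (p, V, E) plus the generator parameters as
#'   attributes.
#' @export
bm_eos_data <- function(V0 = 100, E0 = -50, B0_GPa = 10, B0p = 4,
                        pressures = c(0, 1000, -1000, 2000, -2000,
                                      4000, -4000),
                        noise = 0, seed = 1) {
  B0 <- B0_GPa * 1e4 * units_xt$bar_to_kjmolA3    # kJ/mol/A^3
  energy <- function(V) {
    eta <- (V0 / V)^(2 / 3); x <- eta - 1
    E0 + 9 * V0 * B0 / 16 * (x^3 * B0p + x^2 * (6 - 4 * eta))
  }
  pressure <- function(V) {
    eta <- (V0 / V)^(1 / 3)
    1.5 * B0 * (eta^7 - eta^5) * (1 + 0.75 * (B0p - 4) * (eta^2 - 1)) /
      units_xt$bar_to_kjmolA3
  }
  V <- vapply(pressures, function(pp)
    stats::uniroot(function(v) pressure(v) - pp, c(0.5 * V0, 2 * V0),
                   tol = 1e-12)$root, 0)
  E <- energy(V)
  if (noise > 0) {
    set.seed(seed)
    E <- E + stats::rnorm(length(E), 0, noise)
  }
  out <- data.frame(p = pressures, V = V, E = E)
  attr(out, "params") <- list(V0 = V0, E0 = E0, B0 = B0, B0p = B0p)
  out[order(out$V), ]
}

#' Seeded AR(1) series
#'
#' x_t = phi x_{t-1} + N(0, sigma^2), stationary start; the workhorse
#' for validating reblocking against the analytic SEM ([ar1_sem]).
#'
#' @param n length.
#' @param phi autoregression coefficient, |phi| < 1.
#' @param sigma innovation sd.
#' @param seed RNG seed.
#' @return numeric vector.
#' @export
ar1_series <- function(n, phi = 0.9, sigma = 1, seed = 1) {
  stopifnot(abs(phi) < 1)
  set.seed(seed)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma / sqrt(1 - phi^2))
  innov <- stats::rnorm(n - 1, 0, sigma)
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
  x
}

#' Write a deterministic fixture to disk
#'
#' Emits self-documenting plain-text files (extended-XYZ for structures,
#' CSV for tabular data) with the generator parameters embedded in the
#' header; identical inputs give identical bytes.
#'
#' @param kind one of "harmonic-crystal", "lj-crystal",
#'   "lj-molecular-crystal", "double-well-hbond", "diatomic-gas",
#'   "bent-triatomic-gas", "bm-eos-data", "ar1-series".
#' @param seed generator seed (where randomness is involved).
#' @param dir output directory.
#' @return path(s) of the written file(s), invisibly.
#' @export
make_fixtures <- function(kind, seed = 0, dir = ".") {
  kinds <- c("harmonic-crystal", "lj-crystal", "lj-molecular-crystal",
             "double-well-hbond", "diatomic-gas", "bent-triatomic-gas",
             "bm-eos-data", "ar1-series")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; available: ",
         paste(kinds, collapse = ", "))
  path <- file.path(dir, paste0(gsub("-", "_", kind), ".",
                                if (kind %in% c("bm-eos-data",
                                                "ar1-series")) "csv"
                                else "xyz"))
  write_cfg <- function(cfg, params) {
    cfg$info <- c(cfg$info, params, list(fixture = kind, seed = seed))
    write_extxyz(cfg, path)
  }
  switch(kind,
    "harmonic-crystal" = {
      sysd <- toy_harmonic_crystal()
      write_cfg(sysd$crystal, list(k_intra = 40, k_inter = 15, a = 4))
    },
    "lj-crystal" = {
      sysd <- toy_lj_crystal()
      write_cfg(sysd$crystal, list(epsilon = 1, sigma = 3, a = 4.62))
    },
    "lj-molecular-crystal" = {
      sysd <- toy_molecular_crystal()
      write_cfg(sysd$crystal, list(bond_k = 1000, bond_r0 = 1.1,
                                   epsilon = 0.8, sigma = 3))
    },
    "double-well-hbond" = {
      sysd <- toy_hbond()
      write_cfg(sysd$molecule, list(barrier = 6, well_sep = 0.6,
                                    k_oo = 100, coupling = 270))
    },
    "diatomic-gas" = {
      sysd <- toy_diatomic_gas()
      write_cfg(sysd$molecule, list(bond_k = 500, bond_r0 = 1.1,
                                    linear = TRUE))
    },
    "bent-triatomic-gas" = {
      sysd <- toy_bent_triatomic()
      write_cfg(sysd$molecule, list(bond_k = 800, angle_k = 120,
                                    linear = FALSE))
    },
    "bm-eos-data" = {
      dat <- bm_eos_data(seed = seed)
      pp <- attr(dat, "params")
      hdr <- sprintf("# %s seed=%d V0=%g E0=%g B0=%g B0p=%g",
                     kind, seed, pp$V0, pp$E0, pp$B0, pp$B0p)
      writeLines(c(hdr, "p,V,E",
                   sprintf("%.17g,%.17g,%.17g", dat$p, dat$V, dat$E)),
                 path)
    },
    "ar1-series" = {
      x <- ar1_series(2^16, phi = 0.9, sigma = 1, seed = seed)
      writeLines(c(sprintf("# %s seed=%d phi=0.9 sigma=1 n=%d",
                           kind, seed, length(x)),
                   "x", sprintf("%.17g", x)), path)
    })
  invisible(path)
}
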