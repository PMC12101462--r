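test_that("small-displacement force constants recover the exact spring matrix", {
  sysd <- harmonic_sys()
  phi_exact <- harmonic_phi_matrix(sysd$potential)
  phi_fd <- compute_force_constants(sysd$potential, sysd$crystal, 0.01)
  expect_lt(max(abs(phi_fd - phi_exact)), 1e-8)
  # refuses structures that are not at a minimum
  expect_error(compute_force_constants(sysd$potential,
                                       jiggle(sysd$crystal, 0.1, 1)),
               "not at minimum")
})

test_that("1D chain dispersion matches the analytic omega(q)", {
  # monatomic chain along x: a = 3 A, k = 100, m = 12 (carbon), pure
  # central springs so the longitudinal branch is the textbook
  # omega(q) = 2 sqrt(k/m) |sin(qa/2)|
  a <- 3; k <- 100; m <- 12.011
  unit <- atoms("C", matrix(0, 1, 3), cell = diag(c(a, 20, 20)))
  chain <- build_supercell(unit, c(8, 1, 1))
  pot <- make_harmonic_crystal(chain, cutoff = 1.2 * a, k = k,
                               transverse = 0.25)
  phi <- compute_force_constants(pot, chain, 0.01)
  q <- cbind(seq(0, 7) / 8, 0, 0)
  spec <- phonon_spectrum(phi, chain, q, n_molecules = 1)
  omega_long <- apply(spec$frequencies, 1, max)   # longitudinal branch
  analytic <- 2 * sqrt(units_xt$mass_freq2 * k / m) *
    abs(sin(pi * q[, 1]))
  idx <- q[, 1] != 0
  expect_lt(max(abs(omega_long[idx] - analytic[idx]) / analytic[idx]),
            1e-6)
})

test_that("LJ force constants are converged in the displacement step", {
  lj <- lj_sys()
  rel <- relax_cell_at_pressure(lj$potential, lj$crystal, 0)
  phi1 <- compute_force_constants(lj$potential, rel, 0.01)
  phi2 <- compute_force_constants(lj$potential, rel, 0.005)
  scale <- max(abs(phi1))
  expect_lt(max(abs(phi1 - phi2)) / scale, 1e-3)
})

test_that("solid QHA energy: ZPE, per-mode formula, classical limit", {
  sysd <- harmonic_sys()
  phi <- compute_force_constants(sysd$potential, sysd$crystal)
  mp <- monkhorst_pack(c(2, 2, 2))
  spec <- phonon_spectrum(phi, sysd$crystal, mp$qpoints, mp$weights,
                          n_molecules = 1)
  om <- harmonic_mode_freqs(sysd)
  live <- om > 1e-4
  # T = 0 is exactly the zero-point energy; acoustic modes contribute 0
  expect_equal(qha_vib_energy_solid(spec, 0),
               sum(units_xt$hbar * om[live] / 2) / 8, tolerance = 1e-9)
  # per-mode formula against an independently coded scalar evaluation
  T <- 300
  kB <- units_xt$kB; hb <- units_xt$hbar
  direct <- sum(hb * om[live] / 2 +
                  hb * om[live] / (exp(hb * om[live] / (kB * T)) - 1)) / 8
  expect_equal(qha_vib_energy_solid(spec, T), direct, tolerance = 1e-10)
  # classical equipartition limit: kB T >> hbar omega
  Thot <- 50 * hb * max(om) / kB
  expect_lt(abs(qha_vib_energy_solid(spec, Thot) -
                  sum(live) / 8 * kB * Thot) /
              (sum(live) / 8 * kB * Thot), 0.01)
  # monotone in T
  Ts <- c(0, 50, 150, 300, 600)
  Es <- vapply(Ts, function(tt) qha_vib_energy_solid(spec, tt), 0)
  expect_true(all(diff(Es) > 0))
})

test_that("imaginary modes are a hard error, never dropped", {
  spec <- structure(list(frequencies = rbind(c(-3, 5, 10)),
                         qpoints = rbind(c(0, 0, 0)), weights = 1,
                         n_molecules = 1),
                    class = "phonon_spectrum")
  expect_error(qha_vib_energy_solid(spec, 300), "imaginary")
})

test_that("gas frequencies: diatomic and bent triatomic dof rules", {
  di <- toy_diatomic_gas()
  gm <- gas_frequencies(di$potential, di$molecule, linear = TRUE)
  expect_equal(gm$dof, 1L)
  mu <- atomic_masses[["H"]] / 2
  expect_equal(gm$omega, sqrt(units_xt$mass_freq2 * 500 / mu),
               tolerance = 1e-6)
  tri <- toy_bent_triatomic()
  gt <- gas_frequencies(tri$potential, tri$molecule, linear = FALSE)
  expect_equal(gt$dof, 3L)
  expect_true(all(gt$omega > 0))
  expect_error(gas_frequencies(tri$potential, tri$molecule, linear = TRUE),
               "linearity mismatch")
})

test_that("gas QHA energy matches the scalar mode formula", {
  modes <- list(omega = convert_frequency(c(500, 1200, 2900), "cm-1",
                                          "rad/ps"))
  T <- 290
  kB <- units_xt$kB; hb <- units_xt$hbar
  direct <- sum(hb * modes$omega / 2 +
                  hb * modes$omega /
                    (exp(hb * modes$omega / (kB * T)) - 1))
  expect_equal(qha_vib_energy_gas(modes, T), direct, tolerance = 1e-12)
  # T = 0: pure ZPE; very stiff mode freezes out its thermal part
  expect_equal(qha_vib_energy_gas(modes, 0), sum(hb * modes$omega / 2))
  stiff <- list(omega = 1e5)
  expect_equal(qha_vib_energy_gas(stiff, 300), units_xt$hbar * 1e5 / 2)
})

test_that("uniform mass scaling: 4x mass halves frequencies and the ZPE", {
  sysd <- harmonic_sys()
  om <- harmonic_mode_freqs(sysd)
  heavy <- sysd$crystal
  heavy$masses <- heavy$masses * 4
  sys4 <- list(potential = make_harmonic_crystal(heavy, cutoff = 4.2,
                                                 k = function(d)
                                                   ifelse(d < 2, 40, 15)),
               crystal = heavy)
  om4 <- harmonic_mode_freqs(sys4)
  live <- om > 1e-4
  expect_lt(max(abs(om4[live] - om[live] / 2) / om[live]), 1e-9)
})

test_that("q-grid energies converge with grid size on the LJ crystal", {
  lj <- lj_sys()
  rel <- relax_cell_at_pressure(lj$potential, lj$crystal, 0)
  sc <- build_supercell(rel, c(2, 2, 2))
  pot <- lj$potential
  phi <- compute_force_constants(pot, sc)
  energies <- vapply(c(2, 4, 6), function(L) {
    mp <- monkhorst_pack(c(L, L, L))
    qha_vib_energy_solid(
      phonon_spectrum(phi, sc, mp$qpoints, mp$weights, n_molecules = 4),
      300)
  }, 0)
  expect_lt(abs(energies[3] - energies[2]), abs(energies[2] - energies[1]))
})
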