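test_that("fixed seeds give bit-identical trajectories", {
  sysd <- harmonic_sys()
  r1 <- run_md(sysd$potential, sysd$crystal, "NVT", T = 200,
               n_steps = 500, seed = 3, stride = 5)
  r2 <- run_md(sysd$potential, sysd$crystal, "NVT", T = 200,
               n_steps = 500, seed = 3, stride = 5)
  expect_identical(r1$series, r2$series)
  r3 <- run_md(sysd$potential, sysd$crystal, "NVT", T = 200,
               n_steps = 500, seed = 4, stride = 5)
  expect_false(identical(r1$series$U, r3$series$U))
})

test_that("one-bead path integral reduces exactly to classical MD", {
  sysd <- harmonic_sys()
  md <- run_md(sysd$potential, sysd$crystal, "NVT", T = 300,
               n_steps = 400, seed = 9, stride = 4, store_frames = TRUE)
  pi1 <- run_pimd(sysd$potential, sysd$crystal, P = 1, "NVT", T = 300,
                  n_steps = 400, seed = 9, stride = 4,
                  store_frames = TRUE)
  expect_identical(md$series$U, pi1$series$U)
  expect_identical(md$series$K, pi1$series$K)
  expect_identical(md$frames[[length(md$frames)]]$X,
                   pi1$frames[[length(pi1$frames)]]$X)
})

test_that("harmonic solid NVT satisfies equipartition and the virial theorem", {
  sysd <- harmonic_sys()
  rec <- run_md(sysd$potential, sysd$crystal, "NVT", T = 300,
                n_steps = 30000, seed = 11, stride = 10, friction = 5)
  N <- n_atoms(sysd$crystal)
  kB <- units_xt$kB
  k <- record_stats(rec, "K")
  u <- record_stats(rec, "U")
  # per-atom Langevin thermostats all 3N momenta
  expect_lt(abs(k$mean - 1.5 * N * kB * 300), 3 * k$sem)
  # potential gets (3N-3)/2 kB T: three spring-network zero modes carry
  # no potential energy
  expect_lt(abs(u$mean - 1.5 * (N - 1) * kB * 300), 3 * u$sem)
})

test_that("kinetic energy samples follow the Maxwell-Boltzmann gamma law", {
  sysd <- harmonic_sys()
  rec <- run_md(sysd$potential, sysd$crystal, "NVT", T = 300,
                n_steps = 30000, seed = 13, stride = 50)  # ~decorrelated
  ks <- rec$series$K[-(1:120)]
  shape <- 1.5 * n_atoms(sysd$crystal)
  p <- stats::ks.test(ks / (units_xt$kB * 300), "pgamma",
                      shape = shape)$p.value
  expect_gt(p, 0.01)
})

test_that("timestep robustness: <U> is unbiased at dt and dt/2", {
  sysd <- harmonic_sys()
  exact <- 1.5 * (n_atoms(sysd$crystal) - 1) * units_xt$kB * 300
  u1 <- record_stats(run_md(sysd$potential, sysd$crystal, "NVT", T = 300,
                            n_steps = 20000, dt = 1e-3, seed = 15,
                            stride = 10), "U")
  u2 <- record_stats(run_md(sysd$potential, sysd$crystal, "NVT", T = 300,
                            n_steps = 40000, dt = 5e-4, seed = 15,
                            stride = 20), "U")
  expect_lt(abs(u1$mean - exact), 3 * u1$sem)
  expect_lt(abs(u2$mean - exact), 3 * u2$sem)
})

test_that("NPT sampling reproduces the target pressure on the LJ crystal", {
  lj <- lj_sys()
  rel <- relax_cell_at_pressure(lj$potential, lj$crystal, 0)
  start <- build_supercell(rel, c(2, 2, 2))
  rec <- run_md(lj$potential, start, "NPT", T = 300, p = 1,
                n_steps = 15000, seed = 17, stride = 10)
  pi <- record_stats(rec, "P_inst")
  expect_lt(abs(pi$mean - 1), 3 * pi$sem)
  # thermal expansion: <V> above the 0 K volume
  expect_gt(record_stats(rec, "V")$mean, det(start$cell))
  expect_error(run_md(lj$potential, toy_diatomic_gas()$molecule, "NPT",
                      T = 300, n_steps = 100),
               "periodic")
})

test_that("free ring polymer and collapsed polymer give (3N/2) kB T", {
  kB <- units_xt$kB
  free <- as_potential(function(cfg)
    list(energy = 0, forces = cfg$positions * 0), "free")
  cfg <- atoms("H", matrix(0, 1, 3))
  est <- run_pimd(free, cfg, P = 16, "NVT", T = 250, n_steps = 4000,
                  seed = 19, stride = 5, remove_com = FALSE)
  kcv <- record_stats(est, "K_cv")
  expect_lt(abs(kcv$mean - 1.5 * kB * 250), 3 * max(kcv$sem, 1e-12))
  # estimator function: collapsed polymer and P = 1 are exact
  X <- matrix(rep(c(0.3, -1, 2, 0.1, 0, 0), 5), 6, 5)
  Fb <- matrix(stats::rnorm(30), 6, 5)
  expect_equal(centroid_virial_kinetic(X, Fb, 300),
               1.5 * 2 * kB * 300)
  expect_equal(centroid_virial_kinetic(matrix(1, 3, 1),
                                       matrix(9, 3, 1), 300),
               1.5 * kB * 300)
  expect_error(centroid_virial_kinetic(X, Fb[, 1:3], 300), "mismatch")
})

test_that("PIMD reproduces the exact finite-bead harmonic energy", {
  kB <- units_xt$kB
  T <- 300
  om <- 3 * kB * T / units_xt$hbar       # beta hbar omega = 3
  m <- 1.008
  k <- m * om^2 / units_xt$mass_freq2
  pot <- as_potential(function(cfg)
    list(energy = 0.5 * k * sum(cfg$positions^2),
         forces = -k * cfg$positions), "well")
  cfg <- atoms("H", matrix(0, 1, 3))
  P <- 32
  est <- run_pimd(pot, cfg, P = P, "NVT", T = T, n_steps = 24000,
                  dt = 5e-4, seed = 23, stride = 10, friction = 5,
                  remove_com = FALSE)
  kcv <- record_stats(est, "K_cv"); u <- record_stats(est, "U")
  E <- kcv$mean + u$mean
  sE <- sqrt(kcv$sem^2 + u$sem^2)
  E_P <- 3 * harmonic_finite_p_energy(om, T, P)
  expect_lt(abs(E - E_P), 3 * sE)
  # and the P -> infinity value is approached within the known bias
  E_inf <- 3 * harmonic_quantum_energy(om, T)
  expect_lt(abs(E_P - E_inf) / E_inf, 0.01)   # P = 32 bias at bhw = 3
  # the closed form itself: classical at P = 1, exact as P grows
  expect_equal(harmonic_finite_p_energy(om, T, 1), kB * T,
               tolerance = 1e-12)
  expect_lt(abs(harmonic_finite_p_energy(om, T, 512) -
                  harmonic_quantum_energy(om, T)) /
              harmonic_quantum_energy(om, T), 1e-4)
})

test_that("centroid-virial estimator is exact on directly sampled ring polymers", {
  # draw bead configurations from the exact finite-P normal-mode
  # distribution of a 1D oscillator (no dynamics) and average K_cv
  kB <- units_xt$kB; T <- 200; P <- 24; m <- 2; om <- 80
  k <- m * om^2 / units_xt$mass_freq2
  nm <- xtaltherm:::ring_polymer_modes(P)
  omega_P <- P * kB * T / units_xt$hbar
  Ok2 <- om^2 + (2 * omega_P * sin(pi * nm$wave / P))^2
  sd_q <- sqrt(units_xt$mass_freq2 * kB * P * T / (m * Ok2))
  set.seed(31)
  nsamp <- 4000
  kcv <- numeric(nsamp)
  for (s in seq_len(nsamp)) {
    q <- stats::rnorm(P) * sd_q
    x <- as.numeric(nm$C %*% q)          # bead positions of the 1D mode
    X <- rbind(x, 0, 0)                  # pad y, z as collapsed dofs
    Fb <- -k * X
    # the two collapsed dofs contribute kB T / 2 each through the 3N/2 term
    kcv[s] <- centroid_virial_kinetic(X, Fb, T) - kB * T
  }
  E_P <- harmonic_finite_p_energy(om, T, P)
  # <K_cv> = E_P / 2 for a harmonic mode
  expect_lt(abs(mean(kcv) - E_P / 2), 3 * stats::sd(kcv) / sqrt(nsamp))
})

test_that("gas-phase records carry the ideal-gas bookkeeping exactly", {
  kB <- units_xt$kB
  free <- as_potential(function(cfg)
    list(energy = 0, forces = cfg$positions * 0), "free")
  cfg <- atoms("Ar", matrix(0, 1, 3))
  rec <- run_md(free, cfg, "NVT", T = 300, n_steps = 2000, seed = 33,
                stride = 10)
  # a single atom with centre-of-mass motion removed has no kinetic energy
  expect_lt(max(abs(rec$series$K)), 1e-20)
  res <- sublimation_md(reference_correction(0), rec,
                        constant_record(0, 0, 100), T = 300, p = 0)
  # gas enthalpy contribution reduces to (3/2)RT + RT
  expect_equal(res$terms[["kinetic_gas"]] + res$terms[["potential_gas"]] +
                 res$terms[["ideal_gas"]], 2.5 * units_xt$R * 300)
})

test_that("classical diatomic gas shows full equipartition", {
  di <- toy_diatomic_gas()
  rec <- run_md(di$potential, di$molecule, "NVT", T = 400,
                n_steps = 20000, seed = 35, stride = 10, friction = 5)
  kB <- units_xt$kB
  k <- record_stats(rec, "K"); u <- record_stats(rec, "U")
  # K: (3N-3)/2 kB T with COM removed; U: 1/2 kB T from the bond
  expect_lt(abs(k$mean - 1.5 * kB * 400), 3 * k$sem)
  expect_lt(abs(u$mean - 0.5 * kB * 400), 3 * u$sem)
})

test_that("dynamics guards: divergence, bead cap, bad ensemble", {
  sysd <- harmonic_sys()
  expect_error(run_pimd(sysd$potential, sysd$crystal, P = 600, "NVT",
                        T = 300, n_steps = 10), "512")
  blowup <- as_potential(function(cfg)
    list(energy = 1e9, forces = cfg$positions * 0 + 1e7), "bad")
  expect_error(run_md(blowup, toy_diatomic_gas()$molecule, "NVT",
                      T = 300, n_steps = 50, stride = 5),
               "divergence")
})
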