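test_that("unit system constants and conversions are consistent", {
  expect_lt(abs(units_xt$R - 8.31446e-3) / 8.31446e-3, 1e-5)
  expect_identical(units_xt$R, units_xt$kB)
  # bar <-> kJ/mol/A^3 round trip is involutive
  p <- c(1, 1000, -4000, 0.5)
  back <- convert_pressure(convert_pressure(p, "bar", "kJ/mol/A3"),
                           "kJ/mol/A3", "bar")
  expect_lt(max(abs(back - p)), 1e-12)
  # hbar omega for 100 cm^-1 is the textbook 1.196 kJ/mol
  om <- convert_frequency(100, "cm-1", "rad/ps")
  expect_lt(abs(units_xt$hbar * om - 1.1963) / 1.1963, 1e-3)
})

test_that("extended-XYZ I/O round-trips structures losslessly", {
  # 12-atom benzene-like ring, periodic
  th <- seq(0, 2 * pi, length.out = 13)[1:12]
  ring <- atoms(species = rep(c("C", "H"), 6),
                positions = cbind(2.8 * cos(th), 2.8 * sin(th),
                                  0.01 * seq_len(12)),
                cell = diag(c(10, 10.5, 11)) + 0.1)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_extxyz(ring, path)
  back <- read_extxyz(path)[[1]]
  expect_identical(back$positions, ring$positions)
  expect_identical(back$cell, ring$cell)
  expect_identical(back$species, ring$species)
  expect_identical(back$masses, ring$masses)

  # frame without Lattice key -> gas phase
  gas <- atoms(c("O", "H"), rbind(c(0, 0, 0), c(0.97, 0, 0)))
  write_extxyz(gas, path)
  expect_false(read_extxyz(path)[[1]]$pbc)

  # two frames, order preserved
  write_extxyz(list(gas, ring), path)
  frames <- read_extxyz(path)
  expect_length(frames, 2)
  expect_false(frames[[1]]$pbc)
  expect_true(frames[[2]]$pbc)

  # malformed input errors name the problem
  writeLines(c("2", "Properties=species:S:1:pos:R:3", "H 0 0 0"), path)
  expect_error(read_extxyz(path), "structural|ends early")
  writeLines(c("nonsense"), path)
  expect_error(read_extxyz(path), "parse error")
})

test_that("isotope substitution changes masses only", {
  gas <- atoms(c("O", "H", "H"),
               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  sub <- substitute_isotope(gas, "H", 2.014)
  expect_identical(sub$positions, gas$positions)
  expect_identical(sub$species, gas$species)
  expect_equal(sub$masses, c(atomic_masses[["O"]], 2.014, 2.014))
  # absent element: warning + flagged no-op
  expect_warning(out <- substitute_isotope(gas, "Cl", 34.97), "not present")
  expect_identical(out$masses, gas$masses)
  expect_match(out$info$isotope_warning, "no-op")
})

test_that("classical configurational averages are isotope independent", {
  # same seed, masses differ only on H: velocity draws differ, so compare
  # distributions statistically over a short LJ-bonded dimer crystal run
  sysd <- mol_sys()
  recH <- run_md(sysd$potential, sysd$crystal, "NVT", T = 150,
                 n_steps = 16000, dt = 5e-4, seed = 5, stride = 10,
                 friction = 10)
  cfgD <- substitute_isotope(sysd$crystal, "H", 2.014)
  recD <- run_md(sysd$potential, cfgD, "NVT", T = 150,
                 n_steps = 16000, dt = 5e-4, seed = 6, stride = 10,
                 friction = 10)
  uH <- record_stats(recH, "U"); uD <- record_stats(recD, "U")
  expect_lt(abs(uH$mean - uD$mean), 3 * sqrt(uH$sem^2 + uD$sem^2))
})

test_that("supercell construction is extensive and order preserving", {
  sysd <- harmonic_sys()
  unit <- sysd$unit
  expect_identical(build_supercell(unit, c(1, 1, 1))$positions,
                   unit$positions)
  sc <- build_supercell(unit, c(2, 2, 2))
  expect_equal(n_atoms(sc), 8 * n_atoms(unit))
  # first image is the untranslated unit cell
  expect_identical(sc$positions[1:3, ], unit$positions)
  expect_error(build_supercell(atoms("H", matrix(0, 1, 3)), c(2, 2, 2)),
               "periodic")
  expect_error(build_supercell(unit, c(0, 1, 1)), ">= 1")
})

test_that("periodic potentials are extensive: E per molecule on any supercell", {
  lj <- lj_sys()
  e1 <- evaluate(lj$potential, lj$crystal)$energy / 4
  sc <- build_supercell(lj$crystal, c(2, 2, 2))
  e8 <- evaluate(lj$potential, sc)$energy / 32
  expect_lt(abs(e1 - e8), 1e-8)
  sysm <- mol_sys()
  em1 <- evaluate(sysm$potential, sysm$crystal)$energy / sysm$n_molecules
  big <- toy_molecular_crystal(reps = c(2, 2, 4))
  em2 <- evaluate(big$potential, big$crystal)$energy / big$n_molecules
  expect_lt(abs(em1 - em2), 1e-8)
})

test_that("LJ lattice sums converge with cutoff and are size consistent", {
  # unshifted lattice sums approach the infinite sum as r^-3 in the
  # cutoff (the energy shift is a modelling choice, not a truncation
  # error, so it is removed for this comparison)
  lj <- toy_lj_crystal()
  e <- vapply(c(9, 12, 15, 20), function(rc) {
    pot <- potential_lj(8, 3, cutoff = rc)
    pot$eshift <- 0
    evaluate(pot, lj$crystal)$energy / 4
  }, 0)
  expect_lt(abs(e[4] - e[3]), abs(e[3] - e[2]))
  expect_lt(abs(e[3] - e[2]), abs(e[2] - e[1]))
  # the truncated dispersion tail scales as rc^-3: extrapolating from
  # rc = 12, 15 predicts rc = 20 to a small fraction of the ~0.25
  # kJ/mol tail (discrete shell structure keeps it from being exact)
  rc <- c(9, 12, 15, 20)
  cc <- (e[3] - e[2]) / (rc[3]^-3 - rc[2]^-3)
  e_inf <- e[3] - cc * rc[3]^-3
  expect_lt(abs(e[4] - (e_inf + cc * rc[4]^-3)), 0.05)
  # direct 3x3x3 lattice sum at long cutoff equals the unit-cell sum
  lj_long <- potential_lj(8, 3, cutoff = 15)
  sc <- build_supercell(lj$crystal, c(3, 3, 3))
  e15 <- evaluate(lj_long, lj$crystal)$energy / 4
  expect_lt(abs(evaluate(lj_long, sc)$energy / 108 - e15), 1e-8)
})

test_that("minimum-image distances equal direct distances inside half cell", {
  cell <- diag(c(8, 9, 10))
  set.seed(2)
  dr <- matrix(stats::runif(30, -3.5, 3.5), 10, 3)  # < half shortest cell
  expect_equal(minimum_image(dr, cell), dr)
  # a pair straddling the boundary wraps
  wrapped <- minimum_image(rbind(c(7.5, 0, 0)), cell)
  expect_equal(as.numeric(wrapped), c(-0.5, 0, 0))
})

test_that("topology validates membership and dof counting follows linearity", {
  expect_error(topology(c(1L, 3L)), "partition")
  topo <- topology(c(1L, 1L, 2L, 2L), bonds = rbind(c(1L, 2L), c(3L, 4L)))
  expect_equal(topo$n_molecules, 2L)
  expect_equal(vibrational_dof(2, linear = TRUE), 1L)
  expect_equal(vibrational_dof(3, linear = FALSE), 3L)
  expect_equal(vibrational_dof(3, linear = TRUE), 4L)
})
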