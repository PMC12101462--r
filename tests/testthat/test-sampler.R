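# shared reference scan for the sampler tests (LJ fcc, 7 pressures)
sampler_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lj <- lj_sys()
    rel <- relax_cell_at_pressure(lj$potential, lj$crystal, 0)
    curve <- scan_eos(lj$potential, rel, n_molecules = 4)
    traj <- generate_candidates(lj$potential, curve$configs, T = 100,
                                length_ps = 4, stride = 10, seed = 2)
    cache <<- list(lj = lj, rel = rel, curve = curve, traj = traj)
    cache
  }
})

test_that("candidate generation is deterministic and samples equipartition", {
  fx <- sampler_fixture()
  expect_length(fx$traj, 7)
  traj2 <- generate_candidates(fx$lj$potential, fx$curve$configs,
                               T = 100, length_ps = 4, stride = 10,
                               seed = 2)
  expect_identical(fx$traj[[3]]$frames[[5]]$positions,
                   traj2[[3]]$frames[[5]]$positions)
  expect_error(generate_candidates(fx$lj$potential, fx$curve$configs,
                                   length_ps = 0), "zero-length")
  # displacement RMS matches the harmonic equipartition prediction:
  # <|u|^2> per coordinate = (kB T / 3N) sum_modes 1/(m omega^2), with
  # the diffusing centre of mass removed frame by frame; a dedicated
  # higher-friction run decorrelates the slow modes enough for a single
  # trajectory to average them
  ref <- fx$curve$configs[["0"]]
  phi <- compute_force_constants(fx$lj$potential, ref)
  m <- ref$masses[1]
  lam <- eigen(phi / m * units_xt$mass_freq2, symmetric = TRUE,
               only.values = TRUE)$values
  lam <- lam[lam > 1e-6]
  pred <- units_xt$kB * 100 * 100 / m * sum(1 / lam) /
    (3 * n_atoms(ref))
  tr <- generate_candidates(fx$lj$potential, list(ref), T = 100,
                            length_ps = 6, stride = 10, seed = 3,
                            friction = 5)[[1]]
  late <- tr$frames[(length(tr$frames) %/% 3):length(tr$frames)]
  disp <- vapply(late, function(fr) {
    u <- fr$positions - ref$positions
    u <- sweep(u, 2, colMeans(u))
    mean(u^2)
  }, 0)
  expect_lt(abs(mean(disp) - pred) / pred, 0.20)
})

test_that("initial selection draws the right counts without replacement", {
  fx <- sampler_fixture()
  sel <- select_initial(fx$traj, per_volume = 10, seed = 4)
  expect_length(sel$configs, 70)
  expect_equal(as.vector(table(sel$provenance$volume_index)), rep(10, 7))
  # frames are unique per volume
  expect_false(any(duplicated(sel$provenance[, c("volume_index",
                                                 "frame")])))
  # per_volume = all usable frames returns every frame
  nuse <- length(fx$traj[[1]]$frames) -
    floor(0.2 * length(fx$traj[[1]]$frames))
  all_sel <- select_initial(fx$traj, per_volume = nuse, seed = 4)
  expect_equal(sum(all_sel$provenance$volume_index == 1), nuse)
  expect_error(select_initial(fx$traj, per_volume = 10000), "usable")
})

test_that("two seeds overlap as hypergeometric sampling predicts", {
  fx <- sampler_fixture()
  nf <- length(fx$traj[[1]]$frames) - floor(0.2 *
                                              length(fx$traj[[1]]$frames))
  m <- 10
  overlaps <- vapply(1:100, function(s) {
    a <- select_initial(fx$traj[1], m, seed = s)$provenance$frame
    b <- select_initial(fx$traj[1], m, seed = 10000 + s)$provenance$frame
    length(intersect(a, b))
  }, 0)
  expect_lt(abs(mean(overlaps) - m * m / nf), 0.6)   # E[overlap] = m^2/N
})

test_that("augmentation draws from the worst-deviation volumes first", {
  fx <- sampler_fixture()
  ref <- fx$curve
  # single injected bump at volume index 3
  mod <- ref
  mod$points$E[3] <- mod$points$E[3] + 1
  aug <- augment_by_deviation(mod, ref, fx$traj, per_volume = 5,
                              seed = 6)
  expect_equal(unique(aug$provenance$volume_index), 3)
  expect_length(aug$configs, 5)
  # identical curves: empty augmentation with a note
  none <- augment_by_deviation(ref, ref, fx$traj)
  expect_length(none$configs, 0)
  expect_match(none$note, "below tolerance")
  # two bumps: draw order follows the deviation ranking
  mod2 <- ref
  mod2$points$E[2] <- mod2$points$E[2] + 2
  mod2$points$E[6] <- mod2$points$E[6] + 1
  aug2 <- augment_by_deviation(mod2, ref, fx$traj, per_volume = 3,
                               n_volumes = 2, seed = 6)
  expect_equal(aug2$ranking, c(2L, 6L))
  expect_equal(aug2$provenance$volume_index[1:3], rep(2L, 3))
})

test_that("a realizable surrogate fit reproduces LJ labels to numerical noise", {
  fx <- sampler_fixture()
  sel <- select_initial(fx$traj, per_volume = 6, seed = 8)
  out <- label_and_fit(sel, fx$lj$potential,
                       surrogate_pair_potential(cutoff = 9), seed = 8)
  expect_lt(out$report$validation_rmse[["energy"]], 1e-6)
  expect_lt(out$report$validation_rmse[["force"]], 1e-6)
  # recovered coefficients are the LJ expansion 4 eps sigma^12, -4 eps sigma^6
  expect_equal(out$potential$coef,
               c(4 * 8 * 3^12, -4 * 8 * 3^6), tolerance = 1e-5)
  expect_error(label_structures(list(), fx$lj$potential), "empty")
})

test_that("learning curve: held-out RMSE falls with training size", {
  # unrealizable case: fit the pair basis to a *molecular* crystal and
  # score on a random disjoint held-out set, averaged over repeats
  sysm <- mol_sys()
  rec <- run_md(sysm$potential, sysm$crystal, "NVT", T = 100,
                n_steps = 5000, seed = 12, stride = 10,
                store_frames = TRUE)
  frames <- lapply(rec$frames, function(fr)
    atoms(sysm$crystal$species,
          matrix(fr$X[, 1], ncol = 3, byrow = TRUE), cell = fr$cell,
          masses = sysm$crystal$masses))
  set.seed(99)
  ho_idx <- sample(seq_along(frames), 60)
  holdout <- frames[ho_idx]
  pool <- frames[-ho_idx]
  ho_labels <- vapply(holdout, function(cfg)
    evaluate(sysm$potential, cfg)$energy, 0)
  rmse_at <- function(n) {
    mean(vapply(1:6, function(rep) {
      set.seed(100 * rep)
      take <- sample(seq_along(pool), n)
      ts <- label_structures(pool[take], sysm$potential)
      fit <- fit_surrogate(surrogate_pair_potential(powers = c(12, 6, 4),
                                                    cutoff = 9), ts,
                           validation_frac = 0, seed = rep)
      pred <- vapply(holdout, function(cfg)
        evaluate(fit$potential, cfg)$energy, 0)
      sqrt(mean((pred - ho_labels)^2))
    }, 0))
  }
  r <- c(rmse_at(35), rmse_at(70), rmse_at(140))
  expect_lt(r[2], r[1])
  expect_lt(r[3], r[2])
})

test_that("convergence test passes trivially when fitted equals reference", {
  fx <- sampler_fixture()
  res <- convergence_test(fx$lj$potential, fx$lj$potential, fx$rel,
                          n_molecules = 4, T = 300,
                          supercell_reps = c(1, 1, 1),
                          qgrid = c(2, 2, 2))
  expect_true(res$pass)
  expect_equal(res$lattice_dE, 0, tolerance = 1e-9)
  expect_equal(res$eos_max_dev, 0, tolerance = 1e-8)
  expect_equal(res$qha_dE, 0, tolerance = 1e-8)
})

test_that("constant energy shifts cancel in min-aligned EOS deviation", {
  fx <- sampler_fixture()
  shifted <- as_potential(function(cfg)
    modifyList(evaluate(fx$lj$potential, cfg), list(energy =
      evaluate(fx$lj$potential, cfg)$energy + 5)), "shifted")
  curve_s <- scan_eos(shifted, fx$rel, n_molecules = 4)
  expect_lt(eos_deviation(curve_s, fx$curve)$max_dev, 1e-6)
  # a per-cell shift does move the per-molecule lattice energy
  lat0 <- evaluate(fx$lj$potential, fx$rel)$energy / 4
  lats <- evaluate(shifted, fx$rel)$energy / 4
  expect_equal(lats - lat0, 5 / 4)
})
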