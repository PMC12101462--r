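#' Generate candidate structures across the equation-of-state volumes
#'
#' Runs a short, low-temperature NVT trajectory with the *model*
#' potential (not the reference - that is the cost saving of the whole
#' scheme) at each relaxed EOS volume and keeps the sampled frames as
#' candidates for labelling.
#'
#' @param model_potential the current (cheap) model.
#' @param eos_configs list of relaxed configurations, one per volume
#'   (e.g. `scan_eos(...)$configs`).
#' @param T temperature (K), default 100.
#' @param length_ps trajectory length per volume (ps).
#' @param dt timestep (ps).
#' @param stride sampling stride (steps).
#' @param seed RNG seed; volume v uses seed + v.
#' @param ... further arguments (e.g. `friction`) passed to [run_md].
#' @return list of trajectories; each has `frames` (list of [atoms]),
#'   `volume_index`, `volume`, `seed`.
#' @export
generate_candidates <- function(model_potential, eos_configs, T = 100,
                                length_ps = 5, dt = 1e-3, stride = 25,
                                seed = 1, ...) {
  if (length_ps <= 0) stop("zero-length candidate run requested")
  n_steps <- max(as.integer(round(length_ps / dt)), stride)
  out <- vector("list", length(eos_configs))
  for (v in seq_along(eos_configs)) {
    cfg <- eos_configs[[v]]
    rec <- tryCatch(
      run_md(model_potential, cfg, ensemble = "NVT", T = T,
             n_steps = n_steps, dt = dt, seed = seed + v,
             stride = stride, store_frames = TRUE, ...),
      error = function(e)
        stop("candidate MD diverged at volume ", v, ": ",
             conditionMessage(e)))
    frames <- lapply(rec$frames, function(fr)
      atoms(cfg$species, matrix(fr$X[, 1], ncol = 3, byrow = TRUE),
            cell = fr$cell, masses = cfg$masses))
    out[[v]] <- list(frames = frames, volume_index = v,
                     volume = det(cfg$cell), seed = seed + v)
  }
  out
}

sampler_equilibrated <- function(traj, equilibration = 0.2) {
  nf <- length(traj$frames)
  drop <- floor(equilibration * nf)
  if (drop > 0) traj$frames[-seq_len(drop)] else traj$frames
}

#' Select the initial training structures
#'
#' Uniform random draw without replacement of `per_volume` frames per
#' volume (after the equilibration discard): ~10 structures at each of
#' ~7 volumes gives the ~70-structure starting set.
#'
#' @param trajectories output of [generate_candidates].
#' @param per_volume structures per volume.
#' @param seed RNG seed.
#' @param equilibration fraction of frames discarded before drawing.
#' @return selection: list with `configs` and a `provenance` data.frame
#'   (volume_index, frame, iteration = 1).
#' @export
select_initial <- function(trajectories, per_volume = 10, seed = 1,
                           equilibration = 0.2) {
  set.seed(seed)
  configs <- list(); prov <- list()
  for (traj in trajectories) {
    frames <- sampler_equilibrated(traj, equilibration)
    if (length(frames) < per_volume)
      stop("trajectory at volume ", traj$volume_index, " has only ",
           length(frames), " usable frames (< ", per_volume, ")")
    pick <- if (per_volume == length(frames)) seq_along(frames)
    else sort(sample.int(length(frames), per_volume))
    for (f in pick) {
      configs[[length(configs) + 1]] <- frames[[f]]
      prov[[length(prov) + 1]] <-
        data.frame(volume_index = traj$volume_index, frame = f,
                   iteration = 1L, phase = "solid")
    }
  }
  list(configs = configs, provenance = do.call(rbind, prov))
}

#' Augment the training set where the EOS deviation is worst
#'
#' Volumes are ranked by the model-vs-reference energy deviation (both
#' curves aligned to their own minima) and `per_volume` new frames are
#' drawn from the worst volumes first.
#'
#' @param model_curve,reference_curve `eos_curve` objects on matching
#'   volume ordering (point i of the reference corresponds to
#'   trajectory i).
#' @param trajectories output of [generate_candidates].
#' @param per_volume structures drawn per augmented volume.
#' @param n_volumes how many of the worst volumes to draw from.
#' @param seed RNG seed.
#' @param iteration recorded in the provenance.
#' @param dev_tol deviations below this (kJ/mol) do not trigger
#'   augmentation.
#' @return selection as in [select_initial]; empty (with a `note`) when
#'   the deviation vanishes everywhere.
#' @export
augment_by_deviation <- function(model_curve, reference_curve,
                                 trajectories, per_volume = 5,
                                 n_volumes = 1, seed = 1, iteration = 2L,
                                 dev_tol = 1e-9) {
  dev <- eos_deviation(model_curve, reference_curve)
  if (all(dev$profile$dE <= dev_tol))
    return(list(configs = list(), provenance = NULL,
                note = "EOS deviation below tolerance everywhere"))
  ranking <- order(dev$profile$dE, decreasing = TRUE)
  ranking <- ranking[dev$profile$dE[ranking] > dev_tol]
  ranking <- ranking[seq_len(min(n_volumes, length(ranking)))]
  set.seed(seed)
  configs <- list(); prov <- list()
  for (v in ranking) {
    traj <- trajectories[[v]]
    frames <- sampler_equilibrated(traj)
    pick <- sort(sample.int(length(frames), min(per_volume,
                                                length(frames))))
    for (f in pick) {
      configs[[length(configs) + 1]] <- frames[[f]]
      prov[[length(prov) + 1]] <-
        data.frame(volume_index = traj$volume_index, frame = f,
                   iteration = as.integer(iteration), phase = "solid")
    }
  }
  list(configs = configs, provenance = do.call(rbind, prov),
       ranking = ranking, deviation = dev)
}

#' Label a selection and fit the surrogate
#'
#' @param selection structure selection (from [select_initial] /
#'   [augment_by_deviation], or a plain list of configurations).
#' @param reference_potential labelling potential.
#' @param trainable a [surrogate_pair_potential].
#' @param ... passed to [fit_surrogate].
#' @return list with the fitted `potential`, the RMSE `report`, and the
#'   labelled `training_set`.
#' @export
label_and_fit <- function(selection, reference_potential, trainable, ...) {
  ts <- label_structures(selection, reference_potential)
  fit <- fit_surrogate(trainable, ts, ...)
  list(potential = fit$potential, report = fit$report, training_set = ts)
}

#' Convergence test of a fitted model against the reference
#'
#' The "test" step of the sampling loop: the fitted model passes when
#' (i) the lattice-energy error is below `tol_lattice`, (ii) the largest
#' minimum-aligned EOS deviation is below `tol_eos` and (iii) the
#' quasi-harmonic vibrational-energy error at temperature `T` is below
#' `tol_qha` (thresholds default to the chemical / sub-chemical gates 4,
#' 1 and 2 kJ/mol).
#'
#' @param fitted,reference potentials to compare.
#' @param solid relaxed periodic configuration (reference geometry).
#' @param gas relaxed gas-phase configuration (or NULL to skip the gas
#'   side; a single atom contributes no vibrational term).
#' @param n_molecules molecules in the solid cell.
#' @param T temperature for the vibrational comparison (K).
#' @param supercell_reps supercell for the phonon calculation.
#' @param qgrid q-grid divisions.
#' @param pressures EOS scan pressures (bar).
#' @param tol_lattice,tol_eos,tol_qha gates (kJ/mol).
#' @return list: per-property deviations, per-gate logicals, `pass`.
#' @export
convergence_test <- function(fitted, reference, solid, gas = NULL,
                             n_molecules = 1, T = 300,
                             supercell_reps = c(2, 2, 2),
                             qgrid = c(2, 2, 2),
                             pressures = c(0, 1000, -1000, 2000, -2000,
                                           4000, -4000),
                             tol_lattice = 4, tol_eos = 1, tol_qha = 2) {
  gas_e <- function(pot) if (is.null(gas)) 0 else evaluate(pot, gas)$energy
  relax_f <- relax_cell_at_pressure(fitted, solid, 0)
  relax_r <- relax_cell_at_pressure(reference, solid, 0)
  lat_f <- gas_e(fitted) - evaluate(fitted, relax_f)$energy / n_molecules
  lat_r <- gas_e(reference) -
    evaluate(reference, relax_r)$energy / n_molecules
  d_lattice <- abs(lat_f - lat_r)
  curve_f <- scan_eos(fitted, relax_f, pressures, n_molecules)
  curve_r <- scan_eos(reference, relax_r, pressures, n_molecules)
  d_eos <- eos_deviation(curve_f, curve_r)$max_dev
  qha_for <- function(pot, cfg) {
    sc <- build_supercell(cfg, supercell_reps)
    phi <- compute_force_constants(pot, sc)
    mp <- monkhorst_pack(qgrid)
    qha_vib_energy_solid(
      phonon_spectrum(phi, sc, mp$qpoints, mp$weights, n_molecules), T)
  }
  d_qha <- abs(qha_for(fitted, relax_f) - qha_for(reference, relax_r))
  gates <- c(lattice = unname(d_lattice < tol_lattice),
             eos = unname(d_eos < tol_eos),
             qha = unname(d_qha < tol_qha))
  list(lattice_dE = d_lattice, eos_max_dev = d_eos, qha_dE = d_qha,
       gates = gates, pass = all(gates),
       curves = list(fitted = curve_f, reference = curve_r))
}

#' Data-efficient training loop
#'
#' The full sampling loop: scan the reference EOS once, generate
#' model-driven candidates across its volumes, select ~`per_volume_init`
#' structures per volume, label them with the reference, fit the
#' surrogate, test it, and keep augmenting ~`per_volume_aug` structures
#' per worst-deviation volume until the convergence gates pass or the
#' structure budget (~200) is exhausted.
#'
#' @param start_model the initial (foundation-model stand-in) potential.
#' @param reference the labelling potential.
#' @param trainable the [surrogate_pair_potential] to fit.
#' @param config starting crystal structure.
#' @param gas gas-phase structure or NULL.
#' @param n_molecules molecules per cell.
#' @param per_volume_init,per_volume_aug selection counts.
#' @param budget maximum labelled structures.
#' @param max_iterations loop cap.
#' @param T_md candidate-generation temperature (K).
#' @param seed RNG seed.
#' @param ... passed to [convergence_test].
#' @return list: final `potential`, `history` (per-iteration report),
#'   `n_structures`, `converged`.
#' @export
sampling_loop <- function(start_model, reference, trainable, config,
                          gas = NULL, n_molecules = 1,
                          per_volume_init = 10, per_volume_aug = 5,
                          budget = 200, max_iterations = 5, T_md = 100,
                          seed = 1, ...) {
  ref_curve <- scan_eos(reference, config, n_molecules = n_molecules)
  traj <- generate_candidates(start_model, ref_curve$configs, T = T_md,
                              seed = seed)
  sel <- select_initial(traj, per_volume_init, seed = seed)
  history <- list()
  model <- start_model
  configs <- sel$configs
  prov <- sel$provenance
  for (it in seq_len(max_iterations)) {
    fit <- label_and_fit(list(configs = configs, provenance = prov),
                         reference, trainable, seed = seed + it)
    model <- fit$potential
    test <- convergence_test(model, reference, config, gas, n_molecules,
                             ...)
    history[[it]] <- list(iteration = it, n_structures = length(configs),
                          rmse = fit$report, test = test[
                            c("lattice_dE", "eos_max_dev", "qha_dE",
                              "gates", "pass")])
    if (test$pass)
      return(list(potential = model, history = history,
                  n_structures = length(configs), converged = TRUE))
    if (length(configs) + per_volume_aug > budget) break
    aug <- augment_by_deviation(test$curves$fitted, test$curves$reference,
                                traj, per_volume_aug,
                                seed = seed + 100 + it,
                                iteration = it + 1L)
    if (length(aug$configs) == 0) break
    configs <- c(configs, aug$configs)
    prov <- rbind(prov, aug$provenance)
  }
  list(potential = model, history = history,
       n_structures = length(configs), converged = FALSE)
}
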