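#' Per-system temperature registry
#'
#' Sublimation enthalpies are evaluated at the temperature where
#' experimental estimates exist: room temperature (298.15 K here) for
#' most molecular crystals, with five standard exceptions.
#'
#' @param system optional system name (case-insensitive); if omitted the
#'   whole registry is returned.
#' @param room value used for "room temperature" (K).
#' @return named numeric vector, or a single temperature.
#' @export
temperature_registry <- function(system = NULL, room = 298.15) {
  reg <- c(`acetic acid` = 290, ammonia = 195, benzene = 279,
           `carbon dioxide` = 207, formamide = 276)
  if (is.null(system)) return(c(reg, room = room))
  key <- tolower(system)
  if (key %in% names(reg)) reg[[key]] else room
}

#' Reference lattice-energy correction
#'
#' The zero-temperature electronic contribution of a surrogate or
#' machine-learned potential can be corrected to a higher-level
#' reference (e.g. a diffusion Monte Carlo lattice energy): the
#' correction added to a sublimation enthalpy is
#' (E_gas - E_sol)_ref - (E_gas - E_sol)_model, with the reference
#' uncertainty carried into the result in quadrature.
#'
#' @param e_el_model model-level electronic sublimation term
#'   E_gas - E_sol per molecule (kJ/mol) = the negative of the model
#'   lattice energy.
#' @param e_el_ref same quantity at the reference level, or NULL for a
#'   model-level (uncorrected) result.
#' @param sigma_ref 1-sigma uncertainty of the reference (kJ/mol).
#' @return list of class `ref_correction` with `delta` (kJ/mol added to
#'   the enthalpy), `sigma`, `model_level` flag.
#' @export
reference_correction <- function(e_el_model, e_el_ref = NULL,
                                 sigma_ref = 0) {
  if (is.null(e_el_ref))
    return(structure(list(delta = 0, sigma = 0, model_level = TRUE),
                     class = "ref_correction"))
  structure(list(delta = e_el_ref - e_el_model, sigma = sigma_ref,
                 model_level = FALSE),
            class = "ref_correction")
}

#' Electronic sublimation term of a potential
#'
#' E_gas - E_sol per molecule at the relaxed structures: the negative of
#' the lattice energy, and the dominant (zero-temperature) part of the
#' sublimation enthalpy.
#'
#' @param potential potential object.
#' @param solid relaxed periodic configuration.
#' @param gas relaxed gas-phase molecule.
#' @param n_molecules molecules in the solid cell.
#' @return kJ/mol per molecule.
#' @export
electronic_sublimation_term <- function(potential, solid, gas,
                                        n_molecules) {
  evaluate(potential, gas)$energy -
    evaluate(potential, solid)$energy / n_molecules
}

new_sublimation_result <- function(method, total, sigma, terms,
                                   breakdown, T, p, linear = FALSE) {
  stopifnot(abs(sum(terms) - total) < 1e-10)
  structure(list(method = method, dH = total, sigma = sigma,
                 terms = terms, breakdown = breakdown, T = T, p = p,
                 linear = linear),
            class = "sublimation_result")
}

#' @export
print.sublimation_result <- function(x, ...) {
  cat(sprintf("Sublimation enthalpy [%s] at T = %g K, p = %g bar\n",
              x$method, x$T, x$p))
  for (k in names(x$terms))
    cat(sprintf("  %-18s %10.4f kJ/mol\n", k, x$terms[[k]]))
  cat(sprintf("  %-18s %10.4f +/- %.4f kJ/mol\n", "total dH_sub",
              x$dH, x$sigma))
  invisible(x)
}

#' Quasi-harmonic sublimation enthalpy
#'
#' dH = (E_gas - E_sol) + (E_vib_gas - E_vib_sol) + 4RT for a non-linear
#' molecule; the ideal-gas assembly 4RT = (3/2)RT translation + (3/2)RT
#' rotation + RT pV collapses to (7/2)RT for a linear molecule (rotation
#' contributes RT).  The solid pV term (< 0.05 kJ/mol at ambient
#' pressure) is neglected.
#'
#' @param e_el electronic sublimation term E_gas - E_sol per molecule
#'   (kJ/mol); supply the reference-corrected value to obtain a
#'   reference-level result.
#' @param e_vib_gas,e_vib_solid quasi-harmonic vibrational energies per
#'   molecule (kJ/mol) at temperature `T`.
#' @param T temperature (K), >= 0.
#' @param linear is the gas molecule linear?
#' @param sigma_el uncertainty on `e_el` (kJ/mol).
#' @return a `sublimation_result`.
#' @export
sublimation_qha <- function(e_el, e_vib_gas, e_vib_solid, T,
                            linear = FALSE, sigma_el = 0) {
  if (T < 0) stop("negative temperature")
  RT <- units_xt$R * T
  ideal <- if (linear) 3.5 * RT else 4 * RT
  terms <- c(electronic = e_el, vibrational_gas = e_vib_gas,
             vibrational_solid = -e_vib_solid, ideal_gas = ideal)
  breakdown <- list(kinetic = (e_vib_gas - e_vib_solid) / 2 +
                      (if (linear) 2.5 else 3) * RT,
                    potential = (e_vib_gas - e_vib_solid) / 2,
                    other = e_el + RT)
  new_sublimation_result("QHA", sum(terms), sigma_el, terms, breakdown,
                         T, 0, linear)
}

check_gas_record <- function(record) {
  if (record$pbc) stop("gas record must be aperiodic")
  if (record$ensemble != "NVT") stop("gas record must be NVT")
}

solid_pV <- function(record, p, n_molecules) {
  pk <- p * units_xt$bar_to_kjmolA3
  if (record$ensemble == "NPT") {
    v <- record_stats(record, "V")
    list(mean = pk * v$mean / n_molecules, sem = pk * v$sem / n_molecules,
         vol = v$mean / n_molecules, constant_volume = FALSE)
  } else {
    v <- record$series$V[1]
    list(mean = pk * v / n_molecules, sem = 0, vol = v / n_molecules,
         constant_volume = TRUE)
  }
}

#' Classical (MD) sublimation enthalpy
#'
#' dH = correction + <K + U>_gas - <K + U>_sol + (5/2)RT - p<V>_sol,
#' per molecule: the gas NVT run (centre-of-mass motion removed) gets
#' its (3/2)RT translational energy and RT ideal-gas pV added back
#' analytically, the solid NPT run contributes its sampled p<V>.  The
#' classical sampling contains no zero-point energy.  Statistical errors
#' are reblocked per component and combined in quadrature, gas and solid
#' runs being independent.
#'
#' @param correction a [reference_correction] (use
#'   `reference_correction(0)` for a model-level result where the
#'   electronic term is already inside <U>).
#' @param gas_record NVT `trajectory_record` of the gas molecule.
#' @param solid_record NPT (or fixed-cell NVT, flagged) record of the
#'   solid.
#' @param T temperature (K); must match both records.
#' @param p external pressure (bar).
#' @param n_molecules molecules in the solid cell.
#' @return a `sublimation_result`.
#' @export
sublimation_md <- function(correction, gas_record, solid_record, T, p = 1,
                           n_molecules = 1) {
  check_gas_record(gas_record)
  if (!solid_record$pbc) stop("solid record must be periodic")
  if (abs(gas_record$T - T) > 1e-9 || abs(solid_record$T - T) > 1e-9)
    stop("record temperatures do not match T")
  RT <- units_xt$R * T
  kg <- record_stats(gas_record, "K"); ug <- record_stats(gas_record, "U")
  ks <- record_stats(solid_record, "K"); us <- record_stats(solid_record, "U")
  pv <- solid_pV(solid_record, p, n_molecules)
  terms <- c(electronic_correction = correction$delta,
             kinetic_gas = kg$mean, potential_gas = ug$mean,
             kinetic_solid = -ks$mean / n_molecules,
             potential_solid = -us$mean / n_molecules,
             ideal_gas = 2.5 * RT, pV_solid = -pv$mean)
  sigma <- sqrt(kg$sem^2 + ug$sem^2 + (ks$sem / n_molecules)^2 +
                  (us$sem / n_molecules)^2 + pv$sem^2 +
                  correction$sigma^2)
  breakdown <- list(kinetic = kg$mean + 1.5 * RT - ks$mean / n_molecules,
                    potential = ug$mean - us$mean / n_molecules,
                    other = correction$delta + RT - pv$mean)
  res <- new_sublimation_result("MD", sum(terms), sigma, terms, breakdown,
                                T, p)
  res$constant_volume_solid <- pv$constant_volume
  res$model_level <- correction$model_level
  res
}

#' Quantum (PIMD) sublimation enthalpy
#'
#' dH = correction + <K_cv + U>_gas - <K_cv + U>_sol + RT - p<V>_sol per
#' molecule.  The centroid-virial kinetic estimator already contains the
#' (3/2)RT centre-of-mass energy, so only the ideal-gas pV term RT is
#' added; zero-point energy is naturally included in the sampled K_cv
#' and U.
#'
#' @inheritParams sublimation_md
#' @param gas_record,solid_record `pimd_record` objects.
#' @return a `sublimation_result`.
#' @export
sublimation_pimd <- function(correction, gas_record, solid_record, T,
                             p = 1, n_molecules = 1) {
  check_gas_record(gas_record)
  if (!solid_record$pbc) stop("solid record must be periodic")
  if (abs(gas_record$T - T) > 1e-9 || abs(solid_record$T - T) > 1e-9)
    stop("record temperatures do not match T")
  RT <- units_xt$R * T
  kg <- record_stats(gas_record, "K_cv"); ug <- record_stats(gas_record, "U")
  ks <- record_stats(solid_record, "K_cv")
  us <- record_stats(solid_record, "U")
  pv <- solid_pV(solid_record, p, n_molecules)
  terms <- c(electronic_correction = correction$delta,
             kinetic_cv_gas = kg$mean, potential_gas = ug$mean,
             kinetic_cv_solid = -ks$mean / n_molecules,
             potential_solid = -us$mean / n_molecules,
             ideal_gas = RT, pV_solid = -pv$mean)
  sigma <- sqrt(kg$sem^2 + ug$sem^2 + (ks$sem / n_molecules)^2 +
                  (us$sem / n_molecules)^2 + pv$sem^2 +
                  correction$sigma^2)
  breakdown <- list(kinetic = kg$mean - ks$mean / n_molecules,
                    potential = ug$mean - us$mean / n_molecules,
                    other = correction$delta + RT - pv$mean)
  res <- new_sublimation_result("PIMD", sum(terms), sigma, terms,
                                breakdown, T, p)
  res$constant_volume_solid <- pv$constant_volume
  res$model_level <- correction$model_level
  res
}

#' Kinetic/potential decomposition of method differences
#'
#' Pairwise differences of the sublimation enthalpy and of its kinetic
#' and potential contributions between methods (QHA, MD, PIMD) on the
#' same system and temperature; the bookkeeping identity
#' dH-difference = kinetic-difference + potential-difference +
#' other-difference holds to numerical precision by construction and is
#' asserted.
#'
#' @param results list of >= 2 `sublimation_result` objects at a common
#'   temperature.
#' @return data.frame with one row per ordered method pair: d_total,
#'   d_kinetic, d_potential, d_other.
#' @export
decompose_differences <- function(results) {
  if (length(results) < 2) stop("need at least two results")
  Ts <- vapply(results, function(r) r$T, 0)
  if (diff(range(Ts)) > 1e-9) stop("results are at different temperatures")
  methods <- vapply(results, function(r) r$method, "")
  rows <- list()
  for (a in seq_along(results)) for (b in seq_along(results)) {
    if (a >= b) next
    ra <- results[[a]]; rb <- results[[b]]
    d_tot <- ra$dH - rb$dH
    d_k <- ra$breakdown$kinetic - rb$breakdown$kinetic
    d_u <- ra$breakdown$potential - rb$breakdown$potential
    d_o <- ra$breakdown$other - rb$breakdown$other
    stopifnot(abs(d_tot - (d_k + d_u + d_o)) < 1e-10)
    rows[[length(rows) + 1]] <-
      data.frame(pair = paste(methods[a], methods[b], sep = "-"),
                 d_total = d_tot, d_kinetic = d_k, d_potential = d_u,
                 d_other = d_o)
  }
  do.call(rbind, rows)
}

#' Chemical-accuracy predicate
#'
#' @param value,reference energies (kJ/mol).
#' @param tol threshold, conventionally 4 kJ/mol (~1 kcal/mol).
#' @return logical.
#' @export
is_chemically_accurate <- function(value, reference, tol = 4) {
  abs(value - reference) < tol
}
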