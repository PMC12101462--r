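#' Relax a crystal at a target external pressure
#'
#' Alternates internal-coordinate minimisation (BFGS on the analytic
#' forces at fixed cell) with isotropic cell rescaling (1D enthalpy
#' minimisation over the scale factor) until the residual forces and the
#' static internal pressure P = tr(W)/(3V) meet tolerance.  Full
#' anisotropic cell relaxation is deliberately out of scope for the
#' packaged toy potentials.
#'
#' @param potential potential supplying a virial.
#' @param config periodic starting configuration.
#' @param p_ext external pressure (bar).
#' @param tol_f force tolerance (kJ/mol/A).
#' @param tol_p pressure tolerance (bar).
#' @param max_iter maximum outer iterations.
#' @return relaxed [atoms] object with `info$pressure` (bar),
#'   `info$enthalpy` (kJ/mol, E + pV).
#' @export
relax_cell_at_pressure <- function(potential, config, p_ext = 0,
                                   tol_f = 1e-4, tol_p = 1,
                                   max_iter = 60) {
  if (!config$pbc) stop("cell relaxation requires a periodic configuration")
  p_int_target <- p_ext * units_xt$bar_to_kjmolA3
  cfg <- config
  h_prev <- Inf
  for (iter in seq_len(max_iter)) {
    cfg <- relax_internal(potential, cfg, tol_f)
    out <- evaluate(potential, cfg)
    if (is.null(out$virial)) stop("potential supplies no virial")
    # isotropic scale step: minimise enthalpy over the linear scale s
    frac <- cfg$positions %*% solve(cfg$cell)
    V0c <- det(cfg$cell)
    hs <- function(s) {
      c2 <- cfg$cell * s
      cs <- cfg; cs$cell <- c2; cs$positions <- frac %*% c2
      evaluate(potential, cs)$energy + p_int_target * V0c * s^3
    }
    opt <- stats::optimize(hs, c(0.85, 1.18), tol = 1e-10)
    s <- opt$minimum
    if (s > 1.17) {
      # re-centre and retry once; persistent growth = unbound expansion
      opt2 <- stats::optimize(function(z) hs(1.17 * z), c(0.85, 1.18),
                              tol = 1e-10)
      if (opt2$minimum > 1.16)
        stop("unbound expansion at p = ", p_ext,
             " bar: enthalpy keeps decreasing with volume")
      s <- 1.17 * opt2$minimum
    }
    cellnew <- cfg$cell * s
    cfg$positions <- frac %*% cellnew
    cfg$cell <- cellnew
    cfg <- relax_internal(potential, cfg, tol_f)
    out <- evaluate(potential, cfg)
    Vol <- det(cfg$cell)
    p_now <- sum(diag(out$virial)) / (3 * Vol) / units_xt$bar_to_kjmolA3
    fmax <- max(abs(out$forces))
    h_now <- out$energy + p_int_target * Vol
    if (h_now > h_prev + 1e-8)
      warning("enthalpy increased during relaxation step")
    h_prev <- h_now
    if (fmax <= tol_f && abs(p_now - p_ext) <= tol_p) {
      cfg$info$pressure <- p_now
      cfg$info$enthalpy <- h_now
      return(cfg)
    }
  }
  stop("cell relaxation did not converge in ", max_iter,
       " iterations (last |F|max = ", format(fmax),
       ", P = ", format(p_now), " bar)")
}

# fixed-cell BFGS on the atomic positions with analytic gradient
relax_internal <- function(potential, config, tol_f) {
  x0 <- as.vector(t(config$positions))
  fn <- function(x) {
    evaluate(potential,
             config_with(config, x, config$cell))$energy
  }
  gr <- function(x) {
    -as.vector(t(evaluate(potential,
                          config_with(config, x, config$cell))$forces))
  }
  if (max(abs(gr(x0))) <= tol_f) return(config)
  opt <- stats::optim(x0, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  config$positions <- matrix(opt$par, ncol = 3, byrow = TRUE)
  config
}

#' Energy-volume scan at fixed external pressures
#'
#' Relaxes the crystal at each external pressure and collects one
#' (pressure, volume, energy) point per pressure, all per molecule;
#' the default pressures 0, +/-1, +/-2, +/-4 kbar give a seven-point
#' curve around equilibrium.  A Birch-Murnaghan fit is attached.
#'
#' @param potential potential supplying a virial.
#' @param config periodic starting configuration.
#' @param pressures external pressures (bar).
#' @param n_molecules molecules in `config` (for per-molecule scaling).
#' @param ... passed to [relax_cell_at_pressure].
#' @return object of class `eos_curve`: data.frame `points` (p, V, E per
#'   molecule, sorted by V), `fit` (see [fit_birch_murnaghan]),
#'   `configs` (relaxed structures by pressure).
#' @export
scan_eos <- function(potential, config,
                     pressures = c(0, 1000, -1000, 2000, -2000,
                                   4000, -4000),
                     n_molecules = 1, ...) {
  ord <- order(pressures, decreasing = TRUE)  # compress first, then expand
  cfg <- config
  rows <- list()
  configs <- list()
  failed <- character(0)
  for (pp in pressures[ord]) {
    res <- tryCatch(relax_cell_at_pressure(potential, cfg, pp, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("%g bar (%s)", pp, conditionMessage(res)))
      next
    }
    cfg <- res
    e <- evaluate(potential, cfg)$energy
    rows[[length(rows) + 1]] <-
      data.frame(p = pp, V = det(cfg$cell) / n_molecules,
                 E = e / n_molecules)
    configs[[sprintf("%g", pp)]] <- cfg
  }
  points <- do.call(rbind, rows)
  points <- points[order(points$V), , drop = FALSE]
  curve <- structure(list(points = points, configs = configs,
                          n_molecules = n_molecules,
                          fit = if (nrow(points) >= 5)
                            tryCatch(fit_birch_murnaghan(points$V, points$E),
                                     error = function(e) NULL) else NULL),
                     class = "eos_curve")
  if (length(failed)) {
    cond <- simpleError(paste0("relaxation failed at pressures: ",
                               paste(failed, collapse = "; ")))
    cond$partial_curve <- curve
    stop(cond)
  }
  curve
}

#' Fit a third-order Birch-Murnaghan equation of state
#'
#' E(V) = E0 + 9 V0 B0/16 [ x^3 B0' + x^2 (6 - 4 (V0/V)^(2/3)) ] with
#' x = (V0/V)^(2/3) - 1.  Initialised from a quadratic fit (vertex gives
#' V0 and E0, curvature gives B0, B0' starts at 4), refined by
#' Levenberg-Marquardt least squares; the fit is deterministic.
#'
#' @param V volumes (A^3, per molecule or per cell - any consistent
#'   scale).
#' @param E energies (kJ/mol) on the same per-unit basis.
#' @return object of class `bm_fit`: `V0`, `E0`, `B0` (kJ/mol/A^3),
#'   `B0_GPa`, `B0p`, `rms` residual, and functions `energy(V)`,
#'   `pressure(V)` (bar).
#' @export
fit_birch_murnaghan <- function(V, E) {
  stopifnot(length(V) == length(E))
  if (length(V) < 5) stop("need >= 5 points to fit a Birch-Murnaghan EOS")
  ord <- order(V); V <- V[ord]; E <- E[ord]
  if (which.min(E) %in% c(1, length(E)))
    stop("minimum not bracketed by the energy-volume data")
  qf <- stats::lm(E ~ V + I(V^2))
  cq <- stats::coef(qf)
  V0i <- -cq[2] / (2 * cq[3])
  E0i <- cq[1] + cq[2] * V0i + cq[3] * V0i^2
  B0i <- max(2 * cq[3] * V0i, 1e-8)      # B = V d2E/dV2 at V0
  bm <- function(V, E0, V0, B0, B0p) {
    eta <- (V0 / V)^(2 / 3)
    x <- eta - 1
    E0 + 9 * V0 * B0 / 16 * (x^3 * B0p + x^2 * (6 - 4 * eta))
  }
  dat <- data.frame(V = V, E = E)
  fit <- minpack.lm::nlsLM(
    E ~ bm(V, E0, V0, B0, B0p), data = dat,
    start = list(E0 = unname(E0i), V0 = unname(V0i),
                 B0 = unname(B0i), B0p = 4),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  cf <- stats::coef(fit)
  if (cf[["B0"]] <= 0) stop("fitted bulk modulus is not positive")
  pressure <- function(Vq) {
    eta <- (cf[["V0"]] / Vq)^(1 / 3)
    pk <- 1.5 * cf[["B0"]] * (eta^7 - eta^5) *
      (1 + 0.75 * (cf[["B0p"]] - 4) * (eta^2 - 1))
    pk / units_xt$bar_to_kjmolA3         # bar
  }
  structure(list(V0 = cf[["V0"]], E0 = cf[["E0"]], B0 = cf[["B0"]],
                 B0_GPa = cf[["B0"]] / units_xt$bar_to_kjmolA3 * 1e-4,
                 B0p = cf[["B0p"]],
                 rms = sqrt(mean(stats::resid(fit)^2)),
                 energy = function(Vq) bm(Vq, cf[["E0"]], cf[["V0"]],
                                          cf[["B0"]], cf[["B0p"]]),
                 pressure = pressure),
            class = "bm_fit")
}

#' Energy deviation profile between two equation-of-state curves
#'
#' Both curves are reduced to relative energies (each aligned to its own
#' minimum) and the model curve is interpolated (natural cubic spline)
#' onto the reference volumes; the pointwise |Delta E| profile and the
#' volume of largest deviation drive both validation and training-set
#' augmentation.
#'
#' @param model_curve,reference_curve `eos_curve` objects (or lists with
#'   a `points` data.frame of V and E).
#' @return list: data.frame `profile` (V, dE), `max_dev`, `argmax_V`.
#' @export
eos_deviation <- function(model_curve, reference_curve) {
  mp <- model_curve$points
  rp <- reference_curve$points
  if (max(mp$V) < min(rp$V) || min(mp$V) > max(rp$V))
    stop("model and reference volume ranges do not overlap")
  rel <- function(E) E - min(E)
  mfun <- stats::splinefun(mp$V, rel(mp$E), method = "natural")
  dE <- abs(mfun(rp$V) - rel(rp$E))
  list(profile = data.frame(V = rp$V, dE = dE),
       max_dev = max(dE), argmax_V = rp$V[which.max(dE)])
}
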