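#' Batched potential evaluation over ring-polymer beads
#'
#' Evaluates a potential at P replicas of a configuration stored as the
#' columns of a 3N x P matrix (atom-major coordinate layout).  The
#' default method loops over beads through [evaluate]; analytic
#' potentials with closed-form batch evaluation (the harmonic crystal
#' and the double-well hydrogen bond) override it for speed.
#'
#' @param potential potential object.
#' @param config template [atoms] object (supplies species, masses,
#'   cell).
#' @param X 3N x P matrix of bead coordinates, coordinate layout
#'   (x1, y1, z1, x2, ...).
#' @param caches optional list of per-bead pair-list caches.
#' @return list with `energies` (length P), `forces` (3N x P), `caches`.
#' @export
evaluate_batch <- function(potential, config, X, caches = NULL) {
  UseMethod("evaluate_batch")
}

#' @export
evaluate_batch.default <- function(potential, config, X, caches = NULL) {
  P <- ncol(X)
  if (is.null(caches)) caches <- vector("list", P)
  energies <- numeric(P)
  forces <- matrix(0, nrow(X), P)
  for (b in seq_len(P)) {
    config$positions <- matrix(X[, b], ncol = 3, byrow = TRUE)
    out <- evaluate(potential, config, cache = caches[[b]])
    energies[b] <- out$energy
    forces[, b] <- as.vector(t(out$forces))
    caches[b] <- list(out$cache)
  }
  list(energies = energies, forces = forces, caches = caches)
}

#' @export
evaluate_batch.harmonic_crystal <- function(potential, config, X,
                                            caches = NULL) {
  if (is.null(caches$phi)) caches <- list(phi = harmonic_phi_matrix(potential))
  ref <- as.vector(t(potential$reference$positions))
  U <- X - ref
  PhiU <- caches$phi %*% U
  list(energies = 0.5 * colSums(U * PhiU), forces = -PhiU, caches = caches)
}

#' @export
evaluate_batch.double_well_hbond <- function(potential, config, X,
                                             caches = NULL) {
  pot <- potential
  m <- config$masses
  # layout: rows 1:3 O1(xyz), 4:6 H, 7:9 O2
  s <- X[4, ] - (X[1, ] + X[7, ]) / 2
  R <- X[7, ] - X[1, ]
  dVds <- 4 * pot$barrier * s * (s^2 / pot$s0^2 - 1) / pot$s0^2 +
    2 * pot$coupling * s * (R - pot$r0)
  dVdR <- pot$coupling * s^2 + pot$k_oo * (R - pot$r0)
  E <- hbond_vsr(pot, s, R)
  f <- matrix(0, 9, ncol(X))
  f[1, ] <- 0.5 * dVds + dVdR
  f[4, ] <- -dVds
  f[7, ] <- 0.5 * dVds - dVdR
  tr <- c(2, 3, 5, 6, 8, 9)            # transverse coordinates
  E <- E + 0.5 * pot$k_t * colSums(X[tr, , drop = FALSE]^2)
  f[tr, ] <- -pot$k_t * X[tr, , drop = FALSE]
  xcom <- (m[1] * X[1, ] + m[2] * X[4, ] + m[3] * X[7, ]) / sum(m)
  E <- E + 0.5 * pot$k_com * xcom^2
  for (kidx in c(1, 4, 7))
    f[kidx, ] <- f[kidx, ] - pot$k_com * xcom * m[(kidx + 2) / 3] / sum(m)
  list(energies = E, forces = f, caches = caches)
}

# real orthogonal ring-polymer normal-mode transform (P x P) and the
# integer wave number of each mode column
ring_polymer_modes <- function(P) {
  j <- 0:(P - 1)
  C <- matrix(0, P, P)
  C[, 1] <- 1 / sqrt(P)
  wave <- numeric(P)
  col <- 2L
  kmax <- if (P %% 2 == 0) P / 2 - 1 else (P - 1) / 2
  for (k in seq_len(max(kmax, 0))) {
    C[, col] <- sqrt(2 / P) * cos(2 * pi * j * k / P)
    C[, col + 1] <- sqrt(2 / P) * sin(2 * pi * j * k / P)
    wave[col] <- wave[col + 1] <- k
    col <- col + 2L
  }
  if (P %% 2 == 0) {
    C[, P] <- (-1)^j / sqrt(P)
    wave[P] <- P / 2
  }
  list(C = C, wave = wave)
}

#' Path-integral (and classical) Langevin dynamics
#'
#' One integrator covers both classical MD and PIMD: a ring polymer of P
#' beads is propagated with the BAOAB splitting in normal-mode
#' coordinates, with exact harmonic propagation of the free-ring-polymer
#' springs and PILE thermostatting (centroid at `friction`, internal
#' modes at their optimal coupling gamma_k = 2 omega_k).  P = 1 reduces
#' the scheme exactly to classical Langevin BAOAB, so [run_md] is this
#' function at a single bead.
#'
#' The NPT ensemble uses an isotropic stochastic cell: Monte Carlo
#' volume moves in ln V every `barostat_every` steps with the exact
#' acceptance rule for the discretised (bead-scaled) partition function,
#' so average internal pressure matches the target without a piston
#' parameter.
#'
#' @param potential potential object.
#' @param config starting [atoms] configuration.
#' @param P number of beads (>= 1; > 512 is refused unless
#'   `allow_large_P`).
#' @param ensemble "NVT" or "NPT".
#' @param T temperature (K).
#' @param p external pressure (bar), NPT only.
#' @param n_steps number of timesteps.
#' @param dt timestep (ps), default 1 fs.
#' @param seed RNG seed; fixed (inputs, seed) give bit-identical output.
#' @param stride sampling stride in steps.
#' @param friction centroid thermostat friction (1/ps).
#' @param equilibration fraction of samples discarded by the statistics
#'   helpers (recorded, not dropped).
#' @param remove_com remove the centre-of-mass velocity every step
#'   (default: gas phase yes, solid no).
#' @param store_frames keep bead positions at every stride.
#' @param barostat_every,barostat_dlnV MC barostat cadence and maximum
#'   ln V step.
#' @param allow_large_P override the desk-scale bead-count guard.
#' @return object of class `pimd_record` (and `trajectory_record` when
#'   P = 1) carrying sampled series of t, K, K_cv, U, V, spring energy,
#'   instantaneous pressure (when the potential has a virial), frames,
#'   and all run metadata.
#' @export
run_pimd <- function(potential, config, P = 32,
                     ensemble = c("NVT", "NPT"), T = 300, p = 1,
                     n_steps = 1000, dt = 1e-3, seed = 1, stride = 10,
                     friction = 1, equilibration = 0.2,
                     remove_com = !config$pbc, store_frames = FALSE,
                     barostat_every = 20, barostat_dlnV = 0.02,
                     allow_large_P = FALSE) {
  ensemble <- match.arg(ensemble)
  if (P < 1) stop("P must be >= 1")
  if (P > 512 && !allow_large_P)
    stop("P > 512 refused (desk-scale guard); set allow_large_P = TRUE")
  if (n_steps < 1) stop("n_steps must be positive")
  if (ensemble == "NPT" && !config$pbc)
    stop("NPT requires a periodic configuration")
  kB <- units_xt$kB
  n <- n_atoms(config)
  n3 <- 3L * n
  m3 <- rep(config$masses, each = 3)
  X <- matrix(as.vector(t(config$positions)), n3, P)
  cell <- config$cell
  set.seed(seed)

  # bead-level temperature: the discretised distribution exp(-beta_P H_P)
  # is sampled at beta_P = beta / P, i.e. each bead dof at temperature P*T
  Tbead <- P * T
  sig_v <- sqrt(units_xt$mass_freq2 * kB * Tbead / m3)
  Vel <- matrix(stats::rnorm(n3 * P), n3, P) * sig_v

  nm <- ring_polymer_modes(P)
  omega_P <- P * kB * T / units_xt$hbar         # rad/ps
  omega_k <- 2 * omega_P * sin(pi * nm$wave / P)
  gamma_k <- ifelse(nm$wave == 0, friction, 2 * omega_k)
  c1 <- exp(-gamma_k * dt)
  c2 <- sqrt(1 - c1^2)                          # times sig_v per dof
  cos_h <- cos(omega_k * dt / 2)
  sin_h <- sin(omega_k * dt / 2)
  # q' = q cos + (v/w) sin ; v' = v cos - w q sin  (w = 0: drift)
  w_safe <- ifelse(omega_k == 0, 1, omega_k)
  drift0 <- nm$wave == 0

  ev <- evaluate_batch(potential, config_with(config, X[, 1], cell), X)
  caches <- ev$caches
  acc <- sweep(ev$forces, 1, m3, "/") * units_xt$mass_freq2

  p_int <- if (ensemble == "NPT") p * units_xt$bar_to_kjmolA3 else 0
  beta <- 1 / (kB * T)
  beta_P <- beta / P
  n_samples <- n_steps %/% stride
  ser <- list(t = numeric(n_samples), K = numeric(n_samples),
              K_cv = numeric(n_samples), U = numeric(n_samples),
              V = numeric(n_samples), E_spring = numeric(n_samples),
              P_inst = rep(NA_real_, n_samples))
  frames <- if (store_frames) vector("list", n_samples) else NULL
  have_virial <- FALSE
  n_accept <- 0L; n_propose <- 0L
  isample <- 0L

  spring_energy <- function(Q) {
    0.5 * units_xt$kin *
      sum(m3 * sweep(Q^2, 2, omega_k^2, "*"))
  }

  for (step in seq_len(n_steps)) {
    # B
    Vel <- Vel + 0.5 * dt * acc
    # A(dt/2) O(dt) A(dt/2) in normal modes
    Q <- X %*% nm$C
    W <- Vel %*% nm$C
    Qn <- sweep(Q, 2, cos_h, "*") +
      sweep(sweep(W, 2, w_safe, "/"), 2, sin_h, "*")
    Wn <- sweep(W, 2, cos_h, "*") - sweep(sweep(Q, 2, w_safe, "*"),
                                          2, sin_h, "*")
    if (any(drift0)) {
      Qn[, drift0] <- Q[, drift0] + W[, drift0] * dt / 2
      Wn[, drift0] <- W[, drift0]
    }
    noise <- matrix(stats::rnorm(n3 * P), n3, P)
    Wn <- sweep(Wn, 2, c1, "*") + sweep(noise * sig_v, 2, c2, "*")
    Q2 <- sweep(Qn, 2, cos_h, "*") +
      sweep(sweep(Wn, 2, w_safe, "/"), 2, sin_h, "*")
    W2 <- sweep(Wn, 2, cos_h, "*") - sweep(sweep(Qn, 2, w_safe, "*"),
                                           2, sin_h, "*")
    if (any(drift0)) {
      Q2[, drift0] <- Qn[, drift0] + Wn[, drift0] * dt / 2
      W2[, drift0] <- Wn[, drift0]
    }
    X <- Q2 %*% t(nm$C)
    Vel <- W2 %*% t(nm$C)
    if (remove_com) {
      for (d in 1:3) {
        idx <- seq(d, n3, 3)
        vcom <- sum(m3[idx] * rowSums(Vel[idx, , drop = FALSE])) /
          (sum(m3[idx]) * P)
        Vel[idx, ] <- Vel[idx, ] - vcom
      }
    }
    # B
    ev <- evaluate_batch(potential, config_with(config, X[, 1], cell), X,
                         caches)
    caches <- ev$caches
    acc <- sweep(ev$forces, 1, m3, "/") * units_xt$mass_freq2
    Vel <- Vel + 0.5 * dt * acc

    # MC barostat
    if (ensemble == "NPT" && step %% barostat_every == 0) {
      n_propose <- n_propose + 1L
      dlnV <- stats::runif(1, -barostat_dlnV, barostat_dlnV)
      s <- exp(dlnV / 3)
      Xs <- X * s
      cell_s <- cell * s
      Vold <- det(cell); Vnew <- det(cell_s)
      evs <- evaluate_batch(potential, config_with(config, Xs[, 1], cell_s),
                            Xs)
      Qs <- X %*% nm$C
      espr <- spring_energy(Qs)
      dPhi <- sum(evs$energies) - sum(ev$energies) + (s^2 - 1) * espr
      lnacc <- -beta_P * dPhi - beta * p_int * (Vnew - Vold) +
        (n * P + 1) * dlnV
      if (log(stats::runif(1)) < lnacc) {
        n_accept <- n_accept + 1L
        X <- Xs; cell <- cell_s
        ev <- evs
        caches <- ev$caches %||% caches
        acc <- sweep(ev$forces, 1, m3, "/") * units_xt$mass_freq2
      }
    }

    if (step %% stride == 0) {
      isample <- isample + 1L
      Ubar <- mean(ev$energies)
      if (!is.finite(Ubar) || abs(Ubar) > 1e6)
        stop("energy divergence at step ", step,
             " (U = ", format(Ubar), ")")
      xbar <- rowMeans(X)
      kcv <- 1.5 * n * kB * T -
        0.5 / P * sum((X - xbar) * ev$forces)
      Kkin <- 0.5 * units_xt$kin * sum(m3 * Vel^2) / P
      Q <- X %*% nm$C
      ser$t[isample] <- step * dt
      ser$K[isample] <- Kkin
      ser$K_cv[isample] <- kcv
      ser$U[isample] <- Ubar
      ser$V[isample] <- if (config$pbc) det(cell) else NA_real_
      ser$E_spring[isample] <- spring_energy(Q)
      if (P == 1 && config$pbc && ensemble == "NPT") {
        one <- evaluate(potential, config_with(config, X[, 1], cell),
                        cache = if (!is.null(caches) &&
                                    !is.null(caches[[1]])) caches[[1]])
        if (!is.null(one$virial)) {
          have_virial <- TRUE
          ser$P_inst[isample] <-
            (2 * Kkin + sum(diag(one$virial))) / (3 * det(cell)) /
            units_xt$bar_to_kjmolA3
        }
      }
      if (store_frames)
        frames[[isample]] <- list(X = X, cell = cell)
    }
  }
  structure(list(series = as.data.frame(ser[c("t", "K", "K_cv", "U", "V",
                                              "E_spring", "P_inst")]),
                 frames = frames,
                 ensemble = ensemble, T = T, p = p, P = P, dt = dt,
                 stride = stride, seed = seed,
                 equilibration = equilibration,
                 pbc = config$pbc, n_atoms = n, masses = config$masses,
                 species = config$species,
                 cell_final = cell, remove_com = remove_com,
                 have_virial = have_virial,
                 barostat_acceptance = if (n_propose) n_accept / n_propose
                 else NA_real_),
            class = if (P == 1) c("trajectory_record", "pimd_record")
            else "pimd_record")
}

config_with <- function(config, xvec, cell) {
  config$positions <- matrix(xvec, ncol = 3, byrow = TRUE)
  config$cell <- cell
  config$pbc <- !is.null(cell)
  config
}

#' Classical Langevin molecular dynamics
#'
#' BAOAB Langevin dynamics in the NVT or NPT (isotropic stochastic cell)
#' ensemble; a thin wrapper around [run_pimd] with a single bead, which
#' guarantees that a one-bead path-integral run reproduces the classical
#' trajectory bit for bit.
#'
#' @inheritParams run_pimd
#' @return a `trajectory_record`; the `K` series is the classical
#'   kinetic energy.
#' @export
run_md <- function(potential, config, ensemble = c("NVT", "NPT"),
                   T = 300, p = 1, n_steps = 1000, dt = 1e-3, seed = 1,
                   stride = 10, friction = 1, equilibration = 0.2,
                   remove_com = !config$pbc, store_frames = FALSE,
                   barostat_every = 20, barostat_dlnV = 0.02) {
  run_pimd(potential, config, P = 1, ensemble = match.arg(ensemble),
           T = T, p = p, n_steps = n_steps, dt = dt, seed = seed,
           stride = stride, friction = friction,
           equilibration = equilibration, remove_com = remove_com,
           store_frames = store_frames, barostat_every = barostat_every,
           barostat_dlnV = barostat_dlnV)
}

#' Reblocked statistics of a recorded series
#'
#' Applies the equilibration discard stored in the record, then
#' [reblock].
#'
#' @param record a `pimd_record` / `trajectory_record`.
#' @param what series name ("K", "K_cv", "U", "V", "E_spring", "P_inst").
#' @return list with `mean`, `sem` (reblocked), `n`.
#' @export
record_stats <- function(record, what) {
  x <- record$series[[what]]
  if (is.null(x)) stop("no series named ", what)
  keep <- seq_len(length(x))
  drop <- floor(record$equilibration * length(x))
  if (drop > 0) keep <- keep[-seq_len(drop)]
  x <- x[keep]
  if (length(x) >= 64) {
    rb <- reblock(x)
    list(mean = rb$mean, sem = rb$sem, n = length(x))
  } else {
    list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
         n = length(x))
  }
}

#' Centroid-virial kinetic-energy estimator
#'
#' K_cv = (3N/2) kB T + (1/2P) sum_{beads j, atoms i}
#' (r_i^(j) - rbar_i) . (-F_i^(j)): the low-variance path-integral
#' estimator of the quantum kinetic energy.  When all beads coincide
#' with the centroid (or P = 1) it reduces exactly to (3N/2) kB T.
#'
#' @param X 3N x P bead coordinate matrix.
#' @param forces 3N x P matrix of forces at the beads.
#' @param T temperature (K).
#' @return kinetic energy estimate, kJ/mol.
#' @export
centroid_virial_kinetic <- function(X, forces, T) {
  if (!all(dim(X) == dim(forces)))
    stop("bead and force arrays have mismatched shapes")
  n3 <- nrow(X)
  if (n3 %% 3 != 0) stop("coordinate count must be a multiple of 3")
  P <- ncol(X)
  1.5 * (n3 / 3) * units_xt$kB * T -
    0.5 / P * sum((X - rowMeans(X)) * forces)
}
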