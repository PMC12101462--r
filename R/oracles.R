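#' Exact finite-bead energy of a harmonic mode
#'
#' For a 1D harmonic oscillator of angular frequency omega sampled by a
#' P-bead ring polymer, the discretised partition function is Gaussian
#' and the expected total energy <K_cv + U> has the closed form
#' kB T omega^2 sum_k 1/Omega_k^2 with
#' Omega_k^2 = omega^2 + [2 omega_P sin(pi k / P)]^2 and
#' omega_P = P kB T / hbar.  A zero-frequency (free) mode contributes
#' kB T / 2 through the centroid-virial estimator.  As P grows this
#' converges to the exact quantum result (hbar omega / 2)
#' coth(hbar omega / 2 kB T); at P = 1 it is the classical kB T.
#'
#' This is the independent reference for path-integral runs on harmonic
#' systems: it involves no dynamics, only Gaussian algebra.
#'
#' @param omega angular frequency (rad/ps); vectorised.
#' @param T temperature (K).
#' @param P bead count.
#' @return expected <K_cv + U> per mode (kJ/mol).
#' @export
harmonic_finite_p_energy <- function(omega, T, P) {
  kB <- units_xt$kB
  omega_P <- P * kB * T / units_xt$hbar
  vapply(omega, function(w) {
    if (w <= 1e-10) return(0.5 * kB * T)
    Ok2 <- w^2 + (2 * omega_P * sin(pi * (0:(P - 1)) / P))^2
    kB * T * w^2 * sum(1 / Ok2)
  }, 0)
}

#' Exact quantum energy of a harmonic mode
#'
#' (hbar omega / 2) coth(hbar omega / 2 kB T); the T = 0 limit is the
#' zero-point energy hbar omega / 2.
#'
#' @param omega angular frequency (rad/ps); vectorised.
#' @param T temperature (K), >= 0.
#' @return energy (kJ/mol).
#' @export
harmonic_quantum_energy <- function(omega, T) {
  harmonic_mode_energy(omega, T, omega_tol = 0)
}

#' Exact thermal averages of the double-well hydrogen-bond model
#'
#' Grid diagonalisation of the two internal degrees of freedom of the
#' collinear O-H-O model: the proton-transfer coordinate s (Jacobi mass
#' 2 m_O m_H / (2 m_O + m_H)) and the donor-acceptor separation R
#' (Jacobi mass m_O / 2), with the same V(s, R) as the dynamical model.
#' The kinetic operator uses a 5-point finite-difference stencil; the
#' Boltzmann-weighted <R> and <s^2> over the exact eigenstates are the
#' reference values for path-integral runs (the transverse tether modes
#' are harmonic, mass-independent in their parameters, and separable,
#' so they cancel in H/D differences).
#'
#' @param potential a [potential_double_well_hbond].
#' @param m_h proton (or deuteron) mass, g/mol.
#' @param m_o heavy-atom mass, g/mol.
#' @param T temperature (K); 0 gives ground-state expectations.
#' @param ns,nR grid sizes for s and R.
#' @param s_max half-width of the s grid (Angstrom).
#' @param R_half half-width of the R grid around r0 (Angstrom).
#' @return list: `mean_R`, `mean_s2`, `energies` (lowest few, kJ/mol),
#'   `weights`.
#' @export
hbond_oracle_thermal <- function(potential, m_h = 1.008, m_o = 15.999,
                                 T = 300, ns = 64, nR = 44,
                                 s_max = 1.0, R_half = 0.75) {
  mu_s <- 2 * m_o * m_h / (2 * m_o + m_h)
  mu_R <- m_o / 2
  s <- seq(-s_max, s_max, length.out = ns)
  R <- seq(potential$r0 - R_half, potential$r0 + R_half, length.out = nR)
  ds <- s[2] - s[1]; dR <- R[2] - R[1]
  # 5-point FD second derivative with Dirichlet boundaries
  lap1d <- function(n, h) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      M[i, i] <- -30
      if (i > 1) M[i, i - 1] <- 16
      if (i < n) M[i, i + 1] <- 16
      if (i > 2) M[i, i - 2] <- -1
      if (i < n - 1) M[i, i + 2] <- -1
    }
    M / (12 * h^2)
  }
  pref <- units_xt$hbar^2 * units_xt$mass_freq2 / 2   # kJ/mol A^2 (g/mol)
  Ts <- -pref / mu_s * lap1d(ns, ds)
  TR <- -pref / mu_R * lap1d(nR, dR)
  V <- outer(s, R, function(sv, Rv) hbond_vsr(potential, sv, Rv))
  H <- kronecker(Ts, diag(nR)) + kronecker(diag(ns), TR) + diag(as.vector(t(V)))
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  E <- rev(ev$values)
  U <- ev$vectors[, rev(seq_len(ncol(ev$vectors)))]
  if (T <= 0) {
    w <- c(1, numeric(length(E) - 1))
  } else {
    beta <- 1 / (units_xt$kB * T)
    w <- exp(-beta * (E - E[1]))
    w <- w / sum(w)
  }
  keep <- which(w > 1e-12)
  Rgrid <- rep(R, times = ns)          # state vectors are (s-major, R fast)
  s_grid <- rep(s, each = nR)
  mean_R <- sum(vapply(keep, function(n)
    w[n] * sum(U[, n]^2 * Rgrid), 0))
  mean_s2 <- sum(vapply(keep, function(n)
    w[n] * sum(U[, n]^2 * s_grid^2), 0))
  list(mean_R = mean_R, mean_s2 = mean_s2,
       energies = E[seq_len(min(10, length(E)))], weights = w[keep])
}

#' Analytic standard error of an AR(1) mean
#'
#' For x_t = phi x_{t-1} + e_t with e ~ N(0, sigma^2), the variance of
#' the sample mean of n points is asymptotically
#' sigma^2/(1-phi^2) * (1+phi)/(1-phi) / n.
#'
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param sigma innovation standard deviation.
#' @param n series length.
#' @return standard error of the mean.
#' @export
ar1_sem <- function(phi, sigma, n) {
  stopifnot(abs(phi) < 1)
  sqrt(sigma^2 / (1 - phi^2) * (1 + phi) / (1 - phi) / n)
}
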