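# shared toy systems, built once per test run
.sys <- local({
  cache <- new.env(parent = emptyenv())
  function(name, builder) {
    if (is.null(cache[[name]])) cache[[name]] <- builder()
    cache[[name]]
  }
})

harmonic_sys <- function() .sys("harm", toy_harmonic_crystal)
lj_sys <- function() .sys("lj", toy_lj_crystal)
mol_sys <- function() .sys("mol", toy_molecular_crystal)

# supercell-Hessian mode frequencies (rad/ps) of a harmonic system
harmonic_mode_freqs <- function(sysd) {
  phi <- harmonic_phi_matrix(sysd$potential)
  m3 <- rep(sysd$crystal$masses, each = 3)
  lam <- eigen(phi / sqrt(outer(m3, m3)) * units_xt$mass_freq2,
               symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(lam, 0))
}

# a deterministic jiggled copy of a configuration
jiggle <- function(config, amp = 0.05, seed = 1) {
  set.seed(seed)
  config$positions <- config$positions +
    matrix(stats::rnorm(3 * n_atoms(config), 0, amp), ncol = 3)
  config
}

# closed-form 3rd-order Birch-Murnaghan energy (B0 in GPa)
bm_energy_closed <- function(V, V0, E0, B0_GPa, B0p) {
  B0 <- B0_GPa * 1e4 * units_xt$bar_to_kjmolA3
  eta <- (V0 / V)^(2 / 3)
  x <- eta - 1
  E0 + 9 * V0 * B0 / 16 * (x^3 * B0p + x^2 * (6 - 4 * eta))
}

# fabricate a record with prescribed constant series (for bookkeeping tests)
constant_record <- function(K, U, V, n = 100, ensemble = "NPT", T = 300,
                            pbc = TRUE, Kcv = K) {
  structure(list(series = data.frame(t = seq_len(n), K = K, K_cv = Kcv,
                                     U = U, V = V, E_spring = 0,
                                     P_inst = NA_real_),
                 ensemble = ensemble, T = T, p = 1, P = 1, dt = 1e-3,
                 stride = 1, seed = 0, equilibration = 0, pbc = pbc,
                 n_atoms = 1, frames = NULL),
            class = c("trajectory_record", "pimd_record"))
}
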