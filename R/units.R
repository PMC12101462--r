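#' Internal unit system and physical constants
#'
#' All quantities in the package are carried in one fixed unit system:
#' length in Angstrom, mass in g/mol, time in ps, energy in kJ/mol,
#' temperature in K and pressure in bar.  In these units the molar gas
#' constant R and the per-mole Boltzmann constant coincide.
#'
#' Numerically 1 (g/mol)(A/ps)^2 = 1e-3 kg/mol * 1e-20 m^2 / 1e-24 s^2
#' = 10 J/mol = 0.01 kJ/mol; the element `kin` absorbs this factor so
#' that K = kin * sum(m v^2)/2 is in kJ/mol.  Likewise omega^2 = 100 k/m
#' for spring constants in kJ/mol/A^2 and masses in g/mol (`mass_freq2`).
#'
#' @format A list with elements:
#' \describe{
#'   \item{R}{gas constant, kJ/mol/K}
#'   \item{kB}{Boltzmann constant per mole (identical to R), kJ/mol/K}
#'   \item{hbar}{reduced Planck constant, kJ/mol * ps}
#'   \item{bar_to_kjmolA3}{1 bar expressed in kJ/mol/A^3}
#'   \item{kin}{prefactor turning (g/mol)(A/ps)^2 into kJ/mol (= 0.01)}
#'   \item{mass_freq2}{prefactor: omega^2 [rad^2/ps^2] = mass_freq2 * k/m
#'     for k in kJ/mol/A^2 and m in g/mol (= 100)}
#'   \item{radps_to_cm1}{conversion factor from angular rad/ps to cm^-1}
#' }
#' @export
units_xt <- local({
  avogadro <- 6.02214076e23
  hbar_si  <- 1.054571817e-34           # J s
  c_cm     <- 2.99792458e10             # cm/s
  list(
    R   = 8.31446261815324e-3,          # kJ/mol/K
    kB  = 8.31446261815324e-3,          # per-mole Boltzmann, same units
    hbar = hbar_si * avogadro / 1e3 * 1e12,   # kJ/mol ps = 0.0635078...
    bar_to_kjmolA3 = 1e5 * avogadro / 1e3 / 1e30,  # 6.022e-5
    kin = 1e-2,
    mass_freq2 = 1e2,
    radps_to_cm1 = 1e12 / (2 * pi * c_cm)
  )
})

#' Convert pressure between bar and internal energy density
#'
#' @param p numeric pressure values.
#' @param from,to either "bar" or "kJ/mol/A3".
#' @return converted numeric vector.
#' @export
convert_pressure <- function(p, from = "bar", to = "kJ/mol/A3") {
  units <- c(bar = 1, `kJ/mol/A3` = 1 / units_xt$bar_to_kjmolA3)
  if (!from %in% names(units) || !to %in% names(units))
    stop("unknown pressure unit")
  p * units[[to]] / units[[from]]
}

#' Convert angular frequencies between rad/ps and cm^-1
#'
#' Frequencies are stored internally as angular frequencies in rad/ps;
#' wavenumbers are offered at I/O boundaries only.
#'
#' @param omega numeric frequencies.
#' @param from,to either "rad/ps" or "cm-1".
#' @return converted numeric vector.
#' @export
convert_frequency <- function(omega, from = "rad/ps", to = "cm-1") {
  units <- c(`rad/ps` = 1, `cm-1` = units_xt$radps_to_cm1)
  if (!from %in% names(units) || !to %in% names(units))
    stop("unknown frequency unit")
  omega * units[[to]] / units[[from]]
}
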