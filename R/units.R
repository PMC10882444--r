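# Physical constants. Internal energy unit is cm^-1 throughout; magnetic
# fields are in tesla, hyperfine couplings are carried in MHz and converted
# on demand.

.units <- list(
  mu_B         = 0.4668644770,  # Bohr magneton / hc, cm^-1 T^-1
  k_B          = 0.695035,      # Boltzmann constant, cm^-1 K^-1
  MHz_per_cm1  = 29979.2458,    # c in MHz per cm^-1
  mu_N_MHz     = 7.622593285,   # nuclear magneton / h, MHz T^-1
  mmps_to_MHz  = 11.6248,       # 1 mm s^-1 for the 14.4125 keV 57Fe line
  E_gamma_keV  = 14.4125,
  g_n_57Fe_gnd = 0.18121,       # 57Fe nuclear g, I = 1/2 ground state
  g_n_57Fe_exc = -0.10353,      # 57Fe nuclear g, I = 3/2 excited state
  g_n_55Mn     = 1.3819
)

#' Physical constants used by the package
#'
#' Returns the fixed table of physical constants underlying all unit
#' conversions: the Bohr magneton and Boltzmann constant in cm^-1, the
#' nuclear magneton in MHz/T, the Doppler conversion for the 14.4125 keV
#' 57Fe Moessbauer transition, and the nuclear g-factors of the 57Fe
#' ground/excited states and of 55Mn.
#'
#' @return Named list of constants.
#' @export
#' @examples
#' unit_table()$mu_B   # cm^-1 T^-1
unit_table <- function() .units

#' Convert between MHz and cm^-1
#'
#' @param x Numeric values to convert.
#' @return Converted values.
#' @export
mhz_to_wavenumber <- function(x) x / .units$MHz_per_cm1

#' @rdname mhz_to_wavenumber
#' @export
wavenumber_to_mhz <- function(x) x * .units$MHz_per_cm1

#' Convert a hyperfine coupling between MHz and tesla
#'
#' The field-unit convention divides the energy coupling by \eqn{g_n \mu_N},
#' so the conversion requires the nuclear g-factor of the nucleus involved.
#'
#' @param A Coupling values.
#' @param g_n Nuclear g-factor.
#' @param from Unit of `A`, `"MHz"` or `"T"`.
#' @return Converted coupling (T if `from = "MHz"`, MHz otherwise).
#' @export
#' @examples
#' convert_hyperfine(-20, g_n = unit_table()$g_n_57Fe_gnd, from = "T")
convert_hyperfine <- function(A, g_n, from = c("MHz", "T")) {
  from <- match.arg(from)
  if (from == "MHz") A / (g_n * .units$mu_N_MHz) else A * (g_n * .units$mu_N_MHz)
}

#' Convert velocity (mm/s) to MHz for the 57Fe Moessbauer line
#' @param v Velocities in mm/s.
#' @return Frequencies in MHz.
#' @export
mmps_to_mhz <- function(v) v * .units$mmps_to_MHz

#' @rdname mmps_to_mhz
#' @param f Frequencies in MHz.
#' @export
mhz_to_mmps <- function(f) f / .units$mmps_to_MHz
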