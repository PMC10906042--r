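#' Physical constants and unit conversions
#'
#' Internal unit system: hbar = k_B = 1.  Dimensionless ("atomic-style")
#' parameters, as customary for the spin-boson model, are used as given.
#' Wavenumber-parameterized models (e.g. exciton Hamiltonians in cm^-1)
#' are converted to angular frequency in rad/fs, with time in fs, so that
#' energy and angular frequency coincide.
#'
#' @name krausdyn-units
#' @keywords internal
NULL

## speed of light in cm/fs (CODATA)
.kd_c_cm_fs <- 2.99792458e-5
## Boltzmann constant in cm^-1 / K (CODATA 2018: 0.695034800 cm^-1/K)
.kd_kB_cm1_K <- 0.695034800
## cm^-1 -> rad/fs: omega = 2*pi*c*nu_tilde
.kd_cm1_to_radfs <- 2 * pi * .kd_c_cm_fs

#' Convert between supported physical units
#'
#' Supported conversions: `"cm-1" <-> "rad/fs"` (wavenumber to internal
#' angular frequency), `"K" -> "cm-1"` (temperature to thermal energy
#' k_B T as a wavenumber), `"K" -> "beta_radfs"` (temperature to inverse
#' temperature in the internal rad/fs energy unit) and `"cm-1" -> "beta_cm1"`.
#'
#' @param value numeric vector to convert.
#' @param from,to unit labels (see Details).
#' @return converted numeric vector.
#' @examples
#' convert_units(300, "K", "cm-1")        # ~208.51
#' convert_units(35, "cm-1", "rad/fs")
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value))
  key <- paste(from, to, sep = "->")
  switch(key,
    "cm-1->rad/fs" = value * .kd_cm1_to_radfs,
    "rad/fs->cm-1" = value / .kd_cm1_to_radfs,
    "K->cm-1"      = value * .kd_kB_cm1_K,
    "cm-1->K"      = value / .kd_kB_cm1_K,
    "K->beta_radfs" = 1 / (value * .kd_kB_cm1_K * .kd_cm1_to_radfs),
    "beta_radfs->K" = 1 / (value * .kd_kB_cm1_K * .kd_cm1_to_radfs),
    stop("unsupported unit conversion: ", from, " -> ", to)
  )
}
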