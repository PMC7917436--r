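#' Physical constants and unit conversions
#'
#' Conversion factors used throughout the package. Energies in the electronic
#' records are in eV; vibronic quantities (mode frequencies, reorganization
#' energies, Stokes shifts, spectral axes) are in wavenumbers (cm^-1).
#'
#' @format NULL
#' @name constants
NULL

# 1 eV in cm^-1
EV_TO_CM1 <- 8065.544

# Boltzmann constant in cm^-1 per Kelvin
KB_CM1 <- 0.69503480

# 1 Hartree in cm^-1 (used when converting normal-mode frequencies to
# atomic units for the Huang-Rhys gradient formula)
HARTREE_TO_CM1 <- 219474.6313632

#' Convert energies between eV and wavenumbers
#'
#' @param x numeric vector of energies.
#' @return numeric vector in the target unit (1 eV = 8065.544 cm^-1).
#' @examples
#' ev_to_cm1(0.4)   # ~3226 cm^-1
#' @export
ev_to_cm1 <- function(x) x * EV_TO_CM1

#' @rdname ev_to_cm1
#' @export
cm1_to_ev <- function(x) x / EV_TO_CM1

# trapezoidal area; thin wrapper kept private so the integration rule is
# defined in one place
.trapz <- function(x, y) pracma::trapz(x, y)
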