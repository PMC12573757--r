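# Single source of truth for physical constants and unit conversions.
# Fundamental constants are CODATA 2018; derived conversion factors are
# computed, not transcribed.

.codata <- list(
  hbar = 1.054571817e-34,        # J s
  e    = 1.602176634e-19,        # C
  a0   = 0.529177210903e-10,     # m
  Eh   = 4.3597447222071e-18,    # J
  me   = 9.1093837015e-31,       # kg
  c    = 299792458               # m/s
)

#' Physical constants and conversion factors
#'
#' All internal arithmetic in the package is in Hartree atomic units.  This
#' table is the single place where unit conversions are defined: one atomic
#' unit of electric field is \eqn{E_h/(e a_0)} and one atomic unit of
#' magnetic field (magnetic flux density) is \eqn{\hbar/(e a_0^2)}.  The
#' Angstrom/bohr factor used at all I/O boundaries is fixed here as well.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{angstrom_per_bohr}{length conversion used for XYZ I/O}
#'   \item{efield_au_to_V_per_m}{atomic unit of electric field in V/m}
#'   \item{bfield_au_to_T}{atomic unit of magnetic flux density in tesla}
#'   \item{codata}{the underlying CODATA 2018 fundamental constants (SI)}
#' }
#' @export
qed_constants <- list(
  angstrom_per_bohr   = 0.52917721092,
  efield_au_to_V_per_m = .codata$Eh / (.codata$e * .codata$a0),
  bfield_au_to_T       = .codata$hbar / (.codata$e * .codata$a0^2),
  codata = .codata
)

bohr_from_angstrom <- function(x) x / qed_constants$angstrom_per_bohr
angstrom_from_bohr <- function(x) x * qed_constants$angstrom_per_bohr
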