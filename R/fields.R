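# External-field configuration: cavity modes, static fields, unit
# conversions, cavity-volume identities, and the magnetic one-electron
# Hamiltonian terms.

#' Define a cavity mode
#'
#' A quantized cavity mode is characterised by its coupling vector
#' \eqn{\lambda} (a.u.) and frequency \eqn{\omega} (hartree).  The QED-HF
#' energy depends only on \eqn{\lambda}; \eqn{\omega} is carried for
#' reporting and for the equivalent-field identity
#' \eqn{E = \sqrt{\omega/2}\,|\lambda|}.
#'
#' @param lambda numeric length-3 coupling vector (a.u.).
#' @param omega mode frequency (hartree), non-negative.
#' @return an object of class `cavity_mode`.
#' @export
cavity_mode <- function(lambda, omega = 0.5) {
  lambda <- as.numeric(lambda)
  stopifnot(length(lambda) == 3L, all(is.finite(lambda)), is.finite(omega),
            omega >= 0)
  structure(list(lambda = lambda, omega = omega), class = "cavity_mode")
}

#' Assemble an external-field configuration
#'
#' @param modes list of [cavity_mode()] objects (may be empty).
#' @param E_ext static electric field vector (a.u.).
#' @param B_ext static magnetic field vector (a.u.).
#' @param gauge_origin gauge origin for the magnetic terms (bohr); `NULL`
#'   defers to the integral set's default (centre of nuclear charge).
#' @return an object of class `field_config`.  An empty configuration
#'   (no modes, zero fields) reproduces plain restricted Hartree-Fock.
#' @export
field_config <- function(modes = list(), E_ext = c(0, 0, 0),
                         B_ext = c(0, 0, 0), gauge_origin = NULL) {
  if (inherits(modes, "cavity_mode")) modes <- list(modes)
  stopifnot(all(vapply(modes, inherits, TRUE, "cavity_mode")),
            length(E_ext) == 3L, all(is.finite(E_ext)),
            length(B_ext) == 3L, all(is.finite(B_ext)))
  structure(list(modes = modes, E_ext = as.numeric(E_ext),
                 B_ext = as.numeric(B_ext),
                 gauge_origin = gauge_origin), class = "field_config")
}

fields_are_empty <- function(fields) {
  length(fields$modes) == 0L && all(fields$E_ext == 0) && all(fields$B_ext == 0)
}

has_magnetic <- function(fields) any(fields$B_ext != 0)

#' Coupling strength from cavity volume
#'
#' \eqn{\lambda = \sqrt{4\pi/V}} for a cavity of volume `V` in atomic units.
#'
#' @param volume cavity volume (a.u.), positive.
#' @return coupling magnitude (a.u.).
#' @export
lambda_from_cavity_volume <- function(volume) {
  if (any(volume <= 0)) stop("cavity volume must be positive")
  sqrt(4 * pi / volume)
}

#' Cavity volume from coupling strength
#' @param lambda coupling magnitude (a.u.), positive.
#' @return volume (a.u.); inverse of [lambda_from_cavity_volume()].
#' @export
volume_from_lambda <- function(lambda) {
  if (any(lambda <= 0)) stop("coupling must be positive")
  4 * pi / lambda^2
}

#' Equivalent static electric field of a cavity mode
#'
#' The field-strength identity \eqn{E = \sqrt{\omega/2}\,|\lambda|} (a.u.)
#' eases comparison between light-matter coupling and static fields.
#'
#' @param mode a [cavity_mode()].
#' @return electric-field magnitude (a.u.).
#' @export
equivalent_field_from_coupling <- function(mode) {
  stopifnot(inherits(mode, "cavity_mode"))
  sqrt(mode$omega / 2) * sqrt(sum(mode$lambda^2))
}

.field_units <- local({
  ef <- qed_constants$efield_au_to_V_per_m
  bf <- qed_constants$bfield_au_to_T
  A <- qed_constants$angstrom_per_bohr
  # value of 1 unit expressed in the canonical unit of its dimension
  list(
    efield = c("au_efield" = 1, "V/m" = 1 / ef, "V/nm" = 1e9 / ef),
    bfield = c("au_bfield" = 1, "T" = 1 / bf),
    length = c("bohr" = 1, "angstrom" = 1 / A, "nm" = 10 / A)
  )
})

#' Convert field and length values between atomic and SI-style units
#'
#' Supported units: electric field `"au_efield"`, `"V/m"`, `"V/nm"`;
#' magnetic field `"au_bfield"`, `"T"`; length `"bohr"`, `"angstrom"`,
#' `"nm"`.  Conversion factors derive from the CODATA 2018 constants in
#' [qed_constants].
#'
#' @param value numeric value(s).
#' @param from,to unit names (must share a dimension).
#' @return converted value(s).
#' @export
convert_field_units <- function(value, from, to) {
  for (dim in names(.field_units)) {
    u <- .field_units[[dim]]
    if (from %in% names(u) && to %in% names(u))
      return(value * u[[from]] / u[[to]])
  }
  stop("unsupported unit pair '", from, "' -> '", to, "'; supported units: ",
       paste(unlist(lapply(.field_units, names)), collapse = ", "))
}

#' Magnetic one-electron Hamiltonian terms
#'
#' Assembles the static-magnetic-field contribution to the one-electron
#' Hamiltonian at a fixed gauge origin O:
#' \deqn{-\tfrac12 B\cdot L_O + \tfrac18\left(B^2 r_O^2 - (B\cdot r_O)^2\right)}
#' i.e. the orbital-Zeeman term (imaginary-Hermitian) plus the symmetric-
#' gauge diamagnetic operator built from the stored second-moment matrices.
#' Without London orbitals the result is gauge-origin dependent; the origin
#' must match the one the integrals were computed with.
#'
#' @param ints a [integral_set()].
#' @param B_ext magnetic field vector (a.u.).
#' @param gauge_origin gauge origin (bohr), checked against `ints`.
#' @return complex Hermitian matrix (zero matrix when `B_ext = 0`).
#' @export
magnetic_oei_terms <- function(ints, B_ext, gauge_origin = NULL) {
  B <- as.numeric(B_ext)
  stopifnot(length(B) == 3L, all(is.finite(B)))
  if (!is.null(gauge_origin) &&
      max(abs(gauge_origin - ints$gauge_origin)) > 1e-10)
    stop("gauge-origin mismatch: integrals were computed about (",
         paste(sprintf("%.6f", ints$gauge_origin), collapse = ", "),
         ") but (", paste(sprintf("%.6f", gauge_origin), collapse = ", "),
         ") was requested; recompute the integral set")
  n <- ints$n
  if (all(B == 0)) return(matrix(0 + 0i, n, n))
  # orbital Zeeman: -1/2 B . L with L = -i Lambda  =>  + (i/2) B . Lambda
  zeeman <- (1i / 2) * (B[1] * ints$L$x + B[2] * ints$L$y + B[3] * ints$L$z)
  r2 <- ints$Q$xx + ints$Q$yy + ints$Q$zz
  BB <- sum(B^2)
  Bq <- B[1]^2 * ints$Q$xx + B[2]^2 * ints$Q$yy + B[3]^2 * ints$Q$zz +
    2 * B[1] * B[2] * ints$Q$xy + 2 * B[1] * B[3] * ints$Q$xz +
    2 * B[2] * B[3] * ints$Q$yz
  dia <- (BB * r2 - Bq) / 8
  zeeman + dia
}
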