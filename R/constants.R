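#' Physical constants used throughout the package
#'
#' CODATA values for the molar gas constant, Boltzmann and Planck constants
#' and the Avogadro number, together with the molar volume of liquid water
#' and the kcal/mol conversion used for user-facing energies.
#'
#' All internal computation is in SI units (m, s, mol, J, osmol/m3).
#' User-facing interfaces accept/report the conventional units of the field:
#' um/s for membrane permeabilities P_f, cm3/s for single-channel
#' permeabilities p_f, kcal/mol for activation energies.
#'
#' @format A named list with elements
#' \describe{
#'   \item{R}{molar gas constant, 8.314462618 J/(mol K)}
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{h}{Planck constant, J s}
#'   \item{NA_}{Avogadro constant, 1/mol}
#'   \item{V_w}{molar volume of liquid water, 18.0e-6 m3/mol (configurable
#'     in the functions that use it)}
#'   \item{kcal}{J per kcal, exactly 4184}
#' }
#' @export
aquaflux_constants <- list(
  R    = 8.314462618,
  kB   = 1.380649e-23,
  h    = 6.62607015e-34,
  NA_  = 6.02214076e23,
  V_w  = 18.0e-6,
  kcal = 4184
)

## internal shorthand
.const <- aquaflux_constants

#' TST attempt frequency
#'
#' `nu0(T) = kB * T / h`, the transition-state-theory attempt frequency.
#'
#' @param temperature absolute temperature (K)
#' @return attempt frequency (1/s)
#' @export
attempt_frequency <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  .const$kB * temperature / .const$h
}

## molecular volume of one water molecule (m3)
.v_water_molecule <- function(V_w = .const$V_w) V_w / .const$NA_

## unit conversions (exported as a courtesy; trivial but used everywhere)

#' Unit conversions between SI and conventional units
#'
#' Permeabilities: `um_s` (um/s) <-> m/s; single-channel `cm3_s` <-> m3/s;
#' energies: `kcal_mol` <-> J/mol (1 kcal = 4184 J exactly).
#'
#' @param x numeric vector
#' @return converted numeric vector
#' @name units
NULL

#' @rdname units
#' @export
um_s_to_m_s <- function(x) x * 1e-6

#' @rdname units
#' @export
m_s_to_um_s <- function(x) x * 1e6

#' @rdname units
#' @export
cm3_s_to_m3_s <- function(x) x * 1e-6

#' @rdname units
#' @export
m3_s_to_cm3_s <- function(x) x * 1e6

#' @rdname units
#' @export
kcal_to_J <- function(x) x * .const$kcal

#' @rdname units
#' @export
J_to_kcal <- function(x) x / .const$kcal
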