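#' Enthalpy of activation from the Arrhenius activation energy
#'
#' For a constant-pressure process,
#' \deqn{\Delta H^\ddagger = E_a - RT + P \Delta V^\ddagger,}
#' with the activation volume term fixed at zero, the standard
#' approximation for reactions in solution. The term is retained as an
#' explicit argument for transparency.
#'
#' @param Ea activation energy (J/mol)
#' @param temperature absolute temperature (K)
#' @param PdV pressure-volume activation term (J/mol); fixed 0 by default
#' @return enthalpy of activation (J/mol)
#' @examples
#' J_to_kcal(enthalpy_of_activation(kcal_to_J(3.75), 298))  # 3.16 kcal/mol
#' @export
enthalpy_of_activation <- function(Ea, temperature, PdV = 0) {
  stopifnot(is.numeric(Ea), is.numeric(temperature), all(temperature > 0))
  Ea - .const$R * temperature + PdV
}

#' Gibbs free energy of activation from the single-channel permeability
#'
#' Inverts the TST rate expression
#' \deqn{p_f = \nu_0 v_w \exp(-\Delta G^\ddagger / RT)}
#' with attempt frequency `nu0 = kB T / h` and molecular water volume
#' `v_w = V_w / N_A`:
#' \deqn{\Delta G^\ddagger = RT \ln(\nu_0 v_w / p_f).}
#'
#' @param pf single-channel permeability (m3/s), > 0
#' @param temperature absolute temperature (K)
#' @param V_w molar volume of water (m3/mol)
#' @return Gibbs free energy of activation (J/mol)
#' @export
gibbs_from_pf <- function(pf, temperature, V_w = aquaflux_constants$V_w) {
  stopifnot(is.numeric(pf), all(pf > 0), all(temperature > 0))
  nu0 <- attempt_frequency(temperature)
  .const$R * temperature * log(nu0 * .v_water_molecule(V_w) / pf)
}

#' Gibbs free energy from its enthalpic and entropic components
#'
#' `dG = dH - T dS`.
#'
#' @param dH enthalpy of activation (J/mol)
#' @param dS entropy of activation (J/(mol K))
#' @param temperature absolute temperature (K)
#' @return Gibbs free energy of activation (J/mol)
#' @export
gibbs_decomposition <- function(dH, dS, temperature) {
  stopifnot(is.numeric(dH), is.numeric(dS), all(temperature > 0))
  dH - temperature * dS
}

#' Entropy of activation from permeability, activation energy and kappa
#'
#' Combines the TST rate expression with the Arrhenius form of the
#' single-channel permeability and a transmission coefficient `kappa`
#' correcting for barrier recrossing,
#' \deqn{p_f = \kappa \nu_0 v_w e^{1 + \Delta S^\ddagger / R}
#'       e^{-E_a/RT},}
#' and solves for the entropic barrier:
#' \deqn{\Delta S^\ddagger = R\left[\ln\frac{p_f e^{E_a/RT}}
#'       {\kappa \nu_0 v_w} - 1\right].}
#'
#' @param pf single-channel permeability (m3/s), > 0
#' @param Ea activation energy (J/mol)
#' @param temperature absolute temperature at which `pf` was measured (K);
#'   `nu0` and `v_w` are evaluated here
#' @param kappa transmission coefficient in (0, 1]
#' @param V_w molar volume of water (m3/mol)
#' @return entropy of activation (J/(mol K))
#' @examples
#' entropy_from_pf(cm3_s_to_m3_s(3.2e-13), kcal_to_J(3.75), 278, 0.48)
#' @export
entropy_from_pf <- function(pf, Ea, temperature, kappa,
                            V_w = aquaflux_constants$V_w) {
  stopifnot(is.numeric(pf), all(pf > 0), is.numeric(Ea),
            all(temperature > 0))
  if (!is.numeric(kappa) || any(kappa <= 0) || any(kappa > 1))
    stop("kappa must lie in (0, 1]", call. = FALSE)
  R <- .const$R
  nu0 <- attempt_frequency(temperature)
  R * (log(pf * exp(Ea / (R * temperature)) /
             (kappa * nu0 * .v_water_molecule(V_w))) - 1)
}

#' Rescale an entropy of activation to a different transmission coefficient
#'
#' Holding the fitted pre-exponential factor fixed, a change of the assumed
#' transmission coefficient shifts the inferred entropy by
#' \deqn{\Delta S^\ddagger(\kappa') = \Delta S^\ddagger(\kappa)
#'       + R \ln(\kappa / \kappa').}
#'
#' @param dS entropy of activation at `kappa_old` (J/(mol K))
#' @param kappa_old,kappa_new transmission coefficients in (0, 1]
#' @return entropy of activation at `kappa_new` (J/(mol K))
#' @export
entropy_rescale_kappa <- function(dS, kappa_old, kappa_new) {
  stopifnot(is.numeric(dS))
  for (k in list(kappa_old, kappa_new))
    if (!is.numeric(k) || any(k <= 0) || any(k > 1))
      stop("kappa must lie in (0, 1]", call. = FALSE)
  dS + .const$R * log(kappa_old / kappa_new)
}

#' Propagated uncertainty of the entropy of activation
#'
#' First-order error propagation through the kappa-corrected prefactor
#' relation:
#' \deqn{\delta(\Delta S^\ddagger) = R \sqrt{(\delta p_f / p_f)^2 +
#'       (\delta E_a / RT)^2 + (\delta\kappa / \kappa)^2}.}
#'
#' @param rel_dpf relative uncertainty of the single-channel permeability
#' @param dEa absolute uncertainty of the activation energy (J/mol)
#' @param dkappa absolute uncertainty of the transmission coefficient
#' @param kappa transmission coefficient in (0, 1]
#' @param temperature absolute temperature (K)
#' @return uncertainty of the entropy of activation (J/(mol K))
#' @export
entropy_error <- function(rel_dpf, dEa, dkappa, kappa, temperature) {
  stopifnot(rel_dpf >= 0, dEa >= 0, dkappa >= 0,
            kappa > 0, kappa <= 1, temperature > 0)
  R <- .const$R
  R * sqrt(rel_dpf^2 + (dEa / (R * temperature))^2 + (dkappa / kappa)^2)
}

#' Full TST decomposition of the activation barrier
#'
#' Convenience wrapper combining the pieces: from `(pf, Ea, kappa)` at the
#' measurement temperature it computes the enthalpic, entropic and free
#' energy barriers and, when uncertainties are supplied, their propagated
#' errors. `dG` is evaluated at `T_eval` (default 298 K) as
#' `dH(T_eval) - T_eval * dS`.
#'
#' @param pf single-channel permeability (m3/s)
#' @param Ea activation energy (J/mol)
#' @param kappa transmission coefficient in (0, 1]
#' @param temperature temperature of the `pf` measurement (K)
#' @param T_eval temperature at which dH and dG are reported (K)
#' @param rel_dpf,dEa,dkappa optional uncertainties (see
#'   [entropy_error()]); `dEa` in J/mol
#' @param V_w molar volume of water (m3/mol)
#' @return an object of class `tst_result`
#' @export
tst_decompose <- function(pf, Ea, kappa, temperature = 278, T_eval = 298,
                          rel_dpf = NA, dEa = NA, dkappa = NA,
                          V_w = aquaflux_constants$V_w) {
  dS <- entropy_from_pf(pf, Ea, temperature, kappa, V_w)
  dH <- enthalpy_of_activation(Ea, T_eval)
  dG <- gibbs_decomposition(dH, dS, T_eval)
  dS_err <- if (!anyNA(c(rel_dpf, dEa, dkappa)))
    entropy_error(rel_dpf, dEa, dkappa, kappa, temperature) else NA_real_
  structure(list(
    dH = dH, dS = dS, dG = dG, kappa = kappa,
    pf = pf, Ea = Ea, temperature = temperature, T_eval = T_eval,
    A = attempt_frequency(temperature) * .v_water_molecule(V_w) *
      exp(1 + dS / .const$R),
    PdV = 0,
    dS_err = dS_err, dEa = dEa, rel_dpf = rel_dpf, dkappa = dkappa
  ), class = "tst_result")
}

#' @export
print.tst_result <- function(x, ...) {
  cat("Transition-state decomposition of the permeation barrier\n")
  cat(sprintf("  inputs: pf = %.3g cm3/s at %g K, Ea = %.3g kcal/mol, kappa = %.3g\n",
              m3_s_to_cm3_s(x$pf), x$temperature, J_to_kcal(x$Ea), x$kappa))
  cat(sprintf("  dH = %.3f kcal/mol (at %g K)\n", J_to_kcal(x$dH), x$T_eval))
  if (is.na(x$dS_err))
    cat(sprintf("  dS = %.3f J/(mol K)\n", x$dS))
  else
    cat(sprintf("  dS = %.3f +- %.2f J/(mol K)\n", x$dS, x$dS_err))
  cat(sprintf("  T dS = %.3f kcal/mol, dG = %.3f kcal/mol at %g K\n",
              J_to_kcal(x$T_eval * x$dS), J_to_kcal(x$dG), x$T_eval))
  invisible(x)
}

#' @export
coef.tst_result <- function(object, ...)
  c(dH = object$dH, dS = object$dS, dG = object$dG, kappa = object$kappa)

#' Linearized Eyring fit of a permeability temperature series
#'
#' Ordinary least squares of `ln(pf / T)` on `1/T`. Under the
#' kappa-corrected Eyring form
#' \deqn{p_f = \kappa \frac{k_B T}{h} v_w e^{\Delta S^\ddagger / R}
#'       e^{-\Delta H^\ddagger / RT}}
#' the slope is `-dH/R` and the intercept is
#' `ln(kappa kB v_w / h) + dS/R`.
#'
#' @param pf single-channel permeabilities (m3/s), > 0
#' @param temperature absolute temperatures (K), >= 2 distinct
#' @param kappa transmission coefficient in (0, 1]
#' @param V_w molar volume of water (m3/mol)
#' @return an object of class `eyring_fit` with `dH`, `dS`, standard
#'   errors, and the underlying `lm`
#' @export
eyring_linear_fit <- function(pf, temperature, kappa = 1,
                              V_w = aquaflux_constants$V_w) {
  stopifnot(is.numeric(pf), all(pf > 0), length(pf) == length(temperature),
            length(unique(temperature)) >= 2)
  if (kappa <= 0 || kappa > 1) stop("kappa must lie in (0, 1]", call. = FALSE)
  x <- 1 / temperature
  fit <- stats::lm(log(pf / temperature) ~ x)
  cf <- suppressWarnings(summary(fit)$coefficients)
  R <- .const$R
  icpt0 <- log(kappa * .const$kB * .v_water_molecule(V_w) / .const$h)
  se_ok <- length(pf) > 2
  structure(list(
    dH = unname(-cf["x", "Estimate"] * R),
    dS = unname((cf["(Intercept)", "Estimate"] - icpt0) * R),
    se_dH = if (se_ok) unname(cf["x", "Std. Error"] * R) else NA_real_,
    se_dS = if (se_ok) unname(cf["(Intercept)", "Std. Error"] * R)
            else NA_real_,
    kappa = kappa, lm = fit, pf = pf, temperature = temperature
  ), class = "eyring_fit")
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf("Eyring fit (kappa = %.3g, %d temperatures)\n",
              x$kappa, length(x$temperature)))
  cat(sprintf("  dH = %.4g kcal/mol", J_to_kcal(x$dH)))
  if (!is.na(x$se_dH)) cat(sprintf(" (se %.2g)", J_to_kcal(x$se_dH)))
  cat(sprintf("\n  dS = %.4g J/(mol K)", x$dS))
  if (!is.na(x$se_dS)) cat(sprintf(" (se %.2g)", x$se_dS))
  cat("\n")
  invisible(x)
}

#' @export
coef.eyring_fit <- function(object, ...)
  c(dH = object$dH, dS = object$dS)

#' Sensitivity of the entropy estimate to the evaluation temperature
#'
#' The entropy extraction evaluates the attempt frequency and the
#' Arrhenius exponent at one reference temperature. This helper reports
#' how the inferred entropy shifts when that evaluation temperature is
#' moved across the experimental window, with the supplied permeability
#' carried along its own Arrhenius law
#' `pf(T) = pf exp(-Ea/R (1/T - 1/pf_temperature))` so that the inputs
#' stay mutually consistent. The residual drift reflects the `ln T`
#' temperature dependence of the TST prefactor, which the
#' constant-pre-exponential Arrhenius form neglects.
#'
#' @inheritParams entropy_from_pf
#' @param pf_temperature temperature at which `pf` was measured (K)
#' @param temperatures evaluation temperatures to scan (K)
#' @return data.frame with `temperature_K` and `dS_J_molK`
#' @export
entropy_temperature_sensitivity <- function(pf, Ea, kappa,
                                            pf_temperature = 278,
                                            temperatures = seq(277, 301, 4),
                                            V_w = aquaflux_constants$V_w) {
  R <- .const$R
  data.frame(
    temperature_K = temperatures,
    dS_J_molK = vapply(temperatures, function(Tk) {
      pf_T <- pf * exp(-Ea / R * (1 / Tk - 1 / pf_temperature))
      entropy_from_pf(pf_T, Ea, Tk, kappa, V_w)
    }, 0))
}
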