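## evaluate expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Heterogeneous vesicle suspension model
#'
#' Statistical model of a reconstituted vesicle suspension as probed in a
#' stopped-flow experiment: a fraction `X` of vesicles carries no protein,
#' the remainder carries a Poisson-distributed number of channel protomers
#' (one protomer = one conducting pore), and both the channel and the bare
#' membrane obey Arrhenius temperature scaling of their water
#' permeabilities.
#'
#' Defaults describe an AQP1-like reconstitution into E. coli polar lipid
#' vesicles: single-channel permeability 3.2e-13 cm3/s at 278 K with an
#' activation energy of 3.75 kcal/mol, membrane background 6 um/s with
#' 11.6 kcal/mol, 100 nm vesicle diameter.
#'
#' @param N_mean mean number of channel protomers per proteoliposome (> 0)
#' @param X empty (protein-free) vesicle fraction in \[0, 1\]
#' @param pf_ref_cm3_s single-channel permeability at `T_ref` (cm3/s)
#' @param Ea_c_kcal channel activation energy (kcal/mol)
#' @param Pf_m_ref_um_s channel-free membrane permeability at `T_ref` (um/s)
#' @param Ea_m_kcal membrane activation energy (kcal/mol)
#' @param T_ref reference temperature (K)
#' @param spec a [vesicle_spec()]
#' @param dispersion `"poisson"` for Poisson protomer counts, `"fixed"` for
#'   the zero-variance limit in which every proteoliposome carries exactly
#'   `N_mean` protomers (the deterministic two-population limit)
#' @param radius_cv coefficient of variation of a lognormal vesicle radius
#'   distribution; 0 (default) for monodisperse extruded vesicles
#' @return an object of class `population_model` (SI units internally)
#' @export
population_model <- function(N_mean = 20, X = 0.4,
                             pf_ref_cm3_s = 3.2e-13, Ea_c_kcal = 3.75,
                             Pf_m_ref_um_s = 6, Ea_m_kcal = 11.6,
                             T_ref = 278, spec = vesicle_spec(),
                             dispersion = c("poisson", "fixed"),
                             radius_cv = 0) {
  dispersion <- match.arg(dispersion)
  stopifnot(N_mean > 0, X >= 0, X <= 1, pf_ref_cm3_s >= 0,
            Ea_c_kcal >= 0, Ea_m_kcal >= 0, Pf_m_ref_um_s >= 0,
            T_ref > 0, radius_cv >= 0)
  .check_vesicle_spec(spec)
  structure(list(
    N_mean = N_mean, X = X,
    pf_ref = cm3_s_to_m3_s(pf_ref_cm3_s),
    Ea_c = kcal_to_J(Ea_c_kcal),
    Pf_m_ref = um_s_to_m_s(Pf_m_ref_um_s),
    Ea_m = kcal_to_J(Ea_m_kcal),
    T_ref = T_ref, spec = spec,
    d = 2 * spec$r0,
    dispersion = dispersion, radius_cv = radius_cv
  ), class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "Population model: N_mean = %g (%s), X = %g\n", x$N_mean,
    x$dispersion, x$X))
  cat(sprintf("  pf = %.3g cm3/s (Ea %.3g kcal/mol) at %g K\n",
              m3_s_to_cm3_s(x$pf_ref), J_to_kcal(x$Ea_c), x$T_ref))
  cat(sprintf("  Pf_m = %.3g um/s (Ea %.3g kcal/mol)\n",
              m_s_to_um_s(x$Pf_m_ref), J_to_kcal(x$Ea_m)))
  invisible(x)
}

#' Arrhenius-scaled permeabilities of a population model
#'
#' Scales the reference membrane and single-channel permeabilities from
#' `T_ref` to `temperature` with their respective activation energies,
#' `P(T) = P(T_ref) * exp(-Ea/R * (1/T - 1/T_ref))`.
#'
#' @param model a [population_model()]
#' @param temperature absolute temperature (K), vectorized
#' @return list with `Pf_m` (m/s) and `pf` (m3/s) at `temperature`
#' @export
permeability_at <- function(model, temperature) {
  stopifnot(inherits(model, "population_model"),
            is.numeric(temperature), all(temperature > 0))
  R <- .const$R
  dinv <- 1 / temperature - 1 / model$T_ref
  list(Pf_m = model$Pf_m_ref * exp(-model$Ea_m / R * dinv),
       pf = model$pf_ref * exp(-model$Ea_c / R * dinv))
}

#' Sample channel protomer counts per vesicle
#'
#' A fraction `X` of vesicles is protein-free by construction; the
#' remaining vesicles draw their protomer count from Poisson(`N_mean`)
#' (or carry exactly `N_mean` in the `"fixed"` dispersion limit).
#'
#' @param model a [population_model()]
#' @param n_vesicles number of vesicles to sample
#' @param seed optional RNG seed (restores the caller's RNG state)
#' @return integer (or numeric, for `"fixed"`) vector of counts
#' @export
sample_channel_counts <- function(model, n_vesicles, seed = NULL) {
  stopifnot(inherits(model, "population_model"), n_vesicles >= 1)
  .with_seed(seed, {
    empty <- stats::runif(n_vesicles) < model$X
    n <- if (model$dispersion == "poisson")
      stats::rpois(n_vesicles, model$N_mean)
    else rep(model$N_mean, n_vesicles)
    n[empty] <- 0
    n
  })
}

## exact-mass channel-count bins: counts, weights (sum 1) for the
## proteoliposome subpopulation, truncated at the 1 - 1e-6 quantile
.count_bins <- function(model) {
  if (model$dispersion == "fixed")
    return(list(n = model$N_mean, w = 1))
  K <- stats::qpois(1 - 1e-6, model$N_mean)
  n <- 0:K
  w <- stats::dpois(n, model$N_mean)
  if (sum(w) < 0.9999)
    stop("internal error: Poisson truncation covers < 99.99% of the mass",
         call. = FALSE)
  list(n = n, w = w / sum(w))
}
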