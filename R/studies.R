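## Monte-Carlo studies of how measurement error propagates into the
## Arrhenius activation energy. All studies are reproducible functions of
## (parameters, seed) and return an `ea_study` object.

.new_ea_study <- function(kind, summary, samples, truth_Ea, replicates,
                          seed, extra = list()) {
  structure(c(list(kind = kind, summary = summary, samples = samples,
                   truth_Ea = truth_Ea, replicates = replicates,
                   seed = seed), extra),
            class = "ea_study")
}

#' @export
print.ea_study <- function(x, ...) {
  cat(sprintf("Ea error study (%s), %d replicates, true Ea = %.3g kcal/mol\n",
              x$kind, x$replicates, J_to_kcal(x$truth_Ea)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

## true channel permeabilities (m/s) of a population model at temperatures
.true_Pfc <- function(model, temperatures) {
  per <- permeability_at(model, temperatures)
  total_pf(0, per$pf, model$N_mean, model$d)
}

## one batch of Gaussian-scatter Arrhenius replicates.
## Pf values are drawn at `temps_true` and regressed against
## `temps_recorded`; non-positive draws are redrawn (count returned).
.gauss_arrhenius_batch <- function(Pf_true, temps_recorded, sigma_pf,
                                   replicates) {
  K <- length(Pf_true)
  Ea <- numeric(replicates)
  rejections <- 0L
  for (r in seq_len(replicates)) {
    Pf <- Pf_true * (1 + stats::rnorm(K, 0, sigma_pf))
    while (any(Pf <= 0)) {
      bad <- Pf <= 0
      rejections <- rejections + sum(bad)
      Pf[bad] <- Pf_true[bad] * (1 + stats::rnorm(sum(bad), 0, sigma_pf))
    }
    Ea[r] <- arrhenius_fit(Pf, temps_recorded)$Ea
  }
  list(Ea = Ea, rejections = rejections)
}

#' Activation-energy error versus permeability scatter
#'
#' Draws Gaussian-distributed permeability values (relative sd `sigma_pf`)
#' at each temperature, Arrhenius-fits every replicate, and reports the
#' running mean and standard error of the mean of the activation energy as
#' a function of the number of averaged measurements n. Non-positive
#' permeability draws (possible at large scatter) are redrawn and counted.
#'
#' @param sigma_pf relative standard deviation of the permeability
#'   estimates (e.g. 0.1 for 10%)
#' @param temperatures measurement temperatures (K)
#' @param true_model a [population_model()] supplying the true channel
#'   permeabilities and activation energy
#' @param n_max largest number of averaged measurements reported
#' @param replicates number of simulated activation energies
#' @param seed RNG seed
#' @return an `ea_study`; `summary` has columns `n`, `mean_Ea_kcal`,
#'   `sem_kcal`; `samples` holds all simulated Ea values (J/mol);
#'   `sd_Ea` and `rejections` are attached
#' @export
gaussian_pf_study <- function(sigma_pf,
                              temperatures = c(283, 287, 291, 295, 299),
                              true_model = population_model(),
                              n_max = 100, replicates = 10000, seed = 1) {
  stopifnot(sigma_pf > 0, length(temperatures) >= 2, replicates > 0)
  Pf_true <- .true_Pfc(true_model, temperatures)
  batch <- .with_seed(seed,
    .gauss_arrhenius_batch(Pf_true, temperatures, sigma_pf, replicates))
  Ea <- batch$Ea
  sd_Ea <- stats::sd(Ea)
  ns <- seq_len(min(n_max, replicates))
  summary <- data.frame(
    n = ns,
    mean_Ea_kcal = J_to_kcal(cumsum(Ea[ns]) / ns),
    sem_kcal = J_to_kcal(sd_Ea / sqrt(ns)))
  .new_ea_study("gaussian_pf", summary, Ea, true_model$Ea_c, replicates,
                seed,
                extra = list(sd_Ea = sd_Ea, sigma_pf = sigma_pf,
                             rejections = batch$rejections,
                             temperatures = temperatures))
}

#' Activation-energy precision versus temperature range
#'
#' Repeats the Gaussian-scatter Arrhenius simulation for several sets of
#' measurement temperatures and reports the spread of the fitted
#' activation energy per set, together with the closed-form ordinary
#' least-squares prediction `se = R * sigma / sqrt(sum((1/T - mean)^2))`
#' whose ratio between ranges depends only on the 1/T leverage.
#'
#' @param ranges list of temperature vectors (K), each >= 2 points
#' @param sigma_pf relative sd of the permeability estimates
#' @param true_model a [population_model()]
#' @param replicates replicates per range
#' @param seed RNG seed
#' @return an `ea_study`; `summary` has one row per range with the
#'   empirical `sd_Ea_kcal`, central 95% interval, and
#'   `closed_form_se_kcal`
#' @export
temperature_range_study <- function(
    ranges = list(seq(288, 292), c(283, 287, 291, 295, 299),
                  c(277, 287, 297, 307, 317)),
    sigma_pf = 0.1, true_model = population_model(),
    replicates = 2000, seed = 1) {
  stopifnot(length(ranges) >= 1, all(lengths(ranges) >= 2), sigma_pf > 0)
  samples <- vector("list", length(ranges))
  rows <- vector("list", length(ranges))
  for (i in seq_along(ranges)) {
    temps <- ranges[[i]]
    Pf_true <- .true_Pfc(true_model, temps)
    ## common random numbers across ranges: the comparison is paired
    Ea <- .with_seed(seed,
      .gauss_arrhenius_batch(Pf_true, temps, sigma_pf, replicates))$Ea
    samples[[i]] <- Ea
    x <- 1 / temps
    sxx <- sum((x - mean(x))^2)
    qs <- stats::quantile(Ea, c(0.025, 0.975))
    rows[[i]] <- data.frame(
      range_K = diff(range(temps)), n_temps = length(temps),
      sd_Ea_kcal = J_to_kcal(stats::sd(Ea)),
      ci_lo_kcal = J_to_kcal(qs[[1]]), ci_hi_kcal = J_to_kcal(qs[[2]]),
      closed_form_se_kcal = J_to_kcal(.const$R * sigma_pf / sqrt(sxx)))
  }
  .new_ea_study("temperature_range", do.call(rbind, rows), samples,
                true_model$Ea_c, replicates, seed,
                extra = list(ranges = ranges, sigma_pf = sigma_pf))
}

#' Activation-energy bias from imperfect temperature control
#'
#' Permeabilities are generated at the *true* cuvette temperatures - which
#' deviate from the recorded set points by an error ramping linearly from
#' 0 at the coldest point to `ddt` at the hottest (see
#' [apply_temperature_bias()]) - and Arrhenius-fitted against the
#' *recorded* temperatures. The resulting relative Ea error is reported
#' per `ddt`. In the noiseless limit the relative bias is purely the ratio
#' of the true to the recorded 1/T spread and is independent of the true
#' activation energy.
#'
#' @param ddt_list temperature-control errors to scan (K)
#' @param temperatures recorded temperatures (K)
#' @param sigma_pf relative sd of the permeability estimates (0 allowed)
#' @param true_model a [population_model()]
#' @param replicates replicates per ddt (1 suffices at `sigma_pf = 0`)
#' @param seed RNG seed
#' @return an `ea_study`; `summary` has columns `ddt_K`, `mean_Ea_kcal`,
#'   `rel_error` (relative deviation of the mean Ea from truth), `sd_Ea_kcal`
#' @export
temperature_bias_study <- function(ddt_list = c(0, 2, 4, 6),
                                   temperatures = seq(277, 309, 8),
                                   sigma_pf = 0.05,
                                   true_model = population_model(),
                                   replicates = 500, seed = 1) {
  stopifnot(all(ddt_list >= 0), length(temperatures) >= 2)
  proto <- measurement_protocol(temperatures = temperatures, noise_sd = 0)
  samples <- vector("list", length(ddt_list))
  rows <- vector("list", length(ddt_list))
  for (i in seq_along(ddt_list)) {
    pb <- apply_temperature_bias(proto, ddt_list[i])
    Pf_true <- .true_Pfc(true_model, pb$temperatures_true)
    Ea <- if (sigma_pf > 0)
      .with_seed(seed + i - 1,
        .gauss_arrhenius_batch(Pf_true, temperatures, sigma_pf,
                               replicates))$Ea
    else
      rep(arrhenius_fit(Pf_true, temperatures)$Ea, 1L)
    samples[[i]] <- Ea
    rows[[i]] <- data.frame(
      ddt_K = ddt_list[i],
      mean_Ea_kcal = J_to_kcal(mean(Ea)),
      rel_error = mean(Ea) / true_model$Ea_c - 1,
      sd_Ea_kcal = J_to_kcal(if (length(Ea) > 1) stats::sd(Ea) else 0))
  }
  .new_ea_study("temperature_bias", do.call(rbind, rows), samples,
                true_model$Ea_c, replicates, seed,
                extra = list(ddt_list = ddt_list, sigma_pf = sigma_pf))
}

#' Activation-energy error versus reconstitution heterogeneity
#'
#' Runs the full pipeline - ensemble simulation with Poisson channel
#' counts and an empty-vesicle fraction, followed by each requested
#' fitting routine - over a grid of mean protomer numbers `N_mean`, empty
#' fractions `X` and single-channel permeabilities, and reports the
#' per-cell distribution of the activation-energy error.
#'
#' Routines: `"global"` = [fit_global_ea()]; `"analytical"` = per-trace
#' [fit_analytical_single()] followed by [arrhenius_fit()]; `"exponential"`
#' = per-trace [fit_exponential()] (fast-component permeability, control
#' background subtracted) followed by [arrhenius_fit()]. All routines see
#' identical data and identical control-derived `Pf_m` per replicate.
#'
#' @param N_mean_grid mean protomers per proteoliposome to scan
#' @param X_grid empty-vesicle fractions to scan
#' @param pf_grid_cm3_s single-channel permeabilities at `T_ref` (cm3/s)
#' @param methods subset of `c("global", "analytical", "exponential")`
#' @param base_model template [population_model()] (its `N_mean`, `X`,
#'   `pf_ref` are overridden by the grid)
#' @param protocol a [measurement_protocol()]
#' @param replicates ensembles per grid cell
#' @param seed RNG seed
#' @return an `ea_study`; `summary` has one row per
#'   (N_mean, X, pf, method) with `mean_abs_rel_error`, `rms_rel_error`,
#'   `sd_Ea_kcal` and the count of valid replicates
#' @export
reconstitution_study <- function(N_mean_grid = c(5, 10, 20, 40),
                                 X_grid = c(0.2, 0.5, 0.8),
                                 pf_grid_cm3_s = 3.2e-13,
                                 methods = c("global", "analytical",
                                             "exponential"),
                                 base_model = population_model(),
                                 protocol = measurement_protocol(),
                                 replicates = 20, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  grid <- expand.grid(N_mean = N_mean_grid, X = X_grid,
                      pf_cm3_s = pf_grid_cm3_s,
                      KEEP.OUT.ATTRS = FALSE)
  temps <- protocol$temperatures
  rows <- list(); samples <- list()
  for (g in seq_len(nrow(grid))) {
    model <- population_model(
      N_mean = grid$N_mean[g], X = grid$X[g],
      pf_ref_cm3_s = grid$pf_cm3_s[g],
      Ea_c_kcal = J_to_kcal(base_model$Ea_c),
      Pf_m_ref_um_s = m_s_to_um_s(base_model$Pf_m_ref),
      Ea_m_kcal = J_to_kcal(base_model$Ea_m),
      T_ref = base_model$T_ref, spec = base_model$spec,
      dispersion = "poisson")
    errs <- matrix(NA_real_, replicates, length(methods),
                   dimnames = list(NULL, methods))
    for (r in seq_len(replicates)) {
      ens <- simulate_ensemble(model, protocol,
                               seed = seed + 1000 * g + 17 * r)
      Pf_m <- vapply(ens$controls, function(ct) fit_control(ct)$Pf_m, 0)
      for (m in methods) {
        Ea_hat <- tryCatch(switch(
          m,
          global = fit_global_ea(ens, Pf_m = Pf_m)$Ea,
          analytical = {
            Pfc <- vapply(seq_along(temps), function(k)
              fit_analytical_single(ens$traces[[k]], Pf_m[k])$Pf_c, 0)
            arrhenius_fit(Pfc, temps)$Ea
          },
          exponential = {
            Pfc <- vapply(seq_along(temps), function(k) {
              ef <- fit_exponential(ens$traces[[k]])
              Pf_tot <- if (!is.na(ef$Pf_prot)) ef$Pf_prot else ef$Pf_empty
              Pf_tot - Pf_m[k]
            }, 0)
            if (any(Pfc <= 0)) NA_real_ else arrhenius_fit(Pfc, temps)$Ea
          }), error = function(e) NA_real_)
        errs[r, m] <- Ea_hat / model$Ea_c - 1
      }
    }
    samples[[g]] <- errs
    for (m in methods) {
      e <- errs[, m]
      rows[[length(rows) + 1]] <- data.frame(
        N_mean = grid$N_mean[g], X = grid$X[g],
        pf_cm3_s = grid$pf_cm3_s[g], method = m,
        mean_abs_rel_error = mean(abs(e), na.rm = TRUE),
        rms_rel_error = sqrt(mean(e^2, na.rm = TRUE)),
        sd_Ea_kcal = J_to_kcal(stats::sd(e * model$Ea_c, na.rm = TRUE)),
        n_valid = sum(!is.na(e)))
    }
  }
  .new_ea_study("reconstitution", do.call(rbind, rows), samples,
                base_model$Ea_c, replicates, seed,
                extra = list(grid = grid, methods = methods))
}
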