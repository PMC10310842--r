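#' Stopped-flow measurement protocol
#'
#' Describes how a synthetic temperature series is recorded: the nominal
#' (recorded) temperatures, the sampling grid, the additive Gaussian noise
#' on the normalized intensity, and an optional linear temperature bias
#' (see [apply_temperature_bias()]).
#'
#' Defaults mirror a typical stopped-flow series on extruded vesicles:
#' five temperatures 277-301 K, noise sd 0.01, and a dual time base (as
#' acquired by stopped-flow electronics) sampling the fast channel
#' relaxation densely - 0.5 ms spacing over the first tenth of the trace -
#' and the slow membrane relaxation coarsely out to `t_max`.
#'
#' @param temperatures recorded absolute temperatures (K), >= 2
#' @param t_max trace duration (s)
#' @param times explicit sampling grid (s), strictly increasing from 0;
#'   overrides the default dual time base
#' @param noise_sd additive Gaussian noise sd on I_norm, >= 0
#' @return an object of class `measurement_protocol`; `temperatures_true`
#'   holds the temperatures actually reached in the cuvette (equal to the
#'   recorded ones until a bias is applied)
#' @export
measurement_protocol <- function(temperatures = c(277, 283, 289, 295, 301),
                                 t_max = 1.5, times = NULL,
                                 noise_sd = 0.01) {
  stopifnot(length(temperatures) >= 2, all(temperatures > 0),
            t_max > 0, noise_sd >= 0)
  if (is.null(times)) {
    t_fast <- t_max / 15
    times <- c(seq(0, t_fast, by = 5e-4),
               seq(t_fast + 5e-3, t_max, by = 5e-3))
  }
  stopifnot(is.numeric(times), length(times) >= 20, times[1] == 0,
            all(diff(times) > 0))
  structure(list(
    temperatures = temperatures,
    temperatures_true = temperatures,
    times = times,
    noise_sd = noise_sd
  ), class = "measurement_protocol")
}

#' Apply a linear temperature-control bias to a protocol
#'
#' Models imperfect insulation between the cooling device and the cuvette:
#' the temperature actually reached deviates from the recorded one by an
#' error ramping linearly from 0 at the coldest set point to `ddt` at the
#' hottest. With a positive `ddt` the true 1/T spread is wider than the
#' recorded one, so a downstream Arrhenius fit against the recorded
#' temperatures overestimates the activation energy.
#'
#' @param protocol a [measurement_protocol()]
#' @param ddt maximum temperature error at the hottest set point (K), >= 0
#' @return the protocol with `temperatures_true` adjusted
#' @export
apply_temperature_bias <- function(protocol, ddt) {
  stopifnot(inherits(protocol, "measurement_protocol"),
            is.numeric(ddt), length(ddt) == 1, ddt >= 0)
  Tr <- protocol$temperatures
  ramp <- if (diff(range(Tr)) == 0) rep(0, length(Tr))
          else (Tr - min(Tr)) / (max(Tr) - min(Tr)) * ddt
  protocol$temperatures_true <- Tr + ramp
  protocol
}

## deterministic (noise-free) population signal at one true temperature
.population_signal <- function(model, temperature, times, b) {
  per <- permeability_at(model, temperature)
  bins <- .count_bins(model)
  specs <- list(model$spec)
  rw <- 1
  if (model$radius_cv > 0) {
    ## 7-node mid-quantile discretization of a lognormal radius spread
    q <- (seq_len(7) - 0.5) / 7
    sdl <- sqrt(log(1 + model$radius_cv^2))
    r_nm <- model$spec$r0 * 1e9 *
      stats::qlnorm(q, meanlog = -sdl^2 / 2, sdlog = sdl)
    specs <- lapply(r_nm, function(r)
      vesicle_spec(r0_nm = r, c_in0 = model$spec$c_in0,
                   c_out = model$spec$c_out, V_w = model$spec$V_w))
    rw <- rep(1 / 7, 7)
  }
  V <- 0
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    Vj <- model$X * volume_analytic(times, sp, per$Pf_m)
    for (i in seq_along(bins$n)) {
      Pf_i <- total_pf(per$Pf_m, per$pf, bins$n[i], model$d)
      Vj <- Vj + (1 - model$X) * bins$w[i] * volume_analytic(times, sp, Pf_i)
    }
    ## express every radius class on the reference-volume intensity scale
    V <- V + rw[j] * Vj * (model$spec$V0 / sp$V0)
  }
  1 - b * V
}

#' Simulate one stopped-flow scattering trace
#'
#' Forward model of a stopped-flow measurement of the suspension described
#' by `model` at one temperature: the population mean volume is the
#' channel-count-weighted mixture of closed-form shrinkage curves (exact
#' Poisson mass bins up to the 1 - 1e-6 quantile), mapped to normalized
#' intensity by `I = 1 - b V(t)`, plus i.i.d. Gaussian noise.
#'
#' @param model a [population_model()]
#' @param temperature true cuvette temperature (K)
#' @param protocol a [measurement_protocol()] (supplies time grid and
#'   noise)
#' @param seed optional RNG seed for the noise (caller RNG state is
#'   restored)
#' @param b intensity-per-volume coefficient (1/m3); default `1/V0` so the
#'   noise-free signal starts at 0
#' @param recorded_temperature temperature stored on the returned trace
#'   (defaults to `temperature`; differs when a temperature bias is
#'   simulated)
#' @return an [sf_trace()]
#' @export
simulate_trace <- function(model, temperature, protocol, seed = NULL,
                           b = 1 / model$spec$V0,
                           recorded_temperature = temperature) {
  stopifnot(inherits(model, "population_model"),
            inherits(protocol, "measurement_protocol"),
            temperature > 0, b > 0)
  I <- .population_signal(model, temperature, protocol$times, b)
  if (protocol$noise_sd > 0)
    I <- I + .with_seed(seed,
      stats::rnorm(length(I), 0, protocol$noise_sd))
  sf_trace(protocol$times, I, temperature = recorded_temperature,
           spec = model$spec)
}

#' Simulate a temperature ensemble with matched controls
#'
#' One proteoliposome trace plus one protein-free control trace per
#' protocol temperature, with all permeabilities Arrhenius-scaled from the
#' model reference. Traces are generated at the *true* cuvette
#' temperatures of the protocol but labeled with the *recorded* ones, so a
#' biased protocol (see [apply_temperature_bias()]) propagates its error
#' into downstream fits exactly as in an experiment. A ground-truth record
#' is attached for test harnesses.
#'
#' @param model a [population_model()]
#' @param protocol a [measurement_protocol()]
#' @param seed optional RNG seed; per-trace seeds are derived from it
#' @return an `sf_ensemble`: list with `traces`, `controls` (lists of
#'   [sf_trace()]), `temperatures` (recorded) and `truth`
#' @export
simulate_ensemble <- function(model, protocol, seed = NULL) {
  stopifnot(inherits(model, "population_model"),
            inherits(protocol, "measurement_protocol"))
  K <- length(protocol$temperatures)
  control_model <- model
  control_model$X <- 1
  seeds <- if (is.null(seed)) vector("list", 2 * K)
           else as.list(seed + seq_len(2 * K))
  traces <- controls <- vector("list", K)
  for (k in seq_len(K)) {
    Tt <- protocol$temperatures_true[k]
    Tr <- protocol$temperatures[k]
    traces[[k]] <- simulate_trace(model, Tt, protocol,
                                  seed = seeds[[k]],
                                  recorded_temperature = Tr)
    controls[[k]] <- simulate_trace(control_model, Tt, protocol,
                                    seed = seeds[[K + k]],
                                    recorded_temperature = Tr)
  }
  per <- permeability_at(model, protocol$temperatures_true)
  truth <- list(
    Ea_c_kcal = J_to_kcal(model$Ea_c),
    Ea_m_kcal = J_to_kcal(model$Ea_m),
    X = model$X, N_mean = model$N_mean,
    pf_ref_cm3_s = m3_s_to_cm3_s(model$pf_ref),
    Pf_m_ref_um_s = m_s_to_um_s(model$Pf_m_ref),
    T_ref_K = model$T_ref)
  for (k in seq_len(K)) {
    truth[[sprintf("Pf_m_um_s_%g", protocol$temperatures[k])]] <-
      m_s_to_um_s(per$Pf_m[k])
    truth[[sprintf("Pf_c_um_s_%g", protocol$temperatures[k])]] <-
      m_s_to_um_s(total_pf(0, per$pf[k], model$N_mean, model$d))
  }
  structure(list(traces = traces, controls = controls,
                 temperatures = protocol$temperatures, truth = truth),
            class = "sf_ensemble")
}

#' @export
print.sf_ensemble <- function(x, ...) {
  cat(sprintf(
    "Stopped-flow ensemble: %d temperatures (%s K), trace + control each\n",
    length(x$traces),
    paste(x$temperatures, collapse = ", ")))
  invisible(x)
}
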