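#' Arrhenius regression of channel permeabilities
#'
#' Ordinary least squares of `ln(Pf_c)` on `1/T`. The activation energy is
#' `Ea = -slope * R` and the pre-exponential factor `A = exp(intercept)`,
#' in the units of the supplied permeabilities.
#'
#' @param Pf_c channel permeabilities (any consistent unit), all > 0
#' @param temperature absolute temperatures (K), same length, >= 2 distinct
#' @return an object of class `arrhenius_fit` with `Ea` (J/mol), `A`,
#'   `se_Ea` (J/mol), the underlying `lm` fit, and the data
#' @examples
#' Tk <- c(277, 283, 289, 295, 301)
#' Pf <- 100 * exp(-15000 / 8.3145 * (1 / Tk - 1 / 289))
#' arrhenius_fit(Pf, Tk)   # recovers Ea = 15000 J/mol
#' @export
arrhenius_fit <- function(Pf_c, temperature) {
  stopifnot(is.numeric(Pf_c), is.numeric(temperature),
            length(Pf_c) == length(temperature))
  if (length(Pf_c) < 2 || length(unique(temperature)) < 2)
    stop("need >= 2 distinct temperatures", call. = FALSE)
  if (any(Pf_c <= 0))
    stop("all permeabilities must be > 0 for an Arrhenius plot",
         call. = FALSE)
  x <- 1 / temperature
  fit <- stats::lm(log(Pf_c) ~ x)
  ## exact synthetic data triggers lm's perfect-fit warning; harmless here
  cf <- suppressWarnings(summary(fit)$coefficients)
  R <- .const$R
  structure(list(
    Ea = unname(-cf["x", "Estimate"] * R),
    A = unname(exp(cf["(Intercept)", "Estimate"])),
    se_Ea = if (nrow(cf) == 2 && length(Pf_c) > 2)
      unname(cf["x", "Std. Error"] * R) else NA_real_,
    lm = fit, Pf_c = Pf_c, temperature = temperature
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %d temperatures (%g-%g K)\n",
              length(x$temperature), min(x$temperature), max(x$temperature)))
  cat(sprintf("  Ea = %.4g kcal/mol", J_to_kcal(x$Ea)))
  if (!is.na(x$se_Ea)) cat(sprintf(" (se %.2g)", J_to_kcal(x$se_Ea)))
  cat(sprintf("\n  A  = %.4g (input permeability units)\n", x$A))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...)
  c(Ea = object$Ea, A = object$A)

#' @export
predict.arrhenius_fit <- function(object, temperature = object$temperature,
                                  ...) {
  object$A * exp(-object$Ea / (.const$R * temperature))
}

#' @export
plot.arrhenius_fit <- function(x, ...) {
  graphics::plot(1 / x$temperature, log(x$Pf_c),
                 xlab = "1/T (1/K)", ylab = "ln Pf_c", ...)
  graphics::abline(x$lm, lty = 2)
  invisible(x)
}

#' Global activation-energy fit of a temperature ensemble
#'
#' Simultaneous least-squares fit of all proteoliposome traces of one
#' vesicle suspension measured at different temperatures. Because the same
#' suspension is used at every temperature, the empty-vesicle fraction `X`
#' and the activation energy `Ea` are shared across the ensemble, and the
#' per-temperature channel permeability is constrained to the Arrhenius
#' law,
#' \deqn{P_f(T) = A e^{-E_a / RT} + P_{f,m}(T),}
#' with the protein-free membrane permeability `Pf_m(T)` fixed per
#' temperature from the matching control samples. The only parameter
#' evaluated independently per temperature is the intensity coefficient
#' `b_k` (profiled out analytically). The free global parameters are
#' `(Ea, A, X)`; internally `A` is parameterized as the channel
#' permeability at the median temperature for conditioning, and the
#' Levenberg-Marquardt search is repeated from 5 deterministic perturbed
#' starts, keeping the best optimum.
#'
#' @param ensemble an `sf_ensemble` (see [simulate_ensemble()] /
#'   [read_ensemble()]) or a plain list of [sf_trace()] objects at
#'   distinct temperatures
#' @param Pf_m per-temperature channel-free membrane permeabilities (m/s).
#'   If `NULL` (default) they are fitted from `ensemble$controls` with
#'   [fit_control()].
#' @param dead_time instrument dead time (s)
#' @param n_starts number of perturbed optimizer starts
#' @return an object of class `ea_globalfit` with `Ea` (J/mol), `A` (m/s),
#'   `X`, per-temperature `Pf_c` (m/s, on the Arrhenius curve by
#'   construction), `b` (1/m3), standard errors, `flags`, `rss`, and the
#'   per-trace fitted curves
#' @export
fit_global_ea <- function(ensemble, Pf_m = NULL, dead_time = 1e-3,
                          n_starts = 5) {
  traces <- if (!is.null(ensemble$traces)) ensemble$traces else ensemble
  stopifnot(length(traces) >= 3,
            all(vapply(traces, inherits, TRUE, "sf_trace")))
  temps <- vapply(traces, `[[`, 0, "temperature")
  if (length(unique(temps)) < 3)
    stop("global Ea fit needs >= 3 distinct temperatures", call. = FALSE)
  K <- length(traces)
  if (is.null(Pf_m)) {
    if (is.null(ensemble$controls))
      stop("supply per-temperature Pf_m or an ensemble with control traces",
           call. = FALSE)
    Pf_m <- vapply(ensemble$controls,
                   function(ct) fit_control(ct, dead_time)$Pf_m, 0)
  }
  stopifnot(length(Pf_m) == K, all(Pf_m > 0))

  wins <- lapply(traces, .trace_window, dead_time = dead_time)
  R <- .const$R
  T_ref <- stats::median(temps)

  ## residuals for theta = (Ea [J/mol], ln Pf_ref [m/s], X); b_k profiled
  eval_model <- function(theta) {
    Ea <- theta[1]; Pf_ref <- exp(theta[2]); X <- theta[3]
    Pf_c <- Pf_ref * exp(-Ea / R * (1 / temps - 1 / T_ref))
    res <- vector("list", K); b <- numeric(K); rss <- 0
    for (k in seq_len(K)) {
      V <- mixture_volume(wins[[k]]$t, X, traces[[k]]$spec,
                          Pf_m[k], Pf_m[k] + Pf_c[k])
      pb <- .profile_b(V, wins[[k]]$I)
      res[[k]] <- pb$res; b[k] <- pb$b
    }
    list(res = unlist(res), b = b, Pf_c = Pf_c)
  }
  resid_fn <- function(theta) eval_model(theta)$res

  ## data-driven start: per-trace analytical fits -> Arrhenius regression
  ana0 <- lapply(seq_len(K), function(k)
    tryCatch(fit_analytical_single(traces[[k]], Pf_m[k], dead_time),
             error = function(e) NULL))
  ok <- !vapply(ana0, is.null, TRUE)
  if (any(ok)) {
    Pf0 <- vapply(ana0[ok], `[[`, 0, "Pf_c")
    X0 <- stats::median(vapply(ana0[ok], `[[`, 0, "X"))
    ar0 <- tryCatch(arrhenius_fit(Pf0, temps[ok]), error = function(e) NULL)
  } else {
    Pf0 <- rep(10 * mean(Pf_m), K); X0 <- 0.5; ar0 <- NULL
  }
  Ea0 <- if (!is.null(ar0)) min(max(ar0$Ea, 0.1 * .const$kcal),
                                49 * .const$kcal) else 4 * .const$kcal
  lPf_ref0 <- log(max(stats::median(Pf0), 1e-9))
  X0 <- min(max(X0, 0.05), 0.95)

  lower <- c(0, log(1e-10), 0)
  upper <- c(50 * .const$kcal, log(1), 1)
  starts <- list(c(Ea0, lPf_ref0, X0))
  ## deterministic perturbations around the data-driven start
  bumps <- list(c(1.3, 0.3, 0.15), c(0.7, -0.3, -0.15),
                c(1.6, 0.6, 0.3), c(0.5, -0.6, 0.25))
  for (bmp in bumps[seq_len(max(0, n_starts - 1))])
    starts <- c(starts, list(c(
      min(max(Ea0 * bmp[1], lower[1] + 1), upper[1] - 1),
      min(max(lPf_ref0 + bmp[2], lower[2] + 0.1), upper[2] - 0.1),
      min(max(X0 + bmp[3], 0.01), 0.99))))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("global Ea fit failed to converge from any start", call. = FALSE)

  theta <- best$par
  mod <- eval_model(theta)
  Ea <- theta[1]; Pf_ref <- exp(theta[2]); X <- theta[3]
  A <- Pf_ref * exp(Ea / (R * T_ref))

  ## covariance of (Ea, ln Pf_ref, X) from the profiled residual Jacobian
  J <- .num_jacobian(resid_fn, theta,
                     h = c(max(abs(Ea), 1) * 1e-6, 1e-6, 1e-6),
                     lower = lower, upper = upper)
  dof <- max(length(mod$res) - (3 + K), 1)
  s2 <- sum(mod$res^2) / dof
  cv <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
  flags <- character(0)
  if (is.null(cv) || any(!is.finite(diag(cv))) || any(diag(cv) < 0)) {
    cv <- matrix(Inf, 3, 3); flags <- c(flags, "singular_covariance")
  }
  se <- c(Ea = sqrt(cv[1, 1]),
          A = if (is.finite(cv[2, 2])) {
            ## delta method through A = Pf_ref exp(Ea / (R T_ref))
            g <- c(A / (R * T_ref), A, 0)
            sqrt(drop(t(g) %*% cv %*% g))
          } else Inf,
          X = sqrt(cv[3, 3]))

  if (X < 0.005 || X > 0.995) flags <- c(flags, "X_at_boundary")
  if (any(mod$Pf_c < 0.1 * Pf_m)) flags <- c(flags, "low_contrast")
  if (!(best$info %in% 1:4)) flags <- c(flags, "not_converged")

  fitted <- vector("list", K)
  i0 <- 0
  for (k in seq_len(K)) {
    nk <- length(wins[[k]]$t)
    fitted[[k]] <- wins[[k]]$I - mod$res[i0 + seq_len(nk)]
    i0 <- i0 + nk
  }

  structure(list(
    Ea = Ea, A = A, X = X, T_ref = T_ref, Pf_ref = Pf_ref,
    Pf_c = mod$Pf_c, Pf_m = Pf_m, b = mod$b,
    temperature = temps, se = se, cov = cv, flags = flags,
    rss = best$deviance, residuals = mod$res, fitted = fitted,
    windows = wins, method = "global", n_starts = length(starts)
  ), class = "ea_globalfit")
}

#' @export
print.ea_globalfit <- function(x, ...) {
  cat(sprintf("Global Ea fit: %d temperatures (%g-%g K)\n",
              length(x$temperature), min(x$temperature), max(x$temperature)))
  cat(sprintf("  Ea = %.4g kcal/mol (se %.2g)\n",
              J_to_kcal(x$Ea), J_to_kcal(x$se[["Ea"]])))
  cat(sprintf("  X  = %.4g (se %.2g)\n", x$X, x$se[["X"]]))
  cat(sprintf("  A  = %.4g m/s\n", x$A))
  cat("  Pf_c (um/s):",
      paste(sprintf("%.3g", m_s_to_um_s(x$Pf_c)), collapse = ", "), "\n")
  cat(sprintf("  RSS = %.4g\n", x$rss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ea_globalfit <- function(object, ...) {
  out <- list(
    Ea_kcal = J_to_kcal(object$Ea),
    se_Ea_kcal = J_to_kcal(object$se[["Ea"]]),
    X = object$X, se_X = object$se[["X"]],
    A = object$A,
    table = data.frame(
      temperature_K = object$temperature,
      Pf_c_um_s = m_s_to_um_s(object$Pf_c),
      Pf_m_um_s = m_s_to_um_s(object$Pf_m),
      b = object$b))
  class(out) <- "summary.ea_globalfit"
  out
}

#' @export
print.summary.ea_globalfit <- function(x, ...) {
  cat(sprintf("Ea = %.4g +- %.2g kcal/mol;  X = %.3g +- %.2g\n",
              x$Ea_kcal, x$se_Ea_kcal, x$X, x$se_X))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ea_globalfit <- function(object, ...)
  c(Ea = object$Ea, A = object$A, X = object$X)

#' @export
residuals.ea_globalfit <- function(object, ...) object$residuals

#' Predicted channel permeability at new temperatures
#'
#' @param object an `ea_globalfit`
#' @param temperature temperatures (K)
#' @param ... unused
#' @return channel permeability `Pf_c` (m/s) on the fitted Arrhenius curve
#' @export
predict.ea_globalfit <- function(object, temperature = object$temperature,
                                 ...) {
  object$A * exp(-object$Ea / (.const$R * temperature))
}

#' @export
plot.ea_globalfit <- function(x, ...) {
  graphics::plot(1 / x$temperature, log(x$Pf_c),
                 xlab = "1/T (1/K)", ylab = "ln Pf_c (m/s)",
                 main = sprintf("Ea = %.3g kcal/mol", J_to_kcal(x$Ea)), ...)
  graphics::abline(stats::lm(log(x$Pf_c) ~ I(1 / x$temperature)), lty = 2)
  invisible(x)
}
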