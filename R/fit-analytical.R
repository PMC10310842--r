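## Shared helpers for the analytical (Lambert-W) fits.
##
## The intensity coefficient b enters the model I = 1 - b * V(t) linearly,
## so for any candidate kinetic parameters the optimal b has the closed form
## b = sum(V * (1 - I)) / sum(V^2); the nonlinear search runs over the
## kinetic parameters only (variable projection).

.profile_b <- function(V, I) {
  b <- sum(V * (1 - I)) / sum(V * V)
  list(b = b, res = I - (1 - b * V))
}

#' Fit the membrane permeability of a protein-free control trace
#'
#' Single-population analytical fit: `I = 1 - b * V(t; Pf_m)` with `V` the
#' closed-form shrinkage solution. `b` is profiled out; the search over
#' `Pf_m` is a 1-D golden-section/parabolic minimization on a log scale.
#'
#' @param trace an [sf_trace()] of a protein-free vesicle sample
#' @param dead_time instrument dead time (s)
#' @param interval_um search interval for `Pf_m` in um/s
#' @return list with `Pf_m` (m/s), `b` (1/m3), `rss`
#' @export
fit_control <- function(trace, dead_time = 1e-3, interval_um = c(0.05, 5e4)) {
  stopifnot(inherits(trace, "sf_trace"))
  w <- .trace_window(trace, dead_time)
  obj <- function(lP) {
    V <- volume_analytic(w$t, trace$spec, exp(lP))
    sum(.profile_b(V, w$I)$res^2)
  }
  opt <- stats::optimize(obj, interval = log(um_s_to_m_s(interval_um)),
                         tol = 1e-10)
  Pf_m <- exp(opt$minimum)
  pb <- .profile_b(volume_analytic(w$t, trace$spec, Pf_m), w$I)
  list(Pf_m = Pf_m, b = pb$b, rss = sum(pb$res^2))
}

#' Per-trace analytical fit of a proteoliposome trace
#'
#' Fits the normalized scattering model of a mixed population,
#' `I = 1 - b * [X V(t; Pf_m) + (1 - X) V(t; Pf_m + Pf_c)]`,
#' with the protein-free membrane permeability `Pf_m` held fixed at the
#' value measured on the matching control sample. Free parameters are the
#' channel contribution `Pf_c`, the empty-vesicle fraction `X` and the
#' intensity coefficient `b` (profiled out). Standard errors come from the
#' Jacobian-based covariance of the full (Pf_c, X, b) residual at the
#' optimum.
#'
#' When the two subpopulations are nearly exchangeable (`Pf_c` small
#' compared to `Pf_m`) or `X` is pinned at a boundary, the parameters are
#' not identifiable; the result carries a flag and inflated errors rather
#' than failing silently.
#'
#' @param trace an [sf_trace()] of the proteoliposome sample
#' @param Pf_m fixed channel-free membrane permeability (m/s), from
#'   [fit_control()]
#' @param dead_time instrument dead time (s)
#' @param X_init starting value for the empty fraction
#' @return an object of class `sf_anafit` with `Pf_c`, `X`, `b`, standard
#'   errors `se`, `flags`, `rss`, `fitted`, `residuals`
#' @export
fit_analytical_single <- function(trace, Pf_m, dead_time = 1e-3,
                                  X_init = 0.5) {
  stopifnot(inherits(trace, "sf_trace"),
            is.numeric(Pf_m), length(Pf_m) == 1, Pf_m > 0)
  w <- .trace_window(trace, dead_time)
  spec <- trace$spec

  model_V <- function(Pf_c, X)
    mixture_volume(w$t, X, spec, Pf_m, Pf_m + Pf_c)
  resid_fn <- function(p) {     # p = (log Pf_c [m/s], X)
    V <- model_V(exp(p[1]), p[2])
    .profile_b(V, w$I)$res
  }

  ## deterministic start: exponential fit supplies the fast-component Pf
  Pf_c0 <- tryCatch({
    ef <- fit_exponential(trace, dead_time = dead_time)
    p0 <- if (!is.na(ef$Pf_prot)) ef$Pf_prot - Pf_m else ef$Pf_empty - Pf_m
    max(p0, Pf_m)
  }, error = function(e) 10 * Pf_m)

  fit <- minpack.lm::nls.lm(
    par = c(log(Pf_c0), X_init),
    lower = c(log(1e-10), 0), upper = c(log(1), 1),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  Pf_c <- exp(fit$par[1]); X <- fit$par[2]
  pb <- .profile_b(model_V(Pf_c, X), w$I)

  ## covariance of (Pf_c, X, b) from the unprofiled residual Jacobian
  full_res <- function(q) w$I - (1 - q[3] * model_V(q[1], q[2]))
  q_hat <- c(Pf_c, X, pb$b)
  J <- .num_jacobian(full_res, q_hat,
                     h = abs(q_hat) * 1e-6 + 1e-12,
                     lower = c(0, 0, -Inf), upper = c(Inf, 1, Inf))
  dof <- max(length(w$t) - 3, 1)
  s2 <- sum(pb$res^2) / dof
  JtJ <- crossprod(J)
  cv <- tryCatch(solve(JtJ) * s2, error = function(e) NULL)
  flags <- character(0)
  if (is.null(cv) || any(!is.finite(diag(cv))) || any(diag(cv) < 0)) {
    cv <- matrix(Inf, 3, 3)
    flags <- c(flags, "singular_covariance")
  }
  se <- sqrt(diag(cv))
  names(se) <- c("Pf_c", "X", "b")

  if (Pf_c < 0.1 * Pf_m) flags <- c(flags, "low_contrast")
  if (X > 0.99 || X < 0.01) flags <- c(flags, "X_at_boundary")
  if (is.finite(se[["Pf_c"]]) && se[["Pf_c"]] > Pf_c)
    flags <- c(flags, "Pf_c_unresolved")

  structure(list(
    Pf_c = Pf_c, X = X, b = pb$b, Pf_m = Pf_m,
    se = se, cov = cv, flags = flags,
    rss = sum(pb$res^2), fitted = w$I - pb$res, residuals = pb$res,
    t = w$t, temperature = trace$temperature, spec = spec,
    converged = fit$info %in% 1:4
  ), class = "sf_anafit")
}

## forward-difference Jacobian of a vector-valued function; the step is
## flipped backward where a forward step would leave [lower, upper]
.num_jacobian <- function(f, x, h, lower = -Inf, upper = Inf) {
  f0 <- f(x)
  lower <- rep_len(lower, length(x))
  upper <- rep_len(upper, length(x))
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    hj <- if (x[j] + h[j] > upper[j]) -h[j] else h[j]
    if (x[j] + hj < lower[j]) hj <- -hj
    xp <- x; xp[j] <- xp[j] + hj
    J[, j] <- (f(xp) - f0) / hj
  }
  J
}

#' @export
print.sf_anafit <- function(x, ...) {
  cat("Analytical stopped-flow fit (Pf_m fixed)\n")
  cat(sprintf("  Pf_c = %.4g um/s (se %.2g)\n",
              m_s_to_um_s(x$Pf_c), m_s_to_um_s(x$se[["Pf_c"]])))
  cat(sprintf("  X    = %.4g (se %.2g)\n", x$X, x$se[["X"]]))
  cat(sprintf("  b    = %.4g 1/m^3, Pf_m = %.4g um/s, RSS = %.3g\n",
              x$b, m_s_to_um_s(x$Pf_m), x$rss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.sf_anafit <- function(object, ...)
  c(Pf_c = object$Pf_c, X = object$X, b = object$b)

#' @export
residuals.sf_anafit <- function(object, ...) object$residuals

#' @export
fitted.sf_anafit <- function(object, ...) object$fitted

#' @export
predict.sf_anafit <- function(object, t = object$t, ...) {
  V <- mixture_volume(t, object$X, object$spec, object$Pf_m,
                      object$Pf_m + object$Pf_c)
  1 - object$b * V
}

#' @export
plot.sf_anafit <- function(x, ...) {
  graphics::plot(x$t, x$fitted + x$residuals, pch = ".", col = "grey40",
                 xlab = "time (s)", ylab = "normalized intensity", ...)
  graphics::lines(x$t, x$fitted, col = "red", lwd = 2)
  invisible(x)
}
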