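#' Osmotic vesicle shrinkage rate
#'
#' Rate of volume change of a vesicle with water permeability `Pf` under an
#' osmotic gradient,
#' \deqn{dV/dt = S P_f V_w (c_{in,0} V_0 / V - c_{out}),}
#' where the internal osmolarity follows from solute conservation,
#' `c_in(t) = c_in0 * V0 / V(t)`. Negative for a hyperosmotic exterior.
#'
#' @param V vesicle volume (m3), > 0 (vectorized)
#' @param spec a [vesicle_spec()]
#' @param Pf membrane water permeability (m/s), >= 0
#' @return dV/dt in m3/s
#' @export
shrinkage_rate <- function(V, spec, Pf) {
  .check_vesicle_spec(spec)
  if (!is.numeric(V) || any(V <= 0)) stop("V must be positive", call. = FALSE)
  if (!is.numeric(Pf) || length(Pf) != 1 || Pf < 0)
    stop("Pf must be a single non-negative permeability (m/s)", call. = FALSE)
  spec$S * Pf * spec$V_w * (spec$c_in0 * spec$V0 / V - spec$c_out)
}

#' Closed-form vesicle volume under an osmotic jump
#'
#' Analytical solution of the shrinkage equation in terms of the principal
#' branch of the Lambert W function,
#' \deqn{V(t) = V_0 \frac{c_{in,0}}{c_{out}}\left\{1 + W\!\left(
#'   \frac{c_\Delta}{c_{in,0}} \exp\left(\frac{c_\Delta}{c_{in,0}}
#'   - \frac{S P_f V_w c_{out}^2}{V_0 c_{in,0}} t\right)\right)\right\}}
#' with \eqn{c_\Delta = c_{out} - c_{in,0}}. For a hyperosmotic exterior
#' (`c_delta > 0`) the Lambert argument is positive for all t, the solution
#' is strictly decreasing and approaches the osmotic equilibrium volume
#' `V0 * c_in0 / c_out`.
#'
#' @param t time(s) in seconds, >= 0 (vectorized)
#' @param spec a [vesicle_spec()]
#' @param Pf membrane water permeability (m/s)
#' @return vesicle volume(s), m3
#' @seealso [volume_numeric()] for the ODE-integration cross-check
#' @export
volume_analytic <- function(t, spec, Pf) {
  .check_vesicle_spec(spec)
  if (!is.numeric(t) || any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (!is.numeric(Pf) || length(Pf) != 1 || Pf < 0)
    stop("Pf must be a single non-negative permeability (m/s)", call. = FALSE)
  ratio <- spec$c_delta / spec$c_in0
  decay <- spec$S * Pf * spec$V_w * spec$c_out^2 / (spec$V0 * spec$c_in0)
  arg <- ratio * exp(ratio - decay * t)
  if (any(arg < -exp(-1)))
    stop("Lambert-W argument outside the principal-branch domain ",
         "(requires c_out not too far below c_in0)", call. = FALSE)
  w <- pracma::lambertWp(arg)
  spec$V0 * spec$c_in0 / spec$c_out * (1 + w)
}

#' Numerically integrated vesicle volume
#'
#' Adaptive ODE integration (lsoda) of the shrinkage equation, used as an
#' independent cross-check of [volume_analytic()]. The state is integrated
#' as the reduced volume v = V/V0 for conditioning; local error control is
#' `rtol = 1e-10`, `atol = 1e-12` on v.
#'
#' @param t_grid increasing time grid starting at 0 (s)
#' @param spec a [vesicle_spec()]
#' @param Pf membrane water permeability (m/s)
#' @return volumes (m3) at `t_grid`
#' @export
volume_numeric <- function(t_grid, spec, Pf) {
  .check_vesicle_spec(spec)
  if (!is.numeric(t_grid) || t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must be increasing and start at 0", call. = FALSE)
  if (!is.numeric(Pf) || length(Pf) != 1 || Pf < 0)
    stop("Pf must be a single non-negative permeability (m/s)", call. = FALSE)
  k <- spec$S * Pf * spec$V_w / spec$V0       # 1 / (s osmol/m3)
  rhs <- function(t, y, parms) {
    list(k * (spec$c_in0 / y[1] - spec$c_out))
  }
  sol <- deSolve::ode(y = c(v = 1), times = t_grid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration of the shrinkage equation failed", call. = FALSE)
  unname(sol[, "v"]) * spec$V0
}

#' Map vesicle volume to normalized scattered intensity
#'
#' The scattered intensity is assumed affine in the vesicle volume; after
#' normalization the offset is absorbed and
#' \deqn{I_{norm}(t) = 1 - b V(t).}
#'
#' @param V volume series (m3)
#' @param b intensity-per-volume coefficient (1/m3), > 0
#' @return normalized intensity series (dimensionless)
#' @export
intensity_from_volume <- function(V, b) {
  stopifnot(is.numeric(V), is.numeric(b), length(b) == 1)
  if (b <= 0) stop("b must be > 0", call. = FALSE)
  1 - b * V
}

#' Mean volume of a mixed empty-vesicle / proteoliposome population
#'
#' Convex combination of the closed-form shrinkage curves of the two
#' subpopulations,
#' \deqn{V_{tot}(t) = X V_{empty}(t) + (1 - X) V_{prot}(t),}
#' where `X` is the protein-free (empty) vesicle fraction.
#'
#' @param t time(s), s
#' @param X empty-vesicle fraction in \[0, 1\]
#' @param spec a [vesicle_spec()] shared by both subpopulations
#' @param Pf_empty permeability of the protein-free vesicles (m/s)
#' @param Pf_prot total permeability of the proteoliposomes (m/s)
#' @return mean volume (m3)
#' @export
mixture_volume <- function(t, X, spec, Pf_empty, Pf_prot) {
  if (!is.numeric(X) || length(X) != 1 || X < 0 || X > 1)
    stop("X must lie in [0, 1]", call. = FALSE)
  if (X == 1) return(volume_analytic(t, spec, Pf_empty))
  if (X == 0) return(volume_analytic(t, spec, Pf_prot))
  X * volume_analytic(t, spec, Pf_empty) +
    (1 - X) * volume_analytic(t, spec, Pf_prot)
}

#' Single-channel permeability from the channel contribution
#'
#' The membrane permeability of a channel-doped vesicle decomposes as
#' `P_f = P_f,m + P_f,c` with `P_f,c = n * p_f / (pi * d^2)` for `n`
#' channels in a vesicle of diameter `d`. This inverts the channel term:
#' `p_f = P_f,c * pi * d^2 / n`.
#'
#' @param Pf_c channel contribution to the membrane permeability (m/s)
#' @param n number of channels per vesicle, >= 1
#' @param d vesicle diameter (m)
#' @return single-channel permeability p_f (m3/s)
#' @export
pf_single_channel <- function(Pf_c, n, d) {
  stopifnot(is.numeric(Pf_c), Pf_c >= 0, is.numeric(d), d > 0)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  Pf_c * pi * d^2 / n
}

#' Total membrane permeability of a channel-doped vesicle
#'
#' `P_f = P_f,m + n * p_f / (pi * d^2)`; linear in the channel count.
#'
#' @param Pf_m channel-free membrane permeability (m/s)
#' @param pf single-channel permeability (m3/s)
#' @param n number of channels per vesicle, >= 0 (vectorized)
#' @param d vesicle diameter (m)
#' @return total membrane permeability (m/s)
#' @export
total_pf <- function(Pf_m, pf, n, d) {
  stopifnot(is.numeric(Pf_m), Pf_m >= 0, is.numeric(pf), pf >= 0,
            is.numeric(d), d > 0, is.numeric(n), all(n >= 0))
  Pf_m + n * pf / (pi * d^2)
}
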