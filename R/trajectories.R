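#' Pore geometry for permeation-event counting
#'
#' Boundaries of the single-file pore along its axis, the dividing surface
#' used for half-way counting, and the histogram bin width for free-energy
#' profiles. The defaults place the pore entries/exits at -1.4 and 1.7 nm
#' (as determined from the free-energy profile of a water channel) with
#' the dividing surface at 0 and 0.05 nm bins.
#'
#' @param z_entry,z_exit pore boundaries (nm), `z_entry < z_exit`
#' @param z_div dividing surface (nm), strictly between the boundaries
#' @param bin_width histogram bin width for profiles (nm)
#' @return an object of class `pore_geometry`
#' @export
pore_geometry <- function(z_entry = -1.4, z_exit = 1.7, z_div = 0,
                          bin_width = 0.05) {
  stopifnot(is.numeric(z_entry), is.numeric(z_exit), is.numeric(z_div),
            z_entry < z_div, z_div < z_exit, bin_width > 0)
  structure(list(z_entry = z_entry, z_exit = z_exit, z_div = z_div,
                 bin_width = bin_width),
            class = "pore_geometry")
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat(sprintf("Pore geometry: [%g, %g] nm, z_div = %g nm, bins %g nm\n",
              x$z_entry, x$z_exit, x$z_div, x$bin_width))
  invisible(x)
}

.as_traj_list <- function(trajs) {
  if (inherits(trajs, "permeation_trajectories")) return(trajs$z)
  if (is.numeric(trajs)) return(list(trajs))
  if (is.matrix(trajs)) return(lapply(seq_len(ncol(trajs)), function(j)
    trajs[, j]))
  stopifnot(is.list(trajs), all(vapply(trajs, is.numeric, TRUE)))
  trajs
}

## Region coding along the pore axis:
##   0 below entry | 1 inside, below z_div | 2 inside, >= z_div | 3 above exit
## Consecutive duplicates are collapsed so the event walk touches each
## region change once (the "streaming" pass); the per-sample brute-force
## replay used as a test oracle must agree event for event.
.region_code <- function(z, geom) {
  (z >= geom$z_entry) + (z >= geom$z_div) + (z > geom$z_exit)
}

## one trajectory -> event counts
## Entries that start inside the pore (unknown origin) are not credited
## with entries, traversals or half-way events.
.count_events <- function(z, geom) {
  if (length(z) < 2)
    return(c(through_up = 0L, through_down = 0L,
             halfway_up = 0L, halfway_down = 0L,
             entries_up = 0L, entries_down = 0L))
  if (any(!is.finite(z))) stop("non-finite position in trajectory",
                               call. = FALSE)
  code <- .region_code(z, geom)
  code <- code[c(TRUE, diff(code) != 0)]   # collapse runs
  th_up <- th_dn <- hw_up <- hw_dn <- en_up <- en_dn <- 0L
  ## state: 0 = outside low, 3 = outside high, 1 = inside from low,
  ## 2 = inside from high, -1 = inside, unknown origin
  st <- if (code[1] == 0) 0L else if (code[1] == 3) 3L else -1L
  reached <- FALSE
  for (c_i in code[-1]) {
    if (st == 0L) {                     # outside, low side
      if (c_i >= 1 && c_i <= 2) {
        st <- 1L; en_up <- en_up + 1L
        reached <- c_i == 2
        if (reached) hw_up <- hw_up + 1L
      } else if (c_i == 3) {            # jumped clear across the pore
        en_up <- en_up + 1L; hw_up <- hw_up + 1L; th_up <- th_up + 1L
        st <- 3L
      }
    } else if (st == 3L) {              # outside, high side
      if (c_i >= 1 && c_i <= 2) {
        st <- 2L; en_dn <- en_dn + 1L
        reached <- c_i == 1
        if (reached) hw_dn <- hw_dn + 1L
      } else if (c_i == 0) {
        en_dn <- en_dn + 1L; hw_dn <- hw_dn + 1L; th_dn <- th_dn + 1L
        st <- 0L
      }
    } else if (st == 1L) {              # inside, entered from low
      if (c_i == 2 && !reached) { reached <- TRUE; hw_up <- hw_up + 1L }
      else if (c_i == 3) {
        if (!reached) hw_up <- hw_up + 1L   # exit implies crossing z_div
        th_up <- th_up + 1L; st <- 3L
      } else if (c_i == 0) st <- 0L         # retreated, no traversal
    } else if (st == 2L) {              # inside, entered from high
      if (c_i == 1 && !reached) { reached <- TRUE; hw_dn <- hw_dn + 1L }
      else if (c_i == 0) {
        if (!reached) hw_dn <- hw_dn + 1L
        th_dn <- th_dn + 1L; st <- 0L
      } else if (c_i == 3) st <- 3L
    } else {                            # inside, unknown origin
      if (c_i == 0) st <- 0L else if (c_i == 3) st <- 3L
    }
  }
  c(through_up = th_up, through_down = th_dn,
    halfway_up = hw_up, halfway_down = hw_dn,
    entries_up = en_up, entries_down = en_dn)
}

#' Count completed pore traversals
#'
#' A traversal is an entry across one pore boundary followed by an exit
#' across the opposite boundary without an intervening return past the
#' entry boundary. Counted separately per direction.
#'
#' @param trajs trajectories: a `permeation_trajectories` object, a list
#'   of numeric position vectors (nm), a matrix (one column per particle)
#'   or a single numeric vector
#' @param geom a [pore_geometry()]
#' @return named integer vector `c(up, down, total)` (up = low-to-high)
#' @export
count_permeations <- function(trajs, geom = pore_geometry()) {
  stopifnot(inherits(geom, "pore_geometry"))
  zs <- .as_traj_list(trajs)
  ev <- Reduce(`+`, lapply(zs, .count_events, geom = geom),
               accumulate = FALSE)
  c(up = unname(ev["through_up"]), down = unname(ev["through_down"]),
    total = unname(ev["through_up"] + ev["through_down"]))
}

#' Count half-way pore entries
#'
#' Counts distinct pore entries that reach the dividing surface `z_div`
#' before exiting on either side (entries from the low side must reach
#' `z >= z_div`, entries from the high side `z < z_div`).
#'
#' @inheritParams count_permeations
#' @return named integer vector `c(up, down, total)`
#' @export
count_halfway <- function(trajs, geom = pore_geometry()) {
  stopifnot(inherits(geom, "pore_geometry"))
  zs <- .as_traj_list(trajs)
  ev <- Reduce(`+`, lapply(zs, .count_events, geom = geom))
  c(up = unname(ev["halfway_up"]), down = unname(ev["halfway_down"]),
    total = unname(ev["halfway_up"] + ev["halfway_down"]))
}

#' Transmission coefficient from permeation trajectories
#'
#' Estimates the transmission coefficient of the pore as the fraction of
#' dividing-surface reaches that end in a completed traversal,
#' `kappa = N_through / N_halfway` (default orientation; <= 1 by
#' construction, consistent with kappa as a recrossing correction).
#' `strict_ratio = TRUE` computes the literal inverse ratio
#' `N_halfway / N_through` instead. The standard deviation is taken over
#' trajectory subsets (quarters by default, halves when few trajectories).
#'
#' @inheritParams count_permeations
#' @param strict_ratio compute `N_halfway / N_through` instead (>= 1)
#' @param temperature optional temperature annotation (K)
#' @return an object of class `kappa_estimate` with `kappa`, `sd`,
#'   `N_through`, `N_halfway`, per-direction counts and `z_div`
#' @export
transmission_coefficient <- function(trajs, geom = pore_geometry(),
                                     strict_ratio = FALSE,
                                     temperature = NA) {
  stopifnot(inherits(geom, "pore_geometry"))
  zs <- .as_traj_list(trajs)
  per <- lapply(zs, .count_events, geom = geom)
  ev <- Reduce(`+`, per)
  N_th <- unname(ev["through_up"] + ev["through_down"])
  N_hw <- unname(ev["halfway_up"] + ev["halfway_down"])
  if (N_hw == 0)
    stop("no trajectory reached the dividing surface; ",
         "transmission coefficient undefined", call. = FALSE)
  if (N_th == 0)
    stop("no completed permeation event; transmission coefficient ",
         "undefined (all dividing-surface reaches recrossed)",
         call. = FALSE)
  ratio <- function(e) {
    th <- e["through_up"] + e["through_down"]
    hw <- e["halfway_up"] + e["halfway_down"]
    if (hw == 0 || th == 0) return(NA_real_)
    if (strict_ratio) unname(hw / th) else unname(th / hw)
  }
  ## spread over trajectory subsets
  n_sub <- if (length(zs) >= 8) 4L else if (length(zs) >= 2) 2L else 1L
  sd_k <- NA_real_
  if (n_sub > 1) {
    idx <- cut(seq_along(zs), n_sub, labels = FALSE)
    ks <- vapply(seq_len(n_sub), function(s)
      ratio(Reduce(`+`, per[idx == s])), 0)
    sd_k <- stats::sd(ks, na.rm = TRUE)
  }
  structure(list(
    kappa = ratio(ev), sd = sd_k,
    N_through = N_th, N_halfway = N_hw,
    counts = ev, z_div = geom$z_div, strict_ratio = strict_ratio,
    temperature = temperature, n_trajectories = length(zs)
  ), class = "kappa_estimate")
}

#' @export
print.kappa_estimate <- function(x, ...) {
  lab <- if (x$strict_ratio) "N_halfway / N_through" else
    "N_through / N_halfway"
  cat(sprintf("Transmission coefficient (%s) at z_div = %g nm\n",
              lab, x$z_div))
  cat(sprintf("  kappa = %.3g%s  (N_through = %d, N_halfway = %d, %d trajectories)\n",
              x$kappa,
              if (is.na(x$sd)) "" else sprintf(" +- %.2g", x$sd),
              x$N_through, x$N_halfway, x$n_trajectories))
  invisible(x)
}

#' Free-energy profile along the pore axis
#'
#' Boltzmann inversion of the position distribution of water molecules
#' along the pore axis: positions are histogrammed in `bin_width` bins
#' between the pore boundaries, the distribution is normalized to unit
#' mass over occupied bins, and
#' \deqn{\Delta G(z) = -RT \ln d(z)}
#' per bin. Empty bins are reported as `NA`, not as infinities. The
#' profile is defined up to an additive constant set by the normalization.
#'
#' @param positions numeric vector of axial positions (nm), or
#'   trajectories (flattened)
#' @param geom a [pore_geometry()]
#' @param temperature absolute temperature (K)
#' @return data.frame with `z` (bin midpoint, nm), `count`, `d`
#'   (normalized distribution) and `dG` (J/mol)
#' @export
free_energy_profile <- function(positions, geom = pore_geometry(),
                                temperature = 296) {
  stopifnot(inherits(geom, "pore_geometry"), temperature > 0)
  z <- unlist(.as_traj_list(positions), use.names = FALSE)
  z <- z[z >= geom$z_entry & z <= geom$z_exit]
  if (!length(z)) stop("no samples inside the pore", call. = FALSE)
  breaks <- seq(geom$z_entry, geom$z_exit + geom$bin_width,
                by = geom$bin_width)
  counts <- tabulate(findInterval(z, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1)
  d <- counts / sum(counts)
  dG <- ifelse(counts > 0, -.const$R * temperature * log(d), NA_real_)
  data.frame(z = breaks[-length(breaks)] + geom$bin_width / 2,
             count = counts, d = d, dG = dG)
}

#' Generate 1-D Langevin walker trajectories through a pore
#'
#' Overdamped discrete Langevin dynamics in a configurable 1-D potential:
#' \deqn{z_{t+1} = z_t - \frac{\sigma^2}{2RT} U'(z_t) + v\,\delta
#'       + \sigma \xi_t,}
#' with `sigma` the diffusive step size, `U` the potential (J/mol), `v` an
#' optional constant drift per step, and standard normal `xi`. The domain
#' extends `margin` nm beyond each pore boundary; its edges act as
#' reservoir walls that reflect leaving particles back, keeping the
#' particle number constant (the synthetic analogue of bulk water).
#'
#' @param potential function of z (nm) returning the potential in J/mol;
#'   `NULL` for a flat potential
#' @param geom a [pore_geometry()]
#' @param n_particles number of walkers
#' @param n_steps number of steps per walker
#' @param step_sd diffusive step standard deviation (nm); 0 for
#'   deterministic drift
#' @param drift constant displacement per step (nm)
#' @param temperature absolute temperature (K)
#' @param margin reservoir width beyond each pore boundary (nm)
#' @param z0 initial positions; default uniform over the domain
#'   (deterministic quantile spacing, so only the noise consumes RNG)
#' @param seed RNG seed
#' @return an object of class `permeation_trajectories`: list with `z`
#'   (list of position vectors, nm), `dt = 1` step units, and the
#'   generation parameters
#' @export
generate_walk_trajectories <- function(potential = NULL,
                                       geom = pore_geometry(),
                                       n_particles = 100, n_steps = 1000,
                                       step_sd = 0.05, drift = 0,
                                       temperature = 296, margin = 1,
                                       z0 = NULL, seed = NULL) {
  stopifnot(inherits(geom, "pore_geometry"), n_particles >= 1,
            n_steps >= 1, step_sd >= 0, temperature > 0, margin > 0)
  z_lo <- geom$z_entry - margin
  z_hi <- geom$z_exit + margin
  if (is.null(z0))
    z0 <- z_lo + (seq_len(n_particles) - 0.5) / n_particles * (z_hi - z_lo)
  stopifnot(length(z0) == n_particles)
  RT <- .const$R * temperature
  gradU <- if (is.null(potential)) function(z) 0 else function(z) {
    h <- 1e-4
    (potential(z + h) - potential(z - h)) / (2 * h)
  }
  Z <- matrix(0, n_steps + 1, n_particles)
  Z[1, ] <- z0
  .with_seed(seed, {
    for (s in seq_len(n_steps)) {
      z <- Z[s, ]
      z <- z - step_sd^2 / (2 * RT) * gradU(z) + drift
      if (step_sd > 0) z <- z + stats::rnorm(n_particles, 0, step_sd)
      ## reflecting reservoir walls
      z <- ifelse(z < z_lo, 2 * z_lo - z, z)
      z <- ifelse(z > z_hi, 2 * z_hi - z, z)
      ## a pathological step could overshoot both walls; clamp defensively
      Z[s + 1, ] <- pmin(pmax(z, z_lo), z_hi)
    }
  })
  structure(list(
    z = lapply(seq_len(n_particles), function(j) Z[, j]),
    dt = 1, geom = geom, step_sd = step_sd, drift = drift,
    temperature = temperature, domain = c(z_lo, z_hi), seed = seed
  ), class = "permeation_trajectories")
}

#' @export
print.permeation_trajectories <- function(x, ...) {
  cat(sprintf(
    "Permeation trajectories: %d walkers x %d steps, domain [%g, %g] nm\n",
    length(x$z), length(x$z[[1]]) - 1, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Read / write permeation trajectories as plain tabular text
#'
#' Three whitespace-separated columns `particle step z` with a header
#' line; one row per sample.
#'
#' @param trajs a `permeation_trajectories` object or list of numeric
#'   vectors
#' @param path file path
#' @return `read_trajectories()` returns a list of numeric position
#'   vectors; `write_trajectories()` returns `path` invisibly
#' @export
write_trajectories <- function(trajs, path) {
  zs <- .as_traj_list(trajs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("particle step z", con)
  for (j in seq_along(zs))
    writeLines(sprintf("%d %d %.8g", j, seq_along(zs[[j]]) - 1L, zs[[j]]),
               con)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE)
  stopifnot(all(c("particle", "step", "z") %in% names(tab)))
  tab <- tab[order(tab$particle, tab$step), ]
  unname(split(tab$z, tab$particle))
}
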