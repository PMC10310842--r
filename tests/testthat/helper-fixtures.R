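# Shared fixtures for the test suite. Everything is generated in code;
# seeds are fixed so that every run sees identical data.

# canonical AQP1-like study conditions
aqp1_model <- function(...) {
  population_model(N_mean = 20, X = 0.4, pf_ref_cm3_s = 3.2e-13,
                   Ea_c_kcal = 3.75, Pf_m_ref_um_s = 6,
                   Ea_m_kcal = 11.6, T_ref = 278, ...)
}

# short protocol for fit tests: full dual time base but noiseless
quiet_protocol <- function(noise_sd = 0, ...)
  measurement_protocol(noise_sd = noise_sd, ...)

# brute-force per-sample state-machine replay of the permeation counting
# rules; written independently of the package's run-compressed event walk
# and used as the counting oracle.
brute_force_counts <- function(z, geom) {
  region <- function(zi) {
    if (zi < geom$z_entry) "low"
    else if (zi > geom$z_exit) "high"
    else if (zi >= geom$z_div) "in_hi" else "in_lo"
  }
  th_up <- th_dn <- hw_up <- hw_dn <- 0L
  state <- switch(region(z[1]), low = "out_low", high = "out_high",
                  "in_unknown")
  reached <- FALSE
  for (zi in z[-1]) {
    r <- region(zi)
    if (state == "out_low") {
      if (r %in% c("in_lo", "in_hi")) {
        state <- "in_low"; reached <- r == "in_hi"
        if (reached) hw_up <- hw_up + 1L
      } else if (r == "high") {
        hw_up <- hw_up + 1L; th_up <- th_up + 1L; state <- "out_high"
      }
    } else if (state == "out_high") {
      if (r %in% c("in_lo", "in_hi")) {
        state <- "in_high"; reached <- r == "in_lo"
        if (reached) hw_dn <- hw_dn + 1L
      } else if (r == "low") {
        hw_dn <- hw_dn + 1L; th_dn <- th_dn + 1L; state <- "out_low"
      }
    } else if (state == "in_low") {
      if (r == "in_hi" && !reached) { reached <- TRUE; hw_up <- hw_up + 1L }
      else if (r == "high") {
        if (!reached) hw_up <- hw_up + 1L
        th_up <- th_up + 1L; state <- "out_high"
      } else if (r == "low") state <- "out_low"
    } else if (state == "in_high") {
      if (r == "in_lo" && !reached) { reached <- TRUE; hw_dn <- hw_dn + 1L }
      else if (r == "low") {
        if (!reached) hw_dn <- hw_dn + 1L
        th_dn <- th_dn + 1L; state <- "out_low"
      } else if (r == "high") state <- "out_high"
    } else { # in_unknown
      if (r == "low") state <- "out_low"
      if (r == "high") state <- "out_high"
    }
  }
  c(through = th_up + th_dn, halfway = hw_up + hw_dn,
    up = th_up, down = th_dn)
}
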