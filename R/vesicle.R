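#' Geometry and osmotic state of a vesicle population
#'
#' Describes one class of large unilamellar vesicles subjected to an osmotic
#' jump: radius, the derived volume and surface area, the initial internal
#' osmolarity and the external osmolarity after mixing.
#'
#' Osmotic concentrations are treated as ideal osmolarities. Buffer recipes
#' are converted by the caller; for a fully dissociating 1:1 salt such as
#' NaCl the osmolarity counts both ions (x2). The default gradient matches
#' vesicles equilibrated in 100 mM NaCl + 10 mM MOPS (about 0.21 osmol/L)
#' mixed against the same buffer plus 150 mM sucrose (c_out = c_in0 + 0.15
#' osmol/L).
#'
#' @param r0_nm vesicle radius in nm (> 0); extrusion through 100 nm pores
#'   gives r0 of about 50 nm
#' @param c_in0 initial internal osmolarity (osmol/m3 = mosmol/L); default 210
#' @param c_out external osmolarity after mixing (osmol/m3); default 360
#' @param V_w molar volume of water (m3/mol)
#' @return an object of class `vesicle_spec`: a list with `r0` (m), `V0`
#'   (m3), `S` (m2), `c_in0`, `c_out`, `c_delta = c_out - c_in0` (osmol/m3)
#'   and `V_w` (m3/mol)
#' @examples
#' vesicle_spec()                    # 50 nm, 210 -> 360 mosmol/L jump
#' vesicle_spec(r0_nm = 65, c_out = 710)
#' @export
vesicle_spec <- function(r0_nm = 50, c_in0 = 210, c_out = 360,
                         V_w = aquaflux_constants$V_w) {
  stopifnot(is.numeric(r0_nm), length(r0_nm) == 1, r0_nm > 0,
            is.numeric(c_in0), length(c_in0) == 1, c_in0 > 0,
            is.numeric(c_out), length(c_out) == 1, c_out > 0,
            is.numeric(V_w), length(V_w) == 1, V_w > 0)
  r0 <- r0_nm * 1e-9
  structure(list(
    r0      = r0,
    V0      = 4 / 3 * pi * r0^3,
    S       = 4 * pi * r0^2,
    c_in0   = c_in0,
    c_out   = c_out,
    c_delta = c_out - c_in0,
    V_w     = V_w
  ), class = "vesicle_spec")
}

#' @export
print.vesicle_spec <- function(x, ...) {
  cat("Vesicle spec: r0 =", format(x$r0 * 1e9), "nm,",
      "V0 =", format(x$V0, digits = 4), "m^3,",
      "c_in0 =", x$c_in0, "osmol/m^3,",
      "c_out =", x$c_out, "osmol/m^3\n")
  invisible(x)
}

.check_vesicle_spec <- function(spec) {
  if (!inherits(spec, "vesicle_spec"))
    stop("`spec` must be a vesicle_spec object", call. = FALSE)
  spec
}
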