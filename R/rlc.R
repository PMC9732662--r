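#' Electrical-analog parameters of one artery segment
#'
#' Maps a uniform thin-walled deformable tube onto its lumped electrical
#' analog:
#' * viscous resistance from laminar (Hagen-Poiseuille) flow,
#'   `R = 128 mu l / (pi d^4)`;
#' * blood inertance `L = 4 rho l / (pi d^2)`;
#' * wall compliance from the thin-wall elastic tube law,
#'   `C = pi d^3 l / (4 E h)` with wall thickness `h = h_ratio * d`.
#'
#' @param segment A list or one-row data.frame with fields `length_m`
#'   (or `length`), `effective_diameter` (m), `youngs_modulus` (Pa) and
#'   `wall_thickness_ratio` (h/d, dimensionless).
#' @param blood A [blood_properties()] object.
#' @return A list of class `segment_rlc` with `resistance` (Pa s/m^3),
#'   `inertance` (Pa s^2/m^3) and `compliance` (m^3/Pa).
#' @export
#' @examples
#' seg <- list(length_m = 0.01, effective_diameter = 3e-3,
#'             youngs_modulus = 4e5, wall_thickness_ratio = 0.1)
#' segment_rlc(seg, blood_properties())  # R ~ 1.76e7 Pa s/m^3
segment_rlc <- function(segment, blood) {
  l <- if (!is.null(segment$length_m)) segment$length_m else segment$length
  d <- segment$effective_diameter
  E <- segment$youngs_modulus
  hr <- segment$wall_thickness_ratio
  if (is.null(l) || !is.finite(l) || l <= 0) stop("segment length must be > 0")
  if (is.null(d) || !is.finite(d) || d <= 0)
    stop("segment absent (effective_diameter == 0); prune it instead of computing RLC")
  if (is.null(E) || E <= 0) stop("youngs_modulus must be > 0")
  if (is.null(hr) || hr <= 0) stop("wall_thickness_ratio must be > 0")
  mu <- blood$dynamic_viscosity
  rho <- blood$density
  structure(list(
    resistance = 128 * mu * l / (pi * d^4),
    inertance  = 4 * rho * l / (pi * d^2),
    compliance = pi * d^3 * l / (4 * E * hr * d)
  ), class = "segment_rlc")
}

# vectorized internal version over a segment table (all present)
segment_rlc_table <- function(seg, blood) {
  mu <- blood$dynamic_viscosity
  rho <- blood$density
  d <- seg$effective_diameter
  l <- seg$length_m
  data.frame(
    resistance = 128 * mu * l / (pi * d^4),
    inertance  = 4 * rho * l / (pi * d^2),
    compliance = pi * d^2 * l / (4 * seg$youngs_modulus * seg$wall_thickness_ratio)
  )
}
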