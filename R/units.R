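# Clinical units (mmHg, cm/s, mm, ml) are accepted at the I/O boundary and
# converted once; everything internal is SI (Pa, m, m3, s).

MMHG_PA <- 133.322387415

#' Unit conversions at the clinical I/O boundary
#'
#' Pressures in mmHg, velocities in cm/s, diameters in mm and volumes in ml
#' at the user-facing boundary; Pa, m/s, m and m^3 internally.
#'
#' @param x Numeric vector to convert.
#' @return The converted numeric vector.
#' @name units
#' @export
mmHg_to_Pa <- function(x) x * MMHG_PA

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / MMHG_PA

#' @rdname units
#' @export
cmps_to_mps <- function(x) x / 100

#' @rdname units
#' @export
mps_to_cmps <- function(x) x * 100

#' @rdname units
#' @export
mm_to_m <- function(x) x / 1000

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1000

#' @rdname units
#' @export
ml_to_m3 <- function(x) x / 1e6

#' @rdname units
#' @export
m3_to_ml <- function(x) x * 1e6

#' Blood rheological properties
#'
#' Dynamic viscosity and density used by the Hagen-Poiseuille resistance and
#' inertance laws of every arterial segment.
#'
#' @param dynamic_viscosity Dynamic viscosity in Pa s. Default 3.5e-3 (whole
#'   blood at physiological hematocrit).
#' @param density Density in kg/m^3. Default 1056.
#' @return An object of class `blood_properties`.
#' @export
#' @examples
#' blood_properties()
blood_properties <- function(dynamic_viscosity = 3.5e-3, density = 1056) {
  if (!is.numeric(dynamic_viscosity) || length(dynamic_viscosity) != 1L ||
      !is.finite(dynamic_viscosity) || dynamic_viscosity <= 0)
    stop("dynamic_viscosity must be a single positive number (Pa s)")
  if (!is.numeric(density) || length(density) != 1L ||
      !is.finite(density) || density <= 0)
    stop("density must be a single positive number (kg/m^3)")
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density),
            class = "blood_properties")
}

#' @export
print.blood_properties <- function(x, ...) {
  cat(sprintf("Blood: mu = %.3g Pa s, rho = %.4g kg/m^3\n",
              x$dynamic_viscosity, x$density))
  invisible(x)
}
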