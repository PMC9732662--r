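#' Volume-equivalent diameter of a multi-point vessel measurement
#'
#' Each artery segment is treated as a uniform tube whose diameter preserves
#' the lumen volume of the piecewise tube measured at several points:
#' `d_eq = sqrt(sum(d_i^2 l_i) / sum(l_i))`. With equal sub-lengths this is
#' the root-mean-square of the point diameters.
#'
#' @param point_diameters Numeric vector of diameters (any consistent unit),
#'   all >= 0.
#' @param sub_lengths Optional numeric vector of sub-segment lengths, same
#'   length as `point_diameters`; equal sub-lengths assumed when omitted.
#' @return The volume-equivalent diameter, 0 iff all point diameters are 0.
#' @export
#' @examples
#' volume_equivalent_diameter(c(2, 3, 4))  # sqrt(29/3)
volume_equivalent_diameter <- function(point_diameters, sub_lengths = NULL) {
  if (length(point_diameters) == 0L) stop("point_diameters must be non-empty")
  if (any(!is.finite(point_diameters)) || any(point_diameters < 0))
    stop("point_diameters must be finite and >= 0")
  if (is.null(sub_lengths)) sub_lengths <- rep(1, length(point_diameters))
  if (length(sub_lengths) != length(point_diameters))
    stop("point_diameters and sub_lengths must have the same length")
  if (any(!is.finite(sub_lengths)) || any(sub_lengths <= 0))
    stop("sub_lengths must be finite and > 0")
  sqrt(sum(point_diameters^2 * sub_lengths) / sum(sub_lengths))
}

#' Per-patient vascular geometry
#'
#' Point diameters for every topology segment measured from CTA, in mm, with
#' 0 encoding an absent segment. Values are stored as given (mm) and
#' converted to SI when the network is built.
#'
#' @param investigation_id Identifier of the investigation (one CTA/TCD pair).
#' @param point_diameters_mm Named list: one numeric vector of point
#'   diameters (mm) per segment name.
#' @param heart_period Cardiac period in seconds.
#' @param lengths_m Optional named numeric vector overriding segment lengths.
#' @return An object of class `patient_geometry`.
#' @export
patient_geometry <- function(investigation_id, point_diameters_mm,
                             heart_period = 0.8, lengths_m = NULL) {
  if (!is.list(point_diameters_mm) || is.null(names(point_diameters_mm)))
    stop("point_diameters_mm must be a named list of numeric vectors")
  for (nm in names(point_diameters_mm)) {
    d <- point_diameters_mm[[nm]]
    if (any(!is.finite(d)) || any(d < 0))
      stop("diameters for segment ", nm, " must be finite and >= 0")
  }
  if (!is.numeric(heart_period) || heart_period <= 0)
    stop("heart_period must be > 0")
  structure(list(investigation_id = as.character(investigation_id),
                 point_diameters_mm = point_diameters_mm,
                 heart_period = heart_period,
                 lengths_m = lengths_m),
            class = "patient_geometry")
}

#' @export
print.patient_geometry <- function(x, ...) {
  n_abs <- sum(vapply(x$point_diameters_mm, function(d) all(d == 0), logical(1)))
  cat(sprintf("Patient geometry '%s': %d segments (%d absent), T = %.3g s\n",
              x$investigation_id, length(x$point_diameters_mm), n_abs,
              x$heart_period))
  invisible(x)
}

#' Reference geometry from the topology's default diameters
#'
#' Builds a complete (no absent segment) geometry whose point diameters all
#' equal the topology's reference diameter for that segment. This is the
#' "default synthetic patient" used for smoke tests and as the base the
#' cohort generator perturbs.
#'
#' @param topology A `cow_topology`.
#' @param investigation_id Identifier, default `"reference"`.
#' @param heart_period Cardiac period (s).
#' @return A `patient_geometry`.
#' @export
reference_geometry <- function(topology, investigation_id = "reference",
                               heart_period = 0.8) {
  seg <- topology$segments
  pts <- lapply(seq_len(nrow(seg)),
                function(i) rep(seg$diameter_mm[i], seg$n_points[i]))
  names(pts) <- seg$name
  patient_geometry(investigation_id, pts, heart_period = heart_period)
}

#' Read and write geometry CSV files
#'
#' Schema: columns `investigation_id`, `segment_name`, `point_index`,
#' `diameter_mm`. An absent segment is encoded as a single row with
#' `diameter_mm = 0`.
#'
#' @param path CSV file path.
#' @param geometries A list of `patient_geometry` objects (or a single one).
#' @param heart_periods Optional named vector of cardiac periods (s) per
#'   investigation used when reading (the geometry CSV itself carries none).
#' @return `read_geometry_csv` returns a named list of `patient_geometry`;
#'   `write_geometry_csv` returns `path` invisibly.
#' @export
read_geometry_csv <- function(path, heart_periods = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("investigation_id", "segment_name", "point_index", "diameter_mm")
  if (!all(needed %in% names(df)))
    stop("geometry CSV must have columns: ", paste(needed, collapse = ", "))
  bad <- which(!is.finite(df$diameter_mm) | df$diameter_mm < 0)
  if (length(bad))
    stop("geometry CSV: negative or non-finite diameter at row ", bad[1])
  out <- lapply(split(df, df$investigation_id), function(g) {
    g <- g[order(g$segment_name, g$point_index), ]
    pts <- split(g$diameter_mm, g$segment_name)
    hp <- if (!is.null(heart_periods) &&
              g$investigation_id[1] %in% names(heart_periods))
      heart_periods[[g$investigation_id[1]]] else 0.8
    patient_geometry(g$investigation_id[1], pts, heart_period = hp)
  })
  out[order(names(out))]
}

#' @rdname read_geometry_csv
#' @export
write_geometry_csv <- function(geometries, path) {
  if (inherits(geometries, "patient_geometry")) geometries <- list(geometries)
  rows <- do.call(rbind, lapply(geometries, function(g) {
    do.call(rbind, lapply(names(g$point_diameters_mm), function(nm) {
      d <- g$point_diameters_mm[[nm]]
      if (all(d == 0)) d <- 0  # absent segment: single zero row
      data.frame(investigation_id = g$investigation_id, segment_name = nm,
                 point_index = seq_along(d), diameter_mm = d,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# sub-lengths used for the volume-equivalent diameter: equal fractions of
# the segment length (thirds for 3-point, halves for 2-point measurements)
equal_sublengths <- function(n, length_m) rep(length_m / n, n)
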