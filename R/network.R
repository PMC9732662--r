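#' Build a patient-specific arterial network
#'
#' Instantiates the common topology with one patient's measured diameters:
#' computes each segment's volume-equivalent diameter, prunes segments whose
#' diameters are all 0 (absent in CTA), verifies that every Windkessel
#' terminal remains connected to the inlet, and attaches the electrical-analog
#' R, L, C parameters.
#'
#' @param topology A `cow_topology`.
#' @param geometry A `patient_geometry` covering every topology segment.
#' @param blood A [blood_properties()] object.
#' @param youngs_modulus Named vector `c(cerebral=, systemic=)` of Young's
#'   moduli (Pa) seeding the wall model; calibration steps 2-3 re-fit these.
#' @param wall_thickness_ratio Wall thickness as a fraction of diameter (h/d).
#' @param wall_relaxation_time Voigt viscoelastic relaxation time of the
#'   arterial wall (s): each node compliance carries a series resistance
#'   `tau_wall / C_node` that damps non-physiological high-frequency
#'   inertance-compliance ringing while leaving mean (DC) flows exactly
#'   unchanged. Set 0 for a purely elastic wall.
#' @return An object of class `cow_network`: `segments` (with `effective_diameter`,
#'   `area`, `R`, `L`, `C`), `nodes`, `inlet_node`, `terminals`, `blood`.
#' @export
#' @examples
#' topo <- cow_topology()
#' net <- build_patient_network(topo, reference_geometry(topo), blood_properties())
#' net
build_patient_network <- function(topology, geometry, blood = blood_properties(),
                                  youngs_modulus = c(cerebral = 4e5, systemic = 4e5),
                                  wall_thickness_ratio = 0.1,
                                  wall_relaxation_time = 0.005) {
  seg <- topology$segments
  missing_seg <- setdiff(seg$name, names(geometry$point_diameters_mm))
  if (length(missing_seg))
    stop("geometry does not cover segment(s): ", paste(missing_seg, collapse = ", "))
  if (any(youngs_modulus <= 0)) stop("youngs_modulus must be > 0")
  if (wall_thickness_ratio <= 0) stop("wall_thickness_ratio must be > 0")

  if (!is.null(geometry$lengths_m)) {
    idx <- match(names(geometry$lengths_m), seg$name)
    seg$length_m[idx[!is.na(idx)]] <- geometry$lengths_m[!is.na(idx)]
  }
  d_eff <- vapply(seq_len(nrow(seg)), function(i) {
    pts <- geometry$point_diameters_mm[[seg$name[i]]]
    mm_to_m(volume_equivalent_diameter(pts, equal_sublengths(length(pts), seg$length_m[i])))
  }, numeric(1))
  seg$effective_diameter <- d_eff
  seg$youngs_modulus <- unname(youngs_modulus[seg$group])
  seg$wall_thickness_ratio <- wall_thickness_ratio

  present <- seg$effective_diameter > 0
  seg <- seg[present, , drop = FALSE]
  if (nrow(seg) == 0L) stop("all segments absent")

  nodes <- unique(c(seg$from, seg$to))
  if (!topology$inlet_node %in% nodes)
    stop("inlet node disconnected: no present segment touches ", topology$inlet_node)

  # reachability (undirected: collateral flow may reverse) via igraph
  g <- igraph::graph_from_data_frame(seg[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = nodes))
  reach <- names(igraph::subcomponent(g, topology$inlet_node))
  term <- topology$terminals
  dead <- term$terminal_id[!(term$node %in% reach)]
  if (length(dead))
    stop("non-perfusable territory: terminal(s) ",
         paste(dead, collapse = ", "), " unreachable from the inlet")
  absent_feeder <- term$terminal_id[!(term$feeding_segment %in% seg$name)]
  if (length(absent_feeder))
    stop("non-perfusable territory: feeding segment absent for terminal(s) ",
         paste(absent_feeder, collapse = ", "))

  rlc <- segment_rlc_table(seg, blood)
  seg$R <- rlc$resistance
  seg$L <- rlc$inertance
  seg$C <- rlc$compliance
  seg$area <- pi * seg$effective_diameter^2 / 4

  structure(list(segments = seg, nodes = nodes,
                 inlet_node = topology$inlet_node,
                 terminals = term, blood = blood,
                 wall_relaxation_time = wall_relaxation_time,
                 investigation_id = geometry$investigation_id,
                 heart_period = geometry$heart_period),
            class = "cow_network")
}

#' @export
print.cow_network <- function(x, ...) {
  cat(sprintf("Arterial network '%s': %d present segments (%d cerebral), %d nodes, %d terminals\n",
              x$investigation_id, nrow(x$segments),
              sum(x$segments$group == "cerebral"),
              length(x$nodes), nrow(x$terminals)))
  invisible(x)
}

# degree of each node = number of present incident segments
node_degrees <- function(network) {
  tab <- table(c(network$segments$from, network$segments$to))
  out <- as.integer(tab[network$nodes])
  names(out) <- network$nodes
  out
}

# cross-sectional area (m^2) of each terminal's feeding segment
terminal_areas <- function(network) {
  idx <- match(network$terminals$feeding_segment, network$segments$name)
  a <- network$segments$area[idx]
  names(a) <- network$terminals$terminal_id
  a
}

# terminal ids whose feeding segment belongs to the cerebral group
cerebral_terminals <- function(network) {
  idx <- match(network$terminals$feeding_segment, network$segments$name)
  network$terminals$terminal_id[network$segments$group[idx] == "cerebral"]
}

# replace group-wise Young's modulus by a multiplied value and refresh C
scale_youngs_modulus <- function(network, group, multiplier) {
  sel <- network$segments$group == group
  network$segments$youngs_modulus[sel] <-
    network$segments$youngs_modulus[sel] * multiplier
  network$segments$C[sel] <- network$segments$C[sel] / multiplier
  network
}
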