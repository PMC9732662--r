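#' Common 33-segment arterial topology
#'
#' The frozen common network: 18 cerebral segments resolving the circle of
#' Willis (bilateral distal ICA, M1, A1, A2, P1, P2, PComA and intracranial
#' vertebral arteries, plus the ACoA and basilar artery) and 15 systemic
#' segments (aorta, iliac, subclavian, carotid and extracranial
#' vertebral/carotid arteries) that provide the background circulation.
#' Per-patient simulation replaces the reference diameters with measured
#' ones; a diameter of 0 marks an absent segment, which is pruned.
#'
#' Segment lengths and reference diameters are a declared convention from
#' standard adult anatomy (they are not patient measurements) and can be
#' overridden per patient. The number of measurement points per segment
#' follows the CTA protocol: three points on each ICA/MCA/ACA/PCA segment,
#' two on the basilar and communicating arteries.
#'
#' @return An object of class `cow_topology` with elements `segments`
#'   (data.frame: `name`, `group`, `length_m`, `diameter_mm`, `n_points`,
#'   `from`, `to`), `inlet_node`, and `terminals` (data.frame: `terminal_id`,
#'   `node`, `feeding_segment`).
#' @export
#' @examples
#' topo <- cow_topology()
#' table(topo$segments$group)
cow_topology <- function() {
  seg <- function(name, group, length_mm, diameter_mm, n_points, from, to)
    data.frame(name = name, group = group, length_m = length_mm / 1000,
               diameter_mm = diameter_mm, n_points = n_points,
               from = from, to = to, stringsAsFactors = FALSE)
  segments <- rbind(
    # systemic trunk
    seg("ascending_aorta",          "systemic",  50, 28.0, 1, "AAo_root", "N_arch1"),
    seg("aortic_arch_1",            "systemic",  25, 24.0, 1, "N_arch1",  "N_arch2"),
    seg("aortic_arch_2",            "systemic",  40, 22.0, 1, "N_arch2",  "N_arch3"),
    seg("descending_aorta",         "systemic", 200, 20.0, 1, "N_arch3",  "N_abd"),
    seg("abdominal_aorta",          "systemic", 150, 14.0, 1, "N_abd",    "N_ilbif"),
    seg("R_iliac",                  "systemic", 100,  9.0, 1, "N_ilbif",  "N_R_leg"),
    seg("L_iliac",                  "systemic", 100,  9.0, 1, "N_ilbif",  "N_L_leg"),
    seg("R_subclavian",             "systemic", 100,  8.5, 1, "N_arch1",  "N_R_arm"),
    seg("L_subclavian",             "systemic", 100,  8.5, 1, "N_arch3",  "N_L_arm"),
    seg("R_common_carotid",         "systemic", 120,  7.0, 1, "N_arch1",  "N_R_cbif"),
    seg("L_common_carotid",         "systemic", 140,  7.0, 1, "N_arch2",  "N_L_cbif"),
    seg("R_ICA_extracranial",       "systemic", 130,  4.5, 1, "N_R_cbif", "N_R_ica"),
    seg("L_ICA_extracranial",       "systemic", 130,  4.5, 1, "N_L_cbif", "N_L_ica"),
    seg("R_vertebral_extracranial", "systemic", 140,  3.4, 1, "N_arch1",  "N_R_vert"),
    seg("L_vertebral_extracranial", "systemic", 140,  3.4, 1, "N_arch3",  "N_L_vert"),
    # cerebral network
    seg("R_ICA_distal",             "cerebral",  25,  4.0, 3, "N_R_ica",     "N_R_icaterm"),
    seg("L_ICA_distal",             "cerebral",  25,  4.0, 3, "N_L_ica",     "N_L_icaterm"),
    seg("R_M1",                     "cerebral",  22,  2.8, 3, "N_R_icaterm", "N_R_mca"),
    seg("L_M1",                     "cerebral",  22,  2.8, 3, "N_L_icaterm", "N_L_mca"),
    seg("R_A1",                     "cerebral",  13,  2.2, 3, "N_R_icaterm", "N_R_aca"),
    seg("L_A1",                     "cerebral",  13,  2.2, 3, "N_L_icaterm", "N_L_aca"),
    seg("R_A2",                     "cerebral",  25,  2.3, 3, "N_R_aca",     "N_R_aca2"),
    seg("L_A2",                     "cerebral",  25,  2.3, 3, "N_L_aca",     "N_L_aca2"),
    seg("ACoA",                     "cerebral",   3,  1.4, 2, "N_R_aca",     "N_L_aca"),
    seg("R_PComA",                  "cerebral",  15,  1.4, 2, "N_R_icaterm", "N_R_pcom"),
    seg("L_PComA",                  "cerebral",  15,  1.4, 2, "N_L_icaterm", "N_L_pcom"),
    seg("R_P1",                     "cerebral",   7,  2.1, 3, "N_ba_top",    "N_R_pcom"),
    seg("L_P1",                     "cerebral",   7,  2.1, 3, "N_ba_top",    "N_L_pcom"),
    seg("R_P2",                     "cerebral",  30,  2.0, 3, "N_R_pcom",    "N_R_pca"),
    seg("L_P2",                     "cerebral",  30,  2.0, 3, "N_L_pcom",    "N_L_pca"),
    seg("BA",                       "cerebral",  30,  3.2, 2, "N_vb",        "N_ba_top"),
    seg("R_vertebral_intracranial", "cerebral",  20,  2.9, 2, "N_R_vert",    "N_vb"),
    seg("L_vertebral_intracranial", "cerebral",  20,  2.9, 2, "N_L_vert",    "N_vb")
  )
  terminals <- data.frame(
    terminal_id = c("T_R_MCA", "T_L_MCA", "T_R_ACA", "T_L_ACA",
                    "T_R_PCA", "T_L_PCA", "T_R_arm", "T_L_arm",
                    "T_R_leg", "T_L_leg", "T_visceral"),
    node = c("N_R_mca", "N_L_mca", "N_R_aca2", "N_L_aca2",
             "N_R_pca", "N_L_pca", "N_R_arm", "N_L_arm",
             "N_R_leg", "N_L_leg", "N_abd"),
    feeding_segment = c("R_M1", "L_M1", "R_A2", "L_A2",
                        "R_P2", "L_P2", "R_subclavian", "L_subclavian",
                        "R_iliac", "L_iliac", "descending_aorta"),
    stringsAsFactors = FALSE
  )
  make_topology(segments, inlet_node = "AAo_root", terminals = terminals)
}

#' Construct an arterial network topology
#'
#' Low-level constructor used by [cow_topology()] and by small test networks.
#'
#' @param segments data.frame with columns `name`, `group` (`"cerebral"` or
#'   `"systemic"`), `length_m`, `diameter_mm`, `n_points`, `from`, `to`.
#' @param inlet_node Node receiving the prescribed aortic inflow.
#' @param terminals data.frame with columns `terminal_id`, `node` (where the
#'   WK3 outlet attaches), `feeding_segment` (segment whose cross-section
#'   represents the outlet for area-proportional flow splitting).
#' @return A `cow_topology` object.
#' @export
make_topology <- function(segments, inlet_node, terminals) {
  needed <- c("name", "group", "length_m", "diameter_mm", "n_points", "from", "to")
  if (!all(needed %in% names(segments)))
    stop("segments must have columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(segments$name))
    stop("duplicated segment names")
  if (!all(segments$group %in% c("cerebral", "systemic")))
    stop("segment group must be 'cerebral' or 'systemic'")
  if (any(segments$length_m <= 0)) stop("segment lengths must be positive")
  nodes <- unique(c(segments$from, segments$to))
  if (!inlet_node %in% nodes) stop("inlet_node not found among segment nodes")
  if (!all(terminals$node %in% nodes))
    stop("terminal node(s) not found among segment nodes")
  if (!all(terminals$feeding_segment %in% segments$name))
    stop("terminal feeding_segment(s) not found among segments")
  structure(list(segments = segments, nodes = nodes,
                 inlet_node = inlet_node, terminals = terminals),
            class = "cow_topology")
}

#' @export
print.cow_topology <- function(x, ...) {
  cat(sprintf("Arterial topology: %d segments (%d cerebral, %d systemic), %d nodes, %d WK3 terminals\n",
              nrow(x$segments), sum(x$segments$group == "cerebral"),
              sum(x$segments$group == "systemic"), length(x$nodes),
              nrow(x$terminals)))
  cat("inlet:", x$inlet_node, "\n")
  invisible(x)
}

#' Read or write a topology as versioned JSON
#'
#' The JSON schema lists the segments (`id`, `name`, `group`,
#' `default_length_m`, `default_diameter_mm`, `n_points`, `proximal_node`,
#' `distal_node`), the `inlet_node` and the `terminal_nodes`. A copy of the
#' frozen 33-segment topology ships in `inst/extdata/cow33_topology.json`.
#'
#' @param topology A `cow_topology` object.
#' @param path File path.
#' @return `read_topology_json` returns a `cow_topology`;
#'   `write_topology_json` returns `path` invisibly.
#' @export
write_topology_json <- function(topology, path) {
  seg <- topology$segments
  obj <- list(
    schema = "cowflow/topology/v1",
    segments = data.frame(
      id = seq_len(nrow(seg)), name = seg$name, group = seg$group,
      default_length_m = seg$length_m, default_diameter_mm = seg$diameter_mm,
      n_points = seg$n_points,
      proximal_node = seg$from, distal_node = seg$to,
      stringsAsFactors = FALSE),
    inlet_node = topology$inlet_node,
    terminal_nodes = topology$terminals
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "cowflow/topology/v1"))
    stop("unrecognized topology schema: ", obj$schema)
  seg <- obj$segments
  segments <- data.frame(name = seg$name, group = seg$group,
                         length_m = seg$default_length_m,
                         diameter_mm = seg$default_diameter_mm,
                         n_points = seg$n_points,
                         from = seg$proximal_node, to = seg$distal_node,
                         stringsAsFactors = FALSE)
  make_topology(segments, obj$inlet_node, as.data.frame(obj$terminal_nodes))
}
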