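#' The nine standard TCD insonation sites
#'
#' Bilateral distal cervical internal carotid artery, bilateral proximal
#' middle cerebral artery, bilateral anterior cerebral artery, the basilar
#' artery and the bilateral posterior cerebral artery.
#'
#' @return Character vector of the nine site identifiers.
#' @export
tcd_sites <- function() {
  c("L_ICA", "R_ICA", "L_MCA", "R_MCA", "L_ACA", "R_ACA",
    "BA", "L_PCA", "R_PCA")
}

#' Map TCD insonation sites to model segments
#'
#' The ACA site maps to the pre-communicating A1 segment by default
#' (proximal insonation); the TCD report does not distinguish A1 from A2,
#' which is a known source of disagreement, so the mapping is configurable.
#' The ICA site maps to the distal ICA element and the PCA site to the
#' pre-communicating P1 segment.
#'
#' @param topology A `cow_topology`.
#' @param overrides Optional named character vector of site -> segment
#'   overrides (e.g. `c(L_ACA = "L_A2")`).
#' @return Named character vector mapping all nine sites to segment names.
#' @export
#' @examples
#' site_segment_map(cow_topology())
site_segment_map <- function(topology, overrides = NULL) {
  map <- c(L_ICA = "L_ICA_distal", R_ICA = "R_ICA_distal",
           L_MCA = "L_M1", R_MCA = "R_M1",
           L_ACA = "L_A1", R_ACA = "R_A1",
           BA = "BA",
           L_PCA = "L_P1", R_PCA = "R_P1")
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(map))
    if (length(bad)) stop("unknown TCD site(s): ", paste(bad, collapse = ", "))
    map[names(overrides)] <- overrides
  }
  missing_seg <- setdiff(map, topology$segments$name)
  if (length(missing_seg))
    stop("mapped segment(s) not in topology: ", paste(missing_seg, collapse = ", "))
  map
}

#' Simulated TCD velocity at one insonation site
#'
#' Converts the insonated segment's flow waveform over the final cycle to a
#' cross-section-average velocity `v = Q / A` with `A = pi d_eff^2 / 4`, and
#' reports the mean, systolic (max) and diastolic (min) values in cm/s.
#'
#' @param result A converged `cow_sim`.
#' @param site One of [tcd_sites()].
#' @param network The `cow_network` that was simulated.
#' @param map Site-to-segment map from [site_segment_map()].
#' @return A one-row data.frame (`site`, `segment`, `v_mean_cm_s`,
#'   `v_sys_cm_s`, `v_dia_cm_s`, `source = "simulated"`), or `NULL` with a
#'   warning when the mapped segment is absent from the patient's network.
#' @export
extract_velocity <- function(result, site, network,
                             map = site_segment_map(cow_topology())) {
  if (!site %in% names(map)) stop("unknown TCD site: ", site)
  segname <- map[[site]]
  idx <- match(segname, network$segments$name)
  if (is.na(idx)) {
    warning("site ", site, " omitted: segment ", segname, " absent")
    return(NULL)
  }
  a <- network$segments$area[idx]
  st <- cycle_statistics(result, segname)
  data.frame(site = site, segment = segname,
             v_mean_cm_s = mps_to_cmps(st$mean / a),
             v_sys_cm_s = mps_to_cmps(st$systolic / a),
             v_dia_cm_s = mps_to_cmps(st$diastolic / a),
             source = "simulated", stringsAsFactors = FALSE)
}

#' Simulated TCD report over all nine sites
#'
#' @inheritParams extract_velocity
#' @param sites Sites to report (default all nine).
#' @return A data.frame mirroring the measurement file schema with
#'   `source = "simulated"`; absent-segment sites are omitted.
#' @export
simulate_tcd_report <- function(result, network,
                                map = site_segment_map(cow_topology()),
                                sites = tcd_sites()) {
  rows <- lapply(sites, function(s)
    suppressWarnings(extract_velocity(result, s, network, map)))
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
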