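#' Read TCD measurement and vitals files
#'
#' Measurement schema: `investigation_id`, `site`, `v_mean_cm_s` and
#' optionally `v_sys_cm_s`, `v_dia_cm_s`. Vitals schema:
#' `investigation_id`, `sbp_mmHg`, `dbp_mmHg`, `hr_bpm`.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("investigation_id", "site", "v_mean_cm_s")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("measurement CSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$v_mean_cm_s) | df$v_mean_cm_s <= 0)
  if (length(bad))
    stop("measurement CSV: non-positive mean velocity at row ", bad[1])
  df
}

#' @rdname read_measurements_csv
#' @note The vitals file may carry an optional `map_mmHg` column (e.g. from
#'   invasive monitoring); when absent, the mean pressure defaults to
#'   `DBP + (SBP - DBP)/3`.
#' @export
read_vitals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("investigation_id", "sbp_mmHg", "dbp_mmHg", "hr_bpm")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("vitals CSV missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$sbp_mmHg <= df$dbp_mmHg))
    stop("vitals CSV: SBP must exceed DBP")
  df
}

#' Assemble calibration inputs from measurement + vitals tables
#'
#' @param measurements,vitals Data frames as read by
#'   [read_measurements_csv()] / [read_vitals_csv()].
#' @param investigation_id Which investigation to extract.
#' @return A [calibration_input()].
#' @export
calibration_input_from_files <- function(measurements, vitals, investigation_id) {
  m <- measurements[measurements$investigation_id == investigation_id, , drop = FALSE]
  v <- vitals[vitals$investigation_id == investigation_id, , drop = FALSE]
  if (nrow(m) == 0L) stop("no measurements for ", investigation_id)
  if (nrow(v) != 1L) stop("need exactly one vitals row for ", investigation_id)
  calibration_input(v$sbp_mmHg, v$dbp_mmHg, m, heart_period = 60 / v$hr_bpm,
                    map_mmHg = if ("map_mmHg" %in% names(v)) v$map_mmHg else NULL)
}

#' Write simulation results as tidy CSV and a summary JSON
#'
#' The tidy CSV holds `(time_s, variable, value)` rows for every segment
#' flow and node pressure; the summary JSON holds per-segment
#' mean/systolic/diastolic flow (ml/s) and velocity (cm/s) over the final
#' cycle.
#'
#' @param result A `cow_sim`.
#' @param network The simulated `cow_network`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary list.
#' @export
write_simulation_output <- function(result, network, csv_path = NULL,
                                    json_path = NULL) {
  if (!is.null(csv_path)) {
    wide <- cbind(result$flows, result$node_pressures)
    tidy <- data.frame(
      time_s = rep(result$time, ncol(wide)),
      variable = rep(colnames(wide), each = length(result$time)),
      value = as.vector(wide))
    utils::write.csv(tidy, csv_path, row.names = FALSE, quote = FALSE)
  }
  summary <- lapply(result$segment_names, function(s) {
    st <- cycle_statistics(result, s)
    a <- network$segments$area[match(s, network$segments$name)]
    list(segment = s,
         q_mean_ml_s = m3_to_ml(st$mean), q_sys_ml_s = m3_to_ml(st$systolic),
         q_dia_ml_s = m3_to_ml(st$diastolic),
         v_mean_cm_s = mps_to_cmps(st$mean / a))
  })
  names(summary) <- result$segment_names
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Write a paired velocity table / simulated TCD report CSV
#'
#' @param table A [paired_velocity_table()] or simulated TCD report.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_paired_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (JSON or YAML)
#'
#' Recognized sections: `inflow` (`period_s`, `stroke_volume_ml`,
#' `systolic_fraction`), `wk3` (`proximal_fraction`, `venous_pressure_mmHg`),
#' `solver` (`n_cycles`, `samples_per_cycle`, `periodicity_tol`), and
#' `calibration` overrides; unknown keys are rejected.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A [calib_config()] with the overrides applied.
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("inflow", "wk3", "solver", "calibration")
  bad <- setdiff(names(obj), known)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  cfg <- calib_config()
  if (!is.null(obj$inflow$stroke_volume_ml))
    cfg$stroke_volume <- ml_to_m3(obj$inflow$stroke_volume_ml)
  if (!is.null(obj$inflow$systolic_fraction))
    cfg$systolic_fraction <- obj$inflow$systolic_fraction
  if (!is.null(obj$wk3$proximal_fraction))
    cfg$proximal_fraction <- obj$wk3$proximal_fraction
  if (!is.null(obj$wk3$venous_pressure_mmHg))
    cfg$venous_pressure <- mmHg_to_Pa(obj$wk3$venous_pressure_mmHg)
  if (!is.null(obj$solver)) {
    sim_args <- obj$solver[intersect(names(obj$solver),
                                     c("n_cycles", "samples_per_cycle",
                                       "periodicity_tol", "method"))]
    cfg$sim <- do.call(sim_config, sim_args)
  }
  for (nm in names(obj$calibration)) {
    if (!nm %in% names(cfg)) stop("unknown calibration key: ", nm)
    cfg[[nm]] <- obj$calibration[[nm]]
  }
  cfg
}
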