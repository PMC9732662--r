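#' Specification of a virtual aSAH cohort
#'
#' Describes the population the generator emulates: anatomical variants of
#' the circle of Willis (drawn by zeroing the variant segment's diameters),
#' vasospastic narrowing of cerebral segments, the blood-pressure and
#' heart-rate distributions of an aneurysmal subarachnoid hemorrhage
#' population, the scatter of peripheral resistances across territories,
#' and the measurement-noise model (multiplicative lognormal on TCD
#' velocities, additive truncated-Gaussian on diameters).
#'
#' @param n_patients Number of virtual investigations.
#' @param seed Single integer seeding all randomness of the cohort.
#' @param variant_probabilities Named per-variant absence probabilities.
#' @param vasospasm List: `probability` (per patient), `max_segments`,
#'   `reduction_range` (fractional diameter reduction).
#' @param bp List: `sbp_mean`, `sbp_sd`, `dbp_mean`, `dbp_sd` (mmHg).
#' @param hr List: `mean`, `sd` (beats/min).
#' @param noise List: `velocity_sd` (lognormal sigma on velocities),
#'   `diameter_sd_mm` (Gaussian sd on point diameters, truncated at 0).
#' @param cerebral_flow_fraction Fraction of cardiac output perfusing the
#'   instrumented cerebral territories before perturbation.
#' @param resistance_scatter Lognormal sigma of the per-territory flow
#'   perturbation (the scatter of optimal peripheral resistance).
#' @param e_multiplier_sd Lognormal sigma of the true stiffness/compliance
#'   multipliers.
#' @param diameter_jitter_sd Lognormal sigma of between-patient diameter
#'   variation.
#' @param dci_threshold Resistance-deviation score above which a patient is
#'   given the DCI-like label.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20L, seed = 1L,
                        variant_probabilities = c(ACoA = 0.10,
                                                  L_PComA = 0.25, R_PComA = 0.25,
                                                  L_A1 = 0.10, R_A1 = 0.10,
                                                  L_P1 = 0.15, R_P1 = 0.15),
                        vasospasm = list(probability = 0.5, max_segments = 3L,
                                         reduction_range = c(0.2, 0.5)),
                        bp = list(sbp_mean = 145, sbp_sd = 15,
                                  dbp_mean = 80, dbp_sd = 10),
                        hr = list(mean = 75, sd = 10),
                        noise = list(velocity_sd = 0.10, diameter_sd_mm = 0.10),
                        cerebral_flow_fraction = 0.13,
                        resistance_scatter = 0.25,
                        e_multiplier_sd = 0.15,
                        diameter_jitter_sd = 0.05,
                        dci_threshold = 1.25) {
  if (any(variant_probabilities < 0 | variant_probabilities > 1))
    stop("variant probabilities must be in [0, 1]")
  if (any(vasospasm$reduction_range <= 0 | vasospasm$reduction_range >= 1))
    stop("vasospasm reductions must be in (0, 1)")
  if (noise$velocity_sd < 0 || noise$diameter_sd_mm < 0)
    stop("noise sds must be >= 0")
  if (cerebral_flow_fraction <= 0 || cerebral_flow_fraction >= 1)
    stop("cerebral_flow_fraction must be in (0, 1)")
  structure(as.list(environment()), class = "cohort_spec")
}

# deterministic per-(seed, index) substream; keeps values < 2^31
patient_seed <- function(seed, index)
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 7919) %% 2147483647)

with_patient_rng <- function(seed, index, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(patient_seed(seed, index))
  expr
}

# one draw of anatomical variants + vasospasm applied to the reference
# geometry; kept separate so variant frequencies can be property-tested
# without running the forward model
draw_geometry <- function(spec, topology) {
  seg <- topology$segments
  pts <- lapply(seq_len(nrow(seg)), function(i) {
    jitter <- exp(stats::rnorm(1, 0, spec$diameter_jitter_sd))
    rep(seg$diameter_mm[i] * jitter, seg$n_points[i])
  })
  names(pts) <- seg$name
  absent <- names(spec$variant_probabilities)[
    stats::runif(length(spec$variant_probabilities)) < spec$variant_probabilities]
  for (nm in absent) pts[[nm]] <- rep(0, length(pts[[nm]]))
  spastic <- character(0)
  if (stats::runif(1) < spec$vasospasm$probability) {
    candidates <- setdiff(seg$name[seg$group == "cerebral"], absent)
    k <- sample.int(spec$vasospasm$max_segments, 1)
    spastic <- sample(candidates, min(k, length(candidates)))
    for (nm in spastic) {
      r <- stats::runif(1, spec$vasospasm$reduction_range[1],
                        spec$vasospasm$reduction_range[2])
      pts[[nm]] <- pts[[nm]] * (1 - r)
    }
  }
  list(point_diameters = pts, absent = absent, spastic = spastic)
}

#' Generate one virtual aSAH patient
#'
#' Deterministic given `(spec$seed, index)`. The patient consists of a true
#' geometry (anatomical variants drawn by zeroing diameters, vasospastic
#' narrowing), true hemodynamic parameters (WK3 terminals whose cerebral
#' flows deviate lognormally from the area-proportional allocation, plus
#' true stiffness/compliance multipliers), true site velocities and blood
#' pressure obtained by forward simulation, and noisy observations
#' (geometry and TCD report) in the same schemas the calibration consumes.
#' A variant draw that disconnects a terminal is rejected and redrawn.
#'
#' @param spec A [cohort_spec()].
#' @param index Patient index within the cohort (1-based).
#' @param max_retries Redraw budget for non-perfusable variant combinations.
#' @return An object of class `virtual_patient`: `geometry` (true),
#'   `geometry_observed`, `truth` (network, terminals, multipliers, site
#'   velocities, SBP/DBP), `observations` (`tcd`, `vitals`), `labels`.
#' @export
generate_patient <- function(spec, index, max_retries = 20L) {
  topology <- cow_topology()
  with_patient_rng(spec$seed, index, {
    cfg <- calib_config()
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      cand <- draw_geometry(spec, topology)
      hr_bpm <- max(40, stats::rnorm(1, spec$hr$mean, spec$hr$sd))
      geom <- patient_geometry(sprintf("virt%03d", index),
                               cand$point_diameters,
                               heart_period = 60 / hr_bpm)
      net <- tryCatch(build_patient_network(topology, geom, blood_properties()),
                      error = function(e) NULL)
      if (!is.null(net)) { geom_draw <- cand; ok <- TRUE; break }
    }
    if (!ok)
      stop("could not draw a perfusable anatomy in ", max_retries, " attempts")

    sbp <- stats::rnorm(1, spec$bp$sbp_mean, spec$bp$sbp_sd)
    dbp <- stats::rnorm(1, spec$bp$dbp_mean, spec$bp$dbp_sd)
    # project the drawn pulse pressure onto the range the lumped network can
    # represent within the wall-multiplier bounds (analogous to redrawing
    # non-perfusable anatomies); the SBP distribution -- the stratification
    # covariate -- is preserved and DBP absorbs the projection
    dbp <- min(max(dbp, sbp - 55), sbp - 30)
    map_pa <- mmHg_to_Pa(dbp + (sbp - dbp) / 3)
    waveform <- inflow_waveform(geom$heart_period, cfg$stroke_volume,
                                cfg$systolic_fraction)
    q_in <- mean_inflow(waveform)

    # true terminal flows: instrumented cerebral territories get a share of
    # the cerebral fraction, perturbed lognormally (the scatter of optimal
    # peripheral resistance); the remainder is split area-proportionally
    ids <- net$terminals$terminal_id
    map <- site_segment_map(topology)
    present_sites <- names(map)[map %in% net$segments$name]
    instr_terms <- unname(site_terminal_map[intersect(names(site_terminal_map),
                                                      present_sites)])
    instr_terms <- intersect(instr_terms, ids)
    eps <- stats::setNames(exp(stats::rnorm(length(instr_terms), 0,
                                            spec$resistance_scatter)),
                           instr_terms)
    base_split <- area_proportional_split(net, 1, instr_terms)
    q_instr <- spec$cerebral_flow_fraction * q_in * base_split * eps
    rest <- setdiff(ids, instr_terms)
    q_rest <- area_proportional_split(net, q_in - sum(q_instr), rest)
    q_truth <- c(q_instr, q_rest)[ids]

    terminals <- fit_terminals_to_flows(net, q_truth, map_pa, cfg)

    # a perturbation draw that reverses the net flow of an insonated segment
    # (collateral steal) is outside the class the TCD observation model can
    # encode (velocities are reported as positive antegrade flow): redraw
    # the territory perturbation, like a non-perfusable anatomy
    for (try in seq_len(max_retries)) {
      dc <- dc_solve(net, terminals, q_in)
      seg_ok <- map[intersect(names(site_terminal_map), present_sites)]
      if (all(dc$segment_flow[seg_ok] > 0)) break
      eps <- stats::setNames(exp(stats::rnorm(length(instr_terms), 0,
                                              spec$resistance_scatter)),
                             instr_terms)
      q_instr <- spec$cerebral_flow_fraction * q_in * base_split * eps
      q_rest <- area_proportional_split(net, q_in - sum(q_instr), rest)
      q_truth <- c(q_instr, q_rest)[ids]
      terminals <- fit_terminals_to_flows(net, q_truth, map_pa, cfg)
    }

    # fit the systemic wall multipliers so the simulated waveform reproduces
    # the drawn cuff pressures, then perturb: the cohort inherits the
    # specified blood-pressure distribution while the true multipliers stay
    # random relative to the calibration's default starting point
    input0 <- structure(list(sbp = mmHg_to_Pa(sbp), dbp = mmHg_to_Pa(dbp),
                             map = map_pa,
                             tcd = data.frame(site = character(0),
                                              v_mean = numeric(0),
                                              v_sys = numeric(0),
                                              v_dia = numeric(0)),
                             heart_period = geom$heart_period),
                        class = "calibration_input")
    fit0 <- joint_refine(net, terminals, input0, cfg, c(1, 1),
                         with_gamma = FALSE, tol = 1e-3, max_iter = 20L)
    clamp <- function(x) min(max(x, 0.12), 8)
    alpha <- clamp(fit0$multipliers[[1]] *
                     exp(stats::rnorm(1, 0, spec$e_multiplier_sd)))
    beta <- clamp(fit0$multipliers[[2]] *
                    exp(stats::rnorm(1, 0, spec$e_multiplier_sd)))
    gamma <- exp(stats::rnorm(1, 0, spec$e_multiplier_sd))
    net_true <- scale_youngs_modulus(net, "systemic", alpha)
    net_true <- scale_youngs_modulus(net_true, "cerebral", gamma)
    sys_ids <- setdiff(ids, cerebral_terminals(net))
    terminals$C[terminals$terminal_id %in% sys_ids] <-
      terminals$C[terminals$terminal_id %in% sys_ids] * beta

    sim <- run_simulation(net_true, terminals, waveform, cfg$sim)
    ps <- cycle_pressure_statistics(sim, net_true$inlet_node)
    report <- simulate_tcd_report(sim, net_true, map)
    # TCD detectability floor: a segment carrying no net flow (e.g. a
    # basilar stub when both P1 segments are absent) yields no usable
    # Doppler signal and is omitted from the report
    report <- report[report$v_mean_cm_s > 1, , drop = FALSE]

    # observations: multiplicative lognormal velocity noise, additive
    # truncated-Gaussian diameter noise (absent segments stay 0)
    vfac <- exp(stats::rnorm(nrow(report), 0, spec$noise$velocity_sd))
    tcd_obs <- data.frame(site = report$site,
                          v_mean_cm_s = report$v_mean_cm_s * vfac,
                          v_sys_cm_s = report$v_sys_cm_s * vfac,
                          v_dia_cm_s = report$v_dia_cm_s * vfac,
                          stringsAsFactors = FALSE)
    pts_obs <- lapply(geom$point_diameters_mm, function(d) {
      if (all(d == 0)) return(d)
      pmax(d + stats::rnorm(length(d), 0, spec$noise$diameter_sd_mm), 0.2)
    })
    geom_obs <- patient_geometry(geom$investigation_id, pts_obs,
                                 heart_period = geom$heart_period)

    # DCI-like label: territories whose resistance deviates most from the
    # Hagen-Poiseuille-consistent (area-proportional) allocation
    dev_score <- mean(abs(log(eps)))
    expected_dev <- spec$resistance_scatter * sqrt(2 / pi)
    dci <- dev_score > spec$dci_threshold * expected_dev
    fisher <- sample(1:4, 1, prob = c(0.03, 0.06, 0.455, 0.455))
    aneurysm <- sample(c("anterior", "posterior"), 1, prob = c(0.72, 0.28))

    structure(list(
      investigation_id = geom$investigation_id, index = index,
      geometry = geom, geometry_observed = geom_obs,
      truth = list(network = net_true, terminals = terminals,
                   terminal_flows = q_truth,
                   drawn_sbp_mmHg = sbp, drawn_dbp_mmHg = dbp,
                   stiffness_multiplier = alpha,
                   compliance_multiplier = beta,
                   cerebral_multiplier = gamma,
                   velocities = report,
                   sbp_mmHg = Pa_to_mmHg(ps$systolic),
                   dbp_mmHg = Pa_to_mmHg(ps$diastolic),
                   heart_period = geom$heart_period),
      observations = list(
        tcd = tcd_obs,
        vitals = data.frame(investigation_id = geom$investigation_id,
                            sbp_mmHg = Pa_to_mmHg(ps$systolic),
                            dbp_mmHg = Pa_to_mmHg(ps$diastolic),
                            map_mmHg = Pa_to_mmHg(ps$mean),
                            hr_bpm = 60 / geom$heart_period,
                            stringsAsFactors = FALSE)),
      labels = list(dci = dci, fisher = fisher,
                    fisher_group = if (fisher >= 3) "3-4" else "1-2",
                    sbp_group = if (Pa_to_mmHg(ps$systolic) > 140) ">140" else "<=140",
                    aneurysm_location = aneurysm,
                    absent = geom_draw$absent, spastic = geom_draw$spastic)),
      class = "virtual_patient")
  })
}

# DC fixed point setting each terminal's total resistance so its mean flow
# equals the requested target (used to realize the truth parameters)
fit_terminals_to_flows <- function(network, q_target, map_pa, cfg,
                                   tol = 1e-10, max_iter = 100L) {
  terminals <- initialize_terminals(network, map_pa, q_target,
                                    venous_pressure = cfg$venous_pressure,
                                    proximal_fraction = cfg$proximal_fraction,
                                    tau = cfg$tau,
                                    tau_cerebral = cfg$tau_cerebral)
  q_in <- sum(q_target)
  ids <- terminals$terminal_id
  tau_i <- ifelse(ids %in% cerebral_terminals(network), cfg$tau_cerebral,
                  cfg$tau)
  nodes_of <- network$terminals$node[match(ids, network$terminals$terminal_id)]
  for (it in seq_len(max_iter)) {
    dc <- dc_solve(network, terminals, q_in)
    r_new <- (dc$node_pressure[nodes_of] - cfg$venous_pressure) / q_target[ids]
    # anchor the aortic-root mean pressure to the requested MAP (flow
    # targets alone leave the pressure level undetermined)
    r_new <- r_new * (map_pa - cfg$venous_pressure) /
      (dc$node_pressure[[network$inlet_node]] - cfg$venous_pressure)
    delta <- max(abs(r_new - terminals$total_resistance) /
                 terminals$total_resistance)
    R_d <- (1 - cfg$proximal_fraction) * r_new
    terminals <- wk3_set(ids, cfg$proximal_fraction * r_new, R_d,
                         C = tau_i / R_d, P_ven = cfg$venous_pressure)
    if (delta < tol) break
  }
  terminals
}

#' Generate a virtual cohort and optionally write its files
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; when given, writes `geometry.csv`,
#'   `measurements.csv`, `vitals.csv` and `manifest.json` in the schemas the
#'   calibration/validation commands consume.
#' @return A list of class `virtual_cohort`: `patients`, `spec`, `manifest`
#'   (seed and spec hash).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  patients <- lapply(seq_len(spec$n_patients),
                     function(i) generate_patient(spec, i))
  tmp <- tempfile()
  saveRDS(spec[order(names(spec))], tmp)
  manifest <- list(seed = spec$seed, n_patients = spec$n_patients,
                   spec_hash = unname(tools::md5sum(tmp)))
  unlink(tmp)
  cohort <- structure(list(patients = patients, spec = spec,
                           manifest = manifest),
                      class = "virtual_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_geometry_csv(lapply(patients, function(p) p$geometry_observed),
                       file.path(out_dir, "geometry.csv"))
    meas <- do.call(rbind, lapply(patients, function(p)
      cbind(investigation_id = p$investigation_id, p$observations$tcd)))
    utils::write.csv(meas, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE, quote = FALSE)
    vit <- do.call(rbind, lapply(patients, function(p) p$observations$vitals))
    utils::write.csv(vit, file.path(out_dir, "vitals.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  cohort
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat(sprintf("Virtual aSAH cohort: %d patients (seed %d, velocity noise %.0f%%)\n",
              length(x$patients), x$spec$seed,
              100 * x$spec$noise$velocity_sd))
  invisible(x)
}

#' End-to-end synthetic validation
#'
#' The synthetic twin of the clinical validation design: every patient is
#' calibrated from its noisy observations, simulated, and the simulated
#' site velocities are paired against the noisy "TCD" values; the pooled
#' table feeds the consistency ICC and the log Bland-Altman limits.
#' Per-patient calibration failures are logged and excluded.
#'
#' @param cohort A `virtual_cohort` (or a [cohort_spec()], which is
#'   generated first).
#' @param config A [calib_config()].
#' @return A list of class `end_to_end_result`: `icc` (`icc_result`), `loa`
#'   (`log_loa`), `table` ([paired_velocity_table()]), `n_failed`,
#'   `failures`.
#' @export
end_to_end_agreement <- function(cohort, config = calib_config()) {
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  if (length(cohort$patients) == 0L) stop("empty cohort")
  topology <- cow_topology()
  rows <- list()
  failures <- character(0)
  for (p in cohort$patients) {
    res <- tryCatch({
      net <- build_patient_network(topology, p$geometry_observed,
                                   blood_properties())
      inp <- calibration_input(p$observations$vitals$sbp_mmHg,
                               p$observations$vitals$dbp_mmHg,
                               p$observations$tcd,
                               heart_period = p$truth$heart_period,
                               map_mmHg = p$observations$vitals$map_mmHg)
      cal <- suppressWarnings(calibrate(net, inp, config))
      sim <- tentative_sim(cal$network, cal$terminals, inp, config)
      rep <- simulate_tcd_report(sim, cal$network,
                                 site_segment_map(topology, config$map_overrides))
      idx <- match(rep$site, p$observations$tcd$site)
      data.frame(investigation_id = p$investigation_id, site = rep$site,
                 v_tcd = p$observations$tcd$v_mean_cm_s[idx],
                 v_sim = rep$v_mean_cm_s,
                 dci = p$labels$dci, sbp_group = p$labels$sbp_group,
                 fisher_group = p$labels$fisher_group,
                 aneurysm_location = p$labels$aneurysm_location,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, stats::setNames(res, p$investigation_id))
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("all calibrations failed")
  df <- do.call(rbind, rows)
  # rows with a non-positive paired velocity (a steal configuration under
  # heavy noise) cannot enter the log-scale agreement analysis
  ok <- is.finite(df$v_sim) & is.finite(df$v_tcd) & df$v_sim > 0 & df$v_tcd > 0
  n_dropped <- sum(!ok)
  if (n_dropped)
    warning(n_dropped, " paired row(s) dropped: non-positive velocity")
  df <- df[ok, , drop = FALSE]
  table <- paired_velocity_table(df$investigation_id, df$site, df$v_tcd,
                                 df$v_sim, dci = df$dci,
                                 sbp_group = df$sbp_group,
                                 fisher_group = df$fisher_group,
                                 aneurysm_location = df$aneurysm_location)
  structure(list(icc = icc_consistency(table), loa = log_bland_altman(table),
                 table = table, n_failed = length(failures),
                 n_rows_dropped = n_dropped, failures = failures),
            class = "end_to_end_result")
}

#' @export
print.end_to_end_result <- function(x, ...) {
  print(x$icc)
  print(x$loa)
  if (x$n_failed) cat(x$n_failed, "patient(s) excluded (calibration failure)\n")
  invisible(x)
}
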