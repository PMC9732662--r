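test_that("TCD velocity targets convert to mean-flow targets via the lumen area", {
  topo <- cow_topology()
  g <- reference_geometry(topo)
  g$point_diameters_mm$L_M1 <- rep(3, 3)  # exact 3 mm MCA
  net <- build_patient_network(topo, g, blood_properties())
  inp <- calibration_input(120, 80,
                           data.frame(site = "L_MCA", v_mean_cm_s = 60))
  flows <- velocities_to_flows(inp, net)
  expect_equal(flows$q_mean, 0.60 * pi * 0.0015^2, tolerance = 1e-12)
  expect_equal(m3_to_ml(flows$q_mean), 4.24, tolerance = 1e-3)
  # absent insonated segment: target skipped with a warning
  g$point_diameters_mm$L_A1 <- rep(0, 3)
  net2 <- build_patient_network(topo, g, blood_properties())
  inp2 <- calibration_input(120, 80,
                            data.frame(site = c("L_MCA", "L_ACA"),
                                       v_mean_cm_s = c(60, 50)))
  expect_warning(f2 <- velocities_to_flows(inp2, net2), "skipped")
  expect_equal(f2$site, "L_MCA")
})

test_that("calibration input validates pressures and defaults MAP to DBP + PP/3", {
  tcd <- data.frame(site = "L_MCA", v_mean_cm_s = 60)
  expect_error(calibration_input(80, 120, tcd), "SBP > DBP")
  expect_error(calibration_input(120, 80,
                                 data.frame(site = "L_MCA", v_mean_cm_s = -2)),
               "positive")
  inp <- calibration_input(120, 80, tcd)
  expect_equal(Pa_to_mmHg(inp$map), 80 + 40 / 3, tolerance = 1e-12)
  inp2 <- calibration_input(120, 80, tcd, map_mmHg = 95)
  expect_equal(Pa_to_mmHg(inp2$map), 95)
})

test_that("step 1 reproduces a forward-model terminal set (fixed point)", {
  rs <- reference_setup()
  cfg <- calib_config()
  # forward model: a DC-consistent terminal set (area-proportional flows at
  # an anchored root pressure) -> observed velocities and MAP
  q_in <- mean_inflow(rs$waveform)
  truth <- cowflow:::fit_terminals_to_flows(
    rs$network, area_proportional_split(rs$network, q_in),
    mmHg_to_Pa(100), cfg)
  rs$terminals <- truth
  dc <- dc_solve(rs$network, rs$terminals, q_in)
  map <- site_segment_map(rs$topology)
  v <- vapply(tcd_sites(), function(s) {
    seg <- map[[s]]
    a <- rs$network$segments$area[match(seg, rs$network$segments$name)]
    mps_to_cmps(dc$segment_flow[[seg]] / a)
  }, numeric(1))
  root_mmHg <- Pa_to_mmHg(dc$node_pressure[[rs$network$inlet_node]])
  inp <- calibration_input(root_mmHg + 20, root_mmHg - 12,
                           data.frame(site = names(v), v_mean_cm_s = v),
                           map_mmHg = root_mmHg)
  s1 <- step1_peripheral_resistance(rs$network, inp, cfg)
  expect_true(s1$converged)
  expect_equal(s1$terminals$total_resistance, rs$terminals$total_resistance,
               tolerance = 1e-8)
  expect_lt(max(abs(s1$residuals)), 1e-8)
  # total inflow preserved across terminals
  dc2 <- dc_solve(rs$network, s1$terminals, q_in)
  expect_equal(sum(dc2$terminal_flow), q_in, tolerance = 1e-10)
})

test_that("step 1 on a single branch recovers the closed-form resistance", {
  net <- toy_network(
    data.frame(name = "L_M1", from = "in", to = "out", length_mm = 10,
               d_mm = 3, group = "cerebral"),
    inlet = "in",
    terminals = data.frame(terminal_id = "T1", node = "out",
                           feeding_segment = "L_M1"))
  truth <- wk3_set("T1", 2e8, 1.8e9, 1e-9, P_ven = mmHg_to_Pa(5))
  cfg <- calib_config(stroke_volume = 70e-6)
  q_in <- 70e-6 / 0.8
  dc <- dc_solve(net, truth, q_in)
  a <- net$segments$area
  v <- mps_to_cmps(dc$segment_flow[["L_M1"]] / a)
  root <- Pa_to_mmHg(dc$node_pressure[["in"]])
  inp <- calibration_input(root + 20, root - 12,
                           data.frame(site = "L_MCA", v_mean_cm_s = v),
                           map_mmHg = root)
  # single terminal carries the whole inflow at the anchored root pressure:
  # closed form R_tot = (P_root - P_ven)/Q - R_segment
  s1 <- step1_peripheral_resistance(net, inp, cfg)
  r_expect <- (mmHg_to_Pa(root) - cfg$venous_pressure) / q_in - net$segments$R
  expect_equal(s1$terminals$total_resistance, r_expect, tolerance = 1e-6)
  expect_equal(s1$terminals$total_resistance, truth$total_resistance,
               tolerance = 1e-6)
})

test_that("step 2 is a fixed point at the model's own pressures and is monotone", {
  rs <- reference_setup()
  cfg <- calib_config()
  sim <- run_simulation(rs$network, rs$terminals, rs$waveform, cfg$sim)
  ps <- cycle_pressure_statistics(sim, rs$network$inlet_node)
  tcd <- data.frame(site = "L_MCA", v_mean_cm_s = 60)
  inp <- calibration_input(Pa_to_mmHg(ps$systolic), Pa_to_mmHg(ps$diastolic),
                           tcd, map_mmHg = Pa_to_mmHg(ps$mean))
  s2 <- step2_systemic_compliance(rs$network, rs$terminals, inp, cfg)
  expect_true(s2$converged)
  expect_equal(s2$stiffness_multiplier, 1, tolerance = 0.02)
  expect_equal(s2$compliance_multiplier, 1, tolerance = 0.02)
  # softening the systemic walls (lower stiffness multiplier, higher segment
  # compliance) lowers the pulse pressure -- the lever the step-2 fit uses
  pp <- vapply(c(0.5, 1, 2), function(mult) {
    net <- cowflow:::scale_youngs_modulus(rs$network, "systemic", mult)
    s <- run_simulation(net, rs$terminals, rs$waveform, cfg$sim)
    st <- cycle_pressure_statistics(s, rs$network$inlet_node)
    st$systolic - st$diastolic
  }, numeric(1))
  expect_true(pp[1] < pp[2] && pp[2] < pp[3])
})

test_that("steps 2-3 recover known wall multipliers from forward targets", {
  rs <- reference_setup()
  cfg <- calib_config()
  sys_ids <- setdiff(rs$terminals$terminal_id,
                     cowflow:::cerebral_terminals(rs$network))
  # --- step 2 truth: stiffness 0.7, compliance 1.4, cerebral untouched
  net_t <- cowflow:::scale_youngs_modulus(rs$network, "systemic", 0.7)
  term_t <- rs$terminals
  sel <- term_t$terminal_id %in% sys_ids
  term_t$C[sel] <- term_t$C[sel] * 1.4
  sim_t <- run_simulation(net_t, term_t, rs$waveform, cfg$sim)
  ps <- cycle_pressure_statistics(sim_t, rs$network$inlet_node)
  tcd <- data.frame(site = "L_MCA", v_mean_cm_s = 60)
  inp <- calibration_input(Pa_to_mmHg(ps$systolic), Pa_to_mmHg(ps$diastolic),
                           tcd, map_mmHg = Pa_to_mmHg(ps$mean))
  s2 <- step2_systemic_compliance(rs$network, rs$terminals, inp, cfg)
  expect_equal(s2$stiffness_multiplier, 0.7, tolerance = 0.05)
  expect_equal(s2$compliance_multiplier, 1.4, tolerance = 0.05)
  # --- step 3 truth: an extra cerebral stiffening of 1.5 applied to a
  # physiologically calibrated virtual patient (diastolic flows positive)
  p <- noise_free_patients(n = 3L, seed = 42L)[[1]]
  base_net <- p$truth$network
  base_term <- p$truth$terminals
  net3_t <- cowflow:::scale_youngs_modulus(base_net, "cerebral", 1.5)
  w3 <- inflow_waveform(p$truth$heart_period, cfg$stroke_volume,
                        cfg$systolic_fraction)
  sim3 <- run_simulation(net3_t, base_term, w3, cfg$sim)
  rep3 <- simulate_tcd_report(sim3, net3_t, site_segment_map(rs$topology))
  inp3 <- calibration_input(p$observations$vitals$sbp_mmHg,
                            p$observations$vitals$dbp_mmHg, rep3,
                            heart_period = p$truth$heart_period,
                            map_mmHg = p$observations$vitals$map_mmHg)
  s3 <- step3_cerebral_compliance(base_net, base_term, inp3, cfg)
  expect_false(s3$skipped)
  expect_equal(s3$cerebral_multiplier, 1.5, tolerance = 0.10)
})

test_that("cerebral wall stiffness monotonically shifts flow pulsatility", {
  # direction check for the step-3 search: with fixed WK3 outlets, a stiffer
  # cerebral wall shunts less pulsatile flow through the segment, lowering
  # the systolic-to-diastolic flow ratio at the insonated site
  rs <- reference_setup()
  cfg <- calib_config()
  ratio <- vapply(c(0.5, 1, 2), function(g) {
    net <- cowflow:::scale_youngs_modulus(rs$network, "cerebral", g)
    sim <- run_simulation(net, rs$terminals, rs$waveform, cfg$sim)
    st <- cycle_statistics(sim, "L_M1")
    st$systolic / st$diastolic
  }, numeric(1))
  expect_true(ratio[1] > ratio[2] && ratio[2] > ratio[3])
})

test_that("full calibration recovers a virtual patient and is deterministic", {
  p <- noise_free_patients(n = 3L, seed = 42L)[[2]]
  cal <- calibrate_patient(p)
  expect_true(cal$converged)
  cmp <- merge(p$truth$terminals[, c("terminal_id", "total_resistance")],
               cal$terminals[, c("terminal_id", "total_resistance")],
               by = "terminal_id")
  expect_lt(max(abs(cmp$total_resistance.y / cmp$total_resistance.x - 1)), 0.02)
  expect_lt(max(abs(cal$residuals$rel_error)), 0.01)
  expect_equal(cal$stiffness_multiplier, p$truth$stiffness_multiplier,
               tolerance = 0.05)
  expect_equal(cal$compliance_multiplier, p$truth$compliance_multiplier,
               tolerance = 0.05)
  expect_equal(cal$cerebral_multiplier, p$truth$cerebral_multiplier,
               tolerance = 0.10)
  cal2 <- calibrate_patient(p)
  expect_identical(cal$terminals, cal2$terminals)
  expect_identical(cal$cerebral_multiplier, cal2$cerebral_multiplier)
})

test_that("calibrating a model against its own output is a no-op", {
  p <- noise_free_patients(n = 3L, seed = 42L)[[1]]
  cal <- calibrate_patient(p)
  cfg <- calib_config()
  inp <- calibration_input(p$observations$vitals$sbp_mmHg,
                           p$observations$vitals$dbp_mmHg,
                           p$observations$tcd,
                           heart_period = p$truth$heart_period,
                           map_mmHg = p$observations$vitals$map_mmHg)
  sim <- cowflow:::tentative_sim(cal$network, cal$terminals, inp, cfg)
  rep <- simulate_tcd_report(sim, cal$network)
  ps <- cycle_pressure_statistics(sim, cal$network$inlet_node)
  inp2 <- calibration_input(Pa_to_mmHg(ps$systolic), Pa_to_mmHg(ps$diastolic),
                            rep, heart_period = p$truth$heart_period,
                            map_mmHg = Pa_to_mmHg(ps$mean))
  net0 <- build_patient_network(cow_topology(), p$geometry_observed,
                                blood_properties())
  cal2 <- suppressWarnings(calibrate(net0, inp2, cfg))
  expect_equal(cal2$terminals$total_resistance, cal$terminals$total_resistance,
               tolerance = 1e-3)
})

test_that("missing systolic/diastolic velocities degrade gracefully to steps 1-2", {
  p <- noise_free_patients(n = 3L, seed = 42L)[[3]]
  tcd <- p$observations$tcd[, c("site", "v_mean_cm_s")]
  net <- build_patient_network(cow_topology(), p$geometry_observed,
                               blood_properties())
  inp <- calibration_input(p$observations$vitals$sbp_mmHg,
                           p$observations$vitals$dbp_mmHg, tcd,
                           heart_period = p$truth$heart_period,
                           map_mmHg = p$observations$vitals$map_mmHg)
  expect_warning(cal <- calibrate(net, inp), "step 3 skipped")
  expect_true(is.na(cal$cerebral_multiplier))
  expect_true(cal$steps$step3$skipped)
  # steps 1-2 still deliver their targets
  expect_lt(max(abs(cal$residuals$rel_error)), 0.01)
})
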