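test_that("DC solve matches the independent branch-variable oracle on toy networks", {
  q_in <- 1e-5
  pv <- mmHg_to_Pa(5)
  nets <- list(
    single_branch_network(),
    y_network(c(3, 3)),
    y_network(c(2, 4.5)),
    # 7-node asymmetric chain with side branches
    toy_network(data.frame(
      name = c("a", "b", "c", "d", "e", "f"),
      from = c("n1", "n2", "n2", "n3", "n4", "n4"),
      to = c("n2", "n3", "n6", "n4", "n5", "n7"),
      length_mm = c(30, 25, 18, 22, 14, 9),
      d_mm = c(6, 4, 3, 3.5, 2.5, 2)),
      inlet = "n1",
      terminals = data.frame(terminal_id = c("T5", "T6", "T7"),
                             node = c("n5", "n6", "n7"),
                             feeding_segment = c("e", "c", "f"))),
    # ring with two outlets (collateral loop, like a communicating artery)
    toy_network(data.frame(
      name = c("in1", "top", "bot", "o1", "o2"),
      from = c("s", "p", "p", "q", "p"),
      to = c("p", "q", "q", "r", "u"),
      length_mm = c(20, 15, 25, 10, 12),
      d_mm = c(5, 3, 2, 2.5, 2.2)),
      inlet = "s",
      terminals = data.frame(terminal_id = c("Tr", "Tu"), node = c("r", "u"),
                             feeding_segment = c("o1", "o2")))
  )
  for (net in nets) {
    n_term <- nrow(net$terminals)
    term <- wk3_set(net$terminals$terminal_id,
                    R_p = 1e8 * seq_len(n_term),
                    R_d = 9e8 * rev(seq_len(n_term)),
                    C = rep(1e-9, n_term), P_ven = pv)
    dc <- dc_solve(net, term, q_in)
    oracle <- dc_oracle(net, term, q_in)
    expect_equal(dc$node_pressure, oracle$node_pressure[names(dc$node_pressure)],
                 tolerance = 1e-10)
    expect_equal(dc$segment_flow, oracle$segment_flow[names(dc$segment_flow)],
                 tolerance = 1e-10)
    expect_equal(dc$terminal_flow, oracle$terminal_flow[names(dc$terminal_flow)],
                 tolerance = 1e-10)
    expect_lt(dc$kcl_residual, 1e-10)
  }
})

test_that("DC solve: series circuit, symmetric split, reorder invariance, KCL", {
  # single branch: Q = dP / (R_seg + R_p + R_d)
  net <- single_branch_network()
  term <- wk3_set("T1", 1e8, 9e8, 1e-9, P_ven = 0)
  dc <- dc_solve(net, term, 1e-5)
  r_seg <- net$segments$R
  expect_equal(unname(dc$node_pressure["in"]), 1e-5 * (r_seg + 1e9),
               tolerance = 1e-12)
  # symmetric Y: equal daughters carry equal flow
  nety <- y_network(c(3, 3))
  termy <- wk3_set(c("Ta", "Tb"), 1e8, 9e8, 1e-9, P_ven = 0)
  dcy <- dc_solve(nety, termy, 1e-5)
  expect_equal(unname(dcy$segment_flow["d1"]), unname(dcy$segment_flow["d2"]),
               tolerance = 1e-12)
  # full network KCL and invariance to segment-row reordering
  rs <- reference_setup()
  dc1 <- dc_solve(rs$network, rs$terminals, 8.75e-5)
  expect_lt(dc1$kcl_residual, 1e-10)
  net_perm <- rs$network
  set.seed(3)
  perm <- sample(nrow(net_perm$segments))
  net_perm$segments <- net_perm$segments[perm, ]
  net_perm$nodes <- sample(net_perm$nodes)
  dc2 <- dc_solve(net_perm, rs$terminals, 8.75e-5)
  expect_equal(dc2$node_pressure[names(dc1$node_pressure)], dc1$node_pressure,
               tolerance = 1e-10)
})

test_that("assembled ODE system has the DC solution as its constant-inflow fixed point", {
  rs <- reference_setup()
  ode <- assemble_odes(rs$network, rs$terminals, rs$waveform)
  q_bar <- mean_inflow(rs$waveform)
  x0 <- ode$x0(q_bar)
  rhs <- as.vector(ode$A %*% x0 + ode$b0 + q_bar * ode$w)
  dyn <- seq_len(length(x0) - 2L)  # volume accumulators integrate freely
  expect_lt(max(abs(rhs[dyn])) / max(abs(x0)), 1e-9)
})

test_that("constant inflow converges to the DC solution on every segment", {
  rs <- reference_setup()
  q_bar <- mean_inflow(rs$waveform)
  w_const <- inflow_waveform(0.8, fn = function(t) rep(q_bar, length(t)))
  sim <- run_simulation(rs$network, rs$terminals, w_const,
                        sim_config(n_cycles = 4))
  expect_true(sim$converged)
  expect_lte(sim$cycles_to_converge, 2L)
  dc <- dc_solve(rs$network, rs$terminals, q_bar)
  last <- sim$flows[nrow(sim$flows), ]
  expect_equal(unname(last), unname(dc$segment_flow[sub("^Q_", "", names(last))]),
               tolerance = 1e-3)
})

test_that("a sinusoidally driven WK3 terminal matches the closed-form response", {
  # nearly ideal feed: negligible segment impedance and wall compliance
  net <- toy_network(
    data.frame(name = "feed", from = "in", to = "out", length_mm = 1,
               d_mm = 20),
    inlet = "in",
    terminals = data.frame(terminal_id = "T1", node = "out",
                           feeding_segment = "feed"),
    wall_relaxation_time = 0)
  net$segments$C <- net$segments$C * 0.1  # stiff feed: negligible wall shunt
  rp <- 1e7; rd <- 1e9; cw <- 1.5e-9
  term <- wk3_set("T1", rp, rd, cw, P_ven = 0)
  T <- 0.8; om <- 2 * pi / T
  q0 <- 1e-5; qa <- 4e-6
  w <- inflow_waveform(T, fn = function(t) q0 + qa * sin(om * t))
  sim <- run_simulation(net, term, w, sim_config(n_cycles = 30,
                                                 periodicity_tol = 1e-7,
                                                 samples_per_cycle = 400))
  expect_true(sim$converged)
  rows <- (nrow(sim$node_pressures) - 400):nrow(sim$node_pressures)
  p <- sim$node_pressures[rows, "P_out"]
  tt <- sim$time[rows]
  fit <- stats::lm(p ~ sin(om * tt) + cos(om * tt))
  amp_sim <- sqrt(sum(stats::coef(fit)[2:3]^2))
  phase_sim <- unname(atan2(stats::coef(fit)[3], stats::coef(fit)[2]))
  # closed-form one-pole WK3 response
  z1 <- wk3_impedance(list(R_p = rp, R_d = rd, C = cw), om)
  expect_equal(amp_sim, qa * Mod(z1), tolerance = 5e-3)
  expect_equal(phase_sim, Arg(z1), tolerance = 5e-3)
  # exact two-node phasor oracle including the parasitic feed elements
  seg <- net$segments
  zs <- seg$R + 1i * om * seg$L
  c1 <- seg$C / 2; c2 <- seg$C / 2
  A2 <- matrix(c(1i * om * c1 + 1 / zs, -1 / zs,
                 -1 / zs, 1i * om * c2 + 1 / zs + 1 / z1),
               2, 2, byrow = TRUE)
  p_hat <- solve(A2, c(qa, 0))
  expect_equal(amp_sim, Mod(p_hat[2]), tolerance = 5e-4)
  expect_equal(phase_sim, Arg(p_hat[2]), tolerance = 5e-4)
})

test_that("expm and lsoda integration routes agree", {
  nety <- y_network(c(3, 2.5))
  term <- wk3_set(c("Ta", "Tb"), c(1e8, 2e8), c(9e8, 1.2e9), c(1.5e-9, 1e-9),
                  P_ven = mmHg_to_Pa(5))
  w <- inflow_waveform(0.8, stroke_volume = 8e-6)
  s1 <- run_simulation(nety, term, w, sim_config(n_cycles = 3))
  s2 <- run_simulation(nety, term, w, sim_config(n_cycles = 3, method = "lsoda",
                                                 rtol = 1e-10, atol = 1e-14))
  expect_lt(max(abs(s1$flows - s2$flows)) / max(abs(s2$flows)), 1e-4)
  expect_lt(max(abs(s1$node_pressures - s2$node_pressures)) /
              max(abs(s2$node_pressures)), 1e-4)
})

test_that("the network is dissipative and the periodicity residual decays", {
  rs <- reference_setup()
  ode <- assemble_odes(rs$network, rs$terminals, rs$waveform)
  dyn <- seq_len(length(ode$b0) - 2L)
  ev <- eigen(ode$A[dyn, dyn], only.values = TRUE)$values
  expect_true(all(Re(ev) < 0))
  sim <- run_simulation(rs$network, rs$terminals, rs$waveform,
                        sim_config(n_cycles = 10, periodicity_tol = 1e-9))
  res <- sim$cycle_residuals
  expect_true(all(diff(res[-1]) <= 0))  # non-increasing after cycle 2
})

test_that("halving the output step leaves last-cycle mean flows essentially unchanged", {
  rs <- reference_setup()
  s1 <- run_simulation(rs$network, rs$terminals, rs$waveform,
                       sim_config(samples_per_cycle = 200, init = "periodic",
                                  n_cycles = 3))
  s2 <- run_simulation(rs$network, rs$terminals, rs$waveform,
                       sim_config(samples_per_cycle = 400, init = "periodic",
                                  n_cycles = 3))
  m1 <- vapply(s1$segment_names, function(s) cycle_statistics(s1, s)$mean,
               numeric(1))
  m2 <- vapply(s2$segment_names, function(s) cycle_statistics(s2, s)$mean,
               numeric(1))
  expect_lt(max(abs(m1 - m2) / abs(m2)), 1e-3)
})

test_that("cycle statistics equal quadrature oracles", {
  rs <- reference_setup()
  sim <- run_simulation(rs$network, rs$terminals, rs$waveform,
                        sim_config(init = "periodic", n_cycles = 3))
  st <- cycle_statistics(sim, "ascending_aorta")
  # the root segment carries the full stroke volume: mean = SV / T
  expect_equal(st$mean, 70e-6 / 0.8, tolerance = 2e-3)
  # direct Simpson oracle on the stored samples
  rows <- (nrow(sim$flows) - 200):nrow(sim$flows)
  q <- sim$flows[rows, "Q_L_M1"]
  h <- sim$dt
  simpson <- h / 3 * (q[1] + q[201] + 4 * sum(q[seq(2, 200, 2)]) +
                        2 * sum(q[seq(3, 199, 2)])) / 0.8
  expect_equal(cycle_statistics(sim, "L_M1")$mean, simpson, tolerance = 1e-12)
  expect_equal(cycle_statistics(sim, "L_M1")$systolic, max(q))
  expect_error(cycle_statistics(sim, "nope"), "unknown segment")
  expect_warning(
    cycle_statistics(run_simulation(rs$network, rs$terminals, rs$waveform,
                                    sim_config(n_cycles = 2)), "L_M1"),
    "unconverged")
})

test_that("volume is conserved over the final cycle", {
  rs <- reference_setup()
  sim <- run_simulation(rs$network, rs$terminals, rs$waveform, sim_config())
  expect_lt(volume_conservation(sim), 1e-6)
})
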