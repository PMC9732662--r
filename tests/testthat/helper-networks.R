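# Shared fixtures: small analytic networks and cached expensive objects.

# build a network from a compact segment table:
# data.frame(name, from, to, length_mm, d_mm, group)
toy_network <- function(seg_def, inlet, terminals,
                        blood = blood_properties(),
                        wall_relaxation_time = 0.005) {
  if (is.null(seg_def$group)) seg_def$group <- "systemic"
  segments <- data.frame(name = seg_def$name, group = seg_def$group,
                         length_m = seg_def$length_mm / 1000,
                         diameter_mm = seg_def$d_mm, n_points = 1L,
                         from = seg_def$from, to = seg_def$to,
                         stringsAsFactors = FALSE)
  topo <- make_topology(segments, inlet, terminals)
  pts <- as.list(seg_def$d_mm)
  names(pts) <- seg_def$name
  geom <- patient_geometry("toy", pts, heart_period = 0.8)
  build_patient_network(topo, geom, blood,
                        wall_relaxation_time = wall_relaxation_time)
}

# one segment from the inlet into a single WK3 terminal
single_branch_network <- function(d_mm = 3, length_mm = 10) {
  toy_network(
    data.frame(name = "seg", from = "in", to = "out",
               length_mm = length_mm, d_mm = d_mm),
    inlet = "in",
    terminals = data.frame(terminal_id = "T1", node = "out",
                           feeding_segment = "seg"))
}

# symmetric Y bifurcation: parent into two identical daughters
y_network <- function(d_daughter_mm = c(3, 3)) {
  toy_network(
    data.frame(name = c("parent", "d1", "d2"),
               from = c("in", "j", "j"), to = c("j", "a", "b"),
               length_mm = c(20, 15, 15),
               d_mm = c(5, d_daughter_mm)),
    inlet = "in",
    terminals = data.frame(terminal_id = c("Ta", "Tb"), node = c("a", "b"),
                           feeding_segment = c("d1", "d2")))
}

# independent DC oracle: full branch-variable formulation (unknowns = node
# pressures + segment flows + terminal flows; equations = Ohm per branch,
# series WK3 law per terminal, KCL per node). A different assembly route
# from the nodal conductance solve inside the package.
dc_oracle <- function(network, terminals, q_in) {
  seg <- network$segments
  nodes <- network$nodes
  term <- merge(network$terminals, terminals, by = "terminal_id", sort = FALSE)
  nn <- length(nodes); m <- nrow(seg); nt <- nrow(term)
  N <- nn + m + nt
  A <- matrix(0, N, N)
  b <- numeric(N)
  ip <- function(nd) match(nd, nodes)
  # Ohm's law rows per segment: P_from - P_to - R q = 0
  for (s in seq_len(m)) {
    A[s, ip(seg$from[s])] <- 1
    A[s, ip(seg$to[s])] <- -1
    A[s, nn + s] <- -seg$R[s]
  }
  # WK3 series law per terminal: P_node - (Rp + Rd) qt = P_ven
  for (k in seq_len(nt)) {
    A[m + k, ip(term$node[k])] <- 1
    A[m + k, nn + m + k] <- -(term$R_p[k] + term$R_d[k])
    b[m + k] <- term$P_ven[k]
  }
  # KCL per node
  for (j in seq_len(nn)) {
    r <- m + nt + j
    for (s in seq_len(m)) {
      if (seg$from[s] == nodes[j]) A[r, nn + s] <- A[r, nn + s] - 1
      if (seg$to[s] == nodes[j]) A[r, nn + s] <- A[r, nn + s] + 1
    }
    for (k in seq_len(nt))
      if (term$node[k] == nodes[j]) A[r, nn + m + k] <- A[r, nn + m + k] - 1
    if (nodes[j] == network$inlet_node) b[r] <- -q_in
  }
  # row/column equilibration: pressures (Pa) and flows (m^3/s) differ by
  # ~12 orders of magnitude, so scale flows to keep the solve well posed
  fscale <- 1e-9
  A[, nn + seq_len(m + nt)] <- A[, nn + seq_len(m + nt)] * fscale
  rs <- apply(abs(A), 1, max)
  x <- solve(A / rs, b / rs)
  x[nn + seq_len(m + nt)] <- x[nn + seq_len(m + nt)] * fscale
  list(node_pressure = stats::setNames(x[seq_len(nn)], nodes),
       segment_flow = stats::setNames(x[nn + seq_len(m)], seg$name),
       terminal_flow = stats::setNames(x[nn + m + seq_len(nt)],
                                       term$terminal_id))
}

# reference patient (complete circle of Willis, default diameters) with
# area-proportional WK3 seeding -- the default synthetic patient
reference_setup <- function(heart_period = 0.8, map_mmHg = 100) {
  topo <- cow_topology()
  net <- build_patient_network(topo, reference_geometry(topo,
                                                        heart_period = heart_period),
                               blood_properties())
  w <- inflow_waveform(heart_period)
  term <- initialize_terminals(net, mmHg_to_Pa(map_mmHg),
                               area_proportional_split(net, mean_inflow(w)))
  list(topology = topo, network = net, waveform = w, terminals = term)
}

# cached noise-free recovery cohort shared by calibration and acceptance tests
.fixture_cache <- new.env(parent = emptyenv())
noise_free_patients <- function(n = 20L, seed = 42L) {
  key <- sprintf("nf_%d_%d", n, seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- cohort_spec(n_patients = n, seed = seed,
                      noise = list(velocity_sd = 0, diameter_sd_mm = 0))
  out <- lapply(seq_len(n), function(i) generate_patient(spec, i))
  .fixture_cache[[key]] <- out
  out
}

calibrate_patient <- function(p, config = calib_config()) {
  topo <- cow_topology()
  net <- build_patient_network(topo, p$geometry_observed, blood_properties())
  inp <- calibration_input(p$observations$vitals$sbp_mmHg,
                           p$observations$vitals$dbp_mmHg,
                           p$observations$tcd,
                           heart_period = p$truth$heart_period,
                           map_mmHg = p$observations$vitals$map_mmHg)
  suppressWarnings(calibrate(net, inp, config))
}
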