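#' Simulation configuration
#'
#' @param n_cycles Maximum number of cardiac cycles to integrate (default 10,
#'   the run length at which the network reaches its steady periodic state).
#' @param samples_per_cycle Output samples per cycle.
#' @param periodicity_tol Relative L2 difference between consecutive cycles
#'   below which the run is declared periodic (applied separately to the
#'   pressure and flow blocks; the larger of the two must pass).
#' @param method `"expm"` (exact matrix-exponential stepping of the linear
#'   network, the default) or `"lsoda"` (stiff adaptive integration via
#'   deSolve, kept as an independent cross-check route).
#' @param init `"dc"` starts from the mean-flow (DC) solution and lets the
#'   pulsatile transient decay over the cycles; `"periodic"` (expm only)
#'   solves the one-cycle return map for the exact periodic state, so cycle
#'   averages coincide with the DC solution to discretization accuracy --
#'   used by the calibration loops where unbiased cycle means matter.
#' @param rtol,atol Tolerances passed to lsoda when `method = "lsoda"`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cycles = 10L, samples_per_cycle = 200L,
                       periodicity_tol = 0.01,
                       method = c("expm", "lsoda"),
                       init = c("dc", "periodic"),
                       rtol = 1e-8, atol = 1e-12) {
  method <- match.arg(method)
  init <- match.arg(init)
  if (init == "periodic" && method != "expm")
    stop("periodic initialization requires method = 'expm'")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (samples_per_cycle < 8) stop("samples_per_cycle must be >= 8")
  if (periodicity_tol <= 0) stop("periodicity_tol must be > 0")
  structure(list(n_cycles = as.integer(n_cycles),
                 samples_per_cycle = as.integer(samples_per_cycle),
                 periodicity_tol = periodicity_tol, method = method,
                 init = init, rtol = rtol, atol = atol),
            class = "sim_config")
}

#' Mean-flow (DC) solution of the resistive network
#'
#' Solves the nodal conductance system with inertances shorted and
#' compliances open: each segment contributes its Hagen-Poiseuille
#' conductance, each WK3 outlet its series conductance `1/(R_p + R_d)` to
#' venous pressure, and the prescribed mean inflow enters the inlet node as
#' a current source. This is the linear electric circuit model used by
#' calibration step 1.
#'
#' @param network A `cow_network`.
#' @param terminals A [wk3_set()] covering the network's terminals.
#' @param mean_inflow Mean inflow (m^3/s) at the inlet node.
#' @return A list of class `dc_solution`: `node_pressure` (Pa, named),
#'   `segment_flow` (m^3/s, named, positive from `from` to `to`),
#'   `terminal_flow` (m^3/s, named), `kcl_residual` (max nodal current
#'   imbalance relative to the inflow).
#' @export
dc_solve <- function(network, terminals, mean_inflow) {
  seg <- network$segments
  nodes <- network$nodes
  nn <- length(nodes)
  ni <- match(seg$from, nodes)
  nj <- match(seg$to, nodes)
  G <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
  g <- 1 / seg$R
  for (s in seq_len(nrow(seg))) {
    i <- ni[s]; j <- nj[s]
    G[i, i] <- G[i, i] + g[s]
    G[j, j] <- G[j, j] + g[s]
    G[i, j] <- G[i, j] - g[s]
    G[j, i] <- G[j, i] - g[s]
  }
  rhs <- numeric(nn)
  term <- merge(network$terminals, terminals, by = "terminal_id", sort = FALSE)
  ti <- match(term$node, nodes)
  gt <- 1 / (term$R_p + term$R_d)
  for (k in seq_len(nrow(term))) {
    G[ti[k], ti[k]] <- G[ti[k], ti[k]] + gt[k]
    rhs[ti[k]] <- rhs[ti[k]] + gt[k] * term$P_ven[k]
  }
  rhs[match(network$inlet_node, nodes)] <-
    rhs[match(network$inlet_node, nodes)] + mean_inflow
  p <- tryCatch(solve(G, rhs),
                error = function(e) stop("singular nodal system (isolated subnetwork): ",
                                         conditionMessage(e)))
  names(p) <- nodes
  qseg <- (p[ni] - p[nj]) / seg$R
  names(qseg) <- seg$name
  qterm <- gt * (p[ti] - term$P_ven)
  names(qterm) <- term$terminal_id
  # KCL check: net current at each node (inflow + segments - terminal outflow)
  net <- numeric(nn)
  for (s in seq_len(nrow(seg))) {
    net[ni[s]] <- net[ni[s]] - qseg[s]
    net[nj[s]] <- net[nj[s]] + qseg[s]
  }
  net[ti] <- net[ti] - qterm
  net[match(network$inlet_node, nodes)] <-
    net[match(network$inlet_node, nodes)] + mean_inflow
  structure(list(node_pressure = p, segment_flow = qseg,
                 terminal_flow = qterm,
                 kcl_residual = max(abs(net)) / abs(mean_inflow)),
            class = "dc_solution")
}

#' Assemble the network's governing equations
#'
#' State-space form of the lumped RLC network: one flow state per segment
#' (through its inertance), one pressure state per junction node (the
#' capacitor pressure of the node's share of the adjacent wall compliances,
#' half of each incident segment's C, behind the Voigt viscoelastic series
#' resistance), and one pressure state per WK3 compartment. Two auxiliary
#' states accumulate inflow and venous-outflow volume so conservation can be
#' audited exactly. The system is linear time-invariant, `dx/dt = A x +
#' b0 + q(t) w`, with the prescribed inflow `q(t)` the only time-varying
#' forcing.
#'
#' @inheritParams dc_solve
#' @param waveform An [inflow_waveform()].
#' @return A list of class `cow_ode` with the matrices `A`, `b0`, `w`, index
#'   maps, state names, node compliances, an `rhs(t, y)` function for
#'   deSolve, and `x0(mean_q)` producing the DC initial state.
#' @export
assemble_odes <- function(network, terminals, waveform) {
  seg <- network$segments
  nodes <- network$nodes
  m <- nrow(seg); nn <- length(nodes)
  term <- merge(network$terminals, terminals, by = "terminal_id", sort = FALSE)
  nt <- nrow(term)
  n <- m + nn + nt + 2L
  i_flow <- seq_len(m)
  i_node <- m + seq_len(nn)
  i_wk3 <- m + nn + seq_len(nt)
  i_vin <- n - 1L
  i_vout <- n
  state_names <- c(paste0("Q_", seg$name), paste0("P_", nodes),
                   paste0("Pc_", term$terminal_id), "V_in", "V_out")

  ni <- match(seg$from, nodes)
  nj <- match(seg$to, nodes)
  Cnode <- numeric(nn)
  for (s in seq_len(m)) {
    Cnode[ni[s]] <- Cnode[ni[s]] + seg$C[s] / 2
    Cnode[nj[s]] <- Cnode[nj[s]] + seg$C[s] / 2
  }
  names(Cnode) <- nodes
  tau_w <- if (is.null(network$wall_relaxation_time)) 0 else
    network$wall_relaxation_time
  Rv <- if (tau_w > 0) tau_w / Cnode else rep(0, nn)

  # incidence: S[n, s] = +1 when segment s flows into node n, -1 when out
  S <- matrix(0, nn, m)
  for (s in seq_len(m)) {
    S[nj[s], s] <- S[nj[s], s] + 1
    S[ni[s], s] <- S[ni[s], s] - 1
  }
  e_in <- as.numeric(nodes == network$inlet_node)
  ti <- match(term$node, nodes)

  # junction pressure P_node = alpha*y + beta*(S Q) + gamma*P_c + beta*e q(t)
  # (solving the series-resistance/WK3 proximal algebraic loop per node)
  alpha <- rep(1, nn); beta <- Rv; gam <- numeric(nn)
  denom <- rep(1, nn)
  denom[ti] <- 1 + Rv[ti] / term$R_p
  alpha <- alpha / denom
  beta <- beta / denom
  gam[ti] <- (Rv[ti] / term$R_p) / denom[ti]
  N_y <- diag(alpha, nn)
  N_Q <- beta * S          # nn x m  (row-scaled)
  N_c <- matrix(0, nn, nt)
  N_c[cbind(ti, seq_len(nt))] <- gam[ti]
  n_in <- beta * e_in      # coefficient of q(t) in P_node

  A <- matrix(0, n, n, dimnames = list(state_names, state_names))
  b0 <- numeric(n)
  w <- numeric(n)

  # dQ/dt = diag(1/L) (-t(S) P_node - R Q)
  Linv <- 1 / seg$L
  A[i_flow, i_node] <- -Linv * t(S) %*% N_y
  A[i_flow, i_flow] <- -Linv * t(S) %*% N_Q - diag(seg$R / seg$L, m)
  A[i_flow, i_wk3] <- -Linv * t(S) %*% N_c
  w[i_flow] <- -Linv * as.vector(t(S) %*% n_in)

  # terminal currents T = diag(1/Rp) (P_node[ti] - P_c)
  T_y <- (1 / term$R_p) * N_y[ti, , drop = FALSE]
  T_Q <- (1 / term$R_p) * N_Q[ti, , drop = FALSE]
  T_c <- (1 / term$R_p) * (N_c[ti, , drop = FALSE] - diag(nt))
  T_in <- (1 / term$R_p) * n_in[ti]

  # node capacitor: dy/dt = (S Q + e q - M T) / C_node
  M <- matrix(0, nn, nt)
  M[cbind(ti, seq_len(nt))] <- 1
  Cn_inv <- 1 / Cnode
  A[i_node, i_flow] <- Cn_inv * (S - M %*% T_Q)
  A[i_node, i_node] <- Cn_inv * (-M %*% T_y)
  A[i_node, i_wk3] <- Cn_inv * (-M %*% T_c)
  w[i_node] <- Cn_inv * (e_in - as.vector(M %*% T_in))

  # WK3 compartments: dP_c/dt = (T - (P_c - P_ven)/R_d) / C
  Cw_inv <- 1 / term$C
  A[i_wk3, i_flow] <- Cw_inv * T_Q
  A[i_wk3, i_node] <- Cw_inv * T_y
  A[i_wk3, i_wk3] <- Cw_inv * (T_c - diag(1 / term$R_d, nt))
  w[i_wk3] <- Cw_inv * T_in
  b0[i_wk3] <- term$P_ven / (term$R_d * term$C)

  # cumulative volumes
  w[i_vin] <- 1
  A[i_vout, i_wk3] <- 1 / term$R_d
  b0[i_vout] <- -sum(term$P_ven / term$R_d)

  x0 <- function(mean_q) {
    dc <- dc_solve(network, terminals, mean_q)
    x <- numeric(n)
    x[i_flow] <- dc$segment_flow
    x[i_node] <- dc$node_pressure
    x[i_wk3] <- dc$node_pressure[ti] - dc$terminal_flow * term$R_p
    names(x) <- state_names
    x
  }
  rhs <- function(t, y, parms = NULL)
    list(as.vector(A %*% y + b0 + aortic_inflow(waveform, t) * w))

  structure(list(A = A, b0 = b0, w = w,
                 idx = list(flow = i_flow, node = i_node, wk3 = i_wk3,
                            vin = i_vin, vout = i_vout),
                 state_names = state_names, node_compliance = Cnode,
                 wk3_compliance = stats::setNames(term$C, term$terminal_id),
                 segment_names = seg$name, node_names = nodes,
                 terminal_ids = term$terminal_id,
                 waveform = waveform, x0 = x0, rhs = rhs),
            class = "cow_ode")
}

#' Integrate the network to a steady periodic state
#'
#' Starts from the DC solution at the mean inflow and integrates cardiac
#' cycles until the relative L2 difference between consecutive cycles (for
#' both pressures and flows) drops below the periodicity tolerance, then
#' runs one confirming cycle; capped at `n_cycles`. The default integrator
#' advances the exact solution of the linear network over each output step
#' with the inflow interpolated piecewise-linearly.
#'
#' @inheritParams assemble_odes
#' @param config A [sim_config()].
#' @return An object of class `cow_sim`: `time`, matrices `flows`,
#'   `node_pressures`, `wk3_pressures`, `volumes` (cumulative inflow and
#'   venous outflow), `cycle_residuals`, `converged`, `cycles_to_converge`.
#' @export
run_simulation <- function(network, terminals, waveform, config = sim_config()) {
  ode <- assemble_odes(network, terminals, waveform)
  T <- waveform$heart_period
  spc <- config$samples_per_cycle
  dt <- T / spc
  n <- length(ode$b0)
  x <- ode$x0(mean_inflow(waveform))

  # inflow samples over one cycle (periodic): q_j at t = (j-1) dt,
  # renormalized so the piecewise-linear discretization delivers the exact
  # cycle-average inflow (preserves stroke volume under sampling)
  qcycle <- aortic_inflow(waveform, seq(0, T, by = dt))
  pwl_mean <- sum((qcycle[-1] + qcycle[-length(qcycle)]) / 2) * dt / T
  q_bar <- mean_inflow(waveform)
  if (pwl_mean > 0 && q_bar > 0) qcycle <- qcycle * q_bar / pwl_mean

  if (config$method == "expm") {
    M <- matrix(0, 3 * n, 3 * n)
    M[1:n, 1:n] <- ode$A * dt
    M[1:n, n + 1:n] <- diag(n) * dt
    M[n + 1:n, 2 * n + 1:n] <- diag(n) * dt
    Phi <- as.matrix(Matrix::expm(Matrix::Matrix(M)))
    F <- Phi[1:n, 1:n]
    G1 <- Phi[1:n, n + 1:n]
    G2 <- Phi[1:n, 2 * n + 1:n]
    g0 <- as.vector(G1 %*% ode$b0)
    w1 <- as.vector(G1 %*% ode$w)
    w2 <- as.vector(G2 %*% ode$w)
    step <- function(x, qk, qk1)
      as.vector(F %*% x) + g0 + qk * w1 + ((qk1 - qk) / dt) * w2
    if (identical(config$init, "periodic")) {
      # exact periodic state of the one-cycle return map x -> Fc x + d
      # (restricted to the dynamic states; the volume rows are integrators)
      z <- numeric(n)
      for (j in seq_len(spc)) z <- step(z, qcycle[j], qcycle[j + 1L])
      Fc <- diag(n)
      B <- F
      k <- spc
      while (k > 0) {  # binary exponentiation of the step matrix
        if (k %% 2 == 1) Fc <- B %*% Fc
        B <- B %*% B
        k <- k %/% 2
      }
      dyn0 <- seq_len(n - 2L)
      x <- numeric(n)
      x[dyn0] <- solve(diag(n - 2L) - Fc[dyn0, dyn0], z[dyn0])
      names(x) <- ode$state_names
    }
  }

  X <- matrix(NA_real_, config$n_cycles * spc + 1L, n,
              dimnames = list(NULL, ode$state_names))
  X[1L, ] <- x
  dyn <- c(ode$idx$flow, ode$idx$node, ode$idx$wk3)
  residuals <- numeric(0)
  converged <- FALSE
  cycles_to_converge <- NA_integer_
  cycles_run <- 0L
  for (k in seq_len(config$n_cycles)) {
    r0 <- (k - 1L) * spc + 1L
    if (config$method == "expm") {
      for (j in seq_len(spc)) {
        x <- step(x, qcycle[j], qcycle[j + 1L])
        X[r0 + j, ] <- x
      }
    } else {
      tt <- seq((k - 1L) * T, k * T, by = dt)
      sol <- deSolve::lsoda(y = x, times = tt, func = ode$rhs, parms = NULL,
                            rtol = config$rtol, atol = config$atol,
                            maxsteps = 50000L)
      X[r0 + seq_len(spc), ] <- sol[-1L, -1L, drop = FALSE]
      x <- X[r0 + spc, ]
    }
    if (any(!is.finite(x)))
      stop(sprintf("simulation diverged at t = %.4g s", k * T))
    cycles_run <- k
    if (k >= 2L) {
      prev <- X[(r0 - spc):(r0 - 1L) + 1L, , drop = FALSE]
      cur <- X[r0:(r0 + spc - 1L) + 1L, , drop = FALSE]
      res_blk <- function(cols) {
        den <- sqrt(sum(prev[, cols]^2))
        if (den == 0) return(0)
        sqrt(sum((cur[, cols] - prev[, cols])^2)) / den
      }
      r <- max(res_blk(c(ode$idx$node, ode$idx$wk3)), res_blk(ode$idx$flow))
      residuals <- c(residuals, r)
      if (!converged && r < config$periodicity_tol) {
        converged <- TRUE
        cycles_to_converge <- k
      } else if (converged && k >= cycles_to_converge + 1L) {
        break  # one confirming cycle after convergence
      }
    }
  }
  keep <- seq_len(cycles_run * spc + 1L)
  structure(list(
    time = (keep - 1L) * dt,
    flows = X[keep, ode$idx$flow, drop = FALSE],
    node_pressures = X[keep, ode$idx$node, drop = FALSE],
    wk3_pressures = X[keep, ode$idx$wk3, drop = FALSE],
    volumes = X[keep, c(ode$idx$vin, ode$idx$vout), drop = FALSE],
    cycle_residuals = residuals, converged = converged,
    cycles_to_converge = cycles_to_converge, cycles_run = cycles_run,
    samples_per_cycle = spc, dt = dt, waveform = waveform,
    node_compliance = ode$node_compliance,
    wk3_compliance = ode$wk3_compliance,
    segment_names = ode$segment_names, node_names = ode$node_names,
    terminal_ids = ode$terminal_ids, config = config),
    class = "cow_sim")
}

#' @export
print.cow_sim <- function(x, ...) {
  cat(sprintf("Simulation: %d cycles run, %s (periodicity residual %.2e)\n",
              x$cycles_run,
              if (x$converged) sprintf("periodic after %d cycles", x$cycles_to_converge)
              else "NOT converged",
              if (length(x$cycle_residuals)) utils::tail(x$cycle_residuals, 1) else NA))
  invisible(x)
}

# indices (rows) of the final full cycle, endpoints included
last_cycle_rows <- function(result) {
  nrow_tot <- length(result$time)
  (nrow_tot - result$samples_per_cycle):nrow_tot
}

trapz_mean <- function(t, y) {
  # time average: composite Simpson on the uniform grid (even interval
  # count), trapezoid otherwise. The periodic cycle mean must match the DC
  # solution closely, so quadrature bias matters here.
  n <- length(t)
  if (n %% 2 == 1L && max(abs(diff(diff(t)))) < 1e-12 * (t[n] - t[1])) {
    h <- (t[n] - t[1]) / (n - 1L)
    wgt <- rep(c(4, 2), length.out = n - 2L)
    return(h / 3 * (y[1] + y[n] + sum(wgt * y[2:(n - 1L)])) / (t[n] - t[1]))
  }
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / (t[n] - t[1])
}

#' Flow statistics over the final cycle
#'
#' @param result A `cow_sim`.
#' @param segment Segment name.
#' @return A list `mean` (time average), `systolic` (max), `diastolic` (min)
#'   of the segment flow (m^3/s) over the last simulated cycle.
#' @export
cycle_statistics <- function(result, segment) {
  if (!segment %in% result$segment_names)
    stop("unknown segment: ", segment)
  if (!isTRUE(result$converged))
    warning("cycle statistics on an unconverged simulation")
  rows <- last_cycle_rows(result)
  q <- result$flows[rows, paste0("Q_", segment)]
  t <- result$time[rows]
  list(mean = trapz_mean(t, q), systolic = max(q), diastolic = min(q))
}

#' Pressure statistics over the final cycle
#'
#' @param result A `cow_sim`.
#' @param node Node name (e.g. the inlet node for aortic-root pressure).
#' @return A list `mean`, `systolic`, `diastolic` in Pa.
#' @export
cycle_pressure_statistics <- function(result, node) {
  if (!node %in% result$node_names) stop("unknown node: ", node)
  rows <- last_cycle_rows(result)
  p <- result$node_pressures[rows, paste0("P_", node)]
  t <- result$time[rows]
  list(mean = trapz_mean(t, p), systolic = max(p), diastolic = min(p))
}

#' Volume conservation audit over the final cycle
#'
#' Inflow volume minus venous outflow volume must equal the net change of
#' compliant storage (node compliances plus WK3 compartments) over the
#' cycle.
#'
#' @param result A `cow_sim`.
#' @return Relative residual `|V_in - V_out - dStorage| / V_in`.
#' @export
volume_conservation <- function(result) {
  rows <- last_cycle_rows(result)
  a <- rows[1]; b <- rows[length(rows)]
  v_in <- result$volumes[b, 1] - result$volumes[a, 1]
  v_out <- result$volumes[b, 2] - result$volumes[a, 2]
  d_store <- sum(result$node_compliance *
                 (result$node_pressures[b, ] - result$node_pressures[a, ])) +
    sum(result$wk3_compliance *
        (result$wk3_pressures[b, ] - result$wk3_pressures[a, ]))
  abs(v_in - v_out - d_store) / abs(v_in)
}
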