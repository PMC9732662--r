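#' Prescribed aortic inflow waveform
#'
#' A pluggable flow-rate waveform applied at the root of the ascending
#' aorta. The default template is a half-sine systolic ejection followed by
#' zero diastolic flow, parameterized by cardiac period, stroke volume and
#' systolic fraction; its one-period integral equals the stroke volume.
#'
#' @param heart_period Cardiac period T (s).
#' @param stroke_volume Stroke volume (m^3); default 70 ml.
#' @param systolic_fraction Fraction of the period occupied by ejection.
#' @param fn Optional custom waveform `function(t)` (m^3/s) overriding the
#'   template; it must itself be T-periodic.
#' @return An object of class `inflow_waveform`.
#' @export
#' @examples
#' w <- inflow_waveform(0.8)
#' integrate(function(t) aortic_inflow(w, t), 0, 0.8)$value  # ~7e-5 m^3
inflow_waveform <- function(heart_period = 0.8, stroke_volume = 70e-6,
                            systolic_fraction = 0.35, fn = NULL) {
  if (heart_period <= 0) stop("heart_period must be > 0")
  if (is.null(fn)) {
    if (stroke_volume <= 0) stop("stroke_volume must be > 0")
    if (systolic_fraction <= 0 || systolic_fraction >= 1)
      stop("systolic_fraction must be in (0, 1)")
  }
  structure(list(heart_period = heart_period, stroke_volume = stroke_volume,
                 systolic_fraction = systolic_fraction, fn = fn),
            class = "inflow_waveform")
}

#' Evaluate the aortic inflow at time t
#'
#' @param waveform An [inflow_waveform()].
#' @param t Time(s) in seconds, >= 0; vectorized.
#' @return Flow rate(s) in m^3/s (non-negative for the default template).
#' @export
aortic_inflow <- function(waveform, t) {
  if (any(t < 0)) stop("t must be >= 0")
  if (!is.null(waveform$fn)) return(waveform$fn(t))
  T <- waveform$heart_period
  Ts <- waveform$systolic_fraction * T
  Qpeak <- pi * waveform$stroke_volume / (2 * Ts)
  tau <- t %% T
  ifelse(tau < Ts, Qpeak * sin(pi * tau / Ts), 0)
}

#' Cycle-average inflow of a waveform
#'
#' @param waveform An [inflow_waveform()].
#' @return Mean flow over one cardiac cycle (m^3/s); `stroke_volume /
#'   heart_period` for the default template, numeric quadrature for custom
#'   waveforms.
#' @export
mean_inflow <- function(waveform) {
  if (is.null(waveform$fn))
    return(waveform$stroke_volume / waveform$heart_period)
  stats::integrate(function(t) aortic_inflow(waveform, t), 0,
                   waveform$heart_period, subdivisions = 500L)$value /
    waveform$heart_period
}

#' Three-element Windkessel outlet set
#'
#' One WK3 outlet per terminal branch: proximal resistance `R_p` in series
#' with the parallel combination of distal resistance `R_d` and compliance
#' `C`, referenced to venous pressure.
#'
#' @param terminal_id Character vector of terminal identifiers.
#' @param R_p,R_d Proximal and distal resistances (Pa s/m^3), >= 0.
#' @param C Compliance (m^3/Pa), > 0.
#' @param P_ven Venous reference pressure (Pa).
#' @return A data.frame of class `wk3_set` with a `total_resistance` column.
#' @export
wk3_set <- function(terminal_id, R_p, R_d, C, P_ven) {
  if (any(R_p < 0) || any(R_d < 0)) stop("WK3 resistances must be >= 0")
  if (any(C <= 0)) stop("WK3 compliance must be > 0")
  df <- data.frame(terminal_id = terminal_id, R_p = R_p, R_d = R_d, C = C,
                   P_ven = P_ven, stringsAsFactors = FALSE)
  df$total_resistance <- df$R_p + df$R_d
  class(df) <- c("wk3_set", "data.frame")
  df
}

#' WK3 input impedance
#'
#' `Z(omega) = R_p + R_d / (1 + i omega R_d C)`: total resistance at DC,
#' proximal resistance in the high-frequency limit (the property that avoids
#' artificial wave reflection at the outlets).
#'
#' @param terminal One row of a [wk3_set()] (or any list with `R_p`, `R_d`, `C`).
#' @param angular_frequency Angular frequency (rad/s), >= 0; vectorized.
#' @return Complex impedance (Pa s/m^3).
#' @export
wk3_impedance <- function(terminal, angular_frequency) {
  if (any(angular_frequency < 0)) stop("angular_frequency must be >= 0")
  terminal$R_p + terminal$R_d / (1 + 1i * angular_frequency * terminal$R_d * terminal$C)
}

#' Area-proportional terminal flow split
#'
#' The conventional initialization: each terminal receives a share of the
#' total mean flow proportional to the cross-sectional area of its feeding
#' segment.
#'
#' @param network A `cow_network`.
#' @param total_mean_flow Total mean flow (m^3/s) to distribute.
#' @param terminal_ids Optional subset of terminals to split over (default all).
#' @return Named vector of per-terminal mean flows summing to `total_mean_flow`.
#' @export
area_proportional_split <- function(network, total_mean_flow, terminal_ids = NULL) {
  a <- terminal_areas(network)
  if (!is.null(terminal_ids)) a <- a[terminal_ids]
  if (all(a == 0)) stop("all terminal feeding areas are zero")
  q <- total_mean_flow * a / sum(a)
  q
}

#' Seed WK3 terminals from a mean-flow split
#'
#' Each terminal's total resistance is set to carry its target mean flow
#' under the mean arterial pressure, `R_tot = (MAP - P_ven)/Q`; the
#' proximal:distal partition uses a fixed fraction and the compliance is
#' seeded from a peripheral time constant, `C = tau / R_d` (proportional to
#' the terminal's flow share).
#'
#' @param network A `cow_network`.
#' @param mean_arterial_pressure MAP (Pa).
#' @param splits Named per-terminal mean flows (m^3/s), all > 0.
#' @param venous_pressure Venous reference pressure (Pa), default 5 mmHg.
#' @param proximal_fraction R_p as a fraction of total resistance.
#' @param tau Peripheral RC time constant (s) seeding the compliances; the
#'   default gives a physiological total peripheral compliance
#'   (~1.3 ml/mmHg) and aortic diastolic decay.
#' @param tau_cerebral Time constant for the cerebral territories.
#'   Intracranial arterial beds are far stiffer than systemic ones; the
#'   default 0.06 s gives simulated middle-cerebral pulsatility indices in
#'   the physiological 1-1.5 range with positive diastolic flow.
#' @return A [wk3_set()].
#' @export
initialize_terminals <- function(network, mean_arterial_pressure, splits,
                                 venous_pressure = mmHg_to_Pa(5),
                                 proximal_fraction = 0.1, tau = 1.3,
                                 tau_cerebral = 0.06) {
  ids <- network$terminals$terminal_id
  if (!all(ids %in% names(splits)))
    stop("splits must cover every terminal")
  q <- splits[ids]
  if (any(q <= 0)) stop("unperfused terminal: zero or negative split for ",
                        paste(ids[q <= 0], collapse = ", "))
  dp <- mean_arterial_pressure - venous_pressure
  if (dp <= 0) stop("mean_arterial_pressure must exceed venous_pressure")
  R_tot <- dp / q
  R_p <- proximal_fraction * R_tot
  R_d <- (1 - proximal_fraction) * R_tot
  tau_i <- ifelse(ids %in% cerebral_terminals(network), tau_cerebral, tau)
  wk3_set(ids, R_p, R_d, C = tau_i / R_d, P_ven = venous_pressure)
}
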