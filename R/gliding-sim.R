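#' Engaged-motor table
#'
#' Small helper building the `data.frame` representation of motors engaged
#' with the filament, as used by [solve_filament_velocity()] and
#' [barbed_end_rates()].
#'
#' @param site distance of the bound subunit from the barbed end (nm).
#' @param state `"driving"` or `"resisting"`.
#' @param F strain force carried by the linkage (pN, `>= 0`).
#' @param t_attached attachment time (s).
#' @return A `data.frame` with one row per engaged motor.
#' @export
engaged_motors <- function(site = numeric(), state = character(),
                           F = numeric(), t_attached = 0) {
  state <- as.character(state)
  stopifnot(all(state %in% c("driving", "resisting")),
            length(site) == length(state), length(F) == length(state))
  if (any(F < 0)) stop("motor forces must be >= 0")
  if (any(site < 0)) stop("motor sites must be >= 0")
  data.frame(site = as.numeric(site), state = state, F = as.numeric(F),
             t_attached = rep_len(as.numeric(t_attached), length(site)))
}

#' Slender-body bulk drag coefficient of a filament
#'
#' `xi_b = 4 pi eta_b L / ln(2 L / r)` for a rod of radius `r` dragged
#' sideways through a fluid of viscosity `eta_b`, times a crowding factor
#' for methylcellulose-containing buffer.
#'
#' @param eta_b bulk viscosity (Pa s).
#' @param filament_length filament length (nm).
#' @param crowding multiplicative crowding factor (1 in plain buffer).
#' @param radius filament radius (nm).
#' @return Drag coefficient in pN s / nm.
#' @export
bulk_drag_coefficient <- function(eta_b, filament_length, crowding = 1,
                                  radius = 4) {
  stopifnot(filament_length > 0, eta_b >= 0, crowding >= 0)
  if (filament_length <= 2 * radius) return(0)
  4 * pi * eta_b * crowding * filament_length /
    log(2 * filament_length / radius) * 1e-6
}

#' Instantaneous filament sliding velocity from the motor force balance
#'
#' Solves the linear balance between driving motors, each exerting
#' `F_stall * (1 - v/v0)`, and the loads: bulk drag `xi_b * v` plus the sum
#' of the strain forces of resisting motors,
#' \deqn{N_d F_{stall} (1 - v/v_0) = \xi_b v + \sum_j F_j.}
#' With no driving motor engaged the filament does not move; if the
#' resisting load exceeds the total stall force the velocity clamps at 0.
#'
#' @param engaged an [engaged_motors()] table.
#' @param species a [motor_species()].
#' @param eta_b bulk viscosity (Pa s).
#' @param filament_length filament length (nm).
#' @param v0 unloaded actuation velocity (nm/s).
#' @param crowding crowding factor passed to [bulk_drag_coefficient()].
#' @return Velocity in nm/s, in `[0, v0]`.
#' @export
solve_filament_velocity <- function(engaged, species, eta_b,
                                    filament_length, v0, crowding = 1) {
  stopifnot(inherits(species, "motor_species"), filament_length > 0)
  n_d <- sum(engaged$state == "driving")
  if (n_d == 0 || v0 <= 0) return(0)
  S <- sum(engaged$F[engaged$state == "resisting"])
  xi_b <- bulk_drag_coefficient(eta_b, filament_length, crowding)
  drive <- n_d * species$F_stall
  v <- (drive - S) / (xi_b + drive / v0)
  min(max(v, 0), v0)
}

#' One explicit-Euler update of a resisting motor's strain force
#'
#' The linkage of a resisting motor is loaded by the sliding filament and
#' relaxed by slip of its anchor in the bilayer:
#' `dF/dt = kappa * (v_f - F / xi_anchor)`.  For `xi_anchor = Inf` (rigid
#' substrate) the force grows linearly, `dF = kappa * v_f * dt`; with a
#' finite anchor drag it saturates at the steady state
#' `F_ss = xi_anchor * v_f`.
#'
#' @param m a single-row [engaged_motors()] table with `state =
#'   "resisting"`.
#' @param v_f filament sliding velocity (nm/s).
#' @param species a [motor_species()] supplying `kappa` and `xi_anchor`.
#' @param dt time step (s), `> 0`.
#' @return The updated motor row.
#' @export
anchor_force_step <- function(m, v_f, species, dt) {
  stopifnot(inherits(species, "motor_species"), nrow(m) == 1L)
  if (m$state != "resisting") stop("anchor_force_step applies to resisting motors")
  if (dt <= 0) stop("dt must be > 0")
  vm <- if (is.finite(species$xi_anchor)) m$F / species$xi_anchor else 0
  m$F <- max(0, m$F + species$kappa * (v_f - vm) * dt)
  m
}

#' Barbed-end association and dissociation rates under motor load
#'
#' Association is purely chemical, `r_on = k_on * C_m`, and unaffected by
#' the motors.  Dissociation is enhanced by the load of the resisting motor
#' closest to the barbed end within the tip zone:
#' `r_off = k_off0 * exp(F_tip * delta / kBT)`, with `F_tip = 0` when no
#' resisting motor sits within `ell_tip` of the end.
#'
#' @param engaged an [engaged_motors()] table.
#' @param barbed a [barbed_end_model()].
#' @param C_m G-actin concentration (uM), `>= 0`.
#' @return A named numeric vector `c(r_on = , r_off = )` in subunits/s.
#' @export
barbed_end_rates <- function(engaged, barbed, C_m) {
  stopifnot(inherits(barbed, "barbed_end_model"))
  if (C_m < 0) stop("C_m must be >= 0")
  tip <- engaged$state == "resisting" & engaged$site < barbed$ell_tip
  F_tip <- if (any(tip)) engaged$F[tip][which.min(engaged$site[tip])] else 0
  c(r_on = barbed$k_on * C_m,
    r_off = barbed$k_off0 * exp(min(F_tip * barbed$delta / barbed$kBT, 30)))
}

#' Coarse closed-form velocity of a filament on bilayer-anchored motors
#'
#' Analytic drag-partition estimate used to cross-check the event simulator
#' (never inside it): a filament driven by `N_att` anchored motors, each
#' slipping in the bilayer with drag `xi_anchor`, against a bulk drag
#' `xi_b`, slides at
#' \deqn{\tilde v_f = v_0 / (1 + \xi_b / (N \xi_{anchor})).}
#' The immobilized limit `xi_anchor = Inf` returns `v0`.
#'
#' @param v0 unloaded velocity (nm/s).
#' @param N_att number of attached motors, `>= 1`.
#' @param xi_anchor per-motor anchor drag (pN s/nm).
#' @param xi_b filament bulk drag (pN s/nm).
#' @return Velocity in nm/s.
#' @export
membrane_partition_velocity <- function(v0, N_att, xi_anchor, xi_b) {
  if (N_att < 1) stop("N_att must be >= 1")
  stopifnot(xi_anchor >= 0, xi_b >= 0)
  if (!is.finite(xi_anchor)) return(v0)
  v0 / (1 + xi_b / (N_att * xi_anchor))
}

#' Simulate a single filament gliding over a motor bed
#'
#' Fixed-step stochastic integration of the motor bed (Poisson attachment,
#' stroke completion, catch-slip detachment, anchor loading) coupled to an
#' exact Gillespie sub-loop for barbed/pointed-end subunit exchange within
#' each step.  With `motor_density = 0` the barbed-end process reduces
#' exactly to a two-rate birth-death process.  Identical seeds give
#' identical trajectories.
#'
#' @param config a [sim_config()].
#' @return An object of class `"filament_trajectory"`: a list with
#'   `samples` (data.frame of `time_s`, `x_b_nm`, `x_p_nm`, `length_su`,
#'   `n_on`, `n_off`, `n_p_off`, `n_motors_driving`, `n_motors_resisting`,
#'   `v_inst`), `events` (data.frame `time_s`, `kind` in
#'   `on`/`off`/`pointed_off`), `absorbed` flag and `config` echo.
#' @export
simulate_gliding <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$species
  bb <- config$barbed
  par <- list(
    v0_max = sp$v0_max, K_ATP = sp$K_ATP, ATP = config$ATP,
    attach_rate = sp$attach_rate, F_stall = sp$F_stall, kappa = sp$kappa,
    k_det_c = sp$k_det_c, F_c = sp$F_c, k_det_s = sp$k_det_s, F_s = sp$F_s,
    xi_anchor = config$xi_anchor, d_stroke = sp$d_stroke,
    k_on = if (is.null(bb)) 0 else bb$k_on,
    k_off0 = if (is.null(bb)) 0 else bb$k_off0,
    delta = if (is.null(bb)) 0 else bb$delta,
    ell_tip = if (is.null(bb)) 1 else bb$ell_tip,
    kBT = if (is.null(bb)) 4.1 else bb$kBT,
    C_m = config$C_m, motor_density = config$motor_density,
    capture_halfwidth = config$capture_halfwidth,
    eta_b = config$eta_b, crowding = config$crowding,
    initial_length = config$initial_length, duration = config$duration,
    dt = config$dt, sample_dt = config$sample_dt,
    pointed_off_rate = if (config$pointed_end_active) config$pointed_off_rate else 0,
    seed = config$seed, n_event_max = config$n_event_max)
  raw <- cpp_glide(par)
  samples <- data.frame(
    time_s = raw$times, x_b_nm = raw$x_b,
    x_p_nm = raw$x_b + SUBUNIT_NM * raw$length_su,
    length_su = raw$length_su, n_on = raw$n_on, n_off = raw$n_off,
    n_p_off = raw$n_p_off, n_motors_driving = raw$n_driving,
    n_motors_resisting = raw$n_resisting, v_inst = raw$v_inst)
  events <- data.frame(
    time_s = raw$event_times,
    kind = c("on", "off", "pointed_off")[raw$event_kind])
  structure(list(samples = samples, events = events,
                 absorbed = isTRUE(raw$absorbed), config = config),
            class = "filament_trajectory")
}

#' @export
print.filament_trajectory <- function(x, ...) {
  s <- x$samples
  n <- nrow(s)
  cat(sprintf("<filament_trajectory> %s bed, %s mode, %.0f s (%d samples)%s\n",
              x$config$species$label, x$config$mode, max(s$time_s), n,
              if (x$absorbed) " [fully depolymerized]" else ""))
  cat(sprintf("  length %g -> %g su; %d on / %d off / %d pointed-off events\n",
              s$length_su[1], s$length_su[n], s$n_on[n], s$n_off[n], s$n_p_off[n]))
  cat(sprintf("  barbed end displaced %.0f nm\n", s$x_b_nm[n] - s$x_b_nm[1]))
  invisible(x)
}

#' @export
plot.filament_trajectory <- function(x, ...) {
  s <- x$samples
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(s$time_s, s$x_p_nm, type = "l", xlab = "time (s)",
       ylab = "edge position (nm)", ...)
  lines(s$time_s, s$x_b_nm, lty = 2)
  legend("topleft", legend = c("pointed (leading)", "barbed (trailing)"),
         lty = c(1, 2), bty = "n")
  plot(s$time_s, s$length_su, type = "l", xlab = "time (s)",
       ylab = "length (subunits)")
  invisible(x)
}

#' Sliding and elongation rates of a simulated trajectory
#'
#' Least-squares slopes of the leading (pointed) edge position and of the
#' filament length over the analysis window.  For a stabilized filament the
#' leading-edge slope equals the barbed-edge slope; for a polymerizing
#' filament it isolates gliding from subunit exchange.
#'
#' @param traj a [simulate_gliding()] result.
#' @param window length of the trailing analysis window (s); `NULL` uses
#'   the full trajectory.
#' @return A list with `v_f` (nm/s), `v_p` (subunits/s) and `n` (samples
#'   used).
#' @export
trajectory_summary <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "filament_trajectory"))
  s <- traj$samples
  if (!is.null(window)) {
    stopifnot(window > 0)
    if (window > max(s$time_s) - min(s$time_s))
      stop("trajectory shorter than the requested window")
    s <- s[s$time_s >= max(s$time_s) - window, , drop = FALSE]
  }
  if (nrow(s) < 3) stop("need at least 3 samples to estimate slopes")
  list(v_f = unname(coef(lm(x_p_nm ~ time_s, data = s))[2]),
       v_p = unname(coef(lm(length_su ~ time_s, data = s))[2]),
       n = nrow(s))
}

#' @export
summary.filament_trajectory <- function(object, window = NULL, ...) {
  out <- trajectory_summary(object, window)
  cat(sprintf("v_f = %.2f nm/s, v_p = %.3f su/s over %d samples\n",
              out$v_f, out$v_p, out$n))
  invisible(out)
}

#' Write a trajectory to CSV with a JSON sidecar echoing the configuration
#'
#' @param traj a [simulate_gliding()] result.
#' @param file path of the CSV to write; the sidecar is written next to it
#'   with extension `.json`.
#' @return Invisibly, the CSV path.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "filament_trajectory"))
  s <- traj$samples
  write.csv(s[, c("time_s", "x_b_nm", "length_su", "n_on", "n_off",
                  "n_motors_driving", "n_motors_resisting")],
            file, row.names = FALSE)
  cfg <- traj$config
  cfg$species <- unclass(cfg$species)
  cfg$barbed <- if (is.null(cfg$barbed)) NULL else unclass(cfg$barbed)
  jsonlite::write_json(unclass(cfg), sub("\\.csv$", ".json", file),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Exact Gillespie simulation of the motor-free barbed-end process
#'
#' Independent event-driven implementation of the two-rate birth-death
#' process (association at `r_on`, dissociation at `r_off`), used as the
#' oracle against which the fixed-step simulator's motor-free statistics
#' are checked.
#'
#' @param r_on,r_off association and dissociation rates (events/s).
#' @param length0 initial length (subunits).
#' @param n_events number of events to draw (simulation stops early if the
#'   length reaches 0).
#' @param seed integer seed.
#' @return A list with `times` (event times), `kind` (`"on"`/`"off"`) and
#'   `length_su` (length after each event).
#' @export
gillespie_birth_death <- function(r_on, r_off, length0, n_events,
                                  seed = 1) {
  stopifnot(r_on >= 0, r_off >= 0, r_on + r_off > 0, length0 >= 1)
  set.seed(seed)
  times <- numeric(n_events)
  kind <- character(n_events)
  len <- numeric(n_events)
  t <- 0; L <- length0
  r_tot <- r_on + r_off
  for (i in seq_len(n_events)) {
    t <- t + rexp(1, r_tot)
    on <- runif(1) < r_on / r_tot
    L <- L + if (on) 1 else -1
    times[i] <- t; kind[i] <- if (on) "on" else "off"; len[i] <- L
    if (L <= 0) {
      times <- times[1:i]; kind <- kind[1:i]; len <- len[1:i]
      break
    }
  }
  list(times = times, kind = kind, length_su = len)
}
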