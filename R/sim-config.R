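#' Configuration for one gliding simulation
#'
#' @param species a [motor_species()].
#' @param barbed a [barbed_end_model()], or `NULL` for a stabilized
#'   (phalloidin-like) filament with no end chemistry.
#' @param motor_density surface density of motors (1/um^2).
#' @param C_m bulk G-actin concentration (uM).
#' @param ATP ATP concentration (mM).
#' @param eta_b bulk viscosity (Pa s); `1e-3` for water, `1e-2` for 0.3%
#'   methylcellulose.
#' @param crowding multiplier on the slender-body bulk drag accounting for
#'   crowding in methylcellulose; 1 in plain buffer.
#' @param capture_halfwidth lateral reach of a motor to the filament axis
#'   (nm).
#' @param initial_length initial filament length (subunits).
#' @param duration simulated time (s).
#' @param dt integrator step (s); must satisfy
#'   `dt * fastest configured rate <= 0.1`.
#' @param sample_dt interval at which the trajectory is recorded (s).
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param mode `"immobilized"` (motors rigidly anchored; `xi_anchor` treated
#'   as `Inf`) or `"membrane"` (anchors slip in the bilayer with drag
#'   `xi_anchor`).
#' @param xi_anchor anchor drag used in `"membrane"` mode (pN s/nm);
#'   defaults to the species value.
#' @param pointed_end_active logical; if `TRUE`, the pointed end loses
#'   subunits at `pointed_off_rate`.
#' @param pointed_off_rate pointed-end dissociation rate (subunits/s) used
#'   when `pointed_end_active = TRUE`.
#' @param n_event_max maximum number of end events kept in the event log.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(species = reference_species("myo1b"),
                       barbed = barbed_end_model(),
                       motor_density = 8000, C_m = 0, ATP = 2,
                       eta_b = 1e-3, crowding = 1,
                       capture_halfwidth = 20,
                       initial_length = 2000, duration = 300,
                       dt = 0.01, sample_dt = 1, seed = 1,
                       mode = c("immobilized", "membrane"),
                       xi_anchor = NULL,
                       pointed_end_active = FALSE, pointed_off_rate = 0,
                       n_event_max = 200000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(species, "motor_species"),
            is.null(barbed) || inherits(barbed, "barbed_end_model"))
  if (dt <= 0) stop("dt must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (motor_density < 0) stop("motor_density must be >= 0")
  if (C_m < 0) stop("C_m must be >= 0")
  if (ATP < 0) stop("ATP must be >= 0")
  if (initial_length < 1) stop("initial_length must be >= 1 subunit")
  if (sample_dt < dt) sample_dt <- dt
  xi <- if (mode == "immobilized") Inf
        else if (is.null(xi_anchor)) species$xi_anchor else xi_anchor
  if (mode == "membrane" && !is.finite(xi))
    mode_note <- "membrane mode with infinite anchor drag (rigid limit)"
  mm <- ATP / (ATP + species$K_ATP)
  fastest <- max(species$attach_rate,
                 (species$k_det_c + species$k_det_s) * mm,
                 if (is.null(barbed)) 0 else c(barbed$k_on * C_m, barbed$k_off0),
                 if (pointed_end_active) pointed_off_rate else 0)
  if (dt * fastest > 0.1 + 1e-9)
    stop(sprintf(
      "unstable configuration: dt * fastest rate = %.3g > 0.1; reduce dt",
      dt * fastest))
  structure(list(species = species, barbed = barbed,
                 motor_density = motor_density, C_m = C_m, ATP = ATP,
                 eta_b = eta_b, crowding = crowding,
                 capture_halfwidth = capture_halfwidth,
                 initial_length = initial_length, duration = duration,
                 dt = dt, sample_dt = sample_dt, seed = as.integer(seed),
                 mode = mode, xi_anchor = xi,
                 pointed_end_active = pointed_end_active,
                 pointed_off_rate = pointed_off_rate,
                 n_event_max = as.integer(n_event_max)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$mode, "mode,", x$species$label, "bed\n")
  cat(sprintf("  density %g /um^2, C_m %g uM, ATP %g mM, eta_b %g Pa s (crowding %g)\n",
              x$motor_density, x$C_m, x$ATP, x$eta_b, x$crowding))
  cat(sprintf("  L0 %g su, duration %g s, dt %g s, seed %d\n",
              x$initial_length, x$duration, x$dt, x$seed))
  if (is.null(x$barbed)) cat("  barbed end: stabilized (no end chemistry)\n")
  invisible(x)
}
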