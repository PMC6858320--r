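#' Kinetic and mechanical parameters of one myosin species
#'
#' Bundles the per-motor parameters used by the gliding simulator: the
#' attachment rate within the capture zone, the unloaded actuation velocity
#' and its ATP dependence (single Michaelis-Menten factor), the stall force
#' and linkage stiffness of the working stroke, the two-pathway catch-slip
#' detachment law
#' \deqn{k_{det}(F) = \left(k_c e^{-F/F_c} + k_s e^{F/F_s}\right)
#'   \frac{[ATP]}{[ATP]+K_{ATP}},}
#' and the in-plane drag of the membrane anchor (`xi_anchor = Inf` encodes a
#' motor immobilized on glass).
#'
#' @param label character tag for the species.
#' @param attach_rate per-motor attachment rate within the capture zone
#'   (1/s).
#' @param v0_max unloaded actuation velocity at saturating ATP (nm/s).
#' @param K_ATP Michaelis constant of the ATP dependence (mM).
#' @param F_stall stall force of a driving motor (pN).
#' @param kappa linkage stiffness loading a resisting motor (pN/nm).
#' @param k_det_c,F_c catch-pathway prefactor (1/s) and force scale (pN).
#' @param k_det_s,F_s slip-pathway prefactor (1/s) and force scale (pN).
#' @param xi_anchor drag of the membrane anchor (pN s/nm); `Inf` for motors
#'   immobilized on a rigid substrate.
#' @param d_stroke working-stroke distance (nm).
#'
#' @return An object of class `"motor_species"`.
#' @seealso [reference_species()] for the tuned reference parameter sets.
#' @export
motor_species <- function(label, attach_rate, v0_max, K_ATP, F_stall, kappa,
                          k_det_c, F_c, k_det_s, F_s, xi_anchor = Inf,
                          d_stroke = 5) {
  stopifnot(is.character(label), length(label) == 1L)
  num <- c(attach_rate = attach_rate, v0_max = v0_max, K_ATP = K_ATP,
           F_stall = F_stall, kappa = kappa, k_det_c = k_det_c, F_c = F_c,
           k_det_s = k_det_s, F_s = F_s, xi_anchor = xi_anchor,
           d_stroke = d_stroke)
  if (any(!is.numeric(num)) || any(is.na(num)))
    stop("all motor_species parameters must be numeric and non-missing")
  if (any(num[setdiff(names(num), "xi_anchor")] < 0) || xi_anchor < 0)
    stop("rates, forces, stiffness and drags must be >= 0")
  if (v0_max <= 0) stop("v0_max must be > 0")
  if (k_det_c <= 0 && k_det_s <= 0)
    stop("at least one detachment pathway (k_det_c, k_det_s) must be > 0")
  if (k_det_c > 0 && F_c <= 0) stop("F_c must be > 0 when k_det_c > 0")
  if (k_det_s > 0 && F_s <= 0) stop("F_s must be > 0 when k_det_s > 0")
  structure(as.list(c(list(label = label), as.list(num))),
            class = "motor_species")
}

#' Reference motor parameter sets
#'
#' Returns one of the tuned reference species used throughout the package:
#' `"myo1b"`, a slow catch-bond motor whose detachment slows with load in
#' the few-pN range so that post-stroke motors can anchor transiently and
#' load the barbed end, and `"myoII"`, a fast slip-bond (muscle myosin
#' II-like) motor that detaches faster under load and therefore never builds
#' appreciable tip force despite gliding about five times faster.
#'
#' These values were calibrated once against the observable targets of the
#' assay this package models (mean sliding velocities on glass and on a
#' supported bilayer, the density / ATP dependence of velocity, and the
#' roughly two-fold reduction of barbed-end elongation at 0.6 uM G-actin);
#' the calibration is documented in the methods vignette.
#'
#' @param name `"myo1b"` or `"myoII"`.
#' @return A [motor_species()] object.
#' @export
reference_species <- function(name = c("myo1b", "myoII")) {
  name <- match.arg(name)
  switch(name,
    myo1b = motor_species(
      label = "myo1b", attach_rate = 0.08, v0_max = 80, K_ATP = 0.15,
      F_stall = 10, kappa = 0.02, k_det_c = 5, F_c = 0.8,
      k_det_s = 0.12, F_s = 1.8, xi_anchor = Inf, d_stroke = 5),
    myoII = motor_species(
      label = "myoII", attach_rate = 0.3, v0_max = 320, K_ATP = 0.15,
      F_stall = 3, kappa = 0.005, k_det_c = 0, F_c = 1,
      k_det_s = 25, F_s = 1.2, xi_anchor = Inf, d_stroke = 5))
}

#' @export
print.motor_species <- function(x, ...) {
  cat("<motor_species>", x$label, "\n")
  cat(sprintf("  attach %.3g /s, v0_max %.3g nm/s (K_ATP %.3g mM), F_stall %.3g pN\n",
              x$attach_rate, x$v0_max, x$K_ATP, x$F_stall))
  cat(sprintf("  detach: %.3g exp(-F/%.3g) + %.3g exp(F/%.3g) /s, kappa %.3g pN/nm\n",
              x$k_det_c, x$F_c, x$k_det_s, x$F_s, x$kappa))
  cat(sprintf("  anchor drag %s pN s/nm, stroke %.3g nm\n",
              if (is.finite(x$xi_anchor)) format(x$xi_anchor) else "Inf (rigid)",
              x$d_stroke))
  invisible(x)
}

#' Unloaded actuation velocity at a given ATP concentration
#'
#' Michaelis-Menten dependence `v0 = v0_max * ATP / (ATP + K_ATP)`.
#'
#' @param species a [motor_species()].
#' @param ATP ATP concentration (mM), `>= 0`.
#' @return Velocity in nm/s.
#' @export
actuation_velocity <- function(species, ATP) {
  stopifnot(inherits(species, "motor_species"))
  if (any(ATP < 0)) stop("ATP must be >= 0")
  species$v0_max * ATP / (ATP + species$K_ATP)
}

#' Force-dependent motor detachment rate
#'
#' Two-pathway catch-slip bond scaled by the ATP occupancy factor:
#' `(k_det_c * exp(-F/F_c) + k_det_s * exp(F/F_s)) * ATP/(ATP + K_ATP)`.
#'
#' @param F load on the motor linkage (pN), `>= 0`.
#' @param species a [motor_species()].
#' @param ATP ATP concentration (mM).
#' @return Detachment rate in 1/s.
#' @export
detachment_rate <- function(F, species, ATP = 2) {
  stopifnot(inherits(species, "motor_species"))
  if (any(F < 0)) stop("F must be >= 0")
  mm <- ATP / (ATP + species$K_ATP)
  cc <- if (species$k_det_c > 0) species$k_det_c * exp(-F / species$F_c) else 0
  ss <- if (species$k_det_s > 0) species$k_det_s * exp(pmin(F / species$F_s, 30)) else 0
  (cc + ss) * mm
}

#' Barbed-end kinetic model
#'
#' Parameters of the filament barbed (plus) end: the association rate
#' constant `k_on`, the unloaded dissociation rate `k_off0`, and the
#' mechanical coupling through which a load applied near the tip enhances
#' dissociation by a Bell factor `exp(F * delta / kBT)`.  The load is taken
#' from the resisting motor bound within `ell_tip` of the barbed end that
#' sits closest to it.
#'
#' @param k_on association rate constant (subunits / (uM s)).
#' @param k_off0 unloaded dissociation rate (subunits / s).
#' @param delta mechanical distance of force-enhanced dissociation (nm);
#'   `delta = 0` switches the mechanism off.
#' @param ell_tip length of the tip zone within which an attached motor
#'   loads the barbed end (nm).
#' @param kBT thermal energy (pN nm).
#' @return An object of class `"barbed_end_model"`.
#' @export
barbed_end_model <- function(k_on = 11.6, k_off0 = 1.4, delta = 5,
                             ell_tip = 150, kBT = 4.1) {
  stopifnot(k_on > 0, k_off0 > 0, ell_tip > 0, delta >= 0, kBT > 0)
  structure(list(k_on = k_on, k_off0 = k_off0, delta = delta,
                 ell_tip = ell_tip, kBT = kBT),
            class = "barbed_end_model")
}

#' @export
print.barbed_end_model <- function(x, ...) {
  cat(sprintf("<barbed_end_model> k_on %.3g su/(uM s), k_off0 %.3g su/s, Cc+ %.3g uM\n",
              x$k_on, x$k_off0, x$k_off0 / x$k_on))
  cat(sprintf("  Bell coupling delta %.3g nm over tip zone %.3g nm (kBT %.3g pN nm)\n",
              x$delta, x$ell_tip, x$kBT))
  invisible(x)
}
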