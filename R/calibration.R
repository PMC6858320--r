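#' Density-per-intensity calibration slope from a lipid titration
#'
#' Converts fluorescent-lipid mole fractions to surface densities using the
#' area per lipid (0.68 nm^2 by default, counting both leaflets unless
#' `leaflets = "single"`), then regresses density on measured intensity
#' through the origin.  The slope is the calibration coefficient `A`
#' (density per intensity count), which depends on the illumination and
#' recording settings.
#'
#' @param titration data.frame with columns `fraction` and `intensity`
#'   (the `slb` element of [make_titration_table()] has this layout).
#' @param area_per_lipid area per lipid (nm^2).
#' @param leaflets `"both"` or `"single"`.
#' @return The slope `A` (1/um^2 per count).
#' @export
calibrate_A <- function(titration, area_per_lipid = 0.68,
                        leaflets = c("both", "single")) {
  leaflets <- match.arg(leaflets)
  stopifnot(all(c("fraction", "intensity") %in% names(titration)))
  keep <- titration$fraction > 0
  if (sum(keep) < 2) stop("need at least 2 nonzero fractions")
  if (any(titration$intensity[keep] <= 0))
    stop("intensities at nonzero fractions must be positive")
  nl <- if (leaflets == "both") 2 else 1
  density <- nl * titration$fraction[keep] / area_per_lipid * 1e6
  unname(coef(lm(density ~ 0 + titration$intensity[keep]))[1])
}

#' Bulk brightness ratio of the protein dye to the lipid dye
#'
#' Slope through the origin of the protein-dye intensity against the
#' lipid-dye intensity in a paired bulk titration.
#'
#' @param dye data.frame with columns `I_dope` and `I_alexa` (the `dye`
#'   element of [make_titration_table()]).
#' @return The dimensionless ratio.
#' @export
calibrate_dye_ratio <- function(dye) {
  stopifnot(all(c("I_dope", "I_alexa") %in% names(dye)))
  unname(coef(lm(I_alexa ~ 0 + I_dope, data = dye))[1])
}

#' Assemble a calibration result
#'
#' Combines the density-per-intensity slope `A`, the dye brightness ratio
#' and the degree of labeling `Z` into the prefactor
#' `A / (dye_ratio * Z)` that converts a protein-channel intensity directly
#' into a surface density, optionally together with FRAP-derived mobility.
#'
#' @param A density-per-intensity slope (1/um^2 per count).
#' @param dye_ratio brightness ratio of the protein dye to the lipid dye.
#' @param Z degree of labeling of the protein.
#' @param D diffusion coefficient (um^2/s), optional.
#' @param tau_half FRAP half-recovery time (s), optional.
#' @return An object of class `"calibration_result"`.
#' @export
calibration_result <- function(A, dye_ratio = 1, Z = 1, D = NULL,
                               tau_half = NULL) {
  stopifnot(A > 0, dye_ratio > 0, Z > 0)
  if (!is.null(D) && D <= 0) stop("D must be > 0")
  if (!is.null(tau_half) && tau_half <= 0) stop("tau_half must be > 0")
  structure(list(A = A, dye_ratio = dye_ratio, Z = Z,
                 combined_prefactor = A / (dye_ratio * Z),
                 D = D, tau_half = tau_half),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> A = %.4g, dye ratio = %.4g, Z = %g\n",
              x$A, x$dye_ratio, x$Z))
  cat(sprintf("  combined prefactor A/(ratio*Z) = %.4g per um^2 per count\n",
              x$combined_prefactor))
  if (!is.null(x$D))
    cat(sprintf("  D = %.4g um^2/s (tau_1/2 = %.4g s)\n",
                x$D, if (is.null(x$tau_half)) NA else x$tau_half))
  invisible(x)
}

#' Reference density calibration
#'
#' The bundled calibration of the reference assay: with a degree of
#' labeling of 1 and the two dye channels balanced, the combined conversion
#' prefactor is 0.278 motors per um^2 per intensity count.
#'
#' @return A [calibration_result()].
#' @export
reference_calibration <- function() {
  calibration_result(A = 0.278, dye_ratio = 1, Z = 1)
}

#' Surface density from a protein-channel intensity
#'
#' `n = A / (dye_ratio * Z) * I`.
#'
#' @param I measured intensity (counts), `>= 0`.
#' @param cal a [calibration_result()].
#' @return Density in 1/um^2.
#' @export
density_from_intensity <- function(I, cal) {
  stopifnot(inherits(cal, "calibration_result"))
  if (any(I < 0)) stop("I must be >= 0")
  cal$combined_prefactor * I
}

#' Normalize and average FRAP recovery curves
#'
#' Divides each replicate by the pre-bleach intensity and averages the
#' replicates pointwise; all curves must share a common time base.
#'
#' @param curves a single data.frame (`t`, `I`) or a list of them.
#' @param prebleach pre-bleach intensity used for normalization.
#' @return A data.frame `t`, `I` (averaged normalized curve).
#' @export
normalize_recovery <- function(curves, prebleach = 1) {
  if (is.data.frame(curves)) curves <- list(curves)
  stopifnot(length(curves) >= 1, prebleach > 0)
  t0 <- curves[[1]]$t
  for (c in curves)
    if (length(c$t) != length(t0) || any(abs(c$t - t0) > 1e-9))
      stop("curves do not share a common time base")
  I <- rowMeans(vapply(curves, function(c) c$I / prebleach,
                       numeric(length(t0))))
  data.frame(t = t0, I = I)
}

#' Fit a single-exponential FRAP recovery
#'
#' Fits `I(t) = I_inf - (I_inf - I_0) * exp(-t / tau)` by nonlinear least
#' squares with a deterministic initialization (plateau from the last 10%
#' of points, `tau` from the time at which half of the bleached depth has
#' recovered), and reports the half-recovery time `tau_half = tau * ln 2`.
#'
#' @param curve data.frame with columns `t` (increasing) and `I`.
#' @return An object of class `"frap_fit"`: list with `tau`, `tau_half`,
#'   `plateau` (`I_inf`), `I0` and the `nls` fit.
#' @export
fit_recovery <- function(curve) {
  stopifnot(all(c("t", "I") %in% names(curve)), nrow(curve) >= 5)
  if (any(diff(curve$t) <= 0)) stop("t must be strictly increasing")
  n <- nrow(curve)
  I_inf0 <- mean(tail(curve$I, max(2, ceiling(0.1 * n))))
  I00 <- curve$I[1]
  depth <- I_inf0 - I00
  if (abs(depth) < 1e-6 * max(abs(curve$I), 1))
    stop("no recovery detected: curve is flat")
  half_level <- I00 + depth / 2
  i_half <- which(curve$I >= half_level)[1]
  tau0 <- if (is.na(i_half) || i_half <= 1) diff(range(curve$t)) / 4
          else curve$t[i_half] / log(2)
  fit <- tryCatch(
    nls(I ~ I_inf - (I_inf - I_0) * exp(-t / tau), data = curve,
        start = list(I_inf = I_inf0, I_0 = I00, tau = max(tau0, 1e-6)),
        control = nls.control(maxiter = 500, tol = 1e-12, scaleOffset = 1)),
    error = function(e)
      stop("recovery fit did not converge: ", conditionMessage(e)))
  cf <- coef(fit)
  structure(list(tau = unname(cf["tau"]),
                 tau_half = unname(cf["tau"]) * log(2),
                 plateau = unname(cf["I_inf"]), I0 = unname(cf["I_0"]),
                 fit = fit),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> tau = %.4g s, tau_1/2 = %.4g s, plateau = %.4g\n",
              x$tau, x$tau_half, x$plateau))
  invisible(x)
}

#' Diffusion coefficient from the Soumpasis relation
#'
#' `D = 0.224 * r^2 / tau_half` for a circular bleach spot of radius `r`.
#'
#' @param r bleach-spot radius (um), `> 0`.
#' @param tau_half half-recovery time (s), `> 0`.
#' @return Diffusion coefficient in um^2/s.
#' @export
soumpasis_D <- function(r, tau_half) {
  if (any(r <= 0) || any(tau_half <= 0)) stop("r and tau_half must be > 0")
  0.224 * r^2 / tau_half
}

#' Anchor drag from a measured diffusion coefficient (Einstein relation)
#'
#' Bridges the mobility of a membrane-anchored motor to the simulator's
#' anchor drag: `xi = kBT / D`, with units converted from um^2/s to
#' pN s/nm.
#'
#' @param D diffusion coefficient (um^2/s), `> 0`.
#' @param kBT thermal energy (pN nm).
#' @return Drag in pN s/nm.
#' @export
anchor_drag_from_D <- function(D, kBT = 4.1) {
  if (any(D <= 0)) stop("D must be > 0")
  kBT / (D * 1e6)
}
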