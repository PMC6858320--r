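#' Fit barbed-end kinetics from elongation rates across G-actin
#' concentrations
#'
#' Fits the linear barbed-end rate law `v_p = k_on * C_m - k_off` by
#' (weighted) least squares: `k_on` is the slope, `k_off` minus the
#' intercept, and the critical concentration for polymerization is
#' `C_c+ = k_off / k_on`.  Uncertainties come from a seeded case-resampling
#' bootstrap.
#'
#' @param points data.frame with columns `C_m` (uM) and `v_p` (subunits/s);
#'   an optional `weight` column supplies weights (typically `1/sem^2` for
#'   per-concentration means), otherwise uniform weights are used.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer bootstrap seed.
#' @param conf confidence level of the percentile intervals.
#' @return An object of class `"kinetics_fit"` with components `k_on`,
#'   `k_off`, `C_c_plus`, `se` (named vector), `ci` (matrix), `boot`
#'   (resampled coefficients), `fit` (the underlying `lm`), `n_points` and
#'   `flagged` (`TRUE` when `k_on <= 0`, in which case `C_c_plus` is `NA`).
#' @export
fit_vp_vs_cm <- function(points, n_boot = 2000, seed = 1, conf = 0.95) {
  stopifnot(is.data.frame(points), all(c("C_m", "v_p") %in% names(points)))
  points <- points[complete.cases(points[, c("C_m", "v_p")]), , drop = FALSE]
  if (length(unique(points$C_m)) < 3)
    stop("need at least 3 distinct G-actin concentrations")
  if (diff(range(points$C_m)) <= 0)
    stop("concentrations must span a nonzero range")
  w <- if ("weight" %in% names(points)) points$weight else rep(1, nrow(points))
  fit <- lm(v_p ~ C_m, data = points, weights = w)
  k_on <- unname(coef(fit)[2])
  k_off <- -unname(coef(fit)[1])
  flagged <- k_on <= 0
  set.seed(seed)
  n <- nrow(points)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = 2,
                 dimnames = list(NULL, c("k_on", "k_off")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(points$C_m[idx])) < 2) next
    cf <- coef(lm(v_p ~ C_m, data = points[idx, , drop = FALSE],
                  weights = w[idx]))
    boot[b, ] <- c(cf[2], -cf[1])
  }
  boot <- boot[complete.cases(boot), , drop = FALSE]
  a <- (1 - conf) / 2
  ci <- rbind(k_on = quantile(boot[, "k_on"], c(a, 1 - a), names = FALSE),
              k_off = quantile(boot[, "k_off"], c(a, 1 - a), names = FALSE),
              C_c_plus = if (flagged) c(NA, NA) else
                quantile(boot[, "k_off"] / boot[, "k_on"], c(a, 1 - a),
                         names = FALSE))
  colnames(ci) <- c("lower", "upper")
  structure(list(
    k_on = k_on, k_off = k_off,
    C_c_plus = if (flagged) NA_real_ else k_off / k_on,
    se = c(k_on = sd(boot[, "k_on"]), k_off = sd(boot[, "k_off"])),
    ci = ci, boot = boot, fit = fit, n_points = n, conf = conf,
    flagged = flagged),
    class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit> v_p = k_on * C_m - k_off\n")
  cat(sprintf("  k_on  = %.3f +/- %.3f su/(uM s)\n", x$k_on, x$se["k_on"]))
  cat(sprintf("  k_off = %.3f +/- %.3f su/s\n", x$k_off, x$se["k_off"]))
  if (x$flagged) cat("  flagged: k_on <= 0, critical concentration undefined\n")
  else cat(sprintf("  C_c+  = %.3f uM\n", x$C_c_plus))
  invisible(x)
}

#' @export
summary.kinetics_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  %d points, %d bootstrap resamples, %g%% CIs:\n",
              object$n_points, nrow(object$boot), 100 * object$conf))
  print(round(object$ci, 4))
  invisible(object)
}

#' @export
coef.kinetics_fit <- function(object, ...) {
  c(k_on = object$k_on, k_off = object$k_off, C_c_plus = object$C_c_plus)
}

#' @export
#' @method confint kinetics_fit
confint.kinetics_fit <- function(object, parm, level, ...) object$ci

#' @export
predict.kinetics_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object$fit))
  stopifnot("C_m" %in% names(newdata))
  object$k_on * newdata$C_m - object$k_off
}

#' @export
plot.kinetics_fit <- function(x, ...) {
  d <- x$fit$model
  plot(d$C_m, d$v_p, xlab = expression(C[m] ~ "(uM)"),
       ylab = expression(v[p] ~ "(su/s)"), ...)
  abline(a = -x$k_off, b = x$k_on)
  abline(h = 0, lty = 3)
  if (!x$flagged) points(x$C_c_plus, 0, pch = 4)
  invisible(x)
}

#' Compare dissociation rates of two kinetics fits
#'
#' Bootstrap ratio `k_off_b / k_off_a` with a percentile confidence
#' interval and a two-sided bootstrap test of ratio = 1.
#'
#' @param fit_a,fit_b two [fit_vp_vs_cm()] objects (a = reference).
#' @param conf confidence level.
#' @return A list with `ratio`, `ci` and `p`.
#' @export
compare_koff <- function(fit_a, fit_b, conf = 0.95) {
  stopifnot(inherits(fit_a, "kinetics_fit"), inherits(fit_b, "kinetics_fit"))
  if (fit_a$k_off <= 0) stop("reference k_off must be > 0")
  n <- min(nrow(fit_a$boot), nrow(fit_b$boot))
  ratios <- fit_b$boot[seq_len(n), "k_off"] / fit_a$boot[seq_len(n), "k_off"]
  ratios <- ratios[is.finite(ratios)]
  a <- (1 - conf) / 2
  p_lo <- (sum(ratios <= 1) + 1) / (length(ratios) + 1)
  p_hi <- (sum(ratios >= 1) + 1) / (length(ratios) + 1)
  list(ratio = fit_b$k_off / fit_a$k_off,
       ci = quantile(ratios, c(a, 1 - a), names = FALSE),
       p = min(1, 2 * min(p_lo, p_hi)))
}

#' Mean, standard error and count of a velocity sample
#'
#' @param values numeric vector (e.g. per-filament velocities), `n >= 2`.
#' @return A list with `mean`, `sem` and `n`.
#' @export
summarize_condition <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values")
  list(mean = mean(values), sem = sd(values) / sqrt(length(values)),
       n = length(values))
}
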