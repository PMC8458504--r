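# Closed-form assay computations: 1:1 binding isotherm Kd fitting over
# serial dilutions, FRET efficiency, gelatin degradation, tumor volume,
# TD50 by linear trend, and plasma protein binding.

#' Geometric serial dilution series
#'
#' `c_i = top / factor^i` for `i = 0..n_points-1`; e.g. 18 two-fold
#' steps from 200 uM end at 1.5 nM.
#'
#' @param top top concentration (molar).
#' @param factor dilution factor (> 1; default 2).
#' @param n_points number of points (>= 2).
#' @return numeric vector of concentrations, strictly decreasing.
#' @export
serial_dilution <- function(top, factor = 2, n_points) {
  stopifnot(top > 0, factor > 1, n_points >= 2)
  top / factor^(seq_len(n_points) - 1L)
}

#' Simulate a 1:1 binding titration
#'
#' Hyperbolic ligand-excess model: `signal = s_unbound + (s_bound -
#' s_unbound) * c / (c + kd)` plus seeded Gaussian noise. MST-style
#' normalized-fluorescence curves are simulated this way.
#'
#' @param kd dissociation constant (molar, > 0).
#' @param s_unbound,s_bound signal plateaus (unitless).
#' @param concentrations ligand concentrations (molar).
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param seed RNG seed.
#' @return object of class `titration_curve`: data.frame with
#'   `concentration` and `signal`.
#' @export
simulate_titration <- function(kd, s_unbound, s_bound, concentrations,
                               noise_sd = 0, seed = 1L) {
  stopifnot(kd > 0, all(concentrations > 0))
  mu <- s_unbound + (s_bound - s_unbound) * concentrations /
    (concentrations + kd)
  sig <- if (noise_sd > 0)
    mu + with_seed(seed, stats::rnorm(length(mu), 0, noise_sd)) else mu
  out <- data.frame(concentration = concentrations, signal = sig)
  class(out) <- c("titration_curve", "data.frame")
  out
}

#' Fit the dissociation constant of a 1:1 binding curve
#'
#' Nonlinear least squares on `s_unbound + (s_bound - s_unbound) *
#' c/(c + Kd)` with multistart over log-spaced Kd initial guesses
#' (Levenberg-Marquardt). The Kd standard error comes from the
#' linearized covariance at the optimum.
#'
#' @param curve a `titration_curve` (or data.frame with `concentration`
#'   and `signal`).
#' @return object of class `binding_fit`: `kd`, `kd_se`, `s_unbound`,
#'   `s_bound`, `rss`.
#' @export
fit_kd <- function(curve) {
  cc <- curve$concentration
  ss <- curve$signal
  if (length(cc) < 4L) stop("need at least 4 titration points")
  if (stats::sd(ss) < 1e-12 * max(1, abs(mean(ss))))
    stop("flat titration curve: Kd is unidentifiable")
  starts <- 10^seq(log10(min(cc)), log10(max(cc)), length.out = 7)
  best <- NULL
  for (k0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        signal ~ su + (sb - su) * concentration / (concentration + kd),
        data = data.frame(concentration = cc, signal = ss),
        start = list(su = min(ss), sb = max(ss), kd = k0),
        lower = c(-Inf, -Inf, .Machine$double.xmin),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("Kd fit failed to converge from any start")
  est <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit)))[["kd"]],
                 error = function(e) NA_real_)
  structure(list(kd = unname(est[["kd"]]), kd_se = se,
                 s_unbound = unname(est[["su"]]),
                 s_bound = unname(est[["sb"]]),
                 rss = best$rss),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("1:1 binding fit: Kd = %.3g M (SE %.2g), plateaus %.3g -> %.3g, RSS %.3g\n",
              x$kd, x$kd_se, x$s_unbound, x$s_bound, x$rss))
  invisible(x)
}

#' FRET efficiency
#'
#' `FRETeff = FRETcorr / (FRETcorr + CFP) * 100` (percent), applied
#' per scalar or elementwise per pixel.
#' @param fret_corr corrected FRET intensity (>= 0).
#' @param cfp donor-channel intensity (>= 0).
#' @return efficiency in percent.
#' @export
fret_efficiency <- function(fret_corr, cfp) {
  stopifnot(all(fret_corr >= 0), all(cfp >= 0))
  if (any(fret_corr + cfp == 0))
    stop("FRET efficiency undefined when both intensities are zero")
  fret_corr / (fret_corr + cfp) * 100
}

#' Percent gelatin degradation
#'
#' `(degraded area / cell area) * 100`.
#' @param degraded_area degraded gelatin area (>= 0).
#' @param cell_area corresponding cell area (> 0).
#' @return percent degradation.
#' @export
percent_degradation <- function(degraded_area, cell_area) {
  stopifnot(all(degraded_area >= 0))
  if (any(cell_area <= 0)) stop("cell area must be positive")
  degraded_area / cell_area * 100
}

#' Ellipsoidal tumor volume
#'
#' `0.5 * major * minor^2` in cubic millimeters.
#' @param major,minor caliper axes in mm (both > 0).
#' @return volume in mm^3.
#' @export
tumor_volume <- function(major, minor) {
  stopifnot(all(major > 0), all(minor > 0))
  if (any(major < minor)) warning("major axis smaller than minor axis")
  0.5 * major * minor^2
}

#' Median toxic dose from a linear viability trend
#'
#' Ordinary least squares of viability (percent) on dose; returns the
#' dose at which the fitted line crosses 50% viability.
#' @param doses dose values (>= 2 points).
#' @param viability percent viability at each dose.
#' @return the TD50 dose, in the units of `doses`.
#' @export
td50_linear <- function(doses, viability) {
  if (length(doses) < 2L || length(doses) != length(viability))
    stop("need >= 2 (dose, viability) pairs")
  fit <- stats::lm(viability ~ doses)
  slope <- stats::coef(fit)[["doses"]]
  if (abs(slope) < 1e-12) stop("zero slope: viability does not cross 50%")
  td50 <- (50 - stats::coef(fit)[["(Intercept)"]]) / slope
  rng <- range(doses)
  fitted_range <- range(stats::fitted(fit))
  if (50 < fitted_range[1] || 50 > fitted_range[2])
    stop("fitted line does not cross 50% viability within the dose range")
  td50
}

#' Plasma protein binding percentage
#'
#' `(1 - unbound/total) * 100`.
#' @param total_signal total compound signal (> 0).
#' @param unbound_signal unbound fraction signal (0 <= unbound <= total).
#' @return percent bound.
#' @export
ppb_percent <- function(total_signal, unbound_signal) {
  stopifnot(all(total_signal > 0), all(unbound_signal >= 0))
  if (any(unbound_signal > total_signal))
    stop("unbound signal exceeds total signal")
  (1 - unbound_signal / total_signal) * 100
}
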