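#' Extract the scalar relaxation features from a force curve
#'
#' Reads off the five scalars feeding the surrogate parameter equations:
#' * `F1` - contact force at the phase-1 to phase-2 transition (first
#'   phase-2 sample, raw; reading at the boundary rather than the global
#'   maximum is robust to trigger overshoot),
#' * `F0` - residual force at the end of the hold (mean of the last
#'   `smoothing_window` raw phase-2 samples; the hold tail is flat to
#'   \eqn{e^{-t_{hold}/\tau}}, so on noiseless curves this equals the last
#'   sample while averaging down noise on measured ones),
#' * `t1` - time of the phase-2 start,
#' * `t_mid` - earliest time at which the force crosses
#'   `F_mid = (F1 + F0)/2`, located by linear interpolation between the
#'   bracketing samples of the (optionally smoothed) hold force,
#' * `u_max` - maximum indentation during the hold.
#'
#' Smoothing is a centered moving average of width `smoothing_window`
#' applied only for the midpoint-crossing search; `F1` and `F0` always come
#' from raw samples. On a noiseless single-exponential hold the recovered
#' midpoint satisfies \eqn{t_{mid} - t_1 = \tau \ln 2} to within one
#' sampling interval.
#'
#' @param curve A [force_curve()] containing a complete phase 2.
#' @param smoothing_window Odd sample count for the moving average
#'   (default 21; use 1 for no smoothing).
#' @return An object of class `relaxation_features`: a named list with
#'   `F1`, `F0`, `F_mid` (N), `t1`, `t_mid` (s), `u_max` (m) and `R`
#'   (sample radius in m, `NA` for bulk half-space samples).
#' @export
extract_features <- function(curve, smoothing_window = 21) {
  validate_force_curve(curve)
  w <- as.integer(smoothing_window)
  if (w < 1L) stop("smoothing_window must be >= 1")
  i2 <- which(curve$phase == 2L)
  if (length(i2) < 3L) stop("curve contains no complete phase 2")
  t2 <- curve$time_s[i2]
  f2 <- curve$force_N[i2]

  F1 <- f2[1L]
  F0 <- mean(tail(f2, min(w, length(f2))))
  t1 <- t2[1L]
  u_max <- max(curve$indentation_m[i2])
  F_mid <- (F1 + F0) / 2

  fs <- f2
  if (w > 1L) {
    sm <- as.numeric(stats::filter(f2, rep(1 / w, w), sides = 2))
    fs[!is.na(sm)] <- sm[!is.na(sm)]  # keep raw values at the edges
  }
  below <- fs < F_mid  # strict: a flat (elastic) hold never crosses
  below[1L] <- FALSE
  k <- which(below)[1L]
  if (is.na(k) || F0 >= F1)
    stop("no relaxation midpoint: force never crosses F_mid within phase 2 ",
         "(purely elastic curve or truncated hold?)")
  # linear interpolation between the bracketing samples
  t_mid <- t2[k - 1L] + (F_mid - fs[k - 1L]) / (fs[k] - fs[k - 1L]) *
    (t2[k] - t2[k - 1L])

  m <- curve_meta(curve)
  R <- if (!is.null(m$geometry) && !is.na(m$geometry$sample_radius))
    m$geometry$sample_radius else NA_real_
  structure(list(F1 = F1, F0 = F0, F_mid = F_mid, t1 = t1, t_mid = t_mid,
                 u_max = u_max, R = R),
            class = "relaxation_features")
}

#' @export
print.relaxation_features <- function(x, ...) {
  cat(sprintf(
    "<relaxation_features> F1 = %.4g nN, F0 = %.4g nN, t1 = %.4g s, t_mid = %.4g s, u_max = %.4g um%s\n",
    x$F1 * 1e9, x$F0 * 1e9, x$t1, x$t_mid, x$u_max * 1e6,
    if (is.na(x$R)) "" else sprintf(", R = %.4g um", x$R * 1e6)))
  invisible(x)
}

#' Coerce relaxation features to a one-row data frame
#' @param x A `relaxation_features` object.
#' @param ... Unused.
#' @return One-row data frame with columns `F1, F0, F_mid, t1, t_mid,
#'   u_max, R` (strict SI units).
#' @export
as.data.frame.relaxation_features <- function(x, ...) {
  data.frame(F1 = x$F1, F0 = x$F0, F_mid = x$F_mid, t1 = x$t1,
             t_mid = x$t_mid, u_max = x$u_max, R = x$R)
}

#' Apparent Young's modulus from a Hertz fit of the approach segment
#'
#' Least-squares fit of \eqn{F = \frac{4}{3}\frac{E}{1-\nu^2}
#' \sqrt{R_{eff}}\,\delta^{3/2}} to the phase-1 samples (linear in `E`, so
#' the fit is closed-form). For a purely elastic curve this returns the
#' generating modulus; for a viscoelastic curve it returns an apparent
#' modulus between `E0` and `E0 + E1` that grows with indentation velocity -
#' the stiffening-with-velocity signature of relaxation. Microgel curves
#' should be fitted with the `sphere_double` effective radius (the
#' double-contact correction).
#'
#' @param curve A [force_curve()] whose phase 1 has at least 10 samples with
#'   positive force.
#' @param geometry A [contact_geometry()].
#' @param nu Poisson ratio.
#' @param contact_point Indentation offset (m) subtracted before fitting.
#'   Synthetic curves embed a true contact point of 0; for measured curves
#'   this is a free parameter.
#' @return Apparent Young's modulus in Pa.
#' @export
fit_hertz_approach <- function(curve, geometry, nu = 0.45,
                               contact_point = 0) {
  validate_force_curve(curve)
  i1 <- which(curve$phase == 1L)
  d <- curve$indentation_m[i1] - contact_point
  f <- curve$force_N[i1]
  keep <- d > 0 & f > 0
  if (sum(keep) < 10L)
    stop("phase-1 segment has fewer than 10 samples with positive force")
  d <- d[keep]; f <- f[keep]
  if (all(f == 0)) stop("degenerate approach segment: all-zero force")
  d32 <- d^1.5
  k <- sum(f * d32) / sum(d32^2)  # LS slope through the origin
  k * 3 * (1 - nu^2) / (4 * sqrt(effective_radius(geometry)))
}
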