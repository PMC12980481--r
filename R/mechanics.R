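#' @importFrom stats integrate uniroot approx optimize optim filter rnorm
#' @importFrom utils read.csv tail head packageVersion
NULL

# Dawson function D(x) = exp(-x^2) * integral_0^x exp(s^2) ds, x >= 0.
# pracma::erfi is accurate but its exp(x^2) growth loses nothing here since
# we multiply by exp(-x^2); beyond x = 4.5 the asymptotic series in 1/x is
# already at double precision and avoids large intermediates.
.dawson <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 4.5
  if (any(lo))
    out[lo] <- sqrt(pi) / 2 * exp(-x[lo]^2) * pracma::erfi(x[lo])
  if (any(!lo)) {
    xi <- 1 / x[!lo]
    out[!lo] <- 0.5 * xi + 0.25 * xi^3 + 0.375 * xi^5 +
      0.9375 * xi^7 + 3.28125 * xi^9
  }
  out
}

# Ramp hereditary kernel I(t; tau) = integral_0^t sqrt(s) exp(-(t-s)/tau) ds.
# Substituting s = tau * x^2 gives the exact closed form
#   I = tau^{3/2} (X - D(X)),  X = sqrt(t / tau),
# with D the Dawson function. Vectorized over t.
.ramp_integral <- function(t, tau) {
  X <- sqrt(t / tau)
  tau^1.5 * (X - .dawson(X))
}

# Same integral by adaptive quadrature (scalar t).
.ramp_integral_quad <- function(t, tau, rel.tol = 1e-8) {
  if (t == 0) return(0)
  q <- tryCatch(
    integrate(function(s) sqrt(s) * exp(-(t - s) / tau), 0, t,
              rel.tol = rel.tol, subdivisions = 500L),
    error = function(e) stop("quadrature failed for t = ", t, ", tau = ",
                             tau, ": ", conditionMessage(e)))
  q$value
}

#' Viscoelastic contact force during the approach ramp
#'
#' Force at time `t` of phase 1, when the indenter moves at constant velocity
#' `v` so that \eqn{\delta(t) = v t}. For a standard linear solid in Hertzian
#' contact with non-decreasing contact area, the Lee-Radok hereditary
#' integral gives
#' \deqn{F(t) = C_g \left[E_0 (v t)^{3/2} +
#'   E_1 \tfrac{3}{2} v^{3/2} \int_0^t \sqrt{s}\, e^{-(t-s)/\tau} ds\right],}
#' with \eqn{C_g = 4\sqrt{R_{eff}} / (3(1-\nu^2))}. The integral is evaluated
#' either by adaptive quadrature (relative tolerance 1e-8, the default) or by
#' its exact closed form in terms of the Dawson function; the two agree to
#' near machine precision and the closed form is used internally wherever
#' whole trajectories are sampled.
#'
#' @param material An [sls_material()].
#' @param geometry A [contact_geometry()].
#' @param protocol An [afm_protocol()] (only `velocity` is used).
#' @param t Time(s) within the ramp (s, >= 0). Vectorized.
#' @param method `"quadrature"` (adaptive, rel. tol 1e-8) or `"closed"`
#'   (exact Dawson-function form).
#' @return Force in N, bounded between the elastic Hertz forces at moduli
#'   `E0` and `E0 + E1` for the same indentation.
#' @export
ramp_force <- function(material, geometry, protocol, t,
                       method = c("quadrature", "closed")) {
  method <- match.arg(method)
  stopifnot(inherits(material, "sls_material"),
            inherits(geometry, "contact_geometry"),
            inherits(protocol, "afm_protocol"))
  if (any(t < 0)) stop("t must be non-negative")
  v <- protocol$velocity
  Cg <- .contact_prefactor(geometry, material$nu)
  I <- if (method == "closed") .ramp_integral(t, material$tau)
       else vapply(t, .ramp_integral_quad, numeric(1), tau = material$tau)
  Cg * (material$E0 * (v * t)^1.5 +
          material$E1 * 1.5 * v^1.5 * I)
}

# Solve ramp_force(t1) = trigger for t1. The elastic E0-only response is a
# lower bound on the force, so the purely elastic ramp time is an upper
# bound on t1: bracket [0, t_up] and refine to 1e-12 relative.
.ramp_time <- function(material, geometry, protocol) {
  v <- protocol$velocity
  Cg <- .contact_prefactor(geometry, material$nu)
  F1 <- protocol$trigger_force
  t_up <- (F1 / (Cg * material$E0))^(2 / 3) / v
  f <- function(t) {
    Cg * (material$E0 * (v * t)^1.5 +
            material$E1 * 1.5 * v^1.5 * .ramp_integral(t, material$tau)) - F1
  }
  uniroot(f, c(0, t_up * (1 + 1e-9)), tol = t_up * 1e-12)$root
}

#' Simulate the three-phase stress-relaxation protocol
#'
#' Runs the forward model: (i) finds the ramp duration `t1` at which the
#' contact force first reaches the trigger force (relative tolerance 1e-12 on
#' the bracketing root), (ii) sets the maximum indentation
#' `u_max = velocity * t1`, (iii) samples the phase-1 trajectory from the
#' hereditary integral and the phase-2 (constant displacement) trajectory
#' from its closed form
#' \deqn{F(t) = C_g\left[E_0 u_{max}^{3/2} + E_1 J\, e^{-(t-t_1)/\tau}\right],
#'   \quad J = \tfrac{3}{2} v^{3/2} \int_0^{t_1}\sqrt{s}\,e^{-(t_1-s)/\tau}ds.}
#' The force is continuous at `t1` and strictly decreasing during the hold
#' when `E1 > 0` (constant when `E1 = 0`). The retraction phase is not
#' simulated.
#'
#' @inheritParams ramp_force
#' @return A [force_curve()] with phases 1 and 2 sampled at
#'   `protocol$sampling_rate`, carrying the generating parameters in its
#'   metadata.
#' @examples
#' crv <- simulate_protocol(sls_material(1000, 100, 0.1),
#'                          contact_geometry(5e-6, "half_space"),
#'                          afm_protocol(5e-6, 1e-8))
#' head(crv)
#' @export
simulate_protocol <- function(material, geometry, protocol) {
  stopifnot(inherits(material, "sls_material"),
            inherits(geometry, "contact_geometry"),
            inherits(protocol, "afm_protocol"))
  v <- protocol$velocity
  nu <- material$nu
  Cg <- .contact_prefactor(geometry, nu)
  t1 <- .ramp_time(material, geometry, protocol)
  u_max <- v * t1
  dt <- 1 / protocol$sampling_rate

  # phase 1: t = 0, dt, 2dt, ... < t1 (trigger sample itself opens phase 2)
  n1 <- floor(t1 / dt)
  tt1 <- seq(0, by = dt, length.out = n1 + 1L)
  tt1 <- tt1[tt1 < t1]
  F1s <- Cg * (material$E0 * (v * tt1)^1.5 +
                 material$E1 * 1.5 * v^1.5 *
                   .ramp_integral(tt1, material$tau))

  # phase 2: t = t1, t1 + dt, ..., t1 + hold
  n2 <- floor(protocol$hold_duration / dt)
  tt2 <- t1 + seq(0, by = dt, length.out = n2 + 1L)
  J <- 1.5 * v^1.5 * .ramp_integral(t1, material$tau)
  F2s <- Cg * (material$E0 * u_max^1.5 +
                 material$E1 * J * exp(-(tt2 - t1) / material$tau))

  force_curve(
    time = c(tt1, tt2),
    indentation = c(v * tt1, rep(u_max, length(tt2))),
    force = c(F1s, F2s),
    phase = c(rep(1L, length(tt1)), rep(2L, length(tt2))),
    meta = list(material = material, geometry = geometry,
                protocol = protocol, nu = nu, t1 = t1, u_max = u_max,
                contact_point = 0))
}

# Phase-2 force for an *imposed* displacement history (ramp at velocity v to
# u_max, then hold): used by the stage-2 objective where the experimental
# profile, not the candidate material, fixes u_max and t1.
.hold_force_imposed <- function(material, geometry, v, u_max, t_rel) {
  Cg <- .contact_prefactor(geometry, material$nu)
  t1 <- u_max / v
  J <- 1.5 * v^1.5 * .ramp_integral(t1, material$tau)
  Cg * (material$E0 * u_max^1.5 +
          material$E1 * J * exp(-t_rel / material$tau))
}
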