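#' Standard-linear-solid material
#'
#' Constructs the material parameter triple of a standard linear solid (SLS,
#' a spring in parallel with a Maxwell spring-dashpot arm) plus the Poisson
#' ratio. The relaxation modulus is \eqn{E(t) = E_0 + E_1 e^{-t/\tau}}: at
#' \eqn{t = 0} the material responds with the instantaneous (unrelaxed)
#' modulus \eqn{E_0 + E_1}, and after complete relaxation only the fully
#' relaxed modulus \eqn{E_0} remains. The dashpot viscosity is
#' \eqn{\eta = \tau E_1}.
#'
#' @param E0 Fully relaxed Young's modulus (Pa, > 0).
#' @param E1 Relaxation (viscous) modulus (Pa, >= 0). `E1 = 0` is the purely
#'   elastic limit.
#' @param tau Relaxation time constant (s, > 0). Ignored physically when
#'   `E1 = 0` but must still be positive.
#' @param nu Poisson ratio, `0 <= nu < 0.5`. Defaults to 0.45, appropriate
#'   for nearly incompressible hydrogels.
#' @return An object of class `sls_material`.
#' @examples
#' m <- sls_material(E0 = 1000, E1 = 100, tau = 0.1)
#' relaxation_modulus(m, c(0, 0.1, Inf))
#' @export
sls_material <- function(E0, E1 = 0, tau = 1, nu = 0.45) {
  stopifnot(is.numeric(E0), length(E0) == 1L, is.finite(E0),
            is.numeric(E1), length(E1) == 1L, is.finite(E1),
            is.numeric(tau), length(tau) == 1L,
            is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (E0 <= 0) stop("E0 must be positive (Pa)")
  if (E1 < 0) stop("E1 must be non-negative (Pa)")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive (s)")
  if (nu < 0 || nu >= 0.5) stop("nu must satisfy 0 <= nu < 0.5")
  structure(list(E0 = E0, E1 = E1, tau = tau, nu = nu),
            class = "sls_material")
}

#' @export
print.sls_material <- function(x, ...) {
  cat(sprintf(
    "<sls_material> E0 = %g Pa, E1 = %g Pa, tau = %g s, nu = %g (E_u = %g Pa, eta = %g Pa s)\n",
    x$E0, x$E1, x$tau, x$nu, x$E0 + x$E1, x$tau * x$E1))
  invisible(x)
}

#' Time-dependent relaxation modulus of an SLS material
#'
#' Evaluates \eqn{E(t) = E_0 + E_1 e^{-t/\tau}}. Non-increasing in `t`,
#' bounded between `E0` (fully relaxed) and `E0 + E1` (instantaneous).
#'
#' @param material An [sls_material()].
#' @param t Time(s) since loading, s, >= 0. Vectorized.
#' @return Modulus in Pa, same length as `t`.
#' @export
relaxation_modulus <- function(material, t) {
  stopifnot(inherits(material, "sls_material"), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  material$E0 + material$E1 * exp(-t / material$tau)
}

#' Contact geometry of the probe-sample system
#'
#' Describes the spherical colloidal probe and the sample shape. A bulk gel
#' is a `half_space`; a microgel is a sphere either in a single Hertz contact
#' with the probe (`sphere_single`) or, the experimentally relevant case, a
#' double contact (`sphere_double`) that also deforms against the rigid
#' substrate on its underside (the double-contact correction).
#'
#' @param probe_radius Radius of the spherical probe (m, > 0).
#' @param sample_kind One of `"half_space"`, `"sphere_single"`,
#'   `"sphere_double"`.
#' @param sample_radius Microgel radius R (m, > 0). Required for the
#'   `sphere_*` kinds, ignored for `half_space`.
#' @return An object of class `contact_geometry`.
#' @examples
#' contact_geometry(5e-6, "sphere_double", 35e-6)
#' @export
contact_geometry <- function(probe_radius,
                             sample_kind = c("half_space", "sphere_single",
                                             "sphere_double"),
                             sample_radius = NULL) {
  sample_kind <- match.arg(sample_kind)
  stopifnot(is.numeric(probe_radius), length(probe_radius) == 1L)
  if (!is.finite(probe_radius) || probe_radius <= 0)
    stop("probe_radius must be positive (m)")
  if (sample_kind != "half_space") {
    if (is.null(sample_radius) || !is.numeric(sample_radius) ||
        length(sample_radius) != 1L || !is.finite(sample_radius) ||
        sample_radius <= 0)
      stop("sample_kind '", sample_kind,
           "' requires a positive sample_radius (m)")
  } else {
    sample_radius <- NA_real_
  }
  structure(list(probe_radius = probe_radius, sample_kind = sample_kind,
                 sample_radius = sample_radius),
            class = "contact_geometry")
}

#' @export
print.contact_geometry <- function(x, ...) {
  cat(sprintf("<contact_geometry> probe %g um, %s%s (R_eff = %g um)\n",
              x$probe_radius * 1e6, x$sample_kind,
              if (is.na(x$sample_radius)) ""
              else sprintf(", sample R = %g um", x$sample_radius * 1e6),
              effective_radius(x) * 1e6))
  invisible(x)
}

#' Effective (composite) Hertz radius of the contact
#'
#' * `half_space`: the probe radius itself.
#' * `sphere_single`: the harmonic combination
#'   \eqn{(1/R_p + 1/R)^{-1}} of probe and microgel radii.
#' * `sphere_double`: the probe-gel contact (radius \eqn{R_1} as above) acts
#'   in series with the gel-substrate contact (radius \eqn{R_2 = R}). For a
#'   Hertz contact \eqn{F = K \delta^{3/2}} with \eqn{K \propto \sqrt{R}},
#'   the compliances of two series contacts of the same material add as
#'   \eqn{K^{-2/3}}, giving a single force-equivalent contact of radius
#'   \eqn{(R_1^{-1/3} + R_2^{-1/3})^{-3}}.
#'
#' @param geometry A [contact_geometry()].
#' @return Effective radius in m.
#' @examples
#' effective_radius(contact_geometry(5e-6, "sphere_single", 35e-6)) # 35/8 um
#' @export
effective_radius <- function(geometry) {
  stopifnot(inherits(geometry, "contact_geometry"))
  Rp <- geometry$probe_radius
  switch(geometry$sample_kind,
    half_space = Rp,
    sphere_single = 1 / (1 / Rp + 1 / geometry$sample_radius),
    sphere_double = {
      R1 <- 1 / (1 / Rp + 1 / geometry$sample_radius)
      R2 <- geometry$sample_radius
      (R1^(-1 / 3) + R2^(-1 / 3))^(-3)
    })
}

#' Indentation protocol descriptor
#'
#' The three-phase stress-relaxation protocol: the probe approaches at
#' constant `velocity` until `trigger_force` is reached (phase 1), is then
#' held at constant displacement for `hold_duration` (phase 2), and finally
#' retracted (phase 3, not simulated here because adhesion artifacts make it
#' unusable for parameter extraction).
#'
#' @param velocity Approach velocity (m/s, > 0).
#' @param trigger_force Force ending phase 1 (N, > 0).
#' @param hold_duration Length of the constant-displacement hold (s, > 0).
#'   Default 10 s.
#' @param sampling_rate Samples per second (Hz). The hold must contain at
#'   least 100 samples so the relaxation transient is resolved.
#' @return An object of class `afm_protocol`.
#' @export
afm_protocol <- function(velocity, trigger_force, hold_duration = 10,
                         sampling_rate = 2000) {
  stopifnot(is.numeric(velocity), is.numeric(trigger_force),
            is.numeric(hold_duration), is.numeric(sampling_rate))
  if (velocity <= 0) stop("velocity must be positive (m/s)")
  if (trigger_force <= 0) stop("trigger_force must be positive (N)")
  if (hold_duration <= 0) stop("hold_duration must be positive (s)")
  if (sampling_rate <= 0) stop("sampling_rate must be positive (Hz)")
  if (hold_duration * sampling_rate < 100)
    stop("hold_duration * sampling_rate must be >= 100 ",
         "(too few samples to resolve the relaxation)")
  structure(list(velocity = velocity, trigger_force = trigger_force,
                 hold_duration = hold_duration,
                 sampling_rate = sampling_rate),
            class = "afm_protocol")
}

#' @export
print.afm_protocol <- function(x, ...) {
  cat(sprintf(
    "<afm_protocol> v = %g um/s, trigger = %g nN, hold = %g s @ %g Hz\n",
    x$velocity * 1e6, x$trigger_force * 1e9, x$hold_duration,
    x$sampling_rate))
  invisible(x)
}

#' Hertz contact force of a sphere on an elastic body
#'
#' \eqn{F = \frac{4}{3} \frac{E}{1-\nu^2} \sqrt{R_{eff}}\, \delta^{3/2}}.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio.
#' @param R_eff Effective contact radius (m), see [effective_radius()].
#' @param delta Indentation depth (m, >= 0). Vectorized.
#' @return Force in N.
#' @examples
#' hertz_force(1000, 0.45, 5e-6, 1e-6) # ~3.74 nN
#' @export
hertz_force <- function(E, nu, R_eff, delta) {
  stopifnot(is.numeric(E), is.numeric(nu), is.numeric(R_eff),
            is.numeric(delta))
  if (any(delta < 0)) stop("delta must be non-negative")
  (4 / 3) * E / (1 - nu^2) * sqrt(R_eff) * delta^1.5
}

# Hertz prefactor C_g = 4 sqrt(R_eff) / (3 (1 - nu^2)), so F = C_g * E * d^1.5
.contact_prefactor <- function(geometry, nu) {
  4 * sqrt(effective_radius(geometry)) / (3 * (1 - nu^2))
}
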