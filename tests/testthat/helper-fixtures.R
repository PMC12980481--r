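# Shared fixtures. Simulations in unit tests run at reduced sampling rates
# where the assertion tolerance permits it, to keep the suite fast; the
# sampling interval always enters the tolerance explicitly where it matters.

ref_material <- function(E0 = 1000, E1 = 100, tau = 0.1, nu = 0.45) {
  sls_material(E0, E1, tau, nu)
}

ref_half_space <- function(Rp = 5e-6) contact_geometry(Rp, "half_space")

ref_microgel <- function(Rp = 5e-6, R = 35e-6) {
  contact_geometry(Rp, "sphere_double", sample_radius = R)
}

ref_protocol <- function(v = 5e-6, F1 = 1e-8, hold = 10, rate = 1000) {
  afm_protocol(v, F1, hold, rate)
}

# three-velocity experiment set from one material (the standard design)
three_velocity_curves <- function(material, geometry, F1 = 1e-8,
                                  hold = 10, rate = 1000,
                                  velocities = c(1, 3, 5) * 1e-6) {
  lapply(velocities, function(v)
    simulate_protocol(material, geometry,
                      afm_protocol(v, F1, hold, rate)))
}

# brute-force fixed-step Riemann evaluation of the ramp hereditary integral
riemann_ramp_force <- function(material, geometry, v, t, n_steps = 1e6) {
  Cg <- 4 * sqrt(effective_radius(geometry)) /
    (3 * (1 - material$nu^2))
  s <- (seq_len(n_steps) - 0.5) / n_steps * t
  I <- sum(sqrt(s) * exp(-(t - s) / material$tau)) * t / n_steps
  Cg * (material$E0 * (v * t)^1.5 +
          material$E1 * 1.5 * v^1.5 * I)
}

# a small sub-grid (2x2x2x2x2x1 = 32 runs) reusing the paper-level values,
# for unit tests; the full 1,920-run grid is exercised in the acceptance
# tests
small_grid <- function() {
  calibration_grid(E0_levels = c(500, 2000), R_levels = c(20, 50) * 1e-6,
                   F1_levels = c(2, 10) * 1e-9,
                   ratio_levels = c(0.05, 0.2),
                   tau_levels = c(0.05, 0.2), v_levels = 5e-6)
}
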