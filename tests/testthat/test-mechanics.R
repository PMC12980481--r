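test_that("relaxation modulus follows the single-exponential decay", {
  m <- ref_material(1000, 100, 0.1)
  expect_equal(relaxation_modulus(m, 0), 1100)
  expect_equal(relaxation_modulus(m, 0.1), 1000 + 100 * exp(-1))
  expect_equal(relaxation_modulus(m, 1e6), 1000)
  # purely elastic limit is flat
  me <- ref_material(1000, 0, 1)
  expect_equal(relaxation_modulus(me, c(0, 0.5, 50)), rep(1000, 3))
  # non-increasing and bounded on a dense grid
  Et <- relaxation_modulus(m, seq(0, 1, by = 1e-3))
  expect_true(all(diff(Et) <= 0))
  expect_true(all(Et >= 1000 & Et <= 1100))
  expect_error(relaxation_modulus(m, -0.1), "non-negative")
})

test_that("material constructor rejects unphysical parameters", {
  expect_error(sls_material(-5, 0, 1), "E0")
  expect_error(sls_material(1000, -1, 1), "E1")
  expect_error(sls_material(1000, 100, 0), "tau")
  expect_error(sls_material(1000, 100, 0.1, nu = 0.5), "nu")
})

test_that("effective radius handles the three contact configurations", {
  expect_equal(effective_radius(ref_half_space(5e-6)), 5e-6)
  # harmonic combination: (1/5 + 1/35)^-1 um = 35/8 um
  expect_equal(
    effective_radius(contact_geometry(5e-6, "sphere_single", 35e-6)),
    35e-6 / 8)
  # series double contact, direct evaluation of the composite formula
  R1 <- 35e-6 / 8
  expect_equal(effective_radius(ref_microgel(5e-6, 35e-6)),
               (R1^(-1 / 3) + (35e-6)^(-1 / 3))^(-3))
  expect_equal(effective_radius(ref_microgel(5e-6, 35e-6)) * 1e6,
               1.296, tolerance = 1e-3)
  # ordering: double < single < min(Rp, R)
  single <- effective_radius(contact_geometry(5e-6, "sphere_single", 35e-6))
  dbl <- effective_radius(ref_microgel())
  expect_lt(dbl, single)
  expect_lt(single, 5e-6)
  expect_error(contact_geometry(5e-6, "sphere_single"), "sample_radius")
})

test_that("Hertz force matches the closed form and its symmetries", {
  F <- hertz_force(1000, 0.45, 5e-6, 1e-6)
  expect_equal(F, (4 / 3) * 1000 / (1 - 0.45^2) * sqrt(5e-6) * (1e-6)^1.5)
  expect_equal(F * 1e9, 3.739, tolerance = 1e-3)
  expect_equal(hertz_force(1000, 0.45, 5e-6, 0), 0)
  expect_equal(hertz_force(2000, 0.45, 5e-6, 1e-6), 2 * F)
  # monotone in delta
  d <- seq(0, 2e-6, length.out = 50)
  expect_true(all(diff(hertz_force(1000, 0.45, 5e-6, d)) > 0))
  expect_error(hertz_force(1000, 0.45, 5e-6, -1e-9), "non-negative")
})

test_that("ramp force reduces to Hertz in the elastic and frozen limits", {
  g <- ref_half_space()
  p <- ref_protocol(v = 5e-6)
  t <- c(0.05, 0.1, 0.2)
  # E1 = 0: exactly the relaxed Hertz force at delta = v t
  me <- ref_material(1000, 0, 1)
  expect_equal(ramp_force(me, g, p, t),
               hertz_force(1000, 0.45, 5e-6, 5e-6 * t),
               tolerance = 1e-10)
  # tau -> inf: the dashpot never relaxes, instantaneous modulus applies
  mf <- ref_material(1000, 100, 1e6)
  expect_equal(ramp_force(mf, g, p, t),
               hertz_force(1100, 0.45, 5e-6, 5e-6 * t),
               tolerance = 1e-6)
  # bounding between the relaxed and unrelaxed elastic envelopes
  m <- ref_material(1000, 200, 0.1)
  Fv <- ramp_force(m, g, p, t)
  expect_true(all(Fv >= hertz_force(1000, 0.45, 5e-6, 5e-6 * t)))
  expect_true(all(Fv <= hertz_force(1200, 0.45, 5e-6, 5e-6 * t)))
})

test_that("adaptive quadrature agrees with a fixed-step Riemann oracle", {
  # spec-scale single case at 1e6 steps
  m <- ref_material(1000, 200, 0.1)
  g <- ref_half_space()
  p <- ref_protocol(v = 5e-6)
  oracle <- riemann_ramp_force(m, g, 5e-6, 0.2, n_steps = 1e6)
  expect_equal(ramp_force(m, g, p, 0.2), oracle, tolerance = 1e-5)
  expect_equal(ramp_force(m, g, p, 0.2, method = "closed"), oracle,
               tolerance = 1e-5)
  # seeded 10-case random grid, 5 significant digits
  set.seed(42)
  for (k in 1:10) {
    mk <- sls_material(runif(1, 300, 3000), runif(1, 20, 500),
                       runif(1, 0.02, 1))
    vk <- runif(1, 1e-6, 8e-6)
    tk <- runif(1, 0.02, 0.6)
    pk <- afm_protocol(vk, 1e-8)
    oracle <- riemann_ramp_force(mk, g, vk, tk, n_steps = 1e6)
    expect_equal(ramp_force(mk, g, pk, tk), oracle, tolerance = 1e-5)
  }
})

test_that("simulated protocol is continuous, monotone and correctly phased", {
  m <- ref_material(1000, 100, 0.1)
  g <- ref_half_space()
  crv <- simulate_protocol(m, g, ref_protocol(rate = 2000))
  meta <- curve_meta(crv)
  i2 <- which(crv$phase == 2L)
  # trigger reached exactly at the phase boundary
  expect_equal(crv$force_N[i2[1]], 1e-8, tolerance = 1e-9)
  # continuity at t1: last ramp sample is below but near the trigger
  i1 <- which(crv$phase == 1L)
  expect_lt(crv$force_N[tail(i1, 1)], 1e-8)
  expect_gt(crv$force_N[tail(i1, 1)], 0.97e-8)
  # hold force decreasing for E1 > 0: strictly over the resolvable decay,
  # non-increasing throughout (the tail plateaus at machine precision)
  early <- crv$time_s[i2] - meta$t1 <= 5 * m$tau
  expect_true(all(diff(crv$force_N[i2][early]) < 0))
  expect_true(all(diff(crv$force_N[i2]) <= 0))
  # phase-2 indentation constant at u_max = v * t1
  expect_equal(unique(crv$indentation_m[i2]), meta$u_max)
  expect_equal(meta$u_max, 5e-6 * meta$t1)
  # elastic material: constant hold force equal to the trigger
  crv0 <- simulate_protocol(ref_material(1000, 0, 1), g, ref_protocol())
  f2 <- crv0$force_N[crv0$phase == 2L]
  expect_equal(f2, rep(1e-8, length(f2)), tolerance = 1e-9)
})

test_that("phase-1 force-indentation equals Hertz for an elastic material", {
  crv <- simulate_protocol(ref_material(1200, 0, 1), ref_half_space(),
                           ref_protocol(v = 3e-6, rate = 2000))
  i1 <- crv$phase == 1L
  expect_equal(crv$force_N[i1],
               hertz_force(1200, 0.45, 5e-6, crv$indentation_m[i1]),
               tolerance = 1e-8)
})

test_that("hold decay is single-exponential with rate 1/tau", {
  m <- ref_material(800, 120, 0.15)
  crv <- simulate_protocol(m, ref_half_space(), ref_protocol(rate = 2000))
  meta <- curve_meta(crv)
  i2 <- which(crv$phase == 2L)
  Cg <- 4 * sqrt(5e-6) / (3 * (1 - 0.45^2))
  F_plateau <- Cg * 800 * meta$u_max^1.5
  resid <- crv$force_N[i2] - F_plateau
  # regress log-residuals over the first 5 tau of the hold
  keep <- crv$time_s[i2] - meta$t1 <= 5 * m$tau
  fit <- lm(log(resid[keep]) ~ crv$time_s[i2][keep])
  expect_equal(unname(coef(fit)[2]), -1 / m$tau, tolerance = 1e-3)
  # end-of-hold force equals the elastic plateau (fully relaxed)
  expect_equal(tail(crv$force_N[i2], 1), F_plateau,
               tolerance = exp(-10 / m$tau) * m$E1 / m$E0 + 1e-12)
})

test_that("half-decay time of the hold is exactly tau * ln 2", {
  for (tau in c(0.05, 0.2)) {
    m <- ref_material(1000, 150, tau)
    crv <- simulate_protocol(m, ref_half_space(),
                             ref_protocol(rate = 4000))
    f <- extract_features(crv, smoothing_window = 1)
    expect_equal(f$t_mid - f$t1, tau * log(2), tolerance = 1e-3)
  }
})

test_that("fast ramp approaches the step-load limit (F1-F0)/F0 = E1/E0", {
  m <- ref_material(1000, 100, 0.1)
  crv <- simulate_protocol(m, ref_half_space(),
                           afm_protocol(1e-2, 1e-8, 10, 2000))  # 1e4 um/s
  f2 <- crv$force_N[crv$phase == 2L]
  F1 <- f2[1]
  F0 <- tail(f2, 1)
  expect_equal((F1 - F0) / F0, 0.1, tolerance = 0.01)
})

test_that("forces scale linearly with the modulus pair at fixed history", {
  g <- ref_half_space()
  p <- ref_protocol()
  t <- c(0.05, 0.15, 0.25)
  base <- ramp_force(ref_material(900, 90, 0.12), g, p, t,
                     method = "closed")
  scaled <- ramp_force(ref_material(2700, 270, 0.12), g, p, t,
                       method = "closed")
  expect_equal(scaled, 3 * base, tolerance = 1e-12)
})
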