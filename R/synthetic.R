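#' Measurement-noise model for synthetic curves
#'
#' Additive Gaussian force noise at the thermal-noise scale of a soft AFM
#' cantilever (default sigma 10 pN), optional linear force drift and
#' fractional trigger overshoot (real instruments stop the ramp slightly
#' after the setpoint). A seed is mandatory whenever any stochastic
#' component is non-zero so that every synthetic curve is reproducible.
#'
#' @param force_sigma Standard deviation of the additive force noise (N).
#' @param drift_rate Linear force drift (N/s).
#' @param trigger_overshoot Fractional overshoot of the trigger force
#'   (e.g. 0.02 ends the ramp at 1.02 x trigger).
#' @param seed Integer RNG seed; required when `force_sigma > 0` or
#'   `drift_rate != 0`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(force_sigma = 1e-11, drift_rate = 0,
                        trigger_overshoot = 0, seed = NULL) {
  stopifnot(is.numeric(force_sigma), force_sigma >= 0,
            is.numeric(drift_rate), is.finite(drift_rate),
            is.numeric(trigger_overshoot), trigger_overshoot >= 0)
  if ((force_sigma > 0 || drift_rate != 0) && is.null(seed))
    stop("a seed is mandatory for any non-zero noise component")
  structure(list(force_sigma = force_sigma, drift_rate = drift_rate,
                 trigger_overshoot = trigger_overshoot,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_model")
}

#' Generate a synthetic three-phase force curve
#'
#' Wraps [simulate_protocol()] and superimposes the seeded noise model.
#' With an all-zero noise model the output is identical to the noiseless
#' simulation; with a fixed seed the output is bit-for-bit reproducible.
#' The generating parameters (ground truth) are embedded in the curve
#' metadata so downstream recovery can be scored.
#'
#' @inheritParams simulate_protocol
#' @param noise A [noise_model()].
#' @return A [force_curve()].
#' @export
generate_curve <- function(material, geometry, protocol,
                           noise = noise_model(force_sigma = 0)) {
  stopifnot(inherits(noise, "noise_model"))
  pro <- protocol
  if (noise$trigger_overshoot > 0)
    pro <- afm_protocol(protocol$velocity,
                        protocol$trigger_force *
                          (1 + noise$trigger_overshoot),
                        protocol$hold_duration, protocol$sampling_rate)
  crv <- simulate_protocol(material, geometry, pro)
  if (noise$force_sigma > 0 || noise$drift_rate != 0) {
    n <- nrow(crv)
    eps <- .with_seed(noise$seed,
                      rnorm(n, sd = noise$force_sigma))
    crv$force_N <- crv$force_N + eps + noise$drift_rate * crv$time_s
  }
  m <- curve_meta(crv)
  m$noise <- noise
  m$protocol <- protocol   # record the nominal, not overshot, trigger
  attr(crv, "meta") <- m
  crv
}

# Fixed study materials: one soft microgel and one stiffer bulk gel, both
# with a moderate viscous arm (E1/E0 = 0.15) inside the experimentally
# observed <= 20% range; microgels relax fast, bulk slower.
.study_materials <- function(nu = 0.45) {
  list(microgel = sls_material(400, 60, 0.12, nu),
       bulk = sls_material(1200, 180, 0.8, nu))
}

#' Write a reproducible synthetic study fixture
#'
#' Emulates the experimental design: two sample kinds (microgels modelled
#' as double-contact spheres with radii drawn around 33.9 um, i.e. half the
#' reported mean diameter, and bulk gels as half-spaces) x three approach
#' velocities (1, 3, 5 um/s) x `n_replicates` replicates, each a 10 nN
#' trigger / 10 s hold relaxation curve written as an annotated CSV, plus a
#' JSON manifest carrying the ground truth of every curve.
#'
#' @param out_dir Writable directory (created if absent).
#' @param seed Integer master seed; per-curve noise seeds are derived from
#'   it.
#' @param n_replicates Replicates per sample kind x velocity (default 10).
#' @param force_sigma Additive noise sd (N); 0 gives noiseless curves.
#' @param sampling_rate Hz (default 500: instrument rates are decimated so
#'   a full fixture stays a few MB of text).
#' @param hold_duration,trigger_force Protocol settings.
#' @return Invisibly, the manifest data frame (one row per curve:
#'   `file`, `sample_kind`, `velocity_m_per_s`, `replicate`,
#'   `sample_radius_m`, `E0_Pa`, `E1_Pa`, `tau_s`, `noise_seed`).
#' @export
generate_study_fixture <- function(out_dir, seed = 1L, n_replicates = 10L,
                                   force_sigma = 1e-11,
                                   sampling_rate = 500,
                                   hold_duration = 10,
                                   trigger_force = 1e-8) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  mats <- .study_materials()
  vels <- c(1, 3, 5) * 1e-6
  radii <- .with_seed(seed,
                      rnorm(n_replicates, mean = 33.9e-6, sd = 1.2e-6))
  rows <- list()
  idx <- 0L
  for (kind in names(mats)) {
    for (v in vels) {
      for (rep_i in seq_len(n_replicates)) {
        idx <- idx + 1L
        geo <- if (kind == "microgel")
          contact_geometry(5e-6, "sphere_double",
                           sample_radius = radii[rep_i])
        else contact_geometry(5e-6, "half_space")
        pro <- afm_protocol(v, trigger_force, hold_duration,
                            sampling_rate)
        ns <- if (force_sigma > 0)
          noise_model(force_sigma = force_sigma, seed = seed + idx)
        else noise_model(force_sigma = 0)
        crv <- generate_curve(mats[[kind]], geo, pro, ns)
        file <- sprintf("%s_v%g_rep%02d.csv", kind, v * 1e6, rep_i)
        write_curve(crv, file.path(out_dir, file))
        rows[[idx]] <- data.frame(
          file = file, sample_kind = kind, velocity_m_per_s = v,
          replicate = rep_i,
          sample_radius_m = if (kind == "microgel") radii[rep_i]
                            else NA_real_,
          E0_Pa = mats[[kind]]$E0, E1_Pa = mats[[kind]]$E1,
          tau_s = mats[[kind]]$tau,
          noise_seed = if (force_sigma > 0) seed + idx else NA_integer_)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(manifest)
}
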