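# Run code with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Compact differential evolution (rand/1/bin) with box constraints.
# Deterministic under the caller's RNG state. Returns par, value, n_evals.
.de_optim <- function(fn, lower, upper, pop_size = 20L, max_iter = 80L,
                      f_weight = 0.8, cr = 0.9) {
  d <- length(lower)
  pop <- matrix(stats::runif(pop_size * d, lower, upper),
                nrow = pop_size, ncol = d, byrow = TRUE)
  vals <- apply(pop, 1L, fn)
  n_evals <- pop_size
  for (it in seq_len(max_iter)) {
    for (i in seq_len(pop_size)) {
      idx <- sample(setdiff(seq_len(pop_size), i), 3L)
      trial <- pop[idx[1L], ] + f_weight * (pop[idx[2L], ] - pop[idx[3L], ])
      cross <- stats::runif(d) < cr
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      tv <- fn(trial)
      n_evals <- n_evals + 1L
      if (tv <= vals[i]) {
        pop[i, ] <- trial
        vals[i] <- tv
      }
    }
  }
  b <- which.min(vals)
  list(par = pop[b, ], value = vals[b], n_evals = n_evals)
}

# Per-curve summaries used by both objectives: u_max, t1, end-of-hold force
# (mean of the trailing 1% of hold samples; the tail is flat so this only
# averages noise), and the phase-2 time/force series.
.experiment_summary <- function(curve) {
  validate_force_curve(curve)
  i2 <- which(curve$phase == 2L)
  if (!length(i2)) stop("experiment curve has no phase-2 (hold) samples")
  t2 <- curve$time_s[i2]
  f2 <- curve$force_N[i2]
  n_tail <- max(1L, round(0.01 * length(f2)))
  m <- curve_meta(curve)
  v <- if (!is.null(m$protocol)) m$protocol$velocity else
    stop("curve metadata must carry the protocol (velocity)")
  list(u_max = max(curve$indentation_m[i2]), t1 = t2[1L],
       F_end = mean(tail(f2, n_tail)), t2 = t2, f2 = f2, v = v,
       hold = t2[length(t2)] - t2[1L])
}

#' Stage-1 objective: end-of-hold force mismatch for a candidate E0
#'
#' After a hold much longer than the relaxation time the viscous arm has
#' fully relaxed and the residual force is purely elastic, so a candidate
#' fully relaxed modulus can be scored against the measured end-of-hold
#' forces with an elastic (Hertz) forward model alone:
#' \deqn{z_1(E_0) = \sum_{i=1}^{3} |F_{sim,i} - F_{exp,i}|,}
#' where \eqn{F_{sim,i}} is the Hertz force at the measured maximum
#' indentation of experiment `i`. Residuals are taken in absolute value so
#' that opposite-signed mismatches cannot cancel.
#'
#' @param E0_candidate Candidate fully relaxed modulus (Pa).
#' @param experiments List of [force_curve()]s, one per approach velocity.
#' @param geometry A [contact_geometry()] shared by the experiments.
#' @param nu Poisson ratio.
#' @return The objective value in N (>= 0; 0 iff all end-of-hold forces
#'   match exactly).
#' @export
objective_z1 <- function(E0_candidate, experiments, geometry, nu = 0.45) {
  stopifnot(is.list(experiments), length(experiments) >= 1L)
  Reff <- effective_radius(geometry)
  s <- lapply(experiments, .experiment_summary)
  sum(vapply(s, function(e)
    abs(hertz_force(E0_candidate, nu, Reff, e$u_max) - e$F_end),
    numeric(1)))
}

#' Fit the fully relaxed modulus E0 (stage 1)
#'
#' Minimizes [objective_z1()] by bounded scalar minimization. When the hold
#' is much longer than the relaxation time this recovers the generating `E0`
#' of synthetic viscoelastic data to well within 0.5%; if the hold is too
#' short the residual viscous force \eqn{E_1 e^{-t_{hold}/\tau}} biases the
#' estimate upward (a warning is issued when the optimum sits at a bound).
#'
#' @param experiments List of [force_curve()]s.
#' @param geometry A [contact_geometry()].
#' @param nu Poisson ratio.
#' @param bounds Length-2 numeric, Pa interval bracketing the minimum.
#' @return `E0` in Pa, with attribute `at_bound` (logical).
#' @export
fit_E0 <- function(experiments, geometry, nu = 0.45,
                   bounds = c(10, 1e5)) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  opt <- optimize(objective_z1, interval = bounds,
                  experiments = experiments, geometry = geometry, nu = nu,
                  tol = bounds[2] * 1e-10)
  E0 <- opt$minimum
  at_bound <- min(E0 - bounds[1], bounds[2] - E0) < 1e-3 * diff(bounds)
  if (at_bound)
    warning("fit_E0: minimum lies at a bound of [", bounds[1], ", ",
            bounds[2], "] Pa")
  structure(E0, at_bound = at_bound, z1 = opt$objective)
}

#' Stage-2 objective: weighted force-history mismatch for (E1, tau)
#'
#' With `E0` fixed from stage 1, candidate viscous parameters are scored
#' against the full hold-phase force history at all velocities:
#' \deqn{z_2 = \sum_{i=1}^{3} \sum_{j=1}^{n_i}
#'   \left[(F_{sim,ij} - F_{exp,ij})\, t_j / t_{ges}\right]^2,}
#' where \eqn{t_j} is measured from the phase-2 start, \eqn{t_{ges}} is the
#' hold duration, the simulated force imposes each experiment's displacement
#' profile (ramp at its velocity to its measured `u_max`, then hold), and
#' the experimental force is linearly interpolated onto the simulation
#' times. The \eqn{t_j/t_{ges}} factor up-weights the late, nearly relaxed
#' part of the decay. By default only phase-2 samples enter the sum;
#' `include_phase1 = TRUE` adds the ramp samples with time measured from the
#' curve start and the same normalizer.
#'
#' @param E1_candidate Candidate relaxation modulus (Pa).
#' @param tau_candidate Candidate relaxation time (s).
#' @param E0_fixed Fully relaxed modulus from [fit_E0()] (Pa). Mandatory:
#'   the two stages are sequential.
#' @param experiments List of [force_curve()]s.
#' @param geometry A [contact_geometry()].
#' @param nu Poisson ratio.
#' @param t_ges Weight normalizer (s); defaults to each curve's hold
#'   duration.
#' @param include_phase1 Also sum over phase-1 samples (default FALSE).
#' @return Dimensionless (force^2-scaled) objective value >= 0.
#' @export
objective_z2 <- function(E1_candidate, tau_candidate, E0_fixed,
                         experiments, geometry, nu = 0.45, t_ges = NULL,
                         include_phase1 = FALSE) {
  if (missing(E0_fixed) || is.null(E0_fixed))
    stop("E0_fixed is unset: run fit_E0 first (the stages are sequential)")
  if (E1_candidate < 0 || tau_candidate <= 0) return(Inf)
  mat <- sls_material(E0_fixed, E1_candidate, tau_candidate, nu)
  total <- 0
  for (curve in experiments) {
    s <- .experiment_summary(curve)
    tg <- if (is.null(t_ges)) s$hold else t_ges
    tj <- s$t2 - s$t1
    Fsim <- .hold_force_imposed(mat, geometry, s$v, s$u_max, tj)
    Fexp <- approx(s$t2, s$f2, xout = s$t2, rule = 2)$y
    total <- total + sum(((Fsim - Fexp) * tj / tg)^2)
    if (include_phase1) {
      i1 <- which(curve$phase == 1L)
      tj1 <- curve$time_s[i1] - curve$time_s[1L]
      d1 <- curve$indentation_m[i1]
      Cg <- .contact_prefactor(geometry, nu)
      I <- .ramp_integral(pmax(tj1, 0), tau_candidate)
      Fs1 <- Cg * (E0_fixed * d1^1.5 +
                     E1_candidate * 1.5 * s$v^1.5 * I)
      total <- total + sum(((Fs1 - curve$force_N[i1]) * tj1 / tg)^2)
    }
  }
  total
}

#' Fit the viscous parameters (E1, tau) (stage 2)
#'
#' Global seeded differential-evolution search over the box `bounds`
#' followed by Nelder-Mead polish of [objective_z2()]. Deterministic given
#' `seed`. On noiseless synthetic data at the three standard velocities the
#' generating `(E1, tau)` are recovered to well within 1%.
#'
#' @param experiments List of [force_curve()]s.
#' @param E0_fixed Fully relaxed modulus from [fit_E0()] (Pa).
#' @param geometry A [contact_geometry()].
#' @param nu Poisson ratio.
#' @param bounds List with elements `E1` and `tau`, each a length-2 numeric
#'   interval. The default caps `E1` at 20% of `E0`, the upper end of the
#'   experimentally observed range.
#' @param seed Integer RNG seed for the global stage.
#' @param include_phase1 Passed to [objective_z2()].
#' @param control List: `pop_size` (>= 15), `max_iter` for the global stage.
#' @return List with `E1` (Pa), `tau` (s), `z2`, `n_evals`, `converged`,
#'   `at_bound`.
#' @export
fit_viscous <- function(experiments, E0_fixed, geometry, nu = 0.45,
                        bounds = list(E1 = c(0, 0.2 * E0_fixed),
                                      tau = c(0.005, 5)),
                        seed = 1L, include_phase1 = FALSE,
                        control = list()) {
  pop_size <- if (!is.null(control$pop_size)) control$pop_size else 20L
  max_iter <- if (!is.null(control$max_iter)) control$max_iter else 60L
  if (pop_size < 15L) stop("global stage requires a population of >= 15")
  lower <- c(bounds$E1[1], bounds$tau[1])
  upper <- c(bounds$E1[2], bounds$tau[2])
  fn <- function(p) objective_z2(p[1], p[2], E0_fixed, experiments,
                                 geometry, nu,
                                 include_phase1 = include_phase1)
  res <- .with_seed(seed, {
    de <- .de_optim(fn, lower, upper, pop_size = pop_size,
                    max_iter = max_iter)
    # derivative-free local polish, box-clamped
    fn_clamped <- function(p) fn(pmin(pmax(p, lower), upper))
    pol <- optim(de$par, fn_clamped, method = "Nelder-Mead",
                 control = list(maxit = 500L, reltol = 1e-14))
    list(de = de, pol = pol)
  })
  par <- pmin(pmax(res$pol$par, lower), upper)
  at_bound <- any(abs(par - lower) < 1e-9 * (upper - lower) |
                    abs(upper - par) < 1e-9 * (upper - lower))
  if (at_bound)
    warning("fit_viscous: optimum lies on a bound; widen `bounds`?")
  list(E1 = par[1], tau = par[2], z2 = res$pol$value,
       n_evals = res$de$n_evals + res$pol$counts[["function"]],
       converged = res$pol$convergence == 0L, at_bound = at_bound)
}

#' Two-stage inverse fit of the full material triple
#'
#' Runs [fit_E0()] (stage 1, elastic end-of-hold match) and then
#' [fit_viscous()] (stage 2, weighted force-history match with `E0` frozen),
#' mirroring the sequential protocol that decouples the equilibrium modulus
#' from the decay parameters.
#'
#' @inheritParams fit_viscous
#' @param E0_bounds Pa interval for stage 1.
#' @param viscous_bounds `bounds` for stage 2 (default as in
#'   [fit_viscous()]).
#' @return An object of class `relax_fit`: `material` ([sls_material()]),
#'   `z1` (N), `z2`, `n_evals`, `converged`, `seed`.
#' @export
fit_material <- function(experiments, geometry, nu = 0.45,
                         E0_bounds = c(10, 1e5), viscous_bounds = NULL,
                         seed = 1L, include_phase1 = FALSE,
                         control = list()) {
  E0 <- fit_E0(experiments, geometry, nu, E0_bounds)
  vb <- if (is.null(viscous_bounds))
    list(E1 = c(0, 0.2 * as.numeric(E0)), tau = c(0.005, 5))
  else viscous_bounds
  vis <- fit_viscous(experiments, as.numeric(E0), geometry, nu, vb, seed,
                     include_phase1, control)
  structure(list(
    material = sls_material(as.numeric(E0), vis$E1, vis$tau, nu),
    z1 = attr(E0, "z1"), z2 = vis$z2, n_evals = vis$n_evals,
    converged = vis$converged, seed = seed), class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  m <- x$material
  cat(sprintf(
    "<relax_fit> E0 = %.6g Pa, E1 = %.6g Pa, tau = %.6g s (z1 = %.3g N, z2 = %.3g, %d evals, %s)\n",
    m$E0, m$E1, m$tau, x$z1, x$z2, x$n_evals,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
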