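#' Sampled AFM force curve
#'
#' A force curve is a data frame with columns `time_s`, `indentation_m`,
#' `force_N` and `phase` (integer labels 1 = approach ramp, 2 = hold,
#' 3 = retraction), plus a metadata attribute carrying the geometry and
#' protocol descriptors and, for synthetic curves, the generating ground
#' truth. Time must be strictly increasing and phases must appear in order;
#' within phase 2 the indentation is constant to within a declared tolerance.
#'
#' @param time Sample times (s), strictly increasing.
#' @param indentation Probe displacement into the sample (m).
#' @param force Contact force (N).
#' @param phase Integer phase label per sample, in `{1, 2, 3}`.
#' @param meta Named list of descriptors (geometry, protocol, nu, ground
#'   truth, ...). `meta$indentation_tol` (m) bounds the allowed indentation
#'   wobble during phase 2; default 1e-12 m for noiseless synthetic curves.
#' @param validate Run [validate_force_curve()] on the result (default TRUE).
#' @return An object of classes `force_curve` and `data.frame`.
#' @export
force_curve <- function(time, indentation, force, phase, meta = list(),
                        validate = TRUE) {
  df <- data.frame(time_s = as.numeric(time),
                   indentation_m = as.numeric(indentation),
                   force_N = as.numeric(force),
                   phase = as.integer(phase))
  attr(df, "meta") <- meta
  class(df) <- c("force_curve", "data.frame")
  if (validate) validate_force_curve(df)
  df
}

#' Validate a force curve
#'
#' Checks the structural invariants: required columns, strictly increasing
#' time, phases in order 1 -> 2 -> (optional 3), and constant indentation
#' during phase 2 (within `meta$indentation_tol`, default 1e-12 m).
#'
#' @param curve A [force_curve()].
#' @return The curve, invisibly; stops with a descriptive error otherwise.
#' @export
validate_force_curve <- function(curve) {
  need <- c("time_s", "indentation_m", "force_N", "phase")
  miss <- setdiff(need, names(curve))
  if (length(miss))
    stop("force curve is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(curve) < 2L) stop("force curve needs at least 2 samples")
  if (any(diff(curve$time_s) <= 0))
    stop("time_s must be strictly increasing")
  ph <- curve$phase
  if (!all(ph %in% 1:3)) stop("phase labels must be in {1, 2, 3}")
  if (any(diff(ph) < 0)) stop("phases must appear in order 1 -> 2 -> 3")
  m <- curve_meta(curve)
  tol <- if (!is.null(m$indentation_tol)) m$indentation_tol else 1e-12
  u2 <- curve$indentation_m[ph == 2L]
  if (length(u2) && diff(range(u2)) > tol)
    stop("indentation varies by ", format(diff(range(u2))),
         " m during phase 2 (tolerance ", format(tol), " m)")
  invisible(curve)
}

#' Metadata of a force curve
#' @param curve A [force_curve()].
#' @return The named metadata list.
#' @export
curve_meta <- function(curve) attr(curve, "meta")

#' @export
print.force_curve <- function(x, ...) {
  m <- curve_meta(x)
  ph <- table(factor(x$phase, levels = 1:3))
  cat(sprintf(
    "<force_curve> %d samples (phase 1: %d, 2: %d, 3: %d), t = [%g, %g] s, F_max = %g nN\n",
    nrow(x), ph[[1]], ph[[2]], ph[[3]], min(x$time_s), max(x$time_s),
    max(x$force_N) * 1e9))
  if (!is.null(m$material))
    cat(sprintf("  ground truth: E0 = %g Pa, E1 = %g Pa, tau = %g s\n",
                m$material$E0, m$material$E1, m$material$tau))
  invisible(x)
}
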