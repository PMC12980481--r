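# Curve file dialect: comma-separated values with '#'-prefixed header
# metadata lines ("# key = value"), required columns time_s, indentation_m,
# force_N, phase. Strict SI with unit-suffixed names so Pa/nN/um mixups
# cannot survive a round trip. Numbers are written with 12 significant
# digits.

.meta_keys <- c(probe_radius_m = NA, sample_kind = NA, sample_radius_m = NA,
                velocity_m_per_s = NA, trigger_force_N = NA, hold_s = NA,
                sampling_rate_hz = NA, nu = NA, E0_Pa = NA, E1_Pa = NA,
                tau_s = NA)

.fmt12 <- function(x) sprintf("%.12g", x)

#' Write a force curve to an annotated CSV file
#'
#' Header metadata lines (`# key = value`) carry the geometry, protocol and
#' any ground-truth keys; numeric values are written with 12 significant
#' digits so that a write/read round trip reproduces them exactly at that
#' precision. Unknown metadata entries are preserved.
#'
#' @param curve A [force_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  validate_force_curve(curve)
  m <- curve_meta(curve)
  kv <- list()
  if (!is.null(m$geometry)) {
    kv$probe_radius_m <- .fmt12(m$geometry$probe_radius)
    kv$sample_kind <- m$geometry$sample_kind
    if (!is.na(m$geometry$sample_radius))
      kv$sample_radius_m <- .fmt12(m$geometry$sample_radius)
  }
  if (!is.null(m$protocol)) {
    kv$velocity_m_per_s <- .fmt12(m$protocol$velocity)
    kv$trigger_force_N <- .fmt12(m$protocol$trigger_force)
    kv$hold_s <- .fmt12(m$protocol$hold_duration)
    kv$sampling_rate_hz <- .fmt12(m$protocol$sampling_rate)
  }
  if (!is.null(m$nu)) kv$nu <- .fmt12(m$nu)
  if (!is.null(m$material)) {
    kv$E0_Pa <- .fmt12(m$material$E0)
    kv$E1_Pa <- .fmt12(m$material$E1)
    kv$tau_s <- .fmt12(m$material$tau)
  }
  if (!is.null(m$noise) && m$noise$force_sigma > 0) {
    kv$force_sigma_N <- .fmt12(m$noise$force_sigma)
    kv$noise_seed <- as.character(m$noise$seed)
  }
  for (k in names(m$extra)) kv[[k]] <- as.character(m$extra[[k]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s = %s", names(kv), unlist(kv)), con)
  writeLines("time_s,indentation_m,force_N,phase", con)
  writeLines(paste(.fmt12(curve$time_s), .fmt12(curve$indentation_m),
                   .fmt12(curve$force_N), curve$phase, sep = ","), con)
  invisible(path)
}

#' Read a force curve from an annotated CSV file
#'
#' Parses the `# key = value` metadata header back into geometry, protocol
#' and ground-truth descriptors (unknown keys are kept under `meta$extra`),
#' then the sample table. Both LF and CRLF line endings are accepted. A
#' missing required column is reported by name.
#'
#' @param path File written by [write_curve()] (or any instrument export in
#'   the same dialect).
#' @return A [force_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such curve file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  is_meta <- grepl("^\\s*#", lines)
  kv <- list()
  for (ln in lines[is_meta]) {
    mm <- regmatches(ln, regexec("^\\s*#\\s*([^=]+?)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(mm) == 3L) kv[[mm[2]]] <- mm[3]
  }
  body <- lines[!is_meta & nzchar(lines)]
  if (!length(body)) stop("curve file has no data rows: ", path)
  df <- read.csv(text = paste(body, collapse = "\n"),
                 stringsAsFactors = FALSE)
  need <- c("time_s", "indentation_m", "force_N", "phase")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("curve file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))

  num <- function(k) if (is.null(kv[[k]])) NULL else as.numeric(kv[[k]])
  meta <- list()
  if (!is.null(kv$sample_kind) && !is.null(num("probe_radius_m")))
    meta$geometry <- contact_geometry(num("probe_radius_m"),
                                      kv$sample_kind,
                                      sample_radius = num("sample_radius_m"))
  if (!is.null(num("velocity_m_per_s")) &&
      !is.null(num("trigger_force_N")))
    meta$protocol <- afm_protocol(
      num("velocity_m_per_s"), num("trigger_force_N"),
      if (is.null(num("hold_s"))) 10 else num("hold_s"),
      if (is.null(num("sampling_rate_hz"))) 2000
      else num("sampling_rate_hz"))
  if (!is.null(num("nu"))) meta$nu <- num("nu")
  if (!is.null(num("E0_Pa")))
    meta$material <- sls_material(num("E0_Pa"),
                                  if (is.null(num("E1_Pa"))) 0
                                  else num("E1_Pa"),
                                  if (is.null(num("tau_s"))) 1
                                  else num("tau_s"),
                                  if (is.null(num("nu"))) 0.45
                                  else num("nu"))
  known <- c(names(.meta_keys), "force_sigma_N", "noise_seed")
  meta$extra <- kv[setdiff(names(kv), known)]
  if (!is.null(num("force_sigma_N")))
    meta$noise <- noise_model(num("force_sigma_N"),
                              seed = as.integer(kv$noise_seed))
  # measured curves wobble; accept what the file declares, else be lenient
  meta$indentation_tol <- if (!is.null(num("indentation_tol_m")))
    num("indentation_tol_m") else 1e-9
  force_curve(df$time_s, df$indentation_m, df$force_N, df$phase,
              meta = meta)
}
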