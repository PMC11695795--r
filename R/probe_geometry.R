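#' Probe specification
#'
#' Geometry and bending stiffness of a root-analogue cone penetrometer:
#' a cone on a recessed shaft, the shaft acting as a cantilever of stiffness
#' `k` when the sample orbits around the probe.
#'
#' @param cone_base_radius Cone base radius rc in mm (> 0).
#' @param semi_opening_angle Cone semi-opening angle beta_c in degrees,
#'   strictly between 0 and 90.
#' @param shaft_length Shaft length ls in mm (> 0).
#' @param bending_stiffness Cantilever bending stiffness k in N/mm (> 0).
#' @param material Label for the shaft material (e.g. "steel", "brass").
#' @param orbit_radius Radius of the imposed orbital motion in mm (>= 0);
#'   1 mm in the reference experiment.
#'
#' @return An object of class `probe_spec`.
#' @examples
#' probe_spec(bending_stiffness = 6.96, material = "steel")
#' @export
probe_spec <- function(cone_base_radius = 2.5,
                       semi_opening_angle = 15,
                       shaft_length = 45,
                       bending_stiffness = 6.96,
                       material = "steel",
                       orbit_radius = 1) {
  stopifnot(is.numeric(cone_base_radius), cone_base_radius > 0,
            is.numeric(semi_opening_angle),
            semi_opening_angle > 0, semi_opening_angle < 90,
            is.numeric(shaft_length), shaft_length > 0,
            is.numeric(bending_stiffness), bending_stiffness > 0,
            is.numeric(orbit_radius), orbit_radius >= 0)
  structure(
    list(cone_base_radius = cone_base_radius,
         semi_opening_angle = semi_opening_angle,
         shaft_length = shaft_length,
         bending_stiffness = bending_stiffness,
         material = as.character(material),
         orbit_radius = orbit_radius),
    class = "probe_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf(
    "Penetrometer probe (%s shaft)\n  rc = %.3g mm, beta_c = %.3g deg, ls = %.3g mm\n  k = %.3g N/mm, orbit radius = %.3g mm\n",
    x$material, x$cone_base_radius, x$semi_opening_angle,
    x$shaft_length, x$bending_stiffness, x$orbit_radius))
  invisible(x)
}

#' Cone base area of a probe in mm^2
#' @param probe A [probe_spec()].
#' @return Base area pi * rc^2 in mm^2.
#' @export
cone_base_area <- function(probe) {
  stopifnot(inherits(probe, "probe_spec"))
  pi * probe$cone_base_radius^2
}

deg2rad <- function(x) x * pi / 180

#' Partition a projected deflection-angle series into oscillation windows
#'
#' The orbital-motion rig imposes the oscillation period, so windows are
#' derived from the nominal circumnutation frequency and the penetration
#' speed rather than detected from the signal: with a penetration depth of
#' `d` cm the series is split into `R = f * d` contiguous windows of equal
#' duration. A stationary treatment (`f = 0`) yields zero windows.
#'
#' @param series Data frame with columns `time_min` (strictly increasing)
#'   and `angle_deg` (projected deflection angle to the vertical, degrees).
#' @param frequency Circumnutation frequency f in oscillations per cm of
#'   penetration (>= 0).
#' @param speed Penetration speed in cm/h (default 1).
#' @param depth_cm Penetration depth in cm; by default inferred from the
#'   series span (`speed * span / 60`), rounded to the nearest integer
#'   number of oscillations.
#'
#' @return An object of class `deflection_series`: the input data with an
#'   `oscillation` index column, plus attributes `R` (number of
#'   oscillations) and `frequency`.
#' @export
segment_oscillations <- function(series, frequency, speed = 1,
                                 depth_cm = NULL) {
  stopifnot(is.data.frame(series),
            all(c("time_min", "angle_deg") %in% names(series)),
            is.numeric(frequency), length(frequency) == 1, frequency >= 0,
            speed > 0)
  t <- series$time_min
  if (length(t) < 2 || any(diff(t) <= 0))
    stop("timestamps must be strictly increasing with at least two samples")
  span <- diff(range(t))
  if (is.null(depth_cm)) depth_cm <- speed * (span + diff(t)[1]) / 60
  if (frequency == 0) {
    series$oscillation <- rep(NA_integer_, nrow(series))
    return(structure(series, R = 0L, frequency = 0,
                     class = c("deflection_series", class(series))))
  }
  R <- as.integer(round(frequency * depth_cm))
  if (R < 1)
    stop("incomplete oscillation: series shorter than one full oscillation")
  # R contiguous windows of equal duration across the observed span
  edges <- min(t) + span * seq(0, 1, length.out = R + 1)
  osc <- findInterval(t, edges, rightmost.closed = TRUE)
  osc[osc > R] <- R
  if (length(unique(osc)) < R)
    stop("incomplete oscillation: some windows contain no samples")
  series$oscillation <- as.integer(osc)
  structure(series, R = R, frequency = frequency,
            class = c("deflection_series", class(series)))
}

#' Per-oscillation projected angle ranges
#'
#' Delta-alpha_i is the difference between the maximum and minimum projected
#' deflection angle within oscillation window i, in degrees.
#'
#' @param series A `deflection_series` from [segment_oscillations()].
#' @return Numeric vector of length R (degrees); length 0 for stationary.
#' @export
oscillation_angle_ranges <- function(series) {
  stopifnot(inherits(series, "deflection_series"))
  R <- attr(series, "R")
  if (R == 0) return(numeric(0))
  vapply(seq_len(R), function(i) {
    a <- series$angle_deg[series$oscillation == i]
    max(a) - min(a)
  }, numeric(1))
}

#' Average horizontal deflection of the cone
#'
#' delta_c = (ls / R) * sum_i sin(delta_alpha_i / 2), with delta_alpha_i in
#' degrees converted to radians inside the sine.
#'
#' @param series A `deflection_series`, or a numeric vector of per-oscillation
#'   angle ranges in degrees.
#' @param probe A [probe_spec()] supplying the shaft length ls.
#' @return Horizontal cone deflection delta_c in mm (0 for an all-zero
#'   series; error for a stationary series with no oscillations).
#' @export
cone_deflection <- function(series, probe) {
  stopifnot(inherits(probe, "probe_spec"))
  delta_alpha <- if (inherits(series, "deflection_series"))
    oscillation_angle_ranges(series) else series
  stopifnot(is.numeric(delta_alpha))
  if (length(delta_alpha) == 0)
    stop("no oscillations: cone deflection undefined for stationary series")
  if (any(delta_alpha < 0)) stop("negative angle range")
  mean(sin(deg2rad(delta_alpha) / 2)) * probe$shaft_length
}

#' Circumnutation amplitude
#'
#' The amplitude of the simulated circumnutation is the orbital movement
#' radius minus the horizontal cone deflection: the cone follows the orbit
#' only to the extent that the shaft does not bend away from it.
#'
#' @param delta_c Horizontal cone deflection in mm (from [cone_deflection()]).
#' @param probe A [probe_spec()] supplying the orbit radius.
#' @return Amplitude in mm, in `[0, orbit_radius]`.
#' @export
circumnutation_amplitude <- function(delta_c, probe) {
  stopifnot(inherits(probe, "probe_spec"), is.numeric(delta_c), delta_c >= 0)
  if (any(delta_c > probe$orbit_radius))
    stop("deflection exceeds orbit radius")
  probe$orbit_radius - delta_c
}

#' Axial force corrected for probe deflection
#'
#' Horizontal deflection of the probe tilts the measurement axis, so the
#' vertical force Fz underestimates the actual axial penetration force:
#' Fa = Fz * \[ (1/R) * sum_i cos(delta_alpha_i / 2) \]^-1 >= Fz.
#'
#' @param Fz Measured vertical force in N.
#' @param series A `deflection_series` or numeric vector of per-oscillation
#'   angle ranges (degrees).
#' @return Corrected axial force Fa in N.
#' @export
axial_force_correction <- function(Fz, series) {
  delta_alpha <- if (inherits(series, "deflection_series"))
    oscillation_angle_ranges(series) else series
  stopifnot(is.numeric(Fz), is.numeric(delta_alpha))
  if (length(delta_alpha) == 0)
    stop("no oscillations: correction undefined for stationary series")
  if (any(delta_alpha < 0)) stop("negative angle range")
  Fz / mean(cos(deg2rad(delta_alpha) / 2))
}

#' Relative error of force measurement caused by probe deflection
#'
#' @param Fa Corrected axial force in N.
#' @param Fz Measured vertical force in N (> 0).
#' @return Relative error (Fa - Fz) / Fz * 100, in percent (>= 0).
#' @export
relative_force_error <- function(Fa, Fz) {
  stopifnot(is.numeric(Fa), is.numeric(Fz))
  if (any(Fz <= 0)) stop("Fz must be positive")
  (Fa - Fz) / Fz * 100
}

#' Summarise a deflection series for one replicate
#'
#' Runs the full deflection chain: angle ranges, cone deflection, amplitude
#' and relative force error. Stationary series (R = 0) carry `delta_c = 0`
#' and a missing amplitude, since amplitude is meaningless without orbital
#' motion.
#'
#' @param series A `deflection_series`.
#' @param probe A [probe_spec()].
#' @return One-row data frame with `delta_c_mm`, `amplitude_mm`, `erel_pct`
#'   and `R`.
#' @export
deflection_summary <- function(series, probe) {
  stopifnot(inherits(series, "deflection_series"))
  R <- attr(series, "R")
  if (R == 0)
    return(data.frame(delta_c_mm = 0, amplitude_mm = NA_real_,
                      erel_pct = 0, R = 0L))
  da <- oscillation_angle_ranges(series)
  dc <- cone_deflection(da, probe)
  amp <- circumnutation_amplitude(dc, probe)
  erel <- relative_force_error(axial_force_correction(1, da), 1)
  data.frame(delta_c_mm = dc, amplitude_mm = amp, erel_pct = erel, R = R)
}

#' Read an angle-series CSV
#'
#' Expected columns: `time_min, angle_deg, replicate, treatment` (UTF-8,
#' '.' decimal separator, header row mandatory).
#'
#' @param path Path to the CSV file.
#' @return Data frame with the four columns.
#' @export
read_angle_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "angle_deg", "replicate", "treatment")
  if (!all(need %in% names(df)))
    stop("angle series CSV must have columns: ", paste(need, collapse = ", "))
  df
}
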