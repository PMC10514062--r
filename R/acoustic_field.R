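# Point-source acoustic field model: each piezo element is treated as a
# point source whose effect on a vessel is summarized by the source-to-vessel
# distance r and the incidence angle of the propagation line.

#' Construct a transducer
#'
#' A piezoelectric element modeled as an acoustic point source.
#'
#' @param id transducer identifier.
#' @param center 3-vector position, mm.
#' @param direction nominal propagation direction (unit 3-vector). Under the
#'   point-source convention the effective propagation direction toward a
#'   vessel is recomputed from geometry; this field stores the face normal.
#' @param frequency_khz drive frequency, kHz (default 490).
#' @param voltage_vpp peak-to-peak drive voltage, V.
#' @param active logical flag.
#' @return object of class `transducer`.
#' @export
transducer <- function(id, center, direction = c(0, 0, 1),
                       frequency_khz = 490, voltage_vpp = 15, active = FALSE) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3, all(is.finite(center)))
  direction <- unitize(as.numeric(direction))
  if (abs(vnorm(direction) - 1) > 1e-9) stop("direction must be a unit vector")
  if (frequency_khz <= 0) stop("frequency must be > 0")
  if (voltage_vpp < 0) stop("voltage must be >= 0")
  structure(list(id = id, center = center, direction = direction,
                 frequency_khz = frequency_khz, voltage_vpp = voltage_vpp,
                 active = isTRUE(active)),
            class = "transducer")
}

#' Distance from a transducer to a vessel edge (mm)
#'
#' Euclidean distance from the transducer center to the edge's arc-length
#' midpoint — the single per-vessel distance used by the attenuation model.
#' Per-point distances along the polyline are available with
#' `per_point = TRUE`.
#'
#' @param t a `transducer`.
#' @param e a `vessel_edge`.
#' @param per_point if TRUE, return distances to every polyline vertex.
#' @return distance in mm (scalar, or vector if `per_point`).
#' @export
distance_to_edge <- function(t, e, per_point = FALSE) {
  if (per_point) {
    d2 <- sweep(e$centerline, 2, t$center)
    return(sqrt(rowSums(d2^2)))
  }
  vnorm(edge_midpoint(e) - t$center)
}

#' Inverse-power attenuation model
#'
#' Swarm translation speed falls off with distance r from the source as
#' (r0/r)^n; the default exponent n = 2 is the inverse-square law for a
#' point source.
#'
#' @param r0_mm reference distance, mm (> 0).
#' @param n attenuation exponent (>= 0), default 2.
#' @return object of class `attenuation_model`.
#' @export
attenuation_model <- function(r0_mm = 2.15, n = 2) {
  if (r0_mm <= 0) stop("r0 must be > 0")
  if (n < 0) stop("exponent must be >= 0")
  structure(list(r0_mm = r0_mm, n = n), class = "attenuation_model")
}

#' Attenuation scale factor at distance r
#'
#' @param r_mm distance from the source, mm (> 0).
#' @param model an [attenuation_model()].
#' @return dimensionless factor (r0/r)^n; 1 at r = r0.
#' @export
attenuation_scale <- function(r_mm, model = attenuation_model()) {
  if (any(r_mm <= 0)) stop("attenuation undefined for r <= 0")
  (model$r0_mm / r_mm)^model$n
}

#' Fit the attenuation exponent from (distance, speed) pairs
#'
#' Least-squares slope of -log(speed) against log(distance): for data
#' following v = c / r^n the fit recovers n exactly.
#'
#' @param r_mm distances, mm.
#' @param v_um_s speeds, µm/s (any consistent unit; only the slope matters).
#' @return estimated exponent (numeric scalar).
#' @export
fit_attenuation_exponent <- function(r_mm, v_um_s) {
  stopifnot(length(r_mm) == length(v_um_s))
  if (length(unique(r_mm)) < 2) stop("need at least 2 distinct distances")
  if (any(r_mm <= 0) || any(v_um_s <= 0)) stop("distances and speeds must be > 0")
  fit <- lm(y ~ x, data = data.frame(x = log(r_mm), y = -log(v_um_s)))
  unname(coef(fit)[2])
}

#' Transmitted fraction of ultrasound through tissue
#'
#' Fraction of the reference signal surviving to depth, from two pressure
#' readings. The amplitude convention returns p/p_ref; the energy convention
#' returns (p/p_ref)^2 (acoustic intensity scales with pressure squared).
#'
#' @param p_ref_kpa reference pressure (e.g. directly beneath the skull), kPa.
#' @param p_depth_kpa pressure at the depth of interest, kPa.
#' @param convention "amplitude" or "energy".
#' @return fraction in [0, 1].
#' @export
transmitted_fraction <- function(p_ref_kpa, p_depth_kpa,
                                 convention = c("energy", "amplitude")) {
  convention <- match.arg(convention)
  if (p_ref_kpa <= 0) stop("reference pressure must be > 0")
  if (p_depth_kpa < 0 || p_depth_kpa > p_ref_kpa)
    stop("pressure at depth must lie in [0, p_ref]")
  ratio <- p_depth_kpa / p_ref_kpa
  if (convention == "energy") ratio^2 else ratio
}

#' Construct a depth-pressure profile
#'
#' Ordered samples of acoustic pressure versus depth below the skull
#' surface; queried by piecewise-linear interpolation.
#'
#' @param depth_mm strictly increasing depths, mm.
#' @param pressure_kpa non-negative pressures, kPa.
#' @return object of class `pressure_profile`.
#' @export
pressure_profile <- function(depth_mm, pressure_kpa) {
  stopifnot(length(depth_mm) == length(pressure_kpa), length(depth_mm) >= 2)
  if (any(diff(depth_mm) <= 0)) stop("depths must be strictly increasing")
  if (any(pressure_kpa < 0)) stop("pressures must be >= 0")
  structure(list(depth_mm = depth_mm, pressure_kpa = pressure_kpa),
            class = "pressure_profile")
}

#' Default in vivo depth-pressure profile
#'
#' Piecewise-linear profile through the measured anchor points for the mouse
#' preparation: ~100 kPa directly beneath the skull, ~85 kPa just below the
#' pia (placed at 0.1 mm), 80 and 70 kPa bracketing the 0.5-0.6 mm
#' two-photon imaging band, tapering linearly to the 16 mm measurement
#' extent. Values between anchors are interpolations, not measurements.
#'
#' @return a `pressure_profile`.
#' @export
default_invivo_pressure_profile <- function() {
  pressure_profile(depth_mm = c(0, 0.1, 0.5, 0.6, 16),
                   pressure_kpa = c(100, 85, 80, 70, 5))
}

#' Skull thickness constant for the in vivo preset (mm)
#' @return 2 (mm), geometry bookkeeping only.
#' @export
skull_thickness_mm <- function() 2

#' Interpolate a pressure profile at a depth
#'
#' @param profile a [pressure_profile()].
#' @param depth_mm query depth, mm; must lie within the sampled range
#'   (no extrapolation).
#' @return pressure in kPa.
#' @export
pressure_at_depth <- function(profile, depth_mm) {
  rng <- range(profile$depth_mm)
  if (any(depth_mm < rng[1]) || any(depth_mm > rng[2]))
    stop(sprintf("depth outside sampled range [%g, %g] mm", rng[1], rng[2]))
  approx(profile$depth_mm, profile$pressure_kpa, xout = depth_mm)$y
}

#' Export a pressure profile as CSV
#' @param profile a `pressure_profile`.
#' @param path output path; columns depth_mm, pressure_kPa.
#' @export
write_pressure_profile <- function(profile, path) {
  write.csv(data.frame(depth_mm = profile$depth_mm,
                       pressure_kPa = profile$pressure_kpa),
            path, row.names = FALSE)
  invisible(path)
}
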