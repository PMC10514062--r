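# Per-vessel response model: incidence angle, direction of motion, predicted
# swarm speed, and color-coded vasculature maps for each transducer.

R_MIN_MM <- 0.1  # near-field guard: distances below this raise an error

#' Acoustic calibration preset
#'
#' Anchors the speed model v = v0 * g(alpha) * (r0/r)^n * (V/V0)^q.
#' `v0` is the speed at head-on incidence (alpha = 0) at the reference
#' distance r0 and reference drive V0.
#'
#' @param scenario one of "invitro_cylinder", "invitro_distance", "invivo".
#' @param v0_um_s reference speed, µm/s.
#' @param r0_mm reference distance, mm.
#' @param v0_vpp reference drive voltage, V peak-to-peak.
#' @param n attenuation exponent.
#' @param q voltage exponent (radiation force scales with pressure squared,
#'   pressure with drive voltage, hence default 2).
#' @param angular_law "mixed_cosine" (g = (1 + 2 cos^2 a)/3) or
#'   "cosine_power" (g = cos^2 a, floored at 0).
#' @return object of class `acoustic_calibration`.
#' @export
acoustic_calibration <- function(scenario = c("invitro_cylinder",
                                              "invitro_distance", "invivo"),
                                 v0_um_s = NULL, r0_mm = NULL, v0_vpp = NULL,
                                 n = 2, q = 2,
                                 angular_law = c("mixed_cosine", "cosine_power")) {
  scenario <- match.arg(scenario)
  angular_law <- match.arg(angular_law)
  defaults <- switch(scenario,
    # straight-channel cylinder: 1.2 mm/s head-on at the nearest printed
    # channel distance, 15 Vpp drive
    invitro_cylinder = list(v0 = 1200, r0 = 2.15, V0 = 15),
    # four-distance attenuation devices: 32.2 um/s at 2.15 mm, 2 Vpp drive
    invitro_distance = list(v0 = 32.2, r0 = 2.15, V0 = 2),
    # mouse cranial window: slower than microfluidics; anchored to the
    # fastest in vivo channel speed scale at the window-center distance
    invivo = list(v0 = 800, r0 = 5, V0 = 35))
  out <- structure(list(
    scenario = scenario,
    v0_um_s = if (is.null(v0_um_s)) defaults$v0 else v0_um_s,
    r0_mm = if (is.null(r0_mm)) defaults$r0 else r0_mm,
    v0_vpp = if (is.null(v0_vpp)) defaults$V0 else v0_vpp,
    n = n, q = q, angular_law = angular_law),
    class = "acoustic_calibration")
  if (out$v0_um_s <= 0 || out$r0_mm <= 0 || out$v0_vpp <= 0)
    stop("calibration anchors must be positive")
  if (n < 0 || q < 0) stop("exponents must be >= 0")
  out
}

#' Propagation unit vector from a transducer toward an edge midpoint
#'
#' Point-source convention: the wave reaching a vessel travels along the
#' line from the source to the vessel's midpoint. Set
#' `convention = "face_normal"` to use the transducer's stored direction.
#'
#' @param t a `transducer`.
#' @param e a `vessel_edge`.
#' @param convention "point_source" or "face_normal".
#' @return unit 3-vector.
#' @export
propagation_vector <- function(t, e, convention = c("point_source", "face_normal")) {
  convention <- match.arg(convention)
  if (convention == "face_normal") return(t$direction)
  mid <- edge_midpoint(e)
  d <- mid - t$center
  if (vnorm(d) < .Machine$double.eps)
    stop("transducer coincides with edge midpoint; propagation undefined")
  unitize(d)
}

#' Incidence angle between wave propagation and vessel axis (degrees)
#'
#' alpha = arccos(|u . w|) where u is the propagation unit vector toward the
#' edge midpoint and w the endpoint-to-endpoint edge axis; alpha lies in
#' [0, 90]: 0 = head-on (fastest transport), 90 = vessel perpendicular to
#' the sound path.
#'
#' @inheritParams propagation_vector
#' @return angle in degrees, in [0, 90].
#' @export
incidence_angle <- function(t, e, convention = "point_source") {
  u <- propagation_vector(t, e, convention)
  w <- edge_axis(e)
  cang <- abs(sum(u * w))
  cang <- min(max(cang, 0), 1)
  acos(cang) * 180 / pi
}

#' Predicted direction of swarm motion along an edge
#'
#' Microrobots move away from the transducer in the direction of wave
#' propagation: the sign of the projection of the propagation vector onto
#' the edge axis, +1 along the polyline orientation, -1 against it, 0 when
#' the projection magnitude falls below `tol` (vessel exactly orthogonal to
#' the sound path; transport is then symmetric/bidirectional).
#'
#' @inheritParams propagation_vector
#' @param tol projection tolerance for the orthogonal case.
#' @return -1, 0, or +1.
#' @export
direction_sign <- function(t, e, convention = "point_source", tol = 1e-9) {
  u <- propagation_vector(t, e, convention)
  w <- edge_axis(e)
  proj <- sum(u * w)
  if (abs(proj) < tol) return(0L)
  as.integer(sign(proj))
}

#' Angular speed scale g(alpha)
#'
#' Dimensionless factor multiplying the head-on speed. The default
#' mixed-cosine law g(alpha) = (1 + 2 cos^2 alpha)/3 is exact at both
#' printed endpoints — g(0) = 1 and g(90) = 1/3, mapping a 1.2 mm/s head-on
#' speed to 0.4 mm/s for a parallel channel — and decreases monotonically
#' in between.
#'
#' @param alpha_deg incidence angle in degrees, in [0, 90].
#' @param law "mixed_cosine" or "cosine_power".
#' @return factor in [1/3, 1] (mixed_cosine) or [0, 1] (cosine_power).
#' @export
angular_speed_scale <- function(alpha_deg, law = c("mixed_cosine", "cosine_power")) {
  law <- match.arg(law)
  if (any(alpha_deg < 0 | alpha_deg > 90))
    stop("incidence angle must lie in [0, 90] degrees")
  ca <- cos(alpha_deg * pi / 180)
  switch(law,
         mixed_cosine = (1 + 2 * ca^2) / 3,
         cosine_power = ca^2)
}

#' Predicted swarm translation speed for a vessel (µm/s)
#'
#' v = v0 * g(alpha) * (r0/r)^n * (V/V0)^q, combining the angular response,
#' inverse-power distance attenuation, and quadratic voltage scaling.
#'
#' @param e a `vessel_edge`.
#' @param t a `transducer`.
#' @param calib an [acoustic_calibration()].
#' @param voltage_vpp drive voltage override; defaults to the transducer's.
#' @return predicted speed, µm/s.
#' @export
predict_speed <- function(e, t, calib = acoustic_calibration(),
                          voltage_vpp = NULL) {
  r <- distance_to_edge(t, e)
  if (r <= R_MIN_MM)
    stop(sprintf("distance %.3g mm below near-field guard %.3g mm", r, R_MIN_MM))
  a <- incidence_angle(t, e)
  V <- if (is.null(voltage_vpp)) t$voltage_vpp else voltage_vpp
  calib$v0_um_s *
    angular_speed_scale(a, calib$angular_law) *
    attenuation_scale(r, attenuation_model(calib$r0_mm, calib$n)) *
    (V / calib$v0_vpp)^calib$q
}

#' Trajectory azimuth from transducer azimuth (degrees)
#'
#' On the frustum rim the swarm moves radially away from the active
#' element: the trajectory azimuth beta is the transducer position azimuth
#' shifted by 180 degrees (both measured clockwise from the x = 0 line).
#'
#' @param alpha_pos_deg transducer azimuth in [0, 360).
#' @return beta in [0, 360).
#' @export
trajectory_azimuth <- function(alpha_pos_deg) {
  if (any(alpha_pos_deg < 0 | alpha_pos_deg >= 360))
    stop("azimuth must lie in [0, 360)")
  (alpha_pos_deg + 180) %% 360
}

#' Annotate every edge of a graph for one transducer
#'
#' The "vectors of relative angles and distances": one row per edge with
#' the incidence angle, source distance, predicted speed, direction sign,
#' and an efficiency flag for near-head-on vessels where swarm formation
#' and navigation are expected to be most efficient.
#'
#' @param g a `vessel_graph`.
#' @param t a `transducer`.
#' @param calib an [acoustic_calibration()].
#' @param efficient_alpha_deg cutoff below which an edge is flagged
#'   efficient (default 30 degrees).
#' @return data.frame with columns edge_id, transducer_id, alpha_deg, r_mm,
#'   v_um_s, direction, efficient.
#' @export
annotate_graph <- function(g, t, calib = acoustic_calibration(),
                           efficient_alpha_deg = 30) {
  if (!length(g$edges)) stop("empty graph")
  rows <- lapply(unname(g$edges), function(e) {
    data.frame(edge_id = as.character(e$id),
               transducer_id = as.character(t$id),
               alpha_deg = incidence_angle(t, e),
               r_mm = distance_to_edge(t, e),
               v_um_s = predict_speed(e, t, calib),
               direction = direction_sign(t, e),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$efficient <- out$alpha_deg <= efficient_alpha_deg
  out
}

#' Write annotations as CSV
#' @param ann data.frame from [annotate_graph()].
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  write.csv(ann, path, row.names = FALSE)
  invisible(path)
}

#' Render a color-coded vasculature map
#'
#' Draws every edge of the graph colored by predicted speed, source
#' distance, or direction, with a colorbar — the per-transducer map of
#' which vessels respond fastest. For `color_by = "distance"` the scale is
#' reversed so the nearest vessel takes the fast-velocity end of the
#' colormap (closer to the source means higher expected speed).
#'
#' @param g a `vessel_graph`.
#' @param ann annotations for `g` from [annotate_graph()] (every edge must
#'   be present).
#' @param color_by "speed", "distance", or "direction".
#' @param path output PNG path.
#' @param width,height raster dimensions in pixels.
#' @param lwd line width for vessels.
#' @return invisibly, the raster array re-read from `path`.
#' @export
render_map <- function(g, ann, color_by = c("speed", "distance", "direction"),
                       path, width = 480, height = 480, lwd = 4) {
  color_by <- match.arg(color_by)
  ids <- vapply(g$edges, function(e) as.character(e$id), character(1))
  if (!all(ids %in% ann$edge_id)) stop("missing annotation for some edges")
  ann <- ann[match(ids, ann$edge_id), ]
  pal <- grDevices::hcl.colors(256, "Viridis")
  if (color_by == "direction") {
    cols <- c("#D55E00", "#999999", "#0072B2")[ann$direction + 2L]
    labs <- c("-1", "0", "+1")
  } else {
    val <- if (color_by == "speed") ann$v_um_s else -ann$r_mm  # reversed scale
    rngv <- range(val)
    idx <- if (diff(rngv) > 0) {
      1L + as.integer(round(255 * (val - rngv[1]) / diff(rngv)))
    } else rep(128L, length(val))
    cols <- pal[idx]
  }
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(4, 4, 2, 6))
  xr <- range(unlist(lapply(g$edges, function(e) e$centerline[, 1])))
  yr <- range(unlist(lapply(g$edges, function(e) e$centerline[, 2])))
  graphics::plot(NA, xlim = xr, ylim = yr, asp = 1, xlab = "x (mm)",
                 ylab = "y (mm)", main = sprintf("map: %s", color_by))
  for (i in seq_along(g$edges)) {
    cl <- g$edges[[i]]$centerline
    graphics::lines(cl[, 1], cl[, 2], col = cols[i], lwd = lwd)
  }
  # colorbar / legend
  if (color_by == "direction") {
    graphics::legend("topright", inset = c(-0.25, 0), xpd = TRUE,
                     legend = labs, col = c("#D55E00", "#999999", "#0072B2"),
                     lwd = lwd, title = "sign", bty = "n")
  } else {
    usr <- graphics::par("usr")
    xl <- usr[2] + 0.02 * diff(usr[1:2]); xr2 <- usr[2] + 0.06 * diff(usr[1:2])
    ys <- seq(usr[3], usr[4], length.out = 257)
    graphics::rect(xl, ys[-257], xr2, ys[-1], col = pal, border = NA, xpd = TRUE)
    lab <- if (color_by == "speed") "Vmin -> Vmax (um/s)" else "far -> near"
    graphics::text(xr2, usr[4], lab, adj = c(0, -0.5), xpd = TRUE, cex = 0.7)
  }
  grDevices::dev.off()
  on.exit(NULL, add = FALSE)
  invisible(png::readPNG(path))
}
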