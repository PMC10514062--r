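# Stochastic swarm dynamics: voltage-gated formation, logistic growth to a
# saturation diameter, volume-conserving merging, Poiseuille drag, and the
# radiation-force balance that yields upstream transport at vessel walls.

#' Dynamics parameters
#'
#' @param preset "invivo" (blood, 35 V_PP working point),
#'   "growth44" (in vivo growth scenario at 44 V_PP whose logistic
#'   saturation is the observed 40 µm cap), or "invitro" (water-filled
#'   channels).
#' @param v_min_vpp formation threshold voltage (no swarms below), V_PP.
#' @param size_slope_um_per_vpp slope c of the size-voltage law, µm/V_PP.
#' @param d_cap_um diameter cap, µm.
#' @param growth_rate_per_s logistic growth rate k, 1/s.
#' @param u50_mm_s formation-sigmoid midpoint flow, mm/s.
#' @param width_mm_s formation-sigmoid width, mm/s.
#' @param responder_fraction fraction of injected bubbles that respond.
#' @param viscosity_pa_s dynamic viscosity of the carrier fluid, Pa s.
#' @param bubble_range_um individual bubble diameter band, µm.
#' @param kappa directional-noise concentration (von Mises).
#' @param sigma_log log-scale sd of the swarm-size sampler.
#' @param saturation "equilibrium" (d_sat from the size-voltage law) or
#'   "cap" (d_sat = d_cap; the growth scenario tracking the largest
#'   observed swarms).
#' @param attach_flow_max_mm_s centerline-flow ceiling for wall attachment:
#'   above it shear sweeps clusters off the wall, so newly formed swarms in
#'   fast (arterial) vessels stay free-flowing and advect.
#' @param density_kg_m3 carrier fluid density (buoyancy), kg/m^3.
#' @return object of class `dynamics_params`.
#' @export
dynamics_params <- function(preset = c("invivo", "growth44", "invitro"),
                            v_min_vpp = 20, size_slope_um_per_vpp = 0.25,
                            d_cap_um = 40, growth_rate_per_s = 0.05,
                            u50_mm_s = 5, width_mm_s = 2,
                            responder_fraction = 0.03,
                            viscosity_pa_s = NULL,
                            bubble_range_um = c(1.1, 1.4),
                            kappa = 4, sigma_log = 0.5,
                            saturation = NULL,
                            attach_flow_max_mm_s = 4,
                            density_kg_m3 = 998) {
  preset <- match.arg(preset)
  if (is.null(viscosity_pa_s))
    viscosity_pa_s <- if (preset == "invitro") 1e-3 else 3e-3
  if (is.null(saturation))
    saturation <- if (preset == "growth44") "cap" else "equilibrium"
  saturation <- match.arg(saturation, c("equilibrium", "cap"))
  stopifnot(v_min_vpp > 0, d_cap_um > 0, kappa >= 0,
            responder_fraction > 0, responder_fraction <= 1)
  structure(list(preset = preset, v_min_vpp = v_min_vpp,
                 size_slope_um_per_vpp = size_slope_um_per_vpp,
                 d_cap_um = d_cap_um, growth_rate_per_s = growth_rate_per_s,
                 u50_mm_s = u50_mm_s, width_mm_s = width_mm_s,
                 responder_fraction = responder_fraction,
                 viscosity_pa_s = viscosity_pa_s,
                 bubble_range_um = bubble_range_um,
                 kappa = kappa, sigma_log = sigma_log,
                 saturation = saturation,
                 attach_flow_max_mm_s = attach_flow_max_mm_s,
                 density_kg_m3 = density_kg_m3),
            class = "dynamics_params")
}

#' Swarm state
#'
#' @param id integer id.
#' @param edge_id id of the edge the swarm sits on.
#' @param s_um arc-length position along the edge, µm.
#' @param d_um cluster diameter, µm (equivalent circle).
#' @param n bubble count (>= 1).
#' @param wall_attached logical.
#' @param t_s simulation time, s.
#' @return object of class `swarm_state`.
#' @export
swarm_state <- function(id, edge_id, s_um, d_um, n = 1L,
                        wall_attached = TRUE, t_s = 0) {
  stopifnot(d_um > 0, n >= 1, s_um >= 0)
  structure(list(id = id, edge_id = edge_id, s_um = s_um, d_um = d_um,
                 n = as.integer(n), wall_attached = isTRUE(wall_attached),
                 t_s = t_s),
            class = "swarm_state")
}

#' Equilibrium (median) swarm diameter at a drive voltage
#'
#' 0 below the formation threshold; otherwise min(c V, d_cap). The linear
#' law reproduces the observed halving of mean cluster size when the drive
#' drops from 40 to 20 V_PP.
#'
#' @param v_vpp drive voltage, V_PP.
#' @param p a [dynamics_params()].
#' @return diameter in µm.
#' @export
equilibrium_diameter <- function(v_vpp, p = dynamics_params()) {
  ifelse(v_vpp < p$v_min_vpp, 0,
         pmin(p$size_slope_um_per_vpp * v_vpp, p$d_cap_um))
}

#' One logistic growth update of a swarm
#'
#' d <- d + k d (1 - d/d_sat) dt. The saturation diameter defaults to
#' max(equilibrium diameter, current d); with `p$saturation == "cap"` (the
#' growth scenario) it is the 40 µm cap. Bubble count grows with the added
#' volume.
#'
#' @param state a [swarm_state()].
#' @param dt_s time step, s (> 0).
#' @param v_vpp drive voltage (transducer must be active).
#' @param p a [dynamics_params()].
#' @param d_sat_um optional saturation override, µm.
#' @return updated `swarm_state`.
#' @export
grow_swarm <- function(state, dt_s, v_vpp, p = dynamics_params(), d_sat_um = NULL) {
  stopifnot(dt_s > 0)
  if (is.null(d_sat_um)) {
    d_sat_um <- if (p$saturation == "cap") p$d_cap_um
                else max(equilibrium_diameter(v_vpp, p), state$d_um)
  }
  d0 <- state$d_um
  d1 <- d0 + p$growth_rate_per_s * d0 * (1 - d0 / d_sat_um) * dt_s
  d1 <- min(max(d1, 0.5 * min(p$bubble_range_um)), p$d_cap_um)
  state$d_um <- d1
  state$n <- max(1L, as.integer(round(state$n * (d1 / d0)^3)))
  state$t_s <- state$t_s + dt_s
  state
}

#' Integrate logistic growth to steady state
#'
#' Repeated [grow_swarm()] updates until the per-step diameter change drops
#' below `tol_um`; returns the terminal diameter.
#'
#' @param v_vpp drive voltage.
#' @param p a [dynamics_params()].
#' @param d0_um initial seed diameter, µm.
#' @param dt_s step, s.
#' @param tol_um per-step convergence tolerance, µm.
#' @param max_steps iteration cap.
#' @return terminal diameter, µm.
#' @export
grow_to_saturation <- function(v_vpp, p = dynamics_params("growth44"),
                               d0_um = 2, dt_s = 5, tol_um = 0.01,
                               max_steps = 1e5) {
  st <- swarm_state(1L, "e", 0, d0_um)
  for (i in seq_len(max_steps)) {
    d_prev <- st$d_um
    st <- grow_swarm(st, dt_s, v_vpp, p)
    if (abs(st$d_um - d_prev) < tol_um) break
  }
  st$d_um
}

#' Closed-form logistic growth solution
#'
#' d(t) = d_sat / (1 + ((d_sat - d0)/d0) exp(-k t)) — the analytic solution
#' the discrete update converges to as dt -> 0.
#'
#' @param t_s time, s.
#' @param d0_um initial diameter, µm.
#' @param d_sat_um saturation diameter, µm.
#' @param k_per_s growth rate, 1/s.
#' @return diameter at t, µm.
#' @export
logistic_diameter <- function(t_s, d0_um, d_sat_um, k_per_s) {
  d_sat_um / (1 + ((d_sat_um - d0_um) / d0_um) * exp(-k_per_s * t_s))
}

#' Probability that a swarm forms on an edge
#'
#' Zero below the threshold voltage; otherwise a sigmoid decreasing in the
#' local flow speed (midpoint u50, width w), scaled by responder
#' availability relative to the nominal 3% responding fraction. Slow
#' venous flow therefore favors formation.
#'
#' @param u_flow_mm_s centerline flow speed, mm/s (>= 0).
#' @param v_vpp drive voltage.
#' @param p a [dynamics_params()].
#' @return probability in [0, 1].
#' @export
formation_probability <- function(u_flow_mm_s, v_vpp, p = dynamics_params()) {
  stopifnot(all(u_flow_mm_s >= 0), length(v_vpp) == 1)
  if (v_vpp < p$v_min_vpp) return(rep(0, length(u_flow_mm_s)))
  avail <- min(1, p$responder_fraction / 0.03)
  avail * plogis((p$u50_mm_s - u_flow_mm_s) / p$width_mm_s)
}

#' Sample a swarm diameter at a drive voltage
#'
#' Lognormal with median equal to the equilibrium diameter, truncated to
#' [1, d_cap] µm (the observed size range). At 35 V_PP the default
#' parameters put the majority of draws in the 3-15 µm band.
#'
#' @param n number of draws.
#' @param v_vpp drive voltage (>= formation threshold).
#' @param p a [dynamics_params()].
#' @param seed RNG seed.
#' @return diameters, µm.
#' @export
sample_swarm_diameter <- function(n, v_vpp, p = dynamics_params(), seed = 1L) {
  if (v_vpp < p$v_min_vpp) stop("no swarm formation below the threshold voltage")
  med <- equilibrium_diameter(v_vpp, p)
  with_seed(seed, {
    lo <- 1; hi <- p$d_cap_um
    out <- numeric(n)
    need <- seq_len(n)
    while (length(need)) {  # rejection sampling on the truncation band
      draw <- rlnorm(length(need), log(med), p$sigma_log)
      ok <- draw >= lo & draw <= hi
      out[need[ok]] <- draw[ok]
      need <- need[!ok]
      if (p$sigma_log == 0) { out[need] <- min(max(med, lo), hi); need <- integer(0) }
    }
    out
  })
}

#' Merge two swarms on the same edge
#'
#' Bjerknes-type aggregation as threshold capture: bubble counts add,
#' volume is conserved (d = (d_a^3 + d_b^3)^(1/3), capped), and the merged
#' swarm sits at the volume-weighted mean position.
#'
#' @param a,b `swarm_state` objects on the same edge, within the capture
#'   radius 2 (d_a + d_b).
#' @param p a [dynamics_params()].
#' @param check_capture enforce the capture-radius precondition.
#' @return merged `swarm_state` (keeps `a`'s id).
#' @export
merge_swarms <- function(a, b, p = dynamics_params(), check_capture = FALSE) {
  if (!identical(a$edge_id, b$edge_id)) stop("swarms on different edges")
  if (check_capture && abs(a$s_um - b$s_um) > capture_radius_um(a, b))
    stop("swarms outside capture radius")
  va <- a$d_um^3; vb <- b$d_um^3
  a$n <- a$n + b$n
  a$d_um <- min((va + vb)^(1 / 3), p$d_cap_um)
  a$s_um <- (a$s_um * va + b$s_um * vb) / (va + vb)
  a$wall_attached <- a$wall_attached || b$wall_attached
  a
}

#' Capture radius for merging (µm)
#' @param a,b `swarm_state` objects.
#' @return 2 x (d_a + d_b), µm.
#' @export
capture_radius_um <- function(a, b) 2 * (a$d_um + b$d_um)

#' Poiseuille flow speed at an offset from the vessel wall
#'
#' u(y) = u_centerline (1 - (1 - 2 y / D)^2): zero at the wall (no slip),
#' maximal at the centerline. Wall-attached swarms sample the slow near-wall
#' fluid, which is what makes upstream force balance winnable.
#'
#' @param e a `vessel_edge` (diameter and centerline speed).
#' @param wall_offset_um distance from the wall, µm, in [0, D/2].
#' @return local flow speed, mm/s.
#' @export
local_flow_speed <- function(e, wall_offset_um) {
  D <- e$diameter_um
  if (wall_offset_um < 0 || wall_offset_um > D / 2)
    stop("wall offset must lie in [0, radius]")
  e$flow_mm_s * (1 - (1 - 2 * wall_offset_um / D)^2)
}

#' Calibrate the radiation-force coefficient to the upstream anchor
#'
#' The coefficient C in F_rad = C (pi/6) d^3 g(alpha) (r0/r)^n (V/V0)^q is
#' a per-preset calibration, fixed so the reference in vivo scenario — a
#' wall-attached 10 µm swarm in a 30 µm venule against 10 mm/s centerline
#' flow at 35 V_PP, head-on at the reference distance — nets the headline
#' 1.5 µm/s upstream speed. Anchoring, not prediction.
#'
#' @param p a [dynamics_params()].
#' @param anchor list: d_um, vessel_d_um, u_centerline_mm_s, upstream_um_s.
#' @return C, N/m^3 at reference field conditions.
#' @export
radiation_force_coefficient <- function(p = dynamics_params(),
                                        anchor = list(d_um = 10,
                                                      vessel_d_um = 30,
                                                      u_centerline_mm_s = 10,
                                                      upstream_um_s = 1.5)) {
  d <- anchor$d_um * 1e-6
  offset <- anchor$d_um / 2  # wall-attached: center one radius off the wall
  u_local <- anchor$u_centerline_mm_s *
    (1 - (1 - 2 * offset / anchor$vessel_d_um)^2) * 1e-3       # m/s
  v_rad <- anchor$upstream_um_s * 1e-6 + u_local               # m/s
  f_rad <- 3 * pi * p$viscosity_pa_s * d * v_rad               # N
  f_rad / ((pi / 6) * d^3)                                     # N/m^3
}

#' Net signed swarm velocity along an edge (µm/s)
#'
#' Force balance at low Reynolds number: the swarm is advected at the local
#' Poiseuille speed (sampled one swarm radius off the wall when attached,
#' at the centerline when free) plus the radiation-force slip
#' F_rad / (3 pi mu d) along the predicted direction of motion. Positive
#' values run along the polyline orientation.
#'
#' @param state a [swarm_state()].
#' @param e the `vessel_edge` the swarm is on.
#' @param t the active `transducer`.
#' @param calib an [acoustic_calibration()].
#' @param p a [dynamics_params()].
#' @param coefficient radiation-force coefficient; defaults to the
#'   calibrated [radiation_force_coefficient()].
#' @param voltage_vpp drive voltage override.
#' @param components if TRUE, return a list with the net velocity and its
#'   radiation (`v_rad_um_s`, unsigned) and advection (`u_flow_um_s`,
#'   signed) parts.
#' @return signed velocity along the edge, µm/s (or the component list).
#' @export
net_swarm_velocity <- function(state, e, t, calib = acoustic_calibration("invivo"),
                               p = dynamics_params(), coefficient = NULL,
                               voltage_vpp = NULL, components = FALSE) {
  r <- distance_to_edge(t, e)
  if (r <= R_MIN_MM) stop("distance below near-field guard")
  if (is.null(coefficient)) coefficient <- radiation_force_coefficient(p)
  V <- if (is.null(voltage_vpp)) t$voltage_vpp else voltage_vpp
  d <- state$d_um * 1e-6
  a <- incidence_angle(t, e)
  field <- angular_speed_scale(a, calib$angular_law) *
    attenuation_scale(r, attenuation_model(calib$r0_mm, calib$n)) *
    (V / calib$v0_vpp)^calib$q
  f_rad <- coefficient * (pi / 6) * d^3 * field
  v_rad <- f_rad / (3 * pi * p$viscosity_pa_s * d)             # m/s
  dir <- direction_sign(t, e)
  offset <- if (state$wall_attached) state$d_um / 2 else e$diameter_um / 2
  offset <- min(offset, e$diameter_um / 2)
  u_local <- local_flow_speed(e, offset) * 1e-3                # m/s
  v_net <- (dir * v_rad + e$flow_sign * u_local) * 1e6
  if (components) {
    return(list(v_net_um_s = v_net, v_rad_um_s = v_rad * 1e6,
                u_flow_um_s = e$flow_sign * u_local * 1e6, direction = dir))
  }
  v_net
}

#' Net vertical velocity of a bubble/swarm in a vertical channel (µm/s)
#'
#' Balance of downward radiation force against buoyancy of the gas-filled
#' sphere: (F_rad - F_buoyancy) / (3 pi mu d). Positive = downward. With
#' ultrasound off the result is minus the Stokes rise speed
#' rho g d^2 / (18 mu). The coefficient is anchored so a 1.25 µm bubble at
#' 490 kHz / 10 V_PP propels downward at 165.1 µm/s.
#'
#' @param d_um bubble or swarm diameter, µm.
#' @param v_vpp drive voltage.
#' @param p a [dynamics_params()] (use the "invitro" preset: water).
#' @param anchor list d_um, v_vpp, down_um_s defining the calibration.
#' @return signed vertical velocity, µm/s (+ = downward).
#' @export
vertical_net_velocity <- function(d_um, v_vpp, p = dynamics_params("invitro"),
                                  anchor = list(d_um = 1.25, v_vpp = 10,
                                                down_um_s = 165.1)) {
  g0 <- 9.81
  buoy <- function(d) p$density_kg_m3 * g0 * (pi / 6) * d^3    # N, d in m
  da <- anchor$d_um * 1e-6
  f_rad_anchor <- 3 * pi * p$viscosity_pa_s * da * anchor$down_um_s * 1e-6 +
    buoy(da)
  c_vert <- f_rad_anchor / ((pi / 6) * da^3)                   # N/m^3 at V0
  d <- d_um * 1e-6
  f_rad <- c_vert * (pi / 6) * d^3 * (v_vpp / anchor$v_vpp)^2
  (f_rad - buoy(d)) / (3 * pi * p$viscosity_pa_s * d) * 1e6
}

# ---- von Mises directional noise ----------------------------------------

#' Sample from a von Mises distribution (mean 0)
#'
#' Best-Fisher rejection sampler; kappa = 0 reduces to the uniform circle.
#'
#' @param n number of draws.
#' @param kappa concentration (>= 0).
#' @return angles in radians, in (-pi, pi].
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-9) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(max(min(f, 1), -1))
        break
      }
    }
  }
  out
}

#' Fraction of swarms moving away from the transducer
#'
#' Simulates `n_swarms` in the straight-channel (cylinder) preset: each
#' swarm's heading is the away-from-source direction perturbed by von Mises
#' noise of concentration kappa; the returned fraction is the share whose
#' net displacement has positive dot product with the propagation
#' direction.
#'
#' @param n_swarms number of swarms (>= 1).
#' @param kappa directional-noise concentration (default 4).
#' @param seed RNG seed.
#' @param duration_s displacement integration time, s.
#' @param calib calibration for per-swarm speed.
#' @return list: fraction (scalar), displacement (n x 2 matrix, mm, in the
#'   propagation/transverse frame).
#' @export
away_fraction_experiment <- function(n_swarms, kappa = 4, seed = 42,
                                     duration_s = 1,
                                     calib = acoustic_calibration("invitro_cylinder")) {
  stopifnot(n_swarms >= 1)
  g <- generate_network(phantom_spec("cylinder", seed = 1L))
  td <- place_transducers("cylinder")[[3]]  # a green side element
  e <- g$edges[[1]]
  v <- predict_speed(e, td, calib)          # µm/s at this geometry
  with_seed(seed, {
    theta <- rvonmises(n_swarms, kappa)
    disp <- cbind(cos(theta), sin(theta)) * v * duration_s / 1000  # mm
    list(fraction = mean(disp[, 1] > 0), displacement = disp)
  })
}

# ---- world stepper -------------------------------------------------------

#' Initialize a simulation world
#'
#' @param g a `vessel_graph` (flows assigned).
#' @param transducers list of `transducer`.
#' @param calib an [acoustic_calibration()].
#' @param p a [dynamics_params()].
#' @return object of class `sim_world`.
#' @export
sim_world <- function(g, transducers, calib = acoustic_calibration("invivo"),
                      p = dynamics_params()) {
  structure(list(graph = g, transducers = transducers, calib = calib,
                 params = p, swarms = list(), time_s = 0, next_id = 1L,
                 coefficient = radiation_force_coefficient(p)),
            class = "sim_world")
}

empty_events <- function() {
  data.frame(t = numeric(0), event = character(0), swarm_id = integer(0),
             edge_id = character(0), s_um = numeric(0), d_um = numeric(0),
             n = integer(0), v_um_s = numeric(0), stringsAsFactors = FALSE)
}

event_row <- function(t, event, sw, v = NA_real_) {
  data.frame(t = t, event = event, swarm_id = sw$id,
             edge_id = as.character(sw$edge_id), s_um = sw$s_um,
             d_um = sw$d_um, n = sw$n, v_um_s = v, stringsAsFactors = FALSE)
}

#' Advance the simulation world by one step
#'
#' With an active transducer: seeded formation draws per edge (formation
#' hazard from the local flow and drive voltage), logistic growth, motion
#' by the net force balance with edge-to-edge handoff at nodes (the swarm
#' continues onto the connected edge maximizing projected velocity), and
#' capture-radius merging. With `active_id = NULL` every swarm disassembles
#' into the bloodstream within the step.
#'
#' A "navigate" event is logged when a swarm's net motion follows the
#' radiation-force direction (motion independent of the flow stream);
#' flow-dominated motion logs "advect".
#'
#' @param world a [sim_world()].
#' @param dt_s time step, s (> 0).
#' @param active_id id of the single active transducer, or NULL.
#' @param seed RNG seed for this step (determinism contract).
#' @return list(world, events): updated world and the step's event log.
#' @export
step_simulation <- function(world, dt_s, active_id, seed) {
  stopifnot(dt_s > 0)
  ev <- empty_events()
  t_now <- world$time_s + dt_s
  if (is.null(active_id)) {
    for (sw in world$swarms) {
      sw$t_s <- t_now
      ev <- rbind(ev, event_row(t_now, "disassemble", sw))
    }
    world$swarms <- list()
    world$time_s <- t_now
    return(list(world = world, events = ev))
  }
  td <- NULL
  for (tt in world$transducers) if (identical(as.character(tt$id),
                                             as.character(active_id))) td <- tt
  if (is.null(td)) stop(sprintf("unknown transducer '%s'", active_id))
  p <- world$params; calib <- world$calib; g <- world$graph
  world2 <- with_seed(seed, {
    # --- formation ---
    for (e in g$edges) {
      pr <- formation_probability(e$flow_mm_s, td$voltage_vpp, p)
      hazard <- 1 - exp(-pr * dt_s)
      if (runif(1) < hazard) {
        d0 <- sample_swarm_diameter(1, td$voltage_vpp, p,
                                    seed = sample.int(2^30, 1))
        n0 <- max(1L, as.integer(round((d0 / mean(p$bubble_range_um))^3)))
        sw <- swarm_state(world$next_id, e$id,
                          runif(1) * edge_length_mm(e) * 1000, d0, n0,
                          wall_attached =
                            e$flow_mm_s < p$attach_flow_max_mm_s,
                          t_s = t_now)
        world$next_id <- world$next_id + 1L
        world$swarms[[length(world$swarms) + 1]] <- sw
        ev <- rbind(ev, event_row(t_now, "form", sw))
      }
    }
    # --- growth + motion ---
    for (i in seq_along(world$swarms)) {
      sw <- world$swarms[[i]]
      e <- g$edges[[as.character(sw$edge_id)]]
      sw <- grow_swarm(sw, dt_s, td$voltage_vpp, p)
      vc <- net_swarm_velocity(sw, e, td, calib, p, world$coefficient,
                               components = TRUE)
      v <- vc$v_net_um_s
      sw$s_um <- sw$s_um + v * dt_s
      L <- edge_length_mm(e) * 1000
      if (sw$s_um < 0 || sw$s_um > L) {
        node <- if (sw$s_um < 0) e$from else e$to
        cand <- Filter(function(o) !identical(o$id, e$id) &&
                         (o$from == node || o$to == node), g$edges)
        if (length(cand)) {
          # continue onto the connected edge maximizing projected velocity
          best <- NULL; bestv <- -Inf
          for (o in cand) {
            sw_try <- sw
            sw_try$edge_id <- o$id
            enter_from_start <- identical(o$from, node)
            sw_try$s_um <- if (enter_from_start) 0 else edge_length_mm(o) * 1000
            vo <- net_swarm_velocity(sw_try, o, td, calib, p, world$coefficient)
            proj <- if (enter_from_start) vo else -vo  # speed into the edge
            if (proj > bestv) { bestv <- proj; best <- sw_try }
          }
          sw <- best
          ev <- rbind(ev, event_row(t_now, "handoff", sw, bestv))
        } else {
          sw$s_um <- min(max(sw$s_um, 0), L)  # leaf: hold at the boundary
        }
      }
      sw$t_s <- t_now
      # navigation = motion independent of the flow stream: the radiation
      # slip exceeds the local advection, so the swarm goes where the
      # sound field sends it (including upstream)
      kind <- if (vc$direction != 0 && sw$wall_attached &&
                  vc$v_rad_um_s > abs(vc$u_flow_um_s)) "navigate" else "advect"
      ev <- rbind(ev, event_row(t_now, kind, sw, v))
      world$swarms[[i]] <- sw
    }
    # --- merging ---
    repeat {
      merged <- FALSE
      ns <- length(world$swarms)
      if (ns >= 2) {
        for (i in seq_len(ns - 1)) {
          for (j in seq(i + 1, ns)) {
            a <- world$swarms[[i]]; b <- world$swarms[[j]]
            if (identical(as.character(a$edge_id), as.character(b$edge_id)) &&
                abs(a$s_um - b$s_um) <= capture_radius_um(a, b)) {
              world$swarms[[i]] <- merge_swarms(a, b, p)
              world$swarms[[j]] <- NULL
              ev <- rbind(ev, event_row(t_now, "merge", world$swarms[[i]]))
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
      }
      if (!merged) break
    }
    world$time_s <- t_now
    world
  })
  list(world = world2, events = ev)
}

#' Total bubble count across the world
#' @param world a `sim_world`.
#' @return integer.
#' @export
total_bubbles <- function(world) {
  if (!length(world$swarms)) return(0L)
  sum(vapply(world$swarms, `[[`, integer(1), "n"))
}

#' Write an event log as CSV with a seed-stamped header
#' @param events event data.frame.
#' @param path output path.
#' @param seed seed recorded in the header comment line.
#' @export
write_event_log <- function(events, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sononav event log; seed=%d", as.integer(seed)), con)
  write.csv(events, con, row.names = FALSE)
  invisible(path)
}
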