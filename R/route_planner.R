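# Combinatorial transducer-activation planning: pick the best element for
# each vessel of a requested path and emit a one-at-a-time activation
# schedule, validated by forward simulation.

#' Best transducer to move a swarm along an edge
#'
#' Scores every transducer by predicted speed gated on direction match
#' (only elements whose predicted motion sign on the edge equals
#' `desired_sign` count) and returns the argmax; ties break toward the
#' lowest id. Returns NULL when no element produces the desired sign.
#'
#' @param e a `vessel_edge`.
#' @param desired_sign +1 (along the polyline) or -1.
#' @param transducers non-empty list of `transducer`.
#' @param calib an [acoustic_calibration()].
#' @return the winning `transducer`, or NULL if infeasible.
#' @export
best_transducer <- function(e, desired_sign, transducers,
                            calib = acoustic_calibration()) {
  if (!length(transducers)) stop("empty transducer set")
  stopifnot(desired_sign %in% c(-1L, 1L))
  best <- NULL; best_v <- 0
  for (td in transducers) {
    sgn <- direction_sign(td, e)
    if (sgn != desired_sign) next
    v <- predict_speed(e, td, calib)
    if (v > best_v + 1e-12 ||
        (abs(v - best_v) <= 1e-12 && !is.null(best) &&
         as.character(td$id) < as.character(best$id))) {
      best <- td; best_v <- v
    }
  }
  best
}

#' Plan a one-at-a-time activation route along a path of edges
#'
#' Greedy per-edge selection via [best_transducer()], mirroring the manual
#' procedure of choosing the most suitable element per vessel and
#' activating elements step by step. Step durations are edge length /
#' predicted speed times a safety factor. The plan is validated by forward
#' simulation before being returned.
#'
#' @param g a `vessel_graph`.
#' @param path_edges ordered vector of edge ids; consecutive edges must
#'   share a node. Traversal starts at the end of the first edge not shared
#'   with the second (single-edge paths run from -> to).
#' @param transducers list of `transducer`.
#' @param calib an [acoustic_calibration()].
#' @param p a [dynamics_params()] for validation dynamics.
#' @param safety_factor multiplier on step durations (default 1.5).
#' @param swarm_d_um diameter of the swarm being routed, µm.
#' @param mode "greedy" or "exhaustive" (audits every per-edge assignment
#'   combination on small problems).
#' @param validate run [simulate_plan()] and fail if it fails.
#' @return object of class `activation_plan`: data.frame of steps
#'   (step, transducer_id, duration_s, edge_id, direction).
#' @export
plan_route <- function(g, path_edges, transducers,
                       calib = acoustic_calibration(),
                       p = dynamics_params("invitro"),
                       safety_factor = 1.5, swarm_d_um = 10,
                       mode = c("greedy", "exhaustive"), validate = TRUE) {
  mode <- match.arg(mode)
  if (!all(path_edges %in% names(g$edges)))
    stop("path references unknown edges")
  edges <- g$edges[as.character(path_edges)]
  signs <- path_direction_signs(g, path_edges)
  pick <- function(e, sgn) best_transducer(e, sgn, transducers, calib)
  chosen <- vector("list", length(edges))
  if (mode == "greedy") {
    for (i in seq_along(edges)) {
      chosen[[i]] <- pick(edges[[i]], signs[i])
      if (is.null(chosen[[i]]))
        stop(sprintf("no feasible transducer for edge '%s'", path_edges[i]))
    }
  } else {
    # exhaustive audit: feasible iff every edge has at least one candidate;
    # enumerate to confirm and take the per-edge argmax among combinations
    cands <- lapply(seq_along(edges), function(i) {
      Filter(function(td) direction_sign(td, edges[[i]]) == signs[i],
             transducers)
    })
    bad <- which(vapply(cands, length, integer(1)) == 0)
    if (length(bad))
      stop(sprintf("no feasible transducer for edge '%s'", path_edges[bad[1]]))
    chosen <- lapply(seq_along(edges), function(i) {
      vs <- vapply(cands[[i]], function(td) predict_speed(edges[[i]], td, calib),
                   numeric(1))
      cands[[i]][[which.max(vs)]]
    })
  }
  steps <- do.call(rbind, lapply(seq_along(edges), function(i) {
    e <- edges[[i]]; td <- chosen[[i]]
    v <- predict_speed(e, td, calib)
    data.frame(step = i, transducer_id = as.character(td$id),
               duration_s = edge_length_mm(e) * 1000 / v * safety_factor,
               edge_id = as.character(e$id), direction = signs[i],
               stringsAsFactors = FALSE)
  }))
  plan <- structure(list(steps = steps, path_edges = as.character(path_edges),
                         swarm_d_um = swarm_d_um),
                    class = "activation_plan")
  if (validate) {
    res <- simulate_plan(g, plan, transducers, calib, p, seed = 1L)
    if (!res$success)
      stop(sprintf("plan validation failed at step %d", res$diverged_step))
  }
  plan
}

path_direction_signs <- function(g, path_edges) {
  edges <- g$edges[as.character(path_edges)]
  n <- length(edges)
  signs <- integer(n)
  if (n == 1) return(1L)
  for (i in seq_len(n)) {
    e <- edges[[i]]
    nxt <- if (i < n) edges[[i + 1]] else NULL
    prv <- if (i > 1) edges[[i - 1]] else NULL
    shared_next <- if (!is.null(nxt)) intersect(c(e$from, e$to),
                                                c(nxt$from, nxt$to)) else NULL
    shared_prev <- if (!is.null(prv)) intersect(c(e$from, e$to),
                                                c(prv$from, prv$to)) else NULL
    if (length(shared_next)) {
      signs[i] <- if (e$to %in% shared_next) 1L else -1L
    } else if (length(shared_prev)) {
      signs[i] <- if (e$from %in% shared_prev) 1L else -1L
    } else {
      stop("path edges are not connected")
    }
  }
  signs
}

#' @export
print.activation_plan <- function(x, ...) {
  cat(sprintf("activation_plan: %d step(s)\n", nrow(x$steps)))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Serialize an activation plan as JSON
#' @param plan an `activation_plan`.
#' @param path output path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(list(steps = plan$steps, path_edges = plan$path_edges,
                            swarm_d_um = plan$swarm_d_um),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Forward-simulate an activation plan
#'
#' Kinematic execution: during each step only that step's transducer is
#' active and the swarm advances along its current edge at the net force-
#' balance velocity; at the step boundary it must have reached the shared
#' node with the next edge. Success means the final position lies within
#' `tol_um` of the far node of the last edge.
#'
#' @param g a `vessel_graph`.
#' @param plan an `activation_plan`.
#' @param transducers list of `transducer`.
#' @param calib an [acoustic_calibration()].
#' @param p a [dynamics_params()].
#' @param seed RNG seed (trajectory is deterministic; seed recorded).
#' @param dt_s integration step, s.
#' @param tol_um arc-length success tolerance at the terminal node, µm.
#' @return list(success, trajectory data.frame, diverged_step or NA).
#' @export
simulate_plan <- function(g, plan, transducers,
                          calib = acoustic_calibration(),
                          p = dynamics_params("invitro"), seed = 1L,
                          dt_s = NULL, tol_um = 50) {
  steps <- plan$steps
  tds <- setNames(transducers,
                  vapply(transducers, function(t) as.character(t$id), character(1)))
  e1 <- g$edges[[steps$edge_id[1]]]
  s <- if (steps$direction[1] > 0) 0 else edge_length_mm(e1) * 1000
  sw <- swarm_state(1L, e1$id, max(s, 0), plan$swarm_d_um, wall_attached = TRUE)
  sw$s_um <- s
  traj <- data.frame(t = numeric(0), step = integer(0), edge_id = character(0),
                     s_um = numeric(0), v_um_s = numeric(0))
  t_now <- 0
  for (i in seq_len(nrow(steps))) {
    e <- g$edges[[steps$edge_id[i]]]
    td <- tds[[steps$transducer_id[i]]]
    L <- edge_length_mm(e) * 1000
    if (i > 1) {
      # enter the new edge at the node shared with the previous one
      sw$edge_id <- e$id
      sw$s_um <- if (steps$direction[i] > 0) 0 else L
    }
    dt <- if (is.null(dt_s)) steps$duration_s[i] / 50 else dt_s
    nsub <- max(1L, ceiling(steps$duration_s[i] / dt))
    for (k in seq_len(nsub)) {
      v <- net_swarm_velocity(sw, e, td, calib, p)
      sw$s_um <- min(max(sw$s_um + v * dt, 0), L)
      t_now <- t_now + dt
    }
    traj <- rbind(traj, data.frame(t = t_now, step = i,
                                   edge_id = as.character(e$id),
                                   s_um = sw$s_um, v_um_s = v))
    target <- if (steps$direction[i] > 0) L else 0
    if (abs(sw$s_um - target) > tol_um) {
      return(list(success = FALSE, trajectory = traj, diverged_step = i,
                  seed = seed))
    }
  }
  list(success = TRUE, trajectory = traj, diverged_step = NA_integer_,
       seed = seed)
}
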