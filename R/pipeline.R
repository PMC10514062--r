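# End-to-end orchestration: a single YAML run config drives annotation,
# simulation, and planning stages with one root seed; every artifact is
# stamped with the config hash and seed.

#' Read a run configuration
#'
#' YAML with keys: scenario ("invivo", "cylinder", "frustumB", ...), seed
#' (mandatory), layout (transducer layout tag), outdir, and optional
#' calibration / dynamics / phantom overrides (named lists passed to
#' [acoustic_calibration()], [dynamics_params()], [phantom_spec()]).
#'
#' @param path YAML file, one document per scenario run.
#' @param overrides named list overriding top-level config keys (CLI flags).
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  as_run_config(cfg)
}

#' Build a run config from a list
#' @param cfg named list (see [read_run_config()]).
#' @return a `run_config`.
#' @export
as_run_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config must set a seed")
  if (is.null(cfg$scenario)) stop("config must set a scenario")
  known <- c("invivo", "cylinder", "frustumB", "grid", "random_tree")
  if (!cfg$scenario %in% known)
    stop(sprintf("unknown scenario '%s' (known: %s)", cfg$scenario,
                 paste(known, collapse = ", ")))
  if (is.null(cfg$layout))
    cfg$layout <- switch(cfg$scenario, invivo = "invivo",
                         cylinder = "cylinder", "frustum")
  if (is.null(cfg$outdir)) cfg$outdir <- "sononav_out"
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  # order-independent digest of the config (no external digest dependency):
  # serialize to canonical JSON and fold bytes
  s <- jsonlite::toJSON(cfg[order(names(unclass(cfg)))], auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 97 + 1)) %% 4294967291)
}

scenario_graph <- function(cfg) {
  kind <- switch(cfg$scenario, invivo = "invivo_like", cylinder = "cylinder",
                 frustumB = "frustumB", grid = "grid",
                 random_tree = "random_tree")
  args <- c(list(kind = kind, seed = cfg$seed), cfg$phantom)
  g <- do.call(phantom_spec, args)
  g <- generate_network(g)
  assign_flows(g, seed = cfg$seed + 1L)
}

scenario_calibration <- function(cfg) {
  scen <- if (cfg$scenario == "invivo") "invivo" else "invitro_cylinder"
  do.call(acoustic_calibration, c(list(scenario = scen), cfg$calibration))
}

scenario_dynamics <- function(cfg) {
  preset <- if (cfg$scenario == "invivo") "invivo" else "invitro"
  do.call(dynamics_params, c(list(preset = preset), cfg$dynamics))
}

stamp_sidecar <- function(cfg, outdir) {
  jsonlite::write_json(list(config_hash = config_hash(cfg), seed = cfg$seed,
                            scenario = cfg$scenario),
                       file.path(outdir, "run_stamp.json"), auto_unbox = TRUE)
}

#' Annotate a scenario's vessel graph for every transducer
#'
#' Writes, per transducer, an annotation CSV plus speed and distance maps
#' (the two color conventions), and returns the annotations.
#'
#' @param config a `run_config` (or path to one).
#' @param graph optional pre-built `vessel_graph`; defaults to the
#'   scenario's synthetic network.
#' @return invisibly, a list of annotation data.frames keyed by transducer
#'   id.
#' @export
run_annotate <- function(config, graph = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  g <- if (is.null(graph)) scenario_graph(cfg) else graph
  if (is.null(g)) stop("missing inputs: no graph available for annotation")
  calib <- scenario_calibration(cfg)
  tds <- place_transducers(cfg$layout)
  out <- list()
  for (td in tds) {
    ann <- annotate_graph(g, td, calib)
    base <- file.path(cfg$outdir, sprintf("annotation_t%s", td$id))
    write_annotations(ann, paste0(base, ".csv"))
    render_map(g, ann, "speed", paste0(base, "_speed.png"))
    render_map(g, ann, "distance", paste0(base, "_distance.png"))
    out[[as.character(td$id)]] <- ann
  }
  write_vessel_graph(g, file.path(cfg$outdir, "graph.json"))
  stamp_sidecar(cfg, cfg$outdir)
  invisible(out)
}

#' Run a seeded swarm simulation for a scenario
#'
#' Executes an activation schedule (default: one transducer on for
#' `n_steps` steps, then off for one step) and writes the event log CSV
#' and a JSON summary with swarm counts, a 1-40 µm size histogram, and
#' per-edge navigation outcomes.
#'
#' @param config a `run_config` or path.
#' @param active_id transducer to activate (default: first in layout).
#' @param n_steps active steps (default 20).
#' @param dt_s step length, s (default 1).
#' @return invisibly, list(events, summary, world).
#' @export
run_simulate <- function(config, active_id = NULL, n_steps = 20, dt_s = 1) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  g <- scenario_graph(cfg)
  tds <- place_transducers(cfg$layout)
  if (is.null(active_id)) active_id <- tds[[1]]$id
  world <- sim_world(g, tds, scenario_calibration(cfg), scenario_dynamics(cfg))
  events <- empty_events()
  for (k in seq_len(n_steps)) {
    res <- step_simulation(world, dt_s, active_id, seed = cfg$seed + k)
    world <- res$world
    events <- rbind(events, res$events)
  }
  res <- step_simulation(world, dt_s, NULL, seed = cfg$seed + n_steps + 1L)
  world <- res$world
  events <- rbind(events, res$events)
  formed <- events[events$event == "form", ]
  hist_breaks <- seq(0, 40, by = 5)
  size_hist <- if (nrow(formed)) hist(pmin(formed$d_um, 40),
                                      breaks = hist_breaks, plot = FALSE)$counts
               else rep(0L, length(hist_breaks) - 1)
  nav <- events[events$event == "navigate", ]
  et <- edge_table(g)
  per_edge <- et[, c("edge_id", "vessel_class", "diameter_um")]
  per_edge$navigation_events <-
    vapply(per_edge$edge_id, function(id) sum(nav$edge_id == id), numeric(1))
  summary <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                  n_swarms_formed = nrow(formed),
                  n_merges = sum(events$event == "merge"),
                  final_swarm_count = length(world$swarms),
                  size_hist_breaks_um = hist_breaks,
                  size_hist_counts = size_hist,
                  per_edge = per_edge)
  write_event_log(events, file.path(cfg$outdir, "events.csv"), cfg$seed)
  jsonlite::write_json(summary, file.path(cfg$outdir, "simulation_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  stamp_sidecar(cfg, cfg$outdir)
  invisible(list(events = events, summary = summary, world = world))
}

#' Plan and validate a route for a scenario
#'
#' @param config a `run_config` or path.
#' @param path_edges ordered edge ids through the scenario graph.
#' @return invisibly, list(plan, report); writes plan JSON, a trajectory
#'   CSV and a success/failure report. Infeasible paths raise an error
#'   naming the blocking edge.
#' @export
run_plan <- function(config, path_edges) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  g <- scenario_graph(cfg)
  if (!all(path_edges %in% names(g$edges)))
    stop("path edges not present in the scenario graph")
  tds <- place_transducers(cfg$layout)
  calib <- scenario_calibration(cfg)
  p <- scenario_dynamics(cfg)
  plan <- plan_route(g, path_edges, tds, calib, p, validate = FALSE)
  report <- simulate_plan(g, plan, tds, calib, p, seed = cfg$seed)
  write_plan(plan, file.path(cfg$outdir, "plan.json"))
  write.csv(report$trajectory, file.path(cfg$outdir, "trajectory.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(success = report$success,
                            diverged_step = report$diverged_step,
                            seed = cfg$seed, config_hash = config_hash(cfg)),
                       file.path(cfg$outdir, "plan_report.json"),
                       auto_unbox = TRUE)
  stamp_sidecar(cfg, cfg$outdir)
  invisible(list(plan = plan, report = report))
}
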