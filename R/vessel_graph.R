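#' @importFrom stats approx rlnorm rnorm runif plogis lm coef setNames
#' @importFrom graphics hist
#' @importFrom utils write.csv
NULL

# ---- internal geometry helpers ------------------------------------------

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

#' Cumulative arc length of a polyline
#'
#' @param pts numeric matrix, one 3D point per row.
#' @return numeric vector of cumulative arc lengths, starting at 0.
#' @keywords internal
arc_length <- function(pts) {
  if (nrow(pts) < 2) stop("polyline needs at least 2 points")
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

#' Point at a given arc-length fraction along a polyline
#' @keywords internal
polyline_point_at <- function(pts, s_target) {
  s <- arc_length(pts)
  total <- s[length(s)]
  s_target <- min(max(s_target, 0), total)
  i <- findInterval(s_target, s, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  seg <- s[i + 1] - s[i]
  f <- if (seg > 0) (s_target - s[i]) / seg else 0
  pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
}

# ---- VesselEdge / VesselGraph -------------------------------------------

VESSEL_CLASSES <- c("artery", "arteriole", "vein", "venule", "capillary", "unknown")

#' Construct a vessel edge
#'
#' A vessel segment between two graph nodes, carrying an ordered 3D
#' centerline polyline (mm), a lumen diameter (µm), a vessel class, and a
#' centerline blood-flow speed (mm/s) signed along the polyline orientation.
#'
#' @param id edge identifier (character or integer).
#' @param from,to endpoint node ids.
#' @param centerline numeric matrix (n >= 2 rows, 3 cols) of points in mm with
#'   strictly increasing arc length.
#' @param diameter_um lumen diameter in micrometers, > 0.
#' @param vessel_class one of artery, arteriole, vein, venule, capillary, unknown.
#' @param flow_mm_s centerline flow speed, mm/s, >= 0.
#' @param flow_sign +1 if flow runs from `from` to `to` along the polyline,
#'   -1 otherwise.
#' @return object of class `vessel_edge`.
#' @export
vessel_edge <- function(id, from, to, centerline, diameter_um,
                        vessel_class = "unknown", flow_mm_s = 0, flow_sign = 1L) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) == 2) centerline <- cbind(centerline, 0)
  if (ncol(centerline) != 3) stop("centerline must have 3 columns")
  if (nrow(centerline) < 2) stop("centerline needs at least 2 points")
  if (!all(is.finite(centerline))) stop("centerline must be finite")
  dimnames(centerline) <- NULL
  s <- arc_length(centerline)
  if (any(diff(s) <= 0)) stop("centerline arc length must be strictly increasing")
  if (!is.numeric(diameter_um) || diameter_um <= 0) stop("diameter must be > 0")
  vessel_class <- match.arg(vessel_class, VESSEL_CLASSES)
  if (flow_mm_s < 0) stop("flow speed must be >= 0")
  if (!flow_sign %in% c(-1L, 1L)) stop("flow_sign must be +1 or -1")
  structure(list(id = id, from = from, to = to, centerline = centerline,
                 diameter_um = diameter_um, vessel_class = vessel_class,
                 flow_mm_s = flow_mm_s, flow_sign = as.integer(flow_sign)),
            class = "vessel_edge")
}

#' Total length of a vessel edge in mm
#' @param e a `vessel_edge`.
#' @return length in mm.
#' @export
edge_length_mm <- function(e) {
  s <- arc_length(e$centerline)
  s[length(s)]
}

#' Arc-length midpoint of an edge (mm)
#' @param e a `vessel_edge`.
#' @return numeric 3-vector, mm.
#' @export
edge_midpoint <- function(e) {
  polyline_point_at(e$centerline, edge_length_mm(e) / 2)
}

#' Edge axis unit vector (endpoint-to-endpoint)
#' @param e a `vessel_edge`.
#' @return unit 3-vector pointing from the first to the last polyline point.
#' @export
edge_axis <- function(e) {
  unitize(e$centerline[nrow(e$centerline), ] - e$centerline[1, ])
}

#' Construct a vessel graph
#'
#' Nodes are 3D positions in a named right-handed mm frame; edges are
#' [vessel_edge] objects referencing node ids.
#'
#' @param nodes data.frame with columns id, x, y, z (mm).
#' @param edges list of [vessel_edge].
#' @param frame character tag naming the coordinate frame (device preset).
#' @return object of class `vessel_graph`.
#' @export
vessel_graph <- function(nodes, edges, frame = "lab") {
  stopifnot(is.data.frame(nodes), all(c("id", "x", "y", "z") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("node positions must be finite")
  for (e in edges) {
    if (!inherits(e, "vessel_edge")) stop("edges must be vessel_edge objects")
    if (!all(c(e$from, e$to) %in% nodes$id))
      stop(sprintf("edge %s references missing node", e$id))
    if (edge_length_mm(e) <= 0) stop("zero-length edge")
  }
  ids <- vapply(edges, function(e) as.character(e$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate edge ids")
  names(edges) <- ids
  structure(list(nodes = nodes, edges = edges, frame = frame),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("vessel_graph [frame %s]: %d nodes, %d edges\n",
              x$frame, nrow(x$nodes), length(x$edges)))
  d <- vapply(x$edges, `[[`, numeric(1), "diameter_um")
  if (length(d))
    cat(sprintf("  diameters %.1f-%.1f um; classes: %s\n", min(d), max(d),
                paste(unique(vapply(x$edges, `[[`, character(1), "vessel_class")),
                      collapse = ", ")))
  invisible(x)
}

#' Summarize edges of a vessel graph as a data.frame
#' @param g a `vessel_graph`.
#' @return data.frame with one row per edge.
#' @export
edge_table <- function(g) {
  data.frame(
    edge_id = vapply(g$edges, function(e) as.character(e$id), character(1)),
    from = vapply(g$edges, function(e) as.character(e$from), character(1)),
    to = vapply(g$edges, function(e) as.character(e$to), character(1)),
    length_mm = vapply(g$edges, edge_length_mm, numeric(1)),
    diameter_um = vapply(g$edges, `[[`, numeric(1), "diameter_um"),
    vessel_class = vapply(g$edges, `[[`, character(1), "vessel_class"),
    flow_mm_s = vapply(g$edges, `[[`, numeric(1), "flow_mm_s"),
    flow_sign = vapply(g$edges, `[[`, integer(1), "flow_sign"),
    row.names = NULL, stringsAsFactors = FALSE)
}

# ---- I/O -----------------------------------------------------------------

#' Write a vessel graph to JSON
#'
#' Serializes nodes, edges (with full centerline polylines) and the frame
#' tag. The file round-trips through [read_vessel_graph()].
#'
#' @param g a `vessel_graph`.
#' @param path output file path.
#' @export
write_vessel_graph <- function(g, path) {
  obj <- list(
    frame = g$frame,
    nodes = g$nodes,
    edges = lapply(unname(g$edges), function(e) list(
      id = e$id, from = e$from, to = e$to,
      centerline = e$centerline, diameter_um = e$diameter_um,
      vessel_class = e$vessel_class, flow_mm_s = e$flow_mm_s,
      flow_sign = e$flow_sign)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vessel graph from JSON
#' @param path file written by [write_vessel_graph()].
#' @return a `vessel_graph`.
#' @export
read_vessel_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  edges <- lapply(seq_len(if (is.data.frame(obj$edges)) nrow(obj$edges)
                          else length(obj$edges)), function(i) {
    e <- if (is.data.frame(obj$edges)) lapply(obj$edges, `[[`, i) else obj$edges[[i]]
    cl <- e$centerline
    if (is.list(cl)) cl <- do.call(rbind, cl)
    vessel_edge(e$id, e$from, e$to, matrix(unlist(cl), ncol = 3),
                e$diameter_um, e$vessel_class, e$flow_mm_s, e$flow_sign)
  })
  vessel_graph(as.data.frame(obj$nodes), edges, frame = obj$frame)
}

#' Convert a vessel graph to an igraph object
#'
#' Node positions and edge attributes (length, diameter, class, flow) are
#' carried over; centerline polylines are dropped. Useful for GraphML export
#' via [igraph::write_graph()].
#'
#' @param g a `vessel_graph`.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(g) {
  et <- edge_table(g)
  ig <- igraph::graph_from_data_frame(
    et[, c("from", "to", "edge_id", "length_mm", "diameter_um",
           "vessel_class", "flow_mm_s")],
    directed = FALSE,
    vertices = data.frame(name = as.character(g$nodes$id),
                          x = g$nodes$x, y = g$nodes$y, z = g$nodes$z))
  ig
}

#' Write a vessel graph as GraphML
#' @param g a `vessel_graph`.
#' @param path output path.
#' @export
write_vessel_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' Apply a rigid rotation to a vessel graph
#'
#' @param g a `vessel_graph`.
#' @param R 3x3 rotation matrix.
#' @return rotated graph (same topology and attributes).
#' @export
rotate_graph <- function(g, R) {
  stopifnot(all(dim(R) == c(3, 3)))
  nodes <- g$nodes
  xyz <- as.matrix(nodes[, c("x", "y", "z")]) %*% t(R)
  nodes$x <- xyz[, 1]; nodes$y <- xyz[, 2]; nodes$z <- xyz[, 3]
  edges <- lapply(g$edges, function(e) {
    e$centerline <- e$centerline %*% t(R)
    e
  })
  vessel_graph(nodes, edges, frame = g$frame)
}
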