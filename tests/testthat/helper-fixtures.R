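# Shared fixtures, all built in code.

# straight edge along +x of given length (mm) at a y offset
straight_edge <- function(id = "e", length_mm = 2, y_mm = 0, diameter_um = 30,
                          vessel_class = "unknown", flow_mm_s = 0,
                          flow_sign = 1L, n_pts = 5) {
  xs <- seq(-length_mm / 2, length_mm / 2, length.out = n_pts)
  vessel_edge(id, paste0(id, "_a"), paste0(id, "_b"),
              cbind(xs, y_mm, 0), diameter_um, vessel_class,
              flow_mm_s, flow_sign)
}

# one-edge graph wrapper
one_edge_graph <- function(e, frame = "lab") {
  p1 <- e$centerline[1, ]; p2 <- e$centerline[nrow(e$centerline), ]
  vessel_graph(data.frame(id = c(e$from, e$to),
                          x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
                          z = c(p1[3], p2[3])),
               setNames(list(e), as.character(e$id)), frame = frame)
}

# transducer head-on to straight_edge(): beyond the -x end, aimed at +x
head_on_transducer <- function(e, r_mm = 2.15, voltage_vpp = 15) {
  mid <- edge_midpoint(e)
  transducer("T", mid - c(r_mm, 0, 0), c(1, 0, 0), voltage_vpp = voltage_vpp)
}

# Y-junction graph: three 120 um tubes meeting at (1, 0)
y_junction_graph <- function(diameter_um = 120) {
  nodes <- data.frame(id = c("a", "b", "c", "j"),
                      x = c(0, 2, 2, 1), y = c(0, 1.5, -1.5, 0), z = 0)
  mk <- function(id, a, b) {
    pa <- as.numeric(nodes[nodes$id == a, c("x", "y", "z")])
    pb <- as.numeric(nodes[nodes$id == b, c("x", "y", "z")])
    vessel_edge(id, a, b, rbind(pa, pb), diameter_um)
  }
  vessel_graph(nodes, list(mk("e1", "a", "j"), mk("e2", "j", "b"),
                           mk("e3", "j", "c")))
}

# disk frame for detection tests
disk_frame <- function(radius_px = 10, center = c(32, 32), dim = c(64, 64),
                       voxel_size_um = 1, noise = 0) {
  px <- matrix(0, dim[1], dim[2])
  px[(row(px) - center[1])^2 + (col(px) - center[2])^2 <= radius_px^2] <- 1
  if (noise > 0) px <- px + matrix(runif(length(px), 0, noise), dim[1])
  angiogram_image(px, voxel_size_um)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# reference in vivo upstream scenario (the calibration anchor geometry)
upstream_anchor_scenario <- function(voltage_vpp = 35) {
  e <- vessel_edge("v", "a", "b", rbind(c(0, 0, 0), c(5, 0, 0)), 30,
                   "venule", 10, -1L)  # 10 mm/s opposing the +x direction
  td <- transducer("T", c(2.5 - 2.15, 0, 0), c(1, 0, 0),
                   voltage_vpp = voltage_vpp)
  calib <- acoustic_calibration("invivo", r0_mm = 2.15)
  sw <- swarm_state(1L, "v", 100, 10, 100, wall_attached = TRUE)
  list(edge = e, transducer = td, calib = calib, swarm = sw)
}
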