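test_that("binarization rejects blank and constant images", {
  blank <- angiogram_image(matrix(0, 8, 8), 1)
  expect_error(binarize_vasculature(blank), "blank")
  flat <- angiogram_image(matrix(0.4, 8, 8), 1)
  expect_error(binarize_vasculature(flat), "bimodality")
})

test_that("binarization separates tubes into the right component count", {
  count_components <- function(mask)
    max(EBImage::bwlabel(EBImage::Image(matrix(as.integer(mask), nrow(mask)))))
  sp1 <- phantom_spec("cylinder", extent_mm = 4, voxel_size_um = 25, seed = 1)
  g1 <- generate_network(sp1)
  expect_equal(count_components(binarize_vasculature(render_phantom_image(g1, sp1))), 1)
  # two disjoint tubes
  nodes <- data.frame(id = c("a", "b", "c", "d"),
                      x = c(0, 4, 0, 4), y = c(0, 0, 3, 3), z = 0)
  g2 <- vessel_graph(nodes, list(
    vessel_edge("t1", "a", "b", rbind(c(0, 0, 0), c(4, 0, 0)), 300),
    vessel_edge("t2", "c", "d", rbind(c(0, 3, 0), c(4, 3, 0)), 300)))
  sp2 <- phantom_spec("grid", voxel_size_um = 25, seed = 2)
  expect_equal(count_components(binarize_vasculature(render_phantom_image(g2, sp2))), 2)
})

test_that("a straight tube extracts to 2 nodes, 1 edge, correct diameter", {
  sp <- phantom_spec("cylinder", extent_mm = 5, voxel_size_um = 25, seed = 3)
  g <- generate_network(sp)
  img <- render_phantom_image(g, sp)
  gx <- extract_lattice(binarize_vasculature(img), img$voxel_size_um,
                        img$origin_mm)
  expect_equal(nrow(gx$nodes), 2)
  expect_length(gx$edges, 1)
  expect_lt(abs(gx$edges[[1]]$diameter_um - 400) / 400, 0.2)
  expect_error(extract_lattice(matrix(FALSE, 5, 5), 1), "empty mask")
})

test_that("a Y junction extracts to 4 nodes (3 tips + 1 branch), 3 edges", {
  g <- y_junction_graph()
  sp <- phantom_spec("grid", voxel_size_um = 10, seed = 5)
  img <- render_phantom_image(g, sp)
  gx <- extract_lattice(binarize_vasculature(img), img$voxel_size_um,
                        img$origin_mm)
  expect_equal(nrow(gx$nodes), 4)
  expect_length(gx$edges, 3)
  et <- edge_table(gx)
  deg <- table(c(et$from, et$to))
  expect_equal(sort(as.integer(deg)), c(1, 1, 1, 3))
})

test_that("seeded phantoms round-trip topology exactly, diameters within 20%", {
  for (s in 1:4) {
    sp <- phantom_spec("invivo_like", voxel_size_um = 2, n_edges = 6, seed = s)
    g <- generate_network(sp)
    img <- render_phantom_image(g, sp)
    gx <- extract_lattice(binarize_vasculature(img), img$voxel_size_um,
                          img$origin_mm)
    expect_equal(nrow(gx$nodes), nrow(g$nodes), label = sprintf("nodes seed %d", s))
    expect_length(gx$edges, length(g$edges))
    # match recovered edges to truth by centerline midpoint proximity
    mt <- vapply(g$edges, function(e) edge_midpoint(e)[1:2], numeric(2))
    mx <- vapply(gx$edges, function(e) edge_midpoint(e)[1:2], numeric(2))
    for (i in seq_len(ncol(mt))) {
      j <- which.min(colSums((mx - mt[, i])^2))
      rel <- abs(gx$edges[[j]]$diameter_um - g$edges[[i]]$diameter_um) /
        g$edges[[i]]$diameter_um
      expect_lt(rel, 0.2)
    }
  }
})

test_that("swarm detection recovers the equivalent-circle diameter", {
  fr <- disk_frame(radius_px = 10, noise = 0.05)
  det <- detect_swarm_masks(fr)
  expect_equal(nrow(det), 1)
  A <- sum((row(fr$pixels) - 32)^2 + (col(fr$pixels) - 32)^2 <= 100)
  expect_equal(det$diameter_um, sqrt(4 * A / pi), tolerance = 1e-6)
  expect_equal(det$x_px, 32, tolerance = 0.5)
  # blank frame -> empty result
  expect_equal(nrow(detect_swarm_masks(angiogram_image(matrix(0, 8, 8), 1))), 0)
})

test_that("dim single-bubble speckles are excluded from swarm masks", {
  set.seed(8)
  px <- matrix(0, 64, 64)
  px[(row(px) - 20)^2 + (col(px) - 20)^2 <= 36] <- 1        # one bright blob
  speck <- cbind(sample(40:60, 25, TRUE), sample(5:60, 25, TRUE))
  px[speck] <- 0.3                                           # dim speckles
  det <- detect_swarm_masks(angiogram_image(px, 1), min_area_px = 5)
  expect_equal(nrow(det), 1)
  # detection mask area never exceeds the image foreground
  expect_lte(pi * (det$diameter_um / 2)^2, sum(px > 0) * 1.1)
})

test_that("detection is idempotent on its own binary mask", {
  fr <- disk_frame(radius_px = 8)
  det1 <- detect_swarm_masks(fr)
  mask_img <- angiogram_image((fr$pixels > 0.5) * 1, 1)
  det2 <- detect_swarm_masks(mask_img)
  expect_equal(det2$diameter_um, det1$diameter_um, tolerance = 1e-9)
  expect_equal(det2$x_px, det1$x_px)
})

test_that("tracking computes per-step speeds and starts tracks correctly", {
  mk <- function(cx) {
    m <- matrix(0, 32, 64)
    m[(row(m) - 16)^2 + (col(m) - cx)^2 <= 9] <- 1
    m
  }
  st <- angiogram_image(simplify2array(lapply(c(10, 12, 14, 16), mk)), 1,
                        frame_interval_s = 1)
  tr <- track_swarms(detect_swarm_stack(st), 1, 1, max_link_um = 5)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(as.numeric(na.omit(tr$speed_um_s)), rep(2, 3), tolerance = 1e-9)
  # stationary blob -> zero speed
  st0 <- angiogram_image(simplify2array(lapply(c(20, 20, 20), mk)), 1, 1)
  tr0 <- track_swarms(detect_swarm_stack(st0), 1, 1, max_link_um = 5)
  expect_true(all(na.omit(tr0$speed_um_s) == 0))
  expect_error(track_swarms(detect_swarm_masks(disk_frame()), 1, 1), "2 frames")
})

test_that("well-separated crossing blobs never swap tracks", {
  # two blobs pass on parallel lanes 12 um apart, stepping 2 um/frame;
  # cross-lane distance always exceeds max_link_um = 5
  mk2 <- function(cx1, cx2) {
    m <- matrix(0, 40, 80)
    m[(row(m) - 14)^2 + (col(m) - cx1)^2 <= 4] <- 1
    m[(row(m) - 26)^2 + (col(m) - cx2)^2 <= 4] <- 1
    m
  }
  xs1 <- seq(20, 60, by = 2); xs2 <- seq(60, 20, by = -2)
  st <- angiogram_image(simplify2array(Map(mk2, xs1, xs2)), 1, 1)
  tr <- track_swarms(detect_swarm_stack(st), 1, 1, max_link_um = 5)
  expect_equal(length(unique(tr$track_id)), 2)
  # oracle: the exhaustive 2-track assignment keeps each blob on its lane
  for (id in unique(tr$track_id)) {
    lane <- tr$y_px[tr$track_id == id]
    expect_lt(max(lane) - min(lane), 2)
  }
  # with every detection linked, track count equals the per-frame count
  det <- detect_swarm_stack(st)
  expect_equal(length(unique(tr$track_id)), max(table(det$frame)))
})
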