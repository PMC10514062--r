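# Synthetic inputs with the geometric and statistical structure of the
# study's devices: straight 400 um PDMS channels (cylinder), a branched
# 400 um network in a cone frustum, and quasi-planar pial-like trees with
# 10-40 um vessels, plus phantom renderings, flows, and bubble injections.
# Every generator is a pure function of its spec + seed.

#' Phantom / network specification
#'
#' @param kind one of "cylinder", "frustumA", "frustumB", "grid",
#'   "random_tree", "invivo_like".
#' @param channel_diameter_um channel diameter for device presets, µm.
#' @param extent_mm spatial extent of the network, mm.
#' @param voxel_size_um µm per pixel for phantom rendering.
#' @param blur_sigma_px Gaussian blur sigma in pixels.
#' @param noise_sd additive Gaussian noise sd (intensity units, foreground = 1).
#' @param flow_slope diameter-to-flow slope, (mm/s)/µm.
#' @param n_edges edge count request for random kinds.
#' @param seed mandatory RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("cylinder", "frustumA", "frustumB", "grid",
                                  "random_tree", "invivo_like"),
                         channel_diameter_um = 400, extent_mm = NULL,
                         voxel_size_um = NULL, blur_sigma_px = 1,
                         noise_sd = 0.02, flow_slope = 0.25,
                         n_edges = 8, seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(extent_mm)) extent_mm <- if (kind == "invivo_like") 1 else 15
  if (is.null(voxel_size_um)) voxel_size_um <- if (kind == "invivo_like") 2 else 25
  stopifnot(channel_diameter_um > 0, extent_mm > 0, voxel_size_um > 0,
            blur_sigma_px >= 0, noise_sd >= 0, flow_slope >= 0, n_edges >= 1)
  structure(list(kind = kind, channel_diameter_um = channel_diameter_um,
                 extent_mm = extent_mm, voxel_size_um = voxel_size_um,
                 blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
                 flow_slope = flow_slope, n_edges = n_edges,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

node_df <- function(ids, xyz) {
  data.frame(id = ids, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic vessel network
#'
#' Device presets: `cylinder` is a single straight 400 µm channel along y;
#' `frustumB` a small branched network of 400 µm channels in the frustum's
#' x-y plane; `grid` an orthogonal grid; `random_tree` a random planar tree;
#' `invivo_like` a quasi-planar pial-like tree with diameters drawn in
#' 10-40 µm and venous/arterial subtrees.
#'
#' @param spec a [phantom_spec()].
#' @return a `vessel_graph` (flows all zero; see [assign_flows()]).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, switch(spec$kind,
    cylinder = gen_cylinder(spec),
    frustumA = gen_cylinder(spec),  # chamber device: no embedded channels; reuse straight channel for field tests
    frustumB = gen_frustumB(spec),
    grid = gen_grid(spec),
    random_tree = gen_random_tree(spec),
    invivo_like = gen_invivo(spec),
    stop(sprintf("unknown network kind '%s'", spec$kind))))
}

gen_cylinder <- function(spec) {
  L <- spec$extent_mm
  nodes <- node_df(c("n1", "n2"), rbind(c(0, -L / 2, 0), c(0, L / 2, 0)))
  cl <- cbind(0, seq(-L / 2, L / 2, length.out = 9), 0)
  e <- vessel_edge("e1", "n1", "n2", cl, spec$channel_diameter_um)
  vessel_graph(nodes, list(e), frame = "cylinder")
}

gen_frustumB <- function(spec) {
  # plus-shaped network of interconnected 400 um channels in the frustum
  # midplane (z = 4.5 mm), spanning +-4 mm: a central cross with two side
  # spurs, 6 edges -- enough branch-to-branch routes to emulate the
  # combinatorial activation maneuvers.
  z <- 4.5
  pts <- list(c = c(0, 0, z), e = c(4, 0, z), w = c(-4, 0, z),
              n = c(0, 4, z), s = c(0, -4, z),
              ne = c(4, 4, z), sw = c(-4, -4, z))
  nodes <- node_df(names(pts), do.call(rbind, pts))
  mk <- function(id, a, b) {
    cl <- rbind(pts[[a]], (pts[[a]] + pts[[b]]) / 2, pts[[b]])
    vessel_edge(id, a, b, cl, spec$channel_diameter_um)
  }
  edges <- list(mk("ce", "c", "e"), mk("cw", "c", "w"), mk("cn", "c", "n"),
                mk("cs", "c", "s"), mk("ene", "e", "ne"), mk("wsw", "w", "sw"))
  vessel_graph(nodes, edges, frame = "frustumB")
}

gen_grid <- function(spec) {
  # 2 x 2 orthogonal grid of channels in the x-y plane
  L <- spec$extent_mm / 2
  coords <- expand.grid(x = c(-L, 0, L), y = c(-L, 0, L))
  ids <- sprintf("g%d", seq_len(nrow(coords)))
  nodes <- node_df(ids, cbind(coords$x, coords$y, 0))
  idx <- function(ix, iy) ids[(iy - 1) * 3 + ix]
  edges <- list(); k <- 0
  for (iy in 1:3) for (ix in 1:2) {
    k <- k + 1
    a <- idx(ix, iy); b <- idx(ix + 1, iy)
    pa <- as.numeric(nodes[nodes$id == a, c("x", "y", "z")])
    pb <- as.numeric(nodes[nodes$id == b, c("x", "y", "z")])
    edges[[k]] <- vessel_edge(sprintf("h%d", k), a, b, rbind(pa, pb),
                              spec$channel_diameter_um)
  }
  for (ix in 1:3) for (iy in 1:2) {
    k <- k + 1
    a <- idx(ix, iy); b <- idx(ix, iy + 1)
    pa <- as.numeric(nodes[nodes$id == a, c("x", "y", "z")])
    pb <- as.numeric(nodes[nodes$id == b, c("x", "y", "z")])
    edges[[k]] <- vessel_edge(sprintf("v%d", k), a, b, rbind(pa, pb),
                              spec$channel_diameter_um)
  }
  vessel_graph(nodes, edges, frame = "grid")
}

# minimum distance between 2D segments ab and cd
seg_seg_dist <- function(a, b, c, d) {
  pt_seg <- function(p, u, v) {
    w <- v - u; t <- sum((p - u) * w) / max(sum(w^2), 1e-12)
    t <- min(max(t, 0), 1)
    sqrt(sum((u + t * w - p)^2))
  }
  cross2 <- function(o, p, q) (p[1] - o[1]) * (q[2] - o[2]) -
    (p[2] - o[2]) * (q[1] - o[1])
  # proper intersection check
  d1 <- cross2(c, d, a); d2 <- cross2(c, d, b)
  d3 <- cross2(a, b, c); d4 <- cross2(a, b, d)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(pt_seg(a, c, d), pt_seg(b, c, d), pt_seg(c, a, b), pt_seg(d, a, b))
}

# grow a planar tree by binary branching at leaves: every interior node has
# degree 3 (a detectable branch point), endpoints degree 1 -- no degree-2
# pass-through nodes, which a skeleton cannot recover. New segments must
# clear all non-adjacent existing segments by `sep` (non-degenerate layout).
grow_branching_tree <- function(n_edges, root, root_heading, seg_len, sep,
                                max_tries = 60) {
  pos <- list(root, root + seg_len() * root_heading)
  segs <- list(c(1L, 2L))
  leaves <- 2L
  leaf_dir <- list(unitize(pos[[2]] - pos[[1]]))
  while (length(segs) + 1L < n_edges && length(leaves)) {
    li <- sample.int(length(leaves), 1)
    leaf <- leaves[li]
    base_dir <- leaf_dir[[li]]
    placed <- NULL
    for (try in seq_len(max_tries)) {
      # two children fanning out around the incoming direction; the fan is
      # kept wide so sibling tubes separate within ~1 diameter of the fork
      spread <- runif(1, 70, 110) * pi / 180
      jitter <- runif(2, -10, 10) * pi / 180
      base_ang <- atan2(base_dir[2], base_dir[1])
      angs <- base_ang + c(-spread / 2, spread / 2) + jitter
      p_new <- lapply(1:2, function(j)
        pos[[leaf]] + seg_len() * c(cos(angs[j]), sin(angs[j]), 0))
      ok <- sqrt(sum((p_new[[1]] - p_new[[2]])^2)) >= sep
      if (ok) for (j in 1:2) {
        a <- pos[[leaf]][1:2]; b <- p_new[[j]][1:2]
        for (si in seq_along(segs)) {
          s <- segs[[si]]
          if (leaf %in% s) next  # adjacent segment shares the branch node
          if (seg_seg_dist(a, b, pos[[s[1]]][1:2], pos[[s[2]]][1:2]) < sep) {
            ok <- FALSE; break
          }
        }
        if (!ok) break
      }
      if (ok) { placed <- p_new; break }
    }
    if (is.null(placed)) {  # this leaf cannot branch; retire it
      leaves <- leaves[-li]
      leaf_dir <- leaf_dir[-li]
      next
    }
    leaves <- leaves[-li]
    leaf_dir <- leaf_dir[-li]
    for (j in 1:2) {
      pos[[length(pos) + 1]] <- placed[[j]]
      segs[[length(segs) + 1]] <- c(leaf, length(pos))
      leaves <- c(leaves, length(pos))
      leaf_dir <- c(leaf_dir, list(unitize(placed[[j]] - pos[[leaf]])))
    }
  }
  list(pos = do.call(rbind, pos), segs = do.call(rbind, segs))
}

gen_random_tree <- function(spec) {
  ext <- spec$extent_mm
  tr <- grow_branching_tree(
    n_edges = spec$n_edges, root = c(-ext / 2, 0, 0),
    root_heading = c(1, 0, 0),
    seg_len = function() runif(1, 0.2, 0.35) * ext,
    sep = max(0.1 * ext, 3 * spec$channel_diameter_um / 1000))
  ids <- sprintf("n%d", seq_len(nrow(tr$pos)))
  nodes <- node_df(ids, tr$pos)
  edges <- lapply(seq_len(nrow(tr$segs)), function(i) {
    s <- tr$segs[i, ]
    vessel_edge(sprintf("e%d", i), ids[s[1]], ids[s[2]],
                rbind(tr$pos[s[1], ], tr$pos[s[2], ]),
                spec$channel_diameter_um)
  })
  vessel_graph(nodes, edges, frame = "random_tree")
}

gen_invivo <- function(spec) {
  # quasi-planar pial-like network: a venous and an arterial subtree grown
  # into opposite halves of the window; diameters in 10-40 um (larger
  # trunks get the vein/artery label, finer branches venule/arteriole);
  # small z jitter emulates the pial surface.
  n_half <- max(3L, spec$n_edges %/% 2L)
  ext <- spec$extent_mm
  sep <- max(3 * 0.040, 0.12 * ext)  # >= 3 max diameters between tubes
  build_subtree <- function(root, root_heading, prefix, classes, leaf_band) {
    tr <- grow_branching_tree(n_half, root, root_heading,
                              seg_len = function() runif(1, 0.22, 0.38) * ext,
                              sep = sep)
    pos <- tr$pos
    pos[, 3] <- rnorm(nrow(pos), 0, 0.01)  # ~10 um z jitter
    # terminal branches draw their caliber; internal trunks follow
    # Murray's law (cubes add at bifurcations), which makes the linear
    # flow-diameter law exactly conservation-consistent
    ne <- nrow(tr$segs)
    d <- numeric(ne)
    for (i in rev(seq_len(ne))) {  # children are appended after parents
      kids <- which(tr$segs[, 1] == tr$segs[i, 2])
      d[i] <- if (!length(kids)) runif(1, leaf_band[1], leaf_band[2])
              else min(sum(d[kids]^3)^(1 / 3), 40)
    }
    ids <- sprintf("%s%d", prefix, seq_len(nrow(pos)))
    thr <- mean(range(d)) # larger trunks take the major-vessel label
    list(nodes = node_df(ids, pos),
         edges = lapply(seq_len(ne), function(i) {
           s <- tr$segs[i, ]
           cls <- if (d[i] >= thr) classes[1] else classes[2]
           vessel_edge(sprintf("%se%d", prefix, i), ids[s[1]], ids[s[2]],
                       rbind(pos[s[1], ], pos[s[2], ]), d[i],
                       vessel_class = cls)
         }))
  }
  off <- ext * 0.45
  ven <- build_subtree(c(-off, 0, 0), c(1, 0, 0), "v", c("vein", "venule"),
                       leaf_band = c(10, 20))
  art <- build_subtree(c(off, 0, 0), c(-1, 0, 0), "a",
                       c("artery", "arteriole"), leaf_band = c(10, 13))
  # keep the two subtrees clear of each other: shift each back toward its
  # own half until no cross-subtree segment pair violates the separation
  shift <- 0
  repeat {
    ok <- TRUE
    for (e1 in ven$edges) for (e2 in art$edges) {
      a <- e1$centerline[1, 1:2] - c(shift, 0)
      b <- e1$centerline[2, 1:2] - c(shift, 0)
      cc <- e2$centerline[1, 1:2] + c(shift, 0)
      dd <- e2$centerline[2, 1:2] + c(shift, 0)
      if (seg_seg_dist(a, b, cc, dd) < sep) { ok <- FALSE; break }
    }
    if (ok || shift > 3 * ext) break
    shift <- shift + 0.1 * ext
  }
  apply_shift <- function(part, dx) {
    part$nodes$x <- part$nodes$x + dx
    part$edges <- lapply(part$edges, function(e) {
      e$centerline[, 1] <- e$centerline[, 1] + dx
      e
    })
    part
  }
  ven <- apply_shift(ven, -shift)
  art <- apply_shift(art, shift)
  vessel_graph(rbind(ven$nodes, art$nodes), c(ven$edges, art$edges),
               frame = "invivo")
}

#' Place transducers for a device layout
#'
#' `cylinder`: nine elements on the straight-channel device — eight on the
#' side wall at axial offsets reproducing the incidence-angle set
#' 22.5/45/67.5/90 degrees, plus one on top aligned with the channel.
#' `frustum`: 18 elements in two rows of nine (heights 3 and 6 mm) at 40
#' degree azimuthal spacing on the cone's lateral surface. `invivo`: four
#' elements around the cranial window with orthogonal headings.
#'
#' @param layout "cylinder", "frustum", or "invivo".
#' @param frequency_khz drive frequency, kHz.
#' @param voltage_vpp drive voltage; defaults per layout (15 cylinder,
#'   15 frustum, 35 invivo).
#' @return list of [transducer()] objects.
#' @export
place_transducers <- function(layout = c("cylinder", "frustum", "invivo"),
                              frequency_khz = 490, voltage_vpp = NULL) {
  layout <- match.arg(layout)
  mk <- function(id, center, dir, V)
    transducer(id, center, dir, frequency_khz, V, active = FALSE)
  if (layout == "cylinder") {
    V <- if (is.null(voltage_vpp)) 15 else voltage_vpp
    R <- 2.15  # device radius = nearest printed channel distance, mm
    # side elements at axial offset R/tan(alpha) give incidence angles
    # 67.5 / 45 / 22.5 at the channel midpoint; y = 0 gives 90.
    off <- function(a_deg) R / tan(a_deg * pi / 180)
    centers <- list(
      `1` = c(R, 0, 0),                     # 90 deg, red
      `2` = c(R, off(67.5), 0),             # green side, above origin
      `3` = c(R, off(45), 0),
      `4` = c(R, off(22.5), 0),
      `5` = c(-R, 0, 0),                    # 90 deg, red
      `6` = c(R, -off(22.5), 0),            # yellow side, below origin
      `7` = c(R, -off(45), 0),
      `8` = c(R, -off(67.5), 0),
      `9` = c(0, 9, 0))                     # top element, along the channel
    return(lapply(names(centers), function(id) {
      ctr <- centers[[id]]
      mk(id, ctr, unitize(-ctr), V)
    }))
  }
  if (layout == "frustum") {
    V <- if (is.null(voltage_vpp)) 15 else voltage_vpp
    # cone frustum, bottom radius 5.5 mm tapering 0.15 mm per mm height
    radius_at <- function(z) 5.5 - 0.15 * z
    out <- list(); k <- 0
    for (row in 1:2) {
      z <- c(3, 6)[row]
      for (j in 0:8) {
        k <- k + 1
        az <- j * 40  # degrees, clockwise from the x = 0 line (+y axis)
        ctr <- c(radius_at(z) * sin(az * pi / 180),
                 radius_at(z) * cos(az * pi / 180), z)
        out[[k]] <- mk(as.character(k), ctr, unitize(c(-ctr[1], -ctr[2], 0)), V)
      }
    }
    return(out)
  }
  # invivo: four elements around the window at the cardinal directions,
  # headings pairwise orthogonal between neighbors
  V <- if (is.null(voltage_vpp)) 35 else voltage_vpp
  Rw <- 5  # mm from window center
  dirs <- list(`1` = c(-1, 0, 0), `2` = c(0, -1, 0),
               `3` = c(1, 0, 0), `4` = c(0, 1, 0))
  lapply(names(dirs), function(id)
    mk(id, -Rw * dirs[[id]], dirs[[id]], V))
}

#' Azimuths (degrees, clockwise from x = 0) of a transducer list
#'
#' Helper for rim layouts: polar angle of each element's center in the x-y
#' plane, measured clockwise from the +y axis (the x = 0 line).
#'
#' @param transducers list of `transducer`.
#' @return numeric vector in [0, 360).
#' @export
transducer_azimuths <- function(transducers) {
  vapply(transducers, function(t) {
    a <- atan2(t$center[1], t$center[2]) * 180 / pi
    (a + 360) %% 360
  }, numeric(1))
}

#' Render a vessel graph to a phantom angiogram image
#'
#' Draws each edge as a bright tube of its own diameter on a dark
#' background, then applies Gaussian blur and additive Gaussian noise
#' (both from the spec, seeded). The image covers the x-y bounding box of
#' the graph plus a margin.
#'
#' @param g a `vessel_graph`.
#' @param spec a [phantom_spec()] (voxel size, blur, noise, seed).
#' @return an [angiogram_image()].
#' @export
render_phantom_image <- function(g, spec) {
  vox_mm <- spec$voxel_size_um / 1000
  margin <- max(vapply(g$edges, `[[`, numeric(1), "diameter_um")) / 1000 * 2 +
    4 * spec$blur_sigma_px * vox_mm
  xs <- unlist(lapply(g$edges, function(e) e$centerline[, 1]))
  ys <- unlist(lapply(g$edges, function(e) e$centerline[, 2]))
  x0 <- min(xs) - margin; y0 <- min(ys) - margin
  nx <- ceiling((max(xs) - min(xs) + 2 * margin) / vox_mm)
  ny <- ceiling((max(ys) - min(ys) + 2 * margin) / vox_mm)
  img <- matrix(0, nrow = ny, ncol = nx)  # row = y, col = x
  px <- x0 + (seq_len(nx) - 0.5) * vox_mm
  py <- y0 + (seq_len(ny) - 0.5) * vox_mm
  PX <- matrix(px, ny, nx, byrow = TRUE)
  PY <- matrix(py, ny, nx)
  for (e in g$edges) {
    rad_mm <- e$diameter_um / 2000
    cl <- e$centerline
    for (i in seq_len(nrow(cl) - 1)) {
      a <- cl[i, 1:2]; b <- cl[i + 1, 1:2]
      ab <- b - a; len2 <- sum(ab^2)
      tpar <- ((PX - a[1]) * ab[1] + (PY - a[2]) * ab[2]) / max(len2, 1e-12)
      tpar[tpar < 0] <- 0; tpar[tpar > 1] <- 1
      d2 <- (PX - (a[1] + tpar * ab[1]))^2 + (PY - (a[2] + tpar * ab[2]))^2
      img[d2 <= rad_mm^2] <- 1
    }
  }
  img <- with_seed(spec$seed + 1L, {
    if (spec$blur_sigma_px > 0)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                      sigma = spec$blur_sigma_px))
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                          nrow = nrow(img))
    img
  })
  angiogram_image(img, voxel_size_um = spec$voxel_size_um,
                  origin_mm = c(x0, y0))
}

#' Assign flows to a vessel graph
#'
#' Terminal (leaf) edges receive a centerline speed m x diameter + noise
#' (clipped to [0, 10] mm/s, the physiological ceiling); internal edges
#' receive the speed implied by volumetric conservation of their summed
#' child flows, so junction imbalance vanishes by construction. Venous
#' classes are slowed by a class factor (vein 0.6, venule 0.5) so veins and
#' venules carry slower flow than arteries. Flow runs rootward in venous
#' subtrees and leafward in arterial ones.
#'
#' @param g a `vessel_graph` (tree or forest for conservation; cycles fall
#'   back to the per-edge linear law).
#' @param slope m in (mm/s)/µm, default 0.25 (anchors 40 µm to the 10 mm/s
#'   ceiling).
#' @param noise_sd flow noise sd, mm/s.
#' @param seed RNG seed.
#' @return the graph with `flow_mm_s`/`flow_sign` set on every edge.
#' @export
assign_flows <- function(g, slope = 0.25, noise_sd = 0, seed = 1L) {
  # arteries run faster than veins at matched caliber (pial arterioles vs
  # venules); the factor is uniform within each circuit so conservation
  # propagation stays consistent with the linear law. The base law
  # (factor 1) anchors the 40 um -> 10 mm/s ceiling.
  cls_factor <- c(artery = 1.8, arteriole = 1.8, vein = 0.5, venule = 0.5,
                  capillary = 0.8, unknown = 1)
  et <- edge_table(g)
  ig <- igraph::graph_from_data_frame(et[, c("from", "to")], directed = FALSE,
                                      vertices = as.character(g$nodes$id))
  acyclic <- igraph::ecount(ig) ==
    igraph::vcount(ig) - igraph::count_components(ig)
  flows <- with_seed(seed, {
    base <- pmax(slope * et$diameter_um + rnorm(nrow(et), 0, noise_sd), 0)
    pmin(base * cls_factor[et$vessel_class], 10)
  })
  out <- g
  if (acyclic) {
    # leaves -> root volumetric propagation per connected component: a
    # terminal edge takes the linear diameter law; every internal edge
    # carries the sum of its child edges' volumetric flows, so junction
    # imbalance is zero by construction.
    Q <- rep(NA_real_, nrow(et))  # volumetric flow, mm^3/s
    area <- pi * (et$diameter_um / 2000)^2
    incident <- function(node) which(et$from == node | et$to == node)
    other_end <- function(ei, node) if (et$from[ei] == node) et$to[ei] else et$from[ei]
    visit <- function(node, via) {
      for (ei in setdiff(incident(node), via)) {
        child <- other_end(ei, node)
        visit(child, ei)
        kids <- setdiff(incident(child), ei)
        Q[ei] <<- if (!length(kids)) flows[ei] * area[ei] else sum(Q[kids])
      }
    }
    comp <- igraph::components(ig)$membership
    deg <- igraph::degree(ig)
    for (cid in unique(comp)) {
      vids <- names(comp)[comp == cid]
      root <- vids[which.max(deg[vids])]
      visit(root, integer(0))
    }
    flows <- pmin(Q / area, 10)
  }
  for (i in seq_len(nrow(et))) {
    e <- out$edges[[et$edge_id[i]]]
    e$flow_mm_s <- flows[i]
    # venous subtrees drain rootward (toward `from`), arterial feed leafward
    e$flow_sign <- if (e$vessel_class %in% c("vein", "venule")) -1L else 1L
    out$edges[[et$edge_id[i]]] <- e
  }
  out
}

#' Sample an injected microbubble population
#'
#' Diameters uniform in the manufacturing band 1.1-1.4 µm; a seeded subset
#' (default 3%) is flagged as acoustic responders — the fraction that
#' reacts to ultrasound by joining swarms.
#'
#' @param count number of bubbles (>= 1).
#' @param responder_fraction fraction flagged as responders, default 0.03.
#' @param seed RNG seed.
#' @param diameter_range_um sampling band, µm.
#' @return data.frame with columns diameter_um, responder.
#' @export
sample_bubble_injection <- function(count, responder_fraction = 0.03, seed = 1L,
                                    diameter_range_um = c(1.1, 1.4)) {
  stopifnot(count >= 1, responder_fraction > 0, responder_fraction <= 1)
  with_seed(seed, data.frame(
    diameter_um = runif(count, diameter_range_um[1], diameter_range_um[2]),
    responder = runif(count) < responder_fraction))
}
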