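# Imaging front-end: angiogram containers and TIFF I/O, vessel-mask
# binarization, skeleton-based lattice extraction, swarm detection and
# nearest-neighbor tracking.

#' Construct an angiogram image
#'
#' Grayscale 2D image (or 3D stack) with physical pixel size and, for
#' time-lapse data, the frame interval. Pixels are row-major, 0-based in
#' the exported CSV convention; `origin_mm` maps pixel centers to the mm
#' frame: x = origin[1] + (col - 0.5) * voxel, y = origin[2] + (row - 0.5)
#' * voxel.
#'
#' @param pixels numeric matrix (y by x) or 3D array (y, x, frames).
#' @param voxel_size_um µm per pixel (> 0).
#' @param frame_interval_s seconds between frames (time-lapse only).
#' @param origin_mm x-y origin of the pixel grid in the graph frame, mm.
#' @return object of class `angiogram_image`.
#' @export
angiogram_image <- function(pixels, voxel_size_um, frame_interval_s = NA_real_,
                            origin_mm = c(0, 0)) {
  stopifnot(is.numeric(pixels), all(dim(pixels) >= 1), voxel_size_um > 0,
            all(is.finite(pixels)))
  structure(list(pixels = pixels, voxel_size_um = voxel_size_um,
                 frame_interval_s = frame_interval_s,
                 origin_mm = origin_mm),
            class = "angiogram_image")
}

#' Read a grayscale TIFF (single- or multi-page) as an angiogram
#' @param path TIFF file.
#' @param voxel_size_um µm per pixel.
#' @param frame_interval_s frame interval for stacks, s.
#' @return an `angiogram_image`; multi-page files become 3D arrays.
#' @export
read_angiogram_tiff <- function(path, voxel_size_um, frame_interval_s = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  to_gray <- function(p) if (length(dim(p)) == 3) p[, , 1] else p
  pixels <- if (length(pages) == 1) to_gray(pages[[1]]) else
    simplify2array(lapply(pages, to_gray))
  angiogram_image(pixels, voxel_size_um, frame_interval_s)
}

#' Write an angiogram as TIFF
#' @param image an `angiogram_image`.
#' @param path output path; intensities are clipped to [0, 1].
#' @export
write_angiogram_tiff <- function(image, path) {
  px <- pmin(pmax(image$pixels, 0), 1)
  if (length(dim(px)) == 3) {
    tiff::writeTIFF(lapply(seq_len(dim(px)[3]), function(i) px[, , i]), path)
  } else {
    tiff::writeTIFF(px, path)
  }
  invisible(path)
}

frame_matrix <- function(image, frame = 1L) {
  px <- image$pixels
  if (length(dim(px)) == 3) px[, , frame] else px
}

#' Binarize a vasculature image
#'
#' Foreground = vessel lumen. The default method is Otsu's threshold (the
#' same intensity-based thresholding used for swarm masks); a fixed
#' quantile threshold is available as an alternative.
#'
#' @param image an `angiogram_image` (2D, or a stack whose max projection
#'   is used).
#' @param method "otsu" or "quantile".
#' @param quantile foreground quantile for `method = "quantile"`.
#' @return logical matrix, same x-y shape as the image.
#' @export
binarize_vasculature <- function(image, method = c("otsu", "quantile"),
                                 quantile = 0.9) {
  method <- match.arg(method)
  px <- image$pixels
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), max)
  if (all(px == 0)) stop("blank input")
  rng <- range(px)
  if (diff(rng) <= .Machine$double.eps)
    stop("constant-intensity image: no bimodality to threshold")
  scaled <- (px - rng[1]) / diff(rng)
  thr <- if (method == "otsu") EBImage::otsu(EBImage::Image(scaled))
         else stats::quantile(scaled, quantile)
  scaled > thr
}

# ---- Zhang-Suen morphological thinning ----------------------------------

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Morphological thinning (Guo-Hall) of a binary mask
#'
#' Two-subiteration parallel thinning down to a 1-pixel-wide 8-connected
#' skeleton. The connectivity operator C(p) guarantees simple-point
#' deletion and the min(N1, N2) neighbor count protects line tips —
#' including 2-pixel diagonal tips, which cruder schemes erode or
#' disconnect.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of skeleton pixels.
#' @export
thin_mask <- function(mask) {
  M <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  # neighborhood labels: p1 p2 p3 / p8 p p4 / p7 p6 p5 (row = y down)
  off <- list(p1 = c(-1, -1), p2 = c(-1, 0), p3 = c(-1, 1), p4 = c(0, 1),
              p5 = c(1, 1), p6 = c(1, 0), p7 = c(1, -1), p8 = c(0, -1))
  repeat {
    changed <- FALSE
    for (odd in c(TRUE, FALSE)) {
      # value of the neighbor at (dr, dc) lands at (r, c) after a
      # shift by (-dr, -dc)
      P <- lapply(off, function(o) shift_mat(M, -o[1], -o[2]))
      C <- (1L - P$p2) * pmax(P$p3, P$p4) +
           (1L - P$p4) * pmax(P$p5, P$p6) +
           (1L - P$p6) * pmax(P$p7, P$p8) +
           (1L - P$p8) * pmax(P$p1, P$p2)
      N1 <- pmax(P$p1, P$p2) + pmax(P$p3, P$p4) +
            pmax(P$p5, P$p6) + pmax(P$p7, P$p8)
      N2 <- pmax(P$p2, P$p3) + pmax(P$p4, P$p5) +
            pmax(P$p6, P$p7) + pmax(P$p8, P$p1)
      N <- pmin(N1, N2)
      m <- if (odd) pmax(P$p2, P$p3, 1L - P$p5) * P$p4
           else pmax(P$p6, P$p7, 1L - P$p1) * P$p8
      del <- M == 1L & C == 1L & N >= 2L & N <= 3L & m == 0L
      if (any(del)) {
        M[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  M == 1L
}

neighbor_count <- function(M) {
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  Reduce(`+`, lapply(offs, function(o) shift_mat(M, o[1], o[2])))
}

# crossing number: 0->1 transitions around the 8-neighborhood. 1 at line
# endpoints, 2 on line pixels (staircase corners included), >= 3 at branch
# points -- unlike the raw neighbor count, which misclassifies staircases.
transition_count <- function(M) {
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  P <- lapply(offs, function(o) shift_mat(M, o[1], o[2]))
  ring <- c(P, P[1])
  Reduce(`+`, lapply(1:8, function(i)
    as.integer(ring[[i]] == 0 & ring[[i + 1]] == 1)))
}

#' Extract a vessel lattice from a binary mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning), places nodes at skeleton
#' endpoints and branch points, traces branch-to-branch centerlines, prunes
#' spur branches shorter than the local vessel diameter, and estimates each
#' edge's diameter as 2 x the mean distance-transform value along its
#' centerline.
#'
#' @param mask logical matrix from [binarize_vasculature()].
#' @param voxel_size_um µm per pixel.
#' @param origin_mm pixel-grid origin in the mm frame.
#' @param prune logical; prune spur branches (default TRUE).
#' @param frame frame tag for the output graph.
#' @return a `vessel_graph` with centerlines in mm and diameters in µm.
#' @export
extract_lattice <- function(mask, voxel_size_um, origin_mm = c(0, 0),
                            prune = TRUE, frame = "image") {
  if (!any(mask)) stop("empty mask: no foreground component")
  M <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  dmap <- as.matrix(EBImage::distmap(EBImage::Image(M)))
  skel <- thin_mask(M)
  g <- skeleton_to_graph(skel, dmap, voxel_size_um, origin_mm, frame)
  if (prune) g <- prune_spurs(g)
  g
}

skeleton_to_graph <- function(skel, dmap, voxel_size_um, origin_mm, frame) {
  S <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  cn <- transition_count(S)
  is_node_px <- skel & (cn != 2)
  if (!any(is_node_px)) {
    # closed loop or single pixel: treat extremes as nodes
    idx <- which(skel, arr.ind = TRUE)
    is_node_px[idx[1, 1], idx[1, 2]] <- TRUE
    if (nrow(idx) > 1) is_node_px[idx[nrow(idx), 1], idx[nrow(idx), 2]] <- TRUE
  }
  # cluster node pixels into junction blobs: thinning can fragment one
  # physical branch point into several branch pixels a few pixels apart,
  # so label the dilated mask (radius 2) and read labels back onto the
  # actual node pixels
  np <- matrix(as.integer(is_node_px), nrow(skel))
  dil <- np
  for (pass in 1:2) {
    offs8 <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                  c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
    dil <- pmin(dil + Reduce(`+`, lapply(offs8, function(o)
      shift_mat(dil, o[1], o[2]))), 1L)
  }
  dil_lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(dil))),
                    nrow(skel))
  node_lab <- dil_lab * np
  # renumber labels consecutively over the actual node pixels
  present <- sort(unique(node_lab[node_lab > 0]))
  node_lab <- matrix(match(node_lab, present, nomatch = 0L), nrow(skel))
  n_nodes <- length(present)
  node_pos_px <- t(vapply(seq_len(n_nodes), function(k) {
    idx <- which(node_lab == k, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(2)))
  px_to_mm <- function(rc) {
    vox <- voxel_size_um / 1000
    cbind(origin_mm[1] + (rc[, 2] - 0.5) * vox,
          origin_mm[2] + (rc[, 1] - 0.5) * vox, 0)
  }
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nbrs <- function(r, c) {
    out <- list()
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= nrow(skel) && cc >= 1 && cc <= ncol(skel) &&
          skel[rr, cc]) out[[length(out) + 1]] <- c(rr, cc)
    }
    out
  }
  visited <- matrix(FALSE, nrow(skel), ncol(skel))
  edges <- list(); eid <- 0
  for (k in seq_len(n_nodes)) {
    node_px <- which(node_lab == k, arr.ind = TRUE)
    for (i in seq_len(nrow(node_px))) {
      r0 <- node_px[i, 1]; c0 <- node_px[i, 2]
      for (nbp in nbrs(r0, c0)) {
        if (node_lab[nbp[1], nbp[2]] == k) next          # same junction blob
        if (visited[nbp[1], nbp[2]] && node_lab[nbp[1], nbp[2]] == 0) next
        path <- list(c(r0, c0))
        interior <- list()
        cur <- nbp; prev <- c(r0, c0)
        repeat {
          path[[length(path) + 1]] <- cur
          if (node_lab[cur[1], cur[2]] > 0) break         # reached a node
          visited[cur[1], cur[2]] <- TRUE
          interior[[length(interior) + 1]] <- cur
          cand <- Filter(function(p) !(p[1] == prev[1] && p[2] == prev[2]) &&
                           !(visited[p[1], p[2]] && node_lab[p[1], p[2]] == 0),
                         nbrs(cur[1], cur[2]))
          if (!length(cand)) break
          # terminate at any other node blob before continuing along the line
          labs <- vapply(cand, function(p) node_lab[p[1], p[2]], numeric(1))
          pref <- c(which(labs > 0 & labs != k), which(labs == 0),
                    which(labs == k))
          prev <- cur; cur <- cand[[pref[1]]]
        }
        endk <- node_lab[cur[1], cur[2]]
        if (endk == 0 || (endk == k && length(path) < 10)) {
          # dead trace or a short intra-junction bridge: release its pixels
          # so genuine branches leaving the same blob can still be traced
          for (ip in interior) visited[ip[1], ip[2]] <- FALSE
          next
        }
        rc <- do.call(rbind, path)
        eid <- eid + 1
        dvals <- dmap[rc]
        edges[[eid]] <- list(from = k, to = endk, rc = rc,
                             diameter_um = 2 * mean(dvals) * voxel_size_um)
      }
    }
  }
  # dedupe: the same branch is traced once from each end
  seen <- character(0); keep <- list()
  for (e in edges) {
    mid <- e$rc[ceiling(nrow(e$rc) / 2), ]
    key <- paste(min(e$from, e$to), max(e$from, e$to), mid[1], mid[2])
    if (key %in% seen) next
    seen <- c(seen, key)
    keep[[length(keep) + 1]] <- e
  }
  nodes <- node_df(sprintf("n%d", seq_len(n_nodes)),
                   px_to_mm(matrix(node_pos_px, ncol = 2)))
  vedges <- lapply(seq_along(keep), function(i) {
    e <- keep[[i]]
    cl <- px_to_mm(e$rc)
    # drop consecutive duplicate points (can arise at junction blobs)
    d <- c(TRUE, rowSums(abs(diff(cl))) > 1e-12)
    cl <- cl[d, , drop = FALSE]
    if (nrow(cl) < 2) return(NULL)
    vessel_edge(sprintf("e%d", i), sprintf("n%d", e$from),
                sprintf("n%d", e$to), cl, e$diameter_um)
  })
  vedges <- Filter(Negate(is.null), vedges)
  vessel_graph(nodes, vedges, frame = frame)
}

#' Prune spur branches and dissolve pass-through nodes
#'
#' Removes terminal edges shorter than their own estimated vessel diameter
#' (thinning artifacts at junctions), then merges chains through nodes left
#' with exactly two incident edges.
#'
#' @param g a `vessel_graph`.
#' @return pruned graph.
#' @export
prune_spurs <- function(g) {
  repeat {
    et <- edge_table(g)
    deg <- table(c(et$from, et$to))
    spur <- which(et$length_mm * 1000 < et$diameter_um &
                    (deg[et$from] == 1 | deg[et$to] == 1) &
                    nrow(et) > 1)
    if (!length(spur)) break
    drop_id <- et$edge_id[spur[1]]
    g$edges[[drop_id]] <- NULL
    g <- drop_orphan_nodes(g)
    g <- dissolve_degree2(g)
  }
  dissolve_degree2(drop_orphan_nodes(g))
}

drop_orphan_nodes <- function(g) {
  used <- unique(unlist(lapply(g$edges, function(e) c(e$from, e$to))))
  g$nodes <- g$nodes[g$nodes$id %in% used, , drop = FALSE]
  g
}

dissolve_degree2 <- function(g) {
  repeat {
    et <- edge_table(g)
    if (!nrow(et)) break
    deg <- table(c(et$from, et$to))
    # a pass-through node: exactly 2 distinct incident edges
    cand <- names(deg)[deg == 2]
    cand <- Filter(function(nid) {
      inc <- which(et$from == nid | et$to == nid)
      length(inc) == 2
    }, cand)
    if (!length(cand)) break
    nid <- cand[[1]]
    inc <- which(et$from == nid | et$to == nid)
    e1 <- g$edges[[et$edge_id[inc[1]]]]
    e2 <- g$edges[[et$edge_id[inc[2]]]]
    # orient both polylines so they meet at nid
    cl1 <- if (e1$to == nid) e1$centerline else e1$centerline[nrow(e1$centerline):1, ]
    a1 <- if (e1$to == nid) e1$from else e1$to
    cl2 <- if (e2$from == nid) e2$centerline else e2$centerline[nrow(e2$centerline):1, ]
    a2 <- if (e2$from == nid) e2$to else e2$from
    cl <- rbind(cl1, cl2[-1, , drop = FALSE])
    keep <- c(TRUE, rowSums(abs(diff(cl))) > 1e-12)
    cl <- cl[keep, , drop = FALSE]
    l1 <- edge_length_mm(e1); l2 <- edge_length_mm(e2)
    dnew <- (e1$diameter_um * l1 + e2$diameter_um * l2) / (l1 + l2)
    merged <- vessel_edge(e1$id, a1, a2, cl, dnew, e1$vessel_class,
                          e1$flow_mm_s, e1$flow_sign)
    g$edges[[et$edge_id[inc[1]]]] <- NULL
    g$edges[[et$edge_id[inc[2]]]] <- NULL
    g$edges[[as.character(merged$id)]] <- merged
    g <- drop_orphan_nodes(g)
  }
  g
}

#' Detect microswarm masks in a frame
#'
#' Otsu-thresholds the frame (swarms are the brightest structures), labels
#' connected components, and returns one detection per region above the
#' minimum-area cutoff: centroid (pixels), equivalent-circle diameter in µm
#' (sqrt(4A/pi) x pixel size), and mean intensity. With
#' `diameter = "feret"` the maximum Feret diameter is reported instead.
#'
#' @param frame an `angiogram_image` (single frame).
#' @param min_area_px minimum region area in pixels.
#' @param diameter "equivalent" (circle of equal area) or "feret" (max
#'   caliper).
#' @return data.frame with columns frame, x_px, y_px, diameter_um,
#'   mean_intensity (0 rows if nothing detected).
#' @export
detect_swarm_masks <- function(frame, min_area_px = 5,
                               diameter = c("equivalent", "feret")) {
  diameter <- match.arg(diameter)
  px <- frame_matrix(frame)
  empty <- data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                      diameter_um = numeric(0), mean_intensity = numeric(0))
  rng <- range(px)
  if (diff(rng) <= .Machine$double.eps) return(empty)
  scaled <- (px - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled))
  mask <- scaled > thr
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(
    matrix(as.integer(mask), nrow(mask))))), nrow(mask))
  if (max(lab) == 0) return(empty)
  rows <- lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    A <- nrow(idx)
    if (A < min_area_px) return(NULL)
    d_px <- if (diameter == "equivalent") sqrt(4 * A / pi) else {
      if (A == 1) 1 else max(stats::dist(idx))
    }
    data.frame(frame = 1L, x_px = mean(idx[, 2]), y_px = mean(idx[, 1]),
               diameter_um = d_px * frame$voxel_size_um,
               mean_intensity = mean(px[idx]))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Detect swarms across a time-lapse stack
#' @param stack an `angiogram_image` with a 3D pixel array.
#' @param ... passed to [detect_swarm_masks()].
#' @return data.frame of detections with the frame column set.
#' @export
detect_swarm_stack <- function(stack, ...) {
  nf <- dim(stack$pixels)[3]
  out <- lapply(seq_len(nf), function(f) {
    fr <- angiogram_image(frame_matrix(stack, f), stack$voxel_size_um)
    d <- detect_swarm_masks(fr, ...)
    if (nrow(d)) d$frame <- f
    d
  })
  do.call(rbind, out)
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbor linking between consecutive frames within
#' `max_link_um`; unmatched detections open new tracks. Per-step speed is
#' displacement / frame interval.
#'
#' @param detections data.frame from [detect_swarm_stack()] (columns frame,
#'   x_px, y_px, diameter_um).
#' @param frame_interval_s seconds per frame.
#' @param voxel_size_um µm per pixel.
#' @param max_link_um maximum linking displacement, µm.
#' @return data.frame with track_id, frame, x_px, y_px, diameter_um,
#'   speed_um_s (NA on each track's first frame).
#' @export
track_swarms <- function(detections, frame_interval_s, voxel_size_um,
                         max_link_um = 20) {
  if (!nrow(detections)) return(cbind(detections, track_id = integer(0),
                                      speed_um_s = numeric(0)))
  frames <- sort(unique(detections$frame))
  if (length(frames) < 2) stop("tracking needs at least 2 frames")
  detections$track_id <- NA_integer_
  detections$speed_um_s <- NA_real_
  next_id <- 1L
  prev_idx <- which(detections$frame == frames[1])
  detections$track_id[prev_idx] <- seq_along(prev_idx)
  next_id <- length(prev_idx) + 1L
  for (fi in seq_along(frames)[-1]) {
    cur_idx <- which(detections$frame == frames[fi])
    if (!length(cur_idx)) { prev_idx <- cur_idx; next }
    if (length(prev_idx)) {
      D <- outer(seq_along(prev_idx), seq_along(cur_idx), function(i, j) {
        sqrt((detections$x_px[prev_idx[i]] - detections$x_px[cur_idx[j]])^2 +
             (detections$y_px[prev_idx[i]] - detections$y_px[cur_idx[j]])^2) *
          voxel_size_um
      })
      D <- matrix(D, length(prev_idx), length(cur_idx))
      while (TRUE) {
        m <- which(D == min(D), arr.ind = TRUE)[1, , drop = FALSE]
        if (!is.finite(D[m]) || D[m] > max_link_um) break
        pi_ <- prev_idx[m[1]]; ci <- cur_idx[m[2]]
        detections$track_id[ci] <- detections$track_id[pi_]
        dt <- (detections$frame[ci] - detections$frame[pi_]) * frame_interval_s
        detections$speed_um_s[ci] <- D[m] / dt
        D[m[1], ] <- Inf; D[, m[2]] <- Inf
        if (all(!is.finite(D))) break
      }
    }
    new <- cur_idx[is.na(detections$track_id[cur_idx])]
    if (length(new)) {
      detections$track_id[new] <- seq(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  detections
}

#' Write detections or tracks as CSV
#' @param x data.frame of detections/tracks.
#' @param path output path.
#' @export
write_tracks <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
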