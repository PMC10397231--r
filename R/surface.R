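# 3D vessel surface construction: circular cross-section contours at sampled
# centerline points, parallel-transport framing, lofted triangulated tubes,
# junction repair by contour-radius adjustment + bridging, local Laplacian
# smoothing, and mesh export/import.
#
# 3D convention: the image plane maps to (x, y) = (col, row) * px_size with
# the centerline at z = 0; circular cross-sections supply the z extent. This
# is how a single 2D image yields a 3D model.

.rodrigues <- function(v, axis, ang) {
  if (sqrt(sum(axis^2)) < 1e-12 || abs(ang) < 1e-12) return(v)
  k <- axis / sqrt(sum(axis^2))
  v * cos(ang) + .cross3(k, v) * sin(ang) + k * sum(k * v) * (1 - cos(ang))
}
.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Build circular cross-section contours along a profiled centerline
#'
#' Each sampled centerline point gets a ring of `n_pts` vertices of its
#' measured radius, in the plane orthogonal to the local tangent. Ring
#' orientation is propagated by parallel transport of the first ring's frame
#' (twist-minimizing). Consecutive rings are checked for intersection — a
#' following ring whose vertices fall behind the previous ring's plane is
#' removed (local re-downsampling) so that neighbouring contours never
#' cross; first and last rings are always kept.
#'
#' @param profile a `centerline_profile`.
#' @param n_pts vertices per ring (>= 8).
#' @return list with one element per segment: `centers` (m x 3), `radii`,
#'   `rings` (list of n_pts x 3 matrices), `from`, `to` node ids.
#' @export
build_contours <- function(profile, n_pts = 24L) {
  stopifnot(n_pts >= 8L)
  ps <- profile$px_size
  lapply(profile$segments, function(seg) {
    if (any(seg$radii <= 0)) {
      bad <- which(seg$radii <= 0)[1L]
      stop(sprintf("non-positive radius at segment point %d (row %.1f col %.1f)",
                   bad, seg$points[bad, 1L], seg$points[bad, 2L]))
    }
    m <- nrow(seg$points)
    centers <- cbind(seg$points[, 2L] * ps, seg$points[, 1L] * ps, 0)
    t3 <- cbind(seg$tangents[, 2L], seg$tangents[, 1L], 0)
    theta <- 2 * pi * (seq_len(n_pts) - 1L) / n_pts
    e2 <- c(0, 0, 1)
    e1 <- unit_vec(.cross3(e2, t3[1L, ]))
    rings <- vector("list", m)
    for (i in seq_len(m)) {
      if (i > 1L) {
        axis <- .cross3(t3[i - 1L, ], t3[i, ])
        s <- sqrt(sum(axis^2))
        ang <- atan2(s, sum(t3[i - 1L, ] * t3[i, ]))
        e1 <- .rodrigues(e1, axis, ang)
        # re-orthogonalize against drift
        e1 <- unit_vec(e1 - sum(e1 * t3[i, ]) * t3[i, ])
      }
      e2i <- .cross3(t3[i, ], e1)
      r <- seg$radii[i]
      rings[[i]] <- centers[rep(i, n_pts), , drop = FALSE] +
        r * (outer(cos(theta), e1) + outer(sin(theta), e2i))
    }
    # drop rings that intersect their predecessor's plane
    keep <- 1L
    for (i in 2L:m) {
      prev <- keep[length(keep)]
      ahead <- all((rings[[i]] %*% t3[prev, ]) >
                     sum(centers[prev, ] * t3[prev, ]) + 1e-12) &&
               all((rings[[prev]] %*% t3[i, ]) <
                     sum(centers[i, ] * t3[i, ]) - 1e-12)
      if (ahead || i == m) keep <- c(keep, i)
    }
    # the forced last ring may still clash with its predecessor: drop that
    # predecessor instead (never the endpoints)
    while (length(keep) >= 3L) {
      a <- keep[length(keep) - 1L]; b <- keep[length(keep)]
      ok <- all((rings[[b]] %*% t3[a, ]) > sum(centers[a, ] * t3[a, ]) + 1e-12)
      if (ok) break
      keep <- keep[-(length(keep) - 1L)]
    }
    list(centers = centers[keep, , drop = FALSE],
         radii = seg$radii[keep],
         rings = rings[keep],
         from = seg$from, to = seg$to)
  })
}

#' Loft a sequence of rings into an open triangulated tube
#'
#' Joins ring i vertex j to ring i+1 vertices j and j+1 (mod n), giving
#' 2 * n_pts * (k - 1) wall triangles for k rings.
#'
#' @param rings list of k >= 2 ring matrices with equal vertex counts.
#' @return list with `vertices` and `triangles` (1-based index triples).
#' @export
loft_segment <- function(rings) {
  k <- length(rings)
  if (k < 2L) stop("need at least 2 rings to loft")
  n <- nrow(rings[[1L]])
  if (any(vapply(rings, nrow, integer(1L)) != n)) {
    stop("all rings must have the same number of vertices")
  }
  vertices <- do.call(rbind, rings)
  tri <- matrix(0L, 2L * n * (k - 1L), 3L)
  row <- 1L
  for (i in seq_len(k - 1L)) {
    o1 <- (i - 1L) * n
    o2 <- i * n
    for (j in seq_len(n)) {
      j2 <- if (j == n) 1L else j + 1L
      tri[row, ] <- c(o1 + j, o2 + j, o2 + j2); row <- row + 1L
      tri[row, ] <- c(o1 + j, o2 + j2, o1 + j2); row <- row + 1L
    }
  }
  list(vertices = vertices, triangles = tri)
}

#' Construct a vessel surface mesh from a centerline profile
#'
#' Builds contours, repairs junction radii, lofts each segment into a tube,
#' bridges tube ends into their junction nodes with triangle fans to the
#' shared junction vertex, caps free ends (inlet/outlets), and optionally
#' applies junction-local Laplacian smoothing. The result has no boundary
#' edges: every tube end is either capped or bridged.
#'
#' At each junction the adjacent end-contour radii are compared; while
#' max/min exceeds `radius_ratio_threshold` the most protruding radius (the
#' largest deviation from the junction median on log scale) is pulled to the
#' median. `radius_ratio_threshold = Inf` disables adjustment.
#'
#' @param profile a `centerline_profile`.
#' @param n_pts ring vertices (default 24).
#' @param radius_ratio_threshold junction radius ratio triggering repair.
#' @param smooth_iterations Laplacian iterations applied near junctions.
#' @param lambda smoothing step in (0, 1].
#' @return object of class `vessel_mesh`: `vertices` (N x 3), `triangles`
#'   (M x 3, 1-based), `face_labels` (per triangle: "wall", "junction",
#'   "cap_node_<id>"), `cap_nodes` (node id per cap), `node_vertex` map.
#' @export
build_vessel_surface <- function(profile, n_pts = 24L,
                                 radius_ratio_threshold = 1.5,
                                 smooth_iterations = 3L, lambda = 0.5) {
  contours <- build_contours(profile, n_pts)
  contours <- .repair_junction_radii(contours, radius_ratio_threshold)

  nodes <- profile$nodes
  ps <- profile$px_size
  degree <- table(unlist(lapply(contours, function(s) c(s$from, s$to))))

  vertices <- NULL
  triangles <- NULL
  labels <- character(0)
  cap_nodes <- integer(0)
  node_vertex <- integer(0) # node id -> vertex index (junction centers)

  add_tri <- function(tr, lab) {
    triangles <<- rbind(triangles, tr)
    labels <<- c(labels, rep(lab, nrow(tr)))
  }
  for (seg in contours) {
    tube <- loft_segment(seg$rings)
    off <- if (is.null(vertices)) 0L else nrow(vertices)
    vertices <- rbind(vertices, tube$vertices)
    add_tri(tube$triangles + off, "wall")
    k <- length(seg$rings)
    for (end in c("from", "to")) {
      node_id <- seg[[end]]
      ring_idx <- if (end == "from") seq_len(n_pts) else (k - 1L) * n_pts + seq_len(n_pts)
      ring_idx <- ring_idx + off
      deg <- degree[[as.character(node_id)]]
      if (deg >= 2L) {
        # junction: fan to the shared node-center vertex
        key <- as.character(node_id)
        if (is.na(node_vertex[key] %||% NA)) {
          nd <- nodes[nodes$id == node_id, ]
          vertices <- rbind(vertices, c(nd$col * ps, nd$row * ps, 0))
          node_vertex[key] <- nrow(vertices)
        }
        ctr <- node_vertex[[as.character(node_id)]]
        lab <- "junction"
      } else {
        # free end: flat cap at the ring centroid
        vertices <- rbind(vertices, colMeans(vertices[ring_idx, , drop = FALSE]))
        ctr <- nrow(vertices)
        lab <- paste0("cap_node_", node_id)
        cap_nodes <- c(cap_nodes, node_id)
      }
      fan <- matrix(0L, n_pts, 3L)
      for (j in seq_len(n_pts)) {
        j2 <- if (j == n_pts) 1L else j + 1L
        # orientation: opposite winding at the two ends keeps the closed
        # surface consistently oriented
        fan[j, ] <- if (end == "from") c(ctr, ring_idx[j], ring_idx[j2])
                    else c(ctr, ring_idx[j2], ring_idx[j])
      }
      add_tri(fan, lab)
    }
  }
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         face_labels = labels, cap_nodes = cap_nodes,
                         node_vertex = node_vertex, px_size = ps),
                    class = "vessel_mesh")
  if (mesh_volume(mesh) < 0) { # flip to outward orientation
    mesh$triangles <- mesh$triangles[, c(1L, 3L, 2L)]
  }
  if (smooth_iterations > 0L && length(node_vertex) > 0L) {
    mesh <- laplacian_smooth(mesh, iterations = smooth_iterations,
                             lambda = lambda, junction_only = TRUE)
  }
  mesh
}

# Junction radius repair on the contour lists (see build_vessel_surface).
.repair_junction_radii <- function(contours, threshold) {
  if (!is.finite(threshold)) return(contours)
  stopifnot(threshold >= 1)
  ends <- list() # node id -> list of (segment index, end)
  for (si in seq_along(contours)) {
    for (end in c("from", "to")) {
      key <- as.character(contours[[si]][[end]])
      ends[[key]] <- c(ends[[key]], list(list(si = si, end = end)))
    }
  }
  for (key in names(ends)) {
    grp <- ends[[key]]
    if (length(grp) < 2L) next
    get_r <- function(g) {
      s <- contours[[g$si]]
      if (g$end == "from") s$radii[1L] else s$radii[length(s$radii)]
    }
    repeat {
      rs <- vapply(grp, get_r, numeric(1L))
      if (max(rs) / min(rs) <= threshold) break
      med <- stats::median(rs)
      worst <- which.max(abs(log(rs / med)))
      g <- grp[[worst]]
      s <- contours[[g$si]]
      i <- if (g$end == "from") 1L else length(s$radii)
      old <- s$radii[i]
      others <- rs[-worst]
      # minimal pull toward the median that satisfies the ratio
      s$radii[i] <- if (old > med) {
        max(med, min(others) * threshold * 0.999)
      } else {
        min(med, max(others) / threshold / 0.999)
      }
      # rescale the stored ring about its center
      ring <- s$rings[[i]]
      ctr <- s$centers[i, ]
      s$rings[[i]] <- sweep(sweep(ring, 2L, ctr), 1L, rep(med / old, nrow(ring)), `*`)
      s$rings[[i]] <- sweep(s$rings[[i]], 2L, ctr, `+`)
      contours[[g$si]] <- s
    }
  }
  contours
}

#' Local (or global) Laplacian mesh smoothing
#'
#' Each selected vertex moves toward the centroid of its edge neighbours:
#' v <- v + lambda * (centroid(neighbours) - v), for `iterations` rounds.
#' With `junction_only = TRUE` only vertices within `hops` edge hops of a
#' junction-fan vertex are moved, which irons out the bridged intersections
#' while leaving the tube walls untouched. Vertex and triangle counts are
#' never changed; isolated vertices are skipped with a warning.
#'
#' @param mesh a `vessel_mesh` (or list with `vertices`/`triangles`).
#' @param iterations number of smoothing rounds.
#' @param lambda step size in (0, 1].
#' @param junction_only restrict to the junction neighbourhood.
#' @param hops geodesic (edge-hop) radius of the junction neighbourhood.
#' @return the smoothed mesh.
#' @export
laplacian_smooth <- function(mesh, iterations = 5L, lambda = 0.5,
                             junction_only = FALSE, hops = 3L) {
  stopifnot(lambda > 0, lambda <= 1)
  v <- mesh$vertices
  tr <- mesh$triangles
  n <- nrow(v)
  adj <- vector("list", n)
  for (i in seq_len(nrow(tr))) {
    a <- tr[i, 1L]; b <- tr[i, 2L]; cc <- tr[i, 3L]
    adj[[a]] <- c(adj[[a]], b, cc)
    adj[[b]] <- c(adj[[b]], a, cc)
    adj[[cc]] <- c(adj[[cc]], a, b)
  }
  adj <- lapply(adj, unique)
  isolated <- vapply(adj, length, integer(1L)) == 0L
  if (any(isolated)) warning(sum(isolated), " isolated vertices skipped")
  sel <- rep(TRUE, n)
  if (junction_only) {
    seed <- unique(as.vector(tr[mesh$face_labels == "junction", ]))
    sel <- rep(FALSE, n)
    sel[seed] <- TRUE
    for (h in seq_len(hops)) {
      sel[unique(unlist(adj[sel]))] <- TRUE
    }
  }
  sel <- sel & !isolated
  for (it in seq_len(iterations)) {
    nv <- v
    for (i in which(sel)) {
      ctr <- colMeans(v[adj[[i]], , drop = FALSE])
      nv[i, ] <- v[i, ] + lambda * (ctr - v[i, ])
    }
    v <- nv
  }
  mesh$vertices <- v
  mesh
}

## ---- mesh measures ----

#' Boundary edges of a triangle mesh
#' @param mesh a `vessel_mesh` or list with `triangles`.
#' @return integer count of edges used by exactly one triangle.
#' @export
mesh_boundary_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  sum(table(key) == 1L)
}

#' Euler characteristic V - E + F
#' @param mesh a `vessel_mesh`.
#' @return integer.
#' @export
mesh_euler <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3L, 1L)])
  key <- unique(paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  length(unique(as.vector(tr))) - length(key) + nrow(tr)
}

#' Signed enclosed volume (positive for outward orientation)
#' @param mesh a `vessel_mesh`.
#' @return numeric volume.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  b <- v[tr[, 2L], , drop = FALSE]
  cc <- v[tr[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
      a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
      a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])) / 6
}

#' Total area of (a subset of) mesh triangles
#' @param mesh a `vessel_mesh`.
#' @param labels restrict to these face labels (default: all).
#' @return numeric area.
#' @export
mesh_area <- function(mesh, labels = NULL) {
  keep <- if (is.null(labels)) rep(TRUE, nrow(mesh$triangles))
          else mesh$face_labels %in% labels
  tr <- mesh$triangles[keep, , drop = FALSE]
  v <- mesh$vertices
  tot <- 0
  for (i in seq_len(nrow(tr))) {
    ab <- v[tr[i, 2L], ] - v[tr[i, 1L], ]
    ac <- v[tr[i, 3L], ] - v[tr[i, 1L], ]
    tot <- tot + sqrt(sum(.cross3(ab, ac)^2)) / 2
  }
  tot
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat(sprintf("<vessel_mesh> %d vertices, %d triangles (%d wall, %d junction, %d cap), boundary edges %d\n",
              nrow(x$vertices), nrow(x$triangles),
              sum(x$face_labels == "wall"), sum(x$face_labels == "junction"),
              sum(startsWith(x$face_labels, "cap")), mesh_boundary_edges(x)))
  invisible(x)
}

## ---- export / import ----

#' Export a mesh to OBJ or ASCII STL
#'
#' @param mesh a `vessel_mesh`.
#' @param path output file; extension chooses the format unless `format`
#'   is given.
#' @param format "obj" or "stl".
#' @param strict refuse to write a mesh with boundary edges.
#' @return the path, invisibly.
#' @export
export_mesh <- function(mesh, path, format = NULL, strict = FALSE) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("obj", "stl")) stop("unknown mesh format: ", format)
  if (strict && mesh_boundary_edges(mesh) > 0L) {
    stop("mesh has boundary edges (not watertight); refusing strict export")
  }
  v <- mesh$vertices
  tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("f %d %d %d", tr[, 1L], tr[, 2L], tr[, 3L]), con)
  } else {
    writeLines("solid vessel", con)
    for (i in seq_len(nrow(tr))) {
      a <- v[tr[i, 1L], ]; b <- v[tr[i, 2L], ]; cc <- v[tr[i, 3L], ]
      nrm <- .cross3(b - a, cc - a)
      nl <- sqrt(sum(nrm^2))
      if (nl > 0) nrm <- nrm / nl
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[1L], nrm[2L], nrm[3L]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", c(a[1L], b[1L], cc[1L]),
                           c(a[2L], b[2L], cc[2L]), c(a[3L], b[3L], cc[3L])),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid vessel", con)
  }
  invisible(path)
}

#' Import a mesh written by [export_mesh()]
#' @param path OBJ or ASCII STL file.
#' @return a `vessel_mesh` (face labels all "wall"; labels are not stored in
#'   these formats).
#' @export
read_mesh <- function(path) {
  format <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (format == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, " +"), function(p) as.numeric(p[2:4])))
    tr <- do.call(rbind, lapply(strsplit(fl, " +"), function(p) as.integer(p[2:4])))
  } else if (format == "stl") {
    vl <- grep("^\\s*vertex ", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), " +"),
                                    function(p) as.numeric(p[2:4])))
    # weld identical vertices back together
    key <- apply(coords, 1L, paste, collapse = ",")
    uk <- !duplicated(key)
    v <- coords[uk, , drop = FALSE]
    idx <- match(key, key[uk])
    tr <- matrix(idx, ncol = 3L, byrow = TRUE)
  } else stop("unknown mesh format: ", format)
  structure(list(vertices = v, triangles = tr,
                 face_labels = rep("wall", nrow(tr)),
                 cap_nodes = integer(0), node_vertex = integer(0)),
            class = "vessel_mesh")
}
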