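# Skeletonization and centerline graph extraction: Zhang-Suen thinning,
# endpoint/bifurcation detection from 3x3 neighbour counts, segment tracing,
# and centerline downsampling.

# 8-neighbour offsets in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
# in (row, col) with row growing downward ("north" = row - 1).
.zs_offsets <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                     dc = c(0, 1, 1, 1, 0, -1, -1, -1))

# Stack of the 8 shifted neighbour planes of a 0/1 matrix, in P2..P9 order.
.neighbour_planes <- function(m) {
  lapply(seq_len(8L), function(k) {
    shift_mat(m, -.zs_offsets[k, 1L], -.zs_offsets[k, 2L])
  })
}

#' Zhang-Suen thinning
#'
#' Classic two-subiteration parallel thinning: a foreground pixel is corroded
#' when its 8-neighbour count lies in \[2, 6\], its cyclic neighbour sequence
#' contains exactly one 0-to-1 transition, and the two subiteration-specific
#' directional products (N*E*S, E*S*W in pass one; N*E*W, N*S*W in pass two)
#' are zero. Passes repeat until no pixel changes. The result is a 1-px-wide
#' 8-connected skeleton contained in the input mask.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of class dims equal to input; the skeleton.
#' @export
zhang_suen_thin <- function(mask) {
  m <- matrix(as.numeric(as.logical(mask)), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p <- .neighbour_planes(m)
      b <- Reduce(`+`, p)
      # transitions 0->1 in cyclic order P2..P9,P2
      a <- matrix(0, nrow(m), ncol(m))
      for (k in seq_len(8L)) {
        nxt <- if (k == 8L) 1L else k + 1L
        a <- a + (p[[k]] == 0) * (p[[nxt]] == 1)
      }
      if (pass == 1L) {
        c1 <- p[[1L]] * p[[3L]] * p[[5L]] # N*E*S
        c2 <- p[[3L]] * p[[5L]] * p[[7L]] # E*S*W
      } else {
        c1 <- p[[1L]] * p[[3L]] * p[[7L]] # N*E*W
        c2 <- p[[1L]] * p[[5L]] * p[[7L]] # N*S*W
      }
      kill <- m == 1 & b >= 2 & b <= 6 & a == 1 & c1 == 0 & c2 == 0
      if (any(kill)) {
        m[kill] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1
}

#' Count of 8-connected foreground components
#'
#' Two-pass-free flood fill; used to check that thinning preserves topology.
#' @param mask logical matrix.
#' @return integer component count.
#' @export
count_components8 <- function(mask) {
  m <- as.logical(mask)
  dim(m) <- dim(mask)
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  idx <- which(m & lab == 0L)
  nr <- nrow(m)
  while (length(idx) > 0L) {
    cur <- cur + 1L
    stack <- idx[1L]
    lab[stack] <- cur
    while (length(stack) > 0L) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (i - 1L) %% nr + 1L
      c <- (i - 1L) %/% nr + 1L
      for (k in seq_len(8L)) {
        rr <- r + .zs_offsets[k, 1L]; cc <- c + .zs_offsets[k, 2L]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= ncol(m)) {
          j <- (cc - 1L) * nr + rr
          if (m[j] && lab[j] == 0L) {
            lab[j] <- cur
            stack <- c(stack, j)
          }
        }
      }
    }
    idx <- which(m & lab == 0L)
  }
  cur
}

#' Classify skeleton pixels by 3x3 neighbour count
#'
#' A skeleton pixel with n foreground pixels in its 8-neighbourhood is:
#' n = 0 isolated, n = 1 endpoint, n = 2 a regular (segment interior) pixel,
#' n >= 3 an intersection. Emits a warning when the input contains a solid
#' 2x2 block, which means it is not properly thinned.
#'
#' @param skel logical skeleton matrix.
#' @return data.frame with columns `row`, `col` (0-based), `n_neighbours`,
#'   `kind` (factor: isolated/endpoint/regular/intersection), one row per
#'   skeleton pixel.
#' @export
classify_skeleton_points <- function(skel) {
  m <- matrix(as.numeric(as.logical(skel)), nrow(skel), ncol(skel))
  block <- m * shift_mat(m, 0, 1) * shift_mat(m, 1, 0) * shift_mat(m, 1, 1)
  if (any(block == 1)) {
    warning("input does not look thinned: solid 2x2 block present")
  }
  nb <- Reduce(`+`, .neighbour_planes(m))
  idx <- which(m == 1)
  nr <- nrow(m)
  n <- nb[idx]
  kind <- factor(ifelse(n == 0, "isolated",
                 ifelse(n == 1, "endpoint",
                 ifelse(n == 2, "regular", "intersection"))),
                 levels = c("isolated", "endpoint", "regular", "intersection"))
  data.frame(row = (idx - 1L) %% nr,
             col = (idx - 1L) %/% nr,
             n_neighbours = n,
             kind = kind)
}

#' Trace a skeleton into a vessel graph
#'
#' Nodes are endpoints, isolated pixels, and intersections; 8-adjacent
#' intersection pixels are merged into one node at their centroid. Segments
#' are the ordered regular-pixel paths between nodes (node pixels included at
#' both ends), each listed once in canonical orientation (lower node id
#' first). A skeleton cycle containing no node (a closed ring) gets one
#' synthetic "break" node inserted and is traced as a single closed segment.
#'
#' @param skel logical skeleton matrix (output of [zhang_suen_thin()]).
#' @return object of class `vessel_graph`: list with `nodes` (data.frame id,
#'   row, col, kind) and `segments` (list of lists with `points` n x 2
#'   0-based matrix, `from`, `to` node ids), plus `image_size`.
#' @export
trace_segments <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  cls <- classify_skeleton_points(skel)
  # label matrix: 0 background, >0 node id, -1 regular unvisited
  lab <- matrix(0L, nr, nc)
  reg <- cls[cls$kind == "regular", , drop = FALSE]
  lab[cbind(reg$row + 1L, reg$col + 1L)] <- -1L

  nodes <- list()
  node_kind <- character(0)
  add_node <- function(pix, kind) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- pix # matrix of 0-based (row, col)
    node_kind[id] <<- kind
    lab[cbind(pix[, 1L] + 1L, pix[, 2L] + 1L)] <<- id
    id
  }
  for (k in c("endpoint", "isolated")) {
    sub <- cls[cls$kind == k, , drop = FALSE]
    for (i in seq_len(nrow(sub))) add_node(cbind(sub$row[i], sub$col[i]), k)
  }
  # merge 8-adjacent intersection pixels into cluster nodes
  inter <- cls[cls$kind == "intersection", , drop = FALSE]
  if (nrow(inter) > 0L) {
    im <- matrix(FALSE, nr, nc)
    im[cbind(inter$row + 1L, inter$col + 1L)] <- TRUE
    seen <- matrix(FALSE, nr, nc)
    for (i in seq_len(nrow(inter))) {
      r0 <- inter$row[i] + 1L; c0 <- inter$col[i] + 1L
      if (seen[r0, c0]) next
      stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      clust <- NULL
      while (length(stack) > 0L) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        clust <- rbind(clust, p)
        for (k in seq_len(8L)) {
          rr <- p[1L] + .zs_offsets[k, 1L]; cc <- p[2L] + .zs_offsets[k, 2L]
          if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
              im[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
      add_node(clust - 1L, "intersection")
    }
  }

  segments <- list()
  add_segment <- function(pts, from, to) {
    if (from > to) {
      pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      tmp <- from; from <- to; to <- tmp
    }
    segments[[length(segments) + 1L]] <<- list(points = pts, from = from, to = to)
  }
  neighbours_of <- function(r, c) {
    # returns matrix of in-bounds 8-neighbours (1-based)
    rr <- r + .zs_offsets[, 1L]; cc <- c + .zs_offsets[, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    cbind(rr[ok], cc[ok])
  }
  walk_from <- function(node_id, r, c, r1, c1) {
    # start at node pixel (r,c), first regular step (r1,c1); 1-based coords
    path <- rbind(c(r, c), c(r1, c1))
    lab[r1, c1] <<- -2L # visited regular
    prev <- c(r, c); cur <- c(r1, c1)
    repeat {
      nb <- neighbours_of(cur[1L], cur[2L])
      vals <- lab[nb]
      # a node ends the walk, but never the origin node on the very first
      # step: junction clusters are 8-adjacent to their branches' first
      # regular pixels and must not swallow them
      nxt_node <- which(vals > 0L &
                          !(nb[, 1L] == prev[1L] & nb[, 2L] == prev[2L]) &
                          !(vals == node_id & nrow(path) <= 2L))
      if (length(nxt_node) > 0L) {
        end <- nb[nxt_node[1L], ]
        path <- rbind(path, end)
        return(list(path = path, end_id = lab[end[1L], end[2L]]))
      }
      nxt_reg <- which(vals == -1L)
      if (length(nxt_reg) > 0L) {
        if (length(nxt_reg) > 1L) {
          # prefer the straightest continuation so walks do not hop between
          # branches that run diagonally adjacent near a junction cluster
          dir <- cur - prev
          sc <- vapply(nxt_reg, function(j) {
            sum((nb[j, ] - cur) * dir) / sqrt(sum((nb[j, ] - cur)^2))
          }, numeric(1L))
          nxt_reg <- nxt_reg[order(-sc)]
        }
        step <- nb[nxt_reg[1L], ]
        lab[step[1L], step[2L]] <<- -2L
        path <- rbind(path, step)
        prev <- cur; cur <- step
      } else {
        # dead end among visited pixels (degenerate micro-loop at a cluster)
        return(list(path = path, end_id = NA_integer_))
      }
    }
  }

  # walks out of every node pixel
  for (id in seq_along(nodes)) {
    pix <- nodes[[id]]
    for (i in seq_len(nrow(pix))) {
      r <- pix[i, 1L] + 1L; c <- pix[i, 2L] + 1L
      nb <- neighbours_of(r, c)
      for (j in seq_len(nrow(nb))) {
        v <- lab[nb[j, 1L], nb[j, 2L]]
        if (v == -1L) {
          w <- walk_from(id, r, c, nb[j, 1L], nb[j, 2L])
          if (!is.na(w$end_id)) add_segment(w$path - 1L, id, w$end_id)
        } else if (v > 0L && v > id) {
          # direct node-to-node adjacency (no interior pixels)
          add_segment(rbind(c(r, c), nb[j, , drop = FALSE]) - 1L, id, v)
        }
      }
    }
  }

  # leftover unvisited regular pixels belong to node-free cycles: break them
  repeat {
    left <- which(lab == -1L)
    if (length(left) == 0L) break
    i <- left[1L]
    r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
    id <- add_node(cbind(r - 1L, c - 1L), "break")
    nb <- neighbours_of(r, c)
    v <- lab[nb]
    first <- which(v == -1L)
    if (length(first) == 0L) next # isolated leftover, now an isolated node
    w <- walk_from(id, r, c, nb[first[1L], 1L], nb[first[1L], 2L])
    if (!is.na(w$end_id)) add_segment(w$path - 1L, id, w$end_id)
  }

  centroids <- t(vapply(nodes, function(p) colMeans(matrix(p, ncol = 2L)),
                        numeric(2L)))
  node_df <- data.frame(id = seq_along(nodes),
                        row = centroids[, 1L], col = centroids[, 2L],
                        kind = node_kind)
  structure(list(nodes = node_df, node_pixels = nodes, segments = segments,
                 image_size = c(nr, nc)),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes (%s), %d segments\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", table(x$nodes$kind)[table(x$nodes$kind) > 0],
                            names(table(x$nodes$kind))[table(x$nodes$kind) > 0]),
                    collapse = ", "),
              length(x$segments)))
  invisible(x)
}

#' Downsample a centerline path at a fixed index interval
#'
#' Keeps points 0, interval, 2*interval, ... (0-based positions) and always
#' the final point, preserving order. Used so that neighbouring
#' cross-section contours do not intersect when the surface is lofted.
#'
#' @param path n x 2 point matrix (or n x k).
#' @param interval keep-every-interval count (>= 1).
#' @return the subsampled point matrix.
#' @export
downsample_centerline <- function(path, interval = 1L) {
  if (is.null(dim(path)) || nrow(path) == 0L) stop("empty centerline path")
  if (interval < 1L) stop("interval must be >= 1")
  n <- nrow(path)
  keep <- unique(c(seq(1L, n, by = as.integer(interval)), n))
  path[keep, , drop = FALSE]
}

#' Remove short spur segments from a vessel graph
#'
#' Skeletons of noisy masks grow short dead-end twigs at junctions; dropping
#' segments shorter than `min_length` that end at an endpoint node keeps the
#' traced topology equal to the true tree. Nodes left without segments are
#' removed; a bifurcation reduced to degree 2 keeps its node (harmless for
#' downstream profiling).
#'
#' @param graph a `vessel_graph`.
#' @param min_length minimum polyline length (px) for a dead-end segment.
#' @return pruned `vessel_graph`.
#' @export
prune_spurs <- function(graph, min_length = 6) {
  if (length(graph$segments) == 0L) return(graph)
  kinds <- graph$nodes$kind
  keep <- vapply(graph$segments, function(s) {
    len <- polyline_length(s$points)
    is_spur <- (kinds[s$from] == "endpoint" || kinds[s$to] == "endpoint") &&
      (kinds[s$from] == "intersection" || kinds[s$to] == "intersection")
    !(is_spur && len < min_length)
  }, logical(1L))
  graph$segments <- graph$segments[keep]
  used <- sort(unique(unlist(lapply(graph$segments, function(s) c(s$from, s$to)))))
  remap <- match(seq_len(nrow(graph$nodes)), used)
  graph$nodes <- graph$nodes[graph$nodes$id %in% used, , drop = FALSE]
  graph$nodes$id <- remap[graph$nodes$id]
  graph$node_pixels <- graph$node_pixels[used]
  graph$segments <- lapply(graph$segments, function(s) {
    s$from <- remap[s$from]; s$to <- remap[s$to]; s
  })
  graph
}
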