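# Shared fixture builders. Everything is generated in code; coordinates are
# (row, col), 0-based, as in the package.

# A vessel_tree with a single straight horizontal segment.
straight_tube_tree <- function(radius, length = 80, row = 30, col0 = 8,
                               image_size = c(64L, 100L)) {
  pts <- cbind(rep(row, length + 1L), seq(col0, col0 + length))
  structure(list(segments = list(list(points = pts,
                                      radii = rep(radius, length + 1L),
                                      parent = NA_integer_, level = 1L)),
                 root = pts[1L, ], image_size = as.integer(image_size),
                 class_label = 0L, seed = 0L),
            class = "vessel_tree")
}

# Hand-built centerline profile from straight segments (for surface and
# hemodynamic fixtures that bypass the imaging stages).
make_segment <- function(p0, p1, r, from, to, k = 11L) {
  tt <- seq(0, 1, length.out = k)
  pts <- cbind(p0[1L] + tt * (p1[1L] - p0[1L]), p0[2L] + tt * (p1[2L] - p0[2L]))
  tg <- matrix(rep(unit_vec_t(p1 - p0), k), k, 2L, byrow = TRUE)
  list(points = pts, tangents = tg,
       normals = t(apply(tg, 1L, function(v) c(-v[2L], v[1L]))),
       radii_px = rep(r, k), radii = rep(r, k), from = from, to = to)
}
unit_vec_t <- function(v) v / sqrt(sum(v^2))

make_profile <- function(segments, nodes, px_size = 1,
                         image_size = c(128L, 128L)) {
  structure(list(segments = segments, nodes = nodes, px_size = px_size,
                 image_size = image_size),
            class = "centerline_profile")
}

# Y-shaped profile: thick parent, two thin daughters.
y_profile <- function(parent_r = 6, daughter_r = 2, px_size = 1) {
  nodes <- data.frame(id = 1:4, row = c(50, 50, 30, 70), col = c(10, 50, 80, 80),
                      kind = c("endpoint", "intersection", "endpoint", "endpoint"))
  make_profile(list(
    make_segment(c(50, 10), c(50, 50), parent_r, 1L, 2L),
    make_segment(c(50, 50), c(30, 80), daughter_r, 2L, 3L),
    make_segment(c(50, 50), c(70, 80), daughter_r, 2L, 4L)
  ), nodes, px_size)
}

# Random blob mask for thinning property tests.
random_blob_mask <- function(size = 64L, n_blobs = NULL) {
  m <- matrix(FALSE, size, size)
  rr <- outer(seq_len(size), rep(1L, size))
  cc <- t(rr)
  n_blobs <- n_blobs %||% sample(2:5, 1L)
  for (k in seq_len(n_blobs)) {
    r <- sample(8:(size - 8), 1L)
    c <- sample(8:(size - 8), 1L)
    rad <- sample(3:9, 1L)
    m <- m | ((rr - r)^2 + (cc - c)^2 <= rad^2)
  }
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force AUC oracle: fraction of concordant (positive, negative) score
# pairs, ties counted half. O(P * N).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Independent linear network solver (different formulation from the
# package's reduced solver): full KCL system solved with qr.solve.
oracle_network_flows <- function(net, q_in) {
  ids <- net$nodes$id
  n <- length(ids)
  e <- net$edges
  A <- matrix(0, 0, n)
  b <- c()
  for (i in seq_len(n)) {
    id <- ids[i]
    if (id %in% net$outlets) {
      row <- rep(0, n); row[i] <- 1
      A <- rbind(A, row); b <- c(b, net$outlet_pressure)
    } else {
      row <- rep(0, n)
      for (k in seq_len(nrow(e))) {
        gk <- 1 / e$R_hyd[k]
        if (e$from[k] == id) {
          row[match(e$from[k], ids)] <- row[match(e$from[k], ids)] + gk
          row[match(e$to[k], ids)] <- row[match(e$to[k], ids)] - gk
        }
        if (e$to[k] == id) {
          row[match(e$to[k], ids)] <- row[match(e$to[k], ids)] + gk
          row[match(e$from[k], ids)] <- row[match(e$from[k], ids)] - gk
        }
      }
      A <- rbind(A, row)
      b <- c(b, if (id == net$inlet) q_in else 0)
    }
  }
  p <- qr.solve(A, b)
  (p[match(e$from, ids)] - p[match(e$to, ids)]) / e$R_hyd
}

# Random tree-shaped profile for network property tests.
random_tree_profile <- function(levels = 3L, seed = 1L) {
  set.seed(seed)
  segs <- list()
  nodes <- data.frame(id = 1L, row = 0, col = 0)
  add_node <- function(row, col) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- c(id, row, col)
    id
  }
  grow <- function(from_id, pos, heading, level) {
    len <- runif(1, 25, 60)
    end <- pos + len * c(sin(heading), cos(heading))
    to_id <- add_node(end[1L], end[2L])
    segs[[length(segs) + 1L]] <<- make_segment(pos, end, runif(1, 1.5, 4),
                                               from_id, to_id)
    if (level < levels) {
      for (s in c(-1, 1)) grow(to_id, end, heading + s * runif(1, 0.3, 0.7),
                               level + 1L)
    }
  }
  grow(1L, c(0, 0), 0, 1L)
  make_profile(segs, nodes, px_size = 0.01)
}
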