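# Vessel radius profiling: Canny boundary detection, centerline normals from
# local least-squares line fits, and shortest edge distance along the normal.

#' Canny edge detection
#'
#' Standard pipeline: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction (ties on gradient
#' plateaus are kept on both sides), and hysteresis thresholding that grows
#' strong edges through weak ones. Thresholds are fractions of the gradient
#' magnitude's dynamic range. Works on the fused grayscale or (the default
#' downstream choice) directly on the binary segmentation mask, which
#' decouples boundary localization from illumination.
#'
#' @param img numeric matrix (or logical mask).
#' @param low,high hysteresis thresholds as fractions of max gradient
#'   magnitude; `high` must be >= `low`.
#' @param sigma Gaussian smoothing scale in px.
#' @return logical matrix of thin edge pixels.
#' @export
detect_edges <- function(img, low = 0.1, high = 0.2, sigma = 1.0) {
  if (high < low) stop("high threshold must be >= low threshold")
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  s <- gauss_blur(m, sigma)
  # Sobel; gy along rows (down), gx along cols (right)
  sx <- function(m) shift_mat(m, 0, 1) - shift_mat(m, 0, -1)
  sy <- function(m) shift_mat(m, 1, 0) - shift_mat(m, -1, 0)
  gx <- sx(s) + 0.5 * (sx(shift_mat(s, 1, 0)) + sx(shift_mat(s, -1, 0)))
  gy <- sy(s) + 0.5 * (sy(shift_mat(s, 0, 1)) + sy(shift_mat(s, 0, -1)))
  mag <- sqrt(gx^2 + gy^2)
  # the shift-based gradients see the zero padding at the frame; blank the
  # 1-px border so a constant image has no edges
  mag[c(1L, nrow(mag)), ] <- 0
  mag[, c(1L, ncol(mag))] <- 0
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  # quantize so the exact two-pixel ties flanking an ideal step resolve
  # identically in every orientation
  mag <- round(mag / mx, 9) * mx
  ang <- atan2(gy, gx) %% pi
  # quantize into 4 directions: 0 = E/W, 1 = NE/SW, 2 = N/S, 3 = NW/SE
  bin <- floor((ang + pi / 8) / (pi / 4)) %% 4
  n1 <- matrix(0, nrow(m), ncol(m)); n2 <- n1
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (b in 0:3) {
    o <- offs[[b + 1L]]
    sel <- bin == b
    n1[sel] <- shift_mat(mag, -o[1L], -o[2L])[sel]
    n2[sel] <- shift_mat(mag, o[1L], o[2L])[sel]
  }
  # strict against the +offset neighbour, non-strict against the other: an
  # ideal step's two-pixel tie keeps exactly one pixel (the +offset side),
  # so the response is single-pixel wide and deterministic; across a tube
  # the two walls then resolve to opposite sides, which cancels the
  # half-pixel bias in the two-sided radius average
  nms <- mag > n1 & mag >= n2 & mag > 0
  strong <- nms & (mag >= high * mx)
  weak <- nms & (mag >= low * mx)
  # hysteresis: grow strong through weak (8-connected) until stable
  cur <- strong
  repeat {
    grown <- cur
    for (k in seq_len(8L)) {
      grown <- grown | (shift_mat(cur * 1, .zs_offsets[k, 1L],
                                  .zs_offsets[k, 2L]) > 0)
    }
    grown <- grown & weak
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}

#' Local tangent/normal estimation on a centerline
#'
#' Fits a least-squares line through the points at index +/- `window`
#' (clipped at segment ends) and returns the unit tangent (oriented along
#' increasing index) and the unit normal (tangent rotated +90 degrees in the
#' (row, col) frame).
#'
#' @param points n x 2 centerline point matrix.
#' @param index point index (1-based).
#' @param window half-width of the fit window in points (>= 1).
#' @return list with `tangent` and `normal`, both unit 2-vectors.
#' @export
estimate_normal <- function(points, index, window = 3L) {
  stopifnot(window >= 1L, index >= 1L, index <= nrow(points))
  lo <- max(1L, index - window)
  hi <- min(nrow(points), index + window)
  p <- points[lo:hi, , drop = FALSE]
  ctr <- colMeans(p)
  q <- sweep(p, 2L, ctr)
  if (all(abs(q) < 1e-12)) stop("cannot estimate tangent: window points coincide")
  sv <- svd(q)
  tangent <- sv$v[, 1L]
  # orient along increasing index
  chord <- points[hi, ] - points[lo, ]
  if (sum(tangent * chord) < 0) tangent <- -tangent
  tangent <- unit_vec(tangent)
  list(tangent = tangent, normal = rot90_vec(tangent))
}

#' Measure vessel radius along the local normal
#'
#' Marches from the centerline point along +normal and -normal, finds on
#' each side the first edge pixel lying within a 1-px corridor of the ray
#' (reading a two-pixel edge plateau as its midpoint, since an ideal step
#' edge responds on both flanking pixels), and returns the mean of the two
#' per-wall distances. If only one wall is found,
#' that distance is returned and flagged one-sided; if neither wall is found
#' within `max_search`, the radius is NA and flagged missing.
#'
#' @param point length-2 (row, col) 0-based centerline point.
#' @param normal unit 2-vector.
#' @param edges logical edge matrix from [detect_edges()].
#' @param max_search maximum march distance in px.
#' @return list with `radius` (px or NA), `one_sided`, `missing`,
#'   `hit_plus`, `hit_minus` (per-side distances, NA when absent).
#' @export
measure_radius <- function(point, normal, edges, max_search = 15) {
  stopifnot(max_search > 0)
  nr <- nrow(edges); nc <- ncol(edges)
  r0 <- max(0, floor(point[1L] - max_search)):min(nr - 1, ceiling(point[1L] + max_search))
  c0 <- max(0, floor(point[2L] - max_search)):min(nc - 1, ceiling(point[2L] + max_search))
  sub <- edges[r0 + 1L, c0 + 1L, drop = FALSE]
  hit_idx <- which(sub, arr.ind = TRUE)
  hit_side <- function(sign) {
    if (nrow(hit_idx) == 0L) return(NA_real_)
    er <- r0[hit_idx[, 1L]] - point[1L]
    ec <- c0[hit_idx[, 2L]] - point[2L]
    along <- (er * normal[1L] + ec * normal[2L]) * sign
    tang <- rot90_vec(normal)
    perp <- abs(er * tang[1L] + ec * tang[2L])
    ok <- along > 1e-9 & along <= max_search & perp <= 1
    if (!any(ok)) return(NA_real_)
    d1 <- min(along[ok])
    # an ideal step yields a two-pixel edge plateau; when the next corridor
    # hit sits within ~1 px of the first, the wall is their midpoint
    partner <- along[ok & along > d1 + 1e-9 & along <= d1 + 1.2]
    if (length(partner) > 0L) (d1 + min(partner)) / 2 else d1
  }
  hp <- hit_side(1)
  hm <- hit_side(-1)
  radius <- if (!is.na(hp) && !is.na(hm)) (hp + hm) / 2 else if (!is.na(hp)) hp else hm
  list(radius = radius,
       one_sided = xor(is.na(hp), is.na(hm)),
       missing = is.na(hp) && is.na(hm),
       hit_plus = hp, hit_minus = hm)
}

#' Profile a vessel graph: sampled centerline points, normals and radii
#'
#' For each segment: the centerline is downsampled (by default adaptively,
#' keeping every ceil(radius) points so neighbouring cross-section contours
#' cannot intersect), a unit tangent/normal is estimated per kept point, and
#' the radius is measured on the edge map. Points with a missing radius are
#' dropped; segments reduced to fewer than 2 valid points are removed (with
#' a message). Radii in physical units are attached via `px_size`.
#'
#' @param graph a `vessel_graph`.
#' @param edges logical edge matrix.
#' @param interval fixed downsampling interval, or `"adaptive"` (default).
#' @param window normal-estimation half-width (points on the full path).
#' @param max_search radius search bound in px.
#' @param px_size physical size of one pixel (e.g. cm/px); required for any
#'   downstream physical modelling.
#' @return object of class `centerline_profile`: list with `segments` (each:
#'   `points`, `tangents`, `normals`, `radii_px`, `radii`, `from`, `to`),
#'   `nodes` (from the graph), `px_size`, `image_size`.
#' @export
profile_graph <- function(graph, edges, interval = "adaptive", window = 3L,
                          max_search = 15, px_size = 1) {
  if (length(graph$segments) == 0L) stop("empty vessel graph")
  out <- list()
  for (si in seq_along(graph$segments)) {
    seg <- graph$segments[[si]]
    path <- seg$points
    if (nrow(path) < 2L) next
    # pilot radius at the midpoint decides the adaptive interval
    iv <- if (identical(interval, "adaptive")) {
      mid <- (nrow(path) + 1L) %/% 2L
      nrm <- try(estimate_normal(path, mid, window), silent = TRUE)
      pilot <- if (inherits(nrm, "try-error")) NA_real_ else
        measure_radius(path[mid, ], nrm$normal, edges, max_search)$radius
      if (is.na(pilot)) 3L else max(1L, as.integer(ceiling(pilot)))
    } else as.integer(interval)
    keep <- unique(c(seq(1L, nrow(path), by = iv), nrow(path)))
    pts <- matrix(NA_real_, length(keep), 2L)
    tgs <- matrix(NA_real_, length(keep), 2L)
    nms <- matrix(NA_real_, length(keep), 2L)
    rad <- rep(NA_real_, length(keep))
    for (j in seq_along(keep)) {
      en <- try(estimate_normal(path, keep[j], max(window, iv)), silent = TRUE)
      if (inherits(en, "try-error")) next
      mr <- measure_radius(path[keep[j], ], en$normal, edges, max_search)
      if (mr$missing) next
      pts[j, ] <- path[keep[j], ]
      tgs[j, ] <- en$tangent
      nms[j, ] <- en$normal
      rad[j] <- mr$radius
    }
    ok <- !is.na(rad)
    if (sum(ok) < 2L) {
      message(sprintf("profile: segment %d dropped (%d valid points)", si, sum(ok)))
      next
    }
    out[[length(out) + 1L]] <- list(
      points = pts[ok, , drop = FALSE],
      tangents = tgs[ok, , drop = FALSE],
      normals = nms[ok, , drop = FALSE],
      radii_px = rad[ok],
      radii = rad[ok] * px_size,
      from = seg$from, to = seg$to, interval = iv
    )
  }
  if (length(out) == 0L) stop("all segments dropped during profiling")
  structure(list(segments = out, nodes = graph$nodes, px_size = px_size,
                 image_size = graph$image_size),
            class = "centerline_profile")
}

#' @export
print.centerline_profile <- function(x, ...) {
  rad <- unlist(lapply(x$segments, `[[`, "radii_px"))
  cat(sprintf(
    "<centerline_profile> %d segments, %d sampled points, radii %.2f-%.2f px (px_size %g)\n",
    length(x$segments), length(rad), min(rad), max(rad), x$px_size))
  invisible(x)
}
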