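# Triangle mesh quality indicators: element quality, aspect ratio, maximum
# interior angle, and skewness, plus per-mesh aggregation. All four are
# anchored so an equilateral triangle scores (1, 1, 60 degrees, 0), are
# dimensionless (rigid-motion and scale invariant), and degrade toward
# (0, Inf, 180, 1) for needle triangles.

#' Quality metrics of one triangle
#'
#' * element quality: `4*sqrt(3) * area / sum(side^2)`; 1 iff equilateral,
#'   tends to 0 for degenerate elements.
#' * aspect ratio: circumradius over twice the inradius, `R / (2r)`;
#'   1 iff equilateral, grows without bound as the element degrades.
#' * maximum angle: largest interior angle in degrees (60 is best).
#' * skewness: normalized equiangular deviation,
#'   `max((theta_max - 60)/120, (60 - theta_min)/60)`; 0 best, 1 worst.
#'
#' @param p1,p2,p3 triangle vertices, length-2 or length-3 numeric.
#' @return object of class `triangle_quality`: list with `element_quality`,
#'   `aspect_ratio`, `max_angle`, `skewness`.
#' @export
triangle_metrics <- function(p1, p2, p3) {
  to3 <- function(p) if (length(p) == 2L) c(p, 0) else p
  p1 <- to3(p1); p2 <- to3(p2); p3 <- to3(p3)
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  area <- sqrt(sum(.cross3(p2 - p1, p3 - p1)^2)) / 2
  if (area <= 0 || !is.finite(area) || min(a, b, cc) == 0) {
    stop("degenerate (collinear) triangle")
  }
  eq <- 4 * sqrt(3) * area / (a^2 + b^2 + cc^2)
  s <- (a + b + cc) / 2
  inradius <- area / s
  circumradius <- a * b * cc / (4 * area)
  ar <- circumradius / (2 * inradius)
  angs <- c(acos(clamp((b^2 + cc^2 - a^2) / (2 * b * cc), -1, 1)),
            acos(clamp((a^2 + cc^2 - b^2) / (2 * a * cc), -1, 1)),
            acos(clamp((a^2 + b^2 - cc^2) / (2 * a * b), -1, 1))) * 180 / pi
  sk <- max((max(angs) - 60) / 120, (60 - min(angs)) / 60)
  structure(list(element_quality = eq, aspect_ratio = ar,
                 max_angle = max(angs), skewness = sk),
            class = "triangle_quality")
}

#' Per-mesh quality report: mean and standard deviation of each indicator
#'
#' Aggregates [triangle_metrics()] over the mesh's triangles. Caps and
#' junction fans are excluded by default (quality is a property of the
#' vessel wall elements); pass `labels = NULL` to include every triangle.
#'
#' @param mesh a `vessel_mesh`.
#' @param labels face labels to include (default "wall"; NULL = all).
#' @return data.frame with columns metric, mean, sd, n_triangles.
#' @export
mesh_quality_report <- function(mesh, labels = "wall") {
  keep <- if (is.null(labels)) rep(TRUE, nrow(mesh$triangles))
          else mesh$face_labels %in% labels
  tr <- mesh$triangles[keep, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no triangles to report on")
  v <- mesh$vertices
  vals <- vapply(seq_len(nrow(tr)), function(i) {
    q <- triangle_metrics(v[tr[i, 1L], ], v[tr[i, 2L], ], v[tr[i, 3L], ])
    c(q$element_quality, q$aspect_ratio, q$max_angle, q$skewness)
  }, numeric(4L))
  sds <- apply(vals, 1L, stats::sd)
  if (nrow(tr) == 1L) sds <- rep(0, 4L)
  data.frame(metric = c("element_quality", "aspect_ratio", "max_angle", "skewness"),
             mean = rowMeans(vals),
             sd = sds,
             n_triangles = nrow(tr))
}
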