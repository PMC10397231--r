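straight_profile <- function(r = 1, L = 10, k = 33L, n0 = c(50, 10)) {
  pts <- cbind(rep(n0[1L], k), seq(n0[2L], n0[2L] + L, length.out = k))
  tg <- cbind(rep(0, k), rep(1, k))
  seg <- list(points = pts, tangents = tg,
              normals = t(apply(tg, 1L, function(v) c(-v[2L], v[1L]))),
              radii_px = rep(r, k), radii = rep(r, k), from = 1L, to = 2L)
  nodes <- data.frame(id = 1:2, row = rep(n0[1L], 2L),
                      col = c(n0[2L], n0[2L] + L),
                      kind = c("endpoint", "endpoint"))
  make_profile(list(seg), nodes)
}

test_that("contour rings are exact circles perpendicular to the tangent", {
  prof <- straight_profile(r = 2)
  ct <- build_contours(prof, n_pts = 16L)
  ring <- ct[[1L]]$rings[[1L]]
  ctr <- ct[[1L]]$centers[1L, ]
  d <- sqrt(rowSums(sweep(ring, 2L, ctr)^2))
  expect_lt(max(abs(d - 2)) / 2, 1e-9)
  # ring plane perpendicular to tangent (tube along +x)
  expect_lt(max(abs(ring[, 1L] - ctr[1L])), 1e-12)
  # octagon perimeter closed form at radius 1
  ct8 <- build_contours(straight_profile(r = 1), n_pts = 8L)
  ring8 <- ct8[[1L]]$rings[[1L]]
  per <- sum(sqrt(rowSums((ring8 - ring8[c(2:8, 1L), ])^2)))
  expect_equal(per, 8 * 2 * sin(pi / 8), tolerance = 1e-12)
  expect_error(build_contours(prof, n_pts = 4L), "n_pts")
  bad <- prof; bad$segments[[1L]]$radii[3L] <- 0
  expect_error(build_contours(bad, 16L), "non-positive radius")
})

test_that("crossing rings on a tight bend are re-downsampled until disjoint", {
  # bend radius 1.5 px with tube radius 3 px: consecutive dense rings tilt
  # across each other (the classic contour-crossover failure)
  th <- seq(0, pi / 1.3, length.out = 50L)
  R <- 1.5; r <- 3
  pts <- cbind(30 - R * cos(th), 10 + R * sin(th))
  tg <- cbind(R * sin(th), R * cos(th))
  tg <- tg / sqrt(rowSums(tg^2))
  seg <- list(points = pts, tangents = tg,
              normals = t(apply(tg, 1L, function(v) c(-v[2L], v[1L]))),
              radii_px = rep(r, 50L), radii = rep(r, 50L), from = 1L, to = 2L)
  prof <- make_profile(list(seg),
                       data.frame(id = 1:2, row = c(28.5, 30), col = c(10, 11),
                                  kind = "endpoint"))
  ct <- build_contours(prof, n_pts = 12L)
  expect_lt(length(ct[[1L]]$rings), 50L)
  expect_gte(length(ct[[1L]]$rings), 2L)
  # the segment endpoints always survive
  expect_equal(ct[[1L]]$centers[1L, 1:2], c(pts[1L, 2L], pts[1L, 1L]))
  expect_equal(ct[[1L]]$centers[nrow(ct[[1L]]$centers), 1:2],
               c(pts[50L, 2L], pts[50L, 1L]))
  # a gently curved tube keeps all its rings (no spurious dropping)
  th2 <- seq(0, pi / 2, length.out = 30L)
  pts2 <- cbind(40 - 20 * cos(th2), 10 + 20 * sin(th2))
  tg2 <- cbind(20 * sin(th2), 20 * cos(th2))
  tg2 <- tg2 / sqrt(rowSums(tg2^2))
  seg2 <- list(points = pts2, tangents = tg2,
               normals = t(apply(tg2, 1L, function(v) c(-v[2L], v[1L]))),
               radii_px = rep(2, 30L), radii = rep(2, 30L), from = 1L, to = 2L)
  prof2 <- make_profile(list(seg2),
                        data.frame(id = 1:2, row = c(20, 40), col = c(10, 30),
                                   kind = "endpoint"))
  expect_length(build_contours(prof2, 12L)[[1L]]$rings, 30L)
})

test_that("lofting produces the advertised triangle count and no degenerates", {
  ct <- build_contours(straight_profile(), n_pts = 8L)
  two <- ct[[1L]]$rings[c(1L, 2L)]
  tube <- loft_segment(two)
  expect_equal(nrow(tube$triangles), 16L)
  expect_error(loft_segment(list(two[[1L]])), "at least 2")
  expect_error(loft_segment(list(two[[1L]], two[[2L]][1:4, ])), "same number")
})

test_that("a capped lofted cylinder is watertight with the right area", {
  mesh <- build_vessel_surface(straight_profile(r = 1, L = 10, k = 33L),
                               n_pts = 32L, smooth_iterations = 0L)
  expect_equal(mesh_boundary_edges(mesh), 0L)
  expect_equal(mesh_euler(mesh), 2L)
  expect_gt(mesh_volume(mesh), 0)
  lat <- mesh_area(mesh, "wall")
  expect_lt(abs(lat - 2 * pi * 10) / (2 * pi * 10), 0.02)
})

test_that("lofted lateral area converges to 2*pi*r*L with resolution", {
  errs <- vapply(c(8L, 16L, 32L), function(n) {
    mesh <- build_vessel_surface(straight_profile(r = 1, L = 10, k = 17L),
                                 n_pts = n, smooth_iterations = 0L)
    abs(mesh_area(mesh, "wall") - 2 * pi * 10) / (2 * pi * 10)
  }, numeric(1L))
  expect_true(all(diff(errs) < 0))
})

test_that("junction repair pulls protruding radii and closes all gaps", {
  prof <- y_profile(parent_r = 6, daughter_r = 2)
  mesh <- build_vessel_surface(prof, n_pts = 16L,
                               radius_ratio_threshold = 1.5,
                               smooth_iterations = 3L)
  expect_equal(mesh_boundary_edges(mesh), 0L)
  # radii at the junction now satisfy the ratio
  ct <- fundus3d:::.repair_junction_radii(build_contours(prof, 16L), 1.5)
  end_r <- c(ct[[1L]]$radii[length(ct[[1L]]$radii)],
             ct[[2L]]$radii[1L], ct[[3L]]$radii[1L])
  expect_lte(max(end_r) / min(end_r), 1.5)
  # symmetric junction: nothing to adjust
  sym <- y_profile(parent_r = 2, daughter_r = 2)
  ct2 <- build_contours(sym, 16L)
  expect_identical(fundus3d:::.repair_junction_radii(ct2, 1.5), ct2)
  # infinite threshold: merge without adjustment
  ct3 <- build_contours(prof, 16L)
  expect_identical(fundus3d:::.repair_junction_radii(ct3, Inf), ct3)
})

test_that("Laplacian smoothing contracts volume, respects lambda = 0 limits", {
  mesh <- build_vessel_surface(straight_profile(r = 1, L = 10, k = 17L),
                               n_pts = 12L, smooth_iterations = 0L)
  expect_error(laplacian_smooth(mesh, 1L, lambda = 0), "lambda")
  v0 <- mesh_volume(mesh)
  m <- mesh
  vols <- numeric(0)
  for (i in 1:5) {
    m <- laplacian_smooth(m, 1L, 0.5)
    vols <- c(vols, mesh_volume(m))
  }
  expect_true(all(diff(c(v0, vols)) < 0))
  expect_equal(dim(m$vertices), dim(mesh$vertices))
  expect_equal(dim(m$triangles), dim(mesh$triangles))
  # a vertex already at its neighbours' centroid is a fixed point
  hexa <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  fan <- structure(list(vertices = rbind(c(0, 0, 0), hexa),
                        triangles = cbind(1L, 1L + (1:6),
                                          1L + c(2:6, 1L)),
                        face_labels = rep("wall", 6L)),
                   class = "vessel_mesh")
  sm <- laplacian_smooth(fan, 3L, 1)
  expect_equal(sm$vertices[1L, ], c(0, 0, 0))
})

test_that("mesh export round-trips through OBJ and STL", {
  mesh <- build_vessel_surface(straight_profile(r = 1.5, L = 8, k = 9L),
                               n_pts = 12L, smooth_iterations = 0L)
  fo <- tempfile(fileext = ".obj")
  export_mesh(mesh, fo)
  m2 <- read_mesh(fo)
  expect_equal(nrow(m2$triangles), nrow(mesh$triangles))
  expect_lt(max(abs(m2$vertices - mesh$vertices)), 1e-6)
  fs <- tempfile(fileext = ".stl")
  export_mesh(mesh, fs)
  expect_equal(nrow(read_mesh(fs)$triangles), nrow(mesh$triangles))
  # strict export refuses an open tube
  ct <- build_contours(straight_profile(), n_pts = 8L)
  open_tube <- loft_segment(ct[[1L]]$rings)
  open_mesh <- structure(list(vertices = open_tube$vertices,
                              triangles = open_tube$triangles,
                              face_labels = rep("wall", nrow(open_tube$triangles))),
                         class = "vessel_mesh")
  expect_error(export_mesh(open_mesh, tempfile(fileext = ".stl"),
                           strict = TRUE), "watertight")
  expect_error(export_mesh(mesh, tempfile(fileext = ".xyz")), "unknown")
})
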