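test_that("Canny finds a thin ring at the boundary of a disk", {
  size <- 60L
  rr <- outer(0:(size - 1L), rep(1, size))
  cc <- t(rr)
  disk <- (rr - 30)^2 + (cc - 30)^2 <= 400
  ed <- detect_edges(disk)
  idx <- which(ed, arr.ind = TRUE) - 1L
  d <- sqrt((idx[, 1L] - 30)^2 + (idx[, 2L] - 30)^2)
  expect_lt(abs(mean(d) - 20), 1)
  expect_true(all(abs(d - 20) < 2.5))
})

test_that("Canny on flat input is empty, a step edge gives a 1-px line", {
  expect_equal(sum(detect_edges(matrix(5, 20L, 20L))), 0L)
  step <- matrix(0, 20L, 40L)
  step[, 21:40] <- 1
  ed <- detect_edges(step)
  interior <- ed[5:16, ]
  expect_true(all(rowSums(interior) == 1L))  # one edge pixel per row
  expect_error(detect_edges(step, low = 0.5, high = 0.2), "high threshold")
})

test_that("normals come out perpendicular to lines and arcs", {
  horiz <- cbind(rep(10, 11L), 0:10)
  en <- estimate_normal(horiz, 6L)
  expect_equal(abs(en$normal), c(1, 0))
  expect_equal(sum(en$normal * en$tangent), 0)
  diag45 <- cbind(0:10, 0:10)
  en <- estimate_normal(diag45, 6L)
  expect_equal(abs(en$normal), c(sqrt(2) / 2, sqrt(2) / 2))
  # circle arc: measured normal within 5 degrees of the radial direction
  th <- seq(0, pi / 2, length.out = 60L)
  arc <- cbind(40 - 30 * cos(th), 10 + 30 * sin(th))
  for (i in seq(5L, 55L, by = 10L)) {
    en <- estimate_normal(arc, i, window = 3L)
    radial <- unit_vec_t(arc[i, ] - c(40, 10))
    ang <- acos(min(1, abs(sum(en$normal * radial)))) * 180 / pi
    expect_lt(ang, 5)
  }
  expect_error(estimate_normal(matrix(1, 5L, 2L), 3L), "coincide")
})

test_that("radius measurement recovers tube half-width and flags misses", {
  tree <- straight_tube_tree(5)
  ed <- detect_edges(rasterize_tree(tree))
  mr <- measure_radius(c(30, 50), c(1, 0), ed, 15)
  expect_false(mr$missing)
  expect_lte(abs(mr$radius - 5), 0.5)
  # empty edge map
  mr2 <- measure_radius(c(30, 50), c(1, 0), matrix(FALSE, 64L, 100L), 15)
  expect_true(mr2$missing)
  expect_true(is.na(mr2$radius))
})

test_that("the 1-px corridor ignores unrelated edges off the normal ray", {
  tree <- straight_tube_tree(3)
  ed <- detect_edges(rasterize_tree(tree))
  ed[50:55, 30L] <- TRUE  # unrelated clutter ~20 px below the tube
  mr <- measure_radius(c(30, 29.5), c(1, 0), ed, 10)
  expect_lte(abs(mr$radius - 3), 0.5)
})

test_that("profiling a two-level tree recovers radii within half a pixel", {
  tree <- generate_vessel_tree(n_branch_levels = 2L, root_radius = 8,
                               radius_decay = 0.8, seed = 6L,
                               image_size = c(192L, 192L))
  mask <- rasterize_tree(tree)
  graph <- trace_segments(zhang_suen_thin(mask))
  prof <- profile_graph(graph, detect_edges(mask), px_size = 1)
  expect_gte(length(prof$segments), 3L)
  for (seg in prof$segments) {
    expect_equal(nrow(seg$points), length(seg$radii_px))
    med <- stats::median(seg$radii_px)
    expect_lt(min(abs(med - 8), abs(med - 6.4)), 0.5)
  }
})

test_that("segments without edge coverage are dropped, others survive", {
  tree <- straight_tube_tree(4)
  mask <- rasterize_tree(tree)
  graph <- trace_segments(zhang_suen_thin(mask))
  # add a fake far-away segment with no edges anywhere near it
  graph$segments[[2L]] <- list(points = cbind(rep(5, 12L), 30:41),
                               from = 3L, to = 4L)
  graph$nodes <- rbind(graph$nodes,
                       data.frame(id = 3:4, row = c(5, 5), col = c(30, 41),
                                  kind = "endpoint"))
  edges <- detect_edges(mask)
  expect_message(prof <- profile_graph(graph, edges, px_size = 1), "dropped")
  expect_length(prof$segments, 1L)
  expect_error(profile_graph(graph, matrix(FALSE, 64L, 100L), px_size = 1),
               "all segments dropped")
})

test_that("radius recovery is accurate (RMSE <= 0.5 px) and rotation-stable", {
  errs <- c()
  for (r in c(2, 4, 7, 10)) {
    tree <- straight_tube_tree(r, row = 30.4)
    ed <- detect_edges(rasterize_tree(tree))
    for (col in seq(25, 75, by = 10)) {
      errs <- c(errs, measure_radius(c(30.4, col), c(1, 0), ed, 15)$radius - r)
    }
  }
  expect_lte(sqrt(mean(errs^2)), 0.5)
  # rotate a tube by 90 degrees: recovered radii move by <= 0.25 px
  tree <- straight_tube_tree(4, row = 30.4)
  m1 <- rasterize_tree(tree)
  m2 <- t(m1)[rev(seq_len(ncol(m1))), ]  # 90-degree rotation
  e1 <- detect_edges(m1); e2 <- detect_edges(m2)
  for (col in seq(25, 75, by = 10)) {
    r1 <- measure_radius(c(30.4, col), c(1, 0), e1, 15)$radius
    p2 <- c(ncol(m1) - 1 - col, 30.4)  # rotated coordinates
    r2 <- measure_radius(p2, c(0, 1), e2, 15)$radius
    expect_lte(abs(r1 - r2), 0.25)
  }
})
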