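# Seeded synthetic fixtures: vascular trees with known centerlines and radii,
# fundus-like renderings with exact ground-truth masks, and labelled feature
# tables. Every downstream stage of the pipeline is testable against these.

#' Generate a synthetic planar vessel tree with known geometry
#'
#' Builds a connected binary tree of smooth piecewise-linear vessel segments.
#' Daughter branches inherit `radius_decay` times the parent radius. The tree
#' is the ground truth object for the whole pipeline: its centerlines and
#' radii are what segmentation, skeletonization and radius profiling should
#' recover.
#'
#' Coordinates are (row, col) pixel-center coordinates, 0-based. All
#' centerlines lie in the image plane; the eventual 3D model gains its third
#' dimension only from circular cross-sections.
#'
#' @param image_size integer pair (rows, cols) in pixels.
#' @param n_branch_levels number of segment generations (1 = a single
#'   unbranched vessel).
#' @param root_radius radius of the root segment in pixels (>= 2).
#' @param radius_decay multiplicative radius decay per bifurcation, in (0, 1).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param segment_length approximate length of each segment in pixels;
#'   default scales with the image.
#' @param branch_angle half-opening angle between daughters, radians.
#' @param wiggle standard deviation of the per-step random heading change
#'   (radians); gives vessels gentle curvature.
#' @param max_retries how many fresh attempts to make when a tree escapes the
#'   image bounds before giving up with an error.
#' @return an object of class `vessel_tree`: list with `segments` (each a
#'   list with `points` n x 2 matrix, `radii` length-n vector, `parent`
#'   segment index or NA, `level`), `root` (inlet point), `image_size`,
#'   `class_label`, `seed`.
#' @export
generate_vessel_tree <- function(image_size = c(128L, 128L),
                                 n_branch_levels = 2L,
                                 root_radius = 5,
                                 radius_decay = 0.8,
                                 seed = 1L,
                                 segment_length = NULL,
                                 branch_angle = pi / 5,
                                 wiggle = 0.04,
                                 max_retries = 25L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 32))
  if (root_radius < 2) stop("root_radius must be >= 2 px")
  if (n_branch_levels < 1) stop("n_branch_levels must be >= 1")
  if (radius_decay <= 0 || radius_decay >= 1) stop("radius_decay must be in (0, 1)")
  seg_len <- segment_length %||% (0.9 * image_size[2L] / (n_branch_levels + 0.5))

  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      tree <- try(.grow_tree(image_size, n_branch_levels, root_radius,
                             radius_decay, seg_len, branch_angle, wiggle),
                  silent = TRUE)
      if (!inherits(tree, "try-error")) {
        tree$seed <- as.integer(seed)
        return(tree)
      }
    }
    stop("vessel tree generation failed: tree escaped image bounds after ",
         max_retries, " attempts")
  })
}

# One growth attempt; errors if any tube pixel would leave the image.
.grow_tree <- function(image_size, levels, root_radius, decay, seg_len,
                       branch_angle, wiggle) {
  margin <- root_radius + 2
  start <- c(image_size[1L] / 2 + stats::runif(1, -4, 4), margin)
  heading <- stats::runif(1, -0.15, 0.15) # radians from +col axis
  segments <- list()

  grow <- function(start, heading, level, parent) {
    radius <- root_radius * decay^(level - 1)
    n_steps <- max(4L, as.integer(round(seg_len * stats::runif(1, 0.85, 1.15))))
    pts <- matrix(0, n_steps + 1L, 2L)
    pts[1L, ] <- start
    h <- heading
    for (i in seq_len(n_steps)) {
      h <- h + stats::rnorm(1, 0, wiggle)
      pts[i + 1L, ] <- pts[i, ] + c(sin(h), cos(h))
    }
    if (any(pts[, 1L] < radius + 1.5) || any(pts[, 1L] > image_size[1L] - radius - 2.5) ||
        any(pts[, 2L] < 1.5) || any(pts[, 2L] > image_size[2L] - radius - 2.5)) {
      stop("out of bounds")
    }
    segments[[length(segments) + 1L]] <<- list(
      points = pts,
      radii = rep(radius, n_steps + 1L),
      parent = parent,
      level = level
    )
    idx <- length(segments)
    if (level < levels) {
      end <- pts[n_steps + 1L, ]
      for (s in c(-1, 1)) {
        ang <- h + s * branch_angle * stats::runif(1, 0.8, 1.2)
        grow(end, ang, level + 1L, idx)
      }
    }
    invisible(idx)
  }
  grow(start, heading, 1L, NA_integer_)

  structure(list(
    segments = segments,
    root = segments[[1L]]$points[1L, ],
    image_size = as.integer(image_size),
    class_label = 0L
  ), class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d segments, %d levels, image %dx%d, seed %s\n",
              length(x$segments), max(vapply(x$segments, `[[`, 1L, "level")),
              x$image_size[1L], x$image_size[2L],
              format(x$seed %||% NA)))
  invisible(x)
}

#' Rasterize the tube set of a vessel tree into a binary mask
#'
#' A pixel is vessel iff its center lies within the local radius of the
#' centerline. Centerline points are densified to <= 0.5 px spacing and each
#' stamped as a disk, which matches the analytic capsule of each segment to
#' well under a pixel.
#'
#' @param tree a `vessel_tree`.
#' @param image_size optional override of the tree's image size.
#' @return logical matrix (rows x cols), TRUE = vessel.
#' @export
rasterize_tree <- function(tree, image_size = tree$image_size) {
  mask <- matrix(FALSE, image_size[1L], image_size[2L])
  for (seg in tree$segments) {
    pts <- seg$points
    rad <- seg$radii
    # densify to 0.5 px spacing
    if (nrow(pts) >= 2L) {
      dpts <- list(); drad <- list()
      for (i in seq_len(nrow(pts) - 1L)) {
        step <- sqrt(sum((pts[i + 1L, ] - pts[i, ])^2))
        n <- max(1L, ceiling(step / 0.5))
        tt <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
        dpts[[i]] <- cbind(pts[i, 1L] + tt * (pts[i + 1L, 1L] - pts[i, 1L]),
                           pts[i, 2L] + tt * (pts[i + 1L, 2L] - pts[i, 2L]))
        drad[[i]] <- rad[i] + tt * (rad[i + 1L] - rad[i])
      }
      pts <- rbind(do.call(rbind, dpts), pts[nrow(seg$points), , drop = FALSE])
      rad <- c(unlist(drad), rad[length(rad)])
    }
    for (i in seq_len(nrow(pts))) {
      mask <- .stamp_disk(mask, pts[i, 1L], pts[i, 2L], rad[i])
    }
  }
  mask
}

# Mark pixels whose center is within `rad` of the 0-based point (r0, c0).
.stamp_disk <- function(mask, r0, c0, rad) {
  rows <- max(0L, floor(r0 - rad)):min(nrow(mask) - 1L, ceiling(r0 + rad))
  cols <- max(0L, floor(c0 - rad)):min(ncol(mask) - 1L, ceiling(c0 + rad))
  rr <- outer(rows - r0, rep(1, length(cols)))
  cc <- outer(rep(1, length(rows)), cols - c0)
  hit <- (rr^2 + cc^2) <= rad^2
  mask[rows + 1L, cols + 1L] <- mask[rows + 1L, cols + 1L] | hit
  mask
}

#' Render a synthetic fundus-like image from a vessel tree
#'
#' Produces a 3-channel (R, G, B) image in 0-255 with vessels darker than a
#' textured reddish background. The darkening is placed mainly in the green
#' channel and partly in the red channel, mirroring where real fundus vessel
#' contrast lives, so channel-proportion experiments are meaningful on
#' synthetic data. The returned mask is the exact rasterization of the tree's
#' tubes and is unaffected by the background seed.
#'
#' @param tree a `vessel_tree`.
#' @param background list of texture parameters: `base_rgb` background mean
#'   per channel, `noise_sd` i.i.d. Gaussian texture sd, `contrast` vessel
#'   darkening in the G channel, `r_contrast_frac` fraction of that darkening
#'   applied to R, `blur_sigma` Gaussian softening of the vessel profile in
#'   the rendered image (px; 0 = hard edges).
#' @param seed integer seed for the background texture.
#' @return object of class `fundus_bundle`: list with `image`
#'   (rows x cols x 3 array), `mask` (logical matrix), `tree`, `seed`.
#' @export
render_fundus <- function(tree,
                          background = list(),
                          seed = 1L) {
  bg <- utils::modifyList(list(base_rgb = c(185, 95, 55), noise_sd = 8,
                               contrast = 70, r_contrast_frac = 0.4,
                               blur_sigma = 0.7), background)
  mask <- rasterize_tree(tree)
  dark <- mask * 1.0
  if (bg$blur_sigma > 0) dark <- gauss_blur(dark, bg$blur_sigma)
  h <- nrow(mask); w <- ncol(mask)
  img <- array(0, dim = c(h, w, 3L))
  with_seed(seed, {
    drops <- c(bg$contrast * bg$r_contrast_frac, bg$contrast, 0.1 * bg$contrast)
    for (ch in 1:3) {
      img[, , ch] <- bg$base_rgb[ch] +
        matrix(stats::rnorm(h * w, 0, bg$noise_sd), h, w) -
        drops[ch] * dark
    }
  })
  img <- clamp(img, 0, 255)
  structure(list(image = img, mask = mask, tree = tree, seed = as.integer(seed)),
            class = "fundus_bundle")
}

#' @export
print.fundus_bundle <- function(x, ...) {
  cat(sprintf("<fundus_bundle> %dx%d image, %d vessel px (%.1f%%), seed %d\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$seed))
  invisible(x)
}

#' Generate a labelled synthetic feature table
#'
#' Test bed for the feature-selection stage: `n_informative` features differ
#' between the two balanced classes by `effect_size` standard deviations; the
#' remaining features are pure standard-normal noise. Informative features
#' are the first `n_informative` columns.
#'
#' @param n_subjects total number of subjects (balanced classes; >= 4).
#' @param n_features number of feature columns.
#' @param n_informative number of class-informative features
#'   (<= n_features).
#' @param effect_size standardized mean difference of informative features.
#' @param seed integer seed.
#' @return object of class `feature_table`: list with `x` (subjects x
#'   features numeric matrix with dimnames) and `y` (integer 0/1 labels).
#' @export
generate_feature_dataset <- function(n_subjects = 20L,
                                     n_features = 140L,
                                     n_informative = 4L,
                                     effect_size = 1,
                                     seed = 1L) {
  if (n_subjects < 4L) stop("n_subjects must be >= 4 for leave-one-out evaluation")
  if (n_informative > n_features) stop("n_informative must be <= n_features")
  n1 <- n_subjects %/% 2L
  y <- c(rep(0L, n_subjects - n1), rep(1L, n1))
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_subjects * n_features), n_subjects, n_features)
    if (n_informative > 0L) {
      x[y == 1L, seq_len(n_informative)] <-
        x[y == 1L, seq_len(n_informative), drop = FALSE] + effect_size
    }
    dimnames(x) <- list(sprintf("subject_%02d", seq_len(n_subjects)),
                        sprintf("feature_%03d", seq_len(n_features)))
    feature_table(x, y)
  })
}

#' Construct a feature table
#'
#' @param x numeric matrix, subjects x named features.
#' @param y binary labels (0/1), one per subject.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("feature_%03d", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("feature names must be unique")
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("labels must match rows of x")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (anyNA(x)) stop("feature table must not contain missing values")
  structure(list(x = x, y = y), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features, classes %d/%d\n",
              nrow(x$x), ncol(x$x), sum(x$y == 0L), sum(x$y == 1L)))
  invisible(x)
}

#' Serialize a vessel tree to JSON
#'
#' @param tree a `vessel_tree`.
#' @param path output file path.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(
    image_size = tree$image_size,
    root = tree$root,
    class_label = tree$class_label,
    seed = tree$seed %||% NA_integer_,
    segments = lapply(tree$segments, function(s) list(
      points = unname(s$points),
      radii = s$radii,
      parent = s$parent,
      level = s$level
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vessel tree from JSON
#' @param path file written by [write_tree_json()].
#' @return a `vessel_tree`.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- lapply(seq_len(nrow_or_len(obj$segments)), function(i) {
    s <- if (is.data.frame(obj$segments)) lapply(obj$segments, `[[`, i) else obj$segments[[i]]
    list(points = matrix(unlist(s$points), ncol = 2L, byrow = FALSE),
         radii = as.numeric(unlist(s$radii)),
         parent = if (is.null(s$parent) || is.na(s$parent)) NA_integer_ else as.integer(s$parent),
         level = as.integer(s$level))
  })
  structure(list(segments = segs, root = as.numeric(obj$root),
                 image_size = as.integer(obj$image_size),
                 class_label = as.integer(obj$class_label),
                 seed = obj$seed),
            class = "vessel_tree")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
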