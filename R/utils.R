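# Internal helpers shared across pipeline stages.
#
# Pixel-grid convention used throughout the package: integer coordinates at
# pixel centers, (row, col) order, 0-based. R matrices are 1-based, so element
# access is always mat[row + 1, col + 1].

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are pure
#' functions of their arguments (including the seed).
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shift a matrix by (dr, dc), padding with `fill`. dr > 0 moves content down.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) == 0L || length(sc) == 0L) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

# Separable Gaussian blur with replicate padding.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-rad):rad
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(mat) {
    # along rows (dimension 1), replicate-pad
    nr <- nrow(mat)
    pad <- rbind(
      mat[rep(1L, rad), , drop = FALSE],
      mat,
      mat[rep(nr, rad), , drop = FALSE]
    )
    out <- matrix(0, nr, ncol(mat))
    for (i in seq_along(x)) {
      out <- out + k[i] * pad[(rad + x[i] + 1L):(rad + x[i] + nr), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

# Rotate a 2D vector by 90 degrees (positive rotation in (row, col) frame).
rot90_vec <- function(v) c(-v[2L], v[1L])

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# Polyline length of an n x 2 (or n x 3) point matrix.
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
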