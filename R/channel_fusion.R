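# Channel fusion: compose a grayscale working image from weighted G and R
# channels, and a 1-D lattice local search over the green weight.

#' Fuse green and red channels with a weighted proportion
#'
#' Computes `g * G + r * R` per pixel. The fused image stays floating point;
#' no requantization is performed, so no precision is lost before
#' segmentation. The blue channel is deliberately ignored: fundus vessel
#' contrast lives in G and, to a lesser degree, R.
#'
#' @param image a `fundus_bundle`, or a rows x cols x >=2 array whose first
#'   two planes are R and G (R first, as in an RGB image).
#' @param g,r channel weights in \[0, 1\] with g + r = 1 (machine tolerance).
#' @return numeric matrix, same spatial dimensions as the input.
#' @export
fuse_channels <- function(image, g = 1, r = 1 - g) {
  arr <- if (inherits(image, "fundus_bundle")) image$image else image
  if (length(dim(arr)) != 3L || dim(arr)[3L] < 2L) {
    stop("input must have R and G channels (rows x cols x >= 2 array); ",
         "single-channel input has no G channel to fuse")
  }
  if (g < 0 || g > 1 || r < 0 || r > 1) stop("channel weights must lie in [0, 1]")
  if (abs(g + r - 1) > 1e-9) stop("channel weights must sum to 1")
  g * arr[, , 2L] + r * arr[, , 1L]
}

#' Local search over the green-channel proportion
#'
#' Hill-climbing on the 1-D weight lattice `g + i * step` for i = 1, 2, ...:
#' starting from the best coarse proportion, neighbours at +/- i*step are
#' scored; the radius expands while the best neighbour at the current radius
#' improves the incumbent and stops after one non-improving radius. Weights
#' are clipped to \[0, 1\] (and r = 1 - g). Ties keep the incumbent closest
#' to the start, so a constant evaluator returns the start unchanged.
#'
#' @param evaluator function(g) -> numeric score (higher is better), e.g. a
#'   segmentation AUC computed over a dataset at proportion `g`G + (1-g)R.
#' @param start_g starting green weight.
#' @param step lattice step (default 0.01).
#' @param max_radius largest i to explore.
#' @return list with `best_g`, `best_score`, and `trace` (data.frame of every
#'   evaluated g and its score, in evaluation order).
#' @export
local_search_proportion <- function(evaluator, start_g = 1, step = 0.01,
                                    max_radius = 100L) {
  stopifnot(step > 0, max_radius >= 1)
  score_of <- function(g) {
    s <- tryCatch(evaluator(g), error = function(e) {
      stop(sprintf("evaluator failed at proportion g=%.4f: %s", g,
                   conditionMessage(e)), call. = FALSE)
    })
    as.numeric(s)
  }
  seen <- new.env(parent = emptyenv())
  trace_g <- numeric(0); trace_s <- numeric(0)
  eval_g <- function(g) {
    key <- sprintf("%.10f", g)
    if (!is.null(seen[[key]])) return(seen[[key]])
    s <- score_of(g)
    seen[[key]] <- s
    trace_g <<- c(trace_g, g); trace_s <<- c(trace_s, s)
    s
  }
  best_g <- clamp(start_g, 0, 1)
  best_score <- eval_g(best_g)
  for (i in seq_len(max_radius)) {
    cand <- unique(clamp(c(start_g + i * step, start_g - i * step), 0, 1))
    improved <- FALSE
    for (g in cand) {
      s <- eval_g(g)
      # strict improvement only: ties keep the incumbent nearest the start
      if (s > best_score + 1e-12) {
        best_score <- s
        best_g <- g
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(best_g = best_g, best_score = best_score,
       trace = data.frame(g = trace_g, score = trace_s))
}
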