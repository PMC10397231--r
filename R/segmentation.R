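# Segmentation evaluation (pixel classification metrics + ROC AUC), the
# non-learned vesselness fallback segmenter, and the leave-one-out harness.

#' Pixel-classification metrics for a segmentation
#'
#' Thresholds the probability map and counts true/false positives/negatives
#' against the binary truth; accuracy, sensitivity and specificity follow
#' from the counts. The AUC is threshold-free: the probability that a random
#' vessel pixel scores above a random background pixel, with ties counted
#' half (midrank statistic).
#'
#' @param prob numeric probability/score matrix.
#' @param truth logical/0-1 matrix of the same size.
#' @param threshold binarization threshold for the count-based metrics.
#' @return object of class `seg_metrics`: list with `tp`, `fn`, `tn`, `fp`,
#'   `acc`, `se`, `sp`, `auc`.
#' @export
evaluate_segmentation <- function(prob, truth, threshold = 0.5) {
  if (!all(dim(prob) == dim(truth))) stop("prob and truth dimensions differ")
  tv <- as.logical(truth)
  pv <- as.numeric(prob)
  pred <- pv >= threshold
  tp <- sum(pred & tv); fn <- sum(!pred & tv)
  tn <- sum(!pred & !tv); fp <- sum(pred & !tv)
  np <- sum(tv); nn <- sum(!tv)
  auc <- if (np == 0L || nn == 0L) {
    warning("AUC undefined: truth contains a single class")
    NA_real_
  } else {
    r <- rank(pv)
    (sum(r[tv]) - np * (np + 1) / 2) / (np * nn)
  }
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 acc = (tp + tn) / (tp + tn + fp + fn),
                 se = if (np > 0) tp / (tp + fn) else NA_real_,
                 sp = if (nn > 0) tn / (tn + fp) else NA_real_,
                 auc = auc),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> ACC %.4f  SE %.4f  SP %.4f  AUC %s\n",
              x$acc, x$se, x$sp,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Hessian vesselness segmentation (non-learned fallback)
#'
#' Multi-scale ridge filter for dark tubular structures: at each Gaussian
#' scale the image Hessian's eigenvalues are computed with gamma-normalized
#' (sigma^2) derivatives; pixels where the large eigenvalue is positive
#' (dark ridge) score by a Frangi-style combination of blobness and
#' structure strength; the per-pixel score is the maximum over scales,
#' normalized to \[0,1\]. Shares the probability-map interface of
#' [predict_segmenter()], so the geometric pipeline runs without any
#' training.
#'
#' @param image numeric matrix (fused grayscale; vessels darker than
#'   background).
#' @param scales Gaussian scales in px, spanning the expected radius range.
#' @param beta blobness sensitivity.
#' @param c_frac structure sensitivity as a fraction of the maximum
#'   structure norm.
#' @return numeric matrix of scores in \[0,1\].
#' @export
segment_vesselness <- function(image, scales = c(1.5, 2.5, 4),
                               beta = 0.5, c_frac = 0.5) {
  m <- matrix(as.numeric(image), nrow(image), ncol(image))
  best <- matrix(0, nrow(m), ncol(m))
  for (s in scales) {
    g <- gauss_blur(m, s)
    # second differences, gamma-normalized
    hrr <- (shift_mat(g, -1, 0) + shift_mat(g, 1, 0) - 2 * g) * s^2
    hcc <- (shift_mat(g, 0, -1) + shift_mat(g, 0, 1) - 2 * g) * s^2
    hrc <- (shift_mat(g, -1, -1) + shift_mat(g, 1, 1) -
              shift_mat(g, -1, 1) - shift_mat(g, 1, -1)) / 4 * s^2
    tr <- hrr + hcc
    dt <- sqrt(pmax(0, (hrr - hcc)^2 + 4 * hrc^2))
    l1 <- (tr - dt) / 2  # |l1| <= |l2| after sorting below
    l2 <- (tr + dt) / 2
    swap <- abs(l1) > abs(l2)
    tmp <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tmp
    S <- sqrt(l1^2 + l2^2)
    cc <- c_frac * max(S)
    rb2 <- (l1 / ifelse(l2 == 0, 1, l2))^2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cc^2)))
    v[l2 <= 0] <- 0  # dark vessels: ridge has positive large eigenvalue
    best <- pmax(best, v)
  }
  if (max(best) > 0) best <- best / max(best)
  best
}

#' Binarize a probability map
#'
#' @param prob numeric score matrix.
#' @param threshold cutoff; pixels with score >= threshold are vessel.
#' @return logical matrix.
#' @export
threshold_prob <- function(prob, threshold = 0.5) prob >= threshold

#' Hysteresis binarization of a probability/vesselness map
#'
#' Pixels scoring at least `high` seed the mask, which then grows through
#' 8-connected pixels scoring at least `low`. Recovers the full vessel
#' width from ridge-like score maps whose response decays toward the walls.
#'
#' @param prob numeric score matrix.
#' @param low,high weak and strong thresholds, `low <= high`.
#' @return logical matrix.
#' @export
hysteresis_mask <- function(prob, low = 0.05, high = 0.4) {
  if (high < low) stop("high threshold must be >= low threshold")
  strong <- prob >= high
  weak <- prob >= low
  cur <- strong
  repeat {
    g <- cur
    for (k in seq_len(8L)) {
      g <- g | (shift_mat(cur * 1, .zs_offsets[k, 1L], .zs_offsets[k, 2L]) > 0)
    }
    g <- g & weak
    if (identical(g, cur)) break
    cur <- g
  }
  cur
}

#' Leave-one-out segmentation harness
#'
#' With N images, image i's metrics come from a model trained on the other
#' N-1 images only. Returns per-image metrics plus the training indices
#' used for each fold so the no-peeking contract is checkable.
#'
#' @param images list of grayscale matrices.
#' @param masks list of truth masks.
#' @param config list passed to [build_denseblock_unet()] /
#'   [train_segmenter()] (fields: depth, base_channels, epochs,
#'   steps_per_epoch, batch_size, patch, lr, seed).
#' @return list of folds, each with `test_index`, `train_indices`,
#'   `metrics`.
#' @export
loo_segmentation <- function(images, masks, config = list()) {
  cfg <- utils::modifyList(list(depth = 2L, base_channels = 4L, epochs = 2L,
                                steps_per_epoch = 40L, batch_size = 8L,
                                patch = 32L, lr = 1e-3, seed = 1L), config)
  n <- length(images)
  stopifnot(n >= 2L)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    model <- build_denseblock_unet(cfg$depth, cfg$base_channels,
                                   seed = cfg$seed + i)
    model <- train_segmenter(model, images[tr_idx], masks[tr_idx],
                             epochs = cfg$epochs,
                             steps_per_epoch = cfg$steps_per_epoch,
                             batch_size = cfg$batch_size, patch = cfg$patch,
                             lr = cfg$lr, seed = cfg$seed + 1000L + i)
    prob <- predict_segmenter(model, images[[i]])
    folds[[i]] <- list(test_index = i, train_indices = tr_idx,
                       metrics = evaluate_segmentation(prob, masks[[i]]))
  }
  folds
}
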