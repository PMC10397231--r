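test_that("pixel metrics satisfy their identities on random maps", {
  set.seed(8)
  for (i in 1:10) {
    truth <- matrix(runif(400) < 0.3, 20L, 20L)
    prob <- matrix(runif(400), 20L, 20L)
    m <- evaluate_segmentation(prob, truth, threshold = 0.5)
    expect_equal(m$tp + m$fn + m$tn + m$fp, 400L)
    expect_equal(m$acc, (m$tp + m$tn) / 400)
    expect_equal(m$se, m$tp / (m$tp + m$fn))
    expect_equal(m$sp, m$tn / (m$tn + m$fp))
  }
})

test_that("perfect and inverted maps hit the metric extremes", {
  truth <- matrix(c(TRUE, FALSE), 10L, 10L)
  m <- evaluate_segmentation(truth * 1, truth)
  expect_equal(c(m$acc, m$se, m$sp, m$auc), c(1, 1, 1, 1))
  m2 <- evaluate_segmentation(1 - truth, truth)
  expect_equal(m2$auc, 0)
  expect_warning(evaluate_segmentation(truth * 1, matrix(TRUE, 10L, 10L)),
                 "single class")
  expect_error(evaluate_segmentation(matrix(1, 2L, 2L), matrix(TRUE, 3L, 3L)),
               "dimensions")
})

test_that("rank AUC equals the brute-force concordant-pair oracle with ties", {
  scores <- c(0.1, 0.4, 0.4, 0.35, 0.8, 0.8, 0.2, 0.9)
  labels <- c(0, 0, 1, 0, 1, 0, 1, 1)
  m <- evaluate_segmentation(matrix(scores, 2L), matrix(labels, 2L))
  expect_equal(m$auc, auc_bruteforce(scores, labels))
  set.seed(12)
  for (i in 1:10) {
    s <- round(runif(30), 1)  # coarse scores force ties
    l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2L) next
    m <- evaluate_segmentation(matrix(s, 5L), matrix(l, 5L))
    expect_equal(m$auc, auc_bruteforce(s, l))
  }
})

test_that("AUC is invariant to strictly monotone transforms of the scores", {
  set.seed(13)
  s <- matrix(runif(100), 10L)
  l <- matrix(rbinom(100, 1, 0.4), 10L)
  a1 <- evaluate_segmentation(s, l)$auc
  expect_equal(evaluate_segmentation(exp(3 * s), l)$auc, a1)
  expect_equal(evaluate_segmentation(qlogis(s * 0.98 + 0.01), l)$auc, a1)
})

test_that("parameter count matches hand-computed layer arithmetic", {
  model <- build_denseblock_unet(depth = 1L, base_channels = 8L, seed = 1L)
  conv_n <- function(cin, cout, k = 3L) k * k * cin * cout + cout
  bn_n <- function(c) 2L * c
  db_n <- function(cin, g) conv_n(cin, g) + bn_n(g) +
    conv_n(cin + g, g) + bn_n(g)
  expected <- db_n(1L, 8L) +              # encoder level 1 (out 16)
    db_n(16L, 16L) +                      # bottleneck (out 32)
    (2L * 2L * 32L * 16L + 16L) +         # transposed conv 32 -> 16
    db_n(32L, 8L) +                       # decoder block on concat(16 + 16)
    conv_n(16L, 1L, k = 1L)               # final 1x1
  expect_equal(count_parameters(model), expected)
})

test_that("zeroed final layer yields probability 0.5 and shape is preserved", {
  model <- build_denseblock_unet(depth = 2L, base_channels = 2L, seed = 2L)
  model$final$W[] <- 0
  model$final$b[] <- 0
  p <- predict_segmenter(model, matrix(0, 24L, 24L))
  expect_equal(dim(p), c(24L, 24L))
  expect_true(all(abs(p - 0.5) < 1e-12))
  # non-divisible patch size refused in training
  expect_error(train_segmenter(model, list(matrix(0, 20L, 20L)),
                               list(matrix(FALSE, 20L, 20L)), patch = 10L),
               "divisible")
})

test_that("analytic gradients match finite differences on a tiny net", {
  model <- build_denseblock_unet(depth = 1L, base_channels = 2L, seed = 7L)
  set.seed(1)
  x <- array(rnorm(8 * 8 * 2), c(8L, 8L, 1L, 2L))
  tgt <- array(rbinom(8 * 8 * 2, 1L, 0.3), c(8L, 8L, 1L, 2L))
  loss_of <- function(m) {
    fwd <- fundus3d:::.unet_fwd(m, x, train = TRUE)
    p <- pmin(pmax(fwd$prob, 1e-7), 1 - 1e-7)
    -mean(tgt * log(p) + (1 - tgt) * log(1 - p))
  }
  fwd <- fundus3d:::.unet_fwd(model, x, train = TRUE)
  fg <- fundus3d:::.flatten_grads(model, fundus3d:::.unet_bwd(model, fwd, tgt))
  fp <- fundus3d:::.flatten_params(model)
  set.seed(2)
  for (nm in sample(names(fp), 6L)) {
    i <- sample.int(length(fp[[nm]]), 1L)
    eps <- 1e-5
    up <- fp; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- fp; dn[[nm]][i] <- dn[[nm]][i] - eps
    num <- (loss_of(fundus3d:::.unflatten_params(model, up)) -
            loss_of(fundus3d:::.unflatten_params(model, dn))) / (2 * eps)
    expect_lt(abs(num - fg[[nm]][i]) / max(1e-6, abs(num) + abs(fg[[nm]][i])),
              1e-4)
  }
})

test_that("training is seeded-deterministic, reduces loss, memorizes one image", {
  tree <- generate_vessel_tree(image_size = c(64L, 64L), root_radius = 4,
                               seed = 9L, segment_length = 25)
  b <- render_fundus(tree, seed = 9L)
  img <- fuse_channels(b, g = 1)
  model0 <- build_denseblock_unet(depth = 2L, base_channels = 4L, seed = 3L)
  expect_identical(train_segmenter(model0, list(img), list(b$mask),
                                   epochs = 0L), model0)
  tr <- train_segmenter(model0, list(img), list(b$mask), epochs = 3L,
                        steps_per_epoch = 30L, batch_size = 8L, patch = 32L,
                        seed = 5L)
  tr2 <- train_segmenter(model0, list(img), list(b$mask), epochs = 3L,
                         steps_per_epoch = 30L, batch_size = 8L, patch = 32L,
                         seed = 5L)
  expect_identical(tr$loss_history, tr2$loss_history)
  h <- tr$loss_history
  expect_lt(mean(tail(h, 10L)), mean(head(h, 10L)))
  auc <- evaluate_segmentation(predict_segmenter(tr, img), b$mask)$auc
  expect_gte(auc, 0.99)
})

test_that("the vesselness fallback separates vessels from background", {
  tree <- generate_vessel_tree(seed = 4L)
  b <- render_fundus(tree, seed = 4L)
  v <- segment_vesselness(fuse_channels(b, g = 1))
  expect_gte(evaluate_segmentation(v, b$mask)$auc, 0.98)
  mask <- hysteresis_mask(v, 0.05, 0.4)
  iou <- sum(mask & b$mask) / sum(mask | b$mask)
  expect_gte(iou, 0.8)
  expect_error(hysteresis_mask(v, 0.5, 0.1), "high threshold")
})

test_that("leave-one-out harness never shows a fold its own image", {
  imgs <- list(); msks <- list()
  for (s in 1:3) {
    tree <- generate_vessel_tree(image_size = c(64L, 64L), root_radius = 4,
                                 seed = 30L + s, segment_length = 25)
    b <- render_fundus(tree, seed = 30L + s)
    imgs[[s]] <- fuse_channels(b, g = 1)
    msks[[s]] <- b$mask
  }
  folds <- loo_segmentation(imgs, msks,
                            config = list(epochs = 1L, steps_per_epoch = 5L,
                                          batch_size = 4L))
  expect_length(folds, 3L)
  for (f in folds) {
    expect_false(f$test_index %in% f$train_indices)
    expect_length(f$train_indices, 2L)
    expect_s3_class(f$metrics, "seg_metrics")
  }
})
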