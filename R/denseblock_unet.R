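# DenseBlock-Unet: an encoder-decoder segmenter whose blocks are 2-layer
# dense blocks. Each block layer is conv 3x3 -> batch normalization -> ReLU,
# with dense cross-layer concatenation: the second convolution sees both the
# block input and the first layer's output, and the block emits the
# concatenation of both layer outputs. The encoder downsamples with 2x2 max
# pooling; the decoder upsamples with 2x2 stride-2 transposed convolutions
# and concatenates the matching encoder output (skip connection). A final
# 1x1 convolution and sigmoid give a per-pixel vessel probability.

.db_new <- function(cin, growth) {
  list(conv1 = nn_conv(cin, growth), bn1 = nn_bn(growth),
       conv2 = nn_conv(cin + growth, growth), bn2 = nn_bn(growth),
       cin = cin, growth = growth, cout = 2L * growth)
}

.db_fwd <- function(db, x, train) {
  c1 <- conv_fwd(db$conv1, x)
  b1 <- bn_fwd(db$bn1, c1$out, train)
  r1 <- relu_fwd(b1$out)
  x2 <- concat_ch(x, r1$out)
  c2 <- conv_fwd(db$conv2, x2)
  b2 <- bn_fwd(db$bn2, c2$out, train)
  r2 <- relu_fwd(b2$out)
  list(out = concat_ch(r1$out, r2$out),
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    cin = db$cin, growth = db$growth),
       stats = list(bn1 = b1$stats, bn2 = b2$stats))
}

.db_bwd <- function(db, cache, dout) {
  sp <- split_ch(dout, db$growth)
  dr2 <- relu_bwd(cache$r2, sp$b)
  b2 <- bn_bwd(db$bn2, cache$b2, dr2)
  c2 <- conv_bwd(db$conv2, cache$c2, b2$dx)
  sp2 <- split_ch(c2$dx, db$cin)
  dr1_total <- sp$a + sp2$b
  dr1 <- relu_bwd(cache$r1, dr1_total)
  b1 <- bn_bwd(db$bn1, cache$b1, dr1)
  c1 <- conv_bwd(db$conv1, cache$c1, b1$dx)
  list(dx = c1$dx + sp2$a,
       grads = list(conv1 = c1$grads, bn1 = b1$grads,
                    conv2 = c2$grads, bn2 = b2$grads))
}

#' Build a DenseBlock-Unet model
#'
#' @param depth number of 2x2 pooling levels (input patches must be
#'   divisible by 2^depth).
#' @param base_channels growth (per-layer output channels) of the first
#'   level's dense block; deeper levels double it.
#' @param in_channels input image channels (1 for the fused grayscale).
#' @param seed seed for weight initialization.
#' @return object of class `denseblock_unet`.
#' @export
build_denseblock_unet <- function(depth = 4L, base_channels = 16L,
                                  in_channels = 1L, seed = 1L) {
  stopifnot(depth >= 1L, base_channels >= 1L)
  with_seed(seed, {
    enc <- list()
    cin <- in_channels
    for (l in seq_len(depth)) {
      g <- base_channels * 2L^(l - 1L)
      enc[[l]] <- .db_new(cin, g)
      cin <- 2L * g
    }
    gb <- base_channels * 2L^depth
    bottleneck <- .db_new(cin, gb)
    cin <- 2L * gb
    dec <- list()
    for (l in rev(seq_len(depth))) {
      g <- base_channels * 2L^(l - 1L)
      up <- nn_tconv(cin, 2L * g)
      db <- .db_new(4L * g, g)
      dec[[as.character(l)]] <- list(up = up, db = db)
      cin <- 2L * g
    }
    final <- nn_conv(cin, 1L, k = 1L)
    structure(list(depth = depth, base_channels = base_channels,
                   in_channels = in_channels, enc = enc,
                   bottleneck = bottleneck, dec = dec, final = final,
                   adam = adam_new(), loss_history = numeric(0)),
              class = "denseblock_unet")
  })
}

#' Number of trainable parameters of a DenseBlock-Unet
#' @param model a `denseblock_unet`.
#' @return integer parameter count (conv/tconv weights and biases, BN
#'   gamma/beta).
#' @export
count_parameters <- function(model) {
  n <- 0L
  cnt <- function(layer) {
    switch(layer$type,
           conv = length(layer$W) + length(layer$b),
           tconv = length(layer$W) + length(layer$b),
           bn = length(layer$gamma) + length(layer$beta))
  }
  db_cnt <- function(db) cnt(db$conv1) + cnt(db$bn1) + cnt(db$conv2) + cnt(db$bn2)
  for (db in model$enc) n <- n + db_cnt(db)
  n <- n + db_cnt(model$bottleneck)
  for (d in model$dec) n <- n + cnt(d$up) + db_cnt(d$db)
  n + cnt(model$final)
}

# Full forward pass; x is (H, W, C, N). Returns probabilities plus caches
# needed for the backward pass.
.unet_fwd <- function(model, x, train = FALSE) {
  d <- dim(x)
  if (d[1L] %% 2L^model$depth != 0L || d[2L] %% 2L^model$depth != 0L) {
    stop(sprintf("input size %dx%d not divisible by 2^depth = %d",
                 d[1L], d[2L], 2L^model$depth))
  }
  caches <- list(enc = list(), pool = list(), dec = list())
  stats <- list()
  skips <- list()
  h <- x
  for (l in seq_len(model$depth)) {
    f <- .db_fwd(model$enc[[l]], h, train)
    caches$enc[[l]] <- f$cache
    stats[[paste0("enc", l)]] <- f$stats
    skips[[l]] <- f$out
    pf <- pool_fwd(f$out)
    caches$pool[[l]] <- pf$cache
    h <- pf$out
  }
  f <- .db_fwd(model$bottleneck, h, train)
  caches$bottleneck <- f$cache
  stats$bottleneck <- f$stats
  h <- f$out
  for (l in rev(seq_len(model$depth))) {
    key <- as.character(l)
    uf <- tconv_fwd(model$dec[[key]]$up, h)
    cc <- concat_ch(uf$out, skips[[l]])
    df <- .db_fwd(model$dec[[key]]$db, cc, train)
    caches$dec[[key]] <- list(up = uf$cache, db = df$cache,
                              up_ch = dim(uf$out)[3L])
    stats[[paste0("dec", l)]] <- df$stats
    h <- df$out
  }
  ff <- conv_fwd(model$final, h)
  caches$final <- ff$cache
  prob <- 1 / (1 + exp(-ff$out))
  list(prob = prob, logits = ff$out, caches = caches, stats = stats)
}

# Backward pass for sigmoid + binary cross-entropy; returns flat grads.
.unet_bwd <- function(model, fwd, target) {
  n <- length(target)
  dlogits <- (fwd$prob - target) / n
  grads <- list()
  fb <- conv_bwd(model$final, fwd$caches$final, dlogits)
  grads$final <- fb$grads
  dh <- fb$dx
  for (l in seq_len(model$depth)) {
    key <- as.character(l)
    db <- model$dec[[key]]$db
    dbb <- .db_bwd(db, fwd$caches$dec[[key]]$db, dh)
    sp <- split_ch(dbb$dx, fwd$caches$dec[[key]]$up_ch)
    ub <- tconv_bwd(model$dec[[key]]$up, fwd$caches$dec[[key]]$up, sp$a)
    grads[[paste0("dec", l)]] <- list(up = ub$grads, db = dbb$grads)
    # sp$b flows into the encoder skip; store for later
    fwd$caches$skipgrad[[l]] <- sp$b
    dh <- ub$dx
  }
  bb <- .db_bwd(model$bottleneck, fwd$caches$bottleneck, dh)
  grads$bottleneck <- bb$grads
  dh <- bb$dx
  for (l in rev(seq_len(model$depth))) {
    dpool <- pool_bwd(fwd$caches$pool[[l]], dh)
    dskip <- dpool + fwd$caches$skipgrad[[l]]
    eb <- .db_bwd(model$enc[[l]], fwd$caches$enc[[l]], dskip)
    grads[[paste0("enc", l)]] <- eb$grads
    dh <- eb$dx
  }
  grads
}

# Flatten model params / grads to a named list for Adam; BN running stats
# are excluded (not trainable).
.flatten_params <- function(model) {
  out <- list()
  add_layer <- function(prefix, layer) {
    if (layer$type == "bn") {
      out[[paste0(prefix, ".gamma")]] <<- layer$gamma
      out[[paste0(prefix, ".beta")]] <<- layer$beta
    } else {
      out[[paste0(prefix, ".W")]] <<- layer$W
      out[[paste0(prefix, ".b")]] <<- layer$b
    }
  }
  add_db <- function(prefix, db) {
    add_layer(paste0(prefix, ".conv1"), db$conv1)
    add_layer(paste0(prefix, ".bn1"), db$bn1)
    add_layer(paste0(prefix, ".conv2"), db$conv2)
    add_layer(paste0(prefix, ".bn2"), db$bn2)
  }
  for (l in seq_along(model$enc)) add_db(paste0("enc", l), model$enc[[l]])
  add_db("bottleneck", model$bottleneck)
  for (l in names(model$dec)) {
    add_layer(paste0("dec", l, ".up"), model$dec[[l]]$up)
    add_db(paste0("dec", l, ".db"), model$dec[[l]]$db)
  }
  add_layer("final", model$final)
  out
}

.flatten_grads <- function(model, grads) {
  out <- list()
  add <- function(prefix, g, type) {
    if (type == "bn") {
      out[[paste0(prefix, ".gamma")]] <<- g$gamma
      out[[paste0(prefix, ".beta")]] <<- g$beta
    } else {
      out[[paste0(prefix, ".W")]] <<- g$W
      out[[paste0(prefix, ".b")]] <<- g$b
    }
  }
  add_db <- function(prefix, g) {
    add(paste0(prefix, ".conv1"), g$conv1, "conv")
    add(paste0(prefix, ".bn1"), g$bn1, "bn")
    add(paste0(prefix, ".conv2"), g$conv2, "conv")
    add(paste0(prefix, ".bn2"), g$bn2, "bn")
  }
  for (l in seq_along(model$enc)) add_db(paste0("enc", l), grads[[paste0("enc", l)]])
  add_db("bottleneck", grads$bottleneck)
  for (l in names(model$dec)) {
    g <- grads[[paste0("dec", l)]]
    add(paste0("dec", l, ".up"), g$up, "tconv")
    add_db(paste0("dec", l, ".db"), g$db)
  }
  add("final", grads$final, "conv")
  out
}

.unflatten_params <- function(model, flat) {
  set_layer <- function(prefix, layer) {
    if (layer$type == "bn") {
      layer$gamma <- flat[[paste0(prefix, ".gamma")]]
      layer$beta <- flat[[paste0(prefix, ".beta")]]
    } else {
      # elementwise Adam updates preserve dims, so shapes carry through
      layer$W <- flat[[paste0(prefix, ".W")]]
      layer$b <- flat[[paste0(prefix, ".b")]]
    }
    layer
  }
  set_db <- function(prefix, db) {
    db$conv1 <- set_layer(paste0(prefix, ".conv1"), db$conv1)
    db$bn1 <- set_layer(paste0(prefix, ".bn1"), db$bn1)
    db$conv2 <- set_layer(paste0(prefix, ".conv2"), db$conv2)
    db$bn2 <- set_layer(paste0(prefix, ".bn2"), db$bn2)
    db
  }
  for (l in seq_along(model$enc)) model$enc[[l]] <- set_db(paste0("enc", l), model$enc[[l]])
  model$bottleneck <- set_db("bottleneck", model$bottleneck)
  for (l in names(model$dec)) {
    model$dec[[l]]$up <- set_layer(paste0("dec", l, ".up"), model$dec[[l]]$up)
    model$dec[[l]]$db <- set_db(paste0("dec", l, ".db"), model$dec[[l]]$db)
  }
  model$final <- set_layer("final", model$final)
  model
}

# Merge BN running-stat updates produced by a training forward pass.
.apply_bn_stats <- function(model, stats) {
  put <- function(db, s) {
    if (!is.null(s$bn1)) {
      db$bn1$run_mean <- s$bn1$run_mean; db$bn1$run_var <- s$bn1$run_var
    }
    if (!is.null(s$bn2)) {
      db$bn2$run_mean <- s$bn2$run_mean; db$bn2$run_var <- s$bn2$run_var
    }
    db
  }
  for (l in seq_along(model$enc)) {
    model$enc[[l]] <- put(model$enc[[l]], stats[[paste0("enc", l)]])
  }
  model$bottleneck <- put(model$bottleneck, stats$bottleneck)
  for (l in names(model$dec)) {
    model$dec[[l]]$db <- put(model$dec[[l]]$db, stats[[paste0("dec", l)]])
  }
  model
}

#' Train a DenseBlock-Unet on grayscale/mask pairs
#'
#' Patch-based training with the Adam optimizer on binary cross-entropy.
#' Patches are sampled uniformly at random (seeded); half the patches are
#' re-drawn centred on vessel pixels so thin structures are not swamped by
#' background. Zero epochs returns the model unchanged. Training aborts
#' with diagnostics if the loss becomes non-finite.
#'
#' @param model a `denseblock_unet`.
#' @param images list of numeric matrices (fused grayscale, any range;
#'   internally scaled to \[0,1\] by the global max).
#' @param masks list of logical/0-1 matrices, same sizes.
#' @param epochs,steps_per_epoch,batch_size,patch,lr training parameters;
#'   `patch` must be divisible by 2^depth.
#' @param seed RNG seed for patch sampling.
#' @return the trained model (with `loss_history` appended).
#' @export
train_segmenter <- function(model, images, masks, epochs = 3L,
                            steps_per_epoch = 50L, batch_size = 8L,
                            patch = 32L, lr = 1e-3, seed = 1L) {
  stopifnot(length(images) >= 1L, length(images) == length(masks))
  if (patch %% 2L^model$depth != 0L) {
    stop("patch size must be divisible by 2^depth")
  }
  if (epochs == 0L) return(model)
  scale <- max(1e-8, max(vapply(images, max, numeric(1L))))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (st in seq_len(steps_per_epoch)) {
        xb <- array(0, c(patch, patch, 1L, batch_size))
        tb <- array(0, c(patch, patch, 1L, batch_size))
        for (i in seq_len(batch_size)) {
          k <- sample.int(length(images), 1L)
          im <- images[[k]]; mk <- masks[[k]]
          if (i %% 2L == 0L && any(mk)) {
            v <- which(mk, arr.ind = TRUE)
            ctr <- v[sample.int(nrow(v), 1L), ]
            r0 <- clamp(ctr[1L] - patch %/% 2L, 1L, nrow(im) - patch + 1L)
            c0 <- clamp(ctr[2L] - patch %/% 2L, 1L, ncol(im) - patch + 1L)
          } else {
            r0 <- sample.int(nrow(im) - patch + 1L, 1L)
            c0 <- sample.int(ncol(im) - patch + 1L, 1L)
          }
          xb[, , 1L, i] <- im[r0:(r0 + patch - 1L), c0:(c0 + patch - 1L)] / scale
          tb[, , 1L, i] <- as.numeric(mk[r0:(r0 + patch - 1L), c0:(c0 + patch - 1L)])
        }
        fwd <- .unet_fwd(model, xb, train = TRUE)
        p <- clamp(fwd$prob, 1e-7, 1 - 1e-7)
        loss <- -mean(tb * log(p) + (1 - tb) * log(1 - p))
        if (!is.finite(loss)) {
          stop(sprintf("training aborted: non-finite loss at epoch %d step %d", ep, st))
        }
        model <- .apply_bn_stats(model, fwd$stats)
        grads <- .unet_bwd(model, fwd, tb)
        flat_g <- .flatten_grads(model, grads)
        flat_p <- .flatten_params(model)
        upd <- adam_step(flat_p, flat_g, model$adam, lr = lr)
        model <- .unflatten_params(model, upd$params)
        model$adam <- upd$state
        model$loss_history <- c(model$loss_history, loss)
      }
    }
  })
  model$input_scale <- scale
  model
}

#' Predict a vessel probability map for a full image
#'
#' Pads the image (edge replication) to a multiple of 2^depth, runs the
#' network in inference mode (batch-norm running statistics), and crops back.
#'
#' @param model a trained `denseblock_unet`.
#' @param image numeric matrix (same intensity convention as training).
#' @return numeric matrix of vessel probabilities in \[0,1\].
#' @export
predict_segmenter <- function(model, image) {
  scale <- model$input_scale %||% max(1e-8, max(image))
  m <- image / scale
  f <- 2L^model$depth
  H <- nrow(m); W <- ncol(m)
  H2 <- ceiling(H / f) * f; W2 <- ceiling(W / f) * f
  pad <- matrix(0, H2, W2)
  pad[seq_len(H), seq_len(W)] <- m
  if (H2 > H) pad[(H + 1L):H2, seq_len(W)] <- matrix(m[H, ], H2 - H, W, byrow = TRUE)
  if (W2 > W) pad[, (W + 1L):W2] <- pad[, W]
  x <- array(pad, c(H2, W2, 1L, 1L))
  fwd <- .unet_fwd(model, x, train = FALSE)
  matrix(fwd$prob[seq_len(H), seq_len(W), 1L, 1L], H, W)
}

#' @export
print.denseblock_unet <- function(x, ...) {
  cat(sprintf("<denseblock_unet> depth %d, base %d, %d parameters, %d training steps\n",
              x$depth, x$base_channels, count_parameters(x),
              length(x$loss_history)))
  invisible(x)
}
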