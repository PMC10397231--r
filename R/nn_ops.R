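# Minimal neural-network primitives (forward + analytic backward) used by
# the DenseBlock-Unet. Activations are stored as (H, W, C, N) arrays. All
# convolutions are stride-1 "same"; pooling and transposed convolutions use
# 2x2 windows with stride 2.

# (H, W, N) array shift with zero fill; dr > 0 moves content down.
shift3 <- function(a, dr, dc) {
  d <- dim(a)
  out <- array(0, d)
  if (abs(dr) >= d[1L] || abs(dc) >= d[2L]) return(out)
  r <- max(1L, 1L + dr):min(d[1L], d[1L] + dr)
  c <- max(1L, 1L + dc):min(d[2L], d[2L] + dc)
  out[r, c, ] <- a[r - dr, c - dc, , drop = FALSE]
  out
}

# (H,W,C,N) <-> (H*W*N) x C matrix
a2m <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
}
m2a <- function(m, H, W, C, N) {
  aperm(array(m, c(H, W, N, C)), c(1L, 2L, 4L, 3L))
}

.he_init <- function(n_in, dims) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / n_in)), dims)
}

## ---- convolution (k x k, stride 1, zero-padded "same") ----

nn_conv <- function(cin, cout, k = 3L) {
  offs <- as.matrix(expand.grid(dr = seq_len(k) - (k + 1L) %/% 2L,
                                dc = seq_len(k) - (k + 1L) %/% 2L))
  list(type = "conv", k = k, cin = cin, cout = cout, offs = offs,
       W = matrix(.he_init(k * k * cin, c(k * k * cin, cout)), k * k * cin, cout),
       b = rep(0, cout))
}

conv_im2col <- function(p, x) {
  d <- dim(x)
  k2 <- p$k^2
  Xc <- matrix(0, d[1L] * d[2L] * d[4L], k2 * p$cin)
  for (ci in seq_len(p$cin)) {
    pl <- array(x[, , ci, ], c(d[1L], d[2L], d[4L]))
    for (o in seq_len(k2)) {
      Xc[, (ci - 1L) * k2 + o] <-
        if (p$k == 1L) as.vector(pl) else
          as.vector(shift3(pl, p$offs[o, 1L], p$offs[o, 2L]))
    }
  }
  Xc
}

conv_fwd <- function(p, x) {
  d <- dim(x)
  Xc <- conv_im2col(p, x)
  Y <- Xc %*% p$W
  Y <- Y + matrix(p$b, nrow(Y), p$cout, byrow = TRUE)
  list(out = m2a(Y, d[1L], d[2L], p$cout, d[4L]),
       cache = list(Xc = Xc, d = d))
}

conv_bwd <- function(p, cache, dout) {
  d <- cache$d
  dY <- a2m(dout)
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- dY %*% t(p$W)
  k2 <- p$k^2
  dx <- array(0, d)
  for (ci in seq_len(p$cin)) {
    acc <- array(0, c(d[1L], d[2L], d[4L]))
    for (o in seq_len(k2)) {
      pl <- array(dXc[, (ci - 1L) * k2 + o], c(d[1L], d[2L], d[4L]))
      acc <- acc + if (p$k == 1L) pl else
        shift3(pl, -p$offs[o, 1L], -p$offs[o, 2L])
    }
    dx[, , ci, ] <- acc
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

## ---- batch normalization (per channel) ----

nn_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", c = c, eps = eps, momentum = momentum,
       gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

bn_fwd <- function(p, x, train) {
  d <- dim(x)
  Xm <- a2m(x)
  if (train) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
  } else {
    mu <- p$run_mean
    v <- p$run_var
  }
  iv <- 1 / sqrt(v + p$eps)
  xhat <- sweep(sweep(Xm, 2L, mu), 2L, iv, `*`)
  Y <- sweep(sweep(xhat, 2L, p$gamma, `*`), 2L, p$beta, `+`)
  stats <- if (train) {
    list(run_mean = (1 - p$momentum) * p$run_mean + p$momentum * mu,
         run_var = (1 - p$momentum) * p$run_var + p$momentum * v)
  } else NULL
  list(out = m2a(Y, d[1L], d[2L], d[3L], d[4L]),
       cache = list(xhat = xhat, iv = iv, d = d, train = train),
       stats = stats)
}

bn_bwd <- function(p, cache, dout) {
  d <- cache$d
  dY <- a2m(dout)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  if (cache$train) {
    n <- nrow(dY)
    t1 <- sweep(dY, 2L, colMeans(dY))
    t2 <- sweep(cache$xhat, 2L, colMeans(dY * cache$xhat), `*`)
    dXm <- sweep(t1 - t2, 2L, p$gamma * cache$iv, `*`)
  } else {
    dXm <- sweep(dY, 2L, p$gamma * cache$iv, `*`)
  }
  list(dx = m2a(dXm, d[1L], d[2L], d[3L], d[4L]),
       grads = list(gamma = dgamma, beta = dbeta))
}

## ---- ReLU ----

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

## ---- 2x2 max pooling, stride 2 ----

pool_fwd <- function(x) {
  d <- dim(x)
  H2 <- d[1L] %/% 2L; W2 <- d[2L] %/% 2L
  cand <- array(0, c(H2, W2, d[3L], d[4L], 4L))
  kk <- 1L
  for (a in 0:1) for (b in 0:1) {
    cand[, , , , kk] <- x[seq(1L, 2L * H2, 2L) + a, seq(1L, 2L * W2, 2L) + b, , , drop = FALSE]
    kk <- kk + 1L
  }
  slice <- function(k) array(cand[, , , , k], c(H2, W2, d[3L], d[4L]))
  best <- slice(1L)
  arg <- array(1L, dim(best))
  for (k in 2:4) {
    s <- slice(k)
    better <- s > best
    arg[better] <- k
    best[better] <- s[better]
  }
  list(out = best, cache = list(arg = arg, d = d))
}

pool_bwd <- function(cache, dout) {
  d <- cache$d
  dx <- array(0, d)
  H2 <- dim(dout)[1L]; W2 <- dim(dout)[2L]
  kk <- 1L
  for (a in 0:1) for (b in 0:1) {
    sel <- cache$arg == kk
    g <- dout * sel
    dx[seq(1L, 2L * H2, 2L) + a, seq(1L, 2L * W2, 2L) + b, , ] <-
      dx[seq(1L, 2L * H2, 2L) + a, seq(1L, 2L * W2, 2L) + b, , , drop = FALSE] + g
    kk <- kk + 1L
  }
  dx
}

## ---- 2x2 stride-2 transposed convolution ----

nn_tconv <- function(cin, cout) {
  list(type = "tconv", cin = cin, cout = cout,
       W = .he_init(cin, c(2L, 2L, cin, cout)),
       b = rep(0, cout))
}

tconv_fwd <- function(p, x) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; N <- d[4L]
  Xm <- a2m(x)
  out <- array(0, c(2L * H, 2L * W, p$cout, N))
  for (a in 1:2) for (b in 1:2) {
    Wab <- matrix(p$W[a, b, , ], p$cin, p$cout)
    Yab <- Xm %*% Wab
    out[seq(a, 2L * H, 2L), seq(b, 2L * W, 2L), , ] <- m2a(Yab, H, W, p$cout, N)
  }
  out <- out + array(rep(p$b, each = 4L * H * W), c(2L * H, 2L * W, p$cout, N))
  list(out = out, cache = list(Xm = Xm, d = d))
}

tconv_bwd <- function(p, cache, dout) {
  d <- cache$d
  H <- d[1L]; W <- d[2L]; N <- d[4L]
  dW <- array(0, dim(p$W))
  dXm <- matrix(0, nrow(cache$Xm), p$cin)
  for (a in 1:2) for (b in 1:2) {
    dYab <- a2m(dout[seq(a, 2L * H, 2L), seq(b, 2L * W, 2L), , , drop = FALSE])
    dW[a, b, , ] <- crossprod(cache$Xm, dYab)
    dXm <- dXm + dYab %*% t(matrix(p$W[a, b, , ], p$cin, p$cout))
  }
  db <- colSums(a2m(dout))
  list(dx = m2a(dXm, H, W, p$cin, N), grads = list(W = dW, b = db))
}

## ---- channel concatenation ----

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

split_ch <- function(d, c1) {
  list(a = d[, , seq_len(c1), , drop = FALSE],
       b = d[, , -seq_len(c1), , drop = FALSE])
}

## ---- Adam ----

adam_new <- function() list(t = 0L, m = list(), v = list())

# params/grads: flat named lists of numeric tensors
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
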