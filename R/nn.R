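# Minimal neural-network primitives: forward passes paired with analytic
# backward passes, plus the AdaGrad optimizer.  Everything is plain double
# matrices; all randomness goes through R's RNG so runs are reproducible
# with a single seed.

u_init <- function(nr, nc, range) {
  matrix(stats::runif(nr * nc, -range, range), nr, nc)
}

sigm <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# ---- nested parameter lists ----------------------------------------------

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

add_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) {
      if (is.null(b[[nm]])) stop("gradient component '", nm, "' missing", call. = FALSE)
      a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    }
    a
  } else a + b
}

scale_grads <- function(a, s) {
  if (is.list(a)) lapply(a, scale_grads, s = s) else a * s
}

flatten_theta <- function(x) {
  if (is.list(x)) unlist(lapply(x, flatten_theta), use.names = FALSE) else as.numeric(x)
}

unflatten_theta <- function(proto, v) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- x
    out[] <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  walk(proto)
}

# AdaGrad: per-coordinate step lr * g / (sqrt(sum g^2) + eps)
adagrad_update <- function(theta, grad, acc, lr, eps = 1e-8) {
  walk <- function(th, g, a) {
    if (is.list(th)) {
      out_t <- th; out_a <- a
      for (nm in names(th)) {
        r <- walk(th[[nm]], g[[nm]], a[[nm]])
        out_t[[nm]] <- r$theta
        out_a[[nm]] <- r$acc
      }
      return(list(theta = out_t, acc = out_a))
    }
    a2 <- a + g * g
    list(theta = th - lr * g / (sqrt(a2) + eps), acc = a2)
  }
  walk(theta, grad, acc)
}

# ---- convolution + ReLU + segment max-pool --------------------------------

# x: L x Cin input; K: (w*Cin) x C filter bank (tap-major, channel-minor
# rows); b: length-C bias.  Output: S*C vector (segment-major within each
# channel after as.vector of the S x C pooled matrix).
conv_pool_forward <- function(x, K, b, segments, kernel) {
  Cin <- ncol(x)
  C <- ncol(K)
  w <- kernel
  stopifnot(nrow(K) == w * Cin)
  L0 <- nrow(x)
  # pad short inputs so the convolution yields at least one position per
  # pooling segment (keeps the pooled feature count fixed)
  Lmin <- w + segments - 1L
  if (L0 < Lmin) x <- rbind(x, matrix(0, Lmin - L0, Cin))
  L <- nrow(x)
  P <- L - w + 1L
  Xc <- do.call(cbind, lapply(0:(w - 1L), function(j) x[(1L + j):(P + j), , drop = FALSE]))
  Z <- Xc %*% K + matrix(b, P, C, byrow = TRUE)
  A <- Z
  A[A < 0] <- 0
  S <- segments
  bounds <- floor(seq(0L, P, length.out = S + 1L))
  pooled <- matrix(0, S, C)
  argmax <- matrix(0L, S, C)
  for (s in seq_len(S)) {
    rows <- (bounds[s] + 1L):bounds[s + 1L]
    blk <- A[rows, , drop = FALSE]
    am <- max.col(t(blk), ties.method = "first")
    argmax[s, ] <- rows[am]
    pooled[s, ] <- blk[cbind(am, seq_len(C))]
  }
  list(out = as.vector(pooled),
       cache = list(Xc = Xc, mask = Z > 0, argmax = argmax, K = K,
                    S = S, C = C, P = P, w = w, Cin = Cin, L0 = L0, L = L))
}

conv_pool_backward <- function(cache, dout) {
  with(cache, {
    dpool <- matrix(dout, S, C)
    dA <- matrix(0, P, C)
    dA[cbind(as.vector(argmax), rep(seq_len(C), each = S))] <- as.vector(dpool)
    dZ <- dA * mask
    dK <- crossprod(Xc, dZ)
    db <- colSums(dZ)
    dXc <- tcrossprod(dZ, K)
    dx <- matrix(0, L, Cin)
    for (j in 0:(w - 1L)) {
      dx[(1L + j):(P + j), ] <- dx[(1L + j):(P + j), ] +
        dXc[, (j * Cin + 1L):((j + 1L) * Cin), drop = FALSE]
    }
    list(dx = dx[seq_len(L0), , drop = FALSE], dK = dK, db = db)
  })
}

# ---- dense layer ----------------------------------------------------------

dense_forward <- function(x, W, b) {
  list(out = as.vector(W %*% x + b), cache = list(x = x, W = W))
}

dense_backward <- function(cache, dout) {
  list(dx = as.vector(crossprod(cache$W, dout)),
       dW = tcrossprod(dout, cache$x),
       db = dout)
}

# ---- tanh/softmax attention (projection W, query w) ------------------------
# M = tanh(W H); alpha = softmax(w' M); v = H alpha

attend_forward <- function(H, W, w) {
  M <- tanh(W %*% H)
  scores <- as.vector(crossprod(w, M))
  alpha <- softmax_vec(scores)
  v <- as.vector(H %*% alpha)
  list(v = v, alpha = alpha,
       cache = list(H = H, M = M, alpha = alpha, W = W, w = w))
}

# dv: gradient on v; dalpha: extra gradient flowing directly into alpha;
# dH_direct: extra gradient flowing directly into H (both may be NULL).
attend_backward <- function(cache, dv, dalpha = NULL, dH_direct = NULL) {
  with(cache, {
    if (is.null(dv)) dv <- numeric(nrow(H))
    dH <- tcrossprod(dv, alpha)
    da <- as.vector(crossprod(H, dv))
    if (!is.null(dalpha)) da <- da + dalpha
    ds <- alpha * (da - sum(alpha * da))
    dM <- tcrossprod(w, ds)
    dT <- dM * (1 - M * M)
    dW <- tcrossprod(dT, H)
    dH <- dH + crossprod(W, dT)
    if (!is.null(dH_direct)) dH <- dH + dH_direct
    dw <- as.vector(M %*% ds)
    list(dH = dH, dW = dW, dw = dw)
  })
}

# ---- LSTM over a batch of sequences ---------------------------------------
# X: list over time of (in x B) input matrices (padded steps are all-zero
# columns whose outputs are never read).  Params: Wx (4h x in), Wh (4h x h),
# b (4h), gate order i, f, o, g.

lstm_init <- function(input_dim, hidden, range) {
  b <- stats::runif(4L * hidden, -range, range)
  b[(hidden + 1L):(2L * hidden)] <- 1   # forget-gate bias
  list(Wx = u_init(4L * hidden, input_dim, range),
       Wh = u_init(4L * hidden, hidden, range),
       b = b)
}

lstm_forward <- function(X, params) {
  Tn <- length(X)
  B <- ncol(X[[1]])
  h <- ncol(params$Wh)
  hp <- matrix(0, h, B)
  cp <- matrix(0, h, B)
  steps <- vector("list", Tn)
  H <- vector("list", Tn)
  ix <- seq_len(h)
  for (t in seq_len(Tn)) {
    G <- params$Wx %*% X[[t]] + params$Wh %*% hp + params$b
    i <- sigm(G[ix, , drop = FALSE])
    f <- sigm(G[ix + h, , drop = FALSE])
    o <- sigm(G[ix + 2L * h, , drop = FALSE])
    g <- tanh(G[ix + 3L * h, , drop = FALSE])
    c_t <- f * cp + i * g
    tc <- tanh(c_t)
    h_t <- o * tc
    steps[[t]] <- list(x = X[[t]], hp = hp, cp = cp, i = i, f = f, o = o,
                       g = g, tc = tc)
    H[[t]] <- h_t
    hp <- h_t
    cp <- c_t
  }
  list(H = H, cache = list(steps = steps, params = params, h = h, B = B))
}

lstm_backward <- function(cache, dH) {
  params <- cache$params
  h <- cache$h
  B <- cache$B
  Tn <- length(cache$steps)
  dWx <- params$Wx * 0
  dWh <- params$Wh * 0
  db <- params$b * 0
  dX <- vector("list", Tn)
  dh_carry <- matrix(0, h, B)
  dc_carry <- matrix(0, h, B)
  for (t in rev(seq_len(Tn))) {
    st <- cache$steps[[t]]
    dh <- dh_carry + (if (is.null(dH[[t]])) 0 else dH[[t]])
    do_ <- dh * st$tc
    dtc <- dh * st$o * (1 - st$tc * st$tc) + dc_carry
    dc_carry <- dtc * st$f
    di <- dtc * st$g
    df <- dtc * st$cp
    dg <- dtc * st$i
    dG <- rbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_ * st$o * (1 - st$o),
                dg * (1 - st$g * st$g))
    dWx <- dWx + tcrossprod(dG, st$x)
    dWh <- dWh + tcrossprod(dG, st$hp)
    db <- db + rowSums(dG)
    dX[[t]] <- crossprod(params$Wx, dG)
    dh_carry <- crossprod(params$Wh, dG)
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# ---- RMS normalization ----------------------------------------------------
# y = x / sqrt(mean(x^2) + eps): puts heterogeneous feature blocks on a
# comparable scale before fusion.

rms_norm_forward <- function(x, eps = 1e-6) {
  r <- sqrt(mean(x * x) + eps)
  list(out = x / r, cache = list(x = x, r = r))
}

rms_norm_backward <- function(cache, dout) {
  with(cache, {
    n <- length(x)
    dout / r - x * (sum(dout * x) / (n * r^3))
  })
}

# layer normalization (center + scale): y = (x - mean(x)) / sqrt(var(x)+eps)
layer_norm_forward <- function(x, eps = 1e-6) {
  mu <- mean(x)
  xc <- x - mu
  r <- sqrt(mean(xc * xc) + eps)
  list(out = xc / r, cache = list(xc = xc, r = r))
}

layer_norm_backward <- function(cache, dout) {
  with(cache, {
    n <- length(xc)
    dxh <- dout / r
    dxh - mean(dxh) - xc * (sum(dout * xc) / (n * r^3))
  })
}

# ---- centered scalar-scale batch normalization ----------------------------
# Columns are instances.  Each feature is centered across the batch (killing
# the instance-independent common mode) but the scale is a single scalar,
# the root mean feature variance, so the relative magnitudes of features —
# which carry the learned signal weighting — are preserved (unlike
# per-feature whitening).  Evaluation uses running statistics.

batchnorm_forward <- function(Z, running, train, momentum = 0.1, eps = 1e-8) {
  if (train && ncol(Z) > 1L) {
    mu <- rowMeans(Z)
    zc <- Z - mu
    v <- mean(zc * zc)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
    zc <- Z - mu
  }
  s <- sqrt(v + eps)
  list(out = zc / s, running = running,
       cache = list(zc = zc, s = s, train = train && ncol(Z) > 1L))
}

batchnorm_backward <- function(cache, dout) {
  with(cache, {
    if (!train) return(dout / s)
    n <- length(zc)
    dzc <- dout / s - zc * (sum(dout * zc) / (n * s^3))
    dzc - rowMeans(dzc)
  })
}

# ---- dropout --------------------------------------------------------------

dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(matrix(1, nr, nc))
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}
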