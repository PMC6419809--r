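# Batched text encoder: all description sentences of a set of drugs pass
# through the Bi-LSTM, word attention and bag attention as grouped matrix
# operations.  Numerically identical to the per-drug path in text.R (the
# tests assert this); used by the training loop where per-drug calls would
# dominate the runtime.

# grouped tanh/softmax attention over column groups of H (h x Ttot);
# gs: group index per column (1..G).  Returns pooled vectors V (h x G).
grouped_attend_forward <- function(H, W, w, gs, G) {
  M <- tanh(W %*% H)
  scores <- as.vector(crossprod(w, M))
  gmax <- vapply(split(scores, gs), max, numeric(1))
  e <- exp(scores - gmax[gs])
  denom <- vapply(split(e, gs), sum, numeric(1))
  alpha <- e / denom[gs]
  V <- t(rowsum(t(H * rep(alpha, each = nrow(H))), gs))
  list(V = V, alpha = alpha,
       cache = list(H = H, M = M, alpha = alpha, gs = gs, W = W, w = w))
}

grouped_attend_backward <- function(cache, dV) {
  with(cache, {
    h <- nrow(H)
    dVexp <- dV[, gs, drop = FALSE]
    dalpha <- colSums(H * dVexp)
    dH <- dVexp * rep(alpha, each = h)
    gsum <- rowsum(alpha * dalpha, gs)[, 1]
    ds <- alpha * (dalpha - gsum[gs])
    dM <- tcrossprod(w, ds)
    dT <- dM * (1 - M * M)
    dW <- tcrossprod(dT, H)
    dH <- dH + crossprod(W, dT)
    dw <- as.vector(M %*% ds)
    list(dH = dH, dW = dW, dw = dw)
  })
}

# sent_ids_list: per drug, list of 5 x T id matrices.
text_batch_forward <- function(encoder, sent_ids_list, train = FALSE) {
  p <- encoder$params
  h <- encoder$hidden
  d <- encoder$input_dim
  n_drugs <- length(sent_ids_list)
  sent_flat <- unlist(sent_ids_list, recursive = FALSE)
  ns <- length(sent_flat)
  gd <- rep(seq_len(n_drugs), times = lengths(sent_ids_list))  # drug of sentence
  lens <- vapply(sent_flat, ncol, integer(1))
  if (any(lens == 0L)) stop("empty sentence", call. = FALSE)
  Tmax <- max(lens)
  all_ids <- do.call(cbind, sent_flat)          # 5 x Ttot
  Ttot <- ncol(all_ids)
  gs <- rep(seq_len(ns), times = lens)          # sentence of token column
  starts <- cumsum(c(0L, lens))[seq_len(ns)]
  tables <- p[c("word", "rel_root", "rel_e1", "rel_e2", "dep_tag")]
  E <- lookup_embeddings(all_ids, tables)       # d x Ttot
  Ez <- cbind(E, numeric(d))                    # padding column
  pad <- Ttot + 1L
  ixf <- matrix(pad, Tmax, ns)
  ixb <- matrix(pad, Tmax, ns)
  for (s in seq_len(ns)) {
    ixf[seq_len(lens[s]), s] <- starts[s] + seq_len(lens[s])
    ixb[seq_len(lens[s]), s] <- starts[s] + rev(seq_len(lens[s]))
  }
  Xf <- lapply(seq_len(Tmax), function(t) Ez[, ixf[t, ], drop = FALSE])
  Xb <- lapply(seq_len(Tmax), function(t) Ez[, ixb[t, ], drop = FALSE])
  fwd <- lstm_forward(Xf, p$lstm_f)
  bwd <- lstm_forward(Xb, p$lstm_b)
  # hw columns aligned with E's token columns
  Hw <- matrix(0, h, Ttot)
  for (t in seq_len(Tmax)) {
    live <- ixf[t, ] != pad
    if (!any(live)) next
    cols_f <- ixf[t, live]
    Hw[, cols_f] <- Hw[, cols_f] + fwd$H[[t]][, live, drop = FALSE]
    cols_b <- ixb[t, live]
    Hw[, cols_b] <- Hw[, cols_b] + bwd$H[[t]][, live, drop = FALSE]
  }
  mask <- NULL
  if (train && encoder$dropout > 0) {
    mask <- dropout_mask(h, Ttot, encoder$dropout)
    Hw <- Hw * mask
  }
  wat <- grouped_attend_forward(Hw, p$watt$W, p$watt$w, gs, ns)
  S <- wat$V                                    # h x ns
  if (!is.null(p$bag$A)) {
    Zb <- p$bag$A %*% S
    e <- as.vector(crossprod(p$bag$q, Zb))
  } else {
    Zb <- NULL
    e <- as.vector(crossprod(p$bag$q, S))
  }
  dmax <- vapply(split(e, gd), max, numeric(1))
  ee <- exp(e - dmax[gd])
  dden <- vapply(split(ee, gd), sum, numeric(1))
  a <- ee / dden[gd]
  BAG <- t(rowsum(t(S * rep(a, each = h)), gd))  # h x n_drugs
  OUT <- p$W %*% BAG + p$bw                      # text_dim x n_drugs
  list(out = OUT,
       cache = list(all_ids = all_ids, gs = gs, gd = gd, ixf = ixf, ixb = ixb,
                    pad = pad, lens = lens, ns = ns, Ttot = Ttot, Tmax = Tmax,
                    fwd = fwd$cache, bwd = bwd$cache, wat = wat$cache,
                    S = S, a = a, Zb = Zb, BAG = BAG, mask = mask))
}

text_batch_backward <- function(encoder, cache, dOUT) {
  p <- encoder$params
  h <- encoder$hidden
  with(cache, {
    dW_out <- tcrossprod(dOUT, BAG)
    dbw_out <- rowSums(dOUT)
    dBAG <- crossprod(p$W, dOUT)                 # h x n_drugs
    dBexp <- dBAG[, gd, drop = FALSE]            # h x ns
    da <- colSums(S * dBexp)
    dS <- dBexp * rep(a, each = h)
    gsum <- rowsum(a * da, gd)[, 1]
    de <- a * (da - gsum[gd])
    if (!is.null(p$bag$A)) {
      dq <- as.vector(Zb %*% de)
      dZb <- tcrossprod(p$bag$q, de)
      dA <- tcrossprod(dZb, S)
      dS <- dS + crossprod(p$bag$A, dZb)
      bag_grads <- list(A = dA, q = dq)
    } else {
      dq <- as.vector(S %*% de)
      dS <- dS + tcrossprod(p$bag$q, de)
      bag_grads <- list(q = dq)
    }
    wb <- grouped_attend_backward(wat, dS)
    dHw <- wb$dH
    if (!is.null(mask)) dHw <- dHw * mask
    dHf <- vector("list", Tmax)
    dHb <- vector("list", Tmax)
    for (t in seq_len(Tmax)) {
      live <- ixf[t, ] != pad
      zf <- matrix(0, h, ns)
      zb <- matrix(0, h, ns)
      zf[, live] <- dHw[, ixf[t, live], drop = FALSE]
      zb[, live] <- dHw[, ixb[t, live], drop = FALSE]
      dHf[[t]] <- zf
      dHb[[t]] <- zb
    }
    gf <- lstm_backward(fwd, dHf)
    gb <- lstm_backward(bwd, dHb)
    dE <- matrix(0, encoder$input_dim, Ttot)
    for (t in seq_len(Tmax)) {
      live <- ixf[t, ] != pad
      if (!any(live)) next
      cf <- ixf[t, live]
      dE[, cf] <- dE[, cf] + gf$dX[[t]][, live, drop = FALSE]
      cb <- ixb[t, live]
      dE[, cb] <- dE[, cb] + gb$dX[[t]][, live, drop = FALSE]
    }
    dims <- c(ncol(p$word), ncol(p$rel_root), ncol(p$rel_e1),
              ncol(p$rel_e2), ncol(p$dep_tag))
    offs <- cumsum(c(0L, dims))
    tabs <- c("word", "rel_root", "rel_e1", "rel_e2", "dep_tag")
    dtab <- list()
    for (k in seq_along(tabs)) {
      rows <- (offs[k] + 1L):offs[k + 1L]
      agg <- rowsum(t(dE[rows, , drop = FALSE]), all_ids[tabs[k], ])
      g <- p[[tabs[k]]] * 0
      g[as.integer(rownames(agg)), ] <- agg
      dtab[[tabs[k]]] <- g
    }
    list(grads = list(word = dtab$word, rel_root = dtab$rel_root,
                      rel_e1 = dtab$rel_e1, rel_e2 = dtab$rel_e2,
                      dep_tag = dtab$dep_tag,
                      lstm_f = list(Wx = gf$dWx, Wh = gf$dWh, b = gf$db),
                      lstm_b = list(Wx = gb$dWx, Wh = gb$dWh, b = gb$db),
                      watt = list(W = wb$dW, w = wb$dw),
                      bag = bag_grads,
                      W = dW_out, bw = dbw_out))
  })
}
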