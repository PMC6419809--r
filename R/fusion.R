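# Interactive attention over the three feature blocks, concatenation into
# the final drug representation, the DDI softmax head trained end-to-end
# with AdaGrad/cross-entropy, and the random-forest DDS head.

#' Interactive feature attention (single block)
#'
#' The attention primitive applied to one feature block reshaped to a
#' `dl x m` matrix `H`: `M = tanh(W_sw H)`, `alpha = softmax(w_w' M)`,
#' `v_c = H alpha'`.
#'
#' @param H `dl x m` feature matrix (m >= 1 columns).
#' @param W_sw `dl x dl` projection.
#' @param w_w length-`dl` query.
#' @return list with `v_c` (a convex combination of H's columns), `alpha`
#'   (nonnegative, sums to 1) and `M`.
#' @export
attend_block <- function(H, W_sw, w_w) {
  H <- as.matrix(H)
  if (ncol(H) < 1L) stop("attention needs m >= 1 columns", call. = FALSE)
  at <- attend_forward(H, W_sw, w_w)
  list(v_c = at$v, alpha = at$alpha, M = at$cache$M)
}

# forward through one block's fusion attention; mode "reweight" scales the
# block's column groups by m * alpha (uniform attention = identity),
# "pool" emits the attention-pooled column v_c.
fusion_block_forward <- function(block, params, m, mode) {
  dl <- length(block) %/% m
  H <- matrix(block, dl, m)
  at <- attend_forward(H, params$W, params$w)
  out <- if (mode == "reweight") {
    as.vector(H * rep(m * at$alpha, each = dl))
  } else {
    at$v
  }
  list(out = out, alpha = at$alpha,
       cache = list(at = at$cache, H = H, dl = dl, m = m, mode = mode))
}

fusion_block_backward <- function(cache, dout) {
  with(cache, {
    if (mode == "reweight") {
      dHs <- matrix(dout, dl, m)
      dalpha <- m * colSums(dHs * H)
      dH_direct <- dHs * rep(m * at$alpha, each = dl)
      ab <- attend_backward(at, dv = NULL, dalpha = dalpha,
                            dH_direct = dH_direct)
    } else {
      ab <- attend_backward(at, dv = dout)
    }
    list(dblock = as.vector(ab$dH), grads = list(W = ab$dW, w = ab$dw))
  })
}

#' Fuse the three feature blocks into a drug embedding
#'
#' Each block is passed through its own interactive attention
#' ([attend_block()]) and the results are concatenated in the order pharm,
#' class, text.  In the default `"reweight"` mode the attention weights
#' rescale each block's column groups so block lengths (hence the fused
#' length, 500 + 128 + 128 = 756 under reference defaults) are preserved;
#' `"pool"` concatenates the pooled vectors `v_c` instead.
#'
#' @param pharm,class,text numeric block vectors.
#' @param params named list with `pharm`, `class`, `text`, each holding the
#'   block's `W` and `w` attention parameters.
#' @param m number of column groups per block.
#' @param mode `"reweight"` or `"pool"`.
#' @return list with `fused` and per-block `alpha`s.
#' @export
fuse <- function(pharm, class, text, params, m = 4L, mode = "reweight") {
  blocks <- list(pharm = pharm, class = class, text = text)
  lens <- lengths(blocks)
  if (any(lens %% m != 0L)) {
    stop("block lengths must be divisible by m = ", m, call. = FALSE)
  }
  outs <- lapply(names(blocks), function(nm) {
    fusion_block_forward(blocks[[nm]], params[[nm]], m, mode)
  })
  names(outs) <- names(blocks)
  list(fused = unlist(lapply(outs, `[[`, "out"), use.names = FALSE),
       alpha = lapply(outs, `[[`, "alpha"))
}

# ---- DDI head -------------------------------------------------------------

new_ddi_head <- function(fused_len, config) {
  r <- config$init_range
  C <- config$conv_depth
  w <- config$conv_kernel
  S <- min(config$head_pool_segments, max(fused_len - w + 1L, 1L))
  list(K = u_init(w * 2L, C, r), b = stats::runif(C, -r, r),
       W = u_init(config$head_dim, S * C, r),
       bw = stats::runif(config$head_dim, -r, r),
       Wo = u_init(2L, config$head_dim, r),
       bo = stats::runif(2L, -r, r),
       bn = list(mean = numeric(config$head_dim), var = 1),
       bnp = list(mean = numeric(S * C), var = 1),
       fc = list(mean = numeric(fused_len)),
       segments = S, kernel = w, norm = config$head_norm)
}

# joint layer over a batch of ordered pair instances: columns of FA/FB are
# the first/second drug's fused vectors.  The fully connected output is
# batch-normalized (per feature, across the batch) before the softmax
# projection, which keeps the head's logits centered and sensitive under
# the fixed small-uniform initialization; evaluation uses running
# statistics.
head_forward_batch <- function(FA, FB, head, train = FALSE) {
  B <- ncol(FA)
  use_bn <- head$norm != "none"
  if (use_bn) {
    # center the fused embeddings: the drug-independent mean profile would
    # otherwise dominate the ReLU'd convolution features
    if (train && B > 1L) {
      mu_f <- rowMeans(cbind(FA, FB))
      head$fc$mean <- 0.9 * head$fc$mean + 0.1 * mu_f
    } else {
      mu_f <- head$fc$mean
    }
    FA <- FA - mu_f
    FB <- FB - mu_f
  }
  SC <- head$segments * ncol(head$K)
  P <- matrix(0, SC, B)
  cps <- vector("list", B)
  for (j in seq_len(B)) {
    cp <- conv_pool_forward(cbind(FA[, j], FB[, j]), head$K, head$b,
                            head$segments, head$kernel)
    P[, j] <- cp$out
    cps[[j]] <- cp$cache
  }
  if (use_bn) {
    bnp <- batchnorm_forward(P, head$bnp, train)
    head$bnp <- bnp$running
    Pn <- bnp$out
  } else {
    bnp <- NULL
    Pn <- P
  }
  Z <- head$W %*% Pn + head$bw
  if (use_bn) {
    bn <- batchnorm_forward(Z, head$bn, train)
    head$bn <- bn$running
    pr <- bn$out
  } else {
    bn <- NULL
    pr <- Z
  }
  logits <- head$Wo %*% pr + head$bo
  mx <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, mx))
  y <- sweep(e, 2L, colSums(e), "/")
  list(y = y, logits = logits, head = head,
       cache = list(cps = cps, P = P, Pn = Pn, pr = pr, use_bn = use_bn,
                    bn = if (use_bn) bn$cache else NULL,
                    bnp = if (use_bn) bnp$cache else NULL,
                    train_center = use_bn && train && B > 1L, head = head))
}

head_backward_batch <- function(cache, dlogits) {
  head <- cache$head
  dWo <- tcrossprod(dlogits, cache$pr)
  dbo <- rowSums(dlogits)
  dpr <- crossprod(head$Wo, dlogits)
  dZ <- if (cache$use_bn) batchnorm_backward(cache$bn, dpr) else dpr
  dW <- tcrossprod(dZ, cache$Pn)
  dbw <- rowSums(dZ)
  dPn <- crossprod(head$W, dZ)
  dP <- if (cache$use_bn) batchnorm_backward(cache$bnp, dPn) else dPn
  B <- ncol(dlogits)
  dFA <- matrix(0, 0, 0)
  dFB <- matrix(0, 0, 0)
  for (j in seq_len(B)) {
    dcp <- conv_pool_backward(cache$cps[[j]], dP[, j])
    if (j == 1L) {
      dFA <- matrix(0, nrow(dcp$dx), B)
      dFB <- matrix(0, nrow(dcp$dx), B)
    }
    dFA[, j] <- dcp$dx[, 1]
    dFB[, j] <- dcp$dx[, 2]
    if (j == 1L) {
      gK <- dcp$dK; gb <- dcp$db
    } else {
      gK <- gK + dcp$dK; gb <- gb + dcp$db
    }
  }
  if (isTRUE(cache$train_center)) {
    tot <- (rowSums(dFA) + rowSums(dFB)) / (2 * B)
    dFA <- dFA - tot
    dFB <- dFB - tot
  }
  list(dFA = dFA, dFB = dFB,
       grads = list(K = gK, b = gb, W = dW, bw = dbw, Wo = dWo, bo = dbo))
}

# single-pair evaluation-mode forward (running batch-norm statistics)
head_forward <- function(fa, fb, head) {
  r <- head_forward_batch(matrix(fa, ncol = 1L), matrix(fb, ncol = 1L),
                          head, train = FALSE)
  list(y = as.vector(r$y), logits = as.vector(r$logits), cache = r$cache)
}

#' DDI prediction for one pair of fused drug embeddings
#'
#' Joint layer: the two fused vectors enter as the two input channels of a
#' 1-D convolution (kernel 5, depth 20), then ReLU, segment max-pool, a
#' fully connected layer, ReLU, and the final softmax projection
#' `y = softmax(W_o pr + b_o)`.  With symmetrization the probabilities of
#' the two pair orderings are averaged, so the prediction is exactly
#' symmetric in its arguments.
#'
#' @param drug_a,drug_b fused embedding vectors.
#' @param head a DDI head (from a trained [kmr_model()], `model$head`).
#' @param symmetrize average over both orderings.
#' @return length-2 probability vector `(positive, negative)`.
#' @export
ddi_predict <- function(drug_a, drug_b, head, symmetrize = TRUE) {
  y <- head_forward(drug_a, drug_b, head)$y
  if (symmetrize) {
    y <- (y + head_forward(drug_b, drug_a, head)$y) / 2
  }
  y
}

# ---- full model -----------------------------------------------------------

#' Assemble an untrained model for a dataset
#'
#' Initializes every trainable component (pharmacological reducer, class
#' encoder, text encoder, fusion attention, DDI head) uniformly on
#' \[-init_range, init_range\] from the current RNG state, and freezes the
#' dataset-derived vocabularies and catalogs.
#'
#' @param dataset a `kmr_dataset` ([load_dataset()]).
#' @param config a [kmr_config()].
#' @param channels taxonomy embedding channels
#'   ([learn_class_channels()]); learned here when `NULL`.
#' @param word_table optional pre-trained word embeddings.
#' @return a `kmr_model`.
#' @export
kmr_model <- function(dataset, config = kmr_config(), channels = NULL,
                      word_table = NULL) {
  stopifnot(inherits(dataset, "kmr_dataset"))
  m <- config$fusion_m
  for (f in c("reducer_dim", "class_dim", "text_dim")) {
    if (config[[f]] %% m != 0L) {
      stop(f, " must be divisible by fusion_m = ", m, call. = FALSE)
    }
  }
  if (is.null(channels)) {
    channels <- learn_class_channels(dataset$taxonomy, config, config$seed)
  }
  # length-normalize each node's channel vectors, the usual post-processing
  # of word2vec-family embeddings before downstream use
  channels <- lapply(channels, function(ch) {
    n <- sqrt(rowSums(ch * ch))
    ch / pmax(n, 1e-12)
  })
  input_length <- sum(vapply(dataset$catalogs, function(cat)
    length(cat$items), integer(1))) + dataset$fingerprint_length
  sents <- unlist(lapply(dataset$drugs, `[[`, "sentences"), recursive = FALSE)
  vocab <- unique(unlist(lapply(sents, `[[`, "tokens"), use.names = FALSE))
  tagset <- unique(unlist(lapply(sents, `[[`, "dep_tags"), use.names = FALSE))

  reducer <- new_pharm_reducer(input_length, config)
  class_enc <- new_class_encoder(config)
  text_enc <- new_text_encoder(vocab, tagset, config, word_table)
  r <- config$init_range
  mk_att <- function(len) {
    dl <- len %/% m
    list(W = u_init(dl, dl, r), w = stats::runif(dl, -r, r))
  }
  fusion <- list(pharm = mk_att(config$reducer_dim),
                 class = mk_att(config$class_dim),
                 text = mk_att(config$text_dim))
  fused_len <- config$reducer_dim + config$class_dim + config$text_dim
  if (config$fusion_mode == "pool") fused_len <- fused_len %/% m
  head <- new_ddi_head(fused_len, config)
  structure(list(config = config, reducer = reducer, class_enc = class_enc,
                 text_enc = text_enc, fusion = fusion, head = head,
                 channels = channels, catalogs = dataset$catalogs,
                 fingerprint_length = dataset$fingerprint_length,
                 fused_len = fused_len),
            class = "kmr_model")
}

model_theta <- function(model) {
  list(pharm = model$reducer$params,
       class = model$class_enc$params,
       text = model$text_enc$params,
       fusion = model$fusion,
       head = model$head[c("K", "b", "W", "bw", "Wo", "bo")])
}

model_set_theta <- function(model, theta) {
  model$reducer$params <- theta$pharm
  model$class_enc$params <- theta$class
  model$text_enc$params <- theta$text
  model$fusion <- theta$fusion
  model$head[c("K", "b", "W", "bw", "Wo", "bo")] <-
    theta$head[c("K", "b", "W", "bw", "Wo", "bo")]
  model
}

#' Precompute the static per-drug inputs of a model
#'
#' The IDF-weighted concatenated pharmacological vector, the stacked
#' taxonomy channel matrix, and the token/feature id matrices of every
#' description sentence; none of these change during training.
#'
#' @param dataset a `kmr_dataset`.
#' @param model a [kmr_model()].
#' @return named list per drug with `pharm_x`, `class_X`, `sent_ids`.
#' @export
build_drug_inputs <- function(dataset, model) {
  word_vocab <- rownames(model$text_enc$params$word)
  tag_vocab <- rownames(model$text_enc$params$dep_tag)
  k <- ncol(model$channels[[1]])
  lapply(dataset$drugs, function(drug) {
    fam_vecs <- lapply(dataset$catalogs, function(cat) encode_family(drug, cat))
    fam_vecs$fingerprint <- encode_fingerprint(drug$fingerprint,
                                               dataset$fingerprint_length)
    sp <- concat_pharm(fam_vecs)
    class_X <- vapply(model$channels, function(ch) ch[drug$drug_id, ],
                      numeric(k))
    sent_ids <- lapply(drug$sentences, function(s) {
      token_ids(s, extract_dependency_features(s), word_vocab, tag_vocab)
    })
    # unit-normalize the IDF/fingerprint vector (standard IR practice) so
    # downstream activations start on a comparable scale across drugs
    x <- as_dense(sp)
    if (model$config$normalize_pharm) {
      nrm <- sqrt(sum(x * x))
      if (nrm > 0) x <- x / nrm
    }
    list(pharm_x = x, class_X = class_X, sent_ids = sent_ids,
         sparse = sp)
  })
}

# full forward pass for one drug; train toggles dropout.  text_out, when
# given, is a precomputed text block (from text_batch_forward) and the
# drug's own text pass is skipped.
drug_forward <- function(model, input, train = FALSE, text_out = NULL) {
  cfg <- model$config
  ab <- cfg$ablate
  if (ab == "pharmacology") {
    p_out <- numeric(cfg$reducer_dim); p_cache <- NULL
  } else if (cfg$pharm_reducer == "cnn") {
    pf <- pharm_forward(input$pharm_x, model$reducer)
    p_out <- pf$out; p_cache <- pf$cache
  } else {
    p_out <- baseline_reducers(input$sparse, cfg$pharm_reducer, cfg, cfg$seed)
    p_cache <- NULL
  }
  if (ab == "drug_class") {
    c_out <- numeric(cfg$class_dim); c_cache <- NULL
  } else {
    cf <- class_forward(input$class_X, model$class_enc)
    c_out <- cf$out; c_cache <- cf$cache
  }
  if (ab == "textual_description") {
    t_out <- numeric(cfg$text_dim); t_cache <- NULL
  } else if (!is.null(text_out)) {
    t_out <- text_out; t_cache <- "external"
  } else {
    tf <- text_drug_forward(model$text_enc, input$sent_ids, train = train)
    t_out <- tf$out; t_cache <- tf$cache
  }
  blocks <- list(pharm = p_out, class = c_out, text = t_out)
  # unit-RMS standardization so the three heterogeneous blocks enter
  # fusion on a comparable scale
  ncaches <- lapply(blocks, rms_norm_forward)
  blocks_n <- lapply(ncaches, `[[`, "out")
  fcaches <- list()
  outs <- list()
  for (nm in names(blocks_n)) {
    fb <- fusion_block_forward(blocks_n[[nm]], model$fusion[[nm]],
                               cfg$fusion_m, cfg$fusion_mode)
    fcaches[[nm]] <- fb$cache
    outs[[nm]] <- fb$out
  }
  list(fused = unlist(outs, use.names = FALSE), blocks = blocks,
       cache = list(pharm = p_cache, class = c_cache, text = t_cache,
                    fusion = fcaches, norm = ncaches,
                    block_out_lens = lengths(outs)))
}

drug_backward <- function(model, input, cache, dfused, grads) {
  drug_backward2(model, input, cache, dfused, grads)$grads
}

# as drug_backward, but when the text block was computed externally the
# text-block gradient is returned instead of propagated
drug_backward2 <- function(model, input, cache, dfused, grads) {
  lens <- cache$block_out_lens
  offs <- c(0, cumsum(lens))
  nms <- c("pharm", "class", "text")
  dtext <- NULL
  for (i in seq_along(nms)) {
    nm <- nms[i]
    dslice <- dfused[(offs[i] + 1L):offs[i + 1L]]
    fb <- fusion_block_backward(cache$fusion[[nm]], dslice)
    grads$fusion[[nm]]$W <- grads$fusion[[nm]]$W + fb$grads$W
    grads$fusion[[nm]]$w <- grads$fusion[[nm]]$w + fb$grads$w
    dblock <- rms_norm_backward(cache$norm[[nm]]$cache, fb$dblock)
    if (nm == "pharm" && !is.null(cache$pharm)) {
      pb <- pharm_backward(cache$pharm, dblock)
      grads$pharm <- add_grads(grads$pharm, pb$grads)
    } else if (nm == "class" && !is.null(cache$class)) {
      cb <- class_backward(cache$class, dblock)
      grads$class <- add_grads(grads$class, cb$grads)
    } else if (nm == "text" && !is.null(cache$text)) {
      if (identical(cache$text, "external")) {
        dtext <- dblock
      } else {
        tb <- text_drug_backward(model$text_enc, cache$text, dblock)
        grads$text <- add_grads(grads$text, tb$grads)
      }
    }
  }
  list(grads = grads, dtext = dtext)
}

#' Train the DDI classifier end-to-end
#'
#' Minimizes cross-entropy through the joint layer, fusion attention and
#' all three encoders with AdaGrad (learning rate, dropout, batch size and
#' epoch count from the config).  With symmetrization every pair
#' contributes both orderings to each batch.  Seeded and single-threaded:
#' the same seed reproduces the history and parameters exactly.
#'
#' @param dataset a `kmr_dataset`.
#' @param config a [kmr_config()].
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param train_pairs data.frame of labeled pairs (defaults to all pairs of
#'   the dataset with a DDI label).
#' @param channels optional precomputed [learn_class_channels()].
#' @param word_table optional pre-trained word embeddings.
#' @param verbose print per-epoch loss.
#' @return list with `model` (trained `kmr_model`), `history` (per-epoch
#'   mean training loss) and `inputs` (precomputed drug inputs).
#' @export
train_ddi <- function(dataset, config = kmr_config(), seed = config$seed,
                      train_pairs = NULL, channels = NULL, word_table = NULL,
                      verbose = FALSE) {
  set.seed(seed)
  if (is.null(train_pairs)) {
    train_pairs <- dataset$pairs[!is.na(dataset$pairs$ddi), , drop = FALSE]
  }
  if (!nrow(train_pairs)) stop("empty training set", call. = FALSE)
  if (is.null(channels)) {
    channels <- learn_class_channels(dataset$taxonomy, config, seed)
    set.seed(seed + 1L)
  }
  model <- kmr_model(dataset, config, channels, word_table)
  inputs <- build_drug_inputs(dataset, model)
  theta <- model_theta(model)
  acc <- zero_like(theta)
  n <- nrow(train_pairs)
  bs <- config$batch_size
  history <- numeric(config$epochs)
  orderings <- if (config$symmetrize) 2L else 1L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    n_seen <- 0L
    for (lo in seq(1L, n, by = bs)) {
      ix <- ord[lo:min(lo + bs - 1L, n)]
      batch <- train_pairs[ix, , drop = FALSE]
      ids <- unique(c(batch$drug_a, batch$drug_b))
      use_text <- config$ablate != "textual_description"
      tb <- NULL
      if (use_text) {
        tb <- text_batch_forward(model$text_enc,
                                 lapply(inputs[ids], `[[`, "sent_ids"),
                                 train = TRUE)
      }
      fwd <- lapply(seq_along(ids), function(k) {
        drug_forward(model, inputs[[ids[k]]], train = TRUE,
                     text_out = if (use_text) tb$out[, k] else NULL)
      })
      names(fwd) <- ids
      grads <- zero_like(theta)
      dfused <- lapply(fwd, function(f) numeric(length(f$fused)))
      if (orderings == 2L) {
        ainst <- c(batch$drug_a, batch$drug_b)
        binst <- c(batch$drug_b, batch$drug_a)
        tgt <- c(batch$ddi, batch$ddi)
      } else {
        ainst <- batch$drug_a
        binst <- batch$drug_b
        tgt <- batch$ddi
      }
      FA <- vapply(fwd[ainst], `[[`, numeric(model$fused_len), "fused")
      FB <- vapply(fwd[binst], `[[`, numeric(model$fused_len), "fused")
      Tm <- rbind(tgt == 1L, tgt == 0L) * 1
      hf <- head_forward_batch(FA, FB, model$head, train = TRUE)
      model$head$bn <- hf$head$bn
      model$head$bnp <- hf$head$bnp
      bloss <- -sum(Tm * log(pmax(hf$y, 1e-12))) / orderings
      dlogits <- (hf$y - Tm) / orderings
      hb <- head_backward_batch(hf$cache, dlogits)
      grads$head <- add_grads(grads$head, hb$grads)
      for (j in seq_along(ainst)) {
        dfused[[ainst[j]]] <- dfused[[ainst[j]]] + hb$dFA[, j]
        dfused[[binst[j]]] <- dfused[[binst[j]]] + hb$dFB[, j]
      }
      dtext_mat <- if (use_text) {
        matrix(0, config$text_dim, length(ids))
      } else NULL
      for (k in seq_along(ids)) {
        r <- drug_backward2(model, inputs[[ids[k]]], fwd[[ids[k]]]$cache,
                            dfused[[ids[k]]], grads)
        grads <- r$grads
        if (use_text && !is.null(r$dtext)) dtext_mat[, k] <- r$dtext
      }
      if (use_text) {
        tg <- text_batch_backward(model$text_enc, tb$cache, dtext_mat)
        grads$text <- add_grads(grads$text, tg$grads)
      }
      grads <- scale_grads(grads, 1 / nrow(batch))
      upd <- adagrad_update(theta, grads, acc, config$learning_rate)
      theta <- upd$theta
      acc <- upd$acc
      model <- model_set_theta(model, theta)
      ep_loss <- ep_loss + bloss
      n_seen <- n_seen + nrow(batch)
    }
    history[ep] <- ep_loss / n_seen
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
  }
  # re-estimate the joint layer's batch-norm statistics without dropout so
  # evaluation-mode features match the normalization (dropout inflates the
  # training-time variance the running averages would otherwise track)
  if (model$head$norm != "none") {
    ids <- unique(c(train_pairs$drug_a, train_pairs$drug_b))
    fus <- lapply(ids, function(id) drug_forward(model, inputs[[id]])$fused)
    names(fus) <- ids
    aa <- c(train_pairs$drug_a, train_pairs$drug_b)
    bb <- c(train_pairs$drug_b, train_pairs$drug_a)
    FM <- vapply(fus[c(aa, bb)], identity, numeric(model$fused_len))
    model$head$fc <- list(mean = rowMeans(FM))
    fus <- lapply(fus, function(f) f - model$head$fc$mean)
    SC <- model$head$segments * ncol(model$head$K)
    P <- matrix(0, SC, length(aa))
    for (j in seq_along(aa)) {
      P[, j] <- conv_pool_forward(cbind(fus[[aa[j]]], fus[[bb[j]]]),
                                  model$head$K, model$head$b,
                                  model$head$segments, model$head$kernel)$out
    }
    mup <- rowMeans(P)
    model$head$bnp <- list(mean = mup, var = mean((P - mup)^2))
    Pn <- (P - mup) / sqrt(model$head$bnp$var + 1e-8)
    Z <- model$head$W %*% Pn + model$head$bw
    mu <- rowMeans(Z)
    model$head$bn <- list(mean = mu, var = mean((Z - mu)^2))
  }
  list(model = model, history = history, inputs = inputs)
}

#' Fused drug embeddings from a model
#'
#' Evaluation-mode (no dropout) forward pass for every drug.
#'
#' @param model a (typically trained) [kmr_model()].
#' @param inputs output of [build_drug_inputs()].
#' @return numeric matrix, one row per drug.
#' @export
drug_embeddings <- function(model, inputs) {
  emb <- t(vapply(inputs, function(inp) drug_forward(model, inp)$fused,
                  numeric(model$fused_len)))
  rownames(emb) <- names(inputs)
  emb
}

#' Positive-class DDI probabilities for a table of pairs
#'
#' @param model a trained [kmr_model()].
#' @param inputs output of [build_drug_inputs()].
#' @param pairs data.frame with `drug_a`, `drug_b`.
#' @return numeric vector of P(interaction).
#' @export
predict_ddi <- function(model, inputs, pairs) {
  ids <- unique(c(pairs$drug_a, pairs$drug_b))
  fused <- lapply(ids, function(id) drug_forward(model, inputs[[id]])$fused)
  names(fused) <- ids
  vapply(seq_len(nrow(pairs)), function(r) {
    ddi_predict(fused[[pairs$drug_a[r]]], fused[[pairs$drug_b[r]]],
                model$head, model$config$symmetrize)[1]
  }, numeric(1))
}

#' Random-forest drug-drug similarity head
#'
#' Fits a random-forest regressor on the joined pair representations
#' (concatenation of the two fused embeddings; with symmetrization both
#' orderings are used in training and predictions average the orderings)
#' and predicts held-out similarities.  Trees predict means of training
#' targets, so predictions never leave the training-target range.
#'
#' @param train_pairs data.frame with `drug_a`, `drug_b`, `similarity`
#'   in \[0,1\].
#' @param test_pairs data.frame with `drug_a`, `drug_b`.
#' @param embeddings fused embedding matrix ([drug_embeddings()]).
#' @param config a [kmr_config()] (forest size/depth, symmetrization).
#' @param seed forest seed.
#' @return numeric vector of predicted similarities for `test_pairs`.
#' @export
dds_fit_predict <- function(train_pairs, test_pairs, embeddings,
                            config = kmr_config(), seed = config$seed) {
  train_pairs <- train_pairs[!is.na(train_pairs$similarity), , drop = FALSE]
  if (!nrow(train_pairs)) stop("no training pairs with similarity labels", call. = FALSE)
  if (any(train_pairs$similarity < 0 | train_pairs$similarity > 1)) {
    stop("training similarities must lie in [0,1]", call. = FALSE)
  }
  pair_x <- function(pairs) {
    cbind(embeddings[pairs$drug_a, , drop = FALSE],
          embeddings[pairs$drug_b, , drop = FALSE])
  }
  if (nrow(train_pairs) == 1L) {
    # a forest grown on a single example has one leaf: its target
    return(rep(train_pairs$similarity[1], nrow(test_pairs)))
  }
  x <- pair_x(train_pairs)
  y <- train_pairs$similarity
  if (config$symmetrize) {
    x <- rbind(x, pair_x(data.frame(drug_a = train_pairs$drug_b,
                                    drug_b = train_pairs$drug_a)))
    y <- c(y, y)
  }
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  rf <- ranger::ranger(
    x = x, y = y, num.trees = config$rf_trees,
    max.depth = if (config$rf_max_depth > 0L) config$rf_max_depth else NULL,
    seed = seed, num.threads = 1L)
  xt <- pair_x(test_pairs)
  colnames(xt) <- colnames(x)
  pred <- stats::predict(rf, data = xt, num.threads = 1L)$predictions
  if (config$symmetrize) {
    xr <- pair_x(data.frame(drug_a = test_pairs$drug_b,
                            drug_b = test_pairs$drug_a))
    colnames(xr) <- colnames(x)
    pred <- (pred + stats::predict(rf, data = xr, num.threads = 1L)$predictions) / 2
  }
  pred
}
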