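test_that("attend_block composes tanh projection, softmax and pooling exactly", {
  # m = 1: softmax of a singleton, v_c is the single column
  H1 <- matrix(c(0.3, -0.2), 2, 1)
  W <- diag(2); w <- c(1, 1)
  r1 <- attend_block(H1, W, w)
  expect_equal(r1$alpha, 1)
  expect_equal(r1$v_c, H1[, 1])

  # worked case: H = I2, W = I, w = (1,1)
  r2 <- attend_block(diag(2), diag(2), c(1, 1))
  expect_equal(r2$alpha, c(0.5, 0.5))
  expect_equal(r2$v_c, c(0.5, 0.5))
  expect_equal(r2$M, tanh(diag(2)))

  expect_error(attend_block(matrix(0, 2, 0), W, w), "m >= 1")
})

test_that("attend_block matches a loop-based oracle on 50 random instances", {
  set.seed(14)
  for (rep in 1:50) {
    dl <- sample(2:8, 1); m <- sample(1:6, 1)
    H <- matrix(rnorm(dl * m), dl, m)
    W <- matrix(rnorm(dl * dl), dl, dl)
    w <- rnorm(dl)
    got <- attend_block(H, W, w)
    want <- oracle_attend(H, W, w)
    expect_equal(got$v_c, want$v, tolerance = 1e-10)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-10)
    expect_equal(sum(got$alpha), 1, tolerance = 1e-12)
    # v_c is a convex combination of H's columns
    expect_true(all(got$v_c >= apply(H, 1, min) - 1e-12))
    expect_true(all(got$v_c <= apply(H, 1, max) + 1e-12))
  }
})

mk_fusion_params <- function(lens, m = 4L, seed = 15L) {
  set.seed(seed)
  lapply(lens, function(l) {
    dl <- l %/% m
    list(W = matrix(rnorm(dl * dl, sd = 0.1), dl, dl), w = rnorm(dl, sd = 0.1))
  })
}

test_that("fuse preserves block lengths and locality in reweight mode", {
  lens <- c(pharm = 500L, class = 128L, text = 128L)
  params <- mk_fusion_params(lens)
  blocks <- lapply(lens, function(l) rnorm(l))
  r <- fuse(blocks$pharm, blocks$class, blocks$text, params)
  expect_length(r$fused, 756L)
  expect_equal(vapply(r$alpha, sum, numeric(1)),
               c(pharm = 1, class = 1, text = 1), tolerance = 1e-12)

  # zero blocks fuse to zero
  r0 <- fuse(numeric(500), numeric(128), numeric(128), params)
  expect_equal(r0$fused, numeric(756))

  # zeroing one block changes only its slice
  r_abl <- fuse(numeric(500), blocks$class, blocks$text, params)
  expect_equal(r_abl$fused[501:756], r$fused[501:756])
  expect_equal(r_abl$fused[1:500], numeric(500))

  # pool mode emits the attention-pooled columns
  rp <- fuse(blocks$pharm, blocks$class, blocks$text, params, mode = "pool")
  expect_length(rp$fused, 756L %/% 4L)
  expect_error(fuse(numeric(10), numeric(128), numeric(128), params), "divisible")
})

mk_head <- function(fused_len = 32L, seed = 16L) {
  cfg <- tiny_config()
  set.seed(seed)
  kmr:::new_ddi_head(fused_len, cfg)
}

test_that("ddi_predict is a proper symmetric probability", {
  head <- mk_head()
  a <- rnorm(32); b <- rnorm(32)
  y <- ddi_predict(a, b, head)
  expect_length(y, 2L)
  expect_true(all(y >= 0))
  expect_equal(sum(y), 1, tolerance = 1e-12)
  expect_identical(y, ddi_predict(b, a, head))

  # all-zero weights: softmax of zeros
  h0 <- head
  for (f in c("K", "b", "W", "bw", "Wo", "bo")) h0[[f]][] <- 0
  expect_equal(ddi_predict(a, b, h0), c(0.5, 0.5))

  # pre-softmax logits (ln 3, ln 1) give (0.75, 0.25)
  h1 <- h0
  h1$bo <- c(log(3), 0)
  expect_equal(ddi_predict(a, b, h1), c(0.75, 0.25), tolerance = 1e-12)
})

test_that("DDI training decreases the loss, respects lr = 0 and reproduces by seed", {
  ds <- fixture_dataset()
  cfg <- tiny_config(epochs = 5L, batch_size = 4L)
  pairs <- ds$pairs[!is.na(ds$pairs$ddi), ]
  fit <- train_ddi(ds, cfg, seed = 21L, train_pairs = pairs)
  expect_length(fit$history, 5L)
  expect_lt(fit$history[5], fit$history[1])

  cfg0 <- tiny_config(epochs = 1L, learning_rate = 0)
  fit0 <- train_ddi(ds, cfg0, seed = 21L, train_pairs = pairs)
  set.seed(21L)
  channels <- learn_class_channels(ds$taxonomy, cfg0, 21L)
  set.seed(22L)
  virgin <- kmr_model(ds, cfg0, channels)
  expect_equal(kmr:::flatten_theta(kmr:::model_theta(fit0$model)),
               kmr:::flatten_theta(kmr:::model_theta(virgin)))

  fit2 <- train_ddi(ds, cfg, seed = 21L, train_pairs = pairs)
  expect_identical(fit$history, fit2$history)
  expect_identical(kmr:::flatten_theta(kmr:::model_theta(fit$model)),
                   kmr:::flatten_theta(kmr:::model_theta(fit2$model)))

  expect_error(train_ddi(ds, cfg, train_pairs = pairs[0, ]), "empty")
})

test_that("end-to-end analytic gradients match numeric differentiation", {
  ds <- fixture_dataset()
  cfg <- tiny_config()
  set.seed(23)
  channels <- learn_class_channels(ds$taxonomy, cfg, 23L)
  set.seed(24)
  model <- kmr_model(ds, cfg, channels)
  inputs <- build_drug_inputs(ds, model)
  pairs <- ds$pairs[1:6, ]

  loss_and_grad <- function(model, want_grad = FALSE) {
    theta <- kmr:::model_theta(model)
    grads <- if (want_grad) kmr:::zero_like(theta) else NULL
    ids <- unique(c(pairs$drug_a, pairs$drug_b))
    fwd <- lapply(ids, function(id) kmr:::drug_forward(model, inputs[[id]]))
    names(fwd) <- ids
    FA <- vapply(fwd[pairs$drug_a], `[[`, numeric(model$fused_len), "fused")
    FB <- vapply(fwd[pairs$drug_b], `[[`, numeric(model$fused_len), "fused")
    Tm <- rbind(pairs$ddi == 1L, pairs$ddi == 0L) * 1
    hf <- kmr:::head_forward_batch(FA, FB, model$head, train = TRUE)
    loss <- -sum(Tm * log(pmax(hf$y, 1e-12))) / nrow(pairs)
    if (!want_grad) return(loss)
    dlogits <- (hf$y - Tm)
    hb <- kmr:::head_backward_batch(hf$cache, dlogits)
    grads$head <- kmr:::add_grads(grads$head, hb$grads)
    dfused <- lapply(fwd, function(f) numeric(length(f$fused)))
    for (j in seq_len(nrow(pairs))) {
      dfused[[pairs$drug_a[j]]] <- dfused[[pairs$drug_a[j]]] + hb$dFA[, j]
      dfused[[pairs$drug_b[j]]] <- dfused[[pairs$drug_b[j]]] + hb$dFB[, j]
    }
    for (id in ids) {
      grads <- kmr:::drug_backward(model, inputs[[id]], fwd[[id]]$cache,
                                   dfused[[id]], grads)
    }
    kmr:::scale_grads(grads, 1 / nrow(pairs))
  }

  g <- loss_and_grad(model, want_grad = TRUE)
  gv <- kmr:::flatten_theta(g)
  th <- kmr:::model_theta(model)
  tv <- kmr:::flatten_theta(th)
  set.seed(25)
  probe <- sort(sample(length(tv), 80))
  eps <- 1e-5
  num <- vapply(probe, function(i) {
    tp <- tv; tp[i] <- tv[i] + eps
    lp <- loss_and_grad(kmr:::model_set_theta(model, kmr:::unflatten_theta(th, tp)))
    tm <- tv; tm[i] <- tv[i] - eps
    lm <- loss_and_grad(kmr:::model_set_theta(model, kmr:::unflatten_theta(th, tm)))
    (lp - lm) / (2 * eps)
  }, numeric(1))
  ana <- gv[probe]
  denom <- abs(num) + abs(ana)
  big <- denom > 1e-6
  expect_lt(max(abs(num[big] - ana[big]) / denom[big]), 1e-3)
  expect_lt(max(abs(num[!big] - ana[!big])), 1e-8)
})

test_that("the forest similarity head respects its regression contracts", {
  ds <- fixture_dataset()
  cfg <- tiny_config()
  set.seed(26)
  emb <- matrix(rnorm(length(ds$drugs) * 16), length(ds$drugs), 16,
                dimnames = list(names(ds$drugs), NULL))
  pairs <- ds$pairs[!is.na(ds$pairs$similarity), ]

  # a single training pair predicts its own target everywhere
  p1 <- dds_fit_predict(pairs[1, ], pairs[2:4, ], emb, cfg, seed = 1L)
  expect_equal(p1, rep(pairs$similarity[1], 3))

  # constant training targets give constant predictions
  pc <- pairs[1:6, ]
  pc$similarity <- 0.4
  expect_equal(dds_fit_predict(pc, pairs[7:10, ], emb, cfg, seed = 1L),
               rep(0.4, 4))

  # predictions never leave the training-target range
  tr <- pairs[1:8, ]; te <- pairs[9:12, ]
  pred <- dds_fit_predict(tr, te, emb, cfg, seed = 2L)
  expect_true(all(pred >= min(tr$similarity) - 1e-12))
  expect_true(all(pred <= max(tr$similarity) + 1e-12))

  # seeded determinism
  expect_identical(pred, dds_fit_predict(tr, te, emb, cfg, seed = 2L))
  expect_error(dds_fit_predict(pairs[0, ], te, emb, cfg), "no training pairs")
})
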