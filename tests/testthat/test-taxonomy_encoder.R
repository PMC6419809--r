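path_graph <- function() {
  data.frame(parent = c("a", "b"), child = c("b", "c"),
             is_drug = FALSE, stringsAsFactors = FALSE)
}

clique_pair_graph <- function(k = 10L) {
  cl <- function(tag) {
    nodes <- paste0(tag, seq_len(k))
    do.call(rbind, lapply(seq_len(k - 1L), function(i) {
      data.frame(parent = nodes[i], child = nodes[(i + 1L):k],
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(cl("x"), cl("y"))
}

test_that("node2vec transitions implement the 1/p, 1, 1/q rule", {
  # triangle-ish graph: b's neighbors are a, c (adjacent to a), d (not)
  g <- data.frame(parent = c("a", "b", "b", "a"),
                  child = c("b", "c", "d", "c"), stringsAsFactors = FALSE)
  pr <- node2vec_transition(g, prev = "a", cur = "b", p = 2, q = 0.5)
  expect_equal(pr[c("a", "c", "d")],
               c(a = 0.142857, c = 0.285714, d = 0.571429),
               tolerance = 1e-5)
  # first step (no previous node) is uniform
  pr0 <- node2vec_transition(g, prev = NA, cur = "b", p = 2, q = 0.5)
  expect_equal(unname(pr0), rep(1 / 3, 3))
})

test_that("walker transitions match brute-force enumeration on random trees", {
  set.seed(21)
  for (rep in 1:5) {
    nodes <- sprintf("n%02d", 1:20)
    edges <- random_tree_edges(nodes)[, c("parent", "child")]
    adj <- list()
    for (i in seq_len(nrow(edges))) {
      adj[[edges$parent[i]]] <- c(adj[[edges$parent[i]]], edges$child[i])
      adj[[edges$child[i]]] <- c(adj[[edges$child[i]]], edges$parent[i])
    }
    p <- runif(1, 0.3, 3); q <- runif(1, 0.3, 3)
    for (cur in nodes) {
      for (prev in adj[[cur]]) {
        got <- node2vec_transition(edges, prev, cur, p, q)
        want <- oracle_n2v(adj, prev, cur, p, q)
        expect_equal(got[sort(names(got))], want[sort(names(want))],
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("empirical next-node frequencies match the analytic transitions", {
  corpus <- generate_walks(path_graph(), walks_per_node = 10000L,
                           walk_length = 2L, p = 1, q = 1, seed = 99L)
  from_b <- Filter(function(w) w[1] == "b" && length(w) >= 2, corpus$walks)
  expect_length(from_b, 10000L)
  freq_a <- mean(vapply(from_b, `[[`, character(1), 2L) == "a")
  expect_lt(abs(freq_a - 0.5), 0.02)

  # star graph: from a leaf the only move is the hub
  star <- data.frame(parent = "hub", child = paste0("leaf", 1:5),
                     stringsAsFactors = FALSE)
  ws <- generate_walks(star, walks_per_node = 20L, walk_length = 3L,
                       p = 2, q = 0.5, seed = 1L)
  leaf_starts <- Filter(function(w) startsWith(w[1], "leaf"), ws$walks)
  expect_true(all(vapply(leaf_starts, `[[`, character(1), 2L) == "hub"))
})

test_that("walks only traverse edges and isolated nodes yield length-1 walks", {
  ds <- small_dataset()
  corpus <- generate_walks(ds$taxonomy, walks_per_node = 2L, walk_length = 10L,
                           p = 1, q = 0.5, seed = 3L)
  adj <- new.env()
  e <- ds$taxonomy$edges
  for (i in seq_len(nrow(e))) {
    assign(paste(e$parent[i], e$child[i]), TRUE, envir = adj)
    assign(paste(e$child[i], e$parent[i]), TRUE, envir = adj)
  }
  for (w in corpus$walks) {
    expect_lte(length(w), 10L)
    if (length(w) > 1L) {
      for (i in seq_len(length(w) - 1L)) {
        expect_true(exists(paste(w[i], w[i + 1L]), envir = adj))
      }
    }
  }
})

test_that("skip-gram embeddings separate disconnected cliques", {
  g <- clique_pair_graph(10L)
  seps <- vapply(1:5, function(seed) {
    corpus <- generate_walks(g, walks_per_node = 5L, walk_length = 15L,
                             p = 1, q = 1, seed = seed)
    emb <- train_skipgram(corpus, dim = 8L, window = 3L, negatives = 5L,
                          epochs = 3L, seed = seed)
    x <- emb[startsWith(rownames(emb), "x"), ]
    y <- emb[startsWith(rownames(emb), "y"), ]
    cs <- function(a, b) {
      an <- a / sqrt(rowSums(a^2)); bn <- b / sqrt(rowSums(b^2))
      m <- an %*% t(bn)
      mean(m)
    }
    within <- (cs(x, x) + cs(y, y)) / 2
    within - cs(x, y)
  }, numeric(1))
  expect_gt(mean(seps), 0)

  corpus <- generate_walks(g, walks_per_node = 3L, walk_length = 10L, seed = 7L)
  e1 <- train_skipgram(corpus, dim = 8L, window = 3L, epochs = 2L, seed = 5L)
  e2 <- train_skipgram(corpus, dim = 8L, window = 3L, epochs = 2L, seed = 5L)
  expect_identical(e1, e2)
  expect_error(train_skipgram(corpus, dim = 8L, window = 0L), "window")
  expect_error(train_skipgram(corpus, dim = 0L), "dim")
})

test_that("LINE embeddings attract connected nodes and separate cliques", {
  single <- data.frame(parent = "u", child = "v", stringsAsFactors = FALSE)
  emb <- train_line(single, dim = 8L, order = 1L, epochs = 50L, seed = 2L)
  expect_gt(sum(emb["u", ] * emb["v", ]), 0)

  g <- clique_pair_graph(10L)
  emb2 <- train_line(g, dim = 8L, order = 2L, epochs = 30L, seed = 3L)
  x <- emb2[startsWith(rownames(emb2), "x"), ]
  y <- emb2[startsWith(rownames(emb2), "y"), ]
  nrm <- function(m) m / sqrt(rowSums(m^2))
  within <- (mean(nrm(x) %*% t(nrm(x))) + mean(nrm(y) %*% t(nrm(y)))) / 2
  cross <- mean(nrm(x) %*% t(nrm(y)))
  expect_gt(within, cross)

  e1 <- train_line(g, dim = 4L, order = 2L, epochs = 5L, seed = 11L)
  e2 <- train_line(g, dim = 4L, order = 2L, epochs = 5L, seed = 11L)
  expect_identical(e1, e2)
})

test_that("channel fusion has the contracted shape and is input-deterministic", {
  ds <- small_dataset()
  cfg <- tiny_config()
  set.seed(4)
  channels <- learn_class_channels(ds$taxonomy, cfg, seed = 4L)
  set.seed(5)
  enc <- new_class_encoder(cfg)
  ids <- names(ds$drugs)[1:6]
  out <- fuse_channels(channels, ids, enc)
  expect_equal(dim(out), c(6L, cfg$class_dim))

  # order of drugs does not change each drug's block
  out_rev <- fuse_channels(channels, rev(ids), enc)
  expect_equal(out_rev[ids[1], ], out[ids[1], ])

  # two drugs attached to the same leaf get identical blocks when drugs
  # inherit the leaf embedding
  cfg_leaf <- tiny_config(drug_class_source = "leaf")
  ch_leaf <- learn_class_channels(ds$taxonomy, cfg_leaf, seed = 4L)
  leaf_of <- ds$taxonomy$attach
  mates <- names(leaf_of)[leaf_of == leaf_of[[ids[1]]]]
  out_leaf <- fuse_channels(ch_leaf, mates, enc)
  expect_equal(out_leaf[mates[1], ], out_leaf[mates[2], ])

  # zero channels and zero biases give a zero block
  zero_ch <- lapply(channels, function(m) m * 0)
  enc0 <- enc
  for (i in seq_along(enc0$params$conv)) enc0$params$conv[[i]]$b[] <- 0
  enc0$params$bw[] <- 0
  expect_equal(fuse_channels(zero_ch, ids[1], enc0)[1, ],
               numeric(cfg$class_dim))

  # missing drug names the offending channel
  ch_bad <- channels
  ch_bad$line <- ch_bad$line[rownames(ch_bad$line) != ids[1], ]
  expect_error(fuse_channels(ch_bad, ids, enc), "line")
})

test_that("every channel recovers planted cluster membership by nearest neighbors", {
  ds <- small_dataset()  # 4 planted clusters
  cfg <- tiny_config(class_embed_dim = 16L, walks_per_node = 5L,
                     walk_length = 20L, sg_epochs = 3L)
  truth <- stats::setNames(ds$latent$cluster, ds$latent$drug_id)
  accs <- sapply(1:5, function(seed) {
    channels <- learn_class_channels(ds$taxonomy, cfg, seed = seed)
    vapply(channels, function(emb) {
      m <- emb[names(truth), ]
      d2 <- as.matrix(stats::dist(m))
      diag(d2) <- Inf
      nn <- apply(d2, 1L, which.min)
      mean(truth[rownames(m)[nn]] == truth)
    }, numeric(1))
  })
  expect_gte(mean(accs["deepwalk", ]), 0.8)
  expect_gte(mean(accs["node2vec", ]), 0.8)
  expect_gte(mean(accs["line", ]), 0.8)
})
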