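mk_sentence <- function() {
  parsed_sentence(c("A", "inhibits", "B"), c(2L, 0L, 2L),
                  c("nsubj", "root", "obj"),
                  entity1 = c(1L, 1L), entity2 = c(3L, 3L))
}

test_that("dependency features follow the category rules on the worked case", {
  f <- extract_dependency_features(mk_sentence())
  expect_equal(f$relative_root, c("child_of_root", "root_itself", "child_of_root"))
  expect_equal(f$relative_e1, c("entity_itself", "parent_of_entity", "other"))
  expect_equal(f$relative_e2, c("other", "parent_of_entity", "entity_itself"))

  # degenerate one-token sentence that is both root and entity1
  s1 <- parsed_sentence("X", 0L, "root", entity1 = c(1L, 1L))
  f1 <- extract_dependency_features(s1)
  expect_equal(f1$relative_root, "root_itself")
  expect_equal(f1$relative_e1, "entity_itself")
  expect_equal(f1$relative_e2, "other")

  # a token related to neither root nor entities is "other" everywhere
  s3 <- parsed_sentence(c("r", "m", "x"), c(0L, 1L, 2L), c("root", "d", "d"))
  f3 <- extract_dependency_features(s3)
  expect_equal(f3$relative_root[3], "other")
  expect_equal(f3$relative_e1[3], "other")
  expect_equal(f3$relative_e2[3], "other")
})

test_that("dependency features agree with a brute-force traversal on random trees", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(1:20, 1)
    heads <- random_heads(n)
    span1 <- if (n >= 2) sort(sample.int(n, 2)) else c(1L, 1L)
    span2 <- if (runif(1) < 0.3) NULL else {
      a <- sample.int(n, 1); c(a, a)
    }
    s <- parsed_sentence(paste0("w", seq_len(n)), heads, rep("dep", n),
                         entity1 = span1, entity2 = span2)
    got <- extract_dependency_features(s)
    want <- oracle_dep_features(s$tokens, heads, span1, span2)
    expect_equal(got$relative_root, want$relative_root)
    expect_equal(got$relative_e1, want$relative_e1)
    expect_equal(got$relative_e2, want$relative_e2)
  }
})

test_that("token embeddings concatenate the word part before the dependency part", {
  cfg <- tiny_config()
  enc <- new_text_encoder(c("A", "inhibits", "B"), c("nsubj", "root", "obj"), cfg)
  s <- mk_sentence()
  f <- extract_dependency_features(s)
  tables <- enc$params[c("word", "rel_root", "rel_e1", "rel_e2", "dep_tag")]
  E <- embed_tokens(s, f, tables)
  expect_equal(dim(E), c(cfg$word_dim + 4L * cfg$dep_dim, 3L))
  expect_equal(E[seq_len(cfg$word_dim), 1], unname(tables$word["A", ]))
  expect_equal(E[cfg$word_dim + seq_len(cfg$dep_dim), 2],
               unname(tables$rel_root["root_itself", ]))

  # all-zero tables embed to zero; identical tokens embed identically
  z <- lapply(tables, function(m) m * 0)
  expect_equal(embed_tokens(s, f, z), matrix(0, nrow(E), 3L),
               ignore_attr = TRUE)
  s2 <- parsed_sentence(c("B", "B"), c(0L, 1L), c("root", "obj"))
  E2 <- embed_tokens(s2, extract_dependency_features(s2), tables)
  expect_equal(E2[seq_len(cfg$word_dim), 1], E2[seq_len(cfg$word_dim), 2])

  # out-of-vocabulary words share the UNK row
  s3 <- parsed_sentence(c("qq", "zz"), c(0L, 1L), c("root", "obj"))
  E3 <- embed_tokens(s3, extract_dependency_features(s3), tables)
  expect_equal(E3[seq_len(cfg$word_dim), 1], unname(tables$word["<UNK>", ]))
})

test_that("sentence encoding sums directional outputs and pools by attention", {
  cfg <- tiny_config()
  set.seed(8)
  enc <- new_text_encoder(letters, c("root", "dep"), cfg)
  E <- matrix(rnorm(enc$input_dim * 4), enc$input_dim, 4)
  r <- encode_sentence(E, enc)
  expect_equal(r$hw, r$hf + r$hb)
  expect_equal(ncol(r$hw), 4L)
  expect_true(all(r$word_weights >= 0))
  expect_equal(sum(r$word_weights), 1, tolerance = 1e-12)
  expect_true(all(is.finite(r$sentence_vector)))

  # single token: attention collapses to weight 1 and the vector is hw_1
  r1 <- encode_sentence(E[, 1, drop = FALSE], enc)
  expect_equal(r1$word_weights, 1)
  expect_equal(r1$sentence_vector, as.vector(r1$hw))
  expect_error(encode_sentence(E[, 0, drop = FALSE], enc), "empty")
})

test_that("with tied directional weights, reversing the input reverses hw", {
  cfg <- tiny_config()
  set.seed(9)
  enc <- new_text_encoder(letters, "dep", cfg)
  enc$params$lstm_b <- enc$params$lstm_f
  E <- matrix(rnorm(enc$input_dim * 5), enc$input_dim, 5)
  fwd <- encode_sentence(E, enc)
  rev_ <- encode_sentence(E[, 5:1], enc)
  expect_equal(rev_$hw, fwd$hw[, 5:1], tolerance = 1e-12)
})

test_that("bag attention is the softmax of the sentence scores", {
  cfg <- tiny_config(attention_score = "dot")
  set.seed(10)
  enc <- new_text_encoder(letters, "dep", cfg)
  h <- cfg$hidden_size

  # equal scores: uniform weights over n = 4 sentences
  enc0 <- enc
  enc0$params$bag$q[] <- 0
  S <- matrix(rnorm(h * 4), h, 4)
  b0 <- encode_bag(S, enc0)
  expect_equal(b0$weights, rep(0.25, 4))

  # e = (ln 2, ln 1) -> a = (2/3, 1/3)
  enc1 <- enc
  enc1$params$bag$q <- c(1, numeric(h - 1))
  S2 <- matrix(0, h, 2)
  S2[1, ] <- c(log(2), 0)
  b1 <- encode_bag(S2, enc1)
  expect_equal(b1$scores, c(log(2), 0))
  expect_equal(b1$weights, c(2 / 3, 1 / 3), tolerance = 1e-12)

  # one sentence: the bag vector is that sentence's projected vector
  S3 <- matrix(rnorm(h), h, 1)
  b3 <- encode_bag(S3, enc)
  expect_equal(b3$weights, 1)
  expect_equal(b3$out,
               as.vector(enc$params$W %*% S3[, 1] + enc$params$bw))

  # weights always normalized on random bags (bilinear scorer too)
  encb <- new_text_encoder(letters, "dep", tiny_config())
  for (n in c(2, 5, 9)) {
    b <- encode_bag(matrix(rnorm(h * n), h, n), encb)
    expect_true(all(b$weights >= 0))
    expect_equal(sum(b$weights), 1, tolerance = 1e-12)
  }
})

test_that("dropout perturbs only training-mode forward passes", {
  ds <- fixture_dataset()
  cfg <- tiny_config(dropout = 0.5)
  set.seed(12)
  channels <- learn_class_channels(ds$taxonomy, cfg, seed = 2L)
  set.seed(13)
  model <- kmr_model(ds, cfg, channels)
  inputs <- build_drug_inputs(ds, model)
  enc <- model$text_enc
  sids <- inputs[[1]]$sent_ids

  e1 <- kmr:::text_drug_forward(enc, sids, train = FALSE)$out
  e2 <- kmr:::text_drug_forward(enc, sids, train = FALSE)$out
  expect_identical(e1, e2)

  set.seed(100)
  t1 <- kmr:::text_drug_forward(enc, sids, train = TRUE)$out
  set.seed(101)
  t2 <- kmr:::text_drug_forward(enc, sids, train = TRUE)$out
  expect_false(identical(t1, t2))
})
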