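test_that("IDF weights follow log((N+1)/(DF+1)) with natural log", {
  expect_equal(compute_idf(9, 9), 0)
  expect_equal(compute_idf(0, 9), log(10), tolerance = 1e-12)   # 2.302585...
  expect_equal(compute_idf(4, 99), log(20), tolerance = 1e-12)  # 2.995732...
  expect_error(compute_idf(10, 9), "df")
  expect_error(compute_idf(0, 0), "n_drugs")
})

test_that("IDF is strictly decreasing in df and zero only at df = n", {
  for (n in c(3, 17, 250)) {
    v <- compute_idf(0:n, n)
    expect_true(all(diff(v) < 0))
    expect_equal(which(v == 0), n + 1L)
  }
})

test_that("encode_family places IDF weights at catalog positions", {
  cat3 <- attribute_catalog("side_effect", c("a", "b", "c"),
                            c(2L, 4L, 7L), 10L)
  d <- drug_record("d1", attributes = list(side_effect = "b"))
  v <- encode_family(d, cat3)
  expect_equal(as_dense(v), c(0, log(11 / 5), 0), tolerance = 1e-10)

  # no attributes in the family -> all-zero vector of catalog length
  d0 <- drug_record("d0")
  expect_equal(as_dense(encode_family(d0, cat3)), c(0, 0, 0))

  # attribute shared by every drug gets weight zero
  catall <- attribute_catalog("side_effect", "x", 10L, 10L)
  dall <- drug_record("d2", attributes = list(side_effect = "x"))
  expect_equal(as_dense(encode_family(dall, catall)), 0)

  # unknown attributes are ignored
  dunk <- drug_record("d3", attributes = list(side_effect = c("b", "zzz")))
  expect_equal(as_dense(encode_family(dunk, cat3))[2], log(11 / 5))
})

test_that("encode_family equals a brute-force loop on random instances", {
  set.seed(5)
  for (rep in 1:20) {
    n_items <- sample(3:40, 1)
    n_drugs <- sample(2:30, 1)
    items <- sprintf("it%02d", seq_len(n_items))
    df <- sample(0:n_drugs, n_items, replace = TRUE)
    cat_r <- attribute_catalog("target", items, df, n_drugs)
    have <- sample(items, sample.int(n_items, 1))
    d <- drug_record("dx", attributes = list(target = have))
    got <- as_dense(encode_family(d, cat_r))
    want <- numeric(n_items)
    for (k in seq_len(n_items)) {
      if (items[k] %in% have) want[k] <- log((n_drugs + 1) / (df[k] + 1))
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("fingerprints encode as binary vectors with range checking", {
  expect_equal(as_dense(encode_fingerprint(c(0L, 5L), 8L)),
               c(1, 0, 0, 0, 0, 1, 0, 0))
  expect_equal(as_dense(encode_fingerprint(integer(), 8L)), numeric(8))
  expect_error(encode_fingerprint(8L, 8L), "range")

  # random bit sets round-trip through the fingerprint file format
  set.seed(11)
  fps <- lapply(1:10, function(i) sort(sample(0:165, sample.int(30, 1))))
  names(fps) <- sprintf("D%02d", 1:10)
  f <- withr::local_tempfile()
  write_fingerprints(fps, f)
  fps2 <- read_fingerprints(f, 166L)
  expect_equal(fps2, fps)
})

test_that("concat_pharm lays families out at cumulative offsets", {
  lens <- c(side_effect = 4876L, drug_action = 626L,
            physiological_effect = 1866L, formulation = 867L,
            target = 3880L, fingerprint = 166L)
  vecs <- lapply(lens, function(l) sparse_feature_vector(l))
  out <- concat_pharm(vecs)
  expect_equal(out$length, 12281L)
  offs <- attr(out, "offsets")
  expect_equal(unname(offs), c(0L, cumsum(unname(lens)))[1:6])

  # an entry at position p of family k lands at offset(k) + p
  vecs$formulation <- sparse_feature_vector(867L, 13L, 2.5)
  out2 <- concat_pharm(vecs)
  expect_equal(out2$positions, offs[["formulation"]] + 13L)
  expect_equal(out2$values, 2.5)

  expect_error(concat_pharm(vecs[-2]), "drug_action")
})

test_that("the convolutional reducer has the contracted shape and determinism", {
  cfg <- kmr_config()
  set.seed(1)
  red <- new_pharm_reducer(600L, cfg)
  x <- sparse_feature_vector(600L, c(5L, 100L, 401L), c(2, 1, 3))
  out <- reduce_pharm(x, red)
  expect_length(out, 500L)

  set.seed(1)
  red_again <- new_pharm_reducer(600L, cfg)
  expect_identical(reduce_pharm(x, red_again), out)

  # zero input with zero biases gives exactly zero output
  red0 <- red
  red0$params$b[] <- 0
  red0$params$bw[] <- 0
  expect_equal(reduce_pharm(sparse_feature_vector(600L), red0),
               numeric(500L))

  # inputs shorter than the kernel are padded, not an error
  expect_message(out_small <- reduce_pharm(sparse_feature_vector(3L, 1L, 1), red0),
                 "padding")
  expect_length(out_small, 500L)
})

test_that("reducer analytic gradients match numeric differentiation", {
  cfg <- tiny_config()
  set.seed(3)
  red <- new_pharm_reducer(20L, cfg)
  x <- rnorm(20)
  dir <- rnorm(cfg$reducer_dim)
  loss <- function(params) {
    r <- red
    r$params <- params
    sum(kmr:::pharm_forward(x, r)$out * dir)
  }
  fwd <- kmr:::pharm_forward(x, red)
  g <- kmr:::pharm_backward(fwd$cache, dir)$grads
  gv <- kmr:::flatten_theta(g)
  tv <- kmr:::flatten_theta(red$params)
  eps <- 1e-6
  num <- vapply(seq_along(tv), function(i) {
    tp <- tv; tp[i] <- tv[i] + eps
    tm <- tv; tm[i] <- tv[i] - eps
    (loss(kmr:::unflatten_theta(red$params, tp)) -
       loss(kmr:::unflatten_theta(red$params, tm))) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - gv) / pmax(abs(num) + abs(gv), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("baseline reducers have their documented shapes", {
  cfg <- kmr_config()
  lens <- c(side_effect = 30L, drug_action = 20L, physiological_effect = 25L,
            formulation = 15L, target = 40L, fingerprint = 16L)
  vecs <- lapply(lens, function(l) sparse_feature_vector(l, 1L, 1))
  x <- concat_pharm(vecs)
  expect_equal(baseline_reducers(x, "concatenation"), as_dense(x))
  expect_length(baseline_reducers(x, "fully_conn", cfg, seed = 2), 500L)
  expect_length(baseline_reducers(x, "trans_mat", cfg, seed = 2), 600L)
  expect_error(baseline_reducers(x, "nope"), "unknown")
  # seeded: repeated calls agree
  expect_identical(baseline_reducers(x, "trans_mat", cfg, seed = 2),
                   baseline_reducers(x, "trans_mat", cfg, seed = 2))
})
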