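dir_digest <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  vapply(files, function(f) paste(readLines(f), collapse = "\n"), character(1))
}

test_that("generation is byte-identical under a fixed config", {
  cfg <- generator_config(n_drugs = 20L, n_clusters = 4L, n_pairs = 30L,
                          seed = 77L)
  d1 <- file.path(tempdir(), "kmr_gen_a")
  d2 <- file.path(tempdir(), "kmr_gen_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate(cfg, d1)
  generate(cfg, d2)
  h1 <- dir_digest(d1)
  h2 <- dir_digest(d2)
  expect_equal(unname(h1), unname(h2))
  expect_setequal(basename(names(h1)),
                  c(paste0(kmr_families(), ".tsv"), "fingerprints.tsv",
                    "taxonomy.tsv", "descriptions.conllu", "pairs.tsv",
                    "latent.tsv", "manifest.tsv"))
})

test_that("the noise-free fixture has perfect within-cluster attribute overlap", {
  ds <- fixture_dataset()  # epsilon = 0, disjoint signatures
  cl <- stats::setNames(ds$latent$cluster, ds$latent$drug_id)
  jac <- function(a, b) {
    u <- union(a, b)
    if (!length(u)) return(1)
    length(intersect(a, b)) / length(u)
  }
  ids <- names(ds$drugs)
  for (i in 1:(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      tg_i <- ds$drugs[[ids[i]]]$attributes$target
      tg_j <- ds$drugs[[ids[j]]]$attributes$target
      expected <- if (cl[ids[i]] == cl[ids[j]]) 1 else 0
      expect_equal(jac(tg_i, tg_j), expected)
    }
  }
})

test_that("attribute overlap separates clusters under 5% noise", {
  dir <- file.path(tempdir(), "kmr_gen_sep")
  ds <- cached("sep_ds", function() {
    generate(generator_config(n_drugs = 200L, n_clusters = 8L,
                              epsilon = 0.05, n_pairs = 400L, seed = 3L), dir)
  })
  cl <- stats::setNames(ds$latent$cluster, ds$latent$drug_id)
  ids <- names(ds$drugs)
  sets <- lapply(ds$drugs, function(d) d$attributes$side_effect)
  set.seed(10)
  same <- numeric(300); diff_ <- numeric(300)
  for (k in 1:300) {
    repeat {
      ij <- sample(ids, 2)
      if (cl[ij[1]] == cl[ij[2]]) break
    }
    same[k] <- length(intersect(sets[[ij[1]]], sets[[ij[2]]])) /
      length(union(sets[[ij[1]]], sets[[ij[2]]]))
    repeat {
      ij <- sample(ids, 2)
      if (cl[ij[1]] != cl[ij[2]]) break
    }
    diff_[k] <- length(intersect(sets[[ij[1]]], sets[[ij[2]]])) /
      length(union(sets[[ij[1]]], sets[[ij[2]]]))
  }
  expect_gte(mean(same) - mean(diff_), 0.3)
})

test_that("the worked fixture loads cleanly and its labels are consistent", {
  dir <- file.path(tempdir(), "kmr_fixture_clean")
  expect_no_warning(ds <- worked_fixture(dir))
  expect_length(ds$drugs, 10L)
  expect_equal(length(ds$taxonomy$drug_nodes), 10L)

  # no contradictory duplicate labels for the same unordered pair
  key <- paste(pmin(ds$pairs$drug_a, ds$pairs$drug_b),
               pmax(ds$pairs$drug_a, ds$pairs$drug_b))
  expect_false(any(duplicated(key)))

  # every sentence parses into a valid tree with the drug as entity1
  for (id in names(ds$drugs)) {
    for (s in ds$drugs[[id]]$sentences) {
      expect_s3_class(s, "parsed_sentence")
      expect_equal(s$tokens[s$entity1[1]], id)
    }
  }
})

test_that("fixture IDF weights recompute exactly from its attribute table", {
  ds <- fixture_dataset()
  cat_se <- ds$catalogs$side_effect
  # recount document frequencies from the drug records themselves
  for (item in cat_se$items) {
    df_brute <- sum(vapply(ds$drugs, function(d)
      item %in% d$attributes$side_effect, logical(1)))
    expect_equal(unname(cat_se$df[item]), df_brute)
  }
  d1 <- ds$drugs[[1]]
  v <- as_dense(encode_family(d1, cat_se))
  for (k in seq_along(cat_se$items)) {
    if (cat_se$items[k] %in% d1$attributes$side_effect) {
      expect_equal(v[k], log((cat_se$n_drugs + 1) / (cat_se$df[[k]] + 1)))
    } else {
      expect_equal(v[k], 0)
    }
  }
})

test_that("the planted DDI rule is recoverable by logistic regression", {
  dir <- file.path(tempdir(), "kmr_gen_sep")
  ds <- cached("sep_ds", function() {
    generate(generator_config(n_drugs = 200L, n_clusters = 8L,
                              epsilon = 0.05, n_pairs = 400L, seed = 3L), dir)
  })
  cl <- stats::setNames(ds$latent$cluster, ds$latent$drug_id)
  shared <- vapply(seq_len(nrow(ds$pairs)), function(r) {
    length(intersect(ds$drugs[[ds$pairs$drug_a[r]]]$attributes$target,
                     ds$drugs[[ds$pairs$drug_b[r]]]$attributes$target))
  }, numeric(1))
  same <- as.integer(cl[ds$pairs$drug_a] == cl[ds$pairs$drug_b])
  fit <- suppressWarnings(
    stats::glm(ds$pairs$ddi ~ shared + same, family = stats::binomial()))
  m <- compute_metrics(ds$pairs$ddi, stats::fitted(fit))
  expect_gte(m$auroc, 0.9)
})

test_that("regenerating the worked fixture reproduces the shipped copy", {
  shipped <- system.file("extdata", "worked_fixture", package = "kmr")
  expect_true(nzchar(shipped))
  fresh <- file.path(tempdir(), "kmr_fixture_regen")
  unlink(fresh, recursive = TRUE)
  worked_fixture(fresh)
  for (f in list.files(shipped)) {
    expect_identical(readLines(file.path(fresh, f)),
                     readLines(file.path(shipped, f)))
  }
})

test_that("infeasible generator configurations are rejected", {
  expect_error(generator_config(n_clusters = 1L), "n_clusters")
  expect_error(generator_config(epsilon = 0.6), "epsilon")
  expect_error(generator_config(sim_sigma = -1), "sim_sigma")
  expect_error(generator_config(n_clusters = 4L, attrs_per_cluster = 10L,
                                family_universe = 20L), "universe")
})
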