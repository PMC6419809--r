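# Shared fixtures, built once per test run and cached.

.kmr_test_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .kmr_test_cache)) {
    assign(name, builder(), envir = .kmr_test_cache)
  }
  get(name, envir = .kmr_test_cache)
}

# small 40-drug / 4-cluster dataset for fast pipeline tests
small_dataset <- function() {
  cached("small_ds", function() {
    dir <- file.path(tempdir(), "kmr_test_small")
    generate(generator_config(n_drugs = 40L, n_clusters = 4L,
                              n_pairs = 200L, seed = 7L), dir)
  })
}

# the worked 10-drug fixture
fixture_dataset <- function() {
  cached("fixture_ds", function() {
    worked_fixture(file.path(tempdir(), "kmr_test_fixture"))
  })
}

tiny_config <- function(...) {
  args <- list(reducer_dim = 8L, pharm_pool_segments = 2L,
               class_embed_dim = 8L, class_dim = 8L, walks_per_node = 2L,
               walk_length = 8L, sg_epochs = 1L, word_dim = 4L, dep_dim = 2L,
               hidden_size = 6L, text_dim = 8L, head_dim = 8L,
               head_pool_segments = 2L, epochs = 1L, dropout = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(kmr_config, args)
}
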