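#' Run configuration
#'
#' Bundle of every tunable hyperparameter of the pipeline.  Defaults follow
#' the reference training regime: convolution kernel width 5 with 20
#' channels, a 500-unit fully connected reducer, learning rate 0.003,
#' dropout 0.5 on the Bi-LSTM output layer, batch size 40, maximum sentence
#' length 100 tokens, and uniform parameter initialization on
#' \[-init_range, init_range\] with init_range = 0.1.
#'
#' @param conv_kernel convolution kernel width shared by the pharmacological
#'   reducer and the DDI joint layer.
#' @param conv_depth number of convolution channels (filters).
#' @param reducer_dim output size of the pharmacological reducer's fully
#'   connected layer.
#' @param pharm_pool_segments number of contiguous max-pool segments per
#'   convolution channel in the pharmacological reducer (1 = global max).
#' @param class_embed_dim dimension k of each taxonomy embedding channel.
#' @param class_dim output size of the drug-class feature block.
#' @param class_filter_widths widths of the multi-channel convolution
#'   filters applied to the stacked class-embedding channels.
#' @param walks_per_node,walk_length random-walk corpus size per node.
#' @param window,negatives,sg_epochs,sg_lr skip-gram (negative sampling)
#'   training parameters for the walk-based channels.
#' @param p,q node2vec return and in-out bias parameters; p = q = 1 gives
#'   uniform first-order (DeepWalk) walks.
#' @param line_order,line_epochs,line_lr LINE channel: proximity order
#'   (1 or 2) and training schedule.
#' @param drug_class_source `"own"` attaches each drug as a leaf of its class
#'   node so it receives its own walk-based embedding; `"leaf"` makes a drug
#'   inherit its class node's embedding.
#' @param word_dim,dep_dim word and dependency-feature embedding dimensions.
#' @param hidden_size Bi-LSTM hidden size per direction.
#' @param text_dim output size of the textual-description feature block.
#' @param attention_score sentence-scoring form for bag attention:
#'   `"bilinear"` (query through a learned map) or `"dot"`.
#' @param max_sentence_length hard cap on tokens per sentence.
#' @param fusion_m number of column groups each feature block is reshaped to
#'   before interactive fusion attention.
#' @param fusion_mode `"reweight"` rescales a block's column groups by
#'   m * alpha (length-preserving); `"pool"` concatenates the attention-pooled
#'   columns v_c instead.
#' @param head_dim output size dl of the DDI joint layer's fully connected
#'   stage (the input size of the final softmax projection).
#' @param head_pool_segments max-pool segments in the DDI joint convolution.
#' @param head_norm normalization of the joint layer's fully connected
#'   output before the softmax projection: `"rms"`, `"layer"` or `"none"`.
#' @param symmetrize average DDI/DDS predictions over both pair orderings.
#' @param learning_rate,dropout,batch_size,epochs optimizer settings
#'   (AdaGrad, cross-entropy loss).
#' @param init_range half-width of the uniform initialization interval.
#' @param rf_trees,rf_max_depth random-forest DDS head (0 depth = unlimited).
#' @param pharm_reducer one of `"cnn"` (default), `"concatenation"`,
#'   `"trans_mat"`, `"fully_conn"` — the alternatives exist for the
#'   dimensionality-reduction comparison harness.
#' @param trans_mat_dim per-family output dimension of the `"trans_mat"`
#'   baseline reducer (total = 6 * trans_mat_dim).
#' @param normalize_pharm unit-normalize each drug's concatenated
#'   IDF/fingerprint vector before the reducer.
#' @param ablate feature block to zero before fusion: `"none"`,
#'   `"pharmacology"`, `"drug_class"`, `"textual_description"`.
#' @param sweep_positive_only subsample only positive pairs during the
#'   labeled-prevalence sweep instead of all training pairs.
#' @param seed default random seed.
#'
#' @return an object of class `kmr_config` (a validated named list).
#' @export
kmr_config <- function(conv_kernel = 5L,
                       conv_depth = 20L,
                       reducer_dim = 500L,
                       pharm_pool_segments = 4L,
                       class_embed_dim = 64L,
                       class_dim = 128L,
                       class_filter_widths = c(2L, 3L),
                       walks_per_node = 10L,
                       walk_length = 40L,
                       window = 5L,
                       negatives = 5L,
                       sg_epochs = 3L,
                       sg_lr = 0.05,
                       p = 1,
                       q = 0.5,
                       line_order = 2L,
                       line_epochs = 120L,
                       line_lr = 0.1,
                       drug_class_source = "own",
                       word_dim = 32L,
                       dep_dim = 8L,
                       hidden_size = 64L,
                       text_dim = 128L,
                       attention_score = "bilinear",
                       max_sentence_length = 100L,
                       fusion_m = 4L,
                       fusion_mode = "reweight",
                       head_dim = 500L,
                       head_pool_segments = 4L,
                       head_norm = "rms",
                       symmetrize = TRUE,
                       learning_rate = 0.003,
                       dropout = 0.5,
                       batch_size = 40L,
                       epochs = 5L,
                       init_range = 0.1,
                       rf_trees = 200L,
                       rf_max_depth = 0L,
                       pharm_reducer = "cnn",
                       normalize_pharm = TRUE,
                       trans_mat_dim = 100L,
                       ablate = "none",
                       sweep_positive_only = FALSE,
                       seed = 1L) {
  cfg <- list(
    conv_kernel = as.integer(conv_kernel),
    conv_depth = as.integer(conv_depth),
    reducer_dim = as.integer(reducer_dim),
    pharm_pool_segments = as.integer(pharm_pool_segments),
    class_embed_dim = as.integer(class_embed_dim),
    class_dim = as.integer(class_dim),
    class_filter_widths = as.integer(class_filter_widths),
    walks_per_node = as.integer(walks_per_node),
    walk_length = as.integer(walk_length),
    window = as.integer(window),
    negatives = as.integer(negatives),
    sg_epochs = as.integer(sg_epochs),
    sg_lr = as.numeric(sg_lr),
    p = as.numeric(p),
    q = as.numeric(q),
    line_order = as.integer(line_order),
    line_epochs = as.integer(line_epochs),
    line_lr = as.numeric(line_lr),
    drug_class_source = drug_class_source,
    word_dim = as.integer(word_dim),
    dep_dim = as.integer(dep_dim),
    hidden_size = as.integer(hidden_size),
    text_dim = as.integer(text_dim),
    attention_score = attention_score,
    max_sentence_length = as.integer(max_sentence_length),
    fusion_m = as.integer(fusion_m),
    fusion_mode = fusion_mode,
    head_dim = as.integer(head_dim),
    head_pool_segments = as.integer(head_pool_segments),
    head_norm = head_norm,
    symmetrize = isTRUE(symmetrize),
    learning_rate = as.numeric(learning_rate),
    dropout = as.numeric(dropout),
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    init_range = as.numeric(init_range),
    rf_trees = as.integer(rf_trees),
    rf_max_depth = as.integer(rf_max_depth),
    pharm_reducer = pharm_reducer,
    normalize_pharm = isTRUE(normalize_pharm),
    trans_mat_dim = as.integer(trans_mat_dim),
    ablate = ablate,
    sweep_positive_only = isTRUE(sweep_positive_only),
    seed = as.integer(seed)
  )
  class(cfg) <- "kmr_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("conv_kernel", "conv_depth", "reducer_dim", "pharm_pool_segments",
           "class_embed_dim", "class_dim", "walks_per_node", "walk_length",
           "window", "negatives", "sg_epochs", "word_dim", "dep_dim",
           "hidden_size", "text_dim", "max_sentence_length", "fusion_m",
           "head_dim", "head_pool_segments", "batch_size", "epochs",
           "rf_trees", "trans_mat_dim")
  for (f in pos) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L) {
      stop("config field '", f, "' must be a positive integer", call. = FALSE)
    }
  }
  if (cfg$p <= 0 || cfg$q <= 0) stop("config: p and q must be > 0", call. = FALSE)
  if (cfg$learning_rate < 0) stop("config: learning_rate must be >= 0", call. = FALSE)
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("config: dropout must lie in [0, 1)", call. = FALSE)
  if (cfg$init_range <= 0) stop("config: init_range must be > 0", call. = FALSE)
  if (!cfg$line_order %in% c(1L, 2L)) stop("config: line_order must be 1 or 2", call. = FALSE)
  if (!cfg$head_norm %in% c("none", "rms", "layer")) {
    stop("config: unknown head_norm '", cfg$head_norm, "'", call. = FALSE)
  }
  if (!cfg$fusion_mode %in% c("reweight", "pool")) {
    stop("config: unknown fusion_mode '", cfg$fusion_mode, "'", call. = FALSE)
  }
  if (!cfg$attention_score %in% c("bilinear", "dot")) {
    stop("config: unknown attention_score '", cfg$attention_score, "'", call. = FALSE)
  }
  if (!cfg$drug_class_source %in% c("own", "leaf")) {
    stop("config: unknown drug_class_source '", cfg$drug_class_source, "'", call. = FALSE)
  }
  if (!cfg$pharm_reducer %in% c("cnn", "concatenation", "trans_mat", "fully_conn")) {
    stop("config: unknown pharm_reducer '", cfg$pharm_reducer, "'", call. = FALSE)
  }
  if (!cfg$ablate %in% c("none", "pharmacology", "drug_class", "textual_description")) {
    stop("config: unknown ablation family '", cfg$ablate, "'", call. = FALSE)
  }
  invisible(cfg)
}

#' Desk-scale configuration
#'
#' The reduced configuration used throughout the examples, vignette and test
#' suite: hidden sizes 32-64, feature blocks of 64/32/32 dimensions, short
#' walk corpora.  Training-regime fields (learning rate 0.003, dropout 0.5,
#' batch 40, kernel 5, depth 20, init 0.1) keep their reference defaults.
#'
#' @param ... overrides forwarded to [kmr_config()].
#' @return a `kmr_config`.
#' @export
kmr_desk_config <- function(...) {
  args <- list(
    reducer_dim = 64L, pharm_pool_segments = 4L,
    class_embed_dim = 32L, class_dim = 32L,
    walks_per_node = 5L, walk_length = 20L, sg_epochs = 2L,
    word_dim = 16L, dep_dim = 4L, hidden_size = 32L, text_dim = 32L,
    epochs = 3L
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(kmr_config, args)
}

#' Read / write a run configuration
#'
#' Flat `key = value` text format, one field per line; `#` starts a comment.
#' Unknown keys are an error so a stale file cannot silently drift from the
#' implementation.
#'
#' @param path file path.
#' @return `read_config()` returns a `kmr_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  defaults <- kmr_config()
  vals <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[[i]], "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("config line ", i, " is not 'key = value': ", lines[[i]], call. = FALSE)
    key <- trimws(kv[[1]])
    val <- trimws(kv[[2]])
    if (!key %in% names(defaults)) stop("unknown config key '", key, "'", call. = FALSE)
    proto <- defaults[[key]]
    vals[[key]] <- if (is.character(proto)) {
      strsplit(val, ",", fixed = TRUE)[[1]]
    } else if (is.logical(proto)) {
      as.logical(val)
    } else {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    }
  }
  do.call(kmr_config, vals)
}

#' @rdname read_config
#' @param config a `kmr_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "kmr_config"))
  fmt <- vapply(config, function(v) paste(format(v, scientific = FALSE, trim = TRUE),
                                          collapse = ","), character(1))
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}

#' @export
print.kmr_config <- function(x, ...) {
  cat("<kmr_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ",")))
  }
  invisible(x)
}
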