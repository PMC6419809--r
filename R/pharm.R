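# Pharmacological feature block: IDF-weighted sparse attribute vectors,
# fingerprint bits, concatenation, and convolutional reduction to a dense
# embedding.

#' Sparse feature vector
#'
#' Fixed-length vector stored as (position, value) pairs; absent positions
#' are zero.
#'
#' @param length total vector length.
#' @param positions 1-based positions of the nonzero entries.
#' @param values their values.
#' @return a `sparse_feature_vector`.
#' @export
sparse_feature_vector <- function(length, positions = integer(), values = numeric()) {
  positions <- as.integer(positions)
  if (base::length(positions) != base::length(values)) {
    stop("positions and values lengths differ", call. = FALSE)
  }
  if (base::length(positions) && (any(positions < 1L) || any(positions > length))) {
    stop("sparse position out of range", call. = FALSE)
  }
  structure(list(length = as.integer(length), positions = positions,
                 values = as.numeric(values)),
            class = "sparse_feature_vector")
}

#' Densify a sparse feature vector
#' @param x a [sparse_feature_vector()].
#' @return a numeric vector of length `x$length`.
#' @export
as_dense <- function(x) {
  stopifnot(inherits(x, "sparse_feature_vector"))
  out <- numeric(x$length)
  out[x$positions] <- x$values
  out
}

#' Inverse document frequency weight
#'
#' `IDF(s, Drugs) = log((|Drugs| + 1) / (DF(s, Drugs) + 1))` with natural
#' log: the rarity weight of an attribute possessed by `df` of `n_drugs`
#' drugs.  Strictly decreasing in `df`; zero exactly when every drug has
#' the attribute.
#'
#' @param df number of drugs possessing the attribute (vectorized).
#' @param n_drugs total number of drugs (>= 1).
#' @return numeric IDF weight(s).
#' @export
compute_idf <- function(df, n_drugs) {
  if (n_drugs < 1L) stop("n_drugs must be >= 1", call. = FALSE)
  if (any(df < 0L) || any(df > n_drugs)) {
    stop("df must lie in [0, n_drugs]", call. = FALSE)
  }
  log((n_drugs + 1) / (df + 1))
}

#' IDF-encode one attribute family of a drug
#'
#' The entry at an attribute's catalog position is its IDF weight if the
#' drug possesses the attribute, else 0.  Attributes absent from the
#' (training-frozen) catalog are ignored.
#'
#' @param drug a [drug_record()].
#' @param catalog the family's [attribute_catalog()].
#' @return a [sparse_feature_vector()] of length `|catalog$items|`.
#' @export
encode_family <- function(drug, catalog) {
  stopifnot(inherits(drug, "drug_record"), inherits(catalog, "attribute_catalog"))
  have <- drug$attributes[[catalog$family]]
  pos <- match(have, catalog$items)
  pos <- sort(pos[!is.na(pos)])
  if (!length(pos)) return(sparse_feature_vector(length(catalog$items)))
  sparse_feature_vector(length(catalog$items), pos,
                        compute_idf(unname(catalog$df[pos]), catalog$n_drugs))
}

#' Encode a substructure fingerprint
#'
#' @param bits 0-based indices of set bits.
#' @param length fingerprint length in bits.
#' @return a binary [sparse_feature_vector()].
#' @export
encode_fingerprint <- function(bits, length) {
  bits <- as.integer(bits)
  if (base::length(bits) && (any(bits < 0L) || any(bits >= length))) {
    stop("fingerprint bit index out of range [0, ", length, ")", call. = FALSE)
  }
  bits <- sort(unique(bits))
  sparse_feature_vector(length, bits + 1L, rep(1, base::length(bits)))
}

#' Concatenate the pharmacological feature vectors
#'
#' Fixed family order: side_effect, drug_action, physiological_effect,
#' formulation, target, fingerprint.  The result records per-family offsets
#' so entry p of family k sits at `offset(k) + p`.
#'
#' @param vectors named list of [sparse_feature_vector()]s covering all six
#'   families.
#' @return a [sparse_feature_vector()] with attributes `offsets` and
#'   `block_lengths`.
#' @export
concat_pharm <- function(vectors) {
  order <- c(kmr_families(), "fingerprint")
  miss <- setdiff(order, names(vectors))
  if (length(miss)) stop("missing pharmacological family: ", miss[1], call. = FALSE)
  lens <- vapply(vectors[order], function(v) v$length, integer(1))
  offs <- c(0L, cumsum(lens))[seq_along(order)]
  names(offs) <- order
  pos <- unlist(lapply(seq_along(order), function(k) {
    vectors[[order[k]]]$positions + offs[k]
  }), use.names = FALSE)
  val <- unlist(lapply(order, function(f) vectors[[f]]$values), use.names = FALSE)
  out <- sparse_feature_vector(sum(lens), pos, val)
  attr(out, "offsets") <- offs
  attr(out, "block_lengths") <- lens
  out
}

#' Convolutional pharmacological reducer
#'
#' Dimensionality reduction of the concatenated sparse feature vector:
#' densify, 1-D convolution (kernel width `conv_kernel`, `conv_depth`
#' channels, stride 1), ReLU, max-pool per channel over
#' `pharm_pool_segments` contiguous segments, and a fully connected layer to
#' `reducer_dim` outputs.  Weights are initialized uniformly on
#' \[-init_range, init_range\].
#'
#' @param input_length length of the concatenated pharmacological vector.
#' @param config a [kmr_config()].
#' @return a `pharm_reducer` (parameter list plus shape metadata).
#' @export
new_pharm_reducer <- function(input_length, config = kmr_config()) {
  w <- config$conv_kernel
  C <- config$conv_depth
  S <- min(config$pharm_pool_segments, max(input_length - w + 1L, 1L))
  params <- list(K = u_init(w, C, config$init_range),
                 b = stats::runif(C, -config$init_range, config$init_range),
                 W = u_init(config$reducer_dim, S * C, config$init_range),
                 bw = stats::runif(config$reducer_dim, -config$init_range,
                                   config$init_range))
  structure(list(params = params, kernel = w, depth = C, segments = S,
                 input_length = as.integer(input_length),
                 reducer_dim = config$reducer_dim),
            class = "pharm_reducer")
}

pharm_forward <- function(x_dense, reducer) {
  cp <- conv_pool_forward(matrix(x_dense, ncol = 1L), reducer$params$K,
                          reducer$params$b, reducer$segments, reducer$kernel)
  fc <- dense_forward(cp$out, reducer$params$W, reducer$params$bw)
  list(out = fc$out, cache = list(cp = cp$cache, fc = fc$cache))
}

pharm_backward <- function(cache, dout) {
  dfc <- dense_backward(cache$fc, dout)
  dcp <- conv_pool_backward(cache$cp, dfc$dx)
  list(dx = as.vector(dcp$dx),
       grads = list(K = dcp$dK, b = dcp$db, W = dfc$dW, bw = dfc$db))
}

#' Reduce a pharmacological feature vector to its dense embedding
#'
#' @param vector the concatenated [sparse_feature_vector()] (or a dense
#'   numeric vector).
#' @param reducer a [new_pharm_reducer()].
#' @return dense numeric vector of length `reducer$reducer_dim`.
#' @export
reduce_pharm <- function(vector, reducer) {
  stopifnot(inherits(reducer, "pharm_reducer"))
  x <- if (inherits(vector, "sparse_feature_vector")) as_dense(vector) else as.numeric(vector)
  if (length(x) < reducer$kernel) {
    message("pharm reducer input shorter than kernel; zero-padding applied")
  }
  pharm_forward(x, reducer)$out
}

#' Baseline dimensionality reducers
#'
#' Alternatives used by the comparison harness: `"concatenation"` (identity
#' on the dense concatenated vector), `"trans_mat"` (a fixed seeded random
#' mapping matrix per family, `trans_mat_dim` outputs each, 6 families),
#' and `"fully_conn"` (a single fully connected layer to `reducer_dim`).
#'
#' @param vector output of [concat_pharm()] (needed for its per-family
#'   offsets when `method = "trans_mat"`).
#' @param method reducer name.
#' @param config a [kmr_config()].
#' @param seed seed for the fixed random maps.
#' @return dense numeric vector.
#' @export
baseline_reducers <- function(vector, method, config = kmr_config(), seed = 1L) {
  x <- if (inherits(vector, "sparse_feature_vector")) as_dense(vector) else as.numeric(vector)
  switch(method,
    concatenation = x,
    trans_mat = {
      lens <- attr(vector, "block_lengths")
      if (is.null(lens)) stop("trans_mat needs the concat_pharm block lengths", call. = FALSE)
      offs <- c(0L, cumsum(lens))
      withr_seed(seed, {
        unlist(lapply(seq_along(lens), function(k) {
          blk <- x[(offs[k] + 1L):offs[k + 1L]]
          as.vector(u_init(config$trans_mat_dim, lens[k], config$init_range) %*% blk)
        }), use.names = FALSE)
      })
    },
    fully_conn = {
      withr_seed(seed, {
        W <- u_init(config$reducer_dim, length(x), config$init_range)
        b <- stats::runif(config$reducer_dim, -config$init_range, config$init_range)
        as.vector(W %*% x + b)
      })
    },
    stop("unknown reducer '", method, "'", call. = FALSE)
  )
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}
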