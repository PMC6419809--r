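# Drug-class feature block: random-walk and edge-sampling network
# embeddings of the taxonomy (DeepWalk-, node2vec- and LINE-style
# channels), fused per drug by a multi-width convolution.

# undirected adjacency over all nodes (classes + drug attachments).
# Accepts a taxonomy_graph or any plain edge data.frame with columns
# parent/child, so the walkers and embedding trainers also work on generic
# undirected graphs.
taxonomy_adjacency <- function(graph) {
  if (is.data.frame(graph)) {
    e <- graph
    nodes <- unique(c(e$parent, e$child))
  } else {
    stopifnot(inherits(graph, "taxonomy_graph"))
    nodes <- graph$nodes
    e <- graph$edges
  }
  pi <- match(e$parent, nodes)
  ci <- match(e$child, nodes)
  from <- c(pi, ci)
  to <- c(ci, pi)
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]
  deg <- tabulate(from, nbins = length(nodes))
  start <- cumsum(c(1L, deg))[seq_along(nodes)]
  list(nodes = nodes, flat = to, start = start, deg = deg,
       sets = split(to, factor(from, levels = seq_along(nodes))))
}

#' node2vec transition probabilities
#'
#' Unnormalized second-order walk weights from `cur` given the previously
#' visited node `prev`: 1/p to return to `prev`, 1 to a neighbor of `cur`
#' adjacent to `prev`, 1/q otherwise.  With `prev = NA` (first step) the
#' walk is uniform over neighbors.
#'
#' @param graph a [taxonomy_graph()].
#' @param prev,cur node ids (`prev` may be `NA`).
#' @param p,q return and in-out parameters (> 0).
#' @return named numeric vector of transition probabilities over the
#'   neighbors of `cur`.
#' @export
node2vec_transition <- function(graph, prev, cur, p = 1, q = 1) {
  adj <- taxonomy_adjacency(graph)
  ci <- match(cur, adj$nodes)
  if (is.na(ci)) stop("unknown node '", cur, "'", call. = FALSE)
  nbrs <- adj$sets[[ci]]
  if (!length(nbrs)) return(stats::setNames(numeric(), character()))
  if (is.na(prev)) {
    w <- rep(1, length(nbrs))
  } else {
    pi_ <- match(prev, adj$nodes)
    prev_nbrs <- adj$sets[[pi_]]
    w <- ifelse(nbrs == pi_, 1 / p,
                ifelse(nbrs %in% prev_nbrs, 1, 1 / q))
  }
  stats::setNames(w / sum(w), adj$nodes[nbrs])
}

#' Generate a random-walk corpus over the taxonomy
#'
#' Second-order biased walks in the node2vec sense; `p = q = 1` reduces to
#' uniform first-order walks (DeepWalk).  Tree edges are traversed as
#' undirected; a walk from an isolated node has length 1.
#'
#' @param graph a [taxonomy_graph()].
#' @param walks_per_node walks started from every node.
#' @param walk_length nodes per walk (including the start).
#' @param p,q node2vec bias parameters.
#' @param seed RNG seed (uses the current RNG state when `NULL`).
#' @return a `walk_corpus`: list with `walks` (list of node-id character
#'   vectors) and the walk parameters.
#' @export
generate_walks <- function(graph, walks_per_node = 10L, walk_length = 40L,
                           p = 1, q = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (p <= 0 || q <= 0) stop("p and q must be > 0", call. = FALSE)
  adj <- taxonomy_adjacency(graph)
  n <- length(adj$nodes)
  starts <- rep(seq_len(n), times = walks_per_node)
  nw <- length(starts)
  if (walk_length < 1L) stop("walk_length must be >= 1", call. = FALSE)

  paths <- matrix(NA_integer_, nw, walk_length)
  paths[, 1L] <- starts
  alive <- adj$deg[starts] > 0L
  if (walk_length >= 2L && any(alive)) {
    # first step: uniform over neighbors
    cur <- starts
    idx <- floor(stats::runif(nw) * adj$deg[cur]) + 1L
    nxt <- ifelse(alive, adj$flat[adj$start[cur] + idx - 1L], NA_integer_)
    paths[, 2L] <- nxt
    if (p == 1 && q == 1) {
      if (walk_length >= 3L) {
        for (t in 3:walk_length) {
          cur <- paths[, t - 1L]
          ok <- alive & !is.na(cur)
          idx <- floor(stats::runif(nw) * pmax(adj$deg[cur], 1L)) + 1L
          step <- adj$flat[adj$start[cur] + idx - 1L]
          paths[ok, t] <- step[ok]
        }
      }
    } else if (walk_length >= 3L) {
      sets <- adj$sets
      for (wk in seq_len(nw)) {
        if (!alive[wk]) next
        for (t in 3:walk_length) {
          prev <- paths[wk, t - 2L]
          cur <- paths[wk, t - 1L]
          nbrs <- sets[[cur]]
          if (length(nbrs) == 1L) {
            paths[wk, t] <- nbrs
            next
          }
          w <- ifelse(nbrs == prev, 1 / p,
                      ifelse(nbrs %in% sets[[prev]], 1, 1 / q))
          paths[wk, t] <- nbrs[sample.int(length(nbrs), 1L, prob = w)]
        }
      }
    }
  }
  walks <- lapply(seq_len(nw), function(i) {
    row <- paths[i, ]
    adj$nodes[row[!is.na(row)]]
  })
  structure(list(walks = walks, walks_per_node = walks_per_node,
                 walk_length = walk_length, p = p, q = q,
                 nodes = adj$nodes),
            class = "walk_corpus")
}

# shared negative-sampling update used by skip-gram and LINE: one batched
# "hogwild" pass over (center, context) index pairs
sgns_batch_update <- function(Vin, Vout, wc, ctx, negatives, neg_prob, lr) {
  m <- length(wc)
  d <- ncol(Vin)
  vin <- Vin[wc, , drop = FALSE]
  vpos <- Vout[ctx, , drop = FALSE]
  g <- sigm(rowSums(vin * vpos)) - 1
  dvin <- vpos * g
  dout_idx <- ctx
  dout <- vin * g
  if (negatives > 0L) {
    neg <- sample.int(nrow(Vout), m * negatives, replace = TRUE, prob = neg_prob)
    rep_ix <- rep(seq_len(m), times = negatives)
    vin_rep <- vin[rep_ix, , drop = FALSE]
    vneg <- Vout[neg, , drop = FALSE]
    gn <- sigm(rowSums(vin_rep * vneg))
    gn[neg == ctx[rep_ix]] <- 0   # drawn negative equals the true context
    dvin_neg <- rowsum(vneg * gn, group = rep_ix, reorder = TRUE)
    dvin <- dvin + dvin_neg
    dout_idx <- c(dout_idx, neg)
    dout <- rbind(dout, vin_rep * gn)
  }
  # one averaged step per parameter row: keeps the aggregated update on the
  # scale of a single-sample step regardless of how often a node repeats
  agg_in <- rowsum(dvin, group = wc)
  cnt_in <- rowsum(rep(1, nrow(dvin)), group = wc)[, 1]
  ii <- as.integer(rownames(agg_in))
  Vin[ii, ] <- Vin[ii, , drop = FALSE] - lr * agg_in / cnt_in
  agg_out <- rowsum(dout, group = dout_idx)
  cnt_out <- rowsum(rep(1, nrow(dout)), group = dout_idx)[, 1]
  oo <- as.integer(rownames(agg_out))
  Vout[oo, ] <- Vout[oo, , drop = FALSE] - lr * agg_out / cnt_out
  list(Vin = Vin, Vout = Vout)
}

#' Skip-gram with negative sampling over a walk corpus
#'
#' Walks are treated as sentences; updates are applied in deterministic
#' aggregated mini-batches, so a fixed seed reproduces the embeddings
#' exactly.
#'
#' @param corpus a [generate_walks()] corpus.
#' @param dim embedding dimension.
#' @param window symmetric context window size (> 0).
#' @param negatives negative samples per positive pair.
#' @param epochs passes over the pair list.
#' @param seed RNG seed.
#' @param lr fixed learning rate.
#' @return numeric matrix, one row per node id.
#' @export
train_skipgram <- function(corpus, dim = 64L, window = 5L, negatives = 5L,
                           epochs = 3L, seed = NULL, lr = 0.05) {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (dim <= 0L) stop("embedding dim must be positive", call. = FALSE)
  if (window <= 0L) stop("window must be positive", call. = FALSE)
  if (!length(corpus$walks)) stop("empty walk corpus", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nodes <- corpus$nodes
  n <- length(nodes)
  # (center, context) pairs within the window
  wc <- integer(0); ctx <- integer(0)
  for (walk in corpus$walks) {
    ids <- match(walk, nodes)
    Tn <- length(ids)
    if (Tn < 2L) next
    for (off in seq_len(min(window, Tn - 1L))) {
      a <- ids[seq_len(Tn - off)]
      b <- ids[(off + 1L):Tn]
      wc <- c(wc, a, b)
      ctx <- c(ctx, b, a)
    }
  }
  if (!length(wc)) stop("corpus has no co-occurrence pairs", call. = FALSE)
  counts <- tabulate(ctx, nbins = n)
  neg_prob <- (counts + 1)^0.75
  Vin <- u_init(n, dim, 0.5 / dim)
  Vout <- matrix(0, n, dim)
  chunk <- 512L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(wc))
    for (lo in seq(1L, length(ord), by = chunk)) {
      ix <- ord[lo:min(lo + chunk - 1L, length(ord))]
      upd <- sgns_batch_update(Vin, Vout, wc[ix], ctx[ix], negatives,
                               neg_prob, lr)
      Vin <- upd$Vin
      Vout <- upd$Vout
    }
  }
  rownames(Vin) <- nodes
  Vin
}

#' LINE-style embeddings by edge sampling
#'
#' First- or second-order proximity with negative sampling; every directed
#' edge is visited each epoch in a random order with aggregated batch
#' updates.
#'
#' @param graph a [taxonomy_graph()].
#' @param dim embedding dimension.
#' @param order proximity order, 1 or 2.
#' @param epochs passes over the edge list.
#' @param negatives negative samples per edge.
#' @param seed RNG seed.
#' @param lr fixed learning rate.
#' @return numeric matrix, one row per node id.
#' @export
train_line <- function(graph, dim = 64L, order = 2L, epochs = 30L,
                       negatives = 5L, seed = NULL, lr = 0.1) {
  if (dim <= 0L) stop("embedding dim must be positive", call. = FALSE)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  adj <- taxonomy_adjacency(graph)
  n <- length(adj$nodes)
  src <- rep(seq_len(n), adj$deg)
  dst <- adj$flat
  if (!length(src)) stop("graph has no edges", call. = FALSE)
  neg_prob <- (adj$deg + 1)^0.75
  Vin <- u_init(n, dim, 0.5 / dim)
  Vout <- if (order == 2L) matrix(0, n, dim) else Vin
  chunk <- 256L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(src))
    for (lo in seq(1L, length(ord), by = chunk)) {
      ix <- ord[lo:min(lo + chunk - 1L, length(ord))]
      if (order == 2L) {
        upd <- sgns_batch_update(Vin, Vout, src[ix], dst[ix], negatives,
                                 neg_prob, lr)
        Vin <- upd$Vin
        Vout <- upd$Vout
      } else {
        upd <- sgns_batch_update(Vin, Vin, src[ix], dst[ix], negatives,
                                 neg_prob, lr)
        Vin <- upd$Vin + (upd$Vout - Vin)   # apply both endpoint deltas
      }
    }
  }
  rownames(Vin) <- adj$nodes
  Vin
}

#' Learn the three taxonomy embedding channels
#'
#' DeepWalk (uniform walks), node2vec (biased walks with the configured
#' p, q) and LINE, all at dimension `class_embed_dim`.  With
#' `drug_class_source = "leaf"` each drug inherits its class node's vector
#' instead of its own walk-based one.
#'
#' @param taxonomy a [taxonomy_graph()].
#' @param config a [kmr_config()].
#' @param seed RNG seed.
#' @return named list of embedding matrices `deepwalk`, `node2vec`, `line`.
#' @export
learn_class_channels <- function(taxonomy, config = kmr_config(), seed = 1L) {
  set.seed(seed)
  k <- config$class_embed_dim
  dw_walks <- generate_walks(taxonomy, config$walks_per_node,
                             config$walk_length, p = 1, q = 1)
  dw <- train_skipgram(dw_walks, k, config$window, config$negatives,
                       config$sg_epochs, lr = config$sg_lr)
  n2v_walks <- generate_walks(taxonomy, config$walks_per_node,
                              config$walk_length, p = config$p, q = config$q)
  n2v <- train_skipgram(n2v_walks, k, config$window, config$negatives,
                        config$sg_epochs, lr = config$sg_lr)
  line <- train_line(taxonomy, k, config$line_order, config$line_epochs,
                     config$negatives, lr = config$line_lr)
  channels <- list(deepwalk = dw, node2vec = n2v, line = line)
  if (config$drug_class_source == "leaf") {
    for (nm in names(channels)) {
      channels[[nm]][taxonomy$drug_nodes, ] <-
        channels[[nm]][unname(taxonomy$attach[taxonomy$drug_nodes]), ]
    }
  }
  channels
}

#' Multi-channel convolutional encoder for the class feature block
#'
#' The drug's three channel vectors are stacked into a k x 3 input; filters
#' of the configured widths (default 2 and 3) slide along the embedding
#' axis with the channels as input depth, followed by ReLU, a global max
#' pool per filter, and a fully connected layer to `class_dim`.
#'
#' @param config a [kmr_config()].
#' @return a `class_encoder` parameter object.
#' @export
new_class_encoder <- function(config = kmr_config()) {
  widths <- config$class_filter_widths
  C <- config$conv_depth
  r <- config$init_range
  conv <- lapply(widths, function(w) {
    list(K = u_init(w * 3L, C, r), b = stats::runif(C, -r, r))
  })
  names(conv) <- paste0("w", widths)
  structure(list(params = list(conv = conv,
                               W = u_init(config$class_dim,
                                          length(widths) * C, r),
                               bw = stats::runif(config$class_dim, -r, r)),
                 widths = widths, depth = C, class_dim = config$class_dim),
            class = "class_encoder")
}

class_forward <- function(X, encoder) {
  caches <- vector("list", length(encoder$widths))
  feats <- vector("list", length(encoder$widths))
  for (i in seq_along(encoder$widths)) {
    cp <- conv_pool_forward(X, encoder$params$conv[[i]]$K,
                            encoder$params$conv[[i]]$b,
                            segments = 1L, kernel = encoder$widths[i])
    caches[[i]] <- cp$cache
    feats[[i]] <- cp$out
  }
  names(caches) <- names(encoder$params$conv)
  feat <- unlist(feats, use.names = FALSE)
  fc <- dense_forward(feat, encoder$params$W, encoder$params$bw)
  list(out = fc$out, cache = list(convs = caches, fc = fc$cache,
                                  depth = encoder$depth, X = X))
}

class_backward <- function(cache, dout) {
  dfc <- dense_backward(cache$fc, dout)
  C <- cache$depth
  dX <- cache$X * 0
  conv_grads <- vector("list", length(cache$convs))
  for (i in seq_along(cache$convs)) {
    dseg <- dfc$dx[((i - 1L) * C + 1L):(i * C)]
    g <- conv_pool_backward(cache$convs[[i]], dseg)
    dX <- dX + g$dx
    conv_grads[[i]] <- list(K = g$dK, b = g$db)
  }
  names(conv_grads) <- names(cache$convs)
  list(dX = dX,
       grads = list(conv = conv_grads, W = dfc$dW, bw = dfc$db))
}

#' Fuse the embedding channels into per-drug class feature blocks
#'
#' @param channels output of [learn_class_channels()].
#' @param drug_ids drugs to encode.
#' @param encoder a [new_class_encoder()].
#' @return matrix of dim `length(drug_ids) x class_dim` (rownames =
#'   drug ids).
#' @export
fuse_channels <- function(channels, drug_ids, encoder) {
  stopifnot(inherits(encoder, "class_encoder"))
  for (nm in names(channels)) {
    miss <- setdiff(drug_ids, rownames(channels[[nm]]))
    if (length(miss)) {
      stop("drug '", miss[1], "' missing from channel '", nm, "'", call. = FALSE)
    }
  }
  out <- matrix(0, length(drug_ids), encoder$class_dim,
                dimnames = list(drug_ids, NULL))
  for (i in seq_along(drug_ids)) {
    X <- vapply(channels, function(ch) ch[drug_ids[i], ],
                numeric(ncol(channels[[1]])))
    out[i, ] <- class_forward(X, encoder)$out
  }
  out
}
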