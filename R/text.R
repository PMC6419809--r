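# Textual-description feature block: dependency-derived token features,
# concatenated token embeddings, Bi-LSTM with elementwise-summed
# directional outputs, word-level attention within a sentence, and
# sentence-level (bag) attention across a drug's sentences.

REL_ROOT_LEVELS <- c("root_itself", "child_of_root", "other")
REL_ENTITY_LEVELS <- c("child_of_entity", "parent_of_entity", "entity_itself", "other")

#' Dependency features of a parsed sentence
#'
#' Per-token categorical features read off the dependency tree: the
#' relation of each token to the root (`root_itself`, `child_of_root`,
#' `other`) and to each marked entity span (`entity_itself`,
#' `child_of_entity`, `parent_of_entity`, `other`), plus the token's
#' dependency tag.  A missing entity2 yields uniformly `other`.
#'
#' @param sentence a [parsed_sentence()].
#' @return a `dependency_features` list with character vectors
#'   `relative_root`, `relative_e1`, `relative_e2`, `dep_tags`.
#' @export
extract_dependency_features <- function(sentence) {
  stopifnot(inherits(sentence, "parsed_sentence"))
  n <- length(sentence$tokens)
  heads <- sentence$heads
  root <- which(heads == 0L)
  rel_root <- rep("other", n)
  rel_root[heads == root] <- "child_of_root"
  rel_root[root] <- "root_itself"
  rel_entity <- function(span) {
    out <- rep("other", n)
    if (is.null(span)) return(out)
    ix <- span[1]:span[2]
    out[heads %in% ix] <- "child_of_entity"
    out[unique(heads[ix])] <- "parent_of_entity"
    out[ix] <- "entity_itself"
    out
  }
  structure(list(relative_root = rel_root,
                 relative_e1 = rel_entity(sentence$entity1),
                 relative_e2 = rel_entity(sentence$entity2),
                 dep_tags = sentence$dep_tags),
            class = "dependency_features")
}

#' Token embeddings: word part concatenated with dependency part
#'
#' `word_i = [v_i^w, v_i^d]`: each token's word vector followed by the
#' concatenated embeddings of its four dependency features (relative root,
#' relative entity1, relative entity2, dependency tag).  Out-of-vocabulary
#' words and tags map to the shared `<UNK>` row of their table.
#'
#' @param sentence a [parsed_sentence()].
#' @param dep_features its [extract_dependency_features()].
#' @param tables named list of embedding tables with rownames: `word`,
#'   `rel_root`, `rel_e1`, `rel_e2`, `dep_tag`.
#' @return numeric matrix, one column per token, `d_w + 4 d_f` rows.
#' @export
embed_tokens <- function(sentence, dep_features, tables) {
  ids <- token_ids(sentence, dep_features, rownames(tables$word),
                   rownames(tables$dep_tag))
  lookup_embeddings(ids, tables)
}

token_ids <- function(sentence, dep_features, word_vocab, tag_vocab) {
  wid <- match(sentence$tokens, word_vocab)
  wid[is.na(wid)] <- match("<UNK>", word_vocab)
  tid <- match(dep_features$dep_tags, tag_vocab)
  tid[is.na(tid)] <- match("<UNK>", tag_vocab)
  rbind(word = wid,
        rel_root = match(dep_features$relative_root, REL_ROOT_LEVELS),
        rel_e1 = match(dep_features$relative_e1, REL_ENTITY_LEVELS),
        rel_e2 = match(dep_features$relative_e2, REL_ENTITY_LEVELS),
        dep_tag = tid)
}

lookup_embeddings <- function(ids, tables) {
  rbind(t(tables$word[ids["word", ], , drop = FALSE]),
        t(tables$rel_root[ids["rel_root", ], , drop = FALSE]),
        t(tables$rel_e1[ids["rel_e1", ], , drop = FALSE]),
        t(tables$rel_e2[ids["rel_e2", ], , drop = FALSE]),
        t(tables$dep_tag[ids["dep_tag", ], , drop = FALSE]))
}

#' Text encoder parameters
#'
#' Embedding tables (random uniform unless a pre-trained word table is
#' supplied), forward and backward LSTM cells (forget-gate bias 1), the
#' word-attention projection/query, the bag-attention scorer, and the final
#' fully connected map to `text_dim`.
#'
#' @param vocab character vector of words (`<UNK>` is prepended).
#' @param tagset character vector of dependency tags (`<UNK>` prepended).
#' @param config a [kmr_config()].
#' @param word_table optional pre-trained word embedding matrix (rownames =
#'   words) of `word_dim` columns.
#' @return a `text_encoder`.
#' @export
new_text_encoder <- function(vocab, tagset, config = kmr_config(),
                             word_table = NULL) {
  r <- config$init_range
  dw <- config$word_dim
  df <- config$dep_dim
  h <- config$hidden_size
  vocab <- c("<UNK>", setdiff(unique(vocab), "<UNK>"))
  tagset <- c("<UNK>", setdiff(unique(tagset), "<UNK>"))
  word <- u_init(length(vocab), dw, r)
  rownames(word) <- vocab
  if (!is.null(word_table)) {
    common <- intersect(vocab, rownames(word_table))
    word[common, ] <- word_table[common, seq_len(dw)]
  }
  mk <- function(n) {
    m <- u_init(n, df, r)
    m
  }
  rel_root <- mk(3L); rownames(rel_root) <- REL_ROOT_LEVELS
  rel_e1 <- mk(4L); rownames(rel_e1) <- REL_ENTITY_LEVELS
  rel_e2 <- mk(4L); rownames(rel_e2) <- REL_ENTITY_LEVELS
  dep_tag <- mk(length(tagset)); rownames(dep_tag) <- tagset
  input_dim <- dw + 4L * df
  bag <- if (config$attention_score == "bilinear") {
    list(A = u_init(h, h, r), q = stats::runif(h, -r, r))
  } else {
    list(q = stats::runif(h, -r, r))
  }
  structure(list(params = list(word = word, rel_root = rel_root,
                               rel_e1 = rel_e1, rel_e2 = rel_e2,
                               dep_tag = dep_tag,
                               lstm_f = lstm_init(input_dim, h, r),
                               lstm_b = lstm_init(input_dim, h, r),
                               watt = list(W = u_init(h, h, r),
                                           w = stats::runif(h, -r, r)),
                               bag = bag,
                               W = u_init(config$text_dim, h, r),
                               bw = stats::runif(config$text_dim, -r, r)),
                 hidden = h, input_dim = input_dim,
                 text_dim = config$text_dim,
                 attention_score = config$attention_score,
                 dropout = config$dropout),
            class = "text_encoder")
}

# forward over one drug's sentence bag.
# sent_ids: list per sentence of the 5 x T id matrix from token_ids().
# Sentences are batched through the two LSTMs with end-padding; the
# backward direction consumes each sentence individually reversed.
text_drug_forward <- function(encoder, sent_ids, train = FALSE) {
  p <- encoder$params
  ns <- length(sent_ids)
  if (!ns) stop("drug has no description sentences", call. = FALSE)
  lens <- vapply(sent_ids, ncol, integer(1))
  if (any(lens == 0L)) stop("empty sentence", call. = FALSE)
  Tmax <- max(lens)
  h <- encoder$hidden
  d <- encoder$input_dim
  tables <- p[c("word", "rel_root", "rel_e1", "rel_e2", "dep_tag")]
  E <- lapply(sent_ids, lookup_embeddings, tables = tables)
  Xf <- lapply(seq_len(Tmax), function(t) {
    m <- matrix(0, d, ns)
    for (s in seq_len(ns)) if (t <= lens[s]) m[, s] <- E[[s]][, t]
    m
  })
  Xb <- lapply(seq_len(Tmax), function(t) {
    m <- matrix(0, d, ns)
    for (s in seq_len(ns)) if (t <= lens[s]) m[, s] <- E[[s]][, lens[s] - t + 1L]
    m
  })
  fwd <- lstm_forward(Xf, p$lstm_f)
  bwd <- lstm_forward(Xb, p$lstm_b)
  # hw_t = hf_t + hb_t, per sentence, positions aligned to the original order
  Hw <- vector("list", ns)
  for (s in seq_len(ns)) {
    m <- matrix(0, h, lens[s])
    for (t in seq_len(lens[s])) {
      m[, t] <- fwd$H[[t]][, s] + bwd$H[[lens[s] - t + 1L]][, s]
    }
    Hw[[s]] <- m
  }
  masks <- NULL
  if (train && encoder$dropout > 0) {
    masks <- lapply(seq_len(ns), function(s) dropout_mask(h, lens[s], encoder$dropout))
    Hw <- lapply(seq_len(ns), function(s) Hw[[s]] * masks[[s]])
  }
  watt_caches <- vector("list", ns)
  S <- matrix(0, h, ns)
  walpha <- vector("list", ns)
  for (s in seq_len(ns)) {
    at <- attend_forward(Hw[[s]], p$watt$W, p$watt$w)
    watt_caches[[s]] <- at$cache
    S[, s] <- at$v
    walpha[[s]] <- at$alpha
  }
  if (!is.null(p$bag$A)) {
    Z <- p$bag$A %*% S
    e <- as.vector(crossprod(p$bag$q, Z))
  } else {
    Z <- NULL
    e <- as.vector(crossprod(p$bag$q, S))
  }
  a <- softmax_vec(e)
  bag_vec <- as.vector(S %*% a)
  fc <- dense_forward(bag_vec, p$W, p$bw)
  list(out = fc$out,
       sentence_vectors = S, sentence_weights = a, sentence_scores = e,
       word_weights = walpha, Hw = Hw,
       cache = list(sent_ids = sent_ids, lens = lens, ns = ns,
                    fwd = fwd$cache, bwd = bwd$cache,
                    watt_caches = watt_caches, S = S, a = a, Z = Z,
                    masks = masks, fc = fc$cache, Tmax = Tmax))
}

text_drug_backward <- function(encoder, cache, dout) {
  p <- encoder$params
  ns <- cache$ns
  lens <- cache$lens
  h <- encoder$hidden
  dfc <- dense_backward(cache$fc, dout)
  dbag <- dfc$dx
  S <- cache$S
  a <- cache$a
  dS <- tcrossprod(dbag, a)
  da <- as.vector(crossprod(S, dbag))
  de <- a * (da - sum(a * da))
  if (!is.null(p$bag$A)) {
    dq <- as.vector(cache$Z %*% de)
    dZ <- tcrossprod(p$bag$q, de)
    dA <- tcrossprod(dZ, S)
    dS <- dS + crossprod(p$bag$A, dZ)
    bag_grads <- list(A = dA, q = dq)
  } else {
    dq <- as.vector(S %*% de)
    dS <- dS + tcrossprod(p$bag$q, de)
    bag_grads <- list(q = dq)
  }
  dW_watt <- p$watt$W * 0
  dw_watt <- p$watt$w * 0
  dHf <- rep(list(matrix(0, h, ns)), cache$Tmax)
  dHb <- rep(list(matrix(0, h, ns)), cache$Tmax)
  for (s in seq_len(ns)) {
    ab <- attend_backward(cache$watt_caches[[s]], dv = dS[, s])
    dW_watt <- dW_watt + ab$dW
    dw_watt <- dw_watt + ab$dw
    dHw <- ab$dH
    if (!is.null(cache$masks)) dHw <- dHw * cache$masks[[s]]
    for (t in seq_len(lens[s])) {
      dHf[[t]][, s] <- dHw[, t]
      dHb[[lens[s] - t + 1L]][, s] <- dHw[, t]
    }
  }
  gf <- lstm_backward(cache$fwd, dHf)
  gb <- lstm_backward(cache$bwd, dHb)
  # embedding-table gradients
  tabs <- c("word", "rel_root", "rel_e1", "rel_e2", "dep_tag")
  dtab <- lapply(p[tabs], function(m) m * 0)
  dims <- c(word = ncol(p$word), rel_root = ncol(p$rel_root),
            rel_e1 = ncol(p$rel_e1), rel_e2 = ncol(p$rel_e2),
            dep_tag = ncol(p$dep_tag))
  offs <- c(0, cumsum(unname(dims)))
  for (s in seq_len(ns)) {
    ids <- cache$sent_ids[[s]]
    for (t in seq_len(lens[s])) {
      dE <- gf$dX[[t]][, s] + gb$dX[[lens[s] - t + 1L]][, s]
      for (k in seq_along(tabs)) {
        rows <- (offs[k] + 1L):offs[k + 1L]
        i <- ids[tabs[k], t]
        dtab[[tabs[k]]][i, ] <- dtab[[tabs[k]]][i, ] + dE[rows]
      }
    }
  }
  list(grads = list(word = dtab$word, rel_root = dtab$rel_root,
                    rel_e1 = dtab$rel_e1, rel_e2 = dtab$rel_e2,
                    dep_tag = dtab$dep_tag,
                    lstm_f = list(Wx = gf$dWx, Wh = gf$dWh, b = gf$db),
                    lstm_b = list(Wx = gb$dWx, Wh = gb$dWh, b = gb$db),
                    watt = list(W = dW_watt, w = dw_watt),
                    bag = bag_grads,
                    W = dfc$dW, bw = dfc$db))
}

#' Encode one sentence with the Bi-LSTM and word attention
#'
#' Runs the forward LSTM over the token order and the backward LSTM over
#' the reversed order; per-step outputs are summed elementwise
#' (`hw_t = hf_t + hb_t`), then word-level attention pools the steps into
#' one sentence vector.
#'
#' @param embeddings `d x T` token embedding matrix ([embed_tokens()]).
#' @param encoder a [new_text_encoder()].
#' @return list with `hw` (`h x T`), `hf`, `hb`, `word_weights`
#'   (nonnegative, summing to 1) and `sentence_vector`.
#' @export
encode_sentence <- function(embeddings, encoder) {
  stopifnot(inherits(encoder, "text_encoder"))
  Tn <- ncol(embeddings)
  if (is.null(Tn) || Tn == 0L) stop("empty sentence", call. = FALSE)
  p <- encoder$params
  Xf <- lapply(seq_len(Tn), function(t) embeddings[, t, drop = FALSE])
  Xb <- lapply(seq_len(Tn), function(t) embeddings[, Tn - t + 1L, drop = FALSE])
  hf <- lstm_forward(Xf, p$lstm_f)$H
  hb <- lstm_forward(Xb, p$lstm_b)$H
  h <- encoder$hidden
  Hf <- matrix(0, h, Tn); Hb <- matrix(0, h, Tn)
  for (t in seq_len(Tn)) {
    Hf[, t] <- hf[[t]]
    Hb[, t] <- hb[[Tn - t + 1L]]
  }
  Hw <- Hf + Hb
  at <- attend_forward(Hw, p$watt$W, p$watt$w)
  list(hw = Hw, hf = Hf, hb = Hb, word_weights = at$alpha,
       sentence_vector = at$v)
}

#' Sentence-level (bag) attention over a drug's sentences
#'
#' Scores each sentence vector against a trainable query
#' (`e_i = q' A s_i`, or a plain dot product), normalizes the scores with a
#' softmax (`a_i = exp(e_i) / sum_j exp(e_j)`), pools the weighted
#' sentences, and projects to the text block dimension.
#'
#' @param sentence_vectors `h x n` matrix of sentence vectors.
#' @param encoder a [new_text_encoder()].
#' @return list with `weights` (`a_i`), `scores` (`e_i`), `pooled` (the
#'   weighted sentence sum) and `out` (the drug's text feature block).
#' @export
encode_bag <- function(sentence_vectors, encoder) {
  stopifnot(inherits(encoder, "text_encoder"))
  S <- as.matrix(sentence_vectors)
  if (ncol(S) < 1L) stop("bag needs at least one sentence", call. = FALSE)
  p <- encoder$params
  e <- if (!is.null(p$bag$A)) {
    as.vector(crossprod(p$bag$q, p$bag$A %*% S))
  } else {
    as.vector(crossprod(p$bag$q, S))
  }
  a <- softmax_vec(e)
  pooled <- as.vector(S %*% a)
  list(weights = a, scores = e, pooled = pooled,
       out = as.vector(p$W %*% pooled + p$bw))
}
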