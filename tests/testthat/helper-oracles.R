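# Independent brute-force oracles used to cross-check vectorized
# implementations.  Deliberately written as plain loops.

oracle_df_count <- function(drug, item) {
  items <- unique(item)
  df <- integer(length(items))
  for (k in seq_along(items)) {
    seen <- character()
    for (i in seq_along(item)) {
      if (item[i] == items[k] && !drug[i] %in% seen) seen <- c(seen, drug[i])
    }
    df[k] <- length(seen)
  }
  stats::setNames(df, items)
}

oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

oracle_aupr <- function(labels, scores) {
  # step integration over every distinct threshold, ties as one group
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  prev_rec <- 0
  area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / npos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Eqs-style attention by explicit loops
oracle_attend <- function(H, W, w) {
  dl <- nrow(H); m <- ncol(H)
  M <- matrix(0, dl, m)
  for (i in seq_len(dl)) for (j in seq_len(m)) {
    acc <- 0
    for (k in seq_len(dl)) acc <- acc + W[i, k] * H[k, j]
    M[i, j] <- tanh(acc)
  }
  s <- numeric(m)
  for (j in seq_len(m)) {
    acc <- 0
    for (i in seq_len(dl)) acc <- acc + w[i] * M[i, j]
    s[j] <- acc
  }
  es <- exp(s - max(s))
  a <- es / sum(es)
  v <- numeric(dl)
  for (i in seq_len(dl)) {
    for (j in seq_len(m)) v[i] <- v[i] + H[i, j] * a[j]
  }
  list(v = v, alpha = a)
}

# three-case node2vec rule by direct enumeration over an adjacency list
oracle_n2v <- function(adj, prev, cur, p, q) {
  nbrs <- adj[[cur]]
  w <- numeric(length(nbrs))
  for (i in seq_along(nbrs)) {
    x <- nbrs[i]
    w[i] <- if (x == prev) 1 / p
    else if (x %in% adj[[prev]]) 1
    else 1 / q
  }
  stats::setNames(w / sum(w), nbrs)
}

# dependency features by an explicit child/parent set traversal
oracle_dep_features <- function(tokens, heads, span1, span2) {
  n <- length(tokens)
  root <- which(heads == 0)
  rel_root <- character(n)
  for (i in seq_len(n)) {
    rel_root[i] <- if (i == root) "root_itself"
    else if (heads[i] == root) "child_of_root"
    else "other"
  }
  one <- function(span) {
    out <- character(n)
    for (i in seq_len(n)) {
      if (!is.null(span) && i >= span[1] && i <= span[2]) {
        out[i] <- "entity_itself"
      } else if (!is.null(span) && any(vapply(span[1]:span[2], function(j)
        heads[j] == i, logical(1)))) {
        out[i] <- "parent_of_entity"
      } else if (!is.null(span) && heads[i] >= span[1] && heads[i] <= span[2]) {
        out[i] <- "child_of_entity"
      } else {
        out[i] <- "other"
      }
    }
    out
  }
  list(relative_root = rel_root,
       relative_e1 = one(span1), relative_e2 = one(span2))
}

# random rooted dependency tree on n tokens (token i's head is one of the
# earlier tokens, token 1 is the root)
random_heads <- function(n) {
  if (n == 1) return(0L)
  c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
}

# random free tree as an edge data.frame over given node names
random_tree_edges <- function(nodes) {
  n <- length(nodes)
  parent <- integer(n - 1L)
  for (i in 2:n) parent[i - 1L] <- sample.int(i - 1L, 1L)
  data.frame(parent = nodes[parent], child = nodes[2:n],
             is_drug = FALSE, stringsAsFactors = FALSE)
}
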