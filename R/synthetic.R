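# Synthetic knowledge base with planted latent mechanism clusters: every
# input file of the pipeline (attribute tables, fingerprints, taxonomy,
# dependency-parsed descriptions, labeled pairs) is generated from a small
# generative model so each stage is testable without any external data.

#' Generator configuration
#'
#' Drugs are partitioned into `n_clusters` latent mechanism clusters.  Each
#' cluster owns a disjoint signature of `attrs_per_cluster` attributes per
#' family; a drug draws each signature attribute with probability
#' `1 - epsilon` and each off-signature attribute with probability
#' `epsilon`.  Fingerprints follow the same recipe over per-cluster bit
#' blocks.  The taxonomy is a balanced binary tree whose leaves are the
#' clusters; drugs attach to their cluster leaf.  Descriptions are template
#' sentences over the drug's own attribute tokens with mechanically built
#' dependency trees.  The DDI label of a pair is Bernoulli with
#' `P = sigmoid(beta0 + beta1 * shared_targets + beta2 * same_cluster)`;
#' similarity is the taxonomy kinship (1 same cluster, 0.5 sibling leaves,
#' 0 otherwise) plus Gaussian noise, clamped to \[0,1\].
#'
#' @param n_drugs,n_clusters cohort size and number of latent clusters
#'   (>= 2).
#' @param attrs_per_cluster signature attributes per cluster per family.
#' @param family_universe attribute universe size per family (default:
#'   exactly the disjoint signatures).
#' @param epsilon attribute noise rate in \[0, 0.5).
#' @param fingerprint_length fingerprint bits.
#' @param sentences_per_drug description sentences per drug.
#' @param n_pairs labeled pairs (half sampled within clusters, half across,
#'   emulating interaction-enriched curation).
#' @param ddi_beta coefficients `(beta0, beta1, beta2)` of the planted DDI
#'   rule.
#' @param sim_sigma similarity noise standard deviation (>= 0).
#' @param seed generator seed.
#' @return a `generator_config`.
#' @export
generator_config <- function(n_drugs = 200L, n_clusters = 8L,
                             attrs_per_cluster = 6L, family_universe = NULL,
                             epsilon = 0.05, fingerprint_length = 166L,
                             sentences_per_drug = 3L, n_pairs = 2000L,
                             ddi_beta = c(-3, 0.5, 4), sim_sigma = 0.1,
                             seed = 1L) {
  if (n_clusters < 2L) stop("n_clusters must be >= 2", call. = FALSE)
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must lie in [0, 0.5)", call. = FALSE)
  if (sim_sigma < 0) stop("sim_sigma must be >= 0", call. = FALSE)
  if (is.null(family_universe)) family_universe <- n_clusters * attrs_per_cluster
  if (n_clusters * attrs_per_cluster > family_universe) {
    stop("cluster signatures exceed the family universe", call. = FALSE)
  }
  if (n_clusters * floor(fingerprint_length / n_clusters) < n_clusters) {
    stop("fingerprint too short for one bit per cluster", call. = FALSE)
  }
  structure(list(n_drugs = as.integer(n_drugs),
                 n_clusters = as.integer(n_clusters),
                 attrs_per_cluster = as.integer(attrs_per_cluster),
                 family_universe = as.integer(family_universe),
                 epsilon = epsilon,
                 fingerprint_length = as.integer(fingerprint_length),
                 sentences_per_drug = as.integer(sentences_per_drug),
                 n_pairs = as.integer(n_pairs),
                 ddi_beta = as.numeric(ddi_beta),
                 sim_sigma = sim_sigma, seed = as.integer(seed)),
            class = "generator_config")
}

# balanced binary split of the cluster leaves
build_cluster_taxonomy <- function(n_clusters) {
  ctr <- 0L
  edges <- list()
  split_rec <- function(ids, parent) {
    if (length(ids) == 1L) {
      edges[[length(edges) + 1L]] <<- c(parent, paste0("L", ids), "class")
      return(invisible(NULL))
    }
    ctr <<- ctr + 1L
    me <- paste0("N", ctr)
    edges[[length(edges) + 1L]] <<- c(parent, me, "class")
    h <- ceiling(length(ids) / 2)
    split_rec(ids[seq_len(h)], me)
    split_rec(ids[(h + 1L):length(ids)], me)
  }
  h <- ceiling(n_clusters / 2)
  ids <- seq_len(n_clusters)
  split_rec(ids[seq_len(h)], "ROOT")
  split_rec(ids[(h + 1L):n_clusters], "ROOT")
  e <- do.call(rbind, edges)
  data.frame(parent = e[, 1], child = e[, 2],
             is_drug = FALSE, stringsAsFactors = FALSE)
}

sentence_templates <- function(drug_id, se_tok, tg_tok, fo_tok, pe_tok) {
  list(
    {
      s <- parsed_sentence(
        tokens = c(drug_id, "binds", tg_tok, "and", "causes", se_tok),
        heads = c(2L, 0L, 2L, 5L, 2L, 5L),
        dep_tags = c("nsubj", "root", "obj", "cc", "conj", "obj"),
        entity1 = c(1L, 1L), entity2 = c(3L, 3L))
      attr(s, "drug_id") <- drug_id
      s
    },
    {
      s <- parsed_sentence(
        tokens = c(drug_id, "is", "supplied", "as", fo_tok),
        heads = c(3L, 3L, 0L, 5L, 3L),
        dep_tags = c("nsubj", "aux", "root", "case", "obl"),
        entity1 = c(1L, 1L), entity2 = NULL)
      attr(s, "drug_id") <- drug_id
      s
    },
    {
      s <- parsed_sentence(
        tokens = c(drug_id, "produces", pe_tok, "responses", "in", "patients"),
        heads = c(2L, 0L, 4L, 2L, 6L, 4L),
        dep_tags = c("nsubj", "root", "amod", "obj", "case", "nmod"),
        entity1 = c(1L, 1L), entity2 = c(3L, 3L))
      attr(s, "drug_id") <- drug_id
      s
    })
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes every input file the pipeline consumes (five attribute tables,
#' `fingerprints.tsv`, `taxonomy.tsv`, `descriptions.conllu`, `pairs.tsv`)
#' plus `latent.tsv` (the planted cluster assignment, for evaluation only)
#' and `manifest.tsv`.  Deterministic: the same config yields a
#' byte-identical directory.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if missing).
#' @return the dataset, re-read through [load_dataset()] (invisibly).
#' @export
generate <- function(config = generator_config(), out_dir) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_drugs
  k <- config$n_clusters
  ids <- sprintf("D%03d", seq_len(n))
  cluster <- rep(seq_len(k), length.out = n)
  eps <- config$epsilon
  sig <- config$attrs_per_cluster
  uni <- config$family_universe

  prefixes <- c(side_effect = "se", drug_action = "da",
                physiological_effect = "pe", formulation = "fo",
                target = "tg")
  items <- lapply(prefixes, function(p) sprintf("%s%03d", p, seq_len(uni)))
  sig_ix <- lapply(seq_len(k), function(c) ((c - 1L) * sig + 1L):(c * sig))

  attributes <- list()
  for (fam in names(prefixes)) {
    fam_items <- items[[fam]]
    attributes[[fam]] <- stats::setNames(lapply(seq_len(n), function(i) {
      p <- rep(eps, uni)
      p[sig_ix[[cluster[i]]]] <- 1 - eps
      fam_items[stats::runif(uni) < p]
    }), ids)
  }
  bits_per <- floor(config$fingerprint_length / k)
  fingerprints <- stats::setNames(lapply(seq_len(n), function(i) {
    p <- rep(eps, config$fingerprint_length)
    blk <- ((cluster[i] - 1L) * bits_per + 1L):(cluster[i] * bits_per)
    p[blk] <- 1 - eps
    which(stats::runif(config$fingerprint_length) < p) - 1L
  }), ids)

  tax_edges <- build_cluster_taxonomy(k)
  tax_edges <- rbind(tax_edges,
                     data.frame(parent = paste0("L", cluster), child = ids,
                                is_drug = TRUE, stringsAsFactors = FALSE))
  taxonomy <- taxonomy_graph(tax_edges)

  pick <- function(pool, fallback) {
    if (length(pool)) pool[sample.int(length(pool), 1L)] else fallback
  }
  sentences <- list()
  for (i in seq_len(n)) {
    csig <- sig_ix[[cluster[i]]]
    tmpl <- sentence_templates(
      ids[i],
      se_tok = pick(attributes$side_effect[[i]], items$side_effect[csig[1]]),
      tg_tok = pick(attributes$target[[i]], items$target[csig[1]]),
      fo_tok = pick(attributes$formulation[[i]], items$formulation[csig[1]]),
      pe_tok = pick(attributes$physiological_effect[[i]],
                    items$physiological_effect[csig[1]]))
    for (s in seq_len(config$sentences_per_drug)) {
      sentences[[length(sentences) + 1L]] <- tmpl[[(s - 1L) %% 3L + 1L]]
    }
  }

  # labeled pairs: half within clusters, half across (deduplicated)
  n_pairs <- config$n_pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  same_pool <- do.call(rbind, lapply(seq_len(k), function(c) {
    members <- which(cluster == c)
    if (length(members) < 2L) return(NULL)
    t(utils::combn(members, 2L))
  }))
  n_same <- min(nrow(same_pool), ceiling(n_pairs / 2))
  same_sel <- same_pool[sample.int(nrow(same_pool), n_same), , drop = FALSE]
  seen <- key(same_sel[, 1], same_sel[, 2])
  cross <- matrix(0L, 0L, 2L)
  while (nrow(cross) < n_pairs - n_same) {
    need <- n_pairs - n_same - nrow(cross)
    a <- sample.int(n, 2L * need + 10L, replace = TRUE)
    b <- sample.int(n, 2L * need + 10L, replace = TRUE)
    ok <- cluster[a] != cluster[b] & !duplicated(key(a, b)) &
      !key(a, b) %in% seen
    add <- cbind(a[ok], b[ok])
    if (nrow(add)) {
      add <- add[seq_len(min(nrow(add), need)), , drop = FALSE]
      cross <- rbind(cross, add)
      seen <- c(seen, key(add[, 1], add[, 2]))
    }
  }
  pm <- rbind(same_sel, cross)
  a <- pm[, 1]; b <- pm[, 2]
  shared_targets <- vapply(seq_len(nrow(pm)), function(r) {
    length(intersect(attributes$target[[a[r]]], attributes$target[[b[r]]]))
  }, numeric(1))
  same_cluster <- as.integer(cluster[a] == cluster[b])
  beta <- config$ddi_beta
  p_ddi <- stats::plogis(beta[1] + beta[2] * shared_targets + beta[3] * same_cluster)
  ddi <- stats::rbinom(nrow(pm), 1L, p_ddi)
  parent_of <- function(leaf) {
    e <- taxonomy$edges
    e$parent[!e$is_drug & e$child == leaf][1]
  }
  leaf_parent <- vapply(paste0("L", seq_len(k)), parent_of, character(1))
  kinship <- ifelse(same_cluster == 1L, 1,
                    ifelse(leaf_parent[cluster[a]] == leaf_parent[cluster[b]],
                           0.5, 0))
  similarity <- pmin(1, pmax(0, kinship + stats::rnorm(nrow(pm), 0, config$sim_sigma)))
  pairs <- data.frame(drug_a = ids[a], drug_b = ids[b], ddi = ddi,
                      similarity = round(similarity, 6),
                      stringsAsFactors = FALSE)

  for (fam in names(prefixes)) {
    write_attribute_table(attributes[[fam]], file.path(out_dir, paste0(fam, ".tsv")))
  }
  write_fingerprints(fingerprints, file.path(out_dir, "fingerprints.tsv"))
  write_taxonomy(taxonomy, file.path(out_dir, "taxonomy.tsv"))
  write_conllu(sentences, file.path(out_dir, "descriptions.conllu"))
  write_pairs(pairs, file.path(out_dir, "pairs.tsv"))
  utils::write.table(data.frame(drug_id = ids, cluster = cluster),
                     file.path(out_dir, "latent.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- data.frame(
    key = c("n_drugs", "n_clusters", "attrs_per_cluster", "family_universe",
            "epsilon", "fingerprint_length", "sentences_per_drug", "n_pairs",
            "sim_sigma", "seed"),
    value = c(n, k, sig, uni, eps, config$fingerprint_length,
              config$sentences_per_drug, n_pairs, config$sim_sigma,
              config$seed))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(load_dataset(out_dir))
}

#' The 10-drug worked micro-dataset
#'
#' A hand-sized noise-free dataset (10 drugs, 2 clusters) used by the
#' documentation and tests; a pre-generated copy ships under
#' `inst/extdata/worked_fixture/` and regenerating it is byte-identical.
#'
#' @param out_dir output directory.
#' @return the dataset (invisibly), as from [generate()].
#' @export
worked_fixture <- function(out_dir = file.path(tempdir(), "kmr_worked_fixture")) {
  generate(generator_config(n_drugs = 10L, n_clusters = 2L,
                            attrs_per_cluster = 3L, epsilon = 0,
                            fingerprint_length = 32L, sentences_per_drug = 2L,
                            n_pairs = 12L, sim_sigma = 0.05, seed = 42L),
           out_dir)
}
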