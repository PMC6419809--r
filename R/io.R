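# ---- domain types ---------------------------------------------------------

#' Attribute catalog
#'
#' Ordered universe of one pharmacological attribute family (e.g. side
#' effects) together with per-item document frequencies.  The item order
#' fixes vector positions for the whole life of a model, so it is frozen at
#' first appearance in the training table and preserved across save/load.
#'
#' @param family family name, one of `side_effect`, `drug_action`,
#'   `physiological_effect`, `formulation`, `target`.
#' @param items character vector of unique attribute tokens.
#' @param df integer vector, number of distinct drugs possessing each item.
#' @param n_drugs total number of drugs the catalog was built from.
#' @return an `attribute_catalog`.
#' @export
attribute_catalog <- function(family, items, df, n_drugs) {
  items <- as.character(items)
  df <- as.integer(df)
  n_drugs <- as.integer(n_drugs)
  if (anyDuplicated(items)) stop("catalog items must be unique", call. = FALSE)
  if (length(df) != length(items)) stop("df and items lengths differ", call. = FALSE)
  if (length(items) && (any(df < 0L) || any(df > n_drugs))) {
    stop("document frequencies must lie in [0, n_drugs]", call. = FALSE)
  }
  structure(list(family = family, items = items,
                 df = stats::setNames(df, items), n_drugs = n_drugs),
            class = "attribute_catalog")
}

#' Parsed sentence
#'
#' One dependency-parsed sentence: tokens, 1-based head indices (0 marks the
#' root), dependency labels, and up to two marked entity spans (1-based,
#' inclusive token ranges).
#'
#' @param tokens character vector of word forms.
#' @param heads integer vector, `heads[i]` is the index of token i's parent
#'   (0 for the root).
#' @param dep_tags character vector of dependency labels.
#' @param entity1,entity2 `c(start, end)` token ranges or `NULL`.
#' @return a `parsed_sentence`.
#' @export
parsed_sentence <- function(tokens, heads, dep_tags,
                            entity1 = NULL, entity2 = NULL) {
  n <- length(tokens)
  heads <- as.integer(heads)
  if (length(heads) != n || length(dep_tags) != n) {
    stop("tokens, heads and dep_tags must have equal length", call. = FALSE)
  }
  if (sum(heads == 0L) != 1L) {
    stop("dependency tree must have exactly one root", call. = FALSE)
  }
  if (any(heads < 0L) || any(heads > n)) stop("head index out of bounds", call. = FALSE)
  # cycle check: every token must reach the root
  for (i in seq_len(n)) {
    j <- i
    steps <- 0L
    while (heads[j] != 0L) {
      j <- heads[j]
      steps <- steps + 1L
      if (steps > n) stop("dependency heads contain a cycle", call. = FALSE)
    }
  }
  chk_span <- function(sp, nm) {
    if (is.null(sp)) return(NULL)
    sp <- as.integer(sp)
    if (length(sp) != 2L || sp[1] < 1L || sp[2] > n || sp[1] > sp[2]) {
      stop(nm, " span out of bounds", call. = FALSE)
    }
    sp
  }
  structure(list(tokens = as.character(tokens), heads = heads,
                 dep_tags = as.character(dep_tags),
                 entity1 = chk_span(entity1, "entity1"),
                 entity2 = chk_span(entity2, "entity2")),
            class = "parsed_sentence")
}

#' Taxonomy graph
#'
#' Rooted tree of chemical classes plus drug attachment nodes.  Class edges
#' must form a tree; every drug node has exactly one attachment edge to a
#' class node.
#'
#' @param edges data.frame with columns `parent`, `child`, `is_drug`
#'   (logical: is the child a drug attachment).
#' @return a `taxonomy_graph` with fields `nodes`, `class_nodes`,
#'   `drug_nodes`, `edges`, `root`, `attach` (named vector drug -> class).
#' @export
taxonomy_graph <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("parent", "child", "is_drug") %in% names(edges)))
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  edges$is_drug <- as.logical(edges$is_drug)
  ce <- edges[!edges$is_drug, , drop = FALSE]
  de <- edges[edges$is_drug, , drop = FALSE]
  class_nodes <- unique(c(ce$parent, ce$child, de$parent))
  drug_nodes <- unique(de$child)
  if (length(bad <- intersect(class_nodes, drug_nodes))) {
    stop("node '", bad[1], "' used both as class and drug", call. = FALSE)
  }
  if (anyDuplicated(de$child)) {
    dup <- de$child[duplicated(de$child)][1]
    stop("drug node '", dup, "' has more than one attachment edge", call. = FALSE)
  }
  if (anyDuplicated(ce[c("parent", "child")])) stop("duplicate class edge", call. = FALSE)
  kids <- unique(ce$child)
  if (anyDuplicated(ce$child)) {
    dup <- ce$child[duplicated(ce$child)][1]
    stop("class node '", dup, "' has more than one parent", call. = FALSE)
  }
  roots <- setdiff(class_nodes, kids)
  if (length(roots) != 1L) {
    stop("taxonomy must have exactly one root, found: ",
         paste(roots, collapse = ", "), call. = FALSE)
  }
  # connectivity / acyclicity: BFS from root must reach every class node
  adj <- split(ce$child, ce$parent)
  seen <- roots
  frontier <- roots
  while (length(frontier)) {
    nxt <- unlist(adj[frontier], use.names = FALSE)
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (length(miss <- setdiff(class_nodes, seen))) {
    stop("class node '", miss[1], "' is disconnected from the root (cycle?)",
         call. = FALSE)
  }
  if (nrow(ce) != length(class_nodes) - 1L) {
    stop("class edges do not form a tree (|edges| != |nodes| - 1)", call. = FALSE)
  }
  structure(list(nodes = c(class_nodes, drug_nodes),
                 class_nodes = class_nodes, drug_nodes = drug_nodes,
                 edges = edges, root = roots,
                 attach = stats::setNames(de$parent, de$child)),
            class = "taxonomy_graph")
}

#' Drug record
#'
#' One drug's identity and inputs: attribute sets per family, fingerprint
#' bit indices, taxonomy leaf, and parsed description sentences.
#'
#' @param drug_id drug identifier.
#' @param attributes named list family -> character vector of attribute
#'   tokens.
#' @param fingerprint integer vector of set bit indices (0-based).
#' @param class_leaf taxonomy node the drug attaches to.
#' @param sentences list of [parsed_sentence()].
#' @return a `drug_record`.
#' @export
drug_record <- function(drug_id, attributes = list(), fingerprint = integer(),
                        class_leaf = NA_character_, sentences = list()) {
  structure(list(drug_id = as.character(drug_id),
                 attributes = lapply(attributes, as.character),
                 fingerprint = sort(unique(as.integer(fingerprint))),
                 class_leaf = as.character(class_leaf),
                 sentences = sentences),
            class = "drug_record")
}

#' Names of the pharmacological attribute families, in canonical order
#' @export
kmr_families <- function() {
  c("side_effect", "drug_action", "physiological_effect", "formulation", "target")
}

# ---- attribute tables -----------------------------------------------------

#' Read / write a drug-attribute table
#'
#' Tab-separated file with two columns, `drug_id` and attribute token, one
#' pair per line.  Reading also builds the family's [attribute_catalog()]:
#' document frequencies count *distinct* drugs per item and item order is
#' first appearance.
#'
#' @param path file path.
#' @param family family name stored in the catalog.
#' @return `read_attribute_table()`: list with `attributes` (named list
#'   drug_id -> character vector) and `catalog`.
#' @export
read_attribute_table <- function(path, family) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(list(attributes = stats::setNames(list(), character()),
                catalog = attribute_catalog(family, character(), integer(), 0L)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed attribute line ", lineno[bad[1]], " in ", path,
         ": expected 2 tab-separated fields", call. = FALSE)
  }
  drug <- vapply(parts, `[[`, character(1), 1L)
  item <- vapply(parts, `[[`, character(1), 2L)
  dup <- duplicated(paste0(drug, "\r", item))
  drug <- drug[!dup]
  item <- item[!dup]
  attributes <- split(item, factor(drug, levels = unique(drug)))
  items <- unique(item)
  df <- vapply(split(drug, factor(item, levels = items)),
               function(d) length(unique(d)), integer(1))
  list(attributes = attributes,
       catalog = attribute_catalog(family, items, df, length(attributes)))
}

#' @rdname read_attribute_table
#' @param attributes named list drug_id -> attribute tokens.
#' @export
write_attribute_table <- function(attributes, path) {
  drug <- rep(names(attributes), lengths(attributes))
  item <- unlist(attributes, use.names = FALSE)
  writeLines(paste(drug, item, sep = "\t"), path)
  invisible(path)
}

#' Read / write an attribute catalog
#'
#' One `item<TAB>df` line per item in frozen catalog order; the family name
#' and drug count travel in `#`-comment header lines.
#'
#' @param path file path.
#' @return `read_catalog()` returns an [attribute_catalog()].
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  get_meta <- function(key) {
    m <- sub(paste0("^#\\s*", key, "\\s*=\\s*"), "", meta[grepl(paste0("^#\\s*", key, "\\b"), meta)])
    if (!length(m)) stop("catalog file missing '# ", key, " =' header", call. = FALSE)
    trimws(m[1])
  }
  family <- get_meta("family")
  n_drugs <- as.integer(get_meta("n_drugs"))
  if (!length(body)) return(attribute_catalog(family, character(), integer(), n_drugs))
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed catalog line", call. = FALSE)
  attribute_catalog(family,
                    vapply(parts, `[[`, character(1), 1L),
                    as.integer(vapply(parts, `[[`, character(1), 2L)),
                    n_drugs)
}

#' @rdname read_catalog
#' @param catalog an [attribute_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "attribute_catalog"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# family = ", catalog$family),
               paste0("# n_drugs = ", catalog$n_drugs)), con)
  if (length(catalog$items)) {
    writeLines(paste(catalog$items, unname(catalog$df), sep = "\t"), con)
  }
  invisible(path)
}

# ---- fingerprints ---------------------------------------------------------

#' Read / write substructure fingerprints
#'
#' Format: `drug_id<TAB>comma-separated bit indices` (0-based); an empty
#' second field is an all-zero fingerprint.
#'
#' @param path file path.
#' @param fingerprint_length total number of bits; indices must be smaller.
#' @return `read_fingerprints()`: named list drug_id -> integer vector.
#' @export
read_fingerprints <- function(path, fingerprint_length) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (!length(kv) %in% c(1L, 2L)) stop("malformed fingerprint line ", i, call. = FALSE)
    bits <- if (length(kv) == 2L && nzchar(kv[2])) {
      as.integer(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    } else integer()
    if (anyNA(bits)) stop("non-integer bit index on fingerprint line ", i, call. = FALSE)
    if (length(bits) && any(bits < 0L | bits >= fingerprint_length)) {
      stop("fingerprint bit index out of range on line ", i, call. = FALSE)
    }
    out[[kv[1]]] <- sort(unique(bits))
  }
  out
}

#' @rdname read_fingerprints
#' @param fingerprints named list drug_id -> integer bit indices.
#' @export
write_fingerprints <- function(fingerprints, path) {
  writeLines(paste0(names(fingerprints), "\t",
                    vapply(fingerprints, function(b) paste(b, collapse = ","),
                           character(1))),
             path)
  invisible(path)
}

# ---- taxonomy -------------------------------------------------------------

#' Read / write a drug-class taxonomy
#'
#' Edge-list TSV: `parent<TAB>child` for class edges, with a third column
#' `drug` flagging drug attachment edges.
#'
#' @param path file path.
#' @return `read_taxonomy()` returns a [taxonomy_graph()].
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(!lengths(parts) %in% c(2L, 3L))) {
    stop("malformed taxonomy line ", which(!lengths(parts) %in% c(2L, 3L))[1],
         call. = FALSE)
  }
  taxonomy_graph(data.frame(
    parent = vapply(parts, `[[`, character(1), 1L),
    child = vapply(parts, `[[`, character(1), 2L),
    is_drug = vapply(parts, function(p) length(p) == 3L && p[[3]] == "drug",
                     logical(1)),
    stringsAsFactors = FALSE))
}

#' @rdname read_taxonomy
#' @param graph a [taxonomy_graph()].
#' @export
write_taxonomy <- function(graph, path) {
  stopifnot(inherits(graph, "taxonomy_graph"))
  e <- graph$edges
  writeLines(paste0(e$parent, "\t", e$child, ifelse(e$is_drug, "\tdrug", "")), path)
  invisible(path)
}

# ---- CoNLL-U --------------------------------------------------------------

#' Read / write dependency parses in CoNLL-U
#'
#' Ten tab-separated columns per token; HEAD is 1-based with 0 = root, which
#' is also the internal convention.  Entity spans are carried in the MISC
#' column as `Ent=1` / `Ent=2`; a `# drug_id = X` comment before a sentence
#' associates it with a drug.  Sentences longer than `max_length` tokens are
#' truncated to the first `max_length` tokens (with a warning); a sentence
#' whose root or entity span falls outside the truncation is dropped with a
#' warning.
#'
#' @param path file path.
#' @param max_length maximum tokens per sentence (default 100).
#' @return `read_conllu()`: list of [parsed_sentence()]; each element may
#'   carry a `drug_id` attribute.
#' @export
read_conllu <- function(path, max_length = 100L) {
  lines <- c(readLines(path), "")
  sentences <- list()
  tok <- list()
  drug_id <- NA_character_
  sent_idx <- 0L
  flush <- function() {
    if (!length(tok)) return(NULL)
    sent_idx <<- sent_idx + 1L
    form <- vapply(tok, `[[`, character(1), "form")
    head <- vapply(tok, `[[`, character(1), "head")
    dep <- vapply(tok, `[[`, character(1), "dep")
    misc <- vapply(tok, `[[`, character(1), "misc")
    headi <- suppressWarnings(as.integer(head))
    if (anyNA(headi)) {
      stop("non-integer HEAD in sentence ", sent_idx, " of ", path, call. = FALSE)
    }
    n <- length(form)
    if (n > max_length) {
      warning("sentence ", sent_idx, " truncated from ", n, " to ",
              max_length, " tokens", call. = FALSE)
      keep <- seq_len(max_length)
      ent_tok <- grepl("Ent=", misc, fixed = TRUE)
      if (any(which(ent_tok) > max_length)) {
        warning("sentence ", sent_idx,
                " dropped: entity span outside truncation", call. = FALSE)
        return(NULL)
      }
      form <- form[keep]; headi <- headi[keep]; dep <- dep[keep]; misc <- misc[keep]
      root <- which(headi == 0L)
      if (!length(root)) {
        warning("sentence ", sent_idx, " dropped: root outside truncation",
                call. = FALSE)
        return(NULL)
      }
      headi[headi > max_length] <- 0L
      # keep a single root: re-attach spurious roots to the first
      extra <- setdiff(which(headi == 0L), root[1])
      headi[extra] <- root[1]
      n <- max_length
    }
    span <- function(tag) {
      ix <- which(grepl(paste0("(^|\\|)Ent=", tag, "($|\\|)"), misc))
      if (!length(ix)) NULL else c(min(ix), max(ix))
    }
    s <- parsed_sentence(form, headi, dep, span("1"), span("2"))
    if (!is.na(drug_id)) attr(s, "drug_id") <- drug_id
    s
  }
  for (ln in lines) {
    if (grepl("^#", ln)) {
      if (grepl("^#\\s*drug_id\\s*=", ln)) {
        drug_id <- trimws(sub("^#\\s*drug_id\\s*=", "", ln))
      }
      next
    }
    if (!nzchar(trimws(ln))) {
      s <- flush()
      if (!is.null(s)) sentences[[length(sentences) + 1L]] <- s
      tok <- list()
      drug_id <- NA_character_
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 10L) {
      stop("CoNLL-U line does not have 10 columns: ", ln, call. = FALSE)
    }
    if (grepl("[-.]", f[1])) next  # multiword-token / empty nodes: skip
    tok[[length(tok) + 1L]] <- list(form = f[2], head = f[7], dep = f[8], misc = f[10])
  }
  sentences
}

#' @rdname read_conllu
#' @param sentences list of [parsed_sentence()], optionally carrying
#'   `drug_id` attributes.
#' @export
write_conllu <- function(sentences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sentences) {
    d <- attr(s, "drug_id")
    if (!is.null(d)) writeLines(paste0("# drug_id = ", d), con)
    n <- length(s$tokens)
    misc <- rep("_", n)
    if (!is.null(s$entity1)) misc[s$entity1[1]:s$entity1[2]] <- "Ent=1"
    if (!is.null(s$entity2)) {
      ix <- s$entity2[1]:s$entity2[2]
      misc[ix] <- ifelse(misc[ix] == "_", "Ent=2", paste0(misc[ix], "|Ent=2"))
    }
    writeLines(paste(seq_len(n), s$tokens, "_", "_", "_", "_",
                     s$heads, s$dep_tags, "_", misc, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---- pair labels ----------------------------------------------------------

#' Read / write labeled drug pairs
#'
#' TSV with header `drug_a drug_b ddi similarity`; `ddi` is 0/1/NA and
#' `similarity` a real in \[0,1\] or NA.  Every row must carry at least one
#' label and relate two distinct drugs.
#'
#' @param path file path.
#' @return `read_pairs()` returns a data.frame.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer", "numeric"))
  names(df) <- c("drug_a", "drug_b", "ddi", "similarity")
  validate_pairs(df)
}

validate_pairs <- function(df) {
  if (any(df$drug_a == df$drug_b)) {
    stop("pair with identical drugs: ", df$drug_a[df$drug_a == df$drug_b][1],
         call. = FALSE)
  }
  if (any(is.na(df$ddi) & is.na(df$similarity))) {
    stop("pair without any label", call. = FALSE)
  }
  if (any(!is.na(df$ddi) & !df$ddi %in% c(0L, 1L))) stop("ddi must be 0/1/NA", call. = FALSE)
  if (any(!is.na(df$similarity) & (df$similarity < 0 | df$similarity > 1))) {
    stop("similarity must lie in [0,1]", call. = FALSE)
  }
  df
}

#' @rdname read_pairs
#' @param pairs data.frame with columns `drug_a`, `drug_b`, `ddi`,
#'   `similarity`.
#' @export
write_pairs <- function(pairs, path) {
  validate_pairs(pairs)
  out <- data.frame(drug_a = pairs$drug_a, drug_b = pairs$drug_b,
                    ddi = pairs$ddi,
                    similarity = ifelse(is.na(pairs$similarity), NA,
                                        sprintf("%.6f", pairs$similarity)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# ---- embeddings -----------------------------------------------------------

#' Read / write embedding tables
#'
#' TSV, one row per id: `id<TAB>v1<TAB>v2...`.
#'
#' @param path file path.
#' @return `read_embeddings()`: numeric matrix with ids as rownames.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1]))
  m <- do.call(rbind, vals)
  rownames(m) <- ids
  m
}

#' @rdname read_embeddings
#' @param embeddings numeric matrix with ids as rownames.
#' @export
write_embeddings <- function(embeddings, path) {
  writeLines(paste(rownames(embeddings),
                   apply(embeddings, 1L, function(v)
                     paste(sprintf("%.10g", v), collapse = "\t")),
                   sep = "\t"),
             path)
  invisible(path)
}

# ---- dataset assembly -----------------------------------------------------

#' Load a complete dataset directory
#'
#' Reads every file the synthetic generator (or an equivalent extraction)
#' emits: the five attribute tables, fingerprints, taxonomy, CoNLL-U
#' descriptions, labeled pairs, and the manifest.
#'
#' @param dir dataset directory.
#' @param max_sentence_length forwarded to [read_conllu()].
#' @return a `kmr_dataset`: list with `drugs` (named list of
#'   [drug_record()]), `catalogs`, `fingerprint_length`, `taxonomy`,
#'   `pairs`, and (when present) the generator's `latent` cluster table.
#' @export
load_dataset <- function(dir, max_sentence_length = 100L) {
  manifest_path <- file.path(dir, "manifest.tsv")
  manifest <- if (file.exists(manifest_path)) {
    m <- utils::read.table(manifest_path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
    stats::setNames(m[[2]], m[[1]])
  } else c()
  fp_len <- as.integer(manifest["fingerprint_length"])
  if (is.na(fp_len)) fp_len <- 166L

  atts <- list(); cats <- list()
  for (fam in kmr_families()) {
    r <- read_attribute_table(file.path(dir, paste0(fam, ".tsv")), fam)
    atts[[fam]] <- r$attributes
    cats[[fam]] <- r$catalog
  }
  fps <- read_fingerprints(file.path(dir, "fingerprints.tsv"), fp_len)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  sents <- read_conllu(file.path(dir, "descriptions.conllu"), max_sentence_length)
  pairs <- read_pairs(file.path(dir, "pairs.tsv"))

  by_drug <- split(sents, vapply(sents, function(s) {
    d <- attr(s, "drug_id")
    if (is.null(d)) NA_character_ else d
  }, character(1)))

  ids <- names(fps)
  drugs <- lapply(ids, function(id) {
    drug_record(id,
                attributes = lapply(atts, function(a) {
                  v <- a[[id]]
                  if (is.null(v)) character() else v
                }),
                fingerprint = fps[[id]],
                class_leaf = unname(tax$attach[id]),
                sentences = if (is.null(by_drug[[id]])) list() else by_drug[[id]])
  })
  names(drugs) <- ids

  bad <- ids[!ids %in% tax$drug_nodes]
  if (length(bad)) stop("drug '", bad[1], "' missing from the taxonomy", call. = FALSE)

  latent_path <- file.path(dir, "latent.tsv")
  latent <- if (file.exists(latent_path)) {
    utils::read.table(latent_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL

  structure(list(drugs = drugs, catalogs = cats, fingerprint_length = fp_len,
                 taxonomy = tax, pairs = pairs, latent = latent,
                 manifest = manifest),
            class = "kmr_dataset")
}

#' @export
print.kmr_dataset <- function(x, ...) {
  cat("<kmr_dataset> ", length(x$drugs), " drugs, ",
      nrow(x$pairs), " labeled pairs, ",
      length(x$taxonomy$class_nodes), " taxonomy classes\n", sep = "")
  invisible(x)
}
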