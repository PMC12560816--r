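#' Construct a knowledge graph from integer-encoded triples
#'
#' A `knowledge_graph` is the container used throughout the package: a set of
#' directed labelled edges (head, relation, tail) over a fixed entity and
#' relation vocabulary, with optional per-entity types (e.g. gene, drug,
#' disease) and optional train/valid/test split tags.
#'
#' Entity and relation ids are 1-based contiguous integers indexing the
#' `entities` and `relations` label vectors.
#'
#' @param triples data.frame with integer columns `head`, `relation`, `tail`.
#' @param entities character vector of entity labels; `entities[i]` is the
#'   label of entity id `i`.
#' @param relations character vector of relation labels.
#' @param entity_types optional character vector, one type label per entity.
#' @param split optional factor/character of length `nrow(triples)` with
#'   values in `train`, `valid`, `test`.
#' @return An object of class `knowledge_graph`: a list with elements
#'   `triples`, `entities`, `relations`, `entity_types`, `split`.
#' @examples
#' g <- knowledge_graph(
#'   data.frame(head = c(1L, 2L), relation = c(1L, 1L), tail = c(2L, 1L)),
#'   entities = c("A", "B"), relations = c("r1")
#' )
#' g
#' @export
knowledge_graph <- function(triples, entities, relations,
                            entity_types = NULL, split = NULL) {
  triples <- as.data.frame(triples)
  stopifnot(all(c("head", "relation", "tail") %in% names(triples)))
  triples <- data.frame(
    head = as.integer(triples$head),
    relation = as.integer(triples$relation),
    tail = as.integer(triples$tail)
  )
  n_e <- length(entities)
  n_r <- length(relations)
  if (n_e == 0L || anyDuplicated(entities))
    stop_kg("entity labels must be non-empty and unique")
  if (n_r == 0L || anyDuplicated(relations))
    stop_kg("relation labels must be non-empty and unique")
  if (as.numeric(n_e)^2 * n_r >= 2^53)
    stop_kg("graph too large for exact double-valued triple keys")
  if (nrow(triples) > 0) {
    if (min(triples$head, triples$tail) < 1L || max(triples$head, triples$tail) > n_e)
      stop_kg("entity id out of range 1..%d", n_e)
    if (min(triples$relation) < 1L || max(triples$relation) > n_r)
      stop_kg("relation id out of range 1..%d", n_r)
    keys <- triple_key(triples$head, triples$relation, triples$tail, n_e, n_r)
    if (anyDuplicated(keys))
      stop_kg("duplicate (head, relation, tail) triples are not allowed")
  }
  if (!is.null(split)) {
    split <- factor(as.character(split), levels = c("train", "valid", "test"))
    if (length(split) != nrow(triples) || anyNA(split))
      stop_kg("split must tag every triple as train/valid/test")
  }
  if (!is.null(entity_types)) {
    entity_types <- as.character(entity_types)
    if (length(entity_types) != n_e || anyNA(entity_types))
      stop_kg("entity_types must give exactly one type per entity")
  }
  structure(
    list(triples = triples, entities = entities, relations = relations,
         entity_types = entity_types, split = split),
    class = "knowledge_graph"
  )
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("Knowledge graph: %d triples, %d entities, %d relations\n",
              nrow(x$triples), length(x$entities), length(x$relations)))
  if (!is.null(x$entity_types))
    cat("Entity types:", paste(names(table(x$entity_types)), collapse = ", "), "\n")
  if (!is.null(x$split)) {
    tb <- table(x$split)
    cat(sprintf("Splits: train %d / valid %d / test %d\n",
                tb[["train"]], tb[["valid"]], tb[["test"]]))
  }
  invisible(x)
}

n_triples <- function(g) nrow(g$triples)

kg_triple_keys <- function(g, triples = g$triples) {
  triple_key(triples$head, triples$relation, triples$tail,
             length(g$entities), length(g$relations))
}

#' Extract one split of a knowledge graph
#'
#' Returns a graph containing only the triples tagged with `split`, keeping
#' the full entity/relation vocabulary (so ids remain comparable across
#' splits).
#'
#' @param g a `knowledge_graph` with split tags.
#' @param split one of `"train"`, `"valid"`, `"test"`.
#' @return A `knowledge_graph` without split tags.
#' @export
kg_split <- function(g, split = c("train", "valid", "test")) {
  split <- match.arg(split)
  if (is.null(g$split)) stop_kg("graph has no split tags")
  keep <- which(g$split == split)
  knowledge_graph(g$triples[keep, , drop = FALSE], g$entities, g$relations,
                  entity_types = g$entity_types)
}

#' Load a knowledge graph from a delimited triple file
#'
#' Each non-header line must contain at least three delimited fields, read as
#' head label, relation label, tail label (extra fields are ignored).
#' Vocabularies are built in first-appearance order (head before tail within
#' a line) unless `sorted_vocab = TRUE`. Duplicate lines are collapsed to a
#' single triple and the number of collapsed duplicates is reported via
#' [message()].
#'
#' @param path path to the triple file.
#' @param delimiter field delimiter (default tab); any run of whitespace when
#'   `delimiter = NULL`.
#' @param header logical; skip the first line.
#' @param sorted_vocab assign ids in sorted label order instead of
#'   first-appearance order (reproducible across shuffled files).
#' @param quiet suppress the duplicate-count message.
#' @return A `knowledge_graph`.
#' @seealso [load_kg()] for pre-split benchmark layouts,
#'   [load_entity_types()] to attach types.
#' @export
load_triples <- function(path, delimiter = "\t", header = FALSE,
                         sorted_vocab = FALSE, quiet = FALSE) {
  parsed <- parse_triple_file(path, delimiter, header)
  build_kg_from_labels(list(parsed), sorted_vocab = sorted_vocab,
                       quiet = quiet, source = basename(path))
}

parse_triple_file <- function(path, delimiter = "\t", header = FALSE) {
  if (!file.exists(path)) stop_kg("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  if (header && length(lines) >= 1L) {
    lines <- lines[-1L]
    offset <- 1L
  }
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) stop_kg("no triples in file: %s", path)
  fields <- if (is.null(delimiter)) strsplit(trimws(lines), "[ \t]+")
            else strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop_kg("parse error at line %d of %s: expected 3 fields, found %d",
            which(keep)[bad] + offset, path, nf[bad])
  }
  data.frame(
    head = vapply(fields, `[`, "", 1L),
    relation = vapply(fields, `[`, "", 2L),
    tail = vapply(fields, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

build_kg_from_labels <- function(parts, sorted_vocab = FALSE, quiet = FALSE,
                                 source = "input") {
  all_h <- unlist(lapply(parts, `[[`, "head"), use.names = FALSE)
  all_r <- unlist(lapply(parts, `[[`, "relation"), use.names = FALSE)
  all_t <- unlist(lapply(parts, `[[`, "tail"), use.names = FALSE)
  # first-appearance order interleaves head and tail per line
  ents <- unique(as.vector(rbind(all_h, all_t)))
  rels <- unique(all_r)
  if (sorted_vocab) {
    ents <- sort(ents)
    rels <- sort(rels)
  }
  h <- match(all_h, ents)
  r <- match(all_r, rels)
  t <- match(all_t, ents)
  keys <- triple_key(h, r, t, length(ents), length(rels))
  dup <- duplicated(keys)
  if (any(dup) && !quiet)
    message(sprintf("%s: collapsed %d duplicate triple line(s)",
                    source, sum(dup)))
  sizes <- vapply(parts, nrow, 0L)
  split <- NULL
  if (length(parts) > 1L)
    split <- rep(c("train", "valid", "test")[seq_along(parts)], sizes)[!dup]
  knowledge_graph(
    data.frame(head = h[!dup], relation = r[!dup], tail = t[!dup]),
    ents, rels, split = split
  )
}

#' Load a pre-split knowledge graph (one triple file per split)
#'
#' Benchmark graphs usually ship as separate train/valid/test files over a
#' shared vocabulary. Vocabularies are built across all files (train first).
#' Duplicate triples across files are collapsed, keeping the first split tag.
#'
#' @param train,valid,test paths to triple files; `valid`/`test` optional.
#' @inheritParams load_triples
#' @return A `knowledge_graph` with split tags (when valid/test given).
#' @export
load_kg <- function(train, valid = NULL, test = NULL, delimiter = "\t",
                    header = FALSE, sorted_vocab = FALSE, quiet = FALSE) {
  paths <- c(train, valid, test)
  parts <- lapply(paths, parse_triple_file, delimiter = delimiter,
                  header = header)
  g <- build_kg_from_labels(parts, sorted_vocab = sorted_vocab, quiet = quiet,
                            source = basename(train))
  if (length(parts) == 1L) g$split <- NULL
  g
}

#' Attach entity types from a two-column delimited file
#'
#' The file maps entity label to type label. Entities of the graph that are
#' missing from the file receive type `"unknown"`; labels in the file that
#' are not in the graph are ignored.
#'
#' @param g a `knowledge_graph`.
#' @param path two-column file (entity label, type label).
#' @param delimiter field delimiter.
#' @return `g` with `entity_types` filled in.
#' @export
load_entity_types <- function(g, path, delimiter = "\t") {
  if (!file.exists(path)) stop_kg("file not found: %s", path)
  tab <- utils::read.table(path, sep = delimiter, header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("entity", "type"))
  types <- rep("unknown", length(g$entities))
  idx <- match(tab$entity, g$entities)
  ok <- !is.na(idx)
  types[idx[ok]] <- tab$type[ok]
  g$entity_types <- types
  g
}

#' Write a knowledge graph to delimited files
#'
#' Writes `triples.tsv` (or one file per split: `train.tsv`, `valid.tsv`,
#' `test.tsv`), vocabulary files `entities.tsv` / `relations.tsv`
#' (label, id), and `entity_types.tsv` when types are present.
#'
#' @param g a `knowledge_graph`.
#' @param dir output directory (created if missing).
#' @param delimiter field delimiter.
#' @return `dir`, invisibly.
#' @export
write_kg <- function(g, dir, delimiter = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- data.frame(
    head = g$entities[g$triples$head],
    relation = g$relations[g$triples$relation],
    tail = g$entities[g$triples$tail]
  )
  wr <- function(df, file) utils::write.table(
    df, file.path(dir, file), sep = delimiter, quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  if (is.null(g$split)) {
    wr(lab, "triples.tsv")
  } else {
    for (s in levels(g$split)) {
      rows <- which(g$split == s)
      if (length(rows)) wr(lab[rows, , drop = FALSE], paste0(s, ".tsv"))
    }
  }
  wr(data.frame(g$entities, seq_along(g$entities)), "entities.tsv")
  wr(data.frame(g$relations, seq_along(g$relations)), "relations.tsv")
  if (!is.null(g$entity_types))
    wr(data.frame(g$entities, g$entity_types), "entity_types.tsv")
  invisible(dir)
}

#' Remove reverse-duplicate triples
#'
#' Some graphs materialise every edge in both directions under the same
#' relation: for each triple (h, r, t) the reverse (t, r, h) is also present.
#' This keeps, for every such unordered pair with h != t, the occurrence that
#' comes first in triple order, and drops the other. Self-loops and pairs
#' linked by different relations are untouched. The operation is idempotent,
#' and afterwards no non-self-loop triple has its exact reverse in the graph
#' (i.e. the symmetric-pattern fraction is zero).
#'
#' @param g a `knowledge_graph`.
#' @param quiet suppress the removed-count message.
#' @return A `knowledge_graph` without reverse duplicates.
#' @export
remove_reverse_duplicates <- function(g, quiet = FALSE) {
  tr <- g$triples
  n_e <- length(g$entities)
  n_r <- length(g$relations)
  not_loop <- tr$head != tr$tail
  # canonical key: relation + unordered pair
  a <- pmin(tr$head, tr$tail)
  b <- pmax(tr$head, tr$tail)
  canon <- ((as.numeric(tr$relation) - 1) * n_e + (a - 1)) * n_e + b
  fwd <- triple_key(tr$head, tr$relation, tr$tail, n_e, n_r)
  rev <- triple_key(tr$tail, tr$relation, tr$head, n_e, n_r)
  has_rev <- not_loop & (rev %in% fwd)
  # among reverse pairs keep the first occurrence of each canonical key
  drop <- has_rev & duplicated(canon)
  if (any(drop) && !quiet)
    message(sprintf("removed %d reverse-duplicate triple(s)", sum(drop)))
  knowledge_graph(tr[!drop, , drop = FALSE], g$entities, g$relations,
                  entity_types = g$entity_types,
                  split = if (!is.null(g$split)) g$split[!drop])
}

#' Randomly assign train/valid/test split tags
#'
#' Split sizes are the largest-remainder rounding of `fractions * n_triples`,
#' so they always sum to the number of triples. With `guarantee = TRUE`,
#' valid/test triples whose entities or relations never occur in train are
#' moved into train (the standard precaution against unseen vocabulary at
#' evaluation time); the resulting valid/test shortfall is reported.
#'
#' @param g a `knowledge_graph`.
#' @param fractions numeric length 3 (train, valid, test), positive, sum 1.
#' @param seed integer seed; same seed gives the identical assignment.
#' @param guarantee ensure every valid/test entity and relation occurs in
#'   train.
#' @param quiet suppress the shortfall message.
#' @return `g` with split tags.
#' @export
assign_splits <- function(g, fractions = c(0.8, 0.1, 0.1), seed = NULL,
                          guarantee = FALSE, quiet = FALSE) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions <= 0))
    stop_kg("fractions must be 3 positive numbers")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_kg("fractions must sum to 1 (got %.6f)", sum(fractions))
  n <- n_triples(g)
  sizes <- largest_remainder(fractions, n)
  tags <- local_seed(seed, {
    perm <- sample.int(n)
    out <- character(n)
    out[perm] <- rep(c("train", "valid", "test"), sizes)
    out
  })
  if (guarantee) {
    repeat {
      train_rows <- tags == "train"
      seen_e <- unique(c(g$triples$head[train_rows], g$triples$tail[train_rows]))
      seen_r <- unique(g$triples$relation[train_rows])
      bad <- !train_rows &
        (!(g$triples$head %in% seen_e) | !(g$triples$tail %in% seen_e) |
           !(g$triples$relation %in% seen_r))
      if (!any(bad)) break
      tags[bad] <- "train"
    }
    short <- sizes - c(sum(tags == "train"), sum(tags == "valid"),
                       sum(tags == "test"))
    if (!quiet && any(short != 0))
      message(sprintf(
        "moved %d triple(s) into train to cover vocabulary (valid short %d, test short %d)",
        -short[1], short[2], short[3]))
  }
  g$split <- factor(tags, levels = c("train", "valid", "test"))
  g
}

largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    ord <- order(raw - sizes, decreasing = TRUE)
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1
  }
  as.integer(sizes)
}
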