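#' Power-of-two degree bins
#'
#' Maps degree values to the bins \{1\}, \{2, 3\}, \{4..7\}, \{8..15\}, ...
#' (degree 0, possible for endpoints unseen in the reference graph, gets its
#' own bin). Returned as an ordered factor labelled `"1"`, `"2-3"`,
#' `"4-7"`, ...
#'
#' @param x non-negative integer degrees.
#' @return ordered factor of bin labels.
#' @export
degree_bin <- function(x) {
  stopifnot(all(x >= 0))
  e <- ifelse(x == 0, -1, floor(log2(pmax(x, 1))))
  lab <- ifelse(e < 0, "0",
                ifelse(e == 0, "1",
                       paste0(2^e, "-", 2^(e + 1) - 1)))
  all_e <- -1:max(0, e)
  levels <- ifelse(all_e < 0, "0",
                   ifelse(all_e == 0, "1",
                          paste0(2^all_e, "-", 2^(all_e + 1) - 1)))
  factor(lab, levels = levels, ordered = TRUE)
}

check_aligned <- function(results, topo) {
  if (nrow(results) != nrow(topo) ||
      !all(results$head == topo$head & results$relation == topo$relation &
             results$tail == topo$tail))
    stop_kg("results and topology tables are not aligned on the same triples")
}

group_metrics <- function(results, groups, ks) {
  idx <- split(seq_len(nrow(results)), groups, drop = TRUE)
  out <- lapply(names(idx), function(k) {
    m <- ranking_metrics(results[idx[[k]], , drop = FALSE], ks = ks)
    cbind(data.frame(group = k, n = m$n, mrr = m$mrr),
          as.data.frame(as.list(m$hits), check.names = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Stratified ranking metrics
#'
#' Computes MRR and Hits@K within groups of test triples defined by a
#' topological grouping schema: joint head/tail same-relation degree bins,
#' cardinality class, presence of one pattern flag, or a
#' counterpart-in-train flag. Per-group metrics are exactly
#' [ranking_metrics()] restricted to the group, so weighting group MRRs by
#' group sizes reproduces the global MRR.
#'
#' @param results `ranking_result` rows for the analysed test triples.
#' @param topo aligned [triple_topology()] rows for the same triples (for
#'   test triples, typically computed against the training graph).
#' @param schema `"degree"`, `"cardinality"`, `"pattern"` or
#'   `"counterpart"`.
#' @param pattern for `schema = "pattern"`, one of `is_symmetric`,
#'   `has_inference`, `has_inverse`, `has_composition`; for
#'   `schema = "counterpart"`, a column of `counterpart`.
#' @param counterpart for `schema = "counterpart"`, the flags from
#'   [counterpart_in_train()], aligned with `results`.
#' @param ks Hits@K cutoffs.
#' @return data.frame of class `stratified_metrics`: grouping columns plus
#'   `n`, `mrr` and the Hits columns.
#' @export
stratify <- function(results, topo = NULL,
                     schema = c("degree", "cardinality", "pattern",
                                "counterpart"),
                     pattern = "has_composition", counterpart = NULL,
                     ks = c(1, 10)) {
  schema <- match.arg(schema)
  if (schema != "counterpart") {
    if (is.null(topo)) stop_kg("topology table required for schema '%s'", schema)
    check_aligned(results, topo)
  }
  groups <- switch(schema,
    degree = paste(degree_bin(topo$deg_r_h), degree_bin(topo$deg_r_t),
                   sep = " x "),
    cardinality = as.character(topo$cardinality),
    pattern = {
      stopifnot(pattern %in% pattern_cols)
      ifelse(topo[[pattern]], paste0(pattern, "=TRUE"),
             paste0(pattern, "=FALSE"))
    },
    counterpart = {
      if (is.null(counterpart) || nrow(counterpart) != nrow(results))
        stop_kg("counterpart flags aligned with results are required")
      stopifnot(pattern %in% names(counterpart))
      ifelse(counterpart[[pattern]], paste0(pattern, "=TRUE"),
             paste0(pattern, "=FALSE"))
    })
  out <- group_metrics(results, groups, ks)
  class(out) <- c("stratified_metrics", "data.frame")
  out
}

#' Effect of one edge pattern on MRR within degree bins
#'
#' Within each (head-degree-bin, tail-degree-bin) cell (same-relation
#' degrees, power-of-two bins), the difference in MRR between triples with
#' and without the given pattern flag. Cells where either side is empty get
#' an `NA` delta.
#'
#' @inheritParams stratify
#' @param pattern one of the four flag columns.
#' @return data.frame: `hbin`, `tbin`, `n_with`, `n_without`, `mrr_with`,
#'   `mrr_without`, `delta` (with minus without).
#' @export
pattern_effect <- function(results, topo, pattern = "has_composition",
                           ks = c(1, 10)) {
  stopifnot(pattern %in% pattern_cols)
  check_aligned(results, topo)
  hb <- degree_bin(topo$deg_r_h)
  tb <- degree_bin(topo$deg_r_t)
  cells <- unique(data.frame(hbin = as.character(hb),
                             tbin = as.character(tb)))
  flag <- topo[[pattern]]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    in_cell <- as.character(hb) == cells$hbin[i] &
      as.character(tb) == cells$tbin[i]
    w <- which(in_cell & flag)
    wo <- which(in_cell & !flag)
    mw <- if (length(w)) mean(1 / results$rank[w]) else NA_real_
    mwo <- if (length(wo)) mean(1 / results$rank[wo]) else NA_real_
    data.frame(hbin = cells$hbin[i], tbin = cells$tbin[i],
               n_with = length(w), n_without = length(wo),
               mrr_with = mw, mrr_without = mwo,
               delta = if (length(w) && length(wo)) mw - mwo else NA_real_)
  })
  do.call(rbind, out)
}

#' Counterpart-in-train contrast
#'
#' For each of the symmetric, inverse and inference patterns, ranking
#' metrics for test triples whose counterpart edge was visible in training
#' versus those whose counterpart was not — the leakage-like contrast under
#' which prediction typically becomes much easier.
#'
#' @param results `ranking_result` rows.
#' @param counterpart flags from [counterpart_in_train()], aligned with
#'   `results`.
#' @param ks Hits@K cutoffs.
#' @return data.frame: `pattern`, `counterpart_in_train`, `n`, `mrr`, Hits
#'   columns (groups with no triples are reported with `n = 0` and `NA`
#'   metrics).
#' @export
counterpart_contrast <- function(results, counterpart, ks = c(1, 10)) {
  if (nrow(counterpart) != nrow(results))
    stop_kg("counterpart flags must align with results")
  out <- lapply(names(counterpart), function(p) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(v) {
      rows <- which(counterpart[[p]] == v)
      if (length(rows)) {
        m <- ranking_metrics(results[rows, , drop = FALSE], ks = ks)
        cbind(data.frame(pattern = p, counterpart_in_train = v, n = m$n,
                         mrr = m$mrr),
              as.data.frame(as.list(m$hits), check.names = FALSE))
      } else {
        hits <- as.data.frame(as.list(stats::setNames(
          rep(NA_real_, length(ks)), paste0("hits@", ks))),
          check.names = FALSE)
        cbind(data.frame(pattern = p, counterpart_in_train = v, n = 0L,
                         mrr = NA_real_), hits)
      }
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired case study over triples shared by two graphs
#'
#' Aligns two knowledge graphs by exact entity/relation label match, finds
#' the triples of the given relation present in both, extracts a seeded
#' fraction of them as a common test set, removes those test triples from
#' both graphs' edges, and builds the common candidate tail set (distinct
#' tails of all shared triples of the relation). Training each model on one
#' arm and evaluating both on the shared test set with the common candidates
#' isolates the effect of the additional edges in the larger graph.
#'
#' @param g1,g2 two `knowledge_graph`s (e.g. a graph and its superset).
#' @param relation relation label present in both graphs.
#' @param test_fraction fraction of shared triples held out (default 0.10).
#' @param seed integer seed for the test sample.
#' @return list of class `kg_case_study`: `train1`, `train2` (graphs with
#'   the test triples removed), `test1`, `test2` (the common test triples as
#'   id triples in each graph), `test_labels`, `candidates1`, `candidates2`
#'   (common candidate tail ids per graph), `n_shared`.
#' @export
case_study <- function(g1, g2, relation, test_fraction = 0.1, seed = NULL) {
  r1 <- match(relation, g1$relations)
  r2 <- match(relation, g2$relations)
  if (is.na(r1) || is.na(r2))
    stop_kg("relation '%s' must exist in both graphs", relation)

  lab <- function(g, rows) data.frame(
    head = g$entities[g$triples$head[rows]],
    tail = g$entities[g$triples$tail[rows]])
  rows1 <- which(g1$triples$relation == r1)
  rows2 <- which(g2$triples$relation == r2)
  l1 <- lab(g1, rows1)
  l2 <- lab(g2, rows2)
  k1 <- paste(l1$head, l1$tail, sep = "\r")
  k2 <- paste(l2$head, l2$tail, sep = "\r")
  shared1 <- rows1[k1 %in% k2]
  if (length(shared1) == 0L)
    stop_kg("no shared triples of relation '%s'", relation)
  shared_keys <- k1[k1 %in% k2]

  n_test <- max(1L, round(test_fraction * length(shared1)))
  test_rows1 <- local_seed(seed, sort(sample(shared1, n_test)))
  test_keys <- paste(g1$entities[g1$triples$head[test_rows1]],
                     g1$entities[g1$triples$tail[test_rows1]], sep = "\r")
  test_rows2 <- rows2[k2 %in% test_keys]

  drop_rows <- function(g, rows) knowledge_graph(
    g$triples[-rows, , drop = FALSE], g$entities, g$relations,
    entity_types = g$entity_types)

  test_labels <- data.frame(
    head = g1$entities[g1$triples$head[test_rows1]],
    relation = relation,
    tail = g1$entities[g1$triples$tail[test_rows1]])
  to_ids <- function(g, rid) data.frame(
    head = match(test_labels$head, g$entities),
    relation = rid,
    tail = match(test_labels$tail, g$entities))

  cand_labels <- unique(sub(".*\r", "", shared_keys))
  structure(list(
    train1 = drop_rows(g1, test_rows1),
    train2 = drop_rows(g2, test_rows2),
    test1 = to_ids(g1, r1),
    test2 = to_ids(g2, r2),
    test_labels = test_labels,
    candidates1 = match(cand_labels, g1$entities),
    candidates2 = match(cand_labels, g2$entities),
    n_shared = length(shared1),
    relation = relation
  ), class = "kg_case_study")
}

#' @export
print.kg_case_study <- function(x, ...) {
  cat(sprintf(
    "Case study on relation '%s': %d shared triples, %d held out, %d candidate tails\n",
    x$relation, x$n_shared, nrow(x$test_labels), length(x$candidates1)))
  invisible(x)
}
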