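#' Filtered tail-prediction ranks
#'
#' For every test triple (h, r, t), scores the query (h, r, ?) against the
#' candidate entities and computes the rank of the true tail t after masking
#' the scores of other tails t' known to be true, i.e. with (h, r, t') in
#' `filter_graph` (conventionally the union of all splits). The true tail
#' itself is never masked. Ties are resolved by the mean-rank rule by
#' default (the unbiased choice between the optimistic and pessimistic
#' conventions, both available for cross-library comparison).
#'
#' @param model a fitted [kge()] model.
#' @param test data.frame of test triples (`head`, `relation`, `tail`,
#'   integer ids) or a `knowledge_graph` (its `test` split if tagged, else
#'   all triples).
#' @param filter_graph `knowledge_graph` providing the known-true triples to
#'   mask (all of its splits are used).
#' @param candidates optional integer vector restricting the candidate tail
#'   set (must contain every true tail; default: all entities).
#' @param ties `"mean"`, `"optimistic"` or `"pessimistic"`.
#' @param filter set to `FALSE` for unfiltered (raw) ranks.
#' @return data.frame of class `ranking_result`, one row per test triple:
#'   `head`, `relation`, `tail`, `rank`, `n_candidates` (unmasked candidate
#'   count, including the true tail), `top1` (highest-scoring unmasked
#'   entity id) and, when entity types are known, `top1_type`.
#' @export
filtered_tail_ranks <- function(model, test, filter_graph, candidates = NULL,
                                ties = c("mean", "optimistic", "pessimistic"),
                                filter = TRUE) {
  ties <- match.arg(ties)
  tt <- ranking_test_triples(test)
  n_e <- length(filter_graph$entities)
  n_r <- length(filter_graph$relations)
  cand <- if (is.null(candidates)) seq_len(n_e) else
    unique(as.integer(candidates))

  tkeys <- triple_key(tt$head, tt$relation, tt$tail, n_e, n_r)
  fkeys <- kg_triple_keys(filter_graph)
  if (filter && !all(tkeys %in% fkeys))
    stop_kg("all test triples must be present in filter_graph")

  ftr <- filter_graph$triples
  hr_key <- (as.numeric(ftr$head) - 1) * n_r + as.numeric(ftr$relation)
  tails_by_hr <- split(ftr$tail, hr_key)

  n <- nrow(tt)
  rank <- numeric(n)
  n_cand <- integer(n)
  top1 <- integer(n)
  cand_pos <- match(seq_len(n_e), cand)  # entity id -> candidate index
  for (i in seq_len(n)) {
    h <- tt$head[i]; r <- tt$relation[i]; t <- tt$tail[i]
    ti <- cand_pos[t]
    if (is.na(ti))
      stop_kg("candidate set excludes the true tail of query %d", i)
    s <- score_tails(model, h, r, cand)
    masked <- logical(length(cand))
    if (filter) {
      known <- tails_by_hr[[as.character((h - 1) * n_r + r)]]
      mi <- cand_pos[setdiff(known, t)]
      masked[mi[!is.na(mi)]] <- TRUE
    }
    rk <- rank_from_scores(s, masked, ti, ties)
    rank[i] <- rk$rank
    n_cand[i] <- rk$n_candidates
    top1[i] <- cand[rk$top1_idx]
  }
  out <- data.frame(head = tt$head, relation = tt$relation, tail = tt$tail,
                    rank = rank, n_candidates = n_cand, top1 = top1)
  types <- model$entity_types %||% filter_graph$entity_types
  if (!is.null(types)) out$top1_type <- types[top1]
  class(out) <- c("ranking_result", "data.frame")
  out
}

# Rank of the true candidate among the unmasked scores. The true candidate
# (index true_idx) is never masked; ties with other unmasked candidates are
# resolved by the mean-rank rule (or optimistic/pessimistic variants).
rank_from_scores <- function(scores, masked, true_idx,
                             ties = c("mean", "optimistic", "pessimistic")) {
  ties <- match.arg(ties)
  if (masked[true_idx]) stop_kg("the true tail must not be masked")
  s_true <- scores[true_idx]
  su <- scores[!masked]
  greater <- sum(su > s_true)
  eq <- sum(su == s_true) - 1L  # other candidates tied with the truth
  s_top <- scores
  s_top[masked] <- -Inf
  list(
    rank = switch(ties,
      mean = greater + 1 + eq / 2,
      optimistic = greater + 1,
      pessimistic = greater + 1 + eq),
    n_candidates = length(su),
    top1_idx = which.max(s_top)
  )
}

ranking_test_triples <- function(test) {
  if (inherits(test, "knowledge_graph")) {
    if (!is.null(test$split)) kg_split(test, "test")$triples else test$triples
  } else as.data.frame(test)
}

#' Mean reciprocal rank and Hits@K
#'
#' MRR is the mean of 1/rank over queries; Hits@K the fraction of queries
#' ranked at or below K. Both are invariant under permutation of the result
#' rows.
#'
#' @param results a `ranking_result` (or any data.frame with a `rank`
#'   column).
#' @param ks cutoffs for Hits@K.
#' @return list with `mrr`, `hits` (named numeric vector), `n`.
#' @examples
#' ranking_metrics(data.frame(rank = c(1, 2, 4)), ks = c(1, 3))
#' @export
ranking_metrics <- function(results, ks = c(1, 3, 10)) {
  r <- results$rank
  if (length(r) == 0L) stop_kg("no ranking results")
  hits <- vapply(ks, function(k) mean(r <= k), 0)
  names(hits) <- paste0("hits@", ks)
  list(mrr = mean(1 / r), hits = hits, n = length(r))
}

#' Demixing rate: fraction of top predictions with the correct entity type
#'
#' A model demixes a relation well when it ranks entities of the relation's
#' target type above entities of other types. Measured here as the fraction
#' of queries whose top-1 filtered prediction carries `target_type`.
#'
#' @param results a `ranking_result` carrying `top1_type` (produced when the
#'   graph has entity types), or supply `graph` to look types up.
#' @param target_type the expected tail entity type.
#' @param graph optional `knowledge_graph` with `entity_types`.
#' @return fraction in \[0, 1\].
#' @export
demixing_rate <- function(results, target_type, graph = NULL) {
  types <- results$top1_type
  if (is.null(types) && !is.null(graph) && !is.null(graph$entity_types))
    types <- graph$entity_types[results$top1]
  if (is.null(types))
    stop_kg("entity types unavailable; evaluate on a typed graph or pass one")
  mean(types == target_type)
}

#' Candidate tail set from shared triples of one relation
#'
#' The deduplicated set of entities appearing as tails of the given
#' relation's shared triples — the common candidate set used when comparing
#' models trained on two graphs over the same test triples.
#'
#' @param shared_triples data.frame (`head`, `relation`, `tail`).
#' @param relation relation id to restrict to.
#' @return integer vector of distinct tail ids (in first appearance order).
#' @export
restricted_candidates <- function(shared_triples, relation) {
  tails <- shared_triples$tail[shared_triples$relation == relation]
  if (length(tails) == 0L)
    stop_kg("no shared triples for relation %s", relation)
  unique(tails)
}

#' Expected MRR of uniform-random ranking
#'
#' With n candidates and a uniformly random permutation, the expected
#' reciprocal rank of the truth is \eqn{(1/n) \sum_{k=1}^{n} 1/k} — the
#' closed-form baseline any trained model must beat.
#'
#' @param n candidate-set size(s); vectorized.
#' @return expected reciprocal rank for each `n`.
#' @examples
#' expected_random_mrr(c(2, 10, 100))
#' @export
expected_random_mrr <- function(n) {
  vapply(n, function(m) sum(1 / seq_len(m)) / m, 0)
}
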