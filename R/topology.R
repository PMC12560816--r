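#' Per-triple degree quantities
#'
#' For each triple (h, r, t), computes the four degree quantities used
#' throughout the package, all as *distinct-neighbour* set cardinalities over
#' the reference graph `g`:
#' \describe{
#'   \item{deg_h}{head out-degree: number of distinct tails reachable from h
#'     under any relation.}
#'   \item{deg_t}{tail in-degree: number of distinct heads pointing into t
#'     under any relation.}
#'   \item{deg_r_h}{head out-degree of the same relation type r.}
#'   \item{deg_r_t}{tail in-degree of the same relation type r.}
#' }
#' When `triples` are a subset of `g` every quantity is at least 1 and
#' `deg_h >= deg_r_h`, `deg_t >= deg_r_t`. When classifying held-out triples
#' against a training graph (the information the model saw), degrees of
#' unseen endpoints may be 0.
#'
#' @param g reference `knowledge_graph` supplying the edges to count over.
#' @param triples data.frame of triples to annotate (default: all of `g`).
#' @return data.frame with columns `deg_h`, `deg_t`, `deg_r_h`, `deg_r_t`.
#' @export
triple_degrees <- function(g, triples = g$triples) {
  if (n_triples(g) == 0L) stop_kg("graph is empty")
  tr <- g$triples
  n_e <- length(g$entities)
  n_r <- length(g$relations)

  pk <- pair_key(tr$head, tr$tail, n_e)
  first <- !duplicated(pk)
  deg_h_ent <- tabulate(tr$head[first], nbins = n_e)
  deg_t_ent <- tabulate(tr$tail[first], nbins = n_e)

  # triples are deduplicated, so counting rows per (h, r) counts distinct tails
  hr <- (as.numeric(tr$head) - 1) * n_r + as.numeric(tr$relation)
  rt <- (as.numeric(tr$tail) - 1) * n_r + as.numeric(tr$relation)
  hr_q <- (as.numeric(triples$head) - 1) * n_r + as.numeric(triples$relation)
  rt_q <- (as.numeric(triples$tail) - 1) * n_r + as.numeric(triples$relation)
  hr_tab <- table_by_key(hr)
  rt_tab <- table_by_key(rt)

  data.frame(
    deg_h = deg_h_ent[triples$head],
    deg_t = deg_t_ent[triples$tail],
    deg_r_h = lookup_count(hr_tab, hr_q),
    deg_r_t = lookup_count(rt_tab, rt_q)
  )
}

table_by_key <- function(keys) {
  u <- sort(unique(keys))
  list(keys = u, counts = tabulate(match(keys, u), nbins = length(u)))
}

lookup_count <- function(tab, q) {
  idx <- match(q, tab$keys)
  out <- integer(length(q))
  ok <- !is.na(idx)
  out[ok] <- tab$counts[idx[ok]]
  out
}

#' Edge cardinality class of a triple
#'
#' Classifies a triple by its same-relation degrees: with one tail per head
#' and one head per tail the edge is one-to-one; a head with several
#' same-relation tails but a tail with a single same-relation head is
#' one-to-many; the converse is many-to-one; several on both sides is
#' many-to-many. (The class is read tail-side:head-side, so `deg_r_h > 1`
#' with `deg_r_t = 1` is `"1:M"`.)
#'
#' @param deg_r_h,deg_r_t same-relation head out-degree and tail in-degree
#'   (vectors, each entry >= 1).
#' @return factor with levels `"1:1"`, `"1:M"`, `"M:1"`, `"M:M"`.
#' @examples
#' edge_cardinality(c(1, 2, 1, 2), c(1, 1, 3, 3))
#' @export
edge_cardinality <- function(deg_r_h, deg_r_t) {
  if (length(deg_r_h) != length(deg_r_t))
    stop_kg("degree vectors must have equal length")
  if (any(deg_r_h < 1) || any(deg_r_t < 1))
    stop_kg("same-relation degrees must be >= 1")
  out <- ifelse(deg_r_h == 1,
                ifelse(deg_r_t == 1, "1:1", "M:1"),
                ifelse(deg_r_t == 1, "1:M", "M:M"))
  factor(out, levels = c("1:1", "1:M", "M:1", "M:M"))
}

#' Detect the four edge topological patterns per triple
#'
#' For each triple (h, r, t) of `g`, tested against the edge set of
#' `pattern_graph` (default: `g` itself):
#' \describe{
#'   \item{is_symmetric}{h != t and the exact reverse (t, r, h) is present.}
#'   \item{has_inference}{some other relation r' != r links the same ordered
#'     pair (h, t).}
#'   \item{has_inverse}{some other relation r' != r links the reversed pair
#'     (t, h).}
#'   \item{has_composition}{a directed two-edge path h -> n -> t exists with
#'     intermediate n distinct from both h and t (any relations, which may
#'     equal r or each other).}
#' }
#' Composition is counted via the boolean product of the any-relation sparse
#' adjacency with itself, corrected for paths through h or t themselves, so
#' self-loops never create compositions. `n_comp_relpairs` is the number of
#' distinct ordered relation pairs (r1, r2) realised by valid intermediates.
#'
#' @param g `knowledge_graph` whose triples are classified.
#' @param pattern_graph `knowledge_graph` providing the edge set against
#'   which counterparts and paths are sought (e.g. the training split when
#'   classifying test triples).
#' @return data.frame with columns `head`, `relation`, `tail`,
#'   `is_symmetric`, `has_inference`, `has_inverse`, `has_composition`,
#'   `n_comp_intermediates`, `n_comp_relpairs`.
#' @export
detect_edge_patterns <- function(g, pattern_graph = g) {
  if (n_triples(g) == 0L) stop_kg("graph is empty")
  tr <- g$triples
  G <- pattern_graph$triples
  n_e <- length(g$entities)
  n_r <- length(g$relations)
  if (length(pattern_graph$entities) != n_e ||
      length(pattern_graph$relations) != n_r)
    stop_kg("g and pattern_graph must share vocabularies")

  Gkeys <- triple_key(G$head, G$relation, G$tail, n_e, n_r)
  in_G <- function(h, r, t) triple_key(h, r, t, n_e, n_r) %in% Gkeys

  is_symmetric <- tr$head != tr$tail & in_G(tr$tail, tr$relation, tr$head)

  # distinct relations per ordered pair of G (G is deduplicated)
  Gpairs <- pair_key(G$head, G$tail, n_e)
  pair_tab <- table_by_key(Gpairs)
  fwd_n <- lookup_count(pair_tab, pair_key(tr$head, tr$tail, n_e))
  rev_n <- lookup_count(pair_tab, pair_key(tr$tail, tr$head, n_e))
  has_inference <- (fwd_n - in_G(tr$head, tr$relation, tr$tail)) >= 1
  has_inverse <- (rev_n - in_G(tr$tail, tr$relation, tr$head)) >= 1

  comp <- composition_counts(tr, G, n_e)

  data.frame(
    head = tr$head, relation = tr$relation, tail = tr$tail,
    is_symmetric = is_symmetric,
    has_inference = has_inference,
    has_inverse = has_inverse,
    has_composition = comp$n_intermediates >= 1,
    n_comp_intermediates = comp$n_intermediates,
    n_comp_relpairs = comp$n_relpairs
  )
}

# Sparse two-path counting: A is the 0/1 any-relation adjacency, (A %*% A)[h,t]
# counts intermediates n with h->n->t; subtract paths through n = h or n = t.
composition_counts <- function(tr, G, n_e) {
  Gpairs <- unique(pair_key(G$head, G$tail, n_e))
  gh <- as.integer((Gpairs - 1) %/% n_e) + 1L
  gt <- as.integer((Gpairs - 1) %% n_e) + 1L
  A <- Matrix::sparseMatrix(i = gh, j = gt, x = 1, dims = c(n_e, n_e))
  AA <- A %*% A
  n_int <- as.numeric(AA[cbind(tr$head, tr$tail)])
  loop_h <- as.numeric(A[cbind(tr$head, tr$head)]) > 0
  loop_t <- as.numeric(A[cbind(tr$tail, tr$tail)]) > 0
  direct <- as.numeric(A[cbind(tr$head, tr$tail)]) > 0
  corr <- (loop_h & direct) + (tr$head != tr$tail) * (loop_t & direct)
  n_int <- as.integer(n_int - corr)

  n_relpairs <- integer(nrow(tr))
  idx <- which(n_int >= 1L)
  if (length(idx)) {
    out_by_head <- split(seq_len(nrow(G)), G$head)
    in_by_tail <- split(seq_len(nrow(G)), G$tail)
    hk <- as.character(tr$head[idx])
    tk <- as.character(tr$tail[idx])
    for (j in seq_along(idx)) {
      i <- idx[j]
      oe <- out_by_head[[hk[j]]]
      ie <- in_by_tail[[tk[j]]]
      paths <- merge(
        data.frame(n = G$tail[oe], r1 = G$relation[oe]),
        data.frame(n = G$head[ie], r2 = G$relation[ie]),
        by = "n"
      )
      paths <- paths[paths$n != tr$head[i] & paths$n != tr$tail[i], ]
      n_relpairs[i] <- nrow(unique(paths[c("r1", "r2")]))
    }
  }
  list(n_intermediates = n_int, n_relpairs = n_relpairs)
}

#' Full per-triple topology table
#'
#' Combines [triple_degrees()], [edge_cardinality()] and
#' [detect_edge_patterns()] into one record per triple: the four degree
#' quantities, the cardinality class, the four pattern flags and the
#' composition counts.
#'
#' @inheritParams detect_edge_patterns
#' @return data.frame of class `triple_topology`.
#' @export
triple_topology <- function(g, pattern_graph = g) {
  deg <- triple_degrees(pattern_graph, triples = g$triples)
  pat <- detect_edge_patterns(g, pattern_graph)
  out <- cbind(
    pat[c("head", "relation", "tail")], deg,
    cardinality = edge_cardinality(pmax(deg$deg_r_h, 1L),
                                   pmax(deg$deg_r_t, 1L)),
    pat[c("is_symmetric", "has_inference", "has_inverse", "has_composition",
          "n_comp_intermediates", "n_comp_relpairs")]
  )
  class(out) <- c("triple_topology", "data.frame")
  out
}

pattern_cols <- c("is_symmetric", "has_inference", "has_inverse",
                  "has_composition")

#' Pattern and cardinality census of a graph
#'
#' Fractions of triples carrying each of the four edge patterns, the
#' fraction with none of the four, and the fractions of the four cardinality
#' classes. A triple can satisfy several patterns at once, so pattern
#' fractions may sum above 1; cardinality fractions always sum to 1.
#'
#' @inheritParams detect_edge_patterns
#' @return list of class `pattern_summary` with elements
#'   `pattern_fractions` (named: symmetric, inference, inverse, composition,
#'   none), `cardinality_fractions`, `pattern_counts`, `n_triples`.
#' @export
pattern_summary <- function(g, pattern_graph = g) {
  if (n_triples(g) == 0L) stop_kg("graph is empty")
  topo <- triple_topology(g, pattern_graph)
  n <- nrow(topo)
  counts <- vapply(topo[pattern_cols], sum, 0L)
  none <- sum(!Reduce(`|`, topo[pattern_cols]))
  pf <- c(counts, none = none) / n
  names(pf) <- c("symmetric", "inference", "inverse", "composition", "none")
  structure(
    list(pattern_fractions = pf,
         cardinality_fractions = table(topo$cardinality) / n,
         pattern_counts = c(counts, none = none),
         n_triples = n),
    class = "pattern_summary"
  )
}

#' @export
print.pattern_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Pattern census over %d triples\n", x$n_triples))
  print(round(x$pattern_fractions, digits))
  cat("Cardinality:\n")
  print(round(as.numeric(x$cardinality_fractions), digits))
  invisible(x)
}

#' Composition metapath counts for one relation, by intermediate entity type
#'
#' For every triple of `focus_relation` that has a composition, enumerates
#' the directed two-paths h -> n -> t realising it and accumulates path
#' counts stratified by the entity type of the intermediate n and by the
#' ordered relation pair (r1, r2). Reports both path-instance counts and
#' distinct-intermediate counts per type, plus the number of distinct
#' relation pairs (the quantity annotated on metapath census bar charts).
#'
#' @param g `knowledge_graph` with `entity_types` set.
#' @param focus_relation relation label or id.
#' @param pattern_graph graph supplying the paths (default `g`).
#' @return list with `by_type` (data.frame: `intermediate_type`, `n_paths`,
#'   `n_intermediates`, `n_relpairs`), `relpairs` (data.frame keyed by type
#'   and relation pair), and `n_distinct_relpairs`.
#' @export
metapath_composition_counts <- function(g, focus_relation, pattern_graph = g) {
  if (is.null(g$entity_types))
    stop_kg("entity types are required; attach them with load_entity_types()")
  if (is.character(focus_relation)) {
    rid <- match(focus_relation, g$relations)
    if (is.na(rid)) stop_kg("unknown relation: %s", focus_relation)
  } else rid <- as.integer(focus_relation)

  focus <- g$triples[g$triples$relation == rid, , drop = FALSE]
  empty <- list(
    by_type = data.frame(intermediate_type = character(), n_paths = integer(),
                         n_intermediates = integer(), n_relpairs = integer()),
    relpairs = data.frame(intermediate_type = character(), r1 = character(),
                          r2 = character(), n_paths = integer()),
    n_distinct_relpairs = 0L
  )
  if (nrow(focus) == 0L) return(empty)

  G <- pattern_graph$triples
  out_by_head <- split(seq_len(nrow(G)), G$head)
  in_by_tail <- split(seq_len(nrow(G)), G$tail)
  paths <- vector("list", nrow(focus))
  for (i in seq_len(nrow(focus))) {
    h <- focus$head[i]; t <- focus$tail[i]
    oe <- out_by_head[[as.character(h)]]
    ie <- in_by_tail[[as.character(t)]]
    if (is.null(oe) || is.null(ie)) next
    p <- merge(data.frame(n = G$tail[oe], r1 = G$relation[oe]),
               data.frame(n = G$head[ie], r2 = G$relation[ie]), by = "n")
    p <- p[p$n != h & p$n != t, , drop = FALSE]
    if (nrow(p)) paths[[i]] <- p
  }
  paths <- do.call(rbind, paths)
  if (is.null(paths) || nrow(paths) == 0L) return(empty)

  paths$intermediate_type <- g$entity_types[paths$n]
  key <- paste(paths$intermediate_type, paths$r1, paths$r2, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  relpairs <- data.frame(
    intermediate_type = parts[, 1],
    r1 = g$relations[as.integer(parts[, 2])],
    r2 = g$relations[as.integer(parts[, 3])],
    n_paths = agg$Freq
  )
  by_type <- do.call(rbind, lapply(split(paths, paths$intermediate_type),
    function(p) data.frame(
      intermediate_type = p$intermediate_type[1],
      n_paths = nrow(p),
      n_intermediates = length(unique(p$n)),
      n_relpairs = nrow(unique(p[c("r1", "r2")]))
    )))
  rownames(by_type) <- NULL
  list(by_type = by_type[order(-by_type$n_paths), ],
       relpairs = relpairs,
       n_distinct_relpairs = nrow(unique(paths[c("r1", "r2")])))
}

#' Per-relation pattern fractions and predominant-pattern label
#'
#' Aggregates a per-triple topology table to relation level: for each
#' relation, the fraction of its triples carrying each pattern flag, and a
#' predominant label — the pattern whose fraction strictly exceeds
#' `majority_threshold` (the largest such, ties broken in the order
#' symmetric, inference, inverse, composition), `"none"` when the
#' none-of-the-four fraction exceeds it, otherwise `"mixed"`. Relations with
#' no triples are omitted.
#'
#' @param topo a `triple_topology` table.
#' @param majority_threshold fraction in (0.5, 1]; default 0.95.
#' @return data.frame, one row per relation present in `topo`.
#' @export
aggregate_by_relation <- function(topo, majority_threshold = 0.95) {
  if (majority_threshold <= 0.5 || majority_threshold > 1)
    stop_kg("majority_threshold must lie in (0.5, 1]")
  pieces <- lapply(split(as.data.frame(topo), topo$relation), function(d) {
    fr <- vapply(d[pattern_cols], mean, 0)
    none_fr <- mean(!Reduce(`|`, d[pattern_cols]))
    over <- which(fr > majority_threshold)
    label <- if (length(over)) {
      c("symmetric", "inference", "inverse",
        "composition")[over[which.max(fr[over])]]
    } else if (none_fr > majority_threshold) "none" else "mixed"
    data.frame(relation = d$relation[1], n = nrow(d),
               symmetric = fr[[1]], inference = fr[[2]], inverse = fr[[3]],
               composition = fr[[4]], none = none_fr,
               predominant = label)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Counterpart-in-train flags for test triples
#'
#' For each test triple (h, r, t), whether its symmetric counterpart
#' (t, r, h), an inverse counterpart (t, r', h) with r' != r, or an
#' inference counterpart (h, r', t) with r' != r was visible in the training
#' graph — the leakage-like conditions under which prediction becomes much
#' easier.
#'
#' @param test data.frame of test triples (`head`, `relation`, `tail`) or a
#'   `knowledge_graph`.
#' @param train training `knowledge_graph` (must not contain any test
#'   triple).
#' @return data.frame with logical columns `sym_in_train`, `inv_in_train`,
#'   `inf_in_train`.
#' @export
counterpart_in_train <- function(test, train) {
  tt <- if (inherits(test, "knowledge_graph")) test$triples else
    as.data.frame(test)
  n_e <- length(train$entities)
  n_r <- length(train$relations)
  tkeys <- triple_key(tt$head, tt$relation, tt$tail, n_e, n_r)
  gkeys <- kg_triple_keys(train)
  if (any(tkeys %in% gkeys))
    stop_kg("test triples must be disjoint from the training graph")
  pair_tab <- table_by_key(pair_key(train$triples$head, train$triples$tail,
                                    n_e))
  sym <- triple_key(tt$tail, tt$relation, tt$head, n_e, n_r) %in% gkeys
  rev_n <- lookup_count(pair_tab, pair_key(tt$tail, tt$head, n_e))
  fwd_n <- lookup_count(pair_tab, pair_key(tt$head, tt$tail, n_e))
  data.frame(
    sym_in_train = sym,
    inv_in_train = (rev_n - sym) >= 1,
    inf_in_train = fwd_n >= 1  # test triple itself is absent from train
  )
}
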