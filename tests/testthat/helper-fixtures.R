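# Small graph builders used across the suite.

kg_from_ids <- function(h, r, t, n_entities = max(h, t), n_relations = max(r),
                        entity_types = NULL) {
  knowledge_graph(
    data.frame(head = h, relation = r, tail = t),
    entities = sprintf("E%d", seq_len(n_entities)),
    relations = sprintf("R%d", seq_len(n_relations)),
    entity_types = entity_types
  )
}

# Random multi-relational graph (self-loops allowed at the given rate).
random_kg <- function(n_entities, n_relations, n_triples, seed,
                      loop_rate = 0.05) {
  set.seed(seed)
  seen <- character()
  h <- integer(); r <- integer(); t <- integer()
  while (length(h) < n_triples) {
    hh <- sample.int(n_entities, 1)
    tt <- if (stats::runif(1) < loop_rate) hh else sample.int(n_entities, 1)
    rr <- sample.int(n_relations, 1)
    key <- paste(hh, rr, tt)
    if (key %in% seen) next
    seen <- c(seen, key)
    h <- c(h, hh); r <- c(r, rr); t <- c(t, tt)
  }
  kg_from_ids(h, r, t, n_entities, n_relations)
}

write_triple_file <- function(lines, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Expected per-triple pattern flags implied by a generator ledger: members of
# a planted symmetric pair are both symmetric, of an inverse pair both carry
# has_inverse, of an inference pair both has_inference; the direct edge of a
# planted composition triangle carries has_composition.
ledger_expected_flags <- function(g, ledger) {
  n_e <- length(g$entities)
  n_r <- length(g$relations)
  keys <- kgtopo:::triple_key(g$triples$head, g$triples$relation,
                              g$triples$tail, n_e, n_r)
  mark <- function(h, r, t) match(kgtopo:::triple_key(h, r, t, n_e, n_r), keys)
  out <- data.frame(
    is_symmetric = logical(nrow(g$triples)),
    has_inference = logical(nrow(g$triples)),
    has_inverse = logical(nrow(g$triples)),
    has_composition = logical(nrow(g$triples))
  )
  L <- ledger
  if (nrow(L$symmetric)) {
    out$is_symmetric[mark(L$symmetric$h, L$symmetric$r, L$symmetric$t)] <- TRUE
    out$is_symmetric[mark(L$symmetric$t, L$symmetric$r, L$symmetric$h)] <- TRUE
  }
  if (nrow(L$inverse)) {
    out$has_inverse[mark(L$inverse$h, L$inverse$r, L$inverse$t)] <- TRUE
    out$has_inverse[mark(L$inverse$t, L$inverse$r_inv, L$inverse$h)] <- TRUE
  }
  if (nrow(L$inference)) {
    out$has_inference[mark(L$inference$h, L$inference$r, L$inference$t)] <- TRUE
    out$has_inference[mark(L$inference$h, L$inference$r_inf,
                           L$inference$t)] <- TRUE
  }
  if (nrow(L$composition))
    out$has_composition[mark(L$composition$h, L$composition$r,
                             L$composition$t)] <- TRUE
  out
}

# Clean all-symmetric benchmark: one relation, every base edge has its
# reverse planted, counterpart placement controlled at split time.
symmetric_benchmark <- function(seed, n_entities = 600, n_base = 1000,
                                policy = "in_train") {
  out <- generate_kg(synthetic_config(
    n_entities = n_entities, n_relations = 1, n_base_edges = n_base,
    degree_skew = 0.3, p_sym = 1, p_inv = 0, p_inf = 0, p_comp = 0,
    clean_mode = TRUE, n_reserved_relations = 1, seed = seed))
  g <- controlled_split(out$graph, out$ledger, c(0.8, 0.1, 0.1),
                        seed = seed + 1, counterpart_policy = policy)
  list(graph = g, ledger = out$ledger)
}
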