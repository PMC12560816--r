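# G = {(A,r1,B),(A,r1,C),(D,r1,B),(A,r2,B)} with A=1, B=2, C=3, D=4
deg_fixture <- kg_from_ids(c(1, 1, 4, 1), c(1, 1, 1, 2), c(2, 3, 2, 2),
                           n_entities = 4, n_relations = 2)

test_that("per-triple degrees are distinct-neighbour set cardinalities", {
  deg <- triple_degrees(deg_fixture)
  # (A,r1,B): A reaches {B,C}, B reached from {A,D}, both also under r1
  expect_equal(unlist(deg[1, ]), c(deg_h = 2, deg_t = 2, deg_r_h = 2,
                                   deg_r_t = 2))
  # (A,r2,B): any-relation degrees unchanged, r2-degrees collapse to 1
  expect_equal(unlist(deg[4, ]), c(deg_h = 2, deg_t = 2, deg_r_h = 1,
                                   deg_r_t = 1))
  single <- kg_from_ids(1, 1, 2)
  expect_equal(unlist(triple_degrees(single)), c(deg_h = 1, deg_t = 1,
                                                 deg_r_h = 1, deg_r_t = 1))
  expect_equal(triple_degrees(deg_fixture), oracle_degrees(deg_fixture))
})

test_that("edge cardinality follows the one/many quadrant rule", {
  expect_equal(as.character(edge_cardinality(1, 1)), "1:1")
  expect_equal(as.character(edge_cardinality(2, 1)), "1:M")
  expect_equal(as.character(edge_cardinality(1, 3)), "M:1")
  expect_equal(as.character(edge_cardinality(2, 3)), "M:M")
  expect_error(edge_cardinality(0, 1), ">= 1")
})

test_that("the four pattern flags satisfy their definitions on canonical toys", {
  sym <- detect_edge_patterns(kg_from_ids(c(1, 2), c(1, 1), c(2, 1)))
  expect_true(all(sym$is_symmetric))
  expect_true(all(!sym$has_inference & !sym$has_inverse & !sym$has_composition))

  inf <- detect_edge_patterns(kg_from_ids(c(1, 1), c(1, 2), c(2, 2)))
  expect_true(all(inf$has_inference))
  expect_true(all(!inf$is_symmetric & !inf$has_inverse))

  inv <- detect_edge_patterns(kg_from_ids(c(1, 2), c(1, 2), c(2, 1)))
  expect_true(all(inv$has_inverse))
  expect_true(all(!inv$is_symmetric & !inv$has_inference))

  # A -r1-> N -r2-> B alongside A -r3-> B
  comp <- detect_edge_patterns(kg_from_ids(c(1, 3, 1), c(1, 2, 3), c(3, 2, 2)))
  expect_equal(comp$has_composition, c(FALSE, FALSE, TRUE))
  expect_equal(comp$n_comp_intermediates[3], 1L)
  expect_equal(comp$n_comp_relpairs[3], 1L)

  # a self-loop is not symmetric and cannot serve as an intermediate
  loop <- detect_edge_patterns(kg_from_ids(1, 1, 1))
  expect_false(loop$is_symmetric)
  expect_false(loop$has_composition)
})

test_that("pattern census fractions count flags and the none class", {
  comp <- kg_from_ids(c(1, 3, 1), c(1, 2, 3), c(3, 2, 2))
  ps <- pattern_summary(comp)
  expect_equal(unname(ps$pattern_fractions["composition"]), 1 / 3)
  expect_equal(unname(ps$pattern_fractions["none"]), 2 / 3)
  expect_equal(sum(ps$cardinality_fractions), 1)

  single <- pattern_summary(kg_from_ids(1, 1, 2))
  expect_equal(unname(single$pattern_fractions["none"]), 1)
  expect_true(all(single$pattern_fractions[1:4] == 0))
})

test_that("sparse detectors agree with the brute-force oracle on random graphs", {
  for (seed in 1:30) {
    n_e <- sample(4:15, 1)
    n_r <- sample(1:4, 1)
    n_t <- sample(5:min(60, (n_e * n_e * n_r) %/% 2), 1)
    g <- random_kg(n_e, n_r, n_t, seed = 1000 + seed)
    got <- detect_edge_patterns(g)
    want <- oracle_patterns(g)
    expect_equal(got[names(want)], want, ignore_attr = TRUE)
    expect_equal(triple_degrees(g), oracle_degrees(g), ignore_attr = TRUE)
  }
})

test_that("symmetry is mutual and inverse/inference are reversal duals", {
  for (seed in 1:10) {
    g <- random_kg(8, 3, 40, seed = 2000 + seed)
    topo <- detect_edge_patterns(g)
    keys <- kgtopo:::kg_triple_keys(g)
    rev_idx <- match(kgtopo:::triple_key(g$triples$tail, g$triples$relation,
                                         g$triples$head, 8, 3), keys)
    both <- !is.na(rev_idx)
    expect_equal(topo$is_symmetric[both], topo$is_symmetric[rev_idx[both]])

    # classify each triple's reversal (t, r, h) against the original edge
    # set: an inverse partner of (h, r, t) is an inference partner of its
    # reversal, and vice versa
    grev <- knowledge_graph(
      unique(data.frame(head = g$triples$tail, relation = g$triples$relation,
                        tail = g$triples$head)), g$entities, g$relations)
    rev_of <- match(
      kgtopo:::triple_key(g$triples$tail, g$triples$relation,
                          g$triples$head, 8, 3),
      kgtopo:::kg_triple_keys(grev))
    topo_rev <- detect_edge_patterns(grev, pattern_graph = g)
    expect_equal(topo$has_inverse, topo_rev$has_inference[rev_of])
    expect_equal(topo$has_inference, topo_rev$has_inverse[rev_of])
  }
})

test_that("adding a triple never decreases any degree quantity", {
  g <- random_kg(8, 2, 25, seed = 77)
  deg <- triple_degrees(g)
  keys <- kgtopo:::kg_triple_keys(g)
  repeat {
    cand <- data.frame(head = sample.int(8, 1), relation = sample.int(2, 1),
                       tail = sample.int(8, 1))
    if (!(kgtopo:::triple_key(cand$head, cand$relation, cand$tail, 8, 2)
          %in% keys)) break
  }
  g2 <- knowledge_graph(rbind(g$triples, cand), g$entities, g$relations)
  deg2 <- triple_degrees(g2, triples = g$triples)
  expect_true(all(as.matrix(deg2) >= as.matrix(deg)))
})

test_that("pattern flags are invariant under id relabelling", {
  g <- random_kg(9, 3, 35, seed = 31)
  pe <- sample.int(9)
  pr <- sample.int(3)
  g2 <- knowledge_graph(
    data.frame(head = pe[g$triples$head], relation = pr[g$triples$relation],
               tail = pe[g$triples$tail]),
    entities = g$entities[order(pe)], relations = g$relations[order(pr)])
  t1 <- detect_edge_patterns(g)
  t2 <- detect_edge_patterns(g2)
  cols <- c(kgtopo:::pattern_cols, "n_comp_intermediates", "n_comp_relpairs")
  expect_equal(t1[cols], t2[cols], ignore_attr = TRUE)
})

test_that("metapath counts stratify by intermediate type and relation pair", {
  # (A,rx,B) via N1 (gene, r1/r2) and via N2 (drug, r3/r4)
  g <- kg_from_ids(
    c(1, 3, 4, 1, 1), c(5, 2, 4, 1, 3), c(3, 2, 2, 4, 2),
    n_entities = 4, n_relations = 5,
    entity_types = c("drug", "disease", "gene", "drug"))
  # triples: A-r5->N1, N1-r2->B, N2-r4->B, A-r1->N2, A-r3->B (focus r3)
  mp <- metapath_composition_counts(g, "R3")
  expect_setequal(mp$by_type$intermediate_type, c("gene", "drug"))
  expect_equal(mp$by_type$n_paths[order(mp$by_type$intermediate_type)],
               c(1L, 1L))
  expect_equal(mp$n_distinct_relpairs, 2L)

  empty <- metapath_composition_counts(g, "R2")
  expect_equal(nrow(empty$by_type), 0L)

  g_untyped <- kg_from_ids(1, 1, 2)
  expect_error(metapath_composition_counts(g_untyped, 1), "type")
})

test_that("relation-level aggregation labels predominant patterns", {
  g <- kg_from_ids(c(1, 2), c(1, 1), c(2, 1))
  topo <- triple_topology(g)
  agg <- aggregate_by_relation(topo, majority_threshold = 0.9)
  expect_equal(agg$predominant, "symmetric")
  expect_equal(agg$symmetric, 1)

  # 2 of 4 triples symmetric at a just-above-half threshold -> mixed
  g2 <- kg_from_ids(c(1, 2, 1, 3), c(1, 1, 1, 1), c(2, 1, 3, 4))
  agg2 <- aggregate_by_relation(triple_topology(g2),
                                majority_threshold = 0.51)
  expect_equal(agg2$predominant, "mixed")
  expect_error(aggregate_by_relation(topo, majority_threshold = 0.4),
               "0.5")
})

test_that("counterpart flags look up symmetric/inverse/inference partners in train", {
  train <- kg_from_ids(c(2, 1, 3), c(1, 2, 1), c(1, 2, 1),
                       n_entities = 3, n_relations = 2)
  test <- data.frame(head = 1L, relation = 1L, tail = 2L)
  fl <- counterpart_in_train(test, train)
  expect_true(fl$sym_in_train)   # (2,r1,1) in train
  expect_true(fl$inf_in_train)   # (1,r2,2) in train
  expect_false(fl$inv_in_train)  # only (2,r1,1), same relation = symmetry

  none <- counterpart_in_train(data.frame(head = 3L, relation = 2L, tail = 2L),
                               train)
  expect_false(any(unlist(none)))

  expect_error(
    counterpart_in_train(data.frame(head = 2L, relation = 1L, tail = 1L),
                         train), "disjoint")
})
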