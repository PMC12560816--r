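fake_results <- function(ranks, h = seq_along(ranks), r = 1, t = seq_along(ranks)) {
  structure(data.frame(head = h, relation = r, tail = t, rank = ranks,
                       n_candidates = 100L, top1 = t),
            class = c("ranking_result", "data.frame"))
}

fake_topo <- function(results, deg_r_h, deg_r_t, flags = NULL) {
  topo <- data.frame(head = results$head, relation = results$relation,
                     tail = results$tail,
                     deg_h = deg_r_h, deg_t = deg_r_t,
                     deg_r_h = deg_r_h, deg_r_t = deg_r_t,
                     cardinality = edge_cardinality(pmax(deg_r_h, 1),
                                                    pmax(deg_r_t, 1)),
                     is_symmetric = FALSE, has_inference = FALSE,
                     has_inverse = FALSE, has_composition = FALSE,
                     n_comp_intermediates = 0L, n_comp_relpairs = 0L)
  for (nm in names(flags)) topo[[nm]] <- flags[[nm]]
  class(topo) <- c("triple_topology", "data.frame")
  topo
}

test_that("degree bins are powers of two and cover every triple once", {
  b <- degree_bin(c(1, 2, 3, 4, 7, 8, 15, 16, 0))
  expect_equal(as.character(b),
               c("1", "2-3", "2-3", "4-7", "4-7", "8-15", "8-15", "16-31", "0"))
  expect_false(anyNA(b))
})

test_that("stratified metrics equal per-group ranking metrics", {
  res <- fake_results(c(1, 1, 2, 4))
  topo <- fake_topo(res, deg_r_h = c(1, 1, 2, 2), deg_r_t = c(1, 1, 1, 1))
  st <- stratify(res, topo, schema = "degree")
  st <- st[order(st$group), ]
  expect_equal(st$mrr, c(1.0, 0.375))
  expect_equal(st$n, c(2L, 2L))

  # all triples in one cardinality class reproduce the global metrics
  topo_mm <- fake_topo(res, deg_r_h = rep(3, 4), deg_r_t = rep(5, 4))
  st2 <- stratify(res, topo_mm, schema = "cardinality")
  expect_equal(nrow(st2), 1L)
  expect_equal(st2$mrr, ranking_metrics(res)$mrr)

  expect_error(stratify(res, topo[c(2, 1, 3, 4), ], schema = "degree"),
               "aligned")
})

test_that("any stratification reconstructs the global MRR to 1e-12", {
  set.seed(21)
  res <- fake_results(sample(c(1, 1.5, 2:30), 200, TRUE))
  topo <- fake_topo(res, deg_r_h = sample(1:40, 200, TRUE),
                    deg_r_t = sample(1:40, 200, TRUE),
                    flags = list(has_composition = sample(c(TRUE, FALSE),
                                                          200, TRUE)))
  for (schema in c("degree", "cardinality", "pattern")) {
    st <- stratify(res, topo, schema = schema)
    expect_equal(sum(st$n), nrow(res))
    expect_lt(abs(sum(st$n * st$mrr) / sum(st$n) -
                    ranking_metrics(res)$mrr), 1e-12)
  }
})

test_that("pattern effect is the with-minus-without MRR delta per bin", {
  # with-composition ranks all 1, without all 2, across two head-degree bins
  res <- fake_results(c(1, 2, 1, 2))
  topo <- fake_topo(res, deg_r_h = c(1, 1, 2, 2), deg_r_t = rep(1, 4),
                    flags = list(has_composition = c(TRUE, FALSE, TRUE, FALSE)))
  pe <- pattern_effect(res, topo, "has_composition")
  expect_true(all(pe$delta == 0.5))

  # identical rank distributions -> zero delta
  res0 <- fake_results(c(2, 2))
  topo0 <- fake_topo(res0, deg_r_h = c(1, 1), deg_r_t = c(1, 1),
                     flags = list(has_composition = c(TRUE, FALSE)))
  expect_equal(pattern_effect(res0, topo0, "has_composition")$delta, 0)

  # a bin with only one side populated gets an NA delta
  res1 <- fake_results(c(1, 1))
  topo1 <- fake_topo(res1, deg_r_h = c(1, 4), deg_r_t = c(1, 1),
                     flags = list(has_composition = c(TRUE, TRUE)))
  expect_true(all(is.na(pattern_effect(res1, topo1, "has_composition")$delta)))
})

test_that("counterpart contrast reports both groups with counts", {
  res <- fake_results(c(1, 1, 4, 4))
  fl <- data.frame(sym_in_train = c(TRUE, TRUE, FALSE, FALSE),
                   inv_in_train = rep(FALSE, 4),
                   inf_in_train = rep(FALSE, 4))
  cc <- counterpart_contrast(res, fl)
  sym <- cc[cc$pattern == "sym_in_train", ]
  expect_equal(sym$mrr[sym$counterpart_in_train], 1.0)
  expect_equal(sym$mrr[!sym$counterpart_in_train], 0.25)
  inv <- cc[cc$pattern == "inv_in_train", ]
  expect_equal(inv$n[inv$counterpart_in_train], 0L)
  expect_true(is.na(inv$mrr[inv$counterpart_in_train]))
  # identical flag values -> identical metrics across patterns
  expect_equal(inv$mrr[!inv$counterpart_in_train],
               cc$mrr[cc$pattern == "inf_in_train" &
                        !cc$counterpart_in_train])
})

test_that("case studies share test triples and candidates across both arms", {
  set.seed(33)
  base <- random_kg(30, 2, 100, seed = 51, loop_rate = 0)
  shared_rel <- which(base$triples$relation == 1)
  # g2: same labels, extra edges under a second relation
  extra <- data.frame(head = sample(30, 40, TRUE), relation = 2L,
                      tail = sample(30, 40, TRUE))
  keys <- kgtopo:::triple_key(extra$head, extra$relation, extra$tail, 30, 2)
  extra <- extra[!duplicated(keys) &
                   !(keys %in% kgtopo:::kg_triple_keys(base)), ]
  g2 <- knowledge_graph(rbind(base$triples, extra), base$entities,
                        base$relations)

  cs <- case_study(base, g2, "R1", test_fraction = 0.1, seed = 5)
  n_shared <- length(shared_rel)
  expect_equal(cs$n_shared, n_shared)
  expect_equal(nrow(cs$test_labels), round(0.1 * n_shared))

  # leakage: no test triple remains in either training arm
  k1 <- kgtopo:::triple_key(cs$test1$head, cs$test1$relation, cs$test1$tail,
                            30, 2)
  k2 <- kgtopo:::triple_key(cs$test2$head, cs$test2$relation, cs$test2$tail,
                            30, 2)
  expect_false(any(k1 %in% kgtopo:::kg_triple_keys(cs$train1)))
  expect_false(any(k2 %in% kgtopo:::kg_triple_keys(cs$train2)))

  # common candidate set = distinct tails of the shared triples (label level)
  expect_setequal(base$entities[cs$candidates1],
                  unique(base$entities[base$triples$tail[shared_rel]]))
  expect_equal(base$entities[cs$candidates1], g2$entities[cs$candidates2])

  # determinism
  cs2 <- case_study(base, g2, "R1", test_fraction = 0.1, seed = 5)
  expect_identical(cs$test_labels, cs2$test_labels)

  expect_error(case_study(base, g2, "nope"), "exist")
})
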