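# A tiny graph and a fitted-at-0-epochs model whose embeddings we can set by
# hand to check the scoring formulas directly.
blank_model <- function(scoring, dim, n_e = 5, n_r = 2, norm = 1) {
  g <- kg_from_ids(c(1, 2, 3, 4), c(1, 1, 2, 2), c(2, 3, 4, 5),
                   n_entities = n_e, n_relations = n_r)
  kge(g, scoring, embedding_dim = dim, epochs = 0, seed = 1, split = NULL,
      norm = norm)
}

test_that("scoring functions reproduce hand-computed values", {
  m <- blank_model("distmult", 2)
  m$embeddings$entity[1, ] <- c(1, 2)
  m$embeddings$entity[2, ] <- c(3, 1)
  m$embeddings$relation[1, ] <- c(1, 0)
  expect_equal(score_triples(m, 1, 1, 2), 1 * 1 * 3 + 2 * 0 * 1)

  mt <- blank_model("transe", 2)
  mt$embeddings$entity[1, ] <- c(0, 0)
  mt$embeddings$entity[2, ] <- c(1, 1)
  mt$embeddings$relation[1, ] <- c(1, 1)
  expect_equal(score_triples(mt, 1, 1, 2), 0)  # exact translation, maximum
  expect_equal(score_triples(mt, 2, 1, 1), -4) # L1 distance 4

  mr <- blank_model("rotate", 3)
  mr$embeddings$phase[1, ] <- 0            # identity rotation
  mr$embeddings$entity[2, ] <- mr$embeddings$entity[1, ]
  expect_equal(score_triples(mr, 1, 1, 2), 0)

  mp <- blank_model("triplere", 2)
  mp$embeddings$entity[1, ] <- c(1, 2)
  mp$embeddings$entity[2, ] <- c(2, 1)
  mp$embeddings$rel_head[1, ] <- c(1, 1)
  mp$embeddings$rel_tail[1, ] <- c(1, 1)
  mp$embeddings$rel_mid[1, ] <- c(1, -1)
  # |1*1 - 2*1 + 1| + |2*1 - 1*1 - 1| = 0
  expect_equal(score_triples(mp, 1, 1, 2), 0)

  expect_error(score_triples(m, 99, 1, 1), "out of range")
})

test_that("DistMult is exactly symmetric; TransE generically is not", {
  m <- blank_model("distmult", 8)
  set.seed(4)
  m$embeddings$entity[] <- rnorm(length(m$embeddings$entity))
  m$embeddings$relation[] <- rnorm(length(m$embeddings$relation))
  h <- sample.int(5, 50, TRUE); r <- sample.int(2, 50, TRUE)
  t <- sample.int(5, 50, TRUE)
  expect_identical(score_triples(m, h, r, t), score_triples(m, t, r, h))

  mt <- blank_model("transe", 8)
  set.seed(5)
  mt$embeddings$entity[] <- rnorm(length(mt$embeddings$entity))
  mt$embeddings$relation[] <- rnorm(length(mt$embeddings$relation))
  expect_true(abs(score_triples(mt, 1, 1, 2) -
                    score_triples(mt, 2, 1, 1)) > 1e-8)
})

test_that("batched all-tails scoring equals one-at-a-time scoring", {
  out <- generate_kg(synthetic_config(n_entities = 40, n_base_edges = 60,
                                      seed = 9))
  for (scoring in c("transe", "distmult", "rotate", "triplere")) {
    for (norm in if (scoring %in% c("transe", "triplere")) c(1, 2) else 1) {
      fit <- kge(out$graph, scoring, embedding_dim = 6, epochs = 2,
                 negatives = 4, batch_size = 32, seed = 2, split = NULL,
                 norm = norm)
      batched <- score_tails(fit, 3, 1)
      single <- score_triples(fit, rep(3, 40), rep(1, 40), 1:40)
      expect_equal(batched, single, tolerance = 1e-5)
    }
  }
})

test_that("training is reproducible under a fixed seed", {
  out <- generate_kg(synthetic_config(n_entities = 80, n_base_edges = 150,
                                      clean_mode = TRUE, p_sym = 0.1,
                                      p_inv = 0, p_inf = 0, p_comp = 0,
                                      seed = 13))
  f1 <- kge(out$graph, "distmult", embedding_dim = 8, epochs = 5,
            negatives = 8, seed = 42, split = NULL)
  f2 <- kge(out$graph, "distmult", embedding_dim = 8, epochs = 5,
            negatives = 8, seed = 42, split = NULL)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$embeddings, f2$embeddings)
  f3 <- kge(out$graph, "distmult", embedding_dim = 8, epochs = 5,
            negatives = 8, seed = 43, split = NULL)
  expect_false(identical(f3$loss_history, f1$loss_history))
})

test_that("RotatE relation entries keep unit modulus through training", {
  out <- generate_kg(synthetic_config(n_entities = 50, n_base_edges = 80,
                                      seed = 3))
  fit <- kge(out$graph, "rotate", embedding_dim = 6, epochs = 5,
             negatives = 8, seed = 1, split = NULL)
  ph <- fit$embeddings$phase
  expect_true(all(abs(cos(ph)^2 + sin(ph)^2 - 1) < 1e-4))
})

test_that("training improves held-out MRR over the random initialization", {
  wins <- vapply(1:5, function(seed) {
    out <- generate_kg(synthetic_config(
      n_entities = 120, n_base_edges = 400, degree_skew = 0.3,
      p_sym = 0.2, p_inv = 0, p_inf = 0, p_comp = 0, clean_mode = TRUE,
      seed = 700 + seed))
    g <- controlled_split(out$graph, out$ledger, c(0.85, 0.05, 0.1),
                          seed = seed, counterpart_policy = "in_train")
    test <- kg_split(g, "test")$triples
    untrained <- kge(g, "distmult", embedding_dim = 12, epochs = 0,
                     seed = seed)
    trained <- kge(g, "distmult", embedding_dim = 12, epochs = 30,
                   negatives = 16, batch_size = 128, seed = seed)
    m0 <- ranking_metrics(filtered_tail_ranks(untrained, test, g))$mrr
    m1 <- ranking_metrics(filtered_tail_ranks(trained, test, g))$mrr
    m1 > m0
  }, NA)
  expect_true(all(wins))
})

test_that("margin-ranking loss and sgd optimizer train without divergence", {
  out <- generate_kg(synthetic_config(n_entities = 60, n_base_edges = 100,
                                      seed = 6))
  fit <- kge(out$graph, "transe", embedding_dim = 8, epochs = 5,
             negatives = 8, loss = "margin", optimizer = "sgd",
             learning_rate = 0.01, seed = 1, split = NULL)
  expect_true(all(is.finite(fit$loss_history)))
  # margin violations shrink as the model trains
  expect_lt(mean(utils::tail(fit$loss_history, 2)),
            mean(utils::head(fit$loss_history, 2)))
})
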