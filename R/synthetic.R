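#' Configuration for the synthetic knowledge-graph generator
#'
#' Describes a directed multi-relational graph with heavy-tailed degree
#' structure, multiple entity types, and planted instances of the four edge
#' patterns at controlled rates. The generator first draws `n_base_edges`
#' distinct base triples (no self-loops) with endpoint sampling weights
#' proportional to `rank^-degree_skew` (a power law; 0 gives uniform
#' endpoints), then plants counterparts per base edge:
#' \describe{
#'   \item{p_sym}{add the exact reverse (t, r, h).}
#'   \item{p_inv}{add (t, r', h) with a fresh relation r' from a reserved
#'     pool (an inverse under the same relation would be symmetry).}
#'   \item{p_inf}{add (h, r', t) with a fresh reserved relation.}
#'   \item{p_comp}{add a directed two-path (h, r1, n), (n, r2, t) through an
#'     intermediate n not in \{h, t\}, with r1, r2 drawn from the base
#'     relation pool.}
#' }
#' In `clean_mode` the emitted graph contains *only* the ledgered pattern
#' instances: at most one pattern is planted per base edge (so the four
#' rates must sum to at most 1), base edges occupy globally distinct
#' unordered entity pairs, composition intermediates are fresh entities, and
#' every insertion is checked against accidental two-path/direct-edge
#' completions, with rejection sampling up to `max_retries` per edge.
#'
#' @param n_entities number of entities.
#' @param n_relations number of base relations (a reserved pool of
#'   `n_reserved_relations` extra relation ids is appended for inverse and
#'   inference counterparts).
#' @param n_base_edges number of base triples to draw.
#' @param degree_skew power-law exponent for endpoint sampling weights
#'   (>= 0).
#' @param p_sym,p_inv,p_inf,p_comp planting rates per base edge, each in
#'   \[0, 1\].
#' @param entity_types named numeric vector of type proportions (must sum to
#'   1); types are assigned to contiguous id blocks.
#' @param clean_mode logical; guarantee detector output equals the ledger.
#' @param n_reserved_relations size of the reserved relation pool.
#' @param max_retries rejection-sampling cap per edge in clean mode.
#' @param seed integer seed; identical seeds give identical output.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_entities = 500, n_relations = 4,
                             n_base_edges = 1000, degree_skew = 0.8,
                             p_sym = 0.1, p_inv = 0.1, p_inf = 0.1,
                             p_comp = 0.1,
                             entity_types = c(gene = 0.5, drug = 0.3,
                                              disease = 0.2),
                             clean_mode = FALSE,
                             n_reserved_relations = 2,
                             max_retries = 100, seed = 1) {
  rates <- c(p_sym, p_inv, p_inf, p_comp)
  if (any(rates < 0) || any(rates > 1))
    stop_kg("planting rates must lie in [0, 1]")
  if (clean_mode && sum(rates) > 1)
    stop_kg("in clean_mode the planting rates must sum to at most 1")
  if (abs(sum(entity_types) - 1) > 1e-8)
    stop_kg("entity type proportions must sum to 1")
  if (degree_skew < 0) stop_kg("degree_skew must be >= 0")
  if (n_base_edges > as.numeric(n_entities)^2 * n_relations)
    stop_kg("n_base_edges exceeds the number of possible triples")
  structure(
    list(n_entities = as.integer(n_entities),
         n_relations = as.integer(n_relations),
         n_base_edges = as.integer(n_base_edges),
         degree_skew = degree_skew,
         p_sym = p_sym, p_inv = p_inv, p_inf = p_inf, p_comp = p_comp,
         entity_types = entity_types, clean_mode = clean_mode,
         n_reserved_relations = as.integer(n_reserved_relations),
         max_retries = as.integer(max_retries), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic knowledge graph with a ground-truth pattern ledger
#'
#' Emits a `knowledge_graph` plus a `synthetic_ledger` listing every planted
#' pattern instance as the concrete triples involved. Every ledgered triple
#' exists in the graph; in clean mode, [detect_edge_patterns()] flags
#' exactly the ledgered instances and nothing else.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `graph` (`knowledge_graph`) and `ledger`
#'   (`synthetic_ledger`: data.frames `symmetric(h, r, t)`,
#'   `inverse(h, r, t, r_inv)`, `inference(h, r, t, r_inf)`,
#'   `composition(h, r, t, n, r1, r2)`, ids as in the graph).
#' @examples
#' out <- generate_kg(synthetic_config(n_entities = 50, n_base_edges = 60,
#'                                     seed = 42))
#' out$graph
#' lengths(out$ledger)
#' @export
generate_kg <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  local_seed(config$seed, generate_kg_impl(config))
}

generate_kg_impl <- function(cfg) {
  n_e <- cfg$n_entities
  n_base_rel <- cfg$n_relations
  n_rel <- n_base_rel + cfg$n_reserved_relations

  w <- (seq_len(n_e))^(-cfg$degree_skew)
  st <- new_graph_state(n_e)

  led_sym <- list(); led_inv <- list(); led_inf <- list(); led_comp <- list()
  used_entity <- logical(n_e)  # touched by any edge (clean-mode freshness)

  n_placed <- 0L
  while (n_placed < cfg$n_base_edges) {
    placed <- FALSE
    for (try in seq_len(cfg$max_retries)) {
      h <- sample.int(n_e, 1L, prob = w)
      t <- sample.int(n_e, 1L, prob = w)
      if (h == t) next
      r <- sample.int(n_base_rel, 1L)
      if (st$has_edge(h, r, t)) next
      if (cfg$clean_mode && st$pair_used(h, t)) next

      # choose plantings for this base edge
      if (cfg$clean_mode) {
        u <- stats::runif(1)
        br <- cumsum(c(cfg$p_sym, cfg$p_inv, cfg$p_inf, cfg$p_comp))
        plant <- c(sym = u < br[1], inv = u >= br[1] && u < br[2],
                   inf = u >= br[2] && u < br[3],
                   comp = u >= br[3] && u < br[4])
      } else {
        plant <- stats::runif(4) < c(cfg$p_sym, cfg$p_inv, cfg$p_inf,
                                     cfg$p_comp)
        names(plant) <- c("sym", "inv", "inf", "comp")
      }

      edges <- list(c(h, r, t))
      allow <- NULL
      extra <- list()
      if (plant[["sym"]]) edges <- c(edges, list(c(t, r, h)))
      if (plant[["inv"]]) {
        r_inv <- n_base_rel + sample.int(cfg$n_reserved_relations, 1L)
        edges <- c(edges, list(c(t, r_inv, h)))
        extra$r_inv <- r_inv
      }
      if (plant[["inf"]]) {
        r_inf <- n_base_rel + sample.int(cfg$n_reserved_relations, 1L)
        edges <- c(edges, list(c(h, r_inf, t)))
        extra$r_inf <- r_inf
      }
      if (plant[["comp"]]) {
        n_mid <- pick_intermediate(cfg, used_entity, h, t, w)
        if (is.na(n_mid)) next
        r1 <- sample.int(n_base_rel, 1L)
        r2 <- sample.int(n_base_rel, 1L)
        edges <- c(edges, list(c(h, r1, n_mid), c(n_mid, r2, t)))
        allow <- c(h, t)  # the intended composition completion
        extra$comp <- c(n_mid, r1, r2)
      }

      if (cfg$clean_mode && !st$edges_clean(edges, allow)) next

      # a planted counterpart may already exist (non-clean mode); it is
      # still a ledgered instance but must not duplicate the edge
      for (e in edges)
        if (!st$has_edge(e[1], e[2], e[3])) st$add_edge(e[1], e[2], e[3])
      used_entity[unlist(lapply(edges, function(e) c(e[1], e[3])))] <- TRUE
      if (plant[["sym"]]) led_sym[[length(led_sym) + 1L]] <- c(h, r, t)
      if (plant[["inv"]])
        led_inv[[length(led_inv) + 1L]] <- c(h, r, t, extra$r_inv)
      if (plant[["inf"]])
        led_inf[[length(led_inf) + 1L]] <- c(h, r, t, extra$r_inf)
      if (plant[["comp"]])
        led_comp[[length(led_comp) + 1L]] <- c(h, r, t, extra$comp)
      placed <- TRUE
      break
    }
    if (!placed)
      stop_kg("could not place base edge %d within %d retries; relax the configuration",
              n_placed + 1L, cfg$max_retries)
    n_placed <- n_placed + 1L
  }

  tr <- st$triples()
  types <- rep(names(cfg$entity_types),
               largest_remainder(cfg$entity_types, n_e))
  graph <- knowledge_graph(
    tr,
    entities = sprintf("e%d", seq_len(n_e)),
    relations = c(sprintf("r%d", seq_len(n_base_rel)),
                  sprintf("inv_r%d", seq_len(cfg$n_reserved_relations))),
    entity_types = types
  )
  ledger <- structure(list(
    symmetric = to_df(led_sym, c("h", "r", "t")),
    inverse = to_df(led_inv, c("h", "r", "t", "r_inv")),
    inference = to_df(led_inf, c("h", "r", "t", "r_inf")),
    composition = to_df(led_comp, c("h", "r", "t", "n", "r1", "r2"))
  ), class = "synthetic_ledger")
  list(graph = graph, ledger = ledger)
}

pick_intermediate <- function(cfg, used_entity, h, t, w) {
  if (cfg$clean_mode) {
    pool <- which(!used_entity)
    pool <- setdiff(pool, c(h, t))
    if (!length(pool)) return(NA_integer_)
    if (length(pool) == 1L) pool else sample(pool, 1L)
  } else {
    repeat {
      n_mid <- sample.int(cfg$n_entities, 1L, prob = w)
      if (n_mid != h && n_mid != t) return(n_mid)
    }
  }
}

to_df <- function(lst, nms) {
  if (!length(lst)) {
    df <- as.data.frame(matrix(integer(), ncol = length(nms)))
    names(df) <- nms
    return(df)
  }
  df <- as.data.frame(do.call(rbind, lst))
  names(df) <- nms
  df
}

# Mutable adjacency state: edge-key set plus out/in neighbour lists, used by
# the generator for membership tests and accidental-pattern checks.
new_graph_state <- function(n_e) {
  env <- new.env(parent = emptyenv())
  env$keys <- new.env(parent = emptyenv(), hash = TRUE)
  env$pairs <- new.env(parent = emptyenv(), hash = TRUE)
  env$out_nb <- vector("list", n_e)
  env$in_nb <- vector("list", n_e)
  env$rows <- list()
  ek <- function(h, r, t) paste(h, r, t)
  pk <- function(a, b) paste(a, b)

  env$has_edge <- function(h, r, t)
    !is.null(env$keys[[ek(h, r, t)]])
  env$pair_used <- function(a, b)
    !is.null(env$pairs[[pk(a, b)]]) || !is.null(env$pairs[[pk(b, a)]])
  env$has_pair <- function(a, b) !is.null(env$pairs[[pk(a, b)]])
  env$add_edge <- function(h, r, t) {
    env$keys[[ek(h, r, t)]] <- TRUE
    env$pairs[[pk(h, t)]] <- TRUE
    env$out_nb[[h]] <- union(env$out_nb[[h]], t)
    env$in_nb[[t]] <- union(env$in_nb[[t]], h)
    env$rows[[length(env$rows) + 1L]] <- c(h, r, t)
  }
  env$triples <- function() {
    m <- do.call(rbind, env$rows)
    data.frame(head = m[, 1], relation = m[, 2], tail = m[, 3])
  }

  # Would inserting these edges create a two-path/direct-edge completion
  # other than the allowed pair? Checks each new edge (a, b) in three roles:
  # as the direct edge over an existing path a->c->b, as the first path edge
  # (paths a->b->c with direct edge (a, c)), and as the second path edge
  # (paths c->a->b with direct edge (c, b)). Pending edges of the same group
  # are included so within-group interactions are caught too.
  env$edges_clean <- function(edges, allow = NULL) {
    pend_out <- list(); pend_in <- list()
    p_out <- function(a) unique(c(env$out_nb[[a]],
                                  unlist(pend_out[as.character(a)])))
    p_in <- function(b) unique(c(env$in_nb[[b]],
                                 unlist(pend_in[as.character(b)])))
    has_dir <- function(a, b)
      env$has_pair(a, b) || b %in% unlist(pend_out[as.character(a)])
    allowed <- function(a, b)
      !is.null(allow) && a == allow[1] && b == allow[2]
    for (e in edges) {
      a <- e[1]; b <- e[3]
      if (!allowed(a, b) &&
          length(intersect(p_out(a), setdiff(p_in(b), c(a, b)))))
        return(FALSE)
      for (c_ in setdiff(p_out(b), c(a, b)))
        if (has_dir(a, c_) && !allowed(a, c_)) return(FALSE)
      for (c_ in setdiff(p_in(a), c(a, b)))
        if (has_dir(c_, b) && !allowed(c_, b)) return(FALSE)
      pend_out[[as.character(a)]] <- c(pend_out[[as.character(a)]], b)
      pend_in[[as.character(b)]] <- c(pend_in[[as.character(b)]], a)
    }
    TRUE
  }
  env
}

#' Split a synthetic graph while controlling counterpart placement
#'
#' Assigns train/valid/test tags at the requested fractions, then enforces a
#' placement policy on every planted symmetric/inverse/inference pair that
#' has a member in test: under `"in_train"` the other member is forced into
#' train (the counterpart was seen during training), under `"held_out"` it
#' is forced into test (never seen). Composition path edges always stay in
#' train so planted paths remain visible. Unconstrained triples are then
#' swapped between splits to restore the requested sizes to within 2
#' triples.
#'
#' @param g synthetic `knowledge_graph`.
#' @param ledger the matching `synthetic_ledger`.
#' @param fractions train/valid/test fractions (positive, sum 1).
#' @param seed integer seed.
#' @param counterpart_policy `"in_train"` or `"held_out"`.
#' @return `g` with split tags.
#' @export
controlled_split <- function(g, ledger, fractions = c(0.8, 0.1, 0.1),
                             seed = NULL,
                             counterpart_policy = c("in_train", "held_out")) {
  counterpart_policy <- match.arg(counterpart_policy)
  local_seed(seed, controlled_split_impl(g, ledger, fractions,
                                         counterpart_policy))
}

controlled_split_impl <- function(g, ledger, fractions, policy) {
  n_e <- length(g$entities)
  n_r <- length(g$relations)
  n <- n_triples(g)
  keys <- kg_triple_keys(g)
  row_of <- function(h, r, t) {
    i <- match(triple_key(h, r, t, n_e, n_r), keys)
    if (anyNA(i)) stop_kg("ledger triple missing from graph")
    i
  }
  pairs <- rbind(
    if (nrow(ledger$symmetric)) cbind(
      row_of(ledger$symmetric$h, ledger$symmetric$r, ledger$symmetric$t),
      row_of(ledger$symmetric$t, ledger$symmetric$r, ledger$symmetric$h)),
    if (nrow(ledger$inverse)) cbind(
      row_of(ledger$inverse$h, ledger$inverse$r, ledger$inverse$t),
      row_of(ledger$inverse$t, ledger$inverse$r_inv, ledger$inverse$h)),
    if (nrow(ledger$inference)) cbind(
      row_of(ledger$inference$h, ledger$inference$r, ledger$inference$t),
      row_of(ledger$inference$h, ledger$inference$r_inf,
             ledger$inference$t))
  )
  path_rows <- if (nrow(ledger$composition)) c(
    row_of(ledger$composition$h, ledger$composition$r1,
           ledger$composition$n),
    row_of(ledger$composition$n, ledger$composition$r2,
           ledger$composition$t)) else integer()

  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
    stop_kg("fractions must be positive and sum to 1")
  sizes <- largest_remainder(fractions, n)
  splits <- c("train", "valid", "test")
  tags <- rep(NA_character_, n)
  tags[path_rows] <- "train"  # planted paths stay visible during training

  deficit <- function() {
    have <- tabulate(factor(tags, levels = splits), 3)
    sizes - have
  }
  pick_split <- function() {
    d <- pmax(deficit(), 0)
    if (sum(d) == 0) return("train")
    sample(splits, 1, prob = d)
  }

  # assign planted pairs as units so the policy never distorts the sizes:
  # under in_train a valid/test unit places one member there and its
  # counterpart in train; under held_out both members share the tag
  if (!is.null(pairs)) for (i in sample.int(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (is.na(tags[a]) && is.na(tags[b])) {
      s <- pick_split()
      if (policy == "in_train" && s != "train") {
        tags[a] <- s; tags[b] <- "train"
      } else {
        tags[a] <- s; tags[b] <- s
      }
    } else {
      # row already constrained by an overlapping pair or planted path
      done <- if (is.na(tags[a])) b else a
      other <- if (is.na(tags[a])) a else b
      if (is.na(tags[other]))
        tags[other] <- if (tags[done] == "train") pick_split()
          else if (policy == "in_train") "train" else tags[done]
    }
  }
  for (i in sample.int(n)) if (is.na(tags[i])) tags[i] <- pick_split()

  # enforce the policy exhaustively (overlapping constraints can conflict)
  if (!is.null(pairs)) for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (tags[a] == "test" || tags[b] == "test") {
      if (policy == "in_train") {
        if (tags[a] == "test") tags[b] <- "train" else tags[a] <- "train"
      } else {
        tags[a] <- "test"; tags[b] <- "test"
      }
    }
  }
  g$split <- factor(tags, levels = splits)
  g
}
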