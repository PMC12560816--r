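#' Fit a shallow knowledge-graph-embedding model
#'
#' Learns low-dimensional entity and relation embeddings by stochastic
#' gradient descent on a negative-sampling ranking loss, for one of four
#' scoring functions (higher score = more plausible triple):
#' \describe{
#'   \item{TransE}{\eqn{-\lVert e_h + e_r - e_t \rVert_p}: relations as
#'     translations; cannot model symmetric relations (a high score in both
#'     directions forces \eqn{e_r \approx 0}).}
#'   \item{DistMult}{\eqn{\sum_i e_{h,i} e_{r,i} e_{t,i}}: bilinear diagonal;
#'     scores every relation symmetrically, score(h,r,t) = score(t,r,h).}
#'   \item{RotatE}{\eqn{-\sum_i |h_i \circ r_i - t_i|} with complex entity
#'     entries and unit-modulus relation entries (element-wise rotations,
#'     stored as phases so the modulus constraint holds exactly).}
#'   \item{TripleRE}{\eqn{-\lVert e_h \circ r^{head} - e_t \circ r^{tail} +
#'     r^{mid} \rVert_p}: translation with per-relation head/tail scaling.}
#' }
#' Negatives are drawn by uniformly corrupting the head and/or tail of each
#' positive. The default loss is self-adversarial negative sampling
#' (softmax-weighted negatives at the configured temperature); a
#' margin-ranking loss is available. Training is reproducible: the same
#' seed yields the same final embeddings and loss.
#'
#' @param graph a `knowledge_graph`; if it carries split tags only the
#'   `train` split is used (override with `split = NULL` to train on all
#'   triples).
#' @param scoring one of `"transe"`, `"distmult"`, `"rotate"`,
#'   `"triplere"`.
#' @param embedding_dim embedding dimension (complex dimension for RotatE,
#'   which stores `2 * embedding_dim` reals per entity).
#' @param norm p-norm (1 or 2) for the distance-based scorers.
#' @param margin margin / bias gamma of the loss.
#' @param learning_rate step size.
#' @param epochs full passes over the training triples.
#' @param batch_size positives per mini-batch.
#' @param negatives corrupted samples per positive.
#' @param loss `"self_adversarial"` or `"margin"`.
#' @param adversarial_temperature softmax temperature of the
#'   self-adversarial weights.
#' @param corruption which side to corrupt: `"both"` (side chosen uniformly
#'   per negative), `"tail"`, or `"head"`.
#' @param optimizer `"adagrad"` (default; robust step-size adaptation) or
#'   plain `"sgd"`.
#' @param seed integer seed for initialization and sampling.
#' @param split which split to train on (`"train"`, or `NULL` for all
#'   triples).
#' @param verbose print the mean loss every few epochs.
#' @return An object of class `kge`: a list with `embeddings` (entity
#'   matrix and relation parameter matrices), `scoring`, `config`,
#'   `loss_history` (mean loss per epoch), and the vocabularies. Methods:
#'   [print.kge()], [summary.kge()], [coef.kge()], [predict.kge()],
#'   [plot.kge()].
#' @examples
#' out <- generate_kg(synthetic_config(n_entities = 60, n_base_edges = 80,
#'                                     seed = 3))
#' fit <- kge(out$graph, "distmult", embedding_dim = 8, epochs = 5,
#'            negatives = 8, seed = 1)
#' fit
#' @export
kge <- function(graph, scoring = c("transe", "distmult", "rotate", "triplere"),
                embedding_dim = 64, norm = 1, margin = 6,
                learning_rate = 0.1, epochs = 100, batch_size = 256,
                negatives = 64, loss = c("self_adversarial", "margin"),
                adversarial_temperature = 1,
                corruption = c("both", "tail", "head"),
                optimizer = c("adagrad", "sgd"), seed = 1,
                split = "train", verbose = FALSE) {
  scoring <- match.arg(scoring)
  loss <- match.arg(loss)
  corruption <- match.arg(corruption)
  optimizer <- match.arg(optimizer)
  stopifnot(embedding_dim >= 1, norm %in% c(1, 2), epochs >= 0,
            negatives >= 1)
  tr <- if (!is.null(split) && !is.null(graph$split)) {
    kg_split(graph, split)$triples
  } else graph$triples
  if (nrow(tr) == 0L) stop_kg("no training triples")

  cfg <- list(embedding_dim = embedding_dim, norm = norm, margin = margin,
              learning_rate = learning_rate, epochs = epochs,
              batch_size = batch_size, negatives = negatives, loss = loss,
              adversarial_temperature = adversarial_temperature,
              corruption = corruption, optimizer = optimizer, seed = seed)
  n_e <- length(graph$entities)
  n_r <- length(graph$relations)

  local_seed(seed, {
    par <- kge_init(scoring, n_e, n_r, cfg)
    hist <- numeric(epochs)
    acc <- kge_init_acc(par)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(nrow(tr))
      ep_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, nrow(tr), by = batch_size)) {
        rows <- perm[start:min(start + batch_size - 1L, nrow(tr))]
        step <- kge_step(par, acc, scoring, cfg,
                         tr$head[rows], tr$relation[rows], tr$tail[rows],
                         n_e)
        par <- step$par
        acc <- step$acc
        ep_loss <- ep_loss + step$loss
        n_batches <- n_batches + 1L
      }
      hist[ep] <- ep_loss / n_batches
      if (!is.finite(hist[ep]))
        stop_kg("training diverged at epoch %d (loss %s); reduce learning_rate",
                ep, format(hist[ep]))
      if (verbose && (ep %% max(1L, epochs %/% 10L) == 0L))
        message(sprintf("epoch %d  mean loss %.4f", ep, hist[ep]))
    }
    structure(
      list(scoring = scoring, embeddings = par, config = cfg,
           loss_history = hist, entities = graph$entities,
           relations = graph$relations, entity_types = graph$entity_types,
           n_entities = n_e, n_relations = n_r),
      class = "kge"
    )
  })
}

kge_init <- function(scoring, n_e, n_r, cfg) {
  d <- cfg$embedding_dim
  b <- cfg$margin / d
  runi <- function(n, m, lo = -b, hi = b)
    matrix(stats::runif(n * m, lo, hi), n, m)
  switch(scoring,
    transe = list(entity = runi(n_e, d), relation = runi(n_r, d)),
    distmult = list(entity = matrix(stats::rnorm(n_e * d, sd = 0.1), n_e, d),
                    relation = matrix(stats::rnorm(n_r * d, sd = 0.1), n_r, d)),
    rotate = list(entity = runi(n_e, 2 * d),
                  phase = matrix(stats::runif(n_r * d, 0, 2 * pi), n_r, d)),
    triplere = list(entity = runi(n_e, d),
                    rel_head = runi(n_r, d, 1 - b, 1 + b),
                    rel_tail = runi(n_r, d, 1 - b, 1 + b),
                    rel_mid = runi(n_r, d))
  )
}

kge_init_acc <- function(par) lapply(par, function(m) m * 0 + 1e-8)

# One mini-batch: scores, loss, hand-derived gradients, scatter update.
kge_step <- function(par, acc, scoring, cfg, h, r, t, n_e) {
  nb <- length(h)
  nn <- cfg$negatives
  side <- switch(cfg$corruption,
    tail = rep(TRUE, nb * nn),
    head = rep(FALSE, nb * nn),
    both = stats::runif(nb * nn) < 0.5)  # TRUE = corrupt tail
  corrupt <- sample.int(n_e, nb * nn, replace = TRUE)
  hh <- rep(h, each = nn); rr <- rep(r, each = nn); tt <- rep(t, each = nn)
  hn <- ifelse(side, hh, corrupt)
  tn <- ifelse(side, corrupt, tt)

  s_pos <- kge_score_ids(par, scoring, h, r, t, cfg$norm)
  s_neg <- kge_score_ids(par, scoring, hn, rr, tn, cfg$norm)

  g <- cfg$margin
  if (cfg$loss == "self_adversarial") {
    sm <- matrix(s_neg, nb, nn, byrow = TRUE)
    a <- cfg$adversarial_temperature * sm
    p <- exp(a - apply(a, 1, max))
    p <- p / rowSums(p)
    loss <- mean(-log_sigmoid(g + s_pos) +
                   rowSums(p * -log_sigmoid(-sm - g)))
    w_pos <- -sigmoid(-(g + s_pos)) / nb
    w_neg <- as.vector(t(p * sigmoid(sm + g))) / nb
  } else {
    sm <- matrix(s_neg, nb, nn, byrow = TRUE)
    viol <- pmax(g - s_pos + sm, 0)
    loss <- mean(viol)
    active <- (viol > 0) / (nb * nn)
    w_pos <- -rowSums(active)
    w_neg <- as.vector(t(active))
  }

  gr_pos <- kge_grad_ids(par, scoring, h, r, t, w_pos, cfg$norm)
  gr_neg <- kge_grad_ids(par, scoring, hn, rr, tn, w_neg, cfg$norm)

  for (nm in names(par)) {
    ids <- c(gr_pos[[nm]]$ids, gr_neg[[nm]]$ids)
    gm <- rbind(gr_pos[[nm]]$grad, gr_neg[[nm]]$grad)
    if (is.null(ids)) next
    gsum <- rowsum(gm, ids)
    u <- as.integer(rownames(gsum))
    if (cfg$optimizer == "adagrad") {
      acc[[nm]][u, ] <- acc[[nm]][u, , drop = FALSE] + gsum^2
      par[[nm]][u, ] <- par[[nm]][u, , drop = FALSE] -
        cfg$learning_rate * gsum / sqrt(acc[[nm]][u, , drop = FALSE])
    } else {
      par[[nm]][u, ] <- par[[nm]][u, , drop = FALSE] -
        cfg$learning_rate * gsum
    }
  }
  if (scoring == "rotate")
    par$phase <- par$phase %% (2 * pi)
  list(par = par, acc = acc, loss = loss)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
log_sigmoid <- function(x) ifelse(x > -30, -log1p(exp(-x)), x)

# Raw scores for vectors of ids (the one-at-a-time reference path).
kge_score_ids <- function(par, scoring, h, r, t, norm = 1) {
  switch(scoring,
    transe = {
      d <- par$entity[h, , drop = FALSE] + par$relation[r, , drop = FALSE] -
        par$entity[t, , drop = FALSE]
      -p_norm(d, norm)
    },
    # grouped as (e_h * e_t) * e_r so score(h,r,t) == score(t,r,h) exactly,
    # not merely up to floating-point association
    distmult = rowSums((par$entity[h, , drop = FALSE] *
                          par$entity[t, , drop = FALSE]) *
                         par$relation[r, , drop = FALSE]),
    rotate = {
      k <- ncol(par$phase)
      Hr <- par$entity[h, seq_len(k), drop = FALSE]
      Hi <- par$entity[h, k + seq_len(k), drop = FALSE]
      Tr <- par$entity[t, seq_len(k), drop = FALSE]
      Ti <- par$entity[t, k + seq_len(k), drop = FALSE]
      cs <- cos(par$phase[r, , drop = FALSE])
      sn <- sin(par$phase[r, , drop = FALSE])
      dr <- Hr * cs - Hi * sn - Tr
      di <- Hr * sn + Hi * cs - Ti
      -rowSums(sqrt(dr^2 + di^2))
    },
    triplere = {
      d <- par$entity[h, , drop = FALSE] * par$rel_head[r, , drop = FALSE] -
        par$entity[t, , drop = FALSE] * par$rel_tail[r, , drop = FALSE] +
        par$rel_mid[r, , drop = FALSE]
      -p_norm(d, norm)
    }
  )
}

p_norm <- function(d, norm) {
  if (norm == 1) rowSums(abs(d)) else sqrt(rowSums(d^2))
}

# d(-||d||_p)/dd, row-wise (eps guards the L2 / modulus singularity at 0)
dnorm_dd <- function(d, norm) {
  if (norm == 1) -sign(d) else -d / pmax(sqrt(rowSums(d^2)), 1e-12)
}

# Gradients of sum_i w_i * score_i w.r.t. each parameter matrix, returned as
# (row ids, per-row gradient) pairs ready for rowsum() accumulation.
kge_grad_ids <- function(par, scoring, h, r, t, w, norm = 1) {
  switch(scoring,
    transe = {
      d <- par$entity[h, , drop = FALSE] + par$relation[r, , drop = FALSE] -
        par$entity[t, , drop = FALSE]
      g <- w * dnorm_dd(d, norm)
      list(entity = list(ids = c(h, t), grad = rbind(g, -g)),
           relation = list(ids = r, grad = g))
    },
    distmult = {
      H <- par$entity[h, , drop = FALSE]
      R <- par$relation[r, , drop = FALSE]
      T_ <- par$entity[t, , drop = FALSE]
      list(entity = list(ids = c(h, t), grad = rbind(w * R * T_, w * H * R)),
           relation = list(ids = r, grad = w * H * T_))
    },
    rotate = {
      k <- ncol(par$phase)
      Hr <- par$entity[h, seq_len(k), drop = FALSE]
      Hi <- par$entity[h, k + seq_len(k), drop = FALSE]
      Tr <- par$entity[t, seq_len(k), drop = FALSE]
      Ti <- par$entity[t, k + seq_len(k), drop = FALSE]
      cs <- cos(par$phase[r, , drop = FALSE])
      sn <- sin(par$phase[r, , drop = FALSE])
      rot_r <- Hr * cs - Hi * sn
      rot_i <- Hr * sn + Hi * cs
      dr <- rot_r - Tr
      di <- rot_i - Ti
      m <- pmax(sqrt(dr^2 + di^2), 1e-12)
      # dL/ddr etc., already including w and the -1 of the score sign
      gdr <- -w * dr / m
      gdi <- -w * di / m
      gH <- cbind(gdr * cs + gdi * sn, -gdr * sn + gdi * cs)
      gT <- cbind(-gdr, -gdi)
      gphase <- gdr * (-rot_i) + gdi * rot_r
      list(entity = list(ids = c(h, t), grad = rbind(gH, gT)),
           phase = list(ids = r, grad = gphase))
    },
    triplere = {
      H <- par$entity[h, , drop = FALSE]
      T_ <- par$entity[t, , drop = FALSE]
      Rh <- par$rel_head[r, , drop = FALSE]
      Rt <- par$rel_tail[r, , drop = FALSE]
      d <- H * Rh - T_ * Rt + par$rel_mid[r, , drop = FALSE]
      g <- w * dnorm_dd(d, norm)
      list(entity = list(ids = c(h, t), grad = rbind(g * Rh, -g * Rt)),
           rel_head = list(ids = r, grad = g * H),
           rel_tail = list(ids = r, grad = -g * T_),
           rel_mid = list(ids = r, grad = g))
    }
  )
}

resolve_ids <- function(x, labels, what) {
  if (is.character(x)) {
    i <- match(x, labels)
    if (anyNA(i)) stop_kg("unknown %s label(s): %s", what,
                          paste(x[is.na(i)], collapse = ", "))
    return(i)
  }
  i <- as.integer(x)
  if (any(i < 1L) || any(i > length(labels)))
    stop_kg("%s id out of range 1..%d", what, length(labels))
  i
}

#' Score triples under a fitted embedding model
#'
#' Returns the raw plausibility score of each (h, r, t); higher means more
#' plausible. Ids (1-based) or labels are accepted.
#'
#' @param model a fitted [kge()] model.
#' @param h,r,t equal-length vectors of entity / relation ids or labels.
#' @return numeric vector of scores.
#' @export
score_triples <- function(model, h, r, t) {
  stopifnot(inherits(model, "kge"))
  h <- resolve_ids(h, model$entities, "entity")
  t <- resolve_ids(t, model$entities, "entity")
  r <- resolve_ids(r, model$relations, "relation")
  kge_score_ids(model$embeddings, model$scoring, h, r, t,
                model$config$norm)
}

#' Score one (h, r, ?) query against a set of candidate tails
#'
#' Batched all-tails scoring for a single query, used by the ranking
#' evaluator; a vectorized path algebraically equivalent to
#' [score_triples()] applied tail by tail.
#'
#' @param model a fitted [kge()] model.
#' @param h,r a single entity and relation (id or label).
#' @param candidates candidate tail ids (default: all entities).
#' @return numeric vector of scores, one per candidate.
#' @export
score_tails <- function(model, h, r, candidates = NULL) {
  stopifnot(inherits(model, "kge"))
  h <- resolve_ids(h, model$entities, "entity")[1]
  r <- resolve_ids(r, model$relations, "relation")[1]
  cand <- if (is.null(candidates)) seq_len(model$n_entities) else
    resolve_ids(candidates, model$entities, "entity")
  par <- model$embeddings
  norm <- model$config$norm
  switch(model$scoring,
    transe = {
      v <- par$entity[h, ] + par$relation[r, ]
      d <- sweep(par$entity[cand, , drop = FALSE], 2, v, `-`)
      -p_norm(d, norm)
    },
    distmult = as.numeric(par$entity[cand, , drop = FALSE] %*%
                            (par$entity[h, ] * par$relation[r, ])),
    rotate = {
      k <- ncol(par$phase)
      cs <- cos(par$phase[r, ]); sn <- sin(par$phase[r, ])
      hr <- par$entity[h, seq_len(k)]; hi <- par$entity[h, k + seq_len(k)]
      rot <- c(hr * cs - hi * sn, hr * sn + hi * cs)
      d <- sweep(par$entity[cand, , drop = FALSE], 2, rot, `-`)
      -rowSums(sqrt(d[, seq_len(k), drop = FALSE]^2 +
                      d[, k + seq_len(k), drop = FALSE]^2))
    },
    triplere = {
      v <- par$entity[h, ] * par$rel_head[r, ] + par$rel_mid[r, ]
      Tm <- sweep(par$entity[cand, , drop = FALSE], 2, par$rel_tail[r, ], `*`)
      d <- sweep(-Tm, 2, v, `+`)
      -p_norm(d, norm)
    }
  )
}

#' @export
print.kge <- function(x, ...) {
  cat(sprintf("%s embeddings: %d entities x dim %d, %d relations\n",
              x$scoring, x$n_entities, x$config$embedding_dim,
              x$n_relations))
  if (length(x$loss_history))
    cat(sprintf("trained %d epochs, final mean loss %.4f\n",
                length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
summary.kge <- function(object, ...) {
  ent_norm <- sqrt(rowSums(object$embeddings$entity^2))
  out <- list(scoring = object$scoring, config = object$config,
              loss_history = object$loss_history,
              entity_norm = summary(ent_norm))
  class(out) <- "summary.kge"
  out
}

#' @export
print.summary.kge <- function(x, ...) {
  cat(sprintf("%s model (dim %d, %s loss, %s)\n", x$scoring,
              x$config$embedding_dim, x$config$loss, x$config$optimizer))
  if (length(x$loss_history))
    cat(sprintf("loss: first %.4f -> final %.4f over %d epochs\n",
                x$loss_history[1], utils::tail(x$loss_history, 1),
                length(x$loss_history)))
  cat("entity embedding L2 norms:\n")
  print(x$entity_norm)
  invisible(x)
}

#' Extract embedding tables from a fitted model
#'
#' @param object a fitted [kge()] model.
#' @param ... unused.
#' @return list of parameter matrices (entity table plus the relation
#'   table(s) of the scoring function; RotatE relations are phases).
#' @export
coef.kge <- function(object, ...) object$embeddings

#' Predict plausibility scores for new triples
#'
#' @param object a fitted [kge()] model.
#' @param newdata data.frame with columns `head`, `relation`, `tail`
#'   (ids or labels).
#' @param ... unused.
#' @return numeric vector of scores.
#' @export
predict.kge <- function(object, newdata, ...) {
  score_triples(object, newdata$head, newdata$relation, newdata$tail)
}

#' Plot the training loss trajectory
#'
#' @param x a fitted [kge()] model.
#' @param ... passed to [plot()].
#' @export
plot.kge <- function(x, ...) {
  plot(seq_along(x$loss_history), x$loss_history, type = "l",
       xlab = "epoch", ylab = "mean loss",
       main = sprintf("%s training loss", x$scoring), ...)
  invisible(x)
}
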