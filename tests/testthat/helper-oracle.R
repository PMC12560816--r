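# Brute-force reference implementations of the per-triple definitions,
# written as literal loops over the edge set. Deliberately independent of
# the package's sparse code paths; used to verify them on random graphs.

oracle_degrees <- function(g, triples = g$triples) {
  G <- g$triples
  data.frame(
    deg_h = vapply(triples$head, function(h)
      length(unique(G$tail[G$head == h])), 0L),
    deg_t = vapply(triples$tail, function(t)
      length(unique(G$head[G$tail == t])), 0L),
    deg_r_h = mapply(function(h, r)
      length(unique(G$tail[G$head == h & G$relation == r])),
      triples$head, triples$relation),
    deg_r_t = mapply(function(t, r)
      length(unique(G$head[G$tail == t & G$relation == r])),
      triples$tail, triples$relation)
  )
}

oracle_patterns <- function(g, pattern_graph = g) {
  tr <- g$triples
  G <- pattern_graph$triples
  n_ent <- length(g$entities)
  has <- function(h, r, t) any(G$head == h & G$relation == r & G$tail == t)
  out <- lapply(seq_len(nrow(tr)), function(i) {
    h <- tr$head[i]; r <- tr$relation[i]; t <- tr$tail[i]
    sym <- h != t && has(t, r, h)
    inf <- FALSE; inv <- FALSE
    for (rp in seq_along(g$relations)) {
      if (rp == r) next
      if (has(h, rp, t)) inf <- TRUE
      if (has(t, rp, h)) inv <- TRUE
    }
    n_int <- 0L
    relpairs <- character()
    for (nmid in seq_len(n_ent)) {
      if (nmid == h || nmid == t) next
      r1s <- G$relation[G$head == h & G$tail == nmid]
      r2s <- G$relation[G$head == nmid & G$tail == t]
      if (length(r1s) && length(r2s)) {
        n_int <- n_int + 1L
        relpairs <- c(relpairs,
                      as.vector(outer(r1s, r2s, paste)))
      }
    }
    data.frame(is_symmetric = sym, has_inference = inf, has_inverse = inv,
               has_composition = n_int >= 1L,
               n_comp_intermediates = n_int,
               n_comp_relpairs = length(unique(relpairs)))
  })
  do.call(rbind, out)
}
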