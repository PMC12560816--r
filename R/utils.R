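# Internal helpers shared across modules.

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Encode ordered entity pairs / full triples as double-valued keys.
# Doubles hold exact integers up to 2^53; guarded at graph construction.
pair_key <- function(h, t, n_entities) {
  (as.numeric(h) - 1) * n_entities + as.numeric(t)
}

triple_key <- function(h, r, t, n_entities, n_relations) {
  ((as.numeric(h) - 1) * n_relations + (as.numeric(r) - 1)) * n_entities +
    as.numeric(t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kg <- function(...) stop(sprintf(...), call. = FALSE)
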