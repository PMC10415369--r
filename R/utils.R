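# Internal helpers shared across modules.

# Substream seeds: the first `n` draws of sample.int(2^31 - 1) under the
# master seed. Components that need independent reproducible streams (one per
# subject, one per iteration, ...) each consume one seed from this table, so a
# subset of subjects or iterations can be regenerated without running the rest.
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

# Diagonal RAS affine for an isotropic synthetic grid.
iso_affine <- function(voxel_size_mm) {
  diag(c(rep(voxel_size_mm, 3L), 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)
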