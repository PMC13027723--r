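# Internal helpers shared across modules.

# Seed a generator deterministically without clobbering the caller's RNG
# stream more than base R's simulate() does: if `seed` is NULL the current
# stream is used, otherwise the RNG state is restored on exit.
with_gen_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Uniform angular grid theta_j = 2*pi*j/N on [0, 2*pi).
angle_grid <- function(n) {
  stopifnot(n >= 1)
  2 * pi * (seq_len(n) - 1L) / n
}

stop_degenerate <- function(msg) {
  stop(structure(class = c("rbc_degenerate_input", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
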