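# small internal helpers

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All randomness in the package funnels through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a counter, kept inside the
# 32-bit signed integer range (R seeds are 32-bit).
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 7919) %% 2147483629)
}

# deterministic small integer from a label (for per-subfamily template RNG)
label_seed <- function(label) {
  codes <- utf8ToInt(label)
  as.integer(sum(codes * seq_along(codes) * 131) %% 1000000L + 17L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
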