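# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All generator determinism flows through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# scalar probability check
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  as.numeric(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

# Signed-kb display label relative to the anchor, "-9.9 kb" style.
# `pos` is a 0-based internal coordinate; `offset` the genomic offset of
# position 0 relative to the anchor (e.g. TSS).
kb_label <- function(pos, offset = 0) {
  kb <- (pos + offset) / 1000
  sprintf("%+.1f kb", kb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
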