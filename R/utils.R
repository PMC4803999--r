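#' @keywords internal
"_PACKAGE"

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards.  All randomised operations in the package go
# through this so that a master seed fully determines every output.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# 32-bit FNV-1a over a character string, done in double arithmetic
# (exact below 2^53).  Used for stage-seed fan-out and config hashes.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- bitwXor(as.integer(h - 2^32 * (h >= 2^31)), as.integer(b))
    if (h < 0) h <- h + 2^32
    # multiply mod 2^32 without exceeding double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 2^32
  }
  h
}

# Deterministic per-stage seed derived from a master seed and a stage
# name; adding a stage never shifts another stage's stream.
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) + fnv1a32(stage) %% 1e6) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
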