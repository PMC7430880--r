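# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

#' 32-bit FNV-1a hash of a string
#'
#' Stable across platforms and R sessions; used to derive independent RNG
#' substreams from a single user-facing seed so that adding a metric to a
#' generation spec does not perturb the draws of the others.
#'
#' @param key character scalar.
#' @return integer in `[0, 2^31 - 1)`.
#' @keywords internal
fnv1a32 <- function(key) {
  bytes <- utf8ToInt(enc2utf8(key))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor only touches the low 8 bits since b < 256
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    # 32-bit modular multiply in exact double arithmetic (split at 2^16)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  h %% 2147483647
}

# substream seed for a keyed draw under a global seed
substream_seed <- function(seed, key) {
  as.integer((abs(seed) + fnv1a32(key)) %% 2147483647)
}

# evaluate a draw under a keyed substream without disturbing the caller's RNG
with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, key))
  force(expr)
}

round1 <- function(x) round(x + 1e-12, 1)  # guard against 0.05-at-binary-edge
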