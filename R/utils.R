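#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm rnbinom cor pt sd predict quantile
#' @importFrom utils head tail read.csv write.csv read.table write.table combn
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  force(code)
}

# Derive a child seed from a master seed and a stage tag, keeping the result
# inside the positive 32-bit integer range.
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- fnv1a(charToRaw(paste0(tag, ":", as.integer(seed))))
  as.integer(h %% 2147483646L) + 1L
}

# FNV-1a 32-bit hash over raw bytes, returned as a double in [0, 2^32).
fnv1a <- function(bytes) {
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(bytes)) {
    h <- bitwXor64(h, b)
    h <- (h * p) %% 4294967296
  }
  h
}

bitwXor64 <- function(x, y) {
  lo <- bitwXor(as.integer(x %% 65536), as.integer(y %% 65536))
  hi <- bitwXor(as.integer(x %/% 65536) %% 65536, as.integer(y %/% 65536))
  hi * 65536 + lo
}

#' Short content hash of an R object
#'
#' 32-bit FNV-1a hash of the object's serialized bytes, as 8 hex digits.
#' Used by [run_pipeline()] to record stage-input fingerprints in run reports.
#'
#' @param x Any serializable R object.
#' @return A character scalar of 8 hex digits.
#' @export
object_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  # hash a bounded digest of the bytes so large volumes stay cheap
  if (length(bytes) > 65536) {
    idx <- unique(c(seq(1L, length(bytes), length.out = 65536L)))
    bytes <- bytes[as.integer(idx)]
  }
  h <- fnv1a(bytes)
  paste0(sprintf("%04x", as.integer(h %/% 65536)), sprintf("%04x", as.integer(h %% 65536)))
}

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "factconn_input_error")

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

unit_norm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)
  v / n
}
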