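# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so library internals can draw
#' deterministic numbers without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent condition class so callers can distinguish
# validation failures from I/O failures.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("scembed_validation_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("scembed_format_error", "error")))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_validation(...)
  invisible(TRUE)
}

# Stable 32-bit string hash (FNV-1a over UTF-8 bytes, arithmetic in doubles so
# the result is identical on every platform R runs on).
string_hash32 <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor of two nonnegative doubles < 2^32, done 16 bits at a time to stay exact.
bitwXor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

# Row-wise L2 normalization; zero rows stay zero.
l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
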