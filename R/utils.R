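`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

#' Stable small-integer hash for deriving substream seeds
#'
#' Maps an arbitrary character key and a base seed to an integer in
#' `[0, 2^31)`, so that independent pipeline stages get reproducible,
#' decorrelated seeds from one master seed.
#'
#' @param key character scalar.
#' @param base integer master seed.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(key, base = 0L) {
  bytes <- utf8ToInt(paste0(key, ":", base))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

softmax_weights <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

# Clip numeric vector/matrix into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
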