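`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a root seed and a stream label
#'
#' All randomness in a multi-stage run (splits, tariff bootstrap, symptom
#' subset draws, reference pools) flows from one root integer seed through
#' named substreams, so that any stage is reproducible in isolation.
#'
#' @param seed integer root seed.
#' @param ... labels (character or integer) identifying the substream.
#' @return an integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' child_seed(1, "splits", 17)
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# evaluate fn() under a temporary seed (NULL seed = use current RNG state)
with_seed_ <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(seed, fn())
}

stop_schema <- function(...) stop(..., call. = FALSE)
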