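## Internal helpers shared across modules.

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed; each stochastic
#' operation derives its own substream deterministically from the master seed
#' and a label, so stages can be re-run independently without correlated
#' streams.
#'
#' @param seed master integer seed.
#' @param label character label naming the substream.
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(seed) %% 2147480009 + h * 2654435 %% 2147480009) %% 2147480009)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## consistent stop() with a condition class so callers can test errors
pedqtl_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "pedqtl_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
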