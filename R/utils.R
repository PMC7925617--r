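#' @keywords internal
"_PACKAGE"

#' @importFrom stats median mad prcomp pnorm pchisq pt qnorm rnbinom runif
#'   rnorm rchisq sd var setNames complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream-specific RNG seed from the master seed so that each
# generator stage is reproducible independently of call order.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + 7919 * offset) %% 2147483647L
}

DNA_BASES <- c("A", "C", "G", "T")

stopf <- function(...) stop(sprintf(...), call. = FALSE)
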