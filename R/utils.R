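#' @keywords internal
#' @useDynLib ssaescreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Deterministic sub-seed derivation. Every stochastic step draws its own seed
## from the run seed plus a context tag so that adding a step never perturbs
## the streams of the others. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, ...) {
  tags <- unlist(list(...))
  h <- as.double(seed) %% 2147483629
  for (tag in tags) {
    for (ch in utf8ToInt(as.character(tag))) {
      h <- (h * 131 + ch) %% 2147483629
    }
  }
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
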