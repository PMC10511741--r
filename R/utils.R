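#' @useDynLib thermonet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif predict var sd
#' @importFrom utils read.csv write.csv head
NULL

#' Derive a reproducible sub-stream seed
#'
#' Folds a base seed and any number of integer tags into one 31-bit seed (a
#' small LCG over the parts), so that every random sub-stream in a pipeline
#' is a deterministic function of one master seed.  Results stay strictly
#' below 2^31, the portable range of [set.seed()].
#'
#' @param seed Base integer seed.
#' @param ... Further integer tags identifying the sub-stream.
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(s %% 2147483646) + 1L
}

clip01 <- function(x) {
  # dimension-preserving (pmin/pmax take attributes from their first arg)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
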