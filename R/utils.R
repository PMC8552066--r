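#' @useDynLib afdriverloc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif fft mvfft quantile sd cor predict
#' @importFrom utils head tail write.csv read.csv
NULL

#' Derive a child seed from a parent seed
#'
#' All stochastic stages receive sub-seeds derived deterministically from a
#' single run seed, so that a whole pipeline is reproducible from one
#' integer.  Values stay below 2^31 - 1.
#'
#' @param seed parent integer seed
#' @param stage character tag of the consuming stage
#' @return integer seed
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 9349) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cheap provenance fingerprint of a numeric object
#'
#' Not cryptographic; used only to tag derived artifacts (transfer matrices,
#' datasets) with the identity of their inputs.
#' @param x numeric object
#' @return character fingerprint
#' @export
fingerprint <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) return("empty")
  sprintf("%d-%.8e-%.8e-%.8e", length(v), sum(v), sum(v * seq_along(v) %% 97),
          max(abs(v)))
}

stop_af <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_af("'%s' must be a finite numeric scalar", name)
  invisible(x)
}
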