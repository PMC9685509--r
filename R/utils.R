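#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp evalCpp
#' @importFrom methods as
#' @importFrom stats rnorm runif rbinom rnbinom rpois rgamma pnorm pchisq
#'   sd var setNames as.formula logLik uniroot aggregate vcov
#' @importFrom utils read.csv write.csv head modifyList
#' @useDynLib worrytopics, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed
#'
#' Deterministic mixing of a master seed and a stage offset, kept strictly
#' inside the 32-bit integer range so it is always a valid `set.seed()` input.
#'
#' @param seed master integer seed
#' @param offset non-negative integer stage offset
#' @return an integer seed
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 69621) %%
               2147483562) + 1L
}

log_msg <- function(...) {
  message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)
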