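# Numerically safe link helpers shared across the package.

#' Inverse-logit (logistic) transform
#'
#' @param x numeric vector on the logit scale.
#' @return probabilities in (0, 1).
#' @export
invlogit <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow for large |x|
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x <= 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

# Bernoulli-logit log-likelihood contribution per row: s*eta - log(1+e^eta)
bern_logit_ll <- function(s, eta) s * eta - log1pexp(eta)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_zipfec <- function(...) stop(..., call. = FALSE)
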