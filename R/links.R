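#' Logit and inverse-logit links
#'
#' The logit link used for all eight occupancy/detection parameters.
#' `logit()` maps a probability in (0, 1) to the real line; `inv_logit()`
#' is its inverse, a monotone increasing map onto (0, 1).
#'
#' @param p probability, strictly inside (0, 1).
#' @param x real number (vectorised).
#' @return `logit()` returns a real vector; `inv_logit()` a probability
#'   vector.
#' @examples
#' inv_logit(0)            # 0.5
#' logit(inv_logit(1.7))   # 1.7
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("logit() requires probabilities strictly inside (0, 1)")
  stats::qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

## Row-wise log-sum-exp over a matrix of log terms; -Inf rows allowed.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0        # all -Inf row -> log(0) = -Inf anyway
  mx + log(rowSums(exp(m - mx)))
}

## Clamp probabilities away from 0/1 for log-likelihood arithmetic.
clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a
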