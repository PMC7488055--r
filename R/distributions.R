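# Inverse-gamma distribution, parameterised by shape (alpha) and rate (beta)
# with mean beta / (alpha - 1) for alpha > 1 -- the convention used for the
# theta and tau priors throughout this package.

#' Inverse-gamma density, random draws and quantiles
#'
#' If `X ~ InvGamma(shape, rate)` then `1/X ~ Gamma(shape, rate = rate)`.
#' The mean is `rate / (shape - 1)` for `shape > 1`.
#'
#' @param x,p,n Usual distribution-function arguments.
#' @param shape,rate Positive parameters.
#' @param log Return the log density.
#' @name invgamma
#' @export
dinvgamma <- function(x, shape, rate, log = FALSE) {
  if (shape <= 0 || rate <= 0) stop("shape and rate must be positive")
  ld <- ifelse(x > 0,
               shape * base::log(rate) - lgamma(shape) -
                 (shape + 1) * base::log(x) - rate / x,
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname invgamma
#' @export
rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

#' @rdname invgamma
#' @export
qinvgamma <- function(p, shape, rate) {
  1 / stats::qgamma(1 - p, shape = shape, rate = rate)
}

#' @rdname invgamma
#' @export
pinvgamma <- function(x, shape, rate) {
  stats::pgamma(1 / x, shape = shape, rate = rate, lower.tail = FALSE)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
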