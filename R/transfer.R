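#' Static nonlinearity of the LNP neuron
#'
#' Evaluates the transfer function
#' \deqn{f(h) = r\,a \log\left(1 + e^{(h - h_0)/a}\right)}
#' mapping input potential (mV) to a firing rate (Hz), with an exponential
#' subthreshold tail and a linear suprathreshold branch of slope `r`. For
#' `a = 0` the threshold-linear limit \eqn{f(h) = r [h - h_0]_+} is used.
#'
#' The softplus is evaluated piecewise: for \eqn{(h - h_0)/a > 30} the linear
#' asymptote plus `log1p(exp(-z))` correction is used so that large arguments
#' neither overflow nor lose the (negligible) exponential correction.
#'
#' @param h input potential (mV), numeric vector.
#' @param p a [transfer_params()] object.
#' @return Firing rate(s) in Hz, same length as `h`.
#' @examples
#' p <- transfer_params(r = 3.15, a = 0.2, h0 = 2)
#' transfer_function(2, p)  # r * a * log(2)
#' @export
transfer_function <- function(h, p) {
  stopifnot(inherits(p, "transfer_params"))
  if (!is.numeric(h) || anyNA(h) || any(!is.finite(h)))
    stop("'h' must be finite numeric")
  if (p$a == 0) return(p$r * pmax(h - p$h0, 0))
  z <- (h - p$h0) / p$a
  out <- numeric(length(z))
  hi <- z > 30
  lo <- !hi
  # softplus(z) = z + log1p(exp(-z)) for large z; log1p(exp(z)) otherwise
  out[hi] <- z[hi] + log1p(exp(-z[hi]))
  out[lo] <- log1p(exp(z[lo]))
  p$r * p$a * out
}

#' Derivative of the transfer function
#'
#' \eqn{f'(h) = r / (1 + e^{-(h-h_0)/a})}, the logistic sigmoid scaled by the
#' slope; for `a = 0` the step \eqn{r \cdot 1\{h > h_0\}}.
#'
#' @inheritParams transfer_function
#' @return Derivative in Hz/mV.
#' @export
transfer_deriv <- function(h, p) {
  stopifnot(inherits(p, "transfer_params"))
  if (!is.numeric(h) || anyNA(h) || any(!is.finite(h)))
    stop("'h' must be finite numeric")
  if (p$a == 0) return(p$r * as.numeric(h > p$h0))
  p$r * stats::plogis((h - p$h0) / p$a)
}
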