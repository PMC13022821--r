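#' Inverse Mills ratio
#'
#' Computes the hazard function of the standard normal distribution,
#' \eqn{\lambda(\Lambda) = \phi(\Lambda) / (1 - \Phi(\Lambda))}, elementwise.
#' This is the correction regressor of Heckman's two-step estimator.  The
#' computation is carried out on the log scale so it neither underflows for
#' very negative arguments nor overflows for large positive ones (finite and
#' accurate at least over |Lambda| <= 40).
#'
#' @param lp Numeric vector of linear predictors (finite).
#' @return Numeric vector, \eqn{\lambda(\Lambda)} elementwise.  Always
#'   positive, strictly increasing, and bounded below by
#'   \eqn{\max(0, \Lambda)}.
#' @examples
#' inverse_mills(0)       # dnorm(0) / 0.5
#' inverse_mills(c(-30, 30))
#' @export
inverse_mills <- function(lp) {
  if (any(!is.finite(lp))) stop("inverse_mills: non-finite input")
  exp(stats::dnorm(lp, log = TRUE) -
        stats::pnorm(lp, lower.tail = FALSE, log.p = TRUE))
}

## phi(c)/Phi(c), the selected-probability form of the Mills ratio used in
## the second-stage regression: equals inverse_mills(-c).
.mills_sel <- function(c) {
  exp(stats::dnorm(c, log = TRUE) - stats::pnorm(c, log.p = TRUE))
}
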