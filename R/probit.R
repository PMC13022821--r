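#' Probit regression for a selection indicator
#'
#' Maximum-likelihood probit fit of a binary selection indicator on a design
#' matrix, used as the first stage of Heckman's sample selection model.  The
#' covariance matrix is the inverse of the observed information at the
#' optimum.
#'
#' @param selection_design n x q numeric matrix including an intercept.
#' @param selected Logical or 0/1 vector of length n.
#' @param max_iter Maximum IRLS iterations.
#' @return List with `gamma` (coefficients), `vcov` (inverse observed
#'   information), `linear_predictor`, `loglik`, `iterations`.
#' @examples
#' set.seed(1)
#' w <- cbind(1, z = rnorm(500))
#' r <- runif(500) < pnorm(0.3 + 0.6 * w[, 2])
#' fit_probit(w, r)$gamma
#' @export
fit_probit <- function(selection_design, selected, max_iter = 100L) {
  selection_design <- as.matrix(selection_design)
  r <- as.numeric(selected)
  if (!all(r %in% c(0, 1))) stop("selected must be binary")
  if (all(r == 1) || all(r == 0))
    stop("fit_probit: both selected and non-selected individuals required")
  if (any(apply(selection_design, 2L, function(col) all(col == 0))))
    stop("fit_probit: constant-zero column in selection design")
  fit <- suppressWarnings(
    stats::glm.fit(selection_design, r,
                   family = stats::binomial(link = "probit"),
                   control = list(maxit = max_iter)))
  if (!fit$converged)
    stop("fit_probit: no convergence after ", max_iter,
         " iterations (final deviance ", format(fit$deviance), ")")
  gamma <- fit$coefficients
  if (anyNA(gamma))
    stop("fit_probit: rank-deficient selection design")
  eta <- drop(selection_design %*% gamma)
  ## complete / quasi-complete separation: likelihood has no interior maximum
  if (fit$deviance < 1e-6 || max(abs(eta)) > 30)
    stop("fit_probit: (quasi-)complete separation detected; the probit ",
         "likelihood is maximized on the boundary")
  ## observed information: for r=1 the weight is m(m+eta), m = phi/Phi;
  ## for r=0 it is mt(mt-eta), mt = phi/(1-Phi).  Both strictly positive.
  m <- .mills_sel(eta)
  mt <- inverse_mills(eta)
  w <- ifelse(r == 1, m * (m + eta), mt * (mt - eta))
  info <- crossprod(selection_design * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e)
    stop("fit_probit: singular observed information"))
  ll <- sum(r * stats::pnorm(eta, log.p = TRUE) +
              (1 - r) * stats::pnorm(-eta, log.p = TRUE))
  list(gamma = gamma, vcov = vc, linear_predictor = eta, loglik = ll,
       iterations = fit$iter)
}
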