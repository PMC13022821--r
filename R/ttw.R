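#' Logistic propensity model for selection
#'
#' Maximum-likelihood logistic regression of the selection indicator on a
#' design matrix (covariates plus the instrument for selection), the first
#' stage of the homogeneous-selection-bias estimator.
#'
#' @param design n x q numeric matrix including an intercept.
#' @param selected Logical or 0/1 vector of length n.
#' @return List with `alpha_prop` (coefficients), `fitted_pi` (selection
#'   probabilities, in (0,1)), `vcov`, `loglik`.
#' @examples
#' set.seed(1)
#' w <- cbind(1, z = rnorm(400))
#' r <- runif(400) < plogis(0.4 * w[, 2])
#' fit_propensity(w, r)$alpha_prop
#' @export
fit_propensity <- function(design, selected) {
  design <- as.matrix(design)
  r <- as.numeric(selected)
  if (all(r == 1) || all(r == 0))
    stop("fit_propensity: both classes required")
  fit <- suppressWarnings(
    stats::glm.fit(design, r, family = stats::binomial()))
  if (!fit$converged) stop("fit_propensity: no convergence")
  alpha <- fit$coefficients
  if (anyNA(alpha)) stop("fit_propensity: rank-deficient design")
  eta <- drop(design %*% alpha)
  if (fit$deviance < 1e-6 || max(abs(eta)) > 30)
    stop("fit_propensity: (quasi-)complete separation detected")
  pi_hat <- stats::plogis(eta)
  info <- crossprod(design * sqrt(pi_hat * (1 - pi_hat)))
  ll <- sum(stats::dbinom(r, 1, pi_hat, log = TRUE))
  list(alpha_prop = alpha, fitted_pi = pi_hat,
       vcov = solve(info), loglik = ll)
}

#' Log-likelihood of the homogeneous-selection-bias model
#'
#' Evaluates the joint log-likelihood of the selection indicator and the
#' observed outcomes under the homogeneous selection bias model: every
#' individual contributes a Bernoulli term for selection with probability
#' \eqn{\pi_i = \mathrm{expit}(w_i'\alpha)}, and each selected individual a
#' normal density term with mean \eqn{x_i'\beta + (x_i'\eta)(1 - \pi_i)}
#' and variance \eqn{\sigma^2}, where \eqn{x'\eta} is the selection-bias
#' function.
#'
#' @param params Numeric vector `c(beta, eta, alpha, sigma2)` with `beta`
#'   and `eta` of length `ncol(outcome_design)` and `alpha` of length
#'   `ncol(selection_design)`; `sigma2` must be positive.
#' @param data A [selection_data] object (linear family).
#' @return Scalar log-likelihood.
#' @seealso [ttw_fit()]
#' @export
ttw_loglik <- function(params, data) {
  stopifnot(inherits(data, "selection_data"))
  X <- data$outcome_design; W <- data$selection_design
  p <- ncol(X); q <- ncol(W)
  stopifnot(length(params) == 2 * p + q + 1)
  beta <- params[seq_len(p)]
  eta <- params[p + seq_len(p)]
  alpha <- params[2 * p + seq_len(q)]
  sigma2 <- params[2 * p + q + 1]
  if (sigma2 <= 0) stop("sigma2 must be positive")
  r <- as.numeric(data$selected)
  pi_hat <- stats::plogis(drop(W %*% alpha))
  ll_sel <- sum(stats::dbinom(r, 1, pi_hat, log = TRUE))
  if (!is.finite(ll_sel))
    stop("non-finite Bernoulli term in ttw_loglik")
  sel <- data$selected
  mu <- drop(X[sel, , drop = FALSE] %*% beta) +
    drop(X[sel, , drop = FALSE] %*% eta) * (1 - pi_hat[sel])
  ll_out <- sum(stats::dnorm(data$outcome[sel], mu, sqrt(sigma2),
                             log = TRUE))
  if (!is.finite(ll_out))
    stop("non-finite outcome density term in ttw_loglik")
  ll_sel + ll_out
}

#' Homogeneous-selection-bias (TTW) estimator
#'
#' Fits the outcome regression \eqn{E(Y|X) = g^{-1}(X'\beta)} under MNAR
#' selection using an instrument for selection, via the homogeneous
#' selection bias assumption: the selected-vs-nonselected contrast
#' \eqn{\delta(X) = X'\eta} depends on the covariates but not on the
#' instrument.  The observed-data regression then satisfies, on the link
#' scale, \eqn{X'\beta + \delta(X)(1 - \pi(X, Z))} with a logistic
#' propensity \eqn{\pi}.
#'
#' With `mode = "partial"` the propensity is fitted first and the outcome
#' likelihood is maximized with \eqn{\pi} held fixed; since the mean is then
#' linear in \eqn{(\beta, \eta)} on the link scale this stage is an exact
#' (generalized) least-squares problem solved in closed form.  With
#' `mode = "full"` all parameters are maximized jointly by quasi-Newton,
#' started at the partial solution.  Standard errors invert the negative
#' Hessian of the corresponding objective; partial-mode standard errors
#' deliberately ignore first-stage propensity uncertainty (see
#' [ttw_bootstrap_se()] for a resampling alternative).
#'
#' @param data A [selection_data] object.
#' @param family Outcome family: `"linear"`, `"logistic"` or `"poisson"`.
#'   Defaults to the family recorded in `data`.
#' @param mode `"partial"` (default) or `"full"` optimization.
#' @param bias_design Optional matrix of columns for the selection-bias
#'   function \eqn{\delta}; defaults to the outcome design.
#' @param max_iter Maximum optimizer iterations for full mode.
#' @return An object of class `"ttw_fit"` with components `beta`, `eta`,
#'   `alpha_prop`, `sigma2` (linear family only), `beta_se`, `eta_se`,
#'   `alpha_se`, `loglik` (selection + outcome terms), `mode`, `family`.
#' @examples
#' d <- sim_heckman_example(n = 800, seed = 5)
#' fit <- ttw_fit(d)
#' coef(fit)
#' @export
ttw_fit <- function(data, family = NULL,
                    mode = c("partial", "full"), bias_design = NULL,
                    max_iter = 1000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "selection_data"))
  if (is.null(family)) family <- data$family
  family <- match.arg(family, c("linear", "logistic", "poisson"))
  X <- data$outcome_design
  W <- data$selection_design
  Xd <- if (is.null(bias_design)) X else as.matrix(bias_design)
  r <- data$selected
  y <- data$outcome
  p <- ncol(X); pd <- ncol(Xd); q <- ncol(W)
  if (family == "logistic" && !all(y[r] %in% c(0, 1)))
    stop("logistic family requires a binary outcome on selected rows")
  if (family == "poisson" && any(y[r] < 0 | y[r] != floor(y[r])))
    stop("poisson family requires nonnegative integer outcomes")

  ## identification needs an instrument: at least one selection-design
  ## column outside the span of the outcome design
  resid_w <- W - X %*% qr.coef(qr(X), W)
  resid_w[is.na(resid_w)] <- 0
  if (max(sqrt(colMeans(resid_w^2))) < 1e-8)
    stop("ttw_fit: selection design adds no column beyond the outcome ",
         "design; an instrument for selection is required for ",
         "identification")

  prop <- fit_propensity(W, r)
  pi1 <- prop$fitted_pi[r]
  X1 <- X[r, , drop = FALSE]
  Xd1 <- Xd[r, , drop = FALSE]
  y1 <- y[r]
  A <- cbind(X1, Xd1 * (1 - pi1))
  colnames(A) <- c(colnames(X), paste0("bias:", colnames(Xd)))
  if (kappa(qr.R(qr(A)), exact = FALSE) > 1e10)
    stop("ttw_fit: bias columns nearly collinear with the outcome design ",
         "(weak or absent instrument for selection); beta and eta are not ",
         "separably estimable")

  ## stage 2, propensity fixed: a GLM in (beta, eta) on the augmented design
  if (family == "linear") {
    qrA <- qr(A)
    coefs <- qr.coef(qrA, y1)
    res <- y1 - drop(A %*% coefs)
    n1 <- length(y1)
    sigma2 <- sum(res^2) / n1            # MLE, matching the Hessian-based SE
    Vmean <- sigma2 * chol2inv(qr.R(qrA))
    ll_out <- sum(stats::dnorm(y1, drop(A %*% coefs), sqrt(sigma2),
                               log = TRUE))
  } else {
    fam <- if (family == "logistic") stats::binomial() else stats::poisson()
    gfit <- suppressWarnings(stats::glm.fit(A, y1, family = fam))
    if (!gfit$converged) stop("ttw_fit: stage-2 GLM did not converge")
    coefs <- gfit$coefficients
    if (anyNA(coefs)) stop("ttw_fit: stage-2 design rank deficient")
    mu <- fam$linkinv(drop(A %*% coefs))
    wts <- if (family == "logistic") mu * (1 - mu) else mu
    Vmean <- solve(crossprod(A * sqrt(wts)))
    sigma2 <- NULL
    ll_out <- if (family == "logistic")
      sum(stats::dbinom(y1, 1, mu, log = TRUE))
    else sum(stats::dpois(y1, mu, log = TRUE))
  }
  beta <- coefs[seq_len(p)]
  eta <- coefs[p + seq_len(pd)]
  loglik <- prop$loglik + ll_out

  if (mode == "partial") {
    ses <- sqrt(pmax(diag(Vmean), 0))
    return(.new_ttw_fit(beta, eta, prop$alpha_prop, sigma2,
                        beta_se = ses[seq_len(p)],
                        eta_se = ses[p + seq_len(pd)],
                        alpha_se = sqrt(diag(prop$vcov)),
                        vcov_beta = Vmean[seq_len(p), seq_len(p),
                                          drop = FALSE],
                        loglik = loglik, mode = "partial", family = family,
                        data = data))
  }

  ## full mode: joint quasi-Newton over (beta, eta, alpha[, log sigma2])
  npar <- p + pd + q + (family == "linear")
  start <- c(beta, eta, prop$alpha_prop,
             if (family == "linear") log(sigma2))
  nll <- function(par) {
    b <- par[seq_len(p)]; e <- par[p + seq_len(pd)]
    a <- par[p + pd + seq_len(q)]
    pi_hat <- stats::plogis(drop(W %*% a))
    ll_sel <- sum(stats::dbinom(as.numeric(r), 1, pi_hat, log = TRUE))
    lp <- drop(X1 %*% b) + drop(Xd1 %*% e) * (1 - pi_hat[r])
    ll_out <- switch(family,
      linear = {
        s2 <- exp(par[npar])
        sum(stats::dnorm(y1, lp, sqrt(s2), log = TRUE))
      },
      logistic = sum(stats::dbinom(y1, 1, stats::plogis(lp), log = TRUE)),
      poisson = sum(stats::dpois(y1, exp(pmin(lp, 500)), log = TRUE)))
    val <- ll_sel + ll_out
    if (!is.finite(val)) return(1e10)
    -val
  }
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("ttw_fit (full) did not converge (optim code ",
         opt$convergence, ")")
  pol <- .newton_polish(opt$par, nll)
  opt$par <- pol$par; opt$value <- pol$value
  H <- stats::optimHess(opt$par, nll)
  vc <- tryCatch(solve(H), error = function(e)
    stop("ttw_fit: Hessian not invertible at the optimum (flat ",
         "likelihood, typically a weak instrument for selection)"))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("ttw_fit: Hessian not positive definite at the optimum (flat ",
         "likelihood, typically a weak instrument for selection)")
  par <- opt$par
  ses <- sqrt(pmax(diag(vc), 0))
  .new_ttw_fit(
    beta = stats::setNames(par[seq_len(p)], colnames(X)),
    eta = stats::setNames(par[p + seq_len(pd)], colnames(Xd)),
    alpha_prop = stats::setNames(par[p + pd + seq_len(q)], colnames(W)),
    sigma2 = if (family == "linear") exp(par[npar]),
    beta_se = ses[seq_len(p)], eta_se = ses[p + seq_len(pd)],
    alpha_se = ses[p + pd + seq_len(q)],
    vcov_beta = vc[seq_len(p), seq_len(p), drop = FALSE],
    loglik = -opt$value, mode = "full", family = family, data = data)
}

#' Bootstrap standard errors for the TTW estimator
#'
#' Nonparametric bootstrap of [ttw_fit()], resampling individuals with
#' replacement, as a sensitivity check on the Hessian-based standard errors
#' of the partial optimization (which ignore first-stage propensity
#' uncertainty).
#'
#' @inheritParams ttw_fit
#' @param M Number of bootstrap resamples.
#' @param seed RNG seed.
#' @return Numeric vector of bootstrap standard errors for `beta`, with an
#'   attribute `n_failed` counting resamples whose fit failed.
#' @export
ttw_bootstrap_se <- function(data, family = NULL, mode = "partial",
                             M = 100L, seed = 1L) {
  stopifnot(M >= 2)
  set.seed(seed)
  p <- ncol(data$outcome_design)
  est <- matrix(NA_real_, M, p)
  for (j in seq_len(M)) {
    idx <- sample.int(data$n, data$n, replace = TRUE)
    bd <- selection_data(data$outcome[idx],
                         data$outcome_design[idx, , drop = FALSE],
                         data$selection_design[idx, , drop = FALSE],
                         selected = data$selected[idx],
                         family = data$family)
    fit <- tryCatch(ttw_fit(bd, family = family, mode = mode),
                    error = function(e) NULL)
    if (!is.null(fit)) est[j, ] <- fit$beta
  }
  ok <- stats::complete.cases(est)
  if (mean(!ok) > 0.2)
    stop("ttw_bootstrap_se: more than 20% of resamples failed")
  out <- apply(est[ok, , drop = FALSE], 2L, stats::sd)
  attr(out, "n_failed") <- sum(!ok)
  out
}

.new_ttw_fit <- function(beta, eta, alpha_prop, sigma2, beta_se, eta_se,
                         alpha_se, vcov_beta, loglik, mode, family, data) {
  beta_se <- stats::setNames(as.numeric(beta_se), names(beta))
  eta_se <- stats::setNames(as.numeric(eta_se), names(eta))
  structure(list(beta = beta, eta = eta, alpha_prop = alpha_prop,
                 sigma2 = sigma2, beta_se = beta_se, eta_se = eta_se,
                 alpha_se = alpha_se, vcov = vcov_beta, loglik = loglik,
                 mode = mode, family = family, n = data$n,
                 n_selected = sum(data$selected)),
            class = "ttw_fit")
}

#' @export
coef.ttw_fit <- function(object, ...) object$beta

#' @export
vcov.ttw_fit <- function(object, ...) object$vcov

#' @export
logLik.ttw_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$beta) + length(object$eta) +
              length(object$alpha_prop) + !is.null(object$sigma2),
            class = "logLik")
}

#' @export
confint.ttw_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$beta - z * object$beta_se,
              object$beta + z * object$beta_se)
  rownames(ci) <- names(object$beta)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.ttw_fit <- function(x, digits = 4, ...) {
  cat("Homogeneous-selection-bias (TTW) fit [", x$family, ", ",
      x$mode, " optimization]\n", sep = "")
  cat("n =", x$n, "(", x$n_selected, "selected )\n")
  print(round(cbind(estimate = x$beta, se = x$beta_se), digits))
  cat("bias function eta:",
      paste(format(x$eta, digits = digits), collapse = " "), "\n")
  if (!is.null(x$sigma2))
    cat("sigma2 =", format(x$sigma2, digits = digits), "\n")
  cat("log-likelihood:", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' @export
summary.ttw_fit <- function(object, ...) {
  zval <- object$beta / object$beta_se
  tab <- cbind(Estimate = object$beta, `Std. Error` = object$beta_se,
               `z value` = zval,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.ttw_fit"
  out
}

#' @export
print.summary.ttw_fit <- function(x, ...) {
  print(x$fit)
  cat("\nOutcome equation:\n")
  stats::printCoefmat(x$coefficients)
  cat("\nBias function:\n")
  stats::printCoefmat(cbind(Estimate = x$fit$eta,
                            `Std. Error` = x$fit$eta_se))
  invisible(x)
}
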