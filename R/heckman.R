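#' Heckman's sample selection model, two-step estimator
#'
#' Fits the linear outcome model \eqn{Y = X'\beta + \epsilon} when the
#' outcome is observed only where a correlated latent selection process is
#' positive.  Stage one is a probit regression of the selection indicator on
#' the selection design (which must contain an instrument for selection
#' excluded from the outcome design); stage two regresses the observed
#' outcomes on the outcome design augmented with the inverse Mills ratio
#' evaluated at the probit fit.  The coefficient on the Mills ratio estimates
#' \eqn{\sigma_{12}/\sigma_2} (the error-covariance term driving the
#' selection bias); under the probit normalization \eqn{\sigma_2 = 1} the
#' Mills ratio can be written \eqn{\phi(w'\gamma)/\Phi(w'\gamma)}, the form
#' used internally for numerical stability.
#'
#' Standard errors use Heckman's correction for the two-step procedure,
#' which accounts for the heteroskedasticity of the stage-two residuals and
#' for the first-stage estimation of \eqn{\gamma}.  Plain OLS standard
#' errors are available for diagnostics via `se = "ols"`.
#'
#' @param data A [selection_data] object with a linear-family outcome.
#' @param se `"corrected"` (default) for the Heckman two-step covariance,
#'   `"ols"` for unadjusted least-squares standard errors.
#' @return An object of class `"heckman_fit"` with components `beta`,
#'   `beta_se`, `gamma`, `gamma_se`, `rho_sigma` (coefficient on the Mills
#'   ratio, \eqn{\hat\rho\hat\sigma_1}), `rho`, `sigma1`, `vcov`, `method`,
#'   `loglik` (`NA` for the two-step fit), `n`, `n_selected`.
#' @seealso [heckman_ml()], [heckman_binary_ml()], [selection_data()]
#' @examples
#' d <- sim_heckman_example(n = 800, seed = 2)
#' fit <- heckman_two_step(d)
#' coef(fit)
#' @export
heckman_two_step <- function(data, se = c("corrected", "ols")) {
  se <- match.arg(se)
  stopifnot(inherits(data, "selection_data"))
  if (data$family != "linear")
    stop("heckman_two_step requires a linear-family outcome; see ",
         "heckman_binary_ml for binary outcomes")
  r <- data$selected
  X <- data$outcome_design
  W <- data$selection_design
  p <- ncol(X)
  if (sum(r) < p + 2) stop("too few selected individuals")

  if (all(r)) {
    warning("all individuals selected: the selection model is vacuous; ",
            "returning the OLS fit")
    ols <- .ols_fit(X, data$outcome)
    return(.new_heckman_fit(beta = ols$beta, beta_se = ols$se,
                            vcov_beta = ols$vcov,
                            gamma = NULL, gamma_se = NULL,
                            rho_sigma = 0, rho = 0, sigma1 = ols$sigma,
                            loglik = NA_real_, method = "two_step",
                            data = data, note = "all_selected"))
  }

  step1 <- fit_probit(W, r)
  cc <- step1$linear_predictor          # w'gamma, selected-probability scale
  lam <- .mills_sel(cc)                 # phi/Phi, = inverse_mills(-cc)

  X1 <- X[r, , drop = FALSE]
  y1 <- data$outcome[r]
  lam1 <- lam[r]
  D <- cbind(X1, imr = lam1)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    ## Mills ratio column exactly aliased (e.g. intercept-only selection
    ## design): drop it; the selection correction is absorbed elsewhere.
    warning("inverse Mills ratio is aliased with the outcome design; ",
            "dropping the correction term (no exclusion information)")
    ols <- .ols_fit(X1, y1)
    return(.new_heckman_fit(beta = ols$beta, beta_se = ols$se,
                            vcov_beta = ols$vcov,
                            gamma = step1$gamma,
                            gamma_se = sqrt(diag(step1$vcov)),
                            rho_sigma = NA_real_, rho = NA_real_,
                            sigma1 = ols$sigma, loglik = NA_real_,
                            method = "two_step", data = data,
                            note = "imr_aliased"))
  }
  if (kappa(qr.R(qrD), exact = FALSE) > 1e8)
    stop("inverse Mills ratio nearly collinear with the outcome design: ",
         "the instrument for selection adds no exclusion information")

  b <- qr.coef(qrD, y1)
  e <- y1 - drop(D %*% b)
  n1 <- length(y1)
  bl <- b[["imr"]]                      # sigma12/sigma2 = rho * sigma1
  c1 <- cc[r]
  delta <- lam1 * (lam1 + c1)           # in (0,1)
  sigma2 <- sum(e^2) / n1 + mean(delta) * bl^2
  sigma1 <- sqrt(sigma2)
  rho <- max(-1, min(1, bl / sigma1))

  DtDinv <- chol2inv(qr.R(qrD))
  if (se == "corrected") {
    W1 <- W[r, , drop = FALSE]
    A <- crossprod(D, (1 - rho^2 * delta) * D)
    B <- crossprod(D, delta * W1)       # (p+1) x q
    Q <- rho^2 * B %*% step1$vcov %*% t(B)
    V <- sigma2 * DtDinv %*% (A + Q) %*% DtDinv
  } else {
    s2_ols <- sum(e^2) / (n1 - ncol(D))
    V <- s2_ols * DtDinv
  }
  ses <- sqrt(pmax(diag(V), 0))
  .new_heckman_fit(beta = b[seq_len(p)], beta_se = ses[seq_len(p)],
                   vcov_beta = V[seq_len(p), seq_len(p), drop = FALSE],
                   gamma = step1$gamma, gamma_se = sqrt(diag(step1$vcov)),
                   rho_sigma = bl, rho_sigma_se = ses[p + 1],
                   rho = rho, sigma1 = sigma1,
                   loglik = NA_real_, method = "two_step", data = data,
                   residuals = e)
}

#' Heckman's sample selection model, maximum likelihood
#'
#' Joint maximum-likelihood fit of the bivariate-normal sample selection
#' model over \eqn{(\beta, \gamma, \sigma_1, \rho)}, with the selection
#' error variance fixed at one (probit normalization) and \eqn{\rho}
#' unconstrained through an arctanh transform.  Standard errors come from
#' the inverse negative Hessian at the optimum.
#'
#' @inheritParams heckman_two_step
#' @param start Optional named start: list/vector of `beta`, `gamma`,
#'   `log_sigma`, `atanh_rho`.  Defaults to the two-step estimates.
#' @param max_iter Maximum BFGS iterations.
#' @return A `"heckman_fit"` object (see [heckman_two_step()]) with
#'   `method = "ml"` and a finite `loglik`.  If \eqn{|\hat\rho|} lies within
#'   1e-6 of the boundary the fit carries a `"boundary"` attribute/warning.
#' @examples
#' d <- sim_heckman_example(n = 800, seed = 3)
#' fit <- heckman_ml(d)
#' summary(fit)
#' @export
heckman_ml <- function(data, start = NULL, max_iter = 500L) {
  stopifnot(inherits(data, "selection_data"))
  if (data$family != "linear")
    stop("heckman_ml requires a linear-family outcome")
  r <- data$selected
  X <- data$outcome_design
  W <- data$selection_design
  p <- ncol(X); q <- ncol(W)
  y <- data$outcome

  if (all(r)) {
    warning("all individuals selected: returning the OLS fit")
    ols <- .ols_fit(X, y)
    return(.new_heckman_fit(beta = ols$beta, beta_se = ols$se,
                            vcov_beta = ols$vcov, gamma = NULL,
                            gamma_se = NULL, rho_sigma = 0, rho = 0,
                            sigma1 = ols$sigma, loglik = NA_real_,
                            method = "ml", data = data,
                            note = "all_selected"))
  }

  if (is.null(start)) {
    ts <- tryCatch(suppressWarnings(heckman_two_step(data)),
                   error = function(e) NULL)
    if (is.null(ts) || is.na(ts$rho)) {
      cc <- .ols_fit(X[r, , drop = FALSE], y[r])
      start <- c(cc$beta, fit_probit(W, r)$gamma, log(cc$sigma), 0)
    } else {
      start <- c(ts$beta, ts$gamma, log(ts$sigma1),
                 atanh(max(-0.99, min(0.99, ts$rho))))
    }
  } else start <- as.numeric(unlist(start))
  stopifnot(length(start) == p + q + 2)

  idx_b <- seq_len(p); idx_g <- p + seq_len(q)
  y1 <- y[r]; X1 <- X[r, , drop = FALSE]
  W1 <- W[r, , drop = FALSE]; W0 <- W[!r, , drop = FALSE]
  nll <- function(par) {
    beta <- par[idx_b]; gamma <- par[idx_g]
    s <- exp(par[p + q + 1])
    rho <- max(-1 + 1e-12, min(1 - 1e-12, tanh(par[p + q + 2])))
    eta0 <- drop(W0 %*% gamma); eta1 <- drop(W1 %*% gamma)
    z <- (y1 - drop(X1 %*% beta)) / s
    arg <- (eta1 + rho * z) / sqrt(1 - rho^2)
    ll <- sum(stats::pnorm(-eta0, log.p = TRUE)) +
      sum(stats::dnorm(z, log = TRUE) - log(s) +
            stats::pnorm(arg, log.p = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("heckman_ml did not converge (optim code ", opt$convergence, ")")
  pol <- .newton_polish(opt$par, nll)
  opt$par <- pol$par; opt$value <- pol$value
  H <- stats::optimHess(opt$par, nll)
  vc <- tryCatch(solve(H), error = function(e)
    stop("heckman_ml: singular Hessian at the optimum"))
  par <- opt$par
  rho <- tanh(par[p + q + 2]); sigma1 <- exp(par[p + q + 1])
  ses <- sqrt(pmax(diag(vc), 0))
  fit <- .new_heckman_fit(
    beta = stats::setNames(par[idx_b], colnames(X)),
    beta_se = ses[idx_b],
    vcov_beta = vc[idx_b, idx_b, drop = FALSE],
    gamma = stats::setNames(par[idx_g], colnames(W)),
    gamma_se = ses[idx_g],
    rho_sigma = rho * sigma1, rho = rho, sigma1 = sigma1,
    loglik = -opt$value, method = "ml", data = data)
  if (abs(abs(rho) - 1) < 1e-6) {
    warning("heckman_ml: correlation estimate on the boundary (|rho| = 1)")
    fit$boundary <- TRUE
  }
  fit
}

#' Heckman-type selection model for a binary outcome (bivariate probit)
#'
#' Selection model for a binary outcome: a latent outcome and a latent
#' selection process share correlated standard-normal errors; the binary
#' outcome is observed only for selected individuals.  Coefficients are on
#' the probit scale.  Fitted by maximum likelihood, with the bivariate
#' normal CDF evaluated by a vectorized Gauss-Legendre quadrature.
#'
#' @inheritParams heckman_ml
#' @return A `"heckman_fit"` object with `method = "binary_ml"`;
#'   `sigma1` is fixed at 1 (probit normalization of the outcome).
#' @examples
#' d <- sim_heckman_example(n = 800, seed = 4, binary = TRUE)
#' heckman_binary_ml(d)
#' @export
heckman_binary_ml <- function(data, start = NULL, max_iter = 500L) {
  stopifnot(inherits(data, "selection_data"))
  r <- data$selected
  X <- data$outcome_design
  W <- data$selection_design
  p <- ncol(X); q <- ncol(W)
  y <- data$outcome
  if (!all(y[r] %in% c(0, 1))) stop("outcome must be binary on selected rows")

  if (is.null(start)) {
    pr_y <- suppressWarnings(
      stats::glm.fit(X[r, , drop = FALSE], y[r],
                     family = stats::binomial(link = "probit")))
    start <- c(pr_y$coefficients, fit_probit(W, r)$gamma, 0)
  }
  stopifnot(length(start) == p + q + 1)
  idx_b <- seq_len(p); idx_g <- p + seq_len(q)
  sel1 <- r & y == 1; sel0 <- r & y == 0
  X11 <- X[sel1, , drop = FALSE]; W11 <- W[sel1, , drop = FALSE]
  X10 <- X[sel0, , drop = FALSE]; W10 <- W[sel0, , drop = FALSE]
  W0 <- W[!r, , drop = FALSE]
  nll <- function(par) {
    beta <- par[idx_b]; gamma <- par[idx_g]
    rho <- max(-1 + 1e-12, min(1 - 1e-12, tanh(par[p + q + 1])))
    ll <- sum(stats::pnorm(-drop(W0 %*% gamma), log.p = TRUE)) +
      sum(log(pmax(pbinorm(drop(X11 %*% beta), drop(W11 %*% gamma), rho),
                   1e-300))) +
      sum(log(pmax(pbinorm(-drop(X10 %*% beta), drop(W10 %*% gamma), -rho),
                   1e-300)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("heckman_binary_ml did not converge (optim code ",
         opt$convergence, ")")
  H <- stats::optimHess(opt$par, nll)
  vc <- tryCatch(solve(H), error = function(e)
    stop("heckman_binary_ml: singular Hessian at the optimum"))
  par <- opt$par; rho <- tanh(par[p + q + 1])
  ses <- sqrt(pmax(diag(vc), 0))
  fit <- .new_heckman_fit(
    beta = stats::setNames(par[idx_b], colnames(X)),
    beta_se = ses[idx_b],
    vcov_beta = vc[idx_b, idx_b, drop = FALSE],
    gamma = stats::setNames(par[idx_g], colnames(W)),
    gamma_se = ses[idx_g],
    rho_sigma = rho, rho = rho, sigma1 = 1,
    loglik = -opt$value, method = "binary_ml", data = data)
  if (abs(abs(rho) - 1) < 1e-6) {
    warning("heckman_binary_ml: correlation estimate on the boundary")
    fit$boundary <- TRUE
  }
  fit
}

#' Bivariate standard normal CDF
#'
#' Vectorized \eqn{P(U \le h, V \le k)} for standard normal \eqn{(U, V)}
#' with correlation `rho`, by Gauss-Legendre quadrature of the
#' Drezner-Wesolowsky single-integral representation.  Accurate to roughly
#' 1e-12 for moderate correlations.
#'
#' @param h,k Numeric vectors (recycled to common length).
#' @param rho Scalar correlation in (-1, 1).
#' @return Numeric vector of probabilities.
#' @examples
#' pbinorm(0, 0, 0.5)   # 1/4 + asin(0.5) / (2*pi)
#' @export
pbinorm <- function(h, k, rho) {
  stopifnot(length(rho) == 1, abs(rho) < 1)
  nmax <- max(length(h), length(k))
  h <- rep_len(h, nmax); k <- rep_len(k, nmax)
  if (rho == 0) return(stats::pnorm(h) * stats::pnorm(k))
  gl <- .gauss_legendre_32
  up <- asin(rho)
  theta <- up / 2 * (gl$x + 1)          # nodes on (0, asin(rho))
  st <- sin(theta); ct2 <- cos(theta)^2
  ## integrand evaluated on an nmax x 32 grid
  f <- exp(-(outer(h^2 + k^2, ct2, "/") -
               outer(2 * h * k, st) / rep(ct2, each = nmax)) / 2)
  integral <- drop(f %*% gl$w) * up / 2
  pmin(pmax(stats::pnorm(h) * stats::pnorm(k) + integral / (2 * pi), 0), 1)
}

## 32-point Gauss-Legendre rule on [-1, 1]
.gauss_legendre_32 <- local({
  j <- seq_len(31)
  b <- j / sqrt(4 * j^2 - 1)
  E <- eigen(diag(0, 32) + rbind(cbind(0, diag(b)), 0) +
               t(rbind(cbind(0, diag(b)), 0)), symmetric = TRUE)
  list(x = E$values, w = 2 * E$vectors[1, ]^2)
})

## --- internals -----------------------------------------------------------

## central-difference gradient
.num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + hi
    xm <- x; xm[i] <- xm[i] - hi
    (f(xp) - f(xm)) / (2 * hi)
  }, numeric(1))
}

## a few Newton steps to drive the gradient of a smooth objective to ~0
## after quasi-Newton convergence; steps that fail to decrease are rejected
.newton_polish <- function(par, nll, max_steps = 8L, gtol = 1e-9) {
  val <- nll(par)
  for (s in seq_len(max_steps)) {
    g <- .num_grad(nll, par)
    if (max(abs(g)) < gtol) break
    H <- stats::optimHess(par, nll)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- par - step
    vc <- nll(cand)
    if (!is.finite(vc) || vc > val + 1e-10) {
      cand <- par - 0.5 * step
      vc <- nll(cand)
      if (!is.finite(vc) || vc > val + 1e-10) break
    }
    par <- cand; val <- vc
  }
  list(par = par, value = val)
}

.ols_fit <- function(X, y) {
  qrX <- qr(X)
  b <- qr.coef(qrX, y)
  e <- y - drop(X %*% ifelse(is.na(b), 0, b))
  df <- length(y) - qrX$rank
  s2 <- sum(e^2) / df
  V <- s2 * chol2inv(qr.R(qrX))
  dimnames(V) <- list(colnames(X), colnames(X))
  list(beta = b, se = stats::setNames(sqrt(diag(V)), colnames(X)),
       vcov = V, sigma = sqrt(s2), residuals = e)
}

.new_heckman_fit <- function(beta, beta_se, vcov_beta, gamma, gamma_se,
                             rho_sigma, rho, sigma1, loglik, method, data,
                             rho_sigma_se = NA_real_, note = NULL,
                             residuals = NULL) {
  beta_se <- stats::setNames(as.numeric(beta_se), names(beta))
  structure(list(beta = beta, beta_se = beta_se, vcov = vcov_beta,
                 gamma = gamma, gamma_se = gamma_se,
                 rho_sigma = rho_sigma, rho_sigma_se = rho_sigma_se,
                 rho = rho, sigma1 = sigma1, loglik = loglik,
                 method = method, note = note,
                 n = data$n, n_selected = sum(data$selected),
                 outcome_names = colnames(data$outcome_design),
                 selection_names = colnames(data$selection_design),
                 residuals = residuals),
            class = "heckman_fit")
}

#' @export
coef.heckman_fit <- function(object, ...) object$beta

#' @export
vcov.heckman_fit <- function(object, ...) object$vcov

#' @export
logLik.heckman_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) +
              length(object$gamma) + 2, class = "logLik")
}

#' @export
confint.heckman_fit <- function(object, parm, level = 0.95, ...) {
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
residuals.heckman_fit <- function(object, ...) object$residuals

#' @export
print.heckman_fit <- function(x, digits = 4, ...) {
  cat("Heckman sample selection model (", x$method, ")\n", sep = "")
  cat("n =", x$n, "(", x$n_selected, "selected )\n")
  print(round(cbind(estimate = x$beta, se = x$beta_se), digits))
  cat("rho =", format(x$rho, digits = digits),
      " sigma1 =", format(x$sigma1, digits = digits), "\n")
  if (is.finite(x$loglik))
    cat("log-likelihood:", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' @export
summary.heckman_fit <- function(object, ...) {
  zval <- object$beta / object$beta_se
  tab <- cbind(Estimate = object$beta, `Std. Error` = object$beta_se,
               `z value` = zval,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.heckman_fit"
  out
}

#' @export
print.summary.heckman_fit <- function(x, ...) {
  print(x$fit)
  cat("\nOutcome equation:\n")
  stats::printCoefmat(x$coefficients)
  if (!is.null(x$fit$gamma)) {
    cat("\nSelection equation (probit):\n")
    stats::printCoefmat(cbind(Estimate = x$fit$gamma,
                              `Std. Error` = x$fit$gamma_se))
  }
  invisible(x)
}

#' Simulate a small sample-selection dataset (for examples)
#'
#' Generates data from a linear outcome model with logistic selection on the
#' covariate, the outcome and an independent instrument for selection; used
#' in package examples.
#'
#' @param n Sample size.
#' @param seed RNG seed.
#' @param binary If `TRUE` the outcome is dichotomized at its median before
#'   masking.
#' @return A [selection_data] object.
#' @export
sim_heckman_example <- function(n = 500, seed = 1, binary = FALSE) {
  set.seed(seed)
  z <- stats::rnorm(n); x <- stats::rnorm(n)
  y <- 1 + 0.5 * x + stats::rnorm(n)
  if (binary) y <- as.numeric(y > 1)
  r <- stats::runif(n) < stats::plogis(-0.5 + 0.5 * x + 0.5 * z + 0.5 * y)
  ymask <- ifelse(r, y, NA)
  selection_data(ymask, cbind(`(Intercept)` = 1, x = x),
                 cbind(`(Intercept)` = 1, x = x, z = z), selected = r)
}
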