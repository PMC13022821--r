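#' Complete-case analysis
#'
#' Ordinary GLM of the outcome on the outcome design using only the rows
#' with an observed outcome.  A MAR benchmark: unbiased only when selection
#' is independent of the outcome given the covariates.
#'
#' @param data A [selection_data] object.
#' @param family Outcome family; defaults to the family recorded in `data`.
#' @return An object of class `"reg_fit"` with `beta`, `beta_se`, `vcov`,
#'   `family`, `n_used`.
#' @examples
#' d <- sim_heckman_example(n = 400, seed = 6)
#' cca_fit(d)
#' @export
cca_fit <- function(data, family = NULL) {
  stopifnot(inherits(data, "selection_data"))
  if (is.null(family)) family <- data$family
  family <- match.arg(family, c("linear", "logistic", "poisson"))
  r <- data$selected
  X <- data$outcome_design[r, , drop = FALSE]
  y <- data$outcome[r]
  if (length(y) < ncol(X) + 1) stop("cca_fit: too few complete rows")
  .glm_reg_fit(X, y, family, n_used = sum(r))
}

#' Inverse probability weighting
#'
#' Fits a logistic selection model on a fully observed weight design,
#' weights each selected individual by the inverse of its fitted selection
#' probability, and fits a weighted GLM of the outcome.  Standard errors
#' use the sandwich (robust) variance with the weights treated as fixed.
#' A MAR benchmark estimator.
#'
#' @inheritParams cca_fit
#' @param weight_design n x m numeric matrix for the selection model
#'   (fully observed; by convention excludes the instrument for selection).
#'   Defaults to the outcome design.
#' @param pi_floor Smallest admissible fitted selection probability.
#' @return A `"reg_fit"` object with additional components `weights`
#'   (zero for non-selected rows) and `weight_model`.
#' @examples
#' d <- sim_heckman_example(n = 400, seed = 7)
#' ipw_fit(d)
#' @export
ipw_fit <- function(data, weight_design = NULL, family = NULL,
                    pi_floor = 1e-6) {
  stopifnot(inherits(data, "selection_data"))
  if (is.null(family)) family <- data$family
  family <- match.arg(family, c("linear", "logistic", "poisson"))
  if (is.null(weight_design)) weight_design <- data$outcome_design
  weight_design <- as.matrix(weight_design)
  if (anyNA(weight_design))
    stop("ipw_fit: weight_design must be fully observed")
  r <- data$selected
  wm <- fit_propensity(weight_design, r)
  if (any(wm$fitted_pi[r] < pi_floor))
    stop("ipw_fit: extreme weights; fitted selection probability below ",
         format(pi_floor), " for rows ",
         paste(utils::head(which(r & wm$fitted_pi < pi_floor), 5),
               collapse = ", "))
  w <- ifelse(r, 1 / wm$fitted_pi, 0)
  X <- data$outcome_design[r, , drop = FALSE]
  y <- data$outcome[r]
  fam <- switch(family, linear = stats::gaussian(),
                logistic = stats::binomial(), poisson = stats::poisson())
  df <- data.frame(y = y, X, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", colnames(X)), response = "y",
                            intercept = FALSE)
  gfit <- suppressWarnings(stats::glm(fml, family = fam, data = df,
                                      weights = w[r]))
  V <- sandwich::sandwich(gfit)
  out <- .reg_fit(beta = stats::setNames(stats::coef(gfit), colnames(X)),
                  vcov = V, family = family, n_used = sum(r))
  out$weights <- w
  out$weight_model <- list(design_cols = colnames(weight_design),
                           alpha = wm$alpha_prop)
  out$vcov_model <- summary(gfit)$cov.scaled  # model-based, for diagnostics
  out
}

#' Full-data (oracle) fit
#'
#' GLM of the complete, pre-masking outcome on the outcome design.  Only
#' meaningful in simulations where the truth is available; used as a
#' benchmark.
#'
#' @param outcome Complete outcome vector (no missing values).
#' @param outcome_design Design matrix including an intercept.
#' @param family `"linear"`, `"logistic"` or `"poisson"`.
#' @return A `"reg_fit"` object.
#' @export
oracle_fit <- function(outcome, outcome_design,
                       family = c("linear", "logistic", "poisson")) {
  family <- match.arg(family)
  if (anyNA(outcome)) stop("oracle_fit requires the complete outcome")
  .glm_reg_fit(as.matrix(outcome_design), outcome, family,
               n_used = length(outcome))
}

.glm_reg_fit <- function(X, y, family, n_used) {
  if (family == "linear") {
    ols <- .ols_fit(X, y)
    return(.reg_fit(ols$beta, ols$vcov, family, n_used))
  }
  fam <- if (family == "logistic") stats::binomial() else stats::poisson()
  gfit <- suppressWarnings(stats::glm.fit(X, y, family = fam))
  if (!gfit$converged) stop("GLM did not converge")
  mu <- fam$linkinv(drop(X %*% gfit$coefficients))
  wts <- if (family == "logistic") mu * (1 - mu) else mu
  V <- solve(crossprod(X * sqrt(wts)))
  .reg_fit(stats::setNames(gfit$coefficients, colnames(X)), V, family,
           n_used)
}

.reg_fit <- function(beta, vcov, family, n_used) {
  structure(list(beta = beta,
                 beta_se = stats::setNames(sqrt(pmax(diag(vcov), 0)),
                                           names(beta)),
                 vcov = vcov, family = family, n_used = n_used),
            class = "reg_fit")
}

#' @export
coef.reg_fit <- function(object, ...) object$beta

#' @export
vcov.reg_fit <- function(object, ...) object$vcov

#' @export
print.reg_fit <- function(x, digits = 4, ...) {
  cat("GLM fit (", x$family, "), n used =", x$n_used, "\n")
  print(round(cbind(estimate = x$beta, se = x$beta_se), digits))
  invisible(x)
}
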