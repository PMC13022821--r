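#' Assemble a Mendelian randomization dataset
#'
#' One-sample individual-level MR data: genetic instruments for inference,
#' an exposure and an outcome (either possibly masked by selection), an
#' instrument for selection (which must be observed for every individual),
#' and a selection indicator.
#'
#' @param instruments n x K numeric matrix of genetic instruments
#'   (continuous scores or 0/1/2 allele counts), fully observed.
#' @param exposure Numeric vector, `NA` where masked.
#' @param outcome Numeric vector, `NA` where masked.
#' @param selection_instrument Numeric vector Z, fully observed.
#' @param selected Logical or 0/1 selection indicator.  Defaults to rows
#'   where all partially observed variables are observed.
#' @return An object of class `"mr_data"`.
#' @seealso [mr_two_sample()], [tsls()], [per_variant_summary_stats()]
#' @export
mr_data <- function(instruments, exposure, outcome, selection_instrument,
                    selected = NULL) {
  G <- as.matrix(instruments)
  n <- nrow(G)
  stopifnot(length(exposure) == n, length(outcome) == n,
            length(selection_instrument) == n)
  if (anyNA(G)) stop("instruments must be fully observed")
  if (anyNA(selection_instrument))
    stop("the instrument for selection must be observed for all ",
         "individuals in the sample")
  if (is.null(selected)) selected <- !(is.na(exposure) | is.na(outcome))
  if (is.null(colnames(G))) colnames(G) <- paste0("g", seq_len(ncol(G)))
  structure(list(instruments = G, exposure = as.numeric(exposure),
                 outcome = as.numeric(outcome),
                 selection_instrument = as.numeric(selection_instrument),
                 selected = as.logical(selected), n = n, K = ncol(G)),
            class = "mr_data")
}

#' Two-sample Mendelian randomization dataset
#'
#' Pairs two disjoint [mr_data] samples: `sample_x` is used to estimate the
#' instrument-exposure associations and `sample_y` the instrument-outcome
#' associations.
#'
#' @param sample_x,sample_y [mr_data] objects with the same number of
#'   instruments.
#' @return An object of class `"mr_data_2s"`.
#' @export
mr_two_sample <- function(sample_x, sample_y) {
  stopifnot(inherits(sample_x, "mr_data"), inherits(sample_y, "mr_data"),
            sample_x$K == sample_y$K)
  structure(list(sample_x = sample_x, sample_y = sample_y,
                 K = sample_x$K), class = "mr_data_2s")
}

#' @export
print.mr_data <- function(x, ...) {
  cat("MR dataset: n =", x$n, ", K =", x$K, "instruments,",
      sum(x$selected), "selected\n")
  cat("missing exposure:", sum(is.na(x$exposure)),
      " missing outcome:", sum(is.na(x$outcome)), "\n")
  invisible(x)
}

#' Wald ratio causal estimate
#'
#' Single-instrument causal effect \eqn{\hat\theta = \hat\beta_Y /
#' \hat\beta_X}, with a second-order approximation to its standard error,
#' \eqn{\sqrt{s_Y^2/\hat\beta_X^2 + \hat\beta_Y^2 s_X^2 / \hat\beta_X^4}}.
#'
#' @param beta_x,se_x Instrument-exposure association and standard error.
#' @param beta_y,se_y Instrument-outcome association and standard error.
#' @param adjustment Optional character tags recording how each side was
#'   estimated (e.g. `c(x = "none", y = "heckman")`).
#' @return An object of class `"mr_estimate"`.
#' @examples
#' wald_ratio(0.5, 0.05, 0.1, 0.02)
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, adjustment = NULL) {
  if (beta_x == 0)
    stop("wald_ratio: zero-strength instrument (beta_x = 0)")
  theta <- beta_y / beta_x
  se <- sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  .mr_estimate(theta, se, "wald", adjustment)
}

#' Instrument-association estimate with optional selection adjustment
#'
#' Estimates the association of the genetic instrument(s) with one side of
#' an MR analysis (exposure or outcome).  If the requested side is fully
#' observed this is ordinary least squares; otherwise the regression is
#' fitted by Heckman's sample selection model or the TTW estimator, with
#' selection design `[1, G, Z]` (the instrument for selection Z is always
#' excluded from the outcome design).
#'
#' @param data An [mr_data] object.
#' @param side `"exposure"` or `"outcome"`.
#' @param adjust `"none"`, `"heckman"` or `"ttw"`.
#' @param variant Optional variant index: fit the univariate regression on
#'   instrument `variant` only.  Default uses all instruments jointly.
#' @param heckman_method `"two_step"` (default) or `"ml"`.
#' @return List with `beta` and `se` (coefficients on the instrument
#'   columns, intercept excluded) and the underlying `fit`.
#' @export
estimate_association <- function(data, side = c("exposure", "outcome"),
                                 adjust = c("none", "heckman", "ttw"),
                                 variant = NULL,
                                 heckman_method = c("two_step", "ml")) {
  side <- match.arg(side)
  adjust <- match.arg(adjust)
  heckman_method <- match.arg(heckman_method)
  stopifnot(inherits(data, "mr_data"))
  v <- if (side == "exposure") data$exposure else data$outcome
  G <- if (is.null(variant)) data$instruments
       else data$instruments[, variant, drop = FALSE]
  .adjusted_linreg(v, G, data$selection_instrument, adjust, heckman_method)
}

## Linear regression of a possibly masked variable on [1, G], adjusted for
## selection via [1, G, Z] when masked.  Returns instrument coefficients.
.adjusted_linreg <- function(v, G, Z, adjust, heckman_method = "two_step") {
  X <- cbind(`(Intercept)` = 1, G)
  kcols <- seq_len(ncol(G)) + 1L
  obs <- !is.na(v)
  if (all(obs) || adjust == "none") {
    if (adjust != "none" && all(obs))
      warning("selection adjustment requested for a fully observed ",
              "variable; falling back to OLS")
    ols <- .ols_fit(X[obs, , drop = FALSE], v[obs])
    return(list(beta = ols$beta[kcols], se = ols$se[kcols], fit = ols))
  }
  sd <- selection_data(v, X, cbind(X, z = Z), selected = obs)
  fit <- switch(adjust,
    heckman = if (heckman_method == "two_step") heckman_two_step(sd)
              else heckman_ml(sd),
    ttw = ttw_fit(sd, family = "linear", mode = "partial"))
  list(beta = fit$beta[kcols], se = fit$beta_se[kcols], fit = fit)
}

#' Two-stage least squares with optional selection adjustment
#'
#' Classic 2SLS for one-sample MR: the exposure is regressed on all
#' instruments, and the outcome on the fitted exposure values.  Either
#' stage can be replaced by a selection-adjusted regression (Heckman or
#' TTW) when its dependent variable is masked; fitted exposure values are
#' then computed for all individuals from the adjusted coefficients, so
#' they are free of selection bias.
#'
#' The analytic standard error (residual variance times the inverse
#' instrumented sum of squares) is only valid for the unadjusted
#' estimator; with any adjustment active it must be obtained by
#' bootstrapping individuals ([tsls_bootstrap_se()]), and requesting
#' `se = "analytic"` is an error.  Fully unadjusted fits drop every row
#' with a missing value in any variable used by either stage.
#'
#' @param data An [mr_data] object.
#' @param adjust_first,adjust_second Adjustment for stage 1 (exposure) and
#'   stage 2 (outcome): `"none"`, `"heckman"` or `"ttw"`.
#' @param se `"auto"` (analytic when unadjusted, bootstrap when adjusted
#'   and `boot_M` is given, otherwise none), `"analytic"`, `"bootstrap"`
#'   or `"none"`.
#' @param boot_M Bootstrap resamples for `se = "bootstrap"`.
#' @param seed RNG seed for the bootstrap.
#' @param heckman_method Passed to the adjusted regressions.
#' @return An `"mr_estimate"` with `method = "tsls"`.
#' @export
tsls <- function(data, adjust_first = "none", adjust_second = "none",
                 se = c("auto", "analytic", "bootstrap", "none"),
                 boot_M = NULL, seed = 1L,
                 heckman_method = "two_step") {
  se <- match.arg(se)
  stopifnot(inherits(data, "mr_data"))
  adjusted <- adjust_first != "none" || adjust_second != "none"
  if (se == "analytic" && adjusted)
    stop("the analytic 2SLS standard error cannot be used in conjunction ",
         "with selection-adjusted stages; use a bootstrap standard error")
  if (se == "auto")
    se <- if (!adjusted) "analytic"
          else if (!is.null(boot_M)) "bootstrap" else "none"

  est <- .tsls_point(data, adjust_first, adjust_second, heckman_method)
  theta_se <- NA_real_
  n_boot <- NULL
  if (se == "analytic") theta_se <- est$analytic_se
  if (se == "bootstrap") {
    if (is.null(boot_M)) boot_M <- 100L
    theta_se <- tsls_bootstrap_se(data, adjust_first, adjust_second,
                                  M = boot_M, seed = seed,
                                  heckman_method = heckman_method)
    n_boot <- boot_M
  }
  out <- .mr_estimate(est$theta, theta_se, "tsls",
                      c(first = adjust_first, second = adjust_second),
                      n_boot = n_boot)
  out$n_used <- est$n_used
  out
}

.tsls_point <- function(data, adjust_first, adjust_second,
                        heckman_method = "two_step") {
  G <- data$instruments
  Z <- data$selection_instrument
  x <- data$exposure; y <- data$outcome

  if (adjust_first == "none" && adjust_second == "none") {
    ## complete cases across every variable used in either stage
    cc <- !(is.na(x) | is.na(y))
    Gc <- G[cc, , drop = FALSE]; xc <- x[cc]; yc <- y[cc]
    D1 <- cbind(1, Gc)
    b1 <- qr.coef(qr(D1), xc)
    xhat <- drop(D1 %*% b1)
    W2 <- cbind(1, xhat = xhat)
    b2 <- qr.coef(qr(W2), yc)
    theta <- b2[["xhat"]]
    resid <- yc - b2[[1]] - theta * xc      # structural residuals
    s2 <- sum(resid^2) / (length(yc) - 1)
    V <- s2 * chol2inv(qr.R(qr(W2)))
    return(list(theta = theta, analytic_se = sqrt(V[2, 2]),
                n_used = sum(cc)))
  }

  ## stage 1: instrument-exposure associations, adjusted if X is masked
  if (anyNA(x) && adjust_first != "none") {
    st1 <- .adjusted_linreg(x, G, Z, adjust_first, heckman_method)
    b1 <- c(st1$fit$beta[1], st1$beta)
  } else {
    obs <- !is.na(x)
    b1 <- .ols_fit(cbind(1, G[obs, , drop = FALSE]), x[obs])$beta
  }
  xhat <- drop(cbind(1, G) %*% b1)

  ## stage 2: outcome on fitted exposure, adjusted if Y is masked
  if (anyNA(y) && adjust_second != "none") {
    st2 <- .adjusted_linreg(y, cbind(xhat = xhat), Z, adjust_second,
                            heckman_method)
    theta <- st2$beta[["xhat"]]
  } else {
    obs <- !is.na(y)
    b2 <- .ols_fit(cbind(1, xhat = xhat[obs]), y[obs])$beta
    theta <- b2[["xhat"]]
  }
  list(theta = theta, analytic_se = NA_real_, n_used = data$n)
}

#' Bootstrap standard error for selection-adjusted 2SLS
#'
#' Resamples individuals with replacement, reruns the full adjusted 2SLS
#' pipeline on each resample, and returns the standard deviation of the
#' resampled causal estimates.  Resamples whose fit fails are excluded and
#' counted; more than 20% failures is an error.
#'
#' @inheritParams tsls
#' @param M Number of resamples (>= 2).
#' @return Numeric standard error with attribute `n_failed`.
#' @export
tsls_bootstrap_se <- function(data, adjust_first = "none",
                              adjust_second = "none", M = 100L, seed = 1L,
                              heckman_method = "two_step") {
  stopifnot(M >= 2, inherits(data, "mr_data"))
  set.seed(seed)
  th <- rep(NA_real_, M)
  for (j in seq_len(M)) {
    idx <- sample.int(data$n, data$n, replace = TRUE)
    bd <- mr_data(data$instruments[idx, , drop = FALSE],
                  data$exposure[idx], data$outcome[idx],
                  data$selection_instrument[idx], data$selected[idx])
    th[j] <- tryCatch(
      .tsls_point(bd, adjust_first, adjust_second, heckman_method)$theta,
      error = function(e) NA_real_)
  }
  ok <- !is.na(th)
  if (mean(!ok) > 0.2)
    stop("tsls_bootstrap_se: more than 20% of bootstrap resamples failed (",
         sum(!ok), " of ", M, ")")
  out <- stats::sd(th[ok])
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' Per-variant (selection-adjusted) summary statistics
#'
#' Computes univariate instrument-exposure and instrument-outcome
#' associations for each genetic variant separately, optionally adjusting
#' each side for selection (the adjustment is run once per variant).  For
#' a two-sample dataset the exposure side comes from `sample_x` and the
#' outcome side from `sample_y`.
#'
#' @param data An [mr_data] or [mr_two_sample] object.
#' @param adjust_exposure,adjust_outcome `"none"`, `"heckman"` or `"ttw"`.
#' @param heckman_method Passed to the adjusted regressions.
#' @return A data frame of class `"mr_sumstats"` with columns `variant`,
#'   `beta_x`, `se_x`, `beta_y`, `se_y` and adjustment tags in attributes.
#' @export
per_variant_summary_stats <- function(data, adjust_exposure = "none",
                                      adjust_outcome = "none",
                                      heckman_method = "two_step") {
  if (inherits(data, "mr_data_2s")) {
    dx <- data$sample_x; dy <- data$sample_y
  } else {
    stopifnot(inherits(data, "mr_data"))
    dx <- dy <- data
  }
  K <- dx$K
  out <- data.frame(variant = colnames(dx$instruments),
                    beta_x = NA_real_, se_x = NA_real_,
                    beta_y = NA_real_, se_y = NA_real_)
  for (j in seq_len(K)) {
    ax <- estimate_association(dx, "exposure", adjust_exposure, variant = j,
                               heckman_method = heckman_method)
    ay <- estimate_association(dy, "outcome", adjust_outcome, variant = j,
                               heckman_method = heckman_method)
    out$beta_x[j] <- ax$beta; out$se_x[j] <- ax$se
    out$beta_y[j] <- ay$beta; out$se_y[j] <- ay$se
  }
  attr(out, "adjustment") <- c(x = adjust_exposure, y = adjust_outcome)
  attr(out, "two_sample") <- inherits(data, "mr_data_2s")
  class(out) <- c("mr_sumstats", "data.frame")
  out
}

#' Inverse-variance weighted causal estimate
#'
#' Combines per-variant summary statistics into a single causal estimate,
#' \eqn{\hat\theta = \sum_j \hat\beta_{Xj}\hat\beta_{Yj}\sigma_{Yj}^{-2} /
#' \sum_j \hat\beta_{Xj}^2 \sigma_{Yj}^{-2}}.  With
#' `se_mode = "second_order"` (default) the weights are recomputed once
#' with \eqn{\sigma_{Yj}^2 + \hat\theta^2\sigma_{Xj}^2} in place of
#' \eqn{\sigma_{Yj}^2}, plugging in the first-order estimate.
#'
#' When the summary statistics were computed from a single sample, the IVW
#' combination is vulnerable to sample-overlap (weak instrument) bias; a
#' warning is raised.
#'
#' @param stats An `"mr_sumstats"` data frame (or any data frame with
#'   columns `beta_x`, `se_x`, `beta_y`, `se_y`).
#' @param se_mode `"second_order"` or `"first_order"`.
#' @return An `"mr_estimate"` with `method = "ivw"`.
#' @examples
#' s <- data.frame(beta_x = c(0.2, 0.3), se_x = c(0.02, 0.03),
#'                 beta_y = c(0.04, 0.07), se_y = c(0.01, 0.02))
#' ivw(s, se_mode = "first_order")
#' @export
ivw <- function(stats, se_mode = c("second_order", "first_order")) {
  se_mode <- match.arg(se_mode)
  if (nrow(stats) == 0) stop("ivw: empty summary statistics")
  stopifnot(all(c("beta_x", "se_x", "beta_y", "se_y") %in% names(stats)))
  if (isFALSE(attr(stats, "two_sample")) && nrow(stats) > 1)
    warning("IVW applied to one-sample summary statistics: beware of ",
            "sample-overlap (weak instrument) bias", call. = FALSE)
  bx <- stats$beta_x; by <- stats$beta_y
  sx <- stats$se_x; sy <- stats$se_y
  w1 <- 1 / sy^2
  theta1 <- sum(bx * by * w1) / sum(bx^2 * w1)
  if (se_mode == "first_order") {
    theta <- theta1
    se <- sqrt(1 / sum(bx^2 * w1))
  } else {
    w2 <- 1 / (sy^2 + theta1^2 * sx^2)
    theta <- sum(bx * by * w2) / sum(bx^2 * w2)
    se <- sqrt(1 / sum(bx^2 * w2))
  }
  .mr_estimate(theta, se, "ivw", attr(stats, "adjustment"))
}

.mr_estimate <- function(theta, theta_se, method, adjustment = NULL,
                         n_boot = NULL) {
  structure(list(theta = theta, theta_se = theta_se, method = method,
                 adjustment = adjustment, n_boot = n_boot,
                 ci95 = theta + c(-1, 1) * 1.96 * theta_se),
            class = "mr_estimate")
}

#' @export
coef.mr_estimate <- function(object, ...) c(theta = object$theta)

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  matrix(object$theta + c(-z, z) * object$theta_se, nrow = 1,
         dimnames = list("theta",
                         sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                    1 - (1 - level) / 2))))
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat("MR causal estimate (", x$method, ")\n", sep = "")
  cat("theta =", format(x$theta, digits = digits),
      " se =", format(x$theta_se, digits = digits), "\n")
  if (all(is.finite(x$ci95)))
    cat("95% CI: [", format(x$ci95[1], digits = digits), ",",
        format(x$ci95[2], digits = digits), "]\n")
  if (!is.null(x$adjustment))
    cat("adjustment:", paste(names(x$adjustment), x$adjustment,
                             sep = "=", collapse = ", "), "\n")
  if (!is.null(x$n_boot)) cat("bootstrap resamples:", x$n_boot, "\n")
  invisible(x)
}
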