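#' Define a regression simulation scenario
#'
#' Generative model for the regression simulations: independent standard
#' normal instrument Z, covariate X and error; outcome
#' \eqn{Y = \alpha + \beta X + \epsilon}; logistic selection
#' \eqn{\mathrm{logit}\,\pi_R = \alpha_R + \beta_R X + \gamma_R Z +
#' \delta_R Y} with the outcome masked where the Bernoulli draw is zero.
#' Named variants modify one ingredient at a time (binary instrument /
#' covariate / outcome, Poisson outcome, selection driven by only one of X
#' and Y, or a direct Z-X or Z-Y effect, the latter violating the
#' exclusion restriction).
#'
#' Note the deliberate working-model mismatch: selection is generated from
#' a logistic model while the Heckman estimator assumes probit selection.
#'
#' @param variant One of `"baseline"`, `"null_beta"`, `"binary_Z"`,
#'   `"binary_X"`, `"binary_Y"`, `"poisson_Y"`, `"no_XR"`, `"no_YR"`,
#'   `"ZX_effect"`, `"ZY_effect"`.
#' @param beta,alpha Outcome model coefficients (defaults 0.1 and 1).
#' @param gamma_R Instrument-selection effect (default 0.4, about 2% of
#'   the variation in selection).
#' @param beta_R,delta_R Covariate- and outcome-selection effects
#'   (defaults 0.5).
#' @param alpha_R Selection intercept, or `"auto"` to tune for the target
#'   missingness via [tune_alpha_R()].
#' @param n Sample size per replication.
#' @param beta_XZ Direct Z-X effect (only used by `"ZX_effect"`).
#' @param gamma_ZY Direct Z-Y effect (only used by `"ZY_effect"`).
#' @return An object of class `"regression_scenario"`.
#' @examples
#' regression_scenario("baseline")
#' @export
regression_scenario <- function(variant = "baseline", beta = 0.1,
                                alpha = 1, gamma_R = 0.4, beta_R = 0.5,
                                delta_R = 0.5, alpha_R = "auto",
                                n = 1e4, beta_XZ = 1 / 3,
                                gamma_ZY = 1 / 3) {
  variant <- match.arg(variant, c("baseline", "null_beta", "binary_Z",
                                  "binary_X", "binary_Y", "poisson_Y",
                                  "no_XR", "no_YR", "ZX_effect",
                                  "ZY_effect"))
  if (variant == "null_beta" && missing(beta)) beta <- 0
  if (variant == "no_XR" && missing(beta_R)) beta_R <- 0
  if (variant == "no_YR" && missing(delta_R)) delta_R <- 0
  family <- switch(variant, binary_Y = "logistic", poisson_Y = "poisson",
                   "linear")
  structure(list(variant = variant, beta = beta, alpha = alpha,
                 gamma_R = gamma_R, beta_R = beta_R, delta_R = delta_R,
                 alpha_R = alpha_R, n = n, beta_XZ = beta_XZ,
                 gamma_ZY = gamma_ZY, family = family),
            class = "regression_scenario")
}

#' Define a Mendelian randomization simulation scenario
#'
#' Generative model for the MR simulations.  With a single instrument for
#' inference, G, Z, the confounder U and both error terms are standard
#' normal; \eqn{X = \beta_X G + \gamma_X U + \epsilon_X} with
#' \eqn{\beta_X = \sqrt{2/19}} so that G explains 5% of the variance of X;
#' \eqn{Y = \theta X + \gamma_Y U + \epsilon_Y}.  With K instruments,
#' allele frequencies are drawn uniform on (0.1, 0.9), allele counts
#' binomial(2, f), and per-variant effects from a N(0, 0.05^2) left-
#' truncated at 0.15 (again about 5% of the exposure variance in total).
#' Selection is logistic on X, Z and Y; the variables with nonzero
#' selection effects are the ones masked where selection fails.  Two-sample
#' designs generate two independent samples, masking the exposure only in
#' the exposure sample and the outcome only in the outcome sample.
#'
#' @param theta True causal effect (0.2 or 0 in the study conditions).
#' @param K Number of genetic instruments (1 or 10).
#' @param design `"one_sample"` or `"two_sample"`.
#' @param selection Which variables drive selection (and are masked):
#'   `"Y"`, `"X"` or `"XY"`.
#' @param gamma_R Instrument-selection effect (default 0.5, about 2%).
#' @param gamma_X,gamma_Y Confounder effects (defaults 1).
#' @param alpha_R Selection intercept or `"auto"`.
#' @param n Sample size per sample per replication.
#' @return An object of class `"mr_scenario"`.
#' @examples
#' mr_scenario(theta = 0.2, K = 1, selection = "Y")
#' @export
mr_scenario <- function(theta = 0.2, K = 1L,
                        design = c("one_sample", "two_sample"),
                        selection = c("Y", "X", "XY"), gamma_R = 0.5,
                        gamma_X = 1, gamma_Y = 1, alpha_R = "auto",
                        n = 1e4) {
  design <- match.arg(design)
  selection <- match.arg(selection)
  eff <- switch(selection, Y = c(0, 1), X = c(1, 0), XY = c(0.5, 0.5))
  structure(list(theta = theta, K = as.integer(K), design = design,
                 selection = selection, beta_R = eff[1], delta_R = eff[2],
                 gamma_R = gamma_R, gamma_X = gamma_X, gamma_Y = gamma_Y,
                 alpha_R = alpha_R, n = n,
                 beta_X = sqrt(2 / 19),
                 mask_rule = switch(selection, Y = "Y", X = "X",
                                    XY = c("X", "Y"))),
            class = "mr_scenario")
}

## draw covariates, outcome and the selection linear predictor (without
## intercept) for a regression scenario; shared by tuning and generation
.draw_regression <- function(sc, n) {
  z <- if (sc$variant == "binary_Z") stats::rbinom(n, 1, 0.5)
       else stats::rnorm(n)
  x <- switch(sc$variant,
              binary_X = stats::rbinom(n, 1, 0.5),
              ZX_effect = sc$beta_XZ * z + stats::rnorm(n),
              stats::rnorm(n))
  lp_y <- sc$alpha + sc$beta * x +
    if (sc$variant == "ZY_effect") sc$gamma_ZY * z else 0
  y <- switch(sc$family,
              linear = lp_y + stats::rnorm(n),
              logistic = stats::rbinom(n, 1, stats::plogis(lp_y)),
              poisson = stats::rpois(n, exp(lp_y)))
  list(z = z, x = x, y = y,
       lp_sel = sc$beta_R * x + sc$gamma_R * z + sc$delta_R * y)
}

## draw one MR sample for a scenario; beta_X effects are redrawn per call
## for the multi-instrument design
.draw_mr <- function(sc, n) {
  u <- stats::rnorm(n); z <- stats::rnorm(n)
  ex <- stats::rnorm(n); ey <- stats::rnorm(n)
  if (sc$K == 1L) {
    G <- matrix(stats::rnorm(n), ncol = 1,
                dimnames = list(NULL, "g1"))
    gx <- sc$beta_X * G[, 1]
  } else {
    f <- stats::runif(sc$K, 0.1, 0.9)
    G <- sapply(f, function(fj) stats::rbinom(n, 2, fj))
    colnames(G) <- paste0("g", seq_len(sc$K))
    ## N(0, 0.05^2) left-truncated at 0.15, by inverse-CDF sampling
    ptr <- stats::pnorm(0.15, sd = 0.05)
    bx <- stats::qnorm(stats::runif(sc$K, ptr, 1), sd = 0.05)
    gx <- drop(G %*% bx)
  }
  x <- gx + sc$gamma_X * u + ex
  y <- sc$theta * x + sc$gamma_Y * u + ey
  list(G = G, z = z, x = x, y = y,
       lp_sel = sc$beta_R * x + sc$gamma_R * z + sc$delta_R * y)
}

#' Tune the selection intercept for a target missingness fraction
#'
#' Root-finds the selection-model intercept so that the marginal selection
#' probability, estimated on a large pilot sample from the scenario's
#' generative model, hits the target (50% missingness in the study
#' conditions).  Deterministic given the seed.  When no variable affects
#' selection the answer is `qlogis(target)` exactly.
#'
#' @param scenario A [regression_scenario] or [mr_scenario].
#' @param target Target selection probability in (0, 1).
#' @param tol Tolerance on the achieved pilot selection probability.
#' @param pilot_n Pilot sample size.
#' @param seed RNG seed for the pilot draw.
#' @return The tuned intercept (scalar).
#' @examples
#' tune_alpha_R(regression_scenario("baseline"), pilot_n = 2e4)  # ~ -0.5
#' @export
tune_alpha_R <- function(scenario, target = 0.5, tol = 0.005,
                         pilot_n = 1e6, seed = 1L) {
  stopifnot(target > 0, target < 1)
  slopes_zero <- with(scenario,
                      beta_R == 0 && gamma_R == 0 && delta_R == 0)
  if (slopes_zero) return(stats::qlogis(target))
  set.seed(seed)
  lp <- if (inherits(scenario, "regression_scenario"))
    .draw_regression(scenario, pilot_n)$lp_sel
  else .draw_mr(scenario, pilot_n)$lp_sel
  f <- function(a) mean(stats::plogis(a + lp)) - target
  root <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  achieved <- mean(stats::plogis(root + lp))
  if (abs(achieved - target) > tol)
    stop("tune_alpha_R: tuning failed (achieved ", format(achieved), ")")
  root
}

## fill in alpha_R = "auto"; pilot seed fixed so that generation with the
## same scenario object is reproducible
.resolve_scenario <- function(scenario, pilot_n = 1e6, seed = 760013L) {
  if (identical(scenario$alpha_R, "auto"))
    scenario$alpha_R <- tune_alpha_R(scenario, pilot_n = pilot_n,
                                     seed = seed)
  scenario
}

#' Generate one replication of a regression scenario
#'
#' @param scenario A [regression_scenario]; an `alpha_R = "auto"` intercept
#'   is tuned on the spot (resolve once with [tune_alpha_R()] before
#'   looping over replications).
#' @param seed RNG seed for this replication.
#' @return A [selection_data] object with extra fields `oracle_outcome`
#'   (the pre-masking outcome) and `truth` (the generating parameters).
#' @examples
#' d <- gen_regression(regression_scenario("baseline", alpha_R = -0.5,
#'                                         n = 500), seed = 1)
#' mean(d$selected)
#' @export
gen_regression <- function(scenario, seed) {
  stopifnot(inherits(scenario, "regression_scenario"))
  scenario <- .resolve_scenario(scenario)
  set.seed(seed)
  g <- .draw_regression(scenario, scenario$n)
  r <- stats::runif(scenario$n) < stats::plogis(scenario$alpha_R + g$lp_sel)
  ymask <- ifelse(r, g$y, NA)
  d <- selection_data(ymask,
                      cbind(`(Intercept)` = 1, x = g$x),
                      cbind(`(Intercept)` = 1, x = g$x, z = g$z),
                      selected = r, family = scenario$family)
  d$oracle_outcome <- g$y
  d$truth <- list(beta = scenario$beta, alpha = scenario$alpha,
                  alpha_R = scenario$alpha_R)
  d
}

#' Generate one replication of an MR scenario
#'
#' @param scenario An [mr_scenario]; resolve `alpha_R = "auto"` with
#'   [tune_alpha_R()] before looping.
#' @param seed RNG seed for this replication.
#' @return For a one-sample design, an [mr_data] object with extra fields
#'   `exposure_full`, `outcome_full` (pre-masking copies) and `truth`; for
#'   a two-sample design, an [mr_two_sample] of two such objects.
#' @export
gen_mr <- function(scenario, seed) {
  stopifnot(inherits(scenario, "mr_scenario"))
  scenario <- .resolve_scenario(scenario)
  set.seed(seed)
  one <- function() {
    g <- .draw_mr(scenario, scenario$n)
    r <- stats::runif(scenario$n) <
      stats::plogis(scenario$alpha_R + g$lp_sel)
    g$r <- r
    g
  }
  mask <- function(v, r, name)
    if (name %in% scenario$mask_rule) ifelse(r, v, NA) else v
  build <- function(g, mask_x, mask_y) {
    d <- mr_data(g$G,
                 if (mask_x) mask(g$x, g$r, "X") else g$x,
                 if (mask_y) mask(g$y, g$r, "Y") else g$y,
                 g$z, selected = g$r)
    d$exposure_full <- g$x
    d$outcome_full <- g$y
    d$truth <- list(theta = scenario$theta)
    d
  }
  if (scenario$design == "one_sample") return(build(one(), TRUE, TRUE))
  ## two-sample: mask only the variable each sample is used to measure
  dx <- build(one(), TRUE, FALSE)
  dy <- build(one(), FALSE, TRUE)
  out <- mr_two_sample(dx, dy)
  out$truth <- list(theta = scenario$theta)
  out
}

#' Monte-Carlo metrics from estimates and standard errors
#'
#' @param estimates,ses Numeric vectors of per-replication estimates and
#'   model standard errors (`NA` marks a failed replication).
#' @param truth True parameter value.
#' @return One-row data frame: `mean`, `emp_sd`, `mean_se`, `coverage`
#'   (fraction of 95% intervals containing the truth), `power` (fraction
#'   rejecting zero at the 5% level; the type-I error when the truth is
#'   zero), `n_failed`.
#' @examples
#' compute_metrics(c(0.1, 0.12), c(0.05, 0.05), truth = 0.1)
#' @export
compute_metrics <- function(estimates, ses, truth) {
  ok <- !is.na(estimates)
  est <- estimates[ok]; se <- ses[ok]
  if (!length(est)) stop("no successful replications")
  lo <- est - 1.96 * se; hi <- est + 1.96 * se
  data.frame(mean = mean(est), emp_sd = stats::sd(est),
             mean_se = mean(se),
             coverage = mean(lo <= truth & truth <= hi),
             power = mean(abs(est / se) > 1.96),
             n_failed = sum(!ok))
}

#' Run Monte-Carlo replications of a scenario
#'
#' Generates independent replications of a regression or MR scenario
#' (replication r uses seed `seed + r`), applies each requested method, and
#' summarizes estimates as in a simulation table: mean, empirical SD, mean
#' model SE, 95% coverage and power.  Failed fits are excluded and counted.
#'
#' For regression scenarios the methods are `"cca"`, `"ipw"`, `"heckman"`,
#' `"ttw"`, `"oracle"`, each estimating the slope on X.  For MR scenarios
#' the same names select the adjustment, and `estimator` picks the causal
#' estimator: `"wald"` (K = 1), `"tsls"` (one-sample) or `"ivw"`
#' (summary statistics).  2SLS standard errors for adjusted stages require
#' a bootstrap; set `boot_M > 0` to enable it (expensive), otherwise their
#' SE, coverage and power are reported as `NA`.
#'
#' @param scenario A [regression_scenario] or [mr_scenario].
#' @param methods Character vector of method names.
#' @param n_reps Number of replications.
#' @param seed Base RNG seed.
#' @param estimator MR causal estimator (`"wald"`, `"tsls"`, `"ivw"`);
#'   default is chosen from the scenario (wald if K = 1, else tsls for
#'   one-sample and ivw for two-sample designs).
#' @param heckman_method `"two_step"` or `"ml"` for Heckman fits.
#' @param boot_M Bootstrap resamples for adjusted 2SLS standard errors
#'   (0 disables).
#' @param pilot_n Pilot size for intercept tuning.
#' @param keep_estimates If `TRUE`, attach the per-replication estimate and
#'   SE matrices as attributes `estimates` / `ses`.
#' @return A data frame of class `"sim_metrics"`, one row per method, with
#'   attributes `truth`, `n_reps` and `scenario`.
#' @examples
#' sc <- regression_scenario("baseline", n = 800)
#' run_replications(sc, c("cca", "heckman"), n_reps = 20, seed = 1)
#' @export
run_replications <- function(scenario, methods, n_reps, seed = 1L,
                             estimator = NULL,
                             heckman_method = "two_step", boot_M = 0L,
                             pilot_n = 1e6, keep_estimates = FALSE) {
  scenario <- .resolve_scenario(scenario, pilot_n = pilot_n)
  if (inherits(scenario, "regression_scenario")) {
    truth <- scenario$beta
    fit_one <- function(rep_seed)
      .regression_methods(gen_regression(scenario, rep_seed), methods,
                          scenario, heckman_method)
    label <- scenario$variant
  } else if (inherits(scenario, "mr_scenario")) {
    truth <- scenario$theta
    if (is.null(estimator))
      estimator <- if (scenario$K == 1L) "wald"
                   else if (scenario$design == "one_sample") "tsls"
                   else "ivw"
    estimator <- match.arg(estimator, c("wald", "tsls", "ivw"))
    fit_one <- function(rep_seed)
      .mr_methods(gen_mr(scenario, rep_seed), methods, scenario,
                  estimator, heckman_method, boot_M, rep_seed)
    label <- paste0("mr_", scenario$selection, "_", scenario$design,
                    "_K", scenario$K, "_", estimator)
  } else stop("unknown scenario type")

  est <- matrix(NA_real_, n_reps, length(methods),
                dimnames = list(NULL, methods))
  ses <- est
  for (rr in seq_len(n_reps)) {
    res <- fit_one(seed + rr)
    est[rr, ] <- res$est
    ses[rr, ] <- res$se
  }
  rows <- lapply(methods, function(m)
    cbind(method = m, compute_metrics(est[, m], ses[, m], truth)))
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth
  attr(out, "n_reps") <- n_reps
  attr(out, "scenario") <- label
  attr(out, "heckman_method") <- heckman_method
  if (keep_estimates) {
    attr(out, "estimates") <- est
    attr(out, "ses") <- ses
  }
  class(out) <- c("sim_metrics", "data.frame")
  out
}

#' Read simulation scenarios from a YAML configuration file
#'
#' Each scenario is a mapping with a `kind` field (`"regression"` or
#' `"mr"`); the remaining keys are passed to [regression_scenario()] or
#' [mr_scenario()].  A file may hold one scenario or a named list of them.
#' Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A named list of scenario objects (a single unnamed scenario is
#'   returned under the name `"scenario"`).
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' writeLines("kind: regression\nvariant: baseline\nn: 1000", p)
#' read_scenario_config(p)
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(entry) {
    if (is.null(entry$kind))
      stop("scenario config needs a 'kind' field (regression or mr)")
    kind <- match.arg(entry$kind, c("regression", "mr"))
    entry$kind <- NULL
    ## YAML 1.1 reads a bare `n:` key as boolean FALSE; n is the only
    ## scenario parameter with a boolean alias, so map it back
    names(entry)[names(entry) == "FALSE"] <- "n"
    fun <- if (kind == "regression") regression_scenario else mr_scenario
    known <- names(formals(fun))
    bad <- setdiff(names(entry), known)
    if (length(bad))
      stop("unknown scenario key(s): ", paste(bad, collapse = ", "))
    do.call(fun, entry)
  }
  if (!is.null(cfg$kind)) return(list(scenario = build(cfg)))
  lapply(cfg, build)
}

## one replication of every regression method; returns est/se vectors
.regression_methods <- function(d, methods, sc, heckman_method) {
  est <- se <- stats::setNames(rep(NA_real_, length(methods)), methods)
  X <- d$outcome_design
  for (m in methods) {
    res <- tryCatch(switch(m,
      cca = { f <- cca_fit(d); c(f$beta[["x"]], f$beta_se[["x"]]) },
      ipw = { f <- ipw_fit(d, weight_design = X)
              c(f$beta[["x"]], f$beta_se[["x"]]) },
      oracle = { f <- oracle_fit(d$oracle_outcome, X, family = d$family)
                 c(f$beta[["x"]], f$beta_se[["x"]]) },
      heckman = {
        if (d$family == "poisson")
          stop("Heckman's model does not support a Poisson outcome")
        f <- if (d$family == "logistic") heckman_binary_ml(d)
             else if (heckman_method == "ml") heckman_ml(d)
             else heckman_two_step(d)
        c(f$beta[["x"]], f$beta_se[["x"]])
      },
      ttw = { f <- ttw_fit(d, mode = "partial")
              c(f$beta[["x"]], f$beta_se[["x"]]) },
      stop("unknown method: ", m)), error = function(e) c(NA, NA))
    est[m] <- res[1]; se[m] <- res[2]
  }
  list(est = est, se = se)
}

## one replication of every MR method for the chosen estimator
.mr_methods <- function(d, methods, sc, estimator, heckman_method,
                        boot_M, rep_seed) {
  est <- se <- stats::setNames(rep(NA_real_, length(methods)), methods)
  adj_x <- if ("X" %in% sc$mask_rule) TRUE else FALSE
  adj_y <- if ("Y" %in% sc$mask_rule) TRUE else FALSE
  for (m in methods) {
    res <- tryCatch(
      .mr_one(d, m, sc, estimator, adj_x, adj_y, heckman_method, boot_M,
              rep_seed),
      error = function(e) c(NA, NA))
    est[m] <- res[1]; se[m] <- res[2]
  }
  list(est = est, se = se)
}

.mr_one <- function(d, m, sc, estimator, adj_x, adj_y, heckman_method,
                    boot_M, rep_seed) {
  two_sample <- inherits(d, "mr_data_2s")
  dx <- if (two_sample) d$sample_x else d
  dy <- if (two_sample) d$sample_y else d

  unmask <- function(s) {
    u <- mr_data(s$instruments, s$exposure_full, s$outcome_full,
                 s$selection_instrument, selected = rep(TRUE, s$n))
    u
  }

  if (estimator == "wald" || estimator == "ivw") {
    side <- function(sample, which) {
      v <- if (which == "exposure") sample$exposure else sample$outcome
      masked <- anyNA(v)
      adj <- switch(m, heckman = if (masked) "heckman" else "none",
                    ttw = if (masked) "ttw" else "none", "none")
      if (m == "oracle") sample <- unmask(sample)
      if (m == "ipw" && masked)
        return(.ipw_assoc(sample, which))
      a <- estimate_association(sample, which, adjust = adj,
                                heckman_method = heckman_method)
      c(a$beta, a$se)
    }
    if (estimator == "wald") {
      ax <- side(dx, "exposure"); ay <- side(dy, "outcome")
      w <- wald_ratio(ax[1], ax[2], ay[1], ay[2])
      return(c(w$theta, w$theta_se))
    }
    ## ivw over per-variant summary statistics
    K <- dx$K
    bx <- sx <- by <- sy <- numeric(K)
    for (j in seq_len(K)) {
      vx <- if (m == "oracle") unmask(dx) else dx
      vy <- if (m == "oracle") unmask(dy) else dy
      axj <- .variant_assoc(vx, "exposure", m, j, heckman_method)
      ayj <- .variant_assoc(vy, "outcome", m, j, heckman_method)
      bx[j] <- axj[1]; sx[j] <- axj[2]
      by[j] <- ayj[1]; sy[j] <- ayj[2]
    }
    st <- data.frame(beta_x = bx, se_x = sx, beta_y = by, se_y = sy)
    iv <- ivw(st, se_mode = "second_order")
    return(c(iv$theta, iv$theta_se))
  }

  ## 2SLS
  if (m == "oracle") {
    f <- tsls(unmask(dx), se = "analytic")
    return(c(f$theta, f$theta_se))
  }
  if (m == "cca") {
    f <- tsls(dx, se = "analytic")
    return(c(f$theta, f$theta_se))
  }
  if (m == "ipw") return(.ipw_tsls(dx))
  adj <- m  # heckman or ttw
  a1 <- if (adj_x) adj else "none"
  a2 <- if (adj_y) adj else "none"
  if (boot_M > 0) {
    f <- tsls(dx, a1, a2, se = "bootstrap", boot_M = boot_M,
              seed = rep_seed + 500000L, heckman_method = heckman_method)
  } else {
    f <- tsls(dx, a1, a2, se = "none", heckman_method = heckman_method)
  }
  c(f$theta, f$theta_se)
}

## univariate per-variant association for the summary-statistics estimator
.variant_assoc <- function(sample, which, m, j, heckman_method) {
  v <- if (which == "exposure") sample$exposure else sample$outcome
  masked <- anyNA(v)
  if (m == "ipw" && masked) return(.ipw_assoc(sample, which, variant = j))
  adj <- switch(m, heckman = if (masked) "heckman" else "none",
                ttw = if (masked) "ttw" else "none", "none")
  a <- estimate_association(sample, which, adjust = adj, variant = j,
                            heckman_method = heckman_method)
  c(a$beta, a$se)
}

## IPW instrument association: weights from a logistic model of selection
## on the instruments only (the fully observed columns)
.ipw_assoc <- function(sample, which, variant = NULL) {
  v <- if (which == "exposure") sample$exposure else sample$outcome
  G <- if (is.null(variant)) sample$instruments
       else sample$instruments[, variant, drop = FALSE]
  obs <- !is.na(v)
  sd <- selection_data(v, cbind(`(Intercept)` = 1, G),
                       cbind(`(Intercept)` = 1, G), selected = obs)
  f <- ipw_fit(sd, weight_design = cbind(1, sample$instruments))
  c(f$beta[[2]], f$beta_se[[2]])
}

## IPW 2SLS: weighted two-stage least squares on complete rows, weights
## 1/pi from a logistic selection model on the instruments
.ipw_tsls <- function(d) {
  cc <- !(is.na(d$exposure) | is.na(d$outcome))
  prop <- fit_propensity(cbind(1, d$instruments), d$selected)
  w <- 1 / prop$fitted_pi[cc]
  G <- d$instruments[cc, , drop = FALSE]
  x <- d$exposure[cc]; y <- d$outcome[cc]
  D1 <- cbind(1, G)
  b1 <- qr.coef(qr(D1 * sqrt(w)), x * sqrt(w))
  xhat <- drop(D1 %*% b1)
  W2 <- cbind(1, xhat = xhat)
  b2 <- qr.coef(qr(W2 * sqrt(w)), y * sqrt(w))
  theta <- b2[["xhat"]]
  resid <- y - b2[[1]] - theta * x
  s2 <- sum(w * resid^2) / (sum(w) - 1)
  V <- s2 * solve(crossprod(W2 * sqrt(w)))
  c(theta, sqrt(V[2, 2]))
}

#' @export
print.sim_metrics <- function(x, digits = 3, ...) {
  cat("Monte-Carlo summary (", attr(x, "scenario"), "), ",
      attr(x, "n_reps"), " replications, truth = ",
      attr(x, "truth"), "\n", sep = "")
  print.data.frame(cbind(method = x$method,
                         round(x[, -1, drop = FALSE], digits)),
                   row.names = FALSE)
  invisible(x)
}
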