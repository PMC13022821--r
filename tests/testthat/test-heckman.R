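test_that("intercept-only selection design reduces slopes to complete-case OLS", {
  d <- make_heckman_data(n = 400, seed = 5)
  d2 <- selection_data(d$outcome, d$outcome_design,
                       matrix(1, d$n, 1, dimnames = list(NULL, "(Intercept)")),
                       selected = d$selected)
  expect_warning(fit <- heckman_two_step(d2), "aliased")
  cca <- cca_fit(d)
  expect_equal(fit$beta[["x"]], cca$beta[["x"]], tolerance = 1e-10)
  expect_true(is.na(fit$rho_sigma))
})

test_that("independent selection gives rho_sigma near 0 and OLS-like slopes", {
  d <- make_heckman_data(n = 2e4, rho = 0, seed = 6)
  fit <- heckman_two_step(d)
  expect_lt(abs(fit$rho), 0.1)
  ## compare against OLS on the full pre-masking data, reconstructed
  set.seed(6)
  x <- rnorm(2e4); z <- rnorm(2e4); e2 <- rnorm(2e4)
  y_full <- 1 + 0.5 * x + 1 * (0 * e2 + rnorm(2e4))
  ols <- coef(lm(y_full ~ x))
  expect_equal(fit$beta[["x"]], ols[[2]], tolerance = 0.05)
})

test_that("two-step and joint ML agree within sampling error", {
  d <- make_heckman_data(n = 500, seed = 7)
  ts <- heckman_two_step(d)
  ml <- heckman_ml(d)
  expect_lt(abs(ts$beta[["x"]] - ml$beta[["x"]]), 2 * ts$beta_se[["x"]])
  expect_true(all(ts$beta_se > 0))
  expect_true(all(ml$beta_se > 0))
  expect_gt(ml$sigma1, 0)
})

test_that("ML optimum dominates the two-step point and a random grid", {
  d <- make_heckman_data(n = 300, seed = 8)
  ts <- heckman_two_step(d)
  ml <- heckman_ml(d)
  ## independent likelihood evaluation
  llfun <- function(beta, gamma, s, rho) {
    r <- d$selected
    eta <- drop(d$selection_design %*% gamma)
    z <- (d$outcome[r] - drop(d$outcome_design[r, ] %*% beta)) / s
    sum(pnorm(-eta[!r], log.p = TRUE)) +
      sum(dnorm(z, log = TRUE) - log(s) +
            pnorm((eta[r] + rho * z) / sqrt(1 - rho^2), log.p = TRUE))
  }
  ll_ml <- llfun(ml$beta, ml$gamma, ml$sigma1, ml$rho)
  expect_equal(ll_ml, ml$loglik, tolerance = 1e-6)
  ll_ts <- llfun(ts$beta, ts$gamma, ts$sigma1, max(-0.99, min(0.99, ts$rho)))
  expect_gte(ll_ml, ll_ts - 1e-8)
  set.seed(80)
  for (i in 1:1000) {
    cand <- llfun(ml$beta + rnorm(2, 0, 0.2), ml$gamma + rnorm(3, 0, 0.2),
                  ml$sigma1 * exp(rnorm(1, 0, 0.2)), runif(1, -0.95, 0.95))
    expect_gte(ll_ml, cand)
  }
})

test_that("ML log-likelihood is invariant to rescaling a selection column", {
  d <- make_heckman_data(n = 400, seed = 9)
  f1 <- heckman_ml(d)
  W2 <- d$selection_design
  W2[, "z"] <- W2[, "z"] * 10
  d2 <- selection_data(d$outcome, d$outcome_design, W2,
                       selected = d$selected)
  f2 <- heckman_ml(d2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$gamma[["z"]], 10 * f2$gamma[["z"]], tolerance = 1e-4)
})

test_that("all-selected data fall back to OLS with a warning", {
  set.seed(10)
  x <- rnorm(100); y <- 1 + 0.5 * x + rnorm(100)
  d <- selection_data(y, cbind(1, x = x), cbind(1, x = x, z = rnorm(100)))
  expect_warning(fit <- heckman_two_step(d), "vacuous")
  expect_equal(fit$beta[["x"]], coef(lm(y ~ x))[[2]], tolerance = 1e-10)
})

test_that("bivariate-probit fit matches a generic maximizer and the rho=0 case", {
  ## rho = 0: estimates approach two separate probits (a stochastic
  ## identity; the binary outcome carries little information on rho)
  set.seed(11)
  n <- 6000
  x <- rnorm(n); z <- rnorm(n)
  ystar <- 0.3 + 0.6 * x + rnorm(n)
  rstar <- 0.2 + 0.4 * x + 0.8 * z + rnorm(n)   # independent errors
  r <- rstar > 0
  y <- ifelse(r, as.numeric(ystar > 0), NA)
  d <- selection_data(y, cbind(1, x = x), cbind(1, x = x, z = z),
                      selected = r)
  fit <- heckman_binary_ml(d)
  sep <- glm(y[r] ~ x[r], family = binomial("probit"))
  expect_equal(unname(fit$beta), unname(coef(sep)), tolerance = 0.15)
  expect_lt(abs(fit$rho), 0.2)

  ## correlated errors: compare with an independent mvtnorm-based maximizer
  skip_if_not_installed("mvtnorm")
  set.seed(12)
  n <- 800
  x <- rnorm(n); z <- rnorm(n)
  e2 <- rnorm(n); e1 <- 0.6 * e2 + sqrt(1 - 0.36) * rnorm(n)
  r <- (0.3 + 0.4 * x + 0.8 * z + e2) > 0
  yb <- ifelse(r, as.numeric((0.2 + 0.5 * x + e1) > 0), NA)
  d <- selection_data(yb, cbind(1, x = x), cbind(1, x = x, z = z),
                      selected = r)
  fit <- heckman_binary_ml(d)
  X <- d$outcome_design; W <- d$selection_design
  nll_oracle <- function(par) {
    b <- par[1:2]; g <- par[3:5]; rho <- tanh(par[6])
    S <- matrix(c(1, rho, rho, 1), 2)
    Sm <- matrix(c(1, -rho, -rho, 1), 2)
    ll <- sum(pnorm(-drop(W[!r, ] %*% g), log.p = TRUE))
    for (i in which(r)) {
      ub <- if (yb[i] == 1) c(sum(X[i, ] * b), sum(W[i, ] * g))
            else c(-sum(X[i, ] * b), sum(W[i, ] * g))
      ll <- ll + log(max(mvtnorm::pmvnorm(
        upper = ub, corr = if (yb[i] == 1) S else Sm)[1], 1e-300))
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  start <- c(coef(suppressWarnings(glm(yb[r] ~ x[r],
                                       family = binomial("probit")))),
             fit_probit(W, r)$gamma, 0)
  oracle <- optim(start, nll_oracle, method = "BFGS",
                  control = list(reltol = 1e-14, maxit = 400))
  expect_equal(unname(fit$beta), unname(oracle$par[1:2]),
               tolerance = 1e-4)
  expect_equal(fit$rho, tanh(oracle$par[6]), tolerance = 1e-3)
})
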