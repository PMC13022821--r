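test_that("propensity fit matches a generic logistic maximizer", {
  set.seed(31)
  n <- 2000
  W <- cbind(1, x = rnorm(n), z = rnorm(n))
  r <- as.numeric(runif(n) < plogis(0.2 + 0.4 * W[, 2] + 0.8 * W[, 3]))
  fit <- fit_propensity(W, r)
  oracle <- optim(c(0, 0, 0), function(a) {
    eta <- drop(W %*% a)
    -sum(r * eta - log1p(exp(eta)))
  }, method = "BFGS", control = list(reltol = 1e-15))
  expect_equal(unname(fit$alpha_prop), oracle$par, tolerance = 1e-6)
  expect_true(all(fit$fitted_pi > 0 & fit$fitted_pi < 1))
  ## intercept-only with a 50% rate: logit(0.5) = 0
  fit0 <- fit_propensity(matrix(1, 100, 1), rep(c(0, 1), 50))
  expect_equal(unname(fit0$alpha_prop), 0, tolerance = 1e-8)
})

test_that("homogeneous-bias log-likelihood equals a naive summation", {
  d <- make_ttw_data(n = 50, seed = 32)
  set.seed(33)
  for (i in 1:5) {
    params <- c(rnorm(2), rnorm(2, 0, 0.5), rnorm(3, 0, 0.5),
                runif(1, 0.5, 2))
    expect_equal(ttw_loglik(params, d), naive_ttw_loglik(params, d),
                 tolerance = 1e-10)
  }
})

test_that("with eta = 0 the likelihood factorizes into logistic + Gaussian parts", {
  d <- make_ttw_data(n = 300, seed = 34)
  beta <- c(0.8, 0.4); alpha <- c(0.1, 0.3, 0.6); s2 <- 1.3
  ll <- ttw_loglik(c(beta, 0, 0, alpha, s2), d)
  r <- as.numeric(d$selected)
  pi_hat <- plogis(drop(d$selection_design %*% alpha))
  ll_sep <- sum(dbinom(r, 1, pi_hat, log = TRUE)) +
    sum(dnorm(d$outcome[d$selected],
              drop(d$outcome_design[d$selected, ] %*% beta),
              sqrt(s2), log = TRUE))
  expect_equal(ll, ll_sep, tolerance = 1e-12)
})

test_that("partial-optimization stage two matches a brute-force maximizer", {
  d <- make_ttw_data(n = 2000, seed = 35)
  fit <- ttw_fit(d, mode = "partial")
  ## independent stage-2 maximization with the same fixed propensity
  prop <- fit_propensity(d$selection_design, d$selected)
  r <- d$selected
  X1 <- d$outcome_design[r, ]; pi1 <- prop$fitted_pi[r]; y1 <- d$outcome[r]
  nll2 <- function(par) {
    mu <- drop(X1 %*% par[1:2]) + drop(X1 %*% par[3:4]) * (1 - pi1)
    -sum(dnorm(y1, mu, sqrt(exp(par[5])), log = TRUE))
  }
  oracle <- optim(c(0.5, 0.5, 0, 0, 0), nll2, method = "BFGS",
                  control = list(reltol = 1e-15, maxit = 1000))
  expect_equal(unname(c(fit$beta, fit$eta)), oracle$par[1:4],
               tolerance = 1e-4)
  expect_equal(fit$sigma2, exp(oracle$par[5]), tolerance = 1e-4)
})

test_that("full optimization dominates partial and has a vanishing gradient", {
  d <- make_ttw_data(n = 500, seed = 36)
  fp <- ttw_fit(d, mode = "partial")
  ff <- ttw_fit(d, mode = "full")
  expect_gte(ff$loglik, fp$loglik - 1e-8)
  par <- c(ff$beta, ff$eta, ff$alpha_prop, ff$sigma2)
  g <- sapply(seq_along(par), function(i) {
    h <- 1e-5 * max(1, abs(par[i]))
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    (ttw_loglik(pp, d) - ttw_loglik(pm, d)) / (2 * h)
  })
  expect_lt(max(abs(g)), 1e-5)
})

test_that("a missing instrument for selection is caught as unidentified", {
  d <- make_ttw_data(n = 600, seed = 37)
  W_noz <- d$selection_design[, c("(Intercept)", "x")]
  d2 <- selection_data(d$outcome, d$outcome_design, W_noz,
                       selected = d$selected)
  expect_error(ttw_fit(d2), "collinear|instrument")
})

test_that("likelihood is invariant to compensated rescaling of a column", {
  d <- make_ttw_data(n = 500, seed = 38)
  f1 <- ttw_fit(d, mode = "partial")
  d2 <- d
  d2$selection_design[, "z"] <- d$selection_design[, "z"] * 5
  f2 <- ttw_fit(d2, mode = "partial")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$alpha_prop[["z"]], 5 * f2$alpha_prop[["z"]],
               tolerance = 1e-6)
})

test_that("glm families reduce to ordinary GLMs when the bias is absent", {
  set.seed(39)
  n <- 1500
  x <- rnorm(n); z <- rnorm(n)
  r <- runif(n) < plogis(0.3 + 0.8 * z)       # selection independent of y
  yb <- ifelse(r, rbinom(n, 1, plogis(0.5 + 0.4 * x)), NA)
  d <- selection_data(yb, cbind(1, x = x), cbind(1, x = x, z = z),
                      selected = r, family = "logistic")
  fit <- ttw_fit(d, family = "logistic")
  ref <- glm(yb[r] ~ x[r], family = binomial)
  ## eta is estimated but should be near zero; beta near the plain GLM
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 0.25)
})

test_that("Poisson family optimum matches a brute-force maximizer", {
  set.seed(40)
  n <- 2000
  x <- rnorm(n); z <- rnorm(n)
  pi_t <- plogis(0.2 + 0.3 * x + 0.8 * z)
  r <- runif(n) < pi_t
  mu <- exp(1 + 0.1 * x + (0.3 - 0.1 * x) * (1 - pi_t))
  yp <- ifelse(r, rpois(n, mu), NA)
  d <- selection_data(yp, cbind(1, x = x), cbind(1, x = x, z = z),
                      selected = r, family = "poisson")
  fit <- ttw_fit(d, family = "poisson")
  prop <- fit_propensity(d$selection_design, d$selected)
  X1 <- d$outcome_design[r, ]; pi1 <- prop$fitted_pi[r]; y1 <- yp[r]
  nll2 <- function(par) {
    lp <- drop(X1 %*% par[1:2]) + drop(X1 %*% par[3:4]) * (1 - pi1)
    -sum(dpois(y1, exp(lp), log = TRUE))
  }
  oracle <- optim(c(0, 0, 0, 0), nll2, method = "BFGS",
                  control = list(reltol = 1e-15, maxit = 1000))
  expect_equal(unname(c(fit$beta, fit$eta)), oracle$par, tolerance = 1e-4)
})

test_that("parameters are recovered with shrinking bias as n grows", {
  bias <- sapply(c(1e3, 1e4, 1e5), function(n) {
    est <- sapply(1:3, function(s) {
      d <- make_ttw_data(n = n, seed = 100 * s + n)
      ttw_fit(d, mode = "partial")$beta[["x"]]
    })
    abs(mean(est) - 0.5)
  })
  expect_lt(bias[3], 0.03)
  expect_lt(bias[3], bias[1] + 0.02)
})
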