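## Small simulated fixtures shared across tests.  Everything is generated
## in code under fixed seeds.

## linear outcome with correlated bivariate-normal selection errors: the
## Heckman generative model itself (probit selection)
make_heckman_data <- function(n = 500, beta = c(1, 0.5),
                              gamma = c(0.3, 0.4, 0.7), rho = 0.5,
                              sigma1 = 1, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); z <- rnorm(n)
  e2 <- rnorm(n)
  e1 <- sigma1 * (rho * e2 + sqrt(1 - rho^2) * rnorm(n))
  y <- beta[1] + beta[2] * x + e1
  r <- (gamma[1] + gamma[2] * x + gamma[3] * z + e2) > 0
  selection_data(ifelse(r, y, NA),
                 cbind(`(Intercept)` = 1, x = x),
                 cbind(`(Intercept)` = 1, x = x, z = z),
                 selected = r)
}

## data from the TTW generative model itself: logistic selection and an
## additive homogeneous bias delta(x) = eta0 + eta1 x
make_ttw_data <- function(n = 1000, beta = c(1, 0.5), eta = c(0.6, -0.3),
                          alpha = c(0.2, 0.4, 0.8), sigma = 1, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); z <- rnorm(n)
  pi <- plogis(alpha[1] + alpha[2] * x + alpha[3] * z)
  r <- runif(n) < pi
  mu1 <- beta[1] + beta[2] * x + (eta[1] + eta[2] * x) * (1 - pi)
  y <- ifelse(r, mu1 + sigma * rnorm(n), NA)
  selection_data(y, cbind(`(Intercept)` = 1, x = x),
                 cbind(`(Intercept)` = 1, x = x, z = z), selected = r)
}

## small one-sample MR dataset with outcome-driven selection
make_mr_data <- function(n = 800, theta = 0.2, mask = "Y", seed = 1) {
  set.seed(seed)
  g <- rnorm(n); z <- rnorm(n); u <- rnorm(n)
  x <- sqrt(2 / 19) * g + u + rnorm(n)
  y <- theta * x + u + rnorm(n)
  r <- runif(n) < plogis(-0.5 + 0.5 * z + 0.5 * y)
  mr_data(matrix(g, dimnames = list(NULL, "g1")),
          if ("X" %in% mask) ifelse(r, x, NA) else x,
          if ("Y" %in% mask) ifelse(r, y, NA) else y,
          z, selected = r)
}

## independent naive evaluation of the homogeneous-bias log-likelihood,
## one observation at a time (oracle for ttw_loglik)
naive_ttw_loglik <- function(params, data) {
  p <- ncol(data$outcome_design); q <- ncol(data$selection_design)
  beta <- params[1:p]; eta <- params[p + 1:p]
  alpha <- params[2 * p + 1:q]; s2 <- params[2 * p + q + 1]
  total <- 0
  for (i in seq_len(data$n)) {
    pi_i <- 1 / (1 + exp(-sum(data$selection_design[i, ] * alpha)))
    ri <- as.numeric(data$selected[i])
    total <- total + ri * log(pi_i) + (1 - ri) * log(1 - pi_i)
    if (data$selected[i]) {
      mu <- sum(data$outcome_design[i, ] * beta) +
        sum(data$outcome_design[i, ] * eta) * (1 - pi_i)
      total <- total - 0.5 * log(2 * pi * s2) -
        (data$outcome[i] - mu)^2 / (2 * s2)
    }
  }
  total
}

## independent probit log-likelihood and analytic gradient (oracle)
probit_loglik <- function(gamma, W, r) {
  eta <- drop(W %*% gamma)
  sum(r * pnorm(eta, log.p = TRUE) + (1 - r) * pnorm(-eta, log.p = TRUE))
}
probit_grad <- function(gamma, W, r) {
  eta <- drop(W %*% gamma)
  s <- ifelse(r == 1, dnorm(eta) / pnorm(eta),
              -dnorm(eta) / pnorm(-eta))
  drop(crossprod(W, s))
}
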