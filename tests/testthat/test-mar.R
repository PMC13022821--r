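test_that("with no missingness CCA equals the oracle fit", {
  set.seed(51)
  x <- rnorm(200); y <- 1 + 0.5 * x + rnorm(200)
  d <- selection_data(y, cbind(1, x = x), cbind(1, x = x, z = rnorm(200)))
  cc <- cca_fit(d)
  orc <- oracle_fit(y, d$outcome_design, family = "linear")
  expect_equal(cc$beta, orc$beta, tolerance = 1e-12)
  expect_equal(cc$beta_se, orc$beta_se, tolerance = 1e-12)
})

test_that("constant weights make IPW point estimates equal CCA", {
  d <- make_heckman_data(n = 500, seed = 52)
  f <- ipw_fit(d, weight_design = matrix(1, d$n, 1))
  cc <- cca_fit(d)
  expect_equal(unname(f$beta), unname(cc$beta), tolerance = 1e-8)
})

test_that("IPW sandwich standard errors exceed naive model SEs most of the time", {
  sc <- regression_scenario("baseline", alpha_R = -0.5, n = 1e4)
  hits <- sapply(1:40, function(s) {
    d <- gen_regression(sc, seed = 520 + s)
    f <- ipw_fit(d, weight_design = d$outcome_design)
    f$beta_se[["x"]] >= sqrt(diag(f$vcov_model))[2] * 0.999
  })
  expect_gte(mean(hits), 0.95)
})

test_that("IPW is unbiased under MAR (selection on the covariate only)", {
  est <- sapply(1:150, function(s) {
    set.seed(1000 + s)
    n <- 2000
    x <- rnorm(n); z <- rnorm(n)
    y <- 1 + 0.5 * x + rnorm(n)
    r <- runif(n) < plogis(0.2 + 0.8 * x)       # MAR: depends on x only
    d <- selection_data(ifelse(r, y, NA), cbind(1, x = x),
                        cbind(1, x = x, z = z), selected = r)
    ipw_fit(d, weight_design = d$outcome_design)$beta[["x"]]
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 3 * mc_se)
})

test_that("extreme weights are refused", {
  set.seed(53)
  n <- 500
  x <- rnorm(n)
  r <- runif(n) < plogis(1 + 2 * x)
  y <- ifelse(r, 1 + 0.5 * x + rnorm(n), NA)
  d <- selection_data(y, cbind(1, x = x), cbind(1, x = x),
                      selected = r)
  ## a floor above the smallest fitted selection probability of a selected
  ## row must trigger the guard
  expect_error(ipw_fit(d, weight_design = d$outcome_design, pi_floor = 0.6),
               "extreme")
})
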