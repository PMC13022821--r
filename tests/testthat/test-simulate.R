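test_that("intercept tuning has the closed form when nothing drives selection", {
  sc <- regression_scenario("baseline", beta_R = 0, gamma_R = 0,
                            delta_R = 0)
  expect_identical(tune_alpha_R(sc, target = 0.3), qlogis(0.3))
})

test_that("baseline tuning lands near -0.5 and replays to the target", {
  sc <- regression_scenario("baseline")
  a <- tune_alpha_R(sc, pilot_n = 2e5, seed = 3)
  expect_lt(abs(a - (-0.5)), 0.02)
  sc$alpha_R <- a
  d <- gen_regression(sc, seed = 99)
  expect_lt(abs(mean(d$selected) - 0.5), 0.02)
})

test_that("generated baseline data have the stated marginal structure", {
  sc <- regression_scenario("baseline", alpha_R = -0.5, n = 2e5)
  d <- gen_regression(sc, seed = 7)
  expect_equal(mean(d$selected), 0.5, tolerance = 0.01)
  x <- d$outcome_design[, "x"]; z <- d$selection_design[, "z"]
  ## the instrument moves selection: positive Z-R association
  expect_gt(cor(z, d$selected), 0.05)
  ## oracle outcome follows y = 1 + 0.1 x + e
  ols <- coef(lm(d$oracle_outcome ~ x))
  expect_equal(unname(ols), c(1, 0.1), tolerance = 0.02)
})

test_that("MCAR selection leaves complete-case analysis unbiased", {
  sc <- regression_scenario("baseline", beta_R = 0, gamma_R = 0,
                            delta_R = 0, n = 2000)
  tab <- run_replications(sc, "cca", n_reps = 150, seed = 17)
  mc_se <- tab$emp_sd / sqrt(150)
  expect_lt(abs(tab$mean - 0.1), 3 * mc_se)
})

test_that("single-instrument MR generator gives G about 5% of exposure variance", {
  sc <- mr_scenario(theta = 0, selection = "Y", n = 2e5, alpha_R = -0.5)
  d <- gen_mr(sc, seed = 5)
  g <- d$instruments[, 1]
  share <- var(g * sqrt(2 / 19)) / var(d$exposure_full)
  expect_lt(abs(share - 0.05), 0.005)
  ## null causal effect: G and Y uncorrelated
  expect_lt(abs(cor(g, d$outcome_full)), 0.01)
})

test_that("multi-instrument generator masks both sides and keeps Z complete", {
  sc <- mr_scenario(theta = 0.2, K = 10, selection = "XY", alpha_R = -1,
                    n = 5000)
  d <- gen_mr(sc, seed = 6)
  expect_equal(dim(d$instruments), c(5000, 10))
  expect_true(all(d$instruments %in% 0:2))
  expect_false(anyNA(d$selection_instrument))
  expect_identical(is.na(d$exposure), !d$selected)
  expect_identical(is.na(d$outcome), !d$selected)
  ## two-sample design masks each sample only on its measured side
  sc2 <- mr_scenario(theta = 0.2, K = 3, selection = "Y",
                     design = "two_sample", alpha_R = -0.5, n = 2000)
  d2 <- gen_mr(sc2, seed = 7)
  expect_false(anyNA(d2$sample_x$exposure))
  expect_true(anyNA(d2$sample_y$outcome))
})

test_that("metrics arithmetic is exact on a hand-built fixture", {
  est <- c(0.10, 0.12, 0.08, NA)
  ses <- c(0.01, 0.05, 0.005, 0.01)
  m <- compute_metrics(est, ses, truth = 0.1)
  expect_equal(m$mean, mean(c(0.10, 0.12, 0.08)))
  expect_equal(m$emp_sd, sd(c(0.10, 0.12, 0.08)))
  expect_equal(m$mean_se, mean(c(0.01, 0.05, 0.005)))
  ## intervals: [.0804,.1196] yes, [.022,.218] yes, [.0702,.0898] no
  expect_equal(m$coverage, 2 / 3)
  ## |est/se|: 10, 2.4, 16 -> all reject
  expect_equal(m$power, 1)
  expect_equal(m$n_failed, 1)
})

test_that("replication runs are deterministic given the seed", {
  sc <- regression_scenario("baseline", alpha_R = -0.5, n = 1500)
  t1 <- run_replications(sc, c("cca", "heckman"), n_reps = 20, seed = 123)
  t2 <- run_replications(sc, c("cca", "heckman"), n_reps = 20, seed = 123)
  expect_identical(t1$mean, t2$mean)
  expect_identical(t1$emp_sd, t2$emp_sd)
  t3 <- run_replications(sc, c("cca", "heckman"), n_reps = 20, seed = 124)
  expect_false(identical(t1$mean, t3$mean))
})

test_that("an exclusion-restriction violation biases the adjusted estimators", {
  sc <- regression_scenario("ZY_effect", n = 1e4)
  tab <- run_replications(sc, c("heckman", "ttw"), n_reps = 60, seed = 31,
                          pilot_n = 2e5)
  hk <- tab[tab$method == "heckman", ]
  tw <- tab[tab$method == "ttw", ]
  expect_lt(hk$mean, 0)          # severe downward bias (truth is 0.1)
  expect_lt(hk$coverage, 0.5)
  expect_lt(tw$mean, 0)
  expect_lt(tw$coverage, 0.5)
})
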