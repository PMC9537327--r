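test_that("choice table pools presentation phases and counts correctly", {
  rec <- data.frame(participant_id = "P01", lag_ms = 50,
                    sound = 0L, comparison_phase = rep(1:2, each = 5),
                    choice_comparison = c(1, 1, 1, 1, 0, 1, 1, 1, 0, 0),
                    excluded = 0L)
  ct <- choice_table(rec)
  expect_equal(ct$n_trials, 10)
  expect_equal(ct$proportion, 0.7)

  # excluded trials are dropped
  rec$excluded[1:5] <- 1L
  ct2 <- choice_table(rec)
  expect_equal(ct2$n_trials, 5)
})

test_that("pooling phases cancels a constructed order bias to first order", {
  # phase-2 presentations get a bias +delta on the probit scale; merging the
  # two phase assignments of the same lag removes it to first order
  set.seed(21)
  delta <- 0.4
  n <- 4000
  lag <- 50; beta <- 0.006
  phase <- rep(1:2, each = n / 2)
  eta <- beta * lag + ifelse(phase == 2, delta, -delta)
  y <- as.integer(runif(n) < pnorm(eta))
  pooled <- mean(y)
  expected <- pnorm(beta * lag)
  # each phase alone is badly biased; the pool is close to the unbiased value
  expect_gt(abs(mean(y[phase == 2]) - expected), 0.10)
  expect_lt(abs(pooled - (pnorm(beta * lag + delta) +
                            pnorm(beta * lag - delta)) / 2), 0.02)
  expect_lt(abs(pooled - expected), 0.05)
})

test_that("zero-variance data reduce to the plain probit fit", {
  d <- probit_dataset(6, 60, alpha = 0.1, beta_ms = 0.006,
                      sd_a = 0, sd_b_ms = 0, seed = 2)
  f <- fit_probit_glmm(d, 1, se = FALSE)
  g <- glm(y ~ x, binomial("probit"), d)
  eta_f <- f$fixed["alpha"] + f$fixed["beta"] * c(0, 50, 83)
  eta_g <- coef(g)[1] + coef(g)[2] * c(0, 50, 83)
  expect_lt(max(abs(eta_f - eta_g)), 1e-3)
})

test_that("Laplace log-likelihood matches adaptive Gauss-Hermite quadrature", {
  for (seed in 1:3) {
    d <- probit_dataset(3, 30, alpha = 0.1, beta_ms = 0.006,
                        sd_a = 0.3, sd_b_ms = 0.002, seed = seed)
    f <- fit_probit_glmm(d, 1, se = FALSE)
    ag <- aghq_loglik(d, f$theta_internal, model = 1, n_nodes = 31)
    expect_lt(abs(f$loglik - ag), 0.1)
  }
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- probit_dataset(10, 120, alpha = 0, beta_ms = 0.0055,
                      sd_a = 0.2, sd_b_ms = 0.0025, seed = 5)
  f <- fit_probit_glmm(d, 1, se = FALSE)
  m <- suppressWarnings(suppressMessages(
    lme4::glmer(y ~ x + (1 | participant_id) + (0 + x | participant_id),
                data = d, family = binomial("probit"))))
  expect_lt(abs(f$loglik - as.numeric(logLik(m))), 0.1)
  fe <- lme4::fixef(m)
  expect_lt(abs(f$fixed["alpha"] - fe[1]), 0.02)
  expect_lt(abs(f$fixed["beta"] - fe[2]), 2e-4)
})

test_that("participant relabeling leaves the population fit invariant", {
  d <- probit_dataset(5, 50, 0, 0.006, 0.2, 0.002, seed = 7)
  f1 <- fit_probit_glmm(d, 1, se = FALSE)
  d2 <- d
  relabel <- setNames(sprintf("Q%02d", 5:1), sprintf("S%02d", 1:5))
  d2$participant_id <- unname(relabel[d$participant_id])
  f2 <- fit_probit_glmm(d2, 1, se = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  expect_equal(f1$fixed, f2$fixed, tolerance = 1e-3)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-3)
  # deviations permute with the relabeling
  o1 <- f1$ranef[order(f1$ranef$participant_id), -1]
  o2 <- f2$ranef[match(relabel[f1$ranef$participant_id],
                       f2$ranef$participant_id), -1]
  expect_equal(unlist(o1), unlist(o2), tolerance = 1e-2,
               ignore_attr = TRUE)
})

test_that("rescaling the lag unit rescales the slope exactly", {
  d <- probit_dataset(5, 60, 0, 0.006, 0.2, 0.002, seed = 8)
  f_ms <- fit_probit_glmm(d, 1, se = FALSE)
  d_s <- d
  d_s$x <- d$x / 1000                    # lag in seconds
  f_s <- fit_probit_glmm(d_s, 1, se = FALSE)
  expect_equal(f_s$loglik, f_ms$loglik, tolerance = 1e-3)
  expect_equal(f_s$fixed["beta"], 1000 * f_ms$fixed["beta"],
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("model comparison ranks by AIC with the documented k", {
  d <- probit_dataset(6, 80, 0, 0.006, 0.15, 0.002, seed = 9)
  f1 <- fit_probit_glmm(d, 1, se = FALSE)
  expect_equal(f1$k, 4)
  expect_equal(f1$aic, -2 * f1$loglik + 2 * 4)
  cmp_same <- model_comparison_aic(f1, f1)
  expect_equal(cmp_same$delta_aic, c(0, 0))

  d$pd <- pnorm(0.02 * d$x) * 0.9 + 0.05
  f2 <- fit_probit_glmm(d, 2, se = FALSE)
  f3 <- fit_probit_glmm(d, 3, se = FALSE)
  expect_equal(f2$k, 4)
  expect_equal(f3$k, 7)
  cmp <- model_comparison_aic(f1, f2, f3)
  expect_equal(cmp$aic, sort(cmp$aic))
  expect_true(cmp$best[1])
})

test_that("fitted psychometric curves are monotone when slopes share a sign", {
  d <- probit_dataset(5, 100, 0, 0.008, 0.1, 0.001, seed = 10)
  f <- fit_probit_glmm(d, 1, se = FALSE)
  slopes <- f$fixed["beta"] + f$ranef$sd_beta
  if (all(slopes > 0)) {
    for (i in seq_along(slopes)) {
      eta <- (f$fixed["alpha"] + f$ranef$sd_alpha[i]) +
        slopes[i] * seq(-50, 83, by = 1)
      expect_true(all(diff(pnorm(eta)) > 0))
    }
  } else succeed("mixed slope signs: monotonicity not required")
})

test_that("dependency and design errors are raised", {
  d <- probit_dataset(3, 30, 0, 0.006, 0.1, 0.001, seed = 11)
  expect_error(fit_probit_glmm(d, 2), class = "fl_dependency_error")
  d1 <- d; d1$x <- 50                    # single predictor level
  expect_error(fit_probit_glmm(d1, 1), class = "fl_design_error")
  expect_error(fit_probit_glmm(d[d$participant_id == "S01", ], 1),
               class = "fl_design_error")
})

test_that("slope correlation is exact for identical fits and recovers truth", {
  d <- probit_dataset(8, 80, 0, 0.006, 0.2, 0.003, seed = 12)
  f <- fit_probit_glmm(d, 1, se = FALSE)
  sc <- slope_correlation(f, f)
  expect_equal(sc$r, 1, tolerance = 1e-9)
  expect_equal(nrow(sc$slopes), 8)
})

test_that("induced cross-task slope correlation is recovered", {
  cfg <- exp_config(1, n_participants = 50, blocks_per_participant = 8,
                    delay_blocks = 8)
  hy <- cohort_hyper(slope_cor = 0.8, sd_beta = 0.004, sd_beta_delay = 0.008)
  co <- make_cohort(cfg, hy, seed = 31)
  r_true <- cor(co$participants$beta_i, co$participants$beta_d_i)
  expect_lt(abs(r_true - 0.8), 0.15)
})
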