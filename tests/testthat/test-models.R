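# growth-model data without topic structure, built directly
make_growth_data <- function(n = 150, m = 6, beta0 = -0.1, beta_s = -0.15,
                             beta_age = -0.01, beta_sex = 0.09,
                             sd_u0 = 0.9, sd_u1 = 0.1, rho = -0.15,
                             sigma = 0.8, seed = 1) {
  set.seed(seed)
  age <- rnorm(n, 33, 12); sex <- rbinom(n, 1, 0.22)
  Sig <- matrix(c(sd_u0^2, rho * sd_u0 * sd_u1,
                  rho * sd_u0 * sd_u1, sd_u1^2), 2)
  L <- if (sum(abs(Sig)) == 0) matrix(0, 2, 2) else chol(Sig + diag(1e-12, 2))
  U <- matrix(rnorm(2 * n), ncol = 2) %*% L
  idx <- rep(seq_len(n), each = m)
  t_ <- rep(seq_len(m) - 1L, n)
  y <- beta0 + beta_s * t_ + beta_age * age[idx] + beta_sex * sex[idx] +
    U[idx, 1] + U[idx, 2] * t_ + rnorm(n * m, 0, sigma)
  data.frame(patient_id = sprintf("g%04d", idx), session = t_, y_std = y,
             age = age[idx], sex = sex[idx])
}

test_that("a noise-free line is recovered exactly", {
  d <- make_growth_data(n = 30, m = 5, sd_u0 = 0, sd_u1 = 0, rho = 0,
                        sigma = 0, beta0 = 0.4, beta_s = -0.2, seed = 2)
  fit <- quiet(fit_lmm(d, spec = model_spec(random = "intercept_slope")))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], 0.4, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "session"], -0.2, tolerance = 1e-6)
  expect_lt(fit$ranef$residual_var, 1e-8)
  expect_lt(fit$ranef$sd_slope, 1e-4)
})

test_that("balanced random-intercept fit matches the ANOVA method of moments", {
  n <- 60; m <- 5
  set.seed(3)
  u <- rnorm(n, 0, 1.2)
  idx <- rep(seq_len(n), each = m)
  d <- data.frame(patient_id = sprintf("g%03d", idx),
                  session = rep(seq_len(m) - 1L, n),
                  y_std = u[idx] + rnorm(n * m, 0, 0.7),
                  age = 0, sex = 0)
  fit <- fit_lmm(d, spec = model_spec(random = "intercept",
                                      covariates = character(0)))
  # one-way ANOVA estimators after removing the common session trend (the
  # session covariate is identical across patients, so the balanced
  # decomposition still applies)
  b <- coef(lm(y_std ~ session, data = d,
               weights = NULL))  # common trend removed within patients
  r <- d$y_std - b[1] - b[2] * d$session
  ybar <- tapply(r, d$patient_id, mean)
  ssw <- sum((r - ybar[d$patient_id])^2)
  sigma2_hat <- ssw / (n * (m - 1) - 1)      # 1 within df for the slope
  msb <- m * sum((ybar - mean(ybar))^2) / (n - 1)
  tau2_hat <- (msb - sigma2_hat) / m
  expect_equal(fit$ranef$residual_var, sigma2_hat, tolerance = 1e-4)
  expect_equal(fit$ranef$sd_intercept^2, tau2_hat, tolerance = 1e-3)
})

test_that("fixed effects and variance components are recovered at scale", {
  d <- make_growth_data(n = 600, m = 8, seed = 4)
  fit <- fit_lmm(d, spec = model_spec(random = "intercept_slope"))
  co <- fit$coefficients
  se_s <- co$se[co$term == "session"]
  expect_lt(abs(co$estimate[co$term == "session"] - (-0.15)), 3 * se_s)
  expect_lt(abs(fit$ranef$sd_intercept - 0.9), 0.1)
  expect_lt(abs(fit$ranef$sd_slope - 0.1), 0.04)
  expect_lt(abs(fit$ranef$residual_var - 0.64), 0.06)
  expect_true(fit$converged)
  expect_true(all(co$ci_lo <= co$estimate & co$estimate <= co$ci_hi))
})

test_that("likelihood ratio test arithmetic and edge cases", {
  d <- make_growth_data(n = 80, m = 6, seed = 5)
  m0 <- fit_lmm(d, spec = model_spec(random = "intercept"))
  m1 <- fit_lmm(d, spec = model_spec(random = "intercept_slope"))
  out <- lrt(m0, m1)
  expect_equal(out$df, 2L)
  expect_equal(out$statistic, 2 * (m1$logLik_ML - m0$logLik_ML),
               tolerance = 1e-10)
  # full-model ML likelihood can never fall below the reduced model's
  expect_gte(m1$logLik_ML, m0$logLik_ML - 1e-6)

  # identical models: statistic 0, p 1
  self <- lrt(m0, m0)
  expect_equal(self$statistic, 0)
  expect_equal(self$p, 1)

  # pure arithmetic on synthetic likelihood values
  fake <- function(ll, np) structure(list(logLik_ML = ll, n_obs = 10L,
                                          n_parameters = np),
                                     class = "fit_result")
  expect_equal(lrt(fake(-100, 4), fake(-90, 6))$statistic, 20)
  expect_error(lrt(fake(-90, 6), fake(-100, 4)), "not nested")
})

test_that("LRT null rejection rate is conservative at the boundary", {
  # planted slope SD = 0: the chi2_2 reference over-counts df, so rejections
  # at alpha = 0.05 must not exceed 0.05 + 2 binomial SEs
  # (scaled down: 120 replicates of 100 patients x 5 sessions)
  nrep <- 120
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    d <- make_growth_data(n = 100, m = 5, sd_u1 = 0, rho = 0, seed = 1000 + r)
    m0 <- quiet(fit_lmm(d, spec = model_spec(random = "intercept",
                                             estimation = "ML")))
    m1 <- quiet(fit_lmm(d, spec = model_spec(random = "intercept_slope",
                                             estimation = "ML")))
    rej[r] <- lrt(m0, m1)$p < 0.05
  }
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / nrep))
})

test_that("moderation terms enter correctly and estimates ignore patient order", {
  cfg <- simulation_config(n_patients = 250, vocab_size = 40, k_true = 2,
                           gamma = c(-0.3, 0), seed = 8,
                           entry_effects = list(baseline = c(0, 0, 0),
                                                session = c(0, 0, 0)))
  sim <- simulate_dataset(cfg)
  records <- build_records(sim$sessions, sim$demographics)
  expos <- cbind(sim$truth$entry_counts,
                 sim$truth$occupancy[sim$truth$entry_counts$patient_id, ])
  spec <- model_spec("theta_1", random = "intercept_slope")
  fit <- quiet(fit_lmm(records, expos, spec))
  me <- moderation_effect(fit, "theta_1")
  expect_equal(nrow(me), 1L)
  expect_lt(abs(me$estimate - (-0.3)), 3 * me$se)

  # permuting patients leaves estimates unchanged
  perm <- sample(nrow(expos))
  rec2 <- do.call(rbind, split(records, records$patient_id)[perm])
  fit2 <- quiet(fit_lmm(rec2, expos[perm, ], spec))
  expect_equal(fit$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("the model ladder runs end to end with sane bookkeeping", {
  cfg <- simulation_config(n_patients = 220, vocab_size = 40, k_true = 2,
                           gamma = c(-0.4, 0), seed = 9,
                           entry_effects = list(baseline = c(0, 0, 0),
                                                session = c(0, 0, 0)))
  sim <- simulate_dataset(cfg)
  records <- build_records(sim$sessions, sim$demographics)
  expos <- cbind(sim$truth$entry_counts,
                 sim$truth$occupancy[sim$truth$entry_counts$patient_id, ])
  rep_ <- quiet(run_model_ladder(records, expos, n_topics = 2))
  expect_equal(rep_$base_lrt$df, 2L)
  expect_equal(rep_$base_random, "intercept_slope")
  expect_named(rep_$model4, c("theta_1", "theta_2"))
  expect_equal(nrow(rep_$forest), 4L)  # 2 topics x models 4 and 5
  # the strongly planted topic is flagged, and model 6 fits it
  expect_true("theta_1" %in% rep_$significant_topics)
  expect_false(is.null(rep_$model6))

  dir <- withr::local_tempdir()
  write_ladder_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "model1.csv")))
  expect_true(file.exists(file.path(dir, "forest.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
})
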