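test_that("planted topics are simplex points with the right concentration", {
  # flat limit: huge eta concentrates at the uniform row
  t1 <- generate_topics(4, 1, eta = 1e7, seed = 1)
  expect_equal(as.vector(t1), rep(0.25, 4), tolerance = 1e-2)

  tt <- generate_topics(57, 5, eta = 0.3, seed = 2)
  expect_equal(rowSums(tt), rep(1, 5), tolerance = 1e-12)
  expect_true(all(tt >= 0))

  # reproducibility and parameter validation
  expect_identical(generate_topics(30, 3, 0.1, seed = 9),
                   generate_topics(30, 3, 0.1, seed = 9))
  expect_error(generate_topics(2, 5, 0.1), "vocab_size")
  expect_error(generate_topics(10, 2, 0), "eta")
})

test_that("sparse topics match the closed-form expected Dirichlet entropy", {
  # E[H] for symmetric Dirichlet(eta) on V cells: psi(V eta + 1) - psi(eta + 1)
  V <- 200; eta <- 0.01
  expected <- digamma(V * eta + 1) - digamma(eta + 1)
  h <- replicate(100, {
    p <- generate_topics(V, 1, eta, seed = sample.int(1e6, 1))
    p <- p[p > 0]
    -sum(p * log(p))
  })
  expect_lt(mean(h), 0.5 * log(V))
  expect_equal(mean(h), expected, tolerance = 5 * sd(h) / sqrt(100) / expected)
})

test_that("corpus generation respects entry counts and topic mixtures", {
  set.seed(1)
  # degenerate: nobody writes
  cfg0 <- simulation_config(n_patients = 5, vocab_size = 10, k_true = 2,
                            gamma = c(0, 0),
                            entry_count_dist = list(list(fixed = 0L),
                                                    list(fixed = 0L),
                                                    list(fixed = 0L)))
  out0 <- generate_corpus(cfg0)
  expect_equal(nrow(out0$entries), 0L)
  expect_false(any(out0$truth$has_entries))
  expect_true(all(out0$truth$occupancy == 0))

  # single topic: every entry mixture is exactly (1)
  cfg1 <- benchmark_corpus_config(n_docs = 8, vocab_size = 6, k_true = 1,
                                  tokens_per_doc = 5, seed = 3)
  out1 <- generate_corpus(cfg1)
  expect_true(all(out1$truth$entry_mixtures == 1))
  expect_true(all(out1$truth$occupancy == 1))

  # cohort-scale entry counts match the configured mean within 3 SE
  cfg <- simulation_config(n_patients = 1000, seed = 5)
  out <- generate_corpus(cfg)
  tot <- out$truth$entry_counts$total_entries
  target <- sum(vapply(cfg$entry_count_dist,
                       function(p) (1 - p$pi0) * p$mu, numeric(1)))
  expect_lt(abs(mean(tot) - target), 3 * sd(tot) / sqrt(1000))
})

test_that("zinb calibration reproduces the target moments", {
  pars <- calibrate_zinb(4.7, 5.3, 0.14)
  q <- 1 - pars$pi0
  m <- q * pars$mu
  v <- q * (pars$mu + pars$mu^2 * (1 + 1 / pars$size)) - m^2
  expect_equal(m, 4.7, tolerance = 1e-10)
  expect_equal(sqrt(v), 5.3, tolerance = 1e-10)
  set.seed(2)
  x <- rzinb_fixture(2e5, pars)
  expect_lt(abs(mean(x) - 4.7), 3 * sd(x) / sqrt(2e5))
})

test_that("max-entropy dropout matches its two constraints exactly", {
  p <- calibrate_dropout(7.8, 0.43, 12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(sum(p * 1:12), 7.8, tolerance = 1e-8)
  expect_equal(p[12], 0.43, tolerance = 1e-12)
  expect_error(calibrate_dropout(11.9, 0.01, 12), "infeasible")
})

test_that("noise-free trajectories are an exact line", {
  cfg <- simulation_config(n_patients = 20, vocab_size = 10, k_true = 2,
                           gamma = c(0, 0), sd_u0 = 0, sd_u1 = 0, rho_u = 0,
                           sigma2 = 0,
                           entry_effects = list(baseline = c(0, 0, 0),
                                                session = c(0, 0, 0)),
                           seed = 11)
  corp <- generate_corpus(cfg)
  traj <- generate_trajectories(cfg, corp$truth)
  s <- merge(traj$sessions, traj$demographics, by = "patient_id")
  pred <- cfg$beta0 + cfg$beta_s * s$session + cfg$beta_age * s$age +
    cfg$beta_sex * s$sex
  expect_equal(s$y_std, pred, tolerance = 1e-12)
})

test_that("random-slope dispersion and dropout shape match the planted world", {
  cfg <- simulation_config(n_patients = 10000, vocab_size = 10, k_true = 2,
                           gamma = c(0, 0), seed = 21,
                           entry_count_dist = list(list(fixed = 0L),
                                                   list(fixed = 0L),
                                                   list(fixed = 0L)))
  traj <- generate_trajectories(cfg, generate_corpus(cfg)$truth)
  expect_lt(abs(sd(traj$random_effects$u1) - 0.10) / 0.10, 0.02)

  # completion fraction: ~43% finish all 12 sessions, within 3 SE at n = 1686
  cfg2 <- simulation_config(n_patients = 1686, vocab_size = 10, k_true = 2,
                            gamma = c(0, 0), seed = 22,
                            entry_count_dist = list(list(fixed = 0L),
                                                    list(fixed = 0L),
                                                    list(fixed = 0L)))
  traj2 <- generate_trajectories(cfg2, generate_corpus(cfg2)$truth)
  frac <- mean(traj2$random_effects$n_sessions == 12)
  expect_lt(abs(frac - 0.43), 3 * sqrt(0.43 * 0.57 / 1686))
})

test_that("generation is deterministic and conserves session bookkeeping", {
  cfg <- simulation_config(n_patients = 40, vocab_size = 20, k_true = 3,
                           gamma = rep(0, 3), seed = 31)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$entries, b$entries)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$demographics, b$demographics)

  rows <- table(factor(a$sessions$patient_id,
                       levels = a$random_effects$patient_id))
  expect_equal(as.integer(rows), a$random_effects$n_sessions)
  expect_true(max(a$sessions$session) < cfg$n_sessions)
  expect_true(all(a$sessions$gad7_raw >= 0 & a$sessions$gad7_raw <= 21))

  # occupancy sums to 1 for writers, 0 for non-writers
  occ <- rowSums(a$truth$occupancy)
  expect_equal(unname(occ[a$truth$has_entries]),
               rep(1, sum(a$truth$has_entries)), tolerance = 1e-10)
  expect_true(all(occ[!a$truth$has_entries] == 0))
})

test_that("config validation rejects impossible worlds", {
  expect_error(simulation_config(rho_u = 1.5), "rho_u")
  expect_error(simulation_config(sd_u0 = -1), "variances")
  expect_error(simulation_config(k_true = 3, gamma = c(0, 0)), "gamma")
  expect_error(simulation_config(alpha = 0), "alpha")
})
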