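test_that("patient mean occupancy averages theta and zero-fills non-writers", {
  theta <- rbind(c(0.2, 0.8), c(0.6, 0.4), c(1.0, 0.0))
  doc_map <- data.frame(doc = 1:3, patient_id = c("a", "a", "b"),
                        assignment = c(1L, 2L, 1L))
  occ <- patient_mean_theta(theta, doc_map, patients = c("a", "b", "c"))
  expect_equal(occ$theta_1, c(0.4, 1.0, 0.0))
  expect_equal(occ$theta_2, c(0.6, 0.0, 0.0))
  expect_equal(occ$has_entries, c(TRUE, TRUE, FALSE))

  # single-entry patient: occupancy equals that entry's theta row
  expect_equal(unlist(occ[occ$patient_id == "b", c("theta_1", "theta_2")]),
               c(theta_1 = 1, theta_2 = 0))
})

test_that("entry counts split by assignment and respect dropped documents", {
  doc_map <- data.frame(doc = 1:4, patient_id = c("a", "a", "a", "b"),
                        assignment = c(1L, 1L, 3L, 2L))
  cnt <- entry_counts(doc_map, patients = c("a", "b", "c"))
  expect_equal(cnt$entries1, c(2L, 0L, 0L))
  expect_equal(cnt$entries2, c(0L, 1L, 0L))
  expect_equal(cnt$entries3, c(1L, 0L, 0L))
  expect_equal(cnt$total_entries, cnt$entries1 + cnt$entries2 + cnt$entries3)
})

test_that("standardization anchors at the baseline sample moments", {
  s <- data.frame(patient_id = rep(c("a", "b", "c"), each = 2),
                  session = rep(0:1, 3),
                  gad7_raw = c(9.5, 10, 13.1, 12, 16.7, 14))
  # baseline sample: 9.5, 13.1, 16.7 -> mean 13.1, SD 3.6
  out <- standardize_gad7(s)
  expect_equal(out$y_std[out$gad7_raw == 13.1 & out$session == 0], 0)
  expect_equal(out$y_std[out$gad7_raw == 16.7 & out$session == 0], 1)
  # round trip
  expect_equal(out$y_std * attr(out, "baseline_sd") +
                 attr(out, "baseline_mean"), out$gad7_raw, tolerance = 1e-10)

  # degenerate baseline
  s2 <- s; s2$gad7_raw[s2$session == 0] <- 10
  expect_error(standardize_gad7(s2), "baseline SD")

  # missing baseline: patient excluded, logged
  s3 <- s[-(1:2), ]
  s3 <- rbind(s3, data.frame(patient_id = "d", session = 1L, gad7_raw = 15))
  out3 <- quiet(standardize_gad7(s3))
  expect_false("d" %in% out3$patient_id)
})

test_that("inclusion rules drop low baselines and missing demographics", {
  s <- data.frame(patient_id = paste0("p", 1:3), session = 0L,
                  gad7_raw = c(7, 8, 9))
  d <- data.frame(patient_id = paste0("p", 1:3), age = c(30, 40, 50),
                  sex = c(0L, 1L, 0L))
  inc <- quiet(apply_inclusion(s, d))
  expect_equal(sort(unique(inc$sessions$patient_id)), c("p2", "p3"))

  d2 <- d; d2$age[2] <- NA
  inc2 <- quiet(apply_inclusion(s, d2))
  expect_equal(unique(inc2$sessions$patient_id), "p3")

  # toy cohort of 10: 3 low baselines + 1 missing sex -> 6 survive
  s10 <- data.frame(patient_id = paste0("q", 1:10), session = 0L,
                    gad7_raw = c(5, 6, 7, rep(12, 7)))
  d10 <- data.frame(patient_id = paste0("q", 1:10),
                    age = 30, sex = c(rep(0L, 9), NA))
  inc10 <- quiet(apply_inclusion(s10, d10))
  expect_equal(nrow(inc10$demographics), 6L)
  expect_equal(unname(inc10$exclusions["low_baseline"]), 3L)
  expect_equal(unname(inc10$exclusions["missing_demographics"]), 1L)
})

test_that("zero-entry patients stay in the cohort with zero occupancy", {
  cfg <- simulation_config(n_patients = 120, vocab_size = 30, k_true = 2,
                           gamma = c(0, 0), seed = 55)
  sim <- simulate_dataset(cfg)
  dtm <- quiet(build_dtm(sim$entries))
  fit <- fit_lda(dtm, lda_config(2, n_iter = 60, burnin = 20, seed = 1))
  cohort <- sim$demographics$patient_id
  expos <- build_exposures(fit, dtm, patients = cohort)
  expect_equal(nrow(expos), length(cohort))   # nobody lost
  zero <- expos$total_entries == 0
  expect_true(any(zero))
  expect_true(all(abs(expos[zero, c("theta_1", "theta_2")]) == 0))
  expect_equal(unname(rowSums(expos[!zero, c("theta_1", "theta_2")])),
               rep(1, sum(!zero)), tolerance = 1e-10)
})

test_that("descriptives reproduce the cohort structure", {
  cfg <- simulation_config(n_patients = 400, vocab_size = 30, k_true = 2,
                           gamma = c(0, 0), seed = 66)
  sim <- simulate_dataset(cfg)
  expos <- cbind(sim$truth$entry_counts)
  tab <- descriptives(sim$sessions, sim$demographics, expos)
  expect_equal(tab$overall[tab$statistic == "n"], "400")

  # zero-entry stratum reports exactly zero entries
  expect_match(tab$zero_entries[tab$statistic == "entries_total_mean_sd"],
               "^0\\.0")
  # configured entry mean within 3 SE in the overall column
  m <- as.numeric(sub(" .*", "", tab$overall[tab$statistic ==
                                               "entries_total_mean_sd"]))
  tot <- expos$total_entries
  target <- sum(vapply(cfg$entry_count_dist,
                       function(p) (1 - p$pi0) * p$mu, numeric(1)))
  expect_lt(abs(m - target), 3 * sd(tot) / sqrt(length(tot)) + 0.05)

  # single-patient cohort flags undefined SDs instead of failing
  one <- descriptives(sim$sessions[sim$sessions$patient_id == "P00001", ],
                      sim$demographics[1, ], expos[1, ])
  expect_match(one$overall[one$statistic == "age_mean_sd"], "0 rows for SD")
  expect_error(descriptives(sim$sessions, sim$demographics[0, ], expos),
               "empty cohort")
})
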