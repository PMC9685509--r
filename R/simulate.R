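# Synthetic-data module: diary corpora from a planted LDA generative process
# and GAD-7 trajectories from a planted mixed-effects growth model with
# topic-by-session moderation. Defaults emulate the cohort this pipeline was
# designed for: ~1686 iCBT patients, 12 weekly sessions with dropout, sparse
# per-patient diary writing under three task assignments.

#' Moment-match a zero-inflated negative binomial to a mean/SD pair
#'
#' The cohort tables report only the mean and SD of per-assignment entry
#' counts; given a chosen structural-zero probability `pi0` this solves for
#' the negative-binomial mean and size so the ZINB matches both moments.
#'
#' @param mean,sd target mean and standard deviation of the count
#' @param pi0 structural zero probability in `[0, 1)`
#' @return list with `pi0`, `mu`, `size`
#' @export
calibrate_zinb <- function(mean, sd, pi0) {
  if (pi0 < 0 || pi0 >= 1) stop_param("pi0 must be in [0,1)")
  if (mean <= 0 || sd <= 0) stop_param("mean and sd must be positive")
  q <- 1 - pi0
  mu <- mean / q
  inv_size <- (sd^2 + mean^2 - q * mu - q * mu^2) / (q * mu^2)
  if (inv_size <= 0) {
    # target is at or below the zero-inflated-Poisson variance: use the
    # Poisson limit rather than failing
    return(list(pi0 = pi0, mu = mu, size = Inf))
  }
  list(pi0 = pi0, mu = mu, size = 1 / inv_size)
}

# ZINB draw; a list(fixed = c) short-circuits to a constant count, used by
# benchmark corpora that need an exact number of documents per patient
rzinb <- function(n, pars) {
  if (!is.null(pars$fixed)) return(rep(as.integer(pars$fixed), n))
  z <- runif(n) < pars$pi0
  x <- if (is.infinite(pars$size)) rpois(n, pars$mu) else
    rnbinom(n, mu = pars$mu, size = pars$size)
  x[z] <- 0L
  as.integer(x)
}

#' Maximum-entropy dropout distribution over completed sessions
#'
#' Finds the categorical distribution on `1..n_sessions` with maximum entropy
#' subject to a given mean number of completed sessions and a given
#' probability of completing all sessions. The solution has the exponential
#' form `p_s` proportional to `exp(lambda * s)` on the non-complete cells with
#' the complete cell pinned, so only a one-dimensional root find is needed.
#'
#' @param mean_sessions target mean of completed sessions
#' @param p_complete target probability of completing all `n_sessions`
#' @param n_sessions number of treatment sessions (default 12)
#' @return numeric probability vector of length `n_sessions` (support 1..n)
#' @export
calibrate_dropout <- function(mean_sessions = 7.8, p_complete = 0.43,
                              n_sessions = 12L) {
  if (p_complete <= 0 || p_complete >= 1) stop_param("p_complete must be in (0,1)")
  s <- seq_len(n_sessions - 1L)
  target <- (mean_sessions - p_complete * n_sessions) / (1 - p_complete)
  if (target <= 1 || target >= n_sessions - 1L)
    stop_param("constraints infeasible: conditional mean %.2f outside support", target)
  cond_mean <- function(lam) {
    w <- exp(lam * s)
    sum(s * w) / sum(w)
  }
  lam <- uniroot(function(l) cond_mean(l) - target, c(-5, 5), tol = 1e-12)$root
  w <- exp(lam * s)
  p <- c((1 - p_complete) * w / sum(w), p_complete)
  p / sum(p)
}

#' Simulation configuration for the synthetic cohort
#'
#' Bundles every knob of the generative world: the LDA corpus side (topics,
#' vocabulary, entry and token counts) and the longitudinal side (growth-model
#' fixed effects, random-effect covariance, residual noise, dropout). The
#' defaults describe the reference cohort: 1686 patients, 12 sessions,
#' baseline GAD-7 13.1 (SD 3.6), mean per-session decline -0.147 SD with
#' random-slope SD 0.10, random-intercept SD 0.90, intercept-slope correlation
#' -0.15, residual variance 0.64, and per-assignment entry counts with means
#' (SDs) 4.7 (5.3), 1.6 (4.2), 0.7 (1.6).
#'
#' @param n_patients number of patients
#' @param n_sessions number of treatment sessions (session index runs 0..S-1)
#' @param vocab_size synthetic vocabulary size
#' @param k_true number of planted topics
#' @param alpha symmetric Dirichlet concentration of per-entry topic mixtures
#' @param eta symmetric Dirichlet concentration of topic-word distributions
#' @param entry_count_dist list of 3 ZINB parameter lists (one per assignment),
#'   see [calibrate_zinb()]
#' @param tokens_per_entry_dist list with `lambda`: tokens per entry are
#'   drawn Poisson(`lambda`) truncated to be at least 1
#' @param dropout_dist probability vector over 1..n_sessions completed sessions
#' @param beta0 fixed intercept on the standardized scale
#' @param beta_s fixed per-session slope (SD/session)
#' @param gamma numeric vector, length `k_true`: topic-by-session moderation
#'   coefficients (SD/session per unit topic occupancy)
#' @param entry_effects list with `baseline` and `session`, each length 3:
#'   fixed effects of the per-assignment entry counts on level and slope
#' @param beta_age,beta_sex covariate fixed effects (age in years; sex coded
#'   female = 0, male = 1)
#' @param sd_u0,sd_u1,rho_u random intercept SD, random slope SD, correlation
#' @param sigma2 residual variance
#' @param gad7_baseline_mean,gad7_baseline_sd raw-scale anchors used to map
#'   the standardized outcome back to the GAD-7 0-21 scale
#' @param age_mean,age_sd,age_min truncated-normal age model
#' @param p_male probability of sex = 1
#' @param seed master seed for all stages
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_patients = 1686L,
                              n_sessions = 12L,
                              vocab_size = 200L,
                              k_true = 7L,
                              alpha = 0.1,
                              eta = 0.05,
                              entry_count_dist = list(
                                calibrate_zinb(4.7, 5.3, 0.14),
                                calibrate_zinb(1.6, 4.2, 0.50),
                                calibrate_zinb(0.7, 1.6, 0.40)),
                              tokens_per_entry_dist = list(lambda = 50),
                              dropout_dist = calibrate_dropout(7.8, 0.43, n_sessions),
                              beta0 = -0.087,
                              beta_s = -0.147,
                              gamma = rep(0, k_true),
                              entry_effects = list(
                                baseline = c(0.014, -0.003, -0.031),
                                session = c(-0.001, 0.002, 0.005)),
                              beta_age = -0.009,
                              beta_sex = 0.086,
                              sd_u0 = 0.90,
                              sd_u1 = 0.10,
                              rho_u = -0.15,
                              sigma2 = 0.64,
                              gad7_baseline_mean = 13.1,
                              gad7_baseline_sd = 3.6,
                              age_mean = 33.2, age_sd = 12, age_min = 16,
                              p_male = 0.22,
                              seed = 1L) {
  # coerce vector fields that may arrive as YAML/JSON lists
  gamma <- as.numeric(unlist(gamma))
  dropout_dist <- as.numeric(unlist(dropout_dist))
  entry_effects <- list(baseline = as.numeric(unlist(entry_effects$baseline)),
                        session = as.numeric(unlist(entry_effects$session)))
  cfg <- list(n_patients = as.integer(n_patients),
              n_sessions = as.integer(n_sessions),
              vocab_size = as.integer(vocab_size),
              k_true = as.integer(k_true),
              alpha = alpha, eta = eta,
              entry_count_dist = entry_count_dist,
              tokens_per_entry_dist = tokens_per_entry_dist,
              dropout_dist = dropout_dist,
              beta0 = beta0, beta_s = beta_s, gamma = gamma,
              entry_effects = entry_effects,
              beta_age = beta_age, beta_sex = beta_sex,
              sd_u0 = sd_u0, sd_u1 = sd_u1, rho_u = rho_u, sigma2 = sigma2,
              gad7_baseline_mean = gad7_baseline_mean,
              gad7_baseline_sd = gad7_baseline_sd,
              age_mean = age_mean, age_sd = age_sd, age_min = age_min,
              p_male = p_male, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (k_true < 1L) stop_param("k_true must be >= 1")
    if (vocab_size < k_true) stop_param("vocab_size must be >= k_true")
    if (alpha <= 0 || eta <= 0) stop_param("alpha and eta must be > 0")
    if (sd_u0 < 0 || sd_u1 < 0 || sigma2 < 0) stop_param("variances must be >= 0")
    if (abs(rho_u) > 1) stop_param("|rho_u| must be <= 1")
    if (length(gamma) != k_true) stop_param("gamma must have length k_true")
    if (length(entry_count_dist) != 3L) stop_param("need 3 entry-count distributions")
    if (length(dropout_dist) != n_sessions || any(dropout_dist < 0) ||
        abs(sum(dropout_dist) - 1) > 1e-8)
      stop_param("dropout_dist must be a probability vector over 1..n_sessions")
    if (length(entry_effects$baseline) != 3L || length(entry_effects$session) != 3L)
      stop_param("entry_effects must have baseline and session of length 3")
  })
  invisible(cfg)
}

#' Draw planted topic-word distributions
#'
#' Each of the `k_true` topics is an independent draw from a symmetric
#' Dirichlet(`eta`) on the `vocab_size`-simplex; small `eta` gives sparse,
#' well-separated topics.
#'
#' @param vocab_size vocabulary size V
#' @param k_true number of topics
#' @param eta symmetric Dirichlet concentration (> 0)
#' @param seed integer seed
#' @return `k_true` x `vocab_size` row-stochastic matrix
#' @export
generate_topics <- function(vocab_size, k_true, eta, seed = 1L) {
  if (k_true < 1L || vocab_size < k_true) stop_param("need vocab_size >= k_true >= 1")
  if (eta <= 0) stop_param("eta must be > 0")
  set.seed(derive_seed(seed, 11L))
  g <- matrix(rgamma(k_true * vocab_size, shape = eta, rate = 1),
              nrow = k_true)
  # guard against all-zero rows at extreme sparsity
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, sample.int(vocab_size, sum(zero))] <- 1
  g / rowSums(g)
}

# letters-only synthetic words (digits would be stripped by the tokenizer);
# base-26 encoding is monotonic, so the DTM's sorted vocabulary preserves the
# original word-index order
synthetic_vocab <- function(v) {
  i <- seq_len(v) - 1L
  paste0("w", letters[i %/% 676L + 1L], letters[(i %/% 26L) %% 26L + 1L],
         letters[i %% 26L + 1L])
}
patient_ids <- function(n) sprintf("P%05d", seq_len(n))

#' Generate a synthetic diary corpus with planted topic structure
#'
#' For each patient, per-assignment entry counts are drawn from the
#' configured zero-inflated negative binomials; each entry gets a topic
#' mixture from Dirichlet(`alpha`), a Poisson (truncated at 1) token count,
#' and tokens from the LDA generative process over a synthetic vocabulary
#' (`w0001`, `w0002`, ...). The returned truth object records per-entry
#' mixtures and per-patient mean occupancy, the recovery oracle for every
#' downstream stage.
#'
#' @param config a [simulation_config()]
#' @param topics `k_true` x `vocab_size` topic-word matrix
#'   (default: [generate_topics()] under the config seed)
#' @return list with `entries` (data.frame: patient_id, assignment, text) and
#'   `truth` (topics, per-entry mixtures, per-patient occupancy + entry counts)
#' @export
generate_corpus <- function(config,
                            topics = generate_topics(config$vocab_size,
                                                     config$k_true,
                                                     config$eta,
                                                     config$seed)) {
  validate_simulation_config(config)
  if (!is.matrix(topics) || nrow(topics) != config$k_true ||
      ncol(topics) != config$vocab_size)
    stop_param("topics must be k_true x vocab_size")
  if (config$vocab_size < 1L) stop_param("empty vocabulary")
  set.seed(derive_seed(config$seed, 23L))

  n <- config$n_patients
  K <- config$k_true
  V <- config$vocab_size
  counts <- sapply(config$entry_count_dist, function(p) rzinb(n, p))
  counts <- matrix(as.integer(counts), nrow = n, ncol = 3L)
  total <- rowSums(counts)

  pid <- patient_ids(n)
  occupancy <- matrix(0, nrow = n, ncol = K,
                      dimnames = list(pid, paste0("theta_", seq_len(K))))

  n_entries <- sum(total)
  if (n_entries == 0L) {
    truth <- list(topics = topics, occupancy = occupancy,
                  has_entries = setNames(rep(FALSE, n), pid),
                  entry_counts = data.frame(patient_id = pid,
                                            entries1 = counts[, 1],
                                            entries2 = counts[, 2],
                                            entries3 = counts[, 3],
                                            total_entries = total),
                  entry_mixtures = matrix(numeric(0), ncol = K),
                  config = config)
    return(list(entries = data.frame(patient_id = character(0),
                                     assignment = integer(0),
                                     text = character(0)),
                truth = truth))
  }

  # one row per entry, doc-major order: patient, then assignment 1..3
  ent_pat <- rep(seq_len(n), times = total)
  ent_asg <- unlist(lapply(seq_len(n), function(i)
    rep.int(1:3, counts[i, ])), use.names = FALSE)

  mix <- matrix(rgamma(n_entries * K, shape = config$alpha, rate = 1),
                nrow = n_entries)
  rs <- rowSums(mix)
  deg <- rs == 0
  if (any(deg)) { mix[deg, ] <- 1; rs[deg] <- K }
  mix <- mix / rs

  ntok <- if (!is.null(config$tokens_per_entry_dist$fixed))
    rep(as.integer(config$tokens_per_entry_dist$fixed), n_entries) else
      pmax(1L, rpois(n_entries, config$tokens_per_entry_dist$lambda))
  tok_ent <- rep(seq_len(n_entries), times = ntok)
  N <- length(tok_ent)

  # per-token topic via inverse CDF against each entry's mixture
  cm <- mix %*% upper.tri(diag(K), diag = TRUE)  # row cumsums
  u <- runif(N)
  if (K > 1L) {
    topic <- 1L + as.integer(rowSums(u > cm[tok_ent, -K, drop = FALSE]))
  } else {
    topic <- rep(1L, N)
  }

  word <- integer(N)
  for (k in seq_len(K)) {
    idx <- which(topic == k)
    if (length(idx))
      word[idx] <- sample.int(V, length(idx), replace = TRUE, prob = topics[k, ])
  }

  vocab <- synthetic_vocab(V)
  texts <- vapply(split(vocab[word], tok_ent), paste, character(1),
                  collapse = " ")
  texts <- texts[order(as.integer(names(texts)))]

  occ_num <- rowsum(mix, group = ent_pat)
  occ_rows <- as.integer(rownames(occ_num))
  occupancy[occ_rows, ] <- occ_num / total[occ_rows]

  truth <- list(topics = topics,
                occupancy = occupancy,
                has_entries = setNames(total > 0L, pid),
                entry_counts = data.frame(patient_id = pid,
                                          entries1 = counts[, 1],
                                          entries2 = counts[, 2],
                                          entries3 = counts[, 3],
                                          total_entries = total),
                entry_mixtures = mix,
                config = config)

  list(entries = data.frame(patient_id = pid[ent_pat],
                            assignment = ent_asg,
                            text = unname(texts),
                            stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate GAD-7 trajectories from the planted growth model
#'
#' Draws per-patient random intercepts and slopes from the configured 2x2
#' covariance, a number of completed sessions from the dropout distribution,
#' and for each completed session t = 0..S-1 a standardized outcome
#' \deqn{y_{it} = \beta_0 + (\beta_s + \sum_j \gamma_j x_{ij} + b' e_i) t +
#'   a' e_i + \beta_{age} age_i + \beta_{sex} sex_i + u_{0i} + u_{1i} t +
#'   \epsilon_{it}}
#' where `x_ij` is patient i's true mean occupancy of topic j (0 for
#' non-writers) and `e_i` the three entry counts. The raw GAD-7 channel is
#' emitted both as a continuous unclipped value (`gad7_cont`, for exact
#' recovery) and as a rounded value clipped to 0-21 (`gad7_raw`, realism).
#'
#' @param config a [simulation_config()]
#' @param truth truth object from [generate_corpus()]
#' @return list with `sessions` (patient_id, session, y_std, gad7_cont,
#'   gad7_raw), `demographics` (patient_id, age, sex), and `random_effects`
#' @export
generate_trajectories <- function(config, truth) {
  validate_simulation_config(config)
  n <- config$n_patients
  pid <- patient_ids(n)
  if (!all(pid %in% rownames(truth$occupancy)))
    stop_param("truth does not cover all patients")
  set.seed(derive_seed(config$seed, 37L))

  age <- rnorm(n, config$age_mean, config$age_sd)
  while (any(bad <- age < config$age_min))
    age[bad] <- rnorm(sum(bad), config$age_mean, config$age_sd)
  sex <- rbinom(n, 1L, config$p_male)

  Sigma <- matrix(c(config$sd_u0^2,
                    config$rho_u * config$sd_u0 * config$sd_u1,
                    config$rho_u * config$sd_u0 * config$sd_u1,
                    config$sd_u1^2), 2L)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) stop_param("random-effect covariance is not PSD")
  L <- chol_psd(Sigma)
  U <- matrix(rnorm(2L * n), ncol = 2L) %*% L   # n x 2: u0, u1

  S <- sample.int(config$n_sessions, n, replace = TRUE,
                  prob = config$dropout_dist)

  ec <- truth$entry_counts
  stopifnot(identical(ec$patient_id, pid))
  emat <- as.matrix(ec[, c("entries1", "entries2", "entries3")])
  x <- truth$occupancy[pid, , drop = FALSE]

  slope_i <- config$beta_s + drop(x %*% config$gamma) +
    drop(emat %*% config$entry_effects$session) + U[, 2L]
  level_i <- config$beta0 + drop(emat %*% config$entry_effects$baseline) +
    config$beta_age * age + config$beta_sex * sex + U[, 1L]

  idx <- rep(seq_len(n), times = S)
  t_ <- unlist(lapply(S, function(s) seq.int(0L, s - 1L)), use.names = FALSE)
  y <- level_i[idx] + slope_i[idx] * t_ +
    rnorm(length(t_), 0, sqrt(config$sigma2))
  cont <- config$gad7_baseline_mean + config$gad7_baseline_sd * y
  raw <- as.integer(pmin(21L, pmax(0L, round(cont))))

  list(sessions = data.frame(patient_id = pid[idx], session = t_,
                             y_std = y, gad7_cont = cont, gad7_raw = raw,
                             stringsAsFactors = FALSE),
       demographics = data.frame(patient_id = pid, age = age, sex = sex,
                                 stringsAsFactors = FALSE),
       random_effects = data.frame(patient_id = pid, u0 = U[, 1L],
                                   u1 = U[, 2L], n_sessions = S,
                                   stringsAsFactors = FALSE))
}

# Cholesky factor tolerant of a zero-variance component (returns upper
# triangular L with t(L) %*% L = Sigma)
chol_psd <- function(Sigma) {
  ok <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (!is.null(ok)) return(ok)
  e <- eigen(Sigma, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(v), nrow = length(v)))
}

#' Configuration for a topic-recovery benchmark corpus
#'
#' One document per patient with a fixed token count: the corpus shape used
#' to validate topic-number selection and topic recovery (by default 1000
#' documents of 50 tokens over a 200-word vocabulary with 7 planted topics).
#'
#' @param n_docs number of documents (= patients, one entry each)
#' @param vocab_size,k_true,alpha,eta see [simulation_config()]
#' @param tokens_per_doc fixed token count per document
#' @param seed master seed
#' @return a [simulation_config()]
#' @export
benchmark_corpus_config <- function(n_docs = 1000L, vocab_size = 200L,
                                    k_true = 7L, alpha = 0.1, eta = 0.05,
                                    tokens_per_doc = 50L, seed = 1L) {
  simulation_config(n_patients = n_docs, vocab_size = vocab_size,
                    k_true = k_true, alpha = alpha, eta = eta,
                    entry_count_dist = list(list(fixed = 1L),
                                            list(fixed = 0L),
                                            list(fixed = 0L)),
                    tokens_per_entry_dist = list(fixed = tokens_per_doc),
                    gamma = rep(0, k_true), seed = seed)
}

#' Generate a complete synthetic dataset (corpus + trajectories)
#'
#' @param config a [simulation_config()]
#' @return list with `entries`, `truth`, `sessions`, `demographics`,
#'   `random_effects`
#' @export
simulate_dataset <- function(config) {
  corp <- generate_corpus(config)
  traj <- generate_trajectories(config, corp$truth)
  c(corp, traj)
}

#' Write a simulated dataset to disk
#'
#' Entries go out both as CSV and JSONL, sessions and demographics as CSV,
#' and the planted truth (topics, occupancy, coefficients) as JSON.
#'
#' @param sim result of [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(entries_csv = file.path(dir, "entries.csv"),
             entries_jsonl = file.path(dir, "entries.jsonl"),
             sessions = file.path(dir, "sessions.csv"),
             demographics = file.path(dir, "demographics.csv"),
             truth = file.path(dir, "truth.json"))
  write.csv(sim$entries, paths["entries_csv"], row.names = FALSE)
  con <- file(paths["entries_jsonl"], "w")
  on.exit(close(con))
  if (nrow(sim$entries))
    writeLines(vapply(seq_len(nrow(sim$entries)), function(i)
      jsonlite::toJSON(as.list(sim$entries[i, ]), auto_unbox = TRUE),
      character(1)), con)
  write.csv(sim$sessions, paths["sessions"], row.names = FALSE)
  write.csv(sim$demographics, paths["demographics"], row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(list(topics = tr$topics,
                            occupancy = tr$occupancy,
                            has_entries = tr$has_entries,
                            entry_counts = tr$entry_counts,
                            coefficients = tr$config[c("beta0", "beta_s",
                                                       "gamma", "entry_effects",
                                                       "beta_age", "beta_sex",
                                                       "sd_u0", "sd_u1",
                                                       "rho_u", "sigma2")]),
                       paths["truth"], digits = NA)
  invisible(paths)
}
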