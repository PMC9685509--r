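# Linear mixed-effects growth models for per-session symptom change, with
# correlate-by-session moderation terms. Estimation is delegated to lme4;
# this module owns the model specifications, Wald inference, the likelihood
# ratio test between the random-intercept and random-slope baselines, and
# the model ladder 0-6.

#' Specify a growth model
#'
#' Every model regresses the standardized outcome on the session number, age
#' and sex, with a random intercept per patient (and optionally a correlated
#' random slope). Each correlate enters with a main ("baseline") effect and,
#' when flagged, a correlate-by-session interaction whose coefficient is the
#' treatment moderation effect.
#'
#' @param correlates character vector of exposure column names
#' @param interact logical, recycled along `correlates`: include the
#'   correlate x session interaction (default TRUE)
#' @param random `"intercept_slope"` (unstructured 2x2 covariance) or
#'   `"intercept"`
#' @param estimation `"REML"` (reported estimates) or `"ML"` (for LRTs)
#' @param covariates adjustment covariates (default age and sex; exposed for
#'   degenerate test designs)
#' @return object of class `model_spec`
#' @export
model_spec <- function(correlates = character(),
                       interact = TRUE,
                       random = c("intercept_slope", "intercept"),
                       estimation = c("REML", "ML"),
                       covariates = c("age", "sex")) {
  structure(list(correlates = correlates,
                 interact = rep_len(interact, length(correlates)),
                 random = match.arg(random),
                 estimation = match.arg(estimation),
                 covariates = covariates),
            class = "model_spec")
}

spec_formula <- function(spec) {
  inter <- spec$correlates[spec$interact]
  rhs <- c("session", spec$covariates, spec$correlates,
           if (length(inter)) paste0("session:", inter))
  re <- if (spec$random == "intercept_slope") "(session | patient_id)" else
    "(1 | patient_id)"
  as.formula(paste("y_std ~", paste(c(rhs, re), collapse = " + ")))
}

# fixed-effect + variance-component parameter count, for LRT df
n_parameters <- function(spec) {
  nfix <- 2L + length(spec$covariates) + length(spec$correlates) +
    sum(spec$interact)
  nvar <- if (spec$random == "intercept_slope") 4L else 2L
  nfix + nvar
}

#' Fit a linear mixed-effects growth model
#'
#' Merges records with exposures, builds the formula from the spec and fits
#' it with [lme4::lmer()]. Wald 95% CIs are `estimate +/- 1.96 SE` and
#' p-values are two-sided normal (z), as is conventional for large
#' longitudinal cohorts. When `estimation = "REML"` the model is also
#' refitted by ML so likelihood-ratio tests are always available.
#' Non-convergence and singular fits (e.g. slope variance collapsing to 0)
#' are flagged, never hidden: estimates are returned regardless.
#'
#' @param records longitudinal data.frame (`patient_id`, `session`, `y_std`,
#'   `age`, `sex`)
#' @param exposures per-patient exposure data.frame (ignored if no correlate
#'   needs it)
#' @param spec a [model_spec()]
#' @return object of class `fit_result`
#' @export
fit_lmm <- function(records, exposures = NULL, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  need <- setdiff(spec$correlates, names(records))
  if (length(need)) {
    if (is.null(exposures) || !all(need %in% names(exposures)))
      stop_param("correlates not found in records or exposures: %s",
                 paste(need, collapse = ", "))
    records <- merge(records, exposures[, c("patient_id", need)],
                     by = "patient_id", sort = FALSE)
  }
  if (length(unique(records$patient_id)) < 2L)
    stop_param("need at least 2 patients")

  fm <- spec_formula(spec)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  warn <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fm, data = records, REML = spec$estimation == "REML",
               control = ctrl),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L &&
    fit@optinfo$conv$opt == 0L
  singular <- lme4::isSingular(fit, tol = 1e-4)

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  zc <- 1.96
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      ci_lo = unname(est - zc * se),
                      ci_hi = unname(est + zc * se),
                      p = unname(2 * pnorm(-abs(est / se))),
                      stringsAsFactors = FALSE)

  vc <- lme4::VarCorr(fit)
  sd_int <- attr(vc$patient_id, "stddev")[["(Intercept)"]]
  sd_slope <- if (spec$random == "intercept_slope")
    attr(vc$patient_id, "stddev")[["session"]] else NA_real_
  corr <- if (spec$random == "intercept_slope")
    attr(vc$patient_id, "correlation")["(Intercept)", "session"] else NA_real_
  res_var <- attr(vc, "sc")^2

  ll_reml <- if (spec$estimation == "REML") as.numeric(logLik(fit)) else NA_real_
  ml_fit <- if (spec$estimation == "REML")
    suppressWarnings(lme4::refitML(fit)) else fit
  ll_ml <- as.numeric(logLik(ml_fit))

  structure(list(coefficients = coefs,
                 ranef = list(residual_var = res_var,
                              sd_intercept = unname(sd_int),
                              sd_slope = unname(sd_slope),
                              corr_intercept_slope = unname(corr)),
                 logLik_ML = ll_ml,
                 logLik_REML = ll_reml,
                 n_obs = nrow(records),
                 n_patients = length(unique(records$patient_id)),
                 n_parameters = n_parameters(spec),
                 converged = converged,
                 singular = singular,
                 warnings = warn,
                 spec = spec,
                 formula = fm,
                 fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(deparse(x$formula), "\n")
  print(x$coefficients, digits = 3)
  cat(sprintf("residual var %.3f | intercept SD %.3f | slope SD %s | corr %s\n",
              x$ranef$residual_var, x$ranef$sd_intercept,
              format(x$ranef$sd_slope, digits = 3),
              format(x$ranef$corr_intercept_slope, digits = 3)))
  cat(sprintf("n_obs %d, n_patients %d, converged %s, singular %s\n",
              x$n_obs, x$n_patients, x$converged, x$singular))
  invisible(x)
}

#' Extract a moderation (correlate-by-session) coefficient
#'
#' @param fit a `fit_result`
#' @param correlate exposure name
#' @return one-row data.frame (estimate, se, ci, p)
#' @export
moderation_effect <- function(fit, correlate) {
  co <- fit$coefficients
  hit <- co$term %in% paste0(c("session:", ""), correlate, c("", ":session"))
  if (!any(hit)) stop_param("no interaction term for %s", correlate)
  co[hit, , drop = FALSE]
}

#' Likelihood ratio test between nested growth models
#'
#' Uses the ML log-likelihoods. The reference distribution is the naive
#' chi-squared with df equal to the parameter-count difference (model 0 vs 1:
#' df = 2), with no boundary correction; for variance-component tests this is
#' conservative, which is documented rather than corrected.
#'
#' @param fit_reduced,fit_full `fit_result`s fitted on the same records
#' @return list with `statistic`, `df`, `p`
#' @export
lrt <- function(fit_reduced, fit_full) {
  if (fit_reduced$n_obs != fit_full$n_obs)
    stop_param("models were not fitted on the same data")
  df <- fit_full$n_parameters - fit_reduced$n_parameters
  if (df < 0) stop_param("models are not nested (df = %d)", df)
  stat <- max(0, 2 * (fit_full$logLik_ML - fit_reduced$logLik_ML))
  # df = 0: identical specifications, the test is vacuous
  p <- if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Run the full model ladder
#'
#' Fits, in order: model 0 (random intercept) and model 1 (random intercept +
#' slope), choosing the base random structure by LRT at `alpha_level`;
#' model 2 (total entries); model 3 (the three per-assignment entry counts);
#' model 4 (each topic separately); model 5 (each topic adjusted for the
#' entry counts); and model 6 (all topics whose model-5 moderation CI
#' excludes 0, jointly, still entry-adjusted — skipped with a note when no
#' topic qualifies). Every correlate enters with both a baseline term and a
#' session interaction. Also emits a forest-table of per-topic moderation
#' effects (models 4 and 5), the data behind the usual forest plots.
#'
#' @param records longitudinal records
#' @param exposures exposure table with `theta_1..theta_K`, `total_entries`,
#'   `entries1..3`
#' @param n_topics number of topic columns (default: inferred)
#' @param alpha_level significance level for base selection and topic
#'   carry-forward (default 0.05)
#' @return object of class `ladder_report`
#' @export
run_model_ladder <- function(records, exposures, n_topics = NULL,
                             alpha_level = 0.05) {
  if (is.null(n_topics))
    n_topics <- sum(grepl("^theta_[0-9]+$", names(exposures)))
  if (!all(unique(records$patient_id) %in% exposures$patient_id))
    stop_param("exposures do not cover all patients in records")

  m0 <- fit_lmm(records, exposures, model_spec(random = "intercept"))
  m1 <- fit_lmm(records, exposures, model_spec(random = "intercept_slope"))
  base_lrt <- lrt(m0, m1)
  base_random <- if (base_lrt$p < alpha_level) "intercept_slope" else "intercept"

  fit_base <- function(correlates)
    fit_lmm(records, exposures, model_spec(correlates, random = base_random))

  m2 <- fit_base("total_entries")
  m3 <- fit_base(c("entries1", "entries2", "entries3"))

  topics <- paste0("theta_", seq_len(n_topics))
  m4 <- lapply(topics, fit_base)
  m5 <- lapply(topics, function(tp)
    fit_base(c(tp, "entries1", "entries2", "entries3")))
  names(m4) <- names(m5) <- topics

  forest <- do.call(rbind, lapply(topics, function(tp) {
    rbind(cbind(model = "model4", topic = tp, moderation_effect(m4[[tp]], tp)),
          cbind(model = "model5", topic = tp, moderation_effect(m5[[tp]], tp)))
  }))

  sig5 <- topics[vapply(topics, function(tp) {
    me <- moderation_effect(m5[[tp]], tp)
    me$ci_lo > 0 || me$ci_hi < 0
  }, logical(1))]
  m6 <- NULL
  note <- NULL
  if (length(sig5) >= 1L) {
    m6 <- fit_base(c(sig5, "entries1", "entries2", "entries3"))
  } else {
    note <- "no topic significant in model 5; model 6 skipped"
    log_msg("run_model_ladder: %s", note)
  }

  structure(list(model0 = m0, model1 = m1, base_lrt = base_lrt,
                 base_random = base_random,
                 model2 = m2, model3 = m3, model4 = m4, model5 = m5,
                 model6 = m6, significant_topics = sig5,
                 forest = forest, note = note),
            class = "ladder_report")
}

#' @export
print.ladder_report <- function(x, ...) {
  cat(sprintf("base model: %s (LRT chi2_%d = %.2f, p = %.3g)\n",
              x$base_random, x$base_lrt$df, x$base_lrt$statistic, x$base_lrt$p))
  cat("moderation effects (forest table):\n")
  print(x$forest, digits = 3)
  if (!is.null(x$note)) cat(x$note, "\n")
  invisible(x)
}

#' Write a ladder report to disk
#'
#' One CSV per model (coefficients + random-effect block), the forest table,
#' and a JSON summary.
#'
#' @param report a `ladder_report`
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_ladder_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dump1 <- function(fit, name) {
    co <- fit$coefficients
    re <- data.frame(term = c("residual_variance", "sd_intercept",
                              "sd_slope", "corr_intercept_slope"),
                     estimate = unlist(fit$ranef), se = NA, ci_lo = NA,
                     ci_hi = NA, p = NA)
    write.csv(rbind(co, re), file.path(dir, paste0(name, ".csv")),
              row.names = FALSE)
  }
  dump1(report$model0, "model0"); dump1(report$model1, "model1")
  dump1(report$model2, "model2"); dump1(report$model3, "model3")
  for (tp in names(report$model4)) {
    dump1(report$model4[[tp]], paste0("model4_", tp))
    dump1(report$model5[[tp]], paste0("model5_", tp))
  }
  if (!is.null(report$model6)) dump1(report$model6, "model6")
  write.csv(report$forest, file.path(dir, "forest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(base_random = report$base_random,
         base_lrt = report$base_lrt,
         significant_topics = report$significant_topics,
         note = report$note),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
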