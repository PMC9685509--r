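# Exposure construction: per-patient mean topic occupancy, entry counts per
# task assignment, standardized GAD-7 outcome records, inclusion filtering,
# and cohort descriptives. Patients who wrote nothing are retained in the
# modeling table with zero occupancy — writing activity itself is a
# correlate, so non-writers must stay in the cohort.

#' Per-patient mean topic occupancy
#'
#' The unweighted mean of the document-topic rows (theta) over each patient's
#' entries. Patients listed in `patients` but absent from `doc_map` (no
#' surviving entries) get the zero vector, flagged by `has_entries = FALSE`.
#'
#' @param lda_model an `lda_model` (or a D x K theta matrix)
#' @param doc_map data.frame with `doc` (theta row index) and `patient_id`
#' @param patients character vector of cohort patient ids (default: those in
#'   `doc_map`)
#' @return data.frame: patient_id, theta_1..theta_K, has_entries
#' @export
patient_mean_theta <- function(lda_model, doc_map,
                               patients = unique(doc_map$patient_id)) {
  theta <- if (inherits(lda_model, "lda_model")) lda_model$theta else lda_model
  stopifnot(is.matrix(theta), nrow(theta) >= max(doc_map$doc))
  K <- ncol(theta)
  m <- rowsum(theta[doc_map$doc, , drop = FALSE], group = doc_map$patient_id)
  m <- m / as.vector(table(doc_map$patient_id)[rownames(m)])
  out <- matrix(0, nrow = length(patients), ncol = K,
                dimnames = list(patients, paste0("theta_", seq_len(K))))
  hit <- intersect(patients, rownames(m))
  out[hit, ] <- m[hit, , drop = FALSE]
  data.frame(patient_id = patients, out,
             has_entries = patients %in% rownames(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-patient entry counts by assignment
#'
#' Counts surviving documents (post-preprocessing) per patient overall and
#' under each of the three task assignments. Entries emptied by
#' preprocessing do not count (consistent with the dropped-document policy).
#'
#' @param doc_map data.frame with `patient_id` and `assignment`
#' @param patients cohort patient ids (default: those present)
#' @return data.frame: patient_id, entries1..3, total_entries
#' @export
entry_counts <- function(doc_map, patients = unique(doc_map$patient_id)) {
  tab <- table(factor(doc_map$patient_id, levels = patients),
               factor(doc_map$assignment, levels = 1:3))
  data.frame(patient_id = patients,
             entries1 = as.integer(tab[, 1]),
             entries2 = as.integer(tab[, 2]),
             entries3 = as.integer(tab[, 3]),
             total_entries = as.integer(rowSums(tab)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine occupancy and writing-activity variables
#'
#' @param lda_model fitted `lda_model`
#' @param dtm the `dtm` the model was fitted on (provides `doc_map`)
#' @param patients cohort patient ids
#' @return data.frame with occupancy, entry counts and `has_entries`
#' @export
build_exposures <- function(lda_model, dtm, patients = NULL) {
  if (is.null(patients)) patients <- unique(dtm$doc_map$patient_id)
  occ <- patient_mean_theta(lda_model, dtm$doc_map, patients)
  cnt <- entry_counts(dtm$doc_map, patients)
  merge(occ, cnt, by = "patient_id", sort = FALSE)
}

#' Standardize GAD-7 scores against the baseline distribution
#'
#' z-scores every measurement using the sample mean and SD of the session-0
#' (baseline) scores over the patients present. Patients without a baseline
#' record are excluded (logged). A degenerate baseline (SD = 0) is an error.
#'
#' @param sessions data.frame with `patient_id`, `session` (from 0) and the
#'   score column
#' @param score_col which raw score to standardize (default `"gad7_raw"`;
#'   synthetic data also carries the continuous channel `"gad7_cont"`)
#' @return the input with a `y_std` column added (excluded patients removed);
#'   baseline mean/sd attached as attributes `baseline_mean`, `baseline_sd`
#' @export
standardize_gad7 <- function(sessions, score_col = "gad7_raw") {
  stopifnot(all(c("patient_id", "session", score_col) %in% names(sessions)))
  base <- sessions[sessions$session == 0L, ]
  have <- unique(base$patient_id)
  missing <- setdiff(unique(sessions$patient_id), have)
  if (length(missing)) {
    log_msg("standardize_gad7: excluded %d patients without a baseline record",
            length(missing))
    sessions <- sessions[sessions$patient_id %in% have, , drop = FALSE]
    base <- sessions[sessions$session == 0L, ]
  }
  m <- mean(base[[score_col]])
  s <- sd(base[[score_col]])
  if (!is.finite(s) || s == 0) stop_param("baseline SD is zero; cannot standardize")
  sessions$y_std <- (sessions[[score_col]] - m) / s
  attr(sessions, "baseline_mean") <- m
  attr(sessions, "baseline_sd") <- s
  sessions
}

#' Apply cohort inclusion criteria
#'
#' Drops patients with baseline (session 0) score below `cutoff` and patients
#' with missing age or sex; each exclusion count is logged and returned.
#'
#' @param sessions longitudinal table (`patient_id`, `session`, score column)
#' @param demographics data.frame with `patient_id`, `age`, `sex`
#' @param cutoff minimum baseline score for inclusion (default 8)
#' @param score_col score column used for the baseline criterion
#' @return list with filtered `sessions`, `demographics`, and `exclusions`
#'   (named counts)
#' @export
apply_inclusion <- function(sessions, demographics, cutoff = 8,
                            score_col = "gad7_raw") {
  base <- sessions[sessions$session == 0L, c("patient_id", score_col)]
  low <- base$patient_id[base[[score_col]] < cutoff]
  miss <- demographics$patient_id[is.na(demographics$age) |
                                    is.na(demographics$sex)]
  no_demo <- setdiff(unique(sessions$patient_id), demographics$patient_id)
  drop <- unique(c(low, miss, no_demo))
  excl <- c(low_baseline = length(low), missing_demographics = length(miss) +
              length(no_demo))
  if (length(drop))
    log_msg("apply_inclusion: excluded %d patients (%d baseline < %s, %d missing demographics)",
            length(drop), excl[1], format(cutoff), excl[2])
  list(sessions = sessions[!sessions$patient_id %in% drop, , drop = FALSE],
       demographics = demographics[!demographics$patient_id %in% drop, ,
                                   drop = FALSE],
       exclusions = excl)
}

#' Build the longitudinal modeling records
#'
#' Merges (standardized) session scores with demographics into one record
#' per (patient, session).
#'
#' @param sessions output of [standardize_gad7()] (or any table with `y_std`)
#' @param demographics data.frame with `patient_id`, `age`, `sex`
#' @return data.frame: patient_id, session, y_std, age, sex (plus raw scores
#'   when present)
#' @export
build_records <- function(sessions, demographics) {
  stopifnot("y_std" %in% names(sessions))
  out <- merge(sessions, demographics, by = "patient_id", sort = FALSE)
  if (anyDuplicated(out[, c("patient_id", "session")]))
    stop_param("duplicate (patient, session) records")
  out[order(out$patient_id, out$session), , drop = FALSE]
}

#' Cohort descriptive statistics
#'
#' Emits, for the full modeling cohort and stratified by writing status
#' (any entries vs zero entries): n, % female/male, mean (SD) age, mean (SD)
#' finished sessions, % finishing all sessions, mean (SD) entries overall and
#' per assignment, and mean (SD) baseline score.
#'
#' @param sessions longitudinal table (session from 0, score column present)
#' @param demographics data.frame with `patient_id`, `age`, `sex`
#' @param exposures data.frame from [build_exposures()] (or the entry-count
#'   columns thereof)
#' @param n_sessions total number of treatment sessions (default 12)
#' @param score_col baseline score column (default `"gad7_raw"`)
#' @return data.frame with one row per statistic and columns overall /
#'   writers / zero_entries
#' @export
descriptives <- function(sessions, demographics, exposures,
                         n_sessions = 12L, score_col = "gad7_raw") {
  if (nrow(demographics) == 0L) stop_param("empty cohort")
  fin <- aggregate(session ~ patient_id, sessions, function(s) max(s) + 1L)
  names(fin)[2] <- "finished"
  d <- merge(demographics, fin, by = "patient_id", all.x = TRUE)
  d$finished[is.na(d$finished)] <- 0L
  base <- sessions[sessions$session == 0L, c("patient_id", score_col)]
  names(base)[2] <- "baseline"
  d <- merge(d, base, by = "patient_id", all.x = TRUE)
  d <- merge(d, exposures[, c("patient_id", "entries1", "entries2",
                              "entries3", "total_entries")],
             by = "patient_id", all.x = TRUE)

  strata <- list(overall = d,
                 writers = d[d$total_entries > 0, ],
                 zero_entries = d[d$total_entries == 0, ])
  msd <- function(x) if (length(x) <= 1L)
    sprintf("%.1f (0 rows for SD)", mean(x)) else
      sprintf("%.1f (%.1f)", mean(x), sd(x))
  one <- function(s) {
    if (nrow(s) == 0L) return(rep(NA_character_, 11L))
    c(n = sprintf("%d", nrow(s)),
      female = sprintf("%d (%.0f%%)", sum(s$sex == 0), 100 * mean(s$sex == 0)),
      male = sprintf("%d (%.0f%%)", sum(s$sex == 1), 100 * mean(s$sex == 1)),
      age = msd(s$age),
      finished_sessions = msd(s$finished),
      finished_all = sprintf("%d (%.0f%%)", sum(s$finished == n_sessions),
                             100 * mean(s$finished == n_sessions)),
      entries_total = msd(s$total_entries),
      entries1 = msd(s$entries1),
      entries2 = msd(s$entries2),
      entries3 = msd(s$entries3),
      baseline = msd(s$baseline))
  }
  tab <- vapply(strata, one, character(11L))
  rownames(tab) <- c("n", "female_n_pct", "male_n_pct", "age_mean_sd",
                     "finished_sessions_mean_sd", "finished_all_n_pct",
                     "entries_total_mean_sd", "entries1_mean_sd",
                     "entries2_mean_sd", "entries3_mean_sd",
                     "baseline_gad7_mean_sd")
  data.frame(statistic = rownames(tab), tab, row.names = NULL,
             stringsAsFactors = FALSE)
}
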