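# Pipeline orchestration: simulate-or-ingest -> preprocess -> select-k ->
# fit-lda -> exposures -> model ladder, with a manifest recording seeds,
# input hashes and per-stage artifacts. Stage artifacts are immutable files
# so any stage can be re-run and inspected independently.

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML or JSON file (or an R list) with exactly one
#' of an `input` block (paths to `entries`, `sessions`, `demographics`) or a
#' `simulate` block ([simulation_config()] fields), plus optional
#' `preprocess`, `lda`, `selection`, `ladder` sub-blocks, a `seed`, and an
#' output directory `out`.
#'
#' @param config path to a YAML/JSON file, or a list
#' @return validated config list of class `pipeline_config`
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  }
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim)
    stop_param("config must contain exactly one of 'input' or 'simulate'")
  if (has_input &&
      !all(c("entries", "sessions", "demographics") %in% names(config$input)))
    stop_param("input block needs entries, sessions, demographics paths")
  config$seed <- as.integer(config$seed %||% 1L)
  config$out <- config$out %||% "worrytopics_out"
  structure(config, class = "pipeline_config")
}

#' Run the end-to-end analysis
#'
#' Executes every stage and writes a manifest (`manifest.json`) with package
#' version, seeds, input hashes and per-stage artifact paths. Any stage
#' failure halts with a stage-labeled error.
#'
#' @param config a [pipeline_config()] (or anything it accepts)
#' @return the manifest, invisibly
#' @export
run_all <- function(config) {
  config <- pipeline_config(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "worrytopics",
                   version = as.character(utils::packageVersion("worrytopics")),
                   seed = config$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  stage <- function(name, expr) {
    log_msg("stage %s ...", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      args <- config$simulate
      args$seed <- args$seed %||% config$seed
      cfg <- do.call(simulation_config, args)
      simulate_dataset(cfg)
    })
    paths <- write_simulation(sim, file.path(out, "simulated"))
    entries <- sim$entries
    sessions <- sim$sessions
    demographics <- sim$demographics
    manifest$stages$simulate <- list(artifacts = as.list(paths))
  } else {
    entries <- stage("ingest", read_entries(config$input$entries))
    sessions <- stage("ingest", read.csv(config$input$sessions,
                                         stringsAsFactors = FALSE))
    demographics <- stage("ingest", read.csv(config$input$demographics,
                                             stringsAsFactors = FALSE))
    manifest$stages$ingest <- list(
      inputs = as.list(unlist(config$input)),
      md5 = as.list(tools::md5sum(unlist(config$input))))
  }

  pp <- config$preprocess %||% list()
  pcfg <- preprocess_config(
    stopwords = if (!is.null(pp$stopwords_file))
      readLines(pp$stopwords_file) else pp$stopwords %||% character(),
    stemmer = pp$stemmer %||% "identity",
    keep_language = pp$keep_language,
    min_tokens = pp$min_tokens %||% 1L,
    min_doc_freq = pp$min_doc_freq %||% 1L)
  dtm <- stage("preprocess", build_dtm(entries, pcfg))
  dtm_paths <- write_dtm(dtm, file.path(out, "dtm"))
  manifest$stages$preprocess <- list(
    docs = nrow(dtm$counts), vocab = length(dtm$vocabulary),
    dropped = nrow(dtm$dropped), artifacts = as.list(dtm_paths))

  selcfg <- config$selection %||% list()
  if (isTRUE(selcfg$skip)) {
    k_use <- as.integer(selcfg$k %||% config$lda$k %||% 7L)
    manifest$stages$select_k <- list(skipped = TRUE, k = k_use)
  } else {
    sel <- stage("select_k", select_k(
      dtm,
      grid = as.integer(selcfg$grid %||% c(3L, 5L, 7L, 10L, 15L, 20L, 25L)),
      alpha = selcfg$alpha %||% 0.1, beta = selcfg$beta %||% 0.05,
      sweeps = as.integer(selcfg$sweeps %||% 200L),
      seed = derive_seed(config$seed, 2L)))
    sel_path <- file.path(out, "selection.json")
    jsonlite::write_json(list(grid = sel$grid,
                              log_marginal = sel$log_marginal_estimates,
                              mc_se = sel$mc_se,
                              selected_k = sel$selected_k),
                         sel_path, auto_unbox = TRUE, digits = NA)
    write.csv(data.frame(k = sel$grid,
                         log_marginal = sel$log_marginal_estimates,
                         mc_se = sel$mc_se),
              file.path(out, "selection.csv"), row.names = FALSE)
    k_use <- sel$selected_k
    manifest$stages$select_k <- list(selected_k = k_use,
                                     artifacts = list(json = sel_path))
  }

  ldacfg <- config$lda %||% list()
  model <- stage("fit_lda", fit_lda(dtm, lda_config(
    k = k_use,
    alpha = ldacfg$alpha %||% 0.1, beta = ldacfg$beta %||% 0.05,
    n_iter = as.integer(ldacfg$n_iter %||% 2000L),
    burnin = as.integer(ldacfg$burnin %||% 500L),
    n_chains = as.integer(ldacfg$n_chains %||% 1L),
    seed = derive_seed(config$seed, 3L))))
  lda_paths <- write_lda_model(model, file.path(out, "lda"))
  manifest$stages$fit_lda <- list(k = k_use, artifacts = as.list(lda_paths))

  cohort <- stage("exposures", {
    inc <- apply_inclusion(sessions, demographics,
                           cutoff = config$baseline_cutoff %||% 8)
    std <- if ("y_std" %in% names(inc$sessions)) inc$sessions else
      standardize_gad7(inc$sessions)
    records <- build_records(std, inc$demographics)
    expos <- build_exposures(model, dtm,
                             patients = unique(inc$demographics$patient_id))
    desc <- descriptives(std, inc$demographics, expos,
                         n_sessions = config$n_sessions %||% 12L)
    list(records = records, expos = expos, desc = desc,
         exclusions = inc$exclusions)
  })
  write.csv(cohort$expos, file.path(out, "exposures.csv"), row.names = FALSE)
  write.csv(cohort$records, file.path(out, "longitudinal.csv"),
            row.names = FALSE)
  write.csv(cohort$desc, file.path(out, "descriptives.csv"), row.names = FALSE)
  manifest$stages$exposures <- list(
    n_patients = nrow(cohort$expos),
    exclusions = as.list(cohort$exclusions),
    artifacts = list(exposures = file.path(out, "exposures.csv"),
                     longitudinal = file.path(out, "longitudinal.csv"),
                     descriptives = file.path(out, "descriptives.csv")))

  ladder <- stage("model_ladder",
                  run_model_ladder(cohort$records, cohort$expos,
                                   n_topics = k_use,
                                   alpha_level = config$ladder$alpha_level %||% 0.05))
  write_ladder_report(ladder, file.path(out, "models"))
  manifest$stages$model_ladder <- list(
    base_random = ladder$base_random,
    lrt_statistic = ladder$base_lrt$statistic,
    significant_topics = ladder$significant_topics,
    artifacts = list(dir = file.path(out, "models")))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

read_entries <- function(path) {
  if (grepl("\\.jsonl$", path)) {
    rows <- lapply(readLines(path), jsonlite::fromJSON)
    do.call(rbind, lapply(rows, as.data.frame))
  } else read.csv(path, stringsAsFactors = FALSE)
}

#' Save / load a fitted LDA model as plain text
#'
#' JSON header (config, dimensions) plus TSV matrices for phi and theta.
#'
#' @param model an `lda_model`
#' @param prefix path prefix
#' @return invisibly, the paths written
#' @export
write_lda_model <- function(model, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(header = paste0(prefix, ".json"),
             phi = paste0(prefix, ".phi.tsv"),
             theta = paste0(prefix, ".theta.tsv"))
  jsonlite::write_json(list(k = model$config$k, alpha = model$config$alpha,
                            beta = model$config$beta,
                            n_iter = model$config$n_iter,
                            burnin = model$config$burnin,
                            seed = model$config$seed,
                            estimate_average = model$config$estimate_average,
                            vocabulary = colnames(model$phi)),
                       paths["header"], auto_unbox = TRUE, digits = NA)
  utils::write.table(model$phi, paths["phi"], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$theta, paths["theta"], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(prefix) {
  hd <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  phi <- as.matrix(read.delim(paste0(prefix, ".phi.tsv"), header = FALSE))
  theta <- as.matrix(read.delim(paste0(prefix, ".theta.tsv"), header = FALSE))
  dimnames(phi) <- list(NULL, hd$vocabulary)
  dimnames(theta) <- NULL
  cfg <- lda_config(hd$k, hd$alpha, hd$beta, hd$n_iter, hd$burnin,
                    seed = hd$seed, estimate_average = hd$estimate_average)
  structure(list(phi = phi, theta = theta, z = NULL,
                 log_joint_trace = NULL, config = cfg, chains = NULL),
            class = "lda_model")
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `preprocess`, `select-k`, `fit-lda`, `exposures`,
#' `fit-models`, `run-all`. Invoke via the installed script
#' `system.file("cli", "worrytopics.R", package = "worrytopics")` or
#' `Rscript -e 'worrytopics::worry_cli()' <subcommand> ...`.
#'
#' @param args command-line arguments (default: `commandArgs(TRUE)`)
#' @return exit status, invisibly
#' @export
worry_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: worrytopics <subcommand> [options]",
    "subcommands:",
    "  simulate   --config cfg.yaml --out dir --seed N",
    "  preprocess --entries entries.csv --out prefix [--stopwords file]",
    "  select-k   --dtm prefix --grid 3,5,7 --seed N --out selection.json",
    "  fit-lda    --dtm prefix --k K [--alpha A --beta B --iters I",
    "             --burnin B2 --seed N] --out prefix",
    "  exposures  --dtm prefix --model prefix --sessions s.csv",
    "             --demographics d.csv --out dir",
    "  fit-models --long long.csv --expos expos.csv --out dir",
    "  run-all    --config cfg.yaml", sep = "\n")
  if (length(args) == 0L) { cat(usage, "\n"); return(invisible(1L)) }
  sub <- args[[1L]]
  rest <- args[-1L]
  opt <- function(flags) {
    p <- optparse::OptionParser(option_list = flags, add_help_option = TRUE)
    optparse::parse_args(p, args = rest)
  }
  o <- optparse::make_option

  switch(sub,
    "simulate" = {
      x <- opt(list(o("--config", type = "character", default = NULL),
                    o("--out", type = "character", default = "sim_out"),
                    o("--seed", type = "integer", default = 1L)))
      fields <- if (!is.null(x$config)) pipeline_config_block(x$config) else list()
      fields$seed <- x$seed
      sim <- simulate_dataset(do.call(simulation_config, fields))
      write_simulation(sim, x$out)
    },
    "preprocess" = {
      x <- opt(list(o("--entries", type = "character"),
                    o("--out", type = "character", default = "dtm"),
                    o("--stopwords", type = "character", default = NULL),
                    o("--keep-language", type = "character", default = NULL),
                    o("--min-tokens", type = "integer", default = 1L)))
      cfg <- preprocess_config(
        stopwords = if (!is.null(x$stopwords)) readLines(x$stopwords)
          else character(),
        keep_language = x$`keep-language`, min_tokens = x$`min-tokens`)
      write_dtm(build_dtm(read_entries(x$entries), cfg), x$out)
    },
    "select-k" = {
      x <- opt(list(o("--dtm", type = "character"),
                    o("--grid", type = "character", default = "3,5,7,10,15,20,25"),
                    o("--alpha", type = "double", default = 0.1),
                    o("--beta", type = "double", default = 0.05),
                    o("--sweeps", type = "integer", default = 200L),
                    o("--seed", type = "integer", default = 1L),
                    o("--out", type = "character", default = "selection.json")))
      sel <- select_k(read_dtm(x$dtm),
                      grid = as.integer(strsplit(x$grid, ",")[[1]]),
                      alpha = x$alpha, beta = x$beta, sweeps = x$sweeps,
                      seed = x$seed)
      jsonlite::write_json(list(grid = sel$grid,
                                log_marginal = sel$log_marginal_estimates,
                                mc_se = sel$mc_se,
                                selected_k = sel$selected_k),
                           x$out, auto_unbox = TRUE, digits = NA)
      print(sel)
    },
    "fit-lda" = {
      x <- opt(list(o("--dtm", type = "character"),
                    o("--k", type = "integer"),
                    o("--alpha", type = "double", default = 0.1),
                    o("--beta", type = "double", default = 0.05),
                    o("--iters", type = "integer", default = 2000L),
                    o("--burnin", type = "integer", default = 500L),
                    o("--seed", type = "integer", default = 1L),
                    o("--out", type = "character", default = "lda")))
      model <- fit_lda(read_dtm(x$dtm),
                       lda_config(x$k, x$alpha, x$beta, x$iters, x$burnin,
                                  seed = x$seed))
      write_lda_model(model, x$out)
    },
    "exposures" = {
      x <- opt(list(o("--dtm", type = "character"),
                    o("--model", type = "character"),
                    o("--sessions", type = "character"),
                    o("--demographics", type = "character"),
                    o("--out", type = "character", default = "exposures_out")))
      dtm <- read_dtm(x$dtm)
      model <- read_lda_model(x$model)
      sessions <- read.csv(x$sessions, stringsAsFactors = FALSE)
      demo <- read.csv(x$demographics, stringsAsFactors = FALSE)
      inc <- apply_inclusion(sessions, demo)
      std <- if ("y_std" %in% names(inc$sessions)) inc$sessions else
        standardize_gad7(inc$sessions)
      dir.create(x$out, recursive = TRUE, showWarnings = FALSE)
      expos <- build_exposures(model, dtm,
                               patients = unique(inc$demographics$patient_id))
      write.csv(expos, file.path(x$out, "exposures.csv"), row.names = FALSE)
      write.csv(build_records(std, inc$demographics),
                file.path(x$out, "longitudinal.csv"), row.names = FALSE)
    },
    "fit-models" = {
      x <- opt(list(o("--long", type = "character"),
                    o("--expos", type = "character"),
                    o("--out", type = "character", default = "models")))
      records <- read.csv(x$long, stringsAsFactors = FALSE)
      expos <- read.csv(x$expos, stringsAsFactors = FALSE)
      write_ladder_report(run_model_ladder(records, expos), x$out)
    },
    "run-all" = {
      x <- opt(list(o("--config", type = "character")))
      run_all(x$config)
    },
    { cat(usage, "\n"); return(invisible(1L)) })
  invisible(0L)
}

pipeline_config_block <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
}
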