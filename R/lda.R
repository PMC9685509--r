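# LDA by collapsed Gibbs sampling. theta and phi are integrated out; the
# sampler resamples token-topic assignments z from
#   p(z_i = k | .) propto (n_dk + alpha) (n_kv + beta) / (n_k + V beta)
# and reports smoothed posterior-mean (or last-sample) estimates
#   theta_dk = (n_dk + alpha) / (n_d + K alpha)
#   phi_kv  = (n_kv + beta) / (n_k + V beta).

#' LDA sampler configuration
#'
#' @param k number of topics (>= 1)
#' @param alpha symmetric document-topic Dirichlet concentration
#' @param beta symmetric topic-word Dirichlet concentration
#' @param n_iter total Gibbs sweeps
#' @param burnin sweeps discarded before averaging (`n_iter > burnin >= 0`)
#' @param n_chains independent chains (kept separate: topics are
#'   label-unidentified, so chains are never averaged; chain 1 is the
#'   designated chain used downstream)
#' @param seed integer seed; chain c uses a seed derived from it
#' @param estimate_average `"post-burnin-mean"` (default, lower variance) or
#'   `"last-sample"`
#' @return object of class `lda_config`
#' @export
lda_config <- function(k, alpha = 0.1, beta = 0.05, n_iter = 2000L,
                       burnin = 500L, n_chains = 1L, seed = 1L,
                       estimate_average = c("post-burnin-mean", "last-sample")) {
  if (k < 1L) stop_param("k must be >= 1")
  if (alpha <= 0 || beta <= 0) stop_param("alpha and beta must be > 0")
  if (!(n_iter > burnin && burnin >= 0)) stop_param("need n_iter > burnin >= 0")
  structure(list(k = as.integer(k), alpha = alpha, beta = beta,
                 n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 estimate_average = match.arg(estimate_average)),
            class = "lda_config")
}

#' Expand a document-term matrix into the sampler's token stream
#'
#' Order is doc-major, and within a document tokens appear in increasing
#' vocabulary index, each word repeated by its count. This fixed ordering is
#' part of the sampler's determinism contract and of the meaning of the
#' `assignments` vector in [log_joint()].
#'
#' @param dtm a `dtm` object
#' @return list with 0-based integer vectors `word`, `doc`, and sizes
#' @export
dtm_token_stream <- function(dtm) {
  tr <- Matrix::summary(dtm$counts)
  o <- order(tr$i, tr$j)
  i <- rep.int(tr$i[o], tr$x[o])
  j <- rep.int(tr$j[o], tr$x[o])
  list(word = as.integer(j - 1L), doc = as.integer(i - 1L),
       D = nrow(dtm$counts), V = ncol(dtm$counts), N = length(i))
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' @param dtm a non-empty `dtm` object
#' @param config an [lda_config()]
#' @return object of class `lda_model` with `phi` (K x V, columns named by
#'   vocabulary), `theta` (D x K), `log_joint_trace` (per sweep, chain 1),
#'   final assignments `z`, `config`, and (if `n_chains > 1`) a `chains`
#'   list of the per-chain results
#' @export
fit_lda <- function(dtm, config) {
  stopifnot(inherits(dtm, "dtm"), inherits(config, "lda_config"))
  st <- dtm_token_stream(dtm)
  if (st$N == 0L) stop_param("empty document-term matrix")
  if (config$k > st$N)
    warning("more topics than tokens; model is defined but most topics stay empty")

  run_chain <- function(chain) {
    set.seed(derive_seed(config$seed, 100L + chain))
    res <- .lda_gibbs_cpp(st$word, st$doc, st$D, st$V, config$k,
                          config$alpha, config$beta,
                          config$n_iter, config$burnin, 1.0,
                          integer(0),
                          config$estimate_average == "post-burnin-mean",
                          FALSE, TRUE)
    use_mean <- config$estimate_average == "post-burnin-mean" &&
      !is.null(res$theta_mean)
    phi <- if (use_mean) res$phi_mean else res$phi_last
    theta <- if (use_mean) res$theta_mean else res$theta_last
    colnames(phi) <- dtm$vocabulary
    list(phi = phi, theta = theta, z = res$z + 1L,
         log_joint_trace = res$logjoint_trace)
  }

  chains <- lapply(seq_len(config$n_chains), run_chain)
  main <- chains[[1L]]
  structure(list(phi = main$phi, theta = main$theta, z = main$z,
                 log_joint_trace = main$log_joint_trace,
                 config = config,
                 chains = if (config$n_chains > 1L) chains),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("LDA model: K=%d, V=%d, D=%d (%s estimate)\n",
              nrow(x$phi), ncol(x$phi), nrow(x$theta),
              x$config$estimate_average))
  invisible(x)
}

#' Collapsed log joint probability log p(w, z)
#'
#' With theta and phi integrated out under symmetric Dirichlet priors,
#' \deqn{\log p(w, z) = \sum_d [\log B(n_{d.} + \alpha 1) - \log B(\alpha 1)]
#'   + \sum_k [\log B(n_{k.} + \beta 1) - \log B(\beta 1)]}
#' where B is the multivariate Beta function, `n_d.` the topic counts of
#' document d and `n_k.` the word counts of topic k. `assignments` indexes
#' topics 1..K for each token of the stream defined by [dtm_token_stream()].
#'
#' @param dtm a `dtm` object
#' @param assignments integer vector, one topic per token
#' @param alpha,beta symmetric Dirichlet concentrations
#' @param k number of topics (default `max(assignments)`)
#' @return scalar log probability
#' @export
log_joint <- function(dtm, assignments, alpha, beta, k = max(assignments)) {
  st <- dtm_token_stream(dtm)
  if (length(assignments) != st$N)
    stop_param("assignments must cover every token (need %d, got %d)",
               st$N, length(assignments))
  if (any(assignments < 1L | assignments > k))
    stop_param("assignments out of range 1..k")
  z <- as.integer(assignments)
  D <- st$D; V <- st$V
  ndk <- tabulate((st$doc) * k + z, nbins = D * k)
  nkv <- tabulate((st$word) * k + z, nbins = V * k)
  nk <- tabulate(z, nbins = k)
  nd <- tabulate(st$doc + 1L, nbins = D)
  doc_side <- sum(lgamma(ndk + alpha)) - D * k * lgamma(alpha) +
    D * lgamma(k * alpha) - sum(lgamma(nd + k * alpha))
  word_side <- sum(lgamma(nkv + beta)) - k * V * lgamma(beta) +
    k * lgamma(V * beta) - sum(lgamma(nk + V * beta))
  doc_side + word_side
}
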