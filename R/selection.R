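# Bayesian selection of the number of topics. The marginal likelihood
# p(w | K) is estimated by power-posterior thermodynamic integration:
#   log p(w) = integral_0^1 E_{p_t(z|w)}[ log p(w|z) ] dt,
# where p_t(z|w) propto p(z) p(w|z)^t, sampled by the tempered collapsed
# Gibbs kernel. An exact enumeration oracle over all K^N token assignments
# validates the estimator on tiny corpora.

#' Exact log marginal likelihood by enumeration
#'
#' Computes `log p(w | k)` as a log-sum-exp of the collapsed joint over all
#' `k^N` token assignments. Refuses (with an error, never a silent
#' approximation) when the enumeration exceeds `budget` terms. For `k = 1`
#' the Dirichlet-multinomial closed form is used unless
#' `force_enumeration = TRUE`.
#'
#' @param dtm a `dtm` object
#' @param k number of topics
#' @param alpha,beta symmetric Dirichlet concentrations
#' @param budget maximum number of enumeration terms (default 2^18)
#' @param force_enumeration enumerate even when a closed form exists
#' @return scalar log marginal likelihood
#' @export
exact_log_marginal <- function(dtm, k, alpha, beta, budget = 2^18,
                               force_enumeration = FALSE) {
  st <- dtm_token_stream(dtm)
  N <- st$N
  if (k == 1L && !force_enumeration)
    return(log_marginal_k1(dtm, beta))
  n_terms <- k^N
  if (n_terms > budget)
    stop_param("enumeration budget exceeded: k^N = %.3g > %g (refusing)",
               n_terms, budget)

  D <- st$D; V <- st$V
  lgam_a <- lgamma(0:N + alpha)
  lgam_b <- lgamma(0:N + beta)
  z <- rep(1L, N)
  lp <- numeric(n_terms)
  for (i in seq_len(n_terms)) {
    ndk <- tabulate(st$doc * k + z, nbins = D * k)
    nkv <- tabulate(st$word * k + z, nbins = V * k)
    nk <- tabulate(z, nbins = k)
    lp[i] <- sum(lgam_a[ndk + 1L]) - D * k * lgamma(alpha) +
      sum(lgam_b[nkv + 1L]) - k * V * lgamma(beta) -
      sum(lgamma(nk + V * beta))
    # increment base-k counter over assignments
    j <- 1L
    while (j <= N) {
      if (z[j] < k) { z[j] <- z[j] + 1L; break }
      z[j] <- 1L; j <- j + 1L
    }
  }
  # assignment-independent remainder of log p(w, z)
  const <- D * lgamma(k * alpha) -
    sum(lgamma(tabulate(st$doc + 1L, D) + k * alpha)) +
    k * lgamma(V * beta)
  logsumexp(lp) + const
}

# Dirichlet-multinomial closed form for a single topic: all tokens share one
# topic-word urn; the document side is degenerate.
log_marginal_k1 <- function(dtm, beta) {
  nv <- Matrix::colSums(dtm$counts)
  V <- length(nv)
  N <- sum(nv)
  lgamma(V * beta) - lgamma(N + V * beta) +
    sum(lgamma(nv + beta)) - V * lgamma(beta)
}

#' Power-posterior (thermodynamic integration) estimate of log p(w | k)
#'
#' Runs the tempered collapsed Gibbs sampler along a temperature ladder
#' `0 = t_0 < ... < t_J = 1`, warm-starting each rung from the previous one;
#' the per-rung post-burn-in averages of `log p(w | z)` are combined by
#' trapezoidal quadrature. The Monte-Carlo standard error combines per-rung
#' batch-means variances through the quadrature weights (cross-rung
#' correlation from warm starts is ignored, which is mildly optimistic and
#' stated here rather than hidden).
#'
#' @param dtm a `dtm` object
#' @param k number of topics
#' @param alpha,beta symmetric Dirichlet concentrations
#' @param ladder increasing temperatures from 0 to 1; default 16 rungs
#'   `((0:15)/15)^5`, dense near 0 where the integrand moves fastest
#' @param sweeps Gibbs sweeps per rung (default 200)
#' @param burnin_frac fraction of each rung's sweeps discarded (default 0.2)
#' @param seed integer seed
#' @param n_batches batches for the batch-means variance (default 10)
#' @param direction `"down"` (default) anneals from the posterior end: the
#'   chain is first converged at t = 1 (best of `n_init_chains` short runs by
#'   log joint) and the ladder is walked downward, so the sticky high-t rungs
#'   inherit a converged state; `"up"` walks from the prior end. Both target
#'   the same integral; `"down"` is markedly more reliable on multimodal
#'   posteriors (many topics, large corpora)
#' @param n_init_chains short t = 1 chains raced for the `"down"` start
#' @return list with `estimate`, `mc_se`, and a per-rung `table`
#' @export
estimate_log_marginal <- function(dtm, k, alpha, beta,
                                  ladder = ((0:15) / 15)^5,
                                  sweeps = 200L, burnin_frac = 0.2,
                                  seed = 1L, n_batches = 10L,
                                  direction = c("down", "up"),
                                  n_init_chains = 2L) {
  direction <- match.arg(direction)
  if (length(ladder) < 2L || ladder[1] != 0 || ladder[length(ladder)] != 1 ||
      any(diff(ladder) <= 0))
    stop_param("ladder must increase strictly from 0 to 1")
  if (sweeps < 1L) stop_param("need at least one sweep per rung")
  st <- dtm_token_stream(dtm)
  if (st$N == 0L) stop_param("empty document-term matrix")

  J <- length(ladder)
  set.seed(derive_seed(seed, 1000L + k))
  Ebar <- Vbar <- numeric(J)
  burn <- max(0L, min(sweeps - 1L, as.integer(floor(sweeps * burnin_frac))))

  z <- integer(0)
  rungs <- seq_len(J)
  if (direction == "down") {
    # race short posterior chains, keep the best mode by log p(w | z)
    best <- -Inf
    for (c_ in seq_len(max(1L, n_init_chains))) {
      cand <- .lda_gibbs_cpp(st$word, st$doc, st$D, st$V, k, alpha, beta,
                             as.integer(sweeps), 0L, 1.0, integer(0),
                             FALSE, FALSE, FALSE)
      score <- mean(utils::tail(cand$logpw_trace, 10L))
      if (score > best) { best <- score; z <- cand$z }
    }
    rungs <- rev(rungs)
  }

  for (j in rungs) {
    res <- .lda_gibbs_cpp(st$word, st$doc, st$D, st$V, k, alpha, beta,
                          as.integer(sweeps), 0L, ladder[j], z,
                          FALSE, FALSE, FALSE)
    z <- res$z
    kept <- res$logpw_trace[(burn + 1L):sweeps]
    Ebar[j] <- mean(kept)
    nb <- max(2L, min(n_batches, length(kept)))
    bm <- tapply(kept, cut(seq_along(kept), nb, labels = FALSE), mean)
    Vbar[j] <- var(bm) / nb
  }
  w <- trapezoid_weights(ladder)
  list(estimate = sum(w * Ebar),
       mc_se = sqrt(sum(w^2 * Vbar)),
       table = data.frame(t = ladder, mean_logpw = Ebar,
                          var_mean = Vbar, weight = w))
}

trapezoid_weights <- function(t) {
  J <- length(t)
  w <- numeric(J)
  dt <- diff(t)
  w[1] <- dt[1] / 2
  w[J] <- dt[J - 1] / 2
  if (J > 2) w[2:(J - 1)] <- (dt[-(J - 1)] + dt[-1]) / 2
  w
}

#' Select the number of topics by estimated log marginal likelihood
#'
#' Runs [estimate_log_marginal()] for every candidate `k`; the selected `k`
#' maximizes the estimate, ties broken toward the smaller `k` (parsimony).
#' Per-candidate failures are recorded as warnings and the candidate is
#' excluded; if all fail, an error is raised.
#'
#' @param dtm a `dtm` object
#' @param grid candidate numbers of topics (default spans 3..25)
#' @param alpha,beta symmetric Dirichlet concentrations
#' @param ladder,sweeps,burnin_frac see [estimate_log_marginal()]
#' @param seed integer seed
#' @param coherence_top_m if non-NULL, a short LDA fit per candidate provides
#'   UMass coherence diagnostics with this many top words (adds cost;
#'   default NULL = skip, diagnostics are NA)
#' @return object of class `selection_result`: `grid`,
#'   `log_marginal_estimates`, `mc_se`, `selected_k`, `diagnostics`
#' @export
select_k <- function(dtm, grid = c(3L, 5L, 7L, 10L, 15L, 20L, 25L),
                     alpha = 0.1, beta = 0.05,
                     ladder = ((0:15) / 15)^5, sweeps = 200L,
                     burnin_frac = 0.2, seed = 1L,
                     coherence_top_m = NULL) {
  if (length(grid) == 0L || any(grid < 1L)) stop_param("grid must contain k >= 1")
  est <- se <- rep(NA_real_, length(grid))
  diag_ <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    r <- tryCatch(
      estimate_log_marginal(dtm, grid[i], alpha, beta, ladder, sweeps,
                            burnin_frac, seed = derive_seed(seed, grid[i])),
      error = function(e) {
        warning(sprintf("k = %d failed: %s", grid[i], conditionMessage(e)))
        NULL
      })
    if (!is.null(r)) { est[i] <- r$estimate; se[i] <- r$mc_se }
    if (!is.null(coherence_top_m) && !is.null(r)) {
      fit <- fit_lda(dtm, lda_config(grid[i], alpha, beta, n_iter = 200L,
                                     burnin = 100L,
                                     seed = derive_seed(seed, 50L + grid[i])))
      diag_[i] <- mean(coherence(fit$phi, dtm, coherence_top_m))
    }
  }
  if (all(is.na(est))) stop_param("marginal-likelihood estimation failed for every k")
  ok <- which(!is.na(est))
  sel <- ok[order(-est[ok], grid[ok])][1L]
  structure(list(grid = grid,
                 log_marginal_estimates = est,
                 mc_se = se,
                 selected_k = grid[sel],
                 diagnostics = diag_),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Bayesian topic-number selection\n")
  print(data.frame(k = x$grid, log_marginal = x$log_marginal_estimates,
                   mc_se = x$mc_se, coherence = x$diagnostics))
  cat(sprintf("selected k = %d\n", x$selected_k))
  invisible(x)
}

#' UMass topic coherence
#'
#' For each topic's `top_m` highest-probability words (descending by phi,
#' ties by vocabulary order), the score is
#' `sum_{i=2..m} sum_{j<i} log((D(w_i, w_j) + 1) / D(w_j))`
#' with `D(.)` document (co-)occurrence counts from the DTM. Higher is more
#' coherent. The score is asymmetric in the word ranking by definition.
#'
#' @param phi K x V topic-word matrix (columns in DTM vocabulary order)
#' @param dtm the `dtm` the counts are taken from
#' @param top_m number of top words per topic (>= 2; clipped to V with a
#'   warning if larger)
#' @return numeric vector of per-topic scores
#' @export
coherence <- function(phi, dtm, top_m = 10L) {
  if (top_m < 2L) stop_param("top_m must be >= 2")
  V <- ncol(dtm$counts)
  if (top_m > V) {
    warning("top_m exceeds vocabulary size; clipped")
    top_m <- V
  }
  bin <- dtm$counts > 0
  apply(phi, 1L, function(p) {
    top <- order(-p)[seq_len(top_m)]
    s <- 0
    for (i in 2:top_m) for (j in seq_len(i - 1L)) {
      dj <- sum(bin[, top[j]])
      dij <- sum(bin[, top[i]] & bin[, top[j]])
      s <- s + log((dij + 1) / dj)
    }
    s
  })
}
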