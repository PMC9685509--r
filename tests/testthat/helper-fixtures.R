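# Shared fixtures, built in code at test time.

# dtm with counts [[2,1,0],[0,1,1]] over vocab a,b,c
tiny_entries <- function() {
  data.frame(patient_id = c("p1", "p2"), assignment = c(1L, 2L),
             text = c("a b a", "b c"), stringsAsFactors = FALSE)
}

tiny_dtm <- function() suppressMessages(build_dtm(tiny_entries()))

# 2 docs x 3 tokens each over V = 3: the 6-token enumeration corpus
six_token_dtm <- function() {
  e <- data.frame(patient_id = c("p1", "p2"), assignment = c(1L, 1L),
                  text = c("a a b", "b c c"), stringsAsFactors = FALSE)
  suppressMessages(build_dtm(e))
}

# construct a dtm object directly from a dense count matrix
dtm_from_counts <- function(m, vocab = letters[seq_len(ncol(m))],
                            patient_id = paste0("p", seq_len(nrow(m)))) {
  structure(list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                      "CsparseMatrix"),
                 vocabulary = vocab,
                 doc_map = data.frame(doc = seq_len(nrow(m)),
                                      patient_id = patient_id,
                                      assignment = 1L,
                                      stringsAsFactors = FALSE),
                 dropped = data.frame(patient_id = character(0),
                                      assignment = integer(0))),
            class = "dtm")
}

# independent Dirichlet-multinomial oracle for the collapsed joint:
# log DM(counts | concentration a) for one urn
log_dirmult <- function(counts, a) {
  lgamma(length(counts) * a) - lgamma(sum(counts) + length(counts) * a) +
    sum(lgamma(counts + a)) - length(counts) * lgamma(a)
}

# oracle log p(w, z) built from per-group Dirichlet-multinomials only
oracle_log_joint <- function(dtm, z, alpha, beta, k) {
  st <- dtm_token_stream(dtm)
  doc_side <- sum(vapply(seq_len(st$D), function(d) {
    log_dirmult(tabulate(z[st$doc == d - 1L], k), alpha)
  }, numeric(1)))
  word_side <- sum(vapply(seq_len(k), function(kk) {
    log_dirmult(tabulate(st$word[z == kk] + 1L, st$V), beta)
  }, numeric(1)))
  doc_side + word_side
}

# all k^N token assignments as rows
all_assignments <- function(N, k) {
  as.matrix(rev(expand.grid(rev(replicate(N, seq_len(k), simplify = FALSE)))))
}

# small planted-topic corpus for recovery tests
planted_dtm <- function(n_docs = 400L, vocab_size = 100L, k_true = 3L,
                        tokens = 40L, seed = 1L) {
  cfg <- benchmark_corpus_config(n_docs = n_docs, vocab_size = vocab_size,
                                 k_true = k_true, tokens_per_doc = tokens,
                                 seed = seed)
  corp <- generate_corpus(cfg)
  list(dtm = suppressMessages(build_dtm(corp$entries)), truth = corp$truth)
}

# greedy matching of estimated topic rows to planted rows by cosine
greedy_cosine <- function(phi, topics_obs) {
  k <- nrow(phi)
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sims <- outer(seq_len(k), seq_len(k),
                Vectorize(function(i, j) cs(phi[i, ], topics_obs[j, ])))
  out <- numeric(k)
  for (i in seq_len(k)) {
    best <- which(sims == max(sims), arr.ind = TRUE)[1, ]
    out[i] <- sims[best[1], best[2]]
    sims[best[1], ] <- -Inf
    sims[, best[2]] <- -Inf
  }
  out
}

# restrict a planted topic matrix to the columns that survived in the dtm
observed_topics <- function(truth, dtm) {
  idx <- match(dtm$vocabulary, synthetic_vocab_fixture(ncol(truth$topics)))
  topics <- truth$topics[, idx, drop = FALSE]
  topics / rowSums(topics)
}

synthetic_vocab_fixture <- function(v) {
  i <- seq_len(v) - 1L
  paste0("w", letters[i %/% 676L + 1L], letters[(i %/% 26L) %% 26L + 1L],
         letters[i %% 26L + 1L])
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# independent ZINB draw (oracle for the calibration check)
rzinb_fixture <- function(n, pars) {
  z <- runif(n) < pars$pi0
  x <- rnbinom(n, mu = pars$mu, size = pars$size)
  x[z] <- 0L
  x
}
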