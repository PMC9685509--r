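# Preprocessing: raw diary entries -> sparse document-term matrix.
# Tokens are unicode-letter runs, lowercased; stop words removed; stemming is
# a pluggable transform (identity by default — the synthetic vocabulary needs
# none, and real-language stemmers can be injected).

#' Preprocessing configuration
#'
#' @param stopwords character vector of stop words (compared after
#'   lowercasing, before stemming)
#' @param stemmer either a function `character -> character` applied
#'   elementwise to tokens, or one of the named transforms `"identity"`,
#'   `"truncate5"` (crude prefix stemmer, truncates tokens to 5 characters)
#' @param keep_language if non-NULL, entries whose `language` tag differs are
#'   dropped by [filter_language()]; untagged entries are always kept
#' @param min_tokens documents with fewer surviving tokens are dropped from
#'   the DTM (default 1)
#' @param min_doc_freq vocabulary pruning: words occurring in fewer documents
#'   are removed (default 1 = no pruning)
#' @return object of class `preprocess_config`
#' @export
preprocess_config <- function(stopwords = character(),
                              stemmer = "identity",
                              keep_language = NULL,
                              min_tokens = 1L,
                              min_doc_freq = 1L) {
  if (min_tokens < 1L) stop_param("min_tokens must be >= 1")
  structure(list(stopwords = tolower(stopwords),
                 stemmer = resolve_stemmer(stemmer),
                 stemmer_name = if (is.character(stemmer)) stemmer else "custom",
                 keep_language = keep_language,
                 min_tokens = as.integer(min_tokens),
                 min_doc_freq = as.integer(min_doc_freq)),
            class = "preprocess_config")
}

resolve_stemmer <- function(stemmer) {
  if (is.function(stemmer)) return(stemmer)
  switch(match.arg(stemmer, c("identity", "truncate5")),
         identity = identity,
         truncate5 = function(x) substr(x, 1L, 5L))
}

#' Tokenize and normalize a text
#'
#' Lowercases, splits on any run of non-letter characters (so punctuation and
#' digits vanish), removes stop words, applies the stemmer; token order is
#' preserved. Empty input yields an empty token vector.
#'
#' @param text a character scalar
#' @param config a [preprocess_config()]
#' @return character vector of tokens
#' @export
tokenize_normalize <- function(text, config = preprocess_config()) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^\\p{L}]+", perl = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(config$stopwords))
    toks <- toks[!toks %in% config$stopwords]
  if (length(toks)) toks <- config$stemmer(toks)
  toks
}

#' Drop entries written in other languages
#'
#' Entries carrying a `language` tag different from `keep_language` are
#' removed; entries without a tag (or an NA tag) are kept. The number of
#' dropped entries is reported via `message()`.
#'
#' @param entries data.frame with at least `patient_id`, `assignment`,
#'   `text`, optionally `language`
#' @param keep_language language tag to keep (e.g. `"fi"`)
#' @return the filtered entries data.frame
#' @export
filter_language <- function(entries, keep_language) {
  if (is.null(keep_language) || is.null(entries$language)) return(entries)
  drop <- !is.na(entries$language) & entries$language != keep_language
  if (any(drop))
    log_msg("filter_language: dropped %d of %d entries (language != %s)",
            sum(drop), nrow(entries), keep_language)
  entries[!drop, , drop = FALSE]
}

#' Build a sparse document-term matrix from diary entries
#'
#' One row per entry that retains at least `min_tokens` tokens after
#' preprocessing; dropped entries are logged with their patient identity and
#' returned in the `dropped` slot (downstream they count as "no entry").
#' The vocabulary is the lexicographically sorted union of surviving tokens.
#'
#' @param entries data.frame with `patient_id`, `assignment`, `text`, and
#'   optionally `language`
#' @param config a [preprocess_config()]
#' @return object of class `dtm`: list with `counts` (dgCMatrix, docs x
#'   words), `vocabulary`, `doc_map` (doc, patient_id, assignment), `dropped`
#' @export
build_dtm <- function(entries, config = preprocess_config()) {
  stopifnot(is.data.frame(entries),
            all(c("patient_id", "assignment", "text") %in% names(entries)))
  entries <- filter_language(entries, config$keep_language)
  if (nrow(entries) == 0L) stop_param("empty corpus: no entries to process")

  tok <- lapply(entries$text, tokenize_normalize, config = config)
  nt <- lengths(tok)
  keep <- nt >= config$min_tokens
  dropped <- entries[!keep, c("patient_id", "assignment"), drop = FALSE]
  if (nrow(dropped))
    log_msg("build_dtm: dropped %d empty/short documents after preprocessing",
            nrow(dropped))
  tok <- tok[keep]
  if (length(tok) == 0L) stop_param("empty corpus: all documents dropped")

  vocab <- sort(unique(unlist(tok, use.names = FALSE)), method = "radix")
  di <- rep(seq_along(tok), lengths(tok))
  wi <- match(unlist(tok, use.names = FALSE), vocab)
  counts <- Matrix::sparseMatrix(i = di, j = wi, x = 1,
                                 dims = c(length(tok), length(vocab)))
  counts <- methods::as(counts, "CsparseMatrix")

  if (config$min_doc_freq > 1L) {
    df <- Matrix::colSums(counts > 0)
    keepw <- df >= config$min_doc_freq
    counts <- counts[, keepw, drop = FALSE]
    vocab <- vocab[keepw]
    nz <- Matrix::rowSums(counts) >= config$min_tokens
    if (any(!nz)) {
      dropped <- rbind(dropped,
                       entries[keep, c("patient_id", "assignment")][!nz, ])
      counts <- counts[nz, , drop = FALSE]
      di_keep <- which(keep)[nz]
    } else di_keep <- which(keep)
    if (nrow(counts) == 0L) stop_param("empty corpus: all documents dropped")
  } else di_keep <- which(keep)

  doc_map <- data.frame(doc = seq_len(nrow(counts)),
                        patient_id = entries$patient_id[di_keep],
                        assignment = entries$assignment[di_keep],
                        stringsAsFactors = FALSE)
  structure(list(counts = counts, vocabulary = vocab, doc_map = doc_map,
                 dropped = dropped),
            class = "dtm")
}

#' @export
print.dtm <- function(x, ...) {
  cat(sprintf("document-term matrix: %d docs x %d words, %d tokens\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Write / read a document-term matrix
#'
#' Serialized as Matrix Market (`<prefix>.mtx`) plus a vocabulary text file
#' (`<prefix>.vocab.txt`, one word per line) and a doc-map CSV
#' (`<prefix>.docmap.csv`).
#'
#' @param dtm a `dtm` object
#' @param prefix path prefix (directories created as needed)
#' @return `write_dtm`: invisibly, the paths; `read_dtm`: a `dtm` object
#' @export
write_dtm <- function(dtm, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(mtx = paste0(prefix, ".mtx"),
             vocab = paste0(prefix, ".vocab.txt"),
             docmap = paste0(prefix, ".docmap.csv"))
  Matrix::writeMM(dtm$counts, paths["mtx"])
  writeLines(dtm$vocabulary, paths["vocab"])
  write.csv(dtm$doc_map, paths["docmap"], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_dtm
#' @export
read_dtm <- function(prefix) {
  counts <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  vocab <- readLines(paste0(prefix, ".vocab.txt"))
  doc_map <- read.csv(paste0(prefix, ".docmap.csv"), stringsAsFactors = FALSE)
  structure(list(counts = counts, vocabulary = vocab, doc_map = doc_map,
                 dropped = doc_map[0, c("patient_id", "assignment")]),
            class = "dtm")
}
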