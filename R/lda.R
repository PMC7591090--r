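# Synthetic text: a Latent Dirichlet Allocation corpus with known ground
# truth, standing in for a natural-language training set so the text analyses
# run with controlled statistics and no downloads.

#' Parameters of the synthetic LDA corpus
#'
#' Defaults reproduce the reference corpus: a 1000-word artificial
#' vocabulary, 10 topics, concentration 0.1 on both the document-topic and
#' topic-word Dirichlets, and 20000 documents. Documents are fixed-length
#' bags of 40 tokens (matching the 40-word excerpts used for natural text).
#'
#' @param vocab_size,n_topics Positive integers.
#' @param doc_topic_concentration,topic_word_concentration Positive Dirichlet
#'   concentration parameters (symmetric).
#' @param n_docs,doc_length Positive integers.
#' @param seed Integer seed.
#' @return An object of class `lda_params`.
#' @export
lda_params <- function(vocab_size = 1000L, n_topics = 10L,
                       doc_topic_concentration = 0.1,
                       topic_word_concentration = 0.1,
                       n_docs = 20000L, doc_length = 40L, seed = 1L) {
  stopifnot(vocab_size >= 1, n_topics >= 1, doc_topic_concentration > 0,
            topic_word_concentration > 0, n_docs >= 1, doc_length >= 1)
  structure(list(vocab_size = as.integer(vocab_size),
                 n_topics = as.integer(n_topics),
                 doc_topic_concentration = as.numeric(doc_topic_concentration),
                 topic_word_concentration = as.numeric(topic_word_concentration),
                 n_docs = as.integer(n_docs),
                 doc_length = as.integer(doc_length),
                 seed = as.integer(seed)),
            class = "lda_params")
}

# Rows iid Dirichlet(alpha) via normalised gammas.
rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  s <- rowSums(x)
  bad <- s == 0  # all-components underflow at tiny alpha; fall back to uniform
  if (any(bad)) {
    x[bad, ] <- 1
    s[bad] <- k
  }
  x / s
}

#' Generate a synthetic LDA corpus
#'
#' Samples topic-word distributions `phi_k ~ Dirichlet(topic_word)`, one
#' document-topic mixture `theta_d ~ Dirichlet(doc_topic)` per document, and
#' `doc_length` tokens per document iid from the mixture
#' `sum_k theta_k phi_k`. The planted ground truth is returned for
#' parameter-recovery tests.
#'
#' @param params An [lda_params()].
#' @return A list of class `lda_corpus` with `counts` (an
#'   `n_docs x vocab_size` integer bag-of-words matrix), `vocab` (a
#'   [new_vocabulary()] with corpus occurrence counts), `true_topics`
#'   (`n_topics x vocab_size` matrix of phi), `true_doc_topics`
#'   (`n_docs x n_topics` matrix of theta) and `params`.
#' @export
generate_lda_corpus <- function(params = lda_params()) {
  stopifnot(inherits(params, "lda_params"))
  V <- params$vocab_size
  K <- params$n_topics
  n <- params$n_docs
  L <- params$doc_length
  with_seed(params$seed, {
    phi <- rdirichlet_rows(K, rep(params$topic_word_concentration, V))
    theta <- rdirichlet_rows(n, rep(params$doc_topic_concentration, K))
    P <- theta %*% phi
    counts <- matrix(0L, n, V)
    for (i in seq_len(n))
      counts[i, ] <- as.integer(stats::rmultinom(1L, L, P[i, ]))
  })
  words <- sprintf("w%04d", seq_len(V))
  vocab <- new_vocabulary(words, colSums(counts))
  structure(list(counts = counts, vocab = vocab, true_topics = phi,
                 true_doc_topics = theta, params = params),
            class = "lda_corpus")
}

#' Expand bag-of-words counts to token lists
#'
#' The inverse of bag-of-words counting: each count vector becomes a token
#' multiset (tokens emitted in vocabulary order). Round-trips with
#' [bow_vectorize()].
#'
#' @param corpus An `lda_corpus`, or a count matrix / single count vector.
#' @param vocab A [new_vocabulary()] or character vector of words; defaults
#'   to the corpus's own vocabulary.
#' @return A list of character vectors, one per document.
#' @export
corpus_to_documents <- function(corpus, vocab = NULL) {
  if (inherits(corpus, "lda_corpus")) {
    if (is.null(vocab)) vocab <- corpus$vocab
    corpus <- corpus$counts
  }
  if (is.null(vocab)) stop("a vocabulary is required")
  words <- if (inherits(vocab, "vocabulary")) vocab$words else as.character(vocab)
  if (is.null(dim(corpus))) corpus <- matrix(corpus, nrow = 1L)
  if (ncol(corpus) > length(words))
    stop("count vectors are longer than the vocabulary")
  lapply(seq_len(nrow(corpus)), function(i)
    rep(words[seq_len(ncol(corpus))], corpus[i, ]))
}

#' Corpus and vocabulary file formats
#'
#' A corpus is written as JSONL — one JSON array of tokens per line — and a
#' vocabulary as plain text with one `word<TAB>count` per line.
#'
#' @param corpus An `lda_corpus` or count matrix.
#' @param vocab Vocabulary (defaults to the corpus's own).
#' @param path File path.
#' @return The written path (invisibly), or the parsed object for readers.
#' @export
write_corpus_jsonl <- function(corpus, path, vocab = NULL) {
  docs <- corpus_to_documents(corpus, vocab)
  con <- file(path, "w")
  on.exit(close(con))
  for (d in docs)
    writeLines(jsonlite::toJSON(d), con)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines, function(l) as.character(jsonlite::fromJSON(l)))
}

#' @rdname write_corpus_jsonl
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "vocabulary"))
  writeLines(sprintf("%s\t%d", vocab$words, as.integer(vocab$counts)), path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_vocabulary <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("word", "count"),
                           colClasses = c("character", "integer"))
  new_vocabulary(tab$word, tab$count)
}
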