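# Bag-of-words text domain: the word-generation likelihood, DRM word lists,
# distinct-word constrained reconstruction and recall-frequency read-outs.

#' Vocabulary with corpus occurrence counts
#'
#' @param words Character vector of unique words; indices are their dense
#'   0-based positions in count vectors.
#' @param counts Nonnegative corpus occurrence counts (training-set
#'   frequencies), used by the DRM list filters.
#' @return An object of class `vocabulary`.
#' @export
new_vocabulary <- function(words, counts = rep(0L, length(words))) {
  words <- as.character(words)
  if (anyDuplicated(words)) stop("vocabulary words must be unique")
  counts <- as.numeric(counts)
  if (length(counts) != length(words) || any(counts < 0))
    stop("counts must be nonnegative, one per word")
  structure(list(words = words, counts = counts,
                 index = stats::setNames(seq_along(words), words)),
            class = "vocabulary")
}

#' Bag-of-words count vector of a token list
#'
#' Out-of-vocabulary tokens are dropped; their number is attached as the
#' `n_oov` attribute.
#'
#' @param tokens Character vector of tokens.
#' @param vocab A [new_vocabulary()].
#' @return A numeric count vector of length `|V|` with attribute `n_oov`.
#' @export
bow_vectorize <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  idx <- vocab$index[as.character(tokens)]
  n_oov <- sum(is.na(idx))
  counts <- tabulate(idx[!is.na(idx)], nbins = length(vocab$words))
  structure(as.numeric(counts), n_oov = n_oov)
}

#' Word-generation parameters of a text model
#'
#' The text decoder generates tokens through a linear map and a softmax:
#' `e_i = exp(-z' R x_i + b_i)`, `p(x_i | z) = e_i / sum_j e_j`, where the
#' columns of `R` act as a semantic word embedding (the negative sign is the
#' printed convention; it is equivalent to the unsigned form under
#' `R -> -R`). Here `z` is the activation vector feeding the final linear
#' layer of the decoder (the latent code itself when the decoder has no
#' hidden layers).
#'
#' `word_gen_params` extracts `(R, b)` from a trained bag-of-words model.
#'
#' @param R A `|z| x |V|` numeric matrix.
#' @param b A numeric bias vector of length `|V|`.
#' @return An object of class `word_gen_params`.
#' @export
word_gen_params <- function(R, b) {
  R <- as.matrix(R)
  b <- as.numeric(b)
  if (ncol(R) != length(b)) stop("R and b disagree on vocabulary size")
  structure(list(R = R, b = b), class = "word_gen_params")
}

#' @rdname word_gen_params
#' @param model A trained `bvae` with a bag-of-words likelihood.
#' @export
model_word_gen_params <- function(model) {
  stopifnot(inherits(model, "bvae"))
  if (model$likelihood$type != "bow")
    stop("word-generation parameters exist only for bag-of-words models")
  final <- model$params$dec[[length(model$params$dec)]]
  word_gen_params(R = -final$W, b = final$b)
}

#' Word probabilities given an activation vector
#'
#' @param z Numeric activation vector (length `nrow(params$R)`).
#' @param params A [word_gen_params()].
#' @return A strictly positive probability vector over the vocabulary,
#'   summing to one.
#' @export
word_probabilities <- function(z, params) {
  stopifnot(inherits(params, "word_gen_params"))
  z <- as.numeric(z)
  if (length(z) != nrow(params$R))
    stop("activation vector has length ", length(z), "; expected ",
         nrow(params$R))
  logits <- -as.numeric(z %*% params$R) + params$b
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Build the bag-of-words text beta-VAE
#'
#' Encoder: the document count vector through dense sigmoid layers to a
#' diagonal-Gaussian posterior; decoder: sigmoid hidden layers (mirroring the
#' encoder) followed by the linear-softmax word-generation layer, so the
#' document log-likelihood is the sum of per-token log-probabilities.
#' Full-scale defaults follow the reference architecture (two hidden layers
#' of 2000 units, 100 latent dimensions, Adam with learning rate 1e-5, batch
#' size 100, calibrated beta 0.5 for the synthetic corpus);
#' [text_desk_config()] is the reduced workstation preset.
#'
#' @param vocab A [new_vocabulary()] (fixes the input/output dimension).
#' @param config A [train_config()].
#' @return An untrained `bvae` with a bag-of-words likelihood.
#' @export
build_text_vae <- function(vocab, config = text_full_config()) {
  stopifnot(inherits(vocab, "vocabulary"))
  new_bvae(likelihood_bow(length(vocab$words)), config)
}

#' @rdname build_text_vae
#' @param seed,n_steps,beta Overrides threaded into the configuration.
#' @export
text_full_config <- function(seed = 1L, n_steps = 50000L, beta = 0.5) {
  train_config(beta = beta, learning_rate = 1e-5, batch_size = 100L,
               n_steps = n_steps, seed = seed, latent_dim = 100L,
               hidden_widths = c(2000L, 2000L))
}

#' @rdname build_text_vae
#' @export
text_desk_config <- function(seed = 1L, n_steps = 1200L, beta = 0.5) {
  train_config(beta = beta, learning_rate = 1e-3, batch_size = 100L,
               n_steps = n_steps, seed = seed, latent_dim = 32L,
               hidden_widths = c(256L, 256L))
}

#' DRM word list
#'
#' A studied list plus its critical lure: the semantically central word that
#' is never shown but tends to be falsely recalled.
#'
#' @param lure A single word, not among the studied words.
#' @param studied Character vector of unique studied words.
#' @return An object of class `drm_list`.
#' @export
drm_list <- function(lure, studied) {
  lure <- as.character(lure)
  studied <- as.character(studied)
  stopifnot(length(lure) == 1L, length(studied) >= 1L)
  if (anyDuplicated(studied)) stop("studied words must be unique")
  if (lure %in% studied) stop("the lure must not be among the studied words")
  structure(list(lure = lure, studied = studied), class = "drm_list")
}

#' Read / write DRM word lists as plain text
#'
#' Format: first line the lure, subsequent lines the studied words.
#'
#' @param path File path.
#' @param x A [drm_list()].
#' @export
read_drm_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("a DRM list file needs a lure plus words")
  drm_list(lines[1L], lines[-1L])
}

#' @rdname read_drm_list
#' @export
write_drm_list <- function(x, path) {
  stopifnot(inherits(x, "drm_list"))
  writeLines(c(x$lure, x$studied), path)
  invisible(path)
}

# Batched decoder word probabilities for a matrix of latent draws.
decoder_word_probs <- function(model, Z) {
  logits <- mlp_forward(model$params$dec, Z)$out
  E <- exp(logits - row_max(logits))
  E / rowSums(E)
}

# Sequentially sample k distinct word indices without replacement from p,
# renormalising after each draw.
sample_distinct <- function(p, k) {
  out <- integer(k)
  avail <- p
  for (j in seq_len(k)) {
    w <- sample.int(length(avail), 1L, prob = avail)
    out[j] <- w
    avail[w] <- 0
  }
  out
}

#' Sampled reconstructions of a studied word list
#'
#' Encodes the studied words as a bag of words, then for each sample draws
#' `z ~ q(z | x)` and generates `length(studied)` distinct words by
#' sequential sampling without replacement from the decoder's word
#' distribution (renormalising after each draw) — the recall read-out of the
#' false-memory experiment.
#'
#' @param list A [drm_list()]; all studied words must be in the vocabulary.
#' @param model A trained bag-of-words `bvae`.
#' @param vocab The [new_vocabulary()] the model was trained on.
#' @param n_samples Number of sampled recall lists (default 100).
#' @param seed Optional seed.
#' @return A list of `n_samples` character vectors of distinct words.
#' @export
reconstruct_word_list <- function(list, model, vocab, n_samples = 100L,
                                  seed = NULL) {
  check_trained(model)
  stopifnot(inherits(list, "drm_list"), inherits(vocab, "vocabulary"))
  k <- length(list$studied)
  if (k > length(vocab$words))
    stop("list is longer than the vocabulary")
  if (!all(list$studied %in% vocab$words))
    stop("studied words missing from the vocabulary: ",
         paste(setdiff(list$studied, vocab$words), collapse = ", "))
  x <- bow_vectorize(list$studied, vocab)
  enc <- encode_batch(model, obs_matrix(model$likelihood, x))
  mu <- as.numeric(enc$mu)
  sd <- exp(0.5 * as.numeric(enc$logvar))
  d <- model$config$latent_dim
  with_seed(seed, {
    eps <- matrix(stats::rnorm(n_samples * d), n_samples, d)
    Z <- matrix(mu, n_samples, d, byrow = TRUE) + matrix(sd, n_samples, d, byrow = TRUE) * eps
    P <- decoder_word_probs(model, Z)
    lapply(seq_len(n_samples), function(s)
      vocab$words[sample_distinct(P[s, ], k)])
  })
}

#' Recall frequencies from sampled reconstructions
#'
#' For each studied word and for the lure, the fraction of sampled recall
#' lists that contain the word.
#'
#' @param samples A list of character vectors (from
#'   [reconstruct_word_list()]).
#' @param list The [drm_list()] the samples reconstruct.
#' @return A data.frame with columns `word`, `role` (`"studied"`/`"lure"`)
#'   and `recall_frequency`.
#' @export
recall_frequencies <- function(samples, list) {
  stopifnot(length(samples) >= 1L, inherits(list, "drm_list"))
  words <- c(list$studied, list$lure)
  roles <- c(rep("studied", length(list$studied)), "lure")
  freq <- vapply(words, function(w)
    mean(vapply(samples, function(s) w %in% s, logical(1L))), numeric(1L))
  data.frame(word = words, role = roles, recall_frequency = as.numeric(freq),
             row.names = NULL)
}

#' Filter DRM lists against corpus statistics
#'
#' Drops lists whose lure occurs fewer than `min_lure` times in the training
#' corpus, deletes studied words occurring fewer than `min_word` times, and
#' drops lists left with fewer than `min_len` studied words. Defaults are the
#' reference thresholds for natural-language corpora (2000 / 100 / 12).
#'
#' @param lists A list of [drm_list()] objects.
#' @param vocab A [new_vocabulary()] carrying corpus counts.
#' @param min_lure,min_word,min_len Filter thresholds.
#' @return The surviving (possibly shortened) lists.
#' @export
filter_drm_lists <- function(lists, vocab, min_lure = 2000L, min_word = 100L,
                             min_len = 12L) {
  stopifnot(inherits(vocab, "vocabulary"))
  count_of <- function(w) {
    i <- vocab$index[w]
    if (is.na(i)) 0 else vocab$counts[i]
  }
  out <- list()
  for (l in lists) {
    if (count_of(l$lure) < min_lure) next
    keep <- vapply(l$studied, function(w) count_of(w) >= min_word, logical(1L))
    studied <- l$studied[keep]
    if (length(studied) < min_len) next
    out[[length(out) + 1L]] <- drm_list(l$lure, studied)
  }
  out
}

#' Nearest associates of a word in the learned embedding
#'
#' The `k` vocabulary words whose embedding columns (columns of `R`) are most
#' cosine-similar to the query word's, excluding the query itself; ties are
#' broken towards the lower vocabulary index.
#'
#' @param params A [word_gen_params()].
#' @param word Query word (must be in the vocabulary).
#' @param k Number of associates (default 15).
#' @param vocab A [new_vocabulary()].
#' @return A character vector of `k` words, most similar first.
#' @export
nearest_associates <- function(params, word, k = 15L, vocab) {
  stopifnot(inherits(params, "word_gen_params"), inherits(vocab, "vocabulary"))
  i <- vocab$index[as.character(word)]
  if (is.na(i)) stop("unknown word: ", word)
  if (k >= length(vocab$words)) stop("k must be smaller than the vocabulary")
  R <- params$R
  nrm <- sqrt(colSums(R^2))
  nrm[nrm == 0] <- 1e-12
  sims <- as.numeric(crossprod(R[, i], R)) / (nrm * nrm[i])
  sims[i] <- -Inf
  # order() is stable, so equal similarities resolve to the lower index
  vocab$words[order(sims, decreasing = TRUE)[seq_len(k)]]
}

#' Corpus-scaled DRM frequency thresholds
#'
#' The reference thresholds (500 occurrences for lures and studied words)
#' were set against a corpus whose words occur 800 times on average (20000
#' documents of 40 tokens over 1000 words). For corpora of other sizes the
#' thresholds are read as relative frequencies: `500 / 800` of the mean
#' corpus count per word, so list construction behaves comparably at any
#' corpus scale.
#'
#' @param vocab A [new_vocabulary()] carrying corpus counts.
#' @param reference_count,reference_mean The reference threshold and the mean
#'   per-word count of the corpus it was defined for.
#' @return A single integer threshold.
#' @export
scaled_drm_threshold <- function(vocab, reference_count = 500,
                                 reference_mean = 800) {
  stopifnot(inherits(vocab, "vocabulary"))
  max(1L, as.integer(round(reference_count * mean(vocab$counts) / reference_mean)))
}

#' Construct synthetic DRM lists from a trained model
#'
#' One candidate list per vocabulary word with at least `min_lure` corpus
#' occurrences: that word is the lure and its `k` nearest embedding
#' associates are the studied words. Associates occurring fewer than
#' `min_word` times are removed and lists left shorter than `min_len` are
#' discarded. Defaults are the reference thresholds for the synthetic corpus
#' (500 / 500 / 12).
#'
#' @param model A trained bag-of-words `bvae` (the association model).
#' @param vocab The corpus [new_vocabulary()].
#' @param k Associates per list (default 15).
#' @param min_lure,min_word,min_len Thresholds.
#' @return A list of [drm_list()] objects.
#' @export
build_synthetic_drm_lists <- function(model, vocab, k = 15L, min_lure = 500L,
                                      min_word = 500L, min_len = 12L) {
  check_trained(model)
  stopifnot(inherits(vocab, "vocabulary"))
  params <- model_word_gen_params(model)
  lures <- vocab$words[vocab$counts >= min_lure]
  out <- list()
  for (lure in lures) {
    studied <- nearest_associates(params, lure, k, vocab)
    studied <- studied[vocab$counts[vocab$index[studied]] >= min_word]
    if (length(studied) < min_len) next
    out[[length(out) + 1L]] <- drm_list(lure, studied)
  }
  out
}
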