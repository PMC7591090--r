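test_that("bag-of-words vectorisation counts tokens and drops unknowns", {
  vocab <- new_vocabulary(c("a", "b", "c"))
  x <- bow_vectorize(c("a", "b", "a"), vocab)
  expect_equal(as.numeric(x), c(2, 1, 0))
  expect_identical(attr(x, "n_oov"), 0L)
  expect_equal(as.numeric(bow_vectorize(character(0), vocab)), c(0, 0, 0))
  y <- bow_vectorize(c("a", "zzz"), vocab)
  expect_equal(as.numeric(y), c(1, 0, 0))
  expect_identical(attr(y, "n_oov"), 1L)
  expect_error(new_vocabulary(c("a", "a")), "unique")
})

test_that("word probabilities follow the signed linear-softmax generation rule", {
  # z = 0 and zero bias: uniform over the vocabulary
  p0 <- word_probabilities(rep(0, 3), word_gen_params(matrix(0, 3, 7), rep(0, 7)))
  expect_equal(p0, rep(1 / 7, 7), tolerance = 1e-12)
  # hand-computed softmax: |z| = 1, z = 1, R = (1, -1), b = 0
  p <- word_probabilities(1, word_gen_params(matrix(c(1, -1), 1, 2), c(0, 0)))
  expect_equal(p, exp(c(-1, 1)) / sum(exp(c(-1, 1))), tolerance = 1e-12)
  # normalisation for random parameters
  set.seed(6)
  for (i in 1:50) {
    wp <- word_gen_params(matrix(rnorm(4 * 11), 4, 11), rnorm(11))
    pr <- word_probabilities(rnorm(4), wp)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_true(all(pr > 0))
  }
  expect_error(word_probabilities(rnorm(3), wp), "length")
})

test_that("model word-generation parameters reproduce the decoder distribution", {
  # no decoder hidden layers: R maps the latent code directly to words
  vocab <- new_vocabulary(sprintf("w%02d", 1:9))
  cfg <- train_config(beta = 0.5, latent_dim = 3L, hidden_widths = 6L,
                      decoder_widths = integer(0), n_steps = 40L,
                      batch_size = 4L, seed = 12L, learning_rate = 5e-3)
  m <- build_text_vae(vocab, cfg)
  m <- train_vae(m, matrix(rpois(8 * 9, 2), 8, 9), cfg)$model
  wp <- model_word_gen_params(m)
  z <- rnorm(3)
  expect_equal(word_probabilities(z, wp),
               as.numeric(semcomp:::decoder_word_probs(m, matrix(z, 1))),
               tolerance = 1e-12)
})

test_that("text presets match the stated architecture", {
  full <- text_full_config()
  expect_identical(full$latent_dim, 100L)
  expect_identical(full$hidden_widths, c(2000L, 2000L))
  expect_identical(full$learning_rate, 1e-5)
  expect_identical(full$batch_size, 100L)
  expect_identical(full$beta, 0.5)
  desk <- text_desk_config()
  expect_identical(desk$latent_dim, 32L)
  expect_identical(desk$hidden_widths, c(256L, 256L))
})

test_that("DRM lists enforce their invariants", {
  expect_error(drm_list("sleep", c("bed", "bed")), "unique")
  expect_error(drm_list("sleep", c("bed", "sleep")), "lure")
  l <- drm_list("sleep", c("bed", "rest", "dream"))
  f <- tempfile(fileext = ".txt")
  write_drm_list(l, f)
  l2 <- read_drm_list(f)
  expect_identical(l2$lure, "sleep")
  expect_identical(l2$studied, l$studied)
})

test_that("reconstructed word lists contain distinct words and are seeded", {
  vocab <- new_vocabulary(sprintf("w%02d", 1:12))
  cfg <- train_config(beta = 0.5, latent_dim = 2L, hidden_widths = 6L,
                      n_steps = 30L, batch_size = 4L, seed = 3L,
                      learning_rate = 5e-3)
  m <- train_vae(build_text_vae(vocab, cfg), matrix(rpois(10 * 12, 1), 10, 12),
                 cfg)$model
  l <- drm_list("w01", c("w02", "w03", "w04", "w05"))
  s1 <- reconstruct_word_list(l, m, vocab, n_samples = 40L, seed = 2L)
  s2 <- reconstruct_word_list(l, m, vocab, n_samples = 40L, seed = 2L)
  expect_identical(s1, s2)
  for (s in s1) {
    expect_length(s, 4L)
    expect_identical(anyDuplicated(s), 0L)
  }
  bad <- drm_list("w01", sprintf("x%02d", 1:4))
  expect_error(reconstruct_word_list(bad, m, vocab), "missing")
})

test_that("no duplicate ever appears across many sampled reconstructions", {
  vocab <- new_vocabulary(sprintf("w%02d", 1:15))
  cfg <- train_config(beta = 0.5, latent_dim = 2L, hidden_widths = 8L,
                      n_steps = 40L, batch_size = 5L, seed = 6L,
                      learning_rate = 5e-3)
  m <- train_vae(build_text_vae(vocab, cfg),
                 matrix(rpois(20 * 15, 1), 20, 15), cfg)$model
  l <- drm_list("w01", sprintf("w%02d", 2:7))
  s <- reconstruct_word_list(l, m, vocab, n_samples = 10000L, seed = 13L)
  expect_identical(sum(vapply(s, anyDuplicated, integer(1)) > 0L), 0L)
})

test_that("a decoder with mass on two words always recalls exactly those", {
  bias <- c(log(0.9), log(0.1), rep(-40, 4))
  m <- fixed_bow_model(6L, bias)
  vocab <- new_vocabulary(sprintf("w%02d", 1:6))
  l <- drm_list("w06", c("w01", "w02"))
  s <- reconstruct_word_list(l, m, vocab, n_samples = 30L, seed = 9L)
  for (si in s) expect_setequal(si, c("w01", "w02"))
})

test_that("recall frequencies count sample membership", {
  l <- drm_list("lure", c("a", "b"))
  samples <- c(replicate(3, c("a", "b"), simplify = FALSE),
               replicate(1, c("a", "lure"), simplify = FALSE))
  rf <- recall_frequencies(samples, l)
  expect_identical(rf$role, c("studied", "studied", "lure"))
  expect_equal(rf$recall_frequency[rf$word == "a"], 1.0)
  expect_equal(rf$recall_frequency[rf$word == "b"], 0.75)
  expect_equal(rf$recall_frequency[rf$word == "lure"], 0.25)
  # a degenerate recaller that always emits the studied set
  perfect <- replicate(100, c("a", "b"), simplify = FALSE)
  rfp <- recall_frequencies(perfect, l)
  expect_equal(rfp$recall_frequency, c(1, 1, 0))
})

test_that("DRM list filters apply the frequency and length thresholds", {
  words <- c("lureA", "lureB", sprintf("s%02d", 1:20))
  counts <- c(1999, 2500, rep(150, 11), rep(50, 4), rep(150, 5))
  vocab <- new_vocabulary(words, counts)
  # lure below 2000 occurrences: the whole list is excluded
  lA <- drm_list("lureA", sprintf("s%02d", 1:15))
  # lure ok, but 4 of 15 studied words fall below 100 -> 11 remain -> excluded
  lB <- drm_list("lureB", sprintf("s%02d", 1:15))
  # lure ok and 12 frequent studied words survive -> kept, shortened to 12
  lC <- drm_list("lureB", sprintf("s%02d", c(1:11, 12:15, 16)))
  out <- filter_drm_lists(list(lA, lB, lC), vocab)
  expect_length(out, 1L)
  expect_identical(out[[1]]$lure, "lureB")
  expect_length(out[[1]]$studied, 12L)
  expect_false(any(sprintf("s%02d", 12:15) %in% out[[1]]$studied))
  # all-above-threshold lists pass unchanged
  rich <- new_vocabulary(words, rep(3000, length(words)))
  out2 <- filter_drm_lists(list(lA), rich)
  expect_identical(out2[[1]]$studied, lA$studied)
})

test_that("nearest associates agree with a brute-force cosine scan", {
  set.seed(15)
  R <- matrix(rnorm(4 * 50), 4, 50)
  vocab <- new_vocabulary(sprintf("w%02d", 1:50))
  wp <- word_gen_params(R, rep(0, 50))
  for (i in c(1, 17, 50)) {
    got <- nearest_associates(wp, vocab$words[i], k = 15L, vocab)
    expect_identical(got, vocab$words[oracle_nearest(R, i, 15L)])
  }
  # a duplicated embedding column ranks first
  R2 <- R; R2[, 30] <- R[, 7]
  wp2 <- word_gen_params(R2, rep(0, 50))
  expect_identical(nearest_associates(wp2, "w07", 3L, vocab)[1], "w30")
  expect_error(nearest_associates(wp, "nope", 3L, vocab), "unknown")
  expect_error(nearest_associates(wp, "w01", 50L, vocab), "smaller")
})

test_that("synthetic DRM list construction applies lure and associate thresholds", {
  V <- 30L
  vocab_words <- sprintf("w%02d", 1:V)
  # two embedding clusters; words 1..16 frequent, 17..30 rare
  R <- matrix(0, 3, V)
  R[1, 1:16] <- 1; R[2, 17:V] <- 1
  R <- R + matrix(seq_len(3 * V) * 1e-3, 3, V)  # break ties deterministically
  counts <- c(rep(600, 16), rep(100, 14))
  vocab <- new_vocabulary(vocab_words, counts)
  cfg <- train_config(latent_dim = 3L, hidden_widths = 4L,
                      decoder_widths = integer(0), n_steps = 2L,
                      batch_size = 2L, seed = 1L)
  m <- train_vae(build_text_vae(vocab, cfg), matrix(1, 3, V), cfg)$model
  m$params$dec[[length(m$params$dec)]]$W <- -R  # embedding is -W
  lists <- build_synthetic_drm_lists(m, vocab, k = 15L, min_lure = 500L,
                                     min_word = 500L, min_len = 12L)
  # every frequent word's 15 nearest include the other 15 frequent words
  expect_length(lists, 16L)
  for (l in lists) {
    expect_gte(length(l$studied), 12L)
    expect_true(all(vocab$counts[vocab$index[l$studied]] >= 500))
    expect_false(l$lure %in% l$studied)
  }
  # raising the lure threshold above every count removes all lists
  expect_length(build_synthetic_drm_lists(m, vocab, min_lure = 1000L), 0L)
})

test_that("corpus-scaled thresholds reduce to the reference at reference scale", {
  v1 <- new_vocabulary(sprintf("w%03d", 1:100), rep(800, 100))
  expect_identical(scaled_drm_threshold(v1), 500L)
  v2 <- new_vocabulary(sprintf("w%03d", 1:100), rep(400, 100))
  expect_identical(scaled_drm_threshold(v2), 250L)
})
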