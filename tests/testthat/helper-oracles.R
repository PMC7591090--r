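# Independent oracles used across tests: deliberately naive implementations
# that share no code with the package internals.

# Exhaustive per-square comparison oracles for board scoring.
oracle_score_pieces <- function(a, b) {
  n <- 0L
  for (i in 1:64) if (a[i] != 0L && a[i] == b[i]) n <- n + 1L
  n
}

oracle_score_squares <- function(a, b) {
  n <- 0L
  for (i in 1:64) if (a[i] == b[i]) n <- n + 1L
  n / 64
}

# Monte-Carlo estimate of KL(q || N(0, I)) for a diagonal Gaussian, with its
# standard error: draws z ~ q and averages log q(z) - log p(z).
oracle_kl_mc <- function(mu, v, n = 20000L) {
  d <- length(mu)
  z <- matrix(stats::rnorm(n * d), n, d) * rep(sqrt(v), each = n) +
    rep(mu, each = n)
  lq <- rowSums(stats::dnorm(z, mean = rep(mu, each = n),
                             sd = rep(sqrt(v), each = n), log = TRUE))
  lp <- rowSums(stats::dnorm(z, log = TRUE))
  diff <- lq - lp
  list(est = mean(diff), se = stats::sd(diff) / sqrt(n))
}

# Brute-force cosine nearest neighbours over embedding columns.
oracle_nearest <- function(R, i, k) {
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sims <- vapply(seq_len(ncol(R)), function(j) cs(R[, i], R[, j]), numeric(1))
  sims[i] <- -Inf
  order(sims, decreasing = TRUE)[seq_len(k)]
}

# A tiny trained bag-of-words model whose decoder is overwritten so that the
# word distribution is a fixed softmax(bias), independent of the latent code.
fixed_bow_model <- function(vocab_size, bias, seed = 1L) {
  cfg <- train_config(beta = 0.5, latent_dim = 2L, hidden_widths = 4L,
                      n_steps = 2L, batch_size = 2L, seed = seed)
  m <- new_bvae(likelihood_bow(vocab_size), cfg)
  counts <- matrix(1, 3L, vocab_size)
  m <- train_vae(m, counts, cfg)$model
  last <- length(m$params$dec)
  m$params$dec[[last]]$W[] <- 0
  m$params$dec[[last]]$b <- bias
  m
}

# A minimal hand-built game record (for make_test_boards edge cases).
fake_game <- function(n_plies) {
  b <- start_board()
  boards <- matrix(rep(b, n_plies + 1L), n_plies + 1L, 64L, byrow = TRUE)
  structure(list(boards = boards, san = rep("e4", n_plies), result = "*",
                 n_plies = n_plies), class = "game_record")
}
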