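#' Training configuration for a beta-VAE
#'
#' Bundles every setting that determines a training run. Given identical data
#' and an identical `train_config`, [train_vae()] is fully deterministic: the
#' `seed` fixes both the weight initialisation and the batch order.
#'
#' @param beta Nonnegative rate-distortion trade-off weight multiplying the
#'   KL (rate) term of the objective. Large `beta` buys a smaller memory
#'   trace at the price of reconstruction fidelity.
#' @param learning_rate Positive Adam step size.
#' @param batch_size Positive integer minibatch size. If it exceeds the
#'   dataset size, batches are drawn with replacement.
#' @param n_steps Nonnegative integer number of gradient steps.
#' @param seed Integer seed controlling initialisation and batch order.
#' @param latent_dim Positive integer dimension of the Gaussian latent code.
#' @param hidden_widths Integer vector of encoder hidden-layer widths
#'   (sigmoid activations).
#' @param decoder_widths Integer vector of decoder hidden-layer widths;
#'   defaults to `rev(hidden_widths)` (a mirrored architecture).
#' @param var_floor Positive lower bound applied to posterior variances, a
#'   numerical guard against degenerate KL terms.
#' @return An object of class `train_config`.
#' @export
train_config <- function(beta = 1, learning_rate = 1e-3, batch_size = 64L,
                         n_steps = 1000L, seed = 1L, latent_dim = 16L,
                         hidden_widths = c(64L), decoder_widths = NULL,
                         var_floor = 1e-6) {
  stopifnot(
    is.numeric(beta), length(beta) == 1L, beta >= 0,
    is.numeric(learning_rate), learning_rate > 0,
    batch_size >= 1, n_steps >= 0, latent_dim >= 1,
    length(hidden_widths) >= 1L, all(hidden_widths >= 1),
    var_floor > 0
  )
  if (is.null(decoder_widths)) decoder_widths <- rev(hidden_widths)
  structure(list(
    beta = as.numeric(beta), learning_rate = as.numeric(learning_rate),
    batch_size = as.integer(batch_size), n_steps = as.integer(n_steps),
    seed = as.integer(seed), latent_dim = as.integer(latent_dim),
    hidden_widths = as.integer(hidden_widths),
    decoder_widths = as.integer(decoder_widths),
    var_floor = as.numeric(var_floor)
  ), class = "train_config")
}

#' Diagonal-Gaussian latent posterior
#'
#' The "memory trace": the approximate posterior q(z|x) over the latent code,
#' parameterised by its mean and (strictly positive) per-dimension variance.
#'
#' @param mean Numeric vector of posterior means.
#' @param variance Numeric vector of posterior variances, same length,
#'   all strictly positive.
#' @return An object of class `latent_posterior`.
#' @export
latent_posterior <- function(mean, variance) {
  mean <- as.numeric(mean)
  variance <- as.numeric(variance)
  if (length(mean) != length(variance))
    stop("mean and variance must have the same length")
  if (!all(is.finite(mean)) || !all(is.finite(variance)))
    stop("posterior parameters must be finite")
  if (any(variance <= 0))
    stop("posterior variances must be strictly positive")
  structure(list(mean = mean, variance = variance), class = "latent_posterior")
}

#' KL divergence of a diagonal-Gaussian posterior from the standard normal
#'
#' Closed form of KL(q || N(0, I)) in nats: sum over dimensions of
#' (mu^2 + sigma^2 - 1 - log sigma^2) / 2. This is the "rate" of a memory
#' trace: the information (in nats) the trace carries beyond the prior.
#'
#' @param posterior A [latent_posterior()], or a numeric mean vector when
#'   `variance` is supplied separately.
#' @param variance Optional numeric variance vector (strictly positive).
#' @return A single nonnegative number (nats); exactly 0 iff the posterior
#'   equals the prior.
#' @export
kl_diag_gaussian <- function(posterior, variance = NULL) {
  if (!is.null(variance)) posterior <- latent_posterior(posterior, variance)
  if (!inherits(posterior, "latent_posterior"))
    posterior <- latent_posterior(posterior$mean, posterior$variance)
  mu <- posterior$mean
  v <- posterior$variance
  sum(0.5 * (mu^2 + v - 1 - log(v)))
}

# ---------------------------------------------------------------------------
# Likelihood (decoder output distribution) plug-ins.

#' Categorical-grid decoder likelihood
#'
#' Observations are grids of `n_factors` positions, each carrying one of
#' `n_classes` symbols (for chess: 64 squares times 13 symbols). The decoder
#' emits an independent categorical distribution per factor; encoder input is
#' the flattened one-hot matrix.
#'
#' @param n_factors Number of grid positions.
#' @param n_classes Number of symbols per position.
#' @return A likelihood descriptor used by [new_bvae()].
#' @export
likelihood_categorical_grid <- function(n_factors, n_classes) {
  structure(list(type = "categorical_grid",
                 n_factors = as.integer(n_factors),
                 n_classes = as.integer(n_classes),
                 input_dim = as.integer(n_factors * n_classes),
                 output_dim = as.integer(n_factors * n_classes)),
            class = "bvae_likelihood")
}

#' Bag-of-words decoder likelihood
#'
#' Observations are count vectors over a vocabulary; tokens are generated
#' independently given the latent code from a softmax over the vocabulary
#' (the neural variational document model likelihood). The document
#' log-likelihood is the sum of per-token log-probabilities.
#'
#' @param vocab_size Vocabulary size |V|.
#' @return A likelihood descriptor used by [new_bvae()].
#' @export
likelihood_bow <- function(vocab_size) {
  structure(list(type = "bow",
                 vocab_size = as.integer(vocab_size),
                 input_dim = as.integer(vocab_size),
                 output_dim = as.integer(vocab_size)),
            class = "bvae_likelihood")
}

# Coerce user-level observations into the internal row-matrix form:
# categorical_grid -> integer matrix of 1-based class indices (n x F);
# bow -> numeric count matrix (n x V). Single observations become one row.
obs_matrix <- function(lik, x) {
  if (lik$type == "categorical_grid") {
    if (is.null(dim(x))) x <- matrix(as.integer(x), nrow = 1L)
    storage.mode(x) <- "integer"
    if (ncol(x) != lik$n_factors)
      stop("observation has ", ncol(x), " factors; expected ", lik$n_factors)
    if (any(x < 0L) || any(x >= lik$n_classes))
      stop("symbol codes must lie in [0, ", lik$n_classes - 1L, "]")
    x + 1L
  } else {
    if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
    storage.mode(x) <- "double"
    if (ncol(x) != lik$vocab_size)
      stop("count vector has length ", ncol(x), "; expected ", lik$vocab_size)
    if (any(x < 0)) stop("counts must be nonnegative")
    x
  }
}

# Per-item negative log-likelihood and (optionally) its gradient w.r.t. the
# decoder logits. Returns list(recon = n-vector, dlogits = n x output_dim).
likelihood_terms <- function(lik, logits, xb, grad = TRUE) {
  n <- nrow(logits)
  if (lik$type == "categorical_grid") {
    lt <- cpp_grid_likelihood(logits, xb, lik$n_classes, grad)
    list(recon = as.numeric(lt$recon),
         dlogits = if (grad) lt$dlogits else NULL)
  } else {
    M <- logits - row_max(logits)
    E <- exp(M)
    logZ <- log(rowSums(E))
    logp <- M - logZ
    recon <- -rowSums(xb * logp)
    dlogits <- NULL
    if (grad) dlogits <- rowSums(xb) * exp(logp) - xb
    list(recon = recon, dlogits = dlogits)
  }
}

# Decoder output probabilities in natural layout:
# categorical_grid -> list of n matrices F x C; bow -> n x V matrix.
decoder_probs <- function(lik, logits) {
  n <- nrow(logits)
  if (lik$type == "categorical_grid") {
    FF <- lik$n_factors
    C <- lik$n_classes
    M <- matrix(aperm(array(logits, c(n, C, FF)), c(1L, 3L, 2L)), n * FF, C)
    E <- exp(M - row_max(M))
    P <- E / rowSums(E)
    lapply(seq_len(n), function(i) {
      matrix(P[i + (seq_len(FF) - 1L) * n, , drop = FALSE], FF, C)
    })
  } else {
    E <- exp(logits - row_max(logits))
    E / rowSums(E)
  }
}

# ---------------------------------------------------------------------------
# Model construction and parameter handling.

#' Construct a beta-VAE
#'
#' A domain-agnostic beta-VAE: a dense sigmoid encoder mapping observations
#' to a diagonal-Gaussian posterior over the latent code, and a dense sigmoid
#' decoder ending in the configured likelihood. Parameters are initialised
#' deterministically from `config$seed`; the model is marked untrained until
#' [train_vae()] has run.
#'
#' @param likelihood A likelihood descriptor from
#'   [likelihood_categorical_grid()] or [likelihood_bow()].
#' @param config A [train_config()].
#' @return An object of class `bvae`.
#' @export
new_bvae <- function(likelihood, config) {
  stopifnot(inherits(likelihood, "bvae_likelihood"),
            inherits(config, "train_config"))
  model <- structure(list(
    likelihood = likelihood,
    config = config,
    params = NULL,
    trained = FALSE
  ), class = "bvae")
  model$params <- with_seed(config$seed, init_params(model))
  model
}

# Glorot-uniform initialisation of all dense layers, under the caller's RNG.
init_params <- function(model) {
  cfg <- model$config
  lik <- model$likelihood
  enc_dims <- c(lik$input_dim, cfg$hidden_widths, 2L * cfg$latent_dim)
  dec_dims <- c(cfg$latent_dim, cfg$decoder_widths, lik$output_dim)
  make_layers <- function(dims) {
    lapply(seq_len(length(dims) - 1L), function(l) {
      fan_in <- dims[l]
      fan_out <- dims[l + 1L]
      s <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out),
           b = numeric(fan_out))
    })
  }
  list(enc = make_layers(enc_dims), dec = make_layers(dec_dims))
}

# Forward pass through a stack of dense layers: sigmoid on all but the last
# (linear) layer. Returns the output and per-layer activations for backprop.
mlp_forward <- function(layers, X) {
  nl <- length(layers)
  acts <- vector("list", nl)  # input to each layer
  A <- X
  for (l in seq_len(nl)) {
    acts[[l]] <- A
    A <- add_bias(A %*% layers[[l]]$W, layers[[l]]$b)
    if (l < nl) A <- sigmoid(A)
  }
  list(out = A, acts = acts)
}

# Backward pass matching mlp_forward. dOut is the gradient at the linear
# output. Returns per-layer list(dW, db) and (if need_dinput) the gradient
# at the stack's input.
mlp_backward <- function(layers, acts, out, dOut, need_dinput = TRUE) {
  nl <- length(layers)
  grads <- vector("list", nl)
  d <- dOut
  dInput <- NULL
  for (l in rev(seq_len(nl))) {
    A <- acts[[l]]
    grads[[l]] <- list(dW = crossprod(A, d), db = colSums(d))
    if (l == 1L && !need_dinput) break
    dA <- tcrossprod(d, layers[[l]]$W)
    if (l > 1L) {
      H <- A  # A is the sigmoid output of layer l-1
      d <- dA * H * (1 - H)
    } else {
      dInput <- dA
    }
  }
  list(grads = grads, dInput = dInput)
}

# Encoder posterior for a batch, from the internal observation form.
# Categorical grids use the one-hot gather kernel for the first layer (the
# one-hot input is never materialised); bags of words feed counts directly.
# Applies the variance floor.
encode_batch <- function(model, xb) {
  cfg <- model$config
  layers <- model$params$enc
  if (model$likelihood$type == "categorical_grid") {
    h1 <- cpp_onehot_dense_forward(xb, layers[[1L]]$W, layers[[1L]]$b,
                                   model$likelihood$n_classes)
    fwd <- mlp_forward(layers[-1L], h1)
    fwd$h1 <- h1
  } else {
    fwd <- mlp_forward(layers, xb)
  }
  d <- cfg$latent_dim
  mu <- fwd$out[, seq_len(d), drop = FALSE]
  logvar_raw <- fwd$out[, d + seq_len(d), drop = FALSE]
  lo <- log(cfg$var_floor)
  logvar <- pmin(pmax(logvar_raw, lo), 15)
  list(mu = mu, logvar = logvar, logvar_raw = logvar_raw, fwd = fwd)
}

# Backward pass through the encoder given the gradient at its linear output.
encoder_backward <- function(model, xb, enc, dEncOut) {
  layers <- model$params$enc
  if (model$likelihood$type == "categorical_grid") {
    bw <- mlp_backward(layers[-1L], enc$fwd$acts, enc$fwd$out, dEncOut,
                       need_dinput = TRUE)
    h1 <- enc$fwd$h1
    dPre1 <- bw$dInput * h1 * (1 - h1)
    g1 <- list(dW = cpp_onehot_dense_dW(xb, dPre1,
                                        model$likelihood$n_classes),
               db = colSums(dPre1))
    c(list(g1), bw$grads)
  } else {
    mlp_backward(layers, enc$fwd$acts, enc$fwd$out, dEncOut,
                 need_dinput = FALSE)$grads
  }
}

# One full forward (and optionally backward) pass on a batch.
# xb is in internal observation form; eps is the n x d reparameterisation
# noise. Per-item terms: recon_i = -log p(x_i | z_i), kl_i closed form.
vae_pass <- function(model, xb, eps, beta, grad = TRUE) {
  lik <- model$likelihood
  n <- nrow(xb)
  enc <- encode_batch(model, xb)
  v <- exp(enc$logvar)
  sd <- exp(0.5 * enc$logvar)
  z <- enc$mu + sd * eps
  kl <- 0.5 * rowSums(enc$mu^2 + v - 1 - enc$logvar)
  dec <- mlp_forward(model$params$dec, z)
  lt <- likelihood_terms(lik, dec$out, xb, grad = grad)
  recon <- lt$recon
  loss <- mean(recon) + beta * mean(kl)
  out <- list(recon = recon, kl = kl, loss = loss, z = z,
              mu = enc$mu, logvar = enc$logvar, logits = dec$out)
  if (!grad) return(out)

  dlogits <- lt$dlogits / n
  bw_dec <- mlp_backward(model$params$dec, dec$acts, dec$out, dlogits)
  dz <- bw_dec$dInput
  # clamp gradient mask: flat outside the active logvar range
  active <- (enc$logvar_raw > log(model$config$var_floor)) & (enc$logvar_raw < 15)
  dmu <- dz + (beta / n) * enc$mu
  dlogvar <- (dz * eps * 0.5 * sd + (beta / n) * 0.5 * (v - 1)) * active
  out$grads <- list(enc = encoder_backward(model, xb, enc, cbind(dmu, dlogvar)),
                    dec = bw_dec$grads)
  out
}

#' ELBO terms for observations under a beta-VAE
#'
#' Computes the two terms of the (negated, beta-weighted) evidence lower
#' bound for each observation: the reconstruction term (distortion,
#' `-log p(x|z)` estimated with one reparameterised posterior sample) and the
#' rate (the closed-form KL of the posterior from the prior). The loss is
#' exactly `reconstruction + beta * rate`.
#'
#' @param model A `bvae`.
#' @param x One observation or a row-matrix of observations in the model's
#'   native form (symbol codes for a categorical grid, counts for
#'   bag-of-words).
#' @param beta Trade-off weight; defaults to the model's configured beta.
#' @param seed Optional seed making the single-sample estimate reproducible.
#' @return A list with numeric fields `reconstruction`, `rate` and `loss`
#'   (means over the supplied observations, in nats).
#' @export
elbo_terms <- function(model, x, beta = model$config$beta, seed = NULL) {
  stopifnot(inherits(model, "bvae"))
  xb <- obs_matrix(model$likelihood, x)
  eps <- with_seed(seed, matrix(stats::rnorm(nrow(xb) * model$config$latent_dim),
                                nrow(xb), model$config$latent_dim))
  p <- vae_pass(model, xb, eps, beta, grad = FALSE)
  list(reconstruction = mean(p$recon), rate = mean(p$kl), loss = p$loss)
}

#' Posterior over the latent code for one observation
#'
#' @param model A `bvae`.
#' @param x A single observation in the model's native form.
#' @return A [latent_posterior()].
#' @export
encode_posterior <- function(model, x) {
  stopifnot(inherits(model, "bvae"))
  xb <- obs_matrix(model$likelihood, x)
  if (nrow(xb) != 1L) stop("encode_posterior expects a single observation")
  enc <- encode_batch(model, xb)
  latent_posterior(as.numeric(enc$mu), as.numeric(exp(enc$logvar)))
}

#' Train a beta-VAE with Adam
#'
#' Minimises `mean(-log p(x|z)) + beta * mean(KL(q(z|x) || p(z)))` by
#' minibatch gradient descent with the Adam optimiser. The run is fully
#' deterministic given `config$seed`, which re-initialises the parameters and
#' fixes the batch order. Training stops early when a validation plateau is
#' detected (if `validation` is supplied), otherwise after `config$n_steps`.
#'
#' @param model A `bvae` from [new_bvae()] or a domain builder.
#' @param dataset Row-matrix of observations in the model's native form.
#' @param config A [train_config()]; defaults to the model's own.
#' @param validation Optional row-matrix of held-out observations. When
#'   given, the full-objective validation loss is evaluated every
#'   `plateau_every` steps and training stops once the relative improvement
#'   stays below `plateau_tol` for two consecutive checks.
#' @param plateau_every,plateau_tol Plateau-criterion settings.
#' @return A list with `model` (trained) and `log`, a data.frame with columns
#'   `step`, `loss`, `reconstruction`, `kl` satisfying
#'   `loss == reconstruction + beta * kl` at every step.
#' @export
train_vae <- function(model, dataset, config = model$config, validation = NULL,
                      plateau_every = 100L, plateau_tol = 1e-3) {
  stopifnot(inherits(model, "bvae"), inherits(config, "train_config"))
  xb <- obs_matrix(model$likelihood, dataset)
  n <- nrow(xb)
  if (n == 0L) stop("dataset is empty")
  vb <- if (!is.null(validation)) obs_matrix(model$likelihood, validation)
  model$config <- config
  bias0 <- output_bias_init(model$likelihood, xb)
  d <- config$latent_dim
  bs <- config$batch_size

  log_loss <- log_recon <- log_kl <- numeric(config$n_steps)
  n_done <- 0L

  with_seed(config$seed, {
    # init_params returns freshly allocated matrices owned by this run only,
    # so the optimiser may update them in place.
    model$params <- init_params(model)
    # likelihood-specific output-bias start (see output_bias_init); the + 0
    # copy keeps the in-place optimiser off the shared bias0 vector
    model$params$dec[[length(model$params$dec)]]$b <- bias0 + 0
    opt <- adam_init(model$params)
    b1 <- 0.9
    b2 <- 0.999
    prev_val <- Inf
    stale <- 0L
    t <- 0L
    while (t < config$n_steps) {
      t <- t + 1L
      idx <- sample.int(n, min(bs, n), replace = bs > n)
      eps <- matrix(stats::rnorm(length(idx) * d), length(idx), d)
      p <- vae_pass(model, xb[idx, , drop = FALSE], eps, config$beta)
      if (!is.finite(p$loss))
        stop("training diverged (non-finite loss) at step ", t)
      bc1 <- 1 - b1^t
      bc2 <- 1 - b2^t
      for (part in c("enc", "dec")) {
        for (l in seq_along(model$params[[part]])) {
          cpp_adam_update(model$params[[part]][[l]]$W,
                          p$grads[[part]][[l]]$dW,
                          opt$m[[part]][[l]]$W, opt$v[[part]][[l]]$W,
                          config$learning_rate, b1, b2, 1e-8, bc1, bc2)
          cpp_adam_update(model$params[[part]][[l]]$b,
                          p$grads[[part]][[l]]$db,
                          opt$m[[part]][[l]]$b, opt$v[[part]][[l]]$b,
                          config$learning_rate, b1, b2, 1e-8, bc1, bc2)
        }
      }
      log_loss[t] <- p$loss
      log_recon[t] <- mean(p$recon)
      log_kl[t] <- mean(p$kl)
      n_done <- t
      if (!is.null(vb) && t %% plateau_every == 0L) {
        eps_v <- matrix(stats::rnorm(nrow(vb) * d), nrow(vb), d)
        val <- vae_pass(model, vb, eps_v, config$beta, grad = FALSE)$loss
        rel <- (prev_val - val) / max(abs(prev_val), 1e-12)
        stale <- if (is.finite(rel) && rel < plateau_tol) stale + 1L else 0L
        prev_val <- val
        if (stale >= 2L) break
      }
    }
  })
  model$trained <- TRUE
  keep <- seq_len(n_done)
  list(model = model,
       log = data.frame(step = keep, loss = log_loss[keep],
                        reconstruction = log_recon[keep], kl = log_kl[keep]))
}

# Zeroed Adam moment buffers matching the parameter shapes. The update
# itself happens in place in compiled code (cpp_adam_update).
adam_init <- function(params) {
  zero_like <- function(layers) lapply(layers, function(l)
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b))))
  list(m = list(enc = zero_like(params$enc), dec = zero_like(params$dec)),
       v = list(enc = zero_like(params$enc), dec = zero_like(params$dec)))
}

#' Write a training log to CSV
#'
#' @param log The `log` data.frame returned by [train_vae()].
#' @param path Output file path.
#' @export
write_training_log <- function(log, path) {
  utils::write.csv(log[, c("step", "loss", "reconstruction", "kl")], path,
                   row.names = FALSE)
  invisible(path)
}

# Output-bias initialisation. Bag-of-words decoders start at the smoothed
# log unigram frequencies (standard for neural document models; saves the
# early training budget otherwise spent re-deriving base rates). Categorical
# grids start at zero: handing every model its dataset's per-square marginal
# would leak game statistics into the low-data models, whose uniform-board
# augmentation is supposed to act as an uninformative prior there.
output_bias_init <- function(lik, xb) {
  if (lik$type == "categorical_grid") {
    numeric(lik$output_dim)
  } else {
    w <- colSums(xb) + 1
    log(w / sum(w))
  }
}

check_trained <- function(model) {
  if (!inherits(model, "bvae") || is.null(model$params))
    stop("expected an initialised bvae model")
  if (!isTRUE(model$trained))
    stop("model has not been trained; call train_vae() first")
}

#' MAP reconstruction of an observation
#'
#' Encodes `x`, decodes at the posterior mean (no sampling anywhere on this
#' path) and returns the per-factor mode of the decoder distribution. For a
#' categorical grid this is the argmax symbol per position (ties broken
#' towards the lowest symbol index); for bag-of-words it is the count vector
#' of the `sum(x)` highest-probability distinct words, the mode of the
#' distinct-word sequential sampling process.
#'
#' @param x A single observation in the model's native form.
#' @param model A trained `bvae`.
#' @return An observation of the same form as `x`.
#' @export
reconstruct_map <- function(x, model) {
  check_trained(model)
  lik <- model$likelihood
  xb <- obs_matrix(lik, x)
  if (nrow(xb) != 1L) stop("reconstruct_map expects a single observation")
  enc <- encode_batch(model, xb)
  dec <- mlp_forward(model$params$dec, enc$mu)
  probs <- decoder_probs(lik, dec$out)
  if (lik$type == "categorical_grid") {
    as.integer(max.col(probs[[1L]], ties.method = "first") - 1L)
  } else {
    ntok <- sum(xb)
    counts <- numeric(lik$vocab_size)
    if (ntok >= 1) {
      top <- order(probs[1L, ], decreasing = TRUE)[seq_len(min(ntok, lik$vocab_size))]
      counts[top] <- 1
    }
    counts
  }
}

#' Sampled reconstructions of an observation
#'
#' For each sample, draws z from the posterior q(z|x) and then an observation
#' from the decoder likelihood p(x|z) — the generative read-out of a stored
#' memory trace.
#'
#' @param x A single observation in the model's native form.
#' @param model A trained `bvae`.
#' @param n_samples Positive integer number of reconstructions.
#' @param seed Optional seed for reproducibility.
#' @return A list of `n_samples` observations.
#' @export
reconstruct_sample <- function(x, model, n_samples, seed = NULL) {
  check_trained(model)
  if (n_samples < 1) stop("n_samples must be at least 1")
  n_samples <- as.integer(n_samples)
  lik <- model$likelihood
  xb <- obs_matrix(lik, x)
  if (nrow(xb) != 1L) stop("reconstruct_sample expects a single observation")
  enc <- encode_batch(model, xb)
  d <- model$config$latent_dim
  sd <- exp(0.5 * as.numeric(enc$logvar))
  mu <- as.numeric(enc$mu)
  with_seed(seed, {
    lapply(seq_len(n_samples), function(s) {
      z <- matrix(mu + sd * stats::rnorm(d), 1L, d)
      logits <- mlp_forward(model$params$dec, z)$out
      probs <- decoder_probs(lik, logits)
      if (lik$type == "categorical_grid") {
        P <- probs[[1L]]
        as.integer(vapply(seq_len(lik$n_factors), function(f)
          sample.int(lik$n_classes, 1L, prob = P[f, ]), integer(1L)) - 1L)
      } else {
        ntok <- as.integer(sum(xb))
        as.numeric(stats::rmultinom(1L, ntok, probs[1L, ]))
      }
    })
  })
}

#' Locate a model on the rate-distortion plane
#'
#' Rate is the mean closed-form KL of the posterior from the prior over the
#' dataset (nats/observation); distortion is the mean reconstruction term
#' (negative log-likelihood, nats/observation) estimated with one
#' reparameterised sample per observation under a fixed evaluation seed.
#'
#' @param model A trained `bvae`.
#' @param dataset Row-matrix of observations.
#' @param seed Evaluation seed for the distortion estimate.
#' @return A list of class `rd_point` with numeric `rate` and `distortion`.
#' @export
rd_point <- function(model, dataset, seed = 0L) {
  check_trained(model)
  xb <- obs_matrix(model$likelihood, dataset)
  if (nrow(xb) == 0L) stop("dataset is empty")
  d <- model$config$latent_dim
  eps <- with_seed(seed, matrix(stats::rnorm(nrow(xb) * d), nrow(xb), d))
  p <- vae_pass(model, xb, eps, beta = 0, grad = FALSE)
  structure(list(rate = mean(p$kl), distortion = mean(p$recon)),
            class = "rd_point")
}

#' Save / load a beta-VAE checkpoint
#'
#' A single-file serialized parameter set with the embedded training
#' configuration. The format is versioned (`bvae-checkpoint-1`).
#'
#' @param model A `bvae`.
#' @param path File path.
#' @return `save_vae` returns `path` invisibly; `load_vae` returns the model.
#' @export
save_vae <- function(model, path) {
  stopifnot(inherits(model, "bvae"))
  saveRDS(list(format = "bvae-checkpoint-1", model = model), path)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "bvae-checkpoint-1"))
    stop("not a recognised bvae checkpoint: ", path)
  obj$model
}
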