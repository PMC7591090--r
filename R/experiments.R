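# Orchestration of the three analyses: expertise curves on chess boards,
# gist-based lure intrusion on DRM word lists, and forgetting as a sweep of
# the rate-distortion trade-off parameter beta.

#' Sweep configuration
#'
#' @param beta_grid Strictly increasing vector of at least three positive
#'   betas. Separate models are trained at every grid point (no annealing).
#' @param seeds Integer seeds, one independent replicate per seed.
#' @param base_config The [train_config()] whose beta/seed get overridden.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(beta_grid, seeds = 1:3, base_config = text_desk_config()) {
  beta_grid <- as.numeric(beta_grid)
  if (length(beta_grid) < 3L)
    stop("beta_grid needs length at least 3")
  if (any(beta_grid <= 0) || any(diff(beta_grid) <= 0))
    stop("beta_grid must be positive and strictly increasing")
  stopifnot(inherits(base_config, "train_config"))
  structure(list(beta_grid = beta_grid, seeds = as.integer(seeds),
                 base_config = base_config), class = "sweep_config")
}

# Batched MAP board reconstruction (argmax symbol per square at the
# posterior mean), used by the expertise read-out.
map_boards <- function(model, boards) {
  lik <- model$likelihood
  xb <- obs_matrix(lik, boards)
  n <- nrow(xb)
  enc <- encode_batch(model, xb)
  logits <- mlp_forward(model$params$dec, enc$mu)$out
  FF <- lik$n_factors
  C <- lik$n_classes
  M <- matrix(aperm(array(logits, c(n, C, FF)), c(1L, 3L, 2L)), n * FF, C)
  matrix(max.col(M, ties.method = "first") - 1L, n, FF)
}

default_reconstructor <- function(model, boards) map_boards(model, boards)

#' Run the chess expertise experiment
#'
#' Generates (or takes) a corpus of games, splits off a held-out test set by
#' game, builds skill-graded training sets (subsampled game positions plus
#' uniform-board augmentation), trains one chess beta-VAE per skill fraction
#' and seed, and scores MAP reconstructions of the held-out test boards in
#' the game and shuffled (random) conditions.
#'
#' @param games Optional list of game records; generated when `NULL`.
#' @param n_games Number of synthetic games when generating.
#' @param fractions Skill fractions of the pooled training positions.
#' @param n_augment Uniform random boards added to every training set.
#' @param seeds One training replicate per seed (controls subsampling,
#'   initialisation and batch order).
#' @param config Base [train_config()]; its seed is overridden per replicate.
#' @param test_fraction Fraction of games held out for testing (split by
#'   game before any subsampling).
#' @param data_seed Seed for game generation and the train/test split.
#' @param reconstructor Function `(model, boards) -> boards` producing
#'   reconstructions; the default is the MAP read-out. Exposed so a known
#'   oracle can stand in for the model in pipeline checks.
#' @return A data.frame with one row per fraction x condition x seed:
#'   `fraction`, `condition`, `seed`, `n_test`, `mean_pieces`,
#'   `mean_square_acc`, `beta`, `config_hash`.
#' @export
run_expertise <- function(games = NULL, n_games = 2000L,
                          fractions = c(0.001, 0.01, 0.10, 0.90),
                          n_augment = 10000L, seeds = 1:3,
                          config = chess_desk_config(),
                          test_fraction = 0.1, data_seed = 2024L,
                          reconstructor = default_reconstructor) {
  if (is.null(games))
    games <- generate_legal_games(n_games, max_plies = 80L, seed = data_seed)
  n <- length(games)
  idx_test <- with_seed(data_seed + 1L,
                        sample.int(n, max(1L, round(test_fraction * n))))
  test <- make_test_boards(games[idx_test], seed = data_seed + 2L)
  train_games <- games[-idx_test]
  chash <- config_hash(list(config, fractions, n_augment, n_games))

  rows <- list()
  for (seed in seeds) {
    datasets <- make_skill_datasets(train_games, fractions, n_augment,
                                    seed = seed)
    for (ds in datasets) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      model <- build_chess_vae(cfg)
      fit <- train_vae(model, ds$boards, cfg)
      for (cond in c("game", "random")) {
        boards <- if (cond == "game") test$game_condition else test$random_condition
        rec <- reconstructor(fit$model, boards)
        pieces <- vapply(seq_len(nrow(boards)), function(i)
          score_pieces(boards[i, ], rec[i, ]), numeric(1L))
        squares <- vapply(seq_len(nrow(boards)), function(i)
          score_squares(boards[i, ], rec[i, ]), numeric(1L))
        rows[[length(rows) + 1L]] <- data.frame(
          fraction = ds$fraction, condition = cond, seed = seed,
          n_test = nrow(boards), mean_pieces = mean(pieces),
          mean_square_acc = mean(squares), beta = cfg$beta,
          config_hash = chash)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$seed, out$fraction, out$condition), , drop = FALSE]
}

# Train a text model on an LDA corpus at one (beta, seed) setting.
train_text_model <- function(corpus, config, beta, seed) {
  cfg <- config
  cfg$beta <- as.numeric(beta)
  cfg$seed <- as.integer(seed)
  model <- build_text_vae(corpus$vocab, cfg)
  train_vae(model, corpus$counts, cfg)$model
}

# Mean studied / lure recall of a model over a set of DRM lists.
eval_recall <- function(model, corpus, lists, n_samples, seed) {
  per_list <- lapply(seq_along(lists), function(i) {
    samples <- reconstruct_word_list(lists[[i]], model, corpus$vocab,
                                     n_samples = n_samples,
                                     seed = seed * 1000L + i)
    rf <- recall_frequencies(samples, lists[[i]])
    rf$list_id <- i
    rf$lure <- lists[[i]]$lure
    rf
  })
  detail <- do.call(rbind, per_list)
  list(detail = detail,
       studied = mean(detail$recall_frequency[detail$role == "studied"]),
       lure = mean(detail$recall_frequency[detail$role == "lure"]))
}

#' Grid calibration of beta for the DRM experiment
#'
#' Trains one model per grid beta and picks the beta minimising the absolute
#' difference between mean lure and mean studied recall — the operational
#' definition of "immediate recall", where the two are approximately equal.
#'
#' @param corpus An `lda_corpus`.
#' @param lists DRM lists (from [build_synthetic_drm_lists()]).
#' @param beta_grid Candidate betas.
#' @param config Base [train_config()].
#' @param seed Training/evaluation seed.
#' @param n_samples Recall samples per list.
#' @return A list with `beta` (the calibrated value) and `table`
#'   (per-beta mean studied/lure recall).
#' @export
calibrate_beta <- function(corpus, lists, beta_grid, config = text_desk_config(),
                           seed = 1L, n_samples = 100L) {
  stopifnot(length(beta_grid) >= 1L, length(lists) >= 1L)
  rows <- lapply(beta_grid, function(b) {
    model <- train_text_model(corpus, config, b, seed)
    ev <- eval_recall(model, corpus, lists, n_samples, seed)
    data.frame(beta = b, studied_recall = ev$studied, lure_recall = ev$lure,
               gap = abs(ev$lure - ev$studied))
  })
  tab <- do.call(rbind, rows)
  list(beta = tab$beta[which.min(tab$gap)], table = tab)
}

#' Run the DRM false-memory experiment
#'
#' Trains an association model on the corpus, derives synthetic DRM lists
#' from its word embedding, then for each seed trains an evaluation model at
#' the calibrated beta and measures recall frequencies of studied words and
#' lures from sampled, distinct-word reconstructions. A control compares
#' recall of the coherent lists against length-matched lists of uniformly
#' random vocabulary words.
#'
#' @param corpus An `lda_corpus`.
#' @param beta Rate-distortion weight for the evaluation models (default:
#'   the base config's calibrated value).
#' @param seeds Replicate seeds.
#' @param config Base [train_config()].
#' @param n_samples Recall samples per list (default 100).
#' @param max_lists Evaluate at most this many lists (those with the most
#'   frequent lures), keeping the run time bounded.
#' @param lists Optional pre-built DRM lists; built from an association model
#'   when `NULL`.
#' @param assoc_seed Seed of the association model.
#' @return A list with `recall` (per-list, per-word rows with columns
#'   `list_id`, `lure`, `word`, `role`, `recall_frequency`, `beta`, `seed`)
#'   and `summary` (per-seed mean studied, lure and random-list recall).
#' @export
run_drm <- function(corpus, beta = config$beta, seeds = 1:3,
                    config = text_desk_config(), n_samples = 100L,
                    max_lists = 20L, lists = NULL, assoc_seed = 101L) {
  if (is.null(lists)) {
    assoc <- train_text_model(corpus, config, beta, assoc_seed)
    thr <- scaled_drm_threshold(corpus$vocab)
    lists <- build_synthetic_drm_lists(assoc, corpus$vocab,
                                       min_lure = thr, min_word = thr)
  }
  if (length(lists) == 0L)
    stop("no DRM lists survive the frequency filters")
  lists <- select_lists(lists, corpus$vocab, max_lists)
  chash <- config_hash(list(config, beta, n_samples, max_lists))

  detail_rows <- list()
  summary_rows <- list()
  for (seed in seeds) {
    model <- train_text_model(corpus, config, beta, seed)
    ev <- eval_recall(model, corpus, lists, n_samples, seed)
    det <- ev$detail
    det$beta <- beta
    det$seed <- seed
    det$config_hash <- chash
    detail_rows[[length(detail_rows) + 1L]] <- det

    rand_lists <- random_word_lists(lists, corpus$vocab, seed = seed + 5000L)
    ev_r <- eval_recall(model, corpus, rand_lists, n_samples, seed + 9000L)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      seed = seed, beta = beta, n_lists = length(lists),
      mean_studied = ev$studied, mean_lure = ev$lure,
      mean_random_list = ev_r$studied, config_hash = chash)
  }
  list(recall = do.call(rbind, detail_rows),
       summary = do.call(rbind, summary_rows),
       lists = lists)
}

# A seeded uniform subsample of the surviving lists: representative of the
# full list population (selecting, say, the most frequent lures would bias
# the lure-intrusion measurements), deterministic given the seed.
select_lists <- function(lists, vocab, max_lists, seed = 55L) {
  if (length(lists) <= max_lists) return(lists)
  with_seed(seed, sample(lists, max_lists))
}

# Length-matched lists of uniformly random vocabulary words (the incoherent
# control condition).
random_word_lists <- function(lists, vocab, seed) {
  with_seed(seed, lapply(lists, function(l) {
    k <- length(l$studied)
    w <- sample(vocab$words, k + 1L)
    drm_list(w[1L], w[-1L])
  }))
}

#' Run the forgetting sweep over beta
#'
#' Models increasing retention delay as an increasing rate-distortion weight:
#' one model is trained per (beta, seed) cell on the same corpus, and recall
#' of studied words and lures over a fixed set of DRM lists is measured,
#' together with the model's position on the rate-distortion plane.
#'
#' @param corpus An `lda_corpus`.
#' @param lists DRM lists held fixed across the sweep; built from an
#'   association model when `NULL`.
#' @param config A [sweep_config()].
#' @param n_samples Recall samples per list.
#' @param max_lists Cap on the number of lists evaluated.
#' @param n_rd_docs Number of corpus documents used for the rate/distortion
#'   estimate.
#' @param assoc_seed Seed of the association model when `lists` is `NULL`.
#' @param random_control If `TRUE`, each cell also measures studied-word
#'   recall on length-matched lists of uniformly random vocabulary words
#'   (column `random_list_recall`), the incoherent control condition.
#' @return A data.frame with one row per beta x seed: `beta`, `seed`,
#'   `studied_recall`, `lure_recall`, `difference` (lure - studied), `rate`,
#'   `distortion`, `config_hash` (plus `random_list_recall` when requested).
#' @export
run_forgetting_sweep <- function(corpus, config, lists = NULL,
                                 n_samples = 100L, max_lists = 20L,
                                 n_rd_docs = 500L, assoc_seed = 101L,
                                 random_control = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  if (is.null(lists)) {
    assoc <- train_text_model(corpus, config$base_config,
                              config$base_config$beta, assoc_seed)
    thr <- scaled_drm_threshold(corpus$vocab)
    lists <- build_synthetic_drm_lists(assoc, corpus$vocab,
                                       min_lure = thr, min_word = thr)
  }
  if (length(lists) == 0L)
    stop("no DRM lists survive the frequency filters")
  lists <- select_lists(lists, corpus$vocab, max_lists)
  chash <- config_hash(list(config, n_samples, max_lists))
  rd_idx <- seq_len(min(n_rd_docs, nrow(corpus$counts)))

  rows <- list()
  for (beta in config$beta_grid) {
    for (seed in config$seeds) {
      model <- tryCatch(
        train_text_model(corpus, config$base_config, beta, seed),
        error = function(e) stop("sweep cell beta=", beta, " seed=", seed,
                                 " failed: ", conditionMessage(e)))
      ev <- eval_recall(model, corpus, lists, n_samples, seed)
      rd <- rd_point(model, corpus$counts[rd_idx, , drop = FALSE])
      row <- data.frame(
        beta = beta, seed = seed,
        studied_recall = ev$studied, lure_recall = ev$lure,
        difference = ev$lure - ev$studied,
        rate = rd$rate, distortion = rd$distortion, config_hash = chash)
      if (random_control) {
        rl <- random_word_lists(lists, corpus$vocab, seed = seed + 5000L)
        row$random_list_recall <-
          eval_recall(model, corpus, rl, n_samples, seed + 9000L)$studied
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Write experiment tables to disk
#'
#' Writes each table as CSV and a JSON summary of every numeric column's
#' mean, under deterministic file names embedding a configuration hash, so
#' re-running an identical configuration overwrites with identical bytes.
#'
#' @param tables A named list of data.frames.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
report <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  h <- config_hash(tables)
  files <- character(0)
  summary <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    f <- file.path(out_dir, sprintf("%s-%s.csv", nm, h))
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
    num <- vapply(tab, is.numeric, logical(1L))
    summary[[nm]] <- c(list(n_rows = nrow(tab)),
                       lapply(tab[num], function(col) mean(col)))
  }
  jf <- file.path(out_dir, sprintf("summary-%s.json", h))
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, jf))
}

#' Load an experiment configuration from YAML
#'
#' Reads a YAML file with optional sections `expertise`, `drm` and `sweep`,
#' whose keys are the arguments of [run_expertise()], [run_drm()] and
#' [run_forgetting_sweep()].
#'
#' @param path YAML file path.
#' @return A named list of per-experiment argument lists.
#' @export
load_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  yaml::read_yaml(path)
}
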