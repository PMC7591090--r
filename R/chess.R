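#' @useDynLib semcomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Board representation: an integer vector of length 64 indexed a1..h8 (file
# fastest), with symbol codes 0 = empty, 1..6 = white P,N,B,R,Q,K and
# 7..12 = black p,n,b,r,q,k.

#' Chess piece symbols
#'
#' The 13 board symbols in code order (code 0 first): empty, then the white
#' and black pieces.
#' @export
piece_symbols <- function() {
  c(".", "P", "N", "B", "R", "Q", "K", "p", "n", "b", "r", "q", "k")
}

#' Standard starting position
#'
#' @return An integer vector of 64 symbol codes.
#' @export
start_board <- function() cpp_start_board()

validate_board <- function(board) {
  board <- as.integer(board)
  if (length(board) != 64L) stop("a board must have exactly 64 squares")
  if (any(board < 0L) || any(board > 12L))
    stop("unknown symbol code; codes must lie in 0..12")
  board
}

#' One-hot encoding of a board
#'
#' Represents a position as a 64 x 13 matrix: row r is the one-hot indicator
#' of square r's symbol, so every row sums to one. This is the input and
#' target representation of the chess beta-VAE.
#'
#' @param board Integer vector of 64 symbol codes (0..12).
#' @return A 64 x 13 numeric matrix.
#' @export
encode_board <- function(board) {
  board <- validate_board(board)
  M <- matrix(0, 64L, 13L)
  M[cbind(seq_len(64L), board + 1L)] <- 1
  M
}

#' Decode a 64 x 13 matrix back to a board
#'
#' Accepts one-hot rows or arbitrary per-square probability/score rows; each
#' square takes the argmax symbol, with ties broken deterministically towards
#' the lowest symbol index. Exact inverse of [encode_board()] on one-hot
#' input; also used on decoder categorical outputs.
#'
#' @param matrix A 64 x 13 numeric matrix.
#' @return An integer vector of 64 symbol codes.
#' @export
decode_board <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) != 64L || ncol(matrix) != 13L)
    stop("expected a 64 x 13 matrix")
  as.integer(max.col(matrix, ties.method = "first") - 1L)
}

#' Structural legality check for a board
#'
#' Verifies position invariants that any board reachable by legal play must
#' satisfy: exactly one king per side, at most eight pawns per side, no pawns
#' on the first or last rank, at most sixteen men per side, and kings not on
#' adjacent squares. Used as an independent check on generated games; it does
#' not (and need not) prove full reachability.
#'
#' @param board Integer vector of 64 symbol codes.
#' @return `TRUE` if all invariants hold, otherwise `FALSE`.
#' @export
check_board_sanity <- function(board) {
  board <- validate_board(board)
  ranks <- (seq_len(64L) - 1L) %/% 8L  # 0..7
  wk <- which(board == 6L)
  bk <- which(board == 12L)
  if (length(wk) != 1L || length(bk) != 1L) return(FALSE)
  if (sum(board == 1L) > 8L || sum(board == 7L) > 8L) return(FALSE)
  pawn_ranks <- ranks[board == 1L | board == 7L]
  if (any(pawn_ranks == 0L | pawn_ranks == 7L)) return(FALSE)
  if (sum(board >= 1L & board <= 6L) > 16L) return(FALSE)
  if (sum(board >= 7L) > 16L) return(FALSE)
  dr <- abs((wk - 1L) %/% 8L - (bk - 1L) %/% 8L)
  df <- abs((wk - 1L) %% 8L - (bk - 1L) %% 8L)
  if (dr <= 1L && df <= 1L) return(FALSE)
  TRUE
}

#' Generate random legal chess games
#'
#' Plays `n_games` games of uniformly random legal moves from the standard
#' starting position, stopping at checkmate, stalemate or `max_plies`
#' half-moves. These synthetic games stand in for human game archives: their
#' positions occupy the structured manifold of legal play, which is the
#' property the expertise analysis contrasts against shuffled boards.
#'
#' @param n_games Positive integer number of games.
#' @param max_plies Maximum half-moves per game.
#' @param seed Integer seed; the same seed reproduces the same games.
#' @return A list of game records, each a list with `boards` (an
#'   `(n_plies + 1) x 64` integer matrix whose first row is the starting
#'   position and row `k + 1` the position after ply `k`), `san` (the move
#'   list in standard algebraic notation), `result` and `n_plies`.
#' @export
generate_legal_games <- function(n_games, max_plies = 80L, seed = 1L) {
  stopifnot(n_games >= 1, max_plies >= 1)
  raw <- cpp_random_games(as.integer(n_games), as.integer(max_plies),
                          as.integer(seed))
  start <- cpp_start_board()
  lapply(raw, function(g) {
    boards <- rbind(matrix(start, 1L, 64L), g$boards)
    structure(list(boards = boards, san = as.character(g$san),
                   result = g$result, n_plies = nrow(g$boards)),
              class = "game_record")
  })
}

#' Write and read games as PGN
#'
#' `write_pgn` writes game records as standard PGN movetext with minimal
#' headers; `read_pgn` parses a PGN file (headers ignored, comments,
#' variations are not supported) and replays the moves through the package's
#' move generator, returning game records.
#'
#' @param games A list of game records from [generate_legal_games()].
#' @param path File path.
#' @return `write_pgn` returns `path` invisibly; `read_pgn` a list of game
#'   records.
#' @export
write_pgn <- function(games, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(games)) {
    g <- games[[i]]
    result <- if (is.null(g$result)) "*" else g$result
    writeLines(c(sprintf('[Event "synthetic random self-play"]'),
                 sprintf('[Round "%d"]', i),
                 sprintf('[Result "%s"]', result), ""), con)
    san <- g$san
    toks <- character(0)
    for (j in seq_along(san)) {
      if (j %% 2L == 1L) toks <- c(toks, sprintf("%d.", (j + 1L) %/% 2L))
      toks <- c(toks, san[j])
    }
    toks <- c(toks, result)
    writeLines(paste(strwrap(paste(toks, collapse = " "), 79), collapse = "\n"),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_pgn
#' @export
read_pgn <- function(path) {
  lines <- readLines(path, warn = FALSE)
  games <- list()
  cur <- character(0)
  seen_moves <- FALSE
  flush_game <- function(txt) {
    txt <- paste(txt, collapse = " ")
    txt <- gsub("\\{[^}]*\\}", " ", txt)       # comments
    txt <- gsub("\\$\\d+", " ", txt)            # NAGs
    toks <- strsplit(trimws(txt), "\\s+")[[1]]
    toks <- toks[!grepl("^\\d+\\.+$", toks)]    # move numbers
    toks <- sub("^\\d+\\.+", "", toks)          # glued move numbers
    toks <- toks[!(toks %in% c("1-0", "0-1", "1/2-1/2", "*", ""))]
    if (length(toks) == 0L) return(NULL)
    boards <- cpp_replay_san(toks)
    boards <- rbind(matrix(cpp_start_board(), 1L, 64L), boards)
    structure(list(boards = boards, san = toks, result = "*",
                   n_plies = length(toks)), class = "game_record")
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      if (seen_moves) {
        g <- flush_game(cur)
        if (!is.null(g)) games[[length(games) + 1L]] <- g
        cur <- character(0)
        seen_moves <- FALSE
      }
    } else if (nzchar(trimws(ln))) {
      cur <- c(cur, ln)
      seen_moves <- TRUE
    }
  }
  g <- flush_game(cur)
  if (!is.null(g)) games[[length(games) + 1L]] <- g
  games
}

#' Sample a uniformly random board configuration
#'
#' Each of the 64 squares is drawn independently and uniformly over the 13
#' symbols, irrespective of chess legality. Such boards augment the training
#' data as an uninformative prior over the whole configuration space, which
#' dominates in the low-data (unskilled) regime.
#'
#' @param seed Optional integer seed; with `NULL` the current RNG stream is
#'   used.
#' @return An integer vector of 64 symbol codes.
#' @export
sample_uniform_board <- function(seed = NULL) {
  with_seed(seed, as.integer(sample.int(13L, 64L, replace = TRUE) - 1L))
}

#' Shuffle pieces across the occupied squares of a board
#'
#' Applies a uniformly random permutation of the piece identities over
#' exactly the originally occupied squares; empty squares are untouched. The
#' result has the same occupied-square set and the same piece multiset as the
#' input — the "random condition" of the board-memory experiment.
#'
#' @param board Integer vector of 64 symbol codes with at least one piece.
#' @param seed Optional integer seed.
#' @return An integer vector of 64 symbol codes.
#' @export
shuffle_board <- function(board, seed = NULL) {
  board <- validate_board(board)
  occ <- which(board != 0L)
  if (length(occ) == 0L) stop("cannot shuffle a fully empty board")
  with_seed(seed, {
    board[occ] <- board[occ][sample.int(length(occ))]
  })
  board
}

#' Piece-count reconstruction score
#'
#' Counts the squares where the original holds a piece and the
#' reconstruction carries the identical piece — the classic board-recall
#' criterion of the chess-expertise literature. Pieces hallucinated onto
#' originally empty squares are not penalised here (see [score_squares()]).
#'
#' @param original,reconstruction Integer vectors of 64 symbol codes.
#' @return A nonnegative integer.
#' @export
score_pieces <- function(original, reconstruction) {
  original <- validate_board(original)
  reconstruction <- validate_board(reconstruction)
  sum(original != 0L & original == reconstruction)
}

#' Per-square reconstruction accuracy
#'
#' Fraction of all 64 squares (including empty ones) whose symbol matches
#' between the original and the reconstruction.
#'
#' @param original,reconstruction Integer vectors of 64 symbol codes.
#' @return A number in \[0, 1\].
#' @export
score_squares <- function(original, reconstruction) {
  original <- validate_board(original)
  reconstruction <- validate_board(reconstruction)
  mean(original == reconstruction)
}

#' Cache a board pool as CSV
#'
#' A board pool (any `n x 64` matrix of symbol codes, e.g. the pooled
#' positions behind a skill dataset) written as plain CSV with columns
#' `sq1..sq64`, one board per row.
#'
#' @param boards An `n x 64` integer matrix of symbol codes.
#' @param path File path.
#' @export
write_board_pool <- function(boards, path) {
  boards <- matrix(as.integer(boards), nrow = nrow(boards))
  stopifnot(ncol(boards) == 64L)
  colnames(boards) <- sprintf("sq%d", seq_len(64L))
  utils::write.csv(boards, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_board_pool
#' @export
read_board_pool <- function(path) {
  tab <- utils::read.csv(path)
  boards <- as.matrix(tab)
  stopifnot(ncol(boards) == 64L)
  boards <- matrix(as.integer(boards), nrow(boards), 64L)
  if (anyNA(boards) || any(boards < 0L) || any(boards > 12L))
    stop("board pool contains invalid symbol codes")
  dimnames(boards) <- NULL
  boards
}

# Pool all positions of a list of games into one n x 64 matrix.
pool_boards <- function(games, include_start = FALSE) {
  do.call(rbind, lapply(games, function(g) {
    if (include_start) g$boards else g$boards[-1L, , drop = FALSE]
  }))
}

#' Skill-graded training sets
#'
#' Pools all board positions across the supplied games, subsamples the pool
#' without replacement to each requested fraction (modelling graded
#' expertise: how much play the learner has seen), and augments each subset
#' with `n_augment` uniformly random boards.
#'
#' @param games Game records (the training split; never test games).
#' @param fractions Fractions of the pooled positions, each in (0, 1].
#' @param n_augment Number of uniform random boards added to every dataset.
#' @param seed Integer seed.
#' @return A list of `skill_dataset` objects, each with `fraction`, `boards`
#'   (an `(round(fraction * pool) + n_augment) x 64` integer matrix) and
#'   `n_augment`.
#' @export
make_skill_datasets <- function(games, fractions = c(0.001, 0.01, 0.10, 0.90),
                                n_augment = 10000L, seed = 1L) {
  stopifnot(length(games) >= 1, all(fractions > 0), all(fractions <= 1),
            n_augment >= 0)
  pool <- pool_boards(games)
  n_pool <- nrow(pool)
  with_seed(seed, {
    out <- lapply(fractions, function(f) {
      k <- round(f * n_pool)
      if (k == 0L)
        warning("fraction ", f, " yields 0 game boards; ",
                "dataset contains only augmentation boards")
      keep <- if (k > 0L) pool[sample.int(n_pool, k), , drop = FALSE]
              else pool[0L, , drop = FALSE]
      aug <- if (n_augment > 0L)
        matrix(sample.int(13L, 64L * n_augment, replace = TRUE) - 1L,
               n_augment, 64L)
      else pool[0L, , drop = FALSE]
      structure(list(fraction = f, boards = rbind(keep, aug),
                     n_augment = as.integer(n_augment)),
                class = "skill_dataset")
    })
  })
  out
}

#' Test boards in the game and random conditions
#'
#' From each held-out game long enough, takes the position after full move 21
#' or 41 (a seeded random choice where both exist; games shorter than 21 full
#' moves are skipped, games shorter than 41 use move 21). The random
#' condition applies [shuffle_board()] to each selected board, conserving
#' occupancy and piece multiset while destroying game structure.
#'
#' @param games Held-out game records (never part of any training set).
#' @param seed Integer seed.
#' @return A list with `game_condition` and `random_condition`, two matrices
#'   of boards (rows), plus `move_used`, the full-move index per board.
#' @export
make_test_boards <- function(games, seed = 1L) {
  with_seed(seed, {
    picks <- lapply(games, function(g) {
      np <- g$n_plies
      if (np < 42L) return(NULL)
      mv <- if (np >= 82L) sample(c(21L, 41L), 1L) else 21L
      list(board = g$boards[2L * mv + 1L, ], move = mv)
    })
    picks <- picks[!vapply(picks, is.null, logical(1L))]
    if (length(picks) == 0L)
      stop("no game reaches full move 21; cannot build test boards")
    game_cond <- t(vapply(picks, `[[`, integer(64L), "board"))
    random_cond <- t(apply(game_cond, 1L, shuffle_board))
    list(game_condition = game_cond,
         random_condition = random_cond,
         move_used = vapply(picks, `[[`, integer(1L), "move"))
  })
}

#' Build the chess beta-VAE
#'
#' Encoder: the flattened 64 x 13 one-hot board through dense sigmoid layers
#' to the mean and log-variance of a diagonal-Gaussian latent code; decoder
#' mirrors it, ending in 64 independent 13-way categorical distributions.
#' Full-scale defaults follow the reference architecture (two hidden layers
#' of 3000 units, 64 latent dimensions, beta = 1e-4, Adam with learning rate
#' 1e-4, batch size 65); [chess_desk_config()] provides a reduced preset that
#' preserves the qualitative behaviour at workstation scale.
#'
#' @param config A [train_config()]; defaults to the full-scale settings.
#' @return An untrained `bvae` with a categorical-grid likelihood.
#' @export
build_chess_vae <- function(config = chess_full_config()) {
  new_bvae(likelihood_categorical_grid(64L, 13L), config)
}

#' @rdname build_chess_vae
#' @param seed,n_steps,beta Overrides threaded into the configuration.
#' @export
chess_full_config <- function(seed = 1L, n_steps = 20000L, beta = 1e-4) {
  train_config(beta = beta, learning_rate = 1e-4, batch_size = 65L,
               n_steps = n_steps, seed = seed, latent_dim = 64L,
               hidden_widths = c(3000L, 3000L))
}

#' @rdname build_chess_vae
#' @export
chess_desk_config <- function(seed = 1L, n_steps = 1200L, beta = 1e-4) {
  train_config(beta = beta, learning_rate = 2e-3, batch_size = 130L,
               n_steps = n_steps, seed = seed, latent_dim = 32L,
               hidden_widths = c(512L, 512L))
}
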