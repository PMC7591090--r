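#!/usr/bin/env Rscript
# Generate the synthetic corpora behind all analyses and write them to disk
# in their interchange formats: the LDA text corpus (JSONL + vocabulary) and
# the random-legal-play chess games (PGN).
#
# Everything downstream regenerates these in memory from the same seeds, so
# this script exists to inspect the raw materials, not as a dependency of the
# later steps.

library(semcomp)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## Text: a 6-topic LDA corpus over a 300-word artificial vocabulary.
## (Desk-scale rendition of the reference corpus: 1000 words, 10 topics,
## 20000 documents; concentrations of 0.1 on both Dirichlets are kept, which
## makes documents nearly single-topic and topics sparse.)
params <- lda_params(vocab_size = 300L, n_topics = 6L, n_docs = 4000L,
                     doc_length = 40L, seed = 7L)
corpus <- generate_lda_corpus(params)
cat(sprintf("LDA corpus: %d documents, %d-word vocabulary, %d tokens total\n",
            nrow(corpus$counts), length(corpus$vocab$words),
            sum(corpus$counts)))
cat(sprintf("words occurring >= %d times (scaled lure threshold): %d\n",
            scaled_drm_threshold(corpus$vocab),
            sum(corpus$vocab$counts >= scaled_drm_threshold(corpus$vocab))))

# a small excerpt is enough on disk; the full corpus is regenerated by seed
write_corpus_jsonl(corpus$counts[1:100, ], file.path(out_dir, "corpus_head.jsonl"),
                   vocab = corpus$vocab)
write_vocabulary(corpus$vocab, file.path(out_dir, "vocabulary.tsv"))

## Chess: 2000 games of uniformly random legal play (80-ply cap).
games <- generate_legal_games(2000L, max_plies = 80L, seed = 2024L)
plies <- vapply(games, function(g) g$n_plies, integer(1))
cat(sprintf("chess: %d games, %.1f plies on average, %d boards pooled\n",
            length(games), mean(plies), sum(plies)))
sanity <- vapply(games[1:50], function(g)
  all(apply(g$boards, 1, check_board_sanity)), logical(1))
cat(sprintf("structural legality on 50 spot-checked games: %s\n",
            if (all(sanity)) "all pass" else "FAILURES"))
write_pgn(games[1:20], file.path(out_dir, "games_head.pgn"))

cat("wrote", out_dir, "\n")
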