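#!/usr/bin/env Rscript
# The chess expertise analysis: train one board-memory model per skill level
# (fraction of the pooled game positions seen during learning) and score MAP
# reconstructions of held-out boards, in the game condition and with pieces
# shuffled across the occupied squares.
#
# Expected pattern (cf. the classic board-recall experiments): recall of game
# boards improves with experience, while shuffled boards stay hard at every
# skill level.

library(semcomp)

out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tab <- run_expertise(n_games = 2000L,
                     fractions = c(0.001, 0.01, 0.10, 0.90),
                     n_augment = 10000L,
                     seeds = 1:3,
                     config = chess_desk_config(),
                     data_seed = 2024L)

report(list(expertise = tab), out_dir)

agg <- aggregate(cbind(mean_pieces, mean_square_acc) ~ fraction + condition,
                 tab, mean)
cat("\nmean over 3 seeds:\n")
print(agg, digits = 3)

game <- agg[agg$condition == "game", ]
rand <- agg[agg$condition == "random", ]
cat(sprintf("\ngame-condition pieces, fraction 0.001 -> 0.9: %.2f -> %.2f\n",
            game$mean_pieces[game$fraction == 0.001],
            game$mean_pieces[game$fraction == 0.9]))
cat(sprintf("condition gap at fraction 0.9: game %.2f vs random %.2f pieces\n",
            game$mean_pieces[game$fraction == 0.9],
            rand$mean_pieces[rand$fraction == 0.9]))
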