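#!/usr/bin/env Rscript
# Step 2: sweep the parameter grid over every benchmark case.
#
# Grid: GOP {0.53, 1.03, 1.53, 2.03, 2.53} x GEP {0.123, 0.423, 0.723,
# 1.023} x {BLOSUM62, BLOSUM45, PAM200}, through the built-in progressive
# aligner. The grid deliberately contains the common default combination
# (BLOSUM62, GOP 1.53, GEP 0.123) so step 4 can compare against it. The
# sweep checkpoints to results/sweep.tsv and resumes if interrupted.

library(alnsweep)

cases <- load_benchmark(file.path("results", "benchmark"))
stopifnot(length(cases) > 0L)

grid <- expand.grid(matrix = c("BLOSUM62", "BLOSUM45", "PAM200"),
                    gop = c(0.53, 1.03, 1.53, 2.03, 2.53),
                    gep = c(0.123, 0.423, 0.723, 1.023),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
grid <- grid[order(match(grid$matrix, matrix_names()), grid$gop, grid$gep), ]
message(sprintf("sweeping %d cases x %d combinations = %d cells",
                length(cases), nrow(grid), length(cases) * nrow(grid)))

tab <- run_sweep(cases, grid, builtin_aligner(),
                 checkpoint = file.path("results", "sweep.tsv"), verbose = TRUE)
stopifnot(nrow(tab) == length(cases) * nrow(grid), all(tab$status == "OK"))
message(sprintf("done: %d cells, SPS range %.3f-%.3f; table in results/sweep.tsv",
                nrow(tab), min(tab$sps), max(tab$sps)))
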