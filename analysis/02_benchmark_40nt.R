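#!/usr/bin/env Rscript
# Benchmark the fitness-function panel on the 40nt puzzle set:
# 1000-step adaptive random walks, one per (puzzle, fitness), scored
# under the unique-MFE criterion.  Requires 01_generate_datasets.R.
#
# With the full panel this takes a few minutes; expect probability
# and ensemble defect near the top, free energy far behind with
# GC-rich final sequences.

suppressPackageStartupMessages(library(rnafitness))

n_puzzles <- 60L
master_seed <- 101L
panel <- c("prob", "ed", "fe", "fegc:0.5", "sd:BPD:average", "sd:HD:arbitrary",
           "sd:HD:average", "sd:HD:minimum")

backend <- vienna_backend()
ps <- read_puzzles("results/datasets/set40nt")
ps$targets <- ps$targets[seq_len(n_puzzles)]
ps$sources <- ps$sources[seq_len(n_puzzles)]

bm <- run_benchmark(ps, lapply(panel, parse_fitness_spec), backend,
                    steps = 1000, master_seed = master_seed)
print(bm)
write_results(bm$summary, "results/benchmark_40nt.tsv")
utils::write.csv(bm$records, "results/benchmark_40nt_records.csv",
                 row.names = FALSE)
write_metadata(run_metadata(backend, master_seed, n_puzzles = n_puzzles,
                            steps = 1000, panel = panel),
               "results/benchmark_40nt.meta.json")
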