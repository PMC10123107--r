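#!/usr/bin/env Rscript
# Benchmark on the harder 80nt and 120nt puzzle sets, where the
# fitness functions separate: probability stays strong while the
# others fall away.  Partition-function evaluations scale with the
# cube of the length, so the panel and puzzle counts are kept small;
# expect roughly 10 minutes.  Requires 01_generate_datasets.R.

suppressPackageStartupMessages(library(rnafitness))

backend <- vienna_backend()
master_seed <- 103L

run_one <- function(len, n_puzzles, panel) {
  ps <- read_puzzles(paste0("results/datasets/set", len, "nt"))
  ps$targets <- ps$targets[seq_len(n_puzzles)]
  ps$sources <- ps$sources[seq_len(n_puzzles)]
  bm <- run_benchmark(ps, lapply(panel, parse_fitness_spec), backend,
                      steps = 1000, master_seed = master_seed)
  message(len, "nt:")
  print(bm)
  out <- sprintf("results/benchmark_%snt.tsv", len)
  write_results(bm$summary, out)
  write_metadata(run_metadata(backend, master_seed, n_puzzles = n_puzzles,
                              steps = 1000, panel = panel),
                 paste0(out, ".meta.json"))
  bm
}

run_one(80, 24L, c("prob", "ed", "fe", "sd:HD:average"))
run_one(120, 16L, c("prob", "fe"))
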