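#!/usr/bin/env Rscript
# Rank analysis: how highly does each fitness function rank a known
# "true" structure among all suboptimal structures of its own
# sequence?  Curated natural collections (e.g. ArchiveII) are not
# bundled; point --dir at a directory of CT files to analyse real
# RNAs.  Without one, the script demonstrates the machinery on a
# SYNTHETIC stand-in: sequences whose designated true structure is
# drawn from a 2 kcal/mol suboptimal window (so it is plausible but
# usually not the MFE).
#
#   Rscript analysis/05_rank_structures.R [--dir path/to/ct_files]

suppressPackageStartupMessages(library(rnafitness))

args <- commandArgs(trailingOnly = TRUE)
ct_dir <- if (length(args) >= 2 && args[[1]] == "--dir") args[[2]] else NULL

backend <- vienna_backend()
master_seed <- 105L
specs <- c(prob = "prob", ed = "ed", sd = "sd:HD:average")
dir.create("results", showWarnings = FALSE)

if (is.null(ct_dir)) {
  message("no --dir given: using a synthetic stand-in collection")
  set.seed(master_seed)
  n_rna <- 20L
  inputs <- lapply(seq_len(n_rna), function(k) {
    ps <- generate_puzzles(1, 60, 2.0, backend)
    list(id = sprintf("synthetic_%02d", k), seq = ps$sources[[1]],
         structure = ps$targets[[1]])
  })
} else {
  files <- list.files(ct_dir, pattern = "\\.ct$", full.names = TRUE)
  message("reading ", length(files), " CT files from ", ct_dir)
  inputs <- lapply(files, read_ct)
}

all_rows <- list()
for (sp in names(specs)) {
  spec <- parse_fitness_spec(specs[[sp]])
  rows <- lapply(inputs, function(x) {
    r <- rank_true_structure(x$seq, x$structure, spec, backend,
                             min_structures = 5000, max_window = 10)
    cbind(data.frame(id = x$id, fitness = spec$label), r)
  })
  res <- do.call(rbind, rows)
  all_rows[[sp]] <- res
  curve <- cumulative_rank_curve(res)
  utils::write.csv(curve, sprintf("results/rank_curve_%s.csv", sp),
                   row.names = FALSE)
  kept <- res[!res$excluded, ]
  message(sprintf(
    "%-28s mean rank %5.1f%%  median %5.1f%%  (%d of %d included)",
    spec$label, 100 * mean(kept$percentile),
    100 * stats::median(kept$percentile), nrow(kept), nrow(res)))
}
write_results(do.call(rbind, all_rows), "results/rank_results.tsv")
write_metadata(run_metadata(backend, master_seed,
                            collection = if (is.null(ct_dir))
                              "synthetic stand-in" else ct_dir),
               "results/rank_results.meta.json")
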