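# Benchmark harness: one adaptive-walk run per (puzzle, fitness
# function), scored with the unique-MFE criterion, plus the
# natural-RNA ranking analysis (how highly a fitness function ranks a
# known true structure among all suboptimal structures of its own
# sequence).

#' Run the design benchmark
#'
#' For every fitness spec, runs one adaptive random walk per puzzle
#' (walks for one spec run in lockstep so backend evaluations are
#' batched).  Each puzzle has its own RNG seed derived from
#' `master_seed` by position, so results are bit-reproducible and
#' adding or removing a spec never perturbs the other specs' runs.
#'
#' @param ps a `puzzle_set` from [generate_puzzles()].
#' @param specs list of [fitness_spec()] objects.
#' @param backend thermodynamic backend.
#' @param steps walk budget per puzzle (default 1000).
#' @param seed_gc seed-sequence GC fraction (default 0.5).
#' @param master_seed integer master seed.
#' @param accept_equal walk acceptance policy, see
#'   [adaptive_random_walk()]; default strict improvement.
#' @return A `benchmark_result`: list with `summary` (one row per
#'   spec: `fitness`, `n_correct`, `correct_rate`, `mean_gc`,
#'   `unique_solver`) and `records` (one row per walk: `fitness`,
#'   `puzzle`, `solved`, `gc`, `accepted`, `rng_seed`).
#' @export
run_benchmark <- function(ps, specs, backend, steps = 1000, seed_gc = 0.5,
                          master_seed = 1, accept_equal = FALSE) {
  if (inherits(specs, "fitness_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, length(ps$targets) >= 1)
  W <- length(ps$targets)
  set.seed(master_seed)
  puzzle_seeds <- sample.int(.Machine$integer.max - 1L, W)
  labels <- vapply(specs, `[[`, character(1), "label")
  solved <- matrix(FALSE, W, length(specs), dimnames = list(NULL, labels))
  records <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    res <- arw_engine(ps$targets, specs[[s]], backend, steps, seed_gc,
                      puzzle_seeds, accept_equal = accept_equal)
    co <- be_coopt(backend, res$final)
    ok <- vapply(seq_len(W), function(w)
      length(co[[w]]) == 1L && identical(co[[w]][[1]], ps$targets[[w]]),
      logical(1))
    solved[, s] <- ok
    records[[s]] <- data.frame(
      fitness = labels[[s]], puzzle = seq_len(W), solved = ok,
      gc = vapply(res$final, gc_content, numeric(1), USE.NAMES = FALSE),
      accepted = res$accepted, rng_seed = puzzle_seeds,
      final_sequence = res$final, row.names = NULL)
  }
  only_one <- rowSums(solved) == 1L
  summary <- data.frame(
    fitness = labels,
    n_correct = colSums(solved),
    correct_rate = colSums(solved) / W,
    mean_gc = vapply(records, function(r) mean(r$gc), numeric(1)),
    unique_solver = colSums(solved & only_one),
    row.names = NULL)
  structure(list(summary = summary, records = do.call(rbind, records),
                 n_puzzles = W, steps = steps, seed_gc = seed_gc,
                 master_seed = master_seed,
                 backend_version = backend_version(backend)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>", x$n_puzzles, "puzzles,", x$steps, "steps,",
      x$backend_version, "\n")
  print(x$summary)
  invisible(x)
}

# fitness values for every enumerated structure of one fixed sequence
score_structures <- function(spec, seq, structures, energies, backend) {
  n <- nchar(seq)
  switch(spec$family,
    probability = {
      g <- be_ensemble_g(backend, seq)
      exp((g - energies) / be_rt(backend))
    },
    free_energy = -energies,
    free_energy_gc = stop("the GC penalty depends on the sequence, which is ",
                          "fixed here; rankings equal plain free energy"),
    ensemble_defect = {
      bpp <- be_bpp(backend, seq)
      1 - vapply(structures, function(s) defect_from_bpp(bpp, s),
                 numeric(1), USE.NAMES = FALSE) / n
    },
    structure_distance = {
      members <- be_coopt(backend, seq)[[1]]
      member_pms <- lapply(members, parse_dotbracket)
      d <- vapply(structures, function(s) {
        spm <- parse_dotbracket(s)
        ds <- vapply(member_pms, function(m)
          sd_distance(spec$distance, spm, db_string(m)), numeric(1))
        switch(spec$tiebreak, arbitrary = ds[[1]], average = mean(ds),
               minimum = min(ds))
      }, numeric(1), USE.NAMES = FALSE)
      if (spec$distance == "INF") 1 - d else n - d
    })
}

#' Rank a known true structure among its sequence's suboptimals
#'
#' Enumerates suboptimal structures of `seq` in a growing window
#' (starting at 0 kcal/mol, increased by `increment` until at least
#' `min_structures` structures are enumerated or the window exceeds
#' `max_window`), scores every structure with the fitness spec, sorts
#' best-first and locates the true structure.  When the true structure
#' is absent from the list, its closest enumerated structure by
#' base-pair distance stands in; if even that differs by more than
#' `exclude_frac` of the sequence length the RNA is excluded.  Ties
#' share the best (competition) rank.
#'
#' @param seq the natural sequence.
#' @param true_struct its known structure (dot-bracket or
#'   `rna_structure`).
#' @param spec fitness spec (probability, ensemble_defect or
#'   structure_distance; free energy ranks identically to
#'   probability on a fixed sequence).
#' @param backend thermodynamic backend.
#' @param min_structures window growth stops once this many structures
#'   are enumerated (paper-scale default 200000; reduce for desk use).
#' @param increment,max_window window schedule in kcal/mol.
#' @param exclude_frac exclusion threshold on the closest base-pair
#'   distance, as a fraction of sequence length.
#' @param max_enum hard enumeration cap passed to the backend.
#' @return A one-row data frame: `rank`, `list_size`, `percentile`,
#'   `excluded`, `closest_bpd`, `window`.
#' @export
rank_true_structure <- function(seq, true_struct, spec, backend,
                                min_structures = 200000, increment = 0.2,
                                max_window = 10, exclude_frac = 0.05,
                                max_enum = 1e6) {
  true_db <- db_string(as_structure(true_struct))
  stopifnot(nchar(seq) == nchar(true_db))
  window <- 0
  repeat {
    so <- be_subopt(backend, seq, window, max_enum)
    if (!so$complete || length(so$structures) >= min_structures ||
        window + increment > max_window)
      break
    window <- window + increment
  }
  structures <- so$structures
  energies <- so$energies
  k <- length(structures)
  true_pm <- parse_dotbracket(true_db)
  idx <- match(true_db, structures)
  closest_bpd <- 0L
  if (is.na(idx)) {
    bpds <- vapply(structures, function(s)
      base_pair_distance(true_pm, parse_dotbracket(s)), numeric(1),
      USE.NAMES = FALSE)
    idx <- which.min(bpds)
    closest_bpd <- as.integer(bpds[[idx]])
  }
  excluded <- closest_bpd > exclude_frac * nchar(seq)
  if (excluded) {
    return(data.frame(rank = NA_integer_, list_size = k,
                      percentile = NA_real_, excluded = TRUE,
                      closest_bpd = closest_bpd, window = window))
  }
  fit <- score_structures(spec, seq, structures, energies, backend)
  rank <- 1L + sum(fit > fit[[idx]])
  data.frame(rank = rank, list_size = k, percentile = rank / k,
             excluded = FALSE, closest_bpd = closest_bpd, window = window)
}

#' Cumulative rank curve
#'
#' For each percentile cutoff, counts the RNAs whose true structure
#' (or closest analog) was ranked at or under that percentile.
#'
#' @param results data frame of [rank_true_structure()] rows.
#' @param cutoffs percentile cutoffs in (0, 1].
#' @return Data frame with `cutoff` and `count`; non-decreasing,
#'   reaching the number of included RNAs at cutoff 1.
#' @export
cumulative_rank_curve <- function(results, cutoffs = seq(0.01, 1, by = 0.01)) {
  pct <- results$percentile[!results$excluded & !is.na(results$percentile)]
  data.frame(cutoff = cutoffs,
             count = vapply(cutoffs, function(ct) sum(pct <= ct), integer(1)))
}
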