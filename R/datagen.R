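# Synthetic design-puzzle generator.  A puzzle is a target structure
# drawn from the thermodynamically plausible neighbourhood of a
# random sequence: sample a uniform-random sequence, enumerate every
# suboptimal structure within a free-energy window T of its MFE, and
# keep one of them uniformly at random.  Duplicate targets are
# rejected dataset-wide by redrawing a fresh sequence, which preserves
# the per-sequence uniform target choice.

#' Uniform random RNA sequence
#'
#' Each base drawn i.i.d. uniformly over A, C, G, U; consumes the
#' session RNG.
#'
#' @param n sequence length (>= 1).
#' @return Sequence string of length `n`.
#' @export
random_sequence <- function(n) {
  stopifnot(n >= 1)
  decode_seq(sample.int(4L, n, replace = TRUE))
}

#' Generate a synthetic puzzle set
#'
#' @param count number of distinct target structures to collect.
#' @param n sequence/structure length in nucleotides.
#' @param window suboptimal free-energy window T in kcal/mol; targets
#'   are drawn uniformly from all structures within T of their source
#'   sequence's MFE (T = 0 draws a co-optimal MFE structure).
#' @param backend thermodynamic backend.
#' @param max_enum per-sequence enumeration cap; a sequence whose
#'   window holds more structures is skipped with a warning.
#' @param rng_seed optional seed for reproducible generation.
#' @return A `puzzle_set`: list with `targets` (dot-bracket strings,
#'   no duplicates), `sources` (the sequences they were drawn from),
#'   `n`, `window`, and generation metadata.
#' @export
generate_puzzles <- function(count, n, window, backend, max_enum = 1e6,
                             rng_seed = NULL) {
  stopifnot(count >= 1, window >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  targets <- character(0)
  sources <- character(0)
  seen <- new.env(parent = emptyenv())
  skipped <- 0L
  while (length(targets) < count) {
    src <- random_sequence(n)
    u <- runif(1)
    pick <- be_subopt_pick(backend, src, window, max_enum, u)
    if (isTRUE(pick$skipped)) {
      skipped <- skipped + 1L
      warning("suboptimal enumeration cap exceeded; sequence skipped",
              call. = FALSE)
      next
    }
    tgt <- pick$structure
    if (!is.null(seen[[tgt]])) next # duplicate target: redraw sequence
    seen[[tgt]] <- TRUE
    targets <- c(targets, tgt)
    sources <- c(sources, src)
  }
  structure(list(targets = targets, sources = sources, n = n,
                 window = window, rng_seed = rng_seed,
                 skipped = skipped,
                 backend_version = backend_version(backend)),
            class = "puzzle_set")
}

#' @export
print.puzzle_set <- function(x, ...) {
  cat("<puzzle_set>", length(x$targets), "targets of length", x$n,
      "(window", x$window, "kcal/mol)\n")
  invisible(x)
}

#' Aggregate motif statistics over a puzzle set
#'
#' Runs [motif_census()] on every target and aggregates: totals and
#' per-structure means of the motif counts, and the mean fraction of
#' paired nucleotides.
#'
#' @param ps a `puzzle_set` (or any list with a `targets` character
#'   vector).
#' @return A list with `n_structures`, `mean_paired_fraction`, and a
#'   data frame `motifs` with columns `motif`, `total`, `mean`.
#' @export
dataset_stats <- function(ps) {
  targets <- ps$targets
  stopifnot(length(targets) > 0)
  cens <- lapply(targets, motif_census)
  counts <- c("helix_count", "hairpin_loop_count", "bulge_loop_count",
              "internal_loop_count", "multiloop_count")
  totals <- vapply(counts, function(f)
    sum(vapply(cens, `[[`, numeric(1), f)), numeric(1))
  list(n_structures = length(targets),
       mean_paired_fraction =
         mean(vapply(cens, `[[`, numeric(1), "paired_fraction")),
       motifs = data.frame(motif = sub("_count$", "", counts),
                           total = as.integer(totals),
                           mean = totals / length(targets),
                           row.names = NULL))
}

#' Write a puzzle set to plain-text files
#'
#' Writes `<base>.db` (one dot-bracket target per line), `<base>.fasta`
#' (the source sequences) and `<base>.meta.json` (length, window, seed
#' and backend version, sufficient for exact regeneration).
#'
#' @param ps a `puzzle_set`.
#' @param base path prefix.
#' @return `base`, invisibly.
#' @export
write_puzzles <- function(ps, base) {
  writeLines(ps$targets, paste0(base, ".db"))
  write_fasta(sprintf("puzzle_%04d", seq_along(ps$sources)), ps$sources,
              paste0(base, ".fasta"))
  meta <- list(n = ps$n, window = ps$window, count = length(ps$targets),
               rng_seed = ps$rng_seed, backend = ps$backend_version,
               package = as.character(utils::packageVersion("rnafitness")))
  jsonlite::write_json(meta, paste0(base, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(base)
}

#' Read a puzzle set written by [write_puzzles()]
#'
#' @param base path prefix.
#' @return A `puzzle_set`.
#' @export
read_puzzles <- function(base) {
  targets <- readLines(paste0(base, ".db"))
  fa <- read_fasta(paste0(base, ".fasta"))
  meta <- jsonlite::read_json(paste0(base, ".meta.json"), simplifyVector = TRUE)
  structure(list(targets = targets, sources = fa$seq, n = meta$n,
                 window = meta$window, rng_seed = meta$rng_seed,
                 skipped = NA_integer_, backend_version = meta$backend),
            class = "puzzle_set")
}
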