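# Pluggable thermodynamic backends.  A backend supplies folding,
# free-energy evaluation, ensemble quantities and suboptimal
# enumeration; everything above it (fitness functions, the walk, the
# generators and evaluators) is backend-agnostic.  Sequences cross the
# backend boundary as plain character strings and structures as
# dot-bracket strings; energies are kcal/mol.

#' Free energies of target structures on candidate sequences
#'
#' @param backend a backend from [reference_backend()] or
#'   [vienna_backend()].
#' @param seqs character vector of sequences.
#' @param structs character vector of dot-bracket strings (recycled if
#'   length 1); each must be realizable with canonical pairs on the
#'   matching sequence.
#' @return Numeric vector of free energies in kcal/mol.
#' @export
be_energy <- function(backend, seqs, structs) UseMethod("be_energy")

#' Ensemble free energy -RT log Z of each sequence
#' @inheritParams be_energy
#' @return Numeric vector, kcal/mol.
#' @export
be_ensemble_g <- function(backend, seqs) UseMethod("be_ensemble_g")

#' Equilibrium probability P(t | p) of target structures
#' @inheritParams be_energy
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
be_prob <- function(backend, seqs, structs) UseMethod("be_prob")

#' Ensemble defect D(p, t): expected number of incorrect nucleotides
#' @inheritParams be_energy
#' @return Numeric vector in `[0, n]` (not normalized).
#' @export
be_defect <- function(backend, seqs, structs) UseMethod("be_defect")

#' Single MFE structure (the backend's arbitrary tie representative)
#' @inheritParams be_energy
#' @return List with `structures` (character) and `energies`.
#' @export
be_mfe <- function(backend, seqs) UseMethod("be_mfe")

#' Complete co-optimal MFE structure sets
#' @inheritParams be_energy
#' @return List (one element per sequence) of character vectors of
#'   dot-bracket strings, all attaining the MFE at the backend's
#'   energy resolution.
#' @export
be_coopt <- function(backend, seqs) UseMethod("be_coopt")

#' All suboptimal structures within an energy window
#' @inheritParams be_energy
#' @param seq a single sequence.
#' @param window window above the MFE, kcal/mol.
#' @param max_count enumeration cap; when exceeded the result is
#'   flagged incomplete.
#' @return List with `structures`, `energies`, `complete`.
#' @export
be_subopt <- function(backend, seq, window, max_count = 1e6) UseMethod("be_subopt")

#' Count suboptimal structures and pick one uniformly
#'
#' Used by the puzzle generator: enumerates the window, reports the
#' count, and returns the structure at index `floor(u * count)` so the
#' choice is driven by a uniform deviate from the caller's RNG.
#'
#' @inheritParams be_subopt
#' @param u uniform deviate in `[0, 1)`.
#' @return List with `count`, `structure` and `skipped` (TRUE when the
#'   cap was exceeded).
#' @export
be_subopt_pick <- function(backend, seq, window, max_count, u)
  UseMethod("be_subopt_pick")

#' @export
be_subopt_pick.default <- function(backend, seq, window, max_count, u) {
  so <- be_subopt(backend, seq, window, max_count)
  if (!isTRUE(so$complete))
    return(list(count = NA_integer_, structure = NA_character_, skipped = TRUE))
  k <- length(so$structures)
  idx <- min(floor(u * k) + 1L, k)
  list(count = k, structure = so$structures[[idx]], skipped = FALSE)
}

#' Base-pair probability matrix of one sequence
#' @inheritParams be_subopt
#' @return Symmetric n x n numeric matrix.
#' @export
be_bpp <- function(backend, seq) UseMethod("be_bpp")

#' Thermal energy RT used by a backend (kcal/mol)
#' @inheritParams be_energy
#' @export
be_rt <- function(backend) UseMethod("be_rt")

#' Backend identification string for run metadata
#' @inheritParams be_energy
#' @export
backend_version <- function(backend) UseMethod("backend_version")

#' Fold a sequence, retaining the complete co-optimal set
#'
#' @inheritParams be_subopt
#' @return List with `mfe_energy` (kcal/mol), `cooptimal_structures`
#'   (character vector of dot-bracket strings) and `is_unique`.
#' @export
fold <- function(backend, seq) {
  co <- be_coopt(backend, seq)[[1]]
  list(mfe_energy = be_energy(backend, seq, co[[1]]),
       cooptimal_structures = co,
       is_unique = length(co) == 1L)
}

#' Unique-MFE correctness criterion for a design
#'
#' A sequence is a correct design for a target iff the target is its
#' single, untied minimum free energy structure.  Ties disqualify.
#'
#' @inheritParams be_subopt
#' @param target target structure (dot-bracket or `rna_structure`).
#' @return Logical scalar.
#' @export
is_correct_design <- function(backend, seq, target) {
  co <- be_coopt(backend, seq)[[1]]
  length(co) == 1L && identical(co[[1]], db_string(target))
}
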