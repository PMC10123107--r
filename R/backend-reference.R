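# Self-contained reference energy model.  Nested canonical pairs
# only; the energy of a structure is the sum of stacking terms (one
# value per pair-class combination: strong GC/CG, weak AU/UA, and any
# wobble-containing stack) plus a constant penalty per hairpin, bulge,
# internal loop and multiloop.  Energies are exact centi-kcal
# integers, so co-optimality (tie detection) is exact.  Parameters are
# chosen so that minimum-energy structures are non-trivial from about
# a dozen nucleotides: two strong stacks outweigh one hairpin penalty,
# two weak ones do not.

#' Parameters of the reference energy model
#'
#' @param hairpin,bulge,internal,multiloop constant loop penalties in
#'   centi-kcal/mol.
#' @param stack_strong stacking term when both pairs are GC or CG.
#' @param stack_mixed stacking term for one strong and one weak pair.
#' @param stack_weak stacking term when both pairs are AU or UA.
#' @param stack_wobble stacking term when either pair is GU or UG.
#' @param min_hairpin minimum unpaired positions in a hairpin loop.
#' @param rt thermal energy in kcal/mol (default 0.61633, i.e. 310.15 K,
#'   matching the ViennaRNA default temperature).
#' @return Parameter list consumed by [reference_backend()].
#' @export
ref_params <- function(hairpin = 450L, bulge = 380L, internal = 230L,
                       multiloop = 440L, stack_strong = -330L,
                       stack_mixed = -210L, stack_weak = -110L,
                       stack_wobble = -50L, min_hairpin = 3L,
                       rt = 0.61633) {
  strong <- c(3L, 4L); wobble <- c(5L, 6L)
  stack <- matrix(stack_mixed, 6, 6)
  stack[strong, strong] <- stack_strong
  stack[-c(strong, wobble), -c(strong, wobble)] <- stack_weak
  stack[wobble, ] <- stack_wobble
  stack[, wobble] <- stack_wobble
  list(stack = stack, hairpin = as.integer(hairpin),
       bulge = as.integer(bulge), internal = as.integer(internal),
       multiloop = as.integer(multiloop),
       min_hairpin = as.integer(min_hairpin), rt = rt)
}

#' Reference-model backend
#'
#' @param params model parameters from [ref_params()].
#' @return A backend usable with all `be_*` operations, [fold()],
#'   [adaptive_random_walk()], [generate_puzzles()] and
#'   [run_benchmark()].
#' @export
reference_backend <- function(params = ref_params()) {
  structure(list(name = "reference", params = params),
            class = c("reference_backend", "rna_backend"))
}

#' @export
be_rt.reference_backend <- function(backend) backend$params$rt

#' @export
backend_version.reference_backend <- function(backend)
  paste0("rnafitness reference model ",
         as.character(utils::packageVersion("rnafitness")))

#' @export
be_energy.reference_backend <- function(backend, seqs, structs) {
  if (length(structs) == 1L) structs <- rep(structs, length(seqs))
  stopifnot(length(seqs) == length(structs))
  vapply(seq_along(seqs), function(k) {
    .rf_energy(encode_seq(seqs[[k]]),
               unclass(as_structure(structs[[k]])),
               backend$params) / 100
  }, numeric(1))
}

#' @export
be_ensemble_g.reference_backend <- function(backend, seqs) {
  vapply(seqs, function(s) {
    -backend$params$rt * .rf_pf(encode_seq(s), backend$params, FALSE)$log_z
  }, numeric(1), USE.NAMES = FALSE)
}

#' @export
be_prob.reference_backend <- function(backend, seqs, structs) {
  e <- be_energy(backend, seqs, structs)
  g <- be_ensemble_g(backend, seqs)
  exp((g - e) / backend$params$rt)
}

#' @export
be_bpp.reference_backend <- function(backend, seq) {
  .rf_pf(encode_seq(seq), backend$params, TRUE)$bpp
}

#' @export
be_defect.reference_backend <- function(backend, seqs, structs) {
  if (length(structs) == 1L) structs <- rep(structs, length(seqs))
  vapply(seq_along(seqs), function(k) {
    defect_from_bpp(be_bpp(backend, seqs[[k]]), structs[[k]])
  }, numeric(1))
}

#' Ensemble defect from a base-pair probability matrix
#'
#' D(p, t) = n - sum over target pairs (i,j) of 2 P(i pairs j)
#'             - sum over target-unpaired i of P(i unpaired),
#' with P(i unpaired) = 1 - sum_j P(i pairs j).  This is the
#' probability-weighted expected number of nucleotides whose pairing
#' status differs from the target, computed without enumerating the
#' ensemble.
#'
#' @param bpp symmetric base-pair probability matrix.
#' @param target target structure.
#' @return Defect in `[0, n]`.
#' @export
defect_from_bpp <- function(bpp, target) {
  pm <- unclass(as_structure(target))
  n <- length(pm)
  stopifnot(nrow(bpp) == n)
  p_unpaired <- 1 - rowSums(bpp)
  prs <- structure_pairs(pm)
  paired_term <- if (ncol(prs) > 0) sum(2 * bpp[t(prs)]) else 0
  n - paired_term - sum(p_unpaired[pm == seq_len(n)])
}

#' @export
be_mfe.reference_backend <- function(backend, seqs) {
  co <- be_coopt(backend, seqs)
  list(structures = vapply(co, `[[`, character(1), 1L),
       energies = vapply(seqs, function(s)
         .rf_mfe(encode_seq(s), backend$params) / 100, numeric(1),
         USE.NAMES = FALSE))
}

#' @export
be_coopt.reference_backend <- function(backend, seqs) {
  lapply(seqs, function(s) {
    so <- .rf_subopt(encode_seq(s), backend$params, 0L, 1e6)
    vapply(so$pair_maps, function(pm) db_string(new_structure(pm)),
           character(1))
  })
}

#' @export
be_subopt.reference_backend <- function(backend, seq, window, max_count = 1e6) {
  delta <- as.integer(round(window * 100))
  so <- .rf_subopt(encode_seq(seq), backend$params, delta,
                   as.integer(max_count))
  ord <- order(so$energies)
  list(structures = vapply(so$pair_maps[ord], function(pm)
         db_string(new_structure(pm)), character(1)),
       energies = so$energies[ord] / 100,
       complete = isTRUE(so$complete))
}
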