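# The fitness-function families compared by the benchmark, evaluated
# uniformly as "higher is better" over a (candidate sequence, target
# structure) pair.

FITNESS_FAMILIES <- c("probability", "free_energy", "free_energy_gc",
                      "ensemble_defect", "structure_distance")
SD_DISTANCES <- c("BPD", "HD", "INF")
SD_TIEBREAKS <- c("arbitrary", "average", "minimum")

#' Specify a fitness function
#'
#' @param family one of `"probability"` (P(t|p)), `"free_energy"`
#'   (-dG of the target on the candidate), `"free_energy_gc"`
#'   (free energy with an exponential penalty on GC content above
#'   `gc_target`), `"ensemble_defect"` (1 - D(p,t)/n) or
#'   `"structure_distance"` (similarity between the target and the
#'   candidate's MFE structure(s)).
#' @param distance for `structure_distance`: `"BPD"` (base-pair
#'   distance), `"HD"` (structural Hamming distance) or `"INF"`
#'   (Matthews correlation of base pairs).
#' @param tiebreak for `structure_distance`, how co-optimal MFE ties
#'   are resolved: `"arbitrary"` (the backend's single returned
#'   structure), `"average"` (mean distance over all co-optimals) or
#'   `"minimum"` (best-case distance).
#' @param gc_target for `free_energy_gc`: target GC fraction g
#'   (default 0.5).
#' @return A `fitness_spec`.
#' @export
fitness_spec <- function(family, distance = NULL, tiebreak = NULL,
                         gc_target = 0.5) {
  family <- match.arg(family, FITNESS_FAMILIES)
  if (family == "structure_distance") {
    distance <- match.arg(distance, SD_DISTANCES)
    tiebreak <- match.arg(tiebreak, SD_TIEBREAKS)
  } else {
    if (!is.null(distance) || !is.null(tiebreak))
      stop("distance/tiebreak apply only to structure_distance")
  }
  if (family == "free_energy_gc") {
    stopifnot(gc_target > 0, gc_target < 1)
  }
  label <- switch(family,
    probability = "probability",
    free_energy = "free_energy",
    free_energy_gc = sprintf("free_energy_gc(g=%.2f)", gc_target),
    ensemble_defect = "ensemble_defect",
    structure_distance = sprintf("structure_distance(%s;%s)", distance,
                                 tiebreak))
  structure(list(family = family, distance = distance,
                 tiebreak = tiebreak, gc_target = gc_target,
                 label = label),
            class = "fitness_spec")
}

#' @export
print.fitness_spec <- function(x, ...) {
  cat("<fitness_spec>", x$label, "\n")
  invisible(x)
}

#' Parse a compact fitness-spec string
#'
#' Accepted forms: `"prob"`, `"fe"`, `"fegc"` or `"fegc:0.5"`, `"ed"`,
#' and `"sd:HD:average"` (distance in BPD/HD/INF, tiebreak in
#' arbitrary/average/minimum).
#'
#' @param text spec string.
#' @return A [fitness_spec()].
#' @export
parse_fitness_spec <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  switch(parts[1],
    prob = fitness_spec("probability"),
    fe = fitness_spec("free_energy"),
    fegc = fitness_spec("free_energy_gc",
                        gc_target = if (length(parts) > 1)
                          as.numeric(parts[2]) else 0.5),
    ed = fitness_spec("ensemble_defect"),
    sd = {
      if (length(parts) != 3) stop("structure distance spec needs sd:<dist>:<tiebreak>")
      fitness_spec("structure_distance", distance = parts[2],
                   tiebreak = parts[3])
    },
    stop("unknown fitness spec '", text, "'"))
}

# distance between a target pair map and one folded structure, per the
# configured measure; INF is converted to a distance as 1 - score
sd_distance <- function(measure, target_pm, folded_db) {
  folded <- parse_dotbracket(folded_db)
  switch(measure,
    BPD = base_pair_distance(target_pm, folded),
    HD = hamming_distance(target_pm, folded),
    INF = 1 - inf_score(folded, target_pm))
}

#' Evaluate fitness for a batch of candidates
#'
#' Vectorized core used by the walk engine: element k of `seqs` is
#' scored against element k of `targets`.
#'
#' @param spec a [fitness_spec()].
#' @param seqs character vector of candidate sequences.
#' @param targets character vector of dot-bracket targets (recycled if
#'   length 1).
#' @param backend thermodynamic backend.
#' @return Numeric vector of fitness values (higher is better).
#' @export
fitness_batch <- function(spec, seqs, targets, backend) {
  if (length(targets) == 1L) targets <- rep(targets, length(seqs))
  stopifnot(length(seqs) == length(targets))
  n <- nchar(targets)
  switch(spec$family,
    probability = be_prob(backend, seqs, targets),
    free_energy = -be_energy(backend, seqs, targets),
    free_energy_gc = {
      e <- be_energy(backend, seqs, targets)
      ghat <- vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE)
      penalty <- 10 * (exp(pmax(0, ghat - spec$gc_target)) - 1) /
        (exp(1) - 1) * abs(e)
      -e - penalty
    },
    ensemble_defect = 1 - be_defect(backend, seqs, targets) / n,
    structure_distance = {
      folded <- if (spec$tiebreak == "arbitrary") {
        lapply(be_mfe(backend, seqs)$structures, identity)
      } else {
        be_coopt(backend, seqs)
      }
      d <- vapply(seq_along(seqs), function(k) {
        tpm <- parse_dotbracket(targets[[k]])
        ds <- vapply(folded[[k]], function(f)
          sd_distance(spec$distance, tpm, f), numeric(1))
        switch(spec$tiebreak, arbitrary = ds[[1]], average = mean(ds),
               minimum = min(ds))
      }, numeric(1))
      if (spec$distance == "INF") 1 - d else n - d
    })
}

#' Evaluate fitness of a single candidate
#'
#' @inheritParams fitness_batch
#' @param seq candidate sequence.
#' @param target target structure (dot-bracket or `rna_structure`).
#' @return Scalar fitness value.
#' @export
evaluate_fitness <- function(spec, seq, target, backend) {
  fitness_batch(spec, seq, db_string(as_structure(target)), backend)[[1]]
}
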