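# Brute-force oracles, independent of the package's DP code paths:
# exhaustive enumeration of all nested structures, a from-scratch
# loop-decomposition energy evaluator, and Boltzmann sums over the
# enumerated ensemble.  Only usable at small n; that is the point.

# All nested pair sets on 1..n with >= min_hp unpaired inside every
# hairpin, as 2 x k pair matrices.  Memoized per (n, min_hp).
.enum_cache <- new.env(parent = emptyenv())

enum_pair_sets <- function(n, min_hp = 3) {
  key <- paste(n, min_hp)
  if (!is.null(.enum_cache[[key]])) return(.enum_cache[[key]])
  if (n <= 0) {
    res <- list(matrix(integer(0), 2, 0))
  } else {
    res <- list()
    # position 1 unpaired
    for (s in enum_pair_sets(n - 1, min_hp)) res[[length(res) + 1]] <- s + 1L
    # position 1 paired to j
    for (j in seq_len(n)) {
      if (j - 2 < min_hp) next
      inner <- enum_pair_sets(j - 2, min_hp)
      outer <- enum_pair_sets(n - j, min_hp)
      for (si in inner) for (so in outer) {
        res[[length(res) + 1]] <- cbind(c(1L, j), si + 1L, so + j)
      }
    }
  }
  .enum_cache[[key]] <- res
  res
}

pairs_to_pm <- function(prs, n) {
  pm <- seq_len(n)
  if (ncol(prs) > 0) {
    pm[prs[1, ]] <- prs[2, ]
    pm[prs[2, ]] <- prs[1, ]
  }
  pm
}

oracle_canonical <- function(codes, prs) {
  if (ncol(prs) == 0) return(TRUE)
  all(rnafitness:::PAIR_TYPES[cbind(codes[prs[1, ]], codes[prs[2, ]])] > 0)
}

# every structure realizable by `seq` under the reference rules
oracle_structures <- function(seq, min_hp = 3) {
  codes <- rnafitness:::encode_seq(seq)
  n <- length(codes)
  sets <- Filter(function(p) oracle_canonical(codes, p), enum_pair_sets(n, min_hp))
  lapply(sets, pairs_to_pm, n = n)
}

# from-scratch reference-model energy: walk the loop tree rooted at
# the exterior, classifying each closed loop by its branch count and
# gap pattern
oracle_energy <- function(seq, pm, par = ref_params()) {
  codes <- rnafitness:::encode_seq(seq)
  n <- length(pm)
  children <- function(a, b) { # branch openers strictly inside [a, b]
    out <- integer(0)
    k <- a
    while (k <= b) {
      if (pm[k] > k) { out <- c(out, k); k <- pm[k] + 1L } else k <- k + 1L
    }
    out
  }
  score_pair <- function(i, j) {
    pt_out <- rnafitness:::PAIR_TYPES[codes[i], codes[j]]
    stopifnot(pt_out > 0)
    br <- children(i + 1L, j - 1L)
    e <- if (length(br) == 0) {
      par$hairpin
    } else if (length(br) == 1) {
      k <- br[[1]]; l <- pm[k]
      pt_in <- rnafitness:::PAIR_TYPES[codes[k], codes[l]]
      if (k == i + 1L && l == j - 1L) par$stack[pt_out, pt_in]
      else if (k == i + 1L || l == j - 1L) par$bulge
      else par$internal
    } else {
      par$multiloop
    }
    e + sum(vapply(br, function(k) score_pair(k, pm[k]), numeric(1)))
  }
  sum(vapply(children(1L, n), function(k) score_pair(k, pm[k]), numeric(1)))
}

oracle_boltzmann <- function(seq, par = ref_params()) {
  pms <- oracle_structures(seq, par$min_hairpin)
  e <- vapply(pms, function(pm) oracle_energy(seq, pm, par), numeric(1))
  w <- exp(-e / (100 * par$rt))
  list(pair_maps = pms, energies = e, weights = w, Z = sum(w),
       probs = w / sum(w))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# random valid structure (uniform over the enumerated set, small n)
random_structure_db <- function(n, min_hp = 3) {
  sets <- enum_pair_sets(n, min_hp)
  db_string(rnafitness:::new_structure(
    pairs_to_pm(sets[[sample.int(length(sets), 1)]], n)))
}
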