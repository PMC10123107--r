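#' @useDynLib rnafitness, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif setNames
#' @importFrom utils head modifyList
NULL

RNA_BASES <- c("A", "C", "G", "U")

# canonical pair types, indexed 1..6: AU UA GC CG GU UG
PAIR_TYPES <- matrix(0L, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
PAIR_TYPES["A", "U"] <- 1L
PAIR_TYPES["U", "A"] <- 2L
PAIR_TYPES["G", "C"] <- 3L
PAIR_TYPES["C", "G"] <- 4L
PAIR_TYPES["G", "U"] <- 5L
PAIR_TYPES["U", "G"] <- 6L

# the 6 canonical ordered pairs as base codes (A=1,C=2,G=3,U=4), one
# column per pair type
PAIR_BASES <- matrix(c(1L, 4L,  4L, 1L,  3L, 2L,  2L, 3L,  3L, 4L,  4L, 3L), 2, 6)

encode_seq <- function(seq) {
  if (length(seq) == 1L && is.character(seq)) {
    codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], RNA_BASES)
    if (anyNA(codes)) {
      bad <- which(is.na(codes))[1]
      stop("invalid base at position ", bad, "; alphabet is A, C, G, U")
    }
    codes
  } else {
    as.integer(seq)
  }
}

decode_seq <- function(codes) paste(RNA_BASES[codes], collapse = "")

#' GC content of an RNA sequence
#'
#' @param seq a character string over the alphabet A, C, G, U.
#' @return Fraction of bases that are G or C, in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  codes <- encode_seq(seq)
  mean(codes == 2L | codes == 3L)
}

#' Parse a dot-bracket string into a secondary structure
#'
#' A secondary structure of length n is stored as an integer pair map
#' `pm` with `pm[i] == j` when positions i and j are paired and
#' `pm[i] == i` when i is unpaired (1-based).  Only the plain Vienna
#' dialect is accepted: '.', '(' and ')'.
#'
#' @param text a dot-bracket string.
#' @return An object of class `rna_structure` (an integer pair map).
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad) > 0)
    stop("invalid character '", ch[bad[1]], "' at position ", bad[1])
  n <- length(ch)
  pm <- seq_len(n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (length(open) == 0)
        stop("unbalanced ')' at position ", i)
      j <- open[length(open)]
      open <- open[-length(open)]
      pm[j] <- i
      pm[i] <- j
    }
  }
  if (length(open) > 0)
    stop("unbalanced '(' at position ", open[1])
  new_structure(pm)
}

new_structure <- function(pm) {
  pm <- as.integer(pm)
  class(pm) <- "rna_structure"
  pm
}

#' Coerce to an `rna_structure`
#'
#' @param x a dot-bracket string, an integer pair map, or an
#'   `rna_structure`.
#' @return An `rna_structure`.
#' @export
as_structure <- function(x) {
  if (inherits(x, "rna_structure")) return(x)
  if (is.character(x)) return(parse_dotbracket(x))
  new_structure(x)
}

#' Serialize a structure to dot-bracket notation
#'
#' @param s an `rna_structure` (or anything [as_structure()] accepts).
#' @return A dot-bracket string; round-trips with [parse_dotbracket()].
#' @export
db_string <- function(s) {
  pm <- unclass(as_structure(s))
  n <- length(pm)
  ch <- rep(".", n)
  ch[pm > seq_len(n)] <- "("
  ch[pm < seq_len(n)] <- ")"
  paste(ch, collapse = "")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> n =", length(x), "\n", db_string(x), "\n")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) db_string(x)

# matrix with one column per pair (i < j); 0 columns when unpaired
structure_pairs <- function(s) {
  pm <- unclass(as_structure(s))
  i <- which(pm > seq_along(pm))
  rbind(i, pm[i], deparse.level = 0)
}

#' Validate secondary-structure invariants
#'
#' Checks symmetry of the pair map, proper nesting (no crossing
#' pairs) and the minimum hairpin size.
#'
#' @param s structure to validate.
#' @param min_hairpin minimum number of unpaired positions enclosed by
#'   a hairpin-closing pair (default 3, the usual convention of
#'   nearest-neighbor implementations).
#' @return `s`, invisibly; errors describe the first violation.
#' @export
validate_structure <- function(s, min_hairpin = 3L) {
  pm <- unclass(as_structure(s))
  n <- length(pm)
  if (n < 1) stop("structure must have length >= 1")
  if (any(pm < 1L | pm > n)) stop("pair map index out of range")
  if (any(pm[pm] != seq_len(n))) stop("pair map is not symmetric")
  prs <- structure_pairs(pm)
  if (ncol(prs) > 0) {
    if (any(prs[2, ] - prs[1, ] - 1L < min_hairpin)) {
      k <- which(prs[2, ] - prs[1, ] - 1L < min_hairpin)[1]
      stop("pair (", prs[1, k], ", ", prs[2, k], ") encloses fewer than ",
           min_hairpin, " positions")
    }
    # crossing check via bracket matching on the serialized form
    ok <- tryCatch({
      parse_dotbracket(db_string(pm)); TRUE
    }, error = function(e) FALSE)
    if (!ok || !identical(unclass(parse_dotbracket(db_string(pm))), pm))
      stop("structure contains crossing (pseudoknotted) pairs")
  }
  invisible(as_structure(pm))
}

check_same_length <- function(s1, s2) {
  if (length(s1) != length(s2))
    stop("structures have different lengths (", length(s1), " vs ",
         length(s2), ")")
}

#' Base-pair distance between two structures
#'
#' The number of base pairs present in exactly one of the two
#' structures (the size of the symmetric difference of their pair
#' sets).
#'
#' @param s1,s2 structures of equal length.
#' @return Non-negative integer count.
#' @export
base_pair_distance <- function(s1, s2) {
  p1 <- unclass(as_structure(s1))
  p2 <- unclass(as_structure(s2))
  check_same_length(p1, p2)
  i <- seq_along(p1)
  # count each differing paired position once per pair (i < partner)
  d1 <- sum(p1 > i & p1 != p2)
  d2 <- sum(p2 > i & p2 != p1)
  as.integer(d1 + d2)
}

#' Structural Hamming distance
#'
#' The number of positions whose pairing partner differs between the
#' two structures, under the convention that an unpaired position is
#' its own partner.  This is the "number of incorrect nucleotides"
#' distance that the ensemble defect averages over the ensemble.
#'
#' @inheritParams base_pair_distance
#' @return Integer in `[0, n]`.
#' @export
hamming_distance <- function(s1, s2) {
  p1 <- unclass(as_structure(s1))
  p2 <- unclass(as_structure(s2))
  check_same_length(p1, p2)
  sum(p1 != p2)
}

#' Interaction network fidelity (Matthews correlation of base pairs)
#'
#' Treats every candidate pair (i, j), i < j, as a binary
#' classification instance and returns the Matthews correlation
#' coefficient of the predicted against the true pair set.
#'
#' @param pred predicted structure.
#' @param truth reference structure of the same length.
#' @return Score in `[-1, 1]`; 1 for identical non-empty structures.
#'   When the MCC denominator is zero (e.g. both structures empty) the
#'   convention is to return 0 with a warning, which keeps
#'   distance-based fitness finite on degenerate targets.
#' @export
inf_score <- function(pred, truth) {
  p1 <- unclass(as_structure(pred))
  p2 <- unclass(as_structure(truth))
  check_same_length(p1, p2)
  n <- length(p1)
  i <- seq_len(n)
  npairs1 <- sum(p1 > i)
  npairs2 <- sum(p2 > i)
  tp <- sum(p1 > i & p1 == p2)
  fp <- npairs1 - tp
  fn <- npairs2 - tp
  total <- n * (n - 1) / 2
  tn <- total - tp - fp - fn
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    warning("MCC denominator is zero; returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Motif census of a secondary structure
#'
#' Decomposes a structure into helices (maximal runs of consecutive
#' stacked pairs) and loops, classified by the number of helices they
#' enclose: hairpin loops (0), bulge loops (1, unpaired positions on
#' exactly one side), internal loops (1, unpaired on both sides) and
#' multiloops (2 or more).  The exterior loop is not counted.
#'
#' @param s a structure.
#' @return A list with `paired_fraction`, `helix_count`,
#'   `hairpin_loop_count`, `bulge_loop_count`, `internal_loop_count`
#'   and `multiloop_count`.
#' @export
motif_census <- function(s) {
  pm <- unclass(as_structure(s))
  n <- length(pm)
  prs <- structure_pairs(pm)
  np <- ncol(prs)
  res <- list(paired_fraction = 2 * np / n, helix_count = 0L,
              hairpin_loop_count = 0L, bulge_loop_count = 0L,
              internal_loop_count = 0L, multiloop_count = 0L)
  if (np == 0) return(res)
  has_pair <- function(i, j) i >= 1 && j <= n && pm[i] == j && i < j
  for (k in seq_len(np)) {
    i <- prs[1, k]; j <- prs[2, k]
    # helix outermost pair: (i-1, j+1) is not stacked outside
    if (!has_pair(i - 1L, j + 1L))
      res$helix_count <- res$helix_count + 1L
    # classify the loop closed by (i, j)
    branches <- 0L
    first_k <- NA_integer_; first_l <- NA_integer_
    pos <- i + 1L
    while (pos < j) {
      if (pm[pos] > pos) {
        if (branches == 0L) { first_k <- pos; first_l <- pm[pos] }
        branches <- branches + 1L
        pos <- pm[pos] + 1L
      } else pos <- pos + 1L
    }
    if (branches == 0L) {
      res$hairpin_loop_count <- res$hairpin_loop_count + 1L
    } else if (branches == 1L) {
      left <- first_k - i - 1L
      right <- j - first_l - 1L
      if (left == 0L && right == 0L) {
        # stacked pair, interior of a helix: no loop
      } else if (left == 0L || right == 0L) {
        res$bulge_loop_count <- res$bulge_loop_count + 1L
      } else {
        res$internal_loop_count <- res$internal_loop_count + 1L
      }
    } else {
      res$multiloop_count <- res$multiloop_count + 1L
    }
  }
  res
}
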