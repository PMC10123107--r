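test_that("dot-bracket parsing, serialization and errors", {
  expect_equal(unclass(parse_dotbracket("....")), 1:4)
  s <- parse_dotbracket("((...))")
  expect_equal(unclass(s), c(7L, 6L, 3L, 4L, 5L, 2L, 1L))
  expect_error(parse_dotbracket("((...)"), "position 1")
  expect_error(parse_dotbracket("...)"), "position 4")
  expect_error(parse_dotbracket("(x)"), "position 2")

  set.seed(11)
  for (k in 1:1000) {
    n <- sample(5:14, 1)
    db <- random_structure_db(n)
    expect_identical(db_string(parse_dotbracket(db)), db)
  }
})

test_that("structure validation catches broken invariants", {
  expect_silent(validate_structure("((...))"))
  expect_error(validate_structure(rnafitness:::new_structure(c(2L, 1L, 3L, 4L, 5L))),
               "encloses fewer")
  bad <- c(3L, 5L, 1L, 4L, 2L) # crossing pairs (1,3),(2,5)
  expect_error(validate_structure(rnafitness:::new_structure(bad)), "crossing|encloses")
})

test_that("base pair distance is the pair-set symmetric difference", {
  expect_equal(base_pair_distance("((...))", "((...))"), 0)
  expect_equal(base_pair_distance("((...))", "......."), 2)
  expect_equal(base_pair_distance("((...))", ".(...)."), 1)
  expect_error(base_pair_distance("((...))", "...."), "length")

  # independent oracle: explicit pair-set enumeration
  sym_diff <- function(a, b) {
    pa <- apply(rnafitness:::structure_pairs(parse_dotbracket(a)), 2, paste,
                collapse = ",")
    pb <- apply(rnafitness:::structure_pairs(parse_dotbracket(b)), 2, paste,
                collapse = ",")
    length(setdiff(pa, pb)) + length(setdiff(pb, pa))
  }
  set.seed(3)
  for (k in 1:50) {
    a <- random_structure_db(12)
    b <- random_structure_db(12)
    expect_equal(base_pair_distance(a, b), sym_diff(a, b))
  }
})

test_that("base pair distance is a metric on all structures of length <= 9", {
  all_db <- vapply(enum_pair_sets(9),
                   function(p) db_string(rnafitness:::new_structure(pairs_to_pm(p, 9))),
                   character(1))
  m <- length(all_db)
  d <- matrix(0L, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    d[i, j] <- base_pair_distance(all_db[[i]], all_db[[j]])
  expect_true(all(d == t(d)))
  expect_true(all((d == 0) == diag(m)))
  for (k in seq_len(m)) # triangle inequality through every midpoint k

    expect_true(all(d <= outer(d[, k], d[k, ], `+`)))
})

test_that("Hamming distance counts differing partner entries", {
  expect_equal(hamming_distance("((...))", "((...))"), 0)
  expect_equal(hamming_distance("((...))", "......."), 4)
  set.seed(4)
  for (k in 1:50) {
    a <- random_structure_db(11); b <- random_structure_db(11)
    expect_lte(hamming_distance(a, b), 11)
    # each pair in the symmetric difference moves at most 2 positions
    expect_lte(hamming_distance(a, b), 2 * base_pair_distance(a, b))
  }
})

test_that("INF score is the Matthews correlation over candidate pairs", {
  expect_equal(inf_score("((...))", "((...))"), 1)
  # disjoint pair sets: no true positives, non-positive correlation
  expect_lte(inf_score("((...))...", "...((...))"), 0)
  # brute-force confusion matrix: pred ((...)) pairs {(1,7),(2,6)},
  # truth .(...). pair {(2,6)} -> TP=1 FP=1 FN=0 TN=19 over 21 candidates
  expect_equal(inf_score("((...))", ".(...)."),
               (1 * 19 - 1 * 0) / sqrt(2 * 1 * 20 * 19))
  expect_warning(v <- inf_score(".......", "......."), "denominator")
  expect_equal(v, 0)

  mcc_oracle <- function(pred, truth) {
    pp <- rnafitness:::structure_pairs(parse_dotbracket(pred))
    tp_ <- rnafitness:::structure_pairs(parse_dotbracket(truth))
    n <- nchar(pred)
    key <- function(m) if (ncol(m) == 0) character(0) else
      paste(m[1, ], m[2, ], sep = "-")
    all_keys <- unlist(lapply(1:(n - 1), function(i)
      paste(i, (i + 1):n, sep = "-")))
    y_pred <- all_keys %in% key(pp)
    y_true <- all_keys %in% key(tp_)
    tp <- sum(y_pred & y_true); fp <- sum(y_pred & !y_true)
    fn <- sum(!y_pred & y_true); tn <- sum(!y_pred & !y_true)
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  }
  set.seed(5)
  for (k in 1:30) {
    a <- random_structure_db(12); b <- random_structure_db(12)
    expect_equal(suppressWarnings(inf_score(a, b)),
                 suppressWarnings(mcc_oracle(a, b)))
  }
})

test_that("motif census decomposes helices and loops", {
  mc <- motif_census("((((...))))")
  expect_equal(mc[c("helix_count", "hairpin_loop_count", "bulge_loop_count",
                    "internal_loop_count", "multiloop_count")],
               list(helix_count = 1L, hairpin_loop_count = 1L,
                    bulge_loop_count = 0L, internal_loop_count = 0L,
                    multiloop_count = 0L))
  expect_equal(mc$paired_fraction, 8 / 11)

  # hand-traced: helix (1,12)(2,11), bulge at 3, helix (4,10)(5,9), hairpin
  mc2 <- motif_census("((.((...))))")
  expect_equal(mc2$helix_count, 2L)
  expect_equal(mc2$hairpin_loop_count, 1L)
  expect_equal(mc2$bulge_loop_count, 1L)
  expect_equal(mc2$internal_loop_count, 0L)

  # internal loop and multiloop
  mc3 <- motif_census("((..((...))..))")
  expect_equal(mc3$internal_loop_count, 1L)
  mc4 <- motif_census("((((...))((...))))")
  expect_equal(mc4$multiloop_count, 1L)
  expect_equal(mc4$helix_count, 3L)
  expect_equal(mc4$hairpin_loop_count, 2L)

  mc5 <- motif_census("....")
  expect_equal(mc5$paired_fraction, 0)
  expect_equal(mc5$helix_count, 0L)

  set.seed(6)
  for (k in 1:50) {
    db <- random_structure_db(14)
    mc <- motif_census(db)
    prs <- rnafitness:::structure_pairs(parse_dotbracket(db))
    expect_equal(mc$paired_fraction, 2 * ncol(prs) / 14)
    expect_gte(mc$helix_count, mc$hairpin_loop_count)
  }
})

test_that("gc_content counts G and C", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("AUAU"), 0)
  expect_equal(gc_content("GACU"), 0.5)
  expect_error(gc_content("GAXU"), "position 3")
})
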