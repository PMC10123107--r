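rb <- reference_backend()
prob_spec <- fitness_spec("probability")

test_that("seed sequences realize the target with controlled GC content", {
  set.seed(41)
  tgt <- "((((...)))).."
  for (k in 1:20) {
    s <- seed_sequence(tgt, seed_gc = 0.5)
    expect_equal(nchar(s), nchar(tgt))
    prs <- rnafitness:::structure_pairs(parse_dotbracket(tgt))
    codes <- rnafitness:::encode_seq(s)
    expect_true(all(rnafitness:::PAIR_TYPES[cbind(codes[prs[1, ]],
                                                  codes[prs[2, ]])] > 0))
  }
  # binomial concentration on a large fully unpaired target
  set.seed(42)
  g <- gc_content(seed_sequence(strrep(".", 10000), seed_gc = 0.25))
  expect_lt(abs(g - 0.25), 0.02)
  g <- gc_content(seed_sequence(strrep(".", 10000), seed_gc = 0.75))
  expect_lt(abs(g - 0.75), 0.02)
  # paired positions also track seed_gc (no wobble in seeds)
  set.seed(43)
  hp <- paste0(strrep("(", 2000), strrep(".", 4), strrep(")", 2000))
  g <- gc_content(seed_sequence(hp, seed_gc = 0.25))
  expect_lt(abs(g - 0.25), 0.03)
})

test_that("mutations change exactly one unit and preserve the target", {
  set.seed(44)
  tgt <- "((...)).."
  seq <- seed_sequence(tgt)
  for (k in 1:50) {
    mut <- mutate_sequence(seq, tgt)
    expect_false(identical(mut, seq))
    d <- which(strsplit(mut, "")[[1]] != strsplit(seq, "")[[1]])
    # one unpaired position, or one target pair (a pair switch may
    # touch only one of its two positions, e.g. GC -> GU)
    expect_true(identical(d, 3L) || identical(d, 4L) || identical(d, 5L) ||
                identical(d, 8L) || identical(d, 9L) ||
                all(d %in% c(1L, 7L)) || all(d %in% c(2L, 6L)))
    prs <- rnafitness:::structure_pairs(parse_dotbracket(tgt))
    codes <- rnafitness:::encode_seq(mut)
    expect_true(all(rnafitness:::PAIR_TYPES[cbind(codes[prs[1, ]],
                                                  codes[prs[2, ]])] > 0))
    seq <- mut
  }
  expect_error(mutate_sequence("", ""), "no mutable units|length")
})

test_that("mutation units are selected uniformly", {
  tgt <- "((...)).."
  # units: unpaired {3,4,5,8,9} + pairs {(1,7),(2,6)} -> 7 units
  set.seed(45)
  seq <- seed_sequence(tgt)
  unit_of <- function(d) {
    if (any(d %in% c(1L, 7L))) 6L
    else if (any(d %in% c(2L, 6L))) 7L
    else match(d[[1]], c(3L, 4L, 5L, 8L, 9L))
  }
  counts <- integer(7)
  for (k in 1:7000) {
    mut <- mutate_sequence(seq, tgt)
    d <- which(strsplit(mut, "")[[1]] != strsplit(seq, "")[[1]])
    u <- unit_of(d)
    counts[u] <- counts[u] + 1L
  }
  expect_gt(stats::chisq.test(counts, p = rep(1 / 7, 7))$p.value, 1e-4)
})

test_that("walk basics: zero steps, monotone trace, determinism", {
  tgt <- "((((....))))"
  r0 <- adaptive_random_walk(tgt, prob_spec, rb, steps = 0, rng_seed = 7)
  set.seed(7)
  units <- rnafitness:::walk_units(unclass(parse_dotbracket(tgt)))
  rnd <- rnafitness:::walk_randomness(units, 0L, 0.5, 7)
  expect_equal(r0$final_sequence,
               rnafitness:::decode_seq(rnafitness:::seed_codes(units, rnd, 12)))
  expect_length(r0$fitness_trace, 1)

  r1 <- adaptive_random_walk(tgt, prob_spec, rb, steps = 120, rng_seed = 99)
  r2 <- adaptive_random_walk(tgt, prob_spec, rb, steps = 120, rng_seed = 99)
  expect_identical(r1, r2)
  expect_false(is.unsorted(r1$fitness_trace))
  expect_lte(r1$accepted_count, 120)
})

test_that("a constant fitness function never moves", {
  tgt <- "((((....))))"
  r <- adaptive_random_walk(tgt, NULL, rb, steps = 50, rng_seed = 13,
                            fitness_fun = function(seqs, targets)
                              rep(1, length(seqs)))
  expect_equal(r$accepted_count, 0)
  expect_equal(length(unique(r$fitness_trace)), 1L)
  # and its final sequence is its seed
  r0 <- adaptive_random_walk(tgt, NULL, rb, steps = 0, rng_seed = 13,
                             fitness_fun = function(seqs, targets)
                               rep(1, length(seqs)))
  expect_equal(r$final_sequence, r0$final_sequence)
  # with plateau drift enabled, ties are accepted and the walk moves
  rq <- adaptive_random_walk(tgt, NULL, rb, steps = 50, rng_seed = 13,
                             fitness_fun = function(seqs, targets)
                               rep(1, length(seqs)),
                             accept_equal = TRUE)
  expect_equal(rq$accepted_count, 50)
  expect_false(identical(rq$final_sequence, r0$final_sequence))
})

test_that("every accepted intermediate realizes the target", {
  tgt <- "((....))((....))"
  tracker <- new.env(); tracker$bad <- 0L
  prs <- rnafitness:::structure_pairs(parse_dotbracket(tgt))
  wrapped <- function(seqs, targets) {
    for (s in seqs) {
      codes <- rnafitness:::encode_seq(s)
      if (!all(rnafitness:::PAIR_TYPES[cbind(codes[prs[1, ]],
                                             codes[prs[2, ]])] > 0))
        tracker$bad <- tracker$bad + 1L
    }
    fitness_batch(prob_spec, seqs, targets, rb)
  }
  r <- adaptive_random_walk(tgt, NULL, rb, steps = 150, rng_seed = 17,
                            fitness_fun = wrapped)
  expect_equal(tracker$bad, 0L)
})

test_that("the walk solves an easy hairpin almost always", {
  # sanity on the designer as a whole, not a benchmark number: with
  # probability fitness and a generous budget, a short stem-loop is
  # solved in nearly every seeded run
  tgt <- "((((....))))"
  solved <- vapply(1:100, function(k)
    adaptive_random_walk(tgt, prob_spec, rb, steps = 1000,
                         rng_seed = 5000 + k)$solved, logical(1))
  expect_gte(mean(solved), 0.95)
})

test_that("lockstep benchmark walks match standalone walks bit for bit", {
  targets <- c("((((....))))", "((....))....", "....((....))")
  seeds <- c(301L, 302L, 303L)
  eng <- rnafitness:::arw_engine(targets, prob_spec, rb, steps = 80,
                                 seed_gc = 0.5, seeds = seeds)
  for (w in 1:3) {
    solo <- adaptive_random_walk(targets[[w]], prob_spec, rb, steps = 80,
                                 rng_seed = seeds[[w]])
    expect_identical(solo$final_sequence, eng$final[[w]])
  }
})
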