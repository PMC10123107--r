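rb <- reference_backend()

test_that("benchmark bookkeeping: bounds, unique solver, reproducibility", {
  ps <- generate_puzzles(8, 12, 1.0, rb, rng_seed = 61)
  specs <- list(fitness_spec("probability"), fitness_spec("free_energy"))
  bm <- run_benchmark(ps, specs, rb, steps = 150, master_seed = 62)
  expect_equal(nrow(bm$summary), 2)
  expect_true(all(bm$summary$correct_rate >= 0 & bm$summary$correct_rate <= 1))
  expect_true(all(bm$summary$n_correct <= 8))
  # solved flags re-verify under the unique-MFE criterion
  rec <- bm$records
  for (r in seq_len(nrow(rec)))
    expect_equal(rec$solved[[r]],
                 is_correct_design(rb, rec$final_sequence[[r]],
                                   ps$targets[[rec$puzzle[[r]]]]))
  # unique-solver counts sum to the puzzles solved by exactly one spec
  solved_mat <- matrix(rec$solved, ncol = 2)
  expect_equal(sum(bm$summary$unique_solver), sum(rowSums(solved_mat) == 1))
  # single-spec run: unique solver equals correct count
  bm1 <- run_benchmark(ps, specs[1], rb, steps = 150, master_seed = 62)
  expect_equal(bm1$summary$unique_solver, bm1$summary$n_correct)
  # same master seed, same table; and spec 1 unperturbed by spec 2's presence
  bm2 <- run_benchmark(ps, specs, rb, steps = 150, master_seed = 62)
  expect_identical(bm$summary, bm2$summary)
  expect_identical(bm1$records$final_sequence,
                   bm$records$final_sequence[bm$records$fitness == "probability"])
})

test_that("rank of the true structure matches the enumeration oracle", {
  set.seed(63)
  rt <- be_rt(rb)
  for (k in 1:12) {
    seq <- random_rna(12)
    oracle <- oracle_boltzmann(seq)
    all_db <- vapply(oracle$pair_maps, function(pm)
      db_string(rnafitness:::new_structure(pm)), character(1))
    true_db <- all_db[[sample.int(length(all_db), 1)]]
    for (spec_txt in c("prob", "ed", "sd:HD:average")) {
      spec <- parse_fitness_spec(spec_txt)
      res <- rank_true_structure(seq, true_db, spec, rb,
                                 min_structures = 10, increment = 0.5,
                                 max_window = 100)
      # oracle: score the same window's structures independently
      keep <- oracle$energies <= min(oracle$energies) + round(res$window * 100)
      kept_db <- all_db[keep]
      fit <- switch(spec$family,
        probability = -oracle$energies[keep],
        ensemble_defect = -vapply(kept_db, function(s)
          sum(oracle$probs * vapply(all_db, hamming_distance, numeric(1), s)),
          numeric(1), USE.NAMES = FALSE),
        structure_distance = {
          co <- fold(rb, seq)$cooptimal_structures
          -vapply(kept_db, function(s)
            mean(vapply(co, hamming_distance, numeric(1), s)), numeric(1),
            USE.NAMES = FALSE)
        })
      idx <- match(true_db, kept_db)
      if (is.na(idx)) {
        expect_true(res$excluded || res$closest_bpd > 0)
      } else {
        expect_equal(res$rank, 1L + sum(fit > fit[[idx]] + 1e-12))
        expect_equal(res$list_size, sum(keep))
        expect_equal(res$percentile, res$rank / res$list_size)
      }
    }
  }
})

test_that("probability and free energy rank identically on a fixed sequence", {
  set.seed(64)
  for (k in 1:8) {
    seq <- random_rna(12)
    true_db <- fold(rb, seq)$cooptimal_structures[[1]]
    r1 <- rank_true_structure(seq, true_db, parse_fitness_spec("prob"), rb,
                              min_structures = 20, max_window = 100)
    r2 <- rank_true_structure(seq, true_db, parse_fitness_spec("fe"), rb,
                              min_structures = 20, max_window = 100)
    expect_equal(r1$rank, r2$rank)
    # the unique MFE structure ranks first under probability
    if (fold(rb, seq)$is_unique) expect_equal(r1$rank, 1L)
  }
})

test_that("unrealizable true structures are excluded via closest-BPD", {
  res <- rank_true_structure("AAAAAAAAAAAA", "((((....))))",
                             parse_fitness_spec("prob"), rb,
                             min_structures = 10, max_window = 100)
  expect_true(res$excluded)
  expect_gt(res$closest_bpd, 0.05 * 12)
  expect_true(is.na(res$rank))
})

test_that("cumulative rank curve is a monotone step function", {
  results <- data.frame(rank = c(1L, 1L, 5L, 50L), list_size = rep(100L, 4),
                        percentile = c(0.01, 0.01, 0.05, 0.5),
                        excluded = c(FALSE, FALSE, FALSE, FALSE),
                        closest_bpd = 0L, window = 0)
  curve <- cumulative_rank_curve(results)
  expect_false(is.unsorted(curve$count))
  expect_equal(curve$count[curve$cutoff == 1], 4L)
  expect_equal(curve$count[curve$cutoff == 0.01], 2L)
  # all ranks at the smallest cutoff saturate immediately
  allone <- data.frame(rank = 1L, list_size = 100L, percentile = 0.01,
                       excluded = FALSE, closest_bpd = 0L, window = 0)
  c2 <- cumulative_rank_curve(allone)
  expect_true(all(c2$count == 1L))
  expect_equal(nrow(cumulative_rank_curve(results[0, ])), 100)
})

test_that("ranking ties share the best (competition) rank", {
  # two co-optimal structures tie under probability; both rank 1
  seq <- "CCCAAAGGGAAACCC" # symmetric two-way MFE tie
  f <- fold(rb, seq)
  expect_false(f$is_unique)
  r <- rank_true_structure(seq, f$cooptimal_structures[[2]],
                           parse_fitness_spec("prob"), rb,
                           min_structures = 5, max_window = 100)
  expect_equal(r$rank, 1L)
})
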