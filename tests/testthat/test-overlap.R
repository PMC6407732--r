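grid <- hex_grid()

mk_dwells <- function(hexes, onsets) {
  tibble::tibble(hex = as.integer(hexes), onset = onsets,
                 offset = onsets + 0.4, n_fixations = 1L)
}

test_that("dwell overlap counts only cells highlighted before the dwell", {
  own <- mk_dwells(c(1, 2, 3), c(1, 2, 3))
  # partner highlighted cell 2 from 0.5 s (12 frames) and cell 3 from 4 s
  log <- tibble::tibble(
    frame_time = c(seq(0.5, by = 1 / 60, length.out = 12),
                   seq(4.0, by = 1 / 60, length.out = 12)),
    hex = rep(c(2L, 3L), each = 12)
  )
  expect_equal(dwell_overlap_proportion(own, log), 1 / 3)
  # an empty partner log means no overlap
  expect_equal(dwell_overlap_proportion(own, log[0, ]), 0)
  # every cell highlighted long before the first dwell: full overlap
  all_log <- runs_to_log(0:24, rep(6, 25))
  own_late <- mk_dwells(c(5, 9, 20), c(10, 11, 12))
  expect_equal(dwell_overlap_proportion(own_late, all_log), 1)
  expect_error(dwell_overlap_proportion(own[0, ], log), "no dwells")
})

test_that("flicker-length highlight runs do not count as partner inspections", {
  own <- mk_dwells(2, 1)
  # two frames (~33 ms) at cell 2: ignored
  short_log <- runs_to_log(c(2, 5), c(2, 30))
  expect_equal(dwell_overlap_proportion(own, short_log), 0)
  long_log <- runs_to_log(c(2, 5), c(12, 30))
  expect_equal(dwell_overlap_proportion(own, long_log), 1)
})

test_that("cumulative overlap is the inspected-by-both fraction of the array", {
  a <- mk_dwells(c(0, 1, 2), c(0.2, 0.6, 1.0))
  b <- mk_dwells(c(2, 3), c(0.4, 0.8))
  cv <- cumulative_overlap(own_dwells = a, partner_dwells = b, duration = 2,
                           grid = grid)
  expect_equal(cv$value[cv$time == 0], 0)
  expect_equal(cv$value[cv$time == 2], 1 / 25)  # only cell 2 is shared
  expect_true(all(diff(cv$value) >= 0))
  expect_true(all(cv$value >= 0 & cv$value <= 1))
})

test_that("full coverage by both searchers drives the curve to 1", {
  a <- mk_dwells(0:24, seq(0.1, by = 0.1, length.out = 25))
  b <- mk_dwells(24:0, seq(0.1, by = 0.1, length.out = 25))
  cv <- cumulative_overlap(own_dwells = a, partner_dwells = b, duration = 3,
                           grid = grid)
  expect_equal(max(cv$value), 1)
})

test_that("per-trial curves from simulated pairs are monotone and bounded", {
  strat <- list(a = strategy_params("blind_independent", "top_left",
                                    identification_miss_prob = 1,
                                    max_visits = 30),
                b = strategy_params("blind_independent", "top_right",
                                    identification_miss_prob = 1,
                                    max_visits = 30))
  tr <- simulate_pair(strat, "blind", grid, target = 20, seed = 21)
  cv <- cumulative_overlap(tr)
  for (p in c("a", "b")) {
    v <- cv$value[cv$participant == p]
    expect_equal(v[1], 0)
    expect_true(all(diff(v) >= 0))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("curve aggregation averages live trials and bootstraps the band", {
  t_grid <- seq(0, 1, by = 0.25)
  one <- tibble::tibble(curve_id = "x", time = t_grid,
                        value = c(0, 0.1, 0.2, 0.3, 0.4))
  agg1 <- aggregate_overlap_curves(one, n_boot = 100, seed = 1)
  expect_equal(agg1$mean, one$value)
  expect_equal(agg1$lo, one$value)  # a single curve has a zero-width band
  expect_equal(agg1$hi, one$value)

  # identical curves: zero-width band everywhere
  same <- dplyr::bind_rows(
    dplyr::mutate(one, curve_id = "x"),
    dplyr::mutate(one, curve_id = "y")
  )
  agg_same <- aggregate_overlap_curves(same, n_boot = 100, seed = 1)
  expect_equal(agg_same$lo, agg_same$hi)

  # two curves at 0.2 and 0.4: mean 0.3, band endpoints among resample means
  two <- tibble::tibble(curve_id = rep(c("x", "y"), each = 2),
                        time = rep(c(0, 1), 2),
                        value = rep(c(0.2, 0.4), each = 2))
  agg2 <- aggregate_overlap_curves(two, n_boot = 500, seed = 2)
  expect_equal(agg2$mean, c(0.3, 0.3))
  expect_true(all(agg2$lo %in% c(0.2, 0.3, 0.4)))
  expect_true(all(agg2$hi %in% c(0.2, 0.3, 0.4)))
  expect_identical(agg2, aggregate_overlap_curves(two, n_boot = 500,
                                                  seed = 2))

  # trials of unequal length: the short one leaves the average when it ends
  mixed <- dplyr::bind_rows(
    tibble::tibble(curve_id = "short", time = c(0, 0.25),
                   value = c(0, 0.2)),
    dplyr::mutate(one, curve_id = "long")
  )
  aggm <- aggregate_overlap_curves(mixed, n_boot = 10, seed = 1)
  expect_equal(aggm$n_alive, c(2, 2, 1, 1, 1))
  expect_equal(aggm$mean[1:2], c(0, 0.15))
  expect_equal(aggm$mean[3:5], c(0.2, 0.3, 0.4))
})

test_that("blind baseline takes the faster member of target-matched trials", {
  a <- tibble::tibble(target_hex = 5L, rt = 3.0, correct = TRUE)
  b <- tibble::tibble(target_hex = 5L, rt = 4.0, correct = FALSE)
  bb <- blind_baseline(a, b)
  expect_equal(nrow(bb), 1)
  expect_equal(bb$rt, 3.0)
  expect_true(bb$correct)
  expect_equal(bb$source, "a")

  # disjoint target sets: nothing to match
  b2 <- tibble::tibble(target_hex = 9L, rt = 1.0, correct = TRUE)
  expect_equal(attr(blind_baseline(a, b2), "n_matched"), 0L)

  # repeated targets pair in order of occurrence
  a3 <- tibble::tibble(target_hex = c(5L, 5L, 9L), rt = c(1, 2, 3),
                       correct = TRUE)
  b3 <- tibble::tibble(target_hex = c(5L, 9L, 9L), rt = c(2, 1, 4),
                       correct = TRUE)
  bb3 <- blind_baseline(a3, b3)
  expect_equal(nrow(bb3), 2)
  expect_setequal(bb3$target_hex, c(5L, 9L))
  expect_equal(sort(bb3$rt), c(1, 1))

  # rt ties go to participant A
  at <- tibble::tibble(target_hex = 7L, rt = 2, correct = TRUE)
  bt <- tibble::tibble(target_hex = 7L, rt = 2, correct = FALSE)
  expect_equal(blind_baseline(at, bt)$source, "a")
})

test_that("greedy matching agrees with a brute-force oracle on random trial sets", {
  withr::with_seed(42, {
    for (rep in 1:50) {
      na <- sample(3:20, 1)
      nb <- sample(3:20, 1)
      a <- tibble::tibble(target_hex = sample(0:6, na, replace = TRUE),
                          rt = round(runif(na, 1, 9), 2),
                          correct = runif(na) > 0.1)
      b <- tibble::tibble(target_hex = sample(0:6, nb, replace = TRUE),
                          rt = round(runif(nb, 1, 9), 2),
                          correct = runif(nb) > 0.1)
      got <- blind_baseline(a, b)[, c("target_hex", "rt", "correct",
                                      "source")]
      want <- match_oracle(a, b)
      expect_equal(dplyr::arrange(got, target_hex, rt),
                   dplyr::arrange(want, target_hex, rt),
                   ignore_attr = TRUE)
    }
  })
})
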