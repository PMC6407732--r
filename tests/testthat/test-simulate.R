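grid <- hex_grid()

test_that("strategy parameters are validated", {
  expect_error(strategy_params(identification_miss_prob = 1.2), "\\[0, 1\\]")
  expect_error(strategy_params(fixation_duration_mean = 0), "positive")
  expect_error(strategy_params(dwell_fixations = 0.5), ">= 1")
  expect_error(simulate_searcher(exact_strategy(), grid, target = 12,
                                 seed = 1), "middle")
  expect_error(simulate_searcher(exact_strategy(), grid, target = 40,
                                 seed = 1), "invalid config")
})

test_that("a deterministic raster visits elements in fixed order and rt grows with raster distance", {
  strat <- exact_strategy("raster_full", "top_left")
  itin <- c(0:4, 9:5, 10:14, 19:15, 20:24)  # serpentine from the top-left
  rts <- vapply(c(3, 9, 16, 24), function(tg) {
    tr <- simulate_searcher(strat, grid, target = tg, seed = 1)
    # ground-truth visit order is a prefix of the raster itinerary
    visited <- rle(tr$fixations$hex_id)$values
    expect_equal(visited, itin[seq_along(visited)])
    expect_equal(visited[length(visited)], tg)
    tr$record$rt
  }, numeric(1))
  expect_true(all(diff(rts) > 0))
})

test_that("the same seed reproduces a trial byte for byte", {
  strat <- list(a = strategy_params("random_walk", "top_left"),
                b = strategy_params("fresh_tile_competitor", "top_right"))
  t1 <- simulate_pair(strat, "compete", grid, target = 21, seed = 77)
  t2 <- simulate_pair(strat, "compete", grid, target = 21, seed = 77)
  expect_identical(t1, t2)
  t3 <- simulate_pair(strat, "compete", grid, target = 21, seed = 78)
  expect_false(identical(t3$record$rt, t1$record$rt) &&
                 identical(t3$agents$a$stream, t1$agents$a$stream))
})

test_that("a searcher that always misses ends by the visit cap without reporting", {
  strat <- exact_strategy(identification_miss_prob = 1, max_visits = 30)
  tr <- simulate_searcher(strat, grid, target = 3, seed = 2)
  visits <- rle(tr$fixations$hex_id)$values
  expect_equal(length(visits), 30)
  expect_true(3 %in% visits)          # the target was fixated
  expect_true(is.na(tr$record$responder))  # but never reported
  expect_false(tr$record$correct)
  expect_true(is.na(tr$record$points_delta))
})

test_that("blind-coupled identical deterministic agents move in lockstep", {
  strat <- list(a = exact_strategy("raster_full", "top_left"),
                b = exact_strategy("raster_full", "top_left"))
  tr <- simulate_pair(strat, "blind", grid, target = 17, seed = 3)
  va <- rle(tr$agents$a$fixations$hex_id)$values
  vb <- rle(tr$agents$b$fixations$hex_id)$values
  expect_equal(va, vb)
  expect_equal(tr$record$rt,
               simulate_searcher(strat$a, grid, 17, seed = 3)$record$rt)
})

test_that("fully avoidant collaborators visit disjoint element sets", {
  strat <- list(a = exact_strategy("raster_divided", "top_left",
                                   avoid_partner_prob = 1),
                b = exact_strategy("raster_divided", "bottom_right",
                                   avoid_partner_prob = 1))
  for (seed in 1:5) {
    tr <- simulate_pair(strat, "collaborate", grid, target = 14,
                        seed = seed)
    common <- intersect(unique(tr$agents$a$fixations$hex_id),
                        unique(tr$agents$b$fixations$hex_id))
    expect_length(common, 0)
  }
})

test_that("a coupled pair is never slower than either member alone", {
  strat <- list(a = exact_strategy("raster_full", "top_left"),
                b = exact_strategy("raster_full", "bottom_right"))
  for (tg in c(2, 11, 23)) {
    pair_rt <- simulate_pair(strat, "compete", grid, tg, seed = 9,
                             )$record$rt
    rt_a <- simulate_searcher(strat$a, grid, tg, seed = 9)$record$rt
    rt_b <- simulate_searcher(strat$b, grid, tg, seed = 9)$record$rt
    expect_equal(pair_rt, min(rt_a, rt_b))
  }
})

test_that("streams run at 120 Hz, cover the trial, and carry the noise model", {
  strat <- list(a = strategy_params("raster_full", "top_left",
                                    noise_sd = 0.2),
                b = strategy_params("raster_full", "top_right",
                                    noise_sd = 0.2))
  tr <- simulate_pair(strat, "blind", grid, target = 22, seed = 5)
  for (p in c("a", "b")) {
    s <- tr$agents[[p]]$stream
    expect_equal(diff(s$t), rep(1 / 120, nrow(s) - 1), tolerance = 1e-9)
    expect_equal(min(s$t), 0)
    expect_gte(max(s$t) + 1 / 120, tr$record$rt - 1e-9)
  }
  # left and right eyes are independently noisy around the same point
  expect_gt(sd(tr$agents$a$stream$xl - tr$agents$a$stream$xr), 0.1)
})

test_that("sessions produce the requested records with derived per-trial seeds", {
  sess <- simulate_session(3, c("collaborate", "blind"), seed = 101,
                           grid = grid)
  expect_equal(nrow(sess$records), 6)
  expect_equal(sum(sess$records$condition == "collaborate"), 3)
  expect_length(sess$trials, 6)
  # individual condition yields one record per participant per trial
  sess_i <- simulate_session(2, "individual", seed = 101, grid = grid)
  expect_equal(nrow(sess_i$records), 4)
  expect_setequal(sess_i$records$participant, c("a", "b"))
  # the whole session is reproducible from its master seed
  sess2 <- simulate_session(3, c("collaborate", "blind"), seed = 101,
                            grid = grid)
  expect_identical(sess$records, sess2$records)
})

test_that("targets are uniform over the 24 eligible cells and never the middle", {
  tg <- sample_targets(10000, seed = 6, grid = grid)
  expect_false(any(tg == 12))
  counts <- table(factor(tg, levels = setdiff(0:24, 12)))
  expect_true(all(counts > 0))
  # each count within 5 sd of the uniform expectation
  expected <- 10000 / 24
  sd_bin <- sqrt(10000 * (1 / 24) * (23 / 24))
  expect_true(all(abs(counts - expected) <= 5 * sd_bin))
})

test_that("responses carry the points schedule", {
  strat <- exact_strategy()
  tr <- simulate_searcher(strat, grid, target = 8, seed = 4)
  expect_true(tr$record$correct)
  expect_equal(tr$record$points_delta, 300L)
  expect_equal(tr$record$response_hex, 8L)
  # a searcher who always misclicks loses 600 points
  strat_bad <- exact_strategy(response_error_prob = 1)
  tr_bad <- simulate_searcher(strat_bad, grid, target = 8, seed = 4)
  expect_false(tr_bad$record$correct)
  expect_equal(tr_bad$record$points_delta, -600L)
})
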