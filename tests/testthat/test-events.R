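grid <- hex_grid()

test_that("a constant position gives exactly one full-length fixation", {
  s <- fixation_stream(1.2, -0.7, 1.0)
  fx <- detect_fixations(s)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration, 1.0, tolerance = 1e-9)
  expect_equal(c(fx$x, fx$y), c(1.2, -0.7), tolerance = 1e-12)
})

test_that("noise-free fixations separated by a jump are recovered exactly", {
  s <- fixation_stream(c(0, 5), c(0, 0), c(0.3, 0.3))
  fx <- detect_fixations(s)
  expect_equal(nrow(fx), 2)
  expect_equal(fx$x, c(0, 5), tolerance = 1e-9)
  expect_equal(fx$duration, c(0.3, 0.3), tolerance = 1e-9)
})

test_that("a continuous fast sweep contains no fixations", {
  ts <- seq(0, 0.5, by = 1 / 120)
  s <- tibble::tibble(t = ts, xl = 100 * ts, yl = 0, xr = 100 * ts, yr = 0,
                      valid_l = TRUE, valid_r = TRUE)
  expect_equal(nrow(detect_fixations(s, dispersion = 1.0,
                                     min_duration = 0.060)), 0)
})

test_that("invalid samples split fixation runs", {
  s <- fixation_stream(c(0, 0), c(0, 0), c(0.3, 0.3))
  mid <- abs(s$t - 0.3) < 1e-6
  s$valid_l[mid] <- FALSE
  s$valid_r[mid] <- FALSE
  fx <- detect_fixations(s)
  expect_equal(nrow(fx), 2)
  # an all-invalid stream yields no fixations
  s$valid_l <- FALSE
  s$valid_r <- FALSE
  expect_equal(nrow(detect_fixations(s)), 0)
})

test_that("binocular averaging falls back to the single valid eye", {
  s <- tibble::tibble(t = c(0, 1 / 120), xl = c(1, 1), yl = 0,
                      xr = c(3, 3), yr = 0,
                      valid_l = c(TRUE, FALSE), valid_r = TRUE)
  avg <- binocular_average(s)
  expect_equal(avg$x, c(2, 3))
})

test_that("dwells merge same-cell fixations but not across outside gaps", {
  mk_fx <- function(hexes) {
    ce <- hex_centers(grid)
    x <- ifelse(is.na(hexes), 50, ce$x_deg[match(hexes, ce$hex_id)])
    y <- ifelse(is.na(hexes), 50, ce$y_deg[match(hexes, ce$hex_id)])
    tibble::tibble(onset = seq_along(hexes) * 0.3 - 0.3,
                   offset = seq_along(hexes) * 0.3, x = x, y = y)
  }
  expect_equal(build_dwells(mk_fx(c(5, 5, 7, 7, 5)), grid)$hex, c(5, 7, 5))
  expect_equal(nrow(build_dwells(mk_fx(c(7, 7, 7)), grid)), 1)
  # an outside fixation is dropped but still breaks the merge
  d <- build_dwells(mk_fx(c(5, NA, 5)), grid)
  expect_equal(d$hex, c(5, 5))
  expect_equal(nrow(d), 2)
  # and the repeated dwell produces no self-transition
  expect_equal(nrow(build_transitions(mk_fx(c(5, NA, 5)), grid)), 0)
})

test_that("eye-movement parameters follow their definitions", {
  # three fixations at (0,0), (3,0), (3,4): consecutive-centroid
  # saccade amplitudes are 3 and 4
  fx <- tibble::tibble(onset = c(0, 0.3, 0.6), offset = c(0.3, 0.6, 0.9),
                       x = c(0, 3, 3), y = c(0, 0, 4))
  p <- eye_movement_params(fx, grid, duration = 0.9)
  expect_equal(p$median_saccade_amplitude, median(c(3, 4)))

  # 6 dwells in 3 s is a dwell rate of 2 Hz
  ce <- hex_centers(grid)
  hexes <- c(0, 1, 2, 3, 4, 9)
  fx6 <- tibble::tibble(onset = 0:5 * 0.5, offset = 0:5 * 0.5 + 0.5,
                        x = ce$x_deg[hexes + 1], y = ce$y_deg[hexes + 1])
  expect_equal(eye_movement_params(fx6, grid, duration = 3)$dwell_rate, 2)

  # two fixations inside one cell then one in another:
  # 2 saccades but only 1 transition
  fx3 <- tibble::tibble(onset = c(0, 0.3, 0.6), offset = c(0.3, 0.6, 0.9),
                        x = c(-0.5, 0.5, 4.6), y = c(0, 0, 0))
  p3 <- eye_movement_params(fx3, grid, duration = 0.9)
  expect_equal(p3$n_transitions, 1)
  expect_equal(nrow(fx3) - 1, 2)
  expect_equal(p3$median_transition_amplitude, 4.1)

  # a single fixation leaves saccade metrics undefined
  p1 <- eye_movement_params(fx[1, ], grid, duration = 0.3)
  expect_true(is.na(p1$median_saccade_amplitude))
  expect_error(eye_movement_params(fx[0, ], grid), "no fixations")
})

test_that("transition count equals dwell count minus one without outside gaps", {
  strat <- exact_strategy(identification_miss_prob = 1, max_visits = 40)
  tr <- simulate_searcher(strat, grid, target = 3, seed = 5)
  dw <- build_dwells(tr$fixations, grid)
  trans <- build_transitions(tr$fixations, grid)
  expect_equal(nrow(trans), nrow(dw) - 1)
})

test_that("precision metrics recover constructed noise levels", {
  # constant signal: both metrics zero
  s <- fixation_stream(0, 0, 0.5)
  pm <- precision_metrics(s)
  expect_equal(c(pm$rms_s2s, pm$mean_sd), c(0, 0))

  # x alternating +/-0.1 deg: every step is 0.2 deg
  n <- 120
  s2 <- tibble::tibble(t = (0:(n - 1)) / 120,
                       xl = rep(c(0.1, -0.1), n / 2), yl = 0,
                       xr = rep(c(0.1, -0.1), n / 2), yr = 0,
                       valid_l = TRUE, valid_r = TRUE)
  expect_equal(precision_metrics(s2)$rms_s2s, 0.2, tolerance = 1e-9)

  # monocular isotropic noise sd sigma per axis: sd metric tends to
  # sigma * sqrt(2)
  sig <- 0.2
  s3 <- fixation_stream(0, 0, 50, noise_sd = sig, seed = 3)
  s3$valid_r <- FALSE
  ep <- tibble::tibble(onset = 0, offset = 50)
  pm3 <- precision_metrics(s3, fixations = ep)
  expect_equal(pm3$mean_sd, sig * sqrt(2), tolerance = 0.05)

  # binocular averaging of two independent eyes brings it back to sigma
  s4 <- fixation_stream(0, 0, 50, noise_sd = sig, seed = 4)
  pm4 <- precision_metrics(s4, fixations = ep)
  expect_equal(pm4$mean_sd, sig, tolerance = 0.05)

  expect_error(precision_metrics(s[0, ]), "fewer than two")
})

test_that("overlooking requires two distinct other cells after the target", {
  mk <- function(hexes) tibble::tibble(hex = hexes,
                                       onset = seq_along(hexes),
                                       offset = seq_along(hexes) + 0.5,
                                       n_fixations = 1)
  expect_true(overlooked_target(mk(c(3, 9, 10, 11)), target = 9))
  expect_false(overlooked_target(mk(c(3, 9)), target = 9))
  # one other cell then back to the target: not overlooked
  expect_false(overlooked_target(mk(c(9, 10, 9)), target = 9))
  expect_false(overlooked_target(mk(c(3, 4, 5)), target = 9))
})
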