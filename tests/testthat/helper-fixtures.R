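# Shared fixtures and independent oracles, built in code at test time.

# A binocular 120-Hz stream that fixates a sequence of points for given
# durations; both eyes get independent Gaussian noise of sd `noise_sd`.
fixation_stream <- function(xs, ys, durations, hz = 120, noise_sd = 0,
                            seed = 1) {
  onsets <- cumsum(c(0, durations[-length(durations)]))
  total <- sum(durations)
  ts <- seq(0, total - 1e-9, by = 1 / hz)
  idx <- findInterval(ts, onsets)
  n <- length(ts)
  withr::with_seed(seed, tibble::tibble(
    t = ts,
    xl = xs[idx] + stats::rnorm(n, 0, noise_sd),
    yl = ys[idx] + stats::rnorm(n, 0, noise_sd),
    xr = xs[idx] + stats::rnorm(n, 0, noise_sd),
    yr = ys[idx] + stats::rnorm(n, 0, noise_sd),
    valid_l = TRUE, valid_r = TRUE
  ))
}

# Highlight log built from (hex, n_frames) run pairs at a given frame rate.
runs_to_log <- function(hexes, n_frames, frame_rate = 60) {
  hex <- rep(hexes, n_frames)
  tibble::tibble(
    frame_time = (seq_along(hex) - 1) / frame_rate,
    hex = as.integer(hex)
  )
}

# Even-odd (ray crossing) point-in-polygon test: an oracle for hexagon
# containment that is independent of the analytic test in assign_hex().
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      x_cross <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < x_cross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force entropy oracle: explicit double loop over matrix cells.
entropy_oracle <- function(m) {
  total <- sum(m)
  h_joint <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      p <- m[i, j] / total
      if (p > 0) h_joint <- h_joint - p * log2(p)
    }
  }
  h_cond <- 0
  for (i in seq_len(nrow(m))) {
    ri <- sum(m[i, ])
    if (ri == 0) next
    inner <- 0
    for (j in seq_len(ncol(m))) {
      p <- m[i, j] / ri
      if (p > 0) inner <- inner - p * log2(p)
    }
    h_cond <- h_cond + (ri / total) * inner
  }
  list(conditional = h_cond, joint = h_joint)
}

# Brute-force per-target in-order matcher: oracle for blind_baseline().
match_oracle <- function(a, b) {
  rows <- list()
  for (tg in sort(unique(intersect(a$target_hex, b$target_hex)))) {
    ai <- which(a$target_hex == tg)
    bi <- which(b$target_hex == tg)
    for (k in seq_len(min(length(ai), length(bi)))) {
      ra <- a[ai[k], ]
      rb <- b[bi[k], ]
      faster_a <- ra$rt <= rb$rt
      rows[[length(rows) + 1L]] <- tibble::tibble(
        target_hex = tg,
        rt = min(ra$rt, rb$rt),
        correct = if (faster_a) ra$correct else rb$correct,
        source = if (faster_a) "a" else "b"
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Paired vectors with an exact Pearson correlation rho.
exact_cor_pair <- function(n, rho, seed = 1) {
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    e <- stats::rnorm(n)
    e <- stats::residuals(stats::lm(e ~ x))
    zx <- as.vector(scale(x))
    ze <- as.vector(scale(e))
    list(x = x, y = rho * zx + sqrt(1 - rho^2) * ze)
  })
}

# Fast, deterministic strategies for event-layer ground-truth checks.
exact_strategy <- function(kind = "raster_full", corner = "top_left", ...) {
  args <- list(...)
  defaults <- list(fixation_duration_sd = 0, dwell_fixations = 1,
                   identification_miss_prob = 0, response_error_prob = 0,
                   noise_sd = 0)
  defaults[names(args)] <- args
  do.call(strategy_params, c(list(kind, corner), defaults))
}
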