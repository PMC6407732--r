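#' Binocular average of a gaze stream
#'
#' Averages the valid eyes per sample: both eyes when both are valid, the
#' single valid eye otherwise.  Samples with no valid eye get `NA`
#' coordinates and `valid = FALSE`.
#'
#' @param stream A gaze-stream tibble (`t`, `xl`, `yl`, `xr`, `yr`,
#'   `valid_l`, `valid_r`).
#' @return A tibble with columns `t`, `x`, `y`, `valid`.
#' @export
binocular_average <- function(stream) {
  vl <- stream$valid_l & is.finite(stream$xl) & is.finite(stream$yl)
  vr <- stream$valid_r & is.finite(stream$xr) & is.finite(stream$yr)
  wl <- ifelse(vl, 1, 0)
  wr <- ifelse(vr, 1, 0)
  denom <- wl + wr
  x <- ifelse(denom > 0,
              (ifelse(vl, stream$xl, 0) + ifelse(vr, stream$xr, 0)) / denom,
              NA_real_)
  y <- ifelse(denom > 0,
              (ifelse(vl, stream$yl, 0) + ifelse(vr, stream$yr, 0)) / denom,
              NA_real_)
  tibble::tibble(t = stream$t, x = x, y = y, valid = denom > 0)
}

# greedy dispersion (I-DT) pass over one gap-free segment; returns a list of
# (start, end) index pairs
idt_segment <- function(x, y, min_samples, threshold) {
  n <- length(x)
  out <- list()
  i <- 1L
  while (i + min_samples - 1L <= n) {
    j <- i + min_samples - 1L
    xmin <- min(x[i:j]); xmax <- max(x[i:j])
    ymin <- min(y[i:j]); ymax <- max(y[i:j])
    if (max(xmax - xmin, ymax - ymin) > threshold) {
      i <- i + 1L
      next
    }
    while (j < n) {
      nx <- x[j + 1L]; ny <- y[j + 1L]
      if (max(max(xmax, nx) - min(xmin, nx),
              max(ymax, ny) - min(ymin, ny)) > threshold) break
      xmin <- min(xmin, nx); xmax <- max(xmax, nx)
      ymin <- min(ymin, ny); ymax <- max(ymax, ny)
      j <- j + 1L
    }
    out[[length(out) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  out
}

#' Detect fixations with a dispersion (I-DT) detector
#'
#' Dispersion-based fixation detection on the binocularly averaged gaze
#' signal: maximal sample runs whose bounding-box extent (the larger of the
#' horizontal and vertical ranges) stays within `dispersion` and whose
#' duration reaches `min_duration` become fixations, with the centroid as
#' the fixation position.  Invalid samples split runs.  Externally produced
#' fixation tables (for example from a clustering-based detector) can be
#' passed to all downstream event functions in place of this detector's
#' output, as long as they carry `onset`, `offset`, `x`, `y`.
#'
#' @param stream A gaze-stream tibble.
#' @param dispersion Maximum bounding-box extent in degrees.
#' @param min_duration Minimum fixation duration in seconds.
#' @return A tibble with columns `onset`, `offset`, `x`, `y`, `duration`,
#'   `n_samples`.  An all-invalid or empty stream yields zero rows.
#' @export
detect_fixations <- function(stream, dispersion = 1.0,
                             min_duration = 0.060) {
  stopifnot(dispersion > 0, min_duration > 0)
  empty <- tibble::tibble(onset = numeric(0), offset = numeric(0),
                          x = numeric(0), y = numeric(0),
                          duration = numeric(0), n_samples = integer(0))
  if (is.null(stream) || nrow(stream) == 0) return(empty)
  avg <- binocular_average(stream)
  if (!any(avg$valid)) return(empty)
  dt <- if (nrow(avg) > 1) stats::median(diff(avg$t)) else min_duration
  min_samples <- max(1L, as.integer(round(min_duration / dt)))

  # gap-free valid segments
  seg_id <- cumsum(!avg$valid)
  rows <- list()
  for (s in split(which(avg$valid), seg_id[avg$valid])) {
    if (length(s) < min_samples) next
    x <- avg$x[s]; y <- avg$y[s]; t <- avg$t[s]
    for (ij in idt_segment(x, y, min_samples, dispersion)) {
      k <- ij[1]:ij[2]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        onset = t[ij[1]],
        offset = t[ij[2]] + dt,
        x = mean(x[k]), y = mean(y[k]),
        n_samples = length(k)
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  out$duration <- out$offset - out$onset
  out[, c("onset", "offset", "x", "y", "duration", "n_samples")]
}

#' Collapse fixations into dwells on hexagonal cells
#'
#' Assigns each fixation to a cell via [assign_hex()] and merges runs of
#' consecutive fixations on the same cell into dwells.  Fixations landing
#' outside every cell are dropped, but they still break a run: a cell
#' revisited across an outside fixation starts a new dwell.
#'
#' @param fixations A fixation tibble (`onset`, `offset`, `x`, `y`).
#' @param grid A [hex_grid()] object.
#' @return A tibble with columns `hex`, `onset`, `offset`, `n_fixations`.
#' @export
build_dwells <- function(fixations, grid) {
  stopifnot(inherits(grid, "hex_grid"))
  if (nrow(fixations) == 0) {
    return(tibble::tibble(hex = integer(0), onset = numeric(0),
                          offset = numeric(0), n_fixations = integer(0)))
  }
  hex <- assign_hex(fixations$x, fixations$y, grid)
  # new dwell whenever the cell changes or the previous fixation was outside
  prev <- c(NA_integer_, hex[-length(hex)])
  new_dwell <- is.na(prev) | is.na(hex) | prev != hex
  grp <- cumsum(new_dwell)
  keep <- !is.na(hex)
  tibble::tibble(hex = hex[keep], grp = grp[keep],
                 onset = fixations$onset[keep],
                 offset = fixations$offset[keep]) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(hex = .data$hex[1], onset = min(.data$onset),
                     offset = max(.data$offset),
                     n_fixations = dplyr::n(), .groups = "drop") |>
    dplyr::select("hex", "onset", "offset", "n_fixations")
}

#' Transitions between hexagonal cells
#'
#' A transition is a saccade that carries gaze from one cell to a different
#' cell.  Fixations outside every cell are dropped first; consecutive
#' remaining fixations on different cells form a transition whose amplitude
#' is the distance between the two bounding fixation centroids.
#'
#' @inheritParams build_dwells
#' @return A tibble with columns `from_hex`, `to_hex`, `time` (offset of
#'   the departing fixation), `amplitude`.
#' @export
build_transitions <- function(fixations, grid) {
  stopifnot(inherits(grid, "hex_grid"))
  if (nrow(fixations) < 2) {
    return(tibble::tibble(from_hex = integer(0), to_hex = integer(0),
                          time = numeric(0), amplitude = numeric(0)))
  }
  hex <- assign_hex(fixations$x, fixations$y, grid)
  keep <- !is.na(hex)
  f <- fixations[keep, ]
  h <- hex[keep]
  if (nrow(f) < 2) {
    return(tibble::tibble(from_hex = integer(0), to_hex = integer(0),
                          time = numeric(0), amplitude = numeric(0)))
  }
  i <- seq_len(nrow(f) - 1)
  cross <- h[i] != h[i + 1]
  tibble::tibble(
    from_hex = h[i][cross],
    to_hex = h[i + 1][cross],
    time = f$offset[i][cross],
    amplitude = sqrt((f$x[i + 1] - f$x[i])^2 +
                       (f$y[i + 1] - f$y[i])^2)[cross]
  )
}

#' Scalar eye-movement parameters for one trial
#'
#' Summarises a trial's events into the standard search parameters: median
#' fixation duration, median saccade amplitude (all inter-fixation
#' distances), dwell rate (element visits per second of search time, with a
#' unique-cells variant), and median transition amplitude (only saccades
#' that cross a cell boundary).
#'
#' @param fixations A fixation tibble (`onset`, `offset`, `x`, `y`).
#' @param grid A [hex_grid()] object.
#' @param duration Search duration in seconds (stimulus onset to the
#'   trial-ending response); defaults to the last fixation offset.
#' @return A one-row tibble: `n_fixations`, `median_fixation_duration`,
#'   `median_saccade_amplitude`, `n_dwells`, `dwell_rate`,
#'   `unique_hex_rate`, `n_transitions`, `median_transition_amplitude`.
#'   Saccade and transition medians are `NA` when there are fewer than two
#'   fixations or no transitions.
#' @export
eye_movement_params <- function(fixations, grid, duration = NULL) {
  if (nrow(fixations) < 1) {
    stop("undefined metric: no fixations in trial", call. = FALSE)
  }
  if (is.null(duration)) duration <- max(fixations$offset)
  dwells <- build_dwells(fixations, grid)
  trans <- build_transitions(fixations, grid)
  n_fix <- nrow(fixations)
  sacc <- if (n_fix >= 2) {
    i <- seq_len(n_fix - 1)
    sqrt(diff(fixations$x)^2 + diff(fixations$y)^2)
  } else {
    numeric(0)
  }
  tibble::tibble(
    n_fixations = n_fix,
    median_fixation_duration =
      stats::median(fixations$offset - fixations$onset),
    median_saccade_amplitude =
      if (length(sacc)) stats::median(sacc) else NA_real_,
    n_dwells = nrow(dwells),
    dwell_rate = nrow(dwells) / duration,
    unique_hex_rate = length(unique(dwells$hex)) / duration,
    n_transitions = nrow(trans),
    median_transition_amplitude =
      if (nrow(trans)) stats::median(trans$amplitude) else NA_real_
  )
}

#' Gaze-precision metrics (RMS-S2S and SD)
#'
#' Computes the two standard data-quality metrics on the binocularly
#' averaged signal, within fixation episodes so that saccades do not inflate
#' them: the root-mean-square sample-to-sample distance (RMS-S2S) and the
#' positional standard deviation `sqrt(var_x + var_y)`, each computed per
#' episode and averaged across episodes.
#'
#' @param stream A gaze-stream tibble.
#' @param fixations Optional fixation tibble defining the episodes; detected
#'   with [detect_fixations()] when omitted.
#' @param ... Passed to [detect_fixations()].
#' @return A one-row tibble: `rms_s2s`, `mean_sd`, `n_episodes`.
#' @export
precision_metrics <- function(stream, fixations = NULL, ...) {
  avg <- binocular_average(stream)
  if (sum(avg$valid) < 2) {
    stop("undefined metric: fewer than two valid samples", call. = FALSE)
  }
  if (is.null(fixations)) fixations <- detect_fixations(stream, ...)
  if (nrow(fixations) == 0) {
    stop("undefined metric: no fixation episodes", call. = FALSE)
  }
  dt <- if (nrow(avg) > 1) stats::median(diff(avg$t)) else 0
  rms <- sd_ep <- numeric(nrow(fixations))
  for (k in seq_len(nrow(fixations))) {
    # the half-sample margin keeps the first sample after the episode
    # (already at the next fixation's position) out of the window
    in_ep <- avg$valid & avg$t >= fixations$onset[k] - dt / 2 &
      avg$t < fixations$offset[k] - dt / 2
    x <- avg$x[in_ep]; y <- avg$y[in_ep]
    if (length(x) < 2) {
      rms[k] <- NA_real_; sd_ep[k] <- NA_real_
      next
    }
    rms[k] <- sqrt(mean(diff(x)^2 + diff(y)^2))
    sd_ep[k] <- sqrt(stats::var(x) + stats::var(y))
  }
  tibble::tibble(
    rms_s2s = mean(rms, na.rm = TRUE),
    mean_sd = mean(sd_ep, na.rm = TRUE),
    n_episodes = sum(!is.na(rms))
  )
}

#' Did the searcher overlook the target?
#'
#' A target counts as overlooked when the searcher dwells on the target cell
#' and then visits two or more other distinct cells before the response.
#'
#' @param dwells A dwell tibble from [build_dwells()].
#' @param target Target cell id.
#' @return `TRUE`/`FALSE`.
#' @export
overlooked_target <- function(dwells, target) {
  hit <- which(dwells$hex == target)
  if (length(hit) == 0) return(FALSE)
  after <- dwells$hex[seq_len(nrow(dwells)) > hit[1]]
  length(unique(setdiff(after, target))) >= 2
}
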