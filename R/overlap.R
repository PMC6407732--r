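#' Proportion of dwells overlapping the partner's highlights
#'
#' A dwell overlaps when its cell was already shown as the partner's gaze
#' marker before the dwell began: the cell must appear in the partner's
#' highlight log as a run longer than `min_highlight` (flicker-length runs
#' are measurement error and are ignored) whose onset precedes the dwell's
#' onset.
#'
#' @param own_dwells A dwell tibble from [build_dwells()].
#' @param partner_log The partner's highlight log (tibble `frame_time`,
#'   `hex`).
#' @param min_highlight Minimum highlight-run duration in seconds for the
#'   run to count as the partner having looked there.
#' @return The proportion of the searcher's dwells that overlap.
#' @export
dwell_overlap_proportion <- function(own_dwells, partner_log,
                                     min_highlight = 0.050) {
  if (nrow(own_dwells) == 0) {
    stop("undefined metric: no dwells", call. = FALSE)
  }
  first_on <- partner_first_onsets(partner_log, min_highlight)
  if (nrow(first_on) == 0) return(0)
  onset_of <- first_on$first_onset[match(own_dwells$hex, first_on$hex)]
  mean(!is.na(onset_of) & onset_of < own_dwells$onset)
}

# first onset, per cell, of partner highlight runs longer than min_highlight
partner_first_onsets <- function(partner_log, min_highlight = 0.050) {
  runs <- highlight_runs(partner_log)
  # runs lasting min_highlight or less are ignored (flicker exclusion);
  # the tolerance absorbs frame-interval rounding
  runs <- runs[!is.na(runs$hex) & runs$duration > min_highlight + 1e-9, ]
  if (nrow(runs) == 0) {
    return(tibble::tibble(hex = integer(0), first_onset = numeric(0)))
  }
  runs |>
    dplyr::group_by(.data$hex) |>
    dplyr::summarise(first_onset = min(.data$onset), .groups = "drop")
}

#' First inspection time of each cell
#'
#' @param dwells A dwell tibble from [build_dwells()].
#' @return A tibble with columns `hex`, `first_onset`.
#' @export
coverage_times <- function(dwells) {
  if (nrow(dwells) == 0) {
    return(tibble::tibble(hex = integer(0), first_onset = numeric(0)))
  }
  dwells |>
    dplyr::group_by(.data$hex) |>
    dplyr::summarise(first_onset = min(.data$onset), .groups = "drop")
}

#' Cumulative overlap time course for one trial
#'
#' At each display-frame time the curve gives the proportion of the array's
#' cells that both searchers have inspected by that time, from the viewpoint
#' of one participant: the participant's own inspections are their dwells,
#' and the partner's inspections are the cells the gaze marker highlighted
#' on this participant's screen (runs longer than `min_highlight`).  The
#' curve starts at 0 and is non-decreasing, reaching 1 only if both
#' searchers covered every cell.
#'
#' @param pair A `pair_trial` object from [simulate_pair()], or `NULL` when
#'   supplying the pieces explicitly.
#' @param participant `"a"` or `"b"`: whose screen to take the viewpoint of.
#'   Use `"both"` (default) to return both participants' curves.
#' @param own_dwells,partner_log Explicit inputs overriding `pair`.
#' @param partner_dwells Optional: when no highlight log is available, the
#'   partner's dwells are used as their inspections instead.
#' @param duration Trial duration in seconds; defaults to the trial's
#'   reaction time (or the last event time).
#' @param min_highlight Flicker-exclusion threshold in seconds.
#' @param frame_rate Time-grid resolution in Hz.
#' @param grid A [hex_grid()] object (supplies the cell count).
#' @param dwell_args Arguments passed on to [detect_fixations()] when dwells
#'   must be derived from a pair's streams.
#' @return A tibble of class `overlap_curve` with columns `participant`,
#'   `time`, `value`.
#' @export
cumulative_overlap <- function(pair = NULL, participant = "both",
                               own_dwells = NULL, partner_log = NULL,
                               partner_dwells = NULL, duration = NULL,
                               min_highlight = 0.050, frame_rate = 60,
                               grid = hex_grid(), dwell_args = list()) {
  if (!is.null(pair)) {
    stopifnot(inherits(pair, "pair_trial"))
    who <- if (identical(participant, "both")) c("a", "b") else participant
    curves <- lapply(who, function(p) {
      other <- if (p == "a") "b" else "a"
      fx <- pair$agents[[p]]$fixations
      if (!("hex_id" %in% names(fx))) {
        fx <- do.call(detect_fixations,
                      c(list(pair$agents[[p]]$stream), dwell_args))
      }
      cv <- cumulative_overlap(
        own_dwells = build_dwells(fx, grid),
        partner_log = pair$highlights[[other]],
        duration = pair$record$rt,
        min_highlight = min_highlight, frame_rate = frame_rate, grid = grid
      )
      cv$participant <- p
      cv
    })
    out <- dplyr::bind_rows(curves)[, c("participant", "time", "value")]
    class(out) <- c("overlap_curve", class(tibble::tibble()))
    return(out)
  }

  stopifnot(!is.null(own_dwells))
  own <- coverage_times(own_dwells)
  partner <- if (!is.null(partner_log)) {
    partner_first_onsets(partner_log, min_highlight)
  } else if (!is.null(partner_dwells)) {
    coverage_times(partner_dwells)
  } else {
    stop("need `partner_log` or `partner_dwells`", call. = FALSE)
  }
  if (is.null(duration)) {
    duration <- max(c(own_dwells$offset, partner$first_onset, 0))
  }
  both <- dplyr::inner_join(own, partner, by = "hex",
                            suffix = c("_own", "_partner"))
  joint_time <- pmax(both$first_onset_own, both$first_onset_partner)
  times <- seq(0, duration, by = 1 / frame_rate)
  # a cell counts once both inspections have begun before t, so the curve
  # is 0 at stimulus onset by construction
  value <- vapply(times, function(t) sum(joint_time < t),
                  numeric(1)) / grid$n_elements
  out <- tibble::tibble(participant = NA_character_, time = times,
                        value = value)
  class(out) <- c("overlap_curve", class(tibble::tibble()))
  out
}

#' Average overlap curves with a percentile-bootstrap band
#'
#' Aligns per-trial overlap curves on a common time grid and, at each time,
#' averages over the trials still running (a trial contributes until its
#' own end).  A seeded percentile bootstrap over trials (resampled with
#' replacement) yields the 95% confidence band.
#'
#' @param curves A tibble of per-trial curves with columns `curve_id`,
#'   `time`, `value` (e.g. bound rows of [cumulative_overlap()] outputs with
#'   a distinguishing `curve_id` added).
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level of the percentile band.
#' @return A tibble of class `overlap_summary` with columns `time`, `mean`,
#'   `lo`, `hi`, `n_alive`.
#' @export
aggregate_overlap_curves <- function(curves, n_boot = 1000, seed = 1,
                                     conf = 0.95) {
  stopifnot(nrow(curves) > 0, all(c("curve_id", "time", "value") %in%
                                    names(curves)))
  ids <- unique(curves$curve_id)
  grid_t <- sort(unique(curves$time))
  # step-function values per curve; NA after the curve's own end
  mat <- vapply(ids, function(id) {
    cc <- curves[curves$curve_id == id, ]
    v <- stats::approx(cc$time, cc$value, xout = grid_t,
                       method = "constant", f = 0, rule = 2)$y
    v[grid_t > max(cc$time)] <- NA_real_
    if (length(cc$time) == 1) v[grid_t == cc$time] <- cc$value
    v
  }, numeric(length(grid_t)))
  mat <- matrix(mat, nrow = length(grid_t))
  n_alive <- rowSums(!is.na(mat))
  mean_curve <- rowMeans(mat, na.rm = TRUE)
  mean_curve[n_alive == 0] <- NA_real_

  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      take <- sample.int(length(ids), replace = TRUE)
      rowMeans(mat[, take, drop = FALSE], na.rm = TRUE)
    }, numeric(length(grid_t)))
  })
  boots <- matrix(boots, nrow = length(grid_t))
  band <- t(apply(boots, 1, stats::quantile, probs = qs, na.rm = TRUE))
  out <- tibble::tibble(
    time = grid_t, mean = mean_curve,
    lo = band[, 1], hi = band[, 2], n_alive = n_alive
  )
  out$lo[n_alive == 0] <- NA_real_
  out$hi[n_alive == 0] <- NA_real_
  class(out) <- c("overlap_summary", class(tibble::tibble()))
  out
}

#' Simulated blind-pair baseline from two individuals' trials
#'
#' Builds artificial pair trials from two searchers' individual trials: each
#' of A's trials is greedily matched, in order of occurrence, with B's next
#' unmatched trial that had the target at the same array location.  The
#' artificial trial takes the response, correctness and reaction time of the
#' faster member (ties go to participant A).  Unmatched trials are dropped.
#'
#' @param trials_a,trials_b Trial-record tibbles with at least `target_hex`,
#'   `rt`, `correct` (and optionally `response_hex`).
#' @return A tibble of artificial trials (`target_hex`, `rt`, `correct`,
#'   `response_hex` when available, `source` = `"a"`/`"b"`), with the match
#'   count in attribute `n_matched`.
#' @export
blind_baseline <- function(trials_a, trials_b) {
  need <- c("target_hex", "rt", "correct")
  stopifnot(all(need %in% names(trials_a)), all(need %in% names(trials_b)))
  key <- function(d) {
    d |>
      dplyr::mutate(.order = dplyr::row_number()) |>
      dplyr::group_by(.data$target_hex) |>
      dplyr::mutate(.k = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  a <- key(trials_a)
  b <- key(trials_b)
  keep <- intersect(c("target_hex", ".k", "rt", "correct", "response_hex",
                      ".order"), names(a))
  m <- dplyr::inner_join(a[, keep], b[, intersect(keep, names(b))],
                         by = c("target_hex", ".k"),
                         suffix = c("_a", "_b"))
  if (nrow(m) == 0) {
    out <- tibble::tibble(target_hex = integer(0), rt = numeric(0),
                          correct = logical(0), source = character(0))
    attr(out, "n_matched") <- 0L
    return(out)
  }
  faster_a <- m$rt_a <= m$rt_b  # tie goes to participant A
  out <- tibble::tibble(
    target_hex = m$target_hex,
    rt = pmin(m$rt_a, m$rt_b),
    correct = ifelse(faster_a, m$correct_a, m$correct_b),
    source = ifelse(faster_a, "a", "b")
  )
  if (all(c("response_hex_a", "response_hex_b") %in% names(m))) {
    out$response_hex <- ifelse(faster_a, m$response_hex_a, m$response_hex_b)
  }
  out <- out[order(m$.order_a), ]
  attr(out, "n_matched") <- nrow(out)
  out
}
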