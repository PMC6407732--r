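#' Reconstruct the online gaze-marker (highlight) log
#'
#' Replays the real-time rule that decides, for every display frame, which
#' hexagonal cell is outlined as the partner's gaze marker.  For each frame
#' time `t`, the valid gaze samples that arrived in the trailing half-open
#' window `(t - window, t]` are binocularly averaged (mean of the valid
#' eyes), mapped to cells, and the modal cell is highlighted.  If the modal
#' count is tied - in particular if every sample indicates a different cell,
#' the signature of a saccade in flight - the cell supported by the most
#' recent sample wins.  A frame whose window holds no valid sample keeps the
#' previous frame's highlight (none at trial start).  Samples falling
#' outside every cell do not vote.
#'
#' @param stream A gaze-stream tibble (`t`, `xl`, `yl`, `xr`, `yr`,
#'   `valid_l`, `valid_r`).
#' @param grid A [hex_grid()] object.
#' @param window Trailing window length in seconds (30 ms online).
#' @param frame_rate Display refresh rate in Hz.
#'
#' @return A tibble of class `highlight_log` with columns `frame_time`
#'   (seconds) and `hex` (cell id, `NA` when nothing is highlighted).
#'   An empty stream yields an empty log.
#' @export
highlight_stream <- function(stream, grid, window = 0.030, frame_rate = 60) {
  stopifnot(inherits(grid, "hex_grid"))
  empty <- tibble::tibble(frame_time = numeric(0), hex = integer(0))
  class(empty) <- c("highlight_log", class(empty))
  if (is.null(stream) || nrow(stream) == 0) return(empty)

  avg <- binocular_average(stream)
  ok <- avg$valid
  ts <- avg$t[ok]
  if (length(ts) == 0) return(empty)
  hex <- assign_hex(avg$x[ok], avg$y[ok], grid)

  frame_times <- seq(0, max(avg$t), by = 1 / frame_rate)
  out <- integer(length(frame_times))
  prev <- NA_integer_
  # sample index ranges per frame: samples with t in (frame - window, frame]
  lo <- findInterval(frame_times - window, ts) + 1L
  hi <- findInterval(frame_times, ts)
  for (f in seq_along(frame_times)) {
    if (hi[f] < lo[f]) {
      out[f] <- prev
      next
    }
    h <- hex[lo[f]:hi[f]]
    h <- h[!is.na(h)]
    if (length(h) == 0) {
      out[f] <- prev
      next
    }
    u <- unique(h)
    if (length(u) == 1L) {
      prev <- u
    } else {
      cnt <- tabulate(match(h, u))
      cand <- u[cnt == max(cnt)]
      # among tied modal cells, the one supported most recently
      prev <- h[max(which(h %in% cand))]
    }
    out[f] <- prev
  }
  log <- tibble::tibble(frame_time = frame_times, hex = as.integer(out))
  class(log) <- c("highlight_log", class(log))
  log
}

#' Run-length structure of a highlight log
#'
#' Groups consecutive frames showing the same highlight into runs.  Frames
#' with no highlight form `NA` runs (kept so that run boundaries are
#' faithful, but they are not highlights).
#'
#' @param log A highlight log (tibble with `frame_time`, `hex`).
#' @return A tibble with columns `hex`, `onset` (first frame time), `offset`
#'   (last frame time plus one frame interval), `n_frames`, `duration`.
#' @export
highlight_runs <- function(log) {
  if (is.null(log) || nrow(log) == 0) {
    return(tibble::tibble(hex = integer(0), onset = numeric(0),
                          offset = numeric(0), n_frames = integer(0),
                          duration = numeric(0)))
  }
  dt <- if (nrow(log) > 1) stats::median(diff(log$frame_time)) else 1 / 60
  code <- ifelse(is.na(log$hex), -1L, log$hex)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(
    hex = ifelse(r$values < 0, NA_integer_, r$values),
    onset = log$frame_time[starts],
    offset = log$frame_time[ends] + dt,
    n_frames = r$lengths,
    duration = r$lengths * dt
  )
}

#' Proportion of frames flagged as highlight flicker
#'
#' Highlight runs shorter than `min_duration` (50 ms by default) are treated
#' as visualised measurement error - the viewer experiences them as a
#' flickering outline.  The metric is the number of frames belonging to such
#' short runs divided by the total number of stimulus frames.  Frames with
#' no highlight are never flagged but count toward the total.
#'
#' @param log A highlight log (tibble with `frame_time`, `hex`).
#' @param min_duration Minimum run duration in seconds for a highlight to
#'   count as real.
#' @return A proportion in `[0, 1]`.
#' @export
flicker_metric <- function(log, min_duration = 0.050) {
  if (is.null(log) || nrow(log) == 0) {
    stop("undefined metric: empty highlight log", call. = FALSE)
  }
  runs <- highlight_runs(log)
  # strict "shorter than": a run lasting exactly min_duration is not
  # flicker; the tolerance absorbs frame-interval rounding
  short <- !is.na(runs$hex) & runs$duration < min_duration - 1e-9
  sum(runs$n_frames[short]) / nrow(log)
}
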