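GAZE_SCHEMA <- c("t_s", "lx_deg", "ly_deg", "rx_deg", "ry_deg",
                 "lvalid", "rvalid")
SCHEMA_VERSION <- "1"

#' Write / read a gaze stream as CSV
#'
#' One row per sample with columns `t_s, lx_deg, ly_deg, rx_deg, ry_deg,
#' lvalid, rvalid`.  Reading validates the header, rejects malformed rows
#' with row-numbered diagnostics, and requires strictly increasing
#' timestamps.
#'
#' @param stream A gaze-stream tibble (`t`, `xl`, `yl`, `xr`, `yr`,
#'   `valid_l`, `valid_r`).
#' @param path File path.
#' @return `read_gaze_csv()` returns the stream tibble; `write_gaze_csv()`
#'   returns `stream` invisibly.
#' @export
write_gaze_csv <- function(stream, path) {
  out <- tibble::tibble(
    t_s = stream$t, lx_deg = stream$xl, ly_deg = stream$yl,
    rx_deg = stream$xr, ry_deg = stream$yr,
    lvalid = as.integer(stream$valid_l), rvalid = as.integer(stream$valid_r)
  )
  readr::write_csv(out, path)
  invisible(stream)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, col_types =
                                    readr::cols(.default = "c"),
                                  show_col_types = FALSE))
  missing <- setdiff(GAZE_SCHEMA, header)
  if (length(missing) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      t_s = "d", lx_deg = "d", ly_deg = "d", rx_deg = "d", ry_deg = "d",
      lvalid = "i", rvalid = "i"
    ),
    show_col_types = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("schema error in ", path, ": malformed value(s) at file line(s) ",
         paste(unique(probs$row), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(raw$t_s))) {
    stop("schema error in ", path, ": missing timestamp(s)", call. = FALSE)
  }
  if (nrow(raw) > 1 && any(diff(raw$t_s) <= 0)) {
    stop("integrity error in ", path,
         ": timestamps are not strictly increasing", call. = FALSE)
  }
  tibble::tibble(
    t = raw$t_s, xl = raw$lx_deg, yl = raw$ly_deg,
    xr = raw$rx_deg, yr = raw$ry_deg,
    valid_l = raw$lvalid > 0, valid_r = raw$rvalid > 0
  )
}

#' Write / read a highlight log as CSV
#'
#' Columns `frame_time_s`, `hex_id`; a `hex_id` of -1 encodes "nothing
#' highlighted".  The round trip is bit-exact.
#'
#' @param log A highlight log tibble (`frame_time`, `hex`).
#' @param path File path.
#' @return `read_highlight_csv()` returns the log; `write_highlight_csv()`
#'   returns `log` invisibly.
#' @export
write_highlight_csv <- function(log, path) {
  out <- tibble::tibble(
    frame_time_s = log$frame_time,
    hex_id = ifelse(is.na(log$hex), -1L, as.integer(log$hex))
  )
  readr::write_csv(out, path)
  invisible(log)
}

#' @rdname write_highlight_csv
#' @export
read_highlight_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(frame_time_s = "d",
                                                       hex_id = "i"),
                         show_col_types = FALSE)
  if (!all(c("frame_time_s", "hex_id") %in% names(raw))) {
    stop("schema error in ", path, call. = FALSE)
  }
  if (nrow(raw) > 1 && any(diff(raw$frame_time_s) <= 0)) {
    stop("integrity error in ", path,
         ": frame times are not strictly increasing", call. = FALSE)
  }
  log <- tibble::tibble(
    frame_time = raw$frame_time_s,
    hex = ifelse(raw$hex_id < 0, NA_integer_, raw$hex_id)
  )
  class(log) <- c("highlight_log", class(log))
  log
}

#' Write / read trial records as CSV
#'
#' @param records A trial-record tibble.
#' @param path File path.
#' @return `read_trials_csv()` returns the records tibble;
#'   `write_trials_csv()` returns `records` invisibly.
#' @export
write_trials_csv <- function(records, path) {
  readr::write_csv(records, path, na = "NA")
  invisible(records)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      trial = "i", condition = "c", target_hex = "i", responder = "c",
      response_hex = "i", rt = "d", correct = "l", points_delta = "i",
      participant = "c"
    ),
    show_col_types = FALSE
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("schema error in ", path, ": malformed value(s) in data row(s) ",
         paste(unique(probs$row), collapse = ", "), call. = FALSE)
  }
  raw
}

#' Write a simulated session to disk
#'
#' Writes every trial's gaze streams and highlight logs as CSV, the trial
#' log, the grid configuration, and a JSON manifest naming all parts, so
#' the session can be re-read with [read_session()] and analysed with
#' [run_pipeline()].
#'
#' @param session A `search_session` from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "search_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest_trials <- list()
  for (k in seq_along(session$trials)) {
    tr <- session$trials[[k]]
    if (inherits(tr, "pair_trial")) {
      base <- sprintf("trial%03d_%s", tr$trial, tr$condition)
      entry <- list(trial = tr$trial, condition = tr$condition,
                    target_hex = tr$target, kind = "pair",
                    gaze = list(), highlight = list())
      for (p in c("a", "b")) {
        gf <- paste0(base, "_gaze_", p, ".csv")
        hf <- paste0(base, "_highlight_", p, ".csv")
        write_gaze_csv(tr$agents[[p]]$stream, file.path(dir, gf))
        write_highlight_csv(tr$highlights[[p]], file.path(dir, hf))
        entry$gaze[[p]] <- gf
        entry$highlight[[p]] <- hf
      }
      manifest_trials[[length(manifest_trials) + 1L]] <- entry
    } else {
      p <- tr$participant
      base <- sprintf("trial%03d_individual_%s", tr$trial, p)
      gf <- paste0(base, "_gaze.csv")
      write_gaze_csv(tr$stream, file.path(dir, gf))
      manifest_trials[[length(manifest_trials) + 1L]] <-
        list(trial = tr$trial, condition = "individual",
             target_hex = tr$target, kind = "solo", participant = p,
             gaze = stats::setNames(list(gf), p))
    }
  }
  write_trials_csv(session$records, file.path(dir, "trials.csv"))
  grid_cfg <- session$grid[c("spacing", "n_rows", "n_cols", "jitter_max",
                             "screen_width_mm", "screen_width_px",
                             "viewing_distance_mm", "screen_height_px",
                             "display_px")]
  yaml::write_yaml(grid_cfg, file.path(dir, "grid.yaml"))
  manifest <- list(
    schema_version = SCHEMA_VERSION,
    master_seed = session$seed,
    grid_config = "grid.yaml",
    trial_log = "trials.csv",
    trials = manifest_trials
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory containing `manifest.json`.
#' @return A `search_session` object.  Ground-truth fixation lists are not
#'   stored on disk; [run_pipeline()] re-derives events from the streams.
#' @export
read_session <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  if (!identical(manifest$schema_version, SCHEMA_VERSION)) {
    stop("manifest schema version ", manifest$schema_version,
         " does not match reader version ", SCHEMA_VERSION, call. = FALSE)
  }
  grid <- read_grid_config(file.path(dir, manifest$grid_config))
  records <- read_trials_csv(file.path(dir, manifest$trial_log))
  trials <- lapply(manifest$trials, function(entry) {
    if (identical(entry$kind, "pair")) {
      rec <- records[records$trial == entry$trial &
                       records$condition == entry$condition, ]
      structure(list(
        trial = entry$trial, condition = entry$condition,
        target = entry$target_hex,
        agents = list(
          a = list(stream = read_gaze_csv(file.path(dir, entry$gaze$a))),
          b = list(stream = read_gaze_csv(file.path(dir, entry$gaze$b)))
        ),
        highlights = list(
          a = read_highlight_csv(file.path(dir, entry$highlight$a)),
          b = read_highlight_csv(file.path(dir, entry$highlight$b))
        ),
        record = rec
      ), class = "pair_trial")
    } else {
      p <- entry$participant
      rec <- records[records$trial == entry$trial &
                       records$condition == "individual" &
                       records$participant == p, ]
      structure(list(
        trial = entry$trial, condition = "individual", participant = p,
        target = entry$target_hex,
        stream = read_gaze_csv(file.path(dir, entry$gaze[[p]])),
        record = rec
      ), class = "searcher_trial")
    }
  })
  structure(list(trials = trials, records = records,
                 seed = manifest$master_seed, grid = grid),
            class = "search_session")
}
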