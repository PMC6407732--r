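#' Run the full analysis pipeline over a session
#'
#' Executes the event, coordination, and summary stages for every trial of
#' a session: fixation detection, dwell and transition construction,
#' eye-movement and data-quality parameters, dwell overlap against the
#' partner's highlight log, cumulative-overlap curves with a bootstrap
#' band, per-condition dwell and transition entropies, performance
#' summaries, and (when individual trials are present) the simulated
#' blind-pair baseline.  A stage error in one trial is caught, logged in
#' the failure summary, and does not stop the other trials.  The run is
#' deterministic for fixed inputs and seed.
#'
#' @param session A `search_session` object (from [simulate_session()] or
#'   [read_session()]), or a directory path to pass to [read_session()].
#' @param dispersion,min_duration Fixation-detector settings
#'   ([detect_fixations()]).
#' @param min_highlight Flicker-exclusion threshold in seconds for the
#'   overlap measures.
#' @param n_boot,seed Bootstrap settings for the overlap-curve band.
#' @param frame_rate Display frame rate in Hz for the overlap time grid.
#'
#' @return A list of class `search_analysis`:
#' * `trial_metrics` - one row per trial x participant with eye-movement
#'   parameters, precision, flicker, overlap proportion and overlooking;
#' * `entropy` - one row per condition x participant with [scan_entropy()];
#' * `performance` - [performance_summary()] by condition, plus a
#'   `blind_baseline` row when individual trials allow it;
#' * `overlap_curves` - aggregated cumulative-overlap curves per condition;
#' * `failures` - trials that errored, with the message.
#' @export
run_pipeline <- function(session, dispersion = 1.0, min_duration = 0.060,
                         min_highlight = 0.050, n_boot = 1000, seed = 1,
                         frame_rate = 60) {
  if (is.character(session)) session <- read_session(session)
  stopifnot(inherits(session, "search_session"))
  if (length(session$trials) == 0) stop("empty session: no trials",
                                        call. = FALSE)
  grid <- session$grid
  trial_rows <- list()
  curve_rows <- list()
  seqs <- list()  # dwell sequences per condition:participant
  failures <- list()

  add_seq <- function(cond, p, hexes) {
    key <- paste(cond, p, sep = ":")
    seqs[[key]] <<- c(seqs[[key]], list(hexes))
  }

  for (tr in session$trials) {
    res <- tryCatch({
      if (inherits(tr, "pair_trial")) {
        for (p in c("a", "b")) {
          other <- if (p == "a") "b" else "a"
          stream <- tr$agents[[p]]$stream
          fx <- detect_fixations(stream, dispersion, min_duration)
          dw <- build_dwells(fx, grid)
          emp <- eye_movement_params(fx, grid, duration = tr$record$rt)
          prec <- precision_metrics(stream, fixations = fx)
          ovl <- dwell_overlap_proportion(dw, tr$highlights[[other]],
                                          min_highlight)
          cv <- cumulative_overlap(
            own_dwells = dw, partner_log = tr$highlights[[other]],
            duration = tr$record$rt, min_highlight = min_highlight,
            frame_rate = frame_rate, grid = grid
          )
          cv$curve_id <- paste(tr$condition, tr$trial, p, sep = ":")
          cv$condition <- tr$condition
          curve_rows[[length(curve_rows) + 1L]] <- cv
          add_seq(tr$condition, p, dw$hex)
          trial_rows[[length(trial_rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(trial = tr$trial, condition = tr$condition,
                           participant = p, rt = tr$record$rt,
                           correct = tr$record$correct,
                           target_hex = tr$record$target_hex),
            emp, prec[, c("rms_s2s", "mean_sd")],
            tibble::tibble(
              flicker = flicker_metric(tr$highlights[[p]], min_highlight),
              overlap = ovl,
              overlooked = overlooked_target(dw, tr$record$target_hex)
            )
          )
        }
      } else {
        p <- tr$participant
        fx <- detect_fixations(tr$stream, dispersion, min_duration)
        dw <- build_dwells(fx, grid)
        emp <- eye_movement_params(fx, grid, duration = tr$record$rt)
        prec <- precision_metrics(tr$stream, fixations = fx)
        add_seq("individual", p, dw$hex)
        trial_rows[[length(trial_rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(trial = tr$trial, condition = "individual",
                         participant = p, rt = tr$record$rt,
                         correct = tr$record$correct,
                         target_hex = tr$record$target_hex),
          emp, prec[, c("rms_s2s", "mean_sd")],
          tibble::tibble(flicker = NA_real_, overlap = NA_real_,
                         overlooked = overlooked_target(
                           dw, tr$record$target_hex))
        )
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        trial = tr$trial,
        condition = if (!is.null(tr$condition)) tr$condition else NA,
        error = res
      )
    }
  }

  trial_metrics <- dplyr::bind_rows(trial_rows)
  if (nrow(trial_metrics) == 0) {
    stop("pipeline failed on every trial; first error: ",
         failures[[1]]$error, call. = FALSE)
  }

  entropy <- purrr::imap(seqs, function(s, key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    dplyr::bind_cols(
      tibble::tibble(condition = parts[1], participant = parts[2]),
      scan_entropy(s, grid$n_elements)
    )
  }) |> dplyr::bind_rows()

  performance <- performance_summary(session$records)
  indiv <- session$records[session$records$condition == "individual", ]
  if (nrow(indiv) > 0 && all(c("a", "b") %in% indiv$participant)) {
    bb <- blind_baseline(indiv[indiv$participant == "a", ],
                         indiv[indiv$participant == "b", ])
    if (nrow(bb) > 0) {
      bb$condition <- "blind_baseline"
      performance <- dplyr::bind_rows(performance,
                                      performance_summary(bb))
    }
  }

  curves <- dplyr::bind_rows(curve_rows)
  overlap_curves <- NULL
  if (nrow(curves) > 0) {
    overlap_curves <- curves |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_modify(function(d, g) {
        aggregate_overlap_curves(d, n_boot = n_boot, seed = seed)
      }) |>
      dplyr::ungroup()
  }

  structure(list(
    trial_metrics = trial_metrics,
    entropy = entropy,
    performance = performance,
    overlap_curves = overlap_curves,
    failures = dplyr::bind_rows(failures),
    params = list(dispersion = dispersion, min_duration = min_duration,
                  min_highlight = min_highlight, n_boot = n_boot,
                  seed = seed, frame_rate = frame_rate)
  ), class = "search_analysis")
}

#' @export
print.search_analysis <- function(x, ...) {
  cat(sprintf(
    "<search_analysis> %d trial-level rows, %d failures\n",
    nrow(x$trial_metrics), nrow(x$failures)
  ))
  print(x$performance)
  invisible(x)
}

#' @export
#' @method tidy search_analysis
tidy.search_analysis <- function(x, ...) x$trial_metrics

#' @export
#' @method glance search_analysis
glance.search_analysis <- function(x, ...) x$performance

#' Write the analysis tables of a pipeline run as tidy CSVs
#'
#' @param analysis A `search_analysis` from [run_pipeline()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "search_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(analysis$trial_metrics,
                   file.path(dir, "trial_metrics.csv"))
  readr::write_csv(analysis$entropy, file.path(dir, "entropy.csv"))
  readr::write_csv(analysis$performance, file.path(dir, "performance.csv"))
  if (!is.null(analysis$overlap_curves)) {
    readr::write_csv(analysis$overlap_curves,
                     file.path(dir, "overlap_curves.csv"))
  }
  if (nrow(analysis$failures) > 0) {
    readr::write_csv(analysis$failures, file.path(dir, "failures.csv"))
  }
  invisible(dir)
}
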