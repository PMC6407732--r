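#' Strategy parameters for a simulated searcher
#'
#' Bundles the behavioural parameters of one simulated searcher.  Agents
#' visit search elements according to a scanning policy (`kind`), spend one
#' or more fixations on each element, and report the target after an
#' identification delay unless they overlook it.
#'
#' Policies:
#' * `raster_full` - serpentine raster over all elements from the start
#'   corner; the same itinerary every trial.
#' * `raster_divided` - serpentine raster over the searcher's own half of
#'   the array (split by column, the middle column shared), then the
#'   remaining elements in raster order; emulates a division-of-labour pair.
#' * `random_walk` - steps to a uniformly chosen adjacent unvisited element
#'   (jumping to a random unvisited element when boxed in); a different,
#'   unpredictable path every trial.
#' * `fresh_tile_competitor` - an unsystematic scanner: jumps to a random
#'   element it has not yet inspected itself, restricting the draw (with
#'   probability `avoid_partner_prob`) to tiles the competitor has not yet
#'   highlighted; emulates racing for fresh tiles with an unpredictable
#'   scanpath.
#' * `blind_independent` - identical to `raster_full` but never consults the
#'   partner, whatever the pair coupling.
#'
#' @param kind Scanning policy; see Details.
#' @param start_corner Where scanning begins: one of `"top_left"`,
#'   `"top_right"`, `"bottom_left"`, `"bottom_right"`, `"center_adjacent"`.
#' @param fixation_duration_mean,fixation_duration_sd Mean and SD in seconds
#'   of the truncated-normal fixation duration distribution.
#' @param fixation_duration_floor Lower truncation bound in seconds.
#' @param dwell_fixations Mean number of fixations per element visit
#'   (must be >= 1; the excess over 1 is Poisson distributed).
#' @param identification_miss_prob Probability of overlooking the target on
#'   a visit to the target element.
#' @param response_delay Seconds from the onset of the identifying dwell on
#'   the target to the response key press.
#' @param response_error_prob Probability that the response click lands on a
#'   neighbouring cell instead of the target (an incorrect answer).
#' @param noise_sd Per-eye, per-axis standard deviation in degrees of the
#'   isotropic Gaussian measurement noise added to every gaze sample.
#' @param avoid_partner_prob Probability in `[0, 1]` of skipping an element
#'   the partner has already highlighted.
#' @param max_visits Cap on element visits; a trial with no response ends
#'   when both searchers reach the cap.
#'
#' @return An object of class `strategy_params` (a named list).
#' @export
strategy_params <- function(kind = c("raster_full", "raster_divided",
                                     "random_walk", "fresh_tile_competitor",
                                     "blind_independent"),
                            start_corner = c("top_left", "top_right",
                                             "bottom_left", "bottom_right",
                                             "center_adjacent"),
                            fixation_duration_mean = 0.25,
                            fixation_duration_sd = 0.05,
                            fixation_duration_floor = 0.06,
                            dwell_fixations = 1.3,
                            identification_miss_prob = 0.1,
                            response_delay = 0.35,
                            response_error_prob = 0.02,
                            noise_sd = 0.21,
                            avoid_partner_prob = 1,
                            max_visits = 75) {
  kind <- match.arg(kind)
  start_corner <- match.arg(start_corner)
  probs <- c(identification_miss_prob, response_error_prob,
             avoid_partner_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("strategy probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (fixation_duration_mean <= 0 || fixation_duration_sd < 0 ||
      fixation_duration_floor <= 0 || response_delay <= 0) {
    stop("strategy durations must be positive", call. = FALSE)
  }
  if (dwell_fixations < 1) stop("`dwell_fixations` must be >= 1",
                                call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (max_visits < 1) stop("`max_visits` must be >= 1", call. = FALSE)
  structure(
    list(kind = kind, start_corner = start_corner,
         fixation_duration_mean = fixation_duration_mean,
         fixation_duration_sd = fixation_duration_sd,
         fixation_duration_floor = fixation_duration_floor,
         dwell_fixations = dwell_fixations,
         identification_miss_prob = identification_miss_prob,
         response_delay = response_delay,
         response_error_prob = response_error_prob,
         noise_sd = noise_sd,
         avoid_partner_prob = avoid_partner_prob,
         max_visits = as.integer(max_visits)),
    class = "strategy_params"
  )
}

# element id at a named start position
corner_element <- function(grid, corner) {
  ce <- grid$centers
  switch(corner,
    top_left = ce$hex_id[ce$row == 0 & ce$col == 0],
    top_right = ce$hex_id[ce$row == 0 & ce$col == grid$n_cols - 1],
    bottom_left = ce$hex_id[ce$row == grid$n_rows - 1 & ce$col == 0],
    bottom_right = ce$hex_id[ce$row == grid$n_rows - 1 &
                               ce$col == grid$n_cols - 1],
    center_adjacent = {
      mid <- (grid$n_elements - 1L) %/% 2L
      mid - grid$n_cols  # the cell one row above the middle
    }
  )
}

# serpentine raster itinerary (vector of hex ids) from a start corner
raster_itinerary <- function(grid, corner) {
  rows <- seq_len(grid$n_rows) - 1L
  cols <- seq_len(grid$n_cols) - 1L
  from_bottom <- corner %in% c("bottom_left", "bottom_right")
  from_right <- corner %in% c("top_right", "bottom_right")
  if (from_bottom) rows <- rev(rows)
  out <- integer(0)
  left_to_right <- !from_right
  for (r in rows) {
    cc <- if (left_to_right) cols else rev(cols)
    out <- c(out, r * grid$n_cols + cc)
    left_to_right <- !left_to_right
  }
  out
}

# itinerary for a divided raster: own half (by column) first, rest after
divided_itinerary <- function(grid, corner) {
  full <- raster_itinerary(grid, corner)
  col_of <- grid$centers$col[match(full, grid$centers$hex_id)]
  mid <- (grid$n_cols - 1L) %/% 2L
  own <- if (corner %in% c("top_left", "bottom_left", "center_adjacent")) {
    col_of <= mid
  } else {
    col_of >= mid
  }
  c(full[own], full[!own])
}

# adjacency list of the hexagonal tiling (ids 0-based)
hex_neighbors <- function(grid) {
  ce <- grid$centers
  d <- as.matrix(stats::dist(ce[, c("x_deg", "y_deg")]))
  lapply(seq_len(nrow(ce)), function(i) {
    ce$hex_id[d[i, ] > 0 & d[i, ] < grid$spacing * 1.01]
  })
}

new_agent <- function(params, grid, id) {
  itinerary <- switch(params$kind,
    raster_full = raster_itinerary(grid, params$start_corner),
    blind_independent = raster_itinerary(grid, params$start_corner),
    raster_divided = divided_itinerary(grid, params$start_corner),
    integer(0)
  )
  list(
    id = id,
    params = params,
    itinerary = itinerary,
    start = corner_element(grid, params$start_corner),
    uses_partner = !identical(params$kind, "blind_independent"),
    visited = logical(grid$n_elements),
    visit_seq = integer(0),
    cur = NA_integer_,
    t = 0,
    fix_on = numeric(0), fix_off = numeric(0), fix_hex = integer(0),
    highlight_onset = rep(Inf, grid$n_elements),
    done = FALSE, responded = FALSE, response_time = Inf
  )
}

# next element for one agent; consults the set of elements the partner has
# highlighted by t_now.  Uses the session RNG stream.
choose_next <- function(ag, grid, neighbors, partner_on, t_now) {
  n <- grid$n_elements
  avoid <- if (ag$uses_partner) ag$params$avoid_partner_prob else 0
  highlighted <- partner_on <= t_now

  if (ag$params$kind %in% c("raster_full", "raster_divided",
                            "blind_independent")) {
    unvis <- ag$itinerary[!ag$visited[ag$itinerary + 1L]]
    if (length(unvis) > 0) {
      if (avoid > 0) {
        for (e in unvis) {
          if (highlighted[e + 1L] && stats::runif(1) < avoid) next
          return(e)
        }
        return(unvis[1L])  # every remaining element skipped: forced move
      }
      return(unvis[1L])
    }
    # revisit phase: itinerary order, skipping the element just left
    rev_seq <- ag$itinerary[ag$itinerary != ag$cur]
    return(rev_seq[1L + (length(ag$visit_seq) %% length(rev_seq))])
  }

  if (ag$params$kind == "random_walk") {
    if (is.na(ag$cur)) return(ag$start)
    nb <- neighbors[[ag$cur + 1L]]
    cand <- nb[!ag$visited[nb + 1L]]
    if (length(cand) == 0) cand <- which(!ag$visited) - 1L
    if (length(cand) == 0) cand <- setdiff(seq_len(n) - 1L, ag$cur)
    if (avoid > 0 && any(highlighted)) {
      keep <- vapply(cand, function(e) {
        !highlighted[e + 1L] || stats::runif(1) >= avoid
      }, logical(1))
      if (any(keep)) cand <- cand[keep]
    }
    return(cand[sample.int(length(cand), 1L)])
  }

  # fresh_tile_competitor: an unsystematic scanner that jumps to a random
  # element it has not yet inspected, preferring (with probability
  # `avoid_partner_prob`) tiles the competitor has not highlighted yet
  if (is.na(ag$cur)) return(ag$start)
  unvis <- which(!ag$visited) - 1L
  if (length(unvis) == 0) {
    cand <- setdiff(seq_len(n) - 1L, ag$cur)
    return(cand[sample.int(length(cand), 1L)])
  }
  fresh <- unvis[!highlighted[unvis + 1L]]
  pool <- if (avoid > 0 && length(fresh) > 0 && stats::runif(1) < avoid) {
    fresh
  } else {
    unvis
  }
  pool[sample.int(length(pool), 1L)]
}

# execute one element visit for an agent; returns the updated agent
agent_step <- function(ag, grid, neighbors, partner_on, target, jit,
                       highlight_latency) {
  p <- ag$params
  e <- choose_next(ag, grid, neighbors, partner_on, ag$t)
  t0 <- ag$t
  identify <- FALSE
  if (e == target && !ag$responded) {
    identify <- stats::runif(1) >= p$identification_miss_prob
  }
  if (identify) {
    durs <- p$response_delay
    ag$responded <- TRUE
    ag$response_time <- t0 + p$response_delay
    ag$done <- TRUE
  } else {
    n_fix <- 1L + stats::rpois(1, p$dwell_fixations - 1)
    durs <- pmax(p$fixation_duration_floor,
                 stats::rnorm(n_fix, p$fixation_duration_mean,
                              p$fixation_duration_sd))
  }
  fx <- grid$centers$x_deg[e + 1L] + jit$dx_deg[e + 1L]
  fy <- grid$centers$y_deg[e + 1L] + jit$dy_deg[e + 1L]
  on <- t0 + cumsum(c(0, durs[-length(durs)]))
  ag$fix_on <- c(ag$fix_on, on)
  ag$fix_off <- c(ag$fix_off, on + durs)
  ag$fix_hex <- c(ag$fix_hex, rep(e, length(durs)))
  if (is.finite(ag$highlight_onset[e + 1L]) == FALSE) {
    ag$highlight_onset[e + 1L] <- t0 + highlight_latency
  }
  ag$visited[e + 1L] <- TRUE
  ag$visit_seq <- c(ag$visit_seq, e)
  ag$cur <- e
  ag$t <- t0 + sum(durs)
  if (!ag$responded && length(ag$visit_seq) >= p$max_visits) ag$done <- TRUE
  ag
}

# co-simulate 1-2 agents on a shared clock; assumes an active RNG stream
run_agents <- function(agents, grid, target, coupled, jitter_seed,
                       static_partner_onset = NULL,
                       highlight_latency = 0.030) {
  jit <- jitter_elements(grid, jitter_seed)
  neighbors <- hex_neighbors(grid)
  repeat {
    min_resp <- min(vapply(agents, function(a) a$response_time, numeric(1)))
    live <- which(vapply(agents, function(a) {
      !a$done && a$t < min_resp
    }, logical(1)))
    if (length(live) == 0) break
    i <- live[which.min(vapply(agents[live], function(a) a$t, numeric(1)))]
    partner_on <- if (length(agents) == 2 && coupled) {
      agents[[if (i == 1L) 2L else 1L]]$highlight_onset
    } else if (!is.null(static_partner_onset)) {
      static_partner_onset
    } else {
      rep(Inf, grid$n_elements)
    }
    agents[[i]] <- agent_step(agents[[i]], grid, neighbors, partner_on,
                              target, jit, highlight_latency)
  }
  agents
}

finish_agent <- function(ag, rt, grid, jit) {
  keep <- ag$fix_on < rt
  fx_on <- ag$fix_on[keep]
  fx_off <- pmin(ag$fix_off[keep], rt)
  fx_hex <- ag$fix_hex[keep]
  tibble::tibble(
    onset = fx_on, offset = fx_off,
    x = grid$centers$x_deg[fx_hex + 1L] + jit$dx_deg[fx_hex + 1L],
    y = grid$centers$y_deg[fx_hex + 1L] + jit$dy_deg[fx_hex + 1L],
    hex_id = fx_hex
  )
}

make_stream <- function(fixations, rt, noise_sd, hz = 120) {
  ts <- seq(0, rt, by = 1 / hz)
  idx <- pmax(1L, findInterval(ts, fixations$onset))
  x <- fixations$x[idx]
  y <- fixations$y[idx]
  n <- length(ts)
  tibble::tibble(
    t = ts,
    xl = x + stats::rnorm(n, 0, noise_sd),
    yl = y + stats::rnorm(n, 0, noise_sd),
    xr = x + stats::rnorm(n, 0, noise_sd),
    yr = y + stats::rnorm(n, 0, noise_sd),
    valid_l = TRUE, valid_r = TRUE
  )
}

# response click: usually the target, occasionally a neighbouring cell
response_click <- function(target, grid, error_prob) {
  if (stats::runif(1) < error_prob) {
    nb <- hex_neighbors(grid)[[target + 1L]]
    nb[sample.int(length(nb), 1L)]
  } else {
    target
  }
}

#' Simulate one searcher on one trial
#'
#' Runs a single simulated searcher through a search trial: the agent visits
#' elements according to its strategy, fixates each for a sampled duration,
#' and responds after `response_delay` once it fixates and identifies the
#' target.  Gaze is emitted as a binocular 120-Hz sample stream around the
#' fixated element positions with isotropic Gaussian noise per eye.  Saccades
#' are instantaneous relocations.
#'
#' @param strategy A [strategy_params()] object.
#' @param grid A [hex_grid()] object.
#' @param target Target element id (must not be the middle cell).
#' @param partner_highlights Optional highlight log (tibble with
#'   `frame_time`, `hex`) that the agent treats as its partner's gaze marker
#'   history when deciding which elements to skip.
#' @param seed Integer seed; the trial is deterministic given the seed.
#' @param condition Condition label stored in the trial record.
#' @param participant Participant label stored in the outputs.
#'
#' @return A list of class `searcher_trial` with elements `stream` (the
#'   gaze samples), `fixations` (ground-truth fixation list with element
#'   ids), and `record` (a one-row trial-record tibble).
#' @export
simulate_searcher <- function(strategy, grid, target,
                              partner_highlights = NULL, seed,
                              condition = "individual",
                              participant = "a") {
  stopifnot(inherits(strategy, "strategy_params"), inherits(grid, "hex_grid"))
  check_target(target, grid)
  static_on <- NULL
  if (!is.null(partner_highlights)) {
    runs <- highlight_runs(partner_highlights)
    static_on <- rep(Inf, grid$n_elements)
    if (nrow(runs) > 0) {
      first <- stats::aggregate(onset ~ hex, data = runs, FUN = min)
      static_on[first$hex + 1L] <- first$onset
    }
  }
  withr::with_seed(as.integer(seed), {
    jitter_seed <- sample.int(.Machine$integer.max, 1L)
    jit <- jitter_elements(grid, jitter_seed)
    ag <- run_agents(list(new_agent(strategy, grid, participant)), grid,
                     target, coupled = FALSE, jitter_seed = jitter_seed,
                     static_partner_onset = static_on)[[1]]
    rt <- if (ag$responded) ag$response_time else ag$t
    fixations <- finish_agent(ag, rt, grid, jit)
    stream <- make_stream(fixations, rt, strategy$noise_sd)
    record <- make_record(list(ag), rt, target, grid, condition,
                          participants = participant, trial = 1L)
    structure(list(trial = 1L, stream = stream, fixations = fixations,
                   record = record, target = target,
                   participant = participant),
              class = "searcher_trial")
  })
}

check_target <- function(target, grid) {
  mid <- (grid$n_elements - 1L) %/% 2L
  if (!is.numeric(target) || length(target) != 1 ||
      !(target %in% (seq_len(grid$n_elements) - 1L)) || target == mid) {
    stop("invalid config: `target` must be a grid element id other than ",
         "the middle cell (", mid, ")", call. = FALSE)
  }
  invisible(TRUE)
}

make_record <- function(agents, rt, target, grid, condition, participants,
                        trial) {
  resp_times <- vapply(agents, function(a) a$response_time, numeric(1))
  if (any(is.finite(resp_times))) {
    w <- which.min(resp_times)
    responder <- participants[w]
    click <- response_click(target, grid,
                            agents[[w]]$params$response_error_prob)
    correct <- click == target
    points <- if (correct) 300L else -600L
  } else {
    responder <- NA_character_
    click <- NA_integer_
    correct <- FALSE
    points <- NA_integer_
  }
  tibble::tibble(
    trial = as.integer(trial), condition = condition,
    target_hex = as.integer(target), responder = responder,
    response_hex = as.integer(click), rt = rt, correct = correct,
    points_delta = points
  )
}

#' Simulate a coupled pair of searchers on one trial
#'
#' Runs two agents concurrently on a shared clock.  Under `"collaborate"`
#' and `"compete"` coupling, each agent's element choices consult the set of
#' elements its partner has highlighted so far (an element counts as
#' highlighted from its first fixation onset plus the 30-ms online window);
#' under `"blind"` coupling the agents ignore each other.  The trial ends at
#' the first response and the other agent's stream is truncated there.
#'
#' The returned object also carries the reconstructed highlight logs (what
#' each participant's marker showed on the partner's screen), computed from
#' the simulated streams with [highlight_stream()].
#'
#' @param strategies A list of two [strategy_params()] objects (named or in
#'   order participant a, participant b).
#' @param coupling `"collaborate"`, `"compete"`, or `"blind"`.
#' @param grid A [hex_grid()] object.
#' @param target Target element id.
#' @param seed Integer seed.
#' @param trial Trial number stored in the record.
#'
#' @return A list of class `pair_trial`: `condition`, `target`, `agents`
#'   (per participant: `stream`, `fixations`), `highlights` (per
#'   participant: the log of that participant's own gaze marker), and
#'   `record`.
#' @export
simulate_pair <- function(strategies, coupling = c("collaborate", "compete",
                                                   "blind"),
                          grid, target, seed, trial = 1L) {
  coupling <- match.arg(coupling)
  stopifnot(length(strategies) == 2)
  lapply(strategies, function(s) stopifnot(inherits(s, "strategy_params")))
  stopifnot(inherits(grid, "hex_grid"))
  check_target(target, grid)
  withr::with_seed(as.integer(seed), {
    jitter_seed <- sample.int(.Machine$integer.max, 1L)
    jit <- jitter_elements(grid, jitter_seed)
    agents <- list(new_agent(strategies[[1]], grid, "a"),
                   new_agent(strategies[[2]], grid, "b"))
    agents <- run_agents(agents, grid, target,
                         coupled = coupling != "blind",
                         jitter_seed = jitter_seed)
    resp <- vapply(agents, function(a) a$response_time, numeric(1))
    rt <- if (any(is.finite(resp))) min(resp) else
      max(vapply(agents, function(a) a$t, numeric(1)))
    fixations <- lapply(agents, finish_agent, rt = rt, grid = grid,
                        jit = jit)
    streams <- lapply(seq_along(agents), function(i) {
      make_stream(fixations[[i]], rt, strategies[[i]]$noise_sd)
    })
    record <- make_record(agents, rt, target, grid, coupling,
                          participants = c("a", "b"), trial = trial)
    highlights <- lapply(streams, highlight_stream, grid = grid)
    structure(list(
      trial = as.integer(trial), condition = coupling,
      target = as.integer(target),
      agents = list(
        a = list(stream = streams[[1]], fixations = fixations[[1]]),
        b = list(stream = streams[[2]], fixations = fixations[[2]])
      ),
      highlights = list(a = highlights[[1]], b = highlights[[2]]),
      record = record
    ), class = "pair_trial")
  })
}

#' Draw random target locations
#'
#' Uniform draws over the grid elements excluding the middle cell, where the
#' target never appears (searchers start each trial looking there).
#'
#' @param n Number of targets.
#' @param seed Integer seed.
#' @param grid A [hex_grid()] object.
#' @return An integer vector of element ids.
#' @export
sample_targets <- function(n, seed, grid = hex_grid()) {
  mid <- (grid$n_elements - 1L) %/% 2L
  ids <- setdiff(seq_len(grid$n_elements) - 1L, mid)
  withr::with_seed(as.integer(seed), {
    ids[sample.int(length(ids), n, replace = TRUE)]
  })
}

#' Default pair strategies per condition
#'
#' The study conditions as scanning policies: collaborating pairs divide the
#' array by half and fully avoid elements their partner has highlighted;
#' competing pairs scan unsystematically for fresh tiles with slightly
#' shorter fixations and imperfect avoidance; blind pairs raster
#' independently from neighbouring corners, ignoring each other.
#'
#' @param condition `"individual"`, `"collaborate"`, `"compete"`, `"blind"`.
#' @return A list with elements `a` and `b` ([strategy_params()] objects);
#'   for `"individual"`, the two solo searchers' strategies.
#' @export
default_strategies <- function(condition = c("collaborate", "compete",
                                             "blind", "individual")) {
  condition <- match.arg(condition)
  switch(condition,
    individual = list(
      a = strategy_params("raster_full", "top_left"),
      b = strategy_params("raster_full", "bottom_right")
    ),
    collaborate = list(
      a = strategy_params("raster_divided", "top_left",
                          avoid_partner_prob = 1),
      b = strategy_params("raster_divided", "bottom_right",
                          avoid_partner_prob = 1)
    ),
    compete = list(
      a = strategy_params("fresh_tile_competitor", "top_left",
                          fixation_duration_mean = 0.22,
                          avoid_partner_prob = 0.5),
      b = strategy_params("fresh_tile_competitor", "top_right",
                          fixation_duration_mean = 0.22,
                          avoid_partner_prob = 0.5)
    ),
    blind = list(
      a = strategy_params("blind_independent", "top_left"),
      b = strategy_params("blind_independent", "top_right")
    )
  )
}

#' Simulate a full experimental session
#'
#' Simulates `n_trials` trials for each requested condition with a unique
#' random target per trial (never the middle cell) and per-trial seeds
#' derived from the master seed.  Pair conditions produce [simulate_pair()]
#' trials; the `"individual"` condition produces one solo trial per
#' participant per trial number, usable to construct the blind baseline.
#'
#' @param n_trials Trials per condition.
#' @param conditions Character vector of conditions to simulate.
#' @param strategies Optional named list mapping condition to a list of two
#'   [strategy_params()]; defaults to [default_strategies()].
#' @param seed Master integer seed.
#' @param grid A [hex_grid()] object.
#' @param dir Optional directory: when given, all artifacts (gaze CSVs,
#'   highlight CSVs, trial log, manifest) are written there via
#'   [write_session()].
#'
#' @return A list of class `search_session` with `trials` (list of
#'   `pair_trial` / `searcher_trial` objects), `records` (tibble of all
#'   trial records with a `participant` column for solo trials), `seed`, and
#'   `grid`.
#' @export
simulate_session <- function(n_trials,
                             conditions = c("collaborate", "compete",
                                            "blind"),
                             strategies = NULL, seed,
                             grid = hex_grid(), dir = NULL) {
  stopifnot(n_trials >= 1)
  bad <- setdiff(conditions,
                 c("individual", "collaborate", "compete", "blind"))
  if (length(bad) > 0) stop("unknown condition(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  seeds_and_targets <- withr::with_seed(as.integer(seed), {
    list(
      seeds = matrix(sample.int(.Machine$integer.max - 1L,
                                n_trials * length(conditions)),
                     nrow = n_trials),
      targets = matrix(sample_targets(n_trials * length(conditions),
                                      seed = sample.int(2^31 - 1, 1L),
                                      grid = grid),
                       nrow = n_trials)
    )
  })
  trials <- list()
  records <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    strat <- if (!is.null(strategies) && !is.null(strategies[[cond]])) {
      strategies[[cond]]
    } else {
      default_strategies(cond)
    }
    for (k in seq_len(n_trials)) {
      s <- seeds_and_targets$seeds[k, ci]
      tg <- seeds_and_targets$targets[k, ci]
      if (cond == "individual") {
        for (p in c("a", "b")) {
          tr <- simulate_searcher(strat[[p]], grid, tg,
                                  seed = s + (p == "b"),
                                  condition = "individual",
                                  participant = p)
          tr$record$trial <- as.integer(k)
          tr$trial <- as.integer(k)
          trials[[length(trials) + 1L]] <- tr
          records[[length(records) + 1L]] <-
            dplyr::mutate(tr$record, participant = p)
        }
      } else {
        tr <- simulate_pair(strat, coupling = cond, grid = grid,
                            target = tg, seed = s, trial = k)
        trials[[length(trials) + 1L]] <- tr
        records[[length(records) + 1L]] <-
          dplyr::mutate(tr$record, participant = NA_character_)
      }
    }
  }
  session <- structure(
    list(trials = trials, records = dplyr::bind_rows(records),
         seed = as.integer(seed), grid = grid),
    class = "search_session"
  )
  if (!is.null(dir)) write_session(session, dir)
  session
}

#' @export
print.search_session <- function(x, ...) {
  cat(sprintf("<search_session> %d trials (%s), master seed %d\n",
              length(x$trials),
              paste(unique(x$records$condition), collapse = ", "),
              x$seed))
  invisible(x)
}
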