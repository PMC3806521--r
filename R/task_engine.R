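#' Task configuration for the five-subtest battery
#'
#' Geometry, kinematics and stimulus schedules for the headless subtest
#' engine. The battery's tasks are: (1) selective attention — automatic
#' steering plus pedal responses to a single peripheral target type; (2)
#' eye-hand coordination — the respondent steers, no peripheral task; (3)
#' divided attention — steering and peripheral responses simultaneously; (4)
#' executive function — two peripheral target classes, both requiring a
#' response, while the central motion is ignored; (5) distance judgment and
#' speed regulation — crossing intersections without colliding with crossing
#' traffic. All numeric defaults are engine choices in abstract units; only
#' the task semantics matter for downstream scoring.
#'
#' @param street_half_width half-width of the street (length units).
#' @param avatar_half_width half-width of the steered avatar.
#' @param object_half_width,object_half_height extent of descending objects.
#' @param spawn_rate objects spawned per second.
#' @param object_speed descent speed (units/s).
#' @param spawn_y vertical spawn position.
#' @param stim_rate peripheral stimuli per second.
#' @param distractor_fraction fraction of peripheral stimuli that are
#'   distractors (no response required).
#' @param response_window seconds after target onset within which a pedal
#'   press counts as a hit.
#' @param steer_speed maximal lateral avatar speed (units/s).
#' @param dt simulation time step (s); must not exceed `response_window`.
#' @param duration subtest duration (s); default 180, i.e. about three
#'   minutes per subtest.
#' @param traffic_rate crossing objects per second at each intersection
#'   (subtest 5).
#' @param cross_time seconds a crossing object occupies an intersection.
#' @param intersection_spacing distance between intersections (units).
#' @param car_speed_max maximal forward speed in subtest 5 (units/s).
#' @return An object of class `task_config`.
#' @export
task_config <- function(street_half_width = 5,
                        avatar_half_width = 0.5,
                        object_half_width = 0.8,
                        object_half_height = 0.5,
                        spawn_rate = 0.4,
                        object_speed = 4,
                        spawn_y = 20,
                        stim_rate = 0.25,
                        distractor_fraction = 0.4,
                        response_window = 1.5,
                        steer_speed = 8,
                        dt = 0.05,
                        duration = 180,
                        traffic_rate = 0.25,
                        cross_time = 1,
                        intersection_spacing = 30,
                        car_speed_max = 10) {
  cfg <- as.list(environment())
  pos <- c("street_half_width", "avatar_half_width", "object_half_width",
           "object_half_height", "spawn_rate", "object_speed", "spawn_y",
           "stim_rate", "response_window", "steer_speed", "dt", "duration",
           "traffic_rate", "cross_time", "intersection_spacing",
           "car_speed_max")
  for (p in pos) {
    stop_if_not(is.numeric(cfg[[p]]) && length(cfg[[p]]) == 1 &&
                  is.finite(cfg[[p]]) && cfg[[p]] > 0,
                sprintf("`%s` must be a single positive number", p))
  }
  stop_if_not(distractor_fraction >= 0 && distractor_fraction < 1,
              "`distractor_fraction` must be in [0, 1)")
  stop_if_not(dt <= response_window, "`dt` must not exceed `response_window`")
  stop_if_not(avatar_half_width < street_half_width,
              "avatar must fit inside the street")
  structure(cfg, class = "task_config")
}

#' Simulated respondent agent
#'
#' A parametric stand-in for a human participant. Impairments are expressed
#' as: lateral steering noise, a steering reaction delay, a probability of
#' missing true peripheral targets (lapse), a false-alarm probability on
#' distractors, pedal reaction time, speed-control noise (subtest 5), and a
#' divided-attention degradation factor that multiplies the steering noise
#' and lapse probability when the central and peripheral tasks run
#' simultaneously (subtest 3).
#'
#' @param steer_noise_sd SD of the lateral position noise added per step
#'   (length units).
#' @param reaction_delay steering reaction delay (s).
#' @param lapse_prob probability of missing a true peripheral target.
#' @param false_alarm_prob probability of responding to a distractor.
#' @param pedal_rt_mean,pedal_rt_sd pedal reaction time (s).
#' @param speed_noise_sd SD of speed-control noise in subtest 5 (units/s).
#' @param degradation divided-attention degradation factor (>= 1).
#' @return An object of class `agent_model`. The default agent is ideal:
#'   no noise, no lapses, no delay.
#' @export
agent_model <- function(steer_noise_sd = 0,
                        reaction_delay = 0,
                        lapse_prob = 0,
                        false_alarm_prob = 0,
                        pedal_rt_mean = 0.5,
                        pedal_rt_sd = 0.1,
                        speed_noise_sd = 0,
                        degradation = 1) {
  agent <- as.list(environment())
  stop_if_not(lapse_prob >= 0 && lapse_prob <= 1,
              "`lapse_prob` must be in [0, 1]")
  stop_if_not(false_alarm_prob >= 0 && false_alarm_prob <= 1,
              "`false_alarm_prob` must be in [0, 1]")
  for (p in c("steer_noise_sd", "reaction_delay", "pedal_rt_sd",
              "speed_noise_sd")) {
    stop_if_not(agent[[p]] >= 0, sprintf("`%s` must be >= 0", p))
  }
  stop_if_not(pedal_rt_mean > 0, "`pedal_rt_mean` must be > 0")
  stop_if_not(degradation >= 1, "`degradation` must be >= 1")
  structure(agent, class = "agent_model")
}

subtest_errors <- function(subtest, fp = 0L, fn = 0L, object_collisions = 0L,
                           border_collisions = 0L, log = NULL) {
  stop_if_not(subtest %in% 1:5, "unknown subtest id")
  # structural zeros: no steering in 1 and 4, no peripheral task in 2 and 5
  if (subtest %in% c(1L, 4L)) {
    stopifnot(object_collisions == 0L, border_collisions == 0L)
  }
  if (subtest %in% c(2L, 5L)) stopifnot(fp == 0L, fn == 0L)
  stopifnot(fp >= 0, fn >= 0, object_collisions >= 0, border_collisions >= 0)
  structure(
    list(subtest = as.integer(subtest),
         false_positives = as.integer(fp),
         false_negatives = as.integer(fn),
         object_collisions = as.integer(object_collisions),
         border_collisions = as.integer(border_collisions),
         log = log),
    class = "subtest_errors"
  )
}

#' @export
print.subtest_errors <- function(x, ...) {
  cat(sprintf(
    "Subtest %d errors: FP=%d FN=%d object collisions=%d border collisions=%d\n",
    x$subtest, x$false_positives, x$false_negatives,
    x$object_collisions, x$border_collisions))
  invisible(x)
}

#' Event log of a simulated subtest run
#'
#' @param x a `subtest_errors` object from [run_subtest()].
#' @return A data frame of events (`time`, `event`, `value`): stimulus
#'   onsets, responses, and collisions, for inspection and testing.
#' @export
event_log <- function(x) {
  stop_if_not(inherits(x, "subtest_errors"), "not a subtest_errors object")
  x$log
}

#' Run one subtest of the battery
#'
#' Simulates a single subtest with the given respondent agent, counting false
#' positives and false negatives of the peripheral detection task and
#' collisions with moving objects and with the street border — the error
#' taxonomy the battery records.
#'
#' @param subtest subtest id, 1–5 (see [task_config()] for semantics).
#' @param task a [task_config()].
#' @param agent an [agent_model()].
#' @param seed integer seed; output is deterministic given it.
#' @return A `subtest_errors` object; [event_log()] recovers the event trace.
#' @export
#' @examples
#' run_subtest(3, task_config(duration = 30), agent_model(lapse_prob = 0.3),
#'             seed = 7)
run_subtest <- function(subtest, task, agent, seed) {
  stop_if_not(is.numeric(subtest) && length(subtest) == 1 && subtest %in% 1:5,
              "`subtest` must be an integer in 1..5")
  stop_if_not(inherits(task, "task_config"), "`task` must be a task_config()")
  stop_if_not(inherits(agent, "agent_model"), "`agent` must be an agent_model()")
  subtest <- as.integer(subtest)
  with_seed(seed, {
    switch(subtest,
           run_peripheral_only(1L, task, agent),   # automatic steering
           run_steering_only(2L, task, agent),
           run_divided(task, agent),
           run_peripheral_only(4L, task, agent),   # two target classes
           run_crossing(task, agent))
  })
}

# ---- peripheral detection task (vectorized; onsets are a Poisson stream) ----

simulate_peripheral <- function(task, agent, degraded = FALSE) {
  horizon <- max(task$duration - task$response_window, 0)
  n_stim <- rpois(1L, task$stim_rate * task$duration)
  onsets <- sort(runif(n_stim, 0, horizon))
  is_target <- runif(n_stim) >= task$distractor_fraction

  lapse <- agent$lapse_prob
  if (degraded) lapse <- min(1, lapse * agent$degradation)

  n_t <- sum(is_target)
  n_d <- n_stim - n_t
  lapsed <- runif(n_t) < lapse
  rt <- pmax(rnorm(n_t, agent$pedal_rt_mean, agent$pedal_rt_sd), task$dt)
  hit <- !lapsed & rt <= task$response_window
  fn <- sum(!hit)
  false_alarm <- runif(n_d) < agent$false_alarm_prob
  fp <- sum(false_alarm)

  ev <- data.frame(
    time = onsets,
    event = ifelse(is_target, "target_onset", "distractor_onset"),
    value = NA_real_
  )
  resp_t <- onsets[is_target][hit] + rt[hit]
  resp_d <- onsets[!is_target][false_alarm] + 0.4
  if (length(resp_t) || length(resp_d)) {
    ev <- rbind(ev, data.frame(
      time = c(resp_t, resp_d),
      event = c(rep("response_hit", length(resp_t)),
                rep("response_false_alarm", length(resp_d))),
      value = NA_real_
    ))
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  list(fp = fp, fn = fn, n_targets = n_t, n_distractors = n_d, log = ev)
}

run_peripheral_only <- function(subtest, task, agent) {
  p <- simulate_peripheral(task, agent, degraded = FALSE)
  log <- p$log
  attr(log, "n_targets") <- p$n_targets
  attr(log, "n_distractors") <- p$n_distractors
  subtest_errors(subtest, fp = p$fp, fn = p$fn, log = log)
}

# ---- steering task: objects descend, agent (or autopilot) avoids them ----

# Greedy gap-seeking target. Objects whose time-to-contact with the avatar's
# band is short define forbidden lateral intervals between which the free
# gaps lie. Each gap midpoint is scored by how long it stays safe (minimum
# time-to-contact of any object above it, anywhere in the descent column);
# the controller heads for the safest reachable gap, with a hysteresis bonus
# for the gap it already occupies, and reaches a gap only by crossing
# intervals whose objects arrive after it has passed them.
steer_target <- function(x, obj_x, obj_y, task) {
  # plan strictly inside the border: touching it counts as a border error
  lo <- -task$street_half_width + task$avatar_half_width + 0.1
  hi <- task$street_half_width - task$avatar_half_width - 0.1
  contact_y <- task$object_half_height + 0.5  # avatar half height
  t_contact <- pmax((obj_y - contact_y) / task$object_speed, 0)
  # an object matters until it has fully passed the avatar's band
  active <- obj_y > -(contact_y + 0.1)
  danger <- active & t_contact <= 2
  if (!any(danger)) return(x)
  margin <- task$avatar_half_width + task$object_half_width + 0.25
  dx <- obj_x[danger]; dtc <- t_contact[danger]
  left <- dx - margin
  right <- dx + margin
  ord <- order(left)
  left <- left[ord]; right <- right[ord]
  # merge overlapping forbidden intervals, then walk the free gaps
  gaps <- list()
  cur <- lo
  for (i in seq_along(left)) {
    if (left[i] > cur) gaps[[length(gaps) + 1L]] <- c(cur, min(left[i], hi))
    cur <- max(cur, right[i])
    if (cur >= hi) break
  }
  if (cur < hi) gaps[[length(gaps) + 1L]] <- c(cur, hi)
  gaps <- Filter(function(g) diff(g) > 0, gaps)
  if (!length(gaps)) return(x)  # street fully blocked; hold position
  inside <- vapply(gaps, function(g) x >= g[1] && x <= g[2], logical(1))

  # a gap is as safe as its best spot: narrow pockets a single incoming
  # object covers completely are traps, wide gaps keep open sub-regions
  ax <- obj_x[active]; atc <- t_contact[active]
  point_safety <- function(p) {
    over <- abs(ax - p) < margin
    if (!any(over)) 5 else min(atc[over], 5)
  }
  best <- lapply(gaps, function(g) {
    pts <- seq(g[1], g[2], length.out = max(3L, ceiling(diff(g) / 0.5) + 1L))
    s <- vapply(pts, point_safety, numeric(1))
    # among safest points prefer the one closest to the gap centre
    top <- which(s >= max(s) - 1e-9)
    p <- pts[top[which.min(abs(pts[top] - mean(g)))]]
    c(p, max(s))
  })
  mids <- vapply(best, `[`, numeric(1), 1L)
  safety <- vapply(best, `[`, numeric(1), 2L)

  feasible <- vapply(seq_along(gaps), function(i) {
    if (inside[i]) return(TRUE)
    m <- mids[i]
    span <- range(x, m)
    between <- dx > span[1] - margin & dx < span[2] + margin
    if (!any(between)) return(TRUE)
    far_edge <- ifelse(dx[between] < m, dx[between] + margin,
                       dx[between] - margin)
    clear_t <- abs(far_edge - x) / task$steer_speed
    all(clear_t + 0.1 < dtc[between])
  }, logical(1))
  if (!any(feasible)) return(x)  # wait for a gap to open rather than ram

  score <- safety + ifelse(inside, 0.75, 0) -
    0.01 * abs(mids - x) / task$steer_speed
  score[!feasible] <- -Inf
  mids[which.max(score)]
}

# Draw a spawn position that keeps the object field traversable: together
# with objects in the same vertical neighbourhood the new object must leave
# a free lateral gap wide enough for the avatar, as a well-designed task
# would (otherwise even a perfect player would be forced into collisions).
# Returns NA (spawn skipped) if no admissible position is found.
spawn_x <- function(obj_x, obj_y, task) {
  lo <- -task$street_half_width + task$avatar_half_width
  hi <- task$street_half_width - task$avatar_half_width
  x_span <- task$street_half_width - task$object_half_width
  near_v <- (task$street_half_width * 2 / task$steer_speed + 0.5) *
    task$object_speed
  margin <- task$avatar_half_width + task$object_half_width + 0.25
  neighbours <- obj_x[obj_y > task$spawn_y - near_v]
  gap_min <- 2 * task$avatar_half_width + 0.3
  for (try in 1:30) {
    cand <- runif(1, -x_span, x_span)
    xs <- sort(c(neighbours, cand))
    left <- xs - margin; right <- xs + margin
    cur <- lo; best <- 0
    for (i in seq_along(left)) {
      if (left[i] > cur) best <- max(best, min(left[i], hi) - cur)
      cur <- max(cur, right[i])
      if (cur >= hi) break
    }
    if (cur < hi) best <- max(best, hi - cur)
    if (best >= gap_min) return(cand)
  }
  NA_real_
}

simulate_steering <- function(task, agent, degraded = FALSE,
                              with_log = TRUE) {
  noise <- agent$steer_noise_sd
  if (degraded) noise <- noise * agent$degradation
  steps <- floor(task$duration / task$dt)
  delay_steps <- round(agent$reaction_delay / task$dt)

  x <- 0
  obj_x <- numeric(0); obj_y <- numeric(0); obj_id <- integer(0)
  obj_hit <- logical(0)           # overlap episode already counted
  next_id <- 1L
  in_border <- FALSE
  target_buf <- rep(0, delay_steps + 1L)

  object_collisions <- 0L
  border_collisions <- 0L
  colliding <- integer(0)         # ids currently overlapping
  ev_time <- numeric(0); ev_event <- character(0); ev_value <- numeric(0)

  lo <- -task$street_half_width + task$avatar_half_width
  hi <- task$street_half_width - task$avatar_half_width
  p_spawn <- task$spawn_rate * task$dt
  x_span <- task$street_half_width - task$object_half_width

  for (s in seq_len(steps)) {
    t <- s * task$dt
    if (runif(1) < p_spawn) {
      nx <- spawn_x(obj_x, obj_y, task)
      if (!is.na(nx)) {
        obj_x <- c(obj_x, nx)
        obj_y <- c(obj_y, task$spawn_y)
        obj_id <- c(obj_id, next_id)
        next_id <- next_id + 1L
      }
    }
    obj_y <- obj_y - task$object_speed * task$dt
    keep <- obj_y > -2
    if (!all(keep)) {
      gone <- obj_id[!keep]
      colliding <- setdiff(colliding, gone)
      obj_x <- obj_x[keep]; obj_y <- obj_y[keep]; obj_id <- obj_id[keep]
    }

    tgt <- steer_target(x, obj_x, obj_y, task)
    if (delay_steps > 0) {
      target_buf <- c(target_buf[-1L], tgt)
      tgt <- target_buf[1L]
    }
    step_max <- task$steer_speed * task$dt
    x <- x + max(-step_max, min(step_max, tgt - x))
    if (noise > 0) x <- x + rnorm(1, 0, noise)
    x <- max(-task$street_half_width, min(task$street_half_width, x))

    # border contact: avatar edge reaches the street border (episode = 1)
    at_border <- abs(x) + task$avatar_half_width >= task$street_half_width
    if (at_border && !in_border) {
      border_collisions <- border_collisions + 1L
      if (with_log) {
        ev_time <- c(ev_time, t); ev_event <- c(ev_event, "border_collision")
        ev_value <- c(ev_value, x)
      }
    }
    in_border <- at_border

    if (length(obj_x)) {
      overlap <- abs(obj_x - x) < task$avatar_half_width + task$object_half_width &
        abs(obj_y) < task$object_half_height + 0.5
      now <- obj_id[overlap]
      new_hits <- setdiff(now, colliding)
      if (length(new_hits)) {
        object_collisions <- object_collisions + length(new_hits)
        if (with_log) {
          ev_time <- c(ev_time, rep(t, length(new_hits)))
          ev_event <- c(ev_event, rep("object_collision", length(new_hits)))
          ev_value <- c(ev_value, rep(x, length(new_hits)))
        }
      }
      colliding <- now
    } else {
      colliding <- integer(0)
    }
  }
  log <- if (with_log) {
    data.frame(time = ev_time, event = ev_event, value = ev_value)
  } else {
    NULL
  }
  list(object_collisions = object_collisions,
       border_collisions = border_collisions, log = log)
}

run_steering_only <- function(subtest, task, agent) {
  st <- simulate_steering(task, agent, degraded = FALSE)
  subtest_errors(subtest, object_collisions = st$object_collisions,
                 border_collisions = st$border_collisions, log = st$log)
}

run_divided <- function(task, agent) {
  st <- simulate_steering(task, agent, degraded = TRUE)
  p <- simulate_peripheral(task, agent, degraded = TRUE)
  log <- rbind(p$log,
               if (!is.null(st$log) && nrow(st$log)) st$log else NULL)
  if (!is.null(log)) {
    log <- log[order(log$time), , drop = FALSE]
    rownames(log) <- NULL
    attr(log, "n_targets") <- p$n_targets
    attr(log, "n_distractors") <- p$n_distractors
  }
  subtest_errors(3L, fp = p$fp, fn = p$fn,
                 object_collisions = st$object_collisions,
                 border_collisions = st$border_collisions, log = log)
}

# ---- subtest 5: speed regulation through intersections ----

run_crossing <- function(task, agent) {
  steps <- floor(task$duration / task$dt)
  # crossing traffic per intersection: Poisson arrivals, each occupying the
  # crossing for cross_time seconds
  track_len <- task$car_speed_max * task$duration
  n_inter <- max(1L, floor(track_len / task$intersection_spacing))
  inter_pos <- task$intersection_spacing * seq_len(n_inter)
  occupancy <- lapply(seq_len(n_inter), function(i) {
    k <- rpois(1L, task$traffic_rate * task$duration)
    start <- sort(runif(k, 0, task$duration))
    cbind(start = start, end = start + task$cross_time)
  })

  car_half <- 1
  inter_half <- task$object_half_width
  v_max <- task$car_speed_max
  s_pos <- 0
  collisions <- 0L
  counted <- lapply(seq_len(n_inter), function(i) logical(nrow(occupancy[[i]])))
  ev_time <- numeric(0); ev_event <- character(0); ev_value <- numeric(0)

  for (st in seq_len(steps)) {
    t <- st * task$dt
    # next intersection ahead
    nxt <- which(inter_pos + inter_half > s_pos - car_half)[1]
    v_des <- v_max
    if (!is.na(nxt)) {
      enter <- inter_pos[nxt] - inter_half - car_half
      gap_to <- enter - s_pos
      # only brake while still before the stop line; once committed, clear
      # the intersection at full speed
      if (gap_to > 0 && gap_to <= v_max * task$dt * 2 + 0.5) {
        transit <- gap_to / v_max + (2 * (inter_half + car_half)) / v_max +
          2 * task$dt
        occ <- occupancy[[nxt]]
        conflict <- nrow(occ) > 0 &&
          any(occ[, "start"] < t + transit + task$dt & occ[, "end"] > t)
        if (conflict) v_des <- 0
      }
    }
    v <- v_des
    if (agent$speed_noise_sd > 0) v <- v + rnorm(1, 0, agent$speed_noise_sd)
    v <- max(0, min(v_max, v))
    if (v_des == 0 && !is.na(nxt)) {
      # waiting at the stop line; only control noise can push the car onward
      s_pos <- min(s_pos + v * task$dt,
                   inter_pos[nxt] - inter_half - car_half + v * task$dt)
    } else {
      s_pos <- s_pos + v * task$dt
    }

    if (!is.na(nxt)) {
      inside <- abs(s_pos - inter_pos[nxt]) < inter_half + car_half
      if (inside) {
        occ <- occupancy[[nxt]]
        if (nrow(occ)) {
          live <- occ[, "start"] <= t & occ[, "end"] >= t & !counted[[nxt]]
          if (any(live)) {
            collisions <- collisions + sum(live)
            counted[[nxt]][live] <- TRUE
            ev_time <- c(ev_time, rep(t, sum(live)))
            ev_event <- c(ev_event, rep("object_collision", sum(live)))
            ev_value <- c(ev_value, rep(s_pos, sum(live)))
          }
        }
      }
    }
  }
  log <- data.frame(time = ev_time, event = ev_event, value = ev_value)
  subtest_errors(5L, object_collisions = collisions, log = log)
}

#' Run the full five-subtest battery
#'
#' Runs subtests 1–5 with per-subtest seeds derived from the master seed.
#' Subtest 3 contributes two error totals: central collisions (object plus
#' border) and peripheral detection errors (false positives plus negatives),
#' which feed the two divided-attention subscores downstream.
#'
#' @inheritParams run_subtest
#' @return A list of class `battery_result`: `results` (the five
#'   `subtest_errors`) and `errors`, a named integer vector `e1, e2, e3c,
#'   e3p, e4, e5` of per-subtest error totals ready for scoring.
#' @export
run_battery <- function(task, agent, seed) {
  seeds <- derive_seeds(seed, 5L)
  results <- lapply(1:5, function(i) run_subtest(i, task, agent, seeds[i]))
  total <- function(r) {
    r$false_positives + r$false_negatives + r$object_collisions +
      r$border_collisions
  }
  r3 <- results[[3]]
  errors <- c(
    e1 = total(results[[1]]),
    e2 = total(results[[2]]),
    e3c = r3$object_collisions + r3$border_collisions,
    e3p = r3$false_positives + r3$false_negatives,
    e4 = total(results[[4]]),
    e5 = total(results[[5]])
  )
  structure(list(results = results, errors = errors, seed = seed),
            class = "battery_result")
}

#' @export
print.battery_result <- function(x, ...) {
  cat("Battery run (seed", x$seed, ")\n  errors:",
      paste(sprintf("%s=%d", names(x$errors), x$errors), collapse = " "), "\n")
  invisible(x)
}
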