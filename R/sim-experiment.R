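# Synthetic stepped-oxygen behavioural experiments: a projected-area
# trace with Poisson-timed contraction dips, a dissolved-O2 trace that
# relaxes between schedule steps, and (optionally) rendered frames of a
# bright elliptical body on a dark background.

#' Define the truth of a simulated experiment
#'
#' @param schedule Data.frame with columns `t_start_s` and `percent_as`:
#'   a step function of the target oxygen level (%AS in \[0, 100\]).
#' @param duration_s Total duration in seconds (> 0).
#' @param lambda_per_day Either a single rate, a vector matching
#'   `schedule` rows, or a function of percent air saturation returning
#'   events/day. The default emulates the study organism: ~12 full-body
#'   contractions per day at and above 4 %AS, cessation below 2 %AS.
#' @param event_duration_s Contraction cycle length (default 30 min).
#' @param refractory_s Minimum gap between the end of one event and the
#'   onset of the next (default 20 min).
#' @param class_probs Named probabilities for event classes
#'   `full_body` / `sub` (default all full-body).
#' @param noise_sd Area measurement noise, as a fraction of baseline
#'   area (default 0.02).
#' @param baseline_area_px Expanded-state projected area (default 5000).
#' @param cadence_s Sampling cadence in seconds (default 30, matching a
#'   photo and an O2 reading every 30 s).
#' @param o2_tau_s First-order relaxation time of the bottle O2 towards
#'   each schedule step (default 30 min).
#' @param o2_noise_uM O2 sensor noise SD in uM (default 0.2).
#' @param conditions [oxygen_conditions()] used to convert %AS to uM.
#' @param seed Integer seed.
#' @return List of class `experiment_truth`.
#' @export
experiment_truth <- function(schedule =
                               data.frame(t_start_s = c(0, 86400,
                                                        2 * 86400,
                                                        3 * 86400),
                                          percent_as = c(100, 10, 5, 2)),
                             duration_s = 4 * 86400,
                             lambda_per_day = function(p)
                               if (p >= 4) 12 else 0,
                             event_duration_s = 1800,
                             refractory_s = 1200,
                             class_probs = c(full_body = 1, sub = 0),
                             noise_sd = 0.02,
                             baseline_area_px = 5000,
                             cadence_s = 30,
                             o2_tau_s = 1800,
                             o2_noise_uM = 0.2,
                             conditions = oxygen_conditions(26, 32),
                             seed = 1) {
  stopifnot(is.data.frame(schedule),
            all(c("t_start_s", "percent_as") %in% names(schedule)),
            duration_s > 0)
  if (any(schedule$percent_as < 0 | schedule$percent_as > 100))
    stop("schedule %AS must lie in [0, 100]")
  if (any(diff(schedule$t_start_s) <= 0))
    stop("schedule steps must have increasing start times")
  if (cadence_s <= 0) stop("cadence must be positive")
  lam <- if (is.function(lambda_per_day))
    vapply(schedule$percent_as, lambda_per_day, numeric(1))
  else rep_len(lambda_per_day, nrow(schedule))
  if (any(lam < 0)) stop("event rates must be >= 0")
  structure(list(schedule = schedule, duration_s = duration_s,
                 lambda_per_day = lam,
                 event_duration_s = event_duration_s,
                 refractory_s = refractory_s, class_probs = class_probs,
                 noise_sd = noise_sd,
                 baseline_area_px = baseline_area_px,
                 cadence_s = cadence_s, o2_tau_s = o2_tau_s,
                 o2_noise_uM = o2_noise_uM, conditions = conditions,
                 seed = seed),
            class = "experiment_truth")
}

# amplitude conventions: full-body >= 50% area reduction, sub 10-50%
.draw_amplitude <- function(class) {
  if (class == "full_body") stats::runif(1, 0.55, 0.8)
  else stats::runif(1, 0.15, 0.4)
}

#' Simulate the experiment defined by an [experiment_truth()]
#'
#' Contraction onsets are drawn per schedule plateau from a Poisson
#' process at that plateau's rate, thinned to enforce the refractory
#' period; each event is a raised-cosine dip of the drawn amplitude.
#' The O2 trace relaxes exponentially towards each step's target.
#'
#' @param truth An [experiment_truth()].
#' @return List of class `experiment_sim`: `area` (data.frame
#'   `timestamp_s`, `area_px`), `o2` (data.frame `timestamp_s`, `o2_uM`,
#'   `percent_as`), `events` (the planted truth: `start_s`, `trough_s`,
#'   `end_s`, `amplitude`, `class`), `truth`.
#' @export
simulate_experiment <- function(truth) {
  stopifnot(inherits(truth, "experiment_truth"))
  tt <- seq(0, truth$duration_s, by = truth$cadence_s)
  sched <- truth$schedule
  step_of <- findInterval(tt, sched$t_start_s)
  step_of[step_of < 1L] <- 1L
  res <- .with_seed(truth$seed, {
    # planted events, plateau by plateau, refractory-thinned
    ev <- list()
    last_end <- -Inf
    for (k in seq_len(nrow(sched))) {
      t0 <- sched$t_start_s[k]
      t1 <- if (k < nrow(sched)) sched$t_start_s[k + 1]
            else truth$duration_s
      lam <- truth$lambda_per_day[k] / 86400  # events per second
      n <- stats::rpois(1, lam * (t1 - t0))
      if (n == 0) next
      onsets <- sort(stats::runif(n, t0, t1))
      for (on in onsets) {
        if (on < last_end + truth$refractory_s) next
        if (on + truth$event_duration_s > truth$duration_s) next
        cls <- sample(names(truth$class_probs), 1,
                      prob = truth$class_probs)
        amp <- .draw_amplitude(cls)
        ev[[length(ev) + 1L]] <- data.frame(
          start_s = on, trough_s = on + truth$event_duration_s / 2,
          end_s = on + truth$event_duration_s, amplitude = amp,
          class = cls, stringsAsFactors = FALSE)
        last_end <- on + truth$event_duration_s
      }
    }
    events <- if (length(ev) > 0) do.call(rbind, ev) else .empty_events()

    # area trace: raised-cosine dips plus measurement noise
    dip <- rep(0, length(tt))
    for (k in seq_len(nrow(events))) {
      x <- (tt - events$start_s[k]) / truth$event_duration_s
      inside <- x >= 0 & x <= 1
      dip[inside] <- pmax(dip[inside],
                          events$amplitude[k] * sin(pi * x[inside])^2)
    }
    area <- truth$baseline_area_px * (1 - dip) +
      stats::rnorm(length(tt), 0,
                   truth$noise_sd * truth$baseline_area_px)

    # O2 trace: first-order relaxation towards the scheduled step
    target <- percent_as_to_uM(sched$percent_as, truth$conditions)
    o2 <- numeric(length(tt))
    level <- target[1]
    for (i in seq_along(tt)) {
      tgt <- target[step_of[i]]
      if (i > 1) {
        dt <- tt[i] - tt[i - 1]
        level <- tgt + (level - tgt) * exp(-dt / truth$o2_tau_s)
      }
      o2[i] <- level
    }
    o2_obs <- pmax(0, o2 + stats::rnorm(length(tt), 0, truth$o2_noise_uM))
    list(events = events, area = area, o2 = o2_obs)
  })
  structure(list(
    area = data.frame(timestamp_s = tt, area_px = res$area),
    o2 = data.frame(timestamp_s = tt, o2_uM = res$o2,
                    percent_as = uM_to_percent_as(
                      pmax(0, res$o2), truth$conditions)),
    events = res$events, truth = truth),
    class = "experiment_sim")
}

#' Write the simulated traces as CSV
#'
#' @param sim An [simulate_experiment()] result.
#' @param area_path,o2_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_experiment_csv <- function(sim, area_path, o2_path) {
  utils::write.csv(sim$area, area_path, row.names = FALSE)
  utils::write.csv(sim$o2, o2_path, row.names = FALSE)
  invisible(c(area_path, o2_path))
}

#' Render frames for an area trace
#'
#' Each frame shows a filled ellipse (axis ratio 3:2) whose area equals
#' the trace value, at intensity ~200 on a ~30 background (8-bit),
#' with optional Gaussian pixel noise — emulating a pale sponge against
#' black felt.
#'
#' @param area_px Numeric vector of target areas in pixels.
#' @param dim Frame dimensions `c(rows, cols)` (default 128 x 128).
#' @param noise_sd Pixel noise SD in 8-bit units (default 0).
#' @param angle_rad Ellipse rotation in radians (default 0).
#' @param seed Integer seed for the pixel noise.
#' @return List of `length(area_px)` numeric matrices (0-255).
#' @export
render_frames <- function(area_px, dim = c(128L, 128L), noise_sd = 0,
                          angle_rad = 0, seed = 1) {
  cy <- (dim[1] + 1) / 2
  cx <- (dim[2] + 1) / 2
  yy <- matrix(seq_len(dim[1]), dim[1], dim[2]) - cy
  xx <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE) - cx
  u <- xx * cos(angle_rad) + yy * sin(angle_rad)
  v <- -xx * sin(angle_rad) + yy * cos(angle_rad)
  .with_seed(seed, {
    lapply(area_px, function(a) {
      # area = pi * (1.5 b) * b  =>  b = sqrt(a / (1.5 pi))
      b <- sqrt(max(a, 0) / (1.5 * pi))
      aa <- 1.5 * b
      body <- (u / aa)^2 + (v / b)^2 <= 1
      f <- matrix(30, dim[1], dim[2])
      f[body] <- 200
      if (noise_sd > 0)
        f <- f + matrix(stats::rnorm(length(f), 0, noise_sd),
                        dim[1], dim[2])
      pmax(pmin(f, 255), 0)
    })
  })
}
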