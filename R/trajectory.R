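#' One 2IFC stimulus interval with (or without) a step speed change
#'
#' Describes the motion shown in a single interval: the object moves at
#' `v_before` (cm/s) for `change_time_s`, then at `v_after` for the rest of
#' `duration_s`. A "standard" interval has `v_before == v_after`; a
#' "variable" interval steps from slower to faster at the changepoint. A
#' static image precedes the motion for `static_lead_s`.
#'
#' @param v_before,v_after World speeds in cm/s, > 0.
#' @param change_time_s Time of the step change from motion onset, s.
#' @param duration_s Total motion duration, s.
#' @param static_lead_s Static preview before motion onset, s.
#' @param direction One of "approaching", "receding", "lateral".
#' @return An object of class `speed_change_interval`.
#' @examples
#' speed_change_interval(10, 70) # Fast maximum-change interval
#' @export
speed_change_interval <- function(v_before, v_after,
                                  change_time_s = 0.5,
                                  duration_s = 1,
                                  static_lead_s = 0.25,
                                  direction = c("approaching", "receding", "lateral")) {
  direction <- match.arg(direction)
  if (duration_s <= 0) abort("`duration_s` must be > 0.")
  if (v_before <= 0 || v_after <= 0) abort("Speeds must be > 0.")
  if (change_time_s <= 0 || change_time_s >= duration_s) {
    abort("`change_time_s` must lie strictly inside (0, duration_s).")
  }
  if (static_lead_s < 0) abort("`static_lead_s` must be >= 0.")
  structure(
    list(
      v_before = v_before, v_after = v_after,
      change_time_s = change_time_s, duration_s = duration_s,
      static_lead_s = static_lead_s, direction = direction
    ),
    class = "speed_change_interval"
  )
}

interval_distance <- function(interval) {
  interval$v_before * interval$change_time_s +
    interval$v_after * (interval$duration_s - interval$change_time_s)
}

frame_times <- function(duration_s, refresh_hz) {
  seq(0, floor(duration_s * refresh_hz)) / refresh_hz
}

#' Constant-world-speed trajectory through the screen plane
#'
#' Places the piecewise-linear depth trajectory for an approaching interval
#' symmetrically about the screen plane: the total distance travelled is
#' `d = v_before * t_c + v_after * (T - t_c)`, the start distance is
#' `z0 = D + d/2` and the end distance `z1 = D - d/2`. With the standard
#' design (distance conserved across levels) every level of a condition
#' shares the same start and end points; only the changepoint position
#' differs. For the Fast conditions this gives 117 -> 77 cm and for the
#' Slow conditions 107 -> 87 cm.
#'
#' @param interval A [speed_change_interval()], `direction = "approaching"`.
#' @param geom A [viewing_geometry()].
#' @return An object of class `world_trajectory`: start/end distances,
#'   speeds, changepoint, and the lines' lateral world coordinates.
#' @examples
#' build_world_interval(speed_change_interval(40, 40), viewing_geometry())
#' @export
build_world_interval <- function(interval, geom) {
  stopifnot(inherits(interval, "speed_change_interval"),
            inherits(geom, "viewing_geometry"))
  if (interval$direction != "approaching") {
    abort("Only approaching trajectories are built in world coordinates.")
  }
  total <- interval_distance(interval)
  D <- geom$viewing_distance_cm
  if (total >= 2 * D) {
    abort("Total travel >= 2 * viewing distance: the object would pass the eye.")
  }
  structure(
    list(
      z0_cm = D + total / 2,
      z1_cm = D - total / 2,
      v_before = interval$v_before,
      v_after = interval$v_after,
      change_time_s = interval$change_time_s,
      duration_s = interval$duration_s,
      x_half_cm = geom$half_separation_cm,
      total_distance_cm = total
    ),
    class = "world_trajectory"
  )
}

# piecewise-linear z(t); exact at any t, including t = change_time_s
trajectory_z <- function(traj, t) {
  if (any(t < 0 | t > traj$duration_s + 1e-12)) {
    abort("Times must lie within [0, duration_s].")
  }
  traj$z0_cm - traj$v_before * pmin(t, traj$change_time_s) -
    traj$v_after * pmax(t - traj$change_time_s, 0)
}

#' @export
print.world_trajectory <- function(x, ...) {
  cat("<world_trajectory>", x$z0_cm, "->", x$z1_cm, "cm;",
      x$v_before, "then", x$v_after, "cm/s; change at",
      x$change_time_s, "s of", x$duration_s, "s\n")
  invisible(x)
}

new_retinal_trace <- function(frames, abcd, duration_s, change_time_s, family) {
  structure(
    frames,
    abcd = abcd,
    duration_s = duration_s,
    change_time_s = change_time_s,
    family = family,
    class = c("retinal_trace", class(frames))
  )
}

#' Per-frame retinal angles and angular speeds of a world trajectory
#'
#' Samples the visual angle of each line at frame onsets `i / refresh_hz`
#' for the left eye, right eye (at `+/- ipd/2`) and a cyclopean eye at 0,
#' and attaches the instantaneous angular speed at each frame. The speeds
#' `a`, `b`, `c`, `d` — at interval onset, just before the change, just
#' after it, and at interval end, all cyclopean, for the line at positive
#' `x_w` — are stored as an attribute and available via [trace_speeds()].
#'
#' @param traj A `world_trajectory` from [build_world_interval()].
#' @param geom A [viewing_geometry()].
#' @return A tibble of class `retinal_trace` with columns `time_s`, `line`,
#'   `channel`, `angle_arcmin`, `speed_arcmin_per_s`.
#' @examples
#' tr <- trace_retinal(
#'   build_world_interval(speed_change_interval(40, 40), viewing_geometry()),
#'   viewing_geometry()
#' )
#' trace_speeds(tr)
#' @export
trace_retinal <- function(traj, geom) {
  stopifnot(inherits(traj, "world_trajectory"), inherits(geom, "viewing_geometry"))
  times <- frame_times(traj$duration_s, geom$refresh_hz)
  z <- trajectory_z(traj, times)
  v <- ifelse(times < traj$change_time_s, traj$v_before, traj$v_after)
  channels <- tibble(
    channel = c("left_eye", "right_eye", "cyclopean"),
    e = c(-geom$ipd_cm / 2, geom$ipd_cm / 2, 0)
  )
  lines <- tibble(line = c("left", "right"),
                  x_w = c(-1, 1) * traj$x_half_cm)
  frames <- tidyr::crossing(lines, channels) |>
    purrr::pmap(function(line, x_w, channel, e) {
      xr <- x_w - e
      tibble(
        time_s = times,
        line = line,
        channel = channel,
        angle_arcmin = atan2(xr, z) * RAD_TO_ARCMIN,
        speed_arcmin_per_s = xr * v / (xr^2 + z^2) * RAD_TO_ARCMIN
      )
    }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$time_s, .data$line, .data$channel)
  x <- traj$x_half_cm
  zc <- trajectory_z(traj, traj$change_time_s)
  abcd <- c(
    a = angular_speed(x, traj$z0_cm, traj$v_before),
    b = angular_speed(x, zc, traj$v_before),
    c = angular_speed(x, zc, traj$v_after),
    d = angular_speed(x, traj$z1_cm, traj$v_after)
  )
  new_retinal_trace(frames, abcd, traj$duration_s, traj$change_time_s, "World")
}

#' Speeds at the four landmarks of an interval
#'
#' Returns the named vector `c(a, b, c, d)` (arcmin/s): the cyclopean
#' angular speed at interval onset, immediately before the step change,
#' immediately after it, and at interval end.
#'
#' @param trace A `retinal_trace`.
#' @return Named numeric vector of length 4.
#' @export
trace_speeds <- function(trace) {
  stopifnot(inherits(trace, "retinal_trace"))
  attr(trace, "abcd")
}

#' Constant-retinal-speed interval (Retina and Retina Control stimuli)
#'
#' Builds the per-frame trace for an interval whose angular speed is
#' piecewise constant at the retina: `speed_before` until the changepoint,
#' `speed_after` thereafter. For the `"Retina"` family the two lines move
#' apart symmetrically (a linear size-change cue); for `"RetinaControl"`
#' the separation is fixed and both lines share a common lateral
#' translation, removing all motion-in-depth cues.
#'
#' @param speed_before,speed_after Angular speeds, arcmin/s, > 0.
#' @param duration_s,change_time_s Interval timing, s.
#' @param geom A [viewing_geometry()] (sets the frame rate and the start
#'   separation, taken at the screen plane).
#' @param family `"Retina"` or `"RetinaControl"`.
#' @return A tibble of class `retinal_trace` (cyclopean channel).
#' @examples
#' build_retina_interval(47.6, 47.6)
#' @export
build_retina_interval <- function(speed_before, speed_after,
                                  duration_s = 1, change_time_s = 0.5,
                                  geom = viewing_geometry(),
                                  family = c("Retina", "RetinaControl")) {
  family <- match.arg(family)
  if (speed_before <= 0 || speed_after <= 0) abort("Speeds must be > 0.")
  if (change_time_s <= 0 || change_time_s >= duration_s) {
    abort("`change_time_s` must lie strictly inside (0, duration_s).")
  }
  times <- frame_times(duration_s, geom$refresh_hz)
  disp <- speed_before * pmin(times, change_time_s) +
    speed_after * pmax(times - change_time_s, 0)
  speed <- ifelse(times < change_time_s, speed_before, speed_after)
  start <- atan2(geom$half_separation_cm, geom$viewing_distance_cm) * RAD_TO_ARCMIN
  if (family == "Retina") {
    # lines separate: right line moves right, left line moves left
    frames <- dplyr::bind_rows(
      tibble(time_s = times, line = "left", channel = "cyclopean",
             angle_arcmin = -start - disp, speed_arcmin_per_s = -speed),
      tibble(time_s = times, line = "right", channel = "cyclopean",
             angle_arcmin = start + disp, speed_arcmin_per_s = speed)
    )
  } else {
    # fixed separation, common rightward translation
    frames <- dplyr::bind_rows(
      tibble(time_s = times, line = "left", channel = "cyclopean",
             angle_arcmin = -start + disp, speed_arcmin_per_s = speed),
      tibble(time_s = times, line = "right", channel = "cyclopean",
             angle_arcmin = start + disp, speed_arcmin_per_s = speed)
    )
  }
  frames <- dplyr::arrange(frames, .data$time_s, .data$line)
  abcd <- c(a = speed_before, b = speed_before, c = speed_after, d = speed_after)
  new_retinal_trace(frames, abcd, duration_s, change_time_s, family)
}

#' Time-averaged retinal speed of an interval
#'
#' The constant speed that covers the same total cyclopean angular
#' displacement in the same duration: displacement of the positive-offset
#' line between the first and last frame, divided by the duration. This is
#' the rule used to derive the Retina-condition speeds from the World
#' conditions' retinal traces.
#'
#' @param trace A `retinal_trace`.
#' @return Speed in arcmin/s.
#' @examples
#' geom <- viewing_geometry()
#' tr <- trace_retinal(build_world_interval(speed_change_interval(40, 40), geom), geom)
#' derive_retina_speed(tr) # ~45.7 arcmin/s
#' @export
derive_retina_speed <- function(trace) {
  stopifnot(inherits(trace, "retinal_trace"))
  cyc <- dplyr::filter(as_tibble(trace),
                       .data$channel == "cyclopean", .data$line == "right")
  (cyc$angle_arcmin[nrow(cyc)] - cyc$angle_arcmin[1]) / attr(trace, "duration_s")
}

#' Per-level constant retinal speeds for the Retina conditions
#'
#' The Retina stimuli replace each World level's accelerating trace with a
#' piecewise-constant one. Levels 2-7 use the time-averaged cyclopean speed
#' of each half of the matching World interval; level 1 (no change) uses
#' the whole-interval average, so the no-change interval coincides with the
#' Retina standard. By construction every level covers the same total
#' angular displacement as the standard.
#'
#' @param speed_class `"Fast"` or `"Slow"`.
#' @param geom A [viewing_geometry()].
#' @return A tibble: `level`, `speed_before`, `speed_after` (arcmin/s), and
#'   the Eq.-style `prop_change = (c - b) / c`.
#' @examples
#' retina_speed_ladder("Fast")
#' @export
retina_speed_ladder <- function(speed_class = c("Fast", "Slow"),
                                geom = viewing_geometry()) {
  speed_class <- match.arg(speed_class)
  ladder <- if (speed_class == "Fast") level_ladder(40, 5) else level_ladder(20, 2.5)
  purrr::pmap(ladder, function(level, v_before, v_after) {
    traj <- build_world_interval(speed_change_interval(v_before, v_after), geom)
    x <- traj$x_half_cm
    tc <- traj$change_time_s
    th0 <- atan2(x, traj$z0_cm) * RAD_TO_ARCMIN
    thc <- atan2(x, trajectory_z(traj, tc)) * RAD_TO_ARCMIN
    th1 <- atan2(x, traj$z1_cm) * RAD_TO_ARCMIN
    if (level == 1) {
      s <- (th1 - th0) / traj$duration_s
      tibble(level = level, speed_before = s, speed_after = s)
    } else {
      tibble(
        level = level,
        speed_before = (thc - th0) / tc,
        speed_after = (th1 - thc) / (traj$duration_s - tc)
      )
    }
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(
      prop_change = proportion_speed_change(.data$speed_before, .data$speed_after)
    )
}

#' Published stimulus speed constants
#'
#' The speed values (arcmin/s) printed for the standard and maximum-change
#' intervals of each condition, plus the training-block speeds, carried as
#' configuration constants for replication. The derived values computed by
#' [trace_retinal()] and [retina_speed_ladder()] agree with the World-cell
#' constants to ~0.1-0.2 arcmin/s; the Retina constants reflect the source
#' study's own averaging, which differs slightly from the time average
#' (47.6 vs 45.7 for Fast, 22.3 vs 22.1 for Slow).
#'
#' @return A tibble: `condition`, `level_label`, `speed_before`,
#'   `speed_after` (ranges collapsed to endpoints as `before_end`,
#'   `after_end` for the accelerating cells).
#' @export
published_speed_constants <- function() {
  tibble::tribble(
    ~condition,            ~level_label,      ~speed_before, ~before_end, ~speed_after, ~after_end,
    "World-Fast",          "standard",        30.1,          43.8,        43.9,         69.5,
    "World-Fast",          "maximum change",  7.5,           8.2,         57.6,         121.4,
    "WorldControl-Fast",   "standard",        30.1,          43.8,        43.9,         69.5,
    "WorldControl-Fast",   "maximum change",  7.5,           8.2,         57.6,         121.4,
    "Retina-Fast",         "standard",        47.6,          NA,          47.6,         NA,
    "Retina-Fast",         "maximum change",  7.6,           NA,          87.4,         NA,
    "RetinaControl-Fast",  "standard",        47.6,          NA,          47.6,         NA,
    "RetinaControl-Fast",  "maximum change",  7.7,           NA,          87.5,         NA,
    "World-Slow",          "standard",        18.0,          21.9,        21.9,         27.2,
    "World-Slow",          "maximum change",  4.5,           4.7,         33.1,         47.6,
    "WorldControl-Slow",   "standard",        18.0,          21.9,        21.9,         27.2,
    "WorldControl-Slow",   "maximum change",  4.5,           4.7,         33.1,         47.6,
    "Retina-Slow",         "standard",        22.3,          NA,          22.3,         NA,
    "Retina-Slow",         "maximum change",  4.6,           NA,          40.0,         NA,
    "RetinaControl-Slow",  "standard",        22.3,          NA,          22.3,         NA,
    "RetinaControl-Slow",  "maximum change",  4.6,           NA,          40.1,         NA,
    "Training",            "standard",        283.4,         NA,          283.4,        NA,
    "Training",            "hard change",     212.6,         NA,          354.1,        NA,
    "Training",            "easy change",     70.9,          NA,          495.3,        NA
  )
}

#' Retinal speed summary for every condition and level
#'
#' Recomputes, from the geometry, the `a`/`b`/`c`/`d` landmark speeds for
#' every level of the World (and World Control) conditions and the
#' piecewise-constant speeds of the Retina (and Retina Control) conditions
#' — the computed counterpart of the published speed tables.
#'
#' @param geom A [viewing_geometry()].
#' @param levels Which ladder levels to include (default all 7).
#' @return A tibble: `condition`, `speed_class`, `level`, `v_before`,
#'   `v_after` (cm/s, NA for Retina rows), `a`, `b`, `c`, `d` (arcmin/s).
#' @examples
#' speed_table(levels = c(1, 7))
#' @export
speed_table <- function(geom = viewing_geometry(), levels = 1:7) {
  classes <- tibble(
    speed_class = c("Fast", "Slow"),
    standard = c(40, 20), step = c(5, 2.5)
  )
  world <- purrr::pmap(classes, function(speed_class, standard, step) {
    level_ladder(standard, step) |>
      dplyr::filter(.data$level %in% levels) |>
      purrr::pmap(function(level, v_before, v_after) {
        tr <- trace_retinal(
          build_world_interval(speed_change_interval(v_before, v_after), geom), geom
        )
        s <- trace_speeds(tr)
        tibble(speed_class = speed_class, level = level,
               v_before = v_before, v_after = v_after,
               a = s[["a"]], b = s[["b"]], c = s[["c"]], d = s[["d"]])
      }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()
  retina <- purrr::map(c("Fast", "Slow"), function(cl) {
    retina_speed_ladder(cl, geom) |>
      dplyr::filter(.data$level %in% levels) |>
      dplyr::transmute(
        speed_class = cl, level = .data$level,
        v_before = NA_real_, v_after = NA_real_,
        a = .data$speed_before, b = .data$speed_before,
        c = .data$speed_after, d = .data$speed_after
      )
  }) |>
    purrr::list_rbind()
  dplyr::bind_rows(
    dplyr::mutate(world, family = "World"),
    dplyr::mutate(world, family = "WorldControl"),
    dplyr::mutate(retina, family = "Retina"),
    dplyr::mutate(retina, family = "RetinaControl")
  ) |>
    dplyr::mutate(condition = paste(.data$family, .data$speed_class, sep = "-")) |>
    dplyr::select("condition", family = "family", speed_class = "speed_class",
                  "level", "v_before", "v_after", "a", "b", "c", "d") |>
    dplyr::arrange(.data$condition, .data$level)
}
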