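#' Viewing geometry of the stereoscopic display
#'
#' Fixed scene parameters for the mirror-stereoscope setup: the observer
#' views a screen at distance `viewing_distance_cm`; the stimulus is a pair
#' of vertical lines at world lateral positions `+/- half_separation_cm`
#' that move along the midline in depth. Angles are computed for a cyclopean
#' eye at lateral 0 and for left/right eyes at `-/+ ipd_cm / 2`.
#'
#' @param viewing_distance_cm Viewing distance D in cm (screen plane).
#' @param ipd_cm Interpupillary distance in cm.
#' @param refresh_hz Display refresh rate in frames per second.
#' @param half_separation_cm World lateral offset of each line from the
#'   midline, in cm (one line at `+`, one at `-` this value).
#'
#' @return An object of class `viewing_geometry` (a named list).
#' @examples
#' geom <- viewing_geometry()
#' geom$viewing_distance_cm
#' @export
viewing_geometry <- function(viewing_distance_cm = 97,
                             ipd_cm = 6.5,
                             refresh_hz = 85,
                             half_separation_cm = 3) {
  stopifnot(
    is.numeric(viewing_distance_cm), length(viewing_distance_cm) == 1,
    is.numeric(ipd_cm), length(ipd_cm) == 1,
    is.numeric(refresh_hz), length(refresh_hz) == 1,
    is.numeric(half_separation_cm), length(half_separation_cm) == 1
  )
  if (viewing_distance_cm <= 0) abort("`viewing_distance_cm` must be > 0.")
  if (refresh_hz <= 0) abort("`refresh_hz` must be > 0.")
  if (half_separation_cm <= 0) abort("`half_separation_cm` must be > 0.")
  if (ipd_cm < 0) abort("`ipd_cm` must be >= 0.")
  structure(
    list(
      viewing_distance_cm = viewing_distance_cm,
      ipd_cm = ipd_cm,
      refresh_hz = refresh_hz,
      half_separation_cm = half_separation_cm
    ),
    class = "viewing_geometry"
  )
}

#' @export
print.viewing_geometry <- function(x, ...) {
  cat("<viewing_geometry>\n")
  cat("  viewing distance D:", x$viewing_distance_cm, "cm\n")
  cat("  IPD:", x$ipd_cm, "cm   refresh:", x$refresh_hz, "Hz\n")
  cat("  line half-separation x_w:", x$half_separation_cm, "cm\n")
  invisible(x)
}

check_z_positive <- function(z_w) {
  if (any(z_w <= 0)) {
    abort("`z_w` must be strictly positive: the object cannot be at or behind the eye.")
  }
}

#' World position to visual angle
#'
#' The perspective mapping from a world point at lateral position `x_w`,
#' distance `z_w` from the (cyclopean) eye, to the visual angle it subtends
#' from the midline: `theta = atan(x_w / z_w)`.
#'
#' @param x_w Lateral world position, cm (rightward positive). Vectorised.
#' @param z_w Distance from the eye along the midline, cm; must be > 0.
#' @return Visual angle in radians.
#' @examples
#' world_to_angle(3, 117)
#' @export
world_to_angle <- function(x_w, z_w) {
  check_z_positive(z_w)
  atan2(x_w, z_w)
}

#' Visual angle to screen position
#'
#' Where a point subtending angle `theta` must be drawn on a screen at
#' distance `D` so that it subtends the same angle: `x_s = D * tan(theta)`.
#'
#' @param angle Visual angle in radians; `|angle|` must be < pi/2.
#' @param D Viewing distance (screen distance) in cm.
#' @return Screen position in cm.
#' @examples
#' angle_to_screen(world_to_angle(3, 117), 97)
#' @export
angle_to_screen <- function(angle, D) {
  if (any(abs(angle) >= pi / 2)) {
    abort("`angle` must lie strictly within (-pi/2, pi/2).")
  }
  if (any(D <= 0)) abort("`D` must be > 0.")
  D * tan(angle)
}

#' World position directly to screen position
#'
#' The composition of [world_to_angle()] and [angle_to_screen()], which
#' simplifies to `x_s = D * x_w / z_w`.
#'
#' @inheritParams world_to_angle
#' @param D Viewing distance in cm.
#' @return Screen position in cm.
#' @examples
#' world_to_screen(3, 117, 97)
#' @export
world_to_screen <- function(x_w, z_w, D) {
  check_z_positive(z_w)
  if (any(D <= 0)) abort("`D` must be > 0.")
  D * x_w / z_w
}

#' Instantaneous retinal angular speed of an object moving in depth
#'
#' For a point at lateral offset `x_w` approaching along the midline at
#' world speed `v` (cm/s, positive towards the eye), the visual angle is
#' `theta(t) = atan(x_w / z(t))` and its exact time derivative is
#' `dtheta/dt = x_w * v / (x_w^2 + z^2)`. The result is converted from
#' rad/s to arcmin/s. This is the speed convention used throughout: the
#' instantaneous derivative, not a frame difference.
#'
#' @inheritParams world_to_angle
#' @param v World speed in depth, cm/s (positive = approaching).
#' @return Angular speed in arcmin/s (sign follows `x_w * v`).
#' @examples
#' angular_speed(3, 117, 40) # onset of the Fast standard interval
#' angular_speed(3, 77, 40)  # its end: the image has accelerated
#' @export
angular_speed <- function(x_w, z_w, v) {
  check_z_positive(z_w)
  x_w * v / (x_w^2 + z_w^2) * RAD_TO_ARCMIN
}

#' Per-eye screen positions for a trajectory viewed through a stereoscope
#'
#' Generalises the cyclopean projection to the two eyes: an eye at lateral
#' offset `e` sees the line at angle `atan((x_w - e) / z_w)`, which is drawn
#' on the screen at `e + D * (x_w - e) / z_w`. Binocular disparity (the
#' difference between the two eyes' angles) grows as the object approaches.
#' With `world_control = TRUE` the left eye's half-image is duplicated into
#' both eyes, which removes all binocular cues while keeping the looming
#' (line-separation) signal.
#'
#' @param traj A `world_trajectory` from [build_world_interval()].
#' @param geom A [viewing_geometry()].
#' @param world_control Duplicate the left-eye image into both eyes?
#' @return A tibble with columns `time_s`, `line` ("left"/"right"), `eye`
#'   ("left"/"right"), `screen_x_cm`, `angle_arcmin`.
#' @export
render_stereo <- function(traj, geom, world_control = FALSE) {
  stopifnot(inherits(traj, "world_trajectory"), inherits(geom, "viewing_geometry"))
  times <- frame_times(traj$duration_s, geom$refresh_hz)
  z <- trajectory_z(traj, times)
  D <- geom$viewing_distance_cm
  eyes <- tibble(eye = c("left", "right"), e = c(-1, 1) * geom$ipd_cm / 2)
  lines <- tibble(line = c("left", "right"), x_w = c(-1, 1) * traj$x_half_cm)
  out <- tidyr::crossing(eyes, lines) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      time_s = times,
      eye = .data$eye,
      line = .data$line,
      angle_arcmin = atan2(.data$x_w - .data$e, z) * RAD_TO_ARCMIN,
      screen_x_cm = .data$e + D * (.data$x_w - .data$e) / z
    ) |>
    dplyr::arrange(.data$time_s, .data$line, .data$eye)
  if (world_control) {
    left <- dplyr::filter(out, .data$eye == "left")
    out <- dplyr::bind_rows(
      left,
      dplyr::mutate(left, eye = "right")
    ) |>
      dplyr::arrange(.data$time_s, .data$line, .data$eye)
  }
  out
}

#' Recover the trajectory geometry from endpoint retinal speeds
#'
#' Inverts the kinematics: given the instantaneous retinal speeds at the
#' start (`a`) and end (`d`) of an interval in which the object approaches
#' at constant world speed `v` for `duration_s`, solve for the start
#' distance `z0` and the lateral offset `x_w`. From
#' `a = K x v / (x^2 + z0^2)` and `d = K x v / (x^2 + z1^2)` with
#' `z1 = z0 - v * duration_s` (K the rad-to-arcmin constant), subtracting
#' the two relations gives `z0 + z1 = K x (1/a - 1/d) / duration_s`, which
#' reduces the system to one equation in `x`, solved by bisection.
#'
#' @param a Retinal speed at interval onset, arcmin/s.
#' @param d Retinal speed at interval end, arcmin/s; must exceed `a`.
#' @param v World speed, cm/s.
#' @param duration_s Interval duration, s.
#' @return A tibble with one row: `z0_cm`, `z1_cm`, `x_w_cm`.
#' @examples
#' recover_geometry(30.1, 69.5, 40, 1) # ~117 cm start, ~3 cm offset
#' @export
recover_geometry <- function(a, d, v, duration_s = 1) {
  if (!(d > a && a > 0)) abort("Need `d > a > 0`: the image must accelerate.")
  if (v <= 0 || duration_s <= 0) abort("`v` and `duration_s` must be > 0.")
  K <- RAD_TO_ARCMIN
  travel <- v * duration_s
  z0_of_x <- function(x) (travel + K * x * (1 / a - 1 / d) / duration_s) / 2
  f <- function(x) {
    z0 <- z0_of_x(x)
    x^2 + z0^2 - K * x * v / a
  }
  # the reduced equation can have two roots (a near-eye and a far branch);
  # scan a log grid for every sign change and keep roots with z1 > 0
  grid <- exp(seq(log(1e-6), log(1e3), length.out = 2000))
  fg <- vapply(grid, f, numeric(1))
  idx <- which(fg[-1] * fg[-length(fg)] <= 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  z0s <- z0_of_x(roots)
  valid <- z0s - travel > 0
  if (!any(valid)) {
    abort("No positive solution: the (a, d, v, duration) combination is inconsistent.")
  }
  x <- roots[valid][1]
  z0 <- z0_of_x(x)
  tibble(z0_cm = z0, z1_cm = z0 - travel, x_w_cm = x)
}
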