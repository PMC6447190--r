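test_that("world_to_angle is the arctangent mapping and is antisymmetric", {
  expect_equal(world_to_angle(0, 100), 0)
  expect_equal(world_to_angle(3, 117), atan(3 / 117), tolerance = 1e-12)
  expect_equal(world_to_angle(3, 117), 0.025635, tolerance = 1e-4)
  expect_equal(world_to_angle(-3, 117), -world_to_angle(3, 117))
  expect_error(world_to_angle(3, 0), "positive")
  expect_error(world_to_angle(3, -5), "positive")
})

test_that("angle_to_screen scales by D tan(theta) and rejects grazing angles", {
  expect_equal(angle_to_screen(0, 97), 0)
  expect_equal(angle_to_screen(0.025635, 97), 97 * tan(0.025635), tolerance = 1e-12)
  expect_equal(angle_to_screen(0.025635, 97), 2.4872, tolerance = 1e-4)
  expect_error(angle_to_screen(pi / 2, 97), "pi/2")
})

test_that("world_to_screen equals the angle composition over a grid", {
  expect_equal(world_to_screen(3, 97, 97), 3)
  expect_equal(world_to_screen(3, 117, 97), 2.4872, tolerance = 1e-4)
  expect_equal(world_to_screen(3, 77, 97), 3.7792, tolerance = 1e-4)
  grid <- tidyr::crossing(x = c(-6, -3, -0.5, 0, 0.5, 3, 6),
                          z = c(20, 77, 97, 117, 400))
  direct <- world_to_screen(grid$x, grid$z, 97)
  composed <- angle_to_screen(world_to_angle(grid$x, grid$z), 97)
  expect_equal(direct, composed, tolerance = 1e-12)
  # a point in the screen plane projects to itself
  expect_equal(angle_to_screen(world_to_angle(3, 97), 97), 3, tolerance = 1e-12)
})

test_that("angular_speed is the exact derivative of the visual angle", {
  expect_equal(angular_speed(3, 117, 40), 30.1, tolerance = 0.05)
  expect_equal(angular_speed(3, 97, 40), 43.8, tolerance = 0.05)
  expect_equal(angular_speed(3, 50, 0), 0)
  expect_error(angular_speed(3, -1, 40), "positive")
  # central-difference oracle on theta(t) = atan(x / (z0 - v t))
  h <- 1e-6
  cases <- tidyr::crossing(x = c(0.5, 3, 6), z = c(80, 97, 117), v = c(5, 40, 70))
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; z <- cases$z[i]; v <- cases$v[i]
    numeric_deriv <- (atan(x / (z - v * h)) - atan(x / (z + v * h))) / (2 * h)
    expect_equal(angular_speed(x, z, v), numeric_deriv * 180 / pi * 60,
                 tolerance = 1e-6)
  }
  # speeds up monotonically as the object approaches
  z <- seq(117, 77, by = -5)
  expect_true(all(diff(angular_speed(3, z, 40)) > 0))
})

test_that("recover_geometry inverts the endpoint speeds of both standards", {
  fast <- recover_geometry(30.1, 69.5, 40, 1)
  expect_equal(fast$z0_cm, 117, tolerance = 0.5 / 117)
  expect_equal(fast$x_w_cm, 3.0, tolerance = 0.02)
  slow <- recover_geometry(18.0, 27.2, 20, 1)
  expect_equal(slow$z0_cm, 107, tolerance = 0.5 / 107)
  # round trip from exactly-computed speeds recovers the geometry sharply
  s <- trace_speeds(world_trace(40, 40))
  rt <- recover_geometry(s[["a"]], s[["d"]], 40, 1)
  expect_equal(rt$z0_cm, 117, tolerance = 1e-6)
  expect_equal(rt$x_w_cm, 3, tolerance = 1e-6)
  expect_error(recover_geometry(50, 30, 40, 1), "d > a")
})

test_that("render_stereo reproduces the screen-plane fixed point and disparity growth", {
  geom <- viewing_geometry()
  # static object in the screen plane: each eye draws the line at its own x_w
  traj <- build_world_interval(speed_change_interval(1e-9, 1e-9), geom)
  scr <- render_stereo(traj, geom)
  expect_equal(scr$screen_x_cm,
               ifelse(scr$line == "right", 3, -3) * rep(1, nrow(scr)),
               tolerance = 1e-6)
  # zero IPD collapses both eyes onto the cyclopean projection
  geom0 <- viewing_geometry(ipd_cm = 0)
  traj0 <- build_world_interval(speed_change_interval(40, 40), geom0)
  scr0 <- render_stereo(traj0, geom0) |>
    tidyr::pivot_wider(id_cols = c("time_s", "line"),
                       names_from = "eye", values_from = "screen_x_cm")
  expect_equal(scr0$left, scr0$right, tolerance = 1e-12)
  # disparity (angle difference between the eyes) grows as z shrinks
  traj <- build_world_interval(speed_change_interval(40, 40), geom)
  disp <- render_stereo(traj, geom) |>
    dplyr::filter(line == "right") |>
    tidyr::pivot_wider(id_cols = "time_s", names_from = "eye",
                       values_from = "angle_arcmin") |>
    dplyr::mutate(disparity = left - right)
  expect_gt(abs(disp$disparity[nrow(disp)]), abs(disp$disparity[1]))
  expect_true(all(diff(abs(disp$disparity)) > 0))
  # World Control: the left half-image is shown to both eyes
  wc <- render_stereo(traj, geom, world_control = TRUE) |>
    tidyr::pivot_wider(id_cols = c("time_s", "line"),
                       names_from = "eye", values_from = "screen_x_cm")
  expect_equal(wc$left, wc$right)
})
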