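test_that("world trajectories sit symmetrically about the screen plane", {
  geom <- viewing_geometry()
  fast <- build_world_interval(speed_change_interval(40, 40), geom)
  expect_equal(fast$z0_cm, 117)
  expect_equal(fast$z1_cm, 77)
  max_change <- build_world_interval(speed_change_interval(10, 70), geom)
  expect_equal(max_change$z0_cm, 117)
  expect_equal(speedchange:::trajectory_z(max_change, 0.5), 112)
  expect_equal(max_change$z1_cm, 77)
  slow <- build_world_interval(speed_change_interval(20, 20), geom)
  expect_equal(slow$z0_cm, 107)
  expect_equal(slow$z1_cm, 87)
  expect_error(
    build_world_interval(speed_change_interval(200, 200), geom),
    "pass the eye"
  )
})

test_that("constant world speed produces strictly accelerating retinal speed", {
  for (v in c(20, 40)) {
    tr <- world_trace(v, v)
    cyc <- dplyr::filter(tr, channel == "cyclopean", line == "right")
    expect_true(all(diff(cyc$speed_arcmin_per_s) > 0))
    expect_true(all(diff(cyc$angle_arcmin) > 0))
  }
})

test_that("landmark speeds reproduce the published speed-table cells", {
  fast_std <- trace_speeds(world_trace(40, 40))
  expect_equal(round(fast_std[["a"]], 1), 30.1)
  expect_equal(round(fast_std[["b"]], 1), 43.8)
  expect_equal(round(fast_std[["d"]], 1), 69.5)
  fast_max <- trace_speeds(world_trace(10, 70))
  expect_equal(round(fast_max[["a"]], 1), 7.5)
  expect_equal(round(fast_max[["b"]], 1), 8.2)
  slow_std <- trace_speeds(world_trace(20, 20))
  expect_equal(round(slow_std[["a"]], 1), 18.0)
  expect_equal(round(slow_std[["b"]], 1), 21.9)
  expect_equal(round(slow_std[["d"]], 1), 27.2)
  slow_max <- trace_speeds(world_trace(5, 35))
  expect_equal(round(slow_max[["a"]], 1), 4.5)
  expect_equal(round(slow_max[["b"]], 1), 4.7)
  expect_equal(round(slow_max[["d"]], 1), 47.6)
  # cells where the instantaneous-derivative convention deviates slightly
  expect_equal(fast_max[["c"]], 57.6, tolerance = 0.3 / 57.6)
  expect_equal(fast_max[["d"]], 121.4, tolerance = 0.3 / 121.4)
  expect_equal(slow_max[["c"]], 33.1, tolerance = 0.3 / 33.1)
})

test_that("b <= c exactly when the world speed steps up", {
  up <- trace_speeds(world_trace(10, 70))
  expect_lt(up[["b"]], up[["c"]])
  flat <- trace_speeds(world_trace(40, 40))
  expect_equal(flat[["b"]], flat[["c"]])
})

test_that("every ladder level conserves world distance and duration", {
  geom <- viewing_geometry()
  for (cls in list(c(40, 5), c(20, 2.5))) {
    ladder <- level_ladder(cls[1], cls[2])
    dists <- purrr::pmap_dbl(ladder, function(level, v_before, v_after) {
      speedchange:::interval_distance(speed_change_interval(v_before, v_after))
    })
    expect_equal(dists, rep(cls[1] * 1, 7), tolerance = 1e-9)
    # identical trajectory endpoints at every level
    z0 <- purrr::pmap_dbl(ladder, function(level, v_before, v_after) {
      build_world_interval(speed_change_interval(v_before, v_after), geom)$z0_cm
    })
    expect_equal(z0, rep(z0[1], 7))
  }
})

test_that("retina intervals hold speed constant and conserve angular displacement", {
  geom <- viewing_geometry()
  for (cls in c("Fast", "Slow")) {
    ladder <- retina_speed_ladder(cls, geom)
    std <- ladder$speed_before[1]
    expect_equal(ladder$speed_before[1], ladder$speed_after[1])
    # piecewise-constant speed to within numerical zero
    tr <- build_retina_interval(std, std, geom = geom)
    cyc <- dplyr::filter(tr, channel == "cyclopean", line == "right")
    expect_lt(max(abs(cyc$speed_arcmin_per_s - std)), 1e-9)
    # displacement at every level equals the standard's
    disp <- purrr::pmap_dbl(ladder, function(level, speed_before, speed_after,
                                             prop_change) {
      t <- build_retina_interval(speed_before, speed_after, geom = geom)
      derive_retina_speed(t) * attr(t, "duration_s")
    })
    expect_equal(disp, rep(std * 1, 7), tolerance = 1e-9)
  }
  # zero-change level of the ladder coincides with the standard interval
  lad <- retina_speed_ladder("Fast", geom)
  expect_equal(lad$prop_change[1], 0)
  l1 <- build_retina_interval(lad$speed_before[1], lad$speed_after[1], geom = geom)
  std_tr <- build_retina_interval(lad$speed_before[1], lad$speed_before[1],
                                  geom = geom)
  expect_equal(l1$angle_arcmin, std_tr$angle_arcmin)
})

test_that("retina control translates rigidly while retina separates", {
  sep <- function(tr) {
    tidyr::pivot_wider(tr, id_cols = "time_s", names_from = "line",
                       values_from = "angle_arcmin") |>
      dplyr::mutate(sep = right - left)
  }
  retina <- sep(build_retina_interval(10, 50, family = "Retina"))
  expect_true(all(diff(retina$sep) > 0))
  control <- sep(build_retina_interval(10, 50, family = "RetinaControl"))
  expect_equal(control$sep, rep(control$sep[1], nrow(control)))
})

test_that("time-averaged retinal speed matches the closed form", {
  K <- 180 / pi * 60
  expect_equal(derive_retina_speed(world_trace(40, 40)),
               (atan(3 / 77) - atan(3 / 117)) * K, tolerance = 1e-9)
  expect_equal(derive_retina_speed(world_trace(20, 20)),
               (atan(3 / 87) - atan(3 / 107)) * K, tolerance = 1e-9)
  expect_equal(derive_retina_speed(world_trace(40, 40)), 45.74, tolerance = 1e-3)
  # mean of a constant-speed trace is that speed
  expect_equal(derive_retina_speed(build_retina_interval(47.6, 47.6)), 47.6,
               tolerance = 1e-9)
})

test_that("speed_table covers all conditions and matches the trace landmarks", {
  st <- speed_table(levels = c(1, 7))
  expect_equal(nrow(st), 16)
  expect_setequal(unique(st$condition), condition_grid()$condition)
  wf7 <- dplyr::filter(st, condition == "World-Fast", level == 7)
  expect_equal(unname(trace_speeds(world_trace(10, 70))),
               c(wf7$a, wf7$b, wf7$c, wf7$d))
})
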