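# Mapping-mission geometry: spacings, grid, speed window, blur, full plans.

test_that("footprint orientation maps sensor axes onto the flight frame", {
  cam <- paper_camera()
  wide <- footprint_along_across(cam, 28, "wide_side_along_flight")
  expect_equal(unname(wide), c(18.12364, 12.11636), tolerance = 1e-6)

  short <- footprint_along_across(cam, 28, "short_side_along_flight")
  expect_equal(short[["along"]], wide[["across"]])
  expect_equal(short[["across"]], wide[["along"]])

  expect_equal(
    unname(footprint_along_across(cam, 46, "wide_side_along_flight")),
    c(29.77455, 19.90545),
    tolerance = 1e-6
  )
})

test_that("overlap turns into spacing as footprint * (1 - lap/100)", {
  expect_equal(overlap_spacing(18.12, 0), 18.12)
  expect_equal(overlap_spacing(18.12, 92), 1.4496)
  expect_equal(overlap_spacing(12.12, 75), 3.03)
  expect_error(overlap_spacing(18.12, 100), "zero spacing")
})

test_that("grid counts ceil the extended area and warn past the storage cap", {
  area <- mapping_area(5, 5)
  # exact divisibility: (A_y + G_E) / E = 10 / 2.5
  g <- grid_counts(area, 5, 5, 2.5, 2.5)
  expect_identical(g$n_exposures, 4L)
  expect_identical(g$n_photos, g$n_exposures * g$n_lines)

  g2 <- grid_counts(mapping_area(40, 35), 18.12, 12.12, 1.45, 3.03)
  expect_identical(
    c(g2$n_exposures, g2$n_lines, g2$n_photos), c(37L, 18L, 666L)
  )

  expect_warning(
    grid_counts(mapping_area(40, 35), 18.12, 12.12, 1.45, 3.03, max_photos = 500),
    "storage capacity"
  )
})

test_that("exposure stations form a centred serpentine grid", {
  st <- exposure_stations(mapping_area(1, 1), 2, 2, 1, 1)
  expect_equal(st$x, c(0, 0, 1, 1))
  expect_equal(st$y, c(0, 1, 1, 0))

  # grid centroid equals the area centre for any counts
  for (n in list(c(3, 5), c(4, 4), c(7, 2))) {
    st <- exposure_stations(mapping_area(40, 35), n[1], n[2], 1.3, 2.9)
    expect_equal(mean(st$x), 20)
    expect_equal(mean(st$y), 17.5)
    expect_equal(nrow(st), n[1] * n[2])
  }
})

test_that("speed window follows the duration and trigger-rate limits", {
  area <- mapping_area(40, 35)
  expect_equal(
    min_flight_speed(18, area, 18.12, 12.12, 900), 1.120311,
    tolerance = 1e-6
  )
  expect_lt(min_flight_speed(18, area, 18.12, 12.12, 1e9), 1e-5)
  expect_equal(
    min_flight_speed(1, area, 18.12, 12.12, 900),
    (35 + 18.12 + 40 + 12.12) / 900
  )

  expect_equal(max_flight_speed(2, 1.45), 2.9)
  expect_equal(max_flight_speed(2, 18.12 * 0.05), 1.812)
  expect_equal(max_flight_speed(2, 2 * 1.45), 2 * max_flight_speed(2, 1.45))
  expect_error(max_flight_speed(0, 1.45), "trigger frequency")
})

test_that("motion blur is flight distance during exposure in pixel percent", {
  expect_equal(motion_blur(0, 1 / 2500, 0.005), 0)
  expect_equal(motion_blur(1, 1 / 2500, 0.005), 8)
  expect_equal(motion_blur(4, 1 / 500, 0.005), 160)
})

test_that("blur-budgeted speed is clamped to the window with the binding flag", {
  expect_equal(
    flight_speed_for_blur(0.003, 50, 1 / 500)$speed, 0.75
  )
  unclamped <- flight_speed_for_blur(0.003, 5, 1 / 16000)
  expect_equal(unclamped$candidate, 2.4)
  expect_identical(unclamped$limited_by, "motion_blur")

  clamped <- flight_speed_for_blur(0.003, 5, 1 / 16000, speed_max = 2)
  expect_equal(clamped$speed, 2)
  expect_identical(clamped$limited_by, "trigger_rate")

  raised <- flight_speed_for_blur(0.003, 5, 1 / 16000, speed_min = 3, speed_max = 5)
  expect_equal(raised$speed, 3)
  expect_identical(raised$limited_by, "flight_duration")

  expect_error(
    flight_speed_for_blur(0.003, 5, 1 / 16000, speed_min = 3, speed_max = 2),
    "infeasible"
  )
})

test_that("a full mission plan satisfies its construction invariants", {
  plan <- demo_plan()
  expect_identical(plan$n_photos, nrow(plan$stations))
  expect_identical(
    plan$n_photos, plan$n_exposures_per_line * plan$n_lines
  )
  expect_true(plan$speed_min <= plan$flight_speed)
  expect_true(plan$flight_speed <= plan$speed_max)
  expect_gte(plan$trigger_interval, 1 / plan$camera$sensor$max_trigger_hz - 1e-12)
  expect_lte(plan$motion_blur, plan$spec$max_motion_blur * (1 + 1e-9))
  expect_equal(plan$duration, plan$path_length / plan$flight_speed)

  # achieved laps are at least the requested laps (spacing never recomputed)
  expect_gte(100 * (1 - plan$spacing_along / plan$footprint_along), plan$end_lap)
  expect_gte(100 * (1 - plan$spacing_across / plan$footprint_across), plan$side_lap)

  # determinism: identical spec gives an identical plan
  expect_identical(plan_mission(demo_mission_spec()), plan_mission(demo_mission_spec()))
})

test_that("station footprints jointly cover the whole mapping area", {
  cam <- paper_camera(5.6)
  for (laps in list(c(50, 30), c(85, 70), c(92, 75))) {
    spec <- mission_spec(
      cam, exposure_settings(1 / 2000, 400), mapping_area(22, 17),
      flight_height = 30, end_lap = laps[1], side_lap = laps[2],
      max_motion_blur = 1000
    )
    plan <- plan_mission(spec)
    probe <- expand.grid(x = seq(0, 22, by = 0.25), y = seq(0, 17, by = 0.25))
    covered <- vapply(seq_len(nrow(probe)), function(i) {
      any(abs(plan$stations$x - probe$x[i]) <= plan$footprint_across / 2 &
        abs(plan$stations$y - probe$y[i]) <= plan$footprint_along / 2)
    }, logical(1))
    expect_true(all(covered))
  }
})

test_that("photo count is monotone in overlap and flight height", {
  cam <- paper_camera(5.6)
  n_photos <- function(h, lap_e, lap_s) {
    plan_mission(mission_spec(
      cam, exposure_settings(1 / 2000, 400), mapping_area(40, 35),
      flight_height = h, end_lap = lap_e, side_lap = lap_s,
      max_motion_blur = 1000
    ))$n_photos
  }
  laps <- seq(10, 90, by = 20)
  counts_by_lap <- vapply(laps, function(l) n_photos(30, l, l), numeric(1))
  expect_true(all(diff(counts_by_lap) >= 0))

  heights <- c(15, 25, 40, 60, 90)
  counts_by_h <- vapply(heights, function(h) n_photos(h, 80, 60), numeric(1))
  expect_true(all(diff(counts_by_h) <= 0))
})

test_that("the blur budget propagates into the planned speed and blur", {
  # camera-test conditions: 46 m, 1/2500 s; an 8% budget at 5 mm GSD caps
  # the speed at about 1 m/s
  spec <- mission_spec(
    paper_camera(6.7), exposure_settings(1 / 2500, 350), mapping_area(40, 35),
    flight_height = 46, end_lap = 85, side_lap = 70, max_motion_blur = 8
  )
  plan <- plan_mission(spec)
  expect_equal(plan$motion_blur, 8, tolerance = 1e-9)
  expect_equal(plan$flight_speed, 0.99, tolerance = 0.01)
  expect_equal(round(motion_blur(1, 1 / 2500, 0.005)), 8)

  # an unreachable blur budget under a tight duration fails loudly
  expect_error(
    plan_mission(mission_spec(
      paper_camera(6.7), exposure_settings(1 / 100, 350), mapping_area(200, 200),
      flight_height = 20, end_lap = 90, side_lap = 80,
      max_flight_duration = 300, max_motion_blur = 5
    )),
    "blur limit unreachable|infeasible"
  )
})
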