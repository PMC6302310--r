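# Per-photo optics and exposure. Derived expectations are frozen from direct
# closed-form arithmetic on the formulas (computed independently of the
# package functions) or, where marked, from values the source study prints.

test_that("pixel pitch is the x-axis sensor-size/pixel ratio with a 1% aspect guard", {
  s_exact <- sensor(36, 24, 6000, 4000)
  expect_equal(pixel_pitch(s_exact), 6e-6)

  expect_warning(s_paper <- sensor(35.6, 23.8, 6000, 4000), "0\\.28%")
  expect_equal(pixel_pitch(s_paper) * 1e6, 5.9333, tolerance = 1e-4)

  expect_error(sensor(35.6, 26, 6000, 4000), "aspect ratio")
  expect_error(sensor(-35.6, 23.8, 6000, 4000))
})

test_that("hyperfocal distance follows f^2/(N c) + f and shrinks with N and c", {
  expect_equal(hyperfocal_distance(paper_camera(6.7)), 76.14925, tolerance = 1e-6)
  expect_equal(hyperfocal_distance(paper_camera(5.6)), 91.09633, tolerance = 1e-6)

  # doubling c halves H - f
  cam1 <- suppressWarnings(camera_system(paper_sensor(), lens(55, 6.7), coc_mm = 0.0059333 / 2))
  cam2 <- suppressWarnings(camera_system(paper_sensor(), lens(55, 6.7), coc_mm = 0.0059333))
  f_m <- 0.055
  expect_equal(
    hyperfocal_distance(cam2) - f_m,
    (hyperfocal_distance(cam1) - f_m) / 2
  )

  # strictly decreasing in aperture number
  ns <- c(2.8, 4, 5.6, 8, 11)
  hs <- vapply(ns, function(n) hyperfocal_distance(paper_camera(n)), numeric(1))
  expect_true(all(diff(hs) < 0))

  expect_error(camera_system(paper_sensor(), lens(55, 6.7), coc_mm = 0.01),
    "smaller than or equal"
  )
})

test_that("diffraction limit is 2 * 1.22 * lambda * N, flagged against the CoC", {
  cam <- paper_camera(8)
  d8 <- diffraction_limit(cam$lens, cam$coc)
  expect_equal(d8$limit * 1e6, 10.736, tolerance = 1e-6)
  expect_true(d8$limited)

  d4 <- diffraction_limit(lens(55, 4), cam$coc)
  expect_equal(d4$limit * 1e6, 5.368, tolerance = 1e-6)
  expect_false(d4$limited)

  d0 <- diffraction_limit(lens(55, 8, wavelength_nm = 0), cam$coc)
  expect_equal(d0$limit, 0)
  expect_false(d0$limited)
})

test_that("angle of view is 2 atan(S / 2f) per axis", {
  sq <- suppressWarnings(camera_system(sensor(110, 110 * 2 / 3, 6000, 4000), lens(55, 5.6)))
  expect_equal(angle_of_view(sq)[["x"]], 90)

  aov <- angle_of_view(paper_camera())
  expect_equal(aov[["x"]], 35.86693, tolerance = 1e-6)
  expect_equal(aov[["y"]], 24.41708, tolerance = 1e-6)

  tele <- suppressWarnings(camera_system(paper_sensor(), lens(55000, 5.6)))
  expect_lt(angle_of_view(tele)[["x"]], 0.04)
})

test_that("ground field of view and GSD scale linearly with flight height", {
  cam <- paper_camera()
  expect_equal(unname(ground_field_of_view(cam, 0)), c(0, 0))
  expect_equal(
    unname(ground_field_of_view(cam, 28)), c(18.12364, 12.11636),
    tolerance = 1e-6
  )
  expect_equal(
    unname(ground_field_of_view(cam, 46)), c(29.77455, 19.90545),
    tolerance = 1e-6
  )

  # printed GSD column: 2 / 3 / 5 / 10 mm at 19 / 28 / 46 / 93 m
  gsd_mm <- vapply(
    c(19, 28, 46, 93),
    function(h) 1000 * ground_sampling_distance(cam, h), numeric(1)
  )
  expect_equal(round(gsd_mm), c(2, 3, 5, 10))
  expect_equal(round(gsd_mm[2], 2), 3.02)

  for (h in c(5, 17.3, 46)) {
    expect_equal(
      ground_sampling_distance(cam, 2 * h),
      2 * ground_sampling_distance(cam, h)
    )
  }
})

test_that("flight height for a target GSD inverts the GSD exactly", {
  cam <- paper_camera()
  expect_equal(flight_height_for_gsd(cam, 0), 0)
  expect_equal(round(flight_height_for_gsd(cam, 0.003)), 28)
  for (h in c(1, 28, 46, 120)) {
    expect_equal(
      flight_height_for_gsd(cam, ground_sampling_distance(cam, h)), h
    )
  }
})

test_that("depth of field brackets the focus distance, diverging at the hyperfocal", {
  cam <- paper_camera(6.7)
  h_f <- hyperfocal_distance(cam)

  at_h <- depth_of_field(cam, h_f)
  expect_equal(at_h[["near"]], h_f / 2)
  expect_identical(at_h[["far"]], Inf)

  at_10 <- depth_of_field(cam, 10)
  expect_equal(at_10[["near"]], 8.839224, tolerance = 1e-6)
  expect_equal(at_10[["far"]], 11.511733, tolerance = 1e-6)
  expect_true(at_10[["near"]] <= 10 && 10 <= at_10[["far"]])
})

test_that("ground-centred focus distance solves the depth-of-field midpoint exactly", {
  cam56 <- paper_camera(5.6)
  s <- optimal_focus_distance(cam56, 28)
  expect_equal(s, 25.76088, tolerance = 1e-6)
  expect_equal(s, 25.7, tolerance = 0.1 / 25.7) # printed value, 0.1 m slack
  expect_equal(mean(depth_of_field(cam56, s)), 28, tolerance = 1e-12)

  expect_equal(optimal_focus_distance(paper_camera(6.7), 10), 9.833251,
    tolerance = 1e-6
  )

  # far below the hyperfocal distance the focus sits at the ground
  wide <- suppressWarnings(camera_system(paper_sensor(), lens(55, 1.4)))
  expect_equal(optimal_focus_distance(wide, 2), 2, tolerance = 1e-3)
})

test_that("depth-of-field midpoint and harmonic-mean identities hold across random cameras", {
  set.seed(42)
  for (i in 1:200) {
    w <- runif(1, 5, 40)
    cam <- camera_system(
      sensor(w, w * 2 / 3, 6000, 4000),
      lens(runif(1, 10, 100), runif(1, 1.4, 16))
    )
    h <- runif(1, 2, 150)
    s <- optimal_focus_distance(cam, h)
    dof <- depth_of_field(cam, s)
    expect_lt(abs(mean(dof) - h) / h, 1e-9)
    # harmonic-mean identity 2/s = 1/D_N + 1/D_F for any s below H
    s2 <- runif(1, 0.1, 0.99) * hyperfocal_distance(cam)
    dof2 <- depth_of_field(cam, s2)
    expect_equal(2 / s2, 1 / dof2[["near"]] + 1 / dof2[["far"]], tolerance = 1e-12)
    expect_true(s < hyperfocal_distance(cam))
  }
})

test_that("exposure value and the ISO inverse agree with the definition", {
  expect_equal(exposure_value(1, 1, 100), 0)
  expect_equal(exposure_value(6.7, 1 / 2500, 350), 14.96868, tolerance = 1e-6)
  expect_equal(exposure_value(8, 1 / 500, 320), 13.28771, tolerance = 1e-6)

  expect_equal(iso_for_exposure(8, 1 / 500, 13.28771238), 320, tolerance = 1e-6)
  expect_equal(iso_for_exposure(5.6, 1 / 16000, 15), 1531.25)

  set.seed(7)
  for (i in 1:1000) {
    n <- runif(1, 0.7, 22)
    t <- 10^runif(1, -5, 0)
    iso <- runif(1, 25, 12800)
    expect_equal(iso_for_exposure(n, t, exposure_value(n, t, iso)), iso)
  }

  expect_warning(
    iso_for_exposure(5.6, 1 / 16000, 15, max_iso = 800),
    "reduce shutter speed"
  )
})

test_that("photography summary is internally consistent", {
  p <- photography_summary(paper_camera(5.6), 28)
  expect_equal(p$gsd, p$ground_fov_x / 6000)
  expect_true(p$dof_near <= p$focus_distance && p$focus_distance <= p$dof_far)
  expect_equal(mean(c(p$dof_near, p$dof_far)), 28)
  expect_output(print(p), "GSD")
})
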