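# Per-photo optics and exposure for a digital frame camera on a nadir-looking
# UAS. All stored quantities and return values are SI (metres, seconds);
# millimetres/nanometres appear only in constructor arguments, degrees only at
# the interface.

#' Describe a camera sensor
#'
#' A digital frame-camera sensor is characterised by its physical size and the
#' number of recorded pixels per axis. The pixel pitch (distance between pixel
#' centers) is the ratio of the two; a pixel aspect ratio of one is assumed,
#' so the x- and y-axis pitches must agree to within 1%. A mismatch within
#' tolerance (e.g. 0.28% for a 35.6 x 23.8 mm, 6000 x 4000 px sensor) triggers
#' a warning and the x-axis value is used throughout.
#'
#' @param width_mm,height_mm Physical sensor dimensions in millimetres.
#' @param pixels_x,pixels_y Number of recorded pixels along each axis.
#' @param max_trigger_hz Fastest photo trigger frequency the camera sustains
#'   (exposures per second). Caps the flight speed of a mapping mission.
#' @param max_iso Highest tolerable ISO film-speed setting (signal-to-noise
#'   limit); `NULL` for uncapped.
#' @return An object of class `uas_sensor` (dimensions stored in metres).
#' @examples
#' s <- suppressWarnings(sensor(35.6, 23.8, 6000, 4000, max_iso = 4000))
#' pixel_pitch(s) * 1e6  # pitch in micrometres
#' @export
sensor <- function(width_mm, height_mm, pixels_x, pixels_y,
                   max_trigger_hz = 2, max_iso = NULL) {
  stopifnot(
    is.numeric(width_mm), width_mm > 0,
    is.numeric(height_mm), height_mm > 0,
    pixels_x > 0, pixels_y > 0,
    max_trigger_hz > 0
  )
  pitch_x <- width_mm / pixels_x
  pitch_y <- height_mm / pixels_y
  rel <- abs(pitch_x - pitch_y) / pitch_x
  if (rel > 0.01) {
    stop(sprintf(
      "invalid sensor: pixel pitch differs between axes by %.2f%% (> 1%%); a pixel aspect ratio of one is assumed",
      100 * rel
    ))
  }
  if (rel > 1e-9) {
    warning(sprintf(
      "pixel pitch differs between axes by %.2f%%; the x-axis value is used",
      100 * rel
    ))
  }
  structure(
    list(
      width = width_mm / 1000, height = height_mm / 1000,
      pixels_x = as.integer(pixels_x), pixels_y = as.integer(pixels_y),
      max_trigger_hz = max_trigger_hz,
      max_iso = if (is.null(max_iso)) Inf else max_iso
    ),
    class = "uas_sensor"
  )
}

#' Distance between pixel centers (pixel pitch)
#'
#' Ratio of sensor width to recorded pixels on the x-axis. The x-axis is
#' canonical when the two axes disagree within the 1% tolerance.
#'
#' @param sensor A [sensor()] object.
#' @return Pixel pitch in metres.
#' @export
pixel_pitch <- function(sensor) {
  stopifnot(inherits(sensor, "uas_sensor"))
  sensor$width / sensor$pixels_x
}

#' Describe a (thin) lens
#'
#' @param focal_length_mm Effective physical focal length in millimetres.
#' @param aperture Aperture f-number N (focal length over aperture diameter).
#' @param wavelength_nm Reference wavelength of light for the diffraction
#'   limit, in nanometres. Defaults to 550 nm (mid-visible).
#' @return An object of class `uas_lens` (lengths stored in metres).
#' @export
lens <- function(focal_length_mm, aperture, wavelength_nm = 550) {
  stopifnot(focal_length_mm > 0, aperture >= 0.7, wavelength_nm >= 0)
  structure(
    list(
      focal_length = focal_length_mm / 1000,
      aperture = aperture,
      wavelength = wavelength_nm * 1e-9
    ),
    class = "uas_lens"
  )
}

#' Combine sensor and lens into a camera system
#'
#' The circle-of-confusion limit `c` defaults to the pixel pitch, the
#' resolving limit of the sensing system; it may be overridden downward but
#' never exceeds the pitch.
#'
#' @param sensor A [sensor()] object.
#' @param lens A [lens()] object.
#' @param coc_mm Circle-of-confusion limit in millimetres, or `NULL` for the
#'   pixel pitch.
#' @return An object of class `uas_camera`.
#' @examples
#' cam <- suppressWarnings(
#'   camera_system(sensor(35.6, 23.8, 6000, 4000), lens(55, 6.7))
#' )
#' hyperfocal_distance(cam)
#' @export
camera_system <- function(sensor, lens, coc_mm = NULL) {
  stopifnot(inherits(sensor, "uas_sensor"), inherits(lens, "uas_lens"))
  pitch <- pixel_pitch(sensor)
  coc <- if (is.null(coc_mm)) pitch else coc_mm / 1000
  if (coc <= 0) stop("circle of confusion must be positive")
  if (coc > pitch * (1 + 1e-9)) {
    stop("circle of confusion must be smaller than or equal to the pixel pitch")
  }
  structure(
    list(sensor = sensor, lens = lens, pixel_pitch = pitch, coc = coc),
    class = "uas_camera"
  )
}

#' @export
print.uas_camera <- function(x, ...) {
  s <- x$sensor
  cat("UAS camera system\n")
  cat(sprintf(
    "  sensor: %.1f x %.1f mm, %d x %d px (pitch %.4f um)\n",
    s$width * 1000, s$height * 1000, s$pixels_x, s$pixels_y,
    x$pixel_pitch * 1e6
  ))
  cat(sprintf(
    "  lens:   f = %.1f mm, f/%.1f, lambda = %.0f nm\n",
    x$lens$focal_length * 1000, x$lens$aperture, x$lens$wavelength * 1e9
  ))
  cat(sprintf("  circle of confusion: %.4f um\n", x$coc * 1e6))
  aov <- angle_of_view(x)
  cat(sprintf("  angle of view: %.1f x %.1f deg\n", aov[["x"]], aov[["y"]]))
  cat(sprintf("  hyperfocal distance: %.1f m\n", hyperfocal_distance(x)))
  invisible(x)
}

#' Exposure settings
#'
#' @param shutter_s Shutter (integration) time in seconds.
#' @param iso ISO film-speed setting.
#' @return An object of class `uas_exposure`.
#' @export
exposure_settings <- function(shutter_s, iso) {
  stopifnot(shutter_s > 0, iso > 0)
  structure(list(shutter = shutter_s, iso = iso), class = "uas_exposure")
}

#' Hyperfocal distance
#'
#' Focus distance beyond which all imaged objects stay within the circle of
#' confusion and are regarded as sharp: `H = f^2 / (N c) + f`.
#'
#' @param camera A [camera_system()] object.
#' @return Hyperfocal distance in metres.
#' @export
hyperfocal_distance <- function(camera) {
  stopifnot(inherits(camera, "uas_camera"))
  f <- camera$lens$focal_length
  f^2 / (camera$lens$aperture * camera$coc) + f
}

#' Diffraction limit of a lens aperture
#'
#' Diameter of the diffraction (Airy) spot `d = 2 * 1.22 * lambda * N`. The
#' system is diffraction-limited when the spot exceeds the circle-of-confusion
#' limit.
#'
#' @param lens A [lens()] object.
#' @param coc Circle-of-confusion limit in metres (compare against).
#' @return A list with `limit` (metres) and logical `limited` (`d > coc`).
#' @export
diffraction_limit <- function(lens, coc) {
  stopifnot(inherits(lens, "uas_lens"), coc > 0)
  d <- 2 * 1.22 * lens$wavelength * lens$aperture
  list(limit = d, limited = d > coc)
}

#' Angle of view
#'
#' `AOV = 2 * atan(S / (2 f))` per sensor axis.
#'
#' @param camera A [camera_system()] object.
#' @return Named numeric `c(x =, y =)` in degrees.
#' @export
angle_of_view <- function(camera) {
  stopifnot(inherits(camera, "uas_camera"))
  f <- camera$lens$focal_length
  s <- camera$sensor
  c(
    x = 2 * atan(s$width / (2 * f)) * 180 / pi,
    y = 2 * atan(s$height / (2 * f)) * 180 / pi
  )
}

#' Ground field of view
#'
#' Ground rectangle visible in one nadir photo at flight height `h`:
#' `G = S * h / f` per axis.
#'
#' @param camera A [camera_system()] object.
#' @param height Flight height above ground in metres (>= 0).
#' @return Named numeric `c(x =, y =)` in metres.
#' @export
ground_field_of_view <- function(camera, height) {
  stopifnot(inherits(camera, "uas_camera"), height >= 0)
  f <- camera$lens$focal_length
  c(
    x = camera$sensor$width * height / f,
    y = camera$sensor$height * height / f
  )
}

#' Ground sampling distance
#'
#' Ground extent covered by one sensor pixel, `GSD = S_delta * h / f`.
#'
#' @inheritParams ground_field_of_view
#' @return GSD in metres.
#' @export
ground_sampling_distance <- function(camera, height) {
  stopifnot(inherits(camera, "uas_camera"), height >= 0)
  camera$pixel_pitch * height / camera$lens$focal_length
}

#' Flight height that realises a target ground sampling distance
#'
#' Exact inverse of [ground_sampling_distance()]: `h = GSD * f / S_delta`.
#'
#' @param camera A [camera_system()] object.
#' @param gsd Target ground sampling distance in metres (>= 0).
#' @return Flight height in metres.
#' @export
flight_height_for_gsd <- function(camera, gsd) {
  stopifnot(inherits(camera, "uas_camera"), gsd >= 0)
  gsd * camera$lens$focal_length / camera$pixel_pitch
}

#' Depth of field around a focus distance
#'
#' Near and far limits of acceptable sharpness for focus distance `s`:
#' `D = s H / (H +- s)`; the far limit is infinite for `s >= H`.
#'
#' @param camera A [camera_system()] object.
#' @param focus Focus distance `s` in metres (> 0).
#' @return Named numeric `c(near =, far =)` in metres; `far` may be `Inf`.
#' @export
depth_of_field <- function(camera, focus) {
  stopifnot(inherits(camera, "uas_camera"), focus > 0)
  h_f <- hyperfocal_distance(camera)
  near <- focus * h_f / (h_f + focus)
  far <- if (focus >= h_f) Inf else focus * h_f / (h_f - focus)
  c(near = near, far = far)
}

#' Focus distance with depth of field centred on the ground
#'
#' For nadir UAS photography the depth of field should expand equally before
#' and beyond the ground, i.e. `(D_N(s) + D_F(s)) / 2 = h`. Substituting the
#' depth-of-field limits gives a quadratic in `s` whose admissible root is
#' `s = H (sqrt(H^2 + 4 h^2) - H) / (2 h)`, always strictly below the
#' hyperfocal distance for finite `h` so that the far limit stays finite.
#'
#' @param camera A [camera_system()] object.
#' @param height Flight height above ground in metres (> 0).
#' @return Focus distance in metres.
#' @export
optimal_focus_distance <- function(camera, height) {
  stopifnot(inherits(camera, "uas_camera"), height > 0)
  h_f <- hyperfocal_distance(camera)
  h_f * (sqrt(h_f^2 + 4 * height^2) - h_f) / (2 * height)
}

#' Exposure value of an aperture/shutter/ISO combination
#'
#' `EV = log2(N^2 / I_t) + log2(100 / ISO)`; EV 0 corresponds to f/1, 1 s,
#' ISO 100.
#'
#' @param aperture Aperture f-number.
#' @param shutter Shutter time in seconds.
#' @param iso ISO film speed.
#' @return Exposure value in stops.
#' @export
exposure_value <- function(aperture, shutter, iso) {
  stopifnot(aperture > 0, shutter > 0, iso > 0)
  log2(aperture^2 / shutter) + log2(100 / iso)
}

#' ISO setting that realises a measured exposure value
#'
#' Exact inverse of [exposure_value()] in ISO:
#' `ISO = 25 N^2 2^(2 - EV) / I_t`. When the result exceeds the sensor's
#' tolerable maximum a warning suggests reducing shutter speed (and flight
#' speed, to keep motion blur in check) or opening the aperture.
#'
#' @param aperture Aperture f-number.
#' @param shutter Shutter time in seconds.
#' @param ev Measured exposure value in stops.
#' @param max_iso Highest tolerable ISO; default uncapped.
#' @return ISO setting (not rounded).
#' @export
iso_for_exposure <- function(aperture, shutter, ev, max_iso = Inf) {
  stopifnot(aperture > 0, shutter > 0)
  iso <- 25 * aperture^2 * 2^(2 - ev) / shutter
  if (iso > max_iso) {
    warning(sprintf(
      "required ISO %.0f exceeds the tolerable maximum %.0f; reduce shutter speed (and flight speed) or open the aperture",
      iso, max_iso
    ))
  }
  iso
}

#' Photographic summary at a flight height
#'
#' Gathers the derived per-photo quantities at a given flight height: pixel
#' pitch, hyperfocal distance, diffraction limit, angle and ground field of
#' view, GSD, the ground-centred focus distance and its depth of field.
#'
#' @param camera A [camera_system()] object.
#' @param height Flight height above ground in metres (> 0).
#' @return A list of class `uas_photography`.
#' @export
photography_summary <- function(camera, height) {
  stopifnot(inherits(camera, "uas_camera"), height > 0)
  aov <- angle_of_view(camera)
  gfov <- ground_field_of_view(camera, height)
  diff <- diffraction_limit(camera$lens, camera$coc)
  focus <- optimal_focus_distance(camera, height)
  dof <- depth_of_field(camera, focus)
  structure(
    list(
      flight_height = height,
      pixel_pitch = camera$pixel_pitch,
      circle_of_confusion = camera$coc,
      hyperfocal = hyperfocal_distance(camera),
      diffraction_limit = diff$limit,
      diffraction_limited = diff$limited,
      aov_x = aov[["x"]], aov_y = aov[["y"]],
      ground_fov_x = gfov[["x"]], ground_fov_y = gfov[["y"]],
      gsd = ground_sampling_distance(camera, height),
      focus_distance = focus,
      dof_near = dof[["near"]], dof_far = dof[["far"]]
    ),
    class = "uas_photography"
  )
}

#' @export
print.uas_photography <- function(x, ...) {
  cat("Photography at", format(x$flight_height), "m flight height\n")
  cat(sprintf("  GSD:                %.2f mm\n", x$gsd * 1000))
  cat(sprintf("  ground field of view: %.1f x %.1f m\n", x$ground_fov_x, x$ground_fov_y))
  cat(sprintf("  angle of view:      %.1f x %.1f deg\n", x$aov_x, x$aov_y))
  cat(sprintf("  hyperfocal:         %.1f m\n", x$hyperfocal))
  cat(sprintf(
    "  focus distance:     %.1f m (depth of field %.1f-%s m)\n",
    x$focus_distance, x$dof_near,
    if (is.finite(x$dof_far)) sprintf("%.1f", x$dof_far) else "Inf"
  ))
  cat(sprintf(
    "  diffraction limit:  %.2f um%s\n", x$diffraction_limit * 1e6,
    if (x$diffraction_limited) " (diffraction limited!)" else ""
  ))
  invisible(x)
}
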