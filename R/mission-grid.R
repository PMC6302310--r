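# Mapping-mission geometry: overlaps -> spacings, exposure-station grid,
# flight-speed window, motion blur, flight duration.
#
# Local frame convention: origin at one corner of the rectangular mapping
# area, +y is the flight direction, +x across flight lines. Flight lines run
# parallel to +y and are flown in serpentine (boustrophedon) order starting
# at the line nearest the origin.

#' Rectangular mapping area
#'
#' @param width Extent across flight lines (`A_x`), metres.
#' @param depth Extent along flight direction (`A_y`), metres.
#' @return An object of class `uas_area`.
#' @export
mapping_area <- function(width, depth) {
  stopifnot(width > 0, depth > 0)
  structure(list(width = width, depth = depth), class = "uas_area")
}

#' Ground footprint along and across the flight direction
#'
#' Maps the sensor axes onto the flight frame: with the wide sensor side
#' along the flight direction the along-track footprint is `G_x` and the
#' across-track footprint `G_y`; the other orientation swaps the pair.
#'
#' @param camera A [camera_system()] object.
#' @param height Flight height in metres.
#' @param orientation `"wide_side_along_flight"` or
#'   `"short_side_along_flight"`.
#' @return Named numeric `c(along =, across =)` in metres.
#' @export
footprint_along_across <- function(camera, height,
                                   orientation = c(
                                     "wide_side_along_flight",
                                     "short_side_along_flight"
                                   )) {
  orientation <- match.arg(orientation)
  g <- ground_field_of_view(camera, height)
  if (orientation == "wide_side_along_flight") {
    c(along = g[["x"]], across = g[["y"]])
  } else {
    c(along = g[["y"]], across = g[["x"]])
  }
}

#' Spacing between exposures or flight lines from a percent overlap
#'
#' `spacing = footprint * (1 - lap / 100)`.
#'
#' @param footprint Ground footprint extent in metres.
#' @param lap Requested overlap in percent, `0 <= lap < 100`.
#' @return Spacing in metres.
#' @export
overlap_spacing <- function(footprint, lap) {
  stopifnot(footprint > 0, lap >= 0)
  if (lap >= 100) stop("an overlap of 100% gives zero spacing between exposures")
  footprint * (1 - lap / 100)
}

# ceiling with a small fuzz so that exactly divisible extents do not round up
# due to floating-point noise
ceil_fuzz <- function(x) as.integer(ceiling(x - 1e-9))

#' Exposure and flight-line counts covering an extended mapping area
#'
#' The area is extended by half a footprint in both dimensions and directions
#' so overlap requirements hold up to the area edges:
#' `E_n = ceil((A_y + G_E) / E)`, `S_n = ceil((A_x + G_S) / S)`,
#' `I_n = E_n * S_n`.
#'
#' @param area A [mapping_area()].
#' @param footprint_along,footprint_across Ground footprint along/across the
#'   flight direction, metres.
#' @param spacing_along,spacing_across Spacing between exposures / between
#'   flight lines, metres.
#' @param max_photos Optional storage cap; exceeding it warns.
#' @return List with `n_exposures` (per line), `n_lines`, `n_photos`.
#' @export
grid_counts <- function(area, footprint_along, footprint_across,
                        spacing_along, spacing_across, max_photos = NULL) {
  stopifnot(inherits(area, "uas_area"), spacing_along > 0, spacing_across > 0)
  n_exposures <- ceil_fuzz((area$depth + footprint_along) / spacing_along)
  n_lines <- ceil_fuzz((area$width + footprint_across) / spacing_across)
  n_photos <- n_exposures * n_lines
  if (!is.null(max_photos) && n_photos > max_photos) {
    warning(sprintf(
      "planned number of photos (%d) exceeds the storage capacity (%d)",
      n_photos, max_photos
    ))
  }
  list(n_exposures = n_exposures, n_lines = n_lines, n_photos = n_photos)
}

#' Exposure-station positions in serpentine order
#'
#' The station grid is centred on the mapping area: the slack introduced by
#' the ceiling in the counts is distributed symmetrically to both ends. Lines
#' sit at `x_i = A_x/2 + (i - (S_n - 1)/2) S` and stations within a line at
#' `y_j = A_y/2 + (j - (E_n - 1)/2) E`. Even lines are flown in +y, odd lines
#' in -y.
#'
#' @inheritParams grid_counts
#' @param n_exposures Exposures per flight line.
#' @param n_lines Number of flight lines.
#' @return A data frame with columns `line` (0-based), `x`, `y` in flight
#'   order.
#' @export
exposure_stations <- function(area, n_exposures, n_lines,
                              spacing_along, spacing_across) {
  stopifnot(inherits(area, "uas_area"), n_exposures >= 1, n_lines >= 1)
  xs <- area$width / 2 + (seq_len(n_lines) - 1 - (n_lines - 1) / 2) * spacing_across
  ys <- area$depth / 2 + (seq_len(n_exposures) - 1 - (n_exposures - 1) / 2) * spacing_along
  out <- do.call(rbind, lapply(seq_along(xs), function(i) {
    yy <- if (i %% 2 == 1) ys else rev(ys) # i is 1-based: odd i = even line
    data.frame(line = i - 1L, x = xs[i], y = yy)
  }))
  rownames(out) <- NULL
  out
}

#' Minimum flight speed to finish within the allowed duration
#'
#' Approximates the total path as the flight lines (each `A_y + G_E` long)
#' plus the across-track transit (`A_x + G_S`):
#' `F_v,min = (S_n (A_y + G_E) + A_x + G_S) / F_t,max`.
#'
#' @inheritParams grid_counts
#' @param n_lines Number of flight lines.
#' @param max_duration Maximum allowed flight duration in seconds.
#' @return Minimum flight speed in m/s.
#' @export
min_flight_speed <- function(n_lines, area, footprint_along, footprint_across,
                             max_duration) {
  stopifnot(max_duration > 0, n_lines >= 1)
  path <- mission_path_length(n_lines, area, footprint_along, footprint_across)
  path / max_duration
}

mission_path_length <- function(n_lines, area, footprint_along, footprint_across) {
  n_lines * (area$depth + footprint_along) + area$width + footprint_across
}

#' Maximum flight speed supported by the photo trigger rate
#'
#' `F_v,max = I_f,max * E`: flying faster than this would require triggering
#' faster than the camera supports to keep the end lap.
#'
#' @param max_trigger_hz Fastest supported trigger frequency (1/s).
#' @param spacing_along Spacing between exposures `E` in metres.
#' @return Maximum flight speed in m/s.
#' @export
max_flight_speed <- function(max_trigger_hz, spacing_along) {
  if (max_trigger_hz <= 0) stop("maximum trigger frequency must be positive")
  stopifnot(spacing_along > 0)
  max_trigger_hz * spacing_along
}

#' Motion blur of a moving exposure
#'
#' Image smear during one exposure as a percentage of one pixel:
#' `delta = 100 * F_v * I_t / GSD`.
#'
#' @param speed Flight speed in m/s.
#' @param shutter Shutter time in seconds.
#' @param gsd Ground sampling distance in metres.
#' @return Motion blur in percent of a pixel.
#' @export
motion_blur <- function(speed, shutter, gsd) {
  stopifnot(speed >= 0, shutter > 0, gsd > 0)
  100 * speed * shutter / gsd
}

#' Flight speed realising a motion-blur budget within the speed window
#'
#' The blur-limited candidate `F_v = GSD * (delta/100) / I_t` is clamped to
#' the window `[F_v,min, F_v,max]` set by the flight-duration and
#' trigger-rate limits. The returned `limited_by` flag names the binding
#' constraint.
#'
#' @param gsd Ground sampling distance in metres.
#' @param max_blur Maximum tolerable motion blur in percent.
#' @param shutter Shutter time in seconds.
#' @param speed_min,speed_max Speed window bounds in m/s.
#' @return List with `speed`, `candidate` (unclamped), and `limited_by`, one
#'   of `"motion_blur"`, `"trigger_rate"`, `"flight_duration"`.
#' @export
flight_speed_for_blur <- function(gsd, max_blur, shutter,
                                  speed_min = 0, speed_max = Inf) {
  stopifnot(gsd > 0, max_blur > 0, shutter > 0)
  if (speed_min > speed_max) {
    stop(sprintf(
      "infeasible mission: minimum flight speed %.2f m/s exceeds maximum %.2f m/s; shorten the mission, allow a longer flight or a faster trigger rate",
      speed_min, speed_max
    ))
  }
  candidate <- gsd * (max_blur / 100) / shutter
  if (candidate > speed_max) {
    list(speed = speed_max, candidate = candidate, limited_by = "trigger_rate")
  } else if (candidate < speed_min) {
    list(speed = speed_min, candidate = candidate, limited_by = "flight_duration")
  } else {
    list(speed = candidate, candidate = candidate, limited_by = "motion_blur")
  }
}

#' Specify a mapping mission
#'
#' Bundles camera, exposure and mapping parameters. Exactly one of
#' `flight_height` or `gsd` must be given; a GSD is converted to the exact
#' flight height realising it.
#'
#' @param camera A [camera_system()].
#' @param exposure An [exposure_settings()].
#' @param area A [mapping_area()].
#' @param flight_height Flight height above ground in metres.
#' @param gsd Target ground sampling distance in metres (alternative to
#'   `flight_height`).
#' @param end_lap,side_lap Percent overlap along a line / between lines,
#'   `0 <= lap < 100`.
#' @param orientation Which sensor side points along the flight direction.
#' @param max_flight_duration Maximum allowed flight duration in seconds.
#' @param max_motion_blur Maximum tolerable motion blur in percent of a
#'   pixel.
#' @param positioning_sigma Positioning precision (standard deviation) of the
#'   UAS in metres; used by the viewing-geometry prediction.
#' @param max_photos Optional storage cap on the number of photos.
#' @return An object of class `uas_mission_spec`.
#' @export
mission_spec <- function(camera, exposure, area,
                         flight_height = NULL, gsd = NULL,
                         end_lap, side_lap,
                         orientation = c(
                           "wide_side_along_flight",
                           "short_side_along_flight"
                         ),
                         max_flight_duration = 900,
                         max_motion_blur = 50,
                         positioning_sigma = 0.3,
                         max_photos = NULL) {
  stopifnot(
    inherits(camera, "uas_camera"), inherits(exposure, "uas_exposure"),
    inherits(area, "uas_area"),
    end_lap >= 0, end_lap < 100, side_lap >= 0, side_lap < 100,
    max_flight_duration > 0, max_motion_blur > 0, positioning_sigma >= 0
  )
  orientation <- match.arg(orientation)
  if (is.null(flight_height) == is.null(gsd)) {
    stop("specify exactly one of flight_height or gsd")
  }
  if (is.null(flight_height)) {
    flight_height <- flight_height_for_gsd(camera, gsd)
  }
  stopifnot(flight_height > 0)
  structure(
    list(
      camera = camera, exposure = exposure, area = area,
      flight_height = flight_height, end_lap = end_lap, side_lap = side_lap,
      orientation = orientation, max_flight_duration = max_flight_duration,
      max_motion_blur = max_motion_blur, positioning_sigma = positioning_sigma,
      max_photos = max_photos
    ),
    class = "uas_mission_spec"
  )
}

#' Plan a mapping mission
#'
#' Orchestrates the full pipeline: footprints and GSD at the flight height,
#' overlap spacings, exposure-station grid, speed window, blur-budgeted
#' flight speed, trigger interval and flight duration. Fails with an
#' explanatory error when the speed window is empty or when the minimum
#' flight speed alone violates the motion-blur budget.
#'
#' @param spec A [mission_spec()].
#' @return An object of class `uas_flight_plan`.
#' @examples
#' cam <- suppressWarnings(
#'   camera_system(sensor(35.6, 23.8, 6000, 4000, max_iso = 4000), lens(55, 5.6))
#' )
#' spec <- mission_spec(cam, exposure_settings(1 / 16000, 2500),
#'   mapping_area(40, 35),
#'   gsd = 0.003, end_lap = 92, side_lap = 75, max_motion_blur = 5
#' )
#' plan <- plan_mission(spec)
#' plan$n_photos
#' @export
plan_mission <- function(spec) {
  stopifnot(inherits(spec, "uas_mission_spec"))
  camera <- spec$camera
  h <- spec$flight_height
  gsd <- ground_sampling_distance(camera, h)
  fp <- footprint_along_across(camera, h, spec$orientation)
  e_spacing <- overlap_spacing(fp[["along"]], spec$end_lap)
  s_spacing <- overlap_spacing(fp[["across"]], spec$side_lap)
  counts <- grid_counts(
    spec$area, fp[["along"]], fp[["across"]],
    e_spacing, s_spacing, spec$max_photos
  )
  stations <- exposure_stations(
    spec$area, counts$n_exposures, counts$n_lines, e_spacing, s_spacing
  )
  v_min <- min_flight_speed(
    counts$n_lines, spec$area, fp[["along"]], fp[["across"]],
    spec$max_flight_duration
  )
  v_max <- max_flight_speed(camera$sensor$max_trigger_hz, e_spacing)
  speed <- flight_speed_for_blur(
    gsd, spec$max_motion_blur, spec$exposure$shutter, v_min, v_max
  )
  blur <- motion_blur(speed$speed, spec$exposure$shutter, gsd)
  if (blur > spec$max_motion_blur * (1 + 1e-9)) {
    stop(sprintf(
      "motion-blur limit unreachable: flying at the minimum speed %.2f m/s yields %.0f%% blur (limit %.0f%%); allow a longer flight or a shorter shutter",
      v_min, blur, spec$max_motion_blur
    ))
  }
  path <- mission_path_length(counts$n_lines, spec$area, fp[["along"]], fp[["across"]])
  structure(
    list(
      spec = spec, camera = camera,
      flight_height = h, gsd = gsd, orientation = spec$orientation,
      footprint_along = fp[["along"]], footprint_across = fp[["across"]],
      spacing_along = e_spacing, spacing_across = s_spacing,
      end_lap = spec$end_lap, side_lap = spec$side_lap,
      n_exposures_per_line = counts$n_exposures,
      n_lines = counts$n_lines, n_photos = counts$n_photos,
      stations = stations,
      speed_min = v_min, speed_max = v_max,
      flight_speed = speed$speed, speed_limited_by = speed$limited_by,
      trigger_frequency = speed$speed / e_spacing,
      trigger_interval = e_spacing / speed$speed,
      path_length = path,
      duration = path / speed$speed,
      motion_blur = blur
    ),
    class = "uas_flight_plan"
  )
}

#' @export
print.uas_flight_plan <- function(x, ...) {
  cat("UAS mapping flight plan\n")
  cat(sprintf(
    "  area %g x %g m, flight height %.1f m, GSD %.2f mm\n",
    x$spec$area$width, x$spec$area$depth, x$flight_height, x$gsd * 1000
  ))
  cat(sprintf(
    "  laps %g%% / %g%% -> spacing %.2f m between exposures, %.2f m between lines\n",
    x$end_lap, x$side_lap, x$spacing_along, x$spacing_across
  ))
  cat(sprintf(
    "  %d lines x %d exposures = %d photos\n",
    x$n_lines, x$n_exposures_per_line, x$n_photos
  ))
  cat(sprintf(
    "  flight speed %.2f m/s (%s-limited; window %.2f-%.2f m/s)\n",
    x$flight_speed, sub("_", "-", x$speed_limited_by), x$speed_min, x$speed_max
  ))
  cat(sprintf(
    "  trigger every %.2f s (%.2f 1/s), motion blur %.0f%%\n",
    x$trigger_interval, x$trigger_frequency, x$motion_blur
  ))
  cat(sprintf(
    "  duration %.0f s (~%d min)\n", x$duration, ceiling(x$duration / 60)
  ))
  invisible(x)
}
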