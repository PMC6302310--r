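# Mission briefing: one deterministic summary of every flight-relevant
# quantity, with warnings for the classic mission hazards (ISO cap exceeded,
# diffraction-limited aperture, motion blur above the recommended 50%,
# storage cap, clamped flight speed).

#' Assemble a mission briefing
#'
#' Runs the full planning pipeline on a loaded configuration: photographic
#' quantities at the flight height, the flight plan, the GCP layout (given or
#' auto-placed for the target recover fraction) and its recovery histogram,
#' the zenith-angle distribution of plot-centre views, and a GSD-versus-
#' flight-height table. The briefing is deterministic: the same configuration
#' always yields a byte-identical report.
#'
#' @param config A [load_mission_config()] result (or something it accepts).
#' @return An object of class `uas_briefing`.
#' @export
mission_briefing <- function(config) {
  if (!inherits(config, "uas_mission_config")) {
    config <- load_mission_config(config)
  }
  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)

  camera <- config$camera
  spec <- config$spec
  photo <- photography_summary(camera, spec$flight_height)
  plan <- withCallingHandlers(
    plan_mission(spec),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  if (photo$diffraction_limited) {
    note(sprintf(
      "aperture f/%.1f is diffraction limited (spot %.2f um > circle of confusion %.2f um)",
      camera$lens$aperture, photo$diffraction_limit * 1e6, camera$coc * 1e6
    ))
  }
  if (config$exposure$iso > camera$sensor$max_iso) {
    note(sprintf(
      "ISO %.0f exceeds the tolerable maximum %.0f; reduce shutter speed (and flight speed) or open the aperture",
      config$exposure$iso, camera$sensor$max_iso
    ))
  }
  if (plan$motion_blur > 50) {
    note(sprintf(
      "motion blur %.0f%% exceeds the recommended limit of 50%%",
      plan$motion_blur
    ))
  }
  if (plan$speed_limited_by != "motion_blur") {
    note(sprintf(
      "flight speed clamped by the %s limit to %.2f m/s (blur budget alone would allow a different speed)",
      sub("_", " ", plan$speed_limited_by), plan$flight_speed
    ))
  }
  note(
    "transit legs are assumed flown at cruise speed; some autopilots add time buffers in turning points"
  )

  gcp_layout_out <- NULL
  gcp_recovery <- NULL
  if (!is.null(config$gcp)) {
    g <- config$gcp
    if (!is.null(g$pattern) && !is.null(g$n_x) && !is.null(g$n_y)) {
      gcp_layout_out <- gcp_layout(spec$area, g$pattern, g$n_x, g$n_y)
      gcp_recovery <- gcp_recover_frequency(
        plan$stations, plan$footprint_along, plan$footprint_across,
        gcp_layout_out
      )
    } else if (!is.null(g$target_at_least_one)) {
      gcp_layout_out <- auto_place_gcps(
        plan, spec$area, g$target_at_least_one
      )
      gcp_recovery <- gcp_layout_out$recovery
    }
    if (!is.null(gcp_recovery) && !is.null(g$target_at_least_one) &&
      gcp_recovery$at_least_one < g$target_at_least_one) {
      note(sprintf(
        "GCP layout reaches only %.0f%% of photos with >= 1 GCP (target %.0f%%)",
        100 * gcp_recovery$at_least_one, 100 * g$target_at_least_one
      ))
    }
  }

  viewing <- NULL
  zenith <- NULL
  if (!is.null(config$plots)) {
    viewing <- plot_center_pixel_frequency(plan, config$plots)
    zenith <- zenith_angle_histogram(viewing, camera)
  }

  heights <- config$report$heights_m %||% c(19, 28, 46, 93)
  gsd_table <- data.frame(
    height_m = heights,
    gsd_mm = vapply(
      heights, function(h) 1000 * ground_sampling_distance(camera, h),
      numeric(1)
    )
  )
  gsd_table$motion_blur_pct <- 100 * plan$flight_speed *
    config$exposure$shutter / (gsd_table$gsd_mm / 1000)

  structure(
    list(
      config = config, photography = photo, plan = plan,
      gcp_layout = gcp_layout_out, gcp_recovery = gcp_recovery,
      viewing = viewing, zenith = zenith,
      gsd_table = gsd_table, warnings = warnings
    ),
    class = "uas_briefing"
  )
}

#' Render a briefing as plain text
#'
#' @param x A [mission_briefing()] result.
#' @param ... Unused.
#' @return Character vector of report lines.
#' @export
format.uas_briefing <- function(x, ...) {
  p <- x$photography
  plan <- x$plan
  ex <- x$config$exposure
  ev <- exposure_value(x$config$camera$lens$aperture, ex$shutter, ex$iso)
  lines <- c(
    "UAS MAPPING MISSION BRIEFING",
    "",
    "Photography",
    sprintf("  flight height:        %.1f m", p$flight_height),
    sprintf("  GSD:                  %.0f mm (%.2f mm)", round(p$gsd * 1000), p$gsd * 1000),
    sprintf("  ground field of view: %.1f x %.1f m", p$ground_fov_x, p$ground_fov_y),
    sprintf("  angle of view:        %.1f x %.1f deg", p$aov_x, p$aov_y),
    sprintf("  hyperfocal distance:  %.1f m", p$hyperfocal),
    sprintf(
      "  focus distance:       %.1f m (depth of field %.1f-%s m)",
      p$focus_distance, p$dof_near,
      if (is.finite(p$dof_far)) sprintf("%.1f", p$dof_far) else "Inf"
    ),
    sprintf(
      "  diffraction limit:    %.2f um (%s)", p$diffraction_limit * 1e6,
      if (p$diffraction_limited) "diffraction limited" else "not limited"
    ),
    sprintf(
      "  exposure:             1/%.0f s, ISO %.0f, f/%.1f (EV %.1f)",
      1 / ex$shutter, ex$iso, x$config$camera$lens$aperture, ev
    ),
    "",
    "Flight plan",
    sprintf(
      "  area:                 %g x %g m", plan$spec$area$width,
      plan$spec$area$depth
    ),
    sprintf("  laps (end x side):    %g%% x %g%%", plan$end_lap, plan$side_lap),
    sprintf(
      "  exposures x lines:    %d x %d = %d photos",
      plan$n_exposures_per_line, plan$n_lines, plan$n_photos
    ),
    sprintf(
      "  flight speed:         %.2f m/s (window %.2f-%.2f m/s, %s-limited)",
      plan$flight_speed, plan$speed_min, plan$speed_max,
      sub("_", "-", plan$speed_limited_by)
    ),
    sprintf(
      "  trigger interval:     %.2f s (%.2f photos/s)",
      plan$trigger_interval, plan$trigger_frequency
    ),
    sprintf("  motion blur:          %.0f%%", plan$motion_blur),
    sprintf(
      "  flight duration:      %d min (%.0f s)",
      ceiling(plan$duration / 60), plan$duration
    ),
    "",
    "GSD by flight height",
    sprintf(
      "  %5.1f m -> %2.0f mm (motion blur %3.0f%%)",
      x$gsd_table$height_m, round(x$gsd_table$gsd_mm),
      round(x$gsd_table$motion_blur_pct)
    )
  )
  if (!is.null(x$gcp_recovery)) {
    lines <- c(
      lines, "",
      sprintf(
        "GCPs: %s %d x %d (%d markers)",
        x$gcp_layout$pattern, x$gcp_layout$n_x, x$gcp_layout$n_y,
        x$gcp_layout$n_gcps
      ),
      sprintf(
        "  %s per image: %.0f%%",
        names(x$gcp_recovery$frequencies),
        100 * x$gcp_recovery$frequencies
      ),
      sprintf("  >= 1 per image: %.0f%%", 100 * x$gcp_recovery$at_least_one)
    )
  }
  if (!is.null(x$zenith)) {
    modal <- x$zenith$theta_lower[which.max(x$zenith$freq)]
    lines <- c(
      lines, "",
      "Viewing geometry (plot centres)",
      sprintf(
        "  zenith angles observed up to %.0f deg; modal bin %g-%g deg",
        max(x$zenith$theta_upper[x$zenith$freq > 0]), modal, modal + 1
      )
    )
  }
  if (length(x$warnings)) {
    lines <- c(lines, "", "Warnings", paste0("  - ", x$warnings))
  }
  lines
}

#' @export
print.uas_briefing <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Briefing as a JSON-ready list
#'
#' Flattens the briefing into plain vectors and tables so it can be written
#' with [jsonlite::write_json()] and re-parsed by downstream tools.
#'
#' @param briefing A [mission_briefing()] result.
#' @return A named list.
#' @export
briefing_json <- function(briefing) {
  stopifnot(inherits(briefing, "uas_briefing"))
  p <- briefing$photography
  plan <- briefing$plan
  out <- list(
    photography = list(
      flight_height_m = p$flight_height,
      gsd_m = p$gsd,
      ground_fov_x_m = p$ground_fov_x, ground_fov_y_m = p$ground_fov_y,
      aov_x_deg = p$aov_x, aov_y_deg = p$aov_y,
      hyperfocal_m = p$hyperfocal,
      focus_distance_m = p$focus_distance,
      dof_near_m = p$dof_near, dof_far_m = p$dof_far,
      diffraction_limit_m = p$diffraction_limit,
      diffraction_limited = p$diffraction_limited
    ),
    plan = list(
      n_exposures_per_line = plan$n_exposures_per_line,
      n_lines = plan$n_lines, n_photos = plan$n_photos,
      spacing_along_m = plan$spacing_along,
      spacing_across_m = plan$spacing_across,
      flight_speed_ms = plan$flight_speed,
      speed_window_ms = c(plan$speed_min, plan$speed_max),
      speed_limited_by = plan$speed_limited_by,
      trigger_interval_s = plan$trigger_interval,
      duration_s = plan$duration,
      motion_blur_pct = plan$motion_blur
    ),
    gsd_table = briefing$gsd_table,
    warnings = briefing$warnings
  )
  if (!is.null(briefing$gcp_recovery)) {
    out$gcp <- list(
      pattern = briefing$gcp_layout$pattern,
      n_x = briefing$gcp_layout$n_x, n_y = briefing$gcp_layout$n_y,
      n_gcps = briefing$gcp_layout$n_gcps,
      positions = briefing$gcp_layout$positions,
      recover_frequency = as.list(briefing$gcp_recovery$frequencies),
      at_least_one = briefing$gcp_recovery$at_least_one
    )
  }
  if (!is.null(briefing$zenith)) {
    out$zenith_histogram <- briefing$zenith
  }
  out
}
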