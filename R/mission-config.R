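# Mission configuration I/O: a single JSON document carries every input of a
# mission (camera, exposure, mapping, GCPs, plots, geographic anchors,
# export), mirroring the briefing's "all entered parameters" documentation
# dump. Keys are snake_case with explicit unit suffixes.

config_sections <- c(
  "camera", "exposure", "mission", "gcp", "plots", "geo", "export", "report"
)

camera_keys <- c(
  "preset", "sensor_width_mm", "sensor_height_mm", "pixels_x", "pixels_y",
  "focal_length_mm", "aperture", "wavelength_nm", "max_trigger_frequency_hz",
  "max_iso", "circle_of_confusion_mm"
)
exposure_keys <- c("shutter_s", "iso")
mission_keys <- c(
  "area_width_m", "area_depth_m", "flight_height_m", "gsd_m", "end_lap_pct",
  "side_lap_pct", "orientation", "max_flight_duration_s",
  "max_motion_blur_pct", "positioning_sigma_m", "max_photos"
)
gcp_keys <- c("target_at_least_one", "pattern", "n_x", "n_y")
plot_keys <- c("n_x", "n_y")
geo_keys <- c("start", "edge1", "dir")
export_keys <- c("max_waypoints", "max_leg_length_m")
report_keys <- c("heights_m")

require_key <- function(section, keys, key, section_name) {
  if (!key %in% names(keys) || is.null(keys[[key]])) {
    stop(sprintf("mission config: missing required key '%s.%s'", section_name, key))
  }
  keys[[key]]
}

warn_unknown <- function(given, known, section_name) {
  unknown <- setdiff(names(given), known)
  if (length(unknown)) {
    warning(sprintf(
      "mission config: unknown key%s %s in '%s' ignored",
      if (length(unknown) > 1) "s" else "",
      paste0("'", unknown, "'", collapse = ", "), section_name
    ))
  }
}

#' Look up a bundled camera preset
#'
#' Presets live under `extdata/cameras` as JSON documents with the keys
#' `sensor_width_mm`, `sensor_height_mm`, `pixels_x`, `pixels_y`,
#' `focal_length_mm`, `max_trigger_frequency_hz`, `max_iso` (the aperture is
#' mission-specific and supplied alongside). The bundled `sony_a9_55mm`
#' preset is a 35.6 x 23.8 mm, 6000 x 4000 px full-frame body with a 55 mm
#' prime.
#'
#' @param name Preset name.
#' @return Named list of camera parameters.
#' @export
camera_preset <- function(name) {
  path <- system.file(
    "extdata", "cameras", paste0(name, ".json"),
    package = "uasplan"
  )
  if (path == "") {
    stop(sprintf("mission config: unknown camera preset '%s'", name))
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

camera_from_config <- function(cfg) {
  warn_unknown(cfg, camera_keys, "camera")
  if (!is.null(cfg$preset)) {
    preset <- camera_preset(cfg$preset)
    cfg <- utils::modifyList(preset, cfg[setdiff(names(cfg), "preset")])
  }
  sens <- sensor(
    require_key("camera", cfg, "sensor_width_mm", "camera"),
    require_key("camera", cfg, "sensor_height_mm", "camera"),
    require_key("camera", cfg, "pixels_x", "camera"),
    require_key("camera", cfg, "pixels_y", "camera"),
    max_trigger_hz = cfg$max_trigger_frequency_hz %||% 2,
    max_iso = cfg$max_iso
  )
  ln <- lens(
    require_key("camera", cfg, "focal_length_mm", "camera"),
    require_key("camera", cfg, "aperture", "camera"),
    wavelength_nm = cfg$wavelength_nm %||% 550
  )
  camera_system(sens, ln, coc_mm = cfg$circle_of_confusion_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a mission configuration
#'
#' Reads a JSON mission document (or an already-parsed list), applies
#' defaults, resolves camera presets and builds the package objects. Unknown
#' keys warn; missing required keys fail with the offending key named.
#'
#' @param document Path to a JSON file, or a named list with the same
#'   structure.
#' @return An object of class `uas_mission_config` holding `camera`,
#'   `exposure`, `spec` (a [mission_spec()]), optional `gcp`, `plots`,
#'   `frame`, `export`, `report`, plus the `raw` document.
#' @export
load_mission_config <- function(document) {
  raw <- if (is.character(document)) {
    jsonlite::read_json(document, simplifyVector = TRUE)
  } else if (is.list(document)) {
    document
  } else {
    stop("mission config: expected a file path or a named list")
  }
  warn_unknown(raw, config_sections, "(top level)")
  for (sec in c("camera", "exposure", "mission")) {
    if (is.null(raw[[sec]])) {
      stop(sprintf("mission config: missing required section '%s'", sec))
    }
  }
  camera <- camera_from_config(raw$camera)
  warn_unknown(raw$exposure, exposure_keys, "exposure")
  exposure <- exposure_settings(
    require_key("exposure", raw$exposure, "shutter_s", "exposure"),
    require_key("exposure", raw$exposure, "iso", "exposure")
  )
  m <- raw$mission
  warn_unknown(m, mission_keys, "mission")
  area <- mapping_area(
    require_key("mission", m, "area_width_m", "mission"),
    require_key("mission", m, "area_depth_m", "mission")
  )
  if (is.null(m$flight_height_m) && is.null(m$gsd_m)) {
    stop("mission config: missing required key 'mission.flight_height_m' or 'mission.gsd_m'")
  }
  spec <- mission_spec(
    camera, exposure, area,
    flight_height = m$flight_height_m, gsd = m$gsd_m,
    end_lap = require_key("mission", m, "end_lap_pct", "mission"),
    side_lap = require_key("mission", m, "side_lap_pct", "mission"),
    orientation = m$orientation %||% "wide_side_along_flight",
    max_flight_duration = m$max_flight_duration_s %||% 900,
    max_motion_blur = m$max_motion_blur_pct %||% 50,
    positioning_sigma = m$positioning_sigma_m %||% 0.3,
    max_photos = m$max_photos
  )
  gcp <- NULL
  if (!is.null(raw$gcp)) {
    warn_unknown(raw$gcp, gcp_keys, "gcp")
    gcp <- raw$gcp
    if (!is.null(gcp$target_at_least_one)) {
      stopifnot(gcp$target_at_least_one > 0, gcp$target_at_least_one <= 1)
    }
  }
  plots <- NULL
  if (!is.null(raw$plots)) {
    warn_unknown(raw$plots, plot_keys, "plots")
    plots <- plot_grid(
      area,
      require_key("plots", raw$plots, "n_x", "plots"),
      require_key("plots", raw$plots, "n_y", "plots")
    )
  }
  frame <- NULL
  if (!is.null(raw$geo)) {
    warn_unknown(raw$geo, geo_keys, "geo")
    gp <- function(key) {
      p <- require_key("geo", raw$geo, key, "geo")
      geo_point(
        require_key(key, p, "lat", paste0("geo.", key)),
        require_key(key, p, "lon", paste0("geo.", key))
      )
    }
    frame <- geo_frame(gp("start"), gp("edge1"), gp("dir"))
  }
  exp_spec <- NULL
  if (!is.null(raw$export)) {
    warn_unknown(raw$export, export_keys, "export")
    exp_spec <- export_spec(
      altitude = spec$flight_height,
      max_waypoints = raw$export$max_waypoints %||% 100,
      max_leg_length = raw$export$max_leg_length_m %||% Inf
    )
  }
  report <- NULL
  if (!is.null(raw$report)) {
    warn_unknown(raw$report, report_keys, "report")
    report <- raw$report
  }
  structure(
    list(
      camera = camera, exposure = exposure, spec = spec,
      gcp = gcp, plots = plots, frame = frame, export = exp_spec,
      report = report, raw = raw
    ),
    class = "uas_mission_config"
  )
}

#' Save a mission configuration document
#'
#' Writes the raw (input) document of a loaded config, or any equivalent
#' named list, as pretty-printed JSON. Loading the result reproduces the same
#' configuration.
#'
#' @param config A `uas_mission_config` or the raw named list.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_mission_config <- function(config, path) {
  raw <- if (inherits(config, "uas_mission_config")) config$raw else config
  jsonlite::write_json(raw, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
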