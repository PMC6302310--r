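# Shared fixtures: the full-frame 6000 x 4000 px camera with a 55 mm prime
# used throughout (its 0.28% pixel-pitch mismatch between axes triggers the
# documented warning, hence the suppressWarnings), and the demonstration
# mapping mission (40 x 35 m, 3 mm GSD, 92/75% laps, 5% blur budget).

paper_sensor <- function() {
  suppressWarnings(sensor(35.6, 23.8, 6000, 4000,
    max_trigger_hz = 2, max_iso = 4000
  ))
}

paper_camera <- function(aperture = 6.7) {
  suppressWarnings(camera_system(paper_sensor(), lens(55, aperture)))
}

demo_mission_spec <- function(sigma = 0.3) {
  mission_spec(
    paper_camera(5.6), exposure_settings(1 / 16000, 2500),
    mapping_area(40, 35),
    gsd = 0.003, end_lap = 92, side_lap = 75,
    max_flight_duration = 900, max_motion_blur = 5,
    positioning_sigma = sigma
  )
}

demo_plan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- plan_mission(demo_mission_spec())
    cache
  }
})

demo_frame <- function() {
  geo_frame(
    geo_point(47.44921, 8.68238),
    geo_point(47.44944, 8.68181),
    geo_point(47.44998, 8.68192)
  )
}

exp3_config_path <- function() {
  system.file("extdata", "missions", "mission_exp3.json", package = "uasplan")
}

# minimal hand-built flight-plan stand-in for unit tests that need full
# control over stations and footprints
fake_plan <- function(stations, footprint_along, footprint_across,
                      gsd = 0.003, camera = paper_camera(5.6),
                      orientation = "wide_side_along_flight", sigma = 0.3) {
  structure(
    list(
      stations = stations, footprint_along = footprint_along,
      footprint_across = footprint_across, gsd = gsd, camera = camera,
      orientation = orientation, n_lines = length(unique(stations$x)),
      spec = list(positioning_sigma = sigma)
    ),
    class = "uas_flight_plan"
  )
}
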