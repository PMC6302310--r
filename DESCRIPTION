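Package: uasplan
Title: Photographic Flight Planning for UAS Mapping Missions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Plans photogrammetric mapping missions for unmanned aerial
    systems (UAS) carrying digital frame cameras. Computes per-photo
    optics and exposure (ground sampling distance, angle and ground field
    of view, hyperfocal distance, depth of field, diffraction limit,
    exposure value and ISO), turns end/side-lap requirements into an
    exposure-station grid with flight-speed and motion-blur budgets,
    generates and evaluates ground-control-point layouts via their
    recover frequency in photos, predicts per-pixel plot-center recover
    frequencies and the zenith-angle distribution under positioning
    noise, and exports geo-referenced waypoint flights as waypoint CSV
    and KML files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
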