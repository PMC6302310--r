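# Geographic anchoring of the local flight plan and mission exports.
#
# Geodesy is a spherical tangent-plane approximation (mean Earth radius
# 6371008.8 m, i.e. 111194.93 m per degree of latitude): at the sub-kilometre
# extents of field missions the error is below a centimetre, far under the
# positioning precision of any UAS.

METERS_PER_DEG <- 111194.93 # metres per degree of arc, mean-radius sphere

#' A WGS84 point in decimal degrees
#'
#' @param lat,lon Latitude / longitude in decimal degrees.
#' @return An object of class `uas_geo_point`.
#' @export
geo_point <- function(lat, lon) {
  stopifnot(abs(lat) <= 90, abs(lon) <= 180)
  structure(list(lat = lat, lon = lon), class = "uas_geo_point")
}

#' Initial bearing between two geographic points
#'
#' Tangent-plane bearing from north in `[0, 360)` degrees, computed from the
#' local east/north displacement at the first point's latitude.
#'
#' @param p1,p2 [geo_point()] objects; must not coincide.
#' @return Bearing in degrees from north.
#' @export
heading_between <- function(p1, p2) {
  stopifnot(inherits(p1, "uas_geo_point"), inherits(p2, "uas_geo_point"))
  north <- p2$lat - p1$lat
  east <- (p2$lon - p1$lon) * cos(p1$lat * pi / 180)
  if (north == 0 && east == 0) stop("coincident points have no bearing")
  (atan2(east, north) * 180 / pi) %% 360
}

#' Geographic frame anchoring the local plan
#'
#' Three anchor points orient the mission: `start` is the take-off point and
#' defines the reference altitude; `edge1` is one corner of the mapping area
#' and becomes the local origin; `dir` sets the primary flight direction
#' baseline (edge1 -> dir) which all flight lines align with.
#'
#' @param start,edge1,dir [geo_point()] objects; `edge1` and `dir` must
#'   differ, and latitudes above 85 degrees are unsupported (tangent-plane
#'   longitude scaling degenerates).
#' @return An object of class `uas_geo_frame` with the derived `heading`.
#' @export
geo_frame <- function(start, edge1, dir) {
  stopifnot(
    inherits(start, "uas_geo_point"), inherits(edge1, "uas_geo_point"),
    inherits(dir, "uas_geo_point")
  )
  if (max(abs(c(start$lat, edge1$lat, dir$lat))) > 85) {
    stop("latitudes above 85 degrees are unsupported")
  }
  heading <- heading_between(edge1, dir)
  structure(
    list(start = start, edge1 = edge1, dir = dir, heading = heading),
    class = "uas_geo_frame"
  )
}

#' Convert local plan coordinates to geographic coordinates
#'
#' The local frame has its origin at `edge1`, +y along the frame heading and
#' +x 90 degrees clockwise of it (to the right of the flight direction).
#' Vectorised over `x`, `y`.
#'
#' @param frame A [geo_frame()].
#' @param x,y Local coordinates in metres.
#' @return A data frame with columns `lat`, `lon`.
#' @export
local_to_geo <- function(frame, x, y) {
  stopifnot(inherits(frame, "uas_geo_frame"))
  th <- frame$heading * pi / 180
  east <- x * cos(th) + y * sin(th)
  north <- -x * sin(th) + y * cos(th)
  lat0 <- frame$edge1$lat
  data.frame(
    lat = lat0 + north / METERS_PER_DEG,
    lon = frame$edge1$lon + east / (METERS_PER_DEG * cos(lat0 * pi / 180))
  )
}

#' Convert geographic coordinates back to the local frame
#'
#' Exact inverse of [local_to_geo()] under the same tangent-plane model.
#'
#' @param frame A [geo_frame()].
#' @param lat,lon Coordinates in decimal degrees (vectorised).
#' @return A data frame with columns `x`, `y` in metres.
#' @export
geo_to_local <- function(frame, lat, lon) {
  stopifnot(inherits(frame, "uas_geo_frame"))
  th <- frame$heading * pi / 180
  lat0 <- frame$edge1$lat
  north <- (lat - lat0) * METERS_PER_DEG
  east <- (lon - frame$edge1$lon) * METERS_PER_DEG * cos(lat0 * pi / 180)
  data.frame(
    x = east * cos(th) - north * sin(th),
    y = east * sin(th) + north * cos(th)
  )
}

#' Waypoint-export settings
#'
#' @param altitude Flight altitude in metres relative to the take-off point.
#' @param max_waypoints Waypoint-count cap of the consuming autopilot
#'   (default 100, a common vendor limit).
#' @param max_leg_length Target spacing for intermediate waypoints inserted
#'   along flight lines (terrain-following hook); `Inf` disables
#'   densification.
#' @return An object of class `uas_export_spec`.
#' @export
export_spec <- function(altitude, max_waypoints = 100, max_leg_length = Inf) {
  stopifnot(altitude > 0, max_waypoints >= 2, max_leg_length > 0)
  structure(
    list(
      altitude = altitude, max_waypoints = max_waypoints,
      max_leg_length = max_leg_length
    ),
    class = "uas_export_spec"
  )
}

#' Build the geo-referenced waypoint list of a flight plan
#'
#' Keeps the serpentine line endpoints (never dropped) and inserts
#' intermediate waypoints along each line at a spacing of at most
#' `max_leg_length` so a consuming app can adapt individual waypoint heights
#' to terrain. When the total would exceed `max_waypoints`, intermediates are
#' thinned uniformly (the largest admissible per-line spacing) until the cap
#' holds. Altitude is constant, heading follows the line direction, and the
#' gimbal pitch is -90 degrees (nadir).
#'
#' @param plan A [plan_mission()] result.
#' @param frame A [geo_frame()].
#' @param export An [export_spec()].
#' @return A data frame of class `uas_waypoints` with columns `lat`, `lon`,
#'   `altitude`, `heading`, `gimbal_pitch`.
#' @export
build_waypoints <- function(plan, frame, export) {
  stopifnot(
    inherits(plan, "uas_flight_plan"), inherits(frame, "uas_geo_frame"),
    inherits(export, "uas_export_spec")
  )
  n_lines <- plan$n_lines
  if (export$max_waypoints < 2 * n_lines) {
    stop(sprintf(
      "max_waypoints (%d) is below the %d line endpoints; endpoints cannot be dropped",
      export$max_waypoints, 2 * n_lines
    ))
  }
  st <- plan$stations
  y0 <- min(st$y)
  y1 <- max(st$y)
  line_len <- y1 - y0
  n_int <- if (is.finite(export$max_leg_length) && line_len > 0) {
    max(ceiling(line_len / export$max_leg_length - 1e-9) - 1, 0)
  } else {
    0
  }
  # uniform thinning under the waypoint cap: largest admissible spacing
  n_int <- min(n_int, floor((export$max_waypoints - 2 * n_lines) / n_lines))
  xs <- sort(unique(st$x))
  rows <- lapply(seq_len(n_lines), function(i) {
    ys <- seq(y0, y1, length.out = n_int + 2)
    up <- i %% 2 == 1 # first line flown in +y
    data.frame(
      x = xs[i],
      y = if (up) ys else rev(ys),
      heading = if (up) frame$heading else (frame$heading + 180) %% 360
    )
  })
  local <- do.call(rbind, rows)
  geo <- local_to_geo(frame, local$x, local$y)
  out <- data.frame(
    lat = geo$lat, lon = geo$lon,
    altitude = export$altitude,
    heading = local$heading,
    gimbal_pitch = -90
  )
  class(out) <- c("uas_waypoints", "data.frame")
  out
}

WAYPOINT_CSV_HEADER <- "latitude,longitude,altitude(m),heading(deg),curvesize(m),rotationdir,gimbalmode,gimbalpitchangle"

#' Export waypoints as a waypoint CSV file
#'
#' Writes the widely used waypoint-app CSV dialect with the exact header
#' `latitude,longitude,altitude(m),heading(deg),curvesize(m),rotationdir,gimbalmode,gimbalpitchangle`.
#' Coordinates are written with 7 decimal places (about 1.1 cm of latitude);
#' curve size and rotation direction are 0, gimbal mode 2 with a -90 degree
#' (nadir) pitch.
#'
#' @param waypoints A [build_waypoints()] result.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
export_waypoints_csv <- function(waypoints, path) {
  stopifnot(inherits(waypoints, "uas_waypoints"), nrow(waypoints) >= 1)
  lines <- c(
    WAYPOINT_CSV_HEADER,
    sprintf(
      "%.7f,%.7f,%g,%g,0,0,2,%g",
      waypoints$lat, waypoints$lon, waypoints$altitude, waypoints$heading,
      waypoints$gimbal_pitch
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a waypoint CSV file back
#'
#' @param path A file written by [export_waypoints_csv()].
#' @return A `uas_waypoints` data frame.
#' @export
read_waypoints_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  expected <- strsplit(WAYPOINT_CSV_HEADER, ",")[[1]]
  if (!identical(names(raw), expected)) {
    stop("not a recognised waypoint CSV file: unexpected header")
  }
  out <- data.frame(
    lat = raw$latitude, lon = raw$longitude,
    altitude = raw$`altitude(m)`, heading = raw$`heading(deg)`,
    gimbal_pitch = raw$gimbalpitchangle
  )
  class(out) <- c("uas_waypoints", "data.frame")
  out
}

#' Geographic corners of the mapping area
#'
#' @param frame A [geo_frame()].
#' @param area A [mapping_area()].
#' @return A data frame of the four corners (`lat`, `lon`) in ring order.
#' @export
area_corners_geo <- function(frame, area) {
  stopifnot(inherits(area, "uas_area"))
  local_to_geo(
    frame,
    c(0, area$width, area$width, 0),
    c(0, 0, area$depth, area$depth)
  )
}

#' Export the mapping area and flight path as KML
#'
#' Writes an OGC KML document with one closed Polygon for the mapping area
#' (five lon,lat,alt tuples, first equals last) and one LineString for the
#' flight path, suitable for import into shape-based mission tools.
#'
#' @param corners Data frame of the four area corners (`lat`, `lon`), e.g.
#'   from [area_corners_geo()].
#' @param waypoints A [build_waypoints()] result (the flight path).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
export_area_kml <- function(corners, waypoints, path) {
  stopifnot(is.data.frame(corners), nrow(corners) == 4)
  coord_str <- function(lon, lat, alt) {
    paste(sprintf("%.7f,%.7f,%g", lon, lat, alt), collapse = " ")
  }
  ring <- coord_str(
    c(corners$lon, corners$lon[1]), c(corners$lat, corners$lat[1]), 0
  )
  track <- coord_str(waypoints$lon, waypoints$lat, waypoints$altitude)
  doc <- xml2::xml_new_root("kml", xmlns = "http://www.opengis.net/kml/2.2")
  d <- xml2::xml_add_child(doc, "Document")
  xml2::xml_add_child(d, "name", "UAS mapping mission")
  pm1 <- xml2::xml_add_child(d, "Placemark")
  xml2::xml_add_child(pm1, "name", "mapping area")
  poly <- xml2::xml_add_child(pm1, "Polygon")
  ob <- xml2::xml_add_child(poly, "outerBoundaryIs")
  lr <- xml2::xml_add_child(ob, "LinearRing")
  xml2::xml_add_child(lr, "coordinates", ring)
  pm2 <- xml2::xml_add_child(d, "Placemark")
  xml2::xml_add_child(pm2, "name", "flight path")
  ls <- xml2::xml_add_child(pm2, "LineString")
  xml2::xml_add_child(ls, "altitudeMode", "relativeToGround")
  xml2::xml_add_child(ls, "coordinates", track)
  xml2::write_xml(doc, path)
  invisible(path)
}
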