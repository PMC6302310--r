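# Viewing-geometry prediction: per-pixel plot-center recover frequencies
# under UAS positioning noise and the resulting zenith-angle distribution.
#
# Positioning model: flight lines are positioned with a normal error
# (sd = sigma) across the flight direction; exposure stations along a line
# carry a uniform error on (-sigma/2, sigma/2), reflecting an initial
# positioning error at the line start propagated from exposure to exposure.

#' Grid of plot centres on the mapping area
#'
#' Places `n_x` x `n_y` plot centres at the cell centres of the area, the
#' same convention as the squared GCP arrangement.
#'
#' @param area A [mapping_area()].
#' @param n_x,n_y Number of plot columns / rows.
#' @return A data frame with columns `x`, `y` (local metres).
#' @export
plot_grid <- function(area, n_x, n_y) {
  stopifnot(inherits(area, "uas_area"), n_x >= 1, n_y >= 1)
  centers <- expand.grid(
    x = area$width * (seq_len(n_x) - 0.5) / n_x,
    y = area$depth * (seq_len(n_y) - 0.5) / n_y
  )
  centers[, c("x", "y")]
}

# symmetric bin-centre grid of pixel offsets: -half..half in steps of bin_px
offset_bins <- function(half_px, bin_px) {
  n <- floor(half_px / bin_px)
  seq(-n, n) * bin_px
}

# per-axis recover frequency of plot centres over pixel-offset bins.
# station_vals/plot_vals are the matching local coordinates (metres); cdf is
# the cumulative positioning distribution. The mass of the bin centred at
# offset o is the exact probability that the positioning error falls inside
# the bin's ground extent, P(residual in (o +- bin/2) * GSD), i.e. the bin
# integral of the density; for densities that are smooth at the bin scale
# this equals density x bin width, and it stays exact for the uniform
# distribution whose support may span only a few bins. sigma = 0 collapses to
# a delta placement into the bin containing the offset.
axis_bin_freq <- function(station_vals, plot_vals, half_px, bin_px, gsd,
                          cdf, sigma) {
  centers <- offset_bins(half_px, bin_px)
  n_pairs <- length(station_vals) * length(plot_vals)
  # collapse to unique coordinate values with multiplicities: the grids are
  # highly degenerate (all lines share station y positions and vice versa)
  us <- unique(station_vals)
  ws <- tabulate(match(station_vals, us))
  up <- unique(plot_vals)
  wp <- tabulate(match(plot_vals, up))
  d <- as.vector(outer(up, us, "-")) # plot - station, metres
  w <- as.vector(outer(wp, ws))
  if (sigma == 0) {
    off_px <- d / gsd
    idx <- round((off_px - centers[1]) / bin_px) + 1L
    keep <- idx >= 1L & idx <= length(centers) &
      abs(off_px - centers[pmin(pmax(idx, 1L), length(centers))]) <= bin_px / 2
    freq <- numeric(length(centers))
    for (i in which(keep)) {
      freq[idx[i]] <- freq[idx[i]] + w[i]
    }
    freq <- freq / n_pairs
  } else {
    # residual r = d - a * GSD decreases in a, so the bin [o - bin/2,
    # o + bin/2] in pixel space maps to [d - (o + bin/2) GSD, d - (o - bin/2)
    # GSD] in residual space
    freq <- vapply(centers, function(o) {
      sum(w * (cdf(d - (o - bin_px / 2) * gsd) - cdf(d - (o + bin_px / 2) * gsd)))
    }, numeric(1)) / n_pairs
  }
  data.frame(offset_px = centers, freq = freq)
}

#' Per-pixel recover frequency of plot centres
#'
#' For every pixel-offset bin on each sensor axis, the frequency with which a
#' plot centre is imaged at that offset, averaged over all exposure stations
#' and plots under the positioning-noise model. The across-flight axis uses a
#' normal density, the along-flight axis a uniform density, mapped onto the
#' sensor axes according to the mission orientation. Each bin's mass is the
#' integral of the positioning density over the bin's ground extent
#' (`bin_px * GSD` wide) — the exact counterpart of density times bin width,
#' robust when the uniform support spans only a few bins; the joint
#' distribution is the outer product of the two axis distributions, so its
#' total mass is at most one (mass may fall outside the sensor).
#'
#' @param plan A [plan_mission()] result.
#' @param plots Data frame of plot centres with columns `x`, `y` (see
#'   [plot_grid()]).
#' @param sigma Positioning precision (standard deviation) in metres;
#'   defaults to the mission spec's value. `sigma = 0` gives deterministic
#'   delta placement.
#' @param bin_px Pixel binning factor per axis (default 40, i.e. 151 x 101
#'   bins for a 6000 x 4000 px sensor).
#' @return An object of class `uas_viewing_geometry` with `axis_a`/`axis_b`
#'   data frames (pixel offset bin centre, frequency), the `joint` matrix
#'   (a-bins x b-bins), `total_mass`, `bin_px`, `gsd`.
#' @export
plot_center_pixel_frequency <- function(plan, plots,
                                        sigma = plan$spec$positioning_sigma,
                                        bin_px = 40) {
  stopifnot(
    inherits(plan, "uas_flight_plan"), is.data.frame(plots),
    nrow(plots) >= 1, bin_px >= 1
  )
  if (sigma < 0) stop("positioning sigma must be non-negative")
  s <- plan$camera$sensor
  gsd <- plan$gsd
  cdf_across <- function(d) stats::pnorm(d, mean = 0, sd = sigma)
  cdf_along <- function(d) stats::punif(d, min = -sigma / 2, max = sigma / 2)
  # sensor a-axis (pixels_x) points along the flight direction (local y) when
  # the wide side is flown forward, across (local x) otherwise
  if (plan$orientation == "wide_side_along_flight") {
    axis_a <- axis_bin_freq(
      plan$stations$y, plots$y, s$pixels_x / 2, bin_px, gsd, cdf_along, sigma
    )
    axis_b <- axis_bin_freq(
      plan$stations$x, plots$x, s$pixels_y / 2, bin_px, gsd, cdf_across, sigma
    )
  } else {
    axis_a <- axis_bin_freq(
      plan$stations$x, plots$x, s$pixels_x / 2, bin_px, gsd, cdf_across, sigma
    )
    axis_b <- axis_bin_freq(
      plan$stations$y, plots$y, s$pixels_y / 2, bin_px, gsd, cdf_along, sigma
    )
  }
  joint <- outer(axis_a$freq, axis_b$freq)
  structure(
    list(
      axis_a = axis_a, axis_b = axis_b, joint = joint,
      total_mass = sum(joint), bin_px = bin_px, gsd = gsd, sigma = sigma
    ),
    class = "uas_viewing_geometry"
  )
}

#' Zenith angle of a pixel offset
#'
#' Angular deviation from nadir of the view ray through a pixel at centred
#' offset `(a, b)` from the sensor middle:
#' `theta = atan(S_delta * sqrt(a^2 + b^2) / f)`, so the sensor centre looks
#' straight down and the sensor edge sees half the angle of view.
#'
#' @param camera A [camera_system()].
#' @param a,b Pixel offsets from the sensor centre (vectorised, recycled).
#' @return Zenith angle(s) in degrees.
#' @export
pixel_zenith_angle <- function(camera, a, b) {
  stopifnot(inherits(camera, "uas_camera"))
  atan(camera$pixel_pitch * sqrt(a^2 + b^2) / camera$lens$focal_length) * 180 / pi
}

#' Zenith-angle frequency distribution
#'
#' Sums the joint per-pixel plot-centre frequencies into zenith-angle bins
#' `[theta_i, theta_i + bin_deg)`. Total histogram mass equals the joint
#' total mass; no mass can lie beyond the half-diagonal angle of view.
#'
#' @param result A [plot_center_pixel_frequency()] result.
#' @param camera The [camera_system()] the plan was made for.
#' @param bin_deg Bin width in degrees (default 1).
#' @return A data frame with `theta_lower`, `theta_upper` (degrees) and
#'   `freq`.
#' @export
zenith_angle_histogram <- function(result, camera, bin_deg = 1) {
  stopifnot(inherits(result, "uas_viewing_geometry"), bin_deg > 0)
  theta <- outer(
    result$axis_a$offset_px, result$axis_b$offset_px,
    function(a, b) pixel_zenith_angle(camera, a, b)
  )
  idx <- floor(theta / bin_deg)
  n_bins <- max(idx) + 1L
  freq <- vapply(
    seq_len(n_bins) - 1L,
    function(i) sum(result$joint[idx == i]),
    numeric(1)
  )
  data.frame(
    theta_lower = (seq_len(n_bins) - 1L) * bin_deg,
    theta_upper = seq_len(n_bins) * bin_deg,
    freq = freq
  )
}

#' Write viewing-geometry distributions as CSV tables
#'
#' Emits `<stem>_axis_x.csv`, `<stem>_axis_y.csv` (pixel-offset bin centre,
#' frequency) and `<stem>_zenith.csv` (bin bounds in degrees, frequency).
#'
#' @param result A [plot_center_pixel_frequency()] result.
#' @param camera The matching [camera_system()].
#' @param stem Output path stem.
#' @return The three file paths, invisibly.
#' @export
export_viewing_geometry_csv <- function(result, camera, stem) {
  paths <- paste0(stem, c("_axis_x.csv", "_axis_y.csv", "_zenith.csv"))
  utils::write.csv(result$axis_a, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(result$axis_b, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(
    zenith_angle_histogram(result, camera),
    paths[3],
    row.names = FALSE, quote = FALSE
  )
  invisible(paths)
}
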