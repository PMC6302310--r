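# Ground-control-point (GCP) layouts and their recover frequency in photos.

#' Generate a GCP layout on the mapping area
#'
#' Two arrangements are supported. `squared` places an `n_x` x `n_y` grid at
#' the cell centres `x = A_x (i + 0.5) / n_x`, `y = A_y (j + 0.5) / n_y`.
#' `crosswise` (quincunx) keeps the same rows but offsets every odd row by
#' half the column spacing, with `n_x - 1` points, increasing recover
#' frequency while reducing the number of markers.
#'
#' @param area A [mapping_area()].
#' @param pattern `"squared"` or `"crosswise"`.
#' @param n_x,n_y Number of GCP columns / rows (>= 1).
#' @return An object of class `uas_gcp_layout` with a `positions` data frame
#'   (local x, y metres).
#' @export
gcp_layout <- function(area, pattern = c("squared", "crosswise"), n_x, n_y) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(area, "uas_area"), n_x >= 1, n_y >= 1)
  if (pattern == "crosswise" && n_x < 2) {
    stop("a crosswise arrangement needs at least 2 GCP columns (no offset row possible)")
  }
  ys <- area$depth * (seq_len(n_y) - 0.5) / n_y
  rows <- lapply(seq_len(n_y), function(j) {
    if (pattern == "squared" || j %% 2 == 1) { # even rows (0-based) keep full grid
      data.frame(x = area$width * (seq_len(n_x) - 0.5) / n_x, y = ys[j])
    } else {
      data.frame(x = area$width * seq_len(n_x - 1) / n_x, y = ys[j])
    }
  })
  positions <- do.call(rbind, rows)
  rownames(positions) <- NULL
  structure(
    list(
      pattern = pattern, n_x = n_x, n_y = n_y,
      n_gcps = nrow(positions), positions = positions, area = area
    ),
    class = "uas_gcp_layout"
  )
}

#' @export
print.uas_gcp_layout <- function(x, ...) {
  cat(sprintf(
    "GCP layout: %s %d x %d (%d markers) on %g x %g m\n",
    x$pattern, x$n_x, x$n_y, x$n_gcps, x$area$width, x$area$depth
  ))
  invisible(x)
}

#' Recover frequency of GCPs in photos
#'
#' For each exposure station, counts the GCPs inside the ground footprint
#' (axis-aligned rectangle, boundaries inclusive so a marker on a footprint
#' seam counts in both adjacent photos): `|dx| <= G_S / 2` across and
#' `|dy| <= G_E / 2` along the flight direction. The histogram over counts is
#' normalised by the number of photos, so it sums to one exactly.
#'
#' @param stations Data frame of exposure stations with columns `x`, `y`
#'   (e.g. the `stations` element of a [plan_mission()] result).
#' @param footprint_along,footprint_across Ground footprint extents in
#'   metres.
#' @param layout A [gcp_layout()].
#' @return An object of class `uas_gcp_recovery`: `frequencies` (named vector
#'   over k = 0, 1, ...), `at_least_one`, `counts` (per-station GCP counts).
#' @export
gcp_recover_frequency <- function(stations, footprint_along, footprint_across,
                                  layout) {
  stopifnot(
    is.data.frame(stations), nrow(stations) >= 1,
    footprint_along > 0, footprint_across > 0,
    inherits(layout, "uas_gcp_layout")
  )
  gp <- layout$positions
  tol <- 1e-9
  in_x <- abs(outer(stations$x, gp$x, "-")) <= footprint_across / 2 + tol
  in_y <- abs(outer(stations$y, gp$y, "-")) <= footprint_along / 2 + tol
  counts <- rowSums(in_x & in_y)
  k_max <- max(counts)
  freq <- tabulate(counts + 1L, nbins = k_max + 1L) / nrow(stations)
  names(freq) <- 0:k_max
  structure(
    list(
      frequencies = freq,
      at_least_one = 1 - freq[["0"]],
      counts = counts,
      n_photos = nrow(stations),
      layout = layout
    ),
    class = "uas_gcp_recovery"
  )
}

#' @export
print.uas_gcp_recovery <- function(x, ...) {
  cat("GCP recover frequency over", x$n_photos, "photos\n")
  for (k in names(x$frequencies)) {
    cat(sprintf("  %s per image: %5.1f%%\n", k, 100 * x$frequencies[[k]]))
  }
  cat(sprintf("  >= 1 per image: %.1f%%\n", 100 * x$at_least_one))
  invisible(x)
}

#' Automatic GCP placement for a target recover frequency
#'
#' Deterministic exhaustive search over both arrangements and
#' `n_x, n_y = 1..max_per_axis`. A layout is feasible when the fraction of
#' photos with at least one visible GCP reaches the target. Among feasible
#' layouts the search minimises the number of markers, breaking ties by
#' larger achieved fraction, then squared before crosswise, then smaller
#' `n_x` (favouring even spacing while penalising marker count).
#'
#' @param plan A [plan_mission()] result.
#' @param area A [mapping_area()] (usually `plan$spec$area`).
#' @param target Required fraction of photos with >= 1 visible GCP,
#'   `0 < target <= 1`.
#' @param max_per_axis Search bound per axis (default 12).
#' @return The winning [gcp_layout()] with the achieved `recovery` attached.
#' @export
auto_place_gcps <- function(plan, area, target, max_per_axis = 12) {
  stopifnot(inherits(plan, "uas_flight_plan"), target > 0, target <= 1)
  best <- NULL
  best_key <- NULL
  best_achieved <- -1
  for (pattern in c("squared", "crosswise")) {
    pattern_rank <- if (pattern == "squared") 0 else 1
    for (n_x in seq_len(max_per_axis)) {
      if (pattern == "crosswise" && n_x < 2) next
      for (n_y in seq_len(max_per_axis)) {
        layout <- gcp_layout(area, pattern, n_x, n_y)
        rec <- gcp_recover_frequency(
          plan$stations, plan$footprint_along, plan$footprint_across, layout
        )
        best_achieved <- max(best_achieved, rec$at_least_one)
        if (rec$at_least_one + 1e-12 < target) next
        key <- c(layout$n_gcps, -rec$at_least_one, pattern_rank, n_x)
        if (is.null(best_key) || lex_less(key, best_key)) {
          best <- layout
          best$recovery <- rec
          best_key <- key
        }
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "no feasible GCP layout within %d x %d per pattern: best achieved fraction %.2f < target %.2f",
      max_per_axis, max_per_axis, best_achieved, target
    ))
  }
  best
}

# strict lexicographic comparison of equal-length numeric keys
lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Export a GCP layout for field stake-out
#'
#' Writes the marker positions as a comma-separated table of local `x`, `y`
#' metres, adding `lat`, `lon` columns when a [geo_frame()] is supplied.
#'
#' @param layout A [gcp_layout()].
#' @param path Destination file.
#' @param frame Optional [geo_frame()] anchoring the local plan.
#' @return `path`, invisibly.
#' @export
export_gcp_csv <- function(layout, path, frame = NULL) {
  stopifnot(inherits(layout, "uas_gcp_layout"))
  out <- layout$positions
  if (!is.null(frame)) {
    geo <- local_to_geo(frame, out$x, out$y)
    out$lat <- geo$lat
    out$lon <- geo$lon
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
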