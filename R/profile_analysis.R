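#' Extract the green channel of an 8-bit RGB image
#'
#' The laser is green (543.5 nm), so all intensity quantification uses the
#' green plane of the 8-bit RGB image, values 0-255, returned unchanged.
#'
#' @param image An `angular_image`, or a bare H x W x 3 array of 8-bit
#'   values.
#' @return H x W integer matrix of green values (0-255).
#' @export
extract_green_channel <- function(image) {
  px <- if (inherits(image, "angular_image")) image$pixels else image
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("expected a 3-channel RGB image")
  g <- px[, , 2]
  if (any(g < 0 | g > 255) || any(g != round(g)))
    stop("green channel values must be 8-bit integers in [0, 255]")
  matrix(as.integer(g), nrow = dim(px)[1])
}

# Condition raised when the projected between-base gap is too narrow to
# tell tip bands from gap bands (the oblique-view failure mode).
unresolvable_projection_error <- function(angle_deg, gap_px) {
  stop(errorCondition(
    sprintf(paste0("unresolvable projection at %g deg: projected ",
                   "between-base gap is %.2f px (< %g px)"),
            angle_deg, gap_px, .MIN_RESOLVABLE_GAP_PX),
    class = c("unresolvable_projection", "error", "condition")))
}

# Row-band bookkeeping shared by both sampling modes. Vertical positions
# are unaffected by the (horizontal) camera rotation.
.row_bands <- function(geom, um_per_px, height_px) {
  y_um <- (seq_len(height_px) - 0.5) * um_per_px
  in_array <- y_um < geom$n_rows * geom$pitch_um
  tip <- in_array & .in_tip_band(y_um, geom)
  cell <- floor(y_um / geom$pitch_um)
  list(tip_rows = which(tip), gap_rows = which(in_array & !tip),
       cell = cell)
}

#' Sample horizontal intensity lines from an array image
#'
#' Emulates the manual line-drawing step of the analysis: `n_lines`
#' horizontal lines are sampled from the image, either at seeded-random
#' rows between the tip bands (`mode = "line"`, the transmitted-light
#' regions) or through the centres of `n_lines` randomly chosen tip bands
#' (`mode = "MN"`, "precisely at the tips"). The profile is the per-column
#' mean of the green channel over the sampled rows, against lateral
#' position in micrometres.
#'
#' Positions are de-projected: the camera compresses the horizontal axis by
#' cos(angle), so `position_um = (col - 0.5) * um_per_px / cos(angle)`,
#' putting all angles on the common array coordinate with 0 at the left
#' edge. At angles where the projected between-base gap falls below
#' 2 px the bands cannot be told apart and an `unresolvable_projection`
#' error is raised (with the default geometry and calibration this excludes
#' the 77-degree view).
#'
#' @param image An `angular_image`.
#' @param geom An [array_geometry()]; defaults to the standard 19 x 19
#'   layout.
#' @param mode `"line"` (between tips) or `"MN"` (at tips).
#' @param n_lines Number of sampled lines (default 5).
#' @param seed RNG seed for row selection.
#' @return An object of class `intensity_profile`: list with
#'   `positions_um`, `intensities` (mean green counts, floating point —
#'   never re-quantized), `label`, `angle_deg`, `line_ids` (sampled row
#'   indices).
#' @export
sample_profiles <- function(image, geom = array_geometry(),
                            mode = c("line", "MN"), n_lines = 5L,
                            seed = 1L) {
  stopifnot(inherits(image, "angular_image"))
  mode <- match.arg(mode)
  geom <- validate_geometry(geom)
  gap_px <- geom$gap_um * cos(image$angle_deg * pi / 180) / image$um_per_px
  if (gap_px < .MIN_RESOLVABLE_GAP_PX || !isTRUE(image$resolvable))
    unresolvable_projection_error(image$angle_deg, gap_px)
  g <- extract_green_channel(image)
  bands <- .row_bands(geom, image$um_per_px, nrow(g))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (mode == "line") {
    pool <- bands$gap_rows
    if (length(pool) < n_lines)
      stop("fewer than ", n_lines, " gap rows available")
    rows <- sort(sample(pool, n_lines))
  } else {
    tip_cells <- sort(unique(bands$cell[bands$tip_rows]))
    if (length(tip_cells) < n_lines)
      stop("fewer than ", n_lines, " tip bands available")
    cells <- sort(sample(tip_cells, n_lines))
    # centre row of each selected tip band
    rows <- vapply(cells, function(k) {
      y_mid <- k * geom$pitch_um + geom$gap_um / 2 + geom$base_um / 2
      r <- round(y_mid / image$um_per_px + 0.5)
      max(1L, min(nrow(g), as.integer(r)))
    }, integer(1))
  }
  intensities <- colMeans(g[rows, , drop = FALSE])
  positions <- ((seq_len(ncol(g)) - 0.5) * image$um_per_px) /
    cos(image$angle_deg * pi / 180)
  structure(list(positions_um = positions, intensities = intensities,
                 label = mode, angle_deg = image$angle_deg,
                 line_ids = rows),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf(
    "intensity_profile ('%s', %g deg): %d positions, %d lines, mean %.1f\n",
    x$label, x$angle_deg, length(x$positions_um), length(x$line_ids),
    mean(x$intensities)))
  invisible(x)
}

#' Mean intensity over the central laser-exposure window
#'
#' Summarizes a profile by the arithmetic mean of its intensities at
#' lateral positions inside the half-open window \[lo, hi) — by default
#' 2000-4000 um, the central region of the illuminated beam.
#'
#' @param profile An `intensity_profile`.
#' @param window_um Length-2 numeric, lower < upper (um).
#' @return A one-row data frame: `angle_deg`, `label`, `mean_intensity`,
#'   `n_positions`, `window_lo_um`, `window_hi_um`, `n_lines`.
#' @export
central_window_mean <- function(profile, window_um = c(2000, 4000)) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (length(window_um) != 2L || window_um[1] >= window_um[2])
    stop("window_um must be c(lo, hi) with lo < hi")
  sel <- profile$positions_um >= window_um[1] &
    profile$positions_um < window_um[2]
  if (!any(sel)) stop("window does not overlap the profile support")
  data.frame(angle_deg = profile$angle_deg,
             label = profile$label,
             mean_intensity = mean(profile$intensities[sel]),
             n_positions = sum(sel),
             window_lo_um = window_um[1], window_hi_um = window_um[2],
             n_lines = length(profile$line_ids))
}

#' Isotropy index of per-angle mean intensities
#'
#' Quantifies how angle-invariant the light from one region type is: the
#' coefficient of variation (population standard deviation over mean) of
#' the central-window means across angles for the given label. Zero means
#' perfectly isotropic; the between-tip transmitted light is expected to
#' score much higher than the tip-scattered light. This metric is this
#' package's own summary of angular dependence, not a literature quantity.
#'
#' @param summaries Data frame of central-window means (rows as returned by
#'   [central_window_mean()], at least two angles for the label).
#' @param label `"line"` or `"MN"`.
#' @return The coefficient of variation (dimensionless scalar).
#' @examples
#' s <- data.frame(angle_deg = c(0, 57), label = "line",
#'                 mean_intensity = c(100, 0))
#' isotropy_index(s, "line")  # 1: population sd 50 over mean 50
#' @export
isotropy_index <- function(summaries, label) {
  m <- summaries$mean_intensity[summaries$label == label]
  if (length(m) < 2) stop("need summaries for at least two angles")
  mu <- mean(m)
  if (mu == 0) stop("zero mean intensity: isotropy index undefined")
  sqrt(mean((m - mu)^2)) / mu
}
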