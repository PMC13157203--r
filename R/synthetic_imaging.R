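#' Parametric angular intensity laws
#'
#' The renderer drives the between-tip ("gap") and at-tip brightness with
#' angular laws. `cosine_law` is a peaked law `peak * cos(theta)^exponent`,
#' monotone decreasing over \[0, 90) degrees — the behaviour of directly
#' transmitted laser light, brightest when the camera is aligned with the
#' beam. `constant_law` is angle-invariant — an isotropic scatterer. These
#' defaults are synthetic stylizations chosen to exercise the analysis, not
#' fits to any measurement.
#'
#' @param peak Intensity at 0 degrees (8-bit counts).
#' @param exponent Cosine power (>= 0); larger means faster falloff.
#' @param level Constant intensity (8-bit counts).
#' @return A function of `angle_deg` returning intensity counts, carrying
#'   its parameters in the `"params"` attribute for manifest echoes.
#' @export
cosine_law <- function(peak = 200, exponent = 4) {
  stopifnot(peak >= 0, exponent >= 0)
  f <- function(angle_deg) peak * cos(angle_deg * pi / 180)^exponent
  attr(f, "params") <- list(type = "cosine", peak = peak, exponent = exponent)
  f
}

#' @rdname cosine_law
#' @export
constant_law <- function(level = 150) {
  stopifnot(level >= 0)
  f <- function(angle_deg) rep_len(level, length(angle_deg))
  attr(f, "params") <- list(type = "constant", level = level)
  f
}

#' Rendering specification for synthetic array photographs
#'
#' Bundles everything needed to render seeded 8-bit RGB images emulating
#' lateral photographs of a laser-illuminated MN array at a set of camera
#' angles. The scene is a simplified 2-D band-pattern projection of the
#' array: horizontal tip-row bands alternate with gap-row bands at the
#' array pitch, and the camera angle compresses the horizontal axis by
#' cos(angle). Within the illuminated beam window, gap rows carry the
#' angle-dependent transmitted intensity `gap_law(angle)` (with shallow
#' angle-independent shadows of fraction `tip_shadow_frac` at tip-column
#' positions, which encode the pitch in the image), and tip rows carry the
#' scattered intensity `tip_law(angle)` uniformly. Gaussian noise is added
#' before clipping and 8-bit quantization; red and blue channels are fixed
#' fractions of green (the laser is green, 543.5 nm).
#'
#' @param geometry An [array_geometry()].
#' @param angles_deg Camera angles in degrees, each in \[0, 90). Default
#'   `c(0, 24, 31, 57, 77)`: the aligned initial position plus four oblique
#'   views.
#' @param um_per_px Spatial calibration (default 10 um/px, so the
#'   2000-4000 um central window spans 200 px at 0 degrees).
#' @param gap_law,tip_law Angular laws (functions of angle in degrees
#'   returning counts >= 0); defaults [cosine_law()] and [constant_law()].
#' @param beam_center_um,beam_width_um Illuminated region along the array
#'   (default centred at 3000 um, 2000 um wide: the 2000-4000 um window).
#' @param tip_shadow_frac Brightness fraction of gap-row pixels at tip
#'   columns (default 0.85; set to 1 for structure-free gap rows).
#' @param noise_sd Additive Gaussian noise, counts, pre-quantization
#'   (default 3).
#' @param seed RNG seed for the noise stream.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(geometry = array_geometry(),
                        angles_deg = c(0, 24, 31, 57, 77),
                        um_per_px = 10,
                        gap_law = cosine_law(),
                        tip_law = constant_law(),
                        beam_center_um = 3000,
                        beam_width_um = 2000,
                        tip_shadow_frac = 0.85,
                        noise_sd = 3,
                        seed = 1L) {
  geometry <- validate_geometry(geometry)
  if (um_per_px <= 0) stop("um_per_px must be > 0")
  if (any(angles_deg < 0 | angles_deg >= 90))
    stop("angles must be in [0, 90) degrees")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (tip_shadow_frac < 0 || tip_shadow_frac > 1)
    stop("tip_shadow_frac must be in [0, 1]")
  if (beam_width_um <= 0) stop("beam_width_um must be > 0")
  for (a in angles_deg) {
    if (gap_law(a) < 0 || tip_law(a) < 0)
      stop("intensity laws must be >= 0 at every requested angle")
  }
  structure(list(geometry = geometry, angles_deg = angles_deg,
                 um_per_px = um_per_px, gap_law = gap_law,
                 tip_law = tip_law, beam_center_um = beam_center_um,
                 beam_width_um = beam_width_um,
                 tip_shadow_frac = tip_shadow_frac,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "render_spec")
}

# Fractions of the green channel used for red and blue (543.5 nm is green).
.RED_FRAC <- 0.20
.BLUE_FRAC <- 0.10

# Pixel threshold below which the projected between-base gap makes tip and
# gap bands indistinguishable (mirrors the at-77-degrees exclusion).
.MIN_RESOLVABLE_GAP_PX <- 2

# Classify positions (um, array coordinates) against the repeating
# pitch cell: bases are centred in the cell with half-gap margins.
.in_tip_band <- function(pos_um, geom) {
  m <- pos_um %% geom$pitch_um
  m >= geom$gap_um / 2 & m < geom$gap_um / 2 + geom$base_um
}

# Noiseless green-channel row templates (full image width, counts, not yet
# quantized). Returns list(gap_row, tip_row, in_window) used both by the
# renderer and for manifest ground truth.
.row_templates <- function(spec, angle_deg, width_px, background = 2) {
  geom <- spec$geometry
  ct <- cos(angle_deg * pi / 180)
  x_um <- ((seq_len(width_px) - 0.5) * spec$um_per_px) / ct  # de-projected
  extent <- geom$n_cols * geom$pitch_um
  in_array <- x_um < extent
  in_beam <- in_array &
    x_um >= spec$beam_center_um - spec$beam_width_um / 2 &
    x_um < spec$beam_center_um + spec$beam_width_um / 2
  tip_col <- .in_tip_band(x_um, geom)
  gv <- spec$gap_law(angle_deg)
  tv <- spec$tip_law(angle_deg)
  gap_row <- rep(background, width_px)
  gap_row[in_beam] <- ifelse(tip_col[in_beam],
                             spec$tip_shadow_frac * gv, gv)
  tip_row <- rep(background, width_px)
  tip_row[in_beam] <- tv
  list(gap_row = gap_row, tip_row = tip_row, in_beam = in_beam,
       tip_col = tip_col)
}

# Row classification over image height: TRUE where the row crosses tip
# bands (vertical axis is not affected by the horizontal camera rotation).
.tip_rows <- function(spec, height_px) {
  geom <- spec$geometry
  y_um <- (seq_len(height_px) - 0.5) * spec$um_per_px
  in_array <- y_um < geom$n_rows * geom$pitch_um
  in_array & .in_tip_band(y_um, geom)
}

.image_dims <- function(spec) {
  geom <- spec$geometry
  w <- ceiling(geom$n_cols * geom$pitch_um / spec$um_per_px)
  h <- ceiling(geom$n_rows * geom$pitch_um / spec$um_per_px)
  c(h = h, w = w)
}

#' Render one synthetic array photograph
#'
#' Produces an 8-bit RGB image of the illuminated array as seen from
#' `angle_deg`, together with the ground truth used to render it (the law
#' values and the expected central-window means of the quantized noiseless
#' scene), so downstream analysis can be validated against known values.
#' If more than 5% of beam-window green pixels saturate at 255 the image is
#' flagged with `saturated = TRUE`.
#'
#' Rendering is deterministic under `spec$seed`; identical spec and seed
#' give bit-identical pixels.
#'
#' @param spec A [render_spec()].
#' @param angle_deg Camera angle; must be one of `spec$angles_deg` unless
#'   supplied explicitly here (any value in \[0, 90) is accepted).
#' @return An object of class `angular_image`: list with `pixels`
#'   (H x W x 3 integer array, 0-255), `angle_deg`, `um_per_px`,
#'   `ground_truth`, `resolvable`, `saturated`, `seed`.
#' @export
generate_array_image <- function(spec, angle_deg) {
  stopifnot(inherits(spec, "render_spec"))
  if (angle_deg < 0 || angle_deg >= 90)
    stop("angle must be in [0, 90) degrees")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  .render_image(spec, angle_deg)
}

# Core renderer; draws noise from the current RNG stream.
.render_image <- function(spec, angle_deg) {
  dims <- .image_dims(spec)
  h <- dims[["h"]]; w <- dims[["w"]]
  tmpl <- .row_templates(spec, angle_deg, w)
  tip_row <- .tip_rows(spec, h)
  green <- matrix(0, nrow = h, ncol = w)
  green[tip_row, ] <- matrix(tmpl$tip_row, nrow = sum(tip_row),
                             ncol = w, byrow = TRUE)
  green[!tip_row, ] <- matrix(tmpl$gap_row, nrow = sum(!tip_row),
                              ncol = w, byrow = TRUE)
  quantize <- function(x) {
    if (spec$noise_sd > 0)
      x <- x + stats::rnorm(length(x), sd = spec$noise_sd)
    as.integer(round(pmin(255, pmax(0, x))))
  }
  px <- array(0L, dim = c(h, w, 3L))
  px[, , 1] <- quantize(green * .RED_FRAC)
  px[, , 2] <- quantize(green)
  px[, , 3] <- quantize(green * .BLUE_FRAC)
  beam_cols <- which(tmpl$in_beam)
  gpx <- px[, beam_cols, 2]
  saturated <- length(gpx) > 0 && mean(gpx == 255L) > 0.05
  gap_px <- spec$geometry$gap_um * cos(angle_deg * pi / 180) / spec$um_per_px
  # expected window means are the expectation of the downstream estimator:
  # noise dithers the 8-bit rounding, so with noise_sd > 0 the estimator is
  # unbiased for the raw template; at noise_sd = 0 it recovers the
  # quantized template exactly
  q <- spec$noise_sd == 0
  gt <- list(
    gap_value = spec$gap_law(angle_deg),
    tip_value = spec$tip_law(angle_deg),
    expected_line_mean = .window_mean_of_template(spec, angle_deg,
                                                  tmpl$gap_row, w,
                                                  quantize = q),
    expected_mn_mean = .window_mean_of_template(spec, angle_deg,
                                                tmpl$tip_row, w,
                                                quantize = q))
  structure(list(pixels = px, angle_deg = angle_deg,
                 um_per_px = spec$um_per_px, ground_truth = gt,
                 resolvable = gap_px >= .MIN_RESOLVABLE_GAP_PX,
                 saturated = saturated, seed = spec$seed),
            class = "angular_image")
}

# Mean of a row template over the central window (de-projected positions):
# what the profile analysis is expected to recover. `quantize` applies the
# 8-bit rounding (exact expectation only when no noise dithers it).
.window_mean_of_template <- function(spec, angle_deg, template, width_px,
                                     window_um = c(2000, 4000),
                                     quantize = TRUE) {
  ct <- cos(angle_deg * pi / 180)
  pos <- ((seq_len(width_px) - 0.5) * spec$um_per_px) / ct
  sel <- pos >= window_um[1] & pos < window_um[2]
  if (!any(sel)) return(NA_real_)
  v <- pmin(255, pmax(0, template[sel]))
  if (quantize) v <- round(v)
  mean(v)
}

#' @export
print.angular_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "angular_image: %d x %d px, angle %g deg, %g um/px%s%s\n",
    d[1], d[2], x$angle_deg, x$um_per_px,
    if (!x$resolvable) " [unresolvable projection]" else "",
    if (x$saturated) " [saturation warning]" else ""))
  invisible(x)
}

#' Render the full angle set
#'
#' Renders one image per angle in `spec$angles_deg`, drawing all noise from
#' a single seeded stream so the set is reproducible as a whole, and
#' returns the images with a manifest recording the spec echo and per-angle
#' ground truth. If `out_dir` is given, images are written as 8-bit RGB
#' PNGs (`angle_000.png`, ...) and the manifest as `manifest.json`.
#'
#' @param spec A [render_spec()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list with `images` (list of `angular_image`) and `manifest`.
#' @export
render_angle_set <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "render_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  images <- lapply(spec$angles_deg, function(a) .render_image(spec, a))
  manifest <- list(
    spec = list(
      geometry = unclass(spec$geometry),
      angles_deg = spec$angles_deg,
      um_per_px = spec$um_per_px,
      gap_law = attr(spec$gap_law, "params"),
      tip_law = attr(spec$tip_law, "params"),
      beam_center_um = spec$beam_center_um,
      beam_width_um = spec$beam_width_um,
      tip_shadow_frac = spec$tip_shadow_frac,
      noise_sd = spec$noise_sd,
      seed = spec$seed),
    images = lapply(images, function(im) {
      list(file = sprintf("angle_%03d.png", round(im$angle_deg)),
           angle_deg = im$angle_deg,
           resolvable = im$resolvable,
           saturated = im$saturated,
           ground_truth = im$ground_truth)
    }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (im in images) {
      f <- file.path(out_dir, sprintf("angle_%03d.png", round(im$angle_deg)))
      png::writePNG(aperm(array(im$pixels / 255,
                                dim = dim(im$pixels)), c(1, 2, 3)), f)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(images = images, manifest = manifest)
}

#' Read a rendered image back from PNG
#'
#' Reconstructs an `angular_image` from a PNG written by
#' [render_angle_set()] and its manifest entry.
#'
#' @param path PNG file path.
#' @param manifest_entry The corresponding element of `manifest$images`.
#' @param um_per_px Spatial calibration (from the manifest spec).
#' @return An `angular_image`.
#' @export
read_angular_image <- function(path, manifest_entry, um_per_px) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3L || dim(arr)[3] < 3L)
    stop("expected a 3-channel RGB PNG: ", path)
  px <- array(as.integer(round(arr[, , 1:3] * 255)), dim = c(dim(arr)[1:2], 3L))
  structure(list(pixels = px,
                 angle_deg = manifest_entry$angle_deg,
                 um_per_px = um_per_px,
                 ground_truth = manifest_entry$ground_truth,
                 resolvable = isTRUE(manifest_entry$resolvable),
                 saturated = isTRUE(manifest_entry$saturated),
                 seed = NA_integer_),
            class = "angular_image")
}
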