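#' Microneedle array geometry
#'
#' Constructs and validates the discrete layout of a microneedle (MN) array:
#' a rectangular grid of square-based pyramidal tips. All lengths are in
#' micrometres; unit conversions happen only at I/O boundaries.
#'
#' Two spacing numbers circulate for this kind of array: the edge-to-edge gap
#' between adjacent tip bases and the centre-to-centre pitch. Here the pitch
#' is canonical and the gap is derived as `pitch_um - base_um` (50 um for the
#' defaults: 350 - 300).
#'
#' @param n_rows,n_cols Number of tip rows and columns (default 19 x 19).
#' @param pitch_um Centre-to-centre tip spacing, um (default 350).
#' @param base_um Side length of the square tip base, um (default 300).
#' @param tip_height_um_min,tip_height_um_max Tip height range, um
#'   (default 450-500). Per-tip heights are drawn uniformly in this range
#'   under a seed, or the midpoint is used when deterministic output is
#'   requested.
#' @param tip_shape Currently only `"square_pyramid"`.
#'
#' @return An object of class `array_geometry`: a validated list with the
#'   fields above plus the derived `gap_um`.
#' @examples
#' geom <- array_geometry()
#' geom$gap_um  # 50
#' @export
array_geometry <- function(n_rows = 19L, n_cols = 19L,
                           pitch_um = 350, base_um = 300,
                           tip_height_um_min = 450, tip_height_um_max = 500,
                           tip_shape = "square_pyramid") {
  geom <- structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pitch_um = as.numeric(pitch_um), base_um = as.numeric(base_um),
         tip_height_um_min = as.numeric(tip_height_um_min),
         tip_height_um_max = as.numeric(tip_height_um_max),
         tip_shape = match.arg(tip_shape, "square_pyramid")),
    class = "array_geometry")
  validate_geometry(geom)
}

#' Validate an array geometry
#'
#' Checks every geometric invariant and derives the edge-to-edge gap.
#' Invalid geometries are rejected with an error naming the violated
#' invariant; in particular `pitch_um < base_um` means adjacent tip bases
#' would overlap.
#'
#' @param geom An `array_geometry` (or a plain list with its fields).
#' @return The validated `array_geometry`, with `gap_um` populated.
#' @export
validate_geometry <- function(geom) {
  stopifnot(is.list(geom))
  need <- c("n_rows", "n_cols", "pitch_um", "base_um",
            "tip_height_um_min", "tip_height_um_max")
  miss <- setdiff(need, names(geom))
  if (length(miss))
    stop("geometry is missing fields: ", paste(miss, collapse = ", "))
  for (f in need)
    if (!is.numeric(geom[[f]]) || length(geom[[f]]) != 1L || !is.finite(geom[[f]]))
      stop("geometry field '", f, "' must be a single finite number")
  if (geom$n_rows < 1 || geom$n_cols < 1)
    stop("invalid geometry: n_rows and n_cols must be >= 1")
  if (geom$base_um <= 0)
    stop("invalid geometry: base_um must be > 0")
  if (geom$pitch_um < geom$base_um)
    stop("invalid geometry: overlapping bases (pitch_um < base_um)")
  if (geom$tip_height_um_min <= 0)
    stop("invalid geometry: tip_height_um_min must be > 0")
  if (geom$tip_height_um_max < geom$tip_height_um_min)
    stop("invalid geometry: tip_height_um_max < tip_height_um_min")
  geom$gap_um <- geom$pitch_um - geom$base_um
  if (is.null(geom$tip_shape)) geom$tip_shape <- "square_pyramid"
  class(geom) <- "array_geometry"
  geom
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("MN array geometry: %d x %d %s tips\n",
              x$n_rows, x$n_cols, x$tip_shape))
  cat(sprintf("  pitch %g um, base %g um (gap %g um), tip height %g-%g um\n",
              x$pitch_um, x$base_um, x$gap_um,
              x$tip_height_um_min, x$tip_height_um_max))
  invisible(x)
}

#' Disk-of-emitters optical parameters
#'
#' Parameter container for the analytic source model: isotropic emitters
#' uniformly distributed at surface density `sigma` over a disk of radius
#' `R`, each with reference intensity `I0` at distance `r0`, embedded in a
#' medium with attenuation coefficient `alpha`. All lengths share one unit
#' (um by convention), so `alpha` carries um^-1.
#'
#' @param R Disk radius (> 0).
#' @param sigma Emitter surface density, count per unit area (>= 0).
#' @param I0 Reference intensity at distance `r0` (>= 0, arbitrary units).
#' @param r0 Reference distance (> 0).
#' @param alpha Attenuation coefficient, inverse length (>= 0).
#' @return An object of class `emitter_disk`.
#' @examples
#' emitter_disk(R = 1, sigma = 1, I0 = 1, r0 = 1)
#' @export
emitter_disk <- function(R, sigma = 1, I0 = 1, r0 = 1, alpha = 0) {
  vals <- c(R = R, sigma = sigma, I0 = I0, r0 = r0, alpha = alpha)
  if (any(!is.finite(vals)))
    stop("emitter_disk parameters must be finite")
  if (R <= 0) stop("invalid emitter_disk: R must be > 0")
  if (sigma < 0) stop("invalid emitter_disk: sigma must be >= 0")
  if (I0 < 0) stop("invalid emitter_disk: I0 must be >= 0")
  if (r0 <= 0) stop("invalid emitter_disk: r0 must be > 0")
  if (alpha < 0) stop("invalid emitter_disk: alpha must be >= 0")
  structure(list(R = R, sigma = sigma, I0 = I0, r0 = r0, alpha = alpha),
            class = "emitter_disk")
}

#' @export
print.emitter_disk <- function(x, ...) {
  cat(sprintf(
    "Disk of isotropic emitters: R = %g, sigma = %g, I0 = %g at r0 = %g, alpha = %g\n",
    x$R, x$sigma, x$I0, x$r0, x$alpha))
  invisible(x)
}

#' Photodynamic therapy exposure parameters
#'
#' @param irradiance_mw_cm2 Irradiance (power density), mW/cm^2.
#' @param duration_s Exposure time, seconds.
#' @return An object of class `dose_params`.
#' @seealso [pdt_dose()]
#' @export
dose_params <- function(irradiance_mw_cm2, duration_s) {
  if (!is.numeric(irradiance_mw_cm2) || irradiance_mw_cm2 < 0)
    stop("irradiance_mw_cm2 must be >= 0")
  if (!is.numeric(duration_s) || duration_s < 0)
    stop("duration_s must be >= 0")
  structure(list(irradiance_mw_cm2 = irradiance_mw_cm2,
                 duration_s = duration_s),
            class = "dose_params")
}

#' Serialize / deserialize geometry configuration
#'
#' Writes an `array_geometry` as the `geometry:` block of a YAML config and
#' reads it back; a round-trip compares equal field by field. Only plain um
#' fields are accepted on read — a block declaring any other length unit is
#' rejected, keeping the unit system coherent.
#'
#' @param geom An `array_geometry`.
#' @param path File to write to / read from.
#' @return `geometry_to_yaml` returns `path` invisibly;
#'   `geometry_from_yaml` returns the validated `array_geometry`.
#' @export
geometry_to_yaml <- function(geom, path) {
  geom <- validate_geometry(geom)
  block <- geom[c("n_rows", "n_cols", "pitch_um", "base_um",
                  "tip_height_um_min", "tip_height_um_max", "tip_shape")]
  yaml::write_yaml(list(geometry = block), path)
  invisible(path)
}

#' @rdname geometry_to_yaml
#' @export
geometry_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$geometry)) stop("no 'geometry:' block in ", path)
  geometry_from_config(cfg$geometry)
}

# Internal: build geometry from a parsed config block, rejecting fields that
# declare a unit other than micrometres (e.g. pitch_mm).
geometry_from_config <- function(block) {
  unit_suffixed <- grep("_(mm|cm|nm|m)$", names(block), value = TRUE)
  if (length(unit_suffixed))
    stop("geometry config declares non-micrometre units: ",
         paste(unit_suffixed, collapse = ", "))
  known <- c("n_rows", "n_cols", "pitch_um", "base_um",
             "tip_height_um_min", "tip_height_um_max", "tip_shape", "gap_um")
  unknown <- setdiff(names(block), known)
  if (length(unknown))
    stop("unknown geometry fields: ", paste(unknown, collapse = ", "))
  block$gap_um <- NULL
  validate_geometry(structure(block, class = "array_geometry"))
}
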