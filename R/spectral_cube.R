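#' Hyperspectral cube container
#'
#' A `spectral_cube` holds a wavelength-indexed 3-D raster of non-negative
#' values, either raw sensor counts or reflectance fractions. It is the
#' carrier passed between the reader, the flat-field correction and the
#' colorimetric conversion.
#'
#' Coordinate convention: row 1 is the top of the image. In the capture
#' geometry used for anterior teeth (chin rest, camera level with the
#' incisors) the top of the image is the cervical/gingival side; the
#' third-splitting code relies on this and never guesses orientation.
#'
#' @param data 3-D numeric array `[rows x cols x bands]`, all values >= 0.
#' @param wavelengths Numeric vector of band-center wavelengths in nm,
#'   strictly increasing, all within 300--1100 nm, one per band.
#' @param kind `"raw_counts"` or `"reflectance"`. Reflectance values above 1
#'   are permitted (specular pixels) and merely counted; see
#'   [reflectance_overshoot()].
#' @param meta Named list of free-form header fields (integration time,
#'   capture id, ...). Names must be ASCII.
#' @return An object of class `spectral_cube`.
#' @seealso [read_envi_cube()], [crop_spectral_range()]
#' @export
spectral_cube <- function(data, wavelengths, kind = c("raw_counts", "reflectance"),
                          meta = list()) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [rows x cols x bands]", call. = FALSE)
  if (any(dim(data) == 0L))
    stop("`data` must contain at least one pixel and one band", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length(wavelengths) must equal the band dimension of `data`",
         call. = FALSE)
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  if (any(wavelengths < 300) || any(wavelengths > 1100))
    stop("wavelengths must lie within [300, 1100] nm", call. = FALSE)
  if (any(data < 0, na.rm = TRUE))
    stop("cube values must be non-negative", call. = FALSE)
  if (length(meta) && (is.null(names(meta)) || any(names(meta) == "")))
    stop("`meta` must be a named list", call. = FALSE)
  if (length(meta) && any(grepl("[^\x01-\x7f]", names(meta))))
    stop("`meta` keys must be ASCII", call. = FALSE)
  structure(
    list(data = data, wavelengths = wavelengths, kind = kind, meta = meta),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), kind: %s\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths),
              x$kind))
  if (x$kind == "reflectance") {
    ov <- reflectance_overshoot(x)
    cat(sprintf("  value range [%.4g, %.4g]; %d pixel(s) exceed reflectance 1\n",
                min(x$data), max(x$data), ov$n_pixels))
  } else {
    cat(sprintf("  count range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

#' Count reflectance overshoot
#'
#' Reflectance above 1 (typically specular highlights brighter than the gray
#' reference) is retained, not clipped; this helper reports how much of it a
#' cube contains so it can be masked before ROI statistics. Clipping at 1 is
#' never applied; only the lower bound 0 is enforced at colorimetric
#' integration.
#'
#' @param cube A reflectance `spectral_cube`.
#' @return List with `n_pixels` (pixels with any band > 1), `n_values`
#'   (band-values > 1) and `mask` (logical `[rows x cols]`).
#' @export
reflectance_overshoot <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$kind != "reflectance")
    stop("overshoot is defined for reflectance cubes only", call. = FALSE)
  over <- cube$data > 1
  mask <- apply(over, c(1L, 2L), any)
  list(n_pixels = sum(mask), n_values = sum(over), mask = mask)
}

#' Restrict a cube to a wavelength window
#'
#' Keeps exactly the bands with `lo_nm <= lambda <= hi_nm`, order preserved.
#' Used to cut a 400--1000 nm camera cube down to the visible range before
#' colorimetric integration.
#'
#' @param cube A `spectral_cube`.
#' @param lo_nm,hi_nm Window bounds in nm, `lo_nm < hi_nm`.
#' @return A `spectral_cube` with the selected bands.
#' @export
crop_spectral_range <- function(cube, lo_nm, hi_nm) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!(lo_nm < hi_nm))
    stop("`lo_nm` must be strictly less than `hi_nm`", call. = FALSE)
  keep <- cube$wavelengths >= lo_nm & cube$wavelengths <= hi_nm
  if (!any(keep))
    stop(sprintf("no band within [%g, %g] nm", lo_nm, hi_nm), call. = FALSE)
  spectral_cube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
                kind = cube$kind, meta = cube$meta)
}
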