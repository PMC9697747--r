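#' Reference tile spectrum
#'
#' Calibrated reflectance of the matt diffuse gray ceramic tile captured
#' alongside each scene. The study-style workflow images the tile with the
#' same settings as the teeth; its known reflectance converts the ratio of
#' dark-subtracted counts into absolute reflectance.
#'
#' @param wavelengths Strictly increasing wavelengths in nm.
#' @param reflectance Values in (0, 1], one per wavelength. A single value
#'   gives a spectrally flat tile.
#' @param name Label for reports.
#' @return Object of class `reference_tile`.
#' @export
reference_tile <- function(wavelengths, reflectance, name = "gray tile") {
  wavelengths <- as.numeric(wavelengths)
  if (length(reflectance) == 1L)
    reflectance <- rep(as.numeric(reflectance), length(wavelengths))
  reflectance <- as.numeric(reflectance)
  if (length(reflectance) != length(wavelengths))
    stop("wavelengths and reflectance must have equal length", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("tile wavelengths must be strictly increasing", call. = FALSE)
  if (any(reflectance <= 0) || any(reflectance > 1))
    stop("tile reflectance must lie in (0, 1]", call. = FALSE)
  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 name = name), class = "reference_tile")
}

#' Default flat gray tile
#'
#' The tile's calibrated spectrum is a user input; when none is available a
#' spectrally flat 40% reflector is the working default.
#'
#' @param wavelengths Wavelengths to tabulate at (nm).
#' @param value Flat reflectance, default 0.40.
#' @export
default_gray_tile <- function(wavelengths = seq(350, 1050, by = 10),
                              value = 0.40) {
  reference_tile(wavelengths, value, name = sprintf("flat %.0f%% gray", 100 * value))
}

#' Read a tile spectrum from a two-column CSV
#'
#' Expects columns `wavelength_nm` and `reflectance` (or the first two
#' columns in that order).
#' @param path CSV path.
#' @param name Optional label; defaults to the file name.
#' @export
read_tile_csv <- function(path, name = basename(path)) {
  df <- utils::read.csv(path)
  wl_col <- if ("wavelength_nm" %in% names(df)) "wavelength_nm" else names(df)[1L]
  r_col <- if ("reflectance" %in% names(df)) "reflectance" else names(df)[2L]
  reference_tile(df[[wl_col]], df[[r_col]], name = name)
}

#' Resample a sampled spectrum onto new wavelengths
#'
#' Piecewise-linear interpolation. Targets outside the source hull raise a
#' coverage error unless `extrapolate = TRUE`, which extends the end values
#' as constants (documented behaviour; true extrapolation is never done).
#'
#' @param wavelengths,values Source tabulation (strictly increasing
#'   wavelengths).
#' @param target_wavelengths Wavelengths to evaluate at (nm).
#' @param extrapolate Allow constant extension beyond the hull.
#' @return Numeric vector of interpolated values.
#' @export
resample_spectrum <- function(wavelengths, values, target_wavelengths,
                              extrapolate = FALSE) {
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0))
    stop("source wavelengths must be strictly increasing", call. = FALSE)
  out_of_hull <- target_wavelengths < wavelengths[1L] |
    target_wavelengths > wavelengths[length(wavelengths)]
  if (any(out_of_hull) && !extrapolate)
    stop(sprintf(
      "target wavelengths [%g, %g] nm extend beyond the source hull [%g, %g] nm",
      min(target_wavelengths), max(target_wavelengths),
      wavelengths[1L], wavelengths[length(wavelengths)]), call. = FALSE)
  stats::approx(wavelengths, values, xout = target_wavelengths,
                method = "linear", rule = 2)$y
}

#' Pixel quality masks
#'
#' @param saturated,unstable_reference Logical `[rows x cols]` masks.
#' @return Object of class `pixel_quality`.
#' @export
pixel_quality <- function(saturated, unstable_reference = NULL) {
  if (is.null(unstable_reference))
    unstable_reference <- array(FALSE, dim(saturated))
  if (!identical(dim(saturated), dim(unstable_reference)))
    stop("quality masks must share one spatial shape", call. = FALSE)
  structure(list(saturated = saturated,
                 unstable_reference = unstable_reference),
            class = "pixel_quality")
}

#' @export
print.pixel_quality <- function(x, ...) {
  cat(sprintf("<pixel_quality> %d x %d: %d saturated, %d unstable-reference pixel(s)\n",
              nrow(x$saturated), ncol(x$saturated),
              sum(x$saturated), sum(x$unstable_reference)))
  invisible(x)
}

#' Combined validity mask (neither saturated nor unstable)
#' @param quality A [pixel_quality()] or `NULL` (all valid needs a shape).
#' @keywords internal
.quality_valid <- function(quality) {
  !(quality$saturated | quality$unstable_reference)
}

# Broadcast a dark/gray reference given as cube, spectrum or scalar to the
# [rows x cols x bands] shape of `like`.
.broadcast_reference <- function(ref, like, what) {
  d <- dim(like$data)
  if (inherits(ref, "spectral_cube")) {
    if (!identical(dim(ref$data), d))
      stop(what, " cube shape does not match the raw cube", call. = FALSE)
    if (max(abs(ref$wavelengths - like$wavelengths)) > 1e-9)
      stop(what, " cube wavelengths do not match the raw cube", call. = FALSE)
    return(ref$data)
  }
  ref <- as.numeric(ref)
  if (length(ref) == 1L) ref <- rep(ref, d[3L])
  if (length(ref) != d[3L])
    stop(what, " must be a cube, a per-band spectrum or a scalar", call. = FALSE)
  aperm(array(ref, dim = c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
}

#' Dark/gray flat-field correction to reflectance
#'
#' Converts raw counts to spectral reflectance using the dark-frame and
#' gray-tile captures taken with identical settings:
#' \deqn{R(x,y,\lambda) = \frac{I_{raw} - I_{dark}}{I_{gray} - I_{dark}} \times R_{tile}(\lambda)}
#' This cancels the sensor offset and any spectrally and spatially
#' non-uniform illumination, because the same per-pixel, per-band gain
#' multiplies numerator and denominator.
#'
#' Negative numerators are floored at 0. Pixels whose denominator magnitude
#' falls below `epsilon` in any band get reflectance 0 there and are flagged
#' `unstable_reference`; flagged pixels are excluded from all downstream
#' means.
#'
#' @param raw Raw-counts [spectral_cube()] of the scene.
#' @param dark,gray Dark-frame and gray-tile captures: a matching raw-counts
#'   cube, a per-band spectrum, or a scalar (spatially constant references).
#' @param tile [reference_tile()] whose hull covers the cube wavelengths
#'   (default flat 40% gray).
#' @param full_scale Sensor full scale in counts (default 4095, 12-bit).
#' @param epsilon Denominator stability floor in counts; default
#'   `1e-6 * full_scale`.
#' @return List with `reflectance` (a `spectral_cube`) and `quality`
#'   (a [pixel_quality()] carrying the `unstable_reference` mask).
#' @export
flat_field_correct <- function(raw, dark, gray, tile = default_gray_tile(),
                               full_scale = 4095,
                               epsilon = 1e-6 * full_scale) {
  stopifnot(inherits(raw, "spectral_cube"))
  if (raw$kind != "raw_counts")
    stop("`raw` must be a raw-counts cube", call. = FALSE)
  d <- dim(raw$data)
  dark_a <- .broadcast_reference(dark, raw, "dark")
  gray_a <- .broadcast_reference(gray, raw, "gray")

  r_tile <- resample_spectrum(tile$wavelengths, tile$reflectance,
                              raw$wavelengths)

  num <- raw$data - dark_a
  num[num < 0] <- 0
  den <- gray_a - dark_a
  unstable_vals <- abs(den) < epsilon

  refl <- num / den
  refl <- refl * aperm(array(r_tile, dim = c(d[3L], d[1L], d[2L])),
                       c(2L, 3L, 1L))
  refl[unstable_vals] <- 0
  unstable_mask <- apply(unstable_vals, c(1L, 2L), any)

  list(
    reflectance = spectral_cube(refl, raw$wavelengths, kind = "reflectance",
                                meta = raw$meta),
    quality = pixel_quality(saturated = array(FALSE, d[1:2]),
                            unstable_reference = unstable_mask)
  )
}

#' Flag over-saturated pixels
#'
#' A pixel is saturated iff any band count reaches
#' `full_scale * (1 - guard)`. Saturated pixels are invalidated before Lab
#' conversion so clipped spectra never enter the per-third means.
#'
#' @param cube Raw-counts [spectral_cube()].
#' @param full_scale Sensor full scale in counts, > 0.
#' @param guard Fractional headroom below full scale still treated as
#'   saturated (default 0).
#' @return A [pixel_quality()] with the `saturated` mask set.
#' @export
detect_saturation <- function(cube, full_scale = 4095, guard = 0) {
  stopifnot(inherits(cube, "spectral_cube"), full_scale > 0)
  sat <- apply(cube$data >= full_scale * (1 - guard), c(1L, 2L), any)
  pixel_quality(saturated = sat)
}

#' Merge quality masks (logical OR per flag)
#' @param ... `pixel_quality` objects of one shape.
#' @export
combine_quality <- function(...) {
  qs <- list(...)
  sat <- Reduce(`|`, lapply(qs, `[[`, "saturated"))
  uns <- Reduce(`|`, lapply(qs, `[[`, "unstable_reference"))
  pixel_quality(saturated = sat, unstable_reference = uns)
}

#' Export a quality/region mask as an 8-bit image
#'
#' Writes TRUE pixels as 255 in a single-channel TIFF or PNG, for inspection
#' in external viewers.
#' @param mask Logical matrix.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @export
write_mask_image <- function(mask, path) {
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required for TIFF export", call. = FALSE)
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("package 'png' is required for PNG export", call. = FALSE)
    png::writePNG(img, path)
  } else {
    stop("unsupported mask image format: ", path, call. = FALSE)
  }
  invisible(path)
}
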