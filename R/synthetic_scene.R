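#' @title Synthetic hyperspectral tooth scenes
#' @description Forward model of an in-vivo anterior-tooth capture with
#'   known ground truth: four rectangular "teeth" with a cervical-to-incisal
#'   reflectance gradient, a spatially and spectrally non-uniform
#'   illumination field, a dark offset and additive sensor noise, plus the
#'   matching dark-frame and gray-tile captures. Lets every pipeline stage
#'   be tested without camera hardware or deposited raw images.
#' @name synthetic_data
NULL

#' Sigmoid tooth reflectance model
#'
#' \eqn{R(\lambda) = \mathrm{clip}(base + amp / (1 + e^{-(\lambda -
#' edge)/slope}), 0, 1)} — a monotone non-decreasing edge spectrum. Enamel
#' and dentine reflect more at long wavelengths; a steeper, later edge gives
#' a darker, redder, yellower color, which is how the cervical preset
#' differs from the incisal one.
#'
#' @param base Minimum reflectance (short-wavelength floor), in `[0, 1]`.
#' @param amp Edge amplitude; `base + amp <= 1.05` (clipped at 1).
#' @param edge_nm Sigmoid center wavelength.
#' @param slope_nm Sigmoid width, > 0.
#' @return Object of class `tooth_spectrum_params`.
#' @export
tooth_spectrum_params <- function(base, amp, edge_nm, slope_nm) {
  if (slope_nm <= 0) stop("slope_nm must be > 0", call. = FALSE)
  if (base < 0 || amp < 0 || base + amp > 1.05)
    stop("need base, amp >= 0 and base + amp <= 1.05", call. = FALSE)
  structure(list(base = base, amp = amp, edge_nm = edge_nm,
                 slope_nm = slope_nm), class = "tooth_spectrum_params")
}

#' Evaluate the sigmoid reflectance model
#' @param p A [tooth_spectrum_params()].
#' @param wavelengths Wavelengths in nm.
#' @return Reflectance values in `[0, 1]`.
#' @export
tooth_reflectance <- function(p, wavelengths) {
  stopifnot(inherits(p, "tooth_spectrum_params"))
  r <- p$base + p$amp / (1 + exp(-(wavelengths - p$edge_nm) / p$slope_nm))
  pmin(pmax(r, 0), 1)
}

#' Default per-third spectrum presets
#'
#' Parameter sets per tooth type (central/lateral) and third, chosen so the
#' rendered colors show the anatomical pattern: the cervical third is
#' redder and yellower (higher a*, b*) than the incisal third, the middle
#' third is the lightest, and central incisors are brighter and less
#' chromatic than laterals.
#'
#' @return Nested list `presets[[type]][[third]]` of
#'   [tooth_spectrum_params()].
#' @export
tooth_spectrum_presets <- function() {
  list(
    central = list(
      cervical = tooth_spectrum_params(0.30, 0.42, 585, 48),
      middle = tooth_spectrum_params(0.48, 0.30, 560, 55),
      incisal = tooth_spectrum_params(0.40, 0.26, 565, 55)
    ),
    lateral = list(
      cervical = tooth_spectrum_params(0.24, 0.44, 595, 45),
      middle = tooth_spectrum_params(0.38, 0.30, 570, 52),
      incisal = tooth_spectrum_params(0.33, 0.24, 572, 55)
    )
  )
}

# Flat-ish dark reddish placeholder for gingiva/background.
.background_params <- function() tooth_spectrum_params(0.03, 0.18, 615, 18)

#' Default tooth layout for a scene
#'
#' Four rectangles mimicking the upper incisors seen face-on, left to right
#' ULI1, UCI1, UCI2, ULI2 (patient's right to left): centrals 60 x 90 px,
#' laterals 45 x 80 px at the reference 512 x 512 frame, scaled
#' proportionally for other sizes. Row 1 is the cervical side.
#'
#' @param n_rows,n_cols Scene size in pixels.
#' @return List of placements: `tooth_id`, `type`, `rows`, `cols`.
#' @export
default_tooth_layout <- function(n_rows = 512, n_cols = 512) {
  sc_r <- n_rows / 512; sc_c <- n_cols / 512
  w <- function(px) max(3L, round(px * sc_c))
  h <- function(px) max(9L, round(px * sc_r))
  widths <- c(w(45), w(60), w(60), w(45))
  heights <- c(h(80), h(90), h(90), h(80))
  gap <- max(2L, round(20 * sc_c))
  total <- sum(widths) + 3L * gap
  c0 <- max(1L, round((n_cols - total) / 2))
  ids <- c("ULI1", "UCI1", "UCI2", "ULI2")
  types <- c("lateral", "central", "central", "lateral")
  out <- vector("list", 4L)
  for (i in 1:4) {
    r0 <- max(1L, round((n_rows - heights[i]) / 2))
    out[[i]] <- list(tooth_id = ids[i], type = types[i],
                     rows = c(r0, r0 + heights[i] - 1L),
                     cols = c(c0, c0 + widths[i] - 1L))
    c0 <- c0 + widths[i] + gap
  }
  out
}

#' Synthetic scene parameters
#'
#' Defaults emulate the study capture: 512 x 512 pixels, 204 bands over
#' 400--1000 nm, a 12-bit sensor (full scale 4095 counts), a centered
#' Gaussian vignette of amplitude 0.3 with a linear +/-10% spectral tilt,
#' dark level 100 counts, gain 3500 counts per unit radiance and additive
#' Gaussian noise of 20 counts (about 1% of a typical tooth signal).
#'
#' @param n_rows,n_cols Scene size.
#' @param wavelengths Band centers in nm (default 204 bands, 400--1000 nm).
#' @param teeth Tooth placements, see [default_tooth_layout()].
#' @param presets Spectrum presets, see [tooth_spectrum_presets()].
#' @param illum_amplitude Vignette depth in `[0, 1)` (0 = flat field).
#' @param vignette_sigma_frac Gaussian sigma as a fraction of the image
#'   side.
#' @param spectral_tilt Total relative gain change across the spectral
#'   range (0.2 = +/-10%).
#' @param dark_level,gain,noise_sd,full_scale Sensor model, in counts.
#' @param tile Gray [reference_tile()] used for the gray capture.
#' @param seed RNG seed for the noise.
#' @return Object of class `scene_params`.
#' @export
scene_params <- function(n_rows = 512, n_cols = 512,
                         wavelengths = seq(400, 1000, length.out = 204),
                         teeth = default_tooth_layout(n_rows, n_cols),
                         presets = tooth_spectrum_presets(),
                         illum_amplitude = 0.3, vignette_sigma_frac = 0.45,
                         spectral_tilt = 0.2,
                         dark_level = 100, gain = 3500, noise_sd = 20,
                         full_scale = 4095,
                         tile = default_gray_tile(), seed = 1L) {
  if (dark_level >= full_scale)
    stop("dark_level must be below full_scale", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 wavelengths = as.numeric(wavelengths), teeth = teeth,
                 presets = presets, illum_amplitude = illum_amplitude,
                 vignette_sigma_frac = vignette_sigma_frac,
                 spectral_tilt = spectral_tilt, dark_level = dark_level,
                 gain = gain, noise_sd = noise_sd, full_scale = full_scale,
                 tile = tile, seed = seed),
            class = "scene_params")
}

# Per-row spectrum parameters for one tooth: linear interpolation of the
# third presets between third-band centers, constant beyond the end
# centers, so the cervical->incisal gradient is smooth across third
# boundaries.
.tooth_row_params <- function(placement, presets) {
  r0 <- placement$rows[1L]; r1 <- placement$rows[2L]
  h <- r1 - r0 + 1L
  cut1 <- round(h / 3); cut2 <- round(2 * h / 3)
  centers <- r0 - 1 + c((1 + cut1) / 2, (cut1 + 1 + cut2) / 2,
                        (cut2 + 1 + h) / 2)
  pr <- presets[[placement$type]]
  pm <- sapply(pr[c("cervical", "middle", "incisal")], function(p)
    c(p$base, p$amp, p$edge_nm, p$slope_nm))
  rows <- r0:r1
  t(sapply(rows, function(r) {
    if (r <= centers[1L]) return(pm[, 1L])
    if (r >= centers[3L]) return(pm[, 3L])
    j <- if (r <= centers[2L]) 1L else 2L
    f <- (r - centers[j]) / (centers[j + 1L] - centers[j])
    (1 - f) * pm[, j] + f * pm[, j + 1L]
  }))
}

#' Render a synthetic capture (raw + dark + gray + truth)
#'
#' Forward model, per pixel and band:
#' \deqn{I_{raw} = dark + gain \cdot g(x,y) \cdot S(\lambda) \cdot
#'   R_{scene}(x,y,\lambda) + \varepsilon,\quad
#'   \varepsilon \sim N(0, \sigma^2)}
#' truncated to `[0, full_scale]`. The gray capture replaces
#' \eqn{R_{scene}} by the tile reflectance under the identical gain field,
#' tilt, dark level and noise model, so flat-field correction cancels
#' \eqn{g} and \eqn{S} exactly in the noise-free case.
#'
#' Ground truth carries the noise-free reflectance cube, per-tooth masks
#' with their thirds, and noise-free Lab profiles computed through the same
#' observer/illuminant table as the pipeline under test (crop to
#' 400--780 nm, per-pixel Lab, per-third means).
#'
#' @param s A [scene_params()].
#' @return List with raw-counts cubes `raw`, `dark`, `gray` and `truth`
#'   (fields `reflectance`, `masks`, `thirds`, `profiles`, `params`).
#' @export
render_scene <- function(s) {
  stopifnot(inherits(s, "scene_params"))
  nr <- s$n_rows; nc <- s$n_cols; wl <- s$wavelengths; nb <- length(wl)

  occupied <- matrix(FALSE, nr, nc)
  for (tp in s$teeth) {
    block <- occupied[tp$rows[1L]:tp$rows[2L], tp$cols[1L]:tp$cols[2L]]
    if (any(block))
      stop("tooth placements overlap at ", tp$tooth_id, call. = FALSE)
    occupied[tp$rows[1L]:tp$rows[2L], tp$cols[1L]:tp$cols[2L]] <- TRUE
  }

  # scene reflectance: background everywhere, then per-tooth row gradients
  bg <- tooth_reflectance(.background_params(), wl)
  refl <- array(rep(bg, each = nr * nc), dim = c(nr, nc, nb))
  masks <- list()
  for (tp in s$teeth) {
    rp <- .tooth_row_params(tp, s$presets)
    rows <- tp$rows[1L]:tp$rows[2L]
    cols <- tp$cols[1L]:tp$cols[2L]
    for (i in seq_along(rows)) {
      p <- tooth_spectrum_params(rp[i, 1L], rp[i, 2L], rp[i, 3L], rp[i, 4L])
      rspec <- tooth_reflectance(p, wl)
      refl[rows[i], cols, ] <- matrix(rspec, length(cols), nb, byrow = TRUE)
    }
    m <- matrix(FALSE, nr, nc)
    m[rows, cols] <- TRUE
    masks[[tp$tooth_id]] <- region_mask(m, "tooth")
  }

  # illumination gain field and spectral tilt
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  sigma <- s$vignette_sigma_frac * min(nr, nc)
  r2 <- outer((seq_len(nr) - rc)^2, (seq_len(nc) - cc)^2, `+`)
  g <- 1 - s$illum_amplitude * (1 - exp(-r2 / (2 * sigma^2)))
  tilt <- 1 + s$spectral_tilt * ((wl - mean(range(wl))) / diff(range(wl)))
  r_tile <- resample_spectrum(s$tile$wavelengths, s$tile$reflectance, wl)

  gS <- as.vector(g) # length nr*nc
  # noiseless signals (counts above dark)
  flat_refl <- matrix(refl, nrow = nr * nc, ncol = nb)
  sig_raw <- s$gain * (flat_refl * gS) * matrix(tilt, nr * nc, nb, byrow = TRUE)
  sig_gray <- s$gain * (gS %o% (tilt * r_tile))

  if (!is.null(s$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(s$seed)
  }
  n <- nr * nc * nb
  noisy <- function(signal) {
    x <- s$dark_level + signal +
      if (s$noise_sd > 0) stats::rnorm(n, 0, s$noise_sd) else 0
    x <- pmin(pmax(x, 0), s$full_scale)
    array(x, dim = c(nr, nc, nb))
  }
  raw <- noisy(sig_raw)
  dark <- noisy(0)
  gray <- noisy(sig_gray)

  mk_cube <- function(a) spectral_cube(a, wl, kind = "raw_counts",
                                       meta = list(`capture id` = "synthetic"))
  truth_cube <- spectral_cube(refl, wl, kind = "reflectance")

  # truth profiles through the same colorimetric path as the pipeline
  vis <- crop_spectral_range(truth_cube, 400, 780)
  tab <- cie_table(vis$wavelengths)
  lab <- cube_to_lab_image(vis, tab)
  thirds <- lapply(masks, split_thirds)
  profiles <- lapply(names(masks), function(id)
    mean_lab_per_third(lab, thirds[[id]], id))
  names(profiles) <- names(masks)

  list(raw = mk_cube(raw), dark = mk_cube(dark), gray = mk_cube(gray),
       truth = list(reflectance = truth_cube, masks = masks,
                    thirds = thirds, profiles = profiles, params = s))
}

#' Published per-third reference profiles
#'
#' The four maxillary-incisor profiles (30-subject means and SDs of L*, a*,
#' b* per cervical/middle/incisal third) reported for this capture
#' protocol, verbatim. They serve as a worked-example input: feeding them
#' through the analysis module reproduces the published between- and
#' within-tooth Delta E values, and they anchor regression tests without
#' raw captures (which were never deposited). `n` is the number of
#' subjects (30).
#'
#' @return Named list of four [tooth_color_profile()]s: `ULI1`, `UCI1`,
#'   `UCI2`, `ULI2`.
#' @export
table1_fixture <- function() {
  p <- function(id, cer, mid, inc) {
    third <- function(v) list(L = v[1L], a = v[2L], b = v[3L],
                              sd_L = v[4L], sd_a = v[5L], sd_b = v[6L],
                              n = 30L)
    tooth_color_profile(id, third(cer), third(mid), third(inc))
  }
  list(
    ULI1 = p("ULI1", c(68.78, 8.60, 19.36, 4.58, 1.38, 2.54),
             c(70.95, 4.79, 16.94, 4.89, 1.00, 2.89),
             c(67.01, 4.51, 12.53, 4.65, 1.07, 2.66)),
    UCI1 = p("UCI1", c(75.34, 6.84, 18.85, 5.30, 1.14, 2.83),
             c(79.02, 2.82, 16.18, 5.67, 0.77, 2.61),
             c(73.70, 2.99, 14.35, 4.64, 1.07, 2.75)),
    UCI2 = p("UCI2", c(74.70, 7.08, 18.58, 5.30, 1.34, 2.93),
             c(78.51, 3.08, 16.18, 5.58, 0.98, 3.04),
             c(73.39, 3.25, 14.42, 5.08, 1.16, 2.90)),
    ULI2 = p("ULI2", c(67.97, 8.61, 18.90, 4.90, 1.12, 2.69),
             c(70.65, 4.71, 16.86, 5.29, 1.03, 2.63),
             c(66.54, 4.59, 12.68, 5.48, 1.47, 2.68))
  )
}
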