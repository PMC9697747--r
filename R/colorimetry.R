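#' @title Reflectance to CIELAB colorimetry
#' @description Conversion of spectral reflectance to CIE XYZ and CIELAB
#'   under the CIE 1931 2-degree standard observer and the D65 daylight
#'   illuminant, plus the CIELAB (Delta E*ab) and CIEDE2000 (Delta E00)
#'   color-difference formulas and the dental perceptibility/acceptability
#'   threshold verdicts.
#' @name colorimetry
NULL

.toothshade_env <- new.env(parent = emptyenv())

# Bundled reference tabulation: CIE 1931 2-deg color-matching functions and
# the CIE D65 spectral power distribution at 10 nm steps over 380-780 nm.
.cie_reference <- function() {
  if (is.null(.toothshade_env$cie_ref)) {
    path <- system.file("extdata", "cie1931_2deg_d65_10nm.csv",
                        package = "toothshade", mustWork = TRUE)
    .toothshade_env$cie_ref <- utils::read.csv(path)
  }
  .toothshade_env$cie_ref
}

# Trapezoidal integration weights on a possibly non-uniform grid.
.trapezoid_weights <- function(wl) {
  n <- length(wl)
  if (n < 2L)
    stop("at least two wavelengths are needed for spectral integration",
         call. = FALSE)
  w <- numeric(n)
  w[1L] <- (wl[2L] - wl[1L]) / 2
  w[n] <- (wl[n] - wl[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (wl[3:n] - wl[1:(n - 2L)]) / 2
  w
}

#' Observer/illuminant integration table
#'
#' Resamples the bundled CIE 1931 2-degree color-matching functions and D65
#' spectral power distribution (tabulated at 10 nm, 380--780 nm) onto the
#' camera's band centers by piecewise-linear interpolation, and computes the
#' normalization constant \eqn{k = 100 / \sum S \bar{y} \Delta\lambda} so a
#' perfect reflector yields Y = 100 exactly. Integration weights
#' \eqn{\Delta\lambda} are trapezoidal, valid on non-equidistant grids.
#'
#' @param wavelengths Strictly increasing band centers in nm, within the
#'   tabulation hull (380--780 nm; the observer functions vanish outside the
#'   visible, so cubes are cropped to 400--780 nm first — see
#'   [crop_spectral_range()]).
#' @return Object of class `cie_table` with fields `wavelengths`, `xbar`,
#'   `ybar`, `zbar`, `S`, `weights`, `k` and `white` (XYZ of a perfect
#'   reflector).
#' @export
cie_table <- function(wavelengths) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) == 0L)
    stop("empty wavelength list", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  ref <- .cie_reference()
  xbar <- resample_spectrum(ref$wavelength_nm, ref$xbar, wavelengths)
  ybar <- resample_spectrum(ref$wavelength_nm, ref$ybar, wavelengths)
  zbar <- resample_spectrum(ref$wavelength_nm, ref$zbar, wavelengths)
  S <- resample_spectrum(ref$wavelength_nm, ref$d65, wavelengths)
  w <- .trapezoid_weights(wavelengths)
  k <- 100 / sum(S * ybar * w)
  tab <- structure(list(wavelengths = wavelengths, xbar = xbar, ybar = ybar,
                        zbar = zbar, S = S, weights = w, k = k),
                   class = "cie_table")
  tab$white <- reflectance_to_xyz(rep(1, length(wavelengths)), tab)
  tab
}

#' @export
print.cie_table <- function(x, ...) {
  cat(sprintf(
    "<cie_table> CIE 1931 2-deg observer / D65, %d bands %.1f-%.1f nm\n  white point XYZ = (%.3f, %.3f, %.3f)\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    x$white[1L], x$white[2L], x$white[3L]))
  invisible(x)
}

#' Tristimulus integration of a reflectance spectrum
#'
#' \eqn{X = k \sum R(\lambda) S(\lambda) \bar{x}(\lambda) \Delta\lambda}
#' (likewise Y, Z). Reflectance is clipped below at 0; values above 1 are
#' integrated as-is. The operation is linear in R.
#'
#' @param R Reflectance sampled on `table$wavelengths`, or a matrix
#'   `[n_spectra x n_bands]` for many spectra at once.
#' @param table A [cie_table()] built on the same wavelengths.
#' @return Numeric XYZ triple, or an `[n x 3]` matrix for matrix input.
#' @export
reflectance_to_xyz <- function(R, table) {
  stopifnot(inherits(table, "cie_table"))
  nb <- length(table$wavelengths)
  Sw <- table$S * table$weights * table$k
  M <- cbind(X = table$xbar * Sw, Y = table$ybar * Sw, Z = table$zbar * Sw)
  if (is.matrix(R)) {
    if (ncol(R) != nb)
      stop("R has ", ncol(R), " bands but the table has ", nb, call. = FALSE)
    R[R < 0] <- 0
    return(R %*% M)
  }
  if (length(R) != nb)
    stop("R has ", length(R), " samples but the table has ", nb, call. = FALSE)
  R <- pmax(as.numeric(R), 0)
  c(M[, 1L] %*% R, M[, 2L] %*% R, M[, 3L] %*% R) |>
    stats::setNames(c("X", "Y", "Z"))
}

# CIELAB rational constants: eps = (6/29)^3, kappa = (29/3)^3
.lab_eps <- 216 / 24389
.lab_kappa <- 24389 / 27

.lab_f <- function(t) {
  ifelse(t > .lab_eps, t^(1 / 3), (.lab_kappa * t + 16) / 116)
}

#' XYZ to CIELAB
#'
#' Standard CIELAB transform with the two-branch (cube-root / linear)
#' function and the 216/24389, 24389/27 rational constants. The white point
#' is the tristimulus of a perfect reflector under the same
#' observer/illuminant table, so `xyz_to_lab(table$white, table$white)` is
#' exactly (100, 0, 0).
#'
#' @param xyz XYZ triple, or an `[n x 3]` matrix.
#' @param white Reference white XYZ triple, all components > 0.
#' @return Named Lab triple `(L, a, b)`, or an `[n x 3]` matrix.
#' @export
xyz_to_lab <- function(xyz, white) {
  if (any(!is.finite(white)) || any(white <= 0))
    stop("white point components must be finite and > 0", call. = FALSE)
  if (is.matrix(xyz)) {
    if (any(!is.finite(xyz)))
      stop("non-finite tristimulus values", call. = FALSE)
    fx <- .lab_f(xyz[, 1L] / white[1L])
    fy <- .lab_f(xyz[, 2L] / white[2L])
    fz <- .lab_f(xyz[, 3L] / white[3L])
    return(cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz)))
  }
  if (any(!is.finite(xyz)))
    stop("non-finite tristimulus values", call. = FALSE)
  xyz <- as.numeric(xyz); white <- as.numeric(white)
  fx <- .lab_f(xyz[1L] / white[1L])
  fy <- .lab_f(xyz[2L] / white[2L])
  fz <- .lab_f(xyz[3L] / white[3L])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Convenience: one reflectance spectrum straight to Lab
#' @inheritParams reflectance_to_xyz
#' @export
reflectance_to_lab <- function(R, table) {
  xyz_to_lab(reflectance_to_xyz(R, table), table$white)
}

#' Dental color-difference thresholds
#'
#' 50:50% perceptibility (PT) and acceptability (AT) thresholds for color
#' difference in dentistry, per formula. Defaults: PT Delta E*ab = 1.2,
#' Delta E00 = 0.8; AT Delta E*ab = 2.7, Delta E00 = 1.8.
#'
#' @param PT_ab,PT_00,AT_ab,AT_00 Positive thresholds; PT < AT per formula.
#' @return Object of class `delta_e_thresholds`.
#' @export
delta_e_thresholds <- function(PT_ab = 1.2, PT_00 = 0.8,
                               AT_ab = 2.7, AT_00 = 1.8) {
  vals <- c(PT_ab = PT_ab, PT_00 = PT_00, AT_ab = AT_ab, AT_00 = AT_00)
  if (any(vals <= 0)) stop("thresholds must be positive", call. = FALSE)
  if (PT_ab >= AT_ab || PT_00 >= AT_00)
    stop("PT must be below AT for each formula", call. = FALSE)
  structure(as.list(vals), class = "delta_e_thresholds")
}

#' CIEDE2000 parametric factors
#' @param kL,kC,kH Strictly positive weights for the lightness, chroma and
#'   hue terms; unity is the reference condition.
#' @export
de2000_params <- function(kL = 1, kC = 1, kH = 1) {
  if (any(c(kL, kC, kH) <= 0))
    stop("parametric factors must be strictly positive", call. = FALSE)
  structure(list(kL = kL, kC = kC, kH = kH), class = "de2000_params")
}

.new_color_difference <- function(value, formula, breakdown = NULL) {
  structure(list(value = value, formula = formula, breakdown = breakdown),
            class = "color_difference")
}

#' @export
print.color_difference <- function(x, ...) {
  cat(sprintf("<color_difference> %s = %.4f\n",
              if (x$formula == "CIELAB") "dE*ab" else "dE00", x$value))
  invisible(x)
}

#' CIELAB color difference (Delta E*ab)
#'
#' Euclidean distance in (L*, a*, b*):
#' \eqn{\Delta E^*_{ab} = \sqrt{\Delta L^{*2} + \Delta a^{*2} + \Delta b^{*2}}}.
#'
#' @param c1,c2 Lab triples (numeric length 3, order L, a, b).
#' @return A `color_difference` with `formula = "CIELAB"`.
#' @export
delta_e_ab <- function(c1, c2) {
  d <- as.numeric(c1)[1:3] - as.numeric(c2)[1:3]
  .new_color_difference(sqrt(sum(d^2)), "CIELAB")
}

#' CIEDE2000 color difference (Delta E00)
#'
#' Complete CIEDE2000 procedure: chroma-dependent a* rescaling through the
#' G factor (25^7 term), C' and h' in degrees with the 0/360 conventions,
#' \eqn{\Delta H' = 2\sqrt{C'_1 C'_2}\sin(\Delta h'/2)}, weighting functions
#' SL, SC, SH, and the blue-region rotation term RT. Mean-hue branch rules
#' follow the published worked procedure; a hue difference of exactly 180
#' degrees falls under the `<= 180` rule and takes the direct arithmetic
#' mean, the documented tie-break.
#'
#' @param c1,c2 Lab triples.
#' @param params A [de2000_params()] (default kL = kC = kH = 1).
#' @return A `color_difference` with `formula = "CIEDE2000"` and a
#'   `breakdown` list (`dLp`, `dCp`, `dHp`, `SL`, `SC`, `SH`, `RT`) that
#'   recombines to `value` to machine precision.
#' @export
ciede2000 <- function(c1, c2, params = de2000_params()) {
  stopifnot(inherits(params, "de2000_params"))
  c1 <- as.numeric(c1)[1:3]; c2 <- as.numeric(c2)[1:3]
  L1 <- c1[1L]; a1 <- c1[2L]; b1 <- c1[3L]
  L2 <- c2[1L]; a2 <- c2[2L]; b2 <- c2[3L]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  hue_deg <- function(a, b) {
    if (a == 0 && b == 0) return(0)
    h <- atan2(b, a) * 180 / pi
    if (h < 0) h + 360 else h
  }
  h1p <- hue_deg(a1p, b1)
  h2p <- hue_deg(a2p, b2)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- if (C1p * C2p == 0) 0 else {
    dh <- h2p - h1p
    if (abs(dh) <= 180) dh else if (dh > 180) dh - 360 else dh + 360
  }
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * pi / 360)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hbp <- if (C1p * C2p == 0) h1p + h2p else {
    hs <- h1p + h2p
    if (abs(h1p - h2p) <= 180) hs / 2
    else if (hs < 360) (hs + 360) / 2
    else (hs - 360) / 2
  }

  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
    0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) -
    0.20 * cos((4 * hbp - 63) * pi / 180)
  dTheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dTheta * pi / 180) * RC

  tl <- dLp / (params$kL * SL)
  tc <- dCp / (params$kC * SC)
  th <- dHp / (params$kH * SH)
  value <- sqrt(tl^2 + tc^2 + th^2 + RT * tc * th)

  .new_color_difference(value, "CIEDE2000",
                        breakdown = list(dLp = dLp, dCp = dCp, dHp = dHp,
                                         SL = SL, SC = SC, SH = SH, RT = RT))
}

#' Judge a color difference against PT/AT
#'
#' Values exactly equal to a threshold classify into the higher category
#' (>= PT is perceptible, >= AT is unacceptable).
#'
#' @param d A `color_difference`, or a bare value with `formula` given.
#' @param thresholds A [delta_e_thresholds()].
#' @param formula Needed only when `d` is a bare number: `"CIELAB"` or
#'   `"CIEDE2000"`.
#' @return `"below_PT"`, `"between_PT_AT"` or `"above_AT"`.
#' @export
classify_delta_e <- function(d, thresholds = delta_e_thresholds(),
                             formula = NULL) {
  if (inherits(d, "color_difference")) {
    formula <- d$formula
    d <- d$value
  }
  if (is.null(formula))
    stop("`formula` is required for a bare Delta E value", call. = FALSE)
  formula <- match.arg(formula, c("CIELAB", "CIEDE2000"))
  PT <- if (formula == "CIELAB") thresholds$PT_ab else thresholds$PT_00
  AT <- if (formula == "CIELAB") thresholds$AT_ab else thresholds$AT_00
  if (d >= AT) "above_AT" else if (d >= PT) "between_PT_AT" else "below_PT"
}

#' Half-up rounding used for report display
#'
#' Printed values in dental colorimetry reports are conventionally rounded
#' half-up (0.005 -> 0.01), not to even; this helper applies that rule. A
#' 1e-9 guard compensates for decimal fractions that are not exactly
#' representable in binary (0.565 is stored just below its nominal value),
#' so printed halves reliably round up.
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
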