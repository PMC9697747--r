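#' @title Tooth ROI extraction
#' @description Per-pixel Lab images, tooth mask delineation, splitting of
#'   the crown into cervical/middle/incisal thirds, and per-third mean
#'   CIELAB statistics. Row 1 is the top of the image and is the
#'   cervical/gingival side (see [spectral_cube()]).
#' @name tooth_regions
NULL

#' Per-pixel CIELAB image
#'
#' Applies tristimulus integration and the CIELAB transform to every pixel
#' of a reflectance cube. Pixels flagged saturated or unstable-reference
#' carry `valid = FALSE` and are excluded from all region statistics.
#'
#' @param cube Reflectance [spectral_cube()], already cropped to the
#'   colorimetric range (the intersection of the camera bands with
#'   400--780 nm).
#' @param table A [cie_table()] built on `cube$wavelengths`.
#' @param quality Optional [pixel_quality()] from calibration/saturation.
#' @return Object of class `lab_image`: matrices `L`, `a`, `b` and logical
#'   `valid`, all `[rows x cols]`.
#' @export
cube_to_lab_image <- function(cube, table, quality = NULL) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(table, "cie_table"))
  if (cube$kind != "reflectance")
    stop("Lab conversion requires a reflectance cube", call. = FALSE)
  d <- dim(cube$data)
  if (length(table$wavelengths) != d[3L] ||
      max(abs(table$wavelengths - cube$wavelengths)) > 1e-9)
    stop("table wavelengths do not match the cube bands", call. = FALSE)
  R <- matrix(cube$data, nrow = d[1L] * d[2L], ncol = d[3L])
  lab <- xyz_to_lab(reflectance_to_xyz(R, table), table$white)
  valid <- if (is.null(quality)) matrix(TRUE, d[1L], d[2L]) else
    .quality_valid(quality)
  if (!identical(dim(valid), d[1:2]))
    stop("quality masks do not match the cube's spatial shape", call. = FALSE)
  structure(list(L = matrix(lab[, 1L], d[1L], d[2L]),
                 a = matrix(lab[, 2L], d[1L], d[2L]),
                 b = matrix(lab[, 3L], d[1L], d[2L]),
                 valid = valid),
            class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  cat(sprintf("<lab_image> %d x %d pixels, %d valid (%.1f%%)\n",
              nrow(x$L), ncol(x$L), sum(x$valid),
              100 * mean(x$valid)))
  v <- x$valid
  if (any(v))
    cat(sprintf("  L* %.1f-%.1f  a* %.1f-%.1f  b* %.1f-%.1f (valid pixels)\n",
                min(x$L[v]), max(x$L[v]), min(x$a[v]), max(x$a[v]),
                min(x$b[v]), max(x$b[v])))
  invisible(x)
}

#' Named region mask
#' @param mask Logical matrix.
#' @param label One of `"tooth"`, `"cervical"`, `"middle"`, `"incisal"`,
#'   `"background"`.
#' @export
region_mask <- function(mask, label = c("tooth", "cervical", "middle",
                                        "incisal", "background")) {
  label <- match.arg(label)
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (label != "background" && !any(mask))
    stop("empty mask for label '", label, "'", call. = FALSE)
  structure(list(mask = mask, label = label), class = "region_mask")
}

# Label 4-connected components of a logical matrix; returns integer matrix
# (0 = background). Queue-based flood fill on the linear index.
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx_all <- which(mask)
  cur <- 0L
  queue <- integer(length(idx_all))
  for (seed in idx_all) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    qh <- 1L; qt <- 1L
    queue[1L] <- seed
    lab[seed] <- cur
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                  if (cc > 1L) p - nr, if (cc < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          qt <- qt + 1L
          queue[qt] <- q
        }
      }
    }
  }
  lab
}

#' Threshold-based tooth mask
#'
#' Enamel is bright and weakly chromatic relative to gingiva and lips, so a
#' pixel joins the candidate mask iff it is valid, `L* >= min_L` and its
#' chroma \eqn{\sqrt{a^{*2}+b^{*2}}} is at most `max_ab_radius`. The largest
#' 4-connected component is retained. Externally drawn masks can be used
#' instead by skipping this operation entirely.
#'
#' @param lab A [cube_to_lab_image()] result.
#' @param min_L Lightness floor (default 45).
#' @param max_ab_radius Chroma ceiling (default 40).
#' @return A [region_mask()] labelled `"tooth"`.
#' @export
threshold_tooth_mask <- function(lab, min_L = 45, max_ab_radius = 40) {
  stopifnot(inherits(lab, "lab_image"))
  cand <- lab$valid & lab$L >= min_L &
    sqrt(lab$a^2 + lab$b^2) <= max_ab_radius
  if (!any(cand))
    stop("tooth mask is empty: no valid pixel passed the L*/chroma gates",
         call. = FALSE)
  comp <- .label_components(cand)
  sizes <- tabulate(comp[comp > 0L])
  region_mask(comp == which.max(sizes), "tooth")
}

#' Split a tooth mask into cervical/middle/incisal thirds
#'
#' The bounding rows `[r0, r1]` of the mask are divided at
#' `r0 + round(h/3)` and `r0 + round(2h/3)` with `h = r1 - r0 + 1`; the top
#' band intersected with the mask is the cervical third (row 1 is the
#' gingival side), the bottom band the incisal third. The three outputs
#' always partition the input mask.
#'
#' @param tooth A [region_mask()] (any label) with height >= 3 rows.
#' @return List of three `region_mask`s: `cervical`, `middle`, `incisal`.
#' @export
split_thirds <- function(tooth) {
  stopifnot(inherits(tooth, "region_mask"))
  m <- tooth$mask
  rows <- which(rowSums(m) > 0)
  if (length(rows) == 0L) stop("empty tooth mask", call. = FALSE)
  r0 <- min(rows); r1 <- max(rows)
  h <- r1 - r0 + 1L
  if (h < 3L)
    stop("tooth mask spans fewer than 3 rows; cannot form thirds",
         call. = FALSE)
  cut1 <- r0 + round(h / 3) - 1L       # last cervical row
  cut2 <- r0 + round(2 * h / 3) - 1L   # last middle row
  band <- function(a, b) {
    bm <- matrix(FALSE, nrow(m), ncol(m))
    bm[a:b, ] <- TRUE
    bm & m
  }
  list(cervical = region_mask(band(r0, cut1), "cervical"),
       middle = region_mask(band(cut1 + 1L, cut2), "middle"),
       incisal = region_mask(band(cut2 + 1L, r1), "incisal"))
}

.third_stats <- function(lab, mask) {
  sel <- mask & lab$valid
  n <- sum(sel)
  if (n == 0L)
    stop("a third contains no valid pixel", call. = FALSE)
  list(L = mean(lab$L[sel]), a = mean(lab$a[sel]), b = mean(lab$b[sel]),
       sd_L = stats::sd(lab$L[sel]), sd_a = stats::sd(lab$a[sel]),
       sd_b = stats::sd(lab$b[sel]), n = n)
}

#' Per-third mean CIELAB profile of one tooth
#'
#' Arithmetic mean and SD of L*, a*, b* over the valid pixels of each third.
#' Averaging is done on Lab values (not on spectra followed by conversion);
#' the two differ because the CIELAB transform is nonlinear, and the mean-Lab
#' convention matches how per-third tooth colors are reported.
#'
#' @param lab A [cube_to_lab_image()] result.
#' @param thirds Output of [split_thirds()] (list with `cervical`, `middle`,
#'   `incisal` region masks).
#' @param tooth_id Label: conventionally `"UCI1"`, `"UCI2"` (right/left
#'   upper central incisor), `"ULI1"`, `"ULI2"` (lateral), or any free text.
#' @return A [tooth_color_profile()].
#' @export
mean_lab_per_third <- function(lab, thirds, tooth_id) {
  stopifnot(inherits(lab, "lab_image"))
  st <- lapply(thirds[c("cervical", "middle", "incisal")], function(rm) {
    .third_stats(lab, rm$mask)
  })
  tooth_color_profile(tooth_id,
                      cervical = st$cervical, middle = st$middle,
                      incisal = st$incisal)
}

#' Construct a tooth color profile directly
#'
#' The unit of result: mean L*, a*, b* per cervical/middle/incisal third of
#' one tooth, with optional per-coordinate SDs and pixel/subject counts.
#' Each third may be a length-3 numeric `(L, a, b)` or a list with fields
#' `L, a, b` and optionally `sd_L, sd_a, sd_b, n`.
#'
#' @param tooth_id Tooth label.
#' @param cervical,middle,incisal Per-third colors as described.
#' @return Object of class `tooth_color_profile`.
#' @export
tooth_color_profile <- function(tooth_id, cervical, middle, incisal) {
  norm <- function(x) {
    if (is.numeric(x) && length(x) >= 3L)
      x <- list(L = x[[1L]], a = x[[2L]], b = x[[3L]])
    for (f in c("sd_L", "sd_a", "sd_b")) if (is.null(x[[f]])) x[[f]] <- NA_real_
    if (is.null(x$n)) x$n <- NA_integer_
    if (!all(is.finite(c(x$L, x$a, x$b))))
      stop("third means must be finite", call. = FALSE)
    x[c("L", "a", "b", "sd_L", "sd_a", "sd_b", "n")]
  }
  structure(list(tooth_id = as.character(tooth_id),
                 cervical = norm(cervical), middle = norm(middle),
                 incisal = norm(incisal)),
            class = "tooth_color_profile")
}

#' @export
print.tooth_color_profile <- function(x, ...) {
  cat(sprintf("<tooth_color_profile> %s\n", x$tooth_id))
  for (th in c("cervical", "middle", "incisal")) {
    s <- x[[th]]
    cat(sprintf("  %-8s L* %6.2f  a* %5.2f  b* %5.2f%s\n", th,
                s$L, s$a, s$b,
                if (is.finite(s$n)) sprintf("  (n = %d)", as.integer(s$n)) else ""))
  }
  invisible(x)
}

#' Mean Lab of one third as a numeric triple
#' @param profile A [tooth_color_profile()].
#' @param third `"cervical"`, `"middle"` or `"incisal"`.
#' @export
third_lab <- function(profile, third = c("cervical", "middle", "incisal")) {
  third <- match.arg(third)
  s <- profile[[third]]
  c(L = s$L, a = s$a, b = s$b)
}

#' Export profiles as a flat data frame / CSV
#'
#' Columns: `tooth_id, third, L, a, b, sd_L, sd_a, sd_b, n_pixels`.
#' @param profiles A `tooth_color_profile` or list of them.
#' @param path Optional CSV path; when given the frame is also written.
#' @export
profiles_to_df <- function(profiles, path = NULL) {
  if (inherits(profiles, "tooth_color_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    do.call(rbind, lapply(c("cervical", "middle", "incisal"), function(th) {
      s <- p[[th]]
      data.frame(tooth_id = p$tooth_id, third = th, L = s$L, a = s$a, b = s$b,
                 sd_L = s$sd_L, sd_a = s$sd_a, sd_b = s$sd_b,
                 n_pixels = s$n)
    }))
  }))
  rownames(rows) <- NULL
  if (!is.null(path)) utils::write.csv(rows, path, row.names = FALSE)
  rows
}
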