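wl_vis <- seq(400, 780, by = 10)
tab_vis <- cie_table(wl_vis)

test_that("a uniform perfect reflector maps to L* = 100, a* = b* = 0", {
  cube <- uniform_cube(rep(1, length(wl_vis)), wl_vis, nr = 4, nc = 5)
  lab <- cube_to_lab_image(cube, tab_vis)
  expect_equal(lab$L, matrix(100, 4, 5), tolerance = 1e-9)
  expect_equal(lab$a, matrix(0, 4, 5), tolerance = 1e-9)
  expect_equal(lab$b, matrix(0, 4, 5), tolerance = 1e-9)
  expect_true(all(lab$valid))
})

test_that("per-pixel conversion equals the scalar pipeline per spectrum", {
  set.seed(5)
  s1 <- runif(length(wl_vis), 0.2, 0.5)
  s2 <- runif(length(wl_vis), 0.5, 0.9)
  a <- array(NA_real_, dim = c(2, 4, length(wl_vis)))
  for (r in 1:2) for (cc in 1:4)
    a[r, cc, ] <- if (cc <= 2) s1 else s2
  cube <- spectral_cube(a, wl_vis, kind = "reflectance")
  lab <- cube_to_lab_image(cube, tab_vis)
  lab1 <- reflectance_to_lab(s1, tab_vis)
  lab2 <- reflectance_to_lab(s2, tab_vis)
  expect_equal(lab$L[, 1:2], matrix(lab1[1], 2, 2))
  expect_equal(lab$L[, 3:4], matrix(lab2[1], 2, 2))
  expect_equal(lab$b[1, ], c(lab1[3], lab1[3], lab2[3], lab2[3]),
               ignore_attr = TRUE)
})

test_that("quality flags propagate to valid and block downstream means", {
  cube <- uniform_cube(rep(0.5, length(wl_vis)), wl_vis, nr = 3, nc = 3)
  q <- pixel_quality(saturated = matrix(TRUE, 3, 3))
  lab <- cube_to_lab_image(cube, tab_vis, q)
  expect_false(any(lab$valid))
  m <- region_mask(matrix(TRUE, 3, 3), "tooth")
  expect_error(split_thirds(m) |> (\(th) mean_lab_per_third(lab, th, "X"))(),
               "no valid pixel")
})

test_that("split_thirds follows the bounding-row rounding rule", {
  full <- function(h) region_mask(matrix(TRUE, h, 4), "tooth")
  th9 <- split_thirds(full(9))
  expect_equal(sapply(th9, function(r) sum(rowSums(r$mask) > 0)),
               c(cervical = 3, middle = 3, incisal = 3))
  th10 <- split_thirds(full(10))
  expect_equal(sapply(th10, function(r) sum(rowSums(r$mask) > 0)),
               c(cervical = 3, middle = 4, incisal = 3))
  # brute-force check of the stated rule for h = 3..40
  for (h in 3:40) {
    th <- split_thirds(full(h))
    cut1 <- round(h / 3); cut2 <- round(2 * h / 3)
    expect_equal(unname(sapply(th, function(r) sum(rowSums(r$mask) > 0))),
                 c(cut1, cut2 - cut1, h - cut2))
  }
  expect_error(split_thirds(full(2)), "fewer than 3 rows")
})

test_that("the three thirds always partition the tooth mask", {
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(FALSE, 30, 20)
    r0 <- sample(1:10, 1); h <- sample(5:20, 1)
    for (r in r0:(r0 + h - 1)) {
      c0 <- sample(1:8, 1); w <- sample(3:12, 1)
      m[r, c0:(c0 + w - 1)] <- TRUE
    }
    th <- split_thirds(region_mask(m, "tooth"))
    u <- th$cervical$mask | th$middle$mask | th$incisal$mask
    expect_identical(u, m)
    expect_false(any(th$cervical$mask & th$middle$mask))
    expect_false(any(th$middle$mask & th$incisal$mask))
    expect_false(any(th$cervical$mask & th$incisal$mask))
  }
})

test_that("flipping the image vertically swaps cervical and incisal", {
  m <- matrix(FALSE, 12, 6)
  m[3:11, 2:5] <- TRUE
  th <- split_thirds(region_mask(m, "tooth"))
  flip <- function(x) x[nrow(x):1, , drop = FALSE]
  th_f <- split_thirds(region_mask(flip(m), "tooth"))
  expect_identical(th_f$cervical$mask, flip(th$incisal$mask))
  expect_identical(th_f$incisal$mask, flip(th$cervical$mask))
  expect_identical(th_f$middle$mask, flip(th$middle$mask))
})

test_that("threshold mask recovers a synthetic tooth with high Jaccard", {
  sc <- render_scene(reduced_scene_params(n = 96, nb = 40, seed = 3))
  prof <- recover_profiles(sc)  # exercises the full path first
  ff <- flat_field_correct(sc$raw, sc$dark, sc$gray)
  vis <- crop_spectral_range(ff$reflectance, 400, 780)
  lab <- cube_to_lab_image(vis, cie_table(vis$wavelengths), ff$quality)
  tm <- threshold_tooth_mask(lab)   # defaults min_L = 45, radius = 40
  jacc <- sapply(sc$truth$masks, function(m)
    sum(tm$mask & m$mask) / sum(tm$mask | m$mask))
  # keeps exactly the largest single tooth (a central incisor)
  expect_gte(max(jacc), 0.95)
  expect_true(names(which.max(jacc)) %in% c("UCI1", "UCI2"))

  # uniformly dark background only -> empty-mask error
  dark_lab <- cube_to_lab_image(
    uniform_cube(rep(0.02, length(wl_vis)), wl_vis), tab_vis)
  expect_error(threshold_tooth_mask(dark_lab), "empty")
})

test_that("largest 4-connected component is kept, diagonals do not join", {
  lab <- structure(list(
    L = matrix(20, 7, 7), a = matrix(0, 7, 7), b = matrix(0, 7, 7),
    valid = matrix(TRUE, 7, 7)), class = "lab_image")
  lab$L[1:2, 1:2] <- 80          # 4-pixel blob
  lab$L[4:6, 4:6] <- 80          # 9-pixel blob
  lab$L[3, 3] <- 80              # touches the 9-blob only diagonally
  tm <- threshold_tooth_mask(lab)
  expect_equal(sum(tm$mask), 9)
  expect_false(tm$mask[3, 3])
  expect_true(all(tm$mask[4:6, 4:6]))
})

test_that("per-third means honour masking semantics and pixel order", {
  lab <- structure(list(
    L = matrix(rep(c(60, 70, 80), each = 12), 9, 4, byrow = FALSE),
    a = matrix(5, 9, 4), b = matrix(15, 9, 4),
    valid = matrix(TRUE, 9, 4)), class = "lab_image")
  lab$L <- matrix(rep(c(60, 70, 80), each = 3)[rep(1:9, 4)], 9, 4)
  m <- region_mask(matrix(TRUE, 9, 4), "tooth")
  th <- split_thirds(m)
  p <- mean_lab_per_third(lab, th, "T1")
  expect_equal(p$cervical$L, 60)
  expect_equal(p$middle$L, 70)
  expect_equal(p$incisal$L, 80)
  expect_equal(p$cervical$sd_L, 0)
  expect_equal(p$cervical$n, 12)

  # invalidate half of one third: mean over remaining pixels only
  lab2 <- lab
  lab2$valid[1:3, 1:2] <- FALSE
  lab2$L[1, 1] <- 999  # must not influence anything
  p2 <- mean_lab_per_third(lab2, th, "T1")
  expect_equal(p2$cervical$L, 60)
  expect_equal(p2$cervical$n, 6)
  expect_equal(p2$middle$L, 70)
})

test_that("profile CSV export carries all columns and round-trips", {
  pf <- table1_fixture()
  path <- tempfile(fileext = ".csv")
  df <- profiles_to_df(pf, path)
  expect_equal(nrow(df), 12)
  expect_named(df, c("tooth_id", "third", "L", "a", "b",
                     "sd_L", "sd_a", "sd_b", "n_pixels"))
  back <- read.csv(path)
  expect_equal(back$L, df$L)
  expect_equal(back$third, df$third)
})
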