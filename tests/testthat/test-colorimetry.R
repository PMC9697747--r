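tab_5nm <- cie_table(seq(400, 780, by = 5))

test_that("normalization makes a perfect reflector yield Y = 100 exactly", {
  for (wl in list(seq(400, 780, by = 5), seq(420, 700, by = 10),
                  seq(400, 778, length.out = 129))) {
    tab <- cie_table(wl)
    expect_equal(unname(reflectance_to_xyz(rep(1, length(wl)), tab)[2]), 100,
                 tolerance = 1e-12)
  }
  expect_error(cie_table(numeric(0)), "empty")
})

test_that("the D65/2-degree white point sits at its nominal tristimulus", {
  # guards the bundled CMF/D65 tabulation against transcription error
  expect_equal(unname(tab_5nm$white), c(95.047, 100, 108.883),
               tolerance = 6e-3)
})

test_that("table built on the reference grid returns the bundled values", {
  ref <- read.csv(system.file("extdata", "cie1931_2deg_d65_10nm.csv",
                              package = "toothshade"))
  tab <- cie_table(ref$wavelength_nm)
  expect_equal(tab$xbar, ref$xbar)
  expect_equal(tab$ybar, ref$ybar)
  expect_equal(tab$zbar, ref$zbar)
  expect_equal(tab$S, ref$d65)
})

test_that("nested grids integrate a smooth spectrum consistently", {
  # fine-grid trapezoid integration is the oracle for the coarse grid
  spec_fun <- function(wl) 0.3 + 0.4 / (1 + exp(-(wl - 560) / 40))
  fine <- seq(400, 780, by = 1)
  coarse <- seq(400, 780, by = 10)
  Y_fine <- reflectance_to_xyz(spec_fun(fine), cie_table(fine))[2]
  Y_coarse <- reflectance_to_xyz(spec_fun(coarse), cie_table(coarse))[2]
  expect_lt(abs(Y_fine - Y_coarse), 0.2)
})

test_that("tristimulus integration is linear and clips below zero", {
  n <- length(tab_5nm$wavelengths)
  set.seed(3)
  R <- runif(n)
  expect_equal(reflectance_to_xyz(0.5 * R, tab_5nm),
               0.5 * reflectance_to_xyz(R, tab_5nm))
  expect_equal(unname(reflectance_to_xyz(rep(0, n), tab_5nm)), c(0, 0, 0))
  # negative reflectance treated as 0
  Rneg <- R; Rneg[1:5] <- -1
  Rzero <- R; Rzero[1:5] <- 0
  expect_equal(reflectance_to_xyz(Rneg, tab_5nm),
               reflectance_to_xyz(Rzero, tab_5nm))
  expect_error(reflectance_to_xyz(R[-1], tab_5nm), "bands|samples")
})

test_that("CIELAB transform hits its analytic anchor points", {
  w <- tab_5nm$white
  expect_equal(unname(xyz_to_lab(w, w)), c(100, 0, 0), tolerance = 1e-12)
  expect_equal(unname(xyz_to_lab(c(0, 0, 0), w)), c(0, 0, 0))
  # neutral half-luminance gray: L* = 116 * 0.5^(1/3) - 16, a* = b* = 0
  half <- xyz_to_lab(0.5 * w, w)
  expect_equal(unname(half), c(116 * 0.5^(1 / 3) - 16, 0, 0),
               tolerance = 1e-9)
  expect_error(xyz_to_lab(c(1, 1, 1), c(0, 100, 100)), "white")
})

test_that("delta E*ab is the Euclidean Lab distance with metric properties", {
  uci1_c <- c(75.34, 6.84, 18.85)
  uli1_c <- c(68.78, 8.60, 19.36)
  d <- delta_e_ab(uci1_c, uli1_c)
  expect_equal(round_half_up(d$value), 6.81)
  expect_equal(delta_e_ab(uli1_c, uci1_c)$value, d$value)  # symmetry
  expect_equal(delta_e_ab(uci1_c, uci1_c)$value, 0)

  set.seed(99)
  for (i in 1:50) {
    x <- c(runif(1, 0, 100), runif(2, -60, 60))
    y <- c(runif(1, 0, 100), runif(2, -60, 60))
    z <- c(runif(1, 0, 100), runif(2, -60, 60))
    t <- c(runif(1, -5, 5), runif(2, -5, 5))
    expect_gte(delta_e_ab(x, y)$value, 0)
    expect_lte(delta_e_ab(x, z)$value,
               delta_e_ab(x, y)$value + delta_e_ab(y, z)$value)
    expect_equal(delta_e_ab(x + t, y + t)$value, delta_e_ab(x, y)$value)
  }
})

test_that("ciede2000 matches the independent step-list oracle", {
  set.seed(20000)
  worst <- 0
  for (i in 1:1000) {
    x <- c(runif(1, 0, 100), runif(1, -80, 80), runif(1, -80, 80))
    y <- c(runif(1, 0, 100), runif(1, -80, 80), runif(1, -80, 80))
    got <- ciede2000(x, y)$value
    want <- ciede2000_oracle(x, y)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-6)
  # neutral axis and degenerate-chroma branches
  expect_equal(ciede2000(c(50, 0, 0), c(70, 0, 0))$value,
               ciede2000_oracle(c(50, 0, 0), c(70, 0, 0)))
  expect_equal(ciede2000(c(50, 0, 0), c(50, 3, -4))$value,
               ciede2000_oracle(c(50, 0, 0), c(50, 3, -4)))
})

test_that("ciede2000 identity, symmetry and breakdown recombination", {
  x <- c(61.3, 4.2, 17.9); y <- c(70.1, -2.5, 12.0)
  expect_equal(ciede2000(x, x)$value, 0)
  expect_equal(ciede2000(x, y)$value, ciede2000(y, x)$value)
  d <- ciede2000(x, y)
  b <- d$breakdown
  p <- de2000_params()
  recomb <- sqrt((b$dLp / (p$kL * b$SL))^2 + (b$dCp / (p$kC * b$SC))^2 +
                   (b$dHp / (p$kH * b$SH))^2 +
                   b$RT * (b$dCp / (p$kC * b$SC)) * (b$dHp / (p$kH * b$SH)))
  expect_equal(d$value, recomb, tolerance = 1e-12)
})

test_that("parametric factors damp their terms as the formula prescribes", {
  set.seed(7)
  for (i in 1:20) {
    x <- c(runif(1, 0, 100), runif(2, -60, 60))
    y <- c(runif(1, 0, 100), runif(2, -60, 60))
    base <- ciede2000(x, y)$value
    # kL enters only the pure lightness term: raising it never increases dE00
    expect_lte(ciede2000(x, y, de2000_params(kL = 2))$value, base + 1e-12)
    # scaling all three factors by s divides dE00 exactly by s
    expect_equal(ciede2000(x, y, de2000_params(2, 2, 2))$value, base / 2,
                 tolerance = 1e-12)
    # kC/kH individually are NOT monotone in general: the RT cross term can
    # grow in magnitude relative to the damped squares (blue-region pairs);
    # only the guaranteed direction is asserted for them
    expect_gte(ciede2000(x, y, de2000_params(kC = 2, kH = 2))$value,
               base / 2 - 1e-12)
  }
  expect_error(de2000_params(kL = 0), "positive")
})

test_that("neutral pairs reduce both formulas to the lightness difference", {
  expect_equal(ciede2000(c(60, 0, 0), c(60, 0, 0))$value, 0)
  expect_equal(delta_e_ab(c(60, 0, 0), c(60, 0, 0))$value, 0)
  d_ab <- delta_e_ab(c(60, 0, 0), c(74.5, 0, 0))
  expect_equal(d_ab$value, 14.5)
})

test_that("PT/AT classification uses >= at both boundaries", {
  thr <- delta_e_thresholds()
  expect_equal(classify_delta_e(0.45, thr, formula = "CIEDE2000"), "below_PT")
  expect_equal(classify_delta_e(7.42, thr, formula = "CIELAB"), "above_AT")
  expect_equal(classify_delta_e(1.2, thr, formula = "CIELAB"),
               "between_PT_AT")
  expect_equal(classify_delta_e(2.7, thr, formula = "CIELAB"), "above_AT")
  expect_equal(classify_delta_e(0.8, thr, formula = "CIEDE2000"),
               "between_PT_AT")
  expect_equal(classify_delta_e(1.8, thr, formula = "CIEDE2000"), "above_AT")
  expect_equal(classify_delta_e(delta_e_ab(c(50, 0, 0), c(50.5, 0, 0)), thr),
               "below_PT")
  expect_error(delta_e_thresholds(PT_ab = 3, AT_ab = 2), "PT must be below")
})

test_that("report rounding is half-up, not round-to-even", {
  expect_equal(round_half_up(0.565), 0.57)
  expect_equal(round_half_up(0.575), 0.58)
  expect_equal(round_half_up(-0.565), -0.57)
  expect_equal(round_half_up(2.675), 2.68)
})
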