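test_that("CIEDE2000 reproduces the published sample/reference pairs to 4 decimals", {
  p <- ciede2000_pairs()
  got <- delta_e_ciede2000(p$L1, p$a1, p$b1, p$L2, p$a2, p$b2)
  expect_equal(round(got, 4), p$de)
  # and agrees with an independently coded implementation on the same pairs
  ref <- vapply(seq_len(nrow(p)), function(i) {
    farver::compare_colour(matrix(c(p$L1[i], p$a1[i], p$b1[i]), 1),
                           matrix(c(p$L2[i], p$a2[i], p$b2[i]), 1),
                           from_space = "lab", method = "cie2000")
  }, numeric(1))
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("CIEDE2000 is zero on identical colors and symmetric in its arguments", {
  labs <- random_lab(50, seed = 11)
  expect_equal(delta_e_ciede2000(labs$L, labs$a, labs$b, labs$L, labs$a, labs$b),
               rep(0, 50))
  perm <- rev(seq_len(50))
  fwd <- delta_e_ciede2000(labs$L, labs$a, labs$b,
                           labs$L[perm], labs$a[perm], labs$b[perm])
  bwd <- delta_e_ciede2000(labs$L[perm], labs$a[perm], labs$b[perm],
                           labs$L, labs$a, labs$b)
  expect_equal(fwd, bwd, tolerance = 1e-12)
  expect_true(all(fwd >= 0))
})

test_that("CIELAB and RGB Euclidean distances match their arithmetic definitions", {
  expect_equal(delta_e_cielab(10, 0, 0, 13, 4, 0), 5) # 3-4-5 triangle
  expect_equal(delta_e_rgb(0, 0, 0, 1, 0, 0), 1)
  labs <- random_lab(40, seed = 12)
  ref <- random_lab(40, seed = 13)
  expect_equal(delta_e_cielab(labs$L, labs$a, labs$b, ref$L, ref$a, ref$b),
               sqrt((labs$L - ref$L)^2 + (labs$a - ref$a)^2 + (labs$b - ref$b)^2))
  set.seed(14)
  r1 <- runif(20); g1 <- runif(20); b1 <- runif(20)
  r2 <- runif(20); g2 <- runif(20); b2 <- runif(20)
  expect_equal(delta_e_rgb(r1, g1, b1, r2, g2, b2),
               sqrt((r1 - r2)^2 + (g1 - g2)^2 + (b1 - b2)^2))
})

test_that("component differences decompose the CIELAB distance (Pythagorean identity)", {
  labs <- random_lab(100, seed = 21)
  ref <- random_lab(100, seed = 22)
  comp <- delta_components(labs$L, labs$a, labs$b, ref$L, ref$a, ref$b)
  total <- delta_e_cielab(labs$L, labs$a, labs$b, ref$L, ref$a, ref$b)
  expect_equal(comp$dL^2 + comp$dC^2 + comp$dH^2, total^2, tolerance = 1e-9)
})

test_that("the hue-difference sign rule follows the a_R*b_E vs a_E*b_R comparison", {
  # reference on the +a axis, exposed on the +b axis, equal L and chroma
  comp <- delta_components(50, 0, 1, 50, 1, 0)
  expect_equal(comp$dC, 0)
  expect_equal(comp$dH, sqrt(2)) # a_R*b_E = 1 > a_E*b_R = 0 so s = +1
  # swapped roles flip the sign
  comp2 <- delta_components(50, 1, 0, 50, 0, 1)
  expect_equal(comp2$dH, -sqrt(2))
  # identical colors: every component zero
  comp3 <- delta_components(50, 10, -20, 50, 10, -20)
  # dH amplifies rounding through the square root; 1e-5 absorbs sqrt(eps)
  expect_true(all(abs(unlist(comp3)) < 1e-5))
})

test_that("colorimetric absorbance follows the decade definition, scales with gamma, and is additive", {
  expect_equal(absorbance_rgb(0.5, 0.5), 0)
  expect_equal(absorbance_rgb(0.05, 0.5), 1)          # one decade
  expect_equal(absorbance_rgb(0.05, 0.5, gamma = 2), 2)
  # serial attenuation: Abs(I2/I0) = Abs(I2/I1) + Abs(I1/I0)
  set.seed(31)
  I0 <- runif(25, 0.5, 1); I1 <- I0 * runif(25, 0.2, 0.9); I2 <- I1 * runif(25, 0.2, 0.9)
  expect_equal(absorbance_rgb(I2, I0),
               absorbance_rgb(I2, I1) + absorbance_rgb(I1, I0),
               tolerance = 1e-12)
  expect_error(absorbance_rgb(0.5, 0), "I0")
  expect_warning(absorbance_rgb(0, 0.5), "saturated")
})

test_that("sRGB/CIELAB conversion hits the anchors, round-trips, and matches farver", {
  white <- lab_to_rgb(100, 0, 0)
  expect_true(all(abs(unlist(white[, c("R", "G", "B")]) - 1) < 1e-3))
  black <- lab_to_rgb(0, 0, 0)
  expect_true(all(abs(unlist(black[, c("R", "G", "B")])) < 1e-6))
  set.seed(41)
  rgb <- matrix(runif(150, 0.02, 0.98), ncol = 3)
  lab <- rgb_to_lab(rgb[, 1], rgb[, 2], rgb[, 3])
  back <- lab_to_rgb(lab$L, lab$a, lab$b)
  expect_lt(max(abs(as.matrix(back[, c("R", "G", "B")]) - rgb)), 1e-6)
  expect_false(any(back$clipped))
  ref <- farver::convert_colour(rgb * 255, "rgb", "lab")
  expect_lt(max(abs(as.matrix(lab[, c("L", "a", "b")]) - ref)), 0.02)
  # far out-of-gamut colors are clipped with a warning flag
  expect_warning(oog <- lab_to_rgb(50, 120, -120), "gamut")
  expect_true(oog$clipped)
  expect_true(all(oog$R >= 0 & oog$R <= 1))
})

test_that("color tables round-trip through CSV and pair with their references", {
  tab <- tibble::tibble(
    sample_id = c("s1", "s2", "ref", "sat"),
    role = c("exposed", "exposed", "unexposed", "saturated"),
    L = c(70, 60, 85, 55), a = c(15, 25, 5, 45), b = c(40, 25, 60, 5),
    dose_mJ_cm2 = c(50, 120, NA, NA),
    device_id = "rm200qc", pci_model = "PCI1",
    illuminant_observer = "D65/10")
  path <- withr::local_tempfile(fileext = ".csv")
  write_color_table(tab, path)
  back <- read_color_table(path)
  expect_equal(back$L, tab$L)
  paired <- pair_measurements(back)
  expect_equal(nrow(paired), 2)
  expect_equal(paired$L_ref, c(85, 85))
  # mismatched illuminant/observer tags are refused
  tab2 <- tab
  tab2$illuminant_observer[1] <- "D65/2"
  expect_error(pair_measurements(tab2), "tags differ")
  # missing reference is an error
  expect_error(pair_measurements(dplyr::filter(tab, role == "exposed")),
               "unexposed")
})

test_that("color_differences computes the full metric panel consistently", {
  tab <- tibble::tibble(
    sample_id = c("s1", "ref"), role = c("exposed", "unexposed"),
    L = c(70, 85), a = c(15, 5), b = c(40, 60),
    device_id = "d", pci_model = "PCI1", illuminant_observer = "D65/10")
  out <- color_differences(pair_measurements(tab))
  expect_equal(out$de2000, delta_e_ciede2000(70, 15, 40, 85, 5, 60))
  expect_equal(out$dC_cielab, delta_e_cielab(70, 15, 40, 85, 5, 60))
  expect_equal(out$dL, -15)
  expect_true(all(c("dC_rgb", "dH", "abs_R", "abs_G", "abs_B") %in% names(out)))
})
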