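test_that("white balance inverts synthetic channel gains and is idempotent", {
  img <- gen_swatch_image(80, seed = 2, gains = c(1.2, 1.0, 0.8),
                          pixel_noise_sd = 0)
  wb <- white_balance(img)
  wreg <- region_color(wb, "white")
  expect_equal(unname(unlist(wreg[, c("R", "G", "B")])), rep(0.9, 3),
               tolerance = 1e-6)
  wb2 <- white_balance(wb)
  expect_lt(max(abs(wb2$pixels - wb$pixels)), 1e-9)
  # neutral image only changes by a global exposure scale
  neutral <- gen_swatch_image(80, seed = 2, gains = c(1, 1, 1), pixel_noise_sd = 0)
  nb <- white_balance(neutral)
  ratio <- nb$pixels / pmax(neutral$pixels, 1e-12)
  expect_lt(diff(range(ratio[neutral$pixels > 0.01])), 1e-6)
})

test_that("white balance requires a usable white region", {
  img <- gen_swatch_image(80, seed = 2, pixel_noise_sd = 0)
  dark <- img
  dark$pixels[, , 2] <- 0 # extinguish the green channel everywhere
  expect_error(white_balance(dark), "zero-mean channel")
  noreg <- img
  noreg$regions <- img$regions[img$regions$role != "white", ]
  expect_error(white_balance(noreg), "white")
})

test_that("region means match a brute-force pixel loop and are subdivision-invariant", {
  set.seed(81)
  px <- array(runif(30 * 40 * 3), c(30, 40, 3))
  regions <- tibble::tibble(
    region_name = c("whole", "left", "right"),
    role = "exposed",
    x0 = c(4, 4, 14), y0 = c(5, 5, 5), x1 = c(24, 14, 24), y1 = c(25, 25, 25))
  img <- pci_image(px, regions)
  whole <- region_color(img, "whole")
  # brute force
  manual <- colMeans(matrix(px[6:25, 5:24, ], ncol = 3))
  expect_equal(unname(unlist(whole[, c("R", "G", "B")])), manual, tolerance = 1e-12)
  # area-weighted mean of two halves equals the whole-region mean
  left <- region_color(img, "left"); right <- region_color(img, "right")
  w <- c(left$n_pixels, right$n_pixels)
  expect_equal(
    (unlist(left[, c("R", "G", "B")]) * w[1] +
     unlist(right[, c("R", "G", "B")]) * w[2]) / sum(w),
    unlist(whole[, c("R", "G", "B")]), tolerance = 1e-12)
  # uniform and half-and-half analytic cases
  px2 <- array(0.25, c(10, 10, 3))
  px2[6:10, , ] <- 0.75
  img2 <- pci_image(px2, tibble::tibble(region_name = "all", role = "exposed",
                                        x0 = 0, y0 = 0, x1 = 10, y1 = 10))
  expect_equal(region_color(img2, "all")$R, 0.5)
})

test_that("region geometry is validated against the image bounds", {
  px <- array(0.5, c(10, 10, 3))
  expect_error(pci_image(px, tibble::tibble(region_name = "r", role = "exposed",
                                            x0 = 0, y0 = 0, x1 = 11, y1 = 5)),
               "bounds")
  expect_error(pci_image(px, tibble::tibble(region_name = "r", role = "wrong",
                                            x0 = 0, y0 = 0, x1 = 5, y1 = 5)),
               "role")
  expect_error(pci_image(px * 3), "\\[0, 1\\]")
})

test_that("the device pipeline recovers the synthetic dose-response", {
  doses <- seq(0, 250, length.out = 9)
  imgs <- lapply(seq_along(doses), function(i)
    gen_swatch_image(doses[i], seed = 100 + i, gains = c(1.2, 1.0, 0.8)))
  cal <- device_dose_response(imgs)
  expect_equal(nrow(cal), 9)
  expect_lt(cal$delta_e[1], 0.5) # zero-dose image: negligible color change
  fit <- fit_calibration(cal, "first", s_delta_e = 0.1)
  # the dose-scale parameter is the generator's
  expect_lt(abs(fit$b - 80.4) / 80.4, 0.05)
  # the amplitude is the CIEDE2000 span of the generator's endpoint colors
  amp <- delta_e_ciede2000(55, 45, 5, 85, 5, 60)
  expect_lt(abs(fit$a - amp) / amp, 0.05)
  # a second device with different gains yields the same response after correction
  imgs2 <- lapply(seq_along(doses), function(i)
    gen_swatch_image(doses[i], seed = 200 + i, gains = c(0.9, 1.05, 1.15)))
  cal2 <- device_dose_response(imgs2)
  expect_equal(cal2$delta_e, cal$delta_e, tolerance = 0.05)
})

test_that("end-to-end image quantification recovers a held-out dose within 10%", {
  doses <- seq(0, 250, length.out = 9)
  imgs <- lapply(seq_along(doses), function(i)
    gen_swatch_image(doses[i], seed = 100 + i))
  fit <- fit_calibration(device_dose_response(imgs), "first", s_delta_e = 0.1)
  held_out <- 120
  img <- gen_swatch_image(held_out, seed = 777, gains = c(1.1, 1, 0.9))
  wb <- white_balance(img)
  rc <- region_color(wb, "exposed")
  ref <- region_color(wb, "unexposed")
  de <- delta_e_ciede2000(rc$L, rc$a, rc$b, ref$L, ref$a, ref$b)
  expect_lt(abs(invert_dose(fit, de) - held_out) / held_out, 0.10)
})

test_that("per-pixel dose maps are uniform for uniform swatches and bimodal under masks", {
  doses <- seq(0, 250, length.out = 9)
  imgs <- lapply(seq_along(doses), function(i)
    gen_swatch_image(doses[i], seed = 100 + i))
  fit <- fit_calibration(device_dose_response(imgs), "first", s_delta_e = 0.1)
  uni <- gen_swatch_image(90, seed = 5, pixel_noise_sd = 0.001)
  dm <- dose_image(uni, fit, region_name = "exposed")
  scalar <- invert_dose(fit, delta_e_ciede2000(
    region_color(uni, "exposed")$L, region_color(uni, "exposed")$a,
    region_color(uni, "exposed")$b, region_color(uni, "unexposed")$L,
    region_color(uni, "unexposed")$a, region_color(uni, "unexposed")$b))
  expect_lt(abs(median(dm$dose, na.rm = TRUE) - scalar) / scalar, 0.05)
  expect_lt(mean(dm$saturated), 0.01)
  # mask: two modes near the two generating doses
  masked <- gen_swatch_image(60, seed = 6, mask_dose = 180, pixel_noise_sd = 0.001)
  lo <- dose_image(masked, fit, region_name = "exposed")
  hi <- dose_image(masked, fit, region_name = "masked")
  expect_lt(abs(median(lo$dose, na.rm = TRUE) - 60) / 60, 0.10)
  expect_lt(abs(median(hi$dose, na.rm = TRUE) - 180) / 180, 0.10)
  # all-unexposed image maps to ~zero dose
  zero <- gen_swatch_image(0, seed = 8, pixel_noise_sd = 0)
  z <- dose_image(zero, fit, region_name = "exposed")
  expect_lt(max(z$dose, na.rm = TRUE), 2)
  # saturated pixels are flagged, not clipped
  small <- fit; small$a <- 20 # artificial low asymptote
  sat <- dose_image(gen_swatch_image(250, seed = 9, pixel_noise_sd = 0), small,
                    region_name = "exposed")
  expect_true(all(sat$saturated))
  expect_true(all(is.na(sat$dose)))
})

test_that("images and dose maps round-trip through PNG/TIFF and annotation CSVs", {
  img <- gen_swatch_image(100, seed = 4, pixel_noise_sd = 0)
  png_path <- withr::local_tempfile(fileext = ".png")
  ann_path <- withr::local_tempfile(fileext = ".csv")
  png::writePNG(img$pixels, png_path)
  readr::write_csv(dplyr::mutate(img$regions, image = basename(png_path)), ann_path)
  back <- read_pci_image(png_path, regions = ann_path, device_id = "test")
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 255) # 8-bit quantization
  expect_equal(nrow(back$regions), nrow(img$regions))
  doses <- seq(0, 250, length.out = 9)
  fit <- fit_calibration(device_dose_response(
    lapply(seq_along(doses), function(i) gen_swatch_image(doses[i], seed = 100 + i))),
    "first", s_delta_e = 0.1)
  dm <- dose_image(img, fit, region_name = "exposed")
  tif <- withr::local_tempfile(fileext = ".tif")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_dose_map(dm, tif, csv)
  expect_true(file.exists(tif))
  smry <- readr::read_csv(csv, show_col_types = FALSE)
  expect_true("saturated_fraction" %in% smry$stat)
})
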