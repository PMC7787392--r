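# Run code under a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic calibration dataset with known ground truth
#'
#' Color differences follow the chosen kinetic curve with additive Gaussian
#' noise, truncated at zero. Defaults emulate a PCI1-like experiment: doses
#' spanning 0-250 mJ/cm^2 (the tested design envelope), triplicate
#' measurements, first-order response with `a = 47.1`, `b = 80.4` and noise
#' SD 0.273 (the replicate measurement SD of the CIEDE2000 metric).
#'
#' @param seed Integer RNG seed (fixed seed gives identical output).
#' @param kinetics `"first"` or `"second"`.
#' @param a_true,b_true Generating parameters.
#' @param noise_sd Gaussian dE noise SD (`>= 0`).
#' @param doses Dose levels, mJ/cm^2.
#' @param replicates Measurements per dose level.
#' @return A tibble with `dose_mJ_cm2`, `delta_e`, `replicate` and the
#'   generating truth stored in attribute `truth`.
#' @export
gen_calibration_dataset <- function(seed = 1, kinetics = c("first", "second"),
                                    a_true = 47.1, b_true = 80.4,
                                    noise_sd = 0.273,
                                    doses = seq(0, 250, length.out = 8),
                                    replicates = 3) {
  kinetics <- match.arg(kinetics)
  stopifnot(noise_sd >= 0, replicates >= 1, all(doses >= 0))
  d <- rep(doses, each = replicates)
  mu <- kinetic_delta_e(d, a_true, b_true, kinetics)
  de <- .with_seed(seed, pmax(0, mu + rnorm(length(d), 0, noise_sd)))
  out <- tibble(dose_mJ_cm2 = d, delta_e = de,
                replicate = rep(seq_len(replicates), times = length(doses)))
  attr(out, "truth") <- list(kinetics = kinetics, a = a_true, b = b_true,
                             noise_sd = noise_sd, seed = seed)
  out
}

# Lab color at a given reaction extent between the two endpoint colors.
.extent_lab <- function(extent, unexposed, saturated) {
  cbind(L = unexposed[1] + extent * (saturated[1] - unexposed[1]),
        a = unexposed[2] + extent * (saturated[2] - unexposed[2]),
        b = unexposed[3] + extent * (saturated[3] - unexposed[3]))
}

#' Generate a synthetic PCI swatch image
#'
#' Renders side-by-side patches: the exposed swatch at the reaction extent
#' implied by the dose (`1 - exp(-dose/b)` for first-order kinetics), an
#' unexposed patch, a saturated patch, and a neutral white patch, with
#' optional per-pixel Gaussian noise and optional channel gains emulating an
#' uncorrected device. An optional mask renders the right half of the
#' exposed swatch at a second dose (emulating shadowed exposure). Colors
#' interpolate in CIELAB between a yellow unexposed endpoint and a pink
#' saturated endpoint. Because CIEDE2000 is nonlinear, color differences
#' computed from these interpolated colors follow the generating kinetics
#' only approximately; for strict kinetic ground truth use
#' [gen_calibration_dataset()] (exact-dE mode).
#'
#' @param dose Exposure dose, mJ/cm^2.
#' @param seed Integer RNG seed.
#' @param b_true First-order dose-scale parameter of the simulated chemistry.
#' @param unexposed,saturated Endpoint CIELAB colors (length-3 vectors).
#' @param patch_px Patch side length in pixels.
#' @param pixel_noise_sd Per-pixel Gaussian RGB noise SD.
#' @param gains Length-3 channel gains emulating device white-balance error.
#' @param mask_dose Optional second dose for the masked right half of the
#'   exposed swatch.
#' @param device_id Device label stored on the image.
#' @return An annotated `pci_image` with regions `exposed` (carrying its
#'   `dose_mJ_cm2`), `unexposed`, `saturated` and `white` (and `masked` when
#'   `mask_dose` is given).
#' @export
gen_swatch_image <- function(dose, seed = 1, b_true = 80.4,
                             unexposed = c(85, 5, 60), saturated = c(55, 45, 5),
                             patch_px = 24, pixel_noise_sd = 0.002,
                             gains = c(1, 1, 1), mask_dose = NULL,
                             device_id = "synthetic") {
  stopifnot(dose >= 0, patch_px >= 4, all(gains > 0))
  extent <- 1 - exp(-dose / b_true)
  labs <- rbind(.extent_lab(extent, unexposed, saturated),
                .extent_lab(0, unexposed, saturated),
                .extent_lab(1, unexposed, saturated))
  rgbs <- lab_to_rgb(labs[, 1], labs[, 2], labs[, 3], encoding = "linear")
  patch_cols <- rbind(as.matrix(rgbs[, c("R", "G", "B")]), c(0.92, 0.92, 0.92))
  h <- patch_px; w <- 4 * patch_px
  px <- array(0, c(h, w, 3))
  for (k in 1:4) {
    cols <- (k - 1) * patch_px + seq_len(patch_px)
    for (ch in 1:3) px[, cols, ch] <- patch_cols[k, ch]
  }
  regions <- tibble(
    region_name = c("exposed", "unexposed", "saturated", "white"),
    role = c("exposed", "unexposed", "saturated", "white"),
    x0 = (0:3) * patch_px + 2, y0 = 2,
    x1 = (1:4) * patch_px - 2, y1 = h - 2,
    dose_mJ_cm2 = c(dose, NA, NA, NA)
  )
  if (!is.null(mask_dose)) {
    ext_m <- 1 - exp(-mask_dose / b_true)
    lab_m <- .extent_lab(ext_m, unexposed, saturated)
    rgb_m <- lab_to_rgb(lab_m[1], lab_m[2], lab_m[3], encoding = "linear")
    cols <- seq.int(patch_px %/% 2 + 1, patch_px)
    for (ch in 1:3) px[, cols, ch] <- c(rgb_m$R, rgb_m$G, rgb_m$B)[ch]
    regions$x1[regions$region_name == "exposed"] <- patch_px %/% 2 - 1
    regions <- dplyr::bind_rows(regions, tibble(
      region_name = "masked", role = "exposed",
      x0 = patch_px %/% 2 + 2, y0 = 2, x1 = patch_px - 2, y1 = h - 2,
      dose_mJ_cm2 = mask_dose))
  }
  px <- sweep(px, 3, gains, `*`)
  if (pixel_noise_sd > 0) {
    px <- .with_seed(seed, px + array(rnorm(length(px), 0, pixel_noise_sd), dim(px)))
  }
  px <- pmin(pmax(px, 0), 1)
  pci_image(px, regions, device_id = device_id, encoding = "linear")
}

#' Generate a synthetic lamp irradiance log
#'
#' Exponential warm-up toward `I_max` with time constant `tau_rise`, an
#' optional linear output degradation, Gaussian measurement noise, and an
#' optional terminal shutoff (irradiance collapsing to near zero).
#'
#' @param I_max Plateau irradiance, mW/cm^2.
#' @param tau_rise Warm-up time constant, s (the 10-90% rise time of a pure
#'   exponential is `tau * log(9)`).
#' @param decay_slope Linear output drift, mW/cm^2 per s (typically `<= 0`).
#' @param duration Logged exposure length, s.
#' @param dt Sampling interval, s.
#' @param noise_sd Gaussian irradiance noise SD, mW/cm^2.
#' @param seed Integer RNG seed.
#' @param shutoff Append post-shutoff samples at ~0 irradiance.
#' @return An `irradiance_log` tibble.
#' @export
gen_irradiance_log <- function(I_max = 17, tau_rise = 30, decay_slope = 0,
                               duration = 600, dt = 1, noise_sd = 0,
                               seed = 1, shutoff = TRUE) {
  stopifnot(I_max > 0, tau_rise > 0, duration > 3 * dt, dt > 0, noise_sd >= 0)
  t <- seq(0, duration, by = dt)
  irr <- I_max * (1 - exp(-t / tau_rise)) + decay_slope * t
  irr <- pmax(irr, 0)
  if (noise_sd > 0) {
    irr <- .with_seed(seed, pmax(0, irr + rnorm(length(irr), 0, noise_sd)))
  }
  if (shutoff) {
    t <- c(t, max(t) + dt * (1:3))
    irr <- c(irr, rep(0.001 * I_max, 3))
  }
  as_irradiance_log(tibble(time_s = t, irradiance_mW_cm2 = irr))
}

#' Generate a synthetic treatment-plane dose field
#'
#' Radially symmetric falloff from the plane center: the bounding-box
#' corners receive exactly `corner_fraction` of the center dose (default
#' 0.4, a typical corner-to-center nonuniformity for a multi-bulb
#' enclosure). Replicates get multiplicative Gaussian scatter.
#'
#' @param center_dose Dose at the plane center, mJ/cm^2.
#' @param corner_fraction Corner dose as a fraction of the center dose, in
#'   `(0, 1]`.
#' @param nx,ny Grid points along x and y.
#' @param spacing_mm Grid spacing (default 63.5 mm).
#' @param replicates Replicate measurements per location.
#' @param rep_cv Coefficient of variation of replicate scatter.
#' @param u_frac Per-measurement calibration uncertainty as a fraction of
#'   the dose.
#' @param seed Integer RNG seed.
#' @return A dose-map tibble (the [read_dose_map_csv()] dialect) with the
#'   generating truth in attribute `truth`.
#' @export
gen_spatial_field <- function(center_dose = 1000, corner_fraction = 0.4,
                              nx = 5, ny = 7, spacing_mm = 63.5,
                              replicates = 3, rep_cv = 0.02, u_frac = 0.03,
                              seed = 1) {
  stopifnot(center_dose > 0, corner_fraction > 0, corner_fraction <= 1,
            nx >= 2, ny >= 2, replicates >= 1)
  g <- tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(ny))
  g$x_mm <- (g$ix - 1) * spacing_mm
  g$y_mm <- (g$iy - 1) * spacing_mm
  cx <- mean(range(g$x_mm)); cy <- mean(range(g$y_mm))
  r2 <- (g$x_mm - cx)^2 + (g$y_mm - cy)^2
  dose_true <- center_dose * (1 - (1 - corner_fraction) * r2 / max(r2))
  g$label <- sprintf("r%dc%d", g$iy, g$ix)
  out <- tidyr::expand_grid(i = seq_len(nrow(g)), replicate = seq_len(replicates))
  out <- dplyr::bind_cols(g[out$i, c("label", "x_mm", "y_mm")],
                          tibble(replicate = out$replicate,
                                 dose_true = dose_true[out$i]))
  scatter <- if (rep_cv > 0) {
    .with_seed(seed, rnorm(nrow(out), 1, rep_cv))
  } else rep(1, nrow(out))
  out$surface <- "plane"
  out$dose_mJ_cm2 <- out$dose_true * scatter
  out$u_dose <- u_frac * out$dose_mJ_cm2
  res <- dplyr::select(out, "label", "x_mm", "y_mm", "surface", "replicate",
                       "dose_mJ_cm2", "u_dose")
  attr(res, "truth") <- list(center_dose = center_dose,
                             corner_fraction = corner_fraction,
                             dose_true = setNames(dose_true, g$label),
                             seed = seed)
  res
}
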