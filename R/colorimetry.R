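#' @keywords internal
"_PACKAGE"

#' @import rlang
#' @importFrom dplyr mutate filter select left_join arrange across group_by
#'   summarise ungroup bind_rows rename n row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats coef lm median nls qnorm qt quantile rnorm sd setNames
#'   var vcov
NULL

# sRGB (IEC 61966-2-1) <-> CIE XYZ, D65 white
.srgb_to_xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)
.xyz_to_srgb <- solve(.srgb_to_xyz)
.d65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

.srgb_encode <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * pmax(x, 0)^(1 / 2.4) - 0.055)
}

.srgb_decode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_f_inv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' Convert CIELAB colors to sRGB
#'
#' Standard CIELAB -> sRGB conversion under the D65 white point. Out-of-gamut
#' results are clipped to `[0, 1]` and flagged rather than silently wrapped.
#'
#' @param L,a,b Numeric vectors of CIELAB coordinates (`L` in 0--100).
#' @param encoding `"gamma"` (default) returns gamma-encoded sRGB as consumer
#'   imaging devices store it; `"linear"` returns linear-light channel values.
#' @return A tibble with columns `R`, `G`, `B` (each in `[0, 1]`), `encoding`,
#'   and a logical `clipped` column marking out-of-gamut inputs.
#' @examples
#' lab_to_rgb(100, 0, 0) # white
#' lab_to_rgb(c(85, 55), c(5, 45), c(60, 5)) # yellow and pink PCI endpoints
#' @export
lab_to_rgb <- function(L, a, b, encoding = c("gamma", "linear")) {
  encoding <- match.arg(encoding)
  stopifnot(length(a) == length(L), length(b) == length(L))
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  xyz <- cbind(.lab_f_inv(fx) * .d65["X"],
               .lab_f_inv(fy) * .d65["Y"],
               .lab_f_inv(fz) * .d65["Z"])
  lin <- xyz %*% t(.xyz_to_srgb)
  clipped <- apply(lin < -1e-6 | lin > 1 + 1e-6, 1, any)
  lin <- pmin(pmax(lin, 0), 1)
  out <- if (encoding == "gamma") .srgb_encode(lin) else lin
  if (any(clipped)) {
    warn(sprintf("%d color(s) out of the sRGB gamut were clipped to [0, 1]",
                 sum(clipped)))
  }
  tibble(R = out[, 1], G = out[, 2], B = out[, 3],
         encoding = encoding, clipped = as.vector(clipped))
}

#' Convert sRGB colors to CIELAB
#'
#' @param R,G,B Numeric vectors of channel intensities in `[0, 1]`.
#' @param encoding Encoding of the input: `"gamma"` (default, standard sRGB)
#'   or `"linear"`. Gamma-encoded inputs are linearized with the sRGB transfer
#'   function before the matrix transform.
#' @return A tibble with columns `L`, `a`, `b` and the `illuminant_observer`
#'   tag `"D65/2"` of the sRGB standard.
#' @examples
#' rgb_to_lab(1, 1, 1) # L = 100
#' @export
rgb_to_lab <- function(R, G, B, encoding = c("gamma", "linear")) {
  encoding <- match.arg(encoding)
  stopifnot(length(G) == length(R), length(B) == length(R))
  if (any(c(R, G, B) < -1e-9 | c(R, G, B) > 1 + 1e-9)) {
    abort("RGB channel values must lie in [0, 1]; rescale integer images by their bit depth first")
  }
  chan <- cbind(R, G, B)
  lin <- if (encoding == "gamma") .srgb_decode(chan) else chan
  xyz <- lin %*% t(.srgb_to_xyz)
  fx <- .lab_f(xyz[, 1] / .d65["X"])
  fy <- .lab_f(xyz[, 2] / .d65["Y"])
  fz <- .lab_f(xyz[, 3] / .d65["Z"])
  tibble(L = unname(116 * fy - 16), a = unname(500 * (fx - fy)),
         b = unname(200 * (fy - fz)), illuminant_observer = "D65/2")
}

.check_tags <- function(tag_sample, tag_reference) {
  if (is.null(tag_sample) || is.null(tag_reference)) return(invisible(TRUE))
  if (any(tag_sample != tag_reference)) {
    abort(paste0(
      "sample and reference illuminant/observer tags differ (",
      paste(unique(tag_sample), collapse = ","), " vs ",
      paste(unique(tag_reference), collapse = ","),
      "); color differences across conditions are refused, not adapted"))
  }
  invisible(TRUE)
}

#' CIEDE2000 color difference
#'
#' Full CIEDE2000 formula with lightness, chroma and hue weighting functions
#' and the blue-region rotation term. Parametric factors default to
#' `kL = kC = kH = 1`.
#'
#' @param L1,a1,b1 Sample (exposed) CIELAB coordinates, vectorized.
#' @param L2,a2,b2 Reference CIELAB coordinates.
#' @param kL,kC,kH Parametric weighting factors (default 1).
#' @return Numeric vector of non-negative CIEDE2000 differences. The formula
#'   is symmetric in its two arguments.
#' @examples
#' delta_e_ciede2000(50, 2.6772, -79.7751, 50, 0, -82.7485) # 2.0425
#' @export
delta_e_ciede2000 <- function(L1, a1, b1, L2, a2, b2, kL = 1, kC = 1, kH = 1) {
  n <- max(length(L1), length(L2))
  L1 <- rep_len(L1, n); a1 <- rep_len(a1, n); b1 <- rep_len(b1, n)
  L2 <- rep_len(L2, n); a2 <- rep_len(a2, n); b2 <- rep_len(b2, n)

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) * 180 / pi) %% 360)
  h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) * 180 / pi) %% 360)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
         ifelse(abs(dh) <= 180, dh,
         ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(abs(h1p - h2p) <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  Tw <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
            0.24 * cos(2 * hbp * pi / 180) +
            0.32 * cos((3 * hbp + 6) * pi / 180) -
            0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tw
  RT <- -sin(2 * dtheta * pi / 180) * RC

  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
         RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}

#' CIELAB 1976 Euclidean color difference
#'
#' @inheritParams delta_e_ciede2000
#' @return Non-negative Euclidean distance over (dL, da, db).
#' @export
delta_e_cielab <- function(L1, a1, b1, L2, a2, b2) {
  sqrt((L1 - L2)^2 + (a1 - a2)^2 + (b1 - b2)^2)
}

#' Euclidean RGB color difference
#'
#' @param R1,G1,B1 Sample channel intensities in `[0, 1]`.
#' @param R2,G2,B2 Reference channel intensities.
#' @export
delta_e_rgb <- function(R1, G1, B1, R2, G2, B2) {
  sqrt((R1 - R2)^2 + (G1 - G2)^2 + (B1 - B2)^2)
}

#' Component color differences between exposed and reference colors
#'
#' Signed per-component differences: lightness `dL = L_E - L_R`, chroma
#' `dC = C_E - C_R` with `C = sqrt(a^2 + b^2)`, the CIE 1976 metric hue
#' difference `dH = s * sqrt(2 * (C_E C_R - a_E a_R - b_E b_R))` with sign
#' `s = +1` if `a_R b_E > a_E b_R` else `-1`, and the RGB channel differences
#' `dR`, `dG`, `dB` after conversion through sRGB. The hue radicand is clamped
#' at zero before the square root to absorb floating-point negatives.
#'
#' @param L1,a1,b1 Exposed (sample) CIELAB coordinates.
#' @param L2,a2,b2 Unexposed (reference) CIELAB coordinates.
#' @return A tibble with columns `dL`, `dC`, `dH`, `dR`, `dG`, `dB`.
#' @details The decomposition satisfies `dL^2 + dC^2 + dH^2 = dE_CIELAB^2`.
#' @export
delta_components <- function(L1, a1, b1, L2, a2, b2) {
  CE <- sqrt(a1^2 + b1^2)
  CR <- sqrt(a2^2 + b2^2)
  s <- ifelse(a2 * b1 > a1 * b2, 1, -1)
  dH <- s * sqrt(pmax(0, 2 * (CE * CR - a1 * a2 - b1 * b2)))
  rgb1 <- lab_to_rgb(L1, a1, b1)
  rgb2 <- lab_to_rgb(L2, a2, b2)
  tibble(dL = L1 - L2, dC = CE - CR, dH = dH,
         dR = rgb1$R - rgb2$R, dG = rgb1$G - rgb2$G, dB = rgb1$B - rgb2$B)
}

#' Colorimetric absorbance per RGB channel
#'
#' `Abs = -gamma * log10(I / I0)` for each channel, with the exposed
#' intensity `I` against the unexposed reference `I0`.
#'
#' @param I Exposed channel intensity (vectorized), in `[0, 1]`.
#' @param I0 Unexposed reference intensity, strictly positive.
#' @param gamma Device gamma correction factor (default 1).
#' @return Numeric absorbance vector; `Inf` (with a warning) where the
#'   exposed channel is fully extinguished.
#' @export
absorbance_rgb <- function(I, I0, gamma = 1) {
  stopifnot(gamma > 0)
  if (any(I0 <= 0)) abort("reference channel intensity I0 must be > 0")
  if (any(I < 0)) abort("exposed channel intensity must be >= 0")
  if (any(I == 0)) warn("zero exposed intensity: absorbance is infinite (saturated channel)")
  -gamma * log10(I / I0)
}

#' Read a PCI color table from CSV
#'
#' Expected columns: `sample_id`, `role` (one of `exposed`, `unexposed`,
#' `saturated`), `L`, `a`, `b`, and optionally `dose_mJ_cm2`, `device_id`,
#' `pci_model`, `illuminant_observer`.
#'
#' @param path CSV file path.
#' @return A tibble, one row per color reading.
#' @export
read_color_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "role", "L", "a", "b")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste("color table is missing column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(df$role), c("exposed", "unexposed", "saturated"))
  if (length(bad)) abort(paste("unknown role(s):", paste(bad, collapse = ", ")))
  if (any(df$L < 0 | df$L > 100)) abort("L* must lie in [0, 100]")
  if (!"illuminant_observer" %in% names(df)) df$illuminant_observer <- "D65/10"
  as_tibble(df)
}

#' Write a PCI color table to CSV
#'
#' @param df Color table tibble (see [read_color_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_color_table <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' Pair exposed readings with their unexposed reference
#'
#' Joins each `exposed` row of a color table to the `unexposed` reference with
#' matching `device_id` and `pci_model` (the shared-reference dialect used by
#' flatbed scans; per-sample references can be expressed by giving each pair
#' its own `device_id`). Refuses mixed illuminant/observer tags.
#'
#' @param df Color table tibble.
#' @return A tibble with one row per exposed reading and reference coordinates
#'   in `L_ref`, `a_ref`, `b_ref`.
#' @export
pair_measurements <- function(df) {
  keys <- intersect(c("device_id", "pci_model"), names(df))
  exposed <- dplyr::filter(df, .data$role == "exposed")
  refs <- df |>
    dplyr::filter(.data$role == "unexposed") |>
    dplyr::select(dplyr::all_of(keys), L_ref = "L", a_ref = "a", b_ref = "b",
                  ref_tag = "illuminant_observer")
  if (nrow(refs) == 0) abort("no unexposed reference rows present")
  if (length(keys)) {
    dup <- refs |> dplyr::count(dplyr::across(dplyr::all_of(keys))) |> dplyr::filter(n > 1)
    if (nrow(dup)) abort("multiple unexposed references for the same device/model; disambiguate with device_id")
    out <- dplyr::left_join(exposed, refs, by = keys)
  } else {
    if (nrow(refs) > 1) abort("multiple unexposed references but no device_id/pci_model keys to join on")
    out <- dplyr::bind_cols(exposed, refs)
  }
  if (any(is.na(out$L_ref))) abort("some exposed readings have no matching unexposed reference")
  .check_tags(out$illuminant_observer, out$ref_tag)
  dplyr::select(out, -"ref_tag")
}

#' Compute the full panel of color-difference metrics for paired readings
#'
#' For each exposed/reference pair computes CIEDE2000, the CIELAB 1976 and
#' RGB Euclidean distances, the signed component differences (dL, dC, dH, dR,
#' dG, dB) and the three colorimetric absorbances.
#'
#' @param pairs Output of [pair_measurements()] (columns `L`, `a`, `b`,
#'   `L_ref`, `a_ref`, `b_ref`).
#' @param gamma Gamma factor for the absorbance metrics (default 1).
#' @return The input tibble with one column per metric appended:
#'   `de2000`, `dC_cielab`, `dC_rgb`, `dL`, `dC`, `dH`, `dR`, `dG`, `dB`,
#'   `abs_R`, `abs_G`, `abs_B`.
#' @export
color_differences <- function(pairs, gamma = 1) {
  need <- c("L", "a", "b", "L_ref", "a_ref", "b_ref")
  if (!all(need %in% names(pairs))) {
    abort("pairs must carry L, a, b and L_ref, a_ref, b_ref columns; see pair_measurements()")
  }
  comp <- delta_components(pairs$L, pairs$a, pairs$b,
                           pairs$L_ref, pairs$a_ref, pairs$b_ref)
  rgbE <- lab_to_rgb(pairs$L, pairs$a, pairs$b)
  rgbR <- lab_to_rgb(pairs$L_ref, pairs$a_ref, pairs$b_ref)
  dplyr::bind_cols(
    pairs,
    tibble(
      de2000 = delta_e_ciede2000(pairs$L, pairs$a, pairs$b,
                                 pairs$L_ref, pairs$a_ref, pairs$b_ref),
      dC_cielab = delta_e_cielab(pairs$L, pairs$a, pairs$b,
                                 pairs$L_ref, pairs$a_ref, pairs$b_ref),
      dC_rgb = delta_e_rgb(rgbE$R, rgbE$G, rgbE$B, rgbR$R, rgbR$G, rgbR$B)
    ),
    comp,
    tibble(
      abs_R = absorbance_rgb(rgbE$R, rgbR$R, gamma),
      abs_G = absorbance_rgb(rgbE$G, rgbR$G, gamma),
      abs_B = absorbance_rgb(rgbE$B, rgbR$B, gamma)
    )
  )
}
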