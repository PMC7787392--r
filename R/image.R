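#' Construct an annotated PCI image
#'
#' Wraps an H x W x 3 pixel array (channel intensities in `[0, 1]`) together
#' with named rectangular regions of interest. Gamma-encoded pixels are
#' linearized with the sRGB transfer function on construction so that all
#' region averaging happens in linear light.
#'
#' Region geometry: axis-aligned rectangles in 0-based pixel coordinates with
#' half-open intervals `[x0, x1) x [y0, y1)`; `x` runs along columns, `y`
#' along rows from the top.
#'
#' @param pixels Numeric H x W x 3 array, values in `[0, 1]`.
#' @param regions Optional tibble with columns `region_name`,
#'   `role` (one of exposed, unexposed, saturated, white, pantone), `x0`,
#'   `y0`, `x1`, `y1`, and optionally `dose_mJ_cm2` for exposed regions.
#' @param device_id Device label.
#' @param encoding `"linear"` (default) or `"gamma"` for sRGB-encoded input.
#' @param bit_depth Source bit depth (informational).
#' @return A `pci_image` object (pixels stored linear).
#' @export
pci_image <- function(pixels, regions = NULL, device_id = "",
                      encoding = c("linear", "gamma"), bit_depth = NA_integer_) {
  encoding <- match.arg(encoding)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    abort("pixel values must lie in [0, 1]; scale integer images by their bit depth")
  }
  if (encoding == "gamma") pixels[] <- .srgb_decode(pixels)
  if (!is.null(regions)) {
    regions <- as_tibble(regions)
    need <- c("region_name", "role", "x0", "y0", "x1", "y1")
    if (!all(need %in% names(regions))) {
      abort(paste("regions must have columns:", paste(need, collapse = ", ")))
    }
    bad_role <- setdiff(unique(regions$role),
                        c("exposed", "unexposed", "saturated", "white", "pantone"))
    if (length(bad_role)) abort(paste("unknown region role(s):", paste(bad_role, collapse = ", ")))
    h <- dim(pixels)[1]; w <- dim(pixels)[2]
    ok <- regions$x0 >= 0 & regions$y0 >= 0 & regions$x1 <= w & regions$y1 <= h &
      regions$x1 > regions$x0 & regions$y1 > regions$y0
    if (!all(ok)) abort("region rectangles must be non-empty and lie within image bounds")
  }
  structure(list(pixels = pixels, regions = regions, device_id = device_id,
                 bit_depth = bit_depth), class = "pci_image")
}

#' @export
print.pci_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("PCI image %dx%d px, device '%s', %d region(s)\n",
              d[2], d[1], x$device_id,
              if (is.null(x$regions)) 0L else nrow(x$regions)))
  invisible(x)
}

#' Read a PCI image from TIFF or PNG
#'
#' @param path Image file (`.tif`/`.tiff` or `.png`); values are scaled to
#'   `[0, 1]` by the readers.
#' @param regions Optional region tibble or path to an annotation CSV (see
#'   [read_region_annotations()]); if the CSV covers several images, rows are
#'   filtered to `basename(path)` via the `image` column.
#' @inheritParams pci_image
#' @return A `pci_image`.
#' @export
read_pci_image <- function(path, regions = NULL, device_id = "",
                           encoding = c("linear", "gamma")) {
  if (!file.exists(path)) abort(paste("image file not found:", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(paste("unsupported image format:", ext)))
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3] # drop alpha
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3)) # grayscale
  if (is.character(regions)) {
    regions <- read_region_annotations(regions)
    if ("image" %in% names(regions)) {
      regions <- dplyr::filter(regions, .data$image == basename(path))
    }
  }
  pci_image(px, regions, device_id, encoding)
}

#' Read region annotations from CSV
#'
#' Columns: `image`, `region_name`, `role`, `x0`, `y0`, `x1`, `y1`, and
#' optionally `dose_mJ_cm2`. Coordinates are 0-based, half-open.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_region_annotations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

.region_pixels <- function(image, region) {
  image$pixels[(region$y0 + 1):region$y1, (region$x0 + 1):region$x1, , drop = FALSE]
}

#' White-balance and exposure-correct a PCI image
#'
#' Divides each channel by the mean of the `white` region and rescales so
#' the white region maps to a neutral gray target (default 0.9 per channel,
#' preserving highlight headroom). Output is clipped to `[0, 1]`; the clipped
#' pixel fraction is attached as attribute `clip_fraction`. The operation is
#' idempotent for images whose corrected values stay in gamut.
#'
#' @param image A `pci_image` with a `white` region.
#' @param target Neutral target value for the white region (default 0.9).
#' @return The corrected `pci_image`.
#' @export
white_balance <- function(image, target = 0.9) {
  stopifnot(inherits(image, "pci_image"))
  if (is.null(image$regions) || !"white" %in% image$regions$role) {
    abort("white balance requested but the image has no 'white' region")
  }
  wreg <- image$regions[image$regions$role == "white", ][1, ]
  wpx <- .region_pixels(image, wreg)
  wmean <- apply(wpx, 3, mean)
  if (any(wmean <= 0)) abort("white region has a zero-mean channel; cannot white-balance")
  gains <- target / wmean
  px <- sweep(image$pixels, 3, gains, `*`)
  clip_fraction <- mean(px > 1 | px < 0)
  px <- pmin(pmax(px, 0), 1)
  out <- image
  out$pixels <- px
  attr(out, "clip_fraction") <- clip_fraction
  attr(out, "white_gains") <- gains
  out
}

#' Mean color of an image region
#'
#' Arithmetic per-channel mean over the region pixels (in linear light),
#' reported both as RGB and, via sRGB -> CIELAB conversion, as Lab.
#'
#' @param image A `pci_image`.
#' @param region_name Name of the region to average.
#' @return A one-row tibble: `region_name`, `role`, `R`, `G`, `B`, `L`, `a`,
#'   `b`, `n_pixels`.
#' @export
region_color <- function(image, region_name) {
  stopifnot(inherits(image, "pci_image"), !is.null(image$regions))
  reg <- image$regions[image$regions$region_name == region_name, ]
  if (nrow(reg) == 0) abort(paste("no region named", region_name))
  reg <- reg[1, ]
  px <- .region_pixels(image, reg)
  m <- apply(px, 3, mean)
  lab <- rgb_to_lab(m[1], m[2], m[3], encoding = "linear")
  tibble(region_name = region_name, role = reg$role,
         R = m[1], G = m[2], B = m[3],
         L = lab$L, a = lab$a, b = lab$b,
         n_pixels = prod(dim(px)[1:2]))
}

#' Colors of all regions of an image
#'
#' @param image A `pci_image`.
#' @return A tibble with one row per region (see [region_color()]).
#' @export
region_colors <- function(image) {
  stopifnot(inherits(image, "pci_image"), !is.null(image$regions))
  purrr::map_dfr(image$regions$region_name, function(nm) region_color(image, nm))
}

#' Build a device-specific calibration dataset from annotated images
#'
#' For each image: white-balance (if a white region is present), average the
#' exposed and unexposed regions, and compute the CIEDE2000 difference of
#' each exposed region against the unexposed reference. Supports the camera
#' dialect (one exposed PCI and its own references per image) and the scanner
#' dialect (one image, shared references, many exposed regions). Doses come
#' from the `dose_mJ_cm2` column of the region annotations or, if absent
#' there, from the `doses` argument (one per image).
#'
#' @param images A list of `pci_image` objects (or a single image).
#' @param doses Optional numeric vector of doses, one per image.
#' @param white_balance Apply white-balance correction first (default TRUE).
#' @param target Neutral white target passed to [white_balance()].
#' @return A calibration tibble with columns `dose_mJ_cm2`, `delta_e`,
#'   `region_name`, `device_id`, ready for [fit_calibration()].
#' @export
device_dose_response <- function(images, doses = NULL, white_balance = TRUE,
                                 target = 0.9) {
  if (inherits(images, "pci_image")) images <- list(images)
  purrr::imap_dfr(images, function(img, i) {
    stopifnot(inherits(img, "pci_image"))
    if (white_balance) img <- pcidose::white_balance(img, target)
    if (is.null(img$regions) || !"unexposed" %in% img$regions$role) {
      abort("image has no 'unexposed' reference region")
    }
    ref <- region_color(img, img$regions$region_name[img$regions$role == "unexposed"][1])
    exp_regs <- img$regions[img$regions$role == "exposed", ]
    if (nrow(exp_regs) == 0) abort("image has no 'exposed' region")
    purrr::map_dfr(seq_len(nrow(exp_regs)), function(j) {
      rc <- region_color(img, exp_regs$region_name[j])
      dose <- if ("dose_mJ_cm2" %in% names(exp_regs) && !is.na(exp_regs$dose_mJ_cm2[j])) {
        exp_regs$dose_mJ_cm2[j]
      } else if (!is.null(doses)) {
        doses[[i]]
      } else {
        abort("no dose label: add dose_mJ_cm2 to the annotations or pass doses=")
      }
      tibble(dose_mJ_cm2 = dose,
             delta_e = delta_e_ciede2000(rc$L, rc$a, rc$b, ref$L, ref$a, ref$b),
             region_name = exp_regs$region_name[j],
             device_id = img$device_id)
    })
  })
}

#' Per-pixel dose map from a PCI image
#'
#' Computes the CIEDE2000 difference of every pixel against the unexposed
#' reference color and maps it through the inverse calibration function.
#' Pixels at or beyond the saturation guard of the curve asymptote are
#' flagged and set to `NA`, never silently clipped.
#'
#' @param image A `pci_image` (already white-balanced if desired).
#' @param model A `pci_calibration` fit.
#' @param reference Reference CIELAB color as a list/one-row data frame with
#'   `L`, `a`, `b`; defaults to the mean of the image's `unexposed` region.
#' @param region_name Optional region to restrict the map to (default: whole
#'   image).
#' @param saturation_guard Fraction of the asymptote beyond which pixels are
#'   flagged saturated (default 0.98).
#' @return A list of class `pci_dose_map`: `dose` (matrix, mJ/cm^2, `NA`
#'   where saturated), `delta_e` (matrix), `saturated` (logical matrix),
#'   `reference` (tibble).
#' @export
dose_image <- function(image, model, reference = NULL, region_name = NULL,
                       saturation_guard = 0.98) {
  stopifnot(inherits(image, "pci_image"), inherits(model, "pci_calibration"))
  if (is.null(reference)) {
    if (is.null(image$regions) || !"unexposed" %in% image$regions$role) {
      abort("no reference supplied and no 'unexposed' region present")
    }
    reference <- region_color(
      image, image$regions$region_name[image$regions$role == "unexposed"][1])
  }
  px <- if (is.null(region_name)) image$pixels else {
    reg <- image$regions[image$regions$region_name == region_name, ][1, ]
    .region_pixels(image, reg)
  }
  d <- dim(px)
  flat <- matrix(px, ncol = 3)
  lab <- rgb_to_lab(flat[, 1], flat[, 2], flat[, 3], encoding = "linear")
  de <- delta_e_ciede2000(lab$L, lab$a, lab$b,
                          reference$L, reference$a, reference$b)
  asym <- .asymptote(model$a, model$order)
  saturated <- de > saturation_guard * asym
  dose <- rep(NA_real_, length(de))
  dose[!saturated] <- invert_dose(model, de[!saturated], saturation_guard)
  structure(list(
    dose = matrix(dose, d[1], d[2]),
    delta_e = matrix(de, d[1], d[2]),
    saturated = matrix(saturated, d[1], d[2]),
    reference = as_tibble(reference)
  ), class = "pci_dose_map")
}

#' @export
print.pci_dose_map <- function(x, ...) {
  cat(sprintf(
    "PCI dose map %dx%d px: median dose %.4g mJ/cm^2, %.1f%% saturated\n",
    ncol(x$dose), nrow(x$dose), median(x$dose, na.rm = TRUE),
    100 * mean(x$saturated)))
  invisible(x)
}

#' Write a per-pixel dose map to a 32-bit float TIFF plus CSV summary
#'
#' @param map A `pci_dose_map`.
#' @param tiff_path Output TIFF path (saturated pixels written as `NaN`).
#' @param csv_path Optional CSV path for a summary (quantiles, saturation
#'   fraction).
#' @return `tiff_path`, invisibly.
#' @export
write_dose_map <- function(map, tiff_path, csv_path = NULL) {
  stopifnot(inherits(map, "pci_dose_map"))
  m <- map$dose
  m[is.na(m)] <- NaN
  tiff::writeTIFF(m / max(1, max(m, na.rm = TRUE)), tiff_path,
                  bits.per.sample = 32L)
  if (!is.null(csv_path)) {
    q <- quantile(map$dose, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
    readr::write_csv(tibble(
      stat = c("min", "q25", "median", "q75", "max", "saturated_fraction"),
      value = c(unname(q), mean(map$saturated))), csv_path)
  }
  invisible(tiff_path)
}

#' Plot a per-pixel dose map
#'
#' @param map A `pci_dose_map`.
#' @param ... Unused.
#' @return A ggplot heatmap on the inferno colormap.
#' @export
plot_dose_map <- function(map, ...) {
  stopifnot(inherits(map, "pci_dose_map"))
  df <- tidyr::expand_grid(y = seq_len(nrow(map$dose)),
                           x = seq_len(ncol(map$dose)))
  df$dose <- as.vector(t(map$dose))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", na.value = "grey70",
                                  name = "dose (mJ/cm²)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
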