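#' Read and write spatial dose-map tables
#'
#' The map table dialect has one row per replicate measurement: `label`,
#' `x_mm`, `y_mm`, `surface` (`plane`, `n95_exterior` or `n95_interior`),
#' `replicate`, `dose_mJ_cm2`, `u_dose`. Unmeasured locations are explicit
#' rows with `NA` dose and are excluded from summaries.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_dose_map_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("label", "x_mm", "y_mm", "surface", "replicate", "dose_mJ_cm2", "u_dose")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste("dose map is missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  df
}

#' @rdname read_dose_map_csv
#' @param df Dose map tibble.
#' @export
write_dose_map_csv <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' Aggregate replicate dose measurements per location
#'
#' Per location: mean dose, replicate SD (`u_rep`), mean propagated
#' calibration uncertainty (`u_dose`), and the combined
#' `u_total = sqrt(u_dose^2 + u_rep^2)`. Locations with all-`NA` doses are
#' dropped.
#'
#' @param df Dose map tibble (see [read_dose_map_csv()]).
#' @return A tibble with one row per location: `label`, `x_mm`, `y_mm`,
#'   `surface`, `n_rep`, `dose_mJ_cm2`, `u_rep`, `u_dose`, `u_total`.
#' @export
aggregate_replicates <- function(df) {
  df |>
    dplyr::filter(!is.na(.data$dose_mJ_cm2)) |>
    dplyr::group_by(.data$label, .data$x_mm, .data$y_mm, .data$surface) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      u_dose = mean(.data$u_dose),
      u_rep = if (dplyr::n() > 1) sd(.data$dose_mJ_cm2) else 0,
      dose_mJ_cm2 = mean(.data$dose_mJ_cm2),
      .groups = "drop"
    ) |>
    dplyr::mutate(u_total = combine_uncertainty(.data$u_dose, .data$u_rep)) |>
    dplyr::select("label", "x_mm", "y_mm", "surface", "n_rep",
                  "dose_mJ_cm2", "u_rep", "u_dose", "u_total")
}

#' Apply per-location correction factors
#'
#' Multiplies each location's dose and uncertainty columns by its correction
#' factor (e.g. a radiometer angular-response correction supplied by the
#' user). Factors must be strictly positive; locations without a factor are
#' left unchanged.
#'
#' @param df Aggregated (or raw) dose map tibble with a `label` column.
#' @param factors Named numeric vector (names = labels) or a tibble with
#'   columns `label` and `factor`.
#' @return `df` with dose/uncertainty columns scaled and a
#'   `correction_factor` column appended.
#' @export
apply_correction <- function(df, factors) {
  if (is.numeric(factors) && !is.null(names(factors))) {
    factors <- tibble(label = names(factors), factor = unname(factors))
  }
  if (!all(c("label", "factor") %in% names(factors))) {
    abort("factors must be a named vector or a tibble with label and factor")
  }
  if (any(factors$factor <= 0)) abort("correction factors must be > 0")
  out <- dplyr::left_join(df, factors, by = "label") |>
    dplyr::mutate(correction_factor = dplyr::coalesce(.data$factor, 1)) |>
    dplyr::select(-"factor")
  scale_cols <- intersect(c("dose_mJ_cm2", "u_dose", "u_rep", "u_total",
                            "ci_low", "ci_high"), names(out))
  dplyr::mutate(out, dplyr::across(dplyr::all_of(scale_cols),
                                   ~ .x * correction_factor))
}

#' Normalize a dose map to a reference location
#'
#' Divides each location's dose by the reference location's dose (e.g. the
#' apex of the central respirator) and propagates both uncertainties via
#' [normalize_dose()]. The reference location maps to exactly 1.
#'
#' @param df Aggregated dose map tibble (one row per location, with
#'   `dose_mJ_cm2` and `u_total`).
#' @param reference_label Label of the reference location.
#' @return `df` with `dose_norm` and `u_norm` columns appended.
#' @export
relative_map <- function(df, reference_label) {
  ref <- df[df$label == reference_label, ]
  if (nrow(ref) != 1) abort(paste("reference label must match exactly one location:", reference_label))
  nd <- normalize_dose(df$dose_mJ_cm2, df$u_total, ref$dose_mJ_cm2, ref$u_total)
  dplyr::bind_cols(df, nd)
}

#' Dose uniformity summary of a spatial map
#'
#' Reports the min/max dose ratio, the corner-to-center ratio (mean of the
#' doses at the four bounding-box corner locations divided by the dose at
#' the location nearest the map centroid), and histogram bins. All ratios
#' are invariant under global dose rescaling.
#'
#' @param df Aggregated dose map tibble.
#' @param center_label Optional explicit center location label.
#' @param bins Number of histogram bins (default 10).
#' @return A list with `ratios` (one-row tibble: `min_max_ratio`,
#'   `max_min_ratio`, `corner_center_ratio`, `center_label`) and `histogram`
#'   (tibble of bin mids and counts).
#' @export
uniformity_summary <- function(df, center_label = NULL, bins = 10) {
  df <- dplyr::filter(df, !is.na(.data$dose_mJ_cm2))
  if (nrow(df) < 2) {
    warn("degenerate map with fewer than 2 measured locations")
    return(list(
      ratios = tibble(min_max_ratio = 1, max_min_ratio = 1,
                      corner_center_ratio = 1,
                      center_label = if (nrow(df)) df$label else NA_character_),
      histogram = tibble(bin_mid = if (nrow(df)) df$dose_mJ_cm2 else numeric(),
                         count = if (nrow(df)) 1L else integer())))
  }
  d <- df$dose_mJ_cm2
  if (is.null(center_label)) {
    cx <- mean(range(df$x_mm)); cy <- mean(range(df$y_mm))
    center_label <- df$label[which.min((df$x_mm - cx)^2 + (df$y_mm - cy)^2)]
  }
  center_dose <- df$dose_mJ_cm2[df$label == center_label][1]
  xr <- range(df$x_mm); yr <- range(df$y_mm)
  corner_idx <- unique(unlist(lapply(list(c(xr[1], yr[1]), c(xr[2], yr[1]),
                                          c(xr[1], yr[2]), c(xr[2], yr[2])),
    function(p) which.min((df$x_mm - p[1])^2 + (df$y_mm - p[2])^2))))
  h <- hist(d, breaks = bins, plot = FALSE)
  list(
    ratios = tibble(
      min_max_ratio = min(d) / max(d),
      max_min_ratio = max(d) / min(d),
      corner_center_ratio = mean(df$dose_mJ_cm2[corner_idx]) / center_dose,
      center_label = center_label),
    histogram = tibble(bin_mid = h$mids, count = h$counts)
  )
}

#' Heatmap of a spatial dose map
#'
#' @param df Aggregated dose map tibble.
#' @param value Column to plot (default `dose_mJ_cm2`; use `dose_norm` after
#'   [relative_map()]).
#' @return A ggplot tile heatmap on the inferno colormap.
#' @importFrom graphics hist
#' @export
plot_dose_heatmap <- function(df, value = "dose_mJ_cm2") {
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "inferno", na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
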