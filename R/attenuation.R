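#' Optical filter specification
#'
#' @param name Filter label.
#' @param transmittance Fraction of incident UV-C transmitted, in `(0, 1]`.
#' @param source `"measured"` or `"nominal"`.
#' @return A one-row tibble: `name`, `transmittance`, `od`
#'   (`-log10(transmittance)`), `source`.
#' @export
filter_spec <- function(name, transmittance, source = c("measured", "nominal")) {
  source <- match.arg(source)
  if (transmittance <= 0 || transmittance > 1) {
    abort("transmittance must lie in (0, 1]")
  }
  tibble(name = name, transmittance = transmittance,
         od = -log10(transmittance), source = source)
}

#' Measure filter transmittance from radiometer peaks
#'
#' Transmittance is the peak irradiance through the filtering material
#' divided by the peak irradiance without it.
#'
#' @param peak_filtered Peak irradiance through the filter (mW/cm^2).
#' @param peak_unfiltered Peak irradiance without the filter (mW/cm^2).
#' @param name Filter label.
#' @return A filter spec tibble (see [filter_spec()]).
#' @export
measure_transmittance <- function(peak_filtered, peak_unfiltered,
                                  name = "filter") {
  if (peak_unfiltered <= 0) abort("unfiltered peak irradiance must be > 0")
  if (peak_filtered <= 0) abort("filtered peak irradiance must be > 0")
  if (peak_filtered > peak_unfiltered) {
    abort("filtered peak exceeds unfiltered peak; check the measurement")
  }
  filter_spec(name, peak_filtered / peak_unfiltered, "measured")
}

#' Rescale a calibration model for use behind an optical attenuator
#'
#' A filter of transmittance `T` scales the dose axis: the filtered response
#' satisfies `dE(d; filtered) = dE(T * d; unfiltered)`. For first-order
#' kinetics this means `b' = b / T`; for second-order, `b' = b * T`. The
#' amplitude `a` carries over and the parameter covariance is transformed
#' consistently (the `b` row/column scales with the same factor).
#'
#' @param model A `pci_calibration` fit (unfiltered).
#' @param filter A filter spec tibble or a bare transmittance in `(0, 1]`.
#' @return A `pci_calibration` describing the filtered response.
#' @export
filtered_model <- function(model, filter) {
  stopifnot(inherits(model, "pci_calibration"))
  tr <- if (is.data.frame(filter)) filter$transmittance[1] else filter
  if (!is.numeric(tr) || tr <= 0 || tr > 1) abort("transmittance must lie in (0, 1]")
  f <- if (model$order == "first") 1 / tr else tr
  out <- model
  out$b <- model$b * f
  J <- diag(c(1, f))
  out$cov <- J %*% model$cov %*% t(J)
  dimnames(out$cov) <- dimnames(model$cov)
  out$data <- NULL
  out$metric <- model$metric
  out
}

#' Dynamic-range extension from an optical attenuator
#'
#' Compares an unfiltered calibration with a filtered one (either an
#' independent fit to filtered data or a [filtered_model()] transform).
#' The extension factor is the ratio of dose-scale parameters
#' (`b_filtered / b_unfiltered` for first order, inverted for second order,
#' where smaller `b` means a slower response). The extended limit is the
#' filtered dose whose predicted color change matches the unfiltered
#' prediction at a stated unfiltered dose limit (the color-matching
#' convention).
#'
#' @param unfiltered,filtered `pci_calibration` fits of the same kinetic
#'   order.
#' @param unfiltered_limit Unfiltered dose limit (mJ/cm^2) to match
#'   (default 200, the upper end of the unattenuated quantifiable range).
#' @return A one-row tibble: `extension_factor`, `unfiltered_limit`,
#'   `delta_e_at_limit`, `extended_limit`.
#' @export
range_extension <- function(unfiltered, filtered, unfiltered_limit = 200) {
  stopifnot(inherits(unfiltered, "pci_calibration"),
            inherits(filtered, "pci_calibration"))
  if (unfiltered$order != filtered$order) {
    abort("kinetic orders differ; range extension is only defined within one order")
  }
  ext <- if (unfiltered$order == "first") filtered$b / unfiltered$b
         else unfiltered$b / filtered$b
  de <- predict_delta_e(unfiltered, unfiltered_limit)
  asym_f <- .asymptote(filtered$a, filtered$order)
  extended <- if (de < 0.98 * asym_f) invert_dose(filtered, de) else Inf
  tibble(extension_factor = ext, unfiltered_limit = unfiltered_limit,
         delta_e_at_limit = de, extended_limit = extended)
}
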