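#' Invert a calibration curve: dose from color change
#'
#' First-order kinetics invert to `dose = -b * log(1 - dE/a)`; second-order
#' kinetics to `dose = dE / (0.5 * a^2 * b - a * b * dE)`. Inversion is only
#' defined strictly below the curve asymptote (`a`, or `a/2` for second
#' order); by default values above 98% of the asymptote are refused because
#' the inverse and its partial derivatives diverge there.
#'
#' @param model A `pci_calibration` fit.
#' @param delta_e Measured color difference(s), `>= 0`.
#' @param saturation_guard Fraction of the asymptote beyond which inversion
#'   is refused (default 0.98).
#' @return Dose(s) in mJ/cm^2.
#' @export
invert_dose <- function(model, delta_e, saturation_guard = 0.98) {
  stopifnot(inherits(model, "pci_calibration"))
  if (any(delta_e < 0)) abort("delta_e must be >= 0")
  asym <- .asymptote(model$a, model$order)
  if (any(delta_e > saturation_guard * asym)) {
    abort(sprintf(
      "delta_e %.4g is at or beyond %.0f%% of the curve asymptote (%.4g): indicator saturated, dose not quantifiable",
      max(delta_e), 100 * saturation_guard, asym))
  }
  if (model$order == "first") {
    -model$b * log(1 - delta_e / model$a)
  } else {
    delta_e / (0.5 * model$a^2 * model$b - model$a * model$b * delta_e)
  }
}

#' Partial derivatives of the inverse calibration functions
#'
#' The analytic partials of predicted dose with respect to the fit parameters
#' `a`, `b` and the measured color difference, used in delta-method
#' uncertainty propagation.
#'
#' @param a,b Calibration parameters.
#' @param delta_e Color difference(s), strictly below the asymptote.
#' @param order Kinetic order.
#' @return A tibble with columns `d_da`, `d_db`, `d_de`.
#' @export
inverse_partials <- function(a, b, delta_e, order = c("first", "second")) {
  order <- match.arg(order)
  if (order == "first") {
    tibble(
      d_da = -b * delta_e / (a^2 - a * delta_e),
      d_db = -log(1 - delta_e / a),
      d_de = b / (a - delta_e)
    )
  } else {
    tibble(
      d_da = 4 * delta_e * (delta_e - a) / (b * a^2 * (a - 2 * delta_e)^2),
      d_db = -2 * delta_e / (a * b^2 * (a - 2 * delta_e)),
      d_de = 2 / (b * (a - 2 * delta_e)^2)
    )
  }
}

#' Propagated standard uncertainty of an inverse dose prediction
#'
#' Delta-method variance combining the fit parameter covariance and the
#' color-difference measurement noise:
#' `u^2 = (d/da)^2 s_a^2 + (d/db)^2 s_b^2 + (d/ddE)^2 s_dE^2 + 2 (d/da)(d/db) s_ab`.
#'
#' @inheritParams invert_dose
#' @param s_delta_e Measurement noise SD; defaults to the value stored in the
#'   model.
#' @return Standard uncertainty (mJ/cm^2), same length as `delta_e`.
#' @export
dose_uncertainty <- function(model, delta_e, s_delta_e = model$s_delta_e,
                             saturation_guard = 0.98) {
  stopifnot(inherits(model, "pci_calibration"))
  asym <- .asymptote(model$a, model$order)
  if (any(delta_e < 0) || any(delta_e > saturation_guard * asym)) {
    abort("delta_e must lie in [0, saturation_guard * asymptote)")
  }
  p <- inverse_partials(model$a, model$b, delta_e, model$order)
  v <- p$d_da^2 * model$cov[1, 1] + p$d_db^2 * model$cov[2, 2] +
    p$d_de^2 * s_delta_e^2 + 2 * p$d_da * p$d_db * model$cov[1, 2]
  sqrt(pmax(v, 0))
}

#' Dose estimate with confidence interval from a color-difference reading
#'
#' Inverts the calibration curve and attaches the propagated uncertainty and
#' a Student-t confidence interval `dose +/- u_dose * t(1 - alpha/2, nu)`
#' with the fit's residual degrees of freedom. Relative uncertainty is
#' reported as half the relative CI width.
#'
#' @inheritParams dose_uncertainty
#' @param alpha Significance level (default 0.05 for 95% CIs).
#' @param warn_band Fraction of the asymptote above which estimates are
#'   flagged `near_saturation` (default 0.90).
#' @return A tibble with one row per reading: `delta_e`, `dose_mJ_cm2`,
#'   `u_dose`, `ci_low`, `ci_high`, `alpha`, `rel_ci_width`,
#'   `rel_uncertainty`, `flags`.
#' @export
predict_dose <- function(model, delta_e, alpha = 0.05,
                         s_delta_e = model$s_delta_e,
                         saturation_guard = 0.98, warn_band = 0.90) {
  stopifnot(inherits(model, "pci_calibration"), alpha > 0, alpha < 1)
  dose <- invert_dose(model, delta_e, saturation_guard)
  u <- dose_uncertainty(model, delta_e, s_delta_e, saturation_guard)
  tq <- qt(1 - alpha / 2, model$nu)
  asym <- .asymptote(model$a, model$order)
  flags <- ifelse(delta_e > warn_band * asym, "near_saturation", "")
  rel_w <- ifelse(dose > 0, 2 * u * tq / dose, NA_real_)
  tibble(
    delta_e = delta_e, dose_mJ_cm2 = dose, u_dose = u,
    ci_low = dose - u * tq, ci_high = dose + u * tq, alpha = alpha,
    rel_ci_width = rel_w, rel_uncertainty = rel_w / 2, flags = flags
  )
}

#' Quantify doses for a table of color readings
#'
#' Data-frame-first wrapper: takes a tibble carrying a `delta_e` column (for
#' example the `de2000` output of [color_differences()], renamed or selected
#' via `metric_col`) and appends the dose estimate columns.
#'
#' @param df A data frame of readings.
#' @param model A `pci_calibration` fit.
#' @param metric_col Name of the column holding the color difference
#'   (default `"de2000"`, falling back to `"delta_e"`).
#' @inheritParams predict_dose
#' @return `df` with the [predict_dose()] columns appended.
#' @export
quantify_doses <- function(df, model, metric_col = NULL, alpha = 0.05,
                           saturation_guard = 0.98, warn_band = 0.90) {
  if (is.null(metric_col)) {
    metric_col <- if ("de2000" %in% names(df)) "de2000" else "delta_e"
  }
  if (!metric_col %in% names(df)) {
    abort(sprintf("column '%s' not found in df", metric_col))
  }
  est <- predict_dose(model, df[[metric_col]], alpha = alpha,
                      saturation_guard = saturation_guard,
                      warn_band = warn_band)
  dplyr::bind_cols(df, dplyr::select(est, -"delta_e"))
}

#' Equalize replicate dose estimates to a common target dose
#'
#' Replicate exposures rarely deliver identical doses; each estimate is
#' rescaled by `target_dose / logged_dose` (the radiometer-logged dose for
#' that exposure), which multiplies the dose, its CI bounds and its standard
#' uncertainty by the same factor, leaving relative uncertainty unchanged.
#'
#' @param estimates A tibble of dose estimates (from [predict_dose()]).
#' @param logged_doses Radiometer-logged dose per estimate (mJ/cm^2, `> 0`).
#' @param target_dose Common target dose (mJ/cm^2, `> 0`).
#' @return The estimates tibble with `dose_mJ_cm2`, `u_dose`, `ci_low`,
#'   `ci_high` rescaled and an `equalization_factor` column appended.
#' @export
equalize_replicates <- function(estimates, logged_doses, target_dose) {
  if (any(logged_doses <= 0)) abort("logged doses must be > 0")
  if (target_dose <= 0) abort("target dose must be > 0")
  f <- target_dose / logged_doses
  dplyr::mutate(estimates,
    dose_mJ_cm2 = .data$dose_mJ_cm2 * f,
    u_dose = .data$u_dose * f,
    ci_low = .data$ci_low * f,
    ci_high = .data$ci_high * f,
    equalization_factor = f)
}

#' Combine calibration and replicate uncertainties
#'
#' Root sum of squares `u_total = sqrt(u_dose^2 + u_rep^2)`, where `u_rep`
#' is the standard deviation of replicate dose measurements.
#'
#' @param u_dose Calibration-propagated standard uncertainty.
#' @param u_rep Replicate SD. Alternatively supply `replicate_doses` and the
#'   SD is computed.
#' @param replicate_doses Optional numeric vector of replicate doses.
#' @return Combined standard uncertainty.
#' @export
combine_uncertainty <- function(u_dose, u_rep = NULL, replicate_doses = NULL) {
  if (is.null(u_rep)) {
    if (is.null(replicate_doses)) abort("supply u_rep or replicate_doses")
    u_rep <- sd(replicate_doses)
  }
  sqrt(u_dose^2 + u_rep^2)
}

#' Normalize a dose measurement to a reference measurement
#'
#' Relative dose `dose_norm = dose_meas / dose_ref` with propagated
#' uncertainty
#' `u_norm = |dose_norm| * sqrt((u_meas/dose_meas)^2 + (u_ref/dose_ref)^2)`.
#'
#' @param dose_meas,u_meas Measured dose and its combined uncertainty.
#' @param dose_ref,u_ref Reference dose and its combined uncertainty.
#' @return A tibble with `dose_norm` and `u_norm`.
#' @export
normalize_dose <- function(dose_meas, u_meas, dose_ref, u_ref) {
  if (any(dose_ref <= 0) || any(dose_meas <= 0)) {
    abort("normalization requires strictly positive doses")
  }
  dn <- dose_meas / dose_ref
  tibble(dose_norm = dn,
         u_norm = abs(dn) * sqrt((u_meas / dose_meas)^2 + (u_ref / dose_ref)^2))
}

#' Fraction of color change attributable to non-germicidal wavelengths
#'
#' Ratio of the color change behind a longpass filter (blocking germicidal
#' UV-C) to the total color change from the unfiltered source.
#'
#' @param delta_e_filtered Color change under the longpass filter, `>= 0`.
#' @param delta_e_total Total color change from the unfiltered source, `> 0`.
#' @return Fraction in `[0, 1]`.
#' @export
nongermicidal_fraction <- function(delta_e_filtered, delta_e_total) {
  if (any(delta_e_filtered < 0) || any(delta_e_total <= 0)) {
    abort("color changes must be >= 0 with a positive total")
  }
  if (any(delta_e_filtered > delta_e_total)) {
    abort("filtered color change exceeds total: inputs are inconsistent")
  }
  delta_e_filtered / delta_e_total
}
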