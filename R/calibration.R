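#' Kinetic calibration response
#'
#' Dose-response forms used to calibrate PCI color change against UV-C dose:
#' first-order kinetics `dE = a * (1 - exp(-dose/b))` saturating at `a`, and
#' second-order kinetics `dE = 0.5 * a^2 * b * dose / (1 + a * b * dose)`
#' saturating at `a/2`. Both pass through the origin and increase strictly
#' with dose for `a, b > 0`.
#'
#' @param dose Non-negative dose, mJ/cm^2 (vectorized).
#' @param a Amplitude parameter (dE units), `> 0`.
#' @param b Dose-scale parameter, `> 0` (first order: mJ/cm^2; second order:
#'   inverse dose times inverse dE units).
#' @param order `"first"` or `"second"`.
#' @return Predicted color difference, same length as `dose`.
#' @export
kinetic_delta_e <- function(dose, a, b, order = c("first", "second")) {
  order <- match.arg(order)
  if (any(dose < 0)) abort("dose must be >= 0")
  if (order == "first") a * (1 - exp(-dose / b))
  else 0.5 * a^2 * b * dose / (1 + a * b * dose)
}

.asymptote <- function(a, order) if (order == "first") a else a / 2

#' Fit a PCI calibration curve
#'
#' Unweighted nonlinear least squares of measured color difference against
#' known UV-C dose, using either kinetic order. Parameter covariance comes
#' from the fit Jacobian; degrees of freedom are `n - 2`.
#'
#' @param data A data frame with columns `dose_mJ_cm2` and `delta_e`
#'   (at least 4 points over at least 3 distinct doses).
#' @param order Kinetic order, `"first"` or `"second"`.
#' @param s_delta_e Measurement noise SD of the color-difference metric, in
#'   the same units as `delta_e` (e.g. the replicate SD of unexposed
#'   indicators). If `NULL`, the residual SD `sqrt(SSE/nu)` is substituted
#'   with a message; an instrument-measured value is preferred.
#' @param metric Optional metric label stored with the model.
#' @param dose_unit `"mJ_cm2"` (internal standard) or `"J_cm2"`; doses given
#'   in J/cm^2 are converted to mJ/cm^2 on entry.
#' @return An object of class `pci_calibration`: a list with elements
#'   `order`, `a`, `b`, `cov` (2x2 over (a, b)), `nu`, `s_delta_e`,
#'   `r_squared`, `sse`, `n`, `dose_unit`, `metric`, `data`.
#' @examples
#' d <- tibble::tibble(dose_mJ_cm2 = seq(0, 250, length.out = 12))
#' d$delta_e <- kinetic_delta_e(d$dose_mJ_cm2, 47.1, 80.4, "first")
#' fit <- fit_calibration(d, "first", s_delta_e = 0.273)
#' fit$a
#' @export
fit_calibration <- function(data, order = c("first", "second"),
                            s_delta_e = NULL, metric = "CIEDE2000",
                            dose_unit = c("mJ_cm2", "J_cm2")) {
  order <- match.arg(order)
  dose_unit <- match.arg(dose_unit)
  if (!all(c("dose_mJ_cm2", "delta_e") %in% names(data))) {
    abort("calibration data needs columns dose_mJ_cm2 and delta_e")
  }
  dose <- data$dose_mJ_cm2
  if (dose_unit == "J_cm2") dose <- dose * 1000
  de <- data$delta_e
  keep <- !is.na(dose) & !is.na(de)
  dose <- dose[keep]; de <- de[keep]
  if (length(dose) < 4) abort("calibration requires at least 4 points")
  if (length(unique(dose)) < 3) abort("calibration requires at least 3 distinct doses")
  if (any(dose < 0)) abort("doses must be >= 0")
  if (!is.null(s_delta_e) && s_delta_e <= 0) abort("s_delta_e must be > 0")
  if (max(de) <= 0) abort("degenerate calibration: color difference never rises above 0")

  a0 <- if (order == "first") max(de) else 2 * max(de)
  half_target <- if (order == "first") a0 / 2 else a0 / 4
  above <- dose[de >= half_target & dose > 0]
  dose_half <- if (length(above)) min(above) else max(dose[dose > 0])
  b0 <- if (order == "first") dose_half / log(2) else 1 / (a0 * dose_half)

  df <- data.frame(dose = dose, de = de)
  form <- if (order == "first") de ~ a * (1 - exp(-dose / b))
          else de ~ 0.5 * a^2 * b * dose / (1 + a * b * dose)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = list(a = a0, b = b0),
                      lower = c(a = 1e-12, b = 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) abort(paste("calibration fit failed to converge:",
                                    conditionMessage(e)))
  )
  est <- coef(fit)
  res <- de - kinetic_delta_e(dose, est[["a"]], est[["b"]], order)
  sse <- sum(res^2)
  sst <- sum((de - mean(de))^2)
  nu <- length(dose) - 2L
  if (nu < 1) abort("not enough points for residual degrees of freedom")
  cv <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  dimnames(cv) <- list(c("a", "b"), c("a", "b"))
  if (is.null(s_delta_e)) {
    s_delta_e <- sqrt(sse / nu)
    inform(sprintf(
      "no measured s_delta_e supplied; using residual SD %.4g as the dE noise",
      s_delta_e))
  }
  structure(list(
    order = order, a = unname(est[["a"]]), b = unname(est[["b"]]),
    cov = (cv + t(cv)) / 2, nu = nu, s_delta_e = s_delta_e,
    r_squared = if (sst > 0) 1 - sse / sst else NA_real_, sse = sse,
    n = length(dose), dose_unit = "mJ_cm2", metric = metric,
    data = tibble(dose_mJ_cm2 = dose, delta_e = de)
  ), class = "pci_calibration")
}

#' Predict color change at a given dose
#'
#' @param model A `pci_calibration` fit.
#' @param dose Non-negative dose(s) in mJ/cm^2.
#' @return Predicted color difference vector.
#' @export
predict_delta_e <- function(model, dose) {
  stopifnot(inherits(model, "pci_calibration"))
  kinetic_delta_e(dose, model$a, model$b, model$order)
}

#' @export
predict.pci_calibration <- function(object, dose, ...) {
  predict_delta_e(object, dose)
}

#' @export
print.pci_calibration <- function(x, ...) {
  cat(sprintf(
    "PCI calibration (%s-order kinetics, %s)\n  a = %.4g, b = %.4g  [dose in %s]\n  n = %d, nu = %d, R^2 = %.4f, SSE = %.4g, s_dE = %.4g\n  asymptotic dE = %.4g\n",
    x$order, x$metric, x$a, x$b, x$dose_unit, x$n, x$nu, x$r_squared, x$sse,
    x$s_delta_e, .asymptote(x$a, x$order)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCI calibration fit
#'
#' @param x A `pci_calibration` object.
#' @param conf.level Confidence level for parameter intervals (t-based, `nu`
#'   degrees of freedom).
#' @param ... Unused.
#' @return One row per parameter with estimate, standard error and bounds.
#' @method tidy pci_calibration
#' @export
tidy.pci_calibration <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(pmax(diag(x$cov), 0))
  tq <- qt(1 - (1 - conf.level) / 2, x$nu)
  tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    std.error = se,
    conf.low = c(x$a, x$b) - tq * se,
    conf.high = c(x$a, x$b) + tq * se
  )
}

#' Glance at a PCI calibration fit
#'
#' @param x A `pci_calibration` object.
#' @param ... Unused.
#' @method glance pci_calibration
#' @export
glance.pci_calibration <- function(x, ...) {
  tibble(order = x$order, r.squared = x$r_squared, sse = x$sse,
         s_delta_e = x$s_delta_e, nu = x$nu, nobs = x$n,
         asymptote = .asymptote(x$a, x$order))
}

#' Rank candidate calibration fits by residual error
#'
#' Orders fits by their squared sum of residuals (SSE), the calibration
#' accuracy metric used to compare readout devices and kinetic orders. Ties
#' keep declaration order.
#'
#' @param fits A (optionally named) list of `pci_calibration` objects.
#' @return A tibble with one row per fit: `name`, `order`, `sse`,
#'   `r_squared`, `rank` (1 = best), sorted best first.
#' @export
model_selection_sse <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "pci_calibration")))
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("fit", seq_along(fits))
  out <- tibble(
    name = nm,
    order = vapply(fits, `[[`, "", "order"),
    sse = vapply(fits, `[[`, 0, "sse"),
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    declared = seq_along(fits)
  )
  out <- dplyr::arrange(out, .data$sse, .data$declared)
  out$rank <- seq_len(nrow(out))
  dplyr::select(out, -"declared")
}

#' Serialize a calibration model to JSON
#'
#' @param model A `pci_calibration` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "pci_calibration"))
  obj <- list(
    type = "pci_calibration", order = model$order,
    a = model$a, b = model$b,
    covariance = list(s_a2 = model$cov[1, 1], s_b2 = model$cov[2, 2],
                      s_ab = model$cov[1, 2]),
    nu = model$nu, s_delta_e = model$s_delta_e,
    r_squared = model$r_squared, sse = model$sse, n = model$n,
    dose_unit = model$dose_unit, metric = model$metric,
    generator = paste("pcidose", as.character(utils::packageVersion("pcidose")))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path JSON file written by [write_calibration_json()].
#' @return A `pci_calibration` object (without the original data points).
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "pci_calibration")) {
    abort("not a pci_calibration JSON document")
  }
  cv <- matrix(c(obj$covariance$s_a2, obj$covariance$s_ab,
                 obj$covariance$s_ab, obj$covariance$s_b2), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  structure(list(
    order = obj$order, a = obj$a, b = obj$b, cov = cv,
    nu = as.integer(obj$nu), s_delta_e = obj$s_delta_e,
    r_squared = obj$r_squared, sse = obj$sse, n = obj$n,
    dose_unit = obj$dose_unit, metric = obj$metric, data = NULL
  ), class = "pci_calibration")
}

#' Plot a calibration fit over its data
#'
#' @param object A `pci_calibration` fit carrying its data.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pci_calibration
#' @export
autoplot.pci_calibration <- function(object, ...) {
  stopifnot(!is.null(object$data))
  grid <- tibble(dose_mJ_cm2 = seq(0, max(object$data$dose_mJ_cm2), length.out = 200))
  grid$delta_e <- predict_delta_e(object, grid$dose_mJ_cm2)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$dose_mJ_cm2, .data$delta_e)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, color = "#c0392b") +
    ggplot2::labs(x = "UV-C dose (mJ/cm²)", y = object$metric,
                  title = sprintf("%s-order calibration: a = %.3g, b = %.3g",
                                  object$order, object$a, object$b)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
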