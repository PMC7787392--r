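# Shared fixtures for the test suite. Everything is generated in code.

# Published CIEDE2000 sample/reference validation pairs (CIELAB coordinates)
# with the reference dE00 values, independently recomputed with farver and
# scikit-image before freezing.
ciede2000_pairs <- function() {
  tibble::tribble(
    ~L1, ~a1, ~b1, ~L2, ~a2, ~b2, ~de,
    50.0000, 2.6772, -79.7751, 50.0000, 0.0000, -82.7485, 2.0425,
    50.0000, 3.1571, -77.2803, 50.0000, 0.0000, -82.7485, 2.8615,
    50.0000, 2.8361, -74.0200, 50.0000, 0.0000, -82.7485, 3.4412,
    50.0000, -1.3802, -84.2814, 50.0000, 0.0000, -82.7485, 1.0000,
    50.0000, -1.1848, -84.8006, 50.0000, 0.0000, -82.7485, 1.0000,
    50.0000, -0.9009, -85.5211, 50.0000, 0.0000, -82.7485, 1.0000,
    50.0000, 0.0000, 0.0000, 50.0000, -1.0000, 2.0000, 2.3669,
    50.0000, -1.0000, 2.0000, 50.0000, 0.0000, 0.0000, 2.3669,
    50.0000, 2.4900, -0.0010, 50.0000, -2.4900, 0.0009, 7.1792,
    50.0000, 2.4900, -0.0010, 50.0000, -2.4900, 0.0010, 7.1792
  )
}

# A calibration model with a hand-set covariance, bypassing the fitter, for
# tests that need exact control of the propagation inputs.
make_model <- function(a = 47.1, b = 80.4, order = "first",
                       cov = matrix(c(0.25, 0.5, 0.5, 9), 2, 2),
                       nu = 10L, s_delta_e = 0.273) {
  dimnames(cov) <- list(c("a", "b"), c("a", "b"))
  structure(list(order = order, a = a, b = b, cov = cov, nu = nu,
                 s_delta_e = s_delta_e, r_squared = NA_real_, sse = 0,
                 n = nu + 2L, dose_unit = "mJ_cm2", metric = "CIEDE2000",
                 data = NULL),
            class = "pci_calibration")
}

# Random in-gamut Lab colors drawn through sRGB.
random_lab <- function(n, seed) {
  set.seed(seed)
  rgb <- matrix(runif(3 * n, 0.02, 0.98), ncol = 3)
  pcidose::rgb_to_lab(rgb[, 1], rgb[, 2], rgb[, 3])
}
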