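test_that("predict and invert are mutual inverses on the valid domain", {
  for (ord in c("first", "second")) {
    m <- make_model(a = 47.1, b = if (ord == "first") 80.4 else 6e-4,
                    order = ord)
    set.seed(51)
    doses <- runif(100, 0, if (ord == "first") 250 else 1500)
    back <- invert_dose(m, predict_delta_e(m, doses))
    expect_lt(max(abs(back - doses) / pmax(doses, 1)), 1e-9)
    expect_equal(invert_dose(m, 0), 0)
  }
})

test_that("inversion refuses saturated color changes, naming the asymptote", {
  m <- make_model(a = 47.1, b = 80.4)
  expect_error(invert_dose(m, 47.2), "asymptote")
  expect_error(invert_dose(m, 0.99 * 47.1), "saturated")
  expect_error(invert_dose(m, -0.1), ">= 0")
  m2 <- make_model(a = 47.7, b = 6e-4, order = "second")
  expect_error(invert_dose(m2, 24), "asymptote") # above a/2 = 23.85
})

test_that("analytic inverse partials agree with central finite differences", {
  inv <- function(a, b, de, ord) {
    if (ord == "first") -b * log(1 - de / a)
    else de / (0.5 * a^2 * b - a * b * de)
  }
  set.seed(61)
  for (ord in c("first", "second")) {
    for (rep in 1:20) {
      a <- runif(1, 20, 60)
      b <- if (ord == "first") runif(1, 40, 3000) else runif(1, 1e-5, 1e-3)
      de <- runif(1, 0.05, 0.85) * (if (ord == "first") a else a / 2)
      p <- inverse_partials(a, b, de, ord)
      ha <- 1e-6 * a; hb <- 1e-6 * b; hd <- 1e-6 * max(de, 1)
      fd <- c((inv(a + ha, b, de, ord) - inv(a - ha, b, de, ord)) / (2 * ha),
              (inv(a, b + hb, de, ord) - inv(a, b - hb, de, ord)) / (2 * hb),
              (inv(a, b, de + hd, ord) - inv(a, b, de - hd, ord)) / (2 * hd))
      expect_equal(unlist(p), fd, tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("with zero parameter covariance the uncertainty collapses to the measurement term", {
  m <- make_model(cov = matrix(0, 2, 2))
  de <- c(5, 20, 40)
  p <- inverse_partials(m$a, m$b, de, "first")
  expect_equal(dose_uncertainty(m, de), abs(p$d_de) * m$s_delta_e)
})

test_that("dose uncertainty grows monotonically toward saturation", {
  g <- gen_calibration_dataset(seed = 3)
  f <- fit_calibration(g, "first", s_delta_e = 0.273)
  de <- seq(0.05, 0.95, by = 0.05) * f$a
  u <- dose_uncertainty(f, de)
  expect_true(all(diff(u) > 0))
})

test_that("delta-method uncertainty matches Monte-Carlo propagation away from saturation", {
  g <- gen_calibration_dataset(seed = 7)
  f <- fit_calibration(g, "first", s_delta_e = 0.273)
  de <- 30 # mid-range (asymptote ~47)
  u_delta <- dose_uncertainty(f, de)
  set.seed(99)
  z <- matrix(rnorm(2e5), ncol = 2) %*% chol(f$cov)
  a_s <- f$a + z[, 1]; b_s <- f$b + z[, 2]
  de_s <- de + rnorm(1e5, 0, f$s_delta_e)
  ok <- de_s > 0 & de_s < 0.98 * a_s
  u_mc <- sd(-b_s[ok] * log(1 - de_s[ok] / a_s[ok]))
  expect_lt(abs(u_delta - u_mc) / u_mc, 0.05)
})

test_that("confidence intervals have the stated width, limits, and near-saturation flags", {
  m <- make_model(cov = matrix(0, 2, 2), s_delta_e = 1e-12)
  est <- predict_dose(m, 20)
  expect_lt(est$ci_high - est$ci_low, 1e-6) # u ~ 0: zero-width CI
  expect_equal(est$dose_mJ_cm2, invert_dose(m, 20))
  # nu -> infinity: t quantile approaches the normal 1.95996
  m2 <- make_model(nu = 10000000L)
  est2 <- predict_dose(m2, 20)
  expect_equal((est2$ci_high - est2$dose_mJ_cm2) / est2$u_dose,
               qnorm(0.975), tolerance = 1e-4)
  expect_equal(est2$rel_uncertainty, est2$rel_ci_width / 2)
  # near-saturation estimates are flagged
  est3 <- predict_dose(make_model(), 0.95 * 47.1)
  expect_equal(est3$flags, "near_saturation")
})

test_that("95% CIs cover the true dose at roughly the nominal rate on synthetic calibrations", {
  true_dose <- 100
  de_true <- kinetic_delta_e(true_dose, 47.1, 80.4)
  hits <- vapply(1:150, function(i) {
    f <- fit_calibration(gen_calibration_dataset(seed = i), "first",
                         s_delta_e = 0.273)
    set.seed(10000 + i)
    est <- predict_dose(f, de_true + rnorm(1, 0, 0.273))
    est$ci_low <= true_dose && true_dose <= est$ci_high
  }, logical(1))
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.99)
})

test_that("replicate equalization rescales doses and uncertainties but not relative width", {
  m <- make_model()
  est <- predict_dose(m, c(10, 25, 40))
  same <- equalize_replicates(est, logged_doses = c(1, 1, 1) * 100, target_dose = 100)
  expect_equal(same$dose_mJ_cm2, est$dose_mJ_cm2)
  doubled <- equalize_replicates(est, logged_doses = c(50, 50, 50), target_dose = 100)
  expect_equal(doubled$dose_mJ_cm2, 2 * est$dose_mJ_cm2)
  expect_equal(doubled$u_dose, 2 * est$u_dose)
  expect_equal(doubled$ci_high, 2 * est$ci_high)
  expect_equal(doubled$rel_ci_width, est$rel_ci_width)
  expect_error(equalize_replicates(est, c(0, 1, 1), 100), "> 0")
})

test_that("uncertainty combination and normalization match brute-force propagation", {
  expect_equal(combine_uncertainty(3, 4), 5)
  expect_equal(combine_uncertainty(2, 0), 2)
  expect_equal(combine_uncertainty(1, replicate_doses = c(90, 100, 110)), sqrt(1 + 100))
  set.seed(71)
  u <- runif(20); s <- runif(20)
  expect_equal(combine_uncertainty(u, s), sqrt(u^2 + s^2))
  # symmetric normalization: dose_norm = 1, u_norm = sqrt(2) * u/dose
  nd <- normalize_dose(100, 5, 100, 5)
  expect_equal(nd$dose_norm, 1)
  expect_equal(nd$u_norm, sqrt(2) * 5 / 100)
  # exact reference
  nd2 <- normalize_dose(80, 4, 160, 0)
  expect_equal(nd2$dose_norm, 0.5)
  expect_equal(nd2$u_norm, 4 / 160)
  # random brute force
  dm <- runif(20, 50, 200); um <- runif(20, 1, 5)
  dr <- runif(20, 50, 200); ur <- runif(20, 1, 5)
  nd3 <- normalize_dose(dm, um, dr, ur)
  expect_equal(nd3$u_norm, (dm / dr) * sqrt((um / dm)^2 + (ur / dr)^2))
})

test_that("the non-germicidal fraction is a guarded ratio", {
  expect_equal(nongermicidal_fraction(0, 25), 0)
  expect_equal(nongermicidal_fraction(25, 25), 1)
  expect_equal(nongermicidal_fraction(4.75, 25), 0.19)
  expect_error(nongermicidal_fraction(26, 25), "exceeds")
  expect_error(nongermicidal_fraction(-1, 25), ">= 0")
})

test_that("quantify_doses appends estimates to a readings table", {
  m <- make_model()
  df <- tibble::tibble(sample_id = c("x", "y"), de2000 = c(10, 30))
  out <- quantify_doses(df, m)
  expect_equal(out$dose_mJ_cm2, invert_dose(m, c(10, 30)))
  expect_true(all(c("u_dose", "ci_low", "ci_high", "rel_ci_width") %in% names(out)))
  expect_error(quantify_doses(df, m, metric_col = "nope"), "not found")
})
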