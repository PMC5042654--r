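test_that("confusion counts match a brute-force loop on a random case", {
  set.seed(21)
  labels <- matrix(sample(0:2, 50, replace = TRUE), 5, 10)
  np <- matrix(FALSE, 5, 10)
  np[labels == SEG_CANDIDATE] <- runif(sum(labels == SEG_CANDIDATE)) < 0.5
  det <- hsmad:::new_detection_map(labels, ifelse(np, 1L, NA_integer_),
                                   np, c("np"), 1L, "test")
  truth <- matrix(runif(50) < 0.4, 5, 10)
  cc <- confusion_from_truth(det, truth)
  tp <- fp <- tn <- fn <- 0
  for (i in 1:5) for (j in 1:10) {
    if (labels[i, j] != SEG_CANDIDATE) next
    if (np[i, j] && truth[i, j]) tp <- tp + 1
    if (np[i, j] && !truth[i, j]) fp <- fp + 1
    if (!np[i, j] && !truth[i, j]) tn <- tn + 1
    if (!np[i, j] && truth[i, j]) fn <- fn + 1
  }
  expect_equal(cc, list(tp = tp, fp = fp, tn = tn, fn = fn))
  # perfect agreement and perfect disagreement
  det2 <- hsmad:::new_detection_map(
    matrix(SEG_CANDIDATE, 4, 4), matrix(1L, 4, 4),
    matrix(c(TRUE, FALSE), 4, 4), c("np"), 1L, "test")
  truth2 <- det2$np_mask
  cc2 <- confusion_from_truth(det2, truth2)
  expect_equal(cc2$fp + cc2$fn, 0)
  cc3 <- confusion_from_truth(det2, !truth2)
  expect_equal(cc3$tp + cc3$tn, 0)
  ss <- sens_spec(cc2)
  expect_equal(ss$sensitivity, 1)
  expect_equal(ss$specificity, 1)
})

test_that("sensitivity and specificity are the standard ratios", {
  expect_equal(sens_spec(list(tp = 90, fp = 0, tn = 0, fn = 10))$sensitivity,
               0.9)
  expect_equal(sens_spec(list(tp = 0, fp = 3, tn = 997, fn = 0))$specificity,
               0.997)
  expect_equal(sens_spec(list(tp = 0, fp = 1, tn = 1, fn = 5))$sensitivity, 0)
  expect_error(sens_spec(list(tp = 0, fp = 0, tn = 0, fn = 0)), "score")
})

test_that("the log-method interval matches its closed form", {
  ci <- log_method_ci(90, 100, 1.96)
  expect_equal(round(ci$lo, 3), 0.843)
  expect_equal(round(ci$hi, 3), 0.961)
  # closed form: p * exp(+/- z * sqrt(1/a - 1/n))
  se <- sqrt(1 / 90 - 1 / 100)
  expect_equal(ci$lo, 0.9 * exp(-1.96 * se))
  expect_equal(ci$hi, 0.9 * exp(1.96 * se))
  # degenerate certainty: a = n
  ci1 <- log_method_ci(50, 50)
  expect_equal(c(ci1$lo, ci1$hi), c(1, 1))
  # a = 0 falls back to the rule of three
  ci0 <- log_method_ci(0, 60)
  expect_true(ci0$zero_numerator)
  expect_equal(c(ci0$lo, ci0$hi), c(0, 0.05))
  # width shrinks with n at fixed p
  w <- function(n) { x <- log_method_ci(round(0.9 * n), n); x$hi - x$lo }
  expect_lt(w(1000), w(100))
  expect_error(log_method_ci(5, 4), "denominator")
})

test_that("the PSF sigma reproduces the instrument value and scales linearly", {
  s <- psf_sigma(910, 0.75)
  expect_equal(round(s / 1000, 2), 0.25)  # 0.25 um at 910 nm, NA 0.75
  expect_equal(s, 0.21 * 910 / 0.75)
  expect_equal(psf_sigma(1820, 0.75), 2 * s)
  expect_equal(psf_sigma(500, 0.5), 210)
  expect_error(psf_sigma(-1, 0.75), "wavelength")
  expect_error(psf_sigma(910, 2), "aperture")
})

test_that("single-particle profiles are recognised against the theoretical PSF", {
  g <- wavelength_grid(700, 1000, 31)
  band <- band_window(833, 988)
  psf <- psf_model(910, 0.75, c(410, 408))
  spot <- function(sig_scale) {
    arr <- array(0.01, c(21, 21, 31))
    spec <- lorentzian_spectrum(900, 30, 1, grid = g)
    for (r in 1:21) for (c in 1:21) {
      w <- exp(-0.5 * ((r - 11) * 410 / (sig_scale * psf$sigma_nm))^2
               - 0.5 * ((c - 11) * 408 / (sig_scale * psf$sigma_nm))^2)
      arr[r, c, ] <- arr[r, c, ] + 50 * w * spec
    }
    set.seed(31)
    arr <- arr * (1 + 0.02 * array(rnorm(length(arr)), dim(arr)))
    hyper_cube(arr, g)
  }
  det <- hsmad:::new_detection_map(matrix(SEG_CANDIDATE, 21, 21),
                                   matrix(NA_integer_, 21, 21),
                                   `[<-`(matrix(FALSE, 21, 21), 11, 11, TRUE),
                                   c("np"), 1L, "test")
  ok <- single_particle_check(spot(1), det, c(11, 11), psf, band)
  expect_true(ok$applicable)
  expect_true(ok$consistent)
  expect_lte(ok$peak_offset_px, 1)
  # a blob 3x wider than the theoretical PSF is rejected
  bad <- single_particle_check(spot(3), det, c(11, 11), psf, band)
  expect_false(bad$consistent)
  # non-isolated sites are not applicable
  det2 <- det; det2$np_mask[13, 11] <- TRUE
  na <- single_particle_check(spot(1), det2, c(11, 11), psf, band)
  expect_false(na$applicable)
  # an exact discrete Gaussian profile has zero RMSE
  clean <- spot(1)
  clean$data <- clean$data * 0
  spec <- lorentzian_spectrum(900, 30, 1, grid = g)
  for (r in 1:21) for (c in 1:21) {
    w <- exp(-0.5 * ((r - 11) * 410 / psf$sigma_nm)^2) *
         exp(-0.5 * ((c - 11) * 408 / psf$sigma_nm)^2)
    clean$data[r, c, ] <- w * spec + 1e-9
  }
  ex <- single_particle_check(clean, det, c(11, 11), psf, band)
  expect_lt(ex$rmse_h + ex$rmse_v, 1e-6)
})
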