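test_that("CT signal converts linearly to concentration and round-trips", {
  m <- compartment_model()
  expect_equal(signal_to_total_concentration(50.1, m), 1.0)
  expect_equal(signal_to_total_concentration(0, m), 0)
  hu <- c(10, 100.2, 25.05)
  expect_equal(signal_to_total_concentration(2 * hu, m),
               2 * signal_to_total_concentration(hu, m))
  conc <- c(0.2, 1.7, 3.4)
  expect_equal(signal_to_total_concentration(conc * m$hu_per_conc, m), conc,
               tolerance = 1e-12)
})

test_that("aorta signal maps to plasma concentration via the hematocrit", {
  m <- compartment_model()
  out <- plasma_from_aorta(c(600, 3600), c(50.1, 50.1), m)
  expect_equal(out$Cp, c(2, 2))
  m1 <- compartment_model(hematocrit = 1)
  expect_equal(plasma_from_aorta(c(0, 10) + 1, c(50.1, 25.05), m1)$Cp,
               c(1, 0.5))
  expect_error(compartment_model(hematocrit = 0), "hematocrit")
})

test_that("the exponential plasma fit recovers its parameters", {
  t <- seq(0, 7.2e5, length.out = 12)
  pl <- plasma_model(a = 5, b = 1e-5)
  fit <- fit_plasma(t, plasma_concentration(pl, t))
  expect_equal(fit$a, 5, tolerance = 1e-8)
  expect_equal(fit$b, 1e-5, tolerance = 1e-8)
  # 5% multiplicative noise: clearance rate within 10% of truth
  set.seed(31)
  noisy <- plasma_concentration(pl, t) * (1 + rnorm(12, 0, 0.05))
  fitn <- fit_plasma(t, noisy)
  expect_lt(abs(fitn$b - 1e-5) / 1e-5, 0.1)
  # constant samples degrade to zero clearance
  expect_equal(fit_plasma(t, rep(3, 12))$b, 0)
  expect_equal(fit_plasma(t, rep(3, 12))$a, 3, tolerance = 1e-12)
  expect_error(fit_plasma(t, rep(0, 12)), "positive")
})

test_that("the early-time image yields the vascular fraction", {
  expect_equal(estimate_vascular_fraction(0.03 * 4, 4), 0.03)
  expect_equal(estimate_vascular_fraction(0, 4), 0)
  expect_warning(v <- estimate_vascular_fraction(5, 4), "unphysical")
  expect_equal(v, 1.25)
  expect_error(estimate_vascular_fraction(1, 0), "positive")
})

test_that("interstitial concentration inverts the compartment mixture", {
  m <- compartment_model(eps_p = 0.03, eps_i = 0.30)
  # pure vascular signal leaves nothing in the interstitium
  expect_equal(as.numeric(interstitial_concentration(0.03 * 1.5, 1.5, m)), 0)
  # worked mixture: C_total = 0.33, C_p = 1 -> C_i = 1
  expect_equal(as.numeric(interstitial_concentration(0.33, 1.0, m)), 1.0,
               tolerance = 1e-12)
  out <- interstitial_concentration(c(0.33, 0.01), 1.0, m)
  expect_equal(attr(out, "n_floored"), 1L)
  expect_equal(as.numeric(out)[2], 0)
  # affine in the total concentration with slope 1/eps_i
  tot <- c(0.2, 0.5, 0.9)
  d <- as.numeric(interstitial_concentration(tot + 0.3, 2, m)) -
    as.numeric(interstitial_concentration(tot, 2, m))
  expect_equal(d, rep(1, 3), tolerance = 1e-12)
})

test_that("tumour cropping zeroes outside signal and sizes the buffer box", {
  img <- array(1, dim = c(9, 9, 9))
  mask <- array(FALSE, dim = c(9, 9, 9)); mask[4:6, 4:6, 4:6] <- TRUE
  out <- crop_to_tumour(img, mask, buffer_voxels = 2)
  expect_equal(dim(out$image), c(7, 7, 7))
  expect_equal(sum(out$image), 27)             # only the 3^3 mask survives
  # identity when the mask covers everything and the buffer is zero
  all_mask <- array(TRUE, dim = c(4, 4, 4))
  img2 <- array(rnorm(64), dim = c(4, 4, 4))
  expect_equal(crop_to_tumour(img2, all_mask, 0)$image, img2)
  # signal entirely outside the mask vanishes
  img3 <- array(0, dim = c(9, 9, 9)); img3[1, 1, 1] <- 5
  expect_equal(sum(crop_to_tumour(img3, mask, 1)$image), 0)
  # box clipping at the array edge
  mask2 <- array(FALSE, dim = c(5, 5, 5)); mask2[1, 1, 1] <- TRUE
  expect_equal(crop_to_tumour(array(1, dim = c(5, 5, 5)), mask2, 2)$box[1, ],
               c(1, 3))
  expect_error(crop_to_tumour(img, array(FALSE, dim = c(9, 9, 9))), "empty")
})

test_that("volumes round-trip through NIfTI with spacing preserved", {
  vol <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path, spacing_cm = 0.05)
  back <- read_volume(path)
  expect_equal(back$values, vol, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$spacing_cm[1:3], rep(0.05, 3), tolerance = 1e-7)
})

test_that("ideal imaging of a simulated tumour recovers the interstitial map", {
  # forward-simulated C_i wrapped as C_total = eps_i C_i + eps_p C_p and
  # pushed back through the preprocessing chain returns C_i to round-off
  m <- compartment_model()
  case <- baseline_case(noise_level = 0, seed = 2, nx = 50)
  t2 <- 200 * 3600
  Ci <- case$conc$values[, 150]
  Cp <- plasma_concentration(case$plasma, t2)
  total <- m$eps_i * Ci + m$eps_p * Cp
  hu <- total * m$hu_per_conc
  rec <- interstitial_concentration(signal_to_total_concentration(hu, m), Cp, m)
  expect_equal(as.numeric(rec), Ci, tolerance = 1e-12)
})
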