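test_that("spectra enforce a strictly monotonic paired axis", {
  expect_s3_class(nmr_spectrum(1:5, rep(1, 5)), "nmr_spectrum")
  # ascending input is stored descending
  sp <- nmr_spectrum(seq(0, 1, 0.1), seq(0, 1, 0.1))
  expect_true(all(diff(sp$ppm) < 0))
  expect_error(nmr_spectrum(c(1, 2, 2, 3), rep(0, 4)), "monotonic")
  expect_error(nmr_spectrum(1:3, 1:4), "same length")
  expect_error(nmr_spectrum(c(1, 2, NA), 1:3), "NA")
})

test_that("reference recalibration recovers an injected axis offset", {
  sp <- simulate_spectrum(milk_preset("organic"), quiet_params())
  step <- abs(diff(sp$ppm[1:2]))
  # already calibrated: applied shift below one axis step
  cal <- reference_shift(sp)
  expect_lt(abs(cal$meta$reference_shift_ppm), step)
  # inject +0.02 ppm offset, recover within one axis step
  off <- sp; off$ppm <- off$ppm + 0.02
  fixed <- reference_shift(off)
  expect_lt(abs(fixed$meta$reference_shift_ppm + 0.02), step)
  i_max <- which.max(fixed$intensity[abs(fixed$ppm - 0.172) < 0.05])
  sel <- which(abs(fixed$ppm - 0.172) < 0.05)
  expect_equal(fixed$ppm[sel[i_max]], 0.172, tolerance = step)
})

test_that("reference recalibration fails cleanly without a reference peak", {
  flat <- nmr_spectrum(seq(0, 1, length.out = 1000), rep(0, 1000))
  expect_error(reference_shift(flat), "reference not found")
  const <- nmr_spectrum(seq(0, 1, length.out = 1000), rep(5, 1000))
  expect_error(reference_shift(const), "reference not found")
  away <- nmr_spectrum(seq(2, 3, length.out = 100), rep(0, 100))
  expect_error(reference_shift(away), "does not cover")
})

test_that("window integration is exact on simple shapes", {
  x <- seq(0, 1, by = 1e-3)
  rect <- nmr_spectrum(x, rep(1, length(x)))
  expect_equal(integrate_window(rect, 0.2, 0.3), 0.1, tolerance = 1e-12)
  zero <- nmr_spectrum(x, rep(0, length(x)))
  expect_equal(integrate_window(zero, 0.2, 0.3), 0)
  # Lorentzian of area A over +/- 20 FWHM captures 2/pi*atan(40) = 98.4%
  fw <- 0.005
  lor <- nmr_spectrum(x, (fw / 2 / pi) / ((x - 0.5)^2 + (fw / 2)^2))
  cap <- integrate_window(lor, 0.5 - 20 * fw, 0.5 + 20 * fw)
  expect_equal(cap, 2 / pi * atan(40), tolerance = 1e-4)
  expect_gte(cap, 0.97)
  expect_error(integrate_window(rect, -1, 0.5), "outside axis")
  expect_error(integrate_window(rect, 0.5, 0.2), "lo_ppm")
})

test_that("integration is linear and additive over adjacent windows", {
  sp <- simulate_spectrum(milk_preset("organic"), quiet_params())
  dbl <- sp; dbl$intensity <- 2 * sp$intensity
  expect_equal(integrate_window(dbl, 1.0, 2.0),
               2 * integrate_window(sp, 1.0, 2.0), tolerance = 1e-12)
  whole <- integrate_window(sp, 1.0, 3.0)
  parts <- integrate_window(sp, 1.0, 1.7) + integrate_window(sp, 1.7, 3.0)
  expect_equal(parts, whole, tolerance = 1e-10)
})

test_that("the linear baseline option subtracts the endpoint chord", {
  x <- seq(0, 1, by = 1e-3)
  ramp <- nmr_spectrum(x, 2 * x)          # pure sloped baseline
  expect_equal(integrate_window(ramp, 0.2, 0.6, baseline = "linear"), 0,
               tolerance = 1e-12)
})

test_that("integral extraction covers all ten symbols and flags gaps", {
  sp <- simulate_spectrum(pure_profile("saturated_pool"), quiet_params())
  I <- extract_integral_set(sp)
  expect_named(I, c("I088", "I095", "D", "C", "I277", "I281",
                    "I499", "I580", "I599", "I628"), ignore.order = TRUE)
  expect_true(all(is.finite(unlist(I))))
  # saturated-only: no bis-allylic or conjugated-diene signal
  tl <- I$I088 + I$I095
  expect_lt(I$I277 / tl, 1e-3)
  expect_lt(I$I281 / tl, 1e-3)
  expect_lt(I$I628 / tl, 1e-3)
  # caproleic H9 and H10a are both one proton: integrals agree
  mix <- fa_profile(saturated_pool = 0.89, oleic_pool = 0.10,
                    caproleic = 0.01)
  Im <- extract_integral_set(simulate_spectrum(mix, quiet_params()))
  expect_equal(Im$I580 / Im$I499, 1, tolerance = 0.05)
  # a missing window is reported by name
  win9 <- integration_windows()[-3, ]
  expect_error(extract_integral_set(sp, win9), "I2.02")
})

test_that("bucketing partitions the 0.03-6.34 ppm region into 631 bins", {
  sp <- simulate_spectrum(milk_preset("organic"), seed = 2)
  b <- bucket_spectrum(sp)
  expect_length(b, 631L)
  edges <- attr(b, "edges")
  expect_equal(edges[1], 0.03)
  expect_equal(edges[length(edges)], 6.34, tolerance = 1e-9)
  # partition additivity: bins sum to the full-range integral
  total <- integrate_window(sp, 0.03, 6.34)
  expect_equal(sum(b), total, tolerance = 1e-9 * abs(total))
  expect_error(bucket_spectrum(nmr_spectrum(seq(0, 2, 0.01), rep(0, 201))),
               "does not cover")
})

test_that("a narrow peak lands in its half-open bucket", {
  x <- seq(0, 7, length.out = 2^15)
  fw <- 5e-4
  y <- (fw / 2 / pi) / ((x - 5.995)^2 + (fw / 2)^2)
  b <- bucket_spectrum(nmr_spectrum(x, y))
  centers <- attr(b, "centers")
  expect_equal(centers[which.max(b)], 5.995)   # bucket [5.99, 6.00)
})

test_that("bucket matrices assemble, tag methyl bins, and round-trip CSV", {
  coh <- simulate_cohort(cohort_spec(n_per_class = 2, seed = 8))
  bm <- bucket_matrix(coh$spectra, coh$classes, coh$sample_ids)
  expect_equal(dim(bm$values), c(4L, 631L))
  expect_equal(bm$normalization, "UNor")
  idx <- methyl_bucket_indices(bm$centers)
  expect_length(idx, 20L)                      # 0.82-1.02 ppm at 0.01 ppm
  expect_true(all(bm$centers[idx] > 0.82 & bm$centers[idx] < 1.02))
  path <- withr::local_tempfile(fileext = ".csv")
  write_bucket_matrix(bm, path)
  back <- read_bucket_matrix(path)
  expect_equal(unname(back$values), unname(bm$values), tolerance = 1e-12)
  expect_equal(as.character(back$classes), as.character(bm$classes))
  expect_equal(back$centers, bm$centers)
})

test_that("spectra survive CSV and JCAMP-DX round trips", {
  sp <- simulate_spectrum(milk_preset("organic"),
                          acquisition_params(n_points = 4096L), seed = 4)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, csv)
  back <- read_spectrum_csv(csv)
  expect_equal(back$ppm, sp$ppm)
  expect_equal(back$intensity, sp$intensity)
  jdx <- withr::local_tempfile(fileext = ".jdx")
  write_jcamp(sp, jdx)
  jback <- read_jcamp(jdx)
  expect_equal(jback$ppm, sp$ppm, tolerance = 1e-8)
  scale <- max(abs(sp$intensity))
  expect_lt(max(abs(jback$intensity - sp$intensity)) / scale, 1e-3)
  expect_error(read_jcamp(csv), "not a recognised JCAMP")
})
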