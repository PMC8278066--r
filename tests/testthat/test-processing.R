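# measure FWHM of the tallest peak by interpolated half-maximum crossings
measured_fwhm_hz <- function(spectrum) {
  y <- spectrum$real_part
  ppm <- spectrum$ppm_axis
  pk <- which.max(y)
  half <- y[pk] / 2
  right <- pk + which(y[(pk + 1):length(y)] < half)[1]
  left <- pk - which(rev(y[1:(pk - 1)]) < half)[1]
  crossing <- function(i1, i2) {
    stats::approx(y[c(i1, i2)], ppm[c(i1, i2)], xout = half)$y
  }
  w_ppm <- abs(crossing(left, left + 1) - crossing(right - 1, right))
  w_ppm * spectrum$acquisition$spectrometer_frequency
}

test_that("exponential apodization adds exactly lb Hz of Lorentzian width", {
  acq <- quick_acq(32768L)
  fid <- synthesize_fid(single_line_sample(linewidth = 0.5), acq, seed = 1)
  # lb = 0 is the identity, and t = 0 is never attenuated
  expect_identical(exponential_apodize(fid, 0)$samples, fid$samples)
  expect_equal(exponential_apodize(fid, 2.5)$samples[1], fid$samples[1])
  w0 <- measured_fwhm_hz(transform_to_spectrum(fid, 65536L))
  w1 <- measured_fwhm_hz(
    transform_to_spectrum(exponential_apodize(fid, 0.3), 65536L))
  expect_equal(w0, 0.5, tolerance = 0.02)
  expect_equal(w1, 0.8, tolerance = 0.02)
  expect_error(exponential_apodize(fid, -0.1), "lb")
})

test_that("the transform maps damped exponentials to centred Lorentzians", {
  acq <- accurate_acq()
  zero <- synthesize_fid(single_line_sample(conc = 0), acq, seed = 1)
  zs <- transform_to_spectrum(zero)
  expect_true(all(zs$real_part == 0) && all(zs$imaginary_part == 0))

  fid <- synthesize_fid(single_line_sample(conc = 2), acq, seed = 1)
  spec <- transform_to_spectrum(fid)
  # peak sits at the carrier within one grid step
  pk_ppm <- spec$ppm_axis[which.max(spec$real_part)]
  expect_lt(abs(pk_ppm - acq$frequency_offset),
            acq$spectral_width / acq$data_points * 1.5)
  # lineshape matches the closed-form absorption Lorentzian of area A
  amp <- oracle_amplitude(single_line_analyte(), 2, acq)
  sel <- abs(spec$ppm_axis - acq$frequency_offset) < 0.05
  hz <- (spec$ppm_axis[sel] - acq$frequency_offset) *
    acq$spectrometer_frequency
  lorentz <- amp * (0.5 / (2 * pi)) / (hz^2 + (0.5 / 2)^2) *
    acq$spectrometer_frequency
  expect_equal(spec$real_part[sel], lorentz, tolerance = 0.02)
  # documented normalization: total ppm-integral equals the first FID sample
  tot <- pracma::trapz(rev(spec$ppm_axis), rev(spec$real_part))
  expect_equal(tot, Re(fid$samples[1]), tolerance = 0.01)
})

test_that("zero-filling interpolates without changing region integrals", {
  acq <- quick_acq(8192L)
  fid <- exponential_apodize(
    synthesize_fid(single_line_sample(conc = 1), acq, seed = 2), 2)
  reg <- integration_region("probe", 6.1, 6.25, "probe")
  a1 <- integrate_region(transform_to_spectrum(fid), reg)$absolute_area
  a2 <- integrate_region(transform_to_spectrum(fid, 16384L),
                         reg)$absolute_area
  expect_equal(a2 / a1, 1, tolerance = 1e-3)
  expect_error(transform_to_spectrum(fid, 1024L), "zero_fill_to")
})

test_that("auto phase recovers injected zero- and first-order errors", {
  acq <- quick_acq(8192L)
  spec <- transform_to_spectrum(
    exponential_apodize(synthesize_fid(mixture_sample(), acq, seed = 3),
                        0.3))
  last_params <- function(s) {
    s$processing_log[[length(s$processing_log)]]$params
  }
  # a well-phased spectrum needs essentially no correction
  p0 <- last_params(auto_phase(spec, order = 1))
  expect_lt(abs(p0$phi0), 1)
  expect_lt(abs(p0$phi1), 1)
  # known injected zero-order error
  p1 <- last_params(auto_phase(phase_spectrum(spec, 30, 0), order = 0))
  expect_lt(abs(p1$phi0 + 30), 1)
  # known injected pair
  p2 <- last_params(auto_phase(phase_spectrum(spec, 20, 40), order = 1))
  expect_lt(abs(p2$phi0 + 20), 2)
  expect_lt(abs(p2$phi1 + 40), 2)
  # idempotence: rephasing changes region integrals by < 0.1%
  ph <- auto_phase(spec, order = 1)
  ph2 <- auto_phase(ph, order = 1)
  reg <- default_regions(pad = 0.05)$FLP
  expect_equal(integrate_region(ph2, reg)$absolute_area /
                 integrate_region(ph, reg)$absolute_area,
               1, tolerance = 1e-3)
})

test_that("polynomial baseline correction removes injected drift", {
  acq <- quick_acq(8192L)
  fid <- exponential_apodize(
    synthesize_fid(mixture_sample(), acq, seed = 4), 0.3)
  clean <- transform_to_spectrum(fid)
  excl <- list(c(6.0, 6.6), c(8.0, 8.6), c(3.4, 4.0), c(2.0, 3.0))
  reg <- default_regions(pad = 0.05)

  # constant offset: removed to a residual far below the offset itself
  off <- clean
  off$real_part <- off$real_part + 5
  corr <- baseline_correct(off, excl, order = 0)
  free <- rep(TRUE, length(corr$ppm_axis))
  for (e in excl) free <- free &
      !(corr$ppm_axis >= e[1] & corr$ppm_axis <= e[2])
  expect_lt(abs(mean(corr$real_part[free])), 5 * 1e-6)

  # linear ramp: removed, peak areas preserved within 1%
  a_before <- integrate_region(clean, reg$FLP)$absolute_area
  ramp <- inject_baseline(clean, c(0.3, -0.04))
  corr2 <- baseline_correct(ramp, excl, order = 2)
  a_after <- integrate_region(corr2, reg$FLP)$absolute_area
  expect_equal(a_after / a_before, 1, tolerance = 0.01)

  # nothing injected: correction is a no-op up to tail absorption
  corr3 <- baseline_correct(clean, excl, order = 2)
  expect_equal(integrate_region(corr3, reg$AZH)$absolute_area /
                 integrate_region(clean, reg$AZH)$absolute_area,
               1, tolerance = 0.01)

  expect_error(baseline_correct(clean, list(c(-100, 100))), "entire axis")
})

test_that("axis referencing rigidly shifts to the assigned value", {
  acq <- quick_acq(8192L)
  spec <- process_spectrum(
    synthesize_fid(mixture_sample(), acq, seed = 5),
    phase_order = NA, baseline_order = NA)
  # simulate a miscalibrated axis: solvent observed at 2.48 instead of 2.50
  shifted <- spec
  shifted$ppm_axis <- shifted$ppm_axis - 0.02
  ref <- reference_axis(shifted, 2.48, 2.50)
  step <- acq$spectral_width / acq$data_points
  shifts <- ref$ppm_axis - shifted$ppm_axis
  expect_lt(diff(range(shifts)), 1e-9)  # rigid shift
  expect_lt(abs(mean(shifts) - 0.02), step)
  # FLP line lands back near its configured position (grid-limited)
  sel <- abs(ref$ppm_axis - 6.319) < 0.006
  pk <- ref$ppm_axis[sel][which.max(ref$real_part[sel])]
  expect_lt(abs(pk - 6.319), 2.5 * step)
  # already-referenced axis: identity within a grid step
  again <- reference_axis(ref, 2.50, 2.50)
  expect_lt(max(abs(again$ppm_axis - ref$ppm_axis)), step)
  # no peak in the search window
  expect_error(reference_axis(spec, 12.0, 12.0), "no reference peak")
  expect_error(reference_axis(spec, 40, 40), "outside the axis")
})

test_that("region integrals survive the full processing chain within 1%", {
  acq <- accurate_acq()
  fid <- synthesize_fid(mixture_sample(), acq, seed = 6)
  raw <- transform_to_spectrum(fid)
  reg <- default_regions(pad = 0.05)
  excl <- list(c(6.0, 6.6), c(8.0, 8.6), c(3.4, 4.0), c(2.0, 3.0))
  proc <- process_spectrum(fid, lb = 0.3, phase_order = 1,
                           exclusion_regions = excl, baseline_order = 2)
  for (r in reg) {
    expect_equal(integrate_region(proc, r)$absolute_area /
                   integrate_region(raw, r)$absolute_area,
                 1, tolerance = 0.01)
  }
})

test_that("processing is deterministic and fully logged", {
  acq <- quick_acq(4096L)
  fid <- synthesize_fid(mixture_sample(), acq, seed = 7)
  excl <- list(c(6.2, 6.4), c(8.2, 8.4), c(3.6, 3.8), c(2.3, 2.7))
  s1 <- process_spectrum(fid, exclusion_regions = excl,
                         reference = c(2.5, 2.5))
  s2 <- process_spectrum(fid, exclusion_regions = excl,
                         reference = c(2.5, 2.5))
  expect_identical(s1$real_part, s2$real_part)
  expect_identical(s1$processing_log, s2$processing_log)
  expect_equal(vapply(s1$processing_log, `[[`, "", "step"),
               c("transform", "auto_phase", "baseline_correct",
                 "reference_axis"))
})
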