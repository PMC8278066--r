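#' Longitudinal magnetization recovery between pulses
#'
#' Fraction of the equilibrium z-magnetization recovered after a 90 degree
#' pulse when the next pulse arrives a repetition time TR later:
#' `Mz/M0 = 1 - exp(-TR / T1)`.
#'
#' At TR = 5 T1 the recovery is 99.3\%, the usual quantitative criterion;
#' at TR = T1 it is about 63\%.
#'
#' @param tr Repetition time in seconds (>= 0). Vectorised.
#' @param t1 Longitudinal relaxation time in seconds (> 0). Vectorised.
#' @return Recovered fraction in \[0, 1).
#' @examples
#' longitudinal_recovery(5, 1)  # 0.9933
#' longitudinal_recovery(1, 1)  # 0.6321
#' @export
longitudinal_recovery <- function(tr, t1) {
  if (any(!is.finite(t1)) || any(t1 <= 0)) {
    stop("t1 must be a positive relaxation time in seconds", call. = FALSE)
  }
  if (any(tr < 0)) stop("tr must be >= 0", call. = FALSE)
  1 - exp(-tr / t1)
}

# Ernst steady-state amplitude factor for repeated pulsing at flip angle
# theta (degrees): sin(theta) * (1 - E) / (1 - E cos(theta)), E = exp(-TR/T1).
# Reduces to 1 - exp(-TR/T1) at theta = 90.
steady_state_factor <- function(flip_angle, tr, t1) {
  theta <- flip_angle * pi / 180
  e1 <- exp(-tr / t1)
  sin(theta) * (1 - e1) / (1 - e1 * cos(theta))
}

#' Quantitative signal amplitude
#'
#' The steady-state integrated amplitude of a quantitative signal:
#' `I = Ks * c * n * (1 - exp(-TR / T1))` for a 90 degree pulse, where Ks is
#' the spectrometer constant, c the molar concentration and n the number of
#' protons generating the signal. When TR exceeds 5 T1 this is within 0.7\%
#' of the fully relaxed amplitude `Ks * c * n`.
#'
#' @param c_molar Molar concentration (mol/l).
#' @param n_protons Number of protons generating the signal.
#' @param tr Repetition time, seconds.
#' @param t1 Longitudinal relaxation time, seconds.
#' @param ks Spectrometer constant (arbitrary scale; cancels in all ratios).
#' @param flip_angle Flip angle in degrees; 90 gives the saturation-recovery
#'   expression above, other angles use the steady-state (Ernst) factor.
#' @return Signal amplitude in Ks units.
#' @examples
#' signal_amplitude(2, 1, tr = 5, t1 = 1) # 1.98652
#' @export
signal_amplitude <- function(c_molar, n_protons, tr, t1, ks = 1,
                             flip_angle = 90) {
  stopifnot(
    "c_molar must be >= 0" = all(c_molar >= 0),
    "n_protons must be > 0" = all(n_protons > 0),
    "ks must be > 0" = all(ks > 0)
  )
  if (any(t1 <= 0)) stop("t1 must be > 0", call. = FALSE)
  if (any(tr < 0)) stop("tr must be >= 0", call. = FALSE)
  ks * c_molar * n_protons * steady_state_factor(flip_angle, tr, t1)
}

#' Concentration conversion: mg/ml of weighed substance to molar
#'
#' `c_molar = c_mgml * (purity/100) / molar_mass`; mg/ml equals g/l, so the
#' division by M in g/mol yields mol/l directly.
#'
#' @param c_mgml Concentration of the weighed material in mg/ml.
#' @param molar_mass Molar mass in g/mol.
#' @param purity Declared purity in percent (scales the active amount).
#' @return Molar concentration in mol/l.
#' @export
mgml_to_molar <- function(c_mgml, molar_mass, purity = 100) {
  stopifnot(molar_mass > 0)
  c_mgml * (purity / 100) / molar_mass
}

#' Define a simulated sample
#'
#' A `sample_spec` pairs each [analyte_spec()] with its concentration and
#' optional gravimetric provenance, plus the solvent line, the time-domain
#' noise level, any multiplicative amplitude noise, and frequency-domain
#' baseline drift.
#'
#' @param components List of component lists; each component has `analyte`
#'   (an `analyte_spec`) and either `concentration` (mg/ml of weighed
#'   material) or `weight` (g) together with `volume` (ml), in which case
#'   `concentration = 1000 * weight / volume`.
#' @param solvent Optional residual solvent line: list with `position` (ppm),
#'   `amplitude` (Ks units) and `linewidth` (Hz). Default: DMSO-d6 residual
#'   line at 2.5 ppm.
#' @param noise_sigma_per_scan Standard deviation of the additive complex
#'   Gaussian time-domain noise of a single scan; averaging N scans scales
#'   the retained noise by 1/sqrt(N). 0 disables it.
#' @param amplitude_rsd Relative standard deviation (fraction, e.g. 0.005 for
#'   0.5\%) of multiplicative Gaussian jitter applied to each component's
#'   amplitude, modelling preparation and integration variability. 0 disables.
#' @param baseline_coefficients Numeric vector of polynomial coefficients
#'   (intercept first, in powers of ppm) describing frequency-domain baseline
#'   drift; applied by [inject_baseline()] after transformation.
#' @param ks Spectrometer constant applied to every amplitude in the sample.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(components,
                        solvent = list(position = 2.5, amplitude = 1,
                                       linewidth = 1),
                        noise_sigma_per_scan = 0,
                        amplitude_rsd = 0,
                        baseline_coefficients = numeric(0),
                        ks = 1) {
  stopifnot(
    "components must be a non-empty list" =
      is.list(components) && length(components) >= 1,
    "noise_sigma_per_scan must be >= 0" = noise_sigma_per_scan >= 0,
    "amplitude_rsd must be >= 0" = amplitude_rsd >= 0,
    "ks must be > 0" = ks > 0
  )
  components <- lapply(components, function(cmp) {
    stopifnot("each component needs an analyte_spec" =
                inherits(cmp$analyte, "analyte_spec"))
    if (is.null(cmp$concentration)) {
      stopifnot("component needs concentration or weight + volume" =
                  !is.null(cmp$weight) && !is.null(cmp$volume))
      if (cmp$volume <= 0) stop("component volume must be > 0", call. = FALSE)
      cmp$concentration <- 1000 * cmp$weight / cmp$volume
    }
    if (cmp$concentration < 0) {
      stop("component concentration must be >= 0", call. = FALSE)
    }
    cmp
  })
  structure(
    list(components = components, solvent = solvent,
         noise_sigma_per_scan = noise_sigma_per_scan,
         amplitude_rsd = amplitude_rsd,
         baseline_coefficients = baseline_coefficients,
         ks = ks),
    class = "sample_spec"
  )
}

#' @export
print.sample_spec <- function(x, ...) {
  cat("<sample_spec>\n")
  for (cmp in x$components) {
    cat(sprintf("  %s at %.4g mg/ml\n", cmp$analyte$name, cmp$concentration))
  }
  if (!is.null(x$solvent)) {
    cat(sprintf("  solvent line at %g ppm\n", x$solvent$position))
  }
  cat(sprintf("  noise sigma/scan %g, amplitude rsd %g, Ks %g\n",
              x$noise_sigma_per_scan, x$amplitude_rsd, x$ks))
  invisible(x)
}

#' Simulate the free induction decay of a sample
#'
#' Renders every line of every component as a damped complex exponential
#' `A * exp((2i*pi*nu - pi*w) * t)` where `nu` is the line offset from the
#' carrier in Hz and `w` its Lorentzian FWHM, so that the real part of the
#' transformed spectrum is an absorption Lorentzian of integrated area A.
#' Line amplitudes follow the steady-state signal equation
#' `A = Ks * c_molar * n * f(flip, TR, T1) * relative_intensity`.
#' Additive complex Gaussian noise with standard deviation
#' `noise_sigma_per_scan / sqrt(n_scans)` models scan averaging.
#'
#' @param sample A [sample_spec()].
#' @param acq An [acquisition_params()]; every configured line must fall
#'   inside its spectral window.
#' @param seed Integer seed; the FID is bit-reproducible given
#'   (sample, acq, seed).
#' @return An object of class `nmr_fid` with fields `samples` (complex),
#'   `dwell_time`, `acquisition`, and `provenance` (seed, amplitudes drawn,
#'   baseline coefficients to be injected after transformation).
#' @export
synthesize_fid <- function(sample, acq, seed = 1L) {
  stopifnot(inherits(sample, "sample_spec"),
            inherits(acq, "acquisition_params"))
  win <- ppm_window(acq)
  for (cmp in sample$components) {
    bad <- cmp$analyte$lines$position < win[1] |
      cmp$analyte$lines$position > win[2]
    if (any(bad)) {
      stop(sprintf(
        "line of %s at %s ppm falls outside the spectral window [%g, %g] ppm",
        cmp$analyte$name,
        paste(cmp$analyte$lines$position[bad], collapse = ", "),
        win[1], win[2]), call. = FALSE)
    }
  }

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  tr <- repetition_time(acq)
  n <- acq$data_points
  t <- (seq_len(n) - 1) * acq$dwell_time
  fid <- complex(real = numeric(n), imaginary = numeric(n))

  drawn <- lapply(sample$components, function(cmp) {
    an <- cmp$analyte
    c_molar <- mgml_to_molar(cmp$concentration, an$molar_mass, an$purity)
    amp <- signal_amplitude(c_molar, an$n_protons, tr, an$t1,
                            ks = sample$ks, flip_angle = acq$flip_angle)
    if (sample$amplitude_rsd > 0) {
      amp <- amp * (1 + stats::rnorm(1, sd = sample$amplitude_rsd))
    }
    amp
  })
  for (i in seq_along(sample$components)) {
    an <- sample$components[[i]]$analyte
    amp <- drawn[[i]]
    if (amp == 0) next
    for (j in seq_len(nrow(an$lines))) {
      nu <- (an$lines$position[j] - acq$frequency_offset) *
        acq$spectrometer_frequency
      decay <- pi * an$lines$linewidth[j]
      fid <- fid + amp * an$lines$relative_intensity[j] *
        exp((2i * pi * nu - decay) * t)
    }
  }
  if (!is.null(sample$solvent) && sample$solvent$amplitude != 0) {
    nu <- (sample$solvent$position - acq$frequency_offset) *
      acq$spectrometer_frequency
    fid <- fid + sample$ks * sample$solvent$amplitude *
      exp((2i * pi * nu - pi * sample$solvent$linewidth) * t)
  }
  if (sample$noise_sigma_per_scan > 0) {
    sig <- sample$noise_sigma_per_scan / sqrt(acq$n_scans)
    fid <- fid + complex(real = stats::rnorm(n, sd = sig),
                         imaginary = stats::rnorm(n, sd = sig))
  }

  structure(
    list(samples = fid,
         dwell_time = acq$dwell_time,
         acquisition = acq,
         provenance = list(
           seed = as.integer(seed),
           component_amplitudes = stats::setNames(
             unlist(drawn),
             vapply(sample$components, function(x) x$analyte$name, "")),
           baseline_coefficients = sample$baseline_coefficients)),
    class = "nmr_fid"
  )
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<nmr_fid> %d complex points, dwell %.3g s (aq %.3f s)\n",
              length(x$samples), x$dwell_time,
              length(x$samples) * x$dwell_time))
  invisible(x)
}

#' Inject polynomial baseline drift into a spectrum
#'
#' Adds `sum(coef[k] * ppm^(k-1))` to the real part, emulating the smooth
#' baseline distortion of real spectra. Used by the simulator after
#' transformation (baseline drift is a frequency-domain artefact); the
#' processing chain removes it again with [baseline_correct()].
#'
#' @param spectrum An `nmr_spectrum`.
#' @param coefficients Polynomial coefficients, intercept first, powers of ppm.
#' @return The spectrum with drifted real part (step logged).
#' @export
inject_baseline <- function(spectrum, coefficients) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (length(coefficients) == 0) return(spectrum)
  drift <- outer(spectrum$ppm_axis, seq_along(coefficients) - 1, `^`) %*%
    coefficients
  spectrum$real_part <- spectrum$real_part + as.numeric(drift)
  log_step(spectrum, "inject_baseline",
           list(coefficients = coefficients))
}
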