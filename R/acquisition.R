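#' Acquisition parameters for a 1D proton NMR experiment
#'
#' Bundles the spectrometer and experiment settings that drive both the
#' simulator and the processing chain. Defaults reproduce a routine 400 MHz
#' quantitative acquisition: 15 ppm spectral width centred at 6.175 ppm,
#' 90 degree pulse, 10 s relaxation delay, 64 scans, 65,536 complex points.
#'
#' The dwell time is fixed by the spectral width (`dwell = 1 / sw_Hz`) and the
#' acquisition time is always derived as `data_points * dwell`; it is not an
#' independent setting, which keeps the time and frequency grids consistent.
#'
#' @param spectral_width Spectral width in ppm.
#' @param frequency_offset Carrier position (centre of the window) in ppm.
#' @param spectrometer_frequency Proton Larmor frequency in MHz.
#' @param data_points Number of complex time-domain points acquired.
#' @param pulse_width Excitation pulse width in microseconds.
#' @param flip_angle Excitation flip angle in degrees, in (0, 180].
#' @param relaxation_delay Inter-scan relaxation delay in seconds.
#' @param dead_time Receiver dead time between pulse and sampling, seconds.
#' @param n_scans Number of averaged scans (>= 1).
#' @param receiver_gain Receiver gain in dB. Carried as metadata; all
#'   quantification is ratio-based and independent of this scalar.
#' @param temperature Sample temperature in degrees Celsius (metadata only).
#'
#' @return An object of class `acquisition_params`.
#'
#' @details The repetition time TR -- the time between two excitation pulses --
#'   is the sum of pulse width, dead time, acquisition time and relaxation
#'   delay; retrieve it with [repetition_time()]. Quantitative work requires
#'   TR at least five times the longest T1 in the sample, which recovers
#'   99.3\% of the equilibrium magnetization per scan.
#'
#' @examples
#' acq <- acquisition_params()
#' repetition_time(acq) # about 20.9 s with the defaults
#' @export
acquisition_params <- function(spectral_width = 15,
                               frequency_offset = 6.175,
                               spectrometer_frequency = 400,
                               data_points = 65536L,
                               pulse_width = 13.5,
                               flip_angle = 90,
                               relaxation_delay = 10,
                               dead_time = 0,
                               n_scans = 64L,
                               receiver_gain = 32,
                               temperature = 20) {
  stopifnot(
    "spectral_width must be > 0" = is.numeric(spectral_width) && spectral_width > 0,
    "data_points must be a positive count" =
      is.numeric(data_points) && data_points >= 1 && data_points == round(data_points),
    "spectrometer_frequency must be > 0" = spectrometer_frequency > 0,
    "n_scans must be >= 1" = is.numeric(n_scans) && n_scans >= 1,
    "relaxation_delay must be >= 0" = relaxation_delay >= 0,
    "dead_time must be >= 0" = dead_time >= 0,
    "pulse_width must be >= 0" = pulse_width >= 0
  )
  if (!is.numeric(flip_angle) || flip_angle <= 0 || flip_angle > 180) {
    stop("flip_angle must lie in (0, 180] degrees", call. = FALSE)
  }
  sw_hz <- spectral_width * spectrometer_frequency
  dwell <- 1 / sw_hz
  acq <- structure(
    list(
      spectral_width = spectral_width,
      frequency_offset = frequency_offset,
      spectrometer_frequency = spectrometer_frequency,
      data_points = as.integer(data_points),
      dwell_time = dwell,
      acquisition_time = data_points * dwell,
      pulse_width = pulse_width,
      flip_angle = flip_angle,
      relaxation_delay = relaxation_delay,
      dead_time = dead_time,
      n_scans = as.integer(n_scans),
      receiver_gain = receiver_gain,
      temperature = temperature
    ),
    class = "acquisition_params"
  )
  acq
}

#' Repetition time of an acquisition
#'
#' Total time between two excitation pulses: pulse width + dead time +
#' acquisition time + relaxation delay.
#'
#' @param acq An [acquisition_params()] object.
#' @return Repetition time TR in seconds.
#' @export
repetition_time <- function(acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  acq$pulse_width * 1e-6 + acq$dead_time + acq$acquisition_time +
    acq$relaxation_delay
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("<acquisition_params>\n")
  cat(sprintf("  %g MHz, sw %g ppm (%g Hz), offset %g ppm\n",
              x$spectrometer_frequency, x$spectral_width,
              x$spectral_width * x$spectrometer_frequency,
              x$frequency_offset))
  cat(sprintf("  %d points, aq %.3f s, flip %g deg, d1 %g s, %d scans\n",
              x$data_points, x$acquisition_time, x$flip_angle,
              x$relaxation_delay, x$n_scans))
  cat(sprintf("  TR %.3f s\n", repetition_time(x)))
  invisible(x)
}

# ppm window covered by an acquisition: c(low, high)
ppm_window <- function(acq) {
  c(acq$frequency_offset - acq$spectral_width / 2,
    acq$frequency_offset + acq$spectral_width / 2)
}
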