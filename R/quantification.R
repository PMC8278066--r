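#' Declare an integration region
#'
#' A labelled ppm interval owned by one analyte (or the internal standard).
#' Regions for different owners must not overlap.
#'
#' @param label Region label.
#' @param low,high Region bounds in ppm, `low < high`.
#' @param owner Name of the analyte whose signal the region integrates.
#' @return An object of class `integration_region`.
#' @export
integration_region <- function(label, low, high, owner = label) {
  if (!(is.numeric(low) && is.numeric(high) && low < high)) {
    stop("region bounds must satisfy low < high", call. = FALSE)
  }
  structure(list(label = label, low = low, high = high, owner = owner),
            class = "integration_region")
}

#' Default quantitative regions of the nasal-spray assay
#'
#' The three regions integrate the FLP doublet-of-doublets (6.290-6.319 ppm),
#' the AZH doublet (8.292-8.310 ppm) and the inositol doublet
#' (3.70-3.71 ppm), each padded by `pad` ppm on both sides to capture the
#' Lorentzian tails at routine linewidths.
#'
#' @param pad Padding added to each side of the outermost lines, ppm.
#' @return Named list of [integration_region()] objects
#'   (`FLP`, `AZH`, `inositol`).
#' @export
default_regions <- function(pad = 0.02) {
  list(
    FLP = integration_region("FLP", 6.290 - pad, 6.319 + pad, "FLP"),
    AZH = integration_region("AZH", 8.292 - pad, 8.310 + pad, "AZH"),
    inositol = integration_region("inositol", 3.70 - pad, 3.71 + pad,
                                  "inositol")
  )
}

check_region_overlap <- function(regions) {
  regs <- unname(regions)
  if (length(regs) < 2) return(invisible(TRUE))
  for (i in seq_len(length(regs) - 1)) {
    for (j in (i + 1):length(regs)) {
      a <- regs[[i]]; b <- regs[[j]]
      if (a$owner != b$owner && a$low < b$high && b$low < a$high) {
        stop(sprintf("regions '%s' and '%s' of different owners overlap",
                     a$label, b$label), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Integrate a spectral region
#'
#' Trapezoidal integral of the real part over `[low, high]` ppm on the native
#' grid, the instrument-style region integral. With the package's spectrum
#' normalisation an absorption line of simulated amplitude A integrates to A
#' (up to the Lorentzian tail fraction outside the region).
#'
#' @param spectrum A baseline-corrected `nmr_spectrum`.
#' @param region An [integration_region()].
#' @param solvent_position Optional solvent line position; a warning is
#'   issued if the region contains it.
#' @return A list of class `integral_result` with `region`, `absolute_area`
#'   and (initially `NA`) `ratio_to_standard`.
#' @export
integrate_region <- function(spectrum, region, solvent_position = NULL) {
  stopifnot(inherits(spectrum, "nmr_spectrum"),
            inherits(region, "integration_region"))
  ppm <- spectrum$ppm_axis
  if (region$low < min(ppm) || region$high > max(ppm)) {
    stop(sprintf("region '%s' [%g, %g] lies outside the axis [%g, %g] ppm",
                 region$label, region$low, region$high, min(ppm), max(ppm)),
         call. = FALSE)
  }
  if (!is.null(solvent_position) &&
      solvent_position >= region$low && solvent_position <= region$high) {
    warning(sprintf("region '%s' overlaps the solvent line at %g ppm",
                    region$label, solvent_position))
  }
  sel <- which(ppm >= region$low & ppm <= region$high)
  if (length(sel) < 2) {
    stop(sprintf("region '%s' covers fewer than 2 grid points",
                 region$label), call. = FALSE)
  }
  # axis is descending; integrate on the ascending view for a positive area
  area <- as.numeric(
    pracma::trapz(rev(ppm[sel]), rev(spectrum$real_part[sel])))
  structure(list(region = region, absolute_area = area,
                 ratio_to_standard = NA_real_),
            class = "integral_result")
}

#' @export
print.integral_result <- function(x, ...) {
  cat(sprintf("<integral_result> %s [%g, %g] ppm: area %.6g",
              x$region$label, x$region$low, x$region$high, x$absolute_area))
  if (!is.na(x$ratio_to_standard)) {
    cat(sprintf(", ratio %.6g", x$ratio_to_standard))
  }
  cat("\n")
  invisible(x)
}

#' Ratio of an analyte integral to the internal-standard integral
#'
#' `I1 / I2`, the quantity actually used for quantification. The spectrometer
#' constant and receiver gain cancel: any global rescaling of the spectrum
#' leaves the ratio unchanged, since both areas come from the same spectrum.
#'
#' @param analyte,standard `integral_result` objects from the same spectrum.
#' @return The analyte result with `ratio_to_standard` filled in.
#' @export
integral_ratio <- function(analyte, standard) {
  stopifnot(inherits(analyte, "integral_result"),
            inherits(standard, "integral_result"))
  if (!is.finite(standard$absolute_area) || standard$absolute_area <= 0) {
    stop("degenerate internal-standard area (<= 0)", call. = FALSE)
  }
  analyte$ratio_to_standard <- analyte$absolute_area / standard$absolute_area
  analyte
}

#' Purity from the internal-standard integral ratio
#'
#' The internal-standard purity equation: with equal volumes for analyte and
#' standard,
#' `P1 = (I1/I2) * (n2/n1) * (M1/M2) * (W2/W1) * P2`,
#' where I are integral areas, n proton counts, M molar masses, W gravimetric
#' weights and P2 the declared purity of the standard (percent).
#'
#' @param ratio Integral ratio I1/I2 (analyte over standard), or an
#'   `integral_result` carrying `ratio_to_standard`.
#' @param n1,n2 Proton counts of analyte and standard signals.
#' @param m1,m2 Molar masses, g/mol.
#' @param w1,w2 Gravimetric weights, g (same units for both).
#' @param p2 Declared purity of the standard, percent.
#' @return Analyte purity P1 in percent.
#' @export
purity_from_ratio <- function(ratio, n1, n2, m1, m2, w1, w2, p2) {
  if (inherits(ratio, "integral_result")) ratio <- ratio$ratio_to_standard
  stopifnot(
    "proton counts must be positive" = n1 > 0 && n2 > 0,
    "molar masses must be positive" = m1 > 0 && m2 > 0,
    "p2 must lie in (0, 100]" = p2 > 0 && p2 <= 100
  )
  if (!(w1 > 0 && w2 > 0)) {
    stop("gravimetric weights must be positive", call. = FALSE)
  }
  ratio * (n2 / n1) * (m1 / m2) * (w2 / w1) * p2
}

#' Concentration from a fitted calibration line
#'
#' Inverts the calibration `ratio = a + b * C` to `C = (ratio - a) / b`.
#' Values outside the validated range (optionally extended by
#' `extrapolation_pct` percent) are flagged, not rejected.
#'
#' @param ratio Observed integral ratio(s).
#' @param model A [fit_calibration()] model (class `calibration_model`).
#' @param extrapolation_pct Allowed excursion beyond the validated range
#'   before the `out_of_range` flag is set, in percent of the range span.
#' @return A tibble with columns `ratio`, `concentration`, `out_of_range`.
#' @export
concentration_from_calibration <- function(ratio, model,
                                           extrapolation_pct = 0) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope == 0) stop("calibration slope is zero", call. = FALSE)
  conc <- (ratio - model$intercept) / model$slope
  flag <- rep(FALSE, length(conc))
  if (!is.null(model$range) && all(is.finite(model$range))) {
    span <- diff(model$range) * extrapolation_pct / 100
    lo <- model$range[1] - span
    hi <- model$range[2] + span
    flag <- conc < lo | conc > hi
  }
  tibble::tibble(ratio = ratio, concentration = conc, out_of_range = flag)
}

#' Quantify a processed spectrum against declared regions
#'
#' Integrates every region, forms the ratio of each analyte region to the
#' internal-standard region, and (optionally) converts ratios to
#' concentrations through per-analyte calibration models.
#'
#' @param spectrum A processed `nmr_spectrum`.
#' @param regions List of [integration_region()]s including one owned by
#'   `standard`.
#' @param standard Owner name of the internal-standard region.
#' @param calibrations Optional named list of `calibration_model`s keyed by
#'   analyte owner.
#' @param solvent_position Optional solvent position for overlap warnings.
#' @return A tibble with one row per region: `label`, `owner`, `low`, `high`,
#'   `area`, `ratio`, `concentration`, `out_of_range`.
#' @export
quantify_spectrum <- function(spectrum, regions = default_regions(),
                              standard = "inositol",
                              calibrations = NULL,
                              solvent_position = NULL) {
  check_region_overlap(regions)
  owners <- vapply(regions, function(r) r$owner, "")
  if (!standard %in% owners) {
    stop(sprintf("no region owned by internal standard '%s'", standard),
         call. = FALSE)
  }
  ints <- lapply(regions, integrate_region, spectrum = spectrum,
                 solvent_position = solvent_position)
  std <- ints[[which(owners == standard)[1]]]
  rows <- lapply(ints, function(ir) {
    ratio <- integral_ratio(ir, std)$ratio_to_standard
    conc <- NA_real_
    oor <- NA
    if (!is.null(calibrations) && ir$region$owner %in% names(calibrations)) {
      cc <- concentration_from_calibration(
        ratio, calibrations[[ir$region$owner]])
      conc <- cc$concentration
      oor <- cc$out_of_range
    }
    tibble::tibble(label = ir$region$label, owner = ir$region$owner,
                   low = ir$region$low, high = ir$region$high,
                   area = ir$absolute_area, ratio = ratio,
                   concentration = conc, out_of_range = oor)
  })
  do.call(rbind, rows)
}
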