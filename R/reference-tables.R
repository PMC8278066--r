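#' Reference validation datasets of the FLP/AZH nasal-spray assay
#'
#' Replicate-level results reported for the published validation of the
#' qNMR nasal-spray assay this package models, shipped so that the
#' validation statistics can be recomputed and compared. Each element is a
#' tibble:
#'
#' * `accuracy` -- per-concentration mean recoveries of FLP and AZH in pure
#'   form by qNMR (8 levels each) and by the reference HPLC method (4 levels
#'   each), percent.
#' * `precision` -- intra- and inter-day percent-found triplicates at 1.0,
#'   5.0 and 10.0 mg/ml for both drugs.
#' * `stability` -- percent assay of the sample solution at 0, 6, 12 and
#'   24 h.
#' * `lab_mixture` -- recoveries from the 1:2.74 FLP:AZH laboratory mixture
#'   (qNMR and HPLC, three levels each).
#' * `nasal_spray` -- recoveries from the marketed nasal-spray suspension.
#' * `calibration` -- the reported calibration performance parameters
#'   (slope, intercept, r, Sy/x, Sa, Sb, range) per drug.
#'
#' @return A named list of tibbles.
#' @export
reference_tables <- function() {
  accuracy <- tibble::tibble(
    drug = rep(c("FLP", "AZH"), each = 8),
    method = "qNMR",
    taken = c(0.25, 0.30, 0.80, 1.00, 5.00, 10.00, 15.00, 20.00,
              0.20, 0.30, 0.80, 1.00, 5.00, 8.00, 10.00, 15.00),
    recovery = c(98.80, 100.33, 102.00, 100.10, 99.52, 100.36, 99.84, 100.18,
                 98.50, 98.00, 101.38, 99.60, 99.78, 100.18, 99.96, 99.95)
  )
  accuracy_hplc <- tibble::tibble(
    drug = rep(c("FLP", "AZH"), each = 4),
    method = "HPLC",
    taken = c(0.25, 0.30, 0.80, 1.00, 0.20, 0.30, 0.80, 1.00),
    recovery = c(100.19, 99.26, 101.71, 99.65,
                 98.84, 99.13, 101.04, 99.43)
  )
  precision <- tibble::tibble(
    scheme = rep(c("intra", "inter"), each = 18),
    drug = rep(rep(c("FLP", "AZH"), each = 9), 2),
    concentration = rep(rep(c(1.0, 5.0, 10.0), each = 3), 4),
    found = c(
      # intra-day FLP 1 / 5 / 10
      101.27, 100.06, 101.22, 100.12, 99.52, 100.00, 101.57, 100.36, 100.96,
      # intra-day AZH 1 / 5 / 10
      99.64, 100.36, 100.72, 100.29, 99.78, 99.28, 98.53, 99.96, 99.25,
      # inter-day FLP 1 / 5 / 10
      101.08, 100.06, 99.46, 100.48, 99.52, 99.76, 100.96, 100.36, 99.16,
      # inter-day AZH 1 / 5 / 10
      98.57, 100.36, 99.64, 100.29, 99.78, 98.04, 98.53, 99.96, 100.39)
  )
  stability <- tibble::tibble(
    drug = rep(c("FLP", "AZH"), each = 4),
    time_h = rep(c(0, 6, 12, 24), 2),
    percent_assay = c(100.36, 100.42, 100.30, 100.06,
                      99.96, 99.86, 99.57, 99.93)
  )
  lab_mixture <- tibble::tibble(
    drug = rep(c("FLP", "AZH"), each = 3),
    taken = c(0.37, 1.83, 2.92, 1.00, 5.00, 8.00),
    recovery_qnmr = c(100.84, 98.70, 99.23, 100.36, 99.78, 99.37),
    recovery_hplc = c(99.99, 102.37, 101.62, 99.89, 100.33, 101.43)
  )
  nasal_spray <- tibble::tibble(
    drug = rep(c("FLP", "AZH"), each = 3),
    taken = c(0.40, 0.60, 0.80, 1.096, 1.644, 2.192),
    recovery_qnmr = c(98.64, 100.63, 98.34, 100.98, 98.98, 99.42),
    recovery_hplc = c(99.16, 98.82, 100.89, 99.96, 100.13, 101.75)
  )
  calibration <- tibble::tibble(
    drug = c("FLP", "AZH"),
    range_low = c(0.25, 0.20), range_high = c(20.0, 15.0),
    r = c(0.9999, 0.9999),
    slope = c(0.02, 0.03),
    intercept = c(64e-4, 1e-4),
    lod = c(0.04, 0.02), loq = c(0.12, 0.05),
    sy_x = c(43e-5, 27e-5), sa = c(21e-5, 13e-5), sb = c(2e-5, 2e-5)
  )
  list(accuracy = rbind(accuracy, accuracy_hplc),
       precision = precision,
       stability = stability,
       lab_mixture = lab_mixture,
       nasal_spray = nasal_spray,
       calibration = calibration)
}
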