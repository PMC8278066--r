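#' Describe one compound's quantitative NMR signal
#'
#' An `analyte_spec` holds everything the simulator and the purity equation
#' need to know about one compound: the positions and relative intensities of
#' the lines of its quantitative multiplet, the number of protons generating
#' that multiplet, the molar mass, the declared purity, and the longitudinal
#' relaxation time T1.
#'
#' @param name Compound name (used to match integration regions).
#' @param molar_mass Molar mass M in g/mol.
#' @param n_protons Number of equivalent protons n generating the quantitative
#'   multiplet.
#' @param t1 Longitudinal relaxation time T1 in seconds.
#' @param lines Data frame (or tibble) with columns `position` (ppm),
#'   `relative_intensity` (dimensionless, will be normalised to sum to 1) and
#'   `linewidth` (Lorentzian FWHM, Hz).
#' @param purity Declared purity P in percent, in (0, 100].
#'
#' @return An object of class `analyte_spec`.
#' @seealso [flp_spec()], [azh_spec()], [inositol_spec()] for the built-in
#'   nasal-spray assay compounds.
#' @export
analyte_spec <- function(name, molar_mass, n_protons, t1, lines,
                         purity = 100) {
  lines <- as.data.frame(lines)
  stopifnot(
    "lines needs columns position, relative_intensity, linewidth" =
      all(c("position", "relative_intensity", "linewidth") %in% names(lines)),
    "molar_mass must be > 0" = is.numeric(molar_mass) && molar_mass > 0,
    "n_protons must be >= 1" = is.numeric(n_protons) && n_protons >= 1,
    "at least one line required" = nrow(lines) >= 1,
    "linewidths must be > 0" = all(lines$linewidth > 0),
    "relative intensities must be > 0" = all(lines$relative_intensity > 0)
  )
  if (!is.numeric(t1) || t1 <= 0) {
    stop("t1 must be a positive relaxation time in seconds", call. = FALSE)
  }
  if (!is.numeric(purity) || purity <= 0 || purity > 100) {
    stop("purity must lie in (0, 100] percent", call. = FALSE)
  }
  lines$relative_intensity <- lines$relative_intensity /
    sum(lines$relative_intensity)
  structure(
    list(name = name, molar_mass = molar_mass,
         n_protons = n_protons, t1 = t1,
         lines = lines, purity = purity),
    class = "analyte_spec"
  )
}

#' @export
print.analyte_spec <- function(x, ...) {
  cat(sprintf("<analyte_spec> %s: M %.2f g/mol, n %g H, T1 %g s, P %.2f%%\n",
              x$name, x$molar_mass, x$n_protons, x$t1, x$purity))
  cat(sprintf("  %d line(s) at %s ppm\n", nrow(x$lines),
              paste(format(x$lines$position, digits = 5), collapse = ", ")))
  invisible(x)
}

#' Built-in analytes of the nasal-spray assay
#'
#' Ready-made [analyte_spec()] objects for the three compounds of the
#' fluticasone propionate / azelastine hydrochloride nasal-spray assay:
#'
#' * `flp_spec()` -- fluticasone propionate (FLP), quantified on the vinylic
#'   doublet-of-doublets at 6.290, 6.294, 6.316 and 6.319 ppm (four lines of
#'   equal intensity).
#' * `azh_spec()` -- azelastine hydrochloride (AZH), quantified on the
#'   aromatic doublet at 8.292 and 8.310 ppm. The molar mass is that of the
#'   hydrochloride salt, the form that is weighed.
#' * `inositol_spec()` -- myo-inositol, the internal standard, with its
#'   doublet at 3.70 and 3.71 ppm.
#'
#' T1 values are not critical so long as the repetition time exceeds five
#' times the longest of them (as it does under the default acquisition, TR
#' about 21 s); the defaults of 1.2-2.0 s are typical for small molecules in
#' DMSO-d6 and can be overridden.
#'
#' @param t1 Longitudinal relaxation time in seconds.
#' @param linewidth Lorentzian FWHM of each line, Hz.
#' @param n_protons Protons generating the quantitative multiplet. The
#'   assay's ratio-based quantification is insensitive to this choice as long
#'   as it is used consistently; 1 is the neutral default.
#' @param purity Declared purity in percent.
#' @return An `analyte_spec`.
#' @name builtin_analytes
NULL

multiplet <- function(positions, linewidth) {
  data.frame(position = positions,
             relative_intensity = rep(1 / length(positions), length(positions)),
             linewidth = linewidth)
}

#' @rdname builtin_analytes
#' @export
flp_spec <- function(t1 = 1.2, linewidth = 0.5, n_protons = 1,
                     purity = 99.50) {
  analyte_spec("FLP", molar_mass = 500.57, n_protons = n_protons, t1 = t1,
               lines = multiplet(c(6.290, 6.294, 6.316, 6.319), linewidth),
               purity = purity)
}

#' @rdname builtin_analytes
#' @export
azh_spec <- function(t1 = 1.5, linewidth = 0.5, n_protons = 1,
                     purity = 99.80) {
  analyte_spec("AZH", molar_mass = 418.36, n_protons = n_protons, t1 = t1,
               lines = multiplet(c(8.292, 8.310), linewidth),
               purity = purity)
}

#' @rdname builtin_analytes
#' @export
inositol_spec <- function(t1 = 2.0, linewidth = 0.5, n_protons = 1,
                          purity = 99.50) {
  analyte_spec("inositol", molar_mass = 180.16, n_protons = n_protons,
               t1 = t1,
               lines = multiplet(c(3.70, 3.71), linewidth),
               purity = purity)
}
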