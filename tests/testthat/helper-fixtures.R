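# shared fixtures: a reduced acquisition for fast simulation, and the
# standard three-component panel

quick_acq <- function(data_points = 8192L, ...) {
  acquisition_params(data_points = data_points, ...)
}

# capture-accurate acquisition for absolute-area checks (longer FID, less
# truncation ringing)
accurate_acq <- function() acquisition_params(data_points = 32768L)

test_panel <- function(...) assay_panel(...)

# expected steady-state amplitude of one component, from the quantitative
# signal equation evaluated directly (independent of the simulator path)
oracle_amplitude <- function(analyte, conc_mgml, acq, ks = 1) {
  tr <- repetition_time(acq)
  molar <- conc_mgml * (analyte$purity / 100) / analyte$molar_mass
  theta <- acq$flip_angle * pi / 180
  e1 <- exp(-tr / analyte$t1)
  ks * molar * analyte$n_protons * sin(theta) * (1 - e1) / (1 - e1 * cos(theta))
}

# one analyte + internal standard, noise-free by default
mixture_sample <- function(conc = c(FLP = 5, AZH = 13.7),
                           standard_conc = 10,
                           panel = test_panel(),
                           solvent = list(position = 2.5, amplitude = 1,
                                          linewidth = 1),
                           ...) {
  comps <- list(list(analyte = panel$standard,
                     concentration = standard_conc))
  for (nm in names(conc)) {
    comps <- c(comps, list(list(analyte = panel$analytes[[nm]],
                                concentration = conc[[nm]])))
  }
  sample_spec(comps, solvent = solvent, ...)
}

# a single-line "analyte" centred at the carrier, for lineshape tests
single_line_analyte <- function(position = 6.175, linewidth = 0.5) {
  analyte_spec("probe", molar_mass = 100, n_protons = 1, t1 = 1,
               lines = data.frame(position = position,
                                  relative_intensity = 1,
                                  linewidth = linewidth))
}

multiplet_df <- function() {
  data.frame(position = 1, relative_intensity = 1, linewidth = 0.5)
}

multiplet_df_at <- function(position, linewidth = 0.5) {
  data.frame(position = position,
             relative_intensity = rep(1 / length(position),
                                      length(position)),
             linewidth = linewidth)
}

single_line_sample <- function(conc = 1, position = 6.175,
                               linewidth = 0.5, ...) {
  sample_spec(list(list(analyte = single_line_analyte(position, linewidth),
                        concentration = conc)),
              solvent = NULL, ...)
}
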