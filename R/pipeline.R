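#' Built-in assay panel
#'
#' The standard three-component panel of the nasal-spray assay: FLP and AZH
#' as analytes, inositol as internal standard at 10 mg/ml.
#'
#' @param t1_flp,t1_azh,t1_inositol T1 values, seconds.
#' @param linewidth Common Lorentzian FWHM, Hz.
#' @return List with `analytes` (named list of [analyte_spec()]) and
#'   `standard` (inositol spec).
#' @export
assay_panel <- function(t1_flp = 1.2, t1_azh = 1.5, t1_inositol = 2.0,
                        linewidth = 0.5) {
  list(
    analytes = list(FLP = flp_spec(t1 = t1_flp, linewidth = linewidth),
                    AZH = azh_spec(t1 = t1_azh, linewidth = linewidth)),
    standard = inositol_spec(t1 = t1_inositol, linewidth = linewidth)
  )
}

# baseline-fit exclusion windows: quantitative regions padded wide (the
# Lorentzian tails must not be mistaken for baseline), plus the solvent
# line neighbourhood
default_exclusions <- function(regions = default_regions(),
                               solvent_position = 2.5, extra_pad = 0.25) {
  ex <- lapply(regions, function(r) c(r$low - extra_pad, r$high + extra_pad))
  c(unname(ex), list(c(solvent_position - 0.3, solvent_position + 0.3)))
}

#' Simulate and process one assay spectrum
#'
#' Builds the sample (analytes at the given concentrations plus the internal
#' standard), synthesizes the FID and runs the standard processing chain.
#'
#' @param concentrations Named numeric vector of analyte concentrations in
#'   mg/ml, names matching the panel's analytes (e.g. `c(FLP = 5)`).
#' @param panel An [assay_panel()].
#' @param standard_conc Internal-standard concentration, mg/ml.
#' @param acq An [acquisition_params()].
#' @param amplitude_rsd Multiplicative per-component amplitude noise
#'   (fraction).
#' @param noise_sigma_per_scan Additive time-domain noise per scan.
#' @param baseline_coefficients Injected baseline drift polynomial.
#' @param seed Integer seed.
#' @param lb,phase_order,baseline_order Processing parameters; see
#'   [process_spectrum()].
#' @return A processed `nmr_spectrum`.
#' @export
simulate_assay_spectrum <- function(concentrations,
                                    panel = assay_panel(),
                                    standard_conc = 10,
                                    acq = acquisition_params(),
                                    amplitude_rsd = 0,
                                    noise_sigma_per_scan = 0,
                                    baseline_coefficients = numeric(0),
                                    seed = 1L,
                                    lb = 0.3,
                                    phase_order = 0,
                                    baseline_order = 2) {
  comps <- list(list(analyte = panel$standard,
                     concentration = standard_conc))
  for (nm in names(concentrations)) {
    if (!nm %in% names(panel$analytes)) {
      stop("unknown analyte in concentrations: ", nm, call. = FALSE)
    }
    comps <- c(comps, list(list(analyte = panel$analytes[[nm]],
                                concentration = concentrations[[nm]])))
  }
  sample <- sample_spec(comps,
                        noise_sigma_per_scan = noise_sigma_per_scan,
                        amplitude_rsd = amplitude_rsd,
                        baseline_coefficients = baseline_coefficients)
  fid <- synthesize_fid(sample, acq, seed = seed)
  process_spectrum(fid, lb = lb, phase_order = phase_order,
                   exclusion_regions = default_exclusions(),
                   baseline_order = baseline_order)
}

#' Run a calibration series through the full pipeline
#'
#' Simulates one spectrum per calibration level (analyte at the level, the
#' internal standard at `standard_conc`), processes it, integrates the
#' quantitative regions, forms the integral ratio and fits the calibration
#' line.
#'
#' @param analyte Analyte name within the panel (`"FLP"` or `"AZH"` for the
#'   default panel).
#' @param concentrations Calibration levels, mg/ml.
#' @param seed Base seed; level i uses `seed + i - 1`.
#' @inheritParams simulate_assay_spectrum
#' @param regions Integration regions (see [default_regions()]).
#' @return List with `points` (tibble of concentration, ratio) and `model`
#'   (a [fit_calibration()] model).
#' @export
calibration_study <- function(analyte = "FLP",
                              concentrations = c(0.25, 0.5, 1, 2.5, 5,
                                                 10, 15, 20),
                              panel = assay_panel(),
                              standard_conc = 10,
                              acq = acquisition_params(),
                              amplitude_rsd = 0,
                              noise_sigma_per_scan = 0,
                              seed = 1L,
                              regions = default_regions()) {
  ratios <- vapply(seq_along(concentrations), function(i) {
    conc <- stats::setNames(concentrations[i], analyte)
    spec <- simulate_assay_spectrum(conc, panel, standard_conc, acq,
                                    amplitude_rsd, noise_sigma_per_scan,
                                    seed = seed + i - 1)
    q <- quantify_spectrum(spec, regions)
    q$ratio[q$owner == analyte]
  }, numeric(1))
  points <- tibble::tibble(concentration = concentrations, ratio = ratios)
  list(points = points,
       model = fit_calibration(points$concentration, points$ratio))
}

#' Linearity study over repeated seeded runs
#'
#' Repeats [calibration_study()] `n_runs` times with per-run seeds derived
#' from `base_seed` and collects the r-squared of each fitted calibration.
#'
#' @param n_runs Number of seeded repetitions.
#' @param base_seed Base seed; run k uses seeds
#'   `base_seed * 1000 + (k - 1) * length(concentrations) + i` per level.
#' @inheritParams calibration_study
#' @return Tibble with `run`, `r_squared`, `slope`, `intercept`.
#' @export
linearity_runs <- function(n_runs = 200, base_seed = 1,
                           analyte = "FLP",
                           concentrations = c(0.25, 0.5, 1, 2.5, 5,
                                              10, 15, 20),
                           panel = assay_panel(),
                           standard_conc = 10,
                           acq = acquisition_params(data_points = 8192L),
                           amplitude_rsd = 0.005) {
  rows <- lapply(seq_len(n_runs), function(k) {
    cs <- calibration_study(
      analyte, concentrations, panel, standard_conc, acq,
      amplitude_rsd = amplitude_rsd,
      seed = base_seed * 1000 + (k - 1) * length(concentrations) + 1)
    tibble::tibble(run = k, r_squared = cs$model$r_squared,
                   slope = cs$model$slope, intercept = cs$model$intercept)
  })
  do.call(rbind, rows)
}

#' Precision study on simulated triplicates
#'
#' For each seeded run, simulates `replicates` spectra at each concentration
#' (with multiplicative amplitude noise), quantifies them against a
#' noise-free calibration fitted once under identical conditions, and
#' records the percent-RSD of the found concentrations per cell and the
#' per-run maximum across cells.
#'
#' @param n_runs Number of seeded runs.
#' @param base_seed Base seed for the derived per-spectrum seeds.
#' @param concentrations Assay levels, mg/ml.
#' @param replicates Replicates per level.
#' @inheritParams calibration_study
#' @return List with `cells` (tibble run x concentration: `rsd_percent`,
#'   `mean_recovery`) and `max_rsd` (numeric, per-run maximum %RSD).
#' @export
precision_runs <- function(n_runs = 200, base_seed = 1,
                           concentrations = c(1, 5, 10),
                           replicates = 3,
                           analyte = "FLP",
                           panel = assay_panel(),
                           standard_conc = 10,
                           acq = acquisition_params(data_points = 8192L),
                           amplitude_rsd = 0.005) {
  calib <- calibration_study(analyte, panel = panel,
                             standard_conc = standard_conc, acq = acq,
                             amplitude_rsd = 0, seed = 1L)$model
  cells <- list()
  max_rsd <- numeric(n_runs)
  counter <- 0
  for (k in seq_len(n_runs)) {
    run_rsd <- numeric(length(concentrations))
    for (ci in seq_along(concentrations)) {
      found <- vapply(seq_len(replicates), function(r) {
        counter <<- counter + 1
        spec <- simulate_assay_spectrum(
          stats::setNames(concentrations[ci], analyte),
          panel, standard_conc, acq, amplitude_rsd,
          seed = base_seed * 1000 + counter)
        q <- quantify_spectrum(spec, calibrations = stats::setNames(
          list(calib), analyte))
        q$concentration[q$owner == analyte]
      }, numeric(1))
      st <- recovery_stats(recovery(found, concentrations[ci]))
      run_rsd[ci] <- st$rsd_percent
      cells[[length(cells) + 1]] <- tibble::tibble(
        run = k, concentration = concentrations[ci],
        rsd_percent = st$rsd_percent, mean_recovery = st$mean)
    }
    max_rsd[k] <- max(run_rsd)
  }
  list(cells = do.call(rbind, cells), max_rsd = max_rsd)
}

#' Laboratory-mixture and nasal-spray scenario concentrations
#'
#' `lab_mixture_concentrations()` returns the 1:2.74 FLP:AZH laboratory
#' mixture (7.3 and 20.0 mg/ml). `nasal_spray_concentrations()` models 20
#' actuations of the marketed spray (50 ug FLP and 137 ug AZH per actuation)
#' reconstituted in 1.0 ml: 1.0 and 2.74 mg/ml nominal.
#'
#' @return Named numeric vector of concentrations, mg/ml.
#' @export
lab_mixture_concentrations <- function() c(FLP = 7.3, AZH = 20.0)

#' @rdname lab_mixture_concentrations
#' @export
nasal_spray_concentrations <- function() {
  c(FLP = 20 * 50e-3 / 1.0, AZH = 20 * 137e-3 / 1.0)
}

#' Read a run configuration from YAML
#'
#' Schema (all blocks optional; defaults shown by [default_run_config()]):
#' `mode` (`calibration` or `absolute`), `seed`, `acquisition` (fields of
#' [acquisition_params()]), `standard_conc`, `analytes` (named map of
#' calibration `levels` and `samples` to assay), `noise`
#' (`amplitude_rsd`, `sigma_per_scan`), `output` (directory).
#'
#' @param path YAML file path.
#' @return A run-config list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), cfg)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    mode = "calibration",
    seed = 42,
    acquisition = list(data_points = 8192),
    standard_conc = 10,
    analytes = list(
      FLP = list(levels = c(0.25, 0.5, 1, 2.5, 5, 10, 15, 20),
                 samples = c(7.3)),
      AZH = list(levels = c(0.2, 0.5, 1, 2.5, 5, 8, 10, 15),
                 samples = c(20.0))
    ),
    noise = list(amplitude_rsd = 0.005, sigma_per_scan = 0),
    output = NULL
  )
}

#' Run the end-to-end assay pipeline
#'
#' For every analyte in the configuration: simulate and fit a calibration
#' series, simulate the configured samples, quantify them against the
#' calibration, and assemble recoveries. When `config$output` is set, the
#' calibration points, sample integrals and the report are written as CSV
#' and each sample spectrum as JCAMP-DX into that directory. Deterministic
#' given `config$seed`: two runs with the same configuration produce
#' identical outputs.
#'
#' @param config A run-config list (see [read_run_config()]); missing fields
#'   are filled from [default_run_config()].
#' @return A list of class `pipeline_result` with `calibrations` (named list
#'   of models), `report` (tibble: analyte, taken, found, recovery),
#'   `points` (calibration points per analyte), `summary` (per-analyte
#'   [recovery_stats()]).
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- utils::modifyList(default_run_config(), config)
  if (length(config$analytes) == 0) {
    stop("pipeline configuration declares no analytes", call. = FALSE)
  }
  acq <- do.call(acquisition_params, config$acquisition)
  panel <- assay_panel()
  seed <- as.integer(config$seed)
  calibs <- list()
  points <- list()
  rows <- list()
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  any_sample <- FALSE
  for (nm in names(config$analytes)) {
    acfg <- config$analytes[[nm]]
    cs <- stage(paste0("calibration:", nm), calibration_study(
      nm, acfg$levels, panel, config$standard_conc, acq,
      amplitude_rsd = config$noise$amplitude_rsd,
      noise_sigma_per_scan = config$noise$sigma_per_scan,
      seed = seed))
    calibs[[nm]] <- cs$model
    points[[nm]] <- cs$points
    for (i in seq_along(acfg$samples)) {
      any_sample <- TRUE
      taken <- acfg$samples[i]
      spec <- stage(paste0("sample:", nm), simulate_assay_spectrum(
        stats::setNames(taken, nm), panel, config$standard_conc, acq,
        amplitude_rsd = config$noise$amplitude_rsd,
        noise_sigma_per_scan = config$noise$sigma_per_scan,
        seed = seed + 1000 + i))
      q <- stage(paste0("quantify:", nm),
                 quantify_spectrum(spec, calibrations = calibs))
      found <- q$concentration[q$owner == nm]
      rows[[length(rows) + 1]] <- tibble::tibble(
        analyte = nm, taken = taken, found = found,
        recovery = recovery(found, taken))
      if (!is.null(config$output)) {
        dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
        write_jcampdx(spec, file.path(
          config$output, sprintf("sample_%s_%02d.jdx", nm, i)))
      }
    }
  }
  if (!any_sample) {
    stop("pipeline configuration declares no samples to assay",
         call. = FALSE)
  }
  report <- do.call(rbind, rows)
  summaries <- lapply(split(report$recovery, report$analyte), function(v) {
    if (length(v) >= 2) recovery_stats(v) else NULL
  })
  if (!is.null(config$output)) {
    utils::write.csv(report, file.path(config$output, "report.csv"),
                     row.names = FALSE)
    for (nm in names(points)) {
      utils::write.csv(points[[nm]],
                       file.path(config$output,
                                 sprintf("calibration_%s.csv", nm)),
                       row.names = FALSE)
    }
  }
  structure(list(calibrations = calibs, report = report, points = points,
                 summary = summaries),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$calibrations)) {
    m <- x$calibrations[[nm]]
    cat(sprintf("  %s: ratio = %.5g + %.5g * C, r^2 = %.6f\n",
                nm, m$intercept, m$slope, m$r_squared))
  }
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' Regions file round trip
#'
#' Reads or writes an integration-regions CSV with columns
#' `label, low_ppm, high_ppm, owner`.
#'
#' @param path CSV path.
#' @param regions List of [integration_region()]s (for writing).
#' @return `read_regions_csv()` returns a named list of regions;
#'   `write_regions_csv()` returns `path` invisibly.
#' @export
read_regions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "low_ppm", "high_ppm", "owner") %in% names(df)))
  regs <- lapply(seq_len(nrow(df)), function(i) {
    integration_region(df$label[i], df$low_ppm[i], df$high_ppm[i],
                       df$owner[i])
  })
  stats::setNames(regs, df$label)
}

#' @rdname read_regions_csv
#' @export
write_regions_csv <- function(regions, path) {
  df <- do.call(rbind, lapply(unname(regions), function(r) {
    data.frame(label = r$label, low_ppm = r$low, high_ppm = r$high,
               owner = r$owner)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
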