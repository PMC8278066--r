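#' Fit a calibration line by ordinary least squares
#'
#' Regresses the integral ratio on concentration and reports the quantities
#' conventionally tabulated for an ICH Q2(R1) linearity study: slope b,
#' intercept a, correlation coefficient r, residual standard deviation Sy/x
#' (n - 2 degrees of freedom), and the standard deviations of intercept (Sa)
#' and slope (Sb).
#'
#' @param concentration Concentrations, mg/ml (>= 3 distinct values).
#' @param ratio Observed integral ratios, same length.
#' @return An object of class `calibration_model` with fields `slope`,
#'   `intercept`, `r`, `r_squared`, `sy_x`, `sa`, `sb`, `n_points`, `range`.
#' @export
fit_calibration <- function(concentration, ratio) {
  stopifnot(length(concentration) == length(ratio),
            all(is.finite(concentration)), all(is.finite(ratio)))
  if (length(unique(concentration)) < 3) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(ratio ~ concentration)
  # noise-free synthetic series fit exactly; the perfect-fit warning from
  # summary.lm is expected there and not informative
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(sm)
  r <- stats::cor(concentration, ratio)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = r, r_squared = r^2,
         sy_x = sm$sigma,
         sa = co[1, "Std. Error"],
         sb = co[2, "Std. Error"],
         n_points = length(ratio),
         range = range(concentration)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> ratio = %.6g + %.6g * C, r = %.6f (n = %d)\n",
    x$intercept, x$slope, x$r, x$n_points))
  cat(sprintf("  Sy/x %.3g, Sa %.3g, Sb %.3g, range %g-%g mg/ml\n",
              x$sy_x, x$sa, x$sb, x$range[1], x$range[2]))
  invisible(x)
}

#' Limits of detection and quantification from the calibration intercept
#'
#' `LOD = 3.3 * Sa / b` and `LOQ = 10 * Sa / b`, with Sa the standard
#' deviation of the intercept and b the slope, so LOQ/LOD = 10/3.3 exactly.
#'
#' @param model A [fit_calibration()] model.
#' @return Named numeric vector `c(lod = ..., loq = ...)` in mg/ml.
#' @export
lod_loq <- function(model) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope == 0) stop("calibration slope is zero", call. = FALSE)
  c(lod = 3.3 * model$sa / model$slope,
    loq = 10 * model$sa / model$slope)
}

#' Percent recovery
#'
#' `100 * found / taken`, the accuracy metric.
#'
#' @param found Amount found, mg/ml.
#' @param taken Amount taken, mg/ml (> 0).
#' @return Percent recovery. Vectorised.
#' @export
recovery <- function(found, taken) {
  if (any(taken <= 0)) stop("taken must be > 0", call. = FALSE)
  100 * found / taken
}

#' Summary statistics of a set of recoveries
#'
#' Mean, sample standard deviation (n - 1 denominator), percent relative
#' standard deviation `100 * sd / mean`, and percent error `%RSD / sqrt(n)`
#' (the standard error of the mean expressed relative to the mean).
#'
#' @param values Percent recoveries (n >= 2).
#' @return An object of class `recovery_stats` with `values`, `n`, `mean`,
#'   `sd`, `rsd_percent`, `error_percent`.
#' @export
recovery_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("need at least 2 values for a standard deviation", call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  rsd <- 100 * s / m
  structure(
    list(values = values, n = length(values), mean = m, sd = s,
         rsd_percent = rsd, error_percent = rsd / sqrt(length(values))),
    class = "recovery_stats"
  )
}

#' @export
print.recovery_stats <- function(x, ...) {
  cat(sprintf(
    "<recovery_stats> n %d: mean %.2f +/- %.2f (%%RSD %.2f, %%error %.2f)\n",
    x$n, x$mean, x$sd, x$rsd_percent, x$error_percent))
  invisible(x)
}

as_recovery_stats <- function(x) {
  if (inherits(x, "recovery_stats")) x else recovery_stats(x)
}

#' Pooled-variance two-sample t comparison
#'
#' Two-sided Student's t-test comparing the mean recoveries of two methods,
#' using the pooled variance and `n1 + n2 - 2` degrees of freedom, with the
#' critical value taken from the t quantile at the requested alpha.
#'
#' @param group1,group2 `recovery_stats` objects or numeric vectors.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A list of class `comparison_result` with `t_statistic`, `df`,
#'   `critical_t`, `p_value`, `alpha`, `significant`.
#' @export
two_sample_t <- function(group1, group2, alpha = 0.05) {
  g1 <- as_recovery_stats(group1)
  g2 <- as_recovery_stats(group2)
  if (g1$sd == 0 && g2$sd == 0 && g1$mean == g2$mean) {
    stop("both groups are degenerate (zero variance, equal means)",
         call. = FALSE)
  }
  df <- g1$n + g2$n - 2
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  tval <- abs(g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  crit <- stats::qt(1 - alpha / 2, df)
  structure(
    list(t_statistic = tval, df = df, critical_t = crit,
         p_value = 2 * stats::pt(-tval, df),
         alpha = alpha, significant = tval > crit),
    class = "comparison_result"
  )
}

#' Variance-ratio F comparison
#'
#' `F = larger variance / smaller variance` (so F >= 1), with numerator and
#' denominator degrees of freedom following the larger- and smaller-variance
#' groups and the critical value from the F quantile at alpha.
#'
#' @inheritParams two_sample_t
#' @return A list of class `comparison_result` with `F_statistic`,
#'   `df` (num, den), `critical_F`, `p_value`, `alpha`, `significant`.
#' @export
variance_ratio_F <- function(group1, group2, alpha = 0.05) {
  g1 <- as_recovery_stats(group1)
  g2 <- as_recovery_stats(group2)
  if (g1$sd == 0 || g2$sd == 0) {
    stop("zero variance in a group; F ratio undefined", call. = FALSE)
  }
  if (g1$sd^2 >= g2$sd^2) {
    num <- g1; den <- g2
  } else {
    num <- g2; den <- g1
  }
  fval <- num$sd^2 / den$sd^2
  df <- c(num = num$n - 1, den = den$n - 1)
  crit <- stats::qf(1 - alpha, df[1], df[2])
  structure(
    list(F_statistic = fval, df = df, critical_F = crit,
         p_value = stats::pf(fval, df[1], df[2], lower.tail = FALSE),
         alpha = alpha, significant = fval > crit),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  if (!is.null(x$t_statistic)) {
    cat(sprintf("<comparison_result> t = %.3f (critical %.2f, df %d)%s\n",
                x$t_statistic, x$critical_t, x$df,
                if (x$significant) " *" else ""))
  } else {
    cat(sprintf(
      "<comparison_result> F = %.3f (critical %.2f, df %d,%d)%s\n",
      x$F_statistic, x$critical_F, x$df[1], x$df[2],
      if (x$significant) " *" else ""))
  }
  invisible(x)
}

#' Intra- or inter-day precision table
#'
#' Per-concentration replicate summary: mean, sd (n - 1), %RSD and %error
#' (%RSD / sqrt(n)), the layout of a precision study run in triplicate at
#' several concentrations within one day (intra) or across days (inter).
#'
#' @param assays Data frame with columns `concentration` and `found`
#'   (percent found / recovery), one row per replicate.
#' @param scheme Label carried into the output, e.g. `"intra"` or `"inter"`.
#' @return A tibble with one row per concentration: `scheme`,
#'   `concentration`, `n`, `mean`, `sd`, `rsd_percent`, `error_percent`.
#' @export
precision_study <- function(assays, scheme = c("intra", "inter")) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("concentration", "found") %in% names(assays)))
  concs <- sort(unique(assays$concentration))
  rows <- lapply(concs, function(cc) {
    v <- assays$found[assays$concentration == cc]
    if (length(v) < 2) {
      return(tibble::tibble(scheme = scheme, concentration = cc,
                            n = length(v), mean = mean(v), sd = NA_real_,
                            rsd_percent = NA_real_,
                            error_percent = NA_real_))
    }
    st <- recovery_stats(v)
    tibble::tibble(scheme = scheme, concentration = cc, n = st$n,
                   mean = st$mean, sd = st$sd,
                   rsd_percent = st$rsd_percent,
                   error_percent = st$error_percent)
  })
  do.call(rbind, rows)
}

#' Stability of a sample solution over time
#'
#' Mean and %RSD of the percent assay across the time points; a small %RSD
#' indicates the solution is stable over the studied span.
#'
#' @param time_h Time points in hours (>= 2).
#' @param percent_assay Percent assay at each time point.
#' @return A tibble with `n`, `mean`, `rsd_percent`.
#' @export
stability_series <- function(time_h, percent_assay) {
  stopifnot(length(time_h) == length(percent_assay))
  if (length(time_h) < 2) stop("need at least 2 time points", call. = FALSE)
  st <- recovery_stats(percent_assay)
  tibble::tibble(n = st$n, mean = st$mean, rsd_percent = st$rsd_percent)
}

#' Specificity check from component-wise spectra
#'
#' Measures, for each quantitative region, the fractional area contributed
#' by every spectrum in `spectra` relative to the area its owner contributes,
#' and flags any cross-contribution above `threshold`. Pass the blank and the
#' individual standards as separate spectra, each named after the component
#' it contains (the blank under `"blank"`).
#'
#' @param spectra Named list of processed `nmr_spectrum` objects; names must
#'   match region owners (plus optionally `"blank"`).
#' @param regions List of [integration_region()]s.
#' @param threshold Maximum tolerated cross-contribution fraction
#'   (default 0.01, i.e. 1\%).
#' @return A tibble with one row per (region, source): `region`, `source`,
#'   `area`, `fraction_of_owner`, `flagged`; attribute `pass` is TRUE when no
#'   cross-contribution is flagged.
#' @export
specificity_check <- function(spectra, regions = default_regions(),
                              threshold = 0.01) {
  stopifnot(is.list(spectra), !is.null(names(spectra)))
  check_region_overlap(regions)
  rows <- list()
  for (reg in regions) {
    areas <- vapply(spectra, function(sp) {
      integrate_region(sp, reg)$absolute_area
    }, numeric(1))
    own <- areas[reg$owner]
    if (is.na(own) || own <= 0) own <- max(areas, 0)
    for (src in names(areas)) {
      frac <- if (own > 0) areas[[src]] / own else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        region = reg$label, source = src, area = areas[[src]],
        fraction_of_owner = frac,
        flagged = src != reg$owner && is.finite(frac) && frac > threshold)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pass") <- !any(out$flagged)
  out
}
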