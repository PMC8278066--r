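# brute-force OLS by explicit summation formulas (independent of lm)
brute_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  res <- y - a - b * x
  syx <- sqrt(sum(res^2) / (n - 2))
  sxx_c <- sxx - sx^2 / n
  sb <- syx / sqrt(sxx_c)
  sa <- syx * sqrt(sxx / (n * sxx_c))
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * sum(y^2) - sy^2))
  list(a = a, b = b, r = r, syx = syx, sa = sa, sb = sb)
}

ref <- reference_tables()

test_that("OLS calibration matches the brute-force formulas", {
  # noise-free points on the reported FLP line: recovered exactly
  conc <- c(0.25, 0.5, 1, 2.5, 5, 10, 15, 20)
  m <- fit_calibration(conc, 0.0064 + 0.02 * conc)
  expect_equal(m$slope, 0.02, tolerance = 1e-12)
  expect_equal(m$intercept, 0.0064, tolerance = 1e-12)
  expect_equal(m$r, 1, tolerance = 1e-12)

  # hand-picked points vs the summation oracle
  x <- c(1, 2, 4, 8)
  y <- c(0.9, 2.2, 3.9, 8.3)
  m2 <- fit_calibration(x, y)
  o <- brute_ols(x, y)
  expect_equal(m2$slope, o$b, tolerance = 1e-10)
  expect_equal(m2$intercept, o$a, tolerance = 1e-10)
  expect_equal(m2$r, o$r, tolerance = 1e-10)
  expect_equal(m2$sy_x, o$syx, tolerance = 1e-10)
  expect_equal(m2$sa, o$sa, tolerance = 1e-10)
  expect_equal(m2$sb, o$sb, tolerance = 1e-10)

  # duplicating every point: same line, tighter coefficient uncertainties
  m3 <- fit_calibration(c(x, x), c(y, y))
  expect_equal(m3$slope, m2$slope, tolerance = 1e-12)
  expect_equal(m3$intercept, m2$intercept, tolerance = 1e-12)
  expect_lt(m3$sa, m2$sa)
  expect_lt(m3$sb, m2$sb)

  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("LOD/LOQ derive from the intercept deviation and slope", {
  m <- fit_calibration(c(1, 2, 3, 4), c(1.1, 1.9, 3.05, 3.95))
  ll <- lod_loq(m)
  expect_equal(unname(ll["lod"]), 3.3 * m$sa / m$slope, tolerance = 1e-12)
  expect_equal(unname(ll["loq"] / ll["lod"]), 10 / 3.3, tolerance = 1e-12)
  # arithmetic on the reported FLP Sa and slope
  m$sa <- 21e-5; m$slope <- 0.02
  ll2 <- lod_loq(m)
  expect_equal(unname(ll2["lod"]), 0.03465, tolerance = 1e-10)
  expect_equal(unname(ll2["loq"]), 0.105, tolerance = 1e-10)
  # a perfect fit has zero limits
  m$sa <- 0
  expect_equal(unname(lod_loq(m)), c(0, 0))
  m$slope <- 0
  expect_error(lod_loq(m), "slope")
})

test_that("percent recovery is 100 * found / taken", {
  expect_equal(recovery(5, 5), 100)
  expect_equal(recovery(0, 5), 0)
  expect_equal(recovery(4.98, 5.00), 99.6, tolerance = 1e-12)
  expect_error(recovery(1, 0), "taken")
})

test_that("recovery statistics reproduce the reported accuracy tables", {
  flp <- ref$accuracy$recovery[ref$accuracy$drug == "FLP" &
                                 ref$accuracy$method == "qNMR"]
  st <- recovery_stats(flp)
  expect_equal(st$mean, 100.14, tolerance = 0.005 / 100.14)
  expect_equal(st$sd, 0.91, tolerance = 0.005 / 0.91)
  expect_equal(st$error_percent, 0.32, tolerance = 0.02)

  azh <- ref$accuracy$recovery[ref$accuracy$drug == "AZH" &
                                 ref$accuracy$method == "qNMR"]
  st2 <- recovery_stats(azh)
  expect_equal(st2$mean, 99.67, tolerance = 0.005 / 99.67)
  expect_equal(st2$sd, 1.04, tolerance = 0.005 / 1.04)

  expect_equal(recovery_stats(c(7, 7, 7))$sd, 0)
  expect_equal(recovery_stats(c(7, 7, 7))$rsd_percent, 0)
  expect_error(recovery_stats(5), "at least 2")
})

test_that("pooled t and variance-ratio F reproduce the method comparison", {
  flp_q <- ref$accuracy$recovery[ref$accuracy$drug == "FLP" &
                                   ref$accuracy$method == "qNMR"]
  flp_h <- ref$accuracy$recovery[ref$accuracy$drug == "FLP" &
                                   ref$accuracy$method == "HPLC"]
  tt <- two_sample_t(flp_q, flp_h)
  expect_equal(tt$t_statistic, 0.1, tolerance = 0.05)
  expect_equal(tt$df, 10)
  expect_equal(tt$critical_t, 2.23, tolerance = 0.005)
  expect_false(tt$significant)

  ff <- variance_ratio_F(flp_q, flp_h)
  expect_equal(ff$F_statistic, 1.39, tolerance = 0.005)
  expect_false(ff$significant)

  azh_q <- ref$accuracy$recovery[ref$accuracy$drug == "AZH" &
                                   ref$accuracy$method == "qNMR"]
  azh_h <- ref$accuracy$recovery[ref$accuracy$drug == "AZH" &
                                   ref$accuracy$method == "HPLC"]
  expect_equal(variance_ratio_F(azh_q, azh_h)$F_statistic, 1.11,
               tolerance = 0.005)
  expect_equal(two_sample_t(azh_q, azh_h)$t_statistic, 0.09,
               tolerance = 0.05)

  # identical groups: t is exactly zero
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$t_statistic, 0)
  # equal variances: F is exactly one
  expect_equal(variance_ratio_F(c(1, 2, 3), c(4, 5, 6))$F_statistic, 1)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "degenerate")
  expect_error(variance_ratio_F(c(1, 1), c(1, 2)), "zero variance")
})

test_that("t and F agree with base R's implementations on random data", {
  set.seed(42)
  for (i in 1:20) {
    g1 <- rnorm(sample(3:9, 1), mean = 100, sd = runif(1, 0.2, 2))
    g2 <- rnorm(sample(3:9, 1), mean = 100, sd = runif(1, 0.2, 2))
    tt <- two_sample_t(g1, g2)
    bt <- stats::t.test(g1, g2, var.equal = TRUE)
    expect_equal(tt$t_statistic, abs(unname(bt$statistic)),
                 tolerance = 1e-12)
    expect_equal(tt$p_value, bt$p.value, tolerance = 1e-12)
    ff <- variance_ratio_F(g1, g2)
    bf <- stats::var.test(g1, g2)
    expect_equal(ff$F_statistic,
                 max(unname(bf$statistic), 1 / unname(bf$statistic)),
                 tolerance = 1e-12)
    expect_gte(ff$F_statistic, 1)
  }
})

test_that("summary statistics match explicit summation on random inputs", {
  set.seed(7)
  for (i in 1:25) {
    v <- runif(sample(2:12, 1), 90, 110)
    st <- recovery_stats(v)
    n <- length(v)
    m <- sum(v) / n
    s <- sqrt(sum((v - m)^2) / (n - 1))
    expect_equal(st$mean, m, tolerance = 1e-10)
    expect_equal(st$sd, s, tolerance = 1e-10)
    expect_equal(st$rsd_percent, 100 * s / m, tolerance = 1e-10)
    expect_equal(st$error_percent, 100 * s / m / sqrt(n),
                 tolerance = 1e-10)

    x <- runif(5, 0, 10); y <- 2 + 3 * x + rnorm(5, 0, 0.1)
    mfit <- fit_calibration(x, y)
    o <- brute_ols(x, y)
    expect_equal(mfit$sa, o$sa, tolerance = 1e-10)
    expect_equal(mfit$sb, o$sb, tolerance = 1e-10)
  }
})

test_that("the precision study reproduces the reported intra-day cells", {
  intra_flp <- ref$precision[ref$precision$scheme == "intra" &
                               ref$precision$drug == "FLP", ]
  tab <- precision_study(intra_flp, "intra")
  cell <- tab[tab$concentration == 1.0, ]
  expect_equal(cell$mean, 100.85, tolerance = 0.005 / 100.85)
  expect_equal(round(cell$sd, 2), 0.68)
  expect_equal(cell$error_percent, 0.39, tolerance = 0.02)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$n == 3))

  # constant replicates have zero RSD
  const <- data.frame(concentration = 1, found = c(99, 99, 99))
  expect_equal(precision_study(const, "intra")$rsd_percent, 0)

  # a random cell matches the direct formulas
  set.seed(3)
  v <- rnorm(3, 100, 0.7)
  out <- precision_study(data.frame(concentration = 5, found = v), "inter")
  expect_equal(out$mean, mean(v), tolerance = 1e-12)
  expect_equal(out$rsd_percent, 100 * sd(v) / mean(v), tolerance = 1e-12)

  # a single replicate is reported, not imputed
  lone <- precision_study(data.frame(concentration = 2, found = 99.5))
  expect_true(is.na(lone$sd))
  expect_equal(lone$n, 1)
})

test_that("the stability series reproduces the reported drift statistics", {
  flp <- ref$stability[ref$stability$drug == "FLP", ]
  st <- stability_series(flp$time_h, flp$percent_assay)
  expect_lt(abs(st$mean - 100.29), 0.0051)
  expect_equal(st$rsd_percent, 0.16, tolerance = 0.02)

  azh <- ref$stability[ref$stability$drug == "AZH", ]
  st2 <- stability_series(azh$time_h, azh$percent_assay)
  expect_equal(st2$mean, 99.83, tolerance = 0.005 / 99.83)
  expect_equal(st2$rsd_percent, 0.18, tolerance = 0.02)

  expect_equal(stability_series(c(0, 6), c(99, 99))$rsd_percent, 0)
  expect_error(stability_series(0, 99), "2 time points")
})

test_that("specificity: no cross-contribution between quantitative regions", {
  acq <- quick_acq(8192L)
  panel <- test_panel()
  one <- function(analyte, conc) {
    s <- sample_spec(list(list(analyte = analyte, concentration = conc)))
    process_spectrum(synthesize_fid(s, acq, seed = 8),
                     phase_order = NA, baseline_order = NA)
  }
  spectra <- list(
    blank = one(panel$standard, 0),  # solvent line only
    FLP = one(panel$analytes$FLP, 7.3),
    AZH = one(panel$analytes$AZH, 20),
    inositol = one(panel$standard, 10))
  rep <- specificity_check(spectra)
  expect_true(attr(rep, "pass"))
  # the solvent-only blank contributes essentially nothing anywhere
  expect_true(all(abs(rep$fraction_of_owner[rep$source == "blank"]) < 0.01))

  # a deliberately overlapping impurity at 8.30 ppm is flagged
  impurity <- analyte_spec("impurity", 100, 1, 1, multiplet_df_at(8.30))
  bad <- process_spectrum(
    synthesize_fid(sample_spec(list(list(analyte = impurity,
                                         concentration = 5))), acq,
                   seed = 9),
    phase_order = NA, baseline_order = NA)
  rep2 <- specificity_check(c(spectra, list(impurity = bad)))
  expect_false(attr(rep2, "pass"))
  expect_true(any(rep2$flagged[rep2$source == "impurity" &
                                 rep2$region == "AZH"]))
})

test_that("a validation report survives a CSV round trip", {
  tab <- precision_study(ref$precision[ref$precision$drug == "FLP", ],
                         "intra")
  path <- tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$mean, tab$mean, tolerance = 1e-12)
  expect_equal(back$rsd_percent, tab$rsd_percent, tolerance = 1e-12)
  expect_equal(back$concentration, tab$concentration)
})
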