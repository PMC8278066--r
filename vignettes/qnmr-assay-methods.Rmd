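---
title: "Internal-standard qNMR of a fluticasone/azelastine nasal spray: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-standard qNMR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qnmrassay)
```

# The assay

Quantitative proton NMR (qNMR) determines concentration and purity from
integrated signal areas: under fully relaxed acquisition the integral $I$ of
a resonance is proportional to the molar concentration $c$ of the compound
and the number $n$ of equivalent protons generating the signal,

$$I = K_s \, c \, n \, \bigl(1 - e^{-\mathrm{TR}/T_1}\bigr),$$

where $K_s$ is an instrument scale factor, $\mathrm{TR}$ the repetition time
(pulse width + dead time + acquisition time + relaxation delay) and $T_1$
the longitudinal relaxation time. After one $T_1$ the magnetization has
recovered about 63% of its equilibrium value; at $\mathrm{TR} = 5\,T_1$ the
recovery is 99.3%, the usual criterion for quantitative work. Because $K_s$
is the same for every resonance in one spectrum, the ratio of two integrals
from the same spectrum,

$$\frac{I_1}{I_2} = \frac{c_1 n_1}{c_2 n_2},$$

is instrument-independent, and with a weighed internal standard of declared
purity $P_2$ the analyte purity follows as

$$P_1 = \frac{I_1}{I_2}\cdot\frac{n_2}{n_1}\cdot\frac{M_1}{M_2}
        \cdot\frac{W_2}{W_1}\cdot P_2 ,$$

with $M$ molar masses and $W$ gravimetric weights (equal dissolution
volumes).

The package implements this workflow for the simultaneous assay of
fluticasone propionate (FLP) and azelastine hydrochloride (AZH) in a nasal
spray formulation, with myo-inositol as the internal standard in DMSO-d6.
The quantitative signals are the FLP doublet-of-doublets at 6.290, 6.294,
6.316, 6.319 ppm, the AZH doublet at 8.292, 8.310 ppm, and the inositol
doublet at 3.70, 3.71 ppm; the residual solvent line sits at 2.5 ppm.

No public raw spectra exist for this assay, so the package carries its own
spectrum simulator. All end-to-end claims are therefore statements about
the simulator's signal model plus the processing and statistics; the
replicate-level validation tables shipped in `reference_tables()` are the
published values and are recomputed, not re-measured.

# The simulator

`synthesize_fid()` renders each configured line as a damped complex
exponential $A\,e^{(2\pi i \nu - \pi w)t}$, so the processed spectrum
contains absorption Lorentzians of FWHM $w$ (Hz) whose ppm-integral equals
the steady-state amplitude $A$ from the signal equation above. Design
choices, in decreasing order of consequence:

* **Multiplets as explicit line lists.** Couplings are not specified for
  these signals, so the doublets and the doublet-of-doublets are encoded as
  the printed line positions with equal intensities, not derived from $J$.
  This reproduces every observed position exactly and costs nothing for
  quantification, which only uses summed areas.
* **Flip-angle dependence.** The saturation-recovery factor
  $(1-e^{-\mathrm{TR}/T_1})$ applies to 90° pulses. For other angles the
  simulator uses the steady-state (Ernst) factor
  $\sin\theta\,(1-E)/(1-E\cos\theta)$, $E=e^{-\mathrm{TR}/T_1}$, which
  reduces to the former at $\theta=90^\circ$. This is an extension beyond
  the strict 90° model, used only to emulate flip-angle optimisation
  trends.
* **$T_1$ defaults.** The relaxation times of FLP, AZH and inositol are not
  published; the defaults (1.2, 1.5, 2.0 s) are typical small-molecule
  values in DMSO-d6 and satisfy $\mathrm{TR} > 5\,T_1$ under the default
  acquisition (10 s relaxation delay), so quantification is insensitive to
  their exact values. They are configurable per analyte.
* **Proton counts.** How many protons generate each quantitative multiplet
  is likewise unstated. The default is $n = 1$ for all three signals.
  Ratio-based calibration is invariant to this choice as long as it is
  applied consistently; it enters only the absolute purity equation, where
  the user should supply the true counts for their compounds.
* **Concentration scale.** Components are specified as mg/ml of weighed
  material (for AZH: the hydrochloride salt, which is what is weighed);
  molarity is `c * purity/100 / M`. Gravimetric `weight`/`volume` input is
  accepted and converted the same way.
* **Noise.** Two mechanisms, both optional: additive complex Gaussian
  time-domain noise of standard deviation $\sigma/\sqrt{N_\mathrm{scans}}$
  (scan averaging), and multiplicative Gaussian jitter of the per-component
  amplitude (`amplitude_rsd`), representing preparation and integration
  variability. The stochastic validation studies below use 0.5%
  multiplicative jitter and no additive noise, matching the noise level at
  which the assay's headline precision figures are quoted.
* **Baseline drift** is a low-order polynomial in ppm added to the real
  part after transformation (drift is a frequency-domain artefact);
  `baseline_correct()` removes it again.
* **Seeding.** One integer seed drives the whole pseudorandom stream of a
  simulated FID; the seed and the drawn amplitudes are recorded in the FID
  provenance. Identical inputs and seed give a bit-identical FID, and the
  simulator restores the caller's RNG state.

The printed acquisition parameters are internally inconsistent: 65,536
points across a 15 ppm (6,000 Hz) width implies an acquisition time of
10.9 s, not the quoted 4.08 s (which corresponds to a wider ~20 ppm
digitisation window). The package resolves this by treating the dwell time
as fixed by the spectral width and *deriving* the acquisition time from the
number of points, keeping time and frequency grids consistent; the
repetition time then comes out at ~20.9 s, comfortably quantitative.

# Processing

The elaboration chain mirrors routine practice: exponential apodization
(default 0.3 Hz, adding exactly that much Lorentzian width), discrete
Fourier transform with optional zero-filling, automatic phase correction,
polynomial baseline correction, and axis referencing to a known line.

Numerical choices worth recording:

* **Normalisation.** The transform is scaled by
  $2\,\Delta t\, f_0$ (dwell time times spectrometer frequency; the factor
  2 accounts for the one-sided $t \ge 0$ signal), so intensities are
  per-ppm and an absorption line of amplitude $A$ integrates to $A$. The
  first FID point is halved before transformation (trapezoidal edge
  correction), which removes the flat offset a truncated one-sided signal
  otherwise produces; the total ppm-integral of the spectrum then equals
  the first FID sample.
* **Auto-phase criterion.** The algorithm behind the instrument's "auto
  phase correction" is not public. The package minimises the squared
  negative excursion of the real part -- an absorption spectrum of positive
  peaks has essentially none -- via a coarse grid (evaluated on a decimated
  copy for speed) followed by Nelder-Mead (or golden-section for zero-order
  only). On synthetic spectra this recovers injected zero/first-order
  errors to well under a degree, and it is idempotent. The criterion is a
  single documented function and can be swapped.
* **Baseline.** Polynomial of order ≤ 3 (default 2) fitted to
  user-declared signal-free points. The exclusion windows must be generous:
  Lorentzian tails reach far, and a fit allowed too close to a peak
  absorbs part of it (about 1% of area for windows padded by less than
  ~0.1 ppm at routine linewidths). The pipeline's default exclusions pad
  the quantitative regions by 0.25 ppm and the solvent line by 0.3 ppm.
* **Integration** is trapezoidal on the native grid over declared regions
  -- instrument-style absolute integrals, no peak fitting. Default regions
  are the printed extreme line positions of each multiplet padded by
  0.02 ppm. At 0.8 Hz processed linewidth a ±8 Hz window captures ~98.4%
  of a Lorentzian; this capture fraction is common to analyte and standard
  (equal linewidths), so it cancels in every ratio, and it cancels between
  calibration and sample in calibration-mode quantification. It does *not*
  cancel perfectly in absolute purity mode if linewidths differ -- purity
  work should use wider regions.
* **Axis convention.** The ppm axis is stored strictly descending;
  integration accepts `[low, high]` intervals regardless of direction.

# Validation statistics

The ICH Q2(R1) quantities are implemented exactly as used in the
pharmaceutical tables this package reproduces:

* ordinary least squares calibration with $r$, $S_{y/x}$, $S_a$, $S_b$ at
  $n-2$ residual degrees of freedom; LOD $= 3.3\,S_a/b$,
  LOQ $= 10\,S_a/b$ (so LOQ/LOD $= 10/3.3$ identically);
* sample standard deviations with the $n-1$ denominator throughout -- this
  convention exactly reproduces the published table statistics;
* "% error" defined as $\%\mathrm{RSD}/\sqrt{n}$, the only reading
  consistent with the published tables despite their "(s.d./√n)" label;
* pooled-variance two-sided $t$ with $n_1+n_2-2$ degrees of freedom;
* variance-ratio $F$ with the larger variance in the numerator (so
  $F \ge 1$) and degrees of freedom following the larger/smaller-variance
  groups. The published critical values instead always pair the test
  method's df first, which for one of the two drugs reverses the df order;
  the package computes critical values from the $F$ quantile at the
  stated convention and does not replicate that irregularity;
* critical values from `qt()`/`qf()` at $\alpha = 0.05$, never from
  hard-coded tables.

One published inconsistency is deliberately left unreconciled: the reported
LOD/LOQ values (0.04/0.12 mg/ml FLP, 0.02/0.05 AZH) do not follow from the
reported $S_a$ and slope via the stated formulas
($3.3 \times 21\times10^{-5} / 0.02 = 0.035$, etc.). The formulas are
implemented as stated, tested by direct arithmetic, and the printed values
are not asserted anywhere.

# Simulation studies and their scope

`linearity_runs()` repeats the full pipeline -- simulate 8 calibration
levels over 0.25-20 mg/ml with the internal standard at 10 mg/ml, process,
integrate, ratio, fit -- across seeded runs and collects $r^2$;
`precision_runs()` assays seeded triplicates at 1.0/5.0/10.0 mg/ml against
a noise-free calibration and collects per-cell %RSD. With 0.5%
multiplicative amplitude noise the median $r^2$ is ~0.99996 and the median
worst-cell %RSD ~0.9, inside the assay's published bounds ($r^2 > 0.999$,
%RSD < 1.5). These studies run at 8,192 complex points rather than the
instrument's 65,536 -- a deliberate problem-size choice that leaves the
stochastic results unchanged (the noise is per-amplitude, not per-point)
while keeping a 200-run study in the low minutes; absolute-area tests use
32,768 points, where residual truncation bias of region integrals is below
0.2%.

What passing these studies does and does not show: the generator draws
line positions, widths and amplitudes from the same model family the
processing assumes, so the studies validate the statistical machinery and
the processing chain's area fidelity, not robustness to real-instrument
artefacts (field inhomogeneity, solvent suppression residues, strong
coupling, sample-to-sample linewidth variation, temperature drift). The
specificity check is likewise exact-overlap bookkeeping on synthetic
component spectra, not a claim about unknown excipients.

# Degenerate inputs and edge behaviour

Zero concentrations synthesise silence; a zero-area internal standard is a
hard error; regions outside the axis or owned-region overlaps are errors,
while a region containing the declared solvent line only warns;
concentrations outside the validated calibration range are flagged, not
rejected; phase optimisation failure returns the spectrum unchanged with a
logged `not_converged` status rather than corrupting it; a missing
precision cell is reported absent, never imputed.

# Known limitations

* No spin physics: no J-evolution, strong coupling, or 2D experiments; the
  lineshape is ideal Lorentzian.
* The flip-angle model is steady-state; transient effects of the first
  scans (dummy scans exist for this reason) are not modelled.
* Baseline correction assumes the user can declare signal-free windows;
  crowded spectra would need a different baseline model.
* JCAMP-DX support covers the package's own XYDATA and NTUPLES dialects
  (AFFN pairs); compressed ASDF encodings from other writers are not
  parsed.
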