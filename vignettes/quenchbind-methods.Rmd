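---
title: "Fluorescence quenching binding analysis: models and methods"
author: "quenchbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence quenching binding analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

## The measurement and the model

Serum albumin carries intrinsic tryptophan/tyrosine fluorescence that is
quenched when a ligand binds.  Titrating the protein (a few µM) with
increasing ligand concentrations (tens to hundreds of µM) and recording the
emission intensity yields, per temperature, a series of pairs
$([Q]_i, F_i)$ plus the unquenched intensity $F_0$.  `quenchbind` analyses
such titrations through four linked linear models.

**Stern–Volmer.**  For both collisional and complex-forming quenching the
intensity ratio is linear in the quencher concentration,

$$\frac{F_0}{F} = 1 + K_{sv}[Q],$$

and `stern_volmer_fit()` estimates $K_{sv}$ (L/mol) as the OLS slope of
$F_0/F$ on $[Q]$.  The intercept is fitted freely rather than pinned at 1,
because reporting the intercept and its deviation from 1 is itself a
diagnostic, and it is what binding studies tabulate.  The temperature trend
of $K_{sv}$ identifies the mechanism (`classify_mechanism()`): a
ground-state complex is destabilised by heat, so $K_{sv}$ falls with $T$
(static quenching); diffusive encounters become more frequent, so $K_{sv}$
rises with $T$ (dynamic quenching).  The call is deliberately conservative —
it requires both the sign of the $K_{sv}$-vs-$T$ slope and strict
monotonicity across the sorted temperatures; anything else is
`indeterminate`.

**Double-logarithmic (modified Stern–Volmer).**  For 1:1 association with
constant $K_a$ and $n$ equivalent sites,

$$\log_{10}\frac{F_0 - F}{F} = \log_{10} K_a + n \log_{10}[Q],$$

so `double_log_fit()` returns the binding constant from the intercept and
the apparent stoichiometry from the slope.  Base-10 logarithms are used on
this plot (tabulated $\log K_a \approx 4.4$ for $K_a \approx 2.4\times10^4$
L/mol fixes the convention); the van't Hoff analysis below uses natural
logarithms.  Points with $F \ge F_0$ have no defined left-hand side and are
excluded with a warning.  $n$ is reported exactly as fitted; a 1:1
annotation is appropriate when $|n - 1| < 0.15$ (configurable via
`analysis_config()`), a band wide enough to cover typical fitted values of
1.05–1.09 on real albumin data.

**van't Hoff.**  With per-temperature constants $K_a(T)$,

$$\ln K_a = -\frac{\Delta H}{RT} + \frac{\Delta S}{R},$$

`vant_hoff_fit()` regresses $\ln K_a$ on $1/T$ and returns
$\Delta H = -R\,\beta_1$ and $\Delta S = R\,\beta_0$ with $R = 8.314$
J mol⁻¹ K⁻¹ (fixed, not configurable).  The linear form assumes $\Delta H$
and $\Delta S$ constant over the window, which is standard over spans of a
few tens of kelvin.  Gibbs energies are computed per temperature as
$\Delta G = -RT\ln K_a$ (`gibbs_from_ka()`), each temperature using its own
constant.  The alternative route $\Delta G = \Delta H - T\Delta S$
(`gibbs_from_enthalpy()`) coincides with the first exactly when the
constants lie on the van't Hoff line and differs slightly otherwise,
because $\Delta H$ and $\Delta S$ are fitted quantities; the reporting
layer uses the $-RT\ln K_a$ route, which is what published thermodynamic
tables for this kind of study reproduce.  `classify_forces()` applies the
Ross–Subramanian sign rules: $\Delta H<0,\Delta S<0$ → hydrogen
bonding/van der Waals; both positive → hydrophobic; $\Delta H<0,\Delta S>0$
→ electrostatic; a zero component (or the doubly unfavourable
$\Delta H>0,\Delta S<0$ quadrant) is indeterminate.

## Inner-filter correction and when it matters

Absorbing species attenuate both the excitation beam and the emitted light,
deflating observed intensities:
$F_{corr} = F_{obs}\,10^{(A_{ex}+A_{em})/2}$ (`ife_correct()`).  Two
regimes are worth distinguishing.  A *constant* absorbance (the protein's
own) cancels in every $F_0/F$ ratio as soon as $F_0$ is corrected with the
same factor, and moves no fitted constant at all.  What matters is the
quencher's *differential* contribution across the titration:
numerically, a differential of ~0.002 absorbance units over the
concentration window shifts a fitted $K_{sv}$ of $7.1\times10^3$ L/mol by
about 0.9%, while a differential reaching 0.05 shifts it by roughly 19%.
Negligibility claims therefore hold only for weakly absorbing quenchers;
for strongly absorbing ones the correction is mandatory, which is why the
generator can superimpose an inner-filter attenuation to exercise exactly
that path.

## Synchronous fluorescence, peak shifts

Synchronous scans at a fixed excitation–emission offset report the
tyrosine microenvironment at Δλ = 15 nm and the tryptophan one at
Δλ = 60 nm.  Quenching depth per channel is summarised by
$RSFQ = 1 - F/F_0$ (`rsfq()`), and `rsfq_profile()` decides which residue
class the ligand sits near by majority vote across the concentration grid —
a vote, not a mean, so a single noisy point cannot flip the call; an exact
tie is `"mixed"`.

Band displacements (a ~2 nm red shift of a synchronous band, or a
~26 cm⁻¹ amide-band shift in infrared spectra) are quantified by
`peak_position()`: the grid maximum refined by three-point parabolic
interpolation.  The parabola is exact for quadratic peaks, and for Gaussian
bands at least five grid steps wide the error is below a tenth of a grid
step (worst case ≈ 0.002 nm on a 1 nm grid for a 15 nm-wide band) — ample
for shifts of the magnitude at stake, without the tuning knobs a spline or
centroid method would add.  A maximum on the axis boundary signals a
truncated band and is refused rather than guessed at.  An adjacent-point
tie (a symmetric band centred exactly between grid points) is resolved by
the parabola; distant ties are ambiguous and rejected.  `peak_shift()`
labels wavelength shifts beyond a resolution threshold (default 0.5 axis
units) as red or blue; for wavenumber axes the red/blue vocabulary is
suppressed.

## Competition analysis

Site markers (indomethacin for Sudlow site I in subdomain IIA, diazepam
for site II in subdomain IIIA) and metal ions modulate the apparent $K_a$.
`compare_conditions()` ratios each condition's constant to the blank's —
computed as $10^{\Delta\log_{10}K_a}$, which is exact and identical to the
direct quotient — and calls the effect `unchanged` when
$|1 - \mathrm{ratio}| \le 0.25$ (boundary inclusive), else
`decrease`/`increase`.  The 25% default is a deliberate choice: no numeric
significance criterion is standard in this assay, and ratios a quarter away
from unity are within what run-to-run albumin titrations produce; a ~23%
apparent increase under a non-displacing probe should read as no effect,
while the ~5-fold drop a displacing probe causes is unmistakable.  The
threshold is configurable for stricter designs.  `assign_site()` then
requires displacement by probes of exactly one site; displacement by both
or neither is `ambiguous` rather than forced.

## The synthetic-data generator

No raw intensities are published for studies of this kind, so the
generator (`simulation_spec()`, `generate_titration()`) stands in for the
instrument.  Its defaults *are* the emulated study conditions: five
temperatures {285, 290, 295, 303, 308} K, six quencher concentrations
30–180 µM, $F_0 = 1000$ (arbitrary units), binding driven by
$\Delta H = -52.434$ kJ/mol and $\Delta S = -99.63$ J mol⁻¹ K⁻¹ through
$K_a(T) = \exp(-\Delta H/RT + \Delta S/R)$, and 1% multiplicative Gaussian
intensity noise — a conventional spectrofluorometer figure, chosen once as
an assumption since no empirical anchor exists.  The forward model is the
1:1 static-quenching law $F = F_0/(1 + K_a[Q])$, exactly consistent with
the linear Stern–Volmer form; ligand depletion is ignored because the
quencher is in ≥10-fold excess over protein in the emulated design.  Noise
is multiplicative (detector-like) on the titration points; $F_0$ is the
noiseless reference.  The dynamic mechanism has no fitted counterpart in
this workflow, so its $K_{sv}(T) = K_{sv,ref}(T/285)^4$ is an invented
stand-in whose only job is to rise with temperature.  Each (label,
temperature) series draws from its own deterministic substream of the
master seed, so adding a condition never perturbs existing series.

What the generator does *not* emulate: wavelength-dependent instrument
response, photobleaching, scattering baselines, ligand depletion at low
excess, or replicate structure (a single intensity per point, matching how
such titrations are tabulated).  Tests passing on generated data therefore
validate the estimators against the stated statistical model, not against
instrument systematics.

## Numerical and statistical choices

* All straight lines are unweighted OLS through `stats::lm`; the quenching
  literature reports unweighted fits, and tests cross-check every fit
  against an explicit normal-equations solver at $10^{-10}$ relative.
* Internally all concentrations are mol/L and all energies J/mol;
  binding constants are L/mol so printed "×10³ L/mol" values compare
  directly.  Input files may declare µM or mM (exact factors 1e-6, 1e-3).
* **Estimator efficiency.**  Under the static 1:1 model both the
  Stern–Volmer slope and the double-log intercept estimate the same
  association constant, but not equally well: the double-log intercept is
  an extrapolation of the regression line roughly four decades below the
  sampled $\log_{10}[Q]$ window, which amplifies intensity noise about
  tenfold (median $K_a$ error ~8% at 1% noise, versus ~0.9% for the
  Stern–Volmer slope; the same amplification shows up in the large
  intercept uncertainties of published double-log tables).  Parameter
  recovery benchmarks in this package therefore use the Stern–Volmer
  route for $K_a(T)$ and the van't Hoff line on those constants
  (median $\Delta H$ error ~1% at 1% noise); the double-log fit remains
  the source of the stoichiometry $n$ and of tabulated $\log K_a$.
* Titration sizes in tests and benchmarks follow the emulated design (6
  concentrations × 5 temperatures; 100 seeded replicates for Monte-Carlo
  summaries), which keeps every run deterministic and fast.

## Known limitations

* No sphere-of-action or combined static+dynamic quenching model, and no
  bimolecular rate constant $k_q = K_{sv}/\tau_0$ (the fluorophore
  lifetime is not part of the data model).
* No nonlinear direct fit of $F$ vs $[Q]$ with ligand-depletion
  correction, and no multi-site (Hill/Adair) extensions of the double-log
  model.
* Mechanism classification near-degenerates when $K_{sv}(T)$ changes by
  only a few percent per temperature step: with ~7% adjacent gaps (the
  dynamic stand-in) the strict-monotonicity requirement starts to return
  `indeterminate` for a few percent of 2%-noise datasets; the static
  direction, with 25–40% gaps, is robust at that noise level.
* Secondary-structure quantification from infrared amide-band
  deconvolution is out of scope; only band-shift quantification is
  provided.
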