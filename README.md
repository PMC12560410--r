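# quenchbind

Analysis of protein–ligand binding from steady-state fluorescence
quenching titrations, for spectroscopists and medicinal chemists who
titrate a fluorescent protein (typically serum albumin) with a
small-molecule ligand at several temperatures and want binding constants,
thermodynamics, binding-site assignment and mechanism calls out of the
intensity tables.

The pipeline implements the standard linear workflow of the field:

* **Stern–Volmer**: `F0/F = 1 + Ksv [Q]`; the slope `Ksv` (L/mol) and its
  temperature trend classify the quenching mechanism (static if `Ksv`
  falls with `T`, dynamic if it rises).
* **Inner-filter correction**: `Fcorr = Fobs · 10^((Aex + Aem)/2)` before
  fitting when the ligand absorbs at the working wavelengths.
* **Double-logarithmic plot**: `log10((F0−F)/F) = log10 Ka + n log10 [Q]`
  giving the association constant `Ka` and site number `n`.
* **van't Hoff**: `ln Ka = −ΔH/RT + ΔS/R` giving binding enthalpy and
  entropy; `ΔG = −RT ln Ka` per temperature; Ross–Subramanian sign rules
  name the dominant forces (both negative → hydrogen bonds/van der Waals).
* **Synchronous fluorescence**: `RSFQ = 1 − F/F0` at Δλ = 15 nm (Tyr) vs
  60 nm (Trp) locates the binding microenvironment; parabolic peak
  interpolation quantifies band shifts (nm or cm⁻¹).
* **Competition**: Ka ratios against a blank call site-marker displacement
  (Sudlow site I vs II) and common-ion effects.

A seeded synthetic-data generator produces titrations from the 1:1
static-quenching model `F = F0/(1 + Ka(T)[Q])` with van't Hoff-driven
`Ka(T)`, multiplicative detector noise and optional inner-filter
attenuation, so the whole pipeline is testable without an instrument.

## Worked example

Simulate a five-temperature titration study (285–308 K, 30–180 µM
quencher, 1% noise) and run the full analysis:

```r
library(quenchbind)

spec   <- simulation_spec(seed = 7L)      # defaults are the study design
series <- generate_temperature_series(spec)

sv <- lapply(series, stern_volmer_fit)
classify_mechanism(sv)
#> <mechanism_call> static (dKsv/dT = -872.2 L/mol/K over 5 temperatures)

bl <- lapply(series, double_log_fit)
bl[[1]]
#> <binding_result> blank @ 285 K: Ka = 2.197e+04 L/mol (logKa = 4.3419), n = 0.983

thermo_analysis(bl)
#> <thermo_result> dH = -43.755 kJ/mol, dS = -69.53 J/mol/K, hbond_vdw, spontaneous = TRUE
#>   285 K: dG = -23.689 kJ/mol
#>   290 K: dG = -23.906 kJ/mol
#>   295 K: dG = -23.386 kJ/mol
#>   303 K: dG = -22.350 kJ/mol
#>   308 K: dG = -22.466 kJ/mol
```

Reading this: `Ksv` decreases with temperature, so quenching is static
(complex formation); the double-log fit at 285 K recovers `Ka ≈ 2.2×10⁴`
L/mol with `n ≈ 1` (1:1 binding); the van't Hoff line over the five fitted
constants gives negative ΔH and ΔS — hydrogen-bond/van der Waals-driven,
spontaneous at every temperature.  (The double-log intercept is a long
extrapolation and noisier than the Stern–Volmer slope; see the methods
vignette for the estimator comparison.)

Real data come in as long-format CSV (`label, temperature_K, conc,
intensity`, one `conc = 0` row per series for `F0`) via
`read_titration()`, with µM/mM/M input units set in `analysis_config()`;
`write_report()` emits JSON plus a readable table of all fitted
quantities.  Competition assays go through `compare_conditions()` /
`assign_site()`, spectra through `read_spectrum()`, `rsfq_profile()` and
`peak_shift()`.

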