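# quenchbind

Inference of protein–ligand binding from intrinsic fluorescence quenching
titrations, for spectroscopists and food-protein scientists who record
emission spectra of a tryptophan-bearing protein (e.g. soybean protein
isolate) titrated with a hydrophobic ligand (e.g. β-carotene) at several
temperatures and want the full chain of standard inferences, each auditable:

* **Stern–Volmer quenching fit** — OLS of F₀/F on [Q]:
  `F0/F = 1 + K_SV[Q] = 1 + kq·τ0·[Q]`, with the bimolecular quenching rate
  constant `kq = K_SV/τ0` (τ0 = 10⁻⁸ s by default).
* **Mechanism classification** — static vs dynamic quenching from kq versus
  the diffusion collision limit (2×10¹⁰ L·mol⁻¹·s⁻¹) together with the
  temperature trend of K_SV; a verdict only when both criteria agree.
* **Double-logarithmic binding fit** —
  `lg((F0−F)/F) = lg(Ka) + n·lg[Q]` for the apparent binding constant Ka
  and site number n.
* **Van't Hoff thermodynamics** — `ln Ka = −ΔH/(RT) + ΔS/R`,
  `ΔG = ΔH − T·ΔS` (R = 8.314 J·mol⁻¹·K⁻¹), with driving-force
  classification by the signs of (ΔH, ΔS) (both positive → hydrophobic;
  both negative → van der Waals + hydrogen bonding) and spontaneity
  (ΔG < 0) per temperature.
* **Spectral bookkeeping** — emission-band peak extraction (moving-average
  smoothing + parabolic refinement), blue/red shift calls, molar
  ellipticity conversion `[θ] = θ/(R·C·l·10)` for CD records.
* **Functional indices** — DPPH radical scavenging, foaming
  capacity/stability, emulsifying activity (turbidimetric Pearce–Kinsella
  by default) and emulsion stability.
* **Synthetic titration generator** — a seeded forward model (exact
  conjugate of the fitting equations, Gaussian emission band with
  saturation-coupled blue shift, multiplicative noise) so the entire
  pipeline is verifiable end-to-end with known ground truth.

## Worked example

Simulate a four-temperature titration bundle with the default ground truth
(ΔH = 5225 J/mol, ΔS = 112.98 J·mol⁻¹·K⁻¹, 1% noise), analyze it from the
CSVs, and render the report:

```r
library(quenchbind)

dir <- tempfile()
paths <- run_simulate(default_config(), dir, seed = 1)

cfg <- default_config()
cfg$input$spectra  <- paths$spectra
cfg$input$dpph     <- paths$dpph
cfg$input$foam     <- paths$foam
cfg$input$emulsion <- paths$emulsion

report <- run_analyze(cfg, out_dir = file.path(dir, "out"))
```

which prints

```
Quenching / binding analysis report
===================================
Per-temperature fits:
  T = 273 K: K_SV = 80954.8 L/mol, kq = 8.09548e+12 L/mol/s, Ka = 48004.6 L/mol, n = 0.955036
  T = 298 K: K_SV = 95687 L/mol, kq = 9.5687e+12 L/mol/s, Ka = 135044 L/mol, n = 1.0281
  T = 318 K: K_SV = 107893 L/mol, kq = 1.07893e+13 L/mol/s, Ka = 345992 L/mol, n = 1.1004
  T = 338 K: K_SV = 130062 L/mol, kq = 1.30062e+13 L/mol/s, Ka = 311379 L/mol, n = 1.07393
Quenching mechanism: ambiguous (K_SV trend increasing vs temperature)
  T = 273 K: emission maximum 338.144 -> 337.271 nm (blue shift of 0.873 nm)
  ...
Thermodynamics: dH = 24038 J/mol, dS = 178.615 J/mol/K (r2 = 0.910821)
  driving force: hydrophobic; spontaneous at 4/4 temperatures
  dG(273 K) = -24723.8 J/mol
  ...
Assay tables processed: dpph, foam, emulsion
```

Reading: the Stern–Volmer slopes recover the generated binding constants
(≈0.8–1.3×10⁵ L/mol) to a few percent at 1% noise; kq ≈ 10¹³ L·mol⁻¹·s⁻¹ is
far above the diffusion limit (a static-quenching signature); the mechanism
call is nevertheless `ambiguous` because in the generator's pure static
model K_SV equals Ka and therefore *rises* with temperature for an
endothermic truth — see the vignette for why that is the correct call on
these data. The per-temperature double-log Ka values scatter widely: their
intercept extrapolates five decades beyond the sampled concentrations
(again, see the vignette), which is why the thermodynamic refit of those
values moves (ΔH, ΔS) while still landing on `hydrophobic`/spontaneous.

Working from measured fit results instead of spectra (here the
four-temperature quenching table of the motivating assay):

```r
th <- thermo_analysis(data.frame(temperature_K = c(273, 298, 318, 338),
                                 Ka = c(0.83, 0.89, 1.14, 1.26) * 1e5))
th
#> <van't Hoff analysis> dH = 5225 J/mol, dS = 113 J/mol/K, r2 = 0.917
#>   driving force: hydrophobic; spontaneous at 4/4 temperatures
#>  T_K     Ka     lnKa dG_J_per_mol
#>  273  83000 11.32660    -25619.13
#>  298  89000 11.39639    -28443.69
#>  318 114000 11.64395    -30703.35
#>  338 126000 11.74404    -32963.00
```

A thin command-line wrapper with `simulate`, `analyze` and `report`
subcommands ships at `inst/scripts/quenchbind-cli.R`.

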