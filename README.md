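# rdtherm

Temperature-series structural analysis of a hyperthermophile
rubredoxin-like protein, in R.

Rubredoxins are small (~54-residue) iron–sulfur electron-transfer
proteins; hyperthermophile versions remain folded far above 100 °C, and
Zn-substituted forms are redox-inert structural proxies. Given crystal
structures collected across 100–393 K and molecular-dynamics
trajectories reduced to atom-pair distance series, `rdtherm` answers the
temperature-dependence questions such a series poses:

* **Hydrogen-bond partner switching.** Distance-based (3.5 Å heavy-atom)
  H-bond detection, water-mediated bridge search (≤ 2 waters), and a
  per-temperature partner table — built for the Asp-19 carboxylate,
  which contacts the Trp-37 indole nitrogen at low temperature, the
  Tyr-11 hydroxyl at high temperature, and Tyr-11 through one or two
  ordered waters in between, while the Glu-15 polar network stays fixed.
* **Per-structure geometry and disorder.** Kabsch (SVD, proper-rotation)
  superposition RMSD, metal-site coordination statistics (mean Zn–S
  distance), triclinic unit-cell volume, grid-based van der Waals
  protein volume, and per-residue Cα B-factor profiles with
  per-structure z-score normalization.
* **Thermal trends.** OLS expansion fits (absolute slope, % per 100 K
  relative to the low-temperature value, endpoint % change) and a
  continuous two-segment changepoint fit that locates the drop in
  ordered-water count at the protein dynamical transition near 240 K.
* **Trajectory thermodynamics.** Three-state (W-bonded / intermediate /
  Y-bonded) frame classification, occupancies and dwell times,
  per-residue RMSF after superposition, and a van't Hoff fit

  ln K = −ΔH/(RT) + ΔS/R,  K = π_Y / π_W

  with regression and moving-block-bootstrap uncertainties (block
  length 10× the integrated autocorrelation time of the state
  indicator).
* **Synthetic ground truth.** A first-class generator module builds
  schematic structure series with all of the above programmed in, and
  three-state Markov distance trajectories whose stationary occupancies
  obey a configured van't Hoff law exactly — so every analysis is
  validated by recovering known truth.

## Worked example

```r
library(rdtherm)

models <- generate_structure_series(fixture_config(seed = 1))
partner_switch_table(models)
#>   temperature_K partner    kind min_distance_A n_waters
#> 1           100     W37  direct           2.88        0
#> 2           100     Y11 2-water           8.40        2
#> ...
#> 23          393     W37    none             NA       NA
#> 24          393     Y11  direct           2.88        0
```

The low-temperature structures carry the direct 2.88 Å D19–W37 bond
(with the two-water Y11 bridge at 100 K, one-water at 260 K); at and
above the programmed 300 K switch the table flips to a direct D19–Y11
bond with W37 released.

```r
temps <- c(245, 260, 275, 293, 308, 323)
series <- lapply(seq_along(temps), function(k) {
  sim <- simulate_three_state_markov(
    markov_config(temperature = temps[k], seed = 1000 + k))
  classify_three_state(sim$traceW, sim$traceY)
})
K <- vapply(series, occupancy_ratio, numeric(1))
vant_hoff_fit(data.frame(temperature = temps, K = K),
              series_list = series, seed = 42)
#> van't Hoff fit over 6 temperatures:
#>   dH = 30.67 kJ/mol (se 4.65, boot se 5.34)
#>   dS = 108.96 J/K/mol (se 16.62, boot se 18.98)
```

One 10 µs-equivalent simulated experiment per temperature recovers the
generator's ΔH = 31 kJ mol⁻¹, ΔS = 108 J K⁻¹ mol⁻¹ within a fraction of
a bootstrap standard error. On the crystal side:

```r
changepoint_fit(collect_series(models, "waters"))
#> changepoint fit (n=12): breakpoint 240 K, slopes -0.05812 / -0.3406
expansion_fit(collect_series(models, "cell_volume"))
#> expansion fit (n=12): slope 5.208 per K, 0.96%/100 K, endpoints +2.80%
```

The water changepoint lands on the programmed 240 K dynamical
transition and the unit-cell series reproduces its programmed +2.8%
volume expansion. `run_full_report(run_config(fixture = fixture_config(),
out_dir = "out"))` writes the full TSV/JSON bundle (partner table,
B-factor profiles, thermal series and fits, occupancies, dwell times,
van't Hoff fit, run log).

## Scientific caveats

The synthetic structures are schematic (exact local feature geometry,
no realistic fold); results on them validate the measurement pipeline,
not any claim about real crystals. See the methods vignette
(`vignettes/rubredoxin-thermal-analysis.Rmd`) for the model, parameter
defaults and units, numerical choices, and known limitations.
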