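---
title: "Temperature-series structural analysis of a hyperthermophile rubredoxin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-series structural analysis of a hyperthermophile rubredoxin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdtherm)
```

## The problem

Rubredoxins are ~54-residue iron–sulfur electron-transfer proteins; the
hyperthermophile versions (from organisms growing near 100 °C) are among
the most thermostable proteins known. Zn-substituted forms are
redox-inert structural proxies that avoid radiolysis artifacts at high
temperature. Given a series of crystal structures of such a protein
collected from cryogenic (100 K) through ambient to well above ambient
(~393 K) temperature, plus molecular-dynamics trajectories reduced to
atom-pair distance series, several temperature-dependent questions arise:

* which hydrogen bonds persist and which switch partners as temperature
  rises — in particular, a surface carboxylate (Asp-19) that contacts the
  Trp-37 indole nitrogen at low temperature but the Tyr-11 hydroxyl at
  high temperature, passing through one- and two-water bridges in
  between;
* how crystallographic disorder (B-factors), ordered-water counts, the
  unit cell, and the protein volume trend with temperature;
* what thermodynamics govern the partner-exchange equilibrium, extracted
  from trajectory state occupancies by a van't Hoff analysis.

`rdtherm` implements this full analysis as reusable, tested functions.
Because the real diffraction data and microsecond trajectories are not
shippable inputs, the package carries a first-class synthetic-data module
that generates structure series and trajectories with *known* ground
truth; every headline computation is validated by round-tripping the
generator's programmed values through the analysis code.

## Structures, selections, geometry

Structures are fixed-column PDB (`parse_pdb()`, `write_pdb()`), with the
collection temperature supplied by the caller — REMARK dialects are too
inconsistent to parse for it. Only blank/'A' alternate locations are
kept; high-quality small-protein structures at these resolutions refine
with a single conformation. Hydrogens, if present, are parsed but ignored
by all geometry: every criterion below is a heavy-atom criterion.

Geometric metrics follow standard crystallographic practice:

* **Superposition** is Kabsch's SVD solution with the determinant
  correction, so the result is always a proper rotation. Degenerate
  (collinear) point sets are rejected rather than silently resolved.
* **Unit-cell volume** uses the triclinic closed form
  $V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
  +2\cos\alpha\cos\beta\cos\gamma}$.
* **Protein volume** is a grid-occupancy van der Waals volume (0.5 Å
  spacing; radii C 1.70, N 1.55, O 1.52, S 1.80, Zn 1.39, Fe 1.47 Å).
  The literature rarely states which volume definition a plot uses, and
  absolute values differ by method; only *relative* expansion across the
  series is treated as meaningful, and that is what the trend fits
  report.
* **B-factor profiles** are per-residue Cα values. The "normalized"
  profile is a per-structure z-score, $(B-\bar B)/\mathrm{sd}(B)$ — the
  normalization method is a package choice (it is rarely printed in
  papers); z-scoring is standard practice and makes the *spatial pattern*
  of disorder comparable between structures whose absolute B scales
  differ with temperature. The isotropic conversion
  $B = 8\pi^2\langle u^2\rangle/3$ is provided (`b_to_msd()`) but not
  used in headline outputs.

## Hydrogen bonds and the partner switch

`detect_hbonds()` reports all polar–polar heavy-atom pairs within a
cutoff, default **3.5 Å**. X-ray structures carry no hydrogens, so no
donor–H–acceptor angle is imposed; this is the common distance-only
criterion, and published figure-level statements (e.g. a 2.88 Å
carboxylate-O⋯indole-N contact) are expressed the same way. The cutoff
is configurable; all partner classifications are defined *relative to
it*. The polar-atom chemistry table is a packaged, editable TSV. Both
carboxylate oxygens of Asp/Glu are equivalent donors: the carboxylate
can rotate between them, so partner identity — not oxygen identity —
defines an interaction.

`water_bridges()` searches the contact graph of endpoint atoms and water
oxygens for paths with ≤ 2 bridging waters, ordered by number of waters
then total length. `partner_switch_table()` classifies each configured
partner at each temperature as `direct`, `1-water`, `2-water`, or
`none`. If two partners are both direct-bonded at one temperature, both
rows say so; the table reports, it does not adjudicate. Bonds are
computed within the asymmetric unit only — no crystal-symmetry
expansion.

## Thermal trends

`collect_series()` turns per-structure scalars (water count, cell
volume, protein volume) into temperature series. Two fits are provided,
both deliberately simple:

* `expansion_fit()` — OLS of value on temperature. The relative slope is
  referenced to the fitted value at the lowest temperature (matching the
  "x% increase from 100 to 393 K" phrasing), and the endpoint percent
  change is also reported from the raw endpoints.
* `changepoint_fit()` — continuous two-segment piecewise-linear least
  squares, breakpoint chosen by exhaustive scan on a 1 K grid between
  the 2nd and (n−1)th temperatures, ties to the lowest candidate. A fit
  whose improvement over a single line is below `1e-6` of the total sum
  of squares is flagged `no_changepoint` (the total-SS scale keeps the
  flag meaningful when a single line already fits exactly). This is the
  tool used to locate the drop in ordered waters at the protein
  dynamical transition near 240 K.

## Trajectory thermodynamics

Trajectories enter as per-frame distance traces of the two competing
contacts (carboxylate-O to Trp-37 Nε, and to Tyr-11 OH), with the
carboxylate reduced by the per-frame **minimum** over its two oxygens.
`classify_three_state()` assigns each frame W-bonded, Y-bonded, or
intermediate (both broken) with the same 3.5 Å cutoff as the H-bond
detector; frames with both distances under the cutoff go to the closer
partner and are counted as ambiguous.

The equilibrium constant is the pure two-state ratio
$K = \pi_Y/\pi_W$; intermediate frames are excluded because the
thermodynamic quantity of interest is the partner *exchange*, not
binding versus non-binding. `vant_hoff_fit()` then fits
$\ln K = -\Delta H/(RT) + \Delta S/R$ by OLS
($R = 8.314462618\ \mathrm{J\,mol^{-1}K^{-1}}$ everywhere).
Uncertainties come from the regression and, when frame-level state
series are supplied, from a **moving-block bootstrap**: block length is
10× the integrated autocorrelation time of the Y-state indicator
(estimated by the initial-positive-sequence rule on an FFT-based acf),
200 replicates. Partner exchange on the 100 ns scale sampled at 0.1 ns
makes frames extremely serially correlated; a frame-level bootstrap
would understate errors by an order of magnitude.

`dwell_times()` averages maximal same-state runs (censored first/last
runs are counted and flagged), and `rmsf_profile()` computes per-residue
RMSF after Kabsch superposition of every frame onto the mean structure,
with the mean recomputed once from the fitted frames.

## The synthetic-data generators

### Structure series

`generate_structure_series()` builds one schematic 54-residue model per
temperature (default grid: 100, 140, 180, 220, 240, 260, 293, 323, 353,
363, 383, 393 K): full main chain laid out as four straight strands, the
side-chain atoms the analyses select on, a tetrahedral Zn(S-Cys)₄ site
(Zn–S 2.34 Å), and waters. The programmed features are:

* D19–W37 direct bond at 2.88 Å below the 300 K switch temperature;
  direct D19–Y11 at 2.88 Å at/above it, with W37 released;
* a two-water D19→Y11 bridge at 100 K and a one-water bridge at 260 K
  (legs 2.8 Å);
* an E15 network (E15 N–A2 O, E15 OE1–W4 NE1, E15 OE2–F30 N, all
  2.9 Å) identical at every temperature;
* B-factors linear in temperature with loop residues (16–27, 30–38)
  rising faster than the core;
* an ordered-water count that is piecewise linear with a sharp kink at
  240 K (shallow loss below, steep loss above). A smooth logistic drop
  was considered and rejected: a two-segment changepoint fit of a
  logistic step locates its breakpoint far from the step's centre, so a
  logistic generator could not serve as ground truth for the
  changepoint analysis. The kink form both matches the qualitative
  "sharp drop-off" behaviour being emulated and is exactly recoverable;
* a unit cell whose volume grows linearly to +2.8% at 393 K;
* a programmed noiseless protein-volume series
  (`generate_volume_series()`): slope 0.48 Å³/K with the 100 K volume
  fixed at 8000 Å³ so the relative slope is exactly 0.6%/100 K — the
  only pair of values for which those two numbers cohere. The grid
  volumes of the schematic atoms are *not* tuned to this series;
  absolute volumes are method-dependent (see above) and only the
  programmed trend is meaningful.

The geometry is deliberately schematic: local distances of programmed
features are exact, but the fold is flat and feature side chains float
free of their backbone. Passing tests on these fixtures demonstrates
that the *measurement code* is correct, not that any claim holds for
real crystal structures; incidental polar contacts exist in the fixture
and the tests assert only the programmed features. Construction is
deterministic; a clash (< 1 Å between non-bonded heavy atoms) triggers
seeded-jitter retries and errors after 10 attempts.

### Three-state Markov trajectories

`simulate_three_state_markov()` generates the trajectory ground truth: a
discrete-time chain on {W, I, Y} with transitions only through the
intermediate — the carboxylate must break one H-bond before forming the
other; a direct W↔Y hop can be re-enabled only by editing the
transition matrix, and the no-hop default reflects the large broken-bond
population seen in partner-exchange scatter plots. The stationary
distribution puts mass `pi_I` (default 0.6, the middle of the observed
~50–70% range, held temperature-independent) on the intermediate and
splits the rest by the van't Hoff law
$\pi_Y/\pi_W = e^{-\Delta H/(RT) + \Delta S/R}$ (defaults
ΔH = 31 kJ mol⁻¹, ΔS = 108 J K⁻¹ mol⁻¹). Bonded states exit with
probability `frame_interval/mean_dwell` (defaults 0.1 ns / 100 ns — the
timescale on which the exchange is observed); the intermediate's exit
probabilities follow from detailed balance, so the chain's stationary
distribution is exactly the analytic one (`analytic_occupancies()`, and
`transition_matrix()` exposes the matrix for the eigenvector
cross-check). Chains start from the stationary distribution; starting
from a fixed state and discarding a burn-in is the documented
alternative and converges to the same occupancies, at the cost of an
arbitrary burn-in length.

Emissions are truncated normals: bonded distance ~ N(2.9, 0.15²) ≥ 2.4 Å,
broken ~ N(6.5, 1.0²) ≥ 4.0 Å. With the 3.5 Å cutoff these emission
supports make state recovery essentially perfect (the bonded tail
beyond 3.5 Å has mass ~3×10⁻⁵), so classification-level checks test the
classifier, and occupancy-level checks test the chain.

### Validation protocol and problem sizes

The default validation protocol simulates six temperatures
{245, 260, 275, 293, 308, 323} K spanning the 245–323 K fitting range,
10⁵ frames each, over 20 replicate seed sets. Two readings of "recover
ΔH from the replicates" differ in a way that matters: averaging 20
per-replicate ΔH estimates is *biased upward* (a single trajectory with
100 ns dwells visits its rare bonded state only a handful of times in
10 µs, and the log of a small-count ratio is biased), whereas pooling
the replicates' state counts per temperature before forming K removes
the small-count problem. The package's acceptance script uses the
pooled estimator; per-replicate fits with block-bootstrap errors are
what the ≥95%-coverage recovery test checks, since each replicate's
bootstrap SE correctly reflects its own sampling noise.

One temperature-occupancy subtlety: published scatter panels print only
the dominant fractions (49% W-bonded at 240 K; 29% Y / 7% W at 293 K).
Where an unprinted fraction is needed to complete a generating
distribution, it is filled in from the same van't Hoff law the
trajectories obey (at 240 K: K ≈ 0.079, so π_Y ≈ 0.039 and
π_I ≈ 0.47, consistent with the stated ~50–70% intermediate range).
Occupancy percentages are fractions of *all* frames; treating them as
fractions of classified frames is the documented alternative and would
raise all bonded percentages by 1/(1−π_I).

## Worked example

```{r example, eval = FALSE}
library(rdtherm)

# crystal side: generate the series and tabulate the partner switch
models <- generate_structure_series(fixture_config(seed = 1))
partner_switch_table(models)

# trajectory side: simulate, classify, fit
temps <- c(245, 260, 275, 293, 308, 323)
series <- lapply(seq_along(temps), function(k) {
  sim <- simulate_three_state_markov(
    markov_config(temperature = temps[k], seed = 1000 + k))
  classify_three_state(sim$traceW, sim$traceY)
})
K <- vapply(series, occupancy_ratio, numeric(1))
vant_hoff_fit(data.frame(temperature = temps, K = K),
              series_list = series, seed = 42)
```

## Known limitations

* The fixture fold is schematic; nothing about packing, secondary
  structure, or energetics is realistic, and results on it validate the
  measurement pipeline only.
* H-bond classification is distance-only; with hydrogens present an
  angular criterion would be stricter.
* Protein volume is a van der Waals grid volume; solvent-excluded or
  Voronoi volumes differ in absolute value.
* The changepoint model allows exactly one breakpoint; a plateau–drop–
  plateau shape is approximated by its dominant kink.
* `pi_I` is temperature-independent by default; a temperature-dependent
  intermediate fraction changes the occupancies but not the two-state
  ratio, which is why the van't Hoff analysis is insensitive to it.
* Mean dwell applies to the bonded states; the intermediate's dwell
  follows from detailed balance and is shorter whenever the bonded
  states hold most of the probability.
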