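---
title: "Statistical model and simulator of the droplet phage assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical model and simulator of the droplet phage assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropphage)
```

## The assay and its statistics

A droplet phage screen encapsulates a diluted phage suspension together
with host cells and a cell-impermeant intercalating dye into ~30 µm
water-in-oil droplets. Each droplet is an isolated micro-culture: if it
received at least one viable phage and at least one host cell, infection
cycles amplify the phage genome copy number by orders of magnitude, the
dye stains the progeny genomes, and the droplet becomes brightly
fluorescent. A droplet cytometer records forward scatter (a size proxy)
and fluorescence per droplet; fluorescent droplets are sorted singly into
96-well plates, ruptured, recultivated with fresh host cells, and scored
phage-positive/negative by spot assay.

Three statistical ideas carry the whole analysis, and `dropphage`
implements each with its uncertainty:

1. **Poisson occupancy.** The number of particles a droplet receives is
   `K ~ Poisson(λ)`. `occupancy_pmf()` gives `P(K = k)`;
   `prob_single_given_occupied()` gives the clonality
   `P(K = 1 | K ≥ 1) = λe^{-λ}/(1 - e^{-λ})`, the quantity that justifies
   calling a sorted droplet a *single-phage* isolate at low λ.
2. **Digital quantification.** After cultivation, a dark droplet is one
   that held no viable phage, so the negative fraction estimates
   `p₀ = e^{-λ}` and `lambda_from_negative_fraction()` inverts it,
   `λ̂ = −ln p̂₀`. The companion route,
   `lambda_from_concentration()`, is the plain unit conversion
   `λ = c·V`. The two routes disagree in practice — plated titers count
   only plaque-forming particles while the negative fraction counts all
   propagation-competent ones net of assay losses — and reporting both is
   deliberate.
3. **Binary recovery.** Each isolated well is a Bernoulli trial;
   `digitize_plate()`, `recovery_ci()` and `compare_gates()` provide the
   rates, Wilson/Clopper–Pearson intervals, the Newcombe interval on the
   gate difference, and Fisher's exact test on the 2×2 table.

## The synthetic event generator

No public droplet-level dataset accompanies assays of this kind, so the
package ships a generator whose output has the statistical structure the
analysis assumes, plus a latent-truth table so that every estimator can
be checked against what was actually simulated.

Per droplet the generator draws

* `n_phage ~ Poisson(lambda_phage)` and `n_cells ~ Poisson(lambda_cells)`,
  independently — the co-encapsulation model;
* a **lognormal diameter** with the configured mean and CV. Lognormal is
  chosen over normal because diameters are strictly positive and the
  monodisperse limit (CV → 0) must be exact; at the default 5% CV the two
  are indistinguishable anyway.

Propagation is a **deterministic burst-cycle ladder**: by time `t` a
droplet with phage and cells has completed `⌊t / T_L⌋` cycles (latent
period `T_L`), each multiplying genome copies by the burst size `B`,
saturating at a per-droplet cap:

```
g(t) = min(cap, n_phage · B^⌊t/T_L⌋),   g(t) = n_phage if no cells or no phage.
```

A stochastic kinetic model (per-cell adsorption, lysis-time variance)
would add parameters that droplet-level aggregate data cannot identify;
the analysis stages only require growth that is monotone, fast relative
to the measurement schedule, and saturating, which the ladder provides
with three parameters.

Rendering maps latent state to signals:

* `fluorescence = (fl_baseline + fl_per_genome · g(t)) · ε`,
* `fsc = fsc_gain · π(d/2)² · ε′`,

with `ε, ε′` lognormal with unit mean and CV `fl_noise_cv`
(multiplicative noise, because cytometric intensities are positive and
right-skewed). One noise CV serves both channels: the configuration is
kept to the documented field set, and nothing downstream distinguishes
the two noise sources.

The **artifact channel** models the empirically observed
medium-fluorescence subpopulation that appears late in incubation even
without phage, attributed to starved host cells losing membrane
integrity so that dye reaches their DNA. Eligible droplets are
phage-free, carry more cells than average (faster nutrient depletion),
and have passed `artifact_onset_h`; each becomes an artifact with
probability `artifact_prob`, reading at `artifact_intensity` (validated
to lie strictly between baseline and the full-propagation level).
Whether the real phenomenon is dye entry or nucleic-acid leakage is
unresolved; a single phenomenological mechanism covers either.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| `lambda_cells` | 19 | 10⁹ cells/mL × 18.8 pL effective droplet volume |
| `diameter_mean_um`, `diameter_cv` | 30, 0.05 | monodisperse ~30 µm generation |
| `timepoints_h` | 0, 1, 3, 5, 7, 9, 24 | the standard incubation schedule |
| `n_droplets` | 40 000 | events recorded per cytometric read |
| `latent_period_h`, `burst_size` | 1 h, 100 | representative of a virulent T-even coliphage; free parameters, not measurable from droplet data |
| `genome_cap` | 10⁵ | host-resource ceiling; gives full-scale fluorescence ~10³ a.u. |
| `fl_baseline`, `fl_per_genome` | 10, 0.01 a.u. | dark droplets read ~10 a.u., saturated droplets ~10³ a.u., spanning the decades real samples span |
| `fl_noise_cv` | 0.25 | broad but unimodal intensity clusters |
| `artifact_prob`, `artifact_onset_h`, `artifact_intensity` | 0.01, 7 h, 200 a.u. | a trace medium-intensity group from 7 h onward, ≲0.5% of events |
| `seed` | **required** | every stochastic claim must be replayable |

The seed is deliberately not defaulted. `simulate_experiment()` derives
the no-phage control's stream by a fixed offset so the two emulsions are
independent but jointly reproducible; `render_events()` keys its stream
on the timepoint index so reads are independent across timepoints yet
byte-identical on replay.

### What the generator does *not* emulate

Real event tables carry doublets, satellite droplets, coalescence and
shrinkage during incubation, spectral spillover, and instrument drift
within a read. None of these are modelled. Passing tests therefore
demonstrate that the *analysis* is correct under the stated statistical
assumptions — not that those assumptions exhaust real cytometer output.
In particular the size filter is exercised here against clean lognormal
scatter; on real data it is precisely the unmodelled pathologies it
exists to remove.

## Gating conventions

Numerical conventions are pinned down so results are exact on small
fixtures:

* **Strict inequalities**: an event is fluorescent iff
  `fluorescence > threshold`; an event is removed iff its deviation
  *exceeds* `k·SD`. Ties survive the size filter and count as
  non-fluorescent.
* **Sample (n−1) SD**, computed per `(sample_id, timepoint_h)` group,
  because scatter means drift between reads. A group of one event has no
  SD and raises an error rather than passing silently.
* **Order-statistic quantile**: `derive_threshold()` returns the
  smallest observed intensity with at most `fp_rate` of control events
  strictly above it — no interpolation, so the guarantee
  `FP ≤ fp_rate` holds exactly on the derivation sample.
* **Filter-then-threshold**: the size filter is applied before
  classification (instrument practice removes malformed droplets before
  any biological call); `classify_and_summarize()` documents and tests
  that classifying pre-filtered rows gives identical fractions.

A derived threshold sits at the control's (1−fp) quantile, so roughly
`fp_rate` of genuinely empty droplets land above it; inverting the
negative fraction through such a threshold carries that small upward
bias in λ̂. Where the estimator itself is under study, the fixed
instrument threshold (130 a.u. by convention) is the unbiased choice,
and the calibration tests use it.

## Numerical choices

* Wilson score interval by default for all binomial proportions:
  well-behaved at `p̂₀ → 1` (the low-λ regime) and at observed zeros;
  Clopper–Pearson available where exactness is preferred. Boundary
  observations honour the data (0/n has lower bound exactly 0, n/n upper
  bound exactly 1).
* The λ interval is the monotone transform of the p₀ interval (bounds
  swap through `−ln`); an all-occupied sample (`p̂₀ = 0`) raises an
  error advising dilution rather than returning `Inf`.
* Fisher's exact test (not chi-square) compares gates: a zero cell in
  the control gate is the *expected* outcome and invalidates asymptotics.
* Titer arithmetic warns outside the 3–300 plaque countable window and
  on all-zero counts (below detection) but never drops data. The
  emulsion-rupture dilution is not derivable from first principles (the
  aqueous fraction of a sampled emulsion volume is unknown), so aliquot
  results are reported "per N µL of emulsion" with an explicit
  user-supplied `recovery_dilution`.
* Droplet volume: both the sphere-formula volume (14.1 pL at 30 µm) and
  the 18.8 pL effective-volume convention are representable;
  quantification defaults to 18.8 pL and nothing converts silently
  between the two.

## Isolation and recovery

`simulate_isolation()` closes the loop on synthetic data: it samples
sorted droplets from the high and low gates, looks up their latent
truth, and scores a well positive iff the droplet carried a phage *and*
survived a lumped per-well loss probability ℓ. The single parameter ℓ
covers mis-sorting, failed rupture and adsorption of an ~19 pL droplet
onto labware — effects that are real but individually unquantifiable.
With a pure high gate, observed recovery estimates `1 − ℓ`; recoveries
around 35% against near-perfect gate purity correspond to ℓ ≈ 0.64, the
regime the end-to-end acceptance test checks. The low gate contains no
viable phage under this signal model (no false negatives), so its
recovery is exactly 0.

## Problem sizes in the test suite

The suite favours exact small fixtures plus a few calibrated stochastic
checks: Monte-Carlo oracles use 10⁶ Poisson draws; estimator calibration
uses 500 binomial experiments of 40 000 droplets; the simulator
round-trip uses 100 replicates of 3 000 droplets at each of λ ∈ {0.05,
0.2, 0.8}; the end-to-end isolation check simulates one 40 000-droplet
emulsion. These sizes give 3-SE margins comfortably below the effect
sizes under test while the full suite runs in well under a minute.

## Known limitations

* λ̂ from the negative fraction assumes one effective droplet volume;
  polydispersity-corrected (multi-volume) digital quantification is out
  of scope.
* The propagation ladder has no stochastic lysis timing, so simulated
  time courses step at multiples of the latent period instead of rising
  smoothly through the first hours.
* The artifact channel is phenomenological; it reproduces the rate and
  intensity band of the late medium-fluorescence group, not its
  mechanism.
* Viability is binary in the generator: every simulated particle can
  propagate. The titer-vs-negative-fraction gap seen in real samples
  (non-viable particles) must be introduced by the user via the two
  estimators' inputs, not by a simulator switch.
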