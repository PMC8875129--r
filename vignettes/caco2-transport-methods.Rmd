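---
title: "Methods: bidirectional Caco-2 transport analysis and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional Caco-2 transport analysis and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caco2trans)
```

## The assay and the quantities computed

A Caco-2 monolayer grown on a permeable Transwell support separates an
apical (AP) and a basolateral (BL) compartment. Dosing the AP side and
sampling the BL side measures absorptive transport; the reverse measures
secretion. Three pieces of arithmetic carry the whole analysis:

1. **Monolayer integrity.** `teer()` computes
   $\mathrm{TEER} = (R_1 - R_0)\,A$ in $\Omega\cdot\mathrm{cm}^2$ from a
   measured and a reference resistance. The default insert area is
   1.12 cm². A default advisory threshold of 300 $\Omega\cdot$cm² flags
   leaky wells; it is a lab convention, configurable, and never drops
   data on its own.

2. **Sampling-dilution correction.** Each receiver sample withdraws
   $V_S$ mL (default 0.2) that is replaced by blank buffer. The measured
   concentration series $C_1, C_2, \dots$ therefore underestimates
   cumulative transport. `cumulative_amounts()` applies
   $$\Delta Q_n = C_n V_R + V_S \sum_{i=0}^{n-1} C_i, \qquad C_0 = 0,$$
   i.e. the mass presently in the receiver plus the mass already carried
   away by earlier aliquots. The identity of this formula with explicit
   event-by-event mass bookkeeping is a tested invariant, and $V_S \to 0$
   collapses it to $C_n V_R$.

3. **Permeability and efflux ratio.** `transport_rate()` fits
   $\Delta Q$ against time by ordinary least squares with a free
   intercept (minutes in, µg/s out); `papp()` normalises the slope,
   $P_\mathrm{app} = \frac{\Delta Q/\Delta t}{A\,C_0}$ (cm/s); and
   `efflux_ratio()` forms
   $ER = P_\mathrm{app}^{BL\to AP} / P_\mathrm{app}^{AP\to BL}$.
   `classify_mechanism()` applies the conventional strict rule: $ER > 1.5$
   suggests carrier-mediated (active) efflux, $ER \le 1.5$ is consistent
   with passive diffusion; exactly 1.5 is therefore passive-consistent,
   and a condition without a secretory arm is "undetermined", never
   imputed.

The free intercept in the rate fit deliberately absorbs any initial lag.
The fit window is configurable (default: all samples) because efflux
substrates at high dose visibly slow after the early phase; restricting
to the early sink-phase window (e.g. ≤ 90 min) is then the better
estimator, and the per-well $r^2$ is reported so poor linearity is
visible.

## Group statistics

`summarize_groups()` reports per-direction mean ± SD $P_\mathrm{app}$
(sample SD, $n-1$ denominator — the bioanalytical convention) and takes
the **ratio of the direction means** as the primary ER. This is the
statistic that reproduces published group tables; when both directions
carry equal numbers of wells the mean ± SD of per-well ratios (paired by
replicate order) is reported alongside, since published "ER ± SD" entries
imply per-replicate ratios. Of note, a group ER printed from unrounded
per-well means can differ from the ratio of the rounded printed means by
one unit in the third decimal; `run_reproduce_tables()` flags such rows
as rounding exceptions instead of forcing agreement.

`contrast_groups()` uses the Welch two-sample $t$ test on per-well
$P_\mathrm{app}$ at $\alpha = 0.05$. The underlying study reports only
"mean ± SD" plus significance statements from a statistics package
without naming the test; Welch is the conservative default for small,
possibly unequal-variance groups, and both the test's $\alpha$ and a Holm
adjustment (off by default — typical designs make at most a handful of
contrasts) are exposed as options. Degenerate groups (zero variance both
sides) take the $p = 1$ / $p = 0$ convention by equality of means.

## Calibration and QC

Assays spanning three to four orders of magnitude are fit as two OLS
segments split at a boundary standard (`fit_calibration(split_at =)`);
the boundary standard is included in both segments, the choice that
matches published segment ranges which quote it in both. Fits are
unweighted by default — near-unity correlation coefficients in practice
are consistent with unweighted fits — with $1/x$ and $1/x^2$ weighting
available. A segment correlation below 0.99 warns; fewer than three
standards per segment is an error. `back_calculate()` inverts the
segment whose back-calculated value falls in its own range; values
landing in the gap between segment ranges go to the nearer segment with
a warning, values below the LLOQ (the lowest standard) are flagged but
returned, and negative back-calculations are flagged non-quantifiable. A
round-off guard snaps back-calculated values within $10^{-8}\,\max(hi)$
below zero to exactly zero so that a signal numerically equal to the
intercept maps to concentration 0, not to "negative".

`qc_stats()` computes intra-day RSD (within-day RSD averaged across
days), inter-day RSD (RSD of daily means) and relative recovery
(mean measured / nominal × 100) per QC level, with advisory bands
(RSD ≤ 10%, recovery 85–115%) that flag, never reject.

## The simulator

`simulate_well()` integrates a two-compartment model: donor and receiver
are well stirred, and net donor→receiver flux is

$$J = A\left[\,p\,(C_d - C_r)\; -\; s\,(1-i)\,\frac{V_{max}\,C_d}{K_m + C_d}\right],$$

with $s = +1$ for AP→BL and $s = -1$ for BL→AP: the saturable
Michaelis–Menten term is an apically directed efflux driven by the
donor-side concentration, so it opposes absorption and adds to secretion.
This is the simplest mechanistic form that exhibits the two signatures a
bidirectional assay probes: directionality ($ER > 1$ when $V_{max} > 0$)
and saturation (in the sink regime
$ER \approx \frac{p + V_{max}/(K_m + C_0)}{p - V_{max}/(K_m + C_0)}$,
decreasing in $C_0$). The inhibition fraction $i$ multiplies $(1-i)$
onto $V_{max}$, emulating co-incubation with verapamil/cyclosporin-like
inhibitors; $i = 1$ reproduces the efflux-free model exactly.

Deliberate simplifications:

* **No intracellular compartment.** Only donor and receiver are ever
  measured; a third compartment would add unidentifiable parameters.
* **Static monolayer.** No TEER drift, paracellular leak or viability
  loss over the run.
* **Noise is multiplicative lognormal** on the measured concentration
  only (unit mean; $\sigma_{\log}^2 = \log(1 + \mathrm{CV}^2)$):
  chromatographic error scales with concentration and concentrations
  stay positive. The true trajectory is never perturbed, so sampling
  withdrawals use the true concentration.

Consequently, passing tests demonstrate correctness of the analysis
arithmetic and its statistical behaviour *under this error model*; they
cannot certify robustness to biology the model omits (transporter
expression variability, pH gradients, recovery losses, adsorption).

### Numerical scheme

Between sampling events the two-state ODE is integrated with `deSolve`'s
`lsoda` (adaptive, stiff-capable) at `rtol = 1e-10`, `atol = 1e-12`;
each sampling is an instantaneous state jump (record $C_r$, remove
$C_r V_S$, restore the volume with blank buffer) — the
replace-with-blank-buffer protocol is event-like, not continuous. The
tight tolerances keep total mass (donor + receiver + withdrawn)
conserved to better than $10^{-9}$ relative at every event, a tested
invariant. Non-finite states abort with an error. The noiseless
trajectory for a given (direction, $C_0$) is deterministic, so
`simulate_condition()` computes it once and gives each replicate well
its own seeded noise stream, derived deterministically from the master
seed — identical seeds give byte-identical datasets.

### Default study conditions

| parameter | default | unit | rationale |
|---|---|---|---|
| `area` | 1.12 | cm² | 12-well Transwell insert membrane |
| `vol_ap`, `vol_bl` | 0.5, 1.5 | mL | 12-well Transwell convention; receiver volume is a convention, not a published fact, hence configurable |
| `times` | 30…180 by 30 | min | 180-min runs are standard; the exact grid is rarely published, hence configurable |
| `vs` | 0.2 | mL | the published sampling aliquot |
| `km` | 25 | µg/mL | below the 100–200 µg/mL dose range, so saturation is expressed across it |
| `noise_cv` | 0 (0.05 in noisy scenarios) | — | 5% is a typical HPLC assay CV, consistent with ≤ 10% QC precision limits |
| replicates | 6 per direction in stochastic tests | wells | published group SDs imply n ≥ 3; n = 6 matches the assay's six parallel QC preparations |

## Problem sizes used by the test suite

The dilution-correction/bookkeeping identity is checked on 1,000 random
concentration sequences (tolerance $10^{-12}$ relative); mass
conservation on a 12-case parameter grid ($10^{-9}$); passive parameter
recovery on noiseless sink-regime simulations (within 2%, donor
depletion being the residual bias); the classification rule on 200
seeded runs per scenario at $n = 6$ wells/direction and 5% noise
(passive → passive-consistent and tuned efflux → active-transport-likely,
each in ≥ 95% of runs; 80% inhibition cuts the median ER by well over
30%); and saturation as a strict ER decrease from $C_0 = 100$ to
$200$ µg/mL on noiseless runs. Null and power behaviour of the Welch
contrast are checked on 50 seeded runs each.

## Known limitations

* $P_\mathrm{app}$ from a late-window fit underestimates the true
  permeability once donor depletion or receiver backpressure matter; the
  sink-regime bias at the defaults is ~1–2% and shrinks with an early
  fit window.
* The ER of an asymmetric-volume insert is not exactly 1 even for a
  purely passive compound (≈ 1.01 at the defaults) because the two
  directions deplete their donors at different rates.
* The group-mean ER (ratio of means) and the mean of per-well ERs are
  different statistics; both are reported, and only the former is used
  for classification.
* Calibration assumes straight-line segments; curvature (e.g. detector
  saturation) must be handled upstream.
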