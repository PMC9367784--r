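---
title: "A life-cycle GHG inventory for beef cattle breeding systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A life-cycle GHG inventory for beef cattle breeding systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cattleGHG)
```

## The system and the question

cattleGHG builds annual CO2-equivalent greenhouse-gas inventories for an
intensive beef-fattening system coupled to the corn cropping that feeds it.
Two breeding models are compared:

* **EC (ecological cycle)** — whole-plant silage corn fed at 20 kg/head/d,
  100% of manure returned to the field, all straw used as a resource (no
  open burning), and on-farm silage feed processing.
* **non-EC (conventional)** — common corn fed at 9 kg/head/d, only 45% of
  manure entering the planting system, 85.75% of the regional straw
  resource open-burned, feed purchased rather than processed on-farm.

The reference parameterization describes 10 million head at the 319 kg
default live weight over a 365-day fattening cycle in a corn-belt province.
The system boundary covers corn planting, fertilizer and manure
application, feed processing, straw burning, enteric fermentation and
manure management. Irrigation, transport, energy use, upstream fertilizer
manufacture and soil carbon-stock change are outside the boundary by
design.

## Emission model

All processes are linear emission-factor (IPCC Tier-1 style) calculations.
Masses are carried internally in kg/a; only report writers convert to the
display unit of $10^7$ t/a. Gases are aggregated with GWP100 values
$\mathrm{GWP}_{CH_4} = 28$ and $\mathrm{GWP}_{N_2O} = 265$.

**Corn planting (CO2).** $E_{farm} = Q \cdot ef_{farm}$ with
$ef_{farm} = 1.50$ t CO2 per t corn. For the EC model $Q$ is the annual
silage demand; for the non-EC model it is the straw requirement implied by
the straw balance (below).

**Soil N2O from applied N** (chemical fertilizer, and field-applied manure).
Direct plus two indirect pathways:
$$E = T_N\,(ef_{ND} + ef_{NH} F_{GAS} + ef_{NL} F_{L})\,\tfrac{44}{28}\,
\mathrm{GWP}_{N_2O}$$
The 44/28 conversion of N2O-N to N2O is kept as an exact rational, never a
rounded decimal. Fertilizer N input is reconstructed as
$T_{NF} = A \cdot Q_{SN} \cdot (R_{NF} + R_{CF}\, w_c)$: applied
fertilizer mass over the planting area, reduced to N through the
straight-N share plus the compound share times its N content.

**Feed processing (CO2, EC only).** $E_{feed} = Q_s \cdot ef_{feed}$,
$ef_{feed} = 0.0102$ t/t.

**Straw burning (non-EC only).** Burned mass
$= Q_{straw} R_{burn} G$ with the combustion factor $G = 0.1$; per-gas
factors 1.39 (CO2), 2.19e-3 (CH4), 7e-5 (N2O) kg per kg burned.

**Enteric fermentation (CH4).** One Tier-1 factor per head,
$E = N_a \cdot ef_{EF} \cdot \mathrm{GWP}_{CH_4}$ with $ef_{EF} = 65$
kg/head/a in both models. A feed-dependent (gross-energy/Ym) Tier-2 model
is deliberately out of scope: the comparison isolates system structure,
not diet quality.

**Manure management.** CH4 scales with per-head volatile solids
$VS = VS_{rate} \cdot W/1000 \cdot 365$ and the managed fraction $MS$;
N2O has a direct term plus volatilization and leaching indirect terms on
managed N, $N_{ex} = N_{rate} \cdot W/1000 \cdot 365$ per head.

## The straw balance and its two totals

The non-EC feed demand (3.285e10 kg/a) pins down the regional straw
resource through the 9.88% feed share. Two totals arise and the reference
results are internally calibrated against *different* ones:

* the **normalized** total rescales the two retained fates
  (feed + burning = 95.63%) to sum to one:
  $3.285\mathrm{e}10 \times 0.9563/0.0988 = 31.80\mathrm{e}10$ kg — this is
  what the corn-planting CO2 of the non-EC model consumes;
* the **feed-share** total divides by the feed share alone:
  $3.285\mathrm{e}10 / 0.0988 = 33.25\mathrm{e}10$ kg — only this value
  reproduces the reported straw-burning emissions.

`straw_balance()` therefore carries both, each consuming process names
which one it uses, and the inconsistency is documented here rather than
resolved silently.

## Replication mode, corrected mode, and the as-reported cells

Three cells of the reference results cannot be derived from the published
coefficient set:

1. **EC fertilizer N2O** prints 0.21e7 t/a where the coefficients give
   0.158e7 t/a. No parameter combination we tested reconciles them, so the
   EC scenario carries an explicit as-reported override (0.21e7 t =
   2.1e9 kg/a). Overrides are part of the scenario record and flagged in
   every report.
2. **Manure application N2O** (49.53 / 22.29 t/a) is reproducible only
   with the *per-head* annual manure mass (8030 kg) times the return rate
   as the activity — not herd-level N — and a GWP of 273 rather than the
   265 used everywhere else. The scenario's `gwp_n2o_manure_application`
   field exists solely for this pathway.
3. **Burning CH4** computes 0.175e7 t/a against a printed 0.18e7; we treat
   this as rounding in the source and do not adjust factors to chase it.

`build_inventory(spec, mode)` exposes both conventions. `"replication"`
applies the overrides and the per-head manure-application basis, and
reproduces the reported tables. `"corrected"` ignores overrides and
applies the coefficient set uniformly (herd N excretion, GWP 265
throughout). Both are first-class outputs; the mode and any override flags
travel with every report.

Two further bookkeeping choices follow the source's own conventions. The
per-head manure mass is taken as the printed annual 8030 kg (22.0 kg/d
x 365); the surveyed daily figure of 22.67 kg/d is inconsistent with that
annual value and is not used numerically. Planting areas (9.01e5 and
70.66e5 hm2) are scenario inputs: the stated per-area straw yields do not
reconcile with them under any unit reading we tried, so no attempt is made
to derive one from the other.

## Rounding and report structure

Computation is always full precision; display rounds half-away-from-zero
to 2 decimals in $10^7$ t. The reported totals (19.62 and 75.95e7 t/a) are
sums of *rounded* components, so full-precision totals agree with them to
about 0.1% but not exactly; the same residue explains the non-EC N2O gas
total (full precision 1.375 vs the printed 1.37 = 1.24 + 0.05 + 0.08).
Conservation, by contrast, is exact by construction: process, gas and
industry partitions of a report sum to the same total to machine
precision, and regrouping the process table by gas *is* the gas table.

Comparisons are signed (`non-EC - EC`), so the EC-only feed-production
process appears as a negative "reduction", matching the reference layout.

## Sensitivity and uncertainty

The source discusses uncertainty qualitatively (factor choice, GWP
vintage, data representativeness); the package makes it quantitative.

* `oat_elasticity()` computes central-difference elasticities
  $(\Delta E/E)/(\Delta p/p)$. Because every output is linear in its
  parameters, an elasticity equals the parameter-driven share of the
  output — a built-in cross-check used by the test suite.
* `monte_carlo()` propagates parameter distributions by plain independent
  seeded sampling (no Latin hypercube or variance reduction, for
  auditability), rebuilding the full inventory per draw. Fractions are
  truncated to [0, 1] and all rates to [0, Inf). Identical inputs and
  seed give bit-identical summaries.

The default perturbation set puts a +/-20% uniform band on every emission
factor — the source names factor choice as its main uncertainty but gives
no distributions, so a symmetric band of that width is our choice — plus
the surveyed roughage range (8-10 kg/head/d) on non-EC feed intake.
Concentrate feed (2.5-6.5 kg/head/d) is identical in both models and has
no emission pathway inside the boundary, so it is not perturbed. GWPs are
exposed as perturbable parameters but not perturbed by default.

## The synthetic-scenario generator

`generate_scenario()` and `generate_suite()` produce structurally valid
random scenarios so every pipeline stage is testable without external
data. Herd size is sampled log-uniformly over 1e4-1e7 head so that
linearity properties are exercised across scales; generated non-EC
scenarios keep feed + burn straw fates at 0.9563, mirroring the reference
straw structure; intake ranges follow the surveyed bands. Pinning every
interval (`generation_ranges(kind, pin = TRUE)`) collapses the generator
onto the reference scenarios exactly, making it a strict superset of the
fixtures.

What the generator does *not* emulate: covariance between parameters
(e.g. heavier animals excreting more), regional heterogeneity, or
year-to-year variation. Passing tests on generated scenarios therefore
demonstrate structural correctness of the accounting, not realism of any
particular parameter combination.

## Numerical choices and problem sizes

* Validation collects all invariant violations before erroring, and runs
  before any computation in `build_inventory()`.
* Degenerate scenarios (zero herd, zero area) are legal and produce
  all-zero inventories; a zero straw-feed share is an error with a
  remediation hint, since the straw totals are then undefined.
* Scenario YAML round-trips exactly: numbers are written with the
  shortest decimal representation that reproduces the double.
* The test suite checks every emission formula against independently
  coded one-line arithmetic oracles on 100 random draws at 1e-12 relative
  tolerance, and Monte-Carlo convergence at n = 2000 draws; the
  acceptance script uses n = 500 draws for its uncertainty summary. These
  sizes give sub-percent Monte-Carlo error on linear outputs while
  keeping a full run near-instant.

## Limitations

The inventory is a linear factor model: no process interacts with any
other, so it cannot capture, e.g., diet-dependent enteric emissions or
nitrogen cycling between manure return and fertilizer demand (a real EC
system would displace some chemical fertilizer; here the two pathways are
independent, as in the source). Absolute totals, not per-kg-beef
intensities, are the functional unit. The replication numbers inherit the
documented internal inconsistencies of their source; corrected mode is
the self-consistent variant, not a new calibration.
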