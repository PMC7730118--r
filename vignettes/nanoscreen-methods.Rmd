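---
title: "Models and methods behind nanoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoscreen)
```

This vignette documents the models, conventions and numerical choices
of the package: what is assumed, which knobs matter, and what the
simulation-based tests do and do not demonstrate about real
measurements.

## The measurement model

Single-particle ICP-MS observes detector counts per dwell (integration
window). Dissolved analyte and spectral interferences produce a
continuous background; each particle produces a transient ion cloud —
a spike. The calibration chain that turns a spike into a diameter rests
on four quantities:

* **ionic calibration slope** $a$ (counts per dwell per µg L⁻¹),
  fitted by ordinary least squares over a multi-point dissolved
  standard curve (`fit_ionic_calibration()`). No weighting is applied:
  the counting noise at these concentrations is nearly homoscedastic
  on the scale of the fit and the standard protocol specifies none.
* **transport efficiency** $\eta$, estimated by the particle-size
  method (`estimate_te_size()`): a reference particle of known
  diameter and density (63 nm gold, density 19.30 g cm⁻³ — the
  standard literature value) has known mass $m_\mathrm{ref}$, so
  $\eta = a\, m_\mathrm{ref} / (q\, t_\mathrm{dw}\, \bar I_p)$ with
  $\bar I_p$ the mean *background-corrected, integrated* event
  intensity. Vendor tools differ on whether $\bar I_p$ is modal or
  mean intensity; this package always uses the mean of integrated net
  counts, which is unbiased under Poisson noise and multi-dwell
  spikes. The frequency method (`estimate_te_frequency()`) is provided
  as a cross-check when a number-concentration reference exists.
* **analyte mass fraction** $f = 0.60$ for Ti in TiO₂, stored exactly
  as the screening protocol sets it rather than the stoichiometric
  0.5994 — fidelity to the protocol wins over chemistry, and the
  difference (0.1 %) is far below measurement uncertainty.
* **density** $\rho = 3.9$ g cm⁻³ (anatase), with perfect sphericity
  assumed; the reported size is the equivalent spherical diameter.

Units are fixed package-wide: nm for sizes, fg for masses, mL for
volumes, seconds for times. Flows are accepted in mL min⁻¹ (the unit
instruments display) and converted internally to mL s⁻¹.

## Background and spike detection

`estimate_background()` iterates: compute mean and SD over unflagged
dwells, flag dwells above mean + $k\sigma$, repeat to convergence. The
size detection limit keeps the conventional $k = 3$ definition: the
diameter whose net spike equals $3\sigma_b$.

For *event discrimination* the pipeline defaults to $k = 5$ while
`detect_events()` itself defaults to $k = 3$ (the definitional value,
configurable). The reason is Poisson arithmetic: a 3σ cut on a skewed
counting distribution leaves an irreducible per-dwell false-positive
rate of roughly 0.1–0.3 %, which over the 600 000 dwells of a 60 s /
100 µs scan would contribute on the order of a thousand spurious
single-dwell "events" — comparable to the true particle count. At 5σ
the expected false-positive count is far below one per scan. Using a
stricter discrimination threshold than the LOD definition is standard
practice in spICP-MS software.

Contiguous super-threshold dwells merge into one event (no gap
bridging by default; configurable), because at 100 µs dwell a single
particle's ~0.5 ms ion cloud spans several dwells. Net counts are
gross counts minus the background expectation over the event's dwells.
Events touching the scan boundary are kept — censoring them would bias
number concentration low by a negligible but asymmetric amount.

## Measurands

D-values use linear interpolation of order statistics (position
$1 + (n-1)\,x/100$; `stats::quantile()` type 7), fixed and documented
because vendor packages disagree and D99.5/D99.8 are sensitive to the
convention. D0 and D100 are the sample extremes. The percentage below
100 nm is strict (`< 100`): a particle at exactly 100 nm is not nano.
The most frequent diameter is the argmax of a Gaussian-kernel density
estimate with Silverman's bandwidth on a 1 nm grid from 0 to the
maximum plus three bandwidths; with multiple local maxima the global
maximum wins. The bandwidth is recorded in the report for audit.
The size LOD is reported but never used to filter events — particles
below it are undetectable by construction, so post-hoc filtering would
only introduce a second, inconsistent truncation.

The number concentration of the measured suspension is
$n_\mathrm{events} / (\eta\, q\, T)$; sample-referenced quantities
(total particles, particles per gram) additionally require the
dilution chain (product of step factors) and sample mass. The lower
bound D0 typically lands near the size LOD for E 171-like materials,
but the package reports both without forcing equality — they are
distinct quantities that happen to coincide when the distribution's
lower tail crosses the detection floor.

## The scan simulator

The simulator is the package's testbed: every downstream stage is
validated against its ground truth. Per dwell, arrivals are Poisson
with rate $\lambda = c\, q\, \eta\, t_\mathrm{dw}$; configurations
with $\lambda > 10$ are refused as an unresolvable coincidence regime.
Constituent diameters are lognormal, truncated to 10–1000 nm (the
instrument-observable range; also keeps moments finite). With
probability `p_agg` an event carries a Poisson number of extra
constituents that travel as one cluster — spICP-MS cannot resolve
them, so their masses sum into a single larger event, exactly the
mechanism that biases spICP-MS sizes above TEM sizes. Counts are
Poisson around background + sensitivity × deposited mass; no flicker
or dead-time model (out of scope). Event mass is split equally over
$\lceil \mathrm{pulse\ width} / t_\mathrm{dw} \rceil$ dwells with a
0.5 ms default pulse width — the typical transient duration, and the
single parameter that differentiates 100 µs from 3000 µs dwell
behaviour. Spill-over past the scan end is deposited in the final
dwell so that expected counts conserve injected mass exactly.

Defaults are the study conditions the package emulates, chosen once:

| parameter | default | rationale |
|---|---|---|
| median, GSD | 150 nm, 1.4 | E 171-like number distribution; median matches the ~149 nm scale reported for this material by spICP-MS |
| number concentration | 7.5 × 10⁴ mL⁻¹ | ~1500 events per 60 s scan at η = 0.12, 0.17 mL min⁻¹ — inside the 1000–2000 band the protocol targets |
| flow, dwell, scan | 0.17 mL min⁻¹, 100 µs, 60 s | standard operating point |
| η | 0.12 | middle of the 11.3–13.8 % range typical for the reference instrument |
| sensitivity | 250 counts fg⁻¹ | order-of-magnitude instrument choice (per-lab values unreported in practice) |
| background | 20 counts/dwell | with the sensitivity above, places the size LOD at ≈ 35 nm |

The interlaboratory simulator draws per-lab transport efficiencies
(5–14 %), dwell times (100 µs or 3000 µs, with background scaled to the
integration window), flows (0.17–0.47 mL min⁻¹) and a lognormal
sensitivity bias, reflecting the spread observed across food-control
laboratories; each lab is calibrated through its own simulated ionic
curve and reference scan, so calibration error propagates realistically.
Lab-level seeds derive deterministically from the study seed.

What the simulator does *not* emulate: matrix effects, incomplete
ionisation, detector dead time, drift, non-Poisson flicker noise, and
software-specific data treatment. Passing recovery tests therefore
demonstrate the correctness of the data reduction, not the absence of
instrumental bias in real measurements; between-lab spreads in
simulated studies are narrower than those of a real trial, where
sample preparation and vendor software differences dominate.

## Interlaboratory statistics

The robust route (`robust_precision()`) follows the standard
collaborative-trial estimators: Algorithm A (median/MAD start;
winsorise at $x^* \pm 1.5 s^*$; update with factors 1.483 and 1.134)
on cell means gives the consensus $X_{pt}$ and between-cell scale
$s_d^*$; Algorithm S (limit factor $\eta_\nu$, adjustment factor
$\xi_\nu$, tabulated for $\nu = 1\ldots10$) on cell SDs gives the
repeatability $s_r$; then
$s_R = \sqrt{s_d^{*2} + s_r^2 (1 - 1/\bar n)}$, floored at $s_r$, and
$U(X_{pt}) = 2 s_d^*/\sqrt{p}$ — the natural standard error of the
Algorithm-A mean, a reading confirmed by the internal consistency of
published trial tables to ~2 %. Unbalanced designs use the mean
replicate count $\bar n$; a documented approximation. The Algorithm S
factor table is verified in the test suite by Monte-Carlo unbiasedness
on normal data; above $\nu = 10$ the $\nu = 10$ factors are reused
(they converge slowly toward 1, so the approximation is mild).

A note on breakdown behaviour: when one laboratory's values are
multiplied by 10, the winsorised contribution still shifts the robust
mean by a fraction of $s^*$ (about $0.2$–$0.4\,s^*$ at $p = 7$). The
meaningful robustness statement — and the one the tests assert — is
relative to the corrupted dataset's own standard error: the robust
consensus moves by far less than half that SE, while the classical
mean moves by more, every time.

The classical route (`classical_precision()`) screens cell variances
with Cochran's test and cell means with Grubbs' test, iteratively;
cells significant at 1 % are excluded, those between 5 % and 1 %
flagged as stragglers and retained. Critical values come from F- and
t-distribution closed forms (verified against Monte Carlo) instead of
hard-coded tables. The design is never reduced below three
laboratories: at $p = 3$ suspects are flagged but kept. The retained
cells are decomposed by one-way ANOVA into $s_r$, $s_L$ and
$s_R = \sqrt{s_L^2 + s_r^2}$.

Published trial tables are checked for internal consistency
(`check_precision_consistency()`) with explicit rounding propagation:
each printed value carries half a unit in its last place, and the
identity $\mathrm{RSD} = 100\,s/X_{pt}$ is tested as an interval
overlap. Without this, correctly printed tables would appear
inconsistent (e.g. a printed X of 38 with R = 17.8 and RSD 46.5 %).

## TEM summaries and classification

TEM per-particle tables carry the minimum and maximum Feret diameters;
the aspect ratio is computed when absent. Quantification limits
(defaults 11.5–478 nm) are applied to the measurand being summarised;
the dimensionless aspect ratio is summarised over rows where both
diameters are quantifiable (the limits are lengths — applying them to
a ratio would be meaningless). A floor of 500 analysed particles
triggers a warning, not an error.

The decision rule is deliberately asymmetric. TEM measures constituent
particles, so median < 100 nm ⇒ nanomaterial and median ≥ 100 nm ⇒ not
a nanomaterial. spICP-MS overestimates sizes near the boundary
(detection floor ≈ 35 nm truncates the lower tail; agglomerates appear
as single large particles), so it can only rule a material *in*:
median < 100 nm ⇒ nanomaterial, anything else ⇒ inconclusive, confirm
by TEM. The comparison helper flags the unexpected direction
(spICP-MS below TEM) because under the stated mechanism it should not
occur; on matched simulated samples the bias is reproduced by
construction.

## Numerical and degenerate-input conventions

* `excluded_count()` rounds half-up, matching the integer counts of
  truncation tables.
* Quantiles of constant samples return the constant at every level;
  empty distributions error in `size_quantile()` and produce an
  all-NA report in `distribution_report()`.
* A zero-variance background makes the size LOD degrade to the
  1-count-equivalent diameter, with a warning.
* Algorithm A with zero MAD but non-identical data falls back to the
  classical SD (warned); Algorithm S with all-zero SDs returns 0.
* Transport efficiencies numerically above 1 are clipped to 1 with a
  warning in the size method and are an error in the frequency method
  (there they indicate inconsistent inputs, not noise).
* All simulation randomness flows through explicit mandatory seeds;
  identical seeds give bit-identical scans.

## Problem sizes used in the tests

The test suite simulates full-scale scans where the claim under test
is statistical (60 s at 100 µs dwell, ~1500 events) and short scans
(2–10 s at elevated concentration) where only plumbing is exercised.
Interlaboratory recovery uses 200 simulated balanced 7 × 3 studies;
Monte-Carlo verification of the robust estimators uses 300–400
replicates. These sizes give sampling error comfortably below the
asserted tolerances (e.g. median recovery is tested at 3 % with a
standard error of ~0.9 % at n ≈ 1500).

## Known limitations

* No coincidence deconvolution or dead-time model: at the recommended
  dilution (λ ≈ 0.0025 events/dwell) coincidences are ~0.1 % of
  events.
* The robust estimators may differ in the last digits from commercial
  implementations of the same standard, whose exact variants are not
  public.
* The classical ANOVA decomposition uses the balanced formulas with
  the mean replicate count for mildly unbalanced designs.
* Report JSON/CSV schemas are package conventions; vendor export
  formats are out of scope (plain single-column CSV only).
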