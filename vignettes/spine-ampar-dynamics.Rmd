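---
title: "Quantifying longitudinal spine AMPA-receptor dynamics with spinedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying longitudinal spine AMPA-receptor dynamics with spinedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedyn)
library(dplyr)
```

## The measurement model

spinedyn analyses longitudinal two-photon imaging of dendritic spines
co-expressing SEP-GluA1 (a pH-sensitive GFP fused to the GluA1 AMPA-receptor
subunit, fluorescent only at the cell surface) and dsRed2 (a pH-insensitive
cytosolic fill). The green spine-head signal therefore reports surface AMPAR
content ("sGluA1"), and the red spine signal proxies spine size. Each spine
contributes three regions of interest per channel: a spine-head ROI, a shaft
ROI on the adjacent dendrite, and a matched background ROI.

The core quantity is the shaft ratio

$$\mathrm{sGluA1} = \frac{\text{spine}_{green} - \text{bg}_{green}}
                         {\text{shaft}_{red} - \text{bg}_{red}},
\qquad
\mathrm{size} = \frac{\text{spine}_{red} - \text{bg}_{red}}
                     {\text{shaft}_{red} - \text{bg}_{red}}.$$

Because day-to-day variation in laser power, window clarity and detector
settings multiplies every ROI of a session by a common gain, and the shaft
dsRed signal is not expected to change, dividing by the
background-subtracted shaft dsRed cancels the session gain exactly. The
package treats this invariance as a contract and tests it bit-for-bit.

Downstream normalization modes re-express each spine's trace for specific
analyses: relative to its own day-1 value, relative to the mean of the three
baseline sessions (for deprivation experiments), relative to the mean of its
dendrite at the same session (for cross-spine comparisons), or as
day-over-day change ratios. Per-dendrite summaries use the geometric mean of
spine values, restricted to persistent spines; "average level of the
dendrite" in the relative-to-dendrite normalization is read as the
arithmetic mean, reserving the geometric mean for the explicitly
dendrite-level change summary. Any normalization whose reference value is
missing propagates missingness — nothing is imputed. Negative
background-subtracted numerators are floored at $\varepsilon = 10^{-6}$ and
flagged rather than dropped, keeping trace shapes aligned while excluding
the flagged values from statistics.

## Schedules, fates and dynamics metrics

Two session layouts are supported: ten consecutive daily baseline sessions
(`baseline10`), and three baseline sessions followed by imaging 1, 2, 3 and
7 days after binocular enucleation (`deprivation`; sessions BL1-BL3,
VD1-VD3, VD7).

Spine fate is classified from presence patterns: persistent spines span the
whole schedule, formed spines first appear after session 1, eliminated
spines disappear before the last session. A spine absent at an interior
session but present on both sides is treated as a detection failure rather
than elimination-plus-reformation, since re-formation at the same site is
not a described phenomenon and treating gaps as two events would understate
persistence. The persistence fraction uses the day-1 cohort as denominator:
under independent per-session survival $p$ over $n$ sessions it estimates
$100\,p^{\,n-1}$, which is how the preset survival values were calibrated
(0.958 per session giving 68% over 10 days for L2/3; 0.955 giving 66% for
L5).

Day-to-day dynamics are measured by the coefficient of variation (sample SD
over arithmetic mean) of each spine's relative level across a session
window, requiring at least three valid sessions. Cross-day stability and
size-fluorescence coupling use Pearson correlation — pooled over all daily
transitions for the population coupling, and per spine (minimum three
transitions) for the inverse-correlation fraction, operationalized as a
per-spine correlation below zero since no stricter criterion is defined in
this literature.

## Deprivation analyses

Timecourse figures summarize baseline-normalized per-dendrite geometric
means with mean ± SEM per session and a repeated-measures comparison
against the pooled baseline (see below). Response heterogeneity is captured
by a pure threshold rule: a unit (dendrite, spine or cell) is a "decrease"
unit if its value at VD1 is at most $1 - \theta$, where $\theta$ is the
sample SD of sham-group percent changes at the equivalent session
(`sham_threshold()`). The reference constants from the source experiments —
0.18 for dendrites, 0.435 for spines, 0.098 for cells — are accepted as
fallback configuration values; no per-unit hypothesis test is applied
because the rule is defined by the sham SD alone. Cells pool their apical
dendrites by geometric mean before the rule is applied.

Spatial analyses use min-max coordinates: relative spine depth (most
superficial spine 0, deepest 1) and relative distance from the branch point
(most proximal 0, most distal 1) within each dendrite; dendrite depth is
the mean of its spines, scaled within the imaging ROI. Segments are
`ascending` when they run toward the pia with |ΔDepth|/ΔDistance > 0.1
between endpoints (endpoint geometry, not a per-spine regression),
`descending` in the opposite direction, otherwise excluded; ascending and
descending subsets partition all non-excluded dendrites. The
depth-extremes comparison contrasts the deepest and most superficial 15% of
spines per dendrite, with group size `max(1, round(0.15 n))` (half rounded
away from zero) and depth ties broken by spine id for determinism. The
basal/apical change ratio pools each neuron's dendrites by geometric mean
per compartment and guards the apical denominator at 0.05.

## Statistical routing

Every comparison is first routed by Shapiro-Wilk normality at α = 0.05: if
all groups pass, the parametric branch runs (Student's t, one-sample t, or
repeated-measures one-way ANOVA with Bonferroni-adjusted paired comparisons
of each post-deprivation session against the pooled baseline); otherwise
the non-parametric branch (Mann-Whitney, Wilcoxon signed-rank, or Friedman
with Dunn's post hoc, $z_{j} = (\bar R_j - \bar R_{ref}) / \sqrt{k(k+1)/6n}$
on within-unit ranks). The routing decision, per-group normality p-values
and Bonferroni-adjusted post hoc rows are all reported in the result
object; `tidy()` and `glance()` methods expose them as tibbles. Timecourses
use the repeated one-way design because every dendrite is measured at every
session; the basal-vs-apical within-neuron comparison uses the two-way
repeated design with a rank-transformed fallback. Test kernels are the
standard base-R implementations; the module's contribution is the routing,
the pooled-baseline pairing structure, and the reporting contract.

## The synthetic-data generator

No public raw dataset accompanies the source experiments, so the package
ships a calibrated generator (`spine_preset()`, `simulate_spine_dataset()`)
whose presets are the experimental arms. For each spine the latent sGluA1
at session $s$ is

$$V_{is} = S_i\, e^{\epsilon_{is}}\, m_{is}\, r_{is}$$

with lognormal set-points $S_i$ (log-SD 0.5 across spines, plus a
distance-from-branch gradient of 0.4 so baseline level rises toward the
distal dendrite, a robust cross-layer phenomenon), i.i.d. Gaussian
log-fluctuations $\epsilon_{is}$ scaled so the day-to-day CV matches the
preset (0.30 for L2/3, 0.20 for L5; after deprivation 0.22 and 0.26
respectively), a deprivation multiplier $m_{is}$, and a two-session linear
ramp $r_{is}$ for newly formed or about-to-be-eliminated spines, which also
carry half-sized set-points — making transient spines dimmer and more
variable than their persistent neighbours. The i.i.d. multiplicative
fluctuation around a stable per-spine set-point is the simplest process
matching both a target CV and a stable day-1/day-10 correlation; no
autocorrelation model is claimed by the source data, so none is simulated.
Spine size shares the set-point and fluctuation model with log-correlation
0.7 to sGluA1 (static and in daily changes) and a square-root-attenuated
deprivation effect, making size changes track sGluA1 but smaller.

Deprivation arms draw each L2/3 apical dendrite (or each L5 cell) into a
"decrease" subpopulation with probability 0.51 (0.5 for L5): decrease units
dip to 0.70 at VD1 and recover, no-decrease units rise to 1.30 by VD7;
basal dendrites follow a single increasing profile from VD1 (1.15 to 1.35);
non-V1 declines monotonically to 0.85; L5 recovers to at most ~1.08 with no
significant late increase; GRIP1-KO dips to 0.85 and returns to 1 by VD7.
The L2/3 depth gradient multiplies the deprivation effect by
$1 + 0.25\,(d_i - 0.5)$ with $d_i$ the spine's relative depth — centred on
the dendrite midpoint so depth redistributes the effect without shifting
session means, which keeps the timecourse profiles and the depth
correlation independent, and applied only at post-deprivation sessions
(a static gradient would cancel under baseline normalization).

Raw ROIs are generated as `gain_s × 1000 × latent + 50 + N(0, 3)` with the
per-session lognormal gain (SD 0.1) shared by all ROIs and both channels —
channel-specific gains are unidentifiable under shaft normalization and are
omitted — and matched background ROIs at `50 + N(0, 3)`. Apical dendrites
are drawn 30-120 µm below the pia, basal 150-300 µm, with z increasing
downward; dendrite slopes are drawn in ±(0.05, 0.6) so ascending,
descending and excluded orientations all occur. Presence follows
independent per-session survival after first detection, with new spines
forming at 0.2 per dendrite-session. One RNG stream is seeded per dataset:
a dataset is a deterministic function of (config, seed). Ground-truth
latent fields are carried in `true_*` columns that analysis functions never
read — a firewall asserted by the test suite.

Default cohort sizes mirror the experimental arms (e.g. 16 neurons × 2
apical + 2 basal dendrites for the within-neuron deprivation preset, ~12
spines per dendrite); persistence and CV calibration checks use ~1000
spines (14 neurons × 6 dendrites), the scale at which binomial and CV
sampling error are small relative to the calibration targets.

What the generator does *not* emulate: optics (spines render as Gaussian
blobs, no PSF or motion artifacts), photobleaching, spine-size morphometry
beyond the dsRed intensity proxy, autocorrelated fluctuations, and any
electrophysiology. Tests passing on synthetic data therefore validate the
analysis contracts — normalization algebra, classification rules,
coordinate conventions, statistical routing — not biological effect sizes
in real tissue.

## A worked run

```{r, eval = FALSE}
ds <- simulate_spine_dataset(spine_preset("L23_VD"), seed = 1)
q  <- quantify_intensities(spine_table(ds))
nb <- normalize_trace(q, "to_baseline_mean", ds$sessions)
dsum <- dendrite_summary(nb, ds$sessions)

tc <- timecourse(dsum, ds$sessions)
autoplot(tc)

ba <- basal_apical_ratio(dsum, dendrite_table(ds))
route_test("one_sample_vs_1", x = ba$ratio)
```

## Numerical choices and limitations

* Flagged-invalid measurements become `NA` and are excluded from
  statistics; the flag column retains the reason (`floored`,
  `invalid_shaft`).
* Classification is deliberately a sharp threshold: a unit exactly at
  $1-\theta$ counts as decrease. Units missing the evaluated session are
  excluded and logged, so the decrease percentage's denominator is the
  classified units only.
* The Friedman/Dunn branch operates on within-unit ranks and is invariant
  to monotone transforms of the values; the Bonferroni post hoc compares
  each post-deprivation session to the pooled baseline, not all pairs.
* Dendrites whose spines share a single depth are excluded from depth
  analyses (relative depth undefined); single-dendrite ROIs have undefined
  relative dendrite depth.
* The generator's effect sizes are calibrated to reported summary
  statistics (persistence percentages, CV ordering, decrease fraction,
  qualitative timecourse shapes), not to raw data, which are not public;
  quantitative group means at specific sessions are generator choices and
  should not be read as reproductions of the original measurements.
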