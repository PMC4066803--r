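---
title: "Methods: force-spectroscopy analysis of transcription-coupled quadruplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-spectroscopy analysis of transcription-coupled quadruplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

quadtrace analyses single-molecule optical-tweezers experiments on a
G-quadruplex-forming DNA sequence held in a stalled transcription complex.
During transcription the nascent RNA can join G-tracts of the non-template
strand, so the same locus hosts a population mixture: DNA G-quadruplexes
(GQ), partially folded G-triplexes (GT), DNA/RNA hybrid quadruplexes built
from two or three DNA G-tracts (2G-HQ, 3G-HQ), and plain duplex or R-loop
("none"). The package turns raw force-extension (F-X) and force-jump records
into the population, stability and kinetics quantities that characterise
this mixture — and, because no public instrument data exist for this assay,
it ships a physics-based generator that produces the same kind of records
with known ground truth.

## Tether mechanics

The construct is a ~1595 nm double-stranded handle (4718 bp at 0.338 nm/bp).
Its elasticity is the extensible worm-like chain in the high-force
interpolation,

$$\frac{\Delta x}{\Delta L} \;=\; 1 - \frac12\sqrt{\frac{k_BT}{FP}} + \frac{F}{S},$$

with persistence length $P = 50.9$ nm, stretch modulus $S = 1168$ pN and
$k_BT = 4.089$ pN nm at 23 °C. The same expression doubles as the relative
extension of the tether, and as the conversion between an extension jump
$\Delta x$ at rupture force $F$ and the released contour length $\Delta L$
(`wlc_ratio()`, `delta_L_from_jump()`).

Released contour maps to a nucleotide count through
$n = \mathrm{round}\!\left((\Delta L + w)/c\right)$ with $c = 0.44$ nm/nt and
folded width $w = 2.3$ nm. These two constants are a calibration, not a
measurement: they are chosen once so that the three observed populations at
1.8, 3.8 and 6.0 nm map to 9, 14 and 19 nt (two, three and four G-tracts
plus intervening loops) under nearest-integer rounding, and they are
exposed as explicit parameters (`nt_conversion()`) rather than buried.

## The synthetic assay

`simulate_fx_dataset()` emulates one experimental condition at the study's
own settings: constant-loading-rate ramps at 5.5 pN/s up to 45 pN sampled at
1000 Hz, species drawn per curve from the condition's prevalence table
(`make_condition()`), Gaussian channel noise of 0.5 pN / 1.0 nm, and a
ground-truth manifest for every cycle. Rupture is stochastic with a
Bell-Evans escape rate $k(F) = k_0 e^{F x^\ddagger / k_BT}$, which at
loading rate $r$ gives a closed-form rupture-force distribution
(Gumbel-like, scale $k_BT/x^\ddagger$). The pair $(x^\ddagger, k_0)$ is not
taken from anywhere: per species, $x^\ddagger$ is solved from the reported
width of the force histogram ($\sigma_F = (k_BT/x^\ddagger)\,\pi/\sqrt6$;
5.24 nm for the hybrids at $\sigma_F = 1$ pN, 2.62 nm for GQ/GT at 2 pN) and
$k_0$ from the reported centre (31 pN hybrids, 25 pN GQ/GT) by numerically
inverting the mean of the distribution (`calibrate_bell_evans()`). At
rupture the measured force drops by an effective trap-tether stiffness
(1.0 pN/nm) times the released extension — large enough that the smallest
(1.8 nm) species produces a resolvable drop, small enough that detection is
not trivial at the configured noise.

Prevalence tables are the study conditions themselves: regular
transcription {2G-HQ 17.3%, 3G-HQ 9.4%, GT 3.8%, GQ 12.2%, none 57.3%},
7-deaza-GTP transcription {GT 8.1%, GQ 25.9%, none 66%}, no transcription
{GT 14.7%, GQ 9.6%, none 75.7%}, plus the mutant (2% folded — "very few"
is not a number, so a nominal 2% was fixed once), spacer (7.9%) and
lithium (6.7%) controls. The 3G-HQ/GT split inside the 3.8-nm population
uses the ratio-deconvolution result as generator truth, which is what makes
the deconvolution testable end to end.

`simulate_fpp_series()` emulates the force-pump-probe protocol: unfold at
45 pN, drop to 0 pN, incubate for time $t$, probe with a ramp starting at
10 pN. A species is present at the probe with probability
$p_s(t) = \pi_s\,(1 - e^{-t/\tau_s})$, so $t \to \infty$ recovers the
steady-state prevalences $\pi_s$. Time constants: hybrids 30 ms; GQ 10 ms
under transcription (below the protocol's 20 ms resolution floor, matching
the observation that it saturates within the first accessible point) and
150 ms without transcription. GT has no reported time constant; it is set
equal to the co-populated species of its condition (30 ms under
transcription, 150 ms otherwise) as a neutral default. The FPP generator
emits per-probe-cycle outcome records (incubation time, species, measured
delta-L and rupture force with small measurement noise) rather than
re-synthesising a full 1000-Hz trace for each of thousands of probe cycles;
the probe outcome is exactly what the kinetics analysis consumes.

What the generator does *not* emulate: bead and trap hydrodynamics,
drift, tether misalignment, multiple tethers, refolding transitions on the
relax branch, force-dependent refolding, and correlated (non-white) noise.
Tests passing on this generator therefore demonstrate that the analysis
recovers known truth under idealised instrument behaviour — not that it is
robust to every artefact of real recordings.

## Trace processing

Raw 1000-Hz traces are Savitzky-Golay filtered and decimated to 100 Hz
(`filter_trace()`). The default window is 21 samples at polynomial order 2
— the natural choice for a 10:1 decimation — which attenuates white noise
by the closed-form factor $\sqrt{\sum_i h_i^2} \approx 0.34$, taking the
0.5 pN channel noise below 0.2 pN. Constants and linear ramps pass through
unchanged (polynomial reproduction).

`detect_ruptures()` flags a rupture when the filtered stretch-phase force
drops by at least 1.0 pN within at most 3 samples at 100 Hz; the
accepted-event window is 0.5–10 nm of released contour. These thresholds
are declared, not inferred: at the generator's signal-to-noise they give
recall above 0.95 with a false-event rate below 0.02 per cycle (checked
against the truth manifest). When a cycle yields several accepted events
only the largest release is kept for population accounting — the assay
reports one species per curve and consecutive double events were not
observed — with a single summary warning.

Each event's released contour is measured twice:

* **Flanking points** — the samples two filtered points clear of the drop
  (outside the filter's step response) are translated to the rupture force
  along the tether's WLC curve, using the exact ratio difference rather
  than a linearised compliance (the drop can span several pN and the WLC
  curve is visibly curved over that span); the corrected extension
  difference divided by the ratio gives $\Delta L$.
* **WLC contour fits** — one-parameter least-squares contour fits
  ($x = L\,\rho(F)$, closed form) to the stretch segment below the rupture
  and to the relax branch, both over forces above 10 pN; their difference
  is $\Delta L$.

On noiseless data the two methods agree to better than 0.1% (median), and
the pipeline enforces 5% median agreement there as a regression property.
At the configured noise the flank method carries ~0.5 nm of per-event
noise while the fit method carries ~0.05 nm, so the fit value is the
pipeline's primary $\Delta L$; a per-event 5% consistency requirement
would reject most genuine 1.8-nm events at instrument noise and is
deliberately **not** used as a filter.

## Population deconvolution

`podnano()` pools the event $\Delta L$ values, computes a Gaussian KDE with
Silverman's bandwidth, and takes its local maxima as candidate population
peaks, ignoring bumps below 5% of the tallest peak (stray outliers).
The same bandwidth is reused in every bootstrap resample (3000 by default)
for stability; resampled peaks are matched to pooled peaks within a 1.0 nm
radius, peaks reproduced in fewer than half the resamples are dropped, and
the percentile spread of matched centres gives each peak's CI. The retained
peak centres initialise a k-component Gaussian-mixture EM
(`fit_gaussian_mixture()`; canonical sorted-mean order, SD floor 0.05 nm on
degenerate components), so the component count comes from the data, not
from a hard-coded k.

`percent_formation()` assigns each event-bearing curve to its
maximum-posterior component, labels components by centre (below 2.8 nm:
2G-HQ; below 4.9 nm: the mixed 3G-HQ/GT population; else GQ), and reports
percentages to one decimal with largest-remainder rounding so each
condition's column sums to exactly 100.0. `gt_hq_split()` then separates
the mixed ~4-nm population: the 7-deaza condition contains no hybrids, so
its GT/GQ ratio is pure, and assuming the same ratio under regular
transcription gives $GT = GQ_{reg} \cdot (GT_{dz}/GQ_{dz})$ and
$3G\text{-}HQ = \text{peak} - GT$ (one-decimal rounding, negative values
clipped with a warning). Overlapping rupture-force populations are
separated by `random_force_deconvolution()`: a two-component mixture fit
followed by seeded Bernoulli assignment at each event's posterior — the
randomised assignment appropriate when the populations genuinely
intersect.

## Energetics

The work of one near-instantaneous rupture is approximated by the
rectangle $W = F_r\,\Delta x$. Before Jarzynski averaging, the conjugate
work of stretching the released single strand from 0 to $F_r$
(inextensible WLC, persistence length 1.0 nm, 0.44 nm/nt, 1000-step
trapezoid quadrature over force with a self-convergence test) is
subtracted. The correction is referenced to the *net* released contour
$\Delta L$ — the strand length the rupture actually adds beyond the folded
structure's extension footprint — which keeps works positive for stable
structures; referencing it to the full nucleotide contour would exceed the
raw work for the smallest species and is physically inconsistent with the
measured $\Delta x$. Negative net works on marginal events are kept: the
exponential average needs the whole distribution.

$\Delta G = -k_BT \ln\langle e^{-W/k_BT}\rangle$ is evaluated with a
log-sum-exp guard and converted at 1 kcal/mol = 6.948 pN nm/molecule.
The estimator's finite-sample bias is estimated by recomputing it on 200
seeded half-size subsamples and extrapolating the mean linearly in $1/n$;
the SE is a seeded bootstrap SD. On the synthetic data the estimated
free energies preserve the stability ordering GQ > 3G-HQ > 2G-HQ; their
absolute values depend on the instrument's work distribution and are not
comparable to real-data numbers — the package makes no such claim.

## Folding kinetics

`folded_fraction_series()` tabulates, per incubation time, the fraction of
probe cycles whose event lands in each species group (components below
4.9 nm form the hybrid group, above it the GQ group), with binomial SEs.
`fit_exponential()` fits $f(t) = A(1-e^{-t/\tau})$ by weighted least
squares (inverse binomial variance, +0.5 continuity correction at extreme
fractions), restarting over decades of $\tau$ on non-convergence, and
derives a percentile CI from a 200-replicate seeded parametric bootstrap.
When the fitted $\tau$ falls below the smallest incubation time the series
saturated faster than the protocol can resolve; the fit sets `floor_flag`
and should be reported as "$\tau <$ 20 ms", which is exactly what happens
for GQ under transcription. The amplitude is fitted, not pinned to the
steady-state prevalence; their agreement is a test, not a constraint. The
default incubation grid {0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5} s at 500
cycles per point gives $\tau$ estimates with ~15% sampling spread — the
CIs, not the point estimates, carry the inference.

## Problem sizes and determinism

The packaged analyses run at the study's scale: 2000 pulling curves per
condition (processed in 100-curve batches so raw samples never accumulate),
3000 PoDNano resamples, and 8 × 500 probe cycles per kinetics series.
Every stochastic step takes an explicit integer seed (default 1) and equal
seeds give byte-identical outputs, including written report files.
`run_pipeline()` chains all stages for a set of conditions and emits the
condition-comparison table, the GT/3G-HQ split, quadruplex aggregates,
force classes, per-class free energies, kinetics fits and a seed manifest.

## Known limitations

* The $\Delta L \to$ nt constants and the Bell-Evans $(x^\ddagger, k_0)$
  pairs are calibrations to reported summary statistics, not fitted
  microscopic parameters.
* Rupture detection assumes a clean force drop; slow unfolding
  intermediates or drift would require different detectors (HMM/Bayesian
  step finders are out of scope).
* Free-energy absolute values from synthetic data inherit the generator's
  idealisations; only their ordering and estimator properties are
  meaningful.
* The exponential-refolding law ignores force-dependent folding during the
  probe ramp and multi-exponential or stretched kinetics.
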