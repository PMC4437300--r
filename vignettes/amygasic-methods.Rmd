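---
title: "Methods: ASIC current mapping, cell classification, plasticity and freezing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ASIC current mapping, cell classification, plasticity and freezing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amygasic)
```

`amygasic` implements the quantitative chain of a slice-electrophysiology
study of acid-sensing ion channels (ASICs) in amygdala circuits: from raw
stimulus-locked sweeps through spike-train features, unsupervised cell
classification, channel-kinetics fitting, long-term potentiation (LTP)
quantification, and conditioned-fear freezing scores. Because raw
recordings of this kind are rarely deposited, the package ships a seeded
synthetic-data module that generates every input class with known planted
parameters; every analysis stage is validated by recovering what was
planted.

## The synthetic-data generators

All generators draw from a single master seed through per-call streams
(a hash of the call label and a counter), so identical `(seed, config)`
pairs give bit-identical output and adding one generator call never
changes another's draws.

**Firing phenotypes.** Seven phenotypes are modeled — accommodating,
stuttering, delay-firing and fast-spiking interneurons of the basolateral
amygdala, late- and early-spiking central-amygdala neurons, and
low-threshold bursting output neurons. Spikes are stereotyped 2 ms
triangular depolarizations to +30 mV placed at generator-planned times and
snapped to the sample grid; only spike times matter downstream, so
waveform realism is deliberately not a goal. Hyperpolarizing steps
(−50/−25 pA) deflect by exactly `Rin × I`, making input resistance
recoverable in closed form. Interspike-interval (ISI) patterns are built
so the accommodation factor — the ratio of the mean of the last five ISIs
to the first five — equals its planted value exactly whenever a sweep has
at least eleven spikes. Stuttering cells alternate five-spike bursts with
long jittered gaps; bursting cells fire a fast onset burst then slow
regular spikes. The paper-grade delays of the late- (1769 ms) and
early-spiking (778 ms) central-amygdala types default to their printed
group means on 2 s steps; the remaining phenotype parameters have no
published dispersion table, so the defaults are representative
slice-physiology values (stated in `phenotype_spec()`) and are
user-overridable.

**Channel signals.** Proton-evoked currents follow
$I(t) = (I_\mathrm{peak} - I_\mathrm{ss})\,e^{-t/\tau} + I_\mathrm{ss}$
during the pulse and are zero outside it. pH-response families follow the
Hill law in proton concentration,
$R = A \big/ \left(1 + (EC_{50}/c)^{n}\right)$ with $c = 10^{-\mathrm{pH}}$;
current–voltage families are quadratics with a planted in-span zero
crossing; tachyphylaxis series decay as
$(1-p)e^{-t/\tau} + p$ with the first amplitude 1 by construction.
Noise is additive Gaussian on samples; synaptic-response amplitude noise
is a multiplicative Gaussian coefficient of variation. Neither choice is
dictated by any published model — they are the simplest assumptions that
exercise the fitting code.

**Behavior.** Freezing bouts are drawn as exponential durations
renormalized so the total bout time per epoch equals the requested
fraction of the epoch, then placed with exponential gaps. Real freezing
behavior is temporally autocorrelated in ways this does not capture;
passing tests show the *scoring* is correct, not that the bout model is
realistic.

## Spike-train features

The six per-cell features follow their defining formulas: accommodating
ratio (maximal over sweeps with injected current < 400 pA and more than
10 spikes in the 1 s step), first-spike delay on the rheobase sweep,
maximal coefficient of variation of successive-ISI ratios (sample,
$n-1$, standard deviation), maximal spike count per 1 s step as a rate,
input resistance (steady-state deflection over the final 200 ms of a
−25/−50 pA step, divided by the current), and rheobase. Detection uses a
0 mV threshold with a 1 ms refractory period; neither is stated in
typical acquisition write-ups, and both are arguments. "Maximal" is read
as the maximum over qualifying sweeps throughout. Step duration is taken
from sweep metadata rather than assumed to be 1 s, because delays beyond
1 s require longer steps. Features that cannot be computed are reported
`NA` with a reason and are never imputed; the classifier excludes such
cells and lists them.

## Classification

The classifier reproduces the standard agglomerative recipe: candidate
features are screened by a Kolmogorov–Smirnov test against the uniform
law over each feature's observed range (features that *reject* uniformity
are kept, default alpha 0.05); retained features are min–max normalized
to [0, 1]; and Ward's method on squared Euclidean distances merges the
pair with the minimal increase in total within-cluster error sum of
squares (ESS) at each step. The uniformity reference range is estimated
from the data, which pins the extremes to 0 and 1 and makes the test
conservative — this circularity is inherent to the recipe and documented
rather than hidden. Merge heights are ESS increases themselves (not
square roots), so the tree is directly comparable to an exhaustive oracle
that evaluates candidate merges from cluster members; equal-cost ties
break toward the oldest cluster indices for platform determinism. The
cluster count `k` is an explicit analyst choice; there is no automatic
cut selection. `stats::hclust(method = "ward.D")` on squared distances
reproduces the same trees (heights ×2) and serves as an independent
cross-check in the test suite, never as the implementation.

A note on attainable accuracy: for two 1-D populations at the
published delay means with SDs reconstructed from printed SEMs
(163 ms and 438 ms), any within-SS boundary — including the globally
ESS-optimal split — misassigns the wide population's upper tail, giving
~94% expected label agreement. The package's recovery matches both
`hclust` and the exact optimum; accuracy beyond that is a property of
the criterion, not of the implementation.

## Channel kinetics

Patch geometry uses the prolate-spheroid closed form over semi-axes
$a = \mathrm{major}/2$, $b = \mathrm{minor}/2$:
$S = 2\pi b^2 + 2\pi a b \cdot \arcsin(e)/e$, $e = \sqrt{1-b^2/a^2}$,
with the sphere limit handled analytically and a Knud Thomsen
general-ellipsoid option; the closed form is cross-checked against
numerical surface-of-revolution integration. Capacitance is
$S \times 0.01\ \mathrm{pF}/\mu m^2$ (1 µF/cm²) exactly, and current
density is the baseline-subtracted in-pulse peak over capacitance
(pA/pF), with the expected current direction a config option.

All four fits use bounded Levenberg–Marquardt least squares
(`minpack.lm`, ftol/ptol 1e-12) with data-driven initialization:
desensitization τ from the 1/e crossing, Hill pH₅₀ from the pH nearest
half-range, tachyphylaxis τ from the first e-fold. The Hill fit estimates
the maximal effect $A$ rather than assuming the most acidic response is
maximal, and is parameterization-invariant between pH₅₀ and molar EC₅₀.
Reversal potentials come from the in-span real root of a least-squares
quadratic (the root nearest the observed sign change if two fall in
span). The Nernst reference defaults to 298 K with the temperature as an
argument; with 135 mM external and 14 mM internal Na⁺ it gives ~58 mV at
room temperature and ~60.5 mV at 310 K. The tachyphylaxis plateau is
left free rather than constrained. Non-decaying inputs are flagged, not
force-fitted. All fits pass noiseless round-trip recovery to 1e-6
relative; desensitization τ holds a median relative error below 5% at 2%
amplitude noise (100 seeds).

## Plasticity

Series failing quality control — series-resistance change strictly
greater than 20% of its initial value, or a baseline trend above 5% of
the baseline mean per minute — are excluded. Amplitudes are normalized to
the mean of the baseline window (default: the 5 min immediately
preceding HFS; the published protocols state baseline collection but not
its length), and the LTP magnitude is 100 × the mean normalized response
with post-HFS time in the 25–30 min window, endpoints inclusive. The
between-genotype reduction is computed on potentiation above baseline,
$\Delta\mathrm{LTP}\% = 100\,(P_{WT}-P_{KO})/P_{WT}$ with
$P = \mathrm{magnitude} - 100$: this is the only reading under which
complete LTP abolition maps to 100%, and it is not written out in the
papers that report it; a raw-magnitude-ratio alternative is available via
`method = "ratio"`. The density–reduction correlation accepts whatever
points the analyst supplies (per cell or per synapse type); per-cell
correlations from the original dataset are not reproducible without the
raw data.

## Freezing

A freezing bout counts only if its full merged duration exceeds 2 s; the
rule is applied before intersecting with epochs, so a long bout
straddling an epoch edge still contributes its in-epoch part (the
straddling case is not addressed by the published scoring rule; this
choice keeps scores additive). Abutting bouts are merged first. The
built-in day-1 protocol scores the 1 min inter-trial observation windows
by default, with an option to include the 20 s tone; the cue-test
protocol includes the tone in each observation window, following the
stated "20 s tone plus 1 min observation" design.

## Statistics

The Wilcoxon rank-sum, Wilcoxon signed-rank and Kruskal–Wallis tests are
implemented with exact enumerated nulls at small sample sizes (all
$\binom{n+m}{n}$ assignments for $n+m \le 16$; all $2^n$ sign vectors,
via subset-sum convolution, for $n \le 20$; all distinct rank
partitions for total $n \le 10$), and tie-corrected normal or
chi-squared approximations with continuity correction otherwise.
Midranks handle ties everywhere; exact enumeration declines to the
approximation when ties are present, and the `exact` flag reports which
null was used. Two-sided exact p values double the smaller tail, capped
at 1. Zero differences in the signed-rank test are dropped (the
classical convention, not Pratt's). Regression significance uses
$F = (n-2)r^2/(1-r^2)$ on $F(1, n-2)$; exactly collinear data report the
smallest positive double as a p-value bound. Type-I error at the 5%
level is verified by simulation to lie in [0.03, 0.07] for both rank
tests (1000 runs).

## Problem sizes and worked example

The test suite and the acceptance script run entirely on generated data:
traces at 5–10 kHz for 1.2–2.2 s, 72-cell cohorts, 100-seed simulations
for stochastic claims, and 1000-run calibration for test size. These
sizes were chosen so every stochastic estimate is stable to well under
its assertion tolerance.

```{r example}
cfg <- sim_config(seed = 1)

# pH-response family and Hill fit
tab <- gen_ph_response(6.3, 1.8, c(7.4, 7.0, 6.8, 6.5, 6.3, 6.0, 5.5, 5.0), cfg)
fit_hill_ph(tab)[c("ph50", "hill_n")]

# current density of a proton-evoked current on a 10 x 10 um patch
geom <- patch_capacitance(10, 10)
sw <- gen_asic_current(-471, 300, -20, cfg)
current_density(sw, geom)$density_pa_pf

# LTP magnitude and reduction
wt <- ltp_magnitude(gen_ltp_series(2.11, cfg, noise_cv = 0.1))$magnitude_pct
ko <- ltp_magnitude(gen_ltp_series(1.28, cfg, noise_cv = 0.1))$magnitude_pct
c(wt = wt, ko = ko, delta = delta_ltp(wt, ko))
```

## Known limitations

* The generators emulate the *structure* of the signals (planted
  features, exponential laws, Hill dose dependence), not biophysical
  membrane dynamics; passing tests demonstrate correctness of the
  analysis chain, not realism of the inputs.
* The uniformity filter cannot be validated against the original
  feature-selection outcome (the supplementary table listing the
  retained variables is not available); it is validated against its own
  contract only.
* The exact ellipsoid formula used in the original patch-geometry
  calculations is not recoverable; the prolate closed form is adopted
  and the Thomsen alternative provided.
* Trace-based feature recovery is limited by the sample grid (planted
  spike times are snapped to it); closed-form constructions recover
  planted values to 1e-6.
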