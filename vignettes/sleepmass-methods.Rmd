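---
title: "Inferring hidden cortical excitability from slow-wave sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring hidden cortical excitability from slow-wave sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepmass)
```

## The scientific problem

Deep (slow-wave) sleep EEG in children with epilepsy differs measurably
from that of healthy controls, but the EEG itself is a coarse, indirect
observable: the synaptic quantities that might explain the difference —
population firing rates, excitatory and inhibitory synaptic currents — are
hidden. `sleepmass` addresses this by fitting a mechanistic generative
model of the sleeping cortex to each subject's EEG and reading the hidden
quantities off the fitted model. Three downstream analyses follow: group
contrasts of the emergent properties, in-silico conductance interventions
that emulate drug mechanisms, and a per-subject distance from the resting
fit to a fitted seizure rhythm (spike–wave discharge, SWD).

Because the clinical recordings that motivate this design are not publicly
distributable, the package is organised around a first-class synthetic
cohort generator: the model itself, under group-specific parameter
templates with known ground truth, produces the data every test and
analysis runs on. Everything the package claims is therefore checkable
end-to-end.

## The model

Two interacting neural populations, excitatory ($e$) and inhibitory ($i$),
are described by mean membrane potentials $V_e, V_i$. Firing rates follow
the population sigmoid

$$Q_k(V_k) = \frac{Q_{max,k}}{1 + \exp(-C\,(V_k - \theta_k)/\sigma_k)},
\qquad C = \pi/\sqrt{3},$$

so that $\sigma_k$ is the standard deviation of the underlying threshold
distribution and $Q_k(\theta_k) = Q_{max,k}/2$. Each membrane integrates
four currents (signed so that depolarizing is positive):

$$\tau_e \dot V_e = -g_{L,e}(V_e - E_{L,e})
  + \frac{1}{C_e}\left[I_{exc} + I_{inh} + I_{KNa}\right], \qquad
I_{chan} = -g\, s\, (V - E_{rev}),$$

and similarly for $V_i$ without the KNa term. The synaptic activations
$s_{ee}, s_{ei}, s_{ie}, s_{ii}$ are second-order filters

$$\ddot s = \gamma^2 (N\,Q + \phi - s) - 2\gamma\,\dot s,$$

with mean synapse counts $N$ and a stochastic afferent drive $\phi$
(mean `phi_mean`, white-noise SD `phi_sd`) entering the two excitatory
connections. Slow adaptation comes from activity-dependent sodium,

$$\dot{Na} = \big(\alpha_{Na} Q_e - R_{pump}\,\pi(Na)\big)/\tau_{Na},
\qquad \pi(Na) = \frac{Na^3}{Na^3 + 3375} - \frac{Na_{eq}^3}{Na_{eq}^3 + 3375},$$

which gates the sodium-dependent potassium current through
$w(Na) = 0.37/(1 + (38.7/Na)^{3.5})$, $I_{KNa} = -g_{KNa}\, w(Na)\,(V_e - E_K)$.
This KNa feedback loop is what supports slow (delta-band) oscillations:
depolarized, high-firing periods accumulate sodium, the growing potassium
current terminates them, and the pump resets the cycle.

The simulated EEG proxy is $V_e$; the unidentifiable gain and offset
between a membrane potential and a scalp voltage are removed by z-scoring
before any feature is computed.

### The 32-parameter search space

The tunable space has 32 scalars: 6 firing parameters
($Q_{max,e/i}, \theta_{e/i}, \sigma_{e/i}$), 2 synaptic rate constants
($\gamma_{e/i}$), 4 connectivities ($N_{ee}, N_{ei}, N_{ie}, N_{ii}$), 4
membrane constants ($\tau_{e/i}, C_{e/i}$), 5 conductances
($g_{AMPA}, g_{GABA}, g_{L,e}, g_{L,i}, g_{KNa}$), 5 reversal potentials
($E_{AMPA}, E_{GABA}, E_{L,e}, E_{L,i}, E_K$), 4 sodium parameters
($\alpha_{Na}, \tau_{Na}, R_{pump}, Na_{eq}$) and 2 drive parameters
($\phi_{mean}, \phi_{sd}$). `nmm_bounds()` lists the bounds, units and a
description of each. Two deliberate choices:

* The bounds are the package's own, in self-consistent SI-second units.
  They should be treated as provisional reference ranges, chosen wide
  enough to contain qualitatively distinct regimes (quiescence, noise-driven
  delta resonance, spike-wave limit cycles) while keeping the model stable
  over most of the volume.
* The reversal-potential bounds are non-overlapping
  ($E_{GABA} < E_{L,e} < E_{AMPA}$ for every in-bounds vector), so the
  optimizer never needs a repair step for the physiological ordering.

### Numerical integration

`simulate_nmm()` integrates with fixed-step Euler–Maruyama (`dt_internal =
1e-4` s by default; the stochastic drive rules out adaptive solvers),
discards a 5-s burn-in, and downsamples all states to 128 Hz. The noise
stream is generated by a seeded Mersenne Twister with a Box–Muller
transform implemented in the package's C++ code, so a given seed yields
bit-identical trajectories across platforms. Halving the default step
changes a noise-free trajectory by well under 1% relative L2 (this is a
test). A state excursion beyond ±200 mV or any non-finite value flags the
result as blown up instead of raising, so the optimizer can assign penalty
objectives and keep a total order.

Time-averaged firing rates and the seven synaptic currents are accumulated
inside the integrator at every internal step (not from the 128-Hz
downsampled traces), so `emergent_properties()` is exact for the
simulation it describes.

## Features and objectives

Model and data are compared in a two-feature space:

1. **Normalized Welch spectrum.** Per 30-s epoch, Hann windows of 10 s
   with 50% overlap, zero-padded to 5120 samples so the grid spacing is
   exactly 0.025 Hz; epochs averaged, restricted to 0.6–10 Hz (377 grid
   points) and divided by the trapezoidal area, making the feature
   amplitude-free. A 2.5-s SWD segment is estimated from its single window
   on the same padded grid.
2. **Weighted horizontal visibility graph (HVG) degree.** Samples are
   nodes; two samples are linked when every sample strictly between them is
   lower than both (ties block visibility — the strict convention). Edges
   are weighted by $|\mathrm{atan}(\text{slope})|$ on the unit-variance
   series, and the feature is the mean weighted node degree. The
   construction is the O(n) stack algorithm, tested exactly against an
   O(n²) brute-force oracle. The HVG summary distinguishes waveform
   *shape* (e.g. nonsinusoidal spike-wave cycles) that the normalized
   spectrum alone can miss. The mean-degree summary is the default; the
   pooled degree distribution is also retained (`hvg_stat = "hist"`) for
   distribution-level comparisons.

The objective pair is `f_spec` = Euclidean distance between normalized
spectra and `f_hvg` = absolute difference of mean weighted degrees, both
computed after z-scoring the simulated EEG. Both objectives are invariant
to affine rescaling of the simulation (a test asserts this to 1e-8).

## Fitting: NSGA-II over the bounded space

`fit_subject()` runs NSGA-II (binary tournament on rank and crowding
distance, simulated-binary crossover with $\eta_c = 15$, polynomial
mutation with $\eta_m = 20$ and per-gene probability 1/32, elitist
environmental selection) and returns, per repeat, the final non-dominated
set with a representative solution: the Pareto member minimizing
`f_spec/median(f_spec) + f_hvg/median(f_hvg)` over the front. The
representative rule is injectable; the default was chosen because it is
scale-free in both objectives.

Within a repeat, every candidate simulation uses one fixed noise seed
(common random numbers). This makes objectives a deterministic function of
parameters, so elite survivors keep consistent objective values and the
per-generation minimum of each objective is exactly non-increasing — an
invariant the tests assert. Reseeding each generation is available
(`reseed_each_generation = TRUE`) but then elite traces are only
stochastically monotone.

Repeats (100 at full scale; desk-scale defaults are much smaller) are
independently seeded searches. Their purpose is statistical, not
numerical: the inverse problem is underdetermined, and many parameter
vectors reproduce a subject's features. The collection of per-repeat
solutions *is* the subject's parameter distribution; single repeats should
never be interpreted alone.

### Emergent-property estimators

`subject_summaries()` offers two documented modes:

* `solutions = "best"` — re-simulate each repeat's representative solution
  and average across repeats (each subject's value is a mean over repeats,
  as in the violin-plot convention of per-subject means).
* `solutions = "front"` — average over all Pareto members whose `f_spec`
  lies within 1.25× of the front minimum, then across repeats. This is a
  variance-reduced estimator of the same quantity: the spectrum-proximal
  end of the front is a cloud of near-equivalent fits whose emergent
  properties scatter around the same value, and averaging them reduces the
  considerable per-repeat unidentifiability noise when only a few repeats
  are affordable.

With very few repeats the emergent currents of any single fit carry
sampling noise comparable to realistic group differences; this is the
dominant practical limitation at desk scale, and it is why the package's
own checks run the group-contrast analyses on replicate cohorts and assert
directions, not effect sizes.

## Synthetic cohorts

`generate_cohort()` builds a cohort with known ground truth. Group
templates (`param_template()`):

* **control** — a noise-driven delta-resonant regime: normalized spectral
  peak near 1.1 Hz, with most of the 0.6–10 Hz power below 4 Hz. This was
  chosen (by scripted exploration of the bounded space) as a robust
  slow-wave-sleep-like operating point.
* **patient** — control shifted in six parameters: $\theta_e$ −0.3 mV,
  $N_{ee}$ +2, $N_{ei}$ +1, $\gamma_e$ −12 s⁻¹, $\gamma_i$ −8 s⁻¹,
  $E_{AMPA}$ +0.2 mV. The lowered firing threshold is the hallmark
  hyperexcitability shift (more firing at the same potential); the other
  five are secondary shifts in the same excitability direction.
* **patient_seizure** — the same shifts doubled, emulating patients with
  seizures during the recording admission.
* **swd** — a strongly hyperexcitable corner of the space (lower
  $\theta_e$, higher $N_{ee}$ and $g_{AMPA}$, slower inhibition, fast
  strong sodium adaptation) where the deterministic model runs a 2.7 Hz
  spike-wave limit cycle with pronounced harmonics. The scripted search
  that located it ships as `scripts/find_swd_regime.R`.

Shift magnitudes were fixed once, before any fitting test existed, such
that the ground-truth firing rates, excitatory currents and
|ΔI<sub>exc</sub>| distances to the SWD regime are monotone across
control → patient → patient_seizure. One known departure from the
motivating clinical observations: in this model regime, depolarizing
shifts *speed up* the delta resonance, so the patient templates do not
also reproduce a redistribution of normalized power from high- to
low-delta; the package encodes the firing-rate/current/proximity orderings
and clear group spectral separation instead.

Each subject draws truncated-Gaussian parameter jitter (SD = 2% of each
bound range) around its template, simulates 4 × 30-s epochs at 128 Hz,
adds white measurement noise at 20% of the signal SD (the package's
observation model; the real-data analogue would be sensor and reference
noise), and is emitted as identical F3/F4 channels so the frontal
averaging path is exercised. Synthetic data deliberately omit: scalp
topography, artifacts, sleep-stage transitions, 1/f background from
non-modelled sources, and inter-channel differences. Passing tests on this
cohort therefore demonstrate the *pipeline's* correctness and the
*model's* internal consistency, not clinical validity on real recordings.

## Preprocessing

EDF (16-bit) reading and writing are implemented in the package
(`read_edf()`/`write_edf()`); mV channels are converted to µV. Filtering
is zero-phase (forward–backward) Butterworth — band-pass 0.3–10 Hz order 4
for resting segments, high-pass (default 1 Hz, order 4; the cutoff is a
package choice) for the SWD segment — applied with odd-extension padding
so edge transients decay inside the pad. The 0.3 Hz edge at 128 Hz places
poles very close to the unit circle; direct-form recursion noise then
bounds reproducibility near 1e-6 relative, which is the tolerance the
linearity test uses. Channel averaging (F3/F4) happens before filtering;
epochs are non-overlapping 30 s with partial tails dropped (window overlap
belongs to the Welch estimator, not epoching). Recordings at other rates
are brought to 128 Hz by FIR decimation (integer ratios) or polyphase
resampling.

## Group statistics

Two-sided Mann–Whitney U tests compare subject-level means between groups
(exact enumeration below combined n = 20 without ties, normal
approximation with corrections otherwise), with Bonferroni flags at family
size = number of properties tested. Parameter distributions are compared
by Jensen–Shannon divergence in bits on 20-bin histograms over each
parameter's bounds (additive smoothing 1e-12); `rank_parameters_by_divergence()`
orders all searched parameters by it, and a test asserts the rank-1
identity is stable across 10/20/40 bins. Subject-level means (one point
per subject) are the default comparison unit; pooled per-repeat
distributions are available through `pooled_distribution()`.

## Interventions and seizure proximity

`perturb_conductance()` moves one conductance by a stated fraction of its
*bound range* — decreases for excitatory and leak channels, increases for
inhibitory and KNa, the directions that emulate antiseizure drug
mechanisms — and clips to bounds. `intervention_experiment()` re-simulates
each fitted subject under each channel × fraction condition with 5 fresh
noise seeds, averages the normalized spectra, and measures the Euclidean
spectral change against the subject's unperturbed spectrum (L1 optional).
Perturbation is applied per-subject (not to a group-mean parameter set).

`fit_swd()` reuses the full fitting machinery on the 2.5-s SWD target.
`proximity_scores()` then measures each subject's
$|\bar I_{exc \to e}(\text{subject}) - \bar I_{exc \to e}(\text{SWD})|$,
the SWD value being the mean over SWD fit repeats. The current onto the
excitatory population is the default (an option sums both excitatory
currents). A caveat the package's own experiments expose: while SWD fits
recover the waveform and spectral peak well, the *absolute* excitatory
current of an SWD fit is weakly identified, so distances measured against
a fitted (rather than ground-truth) SWD reference carry that reference's
sampling error; at small repeat counts this is the limiting noise source
of the proximity analysis.

## Problem sizes used by the packaged checks

The package's acceptance-style tests run scaled-down versions of the full
study, with sizes chosen as the package's desk-scale defaults:

* Parameter recovery: 10 synthetic subjects, population 32 × 30
  generations × 3 repeats, `dt_internal = 2e-4` s; checks that the best
  spectral objective reaches the target's self-distance noise floor
  (median spectral distance of fresh-seed simulations of the true
  parameters) and that the fitted $\theta_e$ interquartile range covers
  truth for most subjects.
* Group contrasts and proximity: 10 replicate cohorts of 2 subjects per
  group, 3 repeats each, population 16 × 12 generations,
  `dt_internal = 5e-4` s, front-mode emergent properties.
* SWD reference: one fit at population 32 × 30 generations × 8 repeats.
* The acceptance script (`scripts/acceptance.R`) uses 3 subjects per
  group, population 24 × 20 generations × 3 repeats.

## Known limitations

* Single cortical region; no thalamocortical loop, so spindle/K-complex
  phenomenology and thalamic SWD mechanisms are out of scope by design.
* Euler–Maruyama at a fixed step: adequate (convergence-tested) but first
  order; stiff corners of the bounded space are handled by the blow-up
  guard rather than step adaptation.
* Emergent-property identifiability at small repeat counts, and the
  weakly-identified absolute current of the SWD reference, as discussed
  above — both shrink with repeats, which is exactly the full-scale
  design's remedy.
* The synthetic observation model is white noise on a single derived
  channel; none of the structured artifacts of real polysomnography are
  emulated.
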