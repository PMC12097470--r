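# sleepmass

Neural mass modelling of slow-wave sleep EEG: infer hidden cortical
excitability from delta-band sleep recordings, and relate it to seizure
susceptibility.

## What problem this solves, and for whom

Slow-wave sleep EEG differs between children with focal epilepsy and
healthy controls, but the EEG is an indirect observable: the population
firing rates and synaptic currents that could explain the difference are
hidden. `sleepmass` is for computational neuroscientists and EEG
methodologists who want to fit a mechanistic cortical model to sleep EEG
segments and analyze what the fitted models imply — group differences in
emergent excitability, the spectral effect of in-silico conductance
interventions (drug-mechanism analogues), and each subject's distance to a
fitted seizure rhythm.

## The model and the inference

A conductance-based two-population (excitatory/inhibitory) neural mass
model of the sleeping cortex. Firing rates follow
`Q = Qmax / (1 + exp(-C (V - theta) / sigma))` with `C = pi/sqrt(3)`;
membranes integrate excitatory, inhibitory, leak and sodium-dependent
potassium (KNa) currents `I = -g s (V - E_rev)`; synaptic activations are
second-order filters `s'' = gamma^2 (N Q + phi - s) - 2 gamma s'` with a
stochastic afferent drive on the excitatory connections; slow adaptation
comes from sodium dynamics `dNa/dt = (alpha_Na Q_e - pump(Na))/tau_Na`
gating KNa through `w(Na) = 0.37/(1 + (38.7/Na)^3.5)`. Integration is
seeded Euler–Maruyama in C++ (bit-reproducible), 5-s burn-in, output at
128 Hz.

The 32-dimensional bounded parameter space (`nmm_bounds()`) is searched by
NSGA-II against two objectives: the Euclidean distance between normalized
Welch power spectra on a fixed 0.6–10 Hz grid (0.025 Hz spacing), and the
absolute difference in mean weighted horizontal-visibility-graph degree.
Repeated independent searches form per-subject parameter distributions;
time-averaged firing rates and synaptic currents of the fitted simulations
are the quantities compared across groups (Mann–Whitney U, Bonferroni;
Jensen–Shannon divergence ranking of parameter distributions).

Because the motivating clinical recordings are not distributable, the
package includes a first-class synthetic cohort generator
(`generate_cohort()`): model-generated subjects with known ground-truth
parameters, group templates encoding patient hyperexcitability, and a
model-generated 2.7 Hz spike-wave limit cycle standing in for a recorded
seizure segment. The methods vignette
(`vignettes/sleepmass-methods.Rmd`) documents the model, estimators,
parameter choices and limitations.

## Worked example

```r
library(sleepmass)

# one synthetic "patient" subject with known ground truth
subj <- generate_subject(param_template("patient"), seed = 42,
                         n_epochs = 2, subject_id = "demo01",
                         group_label = "patient_no_seizure")
seg    <- bandpass(average_channels(subj$segment, c("F3", "F4")))
target <- feature_set(make_epochs(seg))
target
#> <feature_set> 2 epoch(s) at 128 Hz, mean weighted degree 3.671
target$spectrum
#> <spectral_feature> 377 points, 0.6-10 Hz, peak at 1.05 Hz

# fit the model to the subject's features (small demo budget)
cfg  <- fit_config(pop_size = 16, generations = 12, n_repeats = 2,
                   base_seed = 7, dt_internal = 5e-4)
fits <- fit_subject(target, cfg)
fits[[1]]
#> <fit_result> repeat 1: 15 Pareto solutions, best (f_spec=3.531, f_hvg=0.002713)

# hidden emergent properties of the fit vs. the ground truth
summ <- subject_summaries(list(demo01 = fits),
                          c(demo01 = "patient_no_seizure"),
                          dt_internal = 5e-4, solutions = "front")
round(summ$mean_Q_e, 2)   # fitted mean excitatory firing rate (1/s)
#> [1] 9.47
round(summ$I_exc_e, 2)    # fitted mean excitatory synaptic current
#> [1] 13.12
truth <- emergent_properties(simulate_nmm(subj$truth, 30, seed = 1))
round(truth[["mean_Q_e"]], 2); round(truth[["I_exc_e"]], 2)
#> [1] 19.01
#> [1] 27.81

# the packaged spike-wave-discharge target
generate_swd_fixture(seed = 1)$target
#> <swd_target> 2.5 s at 128 Hz, spectral peak 2.73 Hz
```

The delta-dominant spectral peak and the waveform-shape feature are
matched well, while the fitted firing rate and excitatory current sit far
from the generating values: at 2 optimization repeats a subject's
emergent properties carry substantial unidentifiability noise — many
parameter sets reproduce the same z-scored features. This is why the
full-scale design averages 100 repeats per subject, and why the package's
group analyses report distributions and directions rather than
single-fit values (see the methods vignette).

The staged end-to-end pipeline (synthetic cohort → EDF ingestion →
features → fits → group statistics → interventions → seizure proximity)
runs from one configuration:

```r
run_pipeline(pipeline_config(
  cohort = cohort_spec(n_control = 3, n_patient_no_seizure = 3,
                       n_patient_seizure = 3),
  fit = fit_config(pop_size = 16, generations = 12, n_repeats = 3,
                   dt_internal = 5e-4)), out_dir = "results/demo")
```

writing `cohort.csv`, per-subject EDFs and fit JSONs, `summaries.csv`,
`comparisons.csv`, `divergence.csv`, `sensitivities.csv` and
`proximity.csv` under the output directory.

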