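# potcell

An R implementation of an **intracellular passage-of-time (POT) model of
the cerebellar Purkinje cell** in delay eyeblink conditioning, for
computational neuroscientists studying interval timing and cerebellar
learning.

In eyeblink conditioning a Purkinje cell learns the interval (ISI) between
a conditional stimulus (CS, parallel-fiber input) and an unconditional
stimulus (US, climbing-fiber input), expressing it as a precisely timed
pause in tonic simple-spike firing. Instead of placing the time base in
the upstream granule-cell network, this model keeps it inside the cell:

- a **write module**, gated by an activation-energy switch driven by CS
  spikes (`dAE/dt = -(AE - AE0)/tau + CS(t)`, threshold 2, refractory
  timer), releases a batch of *recorder units* from a reserve; the units
  drift through time-encoding states (1 ms per ms) while spreading by
  diffusion and drift-rate dispersion;
- the first US spike freezes the batch into a cumulative **archive** — a
  histogram over encoded times that is the cell's memory of the ISI
  (batches are discarded when US onset is < 100 ms, so shorter intervals
  cannot be learned);
- a **read module**, gated by its own switch, samples (and removes) a
  fraction `c` of the archive and converts it into a timed inhibitory
  current: a unit encoding `s` ms inhibits at `s` ms after read
  activation, so `A(t)` mirrors the archive shape;
- the membrane is a leaky integrate-and-fire neuron,
  `tau_m dV/dt = -(V - V_rest) + R_e CS(t) - R_i A(t) + R_p P(t)`,
  with a Poisson pacemaker `P` that produces ~100 Hz tonic firing.

A conditioned response (CR) is scored when the firing rate during the ISI
drops below 25% of the pre-training rate. The model reproduces
acquisition of a well-timed pause near trial 110, invariance of the pause
to probe-CS duration, gradual extinction by archive depletion
(`(1-c)^reads`), single-interval learning under compound stimuli, and a
trials-to-acquisition law `T ≈ 8000 · ISI/ITI`.

## A worked example

```r
library(potcell)

cfg  <- session_config(delay_protocol(200), n_trials = 400,
                       probe_every = 20, probe_start = 300, seed = 1)
sess <- run_session(cfg)

glance(sess)
#> # A tibble: 1 × 7
#>   n_trials n_probes baseline_hz acquisition_trial archive_total reserve_level mass_ledger_error
#>      <int>    <int>       <dbl>             <int>         <dbl>         <dbl>             <dbl>
#> 1      400        5        115.               104        0.0323         0.497          1.69e-14

acquisition_trial(sess)
#> [1] 104
```

The cell fires at ~115 Hz during the ISI before training and first meets
the 25% CR criterion on trial 104 (seed 1; the mean over seeds 1-5 is
~102). `tidy(sess)` returns the per-trial table (spike times, switch
latencies, batch/archive bookkeeping); `compute_psth()`,
`pause_features()`, `detect_bimodal_pause()` and `fit_acquisition_law()`
form the measurement layer, and `autoplot()`/`plot_raster()`/
`plot_archive()` the figures. The six shipped experiments are available
through `build_experiment("sim1")` … `"sim6"` (acquisition + ISI battery,
probe invariance, extinction, interleaved two-ISI training, two-CS /
two-US predictions, and the ISI/ITI sweeps), with a thin command-line
wrapper in `inst/scripts/potcell-run.R`.

See the vignette (`vignettes/pot-model.Rmd`) for the model's assumptions,
the noise law, numerical choices, and known limitations.

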