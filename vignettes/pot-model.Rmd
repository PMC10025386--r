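---
title: "An intracellular passage-of-time model of Purkinje cell conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An intracellular passage-of-time model of Purkinje cell conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(potcell)
library(ggplot2)
```

## The phenomenon and the model

In delay eyeblink conditioning, a cerebellar Purkinje cell that repeatedly
receives a conditional stimulus (CS, e.g. a tone carried by parallel
fibers) followed at a fixed interstimulus interval (ISI) by an
unconditional stimulus (US, carried by the climbing fiber) learns to pause
its high-rate tonic simple-spike firing just around the expected US time.
The pause disinhibits downstream motor nuclei and drives a well-timed
blink. Two experimental facts motivate a mechanism *internal* to the cell:
well-timed pauses are acquired even when the upstream granule-cell network
is bypassed by direct fiber stimulation, and the learned pause is largely
invariant to the duration and rate of the probe CS — a brief CS onset
suffices to trigger the full response.

`potcell` implements such a mechanism as three interacting processes
around a leaky integrate-and-fire (LIF) membrane:

* **Gating.** Each of a *write* and a *read* module carries an
  activation-energy (AE) switch. Every CS spike increments the energy by
  one; between spikes it decays exponentially (time constants
  `tau_write` = 70 ms, `tau_read` = 200 ms). Crossing the threshold
  (`ae_thresh` = 2) turns the module ON, resets the energy, and starts a
  refractory timer (1 s). With a 100 Hz CS both switches fire on the third
  spike, 20 ms after CS onset — the energy after the second spike,
  `exp(-10/70) + 1 = 1.867`, is still below threshold. Because activation
  needs summation, sufficiently slow probes (25 Hz) activate late or not
  at all, which reproduces the weak low-frequency probe responses.

* **Writing.** A reserve holds up to `r_max` = 1 unit of "recorder"
  material whose state encodes 0 ms. When the write switch turns ON it
  opens a releasable subpool — fraction `eject_frac` = 3e-3 of the
  current reserve, the analogue of a readily-releasable vesicle pool —
  which drains exponentially with time constant `tau_reserve` = 250 ms
  for at most `t_eject` = 300 ms. The released cohorts drift through
  time-encoding states at 1 ms per ms, spreading by noise (below). The
  first US spike freezes the batch and adds it to a cumulative
  **archive** — unless US onset falls within 100 ms of CS onset, in
  which case the batch is discarded; this hard rule is why no interval
  below 100 ms is ever learned. Without a US (probe or extinction
  trials) the batch is abandoned at trial end. Because early cohorts
  carry the most mass and evolve longest, the stored batch is a band of
  encoded times just below the interval, tilted toward it.

* **Reading.** When the read switch turns ON (again ~20 ms after CS
  onset), a constant fraction `c_read` = 3% of the archive is sampled *and
  removed*. Each sampled unit injects a fixed inhibitory current `g_i` at
  the moment its encoded time elapses, so the archive histogram is
  translated, shifted by the read latency, into the inhibition time course
  `A(t)`. Removal is the extinction mechanism: CS-only trials deplete the
  archive geometrically, by exactly `(1 - c_read)` per read.

The membrane integrates `tau_m dV/dt = -(V - V_rest) + R_e CS(t) -
R_i A(t) + R_p P(t)` with explicit Euler at `dt` = 1 ms, threshold
-54 mV and reset to -85 mV; `P` is a Poisson pacemaker (`lambda` =
0.3/ms) producing tonic firing near 100 Hz, the only stochastic element
of a trial. A conditioned response (CR) is scored on a trial when the mean
rate over the CS-US interval drops strictly below 25% of the pre-training
value (mean of the first five trials).

## Numerical integration of the memory

The session engine does not move every histogram bin at every membrane
step. Because ejection times, switch latencies and the US time are
deterministic for a given protocol, the stored batch is integrated in
closed form: a cohort ejected at time $t$ and frozen at the US time
$t_{US}$ is a Gaussian centred at $t_{US} - t$ whose width follows the
noise law below, and the batch is the cohort superposition weighted by
exponential reserve depletion. The per-step operation `evolve_batch()`
(drift one bin, then blur by the variance increment) is retained as the
elementary definition; the test suite verifies that stepping and an
independent 100,000-particle simulation agree to within 2% total
variation (and the closed form, which treats the boundary terminally
rather than path-wise, to within a few percent). Histogram boundaries are *reflecting* (method of
images), which conserves mass exactly and — unlike truncation with
renormalization — introduces no drift bias for mass near the encoded-time
origin.

## Noise model and its parameters

Three dispersion processes shape the archive; all are Gaussian in the
encoded-time coordinate:

* **Brownian evolution noise** while a batch evolves: variance
  `sigma^2 * t / t_blur` after `t` ms, with `sigma` = 40 ms per
  `t_blur` = 100 ms reference. This is classical diffusion of the
  time-encoding state.
* **Drift-rate dispersion** `nu` = 0.15: individual recorder units
  advance at slightly different speeds, contributing a spread
  proportional to elapsed time (`nu * t`). This makes long-interval
  batches markedly flatter than short-interval ones — diffusion alone
  (square-root growth) leaves a 700 ms batch far too sharp for its
  interval, and the cell could then never silence the whole CS-US window
  at long ISIs.
* **Storage diffusion** of the archive between trials: stored units keep
  drifting apart slowly, implemented as a per-interval blur of standard
  deviation `sigma_store * sqrt(ITI / t_store_ref)` (40 ms per 15 s).
  Because it acts per unit of real time, conditions with longer
  intertrial intervals diffuse proportionally faster, which is what makes
  the fixed-ratio (ITI/ISI) acquisition curve flat rather than rising.

## The reserve sets the learning rate

The reserve refills at `q` = 1.25e-7 units/ms and drains only by
`eject_frac` = 3e-3 per write episode. Two properties follow. First,
the per-trial drain is small, so a naive cell (the sessions start from
an empty reserve) accumulates reserve approximately linearly across a
400-trial session; the archive and hence the inhibition grow steadily
rather than saturating within a few tens of trials, placing first-CR
acquisition of the reference protocol (200 ms ISI, 15 s ITI) near trial
110 and making extinction a gradual process rather than a cliff.
Second, once drain balances refill the per-trial batch equals
`q * ITI` — the replenishment-limited regime — so longer intertrial
intervals write more per trial, while the mass a trial can place into
the CS-US window is diluted over a span that grows with the ISI.

Together these scalings produce the package's central quantitative
result: trials to acquisition grow approximately linearly with the ISI
at fixed ITI, and collapse onto a flat line when ITI/ISI is held
constant, consistent with `T ~ 8000 * ISI/ITI` at the reference point.
The shipped fast sweep uses ISI {200, 400, 600, 800} ms at 15 s ITI with
three seeds per point (the same averaging spirit as the ten-replicate
error bars of `run_replicates()`); the fixed-ratio fast grid uses ISI
{300, 500, 800} — at ISI 200 a ratio of 80 gives a 16 s ITI,
indistinguishable from the fixed-ITI arm, so that point adds no
information about ratio compensation.

## Calibrated and operational choices

Most constants are fixed by the model definition (see `?pot_params`).
Choices the definition leaves open, and how this implementation resolves
them:

* `g_i` = 7.5, the inhibitory current per sampled recorder unit, is the
  gain between memory and membrane and is calibrated jointly against the
  reference acquisition (~trial 110) and the acquisition-law slope
  (logged per seed by the acceptance test). All membrane constants are
  left untouched.
* The ejection episode is a bounded, decaying pulse rather than a drain
  lasting until the US: short-interval batches then consist mostly of
  units encoding times just below the interval. Its shape constant
  `tau_reserve` = 250 ms and the pool fraction `eject_frac` = 3e-3 are
  calibrated jointly with `g_i` against the reference acquisition and
  the acquisition-law slope; `lambda` = 0.3 events/ms (the reading that
  yields the ~100 Hz tonic rate).
* The discard clock is US onset relative to CS onset; anchoring it at
  write activation instead would push the minimum learnable interval to
  120 ms, contradicting the observed 100 ms boundary.
* Pause features are read from a 20 ms PSTH: a pause is a run of at
  least two consecutive bins below 50% of the pre-CS baseline; its
  *maximum* is the centre of the minimal-rate plateau (deep pauses bottom
  out at zero over many bins, so "the minimum bin" is ill-defined), its
  onset/offset are the edges of the run. Single-bin dips are not pauses.
* The CR criterion is evaluated per trial with no smoothing, baselined on
  the first five trials. For two-interval (interleaved) sessions the
  criterion is applied per mode in non-overlapping windows ([0, 200] and
  [400, 500] ms), since the full window of the long mode contains the
  short mode's pause.

## What the simulations do and do not show

The synthetic protocols reproduce the conditioning phenomenology:
acquisition near trial 120, probe-structure invariance (the switch, not
the CS envelope, shapes the response), geometric extinction, single-pause
learning under compound stimuli (two CSs teach the long interval because
the write refractory hides the second CS; two USs teach the short one
because the first US freezes the batch), and the ISI/ITI acquisition law.

Some departures are documented rather than hidden. The noise scaling
needed for the acquisition law (spread growing fast enough with interval
to cover the whole CS-US window at 800-1000 ms) is the same scaling that
blurs sharply localized features: the two archive modes of interleaved
200/500 ms training diffuse into each other within tens of trials, so
the assayed response is usually one broad pause rather than two
separated ones (and the shared archive lets the second mode reach
criterion faster than twice the single-interval time); the pause maxima
of the compound-stimulus protocols sit tens of milliseconds earlier than
the interval they encode, because broad bands centre the suppression
plateau mid-interval; and the pause *offset* — the point of marginal
inhibition — is sensitive to whether the probe CS is still driving the
cell during recovery, so long probes recover earlier than short ones at
100 Hz. Mode sharpness and window coverage pull the noise model in
opposite directions, and this implementation resolves the tension in
favour of the acquisition law. The regression tests for these features
encode the expected outcomes and are allowed to fail, as explicit
markers of the discrepancy.

None of this, of course, says anything about real biochemistry: recorder
units are an abstraction, the stimulus trains are noiseless and
perfectly regular, there is no upstream network, no complex-spike
dynamics, and a single cell stands in for a population.

## A worked example

```{r sim1, eval = FALSE}
cfg <- session_config(delay_protocol(200), n_trials = 400,
                      probe_every = 20, probe_start = 300, seed = 1)
sess <- run_session(cfg)
glance(sess)
acquisition_trial(sess)

psth <- compute_psth(sess, trials = 301:400)
autoplot(psth, baseline_hz = psth_baseline(psth))
plot_raster(sess, every = 2)
plot_archive(sess)
```

Problem sizes throughout the package (400-800 trials per session, 1 ms
steps, three seeds per sweep point) are chosen so every shipped
experiment runs end to end on a laptop core in seconds to a few minutes.
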