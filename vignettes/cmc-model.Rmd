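---
title: "Stochastic Boolean micro-complex model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic Boolean micro-complex model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcsim)
```

## The model

`cmcsim` simulates the repeating functional unit of the cerebellar cortex —
the micro-complex: a mossy-fibre afferent feeding granule cells and the
deep cerebellar nucleus (DCN), parallel fibres exciting Golgi cells,
inhibitory interneurons and Purkinje cells, a climbing-fibre afferent
exciting Purkinje cells and the DCN, and Purkinje inhibition converging on
the DCN, which is the circuit's only output.

Every neuron is a Boolean unit updated once per time sample.  A synapse
contributes, per activation, a uniformly random drive scaled by its
synaptic strength:

$$\text{drive} = \sum_i \mathrm{SyS}_i\, X_i \,[\text{pre}_i = 1]
             \;-\; \sum_j \mathrm{SyS}_j\, Y_j\, [\text{pre}_j = 1],
\qquad X_i, Y_j \sim U(0,1) \text{ i.i.d.},$$

and the neuron fires iff the drive strictly exceeds its depolarisation
threshold DT.  SyS (default 1.5) is the locus of plasticity and
transmitter-level perturbations; DT (default 0.15, a normalised
resting-to-peak fraction) is the locus of excitability and neuromodulator
effects.  With one active excitatory term at the defaults a neuron fires
with probability $1 - \mathrm{DT}/\mathrm{SyS} = 0.9$.

Rates are carried as **per-sample firing probabilities**:
$p = f / f_s$ for spike frequency $f$ and sampling frequency $f_s$.  The
memoryless engine assumes each sample independent, which caps $f_s$ at
250 Hz (a 4 ms step) so that every neuron is back at rest by the next
sample.  Afferent Boolean states are drawn as $X \ge 1 - p$; both
endpoints are exact ($p=0$ never fires, $p=1$ always fires).

Golgi feedback inhibits the granule layer with a one-sample delay; all
other interactions are resolved within the sample in a fixed order
(granule, Golgi, interneuron, Purkinje, DCN).  Circuits are independent —
the population interacts only through the summed motor vote.

## Random numbers and reproducibility

One seeded generator (R's global RNG) drives a whole run.  Stochastic
operations consume draws in a documented, fixed order — per sample:
mossy afferents, climbing afferents, then each circuit equation
term-by-term in its printed order, then the comparator equations — and an
inactive presynaptic input contributes exactly zero *without consuming a
draw*.  A run is therefore reproducible bit-for-bit from `(seed, config)`.
R's `runif()` draws on the open unit interval; every probability statement
here is unchanged under open/half-open conventions because the endpoints
have probability zero or one exactly.

## Analytic oracle

Each Boolean update asks: what is $P(\sum a_i X_i - \sum b_j Y_j >
\mathrm{DT})$?  `firing_probability()` answers exactly: closed forms for
up to two terms, and for the general case the inclusion–exclusion CDF of a
sum of independent scaled uniforms (each inhibitory term $-bY$ is
rewritten as $bY' - b$).  The exact form was preferred over numeric
convolution because the circuit never exceeds a handful of terms and
exactness makes the Monte-Carlo cross-checks one-sided.  Ties at the
threshold have probability zero, so the strict inequality is a
convention, not a behaviour.

`dcn_marginal()` gives the stationary one-sample DCN firing probability
for homogeneous parameters by total probability over all Boolean states of
the intermediate neurons, respecting the within-sample dependencies
(interneurons require a granule spike; the Purkinje state is mixed over
granule and interneuron; the DCN conditional is mixed over Purkinje).
The delayed Golgi feedback makes the chain non-i.i.d.; its stationary
firing probability is obtained by fixed-point iteration from zero with a
$10^{-10}$ stopping tolerance (a contraction here: the loop gain is well
below 1 at all admissible parameters).  Simulator comparisons discard a
10-sample burn-in to let that loop settle.

## Closed motor loop

The joint is ideal: position in $[0,1]$ (0 extension, 1 flexion), and the
actual / desired positions are encoded linearly into mossy / climbing
firing probabilities (the full $[0,1]$ range by default; the encoder range
is configurable since proprioceptor rate ranges are not constrained by the
model).  The motor signal of each circuit is its climbing-fibre state.
A comparator network per circuit — P1 (DCN minus motor), P2 (motor minus
DCN), P3 (P1 or P2), a flexor inhibited by the DCN, and an extensor
inhibited by an interneuron that the DCN suppresses — turns the DCN/motor
disagreement into flexor and extensor votes.  Muscle power is
$\overline{\text{flexor} - \text{extensor}} \times \text{muscle strength}
(+\text{external force})$, in position-units per sample, added to the
joint and clamped to $[0,1]$.  Clamping is our choice: the update equation
alone is unbounded and the physical joint is not.  A simpler diagnostic
plant using $\overline{\text{motor} - \mathrm{DCN}}$ directly is retained
as `simple_muscle_power()`.

### The comparator's equilibrium offset

The comparator equations are deliberately asymmetric: the flexor is
inhibited directly by the DCN, the extensor only through a DCN-suppressed
interneuron.  Working through the conditional probabilities at the default
parameters, the co-firing case (DCN and motor both active) leaves the
extensor with a net advantage (≈0.70 versus 0.405 per active P3).  The
loop is still a stable negative feedback — the net vote decreases
monotonically in the actual position — but it balances roughly 0.15–0.18
*below* the desired position rather than on it.  Two consequences matter
for interpreting results:

* the intention-tremor metric is a windowed variance and is unaffected by
  a static offset, so tremor comparisons across circuit counts and presets
  are clean;
* the movement error contains a large bias term, so comparisons of
  absolute error between perturbation arms mostly compare how each arm
  shifts that bias.  The GABA-facilitation and glutamate-reduction arms
  both suppress the DCN, shrink the extension bias, and so *reduce*
  median error — the opposite of what one would expect from an unbiased
  plant.  The adaptive model (below) largely removes the offset, which is
  also why it tracks better than the non-adaptive equations.

## Plasticity

Six activity-dependent rules act per circuit, per sample, on five
synapses: parallel-fibre→Purkinje LTD on granule/climbing co-activation
(same-sample Boolean AND) and LTP on isolated high-frequency granule
activity; mossy→granule LTP and mossy→DCN LTD on high / low mossy
activity; climbing→Purkinje LTP on high climbing activity; and
Purkinje→DCN LTD when the DCN fires while Purkinje activity is low.
"High" and "low" are cutoffs (0.6 / 0.2) on an exponential moving average
of each neuron's firing (smoothing 0.05, a ≈20-sample time constant).
Triggered synapses change by ±1% per sample, clipped to $[0.1, 5]$;
untriggered synapses relax toward their baseline at 0.1% per sample.
These magnitudes are choices, not measurements: they are slow relative to
the 250 Hz sampling so that adaptation becomes visible within a few
hundred samples yet the strengths remain bounded, and all of them are
exposed in `plasticity_config()`.  The tests therefore assert recovery
*properties* (error returns within the run, DCN shifts down under an
extension-directed force and returns at offset) rather than fixed numbers.

## Temporal-summation engine

The temporal variant carries a per-neuron "neurotransmitter effect" in
$[-1,1]$ across samples.  The decay factor is
$(\text{refractory} - \text{step})/\text{refractory}$ — $1/3$ at the 3 ms
refractory period and 2 ms step (500 Hz) defaults, and overridable.  A
neuron fires when carried effect plus current drive exceeds DT; on firing
the effect is set to $-1$, otherwise it accumulates the subthreshold drive
(capped), and either way it decays.  How current drive combines with the
carried effect is a design choice: we add them before thresholding and
store the subthreshold remainder, the minimal reading that actually
produces temporal summation.

The absolute refractory period is enforced as an explicit countdown of
$\lceil \text{refractory}/\text{step}\rceil - 1$ samples rather than
"cannot fire while the effect is negative": geometric decay approaches
zero without reaching it, so a sign-based lockout never ends for a neuron
that receives no further drive (in development this depressed firing by
20–40%).  The countdown gives exactly the intended lockout (4 ms spike
spacing at the defaults) and collapses to zero when the step reaches the
refractory period — in that limit, with decay 0, the engine consumes the
identical RNG stream as the memoryless model and reproduces it
bit-for-bit, which the tests assert.  At matched input frequencies the two
engines agree within a few percent in mean firing rates.

## Perturbation presets

All presets are pure config transforms: micro-complex loss (circuit-count
override); ethanol (GABAergic SyS ×1.5, glutamatergic ×0.8 by default —
magnitudes are conventions, only directions are meaningful, and single-arm
variants are obtained by setting one factor to 1); interneuron
hyperexcitability (interneuron DT ×0.5); CaV2.1 channelopathies (SyS of
granule-cell efferents, climbing-fibre efferents and the Purkinje→DCN
terminal ×0.35 "tottering" / ×0.15 "rocker"; the affected synapse set is
an interpretation and is overridable); and a tonic DCN threshold bias for
external-force compensation.  GABAergic = Golgi, interneuron and Purkinje
outputs; everything afferent- or granule-derived is glutamatergic.

One empirical note: the severity ordering of the CaV2.1 variants on the
stationary DCN output holds on average over the afferent grid but not at
every single input pair, because the preset weakens climbing excitation
and Purkinje inhibition of the DCN simultaneously and the cancellation
depends on the input mix.

## Analysis utilities

*Intention tremor* is the windowed variance of joint position about its
own moving mean (window 5, half-window 2).  Edges use truncated windows
with the divisor equal to the samples actually present — the alternative
(padding) fabricates data beyond the series.  The metric is zero for a
constant series and scales quadratically with amplitude.

*Spectrograms* use generalized Morse wavelets (shape $\gamma = 3$,
time-bandwidth 120, so $\beta = 40$), implemented as an FFT filter bank —
no installed R package provides a Morse continuous wavelet transform, so
it is built here and validated on synthetic tones (a 40 Hz tone yields a
stable ridge at 40 Hz; Bernoulli noise does not).  Analysis frequencies
span 0.5–100 Hz on a logarithmic grid; series must contain at least two
cycles of the lowest frequency.

*Afferent-grid sweeps* (`scfh_sweep()`) evaluate the DCN output over a
mossy × climbing probability grid through the analytic marginal (the
simulation path exists to validate it), report $|{\rm DCN} - {\rm CF}|$
in Hz, and extract the central curve — the mossy frequency at which the
DCN output matches the climbing input.  The DCN output is monotone in both
afferents; the mismatch is approximately symmetric about the central
curve (mean normalised asymmetry ≈0.03 on a 21×21 grid); strengthening
Purkinje→DCN inhibition shifts the curve toward higher mossy frequencies.

*Circuit-requirement search* (`required_cmc_search()`) finds, per muscle
strength, the smallest circuit count whose tracking tremor stays below a
threshold in all of `k` seeded replicates (doubling then bisection to 25%
relative precision).  The threshold defaults to the mean tremor of a
high-circuit-count reference run times a 1.5 headroom factor — the
reference is itself a noisy estimate and an exact-floor threshold would
never be met consistently.  Required counts grow steeply with muscle
strength (the vote noise scales as $\text{strength}/\sqrt{n}$).

## Problem sizes and test design

The package's tests run everything at desk scale: $10^5$ circuits for
single-sample oracle cross-checks, $10^2$–$10^4$ circuits and 400–1200
samples for closed-loop properties, 5 seeds for directional comparisons
(a 5/5 sign test reaches $p = 1/32$), 21×21 analytic grids.  The
full-scale defaults (100,000 circuits, 2,500 samples, $10^6$-circuit
grids via the analytic path) are available through `run_experiment()`'s
arguments.  Statistical assertions use 3-binomial-standard-error bands
against the analytic oracle; frozen numeric bounds (e.g. the grid
asymmetry ≤ 0.1) were computed from the oracle before being asserted.

The desired-trajectory generators emulate goal-directed joint movement as
a 0.5 Hz sinusoid spanning $[0.1, 0.9]$, plus constant holds and step
sequences; the adaptive-force experiments use a 0.5 position-units/sample
external force (5% of the default muscle strength), large enough to
displace the uncompensated joint visibly.  What passing tests show is
internal consistency of this model — circuit-loss tremor, adaptive force
compensation, transmitter-perturbation phenotypes *of the simulated
plant* — not validation against physiological recordings, which contain
membrane dynamics, conduction delays and multi-joint couplings that this
reductionist model deliberately omits.

## Known limitations

* The comparator equilibrium offset described above; absolute movement
  errors should be read relative to each configuration's own bias.
* Ethanol-arm *error* orderings (and the combined arm's tremor rank)
  follow the bias, not the intuitive direction; tremor orderings are
  reliable.
* No inter-circuit connectivity, membrane potentials, conduction delays,
  muscle fatigue or friction (config hooks exist for the muscle-side
  extensions but no behaviour is implemented).
* The temporal engine models only an absolute refractory period; there is
  no relative refractory tail beyond the decaying negative effect.
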