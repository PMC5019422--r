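---
title: "Population-density simulation of a layered cortical column"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-density simulation of a layered cortical column}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dipdeR` simulates large homogeneous populations of leaky
integrate-and-fire (LIF) neurons by evolving the probability density of
their membrane voltages instead of individual cells. Each neuron obeys

$$\tau_m \frac{dv}{dt} = -v + \Delta v \sum_i \delta(t - t_i), \qquad
v > v_\theta \Rightarrow v \to v_r = 0,$$

with membrane time constant $\tau_m$, instantaneous (shot-noise)
synaptic jumps $\Delta v$, threshold $v_\theta$ and reset at rest
(voltages are expressed relative to rest). In the limit of a large
homogeneous population the ensemble is described exactly by a master
equation for the voltage density $p(t, v)$: a continuity equation whose
flux combines deterministic leak drift with displacement of probability
mass by $\Delta v$ at the presynaptic event rate $\lambda_{in}$ — a
displacement integro-partial differential equation (DiPDE). Mass
crossing threshold re-enters at reset, and that flux, divided by the
time step, *is* the population firing rate. The simulation is
deterministic: the Poisson background enters only through its effect on
the master equation, never as a realization.

### Finite-volume discretization

The voltage interval $[v_{min}, v_\theta]$ is split into uniform
half-open bins; a value on an edge belongs to the upper bin. Two linear
flux operators act on the vector of per-bin masses:

* **Leak.** Mass crosses the interior edge at voltage $v_e$ toward 0 at
  rate $|v_e| / (\tau_m \, \Delta v_{donor})$, the donor bin lying on
  the far side of the edge from rest. No leak flux crosses threshold or
  the lower wall (the drift points inward at both). This is the upwind
  finite-volume form of the drift $-v/\tau_m$; its numerical diffusion
  is first order in the bin width, which is the leading discretization
  error of the solver.
* **Synaptic displacement.** A unit-rate operator moves each bin's mass
  by the synaptic weight; a jump landing between two bins is split
  between them by linear interpolation, preserving total mass and the
  mean displacement exactly. Excitatory mass displaced beyond
  $v_\theta$ is re-injected at reset and tallied as firing flux;
  inhibitory mass that would cross the lower wall accumulates in the
  lowest bin. Scaling this operator by the presynaptic rate (in-degree
  times source rate for a convergent connection) gives the synaptic
  term of the master equation.

Both operators have zero column sums (probability is conserved to
rounding) and non-negative off-diagonal entries, so the combined
generator $A = L + \sum_s \lambda_s S_s$ is a Metzler matrix.

### Time stepping

The formal one-step solution is $p(t + \Delta t) = e^{\Delta t A} p(t)$.
The package integrates it with Heun (explicit trapezoid) sub-steps,
choosing the sub-step $h$ so that $h \times \max_j(\text{total outflow
rate})_j \le 0.4$. The effective update matrix $I + hA + (hA)^2/2$ has
non-negative entries whenever $h$ times the maximum outflow is at most
1, so the scheme preserves non-negativity and conserves mass exactly;
its agreement with the matrix exponential reference
(`step_density(method = "expm")`) is about $10^{-8}$ per bin over a
10-step test at column-typical input rates. (First-order Euler
sub-stepping at the conventional 0.1 stability bound leaves an error of
about $2\times10^{-6}$ on the same test, which is why the second-order
scheme is the default; it is also twice as fast for equal accuracy.)
The population rate is accumulated with trapezoidal quadrature of the
firing flux across sub-steps.

Defaults for the column analyses: `dt = 0.1` ms, 300 bins of 0.1 mV on
$[-15, 15]$ mV. The lower wall matters more than it may appear: the
most strongly inhibited population (L6e) carries substantial mass far
below reset, and a wall at $-5$ mV biases its stationary rate visibly
(1.89 Hz against 1.20 Hz with the wall at $-15$ mV, where the spiking
oracle gives 1.17 Hz). Refining to 600 bins or halving `dt` changes
stationary rates by well under 1%.

## The cortical column

`build_column()` assembles the four-layer, two cell-type microcircuit
of Potjans & Diesmann (2014, *Cerebral Cortex* 24:785–806): eight
populations (L2/3e … L6i, full-scale sizes totalling ~77,000 neurons),
a connection-probability matrix, and per-population background Poisson
drive. The packaged YAML (`inst/extdata/potjans_diesmann_column.yaml`)
carries the transcribed constants with per-block provenance comments.
Three modelling choices follow the population-density adaptation of
that circuit:

* **Charge-conserving weights.** An exponential-current synapse with
  PSC amplitude $w$ and time constant $\tau_s$ delivers total charge
  $w \tau_s$; the equivalent instantaneous jump is $\Delta v = w \tau_s
  / C_m$. With $w = 87.8$ pA, $\tau_s = 0.5$ ms, $C_m = 250$ pF:
  $+0.1756$ mV per excitatory synapse, and $-0.7024$ mV for inhibitory
  synapses (four times stronger, opposite sign). The L4e→L2/3e
  probability is doubled to 0.088 so a single excitatory weight serves
  every connection.
* **In-degrees from synapse counts.** The source microcircuit derives
  the synapse count of a projection from its pairwise probability
  through the binomial identity $K_{tot} = \ln(1-p) / \ln(1 -
  1/(N_{pre} N_{post}))$, giving a per-neuron in-degree of about
  $-N_{pre}\ln(1-p)$ — up to 25% more than $p\,N_{pre}$ for the
  strongest recurrent inhibition. The difference is material: with
  plain products the column settles roughly 45% above the published
  operating point, while the binomial counts reproduce it (stationary
  L5e ≈ 7.2 Hz). `in_degree()` (the plain product) and
  `in_degree_binomial()` are both exported;
  `build_column(in_degree_method =)` selects, defaulting to
  `"binomial"`.
* **Background rescaling.** The background rate is divided by 8.54 and
  the background weight multiplied by the same factor, preserving the
  mean drive exactly while boosting shot-noise variance; this damps
  the intrinsic oscillations of the original circuit.

Delays are drawn per synapse from normal distributions truncated at the
simulation resolution (excitatory 1.5 ± 0.75 ms, inhibitory 0.75 ±
0.375 ms). The density model represents this as a discretized delay
kernel convolved with the presynaptic rate (`connection(delay_sd =)`).
This is not a cosmetic choice: collapsing each distribution onto its
mean makes the full column ring at several hundred hertz without ever
settling — a single shared loop delay supports a sustained resonance
that the physiological delay spread destroys. Stationary states are
unaffected by delay handling; transients and frequency responses are.

Every population starts from a Gaussian voltage density (mean at reset,
sd 5 mV) and receives background drive for 100 ms, which settles the
column well within the epoch (drift < 0.1 Hz over the following
50 ms). Refractory periods are set to zero; at column rates (≤ ~11 Hz)
a 2 ms refractory period would change rates by under 3%.

```{r column}
library(dipdeR)
column <- build_column()
traces <- run_network(column, duration = 200, dt = 0.1)
final_rates(traces)   # stationary rates, Hz
```

## Stimulus protocols and analyses

A drive is an extra external population projecting with the excitatory
weight onto the targeted population(s) of a layer, with 100 independent
sources per target neuron. Target specificity — `excitatory`,
`inhibitory`, or `balanced` (both cell types, identical per-neuron
input) — determines the character of the response.

```{r drives}
p23 <- step_perturbation(column, "L2/3", "balanced", amplitude = 20)
p4  <- step_perturbation(column, "L4",  "balanced", amplitude = 20)
p23$delta["L5e"]   # ~ -1.5 Hz
p4$delta["L5e"]    # ~ +1.5 Hz
```

Steady-state perturbations are means over the final 20 ms of each
epoch (a window averages residual ripple; a drift check flags windows
that have not settled). Balanced drives into L2/3 and L4 move L5e by
nearly equal and opposite amounts, and their joint effect nearly
cancels — the deep layer reports a subtraction of the two superficial
inputs.

Linearity is quantified two ways. *Homogeneity*: the half-amplitude
response extrapolated to full amplitude, $\Delta F = |(F_{10} - F_0) -
2(F_5 - F_0)|$, zero for a linear response. *Additivity*: two layers
driven separately and jointly; `additivity_test()` returns the summed
single-layer perturbations against the joint run. Pooled over all six
layer pairs, balanced drive sits essentially on the identity line
(r² ≈ 0.999, rms deviation ≈ 0.01 Hz) while cell-type-biased drive
deviates; per-specificity homogeneity errors order the same way.

Whether driving L5i alone produces the *paradoxical* self-suppression
of an inhibition-stabilized network depends on the operating point.
Under the plain product in-degrees (`in_degree_method = "product"`,
stationary L5e ≈ 12.6 Hz) the signature is clear: the L5i rate dips
below baseline (≈ −0.1 Hz around 5–10 Hz drive) and reverses once L5e
is strongly suppressed — a non-monotone response curve. At the
binomial-count operating point (L5e ≈ 7.2 Hz) the recurrent gain is
lower and the L5 subcircuit is no longer inhibition-stabilized: the
L5i self-response is weakly positive throughout 0–20 Hz, even though
L5e is still strongly suppressed. The property test asserts the
paradox on the product-convention column, where the regime that
produces it is present.

`sensitivity_ensemble()` repeats the homogeneity assay over columns
whose connection probabilities are each multiplied by unit-mean
Gaussian noise (5% relative sd, floored at zero, seeded per model).
Models whose background run fails the stationarity check are flagged
`non-stationary` and excluded from summaries, never dropped silently —
a few percent of 5%-perturbed matrices do push the circuit into a
ringing regime. The dispersion statistic is grid-robust, so the
ensemble runs on the coarser 200-bin grid for speed.

### Frequency responses

Sinusoidal drive uses a raised cosine, $x(t) = A(1 - \cos 2\pi f
t)/2$: it starts continuously from baseline, never goes negative, and
has peak excess exactly $A$ (fundamental amplitude $A/2$).
`amplitude_response()` sweeps frequencies, fits $a + b\cos + c\sin$ on
a whole number of post-transient periods, and forms the gain
$A_{out}/A_{in}$.

Two conventions exist for reading a −3 dB cutoff from such a sweep,
and for this circuit they differ because the transfer is not first
order. `cutoff_frequency(reference = "amplitude")` marks the textbook
half-power point (amplitude ratio $1/\sqrt 2$); `reference = "power"`
(the default here) marks where the *power* response
$(A_{out}/A_{in})^2$ has fallen to $1/\sqrt 2$ of its maximum
(amplitude ratio $2^{-1/4} \approx 0.84$) — the reading obtained when
the plotted curve is a spectral power estimate, the scale on which
these population transfers are compared against spiking-simulation
PSDs. On the
power reading the balanced L4→L5e transfer is lowpass with a cutoff
near 15 Hz, and its normalized power curve tracks a first-order RC
filter with time constant close to $\tau_m = 10$ ms across 2–30 Hz; on
the amplitude reading the same sweep crosses near 27 Hz, because the
transfer retains a high-frequency floor (shot-noise populations
transmit fast rate modulations that a membrane-voltage RC picture
would suppress; the spiking oracle confirms the weak 40 Hz
attenuation). Both numbers describe the same curve; the package
reports gain and power gain side by side.

Total harmonic distortion compares power at harmonics of the drive to
the fundamental, $\sum_{i\ge2} V_i^2 / V_1$ with $V_i$ the harmonic
power (the amplitude-ratio form $\sqrt{\sum_{i\ge2} A_i^2}/A_1$ is
reported alongside as `thd_amplitude`). Fundamentals below 0.05 Hz are
flagged rather than ratioed. Balanced drive keeps distortion very low
(THD $\lesssim 10^{-7}$ across the sweep), consistent with the linear
regime.

```{r filter}
fc <- amplitude_response(column, "L4", "L5e",
                         frequencies = c(2, 4, 8, 12, 16, 20, 25, 30, 40, 60),
                         amplitude = 20)
fc$cutoff_hz   # ~15 Hz on the power reading
```

## The spiking oracle

`simulate_ensemble()` integrates the same LIF equation directly for a
finite network: per trial, a fresh connectivity realization (each
target neuron samples its in-degree of sources with replacement;
per-synapse truncated-normal delays), Gaussian initial voltages, and
independent Poisson background/stimulus event counts per neuron per
step, with closed-form decay between events. It is the package's
ground truth: everything the density solver claims can be checked
against trial-averaged spiking statistics.

Two systematic terms frame such comparisons. The solver carries an
$O(h)$ grid bias (about +0.3% at 0.1 mV bins for a 54 Hz population);
the event-gridded ensemble carries an $O(dt)$ bias; and a *scaled-down*
column carries an $O(1/N)$ upward rate bias from shared-input
correlations (in-degrees are preserved when sizes shrink, so at 1/10
scale each pair of neurons shares ten times more inputs than at full
scale — measured: the bias roughly halves from 1/10 to 1/5 scale).
None of these is Monte-Carlo error, so the test suite compares
Richardson-extrapolated limits (solver in bin width, ensemble in `dt`
or in 1/scale) at three standard errors, and asserts separately that
the ensemble-vs-solver discrepancy shrinks as the network grows.
Desk-scale agreement: stationary column rates from the density solver
match the 1/10-scale, 20-trial spiking ensemble to within ~0.2 Hz for
six of eight populations, the remainder explained by the finite-size
term.

## Problem sizes used by the test suite

Simulated protocols are desk-scaled: 200 ms column runs at `dt = 0.1`
ms; frequency sweeps of 8–10 frequencies with three drive periods
fitted per frequency; a 50-model sensitivity ensemble (the full
1000-model ensemble is a `n_models` argument away); spiking-ensemble
checks at 1/10 and 1/5 scale with 6–20 trials. The synthetic-data
generators (the spiking oracle and the closed-form RC/harmonic
fixtures) emulate homogeneous populations with ideal Poisson
background; they do not emulate heterogeneous cell parameters,
conductance synapses, finite axonal propagation, or non-Poisson input
statistics, so passing tests certify the solver and the column
parameterization, not biological completeness.

## Known limitations

* Instantaneous synapses: the charge-equivalent jump approximation is
  good for $\tau_s \ll \tau_m$ (here 0.5 ms vs 10 ms) but removes
  synaptic filtering above ~100 Hz.
* Single weight per connection; no weight heterogeneity or plasticity.
* The hard lower wall truncates $(-\infty, v_\theta]$; keep it several
  inhibitory jumps below reset (the default is 21).
* Population homogeneity is assumed exact; cell-type diversity beyond
  one excitatory and one inhibitory class per layer is out of scope.
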