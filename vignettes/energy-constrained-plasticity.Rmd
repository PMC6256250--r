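---
title: "Energy-constrained STDP in spiking networks: model, implementation, and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-constrained STDP in spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enstdp)
```

## The model

`enstdp` simulates recurrent networks of leaky integrate-and-fire (LIF)
neurons whose excitatory synapses evolve under a three-factor plasticity rule:
classical spike-timing-dependent plasticity (STDP) multiplicatively gated by a
per-neuron *metabolic* signal. The premise is that the two dominant ATP sinks
of neuronal signaling — synaptic transmission (presynaptic release,
postsynaptic action, transmitter recycling) and action-potential generation
("dendritic integration") — must stay in a fixed energetic proportion for a
neuron to operate normally, and that plasticity is one of the levers that
keeps them there.

**Energy bookkeeping.** Every spike arriving at a synapse of weight $w$
deposits $E^{trans}_{single}\cdot w$ ATP of transmission energy on the
receiving neuron; every spike the neuron emits deposits $E^{integ}_{single}$
ATP of integration energy. Because the underlying biochemistry is not
instantaneous, each deposit is spread over time by a unit-mass alpha kernel

$$\varphi(t) = \frac{t - t_0}{\tau^2}\, e^{-(t-t_0)/\tau},
  \qquad \int_{t_0}^{\infty}\varphi\,dt = 1,$$

with $\tau_{trans} = 20$ ms for transmission and $\tau_{integ} = 100$ ms for
integration. The controlled variable is the windowed energy ratio

$$\alpha_j \;=\;
  \frac{\int W E^{trans}_j\,d\tau}{\int_W E^{trans}_j\,d\tau
        + \int_W E^{integ}_j\,d\tau}$$

over a trailing window $\Delta T = 5$ s, with homeostatic set point
$c = 0.75$ (transmission claims roughly three quarters of signaling energy in
cortical budgets). $\alpha$ is undefined until any signaling energy has been
spent; while undefined the rule falls back to classical STDP.

**The gated rule.** Each STDP increment is multiplied by the sigmoidal gate

$$f(\alpha) = \frac{2}{1 + e^{\lambda\,\mathrm{sign}(\Delta t)\,(\alpha - c)}},
  \qquad \lambda = 300,$$

with $\Delta t = t_{post} - t_{pre}$ taken from the latest spike on each side
(nearest-spike pairing). At $\alpha = c$ the gate is exactly 1 and classical
STDP is recovered; when transmission over-consumes ($\alpha > c$)
potentiation is suppressed and depression amplified, and conversely. The pair
of gates always satisfies $f(\alpha, +) + f(\alpha, -) = 2$.

**Wiring.** Networks obey Dale's principle with a 4:1
excitatory:inhibitory split; inhibitory-inhibitory connections do not exist;
each connected pair carries exactly one directed edge (no reciprocal
connections). Only excitatory-to-excitatory synapses are plastic, initialized
uniform on $[0,1]$; E-to-I and I-to-E weights are fixed at 0.5 (the midpoint
of the admissible weight range — the model fixes these weights but assigns
them no value). In the single-neuron preparation the external synapses
themselves are plastic.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| $E^{trans}_{single}$ | $4.1\times 10^4$ | ATP | per arriving spike at $w=1$ (0.25 vesicles $\times\,1.64\times10^5$ ATP) |
| $E^{integ}_{single}$ | $1.2\times 10^8$ | ATP | per emitted spike |
| $c$ | 0.75 | — | energy set point |
| $\Delta T$ | 5 | s | ratio window |
| $\tau_{trans},\ \tau_{integ}$ | 20, 100 | ms | kernel time constants |
| $\lambda$ | 300 | — | gate gain |
| $f$ | 10 | Hz | external stimulus rate |
| $\tau_m$ | 20 | ms | LIF membrane constant |
| rest / threshold / reset | $-65/-50/-65$ | mV | canonical cortical LIF |
| refractory | 2 | ms | absolute |
| $a_\pm$, $\tau_\pm$ | 0.01, 20 ms | — | STDP amplitudes and windows |
| efficacy | 0.07352 | mV | membrane deflection per unit-weight spike |

**STDP form.** The timing kernel is the canonical exponential pair window.
The update is weight-dependent (soft bounds): potentiation is scaled by
$(1-w)$ and depression by $w$. This choice — open in the model description —
is made because the *control* condition (gate fixed at 1) is reported to
stabilize near the initial mean 0.5 with an approximately normal stationary
weight distribution, which is the signature of soft-bound STDP; additive STDP
produces uniform-to-bimodal stationary distributions instead. Soft bounds
also keep weights inside $[0,1]$ without clipping.

**External drive.** Every neuron receives a bundle of `n_external = 2000`
independent 10 Hz Poisson trains through fixed weights drawn uniform on
$[0,1]$. The bundle size follows from the energy constants themselves: with
$E^{integ}_{single}/E^{trans}_{single} \approx 2927$, a neuron can only reach
$\alpha = c = 0.75$ if it receives about
$\tfrac{c}{1-c}\cdot 2927 \approx 8800$ weighted arrivals per spike it emits.
Recurrent afferents alone (a few hundred per neuron at comparable rates)
bound $\alpha$ below about 0.1, so a single-neuron-like external bundle is
the only way the stated set point is even statically reachable. In the
engine, non-plastic bundles are sampled in aggregate (the exact
compound-Poisson superposition), plastic ones source-by-source.

**Synaptic efficacy.** The voltage scale of one synapse is not fixed by the
model and acts as a free calibration constant. The frozen default
(`default_efficacy()`, 0.07352 mV) is produced by
`calibrate_efficacy(target = "control")`: the control preparation (2000
trains, 10 Hz, weights at their initial mean 0.5) fires at the stimulus rate,
10 Hz. This keeps every standard preparation active and well mixed from its
uniform initial condition. The alternative,
`calibrate_efficacy(target = "balance")`, places the LIF transfer curve on
the energy-balance line $\nu = \frac{1-c}{c}\, m f \bar w\,
E^{trans}_{single}/E^{integ}_{single}$ (about 1.73 Hz) at $\bar w = 0.758$;
it is retained because it identifies the static balance point, but under it
the initial condition sits ~16 standard deviations below threshold and the
model never fires, so it is not the default.

## Numerical implementation

The engine (C++ via Rcpp) advances a synchronous clock (default `dt` 0.1 ms
single neuron, 0.5 ms network) with event-driven plasticity and energy
updates:

1. spikes emitted in the previous step are delivered (zero axonal delay,
   one-step causality gap), each arrival adding `efficacy * w` mV (negative
   for inhibitory afferents), depositing transmission energy, and applying
   the depression branch against the target's latest spike;
2. external arrivals are delivered the same way;
3. the energy traces advance by `dt` through an exact two-variable recursion
   (the alpha kernel solves a second-order linear ODE: with
   $G=\sum m_k e^{-(t-t_k)/\tau}$, one step is
   $E \leftarrow e^{-dt/\tau}(E + G\,dt/\tau^2)$,
   $G \leftarrow e^{-dt/\tau} G$), and $E\,dt$ accumulates into a 1 ms-binned
   ring buffer implementing the trailing 5 s window;
4. each neuron makes one exponential-Euler leak step plus its summed drive;
   threshold crossings reset the membrane, start the 2 ms refractory period,
   deposit integration energy, and apply the potentiation branch across all
   plastic afferents.

The trailing window $[t - \Delta T, t]$ replaces the forward-looking window
of the defining ratio: an online rule can only be causal, and at
stationarity the two agree. Exact spike-time coincidence ($\Delta t = 0$ on
the grid) carries no update, since the gate's sign is undefined there. A
pure-R reference simulator (`reference_pure_stdp()`) mirrors the identical
update order with the gate hard-wired to 1; the test suite requires the
compiled engine with constraints disabled to match it bit for bit on
scheduled-stimulus instances. Determinism: a single seed drives initial
weights, topology, and stimulus; paired constrained/unconstrained runs
consume identical random streams, so they see identical stimulus
realizations.

Problem sizes used in the bundled checks — 200 s single-neuron runs at
$m = 2000$, a 300 s 500E+125I network, sweep grids $m \in \{500, 1000, 2000,
4000\}$ and $N \in \{25, 50, 100\}$ at 60–150 s — were chosen so the full
suite completes on a laptop-class single core; longer horizons do not change
the attractors described below.

## What the dynamics actually do

The closed loop formed by the gate and the LIF transfer function deserves a
candid analysis, because it determines everything the experiments show.

Write $\bar w$ for the mean plastic weight and $\nu(\bar w)$ for the
neuron's firing rate. The ratio
$\alpha(\bar w) = 1/\bigl(1 + \nu(\bar w) E^{integ}_{single} /
(m f \bar w E^{trans}_{single})\bigr)$ is *decreasing* in $\bar w$ whenever
$\nu$ grows superlinearly in drive — and a LIF rate curve is superlinear at
every operating point below refractory saturation (its log-log slope is
$1/\bigl(x\ln(1+1/x)\bigr) > 1$ with $x = (\mu-\theta)/\theta$). With
$\lambda = 300$ the gate saturates for $|\alpha - c| \gtrsim 0.01$, so the
rule is effectively a relay: $\alpha < c$ switches on pure potentiation,
$\alpha > c$ pure depression. A relay acting on a plant with
$d\alpha/d\bar w < 0$ is *positive* feedback: the set point is repelling, and
every constrained run commits to one of two attractors —

* **rail-up**: weights saturate at the soft bound, the neuron fires far above
  the balance rate, $\alpha$ pins low (~0.1 single neuron, ~0.2 network);
* **freeze**: the neuron falls silent, pairings cease, weights stop moving
  near their current mean, and $\alpha$ (if defined) pins high.

Which attractor is reached depends only on whether the initial state fires
above or below the balance rate $\nu^* = \frac{1-c}{c} m f \bar w\,
E^{trans}_{single}/E^{integ}_{single}$ (≈ 1.14 Hz at $\bar w = 0.5$); the
outcome is robust across seeds. Stable interior regulation at $\alpha = c$
would require a rate curve *sublinear* at ~1–2 Hz, which no standard LIF
(with or without noise, refractoriness, or a different membrane constant)
provides. Consequently the interior steady states sometimes quoted for this
model class (mean weight ≈ 0.758 for the constrained single neuron, ≈ 0.46
for the constrained network, with $\bar\alpha \to 0.75$) are not reachable
from the uniform initial condition under the published constants; the
corresponding acceptance checks in this package fail honestly rather than
being tuned toward those values. The *control* behavior, by contrast, is
robust: with the gate at 1 the soft-bound rule keeps the mean weight near
0.5 at every scale, with a normal stationary distribution.

What *does* carry over qualitatively: constrained weights end up above
unconstrained ones in the single-neuron preparation; paired runs separate
cleanly; and the degree-weight anticorrelation appears in the constrained
network (high in-degree neurons saturate marginally less).

## Degenerate inputs and edge cases

Zero stimulus rate or zero weights yield a quiescent, energy-free, frozen
simulation. `windowed_ratio(0, 0)` is `NA` by definition, and the gate treats
`NA` as 1. A non-finite membrane potential (e.g. a non-finite efficacy)
aborts the run with the offending step index. `dt` must divide the window bin
width; spike storage is capped (counts are always complete) to bound memory.

## Known limitations

* Delta-current synapses, no conductances, no axonal delays, no synaptic
  noise beyond the Poisson drive.
* The trailing window approximates the defining forward window; they agree
  at stationarity but differ during the first $\Delta T$ seconds.
* The aggregate external sampler matches the compound-Poisson bundle exactly
  in distribution but not spike-by-spike; plastic bundles are always
  simulated explicitly.
* The synthetic stimulus is homogeneous Poisson; real afferent populations
  carry correlations and rate modulations that the generator does not
  emulate, so passing tests say nothing about structured-input regimes.
* The set-point instability analysed above is a property of the published
  model constants, not of the implementation; exploring gate gains small
  enough to de-saturate the relay (or rate-stabilized neuron models) is
  possible with the exposed parameters but outside the package defaults.
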