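---
title: "Cooperative coding: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative coding: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopnet)
```

## The model

`coopnet` studies how a layer of feature neurons can represent a continuous
variable with broad, overlapping receptive fields (RFs) while using as few
synapses as possible. The desired response of neuron $i$ to input neuron $j$
is the exponential profile
$\mathrm{RF}_{ij} = \gamma^{|i-j|}$ with $\gamma = e^{-1/d}$, periodic
distance on a ring of $N$ neurons, and RF size $n_\mathrm{RF} = 2d + 1$ —
the number of feedforward synapses a purely feedforward implementation needs
per neuron.

The same stationary responses arise as the fixed point of a linear rate
network

$$\tau \dot x_i = -x_i + w_\mathrm{rec}(x_{i+1} + x_{i-1}) + w_\mathrm{ff}\, r_i,$$

with only three synapses per neuron, where
$w_\mathrm{rec} = \gamma/(1+\gamma^2)$ and
$w_\mathrm{ff} = (1-\gamma^2)/(1+\gamma^2)$. Neurons share their feedforward
computations through strong like-to-like recurrent excitation
("cooperative coding"); the steady state
$x = (\mathbb{1}-W_\mathrm{rec})^{-1} W_\mathrm{ff} r$ accumulates
poly-synaptic contributions, which the Neumann series
$\mathbb{1} + W_\mathrm{rec} + W_\mathrm{rec}^2 + \dots$ makes explicit
(`neumann_response()`).

The price of the synaptic saving is speed: the loss
$L(t) = |x(t) - x^\mathrm{steady}|_1$ decays with time constant
$\tau_\mathrm{resp} = \tau/(1 - w^\mathrm{rec}_\mathrm{sum})$, which grows
as $\approx \tfrac12 n_\mathrm{RF}^2\,\tau$ — quadratic in the RF size.
Two biologically motivated mechanisms restore speed by *balanced
amplification* (a non-normal coupling from difference modes, where activity
runs ahead of slower negative feedback, into sum modes):

* **Spike-frequency adaptation (SFA)**: a feedback current $-a_\mathrm{SFA}
  u_i$ with $\tau_\mathrm{SFA}\dot u_i = -u_i + x_i$; weights are scaled by
  $1 + a_\mathrm{SFA}$ so the fixed point is unchanged. With
  $\tau_\mathrm{SFA} = \tau$ and $a_\mathrm{SFA}$ optimized per RF size,
  the response-time scaling drops from quadratic to approximately linear.
* **Delayed balancing inhibition**: each excitatory synapse gets an equally
  strong inhibitory twin lagged by $\tau_\mathrm{lag}$, so the balanced part
  of the interaction acts only on activity changes
  $\Delta x_i(t) = x_i(t) - x_i(t-\tau_\mathrm{lag})$. The sum mode obeys the
  scalar delay characteristic equation
  $\tau s = -1 + w^\mathrm{net}_\mathrm{sum} +
  w^\mathrm{bal}_\mathrm{sum}(1 - e^{-s\tau_\mathrm{lag}})$; at the critical
  balance (coalescing dominant roots) the loss decays fastest, with
  $\tau^\mathrm{bal,c}_\mathrm{resp} \approx
  \sqrt{\tau_\mathrm{resp}\tau_\mathrm{lag}/2} \approx \tfrac12
  n_\mathrm{RF}\sqrt{\tau\tau_\mathrm{lag}}$ — linear in RF size.

Mixed-selectivity (MS) grids (two stimuli, six synapses per neuron), the 2D
torus (one 2D stimulus, five synapses), and their balanced versions follow
from the same construction; `scaling_experiment()` runs the full protocols.

## Key parameters

| Parameter | Meaning | Default | Rationale |
|---|---|---|---|
| `N` | neurons per ring (per axis in 2D) | 200 | standard ring size used throughout the rate experiments |
| `tau` | membrane time constant | 1 | all rate times in units of $\tau$ |
| `dt` | integrator step | 0.01 $\tau$ | second-order midpoint makes discretization error negligible at this step |
| `tau_lag` | E–I lag | 0.1 $\tau$ | lag well below $\tau$, as in measured E/I current lags |
| `tau_sfa` | adaptation time constant | 1 $\tau$ | the regime in which adaptation produces balanced amplification |
| `a_sfa` grid | adaptation strengths scanned | 0–20, 41 points + refinement | see below |
| `sigma` (spiking) | background noise (mV) | 2 | see below |
| `x_max` (spiking) | target peak rate | 150 Hz | operating range of the threshold-linear regime |

## Numerical choices

**Integrators.** Plain and balanced rate networks use the explicit midpoint
method; the delayed term uses ring buffers of past full-step and past
midpoint states (history $x(t)=x_0$ for $t\le0$), so the lag must be an
integer multiple of `dt`. SFA networks use the Euler method. The structured
topologies run in compiled kernels; `integrate_rate()` is a generic
reference implementation against which the kernels are tested.

**Response-time measurement.** $\tau_\mathrm{resp}$ is the earliest time
after which $L(t)$ stays below $e^{-1} L(0)$ (last up-crossing). Horizons
are multiples of the analytic estimate; loss targets come from an exact
circulant (DFT) solve rather than a pre-simulation — the two are equivalent
for linear networks, and a pre-run mode is available through
`integrate_rate()`.

**Divergence.** A run is flagged (not an error) when the loss exceeds
$10^3\times$ its initial value or turns non-finite; diverged runs are
excluded from scans and reported.

**The $a_\mathrm{SFA}$ search.** The time-averaged normalized loss
$(1/T)\int_0^T |x - x^*|_1/|x^*|_1\,dt$ over $T = 500\tau$ (zero
initialization, unit input at one site, Euler, `dt` = 0.01) is minimized on
a linear grid from 0 to 20 with 41 points. For broad RFs the minimum sits in
a narrow valley just below the stability boundary of the effective
two-variable sum mode ($a_\mathrm{SFA} \lesssim 1$ for
$w_\mathrm{rec} \to 1/2$), which a 0.5-spaced grid straddles; the search
therefore refines iteratively (three passes, each with a quarter of the
previous spacing around the running optimum). The optimum leaves the network
unstable without adaptation and both effective modes oscillatory, the
signature of balanced amplification (`effective_mode_analysis()`).

**Critical balance and instability.** Both are computed from the scalar
sum-mode characteristic equation, which governs the linearized loss: the
critical balance by eliminating $s$ from $f(s) = f'(s) = 0$ and bisecting,
the instability threshold from the purely imaginary crossing
$\omega\tau = (1-w^\mathrm{net}_\mathrm{sum})
\sin(\omega\tau_\mathrm{lag})/(1-\cos(\omega\tau_\mathrm{lag}))$. The scaled
threshold $(\tau_\mathrm{lag}/\tau)\,w^\mathrm{bal}_\mathrm{sum}$ is
slightly above 1. Simulated divergence of the $N=200$ network brackets the
prediction within 2%.

A known measurement gap: from the constant (zero) initialization the
balanced network converges more slowly than its slowest eigenmode, so the
measured $e^{-1}$ response time exceeds the dominant-root estimate
$1/\lambda$ by a factor of about 2 (e.g. 4.7$\tau$ measured vs 2.2$\tau$
eigenmode at $w^\mathrm{net}_\mathrm{sum}=0.99$,
$\tau_\mathrm{lag}=0.1\tau$). Both numbers are reported; the scaling
exponent is unaffected.

**Wrap-around.** On a finite ring the truncated-distance RF satisfies the
three-synapse fixed-point identity only up to a $\gamma^{N/2}$ correction;
quantitative identities are asserted at sizes where this is below roundoff.

**2D conventions.** The torus feedforward weight defaults to
$1 - 4w^\mathrm{rec}_{2D}$ (unit gain for uniform input; it only scales the
response amplitude). The Bessel-$K_0$ RF approximation is a continuum result
and is accurate (few percent) in the broad-RF regime
$w^\mathrm{rec}_{2D} \to 1/4$ where the 2D scans operate. The measured RF
size $\hat n_\mathrm{RF}$ counts the largest response entries whose
cumulative sum first reaches $1-e^{-1} \approx 63\%$ of the total
(descending sort, first crossing); in 1D this convention reproduces the
coverage of the continuous exponential within one width of its center.

## Spiking implementation

Feature populations of LIF neurons (threshold 10 mV, reset/rest 0 mV,
$\tau_m = 20$ ms, no refractory period, Euler–Maruyama at `dt` = 0.01 ms,
per-synapse delays uniform in (0, 2] ms, fixed indegrees
$K = p\,N_E$ with $p = 0.1$, no autapses) replace the rate neurons. The
tuning proceeds in the stated two stages:

1. *Diffusion approximation + threshold-linear inversion.* The Siegert
   first-passage rate gives the stationary transfer function; a
   threshold-linear fit (gain $g$, threshold $\theta$) over the operating
   range [0, 150 Hz] turns the target profile
   $x_i = x_\mathrm{max}\gamma^{|i-i_0|}$ into a linear self-consistency
   condition whose solution fixes $w_{EE}$
   ($gJ(1+\gamma+\gamma^{-1}) = 1$ with $J = w_{EE}\tau_m K/1000$),
   $I^\mathrm{off}_\mathrm{ext} = \theta$, and
   $I^\mathrm{on}_\mathrm{ext}$. The feedforward drive is deliberately not
   co-tuned in stage 2.
2. *Numerical refinement* (`refine_wee()`): a bracketed search on a
   multiplicative factor of $w_{EE}$ until the measured RF size falls in
   $[n_\mathrm{RF}^\mathrm{target} - 0.5,\, n_\mathrm{RF}^\mathrm{target}]$
   — needed for larger RFs, where the weights approach the instability
   point.

The noise strength is not fixed by the model; $\sigma = 2$ mV was selected
once by scanning $\sigma$ and minimizing the threshold-linear fit residual
(0.9% of $x_\mathrm{max}$ at $\sigma = 2$) while keeping the onset rate at
the fitted threshold small. The onset nonlinearity still produces a low
background plateau in populations far from the stimulus (their drive sits
at $\theta$, where the smoothed transfer is a few Hz); the RF-size fit is
therefore taken over the profile core (rates above 10% of the peak).

The balanced version scales $w_{EE}$ by $s > 1$, sets $w_{IE}$ so that
inhibitory populations mirror their partner excitatory rates
($g\,w_{IE}\tau_m K_{IE}/1000 = 1$), and cancels the added excitation in
the stationary state with $w_{EI} = -(s-1) w_{EE} K_{EE}/K_{EI}$;
`tune_balanced_grid()` grid-searches $s$ (the full protocol uses
$s \in [1.1, 1.9]$ in steps of 0.1) and returns the fastest network whose
stationary profile matches the excitatory reference.

**Response-time estimation at reduced scale.** The raw per-step L1 loss of
instantaneous population rates carries a shot-noise floor that *scales with
the firing rates*; for populations much smaller than the full-scale
$N_E = 4000$ the floor exceeds the systematic transient, so an exponential
fit to the raw loss is unidentifiable. The package instead fits
$x(t) = A - B e^{-t/\tau_\mathrm{resp}}$ to the binned (0.5 ms) rate of the
stimulated excitatory population over a window around its rise — the
"rate response time" of the stimulated population. On noiseless synthetic
traces the estimator is exact; at desk scale it cleanly resolves the
balanced-vs-excitatory ordering (about 1 ms vs 10 ms for
$n_\mathrm{RF} = 3$).

**Seeds.** The connectivity/delay draw uses R's RNG (`set.seed`); the
membrane noise uses a dedicated, explicitly seeded xoshiro256++ stream in
the compiled kernel (billions of normal deviates per run). Both seeds are
logged with every archived run.

## Problem sizes used by the tests

Full-scale protocols (41–61 populations of 4000 neurons, 3.5 s at
0.01 ms; 200×200 tori; 20-point 2D scans up to
$\tau_\mathrm{resp} = 1000\tau$) are available through the exported
functions and the `coopnet` CLI, and run for hours. The test suite and the
acceptance script exercise the same code paths at documented reduced sizes,
chosen so every mechanism remains quantitatively visible:

* rate scans: $N = 200$, $n_\mathrm{RF} \in \{6, 8, \dots, 50\}$ (full
  protocol for the 1D, SFA and balanced families);
* 2D scans: 64×64 torus, 6–8 target response times log-spaced in
  $[10, 100]\tau$ (boundary effects at this grid size are negligible for
  the sizes scanned, since the RF decay length stays well below the torus
  half-width);
* spiking: $N_E = 500$ ($N_I = 125$), $N_F = 21$, 200 ms background +
  1000–1500 ms stimulation, $n_\mathrm{RF} = 3$ — the regime where stage-1
  analytic weights alone reproduce the target profile.

## What the generator does and does not emulate

All inputs are synthetic and fully specified by the model: unit or step
inputs to chosen sites, constant feedforward drives, Gaussian white
membrane noise. Passing tests therefore demonstrate internal consistency of
the implementation with the stated dynamics and tuning theory — they do not
certify behaviour on real neural recordings, non-exponential or
non-translation-invariant RFs (explicitly out of scope), nonlinear mixed
selectivity, or conductance-based synapses. Known limitations: the
$K_0$ RF form degrades for narrow 2D RFs; spiking networks tuned to
$n_\mathrm{RF} > 11$ need steps finer than 0.01 ms; and the low-pass
(rather than explicit-lag) inhibition variant is not implemented — the
explicit-lag model is the one analyzed by the delay-equation machinery.
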