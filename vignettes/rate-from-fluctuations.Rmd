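---
title: "Estimating instantaneous rates from membrane-potential fluctuations, and what it buys synaptic plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating instantaneous rates from membrane-potential fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctrate)
```

## The model

`fluctrate` studies a leaky integrate-and-fire (LIF) neuron embedded in a
loosely balanced network.  In Stein's model the membrane potential obeys

    tau du/dt = -u + tau * sum_k w_k * S_k(t),

where each synapse `k` delivers Poisson spike trains at rate `nu_k` and an
instantaneous jump `w_k` (mV).  Under loose balance the mean input cancels
(`sum w_k nu_k = 0`), so the neuron is *fluctuation driven*: only the input
variance `sum w_k^2 nu_k` matters.  In the high-input (synaptic bombardment)
limit the potential becomes an Ornstein–Uhlenbeck process (OUP)

    du = -u/tau dt + sigma/sqrt(tau) dW,   sigma = sqrt(bf * tau * sum w_k^2 nu_k),

with `bf = 2` for the mirrored excitatory/inhibitory construction.  Its
stationary law is N(0, sigma^2/2) and the stationary firing rate is the
inverse mean first-passage time from reset to threshold (Siegert's formula),
implemented by `siegert_rate()`:

    r(sigma) = 1 / ( tau * sqrt(pi) * Int_{u_r/sigma}^{theta/sigma}
                     exp(x^2) (1 + erf(x)) dx ).

Because excursions to threshold are rare events, the output spike train is
close to Poisson with rate `r(sigma)` (ISI coefficient of variation near 1),
which is the approximation under which all estimator theory below is exact.
`simulate_oup(with_reset = TRUE)` integrates the thresholded process and
quantifies the approximation error; by default simulation returns the free
process plus an independent Poisson train at `r(sigma)`.

### Voltage reference

All voltages are relative to the balanced resting level, which the zero-mean
input pins at the reset potential.  Absolute values quoted for cortical
neurons (threshold −55 mV, reset −70 mV) therefore enter as
`theta = 15 mV`, `u_reset = 0 mV` — the package default.  Using the absolute
values directly inside the first-passage integral is meaningless: the rate
then degenerates to a sigma-independent constant.  Note that the quantities
the package is really about (the minimal estimation window, the
improvement factor) are invariant under rescaling `theta` and `sigma`
together, so this convention affects operating sigmas but not conclusions.

## Rate estimators and their information content

Two local observables compete to reveal the neuron's instantaneous rate:

* **Spikes.** `estimate_rate_spikes()` returns `n/T`, the Poisson MLE.  Its
  variance is `r/T` (`spike_estimator_variance()`); information grows with
  observation time only.
* **Voltage.** The OUP transition density gives a closed-form MLE of sigma
  from samples taken every `epsilon` seconds
  (`estimate_sigma_voltage()`); by invariance `r(sigma_hat)` estimates the
  rate (`estimate_rate_voltage()`).  The Fisher variance is
  `sigma^2 eps/(2T) * (dr/dsigma)^2` (`voltage_estimator_variance()`):
  information grows with time *and* sampling rate.

The ratio of the two variances — the factor by which a stimulus may be
shorter when read from the voltage — is
`time_improvement_factor() = 2 r / (sigma^2 eps (dr/dsigma)^2)`, about 34 at
a 10 Hz operating point with 1 kHz sampling (and still 25 at 40 Hz).

Sampling faster than the synaptic arrival rate (~1–10 kHz in the bombardment
regime) would break the Gaussian-increment assumption, so 1 kHz is used
throughout as a conservative default.

Without balance the rate also depends on the mean depolarization, whose
estimation error decays only with `T/tau`;
`voltage_estimator_variance_unbalanced()` carries the extra term and shows
why the balanced state is what makes fast voltage decoding possible.

### Exactness, asymptotics, and where the formulas bend

For the free OUP the innovations are exactly Gaussian, so
`n * sigma_hat^2 / sigma^2` is chi-squared with `n` degrees of freedom — an
exact sampling law the tests use as an independent oracle.  The variance
formula above and everything downstream of it are first-order delta-method
statements, accurate only when the per-window information is substantial:

* at `n = 10` voltage samples (a 10 ms window at 1 kHz) the exact variance
  of `r(sigma_hat)` at the 10 Hz point is 10.4% *below* the delta-method
  value, and the estimator mean is 9.64 Hz, not 10;
* the spike-side BCM update involves `(n/T)^2`, whose exact Poisson moments
  exceed the delta-method variance by 46% at `r T = 5` expected spikes; the
  discrepancy decays like `1/(rT)`.

Tests therefore check small windows against exact-law oracles (enumeration
over the Poisson mass, chi-squared quadrature) and check the asymptotic
formulas in windows where their own premise holds (hundreds of expected
spikes; hundreds of voltage samples).

### Confidence windows

`spike_coverage()` computes `P(|n/T - r| <= a)` exactly from the Poisson
mass (the exact coverage is non-monotone in `T` because the admissible
count set changes discretely); `voltage_coverage()` uses the Gaussian
delta-method law.  At `r = 10 Hz` and ±5 Hz, spikes reach 70% confidence at
`T = 0.5 s` (coverage 0.742).  The voltage-based window solving the same
problem, `min_duration_voltage()`, is **12.7 ms** at 1 kHz sampling —
a ~34-fold improvement, consistent with the improvement factor.  This
quantity depends only on `(r, tau, epsilon)` and the coverage condition; it
is *not* adjustable through the threshold convention.

## Optimal SDP and VDP realizations of rate rules

A rate-based rule `Delta_w = f(r_pre, r_post)` is *realized* by a spiking
mechanism when the expected applied weight change equals `Delta_w`.  The
minimum-variance realization plugs the optimal rate estimate into `f`:
spike-count (`sdp_update()`) or voltage (`vdp_update()`).  Their
delta-method variances (`sdp_update_variance()`, `vdp_update_variance()`)
are the rate-estimator variances scaled by `(df/dr_post)^2`, so their ratio
is the improvement factor *independently of the rule* — checked in tests for
BCM against a plain Hebbian rule.

For BCM (`bcm_rule()`), `f = eta r_pre (r_post^2 - rbar r_post)` with a
sliding threshold `rbar` relaxing towards the squared postsynaptic rate with
time constant `tau_bcm` (`bcm_threshold_update()`).  Two readings of the
threshold update are possible under noise — squaring the round's rate
estimate, or estimating the square; the package squares the round's
estimate, which is the natural plug-in form of the recursion and requires no
extra machinery.  `tau_bcm` counts protocol rounds, matching the per-round
update of the learning protocol.

## The selectivity experiment

A feed-forward circuit: `N` excitatory input channels with weights `w_k`,
each mirrored by an inhibitory twin so the input stays balanced for every
stimulus.  A stimulus is a rate vector over channels; `selectivity()`
implements

    Sel(w) = 1 - E_P[ r(sigma_j) ] / max_j r(sigma_j),

with responses below `rate_floor = 1 Hz` rounded to zero and the convention
0/0 = 1 (so an entirely silent neuron scores 0, and the maximum over m
equiprobable stimuli is `1 - 1/m`).  The floor applies only inside the
metric, not to the learning dynamics, since it exists to make the metric
non-trivial rather than to model a mechanism.

### Input channels are populations

The printed task parameters (two channels at 10 Hz, weights 0.8 mV) would
put a literal two-synapse neuron at `sigma ≈ 0.5 mV` against a 15 mV
threshold — astronomically silent, and no learning could ever start.  The
package therefore treats each input channel as a population of `n_syn`
statistically independent afferents sharing the channel's rate and weight
(default `n_syn = 1000`, the canonical high-input count, giving ~10 kHz
total arrival rate).  This scales `sigma` by `sqrt(n_syn)`, places the
initial network at ~14 Hz output, and the selective fixed point at channel
weights of ~0.5 mV — the regime in which the task is well posed.  The
channel weight, not the per-afferent weight, is what the protocol adapts
and reports.

### Protocol and its dynamics

`run_protocol()` repeats: draw a stimulus, simulate the output for `T`
seconds (Poisson count for SDP, free-OUP trace for VDP — consistent with
the estimator derivations), apply the per-channel update scaled by the
channel's stimulus rate (both realizations are linear in the presynaptic
rate; a spike-count presynaptic estimate is available via `presyn_mode`),
relax the sliding threshold, and clip weights at zero (excitatory
synapses; disable with `clip_weights = FALSE`).  `realization = "exact"`
iterates the noise-free rule as a reference.

Initialization choices the task description leaves open: the sliding
threshold starts at 5 Hz-scale (mid-range of the stimuli); Gaussian
stimulus centres are evenly spaced with no wraparound, so edge profiles are
truncated.

The dynamics pass through a characteristic transient: the threshold first
chases the (high) initial squared rate, depressing all channels, after
which noise breaks the symmetric state — which is unstable — and one
channel settles where its response equals the threshold (2 Hz for two
equiprobable orthogonal stimuli) while the others fall below the floor.
Symmetry breaking is noise-seeded and slow at `eta = 1e-6`: the orthogonal
task converges reliably within ~60k rounds for the voltage realization.
Experiments therefore default to 150k rounds (orthogonal) and 120k rounds
(Gaussian-profile) — round counts are an exposed parameter, not a printed
constant of the task.  At a 10 ms window the spike realization sees on
average 0.02–0.14 spikes per presentation; single lucky spikes produce
~0.1 mV weight jumps and threshold surges, so the network repeatedly
escapes the selective state — the instability the task is designed to
exhibit.  Matching performance requires the spike realization to observe
each stimulus for ~500 ms, an order of magnitude more total exposure than
the voltage realization needs at 10 ms.

## Numerical choices

* **Quadrature.** The first-passage integrand `exp(x^2)(1+erf(x))` is
  evaluated as `erfcx(-x)` (scaled complementary error function);
  `exp(x^2)` alone overflows past `x ≈ 26.6`.  Adaptive quadrature at
  relative tolerance 1e-10; beyond `theta/sigma = 26` the rate underflows
  double precision and 0 is returned.
* **Derivative.** `dr/dsigma` comes from differentiating the integral at
  its endpoints (Leibniz), exact to quadrature tolerance; tests cross-check
  against step-halved central differences.
* **Inversion.** `sigma_for_rate()` brackets and bisects the monotone map
  (`uniroot`), polishing to 1e-6 relative.
* **Interpolation.** The learning protocol evaluates the rate map tens of
  thousands of times, so it uses a monotone (Hyman) spline of
  `log r(sigma)` (`siegert_rate_fun()`), accurate to < 1e-5 relative, with
  quadrature fallback above the tabulated range and exact zero deep below
  threshold.
* **Trace generation.** Free traces use the exact AR(1) transition of the
  OUP — no Euler bias at any step size; initial conditions are stationary.
* **Reset simulation.** The thresholded OUP integrates on an internal grid
  (`tau/400` by default) and applies the Broadie–Glasserman continuity
  correction (barrier lowered by `0.5826 sigma sqrt(dt/tau)`), without
  which discretely monitored crossings underestimate the rate by ~5% at the
  default step.
* **Degenerate inputs.** `theta <= u_reset` is rejected; `sigma <= 0` is a
  domain error for the rate map, while the interpolator returns 0 at
  `sigma = 0` (silent network); constant traces give the closed-form
  `sigma_hat = |c| sqrt(2(1-a)/(1+a))`; an all-silent stimulus set scores
  selectivity 0 through the 0/0 convention.

## What the generator does and does not emulate

All data are synthetic by design: Poisson afferents, exact OUP traces, the
mirrored-balance construction.  Passing tests show internal consistency of
the theory and its realizations under the stated assumptions — they do not
speak to conductance-based synapses, dendritic filtering of the somatic
potential, refractory effects, correlated afferents, or imperfect balance
(the unbalanced variance formula quantifies the cost of the last).  Spike
generation in the protocol uses the Poisson approximation rather than
explicit threshold crossings; `with_reset` simulation exists precisely to
measure that gap (sub-percent in rate at the operating points used here).

## Problem sizes

Monte-Carlo sizes used by the shipped tests: 10^4 replicates for coverage
and update-variance checks (SDP window 400 s, VDP window 10 s — windows
chosen so the delta-method premise holds, see above), 300–500 replicates
per grid point for scaling-law regressions, 150k/120k protocol rounds for
the learning runs.  The acceptance script solves the minimal-window
quantity analytically and confirms it with 10^4 simulated traces.
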