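---
title: "A presynaptic-variance plasticity rule and population decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A presynaptic-variance plasticity rule and population decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presynvar)
```

## The model

`presynvar` simulates a feedforward circuit of primary visual cortex: one
postsynaptic point neuron receiving excitatory input from $N$
orientation-tuned presynaptic neurons and from a single untuned inhibitory
source.  The question the model addresses is how synaptic weights that
correlate with *presynaptic selectivity* — rather than with the similarity
of pre- and postsynaptic tuning, as classic Hebbian reasoning would have
it — can arise from plasticity, what postsynaptic selectivity they produce,
and how well a neuron that reads its inputs through such weights can decode
the presented stimulus.

### Input population

Each input neuron $i$ has a von Mises tuning curve over stimulus
orientation $\theta$ (period $\pi$):

$$r_i(\theta) = r_{ref}\,
  \frac{e^{\kappa_i \cos 2(\theta - \theta_i^P)}}{2\pi I_0(\kappa_i)},$$

with preferred orientation $\theta_i^P$, width (concentration) $\kappa_i$,
and reference rate $r_{ref} = 125$ Hz.  The normalization is chosen so the
*mean* rate over a uniform stimulus ensemble is $r_{ref}/2\pi \approx
19.9$ Hz for every $\kappa$: width changes how variable a neuron's response
is, not how active it is on average.  This property is what makes the
plasticity rule below selective for tuning sharpness.

Orientations live on a period-$\pi$ circle.  We fix the canonical
representative range to the half-open interval $[-\pi/2, \pi/2)$, so each
orientation has exactly one representative ($\pm\pi/2$ are the same
stimulus); signed orientation differences are wrapped into
$(-\pi/2, \pi/2]$.

### Output neuron

The postsynaptic rate $y$ relaxes with time constant $\tau_y = 1$ ms toward
a rectified-linear drive,

$$\tau_y \frac{dy}{dt} = -y +
  \alpha\Big[w_{ref}\textstyle\sum_i w_i r_i(\theta) + w_I r_I\Big]_+ ,$$

with $\alpha = 0.1\,\mathrm{nA}^{-1}$, $w_{ref} = 16$ nA, inhibitory weight
$w_I = -1.7$ nA and inhibitory rate $r_I = 100$ Hz.  We store $w_I$ in nA
so every term in the bracket carries uniform nA·Hz units.  The rectification
sits inside the bracket, and the integrated rate is additionally clamped at
zero.

### Plasticity rules

The excitatory weights are plastic.  The central rule is the **variance
rule**, in which potentiation depends only on the squared deviation of the
presynaptic normalized rate from its ensemble mean $\mu = 1/2\pi$:

$$\frac{dw_i}{dt} = \eta_1\left(\frac{r_i(\theta)}{r_{ref}} - \mu\right)^2
  - \eta_0 w_i,$$

with $\eta_1 = 0.1$ and $\eta_0 = 0.03$, which we interpret as rates per
second: with stimuli lasting $T = 0.2$ s, $\eta_0 = 0.03/\mathrm{s}$ gives a
weight relaxation time of ${\sim}33$ s, slow compared to a single stimulus
and fast compared to the 200 s protocol, which is what produces the visible
convergence over the stimulation run.  The drift at $w = 0$ is nonnegative,
so weights started nonnegative stay so without clipping.

The control is a classic Hebbian **covariance rule**,

$$\frac{dw_i}{dt} = \eta_1\left(\frac{r_i}{r_{ref}} - \gamma\right)
  \left(\frac{y}{r_{ref}} - \gamma\right) - \eta_0 w_i,
  \qquad \gamma = 0.24,$$

whose drift can be negative at $w = 0$; since the circuit's inputs are
excitatory, covariance-rule weights are floored at zero (a modelling choice
we document rather than one the rule itself implies).

### Equilibrium-weight theory

Averaging the variance rule's per-stimulus fixed point
$w^\ast(r) = (\eta_1/\eta_0)(r/r_{ref} - \mu)^2$ over a uniform stimulus
ensemble yields a closed form used throughout the package as an analytic
oracle:

$$E[W_i] = \frac{\eta_1}{\eta_0}\,\frac{1}{4\pi^2}
  \left(\frac{I_0(2\kappa_i)}{I_0^2(\kappa_i)} - 1\right),$$

i.e. $(\eta_1/\eta_0)$ times the variance of the normalized rate.  It
vanishes at $\kappa = 0$ and increases strictly with $\kappa$ — the rule
converts tuning sharpness into synaptic strength:

```{r}
equilibrium_weight(c(0, 0.25, 0.5, 1))
```

The test suite checks this curve two independent ways: by Monte-Carlo
averaging of `stationary_weight_for_rate()` over random stimuli, and by
comparing $\kappa$-binned converged weights of full simulations against it.

## The stimulation protocol

A run consists of a 200 s warm-up in which every input fires at 20 Hz with
plasticity active — parking all weights at the analytic fixed point
$(\eta_1/\eta_0)(20/125 - 1/2\pi)^2 \approx 2.4\times10^{-6}$ — followed by
1000 stimuli, each a fresh orientation drawn uniformly and shown to the
whole population for $T = 200$ ms.  Defaults are $N = 50$ inputs with
$\kappa_i \sim U(0, 1]$ and $\theta_i^P$ uniform; a wrapped-normal PO
variant (mean 0, sd $\pi/8$) models a biased input ensemble.  Ensembles of
independent runs derive one seed per run from a base seed
(`derive_run_seeds()`), so runs are reproducible and order-independent.

Two decisions the protocol leaves open in principle are fixed as follows:

* **Initial weights** default to 0.  Because the warm-up drives every weight
  to ${\sim}2.4\times10^{-6}$ regardless of its start, the results are
  insensitive to initialization; a uniform $U(0, 0.05)$ option exists and
  converges to the same state.
* **The output rate is integrated continuously** across stimulus
  boundaries, never reset.  Since $\tau_y \ll T$ this is indistinguishable
  from a reset after the first millisecond of each stimulus.

### Integration modes

Because $\tau_y = 1\,\mathrm{ms} \ll T = 200$ ms, the output rate is
effectively always at its fixed point, and during one stimulus the variance
rule is a linear ODE with constant coefficients.  The default `"fast"` mode
exploits both facts: one steady-state evaluation of $y$ and one *exact*
exponential relaxation of each weight per stimulus (the warm-up is chunked
into $T$-length segments so the covariance rule can track the evolving
postsynaptic rate; for the variance rule the chunking is exact).  The
`"euler"` mode integrates both equations by forward Euler at
$dt = 1$ ms.  The modes are required to agree: at default parameters the
final weights match to well under 2% per synapse (the variance rule to
${\sim}10^{-6}$ relative; the covariance rule to ${\sim}1\%$, the residual
coming from the within-stimulus evolution of $y$ that fast mode freezes at
the stimulus onset).

## Analysis conventions

**Tuning estimation.**  Preferred orientation and selectivity are the angle
(halved) and length of the circular resultant
$R = \sum_\theta c(\theta) e^{2i\theta} / \sum_\theta c(\theta)$ of a
binned tuning curve — 20 bins over the orientation range, built from the
last 500 stimuli of a run.  Empty bins are excluded from the sums rather
than zero-filled, which would bias the resultant.  A flat curve has
selectivity 0 and an *undefined* PO, reported as `NA`, never silently as 0.
A small fraction of default-parameter runs ends with a postsynaptic neuron
whose rectified drive never crosses threshold in the analysis window; such
silent outputs have no defined tuning, and ensemble analyses skip those
runs and report how many were skipped.

**Active inputs.**  For each stimulus, an input counts as active when its
rate strictly exceeds $\beta = r_{ref}/2\pi$, the width-independent mean
rate (multipliers 0.5 and 1.5 probe robustness).  "Strictly" matters only
for a flat input, whose rate equals $\beta$ identically; we read "above
threshold" as excluding the boundary.  The total excitatory current
$w_{ref}\sum_i w_i r_i$ is reported without the inhibitory term by default
(a flag adds it), and all three curves — active count, mean active weight,
total current — are binned by the wrapped difference between the stimulus
and the run's estimated postsynaptic PO, so curves from runs with
heterogeneous POs align at 0 before averaging.

**Weighted-sum PO estimate.**  The postsynaptic preference can be predicted
by summing the presynaptic tuning curves weighted by their synaptic
weights; overrides that set all weights and/or all widths to 1 isolate the
contributions of PO geometry, selectivity and weight to the prediction.

## Decoding

A weighted population decoder estimates the stimulus as half the
four-quadrant angle of the response-weighted resultant of doubled preferred
orientations:

$$\hat\theta = \tfrac{1}{2}\,\mathrm{atan2}\!\left(
  \sum_i p_i w_i \sin 2\theta_i^P,\ \sum_i p_i w_i \cos 2\theta_i^P\right).$$

With $w_i = \kappa_i$ this is the maximum-likelihood estimator for
independent Poisson responses with von Mises tuning; for a homogeneous,
equally spaced, noiseless population it is exact to machine precision (the
aliasing harmonics are $I_{M\pm1}(\kappa)$-suppressed).  The two-argument
arctangent resolves the $\pi/2$ ambiguity of the printed ratio form.  A
zero resultant (e.g. two equal masses at orthogonal orientations) leaves
the estimate undefined; such trials are excluded from the statistics and
counted.

Five weight schemes are compared: the learned variance-rule weights, the
ML weights $\kappa_i$, uniform weights, the variance-rule weights shuffled
(decoupling weight from $\kappa$), and the learned covariance-rule weights.
Response noise is Poisson by default; two variants add per-neuron tuning
jitter ($\sigma_i \sim N(0, \pi/50)$, drawn once per run and fixed across
trials, with Poisson sampling around the jittered rates) or replace Poisson
with additive Gaussian rate noise (sd 5 Hz, negative values used as-is
since the decoder accepts any reals; a floor option exists).

Performance is evaluated on 20 orientations equally spaced over the period
(endpoint excluded — $\pm\pi/2$ are one stimulus), 100 trials each.  With
wrapped deviations $d_t = \hat\theta_t \ominus \theta$, the per-orientation
bias is $\langle d \rangle$, the variance
$\langle (d - \langle d\rangle)^2 \rangle$, and the error their sum —
an identity that holds exactly in the implementation.  Deviations must be
wrapped: near the range boundary an unwrapped difference would register a
spurious error of ${\sim}\pi$.  Per run, $|{\rm bias}|$, variance and error
are averaged across orientations.

With $N = 50$ heterogeneous inputs the error is dominated by a
population-specific systematic bias (the zeroth circular harmonic of the
weighted PO ensemble does not cancel in a finite sample), so decoders are
compared as ensemble means over many independent populations.  The learned
variance-rule weights track the ML decoder closely and beat the uniform,
shuffled and covariance controls under all three noise models — but the
equilibrium weights grow faster than linearly in $\kappa$, i.e. steeper
than the ML weighting, so the variance-rule error sits slightly (on the
order of 10–20%) above the ML error rather than exactly at it.  Similarly,
because the estimated postsynaptic PO is itself pulled toward the
high-$\kappa$, strong-weight inputs, the pooled weight-vs-$|\Delta PO|$
correlation under the variance rule is not exactly zero but slightly
negative, even though the rule ignores the postsynaptic neuron entirely.
Both quantities are recomputed from scratch by `scripts/acceptance.R`.

## What the generator does and does not emulate

All data are synthetic and generated by the package itself under the study
conditions above; there is no external input format.  The generator
emulates a diverse, statistically independent input ensemble with exact von
Mises tuning, stationary widths, and stimulus-conditionally deterministic
(plasticity) or Poisson/Gaussian (decoding) responses.  It does not emulate
trial-to-trial correlations between inputs, contrast or adaptation effects,
direction (as opposed to orientation) selectivity, dendritic
nonlinearities, or plastic inhibition — so passing tests demonstrate the
internal consistency of the model and its theory, not properties of
biological recordings.

## Problem sizes and numerical choices

The shipped test suite and acceptance script run the full default protocol
(200 s warm-up, 1000 stimuli) but scale ensemble counts to desk size: 10
plasticity runs for the weight-theory, distribution and circuit analyses,
20 independent populations for the decoder benchmark, 3 runs for the
multi-contact experiment, and one full Euler-mode run for the
integration-mode check.  Other fixed numerical choices:

* weight–theory agreement is assessed on $\kappa$-binned means (10 bins)
  for $\kappa > 0.3$, where the equilibrium weights are large enough for a
  relative band to be meaningful;
* the pooled weight distribution is compared with the push-forward of
  $\kappa \sim U(0,1]$ through the equilibrium curve by a two-sample
  Kolmogorov–Smirnov statistic with a fixed acceptance band of 0.15,
  sized a priori for the ${\sim}8\%$ multiplicative end-of-run weight
  jitter around equilibrium plus the $n = 500$ sampling noise;
* undefined quantities (PO of a flat curve, decoder estimate at a zero
  resultant, correlation of a constant series) are propagated as `NA` or
  errors, never coerced to numbers.

## Limitations

The model is deliberately minimal: a single feedforward layer, rate-based
units, fixed inhibition, and weights whose equilibrium depends only on
presynaptic statistics.  Under the variance rule the converged weight of a
given input is essentially deterministic given its $\kappa$, so the model
cannot produce weight diversity among equally selective inputs; and the
covariance-rule control inherits the zero-floor choice discussed above,
which the rule's original form does not specify.
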