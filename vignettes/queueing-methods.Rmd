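---
title: "Queueing models behind cadtqueue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Queueing models behind cadtqueue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadtqueue)
```

## The question the package answers

Computer-aided triage and notification (CADt) devices flag radiological
images with suspected time-critical findings (large vessel occlusion,
intracranial hemorrhage, pneumothorax, ...) so that radiologists read
them earlier. Regulatory and purchasing decisions need a number: *how
many minutes sooner is a truly diseased image read once the device is
in the workflow?* cadtqueue computes that number from a queueing model
of the reading room, and ships a paired discrete-event simulator to
verify the theory and attach confidence intervals.

The reading room is modelled as a multi-class priority queue.
Radiologists are servers; patient images are customers arriving as a
Poisson stream at rate $\lambda$. A fraction $f$ are *interrupting*
cases that outrank everything. The remaining images carry a disease
with prevalence $\pi$; a CADt with sensitivity $Se$ and specificity
$Sp$ splits the non-interrupting stream $\lambda_{nonf} = (1-f)\lambda$
into an AI-positive class with arrival rate
$\lambda_+ = [\pi\,Se + (1-\pi)(1-Sp)]\,\lambda_{nonf}$ and an
AI-negative class with the complementary rate. Reads are exponential with rates $\mu_f$,
$\mu_D$, $\mu_{ND}$; class-level rates mix $\mu_D$ and $\mu_{ND}$
through the predictive values (PPV for the AI-positive class, NPV for
the AI-negative class). The discipline is preemptive-resume: a
higher-priority arrival interrupts a lower-priority read immediately,
and the interrupted read later resumes where it stopped.

The headline metric is
$$\delta W_D = W_D^{CADt} - W_D^{no\,CADt}, \qquad
  W_D^{CADt} = W_+\,Se + W_-\,(1-Se),$$
the signed change in the mean queue wait of a diseased image; negative
values are savings. The non-diseased counterpart weighs the classes by
$(1-Sp, Sp)$.

## Two workflow models

* **Model 1** ($\mu_D = \mu_{ND}$): all non-interrupting classes read at
  the same rate. One or two radiologists are handled analytically; the
  simulator covers larger teams.
* **Model 2** ($\mu_D \ne \mu_{ND}$, one radiologist): the state must
  remember whether the image currently (or previously, if preempted) in
  service is diseased, because that choice fixes the service rate. The
  chains therefore carry the in-service disease status as a phase, and
  truncated states are duplicated into "resume diseased" / "resume
  non-diseased" copies so a preempted read resumes with the right rate.

Model selection is automatic in `compute_waits()`: equal read times use
Model 1, unequal ones Model 2 (with a clear error for unsupported
staffing).

## Solution method

Each class's chain is level-structured in the class count and solved by
the matrix-geometric method: the rate matrix $R$ solves
$A_0 + R A_1 + R^2 A_2 = 0$ (successive substitution, tolerance
$10^{-12}$, iteration cap $10^6$), boundary levels are solved as a
linear system, the tail is geometric, and the mean class count
$L = \sum_l l\,\pi_l \mathbf 1$ is evaluated in closed form through
$(I-R)^{-1}$ powers — no truncation. Little's law converts $L$ to the
mean queue wait $W_q = L/\lambda_j - 1/\mu_j$.

Higher-priority work enters a class's chain only through *busy periods*
— intervals when no radiologist is free for the tagged class. Recursive
dimensionality reduction replaces each busy period with an
Erlang–Coxian phase-type distribution matched to its first three
moments:

* single-server interrupting busy periods have the M/M/1 closed form
  $m_1 = 1/(\mu(1-\rho))$, $m_2 = 2/(\mu^2(1-\rho)^3)$,
  $m_3 = 6(1+\rho)/(\mu^3(1-\rho)^5)$;
* the aggregated (interrupting + AI-positive) busy periods seen by the
  single-server AI-negative class are Takács-type M/G/1 delay busy
  periods with hyperexponential services, in closed form;
* with two radiologists, the AI-negative class is blocked whenever
  $n_f + n_+ \ge 2$; the six conditional busy periods (start states
  (0,2), (1,1), (2,0); end states (0,1), (1,0)) get their end
  probabilities and conditional moments from first-passage linear
  systems on the truncated high-priority sub-chain. The truncation
  depth is chosen so the geometric excursion mass beyond the cut is
  below $10^{-13}$ (between 30 and 400 levels per dimension), and every
  computed moment set is cross-checked against Monte-Carlo passage
  sampling in the test suite.

A busy period with conditional probability below $10^{-12}$ is dropped
and its mass moved to the sibling end state, so degenerate moment sets
are never fitted.

### Why three moments are enough for the means

Matching three moments does not reproduce a busy-period *distribution*,
but for every single-radiologist chain in the package the stationary
mean wait depends on the interruption law only through its first two
moments (a delay-cycle argument), so the fitted chain returns the mean
wait of the true system to solver precision. The test suite exploits
this: the Model-1 single-server waits are required to match the
two-class preemptive-resume closed forms to $10^{-6}$, Model 2 without
interruptions must match Pollaczek–Khinchine with hyperexponential
service, and the two-radiologist chains must match Erlang-C when the
priority classes empty. With two radiologists and a full class mix the
reduction is a genuine approximation; there the requirement is
agreement with the paired simulator at 95% confidence.

### The Erlang–Coxian fit

`fit_coxian2()` solves the two-phase Coxian moment equations in closed
form (a quadratic in the first phase's mean); the region where that fit
is valid — squared coefficient of variation at least 1/2 with a
compatible third moment — is exactly the region test of
`needs_erlang_stage()`. Outside it, `fit_ec()` prepends the smallest
number of identical-rate Erlang stages whose deconvolved residual
admits a valid Coxian-2 fit, picking the Erlang rate deterministically
from the middle of the feasible interval; exact Erlang targets, which
sit on a single feasible point, are recognized directly. Because the
convolution identities are exact, any feasible choice round-trips the
target moments to machine precision, which the suite checks on 1000
random triples at $10^{-8}$. Probabilities violating $[0,1]$ by more
than $10^{-12}$, or moment triples below the nonnegative-distribution
bounds ($m_2 \ge m_1^2$, $m_1 m_3 \ge m_2^2$), raise errors rather than
being projected.

## Degenerate operating points and numerical conventions

At $Se = 0$ (or $Sp = 0$) one AI class is empty. Its wait is defined as
0 and its weight in $\delta W_D$ is also 0, so the metrics stay
well-defined at the ROC corners, where the computed saving is exactly
zero. Stability is pre-checked per chain (aggregate utilization below
$1 - 10^{-9}$) and again through the drift condition and the spectral
radius of $R$; stationary probabilities below $-10^{-12}$ are clipped,
larger violations raise. The traffic intensity maps to the arrival
rate through the arrival-fraction-weighted mean read time, $1/\mu_{eff}
= f/\mu_f + (1-f)(\pi/\mu_D + (1-\pi)/\mu_{ND})$; this reproduces the
standard busy-clinic benchmark (10-minute reads, $\rho = 0.8$,
$\lambda = 0.08$/min) and is the package's reading of a definition the
notation leaves open when read rates differ across classes.

## The simulator: what it emulates and what it does not

`simulate_run()` draws one arrival stream (Poisson), one class
assignment per image (Bernoulli thinning by $f$, $\pi$, then $Se$ or
$1-Sp$), and one exponential read duration per image, then plays the
identical stream through both worlds. Preemption stores remaining work
and resumes it, so the paired worlds share every duration bit for bit
and the wait difference per image is purely the device's re-ordering.
With several radiologists an arriving higher-priority image displaces
the most-recently-arrived job of the lowest busy priority — under
exponential reads any displacement rule gives the same law; this one is
fixed for reproducibility. One root seed spawns per-run child seeds
(`seed + run`), so the first runs of a batch do not change when more
runs are requested.

A protocol-size batch is 200 runs of roughly 2000 patients; the tests
and the bundled checks run reduced sizes (20–50 runs of 150–1000
patients) chosen so Monte-Carlo error, not bias, dominates. Because
runs start from an empty reading list, short runs bias absolute waits
slightly low at high load — the paired difference cancels most of this,
and `burn_in` can discard early images (default 0, matching the
protocol). Two 95% intervals are reported and labelled: the 2.5/97.5
percentiles of per-run mean deltas, and the normal-theory interval of
the grand mean; the protocol's histogram description does not pin down
one choice, so both are emitted and the percentile interval is used in
checks.

The simulator deliberately omits features of real reading rooms:
non-exponential read times, reader fatigue or backlog-dependent speed,
batching, shift changes, and multiple concurrent CADt devices. Passing
tests therefore demonstrate internal consistency of theory and
simulation under the stated stochastic assumptions, not calibration to
any clinic's data.

## The ROC summary

`delta_map()` re-evaluates the pipeline at every grid point with
$Se = TPR$, $Sp = 1 - FPR$; cells are independent, and unstable cells
are flagged rather than fatal. `delta_along_curve()` profiles
$\delta W_D$ along any monotone curve; the bundled `binormal_curve()`
is a generic smooth family for illustration, not a canonical CADt
curve. `stroke_outcome_scaling()` converts savings to the fraction of
stroke patients with less disability via the linear rule 3.9% per 15
minutes, clamped at zero for delays — an extrapolation of a reported
clinical association, not a patient-level outcome model.

```{r headline}
cfg <- workflow_config(prevalence = 0.1, se = 0.95, sp = 0.89,
                       f = 0, n_rad = 1, read_time_diseased = 10,
                       read_time_nondiseased = 10, rho = 0.8)
evaluate_cadt(cfg)[, c("w_d_no_cadt", "w_d_cadt", "delta_w_d",
                       "delta_w_nd")]
```

In this busy single-radiologist clinic the typical cleared device
(Se 95%, Sp 89%) moves the mean diseased wait from 40 minutes to about
4.2 minutes — a saving of roughly 36 minutes — while delaying the
non-diseased majority by about 4 minutes on average.

## Known limitations

* Model 2 is restricted to one radiologist; Model 1 to two for the
  analytic chains (the simulator has no such limit but larger teams
  dilute the device's benefit anyway).
* Only mean waits are computed theoretically; distributional
  quantities come from simulation.
* Interrupting-class waits are not reported: preemptive interrupting
  cases are unaffected by the device.
* The within-class read-rate split by AI correctness (TP vs FP) is not
  modelled; both share the disease-level rate.
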