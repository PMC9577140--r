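---
title: "Continuous assessment of AV-nodal conduction during AF: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous assessment of AV-nodal conduction during AF: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avnodetrend)
```

## The problem

During atrial fibrillation (AF) the atria bombard the atrioventricular (AV)
node with rapid, irregular impulses; the node's refractoriness and
conduction delay determine which impulses reach the ventricles and hence the
ventricular rhythm seen as RR intervals on the ECG. Rate-control drugs
(beta-blockers, calcium-channel blockers) act on exactly these properties.
`avnodetrend` estimates the AV node's refractory-period and conduction-delay
parameters continuously over 24-hour recordings, from nothing more than the
RR-interval series and an atrial fibrillatory rate (AFR) trend, and then
quantifies circadian variation of the estimates at the population level.

## The dual-pathway network model

The AV node is modelled as 21 nodes: two parallel chains of ten (a fast
pathway, FP, and a slow pathway, SP) converging on a single coupling node.
Every atrial impulse — drawn from a homogeneous Poisson process with rate
$\lambda$ (Hz), the AFR-derived atrial rate — enters the first node of both
chains simultaneously. A node that receives an impulse while refractory
blocks it; otherwise it forwards the impulse after a conduction delay and
becomes refractory. Both quantities depend on the diastolic interval
$\tilde t$ (recovery time since the end of the node's previous refractory
period):

$$R(\tilde t) = R_\min + \Delta R\,(1 - e^{-\tilde t/\tau_R}), \qquad
  D(\tilde t) = D_\min + \Delta D\,e^{-\tilde t/\tau_D},$$

with $\tilde t = t - t_\text{last} - R_\text{last}$; a negative $\tilde t$
means the impulse is blocked. The six constants are shared by all nodes of
a pathway, giving the 12-parameter vector
$\theta = (R_\min^{FP}, \Delta R^{FP}, \tau_R^{FP}, R_\min^{SP}, \Delta
R^{SP}, \tau_R^{SP}, D_\min^{FP}, \Delta D^{FP}, \tau_D^{FP}, D_\min^{SP},
\Delta D^{SP}, \tau_D^{SP})$, all in milliseconds. The coupling node has a
fixed 60 ms delay and a fixed refractory period equal to `RR_min`, the mean
of the ten shortest RR intervals of the data being fitted; each of its
conductions is one ventricular activation, so every simulated RR interval
is bounded below by `RR_min`.

Search bounds (also the ranges $r(p)$ used for weighting): $R_\min \in
[150, 650]$, $\Delta R \in [0, 700]$, $\tau_R \in [40, 300]$, $D_\min \in
[0, 30]$, $\Delta D \in [0, 75]$, $\tau_D \in [40, 300]$ ms. They imply a
maximal single-node refractory period of 1350 ms and a maximal whole-pathway
delay of $10 \times 105 = 1050$ ms, generous envelopes around reported AV
effective refractory periods and PR intervals.

Implementation notes:

* The engine is event-driven (C++, a single time-ordered priority queue);
  ties are broken by (time, FP before SP before coupling, node index) for
  reproducibility. The simulation is a pure function of $(\theta,$ impulse
  train, `RR_min`$)$.
* Topology is a forward chain per pathway. Retrograde and cross-pathway
  conduction are not modelled, so phenomena such as AV-nodal re-entry are
  out of scope.
* Initialization: all nodes start "never activated"; the first impulse is
  treated as arriving after full recovery (delay $D_\min$, refractory
  $R_\min + \Delta R$ issued). Refractoriness is anchored to the last
  *conducted* impulse: blocked impulses leave the node state unchanged.
* The first ventricular activation has no preceding beat; RR intervals
  start at the second.

## Preprocessing

RR series come with per-beat quality flags (beats adjacent to
morphologically deviant QRS complexes); both intervals touching a flagged
beat are removed. Minute windows (aligned to recording start) with fewer
than 20 beats are excised, since they indicate missed detections.
Recordings qualify for circadian analysis only with at least 12 h of
retained data spanning at least 20 h.

The AFR trend (one sample per minute) is mapped to the atrial rate by
$\lambda = \text{AFR}/(1 - \text{AFR} \cdot t_{dep})$, with atrial
depolarization time $t_{dep}$ defaulting to 0 (identity) because no
citable value of $t_{dep}$ is available; the hook is configurable. Outlying
minutes — more than 5 median absolute deviations from a 31-minute rolling
median — are dropped (an automated, reproducible surrogate for manual
screening), and the trend is smoothed with a normalized triangular window of
70 one-minute samples, renormalized over available samples at edges and
gaps.

Estimation segments are windows of exactly $N = 1000$ consecutive retained
RR intervals. The number of windows is `round(retained duration / 108 s)` —
800 for a gap-free 24-hour recording — and their start indices are spread
evenly over the retained interval sequence, so the nominal 108-s stride
adapts locally at gaps and at the recording end and every retained interval
is covered. Each segment carries its mean conditioned $\lambda$, its
`RR_min`, and the clock time of its first interval.

## Fitness: binned Poincare histograms

Because the atrial input is stochastic, beat-to-beat agreement is not a
meaningful objective; model and data are compared at the distribution level
instead. Successive RR pairs $(RR_k, RR_{k+1})$ are binned on a fixed
$32 \times 32$ grid (50 ms bins centered at 250–1800 ms; a pair with either
member outside $[225, 1825)$ ms is dropped, not clamped). The error of a
simulation of $N_{sim}$ intervals with counts $\tilde x_k$ against a data
segment of $N$ intervals with counts $x_k$ is

$$\epsilon = \frac{1}{K} \sum_k
  \frac{(x_k - \tfrac{N}{N_{sim}}\tilde x_k)^2}{\tfrac{N}{N_{sim}}\tilde x_k}.$$

Zero handling: bins empty in both histograms contribute nothing; bins where
the simulation is empty but the data are not use a pseudo-count
$\tilde x_k \leftarrow 0.5$ before scaling, keeping the surface finite and
smooth. The normalization constant $K$ is the per-axis bin count (32). This
is a deliberate convention: with it, a simulation drawn from the generating
process scores $\epsilon \approx 10{-}20$ on $N = 1000$ segments, the
non-stationarity thresholds below (800/2000) are reachable by realistic
regime changes, and the variance contributions of influential parameters
exceed the realization noise so that the uncertainty measure below stays
finite. Normalizing by the full grid size (1024) instead would shrink all
three scales by the same factor but put the fixed thresholds out of reach of
any physiologic RR series.

## Tracking: a problem-specific genetic algorithm

$\theta$ varies over time, making this a dynamic optimization problem. The
estimator keeps one population (default 400 individuals) alive across the
sliding segments, so slow drift is tracked at one generation per segment,
while a data-driven heuristic raises the effort when the series changes
fast: the Poincare difference

$$\Delta P(i) = \frac{1}{K}\sum_k \left(x_k^{(i)} - x_k^{(i+1000)}\right)^2$$

compares two 2000-interval windows offset by 1000 intervals. Segments run 1
generation when $\Delta P < 800$, 2 when $800 \le \Delta P < 2000$, 3 when
$\Delta P \ge 2000$. Since the two windows always share 1000 intervals,
stationary stretches score well below the first threshold (tens to low
hundreds) while abrupt regime switches exceed the second.

Per generation: tournament selection (size 4), two-point crossover
(probability 0.9), creep mutation (per-gene probability 0.3, uniform step
within $\pm 5\%$ of the range, clipped to bounds), one elite copied
unchanged, and every individual evaluated by simulating $N_{sim} = 1500$ RR
intervals at the segment's $\lambda$ and `RR_min`. The ten fittest are then
re-evaluated at $N_{sim} = 5000$ and the best becomes the segment estimate
$\hat\theta(i)$. Tournament size, crossover and mutation settings are the
package's own (configurable) choices of standard operator parameters.

At the start of every segment, immigrants replace the lowest-fitness
members to preserve diversity: their share ramps linearly with $\Delta P$
from 10% at 0 to 70% at $\ge 2000$, drawn in equal parts from (1) the
previous segment's ten fittest, re-scored against the new segment's
histogram from their stored simulated output (no re-simulation), (2) the
best individuals of eight fast helper GAs (16 individuals,
$N_{sim} = 750$) run on the new segment, and (3) fresh Latin hypercube
samples; shortfalls fall back to random samples. The population is
initialized by Latin hypercube sampling within the bounds, and the first
segment of a recording runs `init_generations` (default 10) generations —
a burn-in, since tracking effort assumes a converged predecessor
population. Every evaluation uses a fresh impulse-train seed derived from
the configuration's master seed, so a full run is reproducible end to end.

## Parameter uncertainty

Each estimate gets a local, variance-based uncertainty. Two $30 \times 12$
Latin hypercube matrices $A, B$ are sampled in
$\hat\theta \pm 0.075\,r$ (a box covering 15% of each range, clipped to the
global bounds). For each parameter $p$, $AB_p$ replaces column $p$ of $A$
with that of $B$, and

$$\hat v(p) = \frac{1}{2 \cdot 30} \sum_{q=1}^{30}
  \left(\epsilon(A_q) - \epsilon(AB_{p,q})\right)^2$$

estimates $p$'s contribution (including interactions) to the error
variance. Row $q$ of $A$ and of every $AB_p$ share one fresh impulse-train
seed — pairing that removes most Monte-Carlo noise from the differences;
the seed-pairing policy is configurable since it is a numerical choice, not
part of the estimator's definition. With $\bar\epsilon$ and
$\sigma_\epsilon$ the mean and SD of 30 fresh-seed evaluations at
$\hat\theta$ itself,

$$u(p) = \frac{0.15\, r(p)}{\hat v(p) - \sigma_\epsilon}\; 0.1\,\bar\epsilon:$$

the step parameter $p$ could take before its contribution to $\epsilon$
grows by 10%. When $\hat v(p) \le \sigma_\epsilon$ the contribution is
indistinguishable from realization noise and $u(p)$ is reported unbounded
(`Inf`) rather than capped — the slope interpretation has broken down, and
a capped number would silently understate the uncertainty. $u$ is a
relative measure (between parameters, patients, times of day); it has no
probabilistic coverage interpretation because $\epsilon$ is not a
likelihood.

## Circadian analysis

For each recording, the 12 trends are standardized by their ranges $r(p)$
(so millisecond-scale delay parameters are not swamped; z-scoring is the
configurable alternative), decomposed by PCA, and each component projection
is fitted to $m_c + a_c\cos(2\pi t/24 + \phi_c)$ by Nelder-Mead simplex
search seeded with the closed-form linear fit. The recording's phase
$\phi$ is the $\phi_c$ of the largest-amplitude component. Because a
principal component's sign is arbitrary, $\phi$ carries a $\pi$ ambiguity;
it is anchored by requiring the range-weighted aggregate cosine amplitude
of the raw parameter trends to be positive (the same $\pi$-shift that makes
fitted amplitudes positive), which makes phases comparable across
recordings. $\phi$ is estimated per recording (patient x treatment), the
reading most consistent with indexing the cosinor by recording; a shared
per-patient phase is a switchable alternative.

With $\phi$ fixed the cosinor is linear in $\cos(2\pi t/24 + \phi)$, and
each parameter is fitted across the cohort by a linear mixed-effects model:

$$y_{pat,m}(t) = m_{pat,m} + a_{pat,m}\cos(2\pi t/24 + \phi),$$
$$m_{pat,m} = \alpha + \alpha_m + \eta_{pat} + \eta_{pat,m}, \qquad
  a_{pat,m} = \beta + \beta_m + \xi_{pat} + \xi_{pat,m},$$

where $m$ indexes treatments, $\alpha_m = \beta_m = 0$ at baseline, and the
$\eta$/$\xi$ terms are zero-mean Gaussian random effects (patient level and
recording level; the recording-level terms are structurally zero at
baseline, implemented by multiplying them with a non-baseline indicator).
Estimation is maximum likelihood (`lme4::lmer`, full covariance within each
random term); intervals are 95% Wald intervals from the information matrix.
Setting `random_effects = FALSE` collapses the fit to ordinary least
squares, a useful diagnostic limit. Goodness of fit per recording is the
RMSE between trend and fitted cosine, divided by $r(p)$ and averaged over
the 12 parameters.

Recording averages of each parameter (and of AFR or heart rate, when
supplied) are compared between baseline and each drug with paired two-sided
Wilcoxon signed rank tests over patients having both recordings,
Benjamini-Hochberg-adjusted across the whole drug-by-metric table at a
false discovery rate of 0.05; comparisons with fewer than 6 complete pairs
are flagged underpowered.

## The synthetic cohort generator

Because clinical 24-hour AF recordings cannot be redistributed, the package
generates complete cohorts with known ground truth, emulating the study
design it targets: patients in permanent AF, each recorded for 24 h at
baseline and under verapamil, diltiazem, metoprolol and carvedilol. For
every recording, $\theta(t)$ follows the mixed cosinor above — baseline
means are a representative physiologic parameter set, the planted mean drug
effects are the recording-average treatment differences reported for these
four drugs (refractoriness up under all of them), and the beta-blockers
additionally damp the circadian amplitude of the conduction-delay
parameters by 40% — with Gaussian patient- and recording-level random
effects and a common phase of 1.03 rad (acrophase near 04:00). Baseline
cosinor amplitudes default to 5% of each parameter's range. The atrial
rate follows a 24-h cosine around treatment-specific means near 5 Hz (the
reported AFR scale), and the emitted AFR trend is the inverse of the
$\lambda$ correction map plus small measurement noise.

Generation is piecewise-stationary: $\theta$ and $\lambda$ are frozen on a
one-minute grid (configurable) and the event-driven simulator runs each
cell, keeping the simulator core unmodified. Two artifacts follow, both
deliberate trade-offs: cell boundaries restart the network (about one
boundary per ~90 intervals), and the coupling-node floor is enforced across
boundaries by dropping beats closer than `RR_min` to their predecessor.
Gaps are cut at random positions (default three 10-minute gaps). What the
generator does *not* emulate: QRS detection errors beyond the quality-flag
mechanism, f-wave extraction noise in the AFR beyond additive Gaussian
noise, non-sinusoidal circadian shapes (daytime naps), and within-recording
drug washout. Passing recovery tests on this generator therefore validates
the estimation machinery under the model's own assumptions, not the
upstream ECG processing.

A dedicated scenario for the adaptive-effort comparison switches, at the
midpoint of a short recording, from baseline parameters to a maximally
refractory rate-independent regime ($R_\min = 650$, $\Delta R = 0$) at
$\lambda = 8$ Hz, moving the RR distribution by several hundred
milliseconds within seconds; $\Delta P$ crosses the 2000 threshold around
the switch and stays far below 800 elsewhere.

## Validation scale

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is meaningfully
testable: parameter tracking on 2-hour stationary recordings (population
100, $N_{sim} = 750$, re-evaluation at 5000, two helper GAs), the
switch-scenario comparison on 2-hour recordings with a 360-s stride over
ten seeds (per-seed mean post-switch error, medianed across seeds, so the
transient spike after the switch — the phenomenon of interest — is not
diluted by the segments where both schedules have re-converged),
uncertainty on four segments with the full 30x12 sampling,
mixed-cosinor coverage on 50 replicate 12-patient cohorts drawn directly
from the cosinor model, and false-discovery control on 200 replicate null
cohorts. The simulator-equivalence check runs an exhaustive brute-force
trace on a reduced 2+2+1-node network over all impulse trains of up to five
impulses on a spacing grid. Tracking quality is scored against the mean
error of the generating parameters over three fresh realizations at the
re-evaluation $N_{sim}$ — an unbiased, lower-variance benchmark than a
single draw.

## Known limitations

* Chain topology without retrograde links; no AV-nodal re-entry.
* $\epsilon$ is not a likelihood: no posterior or coverage statements, and
  $u(p)$ is only a relative measure.
* The cosine is a coarse description of circadian shape; recordings with
  daytime sleep fit it poorly.
* Parameter trends are only as identifiable as the Poincare histogram
  allows: distinct $\theta$ with near-identical RR distributions form
  ridges, visible as trend noise and as unbounded $u(p)$ for weakly
  influential parameters (notably fast-pathway delay parameters).
* The AFR-to-$\lambda$ correction defaults to identity until a citable
  depolarization-time constant is supplied.
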