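---
title: "Models and methods: multi-timescale structure in brainstem spike trains"
author: "mtspike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: multi-timescale structure in brainstem spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mtspike)
```

# The scientific problem

Pain-modulatory neurons of the rostral ventromedial medulla (RVM) come in
three functional classes. ON-cells burst and OFF-cells pause just before a
nocifensive withdrawal reflex; NEUTRAL-cells fire tonically and ignore the
stimulus. Two questions organize this package:

1. **Evoked dynamics.** When a noxious heat stimulus drives a withdrawal,
   how do the pooled ON- and OFF-cell populations depart from baseline and,
   critically, on what timescales do they recover?
2. **Ongoing dynamics.** In the absence of stimulation, do the same neurons
   show structured slow rhythms, are those rhythms predictable, and do they
   share structure with autonomic signals such as heart rate?

`mtspike` implements the full analysis chain for both questions — piecewise
Bayesian change-point models of pooled spike counts, periodic
Gaussian-process (GP) models of ongoing firing with a generalized Poisson
observation model, multitaper coherence with surrogate-based family-wise
inference, and animal-level permutation tests — together with a synthetic
cohort generator that emulates the statistical structure of such recordings,
so that every stage is testable end to end without any recording on disk.

# Evoked models: piecewise Poisson regression

Spike counts are pooled (summed over all cells and trials of a class) into
50 ms bins over a window from 10 s before to 100 s after the alignment
event (withdrawal or heat onset), and modeled as
\(y_t \sim \mathrm{Poisson}(\lambda_t)\) with a piecewise rate: a
*response* branch for \(t \le t_s\) and a *recovery* branch for
\(t > t_s\), joined continuously at the switch time \(t_s\).

For ON-cells the response is an exponential rise
\(r_{pre} + k_{pre} e^{(t-t_s)/\tau_1}\) and the recovery is a single or
double exponential decay toward a separate post-event baseline; continuity
fixes the slow amplitude as
\(k_{slow} = k_{pre} + r_{pre} - r_{post} - k_{fast}\)
(`deriveKslow()`). For OFF-cells the response is a four-parameter sigmoid
reparameterized so that it passes exactly through the joining point
\((t_s, u_0)\) via the midpoint
\(t^* = t_s + \tfrac{1}{k}\log\!\big(\tfrac{a-b}{u_0-b}-1\big)\)
(`deriveTstar()`), and the recovery is either linear + exponential or
double exponential. A constant-rate null model completes the set. Note
that in this sigmoid convention a *falling* response (the OFF pause) has
\(k < 0\); slope magnitudes are reported.

Priors follow the model families: log-normal baselines and amplitudes
(\(\log r \sim \mathcal N(3,1)\), \(\log k \sim \mathcal N(1,1)\)),
half-normal inverse time constants (\(\beta_i \sim \mathrm{HN}(5)\),
\(\tau_i = 1/\beta_i\)), OFF asymptotes \(b \sim \mathrm{HN}(4)\),
\(a, c \sim b + \mathrm{HN}(4)\), slope \(k \sim \mathcal N(0,1)\), drift
\(k_3 \sim \mathrm{HN}(1)\), \(u_0 \sim U(b, a)\), and
\(t_s \sim U[-4, 4]\) s. The OFF recovery time constant enters through a
positive rate \(1/\tau \sim \mathrm{HN}(1)\): a negative rate would make
the "recovery" diverge, so the positive half-line is the meaningful
support. In the double-exponential recoveries the fast rate is constrained
to exceed the slow one; without this ordering the two components are
exchangeable and chains can swap labels.

## Sampling

Fitting uses MCMC through JAGS (`fitPiecewise()`), with bins assigned to a
branch by their center time, data-driven initial values, and chain seeds
derived from one integer seed. JAGS's slice/Metropolis updates handle the
kink at \(t_s\) without gradients, which suits a likelihood that is only
piecewise smooth in the switch time. Defaults are 4 chains of 1000 draws
after 1000 adaptation and 1000 burn-in iterations; convergence is
monitored by split-chain potential scale reduction factors and effective
sizes, and fits are flagged (never silently returned) when the maximum
PSRF exceeds 1.1. The weakly identified pair \((b, u_0)\) of the OFF
model mixes slowest; its PSRF flag does not affect the response/recovery
timing parameters, which mix well.

Posterior summaries are means with 97% highest-density intervals
(`hdi()`, the minimum-width interval). Response/recovery timing is
summarized by `thresholdCrossings()`: per posterior draw, the time at
which the rate completes 10/50/90% of its departure (response, baseline to
extremum) or of its return (recovery, extremum toward the post-event
baseline), solved by bisection on the monotone branch. For recoveries with
a linear drift the "post-event baseline" is the model value at the window
end; the \(t \to \infty\) asymptote does not exist for that variant.

Model variants are compared by leave-one-out expected log predictive
density (`compareELPD()`), computed by Pareto-smoothed importance sampling
(PSIS-LOO) with Pareto-\(k\) diagnostics. No packaged PSIS implementation
is available in this stack, so the generalized-Pareto tail fit
(Zhang–Stephens posterior-moment estimator) and the tail smoothing are
implemented here and validated in the test suite against the closed-form
leave-one-out predictive density of a conjugate normal model.

# Ongoing activity

## Spectra and variability

`smoothRate()` converts spikes to a rate with a 2 s boxcar kernel sampled
every 2 s (the kernel shape is a documented choice; a Gaussian is
available), trimming the first and last 2 s. `psdPeak()` estimates a Welch
averaged-periodogram PSD (Hann window, half-overlapping segments, segment
length at least 600 s so that a 300 s rhythm completes two cycles) and
reports the dominant sub-0.1 Hz peak as a period with its FWHM from
interpolated half-power crossings; a peak must exceed 3× the median band
power to count as present. `isiStats()` gives the interspike-interval mean
and coefficient of variation: regular tonic firing has CV well below 1,
Poisson-like firing CV ≈ 1, bursty firing CV above 1.

## Period scan

`periodScan()` computes, for 200 candidate periods, the exact GP negative
log marginal likelihood of the mean-centered rate under the periodic
kernel \(k(t,t') = \sigma^2 \exp\{-2\sin^2(\pi(t-t')/p)/\ell^2\}\) with
fixed \(\ell = 1\) and \(\sigma^2 = 5\) plus a Gaussian noise term fixed
at the sample variance of the centered rate (the likelihood noise level is
not separately identifiable in a fixed-hyperparameter scan, and the sample
variance makes the NLML scale comparable across cells). The candidate grid
is logarithmic over 0.1–1500 s, resolving both sub-second and multi-minute
candidates. Rhythmic cells produce a global minimum at the true period
with subharmonic local minima at its multiples (a signal of period \(p\)
is also consistent with kernels of period \(2p, 3p, \dots\)); aperiodic
cells produce flat profiles.

## Latent GP with generalized Poisson observations

`fitLatentGP()` models 5 s binned counts as
\[
x(t) \sim \mathcal{GP}(c,\, k_{per}),\qquad
\mu_t = A\,\log(1+e^{x_t}) \cdot \Delta,\qquad
y_t \sim \mathrm{GPois}(\theta_t = \mu_t(1-\alpha),\, \alpha),
\]
with \(A = 10\) spikes/s, bin width \(\Delta = 5\) s, and a small uniform
contamination (\(p_{noise} = 10^{-3}\) over \(0..y_{max}\)) that caps the
influence of rare outlier bins. The scaled SoftPlus link avoids the
overflow and gradient pathologies of the exponential link at both rate
extremes. The generalized Poisson has mean \(\theta/(1-\alpha)\) and
variance \(\theta/(1-\alpha)^3\): \(\alpha > 0\) captures bursty
overdispersion, \(\alpha < 0\) the sub-Poisson regularity of tonic cells.
For \(\alpha < 0\) the raw pmf is truncated and does not sum to one, so it
is renormalized over its support (summation capped at mean + 20 sd, where
the neglected mass is far below machine precision).

Hyperparameters \((\sigma^2, p, \ell, \alpha, c)\) maximize a
Laplace-approximate marginal likelihood (type II) with Gaussian log-prior
penalties \(\ell \sim \mathcal N(0.1, 0.1)\) and
\(\alpha \sim \mathcal N(0, 0.5)\), the period initialized at 300 s. At
the durations this analysis targets (≤ 1500 s at 5 s bins, i.e. ≤ 300
bins) the full bin grid is *smaller* than a typical sparse inducing set,
so the latent posterior mode is computed exactly on the grid by damped
Newton iterations and no sparse variational approximation is needed; this
is the package's design choice where a larger problem would call for one.
The final 300 s are held out: hyperparameters see only the training bins
(this purity is asserted bitwise in the tests), and held-out predictions
come from the GP conditional at the optimized hyperparameters.
Accuracy is summarized by the squared-error pseudo-R²
\(1 - \sum(y-\hat\mu)^2 / \sum(y-\bar y_{train})^2\), which is 0 when
predicting the training mean and negative when generalization fails —
exactly the behavior that separates rhythmic from aperiodic cells at test
time. `phaseFold()` folds the fitted rate modulo the fitted period (phase
origin at the training-window start, so profiles are defined up to cyclic
shift).

# Coherence with heart rate

`multitaperCoherence()` bins both series at 2 s, cuts 500 s segments with
50% overlap, demeans each segment, and averages cross- and auto-spectra
over 6 DPSS tapers (time–bandwidth product NW = 3.5) and all segments
before forming
\(C_{xy}(f) = |\bar S_{xy}|^2 / (\bar S_{xx} \bar S_{yy})\). The
frequency resolution is 1/500 = 0.002 Hz and the analysis bandwidth
NW/500 = 0.007 Hz — wide enough that a 1/300 Hz rhythm is smeared across
the lowest bins, so no sub-bandwidth frequency claims are made. The DPSS
tapers are computed from the standard symmetric tridiagonal eigenproblem
(no installed package provides them) and are checked in the tests for
orthonormality and in-band energy concentration.

Significance uses a max-statistic surrogate test (`maxStatTest()`):
surrogates preserve the rate series' amplitude structure but destroy any
consistent phase relation with heart rate, and the maximum coherence over
all frequencies is recorded per surrogate, controlling the family-wise
error rate across the whole spectrum. A frequency is significant when its
observed coherence exceeds the \(\lfloor\alpha(n+1)\rfloor\)-th largest
surrogate maximum (the add-one permutation convention, so the family-wise
level is honored exactly at \(\alpha = 0.001\) with the default 2000
surrogates).

One design point deserves emphasis. Randomizing each 500 s segment
independently preserves every segment's amplitude spectrum exactly, but
with 50% overlap it *breaks the correlation between overlapping segments*
that the observed averages contain, and the resulting null is measurably
anticonservative (family-wise false-positive rates in the percent range
at a nominal 0.001 in our calibration experiments). Randomizing the whole
series once per surrogate preserves that correlation but leaves a shared
narrowband component phase-consistent across segments, destroying power
precisely where it matters. `mtspike` therefore randomizes
*non-overlapping segment-length blocks* of the series and re-segments
with overlap: overlapping segments still share their common samples (so
the null is calibrated — verified against the binomial bound in the
acceptance tests) while distant segments get independent phases (so a
shared sinusoid is still detected). Block-aligned segments keep their
amplitude spectra exactly; segments straddling a block boundary only
approximately. The surrogate inner loop runs in C++ (with R's RNG), and
for large calibration experiments the per-pair decision can be resolved
sequentially (`earlyStop = TRUE`): the accept/reject outcome is identical
to the full run because a pair stops exactly when enough surrogate maxima
have reached the observed maximum to rule significance out.

# Group statistics

Per-cell metrics (e.g. test pseudo-R²) are correlated within animals, so
`signFlipMedianTest()` flips the sign of *all* cells of an animal jointly
(one ±1 per animal per permutation) and recomputes the median metric,
with exact enumeration of the \(2^{n_{animals}}\) patterns whenever that
is cheaper than sampling; p-values use the add-one correction and are
never exactly zero. `permutedMannWhitney()` compares two classes with a U
statistic permuted at the animal level (each null U centered by its own
assignment's \(n_1 n_2 / 2\), since group sizes change when whole animals
move) and applies a Bonferroni multiplier. `kruskalWallisMetrics()` wraps
the standard rank-based H test for three or more classes.

# The synthetic cohort generator

`genCohort()` emulates the study conditions: heat trials every 300 s
(3–4 per cell) with withdrawal latencies of 8.7 ± 1.1 s after heat onset;
ON/OFF evoked responses generated from the piecewise families at the
reported population posterior means; NEUTRAL cells as ~10 Hz gamma-renewal
trains with ISI CV ≈ 0.35 (a Poisson train cannot be that regular, hence
the renewal model); ongoing 300 s quasi-periodic modulation shared within
an animal through a common latent phase; and a heart-rate series at
391.1 bpm, additively coupled to the animal's latent (with a configurable
lag) in a configurable fraction of animals. Evoked pooled counts for the
model-recovery experiments come from `simulateEvokedCounts()`, which draws
Poisson counts directly from the piecewise rate at the 50 ms bin centers —
the same discretization the fit uses, so recovery tests are free of
binning bias.

The unprinted baseline scales (`r_pre` = 20, `r_post` = 18 counts/bin;
peak a few times baseline; OFF asymptotes a = 25, c = 18, u0 = 2.5
counts/bin) were chosen once so that the synthetic pooled counts give
posterior uncertainties comparable to the reported 97% HDI widths — i.e.
the synthetic experiment is as informative as the real one, no more.
Two latent modes exist for ongoing counts: an exact sinusoid (used by the
recovery tests, where sharp ground truth matters) and a GP draw (more
realistic texture). Every generator is a pure function of its arguments
and the R RNG seed; cohort writes are byte-reproducible under a fixed
seed.

What the generator does *not* emulate: refractory structure within evoked
bursts, non-stationary anesthesia drift, correlated noise between
simultaneously recorded cells beyond the shared latent phase, or any
cardiac dynamics beyond an additive oscillation. Passing recovery tests
on this generator therefore demonstrates that the estimators invert the
assumed generative models at realistic signal-to-noise — not that those
models are correct for any particular recording.

# Numerical choices and problem sizes

* Bins are half-open `[left, right)`, left-anchored; trailing partial bins
  are dropped; totals are conserved (property-tested).
* The period-scan kernel matrix is Cholesky-factorized with a small jitter
  retry on ill-conditioning; scans subsample inputs beyond 800 samples.
* The Laplace inner Newton loop is damped with objective backtracking, and
  likelihood curvatures are floored at a small positive value (the
  generalized Poisson likelihood is not globally log-concave).
* Permutation p-values switch to exact enumeration when
  \(2^{n_{animals}}\) (sign flips) or \(\binom{n}{k}\) (label
  permutations) is at most the requested permutation count.
* The test suite and the acceptance script run the evoked fits with 2
  chains and ~1000–1500 retained draws per chain, the period scan on a
  1500 s series, the latent-GP recovery on 1500 s of 5 s bins, and the
  coherence calibration on 1000 independent pairs with 1000 surrogates
  each (the sequential decision rule makes the calibration cheap). These
  sizes are the package's chosen experiment scale; the underlying
  functions accept larger inputs unchanged.

# Known limitations

* The pooled (pseudo-population) evoked model deliberately has no
  per-cell or per-animal random effects; with 3–4 trials per cell the data
  cannot support a multi-level model, and the package does not offer one.
* The switch time is a change-point-like parameter: its posterior is
  asymmetric and its posterior mean scatters by roughly one posterior SD
  (~±0.04 s for ON-cells at the study's signal-to-noise) across data
  realizations.
* \((b, u_0)\) of the OFF sigmoid are only weakly identified when the
  pause is nearly complete at the switch; their slow mixing is flagged but
  harmless to the timing parameters.
* The latent-GP fit returns a local optimum of a multimodal objective;
  initialization at 300 s reflects the period-scan evidence, and scans
  (not the latent fit) should be used to *discover* unknown periods.
* Coherence surrogates preserve straddling-segment spectra only
  approximately (see above); this is the price of a calibrated null under
  50% overlap.
* For a cell with *no* rhythmic modulation at all, the test pseudo-R² is a
  zero-margin boundary quantity: the fitted model reduces to a constant
  whose likelihood-based rate estimate is at least as efficient as the
  arithmetic training mean that pseudo-R² uses as its baseline, so the
  expected test pseudo-R² is approximately zero and individual fits land
  a few thousandths on either side of it. "Fails to generalize" should
  therefore be read as "test pseudo-R² near or below zero", in contrast
  to the ~0.6 of genuinely rhythmic cells; a strict negative sign is not
  guaranteed bin-for-bin. Statements about whole cell classes should use
  the animal-level sign-flip test on the per-cell values, as the group
  statistics module does.
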