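---
title: "Methods: ISI-based decoding and population analysis of auditory cortical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ISI-based decoding and population analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isidecode)
```

# Scope

`isidecode` implements the analysis stack for extracellular recordings made
while mice perform a go/no-go auditory reversal-learning task: behavioral
sensitivity and learning-phase segmentation, classification of single units
as classically responsive (CR; reliable trial-averaged firing-rate changes)
or non-classically responsive (NCR; no reliable rate change, but possibly
task information in spike timing), a single-trial Bayesian decoder that
reads interspike-interval (ISI) sequences, participation-ratio
dimensionality of population activity, and the resampling statistics used
for population-level inference. A synthetic-data generator with known ground
truth stands in for recordings, so every stage is testable end to end.

# The synthetic-data generator

## Spiking model

Units are gamma-renewal processes: ISIs are Gamma(shape $k$, rate $k r$), so
the mean rate is $r$ regardless of $k$, while $k$ controls ISI regularity
($k = 1$ is Poisson, $k < 1$ bursty, $k > 1$ regular). This is the minimal
model in which spike timing can carry information at a fixed firing rate,
which is exactly the premise of a rate-flat, timing-coded NCR unit: such a
unit is generated with `stim_delta = 0` and condition-dependent shapes
(default target/nontarget shapes 0.6 / 2.5). CR units instead receive an
additive rate change during the 100-ms tone (`stim_delta`, default
5 spikes/s in population presets) and/or the 100-ms choice window.

Rates are piecewise constant over a trial: baseline everywhere, baseline +
`stim_delta` during the tone, baseline + `choice_delta` in a 100-ms window
centered on the trial's response time (go trials) or on the session's mean
go latency (no-go trials; the choice window wins where it overlaps the
tone). At every rate or shape boundary the renewal age is reset, and each
segment's first event is drawn from the equilibrium (stationary
forward-recurrence) distribution $U \cdot \mathrm{Gamma}(k + 1, k r)$
rather than a fresh ISI. The equilibrium start matters: a plain age reset
under-counts short windows for $k > 1$, which would systematically
rate-mismatch the two conditions of a timing-coded unit. With it, expected
counts are exactly rate x duration in every segment for every shape. A 1-ms
refractory period is then enforced by deleting the later spike of any
closer pair; for very bursty shapes this trims a few percent of spikes,
which is the one small residual asymmetry between condition shapes.

## Session structure and correlations

Sessions mirror the task: 100-ms tones, a 2.5-s response window, inter-tone
onset intervals uniform on 3-7 s (the passive-protocol spacing, adopted as
the active default because the active inter-trial distribution is not fixed
by the task description; it is configurable). Trials are split exactly
`p_target` / `1 - p_target` (default 50/50, shuffled). Outcomes are
Bernoulli per trial (`p_hit`, `p_fa`; defaults 0.85 / 0.20), with response
latencies log-normal around 0.6 s truncated to the response window.

Pairwise spike-count correlations are induced by a per-trial multiplicative
gain shared across units, log-normal with mean 1 and log-SD
`shared_gain_sd`. The gain scales every unit's rate over the trial span, so
it creates positive covariance without changing any unit's CR/NCR ground
truth. `shared_gain_sd = 0` gives independent units.

## What the generator does and does not emulate

It emulates: condition-locked rate changes, rate-flat ISI-shape coding,
shared-gain covariance, session trial structure, multi-day learning
trajectories (per-day binomial hits/false alarms against specified
trajectories), and step-change kinematic speed traces. It does not emulate:
biophysical membrane dynamics, adaptation or history dependence beyond the
renewal structure, non-stationarity across a session, bursting with
within-burst structure, or realistic pose/video data. Consequently, passing
tests demonstrate that the analysis code recovers the structure it targets
when that structure is present and calibrated absence when it is not; they
do not certify performance under slow drift, adaptation, or other
real-data pathologies the generator omits.

# Behavioral measures

d' is the standard signal-detection sensitivity
$d' = \Phi^{-1}(\mathrm{hit\ rate}) - \Phi^{-1}(\mathrm{FA\ rate})$ with
rates clipped to $[1/(2N), 1 - 1/(2N)]$ per stimulus class ($N$ trials of
that class), keeping perfect sessions finite and allowing the negative d'
seen just after a rule reversal. Percent correct is
$100 (\mathrm{hits} + \mathrm{correct\ rejects}) / N_{\mathrm{total}}$.

Learning phases: progress is $(d' - \min d')/(\max d' - \min d')$ over an
animal's block of sessions; progress < 40% is *early*; sessions meeting
$d' \ge 1.5$ and percent correct $\ge 70$ are *expert* (the expert
criterion takes precedence over the progress band, since it is a criterion
rather than a progress level); the remainder is *late*. Raw per-session d'
is used, not a smoothed curve. Phase slopes are OLS slopes of d' on session
index over the phase's sessions, appending the first session of the next
phase for non-expert phases so the slope spans the transition.

Movement onset: for each frame with 100 frames of context, the difference
between the mean speed over the next 100 frames and the previous 100; onset
is the first frame where this difference exceeds the whole-trace mean plus
2 SD (the SD baseline is taken over the whole trace; a pre-period variant
would need an onset to define, which is circular). Because the difference
trace of a speed step is a 200-frame ramp, the first crossing necessarily
precedes the step; the ramp's peak (`peak_frame`) localizes the step itself
and is reported alongside. Mean speeds in the 0.5-s windows before and from
onset are returned.

# Responsiveness and CR/NCR classification

Baseline rate is the mean rate in the 150 ms before tone onset. Evoked
responses use 50-ms windows sliding over the 200 ms from tone onset
(capturing onset and offset responses); the window with the largest
absolute deviation from baseline gives the signed evoked rate, its absolute
value the stimulus firing-rate modulation. The window step is not part of
the measure's definition; the default is 10 ms (16 windows), configurable
to 1 ms, and the test oracle scans the configured grid exhaustively. Tone
selectivity is $(|R_T| - |R_{NT}|)/(|R_T| + |R_{NT}|)$. Choice modulation
compares the 100-ms response-locked window rate to baseline.

## The subsampled bootstrap and its units

The discrete CR/NCR test subsamples 90% of the per-trial spike-count
changes from baseline, takes the mean, repeats 5,000 times, and labels the
unit CR if at least 95% of means fall outside $[-0.1, +0.1]$, NCR if at
least 95% fall inside, and indeterminate otherwise.

Two choices here were genuinely open and we fixed them by calibration
analysis. First, the units of the $\pm 0.1$ band: expressed as a *rate*
(spikes/s), the band is unattainably narrow - at a typical 5 spikes/s
baseline the trial-averaged rate change has a standard error of
~0.5-0.8 spikes/s at 200 trials, so no null unit would ever be labeled NCR
and the test would collapse. Expressed as per-trial spike *counts* the test
is calibrated, and "change in number of spikes" is what the test actually
resamples. Second, the test window: selecting the extremal sliding window
(as the continuous measure does) before testing biases the null upward by
the maximum of ~16 correlated noise terms and inflates false CR labels; the
default instead uses the first 50 ms of the tone against a length-matched
50-ms baseline window ending at onset, which keeps counts coherent and the
null calibrated ($\le 5\%$ of rate-flat units labeled CR in simulation).
Both choices are configurable (`units = "rate"`, `window = "extremal"` or
`"tone"`) for comparison.

The bootstrap is deliberately conservative: a rate-flat unit at moderate
rates lands NCR or indeterminate, rarely CR. That is why classification
does not stop there: a one-dimensional maximum-margin threshold is fit to
the firing-rate modulations of the bootstrap-labeled units, and *all* units
are classified by their modulation against that threshold (ties go to CR).
The threshold fit minimizes the total violation mass (a zero-margin hinge:
how far each misclassified modulation sits on the wrong side), which is
convex and piecewise linear, and returns the midpoint of the minimizing
interval - on separable data, the classic max-margin midpoint between the
closest opposing values. The fit is deterministic; a brute-force 1-D scan
is kept as a test oracle.

Units enter analysis only with a session-mean rate of at least
0.5 spikes/s; ISIs under 1 ms flag a curation problem. Labels are
period-specific (stimulus or choice), matching how the variable of
relevance changes across analyses.

# The ISI Bayesian decoder

## Single cells

For each task condition (target/nontarget, or go/no-go) the distribution of
ISIs is modeled by Gaussian kernel density estimation on the log-ISI axis -
ISIs are strictly positive and right-skewed, and the log domain avoids
boundary bias without reflection tricks (a linear-domain variant would need
one; the domain is a package choice, not part of the method's definition).
ISIs are extracted from tone onset to the end of the 2.5-s response window
by default (configurable; surrogate controls always preserve the same
per-trial window length).

The bandwidth is chosen by cross-validated maximum likelihood: held-out
mean log-density over a 13-point log-spaced grid spanning Silverman's rule
times $2^{-3} \ldots 2^3$, with deterministic rank-interleaved folds (the
fit is a pure function of its inputs; ties prefer the wider bandwidth).
Within the decoder's cross-validation, the bandwidth is selected once per
unit and condition on the full trial set and then held fixed while kernel
centers are refit on each training fold. This factorization is the
package's runtime choice: re-running the bandwidth search inside every fold
of every iteration would multiply cost by the grid and fold count, and
because the same rule is applied to both conditions symmetrically it cannot
push accuracy toward either class (the synthetic-control suite confirms
chance-level decoding under this scheme).

A trial's posterior follows Bayes' rule under conditional independence of
its ISIs: log-posterior = log-prior + sum of per-ISI log densities,
normalized by log-sum-exp. Priors are flat by default. Evaluated densities
are floored at $10^{-12}$ so an out-of-support ISI cannot contribute an
infinite penalty (configurable). An empty ISI sequence returns the prior;
a posterior exactly at 0.5 scores 0.5 correct rather than a coin flip, so
results are deterministic given the seed.

Cross-validation is stratified 10-fold (every training set contains both
conditions), repeated 500 iterations by default; the accuracy samples are
per-fold fractions correct, giving the 5,000 observations the downstream
rank-sum test consumes. The worked analyses and the acceptance checks run
20 iterations - the grand means they report are stable at that size for
the session sizes used (50-200 trials), and the full 500 remains the
package default.

## Synthetic controls and the task-encoder threshold

Each cell's control resamples its pooled ISIs (all trials, any condition)
i.i.d. with replacement into each trial until the next draw would exceed
the trial's window length. This destroys condition-specific structure while
preserving trial length and the marginal ISI distribution, so control
accuracy estimates the decoder's chance level; a cell is dropped from
decoding analyses when a two-sided Mann-Whitney U test cannot distinguish
its real accuracy samples from its control's. One known bias of the
construction is documented rather than patched: real trials spend part of
the window on entry/exit gaps that contribute no ISI, so surrogate trials
hold on the order of 20% more ISIs than real ones; first-order, the
surrogate count is window / mean(pooled ISI), and decoding conclusions are
unaffected because controls sit at chance regardless.

Cells whose real accuracy cannot be explained by chance variability are
*task encoders*: below-chance accuracies estimate the sampling spread
around chance, and the gap between their 5th percentile and chance,
reflected above chance, is the encoder threshold (at least 20 at-or-below
chance cells by default, else flagged undefined).

## Ensembles

Ensemble decoding multiplies member likelihoods: each member's
per-condition densities are fit on the training folds and each member's
ISIs add to the trial's log posterior, with one shared fold partition per
iteration. An ensemble of size one is therefore *identical*, sample for
sample, to single-cell decoding under the same seed (and is implemented as
the same code path). Ensembles of size $n_1$ (default 10, the smallest
size at which every composition band below is realizable) are sampled
uniformly without replacement within a session, exactly $n_2$ ensembles
per session of $n_2$ units, so high-yield sessions do not dominate pooled
statistics. Composition categories follow the fraction of NCR members:
$\le 30\%$ CR ensemble, 50-70% mixed, $\ge 80\%$ NCR ensemble, anything
else uncategorized and dropped from category contrasts.

# Dimensionality

Population activity is summarized per trial by spike counts in the
stimulus-aligned 200-ms window (the activity window is a package choice -
the participation ratio itself is window-agnostic - and full-trial counts
are available by configuration). With covariance matrix $C$ (unbiased,
$n - 1$ denominator), the participation ratio is
$D = (\mathrm{Tr} C)^2 / \mathrm{Tr}\, C^2$: $n$ for independent equal
variances, 1 for perfect correlation. Expanding the traces gives the
moment form
$$D = \frac{1 + (n-1)\langle \mathrm{Var}_i \mathrm{Var}_j \rangle / \langle \mathrm{Var}_i^2 \rangle}
           {1 + (n-1)\langle \mathrm{Cov}_{ij}^2 \rangle / \langle \mathrm{Var}_i^2 \rangle},
\qquad
D_\infty = \frac{\langle \mathrm{Var}_i \mathrm{Var}_j \rangle}{\langle \mathrm{Cov}_{ij}^2 \rangle},$$
identical to the trace form on complete matrices (verified to $10^{-10}$ in
tests) and estimable from data when units are not all simultaneously
recorded. Mean absolute covariance is reported alongside the squared
moment.

Uncertainty uses a two-level bootstrap reflecting where each moment comes
from: variances exist per unit, so the numerator resamples each animal's
units with replacement at the animal's own count; covariances exist only
within sessions, so the denominator resamples sessions with replacement and
pools all within-session pairs. 2,000 replicates give a mean and s.e.m.;
replicates whose covariance moment degenerates to zero are excluded with a
reported count. $D_\infty$ is flagged infinite when the squared-covariance
moment is exactly zero.

# Population statistics

Population proportions (e.g., percent NCR) are bootstrapped by resampling
each animal's units with replacement at the animal's own count, 2,000
replicates, reporting mean and s.e.m. Group differences use a permutation
test with 250,000 relabelings by default and the $\max(\mathrm{count}, 1)/N$
convention, so the smallest reportable p-value is $1/N = 4 \times 10^{-6}$;
an exact-enumeration mode covers small groups. Benjamini-Hochberg step-up
correction (via `p.adjust`) controls FDR across families of comparisons. A
test-selection dispatcher (D'Agostino-Pearson normality deciding between t
and rank tests) is provided for parity with conventional pipelines, but the
package's own analyses default to the resampling tests above.

# Numerical choices and degenerate inputs

- Density floor $10^{-12}$ per evaluated ISI; posteriors normalized in log
  space; exact posterior ties score 0.5.
- KDE bandwidth grid: Silverman x $2^{-3..3}$, 13 points; ties to the wider
  bandwidth; fewer than 10 ISIs fall back to the widest grid point with a
  warning.
- d' clipping $1/(2N)$ per class; flat learning curves are unsegmentable
  (error); single-point phases with no following phase yield `NA` slopes.
- Threshold classification ties go to CR; an empty training class is an
  error; fewer than 5 units per class warns.
- Bootstrap classification below 20 trials returns indeterminate with a
  warning; all-zero count changes give exact NCR.
- Zero covariance matrices make the participation ratio undefined (error);
  zero-variance units are retained in activity matrices but flagged.
- All stochastic entry points take explicit integer seeds and restore the
  caller's RNG state; derived child seeds stay below $2^{31}$.

# Problem sizes in the shipped checks

The test suite and the acceptance script run at desk scale, chosen for
statistical stability of the quantities they assert: 50-cell control-chance
experiments at 100 trials and 20 CV iterations; classifier recovery on 100
units per class at 200 trials; 50 replicates for the rate-matched coding
and dimensionality-monotonicity checks; permutation floors at the full
$N = 250{,}000$. The method defaults (500 iterations, $B = 2{,}000$,
$N = 250{,}000$) are unchanged by these choices.

# Known limitations

- The generator's stationarity means the suite cannot detect sensitivity
  to drift or adaptation; conclusions about real recordings require the
  usual curation upstream.
- The subsampled bootstrap's band is calibrated for per-trial spike counts
  in 50-100 ms windows; sessions with very high rates or much longer test
  windows shift its operating point (the separating-threshold step absorbs
  most of this, but the bootstrap labels themselves will skew
  indeterminate).
- The synthetic-control ISI-count bias described above is inherent to the
  fill-the-window construction.
- Ensemble decoding assumes conditional independence across members; the
  shared-gain correlations the generator can inject violate it mildly,
  which is realistic but means ensemble posteriors are approximations by
  design.
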