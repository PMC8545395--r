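---
title: "Methods: models, parameters and design choices in condpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in condpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`condpipe` implements the analysis chain for paired hippocampal-CA1 /
prefrontal-cortex (PFC) recordings during appetitive auditory trace
conditioning: a 2 s conditioned sound (CS+ or CS-), a 1 s silent trace
period, and a liquid reward delivered 3 s after CS+ onset. This vignette
explains the models and statistics each stage implements, the parameters
that matter, what the synthetic-session generator does and does not
emulate, and the design decisions taken where the methodology left
genuine freedom.

## The task and the analysis windows

All trial-locked analyses share one clock, CS onset at `t = 0`:
pre-stimulus baseline `[-1, 0)` s, sound `[0, 2)` s, trace `[2, 3)` s,
reward/consumption `[3, 3.5)` s. A sound-evoked window `[0, 0.35)` s
captures short-latency responses. These windows are fixed across the
package so that single-cell scores, population decoding, reduced-rank
regression and assembly modulation all refer to the same task epochs.

## Behavioral learning classification

Learning is read out from anticipatory licking. For every trial the lick
count in the trace window minus the count in the baseline window gives a
per-trial lick change; a two-sample t-test compares CS+ against CS-
changes, and a session counts as *learned* when `p < 0.05` **and** the
CS+ mean exceeds the CS- mean. The directional requirement reflects that
only CS+-specific anticipation is evidence of learning; a symmetric
significance could be triggered by CS- licking. Lick-count windows are
half-open `[a, b)` so a lick on a boundary is never counted twice.

The first *anticipatory lick* of a CS+ trial is the first lick after CS
onset and before reward that is followed by at least three further licks
within one second. Followers may fall after reward delivery; only the
candidate itself must precede it — licking typically continues into
consumption, and requiring pre-reward followers would discard genuine
anticipatory bouts that start late in the trace period.

## Single-cell taxonomy

Spikes are binned at 25 ms, smoothed per trial with a normalized
Gaussian-weighted moving average (25-bin support, SD = 5 bins, mirror
padding, so per-trial totals are conserved), averaged into PSTHs and
z-scored per unit against the mean and SD of the trial-averaged baseline
bins. Units with zero baseline SD are flagged and excluded rather than
producing infinities.

The taxonomy uses inclusive ±1 SD thresholds ("at least one standard
deviation"): a unit is trace-up/trace-down when its mean trace-window z
is ≥ +1 / ≤ −1 in either CS type; evoked and reward scores are the mean
z in their windows. Lick cells are defined on raw rates around the first
anticipatory lick (±250 ms) compared with the pre-trial baseline. One
deliberate choice here: the "one SD" of the lick criterion is the SD of
the **per-trial** baseline rates, not of the baseline bins of the
trial-averaged PSTH. Bin-level SD of a 50-trial smoothed average behaves
like a standard error (a few tenths of a Hz at a 5 Hz baseline), which
would label practically every trace-modulated unit a lick cell and empty
the non-lick population that all population-level analyses are built on;
per-trial SD yields the few-percent lick-cell prevalence expected in this
preparation. The ±1 SD rule is intentionally generous — on unmodulated
units it flags a tail consistent with the baseline variability of the
mean z over effectively few independent (smoothed) bins — which is why
population analyses, not single-cell flags, carry the inferential weight
downstream.

## Population analyses

Population rate vectors use all simultaneously recorded **non-lick**
units (lick cells would trivially encode CS+ through behavior). The
CS+/CS- separation over time is the per-bin Euclidean distance between
trial-averaged condition matrices, z-scored to the pre-stimulus bins;
trajectories are visualized in the space of the first three principal
components of the concatenated conditions (component signs fixed by the
largest loading, for reproducibility).

Trial identity is decoded from per-trial mean trace-period rates with a
linear maximum-margin classifier (cost fixed at 1 — only the method
family is prescribed, and at these dimensionalities the accuracy is flat
in the cost over orders of magnitude), evaluated with stratified 20-fold
cross-validation. Stratification prevents folds that miss a class, which
unconstrained "20 equal partitions" can produce. Single-session
significance uses label permutations (the across-session sign-rank test
has no single-session analogue).

## Reduced-rank regression (RRR)

The communication-subspace question — how many dimensions of one
population's activity predict another population — is answered with
reduced-rank regression: per cross-validation fold, ordinary least
squares from source to target counts, then held-out predictions projected
onto the top-r principal components of the fitted training values. At
full rank the projector is the identity, so the full-rank model *is*
OLS; held-out R² per rank gives the performance curve, and the selected
rank is the smallest within one SEM of the best (the 1-SEM rule).
Activity is spike counts in 100 ms bins within a task period,
concatenated over trials and mean-centered; 100 ms gives ≥10 samples per
trial in the shortest period while keeping counts roughly Gaussian at a
5 Hz baseline. Counts (not z-scored rates) enter the regression; the
regression is scale-equivariant and centering already removes the
baseline offsets.

Four disjoint unit sets (source/target per area) are drawn at the common
size `m = min(⌊N/2⌋)` so that within- and cross-area performances are
comparable, and the whole analysis is averaged over 10 subsample
replicates. A penalized full-rank control is included for the
dimensionality confound; its penalty family is exposed as an
elastic-net mixing weight defaulting to pure ridge, because the
methodological description of this control mixes L1 and ridge
terminology and both readings are defensible.

## Ripple detection and coherence

CA1 LFP is band-passed at 150-300 Hz with a zero-phase 4th-order
Butterworth (forward-backward; the filter family is a standard choice,
not prescribed) and common-average referenced to cancel common-mode
artifacts. The detection channel is the one with the strongest mean
ripple-band power. Events are epochs where the analytic-signal envelope
crosses the low cut (100 µV default), stamped at the envelope peak
(needed for triggered averages); peaks at or above the high cut (500 µV)
are rejected as artifacts; events within 200 ms of a retained earlier
event are dropped (keep-first), and events within ±200 ms of any lick
are excluded. Thresholding the envelope rather than the raw filtered
trace is the standard reading of a band-signal threshold and makes the
amplitude of an event well defined.

Coherence uses Slepian multitapers (time-bandwidth 3, 5 tapers,
computed from the tridiagonal eigenproblem and cached) on per-trial
segments; condition differences are tested per frequency by shuffling
segment labels (two-sided). Segment-level spectra are cached so the
permutation null costs only re-averaging.

## Assembly detection and reactivation

Task-related assemblies are detected on trial activity (-1 to 4 s,
20 ms bins, trials concatenated): each unit is z-scored, and the number
of assemblies is the number of correlation-matrix eigenvalues above the
analytic Marcenko-Pastur bound `(1 + sqrt(n/B))²`. The data are
projected onto the significant principal subspace and unmixed with
FastICA (cube nonlinearity, symmetric decorrelation). Because the
extraction is stochastic, it is restarted five times and the run with
the largest summed component kurtosis is kept; patterns are
back-projected to unit space, normalized to unit norm and sign-aligned
(largest-magnitude weight positive), making detection bit-stable for a
fixed RNG seed.

Assembly expression over time is the quadratic form `zᵀPz` with
`P = wwᵀ` and a zeroed diagonal, on 20 ms bins sliding in 10 ms steps
(50% overlap; the overlap step is a choice — 10 ms keeps the ripple
window sampled at 5 points). The zeroed diagonal means a single active
unit can never express an assembly.

Ripple-triggered reactivation z-scores the activation against a baseline
that excludes the 50 ms ripple-centered windows, restricted to
inter-trial intervals when a schedule is available (the analysis targets
awake ripples in the ITI; including trial periods would mix in
stimulus-locked activation; the whole-session alternative is available
by omitting the schedule). Reactivation per ripple is the mean z in the
50 ms ripple-centered window. Within-session dynamics divide trials into
10 equal blocks and compare the first and last three per assembly group
(reactivation+/− by the sign of the session-mean reactivation — the
natural split once a signed session mean exists). Trial-type modulation
is mean CS+ minus mean CS- activation over stimulus+trace; significance
of per-ripple reactivations uses a robust 2-SD rule with the SD
estimated as 1.4826 × MAD; CA1-PFC coordination is assessed by
median-splitting each area's per-ripple reactivation and comparing the
both-high quadrant (Q1) against the CA1-high/PFC-low quadrant (Q2) over
all assembly pairs.

## The synthetic-session generator

Every analysis is validated against sessions from `generate_session()`,
which emulates exactly the statistical structure the analyses assume:

* **Schedule**: interleaved CS+/CS- onsets, ITIs uniform on 30-45 s,
  reward at +3 s on CS+ trials. Defaults of 50 CS+ and 50 CS- trials —
  sessions in this preparation end at 50 rewards; the CS- count is a
  balance convention.
* **Licking**: post-learning sessions start a 7 Hz lick bout in the late
  stimulus/trace period on 90% of CS+ trials, merging into consumption;
  pre-learning sessions lick only after reward; sparse isolated licks at
  0.05 Hz throughout. Bouts are 6-8 Hz regular trains, comfortably above
  the three-licks-per-second bout criterion.
* **Spiking**: inhomogeneous Poisson units at a 5 Hz baseline with
  planted classes in proportions matching the recorded preparation
  (CA1: 40% trace-down, 17% trace-up, 2% lick; PFC: 38% trace-up, 33%
  trace-down, 4% lick). Effect sizes default to ±2 Hz (trace), +6 Hz
  (evoked class, lick, reward) plus a 0.5 Hz sound-evoked gain shared by
  all units; post-learning PFC responds to CS- at 30% of its CS+ gain
  (the learned discrimination), pre-learning sessions have no trace
  modulation and CS-symmetric evoked responses. These values are chosen
  so that the ±1 SD taxonomy, trace-period decoding and the group-level
  sign pattern (PFC CS+ > CS- evoked; CA1 trace suppression) coexist at
  realistic signal-to-noise.
* **Assemblies**: excess synchronous spikes in shared 20 ms windows
  (additive on the Poisson background, per-member participation 0.8),
  events at 0.5 Hz, optionally biased 3× into CS+ or CS- trials and
  coupled to ripples with a configurable probability.
* **Latent drive**: rank-2 cross-area and rank-2 within-area Gaussian
  latents on 100 ms bins (SD 1.5 Hz loadings) plant the communication
  subspace that RRR should recover.
* **LFP**: leaky-integrated white noise (1/f² spectrum above ~0.5 Hz,
  ~150 µV SD) per channel; ripples as Gaussian-enveloped 180 Hz bursts
  (~75 ms, 200 µV) with a Gaussian depth profile across the 16 channels;
  artifacts as 1200 µV transients with an alternating channel profile
  (so the common average reference does not cancel them); one PFC
  channel sharing a 70-90 Hz band-limited component with CA1 during
  trials, creating the planted coherence.

### What one session cannot show at once

The latent common drive and the planted assemblies are both genuine
correlation structure, and the Marcenko-Pastur criterion is agnostic
about timescale: with the default rank-4 latent drive on, the 20 ms
correlation matrix carries extra eigenvalues above the bound, exactly as
slow co-fluctuations do in recorded data. Exact assembly-count recovery
is therefore tested on sessions with the latent drive off, RRR rank
recovery on sessions without assemblies, and decoder power on sessions
without the (CS-independent, correlated-noise) latent drive — each
validation isolates the structure it targets while keeping that
structure at its default strength. The full default session, with
everything on, is used for the end-to-end sign-pattern and behavioral
checks. Passing these tests shows the estimators recover what was
planted under the generator's assumptions — Poisson spiking, linear
rate superposition, stationary noise — not that they are robust to
bursting, non-stationarity, electrode drift or spike-sorting errors,
none of which the generator emulates.

### Problem sizes used in the validation suite

Simulation-based checks run at the generator's default population and
trial sizes (34 CA1 / 54 PFC units, 50+50 trials) with 10-20 seeds per
claim and 60-200 permutations per test; shorter inter-trial intervals
(8-16 s) are used where only trial-locked structure matters, keeping the
sessions compact. These sizes give the power the claims need (e.g.
binomial intervals on decoding accuracy pool 500 held-out trials) and
are stated here as the package's validation conditions.

## Numerical choices and degenerate inputs

* Gaussian smoothing uses mirror padding and a normalized kernel: trial
  totals are exactly conserved, and baseline bins keep mean ≈ 0 after
  z-scoring.
* Zero-variance units are excluded (flagged) from z-scores and from the
  assembly correlation matrix; their pattern weights are 0.
* The RRR Gram matrix always carries a 1e-8 ridge jitter; at full rank
  the estimator still reproduces OLS to 1e-10.
* For long multichannel recordings, `ripple_band_channel()` exploits the
  linearity of the band-pass (the common average reference equals
  subtracting the filtered cross-channel mean) to select and return the
  detection channel without materializing the full filtered matrix; it
  is verified in the tests to match the full-matrix path exactly.
* Long FFTs (envelope, band-limited noise synthesis) are zero-padded to
  highly composite lengths; arbitrary session durations otherwise
  produce FFT lengths with large prime factors and quadratic cost.
* MAD = 0 (constant reactivations) falls back to the fraction above the
  median, flagged.
* Ties in ripple-channel selection resolve to the lowest channel index;
  PCA and ICA signs are fixed by largest-loading conventions.
* The t-test in the learning classifier degenerates gracefully when both
  groups are constant (p = 1 when equal, 0 when separated).

## Known limitations

* The generator plants a symmetric (shared-latent) communication
  subspace; directional asymmetries between the areas are not emulated,
  so directionality claims are outside what the synthetic validation can
  support.
* Single-session permutation tests replace across-session group tests
  wherever the original statistics operate over sessions; multi-session
  aggregation is left to the caller.
* Movement/treadmill covariates are not simulated; the corresponding
  movement-correlation control analysis has no synthetic counterpart.
* The ±1 SD taxonomy's false-flag rate on unmodulated units is inherent
  to the rule (tail of the baseline variability), not a bug; treat the
  flags as descriptive strata, not hypothesis tests.
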