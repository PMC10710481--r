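---
title: "Methods: decoding, replay detection and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding, replay detection and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical procedures implemented in
`replaykit`, the assumptions behind them, the tunable parameters, what the
synthetic session generator does and does not emulate, and the numerical
and design choices made where the method left room.

## The session model

A session is a seven-epoch two-track protocol: a rest period (PRE), first
exposures to two novel linear tracks (RUN1_T1 with more laps, RUN1_T2 with
fewer), a long rest (POST1), fixed-duration re-exposures (RUN2_T1,
RUN2_T2), and a final rest (POST2). All times are seconds from session
start, positions are cm, and intervals are half-open `[start, end)` so
events and epochs concatenate without double counting.

## Position processing

Tracking is cleaned by two rules applied against the last retained sample:
a maximum jump of 40 cm and a maximum implied speed of 100 cm/s; discarded
samples are linearly interpolated. Cleaning is applied *per epoch*: the
carry between the rest box and a track is a teleport under the jump rule
and would otherwise cascade into discarding entire epochs. Position is
projected onto the track axis; speed is the centred-difference derivative
of the linearized coordinate after a 0.4-s moving average of position. The
position smoothing matters: at 25 frames/s, sub-centimetre tracking jitter
differentiates into several cm/s of apparent speed and would destroy the
4-cm/s immobility classification. Laps are full out-and-back traversals
between the 20-cm end zones (the reward-zone span); since the method
defines no crossing hysteresis, the end zones themselves act as the
hysteresis bands.

## Unit classification and ratemaps

Principal cells have waveform half-width-half-max above 500 µs and
session mean rate below 5 Hz. A principal cell is a place cell on a track
when its unsmoothed ratemap there (spikes speed-filtered to 4–50 cm/s)
peaks above 1 Hz. The peak is evaluated on the 10-cm (decoding-scale) map:
on a 2-cm map with thin occupancy (a handful of laps), a single stray
spike in a briefly-visited bin exceeds 1 Hz almost surely, which would make
the rule vacuous. Ratemaps are spike histograms divided by dwell time;
2-cm bins are kept for display, 10-cm unsmoothed maps are the only ones
used for Bayesian decoding. Smoothed maps (Gaussian, sd = 1 bin — the
method names no kernel, so one bin is the minimal choice and it sits in the
configuration) are used only for per-lap directional theta decoding.
Remapping between map sets is quantified by per-position-bin
population-vector correlation; its null permutes unit identities, the
minimal exchangeability null given that the original shuffle is not
specified.

## Decoding

The naive Bayes decoder evaluates, in log space,
`P(x|n) ∝ P(x) Π_i f_i(x)^{n_i} exp(−τ Σ_i f_i(x))`, normalized per time
window across the concatenated bins of both tracks (the description of the
normalization constant as the summed posterior across both tracks is read
as joint-track column normalization). The prior is uniform — nothing else
is specified and the normalization description is consistent with it. A
rate floor of 0.01 Hz enters the `f_i(x)^{n_i}` term only, so an empty
unsmoothed bin cannot produce `log(0)` while the expected-count term still
uses the raw rates. Window lengths: 250 ms for position during running,
20 ms for replay events, 10 ms for theta sequences. Decoding quality
control decodes the re-exposure runs at 250 ms and requires a median
absolute error of at most 15 cm; windows whose maximum-a-posteriori bin
falls on the wrong track are scored the track length (a cap), and only
windows with the animal moving (> 4 cm/s) enter the median, since the
quantity describes decoding of the running trajectory.

## Candidate events and replay scoring

Multi-unit activity pools all units, is binned at 1 ms, smoothed with a
Gaussian kernel (σ = 5 ms) and z-scored. Burst cores are runs above z = 3
no longer than 300 ms; each core is extended to the nearest z = 0 crossings
(the method thresholds peaks but never defines edges; z = 0 matches its
burst/quiescence framing, with the 300-ms cap on the core and the 750-ms
cap on the extended event). Events must contain ripple-band power above
z = 3 (Hilbert amplitude of the 125–300 Hz band, smoothed 0.1 s), events
within 50 ms are combined, and the survivors are dropped if the animal was
moving above 5 cm/s, fewer than 5 units fired, or the duration left
[100, 750] ms. Z-score baselines are computed per epoch; in run epochs the
baseline is restricted to immobility samples, because locomotor
theta-modulated firing otherwise dominates the epoch's mean and variance
and awake bursts can no longer reach z = 3 — the awake-replay analysis is
only about immobility periods in the first place.

Each event is decoded in 20-ms windows (at least five are required) and
scored per track by the weighted correlation of its posterior sub-matrix.
Significance per track requires the score to exceed the 95th percentile
(or `1 − α` quantile generally) of all three shuffle distributions:

1. spike-train circular shift — each unit's count vector shifted
   independently across the event's windows, then re-decoded;
2. place-field shift — each ratemap of the scored track circularly shifted
   in space, then re-decoded (the other track's maps stay intact so the
   joint normalization is preserved);
3. circular shift of position — each time window's posterior vector
   shifted within the scored track.

Replay can run forward or backward, so the score is the absolute weighted
correlation compared against the absolute shuffle scores; the signed value
is reported. Permutation p-values use the `(1 + #{shuffle ≥ obs}) / (1 + n)`
estimator. Events significant for both tracks are assigned by the Bayesian
bias score (one track's posterior mass over the total; must exceed 0.6 or
the event is discarded). Events that fail outright are split at the MUA
minimum within their middle third (ties resolve to the centre) and each
half that still satisfies the candidate criteria is re-scored at α = 0.025;
splitting is attempted only for failed events, and the bias rule applies to
the scored half. Shuffle RNG is seeded per event from the analysis seed and
an event counter, so a rerun reproduces every decision.

Events are labelled by state: in rest epochs, *sleep* when they fall into a
putative-sleep minute (below), else *rest*; in run epochs, *awake-local*
when the assigned track matches the track the animal is on, else
*awake-remote*.

## Putative sleep

One-minute bins are putative sleep when mean speed is below 4 cm/s and the
z-scored MUA of the most active third of units (by total spike count)
averages above 0. The z baseline is the whole rest epoch — the method does
not state one, and an epoch-level baseline avoids leaking run activity into
rest statistics. Cumulative sleep is clocked per bin and analyses use the
first 30 min of cumulative sleep, truncating the final bin so the window is
exact. The LFP control scorer implements the printed threshold rules
(awake: theta-power z > 0.5 and speed > 4 cm/s; NREM: theta z < 0.5, speed
< 4, theta/delta-ratio z > 0.5; REM: theta z > 0.5, speed < 4, ratio
z > 0.5) and reports the correlation between merged NREM+REM and the
MUA-based mask. The NREM/REM rules as printed are mutually inconsistent
with the usual physiology of the theta/delta ratio (NREM is assigned a
*high* ratio); they are implemented exactly as stated since the method is a
control only, and the inconsistency is surfaced here rather than silently
"fixed".

## Theta sequences

Theta cycles are trough-to-trough intervals of the 4–12 Hz filtered LFP
from an alternating peak/trough scan whose amplitude threshold is 25% of
the median absolute filtered amplitude (the cited peak-finding method is
prominence-based; median absolute amplitude is its natural scale here).
Cycles shorter than 80 ms or longer than 200 ms, slower than 5 cm/s, or in
a reward zone are discarded. Spikes within each cycle are decoded in 10-ms
windows with the smoothed directional ratemap of that lap; cycles with
fewer than two active units are skipped. Per-cycle posteriors are centred
on the animal's position (±40 cm), the inbound direction is mirrored, the
time axis is resampled to a common length, and cycles are averaged.
Per-cycle significance uses the same conjunction logic with the
spike-train shuffle, the position-column shuffle, and a phase-axis shuffle
(circular shift along time within each position bin — it disrupts the
phase domain while preserving each position's total probability). The
score is signed by running direction so that a behind-to-ahead sweep is
positive, and tested one-sided. When a cycle cap is configured
(`theta_max_cycles`), a random subsample is scored and the
significant-sequence count is estimated by scaling the subsample fraction
to all decoded cycles — an unbiased estimator used to keep large-session
analyses tractable.

## Session metrics and regression

Sleep replay rate divides the sleep-labelled events of a track inside the
first 30 min of cumulative sleep by 30 min (by the available sleep time,
flagged, when less exists). Awake local replay rate divides local events by
immobile time on the track. The cumulative replay bias is the running
difference of track-1 minus track-2 sleep replay counts against cumulative
sleep time; its final value equals the difference of total counts by
construction. The decay slope regresses per-10-min-bin replay rate on
cumulative sleep time. Simple regressions report adjusted R² (negative
values in the source quantities are only possible for the adjusted form,
so that is the convention followed; the plain R² is also returned). The
mixed model fits the z-scored response on z-scored fixed effects with a
random intercept per animal via `lme4`, with Wald 95% intervals; a
predictor is significant when its interval excludes zero. Wilcoxon
signed-rank comparisons are two-sided and exact where R's implementation
permits.

## The synthetic generator

The generator emulates exactly the structure the pipeline assumes: two
tracks with independently drawn Gaussian place fields (global remapping)
stable across exposures; lap-structured running at ~20 cm/s with reward
pauses at the ends; inhomogeneous-Poisson spiking with unit-mean von Mises
theta-phase tuning whose preferred phase precesses linearly through the
field (so theta sequences sweep behind-to-ahead within trough-to-trough
cycles); rest epochs alternating whole-minute awake and sleep bouts with
state-dependent baseline rates, persistent-velocity wander in the rest box,
and scheduled time-compressed replay bursts (150–350 ms, ≥ 5 units in
field order along a virtual trajectory at `replay_compression` × running
speed) confined to true sleep; LFP as pink noise plus a movement-gated
theta sinusoid, a sleep-gated delta component and ripple-band bursts
(amplitude 8 × the baseline band SD) coincident with replay. Narrow-spike
high-rate interneuron units are included so the principal-cell classifier
has something to reject and MUA has a realistic floor.

Defaults follow the protocol scale: 200-cm tracks, 16 laps on track 1 and
1–8 (default 4) on track 2, 25-Hz position sampling, 1-kHz LFP, 8-Hz
theta, 15-Hz peak rate with 15-cm fields, sleep replay rates of
0.03/0.02 events/s for tracks 1/2 and awake replay at 0.1 events per
second of pause, near the observed rates for this kind of protocol. Default
POST sleep is 30 min of true sleep, the window all analyses use.
Determinism: one integer seed; each epoch draws from a sub-stream derived
by a fixed offset, so a fixed configuration yields a byte-identical
session.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: spike-sorting errors and unit drift,
non-Poisson firing (bursting, refractoriness), experience-dependent field
development within a session, genuine NREM/REM architecture beyond the
threshold rules, biophysical LFP structure beyond band power, partial or
rate remapping, and any behavioral learning across sessions. Results on
synthetic sessions validate the *implementation* of the statistics, not
the biological claims.

## Problem sizes and numerical choices

The test suite runs at deliberately modest scales chosen as representative
rather than exhaustive: the shared unit-test session uses 15 cells/track
and 6-min POST sleeps; the end-to-end recovery check uses the full default
session (50 cells/track, 30-min sleeps, ~90 embedded sleep events); the
type-I check scores 500 structureless events at 1000 shuffles; the
mixed-model check runs eight coupled sessions (30 cells/track, 20-min
sleeps) in which the sleep replay rate is driven only by the embedded
awake replay count while lap counts and awake rates vary independently of
it; the lap-monotonicity check compares 2/4/8-lap run epochs with a
120-cycle scoring subsample. Oracle comparisons (decoder, weighted
correlation) are exact to 1e-12 in double precision. Degenerate inputs are
defined away rather than patched: zero weighted variance yields `NA` and
the event simply fails significance; zero-occupancy bins carry rate 0 and
are floored only inside the likelihood power term; a flat MUA trace yields
no events, not an error.

## Known limitations

The theta-phase window assignment uses trough-to-trough time windows
rather than interpolating each spike's unwrapped phase onto a 2π grid; for
the regular oscillations the generator produces the two coincide, but on
strongly asymmetric real theta they can differ near cycle edges. The
decoding-error cap for wrong-track windows (track length) is a reporting
convention, not part of the decoder. The LFP sleep-control rules are
implemented as printed despite their internal inconsistency. The
`n_shuffles` default of 1000 gives a p-value floor of ~0.001; studies
needing smaller p-values must raise it.
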