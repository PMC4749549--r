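---
title: "Methods: drift statistics and time decoding for longitudinal calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drift statistics and time decoding for longitudinal calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftclock)
```

## The scientific problem

Hippocampal CA1 ensembles recorded over days show *representational drift*:
even when an animal repeats the same task in the same environment, the subset
of active cells and their event rates change gradually from day to day, while
the spatial tuning of cells that do recur stays put. driftclock implements the
analysis chain for experiments probing this phenomenon on linear tracks: a
mouse runs five 3-minute trials per session, two sessions per day (one in each
of two distinct environments, A and B), every other day for 15 days (recording
days 1, 3, ..., 15), imaged at 20 Hz with a head-mounted one-photon
miniscope. The central question the decoders answer: does ensemble activity
carry a *timestamp* — enough time-specific structure to infer, from a single
trial or session, on which recording day it happened?

## The synthetic experiment

No public dataset accompanies this class of experiment, so all testing runs on
a generator whose ground truth is known (`sim_config()`,
`generate_dataset()`). It emulates the drift phenomenology the analyses
assume, with three mechanistically separate components:

* **Recruitment.** Each cell's day-to-day activity follows a 2-state Markov
  chain with persistence `recruitment_persistence` (default 0.8 per 2-day
  step) and stationary activity `active_fraction` (0.6). By default one chain
  is shared between the environments (`shared_recruitment = TRUE`), with each
  day-active cell expressing in a given environment with probability
  `env_active_prob` (0.9); the recurrence probability of an active cell then
  decays geometrically toward its stationary level with elapsed days, in both
  the same and the other environment.
* **Rate drift.** Log event rates follow Gaussian random walks: a walk shared
  between environments (`shared_drift_sigma`, default 0.12 per calendar day)
  and an environment-private walk (`env_drift_sigma`, 0.06). The shared walk
  is the cross-environment timestamp; the private walk decorrelates the
  environments without carrying one. A static per-cell, per-environment gain
  (`env_gain_sigma`, 0.4) produces rate remapping from day one, which keeps
  within-environment correlations above across-environment correlations at
  every lag (the checkerboard structure of the session correlation matrix).
* **Spatial tuning.** A configurable fraction of cells (0.7) carry a Gaussian
  place field (sd `field_width` = 5 cm on a 96 cm track) whose center is
  fixed across days; under `remap_mode` the two environments draw centers
  independently (global remapping). Events are drawn from an inhomogeneous
  Poisson process, intensity = active flag x exp(log-rate) x tuning(position).

Behavior is a constant-speed (20 cm/s) back-and-forth lap model with
exponentially distributed pauses (mean 1 s) at the track ends, where rewards
are consumed; the pauses provide the stationary epochs that the running-speed
filter and end-bin exclusion must handle. Optional forward models render dF/F
traces (double-exponential kernel, rise 0.05 s, decay 1 s — a slow-indicator
time course — plus white noise) and per-session spatial footprints (Gaussian
somata of sd 6 um, centroid jitter 1.5 um per session per axis, minimum
soma separation 15 um).

Defaults were chosen once to be realistic for CA1 one-photon imaging: mean
event rates of ~0.05 events/s, a few tens of events per cell per session,
60% of cells active per session with ~70-80% day-to-day recurrence, ensemble
correlations decaying from ~0.5 (2-day lag) toward ~0.1 (14-day lag).

What the generator deliberately does **not** emulate: movement artifacts and
neuropil contamination, non-Poisson burstiness, theta-phase structure,
multi-field cells, behavioral variability (speed, lap count), and slow
indicator photobleaching. A green test suite on this generator therefore
validates the *statistical machinery* — estimator identities, null
calibrations, decoder contracts — not robustness to every pathology of real
recordings.

### One root seed, named substreams

All randomness derives from `sim_config(seed = ...)` through
`substream_seed(seed, name)`, so each stage (trajectory, model, events,
traces, footprints, label shuffles) is bit-reproducible independently of
which other stages run. Fixed seed implies byte-identical datasets.

## Event detection

`preprocess_trace()` subtracts a 20 s sliding-window median and applies a
zero-phase second-order Butterworth low-pass at 2 Hz (the filter family is a
design choice; only the cutoff is dictated by the analysis convention).
`detect_events()` then:

1. takes local maxima above `mad_threshold` (4 for slow, 5 for fast
   indicators) times the raw median absolute deviation of the trace — raw
   MAD, without the 1.4826 normal-consistency factor, since the integer
   multipliers are empirical and absorb the constant;
2. merges maxima separated by shallow troughs: within a transient, a later
   peak survives only if it rises `peak_over_prev` MAD above the intervening
   trough and the earlier peak drops `peak_over_next` MAD to it — one event
   per calcium transient, timed at its fluorescence peak;
3. applies a kinetic filter: rise and decay times are measured symmetrically
   as the time between the peak and its 1/e-of-peak crossings (the backward
   scan stops at a preceding trough, so a transient riding another's decay is
   timed from that trough). The decay must fall within `decay_tol` (default
   0.2x-5x) of the nominal indicator decay and the decay/rise ratio must be
   at least `decay_rise_ratio_min` (default 2). A decay that the trace ends
   before revealing is not held against the event.

The 1/e convention matters: a zero-phase low-pass symmetrically widens
onsets, so measuring rise depth-asymmetrically (e.g. down to 10% of peak)
inflates rise times and rejects genuine slow-indicator transients whose
filtered decay/rise ratio sits near 2.

`resolve_crosstalk()` enforces that cells with session centroids closer than
18 um never both register an event within a 200 ms window (closed interval
on the peak-time difference): the highest peak wins. Neighbor pairs whose
event trains correlate above 0.9 — computed on 100 ms-binned event counts, a
documented interpretation since the convention does not specify the
correlation substrate — lose the lower-mean-amplitude member outright, as a
duplicate component of a single cell.

On rendered traces at the default SNR, detection recovers planted transients
with precision and recall above 0.9. Ground truth here is the *resolvable
transient*: two Poisson events landing within the kernel's decay of one
another render as one compound fluorescence transient, which no peak-based
detector is expected to split — exactly the situation the one-event-per-
transient rule codifies.

## Across-session registration

Footprints are thresholded at 50% of their maximum (`footprint_qc()`), with
sub-threshold pixels set to exactly zero; filters with effective radius
outside 5-14 um or circularity below 0.8 are discarded. Circularity is
`4*pi*A/P^2` on the thresholded mask with the perimeter estimated from the
4-connectivity boundary edge count scaled by pi/4 (Cauchy-Crofton), clamped
to 1 — on a pixel grid an ideal disk then scores ~0.9-1.

`align_session_maps()` estimates one rigid transform per session into a
reference session's frame (the first session by default; one global
reference-anchored alignment rather than chained pairwise alignments, since a
single reference is sufficient and keeps the transforms consistent). The
projection cross-correlation between centroid maps is maximized sparsely: for
each candidate rotation, the pairwise centroid displacement field is
histogrammed on a 2 um grid, the top displacement modes are scored by their
mutual-nearest-neighbor match count, and the best coarse match is refined by
an iterated closed-form rigid (Kabsch) fit on mutually nearest pairs. Planted
transforms of a few degrees and microns are recovered to well under 0.25
degrees and ~1 um.

`register_cells()` then walks sessions in order, comparing each local cell to
the running master list either by footprint spatial correlation (register if
> 0.7) or by centroid distance (register if < 5 um). Candidates are assigned
greedily from the best score down — deterministic and order-independent after
the score sort, which is the package's resolution of how competing candidates
are arbitrated. Unmatched cells found new master identities (cells active in
a single session get singleton ids, which the per-session activity accounting
needs). Master centroids are running means over their assigned sessions,
which halves the effective jitter as evidence accumulates. Footprint patches
are compared after translation only: the synthetic somata are isotropic, so
the residual sub-degree rotation is immaterial; real pipelines with
anisotropic footprints would rotate the patch.

Within a session, nearest-neighbor footprints correlate below 0.6 and sit
more than 6 um apart under the default geometry, while the same cell across
sessions correlates far above 0.7 — the separation that makes the thresholds
work, summarized by `registration_quality_stats()` together with the
candidates-per-cell curve (flat near 1 over thresholds 0.5-0.85 at low
jitter). Downstream decoder accuracy agrees between the two methods within 5
percentage points on a fixed dataset.

## Place fields and population vectors

The 96 cm track is divided into 24 bins of 4 cm; the last two bins at each
end are excluded (bins 3-22 are valid; 1-based indexing). Only frames with
running speed above 1 cm/s count, separately per running direction.
`compute_rate_map()` smooths the occupancy and event-count maps with a
truncated Gaussian kernel (sigma 1.5 bins, size 5 bins) and divides them;
the field position is the peak of the smoothed map, ties broken toward the
lower bin.

Spatial information (bits/event) is computed on the *unsmoothed* rate map:

$$\mathrm{SI} = \sum_i p_i \frac{r_i}{\bar r} \log_2 \frac{r_i}{\bar r},
\qquad \bar r = \sum_i p_i r_i,$$

with $0 \log 0 \equiv 0$; it is zero on a uniform map, $\log_2 n$ on a
single-bin map over $n$ equally occupied bins, and invariant to rate
rescaling. Significance (`place_field_significance()`) redraws each event's
position from the session/direction occupancy distribution — an
occupancy-weighted independent redraw, the package's interpretation of
shuffling "accounting for spatial coverage"; a circular-shift shuffle is the
main alternative and would preserve within-trial event autocorrelation that
the generator does not produce. With 1000 shuffles,
$p = (1 + \#\{SI_{\rm shuffle} \ge SI_{\rm obs}\})/(1001)$ — the add-one
estimator avoids $p = 0$. Cells with 5 or fewer events are ineligible. On
occupancy-null cells the test's type-I error at $p \le 0.05$ is calibrated
to 5%.

Field-shift distributions between days use a cell-identity shuffle null
(independent permutations on each day, 10,000 shuffle pairs), symmetric about
zero by construction; stable fields concentrate the observed distribution at
zero and a two-sample KS test quantifies the separation.

`population_vector_correlation()` correlates, bin by valid bin, the vector of
all cells' rates (both directions stacked) between two sessions and averages
over bins. Zero-variance bins are skipped rather than scored 0: the Pearson
correlation is undefined there, and skipping matches averaging over positions
with defined values. Because two linear tracks admit two end-to-end
alignments, cross-environment comparisons evaluate both (reversing bin order
and swapping directions) and keep the higher mean — the same convention feeds
`peak_displacement()`.

## Drift statistics

`ensemble_correlation_matrix()` correlates the 16 session-level activity
vectors and summarizes mean correlation against elapsed days, split into
within- and across-environment pairs. `recurrence_probability()` reports
P(active at lag | active), within- and across-environment; the
across-environment conditioning is P(active in the other environment at
d + lag | active in one at d), with the both-environments conditioning
variant left to the caller by filtering the activity flags. Rates are
expressed per minute of session; divergence and CV are unit-free.

`activity_divergence()` is the ratio of mean absolute trial-rate differences
across environments to those within environments (1 = environments no more
different than trial-to-trial variability). `peak_displacement()` averages
per-cell distances between the two environments' peak locations under the
PV-selected alignment. `maximal_monotonic_sequence()` measures the longest
run of same-sign consecutive-day rate differences (ties break runs — a zero
difference evidences neither trend, matching the score's treatment of tied
pairs); `monotonicity_score()` normalizes the signed count of ordered day
pairs by the 28 pairs of an 8-day series. `rate_cv_poisson_null()` compares
session-rate CVs of always-active cells with matched stationary Poisson
simulations (a drifting population stochastically dominates its Poisson
null); the null mean CV is $\approx 1/\sqrt{\text{mean count}}$ up to the
small-sample bias of an 8-session sd. `population_monotonicity()` aligns
each cell's normalized rates to its peak day (earliest on ties), giving 1 at
lag 0 by construction and a curve that decays with |lag| under drift but is
flat under per-cell day permutation.

## Time decoders

All decoders work on ensemble activity vectors (`build_activity_vectors()`):
per-episode event counts over the full registered master list, zeros for
absent cells, with optional restrictions (running epochs — speed >= 1 cm/s
and more than 8 cm from either end; stationary epochs; place-cell or other
cell subsets; trial segments of a chosen duration). Correlations are Pearson
over the full master list, zeros included, with a zero-variance guard.

**Ordinal decoder.** Over all orderings of the 8 days up to reversal
(8!/2 = 20160 classes — the objective is reversal-invariant, hence the /2),
maximize the mean correlation between patterns on neighboring days; with
both environments included the objective averages the two environments under
a common ordering. The permutation p-value of the true chronological order
is its objective's rank among all classes; when the true order is the unique
maximum, p = 1/20160 < 5e-5. Under default drift the true order usually
wins, but a days-scale random walk can legitimately back-track (day 8
resembling day 4 more than day 5 does), in which case a near-chronological
ordering scores higher; the permutation p-value, not guaranteed recovery, is
the decoder's contract.

**Within-environment decoder.** Each test trial $j$ of day $i$ is scored
against every candidate day $d$'s training pattern $V_d - v_{d,j}$ (the
corresponding trial index is excluded from *every* training session, not
just the test day's, to evade bias), with the correlation normalized by
subtracting the mean correlation of trial-$j$ vectors from all days against
that training pattern. The normalization expectation runs over all 8 days
including $d$ itself, exactly as the scoring rule is defined. Argmax ties
break toward the earlier day, deterministically. With `exclude_same_day`
the test day leaves the candidate set; under drift the inferred day is then
overwhelmingly a +-1 recording-day neighbor. Errors are counted in
recording-day steps (one step = 2 calendar days).

**Across-environment decoder.** Test episodes from one environment are
scored against the other environment's sessions, session-level or
trial-level; the trial-level variant subtracts the same trial index from
each training session, mirroring the within-environment exclusion (the
package resolves the trial-index bookkeeping of the two-environment case by
excluding matching indices on the training side). Only the shared drift
component can support this decoder: with `shared_drift_sigma = 0` and
independent recruitment it sits at chance (12.5%), the package's
falsification control, while any shared component lifts it above chance.

**Chance controls.** `shuffle_day_labels()` permutes each cell's day
sequence independently (preserving the per-cell multiset of day counts).
The ordinal decoder is evaluated directly on shuffled session patterns;
trial-level decoders decode the *original* test trials against shuffled
training patterns — permuting test and training together would move each
cell's test trial with its own session and leave accuracy intact. The
leave-trial-out subtraction remains exact through the shuffle. Accuracies
over shuffles are compared at the shuffle level (items within a shuffle
share its permutation, so the binomial SE understates the spread).

## Problem sizes and numerical choices

The test suite and the acceptance script run on 80-150 cells with the full
8-day x 2-environment x 5-trial schedule — large enough for every
statistical check to have power, small enough to keep a full run in minutes.
Null calibrations use 199-500 shuffles with the add-one p estimator;
closed-form checks (Markov recurrence, Poisson CV, uniform-displacement
means) are asserted within 3 standard errors of their analytic values.
Degenerate inputs error early and by name: zero-variance sessions, zero
occupancy, zero mean rate, all-excluded candidate sets, sub-minimum cell
counts.

## Known limitations

* The drift model is a minimal phenomenological stand-in (Markov recruitment
  plus log-normal rate walks); it reproduces decaying correlations, stable
  fields and cross-environment timestamps, but not, e.g., experience-
  dependent drift rates or within-session nonstationarity.
* Registration compares footprints by translation only and models rigid
  motion; non-rigid deformation is out of scope.
* Decoders are correlation-based by design; likelihood-based or Bayesian
  day decoding is out of scope.
* Trial segments tile from seeded random offsets; inter-trial intervals are
  not modeled, so segment decoding reflects within-trial data volume only.
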