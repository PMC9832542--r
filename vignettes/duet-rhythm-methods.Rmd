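---
title: "Rhythm, causality and synchrony in duetting song: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm, causality and synchrony in duetting song: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duetrhythm)
```

## Scope

duetrhythm analyses interval-annotated animal vocal sequences — songs in
which every note of every singer has an annotated onset and offset — with
an emphasis on duetting species such as gibbons. It computes four families
of statistics: rhythm-ratio/isochrony measures, call rates, a bidirectional
Granger-causality census between co-singers, and phonation-overlap
(synchrony) measures with a chunk-permutation chance model. It does not fit
the downstream mixed models a comparative study would use; it produces the
per-contribution and per-chunk tables such models consume.

## Rhythm model

For a contribution with onsets $o_1 < o_2 < \dots$, the inter-onset
intervals are $t_k = o_{k+1} - o_k$. Intervals above a ceiling (default
5 s, the conventional upper bound for meter perception) are masked: they
stay in the sequence as excluded values but are never bridged, so no
derived quantity mixes rhythm across a long silence.

The rhythm ratio of two adjacent intervals is

$$r_k = \frac{t_k}{t_k + t_{k+1}} \in (0, 1),$$

which is 0.5 exactly when $t_k = t_{k+1}$ (isochrony, a 1:1 interval
ratio) and is invariant to a global tempo rescaling. Ratios are computed
only for pairs where both intervals are adjacent in the original note
sequence and both survived the ceiling.

### On/off-isochrony bands and the isochrony rate

Ratios are tallied into an on-isochrony band around 0.5 and two flanking
off-isochrony bands, delimited by the four cut points 0.400, 0.440, 0.555,
0.600. Three conventions are worth making explicit, since the cut points
alone do not determine them:

* the on-band is closed, $[0.440, 0.555]$; the off-bands own their outer
  endpoints and exclude the shared inner ones, $[0.400, 0.440) \cup
  (0.555, 0.600]$ — so every ratio inside $[0.400, 0.600]$ is counted in
  exactly one sector;
* ratios outside $[0.400, 0.600]$ belong to neither sector and appear only
  in the total;
* the cut points are deliberately asymmetric about 0.5 (0.060 below,
  0.055 above) and are used verbatim, not symmetrized.

The *isochrony rate* is the on/off count ratio per contribution or chunk.
When the off-count is zero the rate is reported as undefined rather than
smoothed with a pseudo-count: the statistic is used log-transformed
downstream, and an invented offset would change it. Perfectly regular
synthetic songs therefore produce *undefined* rates, not infinite ones, in
the output tables (the raw counts are always reported alongside).

### Call rate

Call rate is the number of note onsets per 10-s window, in Hz. Windows are
consecutive, non-overlapping, and anchored at the contribution's first
onset; the final partial window (relative to the last note offset) is
discarded, since a short remainder would bias rates downward. The
high/low split is taken at the median of the song type, with ties
assigned "low" — the split is defined by "above the median", and a value
exactly at the median is not above it.

### Tempo peaks

Pooled $t_k$ values per song type are summarized by a Gaussian kernel
density estimate on a 1-ms grid over $(0, 5]$ s, with Silverman's
rule-of-thumb bandwidth by default (configurable; for degenerate
zero-variance input the bandwidth falls back to one grid step). Peaks are
local maxima exceeding 5% of the global density maximum, and each peak's
tempo is its exact inverse, so `tempo * peak_ioi == 1` holds identically.

## Granger-causality census

Each contribution is binarized at 10-ms resolution: a bin is 1 when it has
any positive intersection with a note interval. Co-singers share one time
base spanning from the earlier first onset to the later last offset. A
small numerical guard (1 ns) keeps bin assignment stable when note
boundaries fall exactly on bin edges.

The directional test is the standard Granger construction on ordinary
least squares, kept linear despite the 0/1 response: the restricted model
regresses the target series on its own $L$ lags plus an intercept, the
full model adds $L$ lags of the source, and

$$F = \frac{(\mathrm{RSS}_r - \mathrm{RSS}_f) / L}
          {\mathrm{RSS}_f / (n_\mathrm{used} - 2L - 1)}$$

is referred to the $F(L,\, n_\mathrm{used} - 2L - 1)$ distribution. The
default lag order is 5 bins (50 ms of history). The reference analysis
this mirrors printed a second number, an "order" of 500, whose meaning in
the cited routine is ambiguous; the `max_len` option truncates series to
500 bins to reproduce that reading, and both knobs are exposed rather than
guessing intent. Degenerate fits (constant target, collinear design, or a
series too short for the lag order) yield a flagged result with an
undefined p-value and count as non-significant in the census; they are
reported, never dropped.

A duet is classed *reciprocal* when both directions are significant at
$\alpha$ (default 0.001), *one-way* when exactly one is, *none*
otherwise. The census restricts to wild-recorded songs by default, since
captive recordings carry external disturbances; a flag lifts the
restriction.

One property of this machinery deserves emphasis. With a strongly
periodic singer, the 5-lag autoregression understates the singer's own
predictability, and a partner who *responds* to it carries information
about its longer history; the reverse direction of a one-way coupling can
then test significant as well. This is a known behaviour of short-lag
bivariate Granger tests on periodic point processes, not an implementation
artefact; the test suite therefore asserts calibration on independent
series and power in the genuinely coupled direction, and does not assert a
null rate for the reverse direction of a coupled pair.

## Synchrony and the permutation chance model

A singer's phonation set is the disjoint union of its note intervals. The
overlap between co-singers is the exact summed intersection, computed by a
linear sweep over the merged endpoints (the suite cross-checks it against
a discretized 1-ms oracle). Three metrics come from one pass: raw overlap
in seconds; the per-singer rate, overlap over that singer's total
phonation, in $[0, 1]$; and the *normalized overlap*, overlap over the
summed phonation of both singers, in $[0, 0.5]$, attaining 0.5 exactly
when the two phonation sets coincide.

For the chance model, songs are cut into 3-min chunks on the song's own
time grid (shared by both singers); notes are clipped at chunk borders and
each chunk is re-based to zero. The final partial chunk is kept when at
least 30 s long (configurable; at 0 the chunking conserves phonation
exactly). Simulated duets pair a female chunk with a male chunk it did not
originally co-occur with — from the same mated pair's repertoire
(*real couples*) or from different groups (*random couples*); pairings are
always female x male. Because chunks can have unequal spans, both members
of a pair are truncated to the shorter span before the overlap is
computed, which keeps the normalized metric comparable across pairs. Draws
sample eligible pairings uniformly with replacement, under an explicit
seed.

The comparison of real duets against a null distribution uses the add-one
empirical estimator $p = (1 + \#\{\mathrm{null} \ge
\overline{\mathrm{real}}\}) / (1 + n_\mathrm{null})$, which can never
return zero, plus a bootstrap percentile interval for the mean difference.
The REAL-vs-SIMULATED mixed model of a full comparative analysis is out of
scope; the long labelled table it needs is emitted instead.

## The synthetic-duet generator

Field recordings are not required for testing: the generator produces
songs with known ground truth for every quantity the pipeline estimates.

Each singer is a jittered renewal process. An interval is, with
probability `pause_prob` (default 0.1), an inter-phrase pause drawn
uniformly from 2–8 s; otherwise a draw from a one- or two-point tempo
mixture plus Gaussian jitter truncated at a 0.05-s floor. Default tempi
are the characteristic IOI peaks of the three gibbon song types
(0.181/0.503 s female duet, 0.204/0.637 s male duet, 0.322 s male solo);
jitter defaults to 0.02 s; note durations are Gaussian (mean 0.12 s, sd
0.03 s), truncated positive and clipped below the following interval so a
singer never overlaps itself. The pause component exists because real
songs have phrase structure: without it, a pure mixture of the short
tempo peaks would imply call rates several times the field magnitudes.
With it, default call rates land near 1 Hz while the IOI density still
peaks at the configured tempi (pauses almost always exceed the 5-s
ceiling or fall far outside the peak region).

Coupling is applied at onset-generation time, not by post-hoc shifting.
The two singers are generated jointly in time order; when a coupled
singer's partner has sung since the singer's own last note, the next onset
is the convex combination $(1-c) \cdot (\text{own renewal time}) + c \cdot
(\text{partner's latest onset} + \text{lag})$, floored at the minimum
interval; otherwise the singer renews independently. The guard matters:
without it, a singer anchored to a long-past partner onset would fire at
the interval floor during the partner's pauses. At $c = 1$, zero lag and
deterministic durations the follower reproduces the leader exactly, which
pins the normalized-overlap maximum of 0.5; at $c = 0$ the singers are
independent, which pins the Granger null and the permutation-null
expectation $d_f\, d_m \cdot \text{chunk}_s$ for the mean per-chunk
overlap at duty cycles $d_f, d_m$. This parametrization is an invention
for testing — no quantitative coupling model exists for real duets — and
ground truth for every parameter is recorded with each generated dataset.

## Numerical and design choices

* Ceiling-filter adjacency: never bridge a masked gap (a bridged ratio
  would mix non-contiguous rhythm).
* Abutting notes (offset exactly equal to the next onset) are accepted as
  distinct notes; only positive-measure overlap is a validation error.
* TextGrid I/O accepts long and short text formats in UTF-8 or UTF-16
  (both occur in Praat field data) and always emits long-format UTF-8;
  tier names encode `<individual_id>_<sex>` unless an explicit tier map
  is supplied. Round-trips preserve times to well below 1 ns.
* Binarization uses a 1-ns epsilon on bin-edge comparisons so that exact
  multiples of the bin width do not flip bins through floating-point
  noise.
* KDE grid step 1 ms; peak prominence threshold 5% of the maximum;
  plateau maxima resolve to their left edge.
* Median-split ties go to "low"; the split is invariant to row order.
* The permutation engine's seed is local: it never perturbs the caller's
  RNG state.

## What the tests do and do not show

The suite verifies the analytic identities (ratio reversal and scale
invariance, the 0.5 isochrony point, the overlap bounds, tempo-peak
inversion), agreement with independent oracles (explicit normal-equations
Granger on short series, a discretized intersection oracle), and the
statistical behaviour of the pipeline on generated data: type-I
calibration at $\alpha = 0.001$ over 1000 independent-series replicates,
&gt;90% detection over 200 coupled duets of at least 3000 bins, a falling
pooled isochrony rate over a jitter grid of 0 to 0.1 s (200 contributions
per point; pooled on/off counts, since per-contribution rates are all
undefined at very low jitter), tempo recovery within one KDE grid step at
jitter up to 0.01 s, the independence expectation of the permutation
null, and uniformity of the chance-test p-value over 200 null replicates.
These problem sizes are the package's chosen trade-off between
statistical resolution and a test suite that runs in minutes.

Passing them shows the machinery is correct on data matching the
generator's assumptions: renewal-like tempo structure, Gaussian jitter,
stationary duty cycles, a convex-combination response rule. Real songs
have section structure (introductions, climaxes, codas), drifting tempo
and amplitude-dependent annotation error, none of which the generator
emulates; conclusions about real repertoires still require real
annotated recordings. The pipeline's real-data outputs (call-rate
magnitudes, overlap means, census percentages) depend on those recordings
and are not reproduced by any test here.
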