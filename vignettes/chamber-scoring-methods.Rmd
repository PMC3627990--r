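---
title: "Scoring escape behavior in a 1-D conditioning chamber: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring escape behavior in a 1-D conditioning chamber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(apistrack)
```

## The assay

A forager honey bee walks freely in a translucent corridor 14.8 cm long and
2 cm wide whose inner surfaces carry an electrifiable grid. Odors enter
from the two narrow ends; 26 infrared photo sensors report the bee's
position along the corridor at 5 Hz. Training pairs one odor (CS+) with a
mild shock train (3 s at 1.2 pulses/s, 200-ms pulses, 10 V; starting 2 s
after odor onset on the bee's first CS+, 1 s thereafter) while the other
odor (CS−) is never reinforced. Eight 4-s training stimuli are presented in
a pseudorandomized order (ABBABAAB or BAABABBA, A = CS+) with a 34-s
inter-trial interval; five minutes later four unreinforced test stimuli
(ABBA or BAAB) probe short-term memory. During the test the odor is
released on whichever side the bee occupies, giving it the opportunity to
withdraw.

Positions are expressed in cm on a symmetric axis: 0 at the midline, −7.4
at the left end, +7.4 at the right end. Each stimulus carries a side index
SI ∈ {−1, +1} marking the injected end, and every readout below is
expressed odor-relative through SI, so left/right asymmetries cancel.

## The three readouts

**Escape.** A presentation counts as an escape when the bee starts on the
odor side and crosses the midline without returning before the stimulus
ends. On the discrete 5-Hz grid this is evaluated as: there exists a sample
from which *all* remaining in-window samples lie on the non-odor side. The
side of a sample is `sign(x)`; a sample exactly at 0 inherits the side of
the previous sample (there is no sensor at the midline, so this arises only
in hand-made traces). Working on samples rather than any reconstructed path
means a single 0.2-s excursion back across the midline cancels the call —
the strict reading of "without returning", and the only one available for
real logs. A bee caught on the wrong side at onset (possible in training,
where sides are scheduled) is flagged `start_side_ok = FALSE` and excluded
from rate summaries rather than scored as a non-escape.

**Signed velocity.** Velocity is computed over the first 2 s of the
stimulus from the dwell structure of the trace: consecutive samples at the
same logged position collapse into one knot at the midpoint of the dwell,
and a natural cubic spline is fitted through the knots. The reported value
is the mean of the spline's derivative over the window, which by the
fundamental theorem of calculus is just the endpoint form
`SI * (s(t0 + 2) - s(t0)) / 2`. Documenting this equivalence matters: no
numerical differentiation is ever needed, and the spline's real job is to
interpolate the boundary positions when the window edges fall between
knots. Outside the knot range the spline is extended with the nearest knot
value rather than extrapolated linearly — extrapolating through the first
dwell of a freezing bee manufactures spurious displacement, and the
constant extension parallels the boundary rule of the integral below.
Fewer than two distinct knots means a stationary bee and a velocity of 0.

**Attractance Index.** The raw quantity is the side-signed time integral
of position over the 4-s window, approximated with the composite trapezoid
rule over the samples, with the two boundary positions taken at exactly the
onset and offset times by linear interpolation between the flanking
samples (nearest sample extended at a trace edge). The trapezoid rule is
exact on piecewise-linear traces, which the logged dwell-and-step data
locally are. Raw integrals are then normalized over the pooled population
of all test stimuli of all bees in the analysed cohort:
`ai = 2 (raw - min) / (max - min) - 1`, so the observed minimum and maximum
map to −1 and +1. This min–max mapping is the default because the
published values span exactly [−1, 1]; a zero-preserving alternative
`ai = raw / max(|min|, |max|)` is available behind
`normalize_ai(..., method = "symmetric")` for analyses where "integral 0 ⇒
AI 0" matters more than attaining both extremes. Whether the original
normalization pooled both signs jointly is not documented; joint pooling is
assumed, and the constants are stored in the output so AI values remain
comparable across runs. A degenerate cohort (all integrals equal) maps to
0. AI ≥ 0.3 is classified as attraction, ≤ 0.1 as avoidance, the open
interval between as indeterminate.

## The statistical layer

Escape rates are summarized with exact Clopper–Pearson intervals
(`stats::binom.test` under the hood; the tests validate the bounds against
direct tail inversion). Between-group rate comparisons use the 1-df
chi-square proportion test (`prop.test`, continuity correction on by
default); within-bee comparisons use McNemar's test on the discordant
pairs. McNemar defaults to the uncorrected textbook statistic
`(b − c)² / (b + c)` with the continuity-corrected variant behind a flag;
because the pairing actually used for the published within-method
chi-squares is not documented, `cohort_stats()` reports both per-trial
pairings (1st CS+ vs 1st CS−, etc.) and a per-bee pooled pairing, labelled
as such. No multiple-testing adjustment is applied anywhere; raw p-values
are reported.

Group means of velocity and AI by stimulus class are compared with a
cluster bootstrap instead of a linear mixed model with bee as random
effect: bees are resampled whole, with replacement, within each group;
each group gets its observed mean and a percentile 95% interval; and the
significance measure is the overlap probability — the fraction of one
group's resampled means falling inside the other group's interval, the
same decision rule used with simulated posterior parameter sets. The
bootstrap delivers the identical deliverables (means, intervals, overlap
probabilities) without re-implementing REML machinery, is exact about the
clustering, and with flat-prior Gaussian models the posterior intervals it
replaces closely resemble confidence intervals anyway. With every cluster
of size one it reduces to the ordinary case bootstrap. Rank correlations
(velocity–escape, AI–escape, velocity–AI) use the tie-corrected
average-rank Spearman coefficient with a case-bootstrap standard error.

## The simulator

No raw traces were deposited with the original experiment, so the package
carries an agent-based simulator that doubles as the fixture generator for
every test. A bee is a four-mode state machine — explore, attracted,
escaping, startled — integrated at 50 Hz with Euler steps; only the 5-Hz
sensor-quantized trace is exported, so the scoring never sees the hidden
path. Quantization reports the center of the sensor interval the bee
occupies (pitch 14.8/26 ≈ 0.569 cm, error ≤ 0.285 cm), rounded to 4
decimals, the resolution of the log dialect — which is why a written log
re-reads into an identical record.

Between stimuli the bee shuttles end to end: it walks at `explore_speed`
(2 cm/s, chosen so the chamber is traversed several times per 34-s
inter-trial interval) to a drawn waypoint, pauses 0.3–1.5 s, and heads off
again, choosing the left half with probability `left_bias` (0.5 by
default; the published side bias has no printed magnitude, so the default
is symmetric). During training CS+ windows the bee startles — an
instantaneous `startle_jump` displacement at each shock pulse and a
transient speed-up. Training behavior is simulated but never scored,
mirroring the fact that acquisition could not be quantified at 5 Hz in the
original assay.

On each test stimulus the odor side is set to the bee's current side (the
delivery rule of the assay) and an escape is drawn with probability
`p_escape_csplus` or `p_escape_csminus`. The same probability is applied
to both trials of a class because the first-to-second change in the
published rates was not significant. An escaping bee freezes for a uniform
0.2–1.0 s latency, then runs away at the speed that makes its displacement
over the first 2 s equal `2 v` for a drawn `v ~ N(v_escape, sd_velocity)` —
so the spline estimator recovers the drawn velocity by construction — and
continues past the velocity phase to a dwell point whose depth grows with
the drawn speed. A run too slow to have crossed by then accelerates so the
midline is always crossed well inside the window; this adaptive speed-up
(rather than resampling the drawn velocity until it can cross) keeps the
drawn velocity distribution untruncated, which is what lets the estimator
recover the configured −2.5 cm/s within 0.2 cm/s. A non-escaping bee
drifts at `v ~ N(v_nonescape, sd_velocity)` for the 2-s velocity phase and
then settles at a home position that continues the drift; CS− bees are
pulled into the odor-side third with probability `attraction_dwell`,
which is what produces the positive CS− attractance.

### Parameters and provenance

| parameter | default | unit | origin |
|---|---|---|---|
| `p_escape_csplus` | 0.540 | — | published first-CS+ escape rate |
| `p_escape_csminus` | 0.178 | — | published first-CS− escape rate |
| `v_escape_csplus` | −2.5 | cm/s | published escape-subset CS+ mean |
| `v_escape_csminus` | −1.8 | cm/s | moment matching: solve 0.178·v_esc + 0.822·v_non = −0.2 with the CS− population mean |
| `v_nonescape_csplus` | −0.33 | cm/s | moment matching: (−1.5 − 0.54·(−2.5)) / 0.46 |
| `v_nonescape_csminus` | +0.15 | cm/s | moment matching to the −0.2 cm/s CS− mean |
| `sd_velocity` | 1.0 | cm/s | calibrated to the −0.73 velocity–escape correlation |
| `explore_speed` | 2.0 | cm/s | several chamber traversals per ITI |
| `attraction_dwell` | 0.8 | — | calibrated to the CS− mean AI |
| `startle_jump` | 1.5 | cm | free (training only, unscored) |
| `left_bias` | 0.5 | — | symmetric (no printed magnitude) |

The movement mechanics around these parameters (waypoint exploration,
dwell-depth intercepts and slopes, the crossing deadline) are internal
constants that were fixed once, by calibrating the emergent cohort
statistics — the AI class means and the three rank correlations, none of
which is directly configured — against the published values, and then
frozen. The velocity–AI correlation in particular is purely structural:
both readouts derive from the same trace, and its ≈ 0.84 value emerges
from the drift-continuation dwell model.

### What the simulator does and does not emulate

It emulates the geometry, sampling, quantization, protocol timing, the
delivery rule, and recall-phase response statistics calibrated to the
published cohort. It does not emulate 2-D posture, floor/ceiling
distinction, odor plume dynamics or airflow, alarm pheromone, buzzing,
between-bee individuality in escape probability (draws are independent per
stimulus), or acquisition dynamics across training trials. Tests passing
against simulated cohorts therefore demonstrate that the scoring and
inference recover the configured and calibrated behavior through the full
sensor/logging chain — not that the generative model is a faithful model
of real bees.

## Numerical choices and degenerate inputs

* Internal integration at 50 Hz; stimulus onsets may fall between samples
  (scoring interpolates window boundaries linearly; the velocity spline is
  evaluated with constant extension outside its knot range).
* Timestamps are seconds from session start at exact multiples of 0.2 s;
  the log reader rejects non-monotone or misspaced timestamps, out-of-range
  positions and malformed lines with the offending line number — never a
  silent coercion.
* Logged positions carry 4 decimals, times 3; serialization is
  deterministic, so identical records produce identical bytes and
  `read_trace_log(write_trace_log(r))` is an identity.
* Midline tie-break: a sample at exactly 0 inherits the previous sample's
  side.
* Stationary windows score velocity 0; empty cohorts refuse normalization;
  a cohort with equal integrals maps every AI to 0; single-bee runs
  complete with the undefined statistics flagged `degenerate` instead of
  failing.
* All stochastic operations (simulation, bootstraps) are reproducible
  bit-for-bit given their seed, and seeded helpers restore the caller's
  RNG state.

## Problem sizes in the test suite

The suite scores 174-bee cohorts (the published cohort size) for the
end-to-end checks, with 20 replicate cohorts for the escape-rate recovery;
property tests use 1000 random traces against a brute-force escape oracle,
200-bee cohorts per probability setting for parameter recovery, 130-bee
forced-escape cohorts (>500 escape runs) for velocity recovery, and
150-cohort coverage runs for the cluster bootstrap. These sizes are the
package's choice of a balance between statistical resolution and a test
suite that runs in a few minutes.

## Known limitations

* The escape definition is the literal suffix-run reading of "crossing
  without returning"; alternative readings (e.g. tolerance for single-
  sample returns) are not offered.
* The dwell-knot construction for the velocity spline is one defensible
  reading of the dwell-time procedure; others (knot at dwell start or end)
  would shift velocities by at most one sample interval.
* AI values are only comparable within a normalization pool; scores from
  different cohorts must be renormalized jointly before comparison.
* The simulator's escape probability is memoryless across trials, so it
  cannot express extinction within the test phase.
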