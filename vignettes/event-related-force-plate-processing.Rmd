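---
title: "Event-related processing of force-plate recordings: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-related processing of force-plate recordings: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fptrials)
```

## The problem

A force plate measures ground-reaction forces (Fx, Fy, Fz, in N) and
moments (Mx, My, Mz, in N·m) continuously, typically at 1000 Hz. Balance
research has traditionally summarized such recordings over blocks of many
seconds to minutes, which averages away any coupling between balance
control and the fast, trial-locked cognitive events of an experiment. An
*event-related* analysis instead cuts the continuous recording into
trials, aligns short time bins (e.g. 150 ms) to recurring events such as
stimulus or response onset, and summarizes each bin per trial — giving one
or a few rows of dependent measures per trial for downstream models. The
within-bin variability of the mediolateral moment Mx is of particular
interest: it indexes the intermittent neuromuscular adjustments devoted to
keeping the body upright in that short window.

This requires that the recording carry *triggers*: integer codes
transmitted (usually over the parallel port, whose `N` pins allow `2^N`
codes) by the experiment software and sampled alongside the force-plate
channels. fptrials assumes, and the synthetic generator emulates,
*level-held* trigger semantics: a code is set at an event and held until
the next event, so the code series is piecewise constant and the stream of
maximal constant runs is exactly the stream of events.

## The processing model

The pipeline applies four stages in a fixed order; each is available as a
standalone function and wired together by `run_pipeline()`.

**1. Filtering** (`design_lowpass_butterworth()`,
`zero_phase_filter_mirrored()`). The default filter is a fourth-order
low-pass Butterworth with a 10-Hz cut-off — the conventional choice for
kinesiological data, motivated by situational balance adjustments taking
on the order of 100 ms and by measurement noise (muscle twitches,
electromagnetic interference) living well above 10 Hz. The digital design
uses the bilinear transform with frequency prewarping, so the single-pass
gain is exactly $2^{-1/2}$ at the cut-off and 1 at DC. The filter is
applied forward and then backward, which cancels the phase response and
squares the magnitude response (two-pass gain $|H(f)|^2$, i.e. 0.5 at the
cut-off). Before *each* pass the first `pad_count = 2000` samples of the
series about to be filtered are prepended in reverse order and their
outputs discarded afterwards, so each causal pass starts on a mirrored
continuation of the data rather than on zeros and its start-up transient
never reaches retained samples. Each pass uses zero initial filter state;
the pad exists precisely to make results insensitive to that choice.
Filtering is applied to the whole continuous block *before* segmentation.

Numerical notes: with `pad_count = 0` the scheme degenerates to plain
forward–backward filtering; the pad is capped at `length(x) - 1`; series
no longer than the filter order are refused. Because each pass mirror-pads
only the start of the series it sees, residual boundary effects are
confined to within a filter-settling length (a few hundred samples at
1000 Hz) of the two block edges; trials sit far inside the block in any
realistic recording, and properties such as time-reversal symmetry hold in
the interior to ~1e-11 but not at the edges. Users can substitute any
stable rational filter via `as_filter_coef()`.

**2. Segmentation** (`segment_recording()`). Trial $i$ spans samples
$[\text{onset}_i, \text{onset}_{i+1})$ of the start trigger (default code
128, the fixation-cross onset); the last trial runs to the end of the
block, and samples before the first start onset belong to no trial — with
level-held triggers this tiles the recording exactly. Within-trial events
are re-expressed relative to trial start; condition labels are resolved by
pure lookup from code→label maps, with unmatched trials labelled
`"unknown"` rather than dropped; trials missing a stimulus or response
event are flagged `complete = FALSE` but always retained — exclusion is an
explicit analyst decision via `exclude_rows()`. Trial numbering restarts
at 1 per block; `run_pipeline()` also emits a global trial counter.

**3. Baseline correction** (`baseline_correct()`). The mean of the
fixation interval — a phase without cognitive or muscular task demands —
is subtracted from the entire trial, channel by channel. The interval is
closed in ms at sample resolution, default `[0, 215]` relative to the
fixation onset: exactly 216 samples at 1000 Hz. In the emulated design the
actual fixation duration varies slightly from trial to trial (almost
always 216 or 217 ms, occasionally 214–250 ms); the package uses the fixed
window rather than the per-trial fixation run, which is the reproducible
convention, and exposes the interval as a parameter for users who prefer a
different window. When the baseline code equals the start code the
interval anchors at the trial's own start onset. The correction is
idempotent, and a missing baseline event leaves the trial uncorrected and
flagged rather than failing the run.

**4. Time-locked bin statistics** (`compute_bin_stats()`). Bins are
defined in ms relative to a lock event — default: the response onset
(codes 32/64), boundaries `c(-150, 150)`, width 150 ms, i.e. one bin just
before and one just after the response. Bins are half-open $[a, b)$ so
every sample is counted exactly once; sample $s$ belongs to a bin iff
$a \le (s - \text{anchor}) \cdot 1000 / f_s < b$, which puts the anchor
sample ($t = 0$) in the post-event bin and makes a 150-ms bin hold exactly
150 samples at 1000 Hz. The first matching lock event anchors the trial
(configurable to the last, for designs with repeated sub-tasks). Each
statistic is a pure function of the raw slice; the defaults are the mean,
the sample standard deviation ($n-1$ denominator), and the range as the
single scalar $\max - \min$. Bins cut short by trial edges use the
available samples and set a truncation flag; empty bins and trials without
a lock event yield `NA`, never silent zeros.

Behavioral tables are prepared with `prep_exp_data()` (identity injected
from the `subj`/`block` file-name contract, rows/columns dropped only by
explicit predicate/list, trials renumbered within subject × block) and
merged with `combine_data()`, which joins on identical key sets, stacks
disjoint ones, and refuses partial overlap instead of silently losing
rows. When neither table carries explicit trial IDs the alignment is
positional within (subject, block); `run_pipeline()` verifies per-block
trial counts before joining and errors on mismatch.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `filter.order` / `filter.cutoff_hz` | 4 / 10 | — / Hz | conventional low-pass for sway; balance adjustments ≳100 ms |
| `filter.pad_count` | 2000 | samples | absorbs the two passes' start-up transients (2 s at 1000 Hz) |
| `segmentation.start_trigger` | 128 | code | fixation onset; natural trial delimiter |
| `segmentation.baseline_interval_ms` | [0, 215] | ms | fixed 216-sample fixation window |
| `binstats.lock_triggers` | 32, 64 | codes | response onset (correct/incorrect) |
| `binstats.boundaries_ms` / `bin_width_ms` | −150, 150 / 150 | ms | one pre- and one post-response bin |
| `binstats.statistics` | mean, sd, range | — | standard sway-variability summaries |
| `triggers.min_glitch_ms` | 0 (off) | ms | transient-code guard at pin switches; opt-in |

All of these are keys of the pipeline configuration; the fully resolved
configuration is written next to every run's outputs, so a run is
reproducible from the emitted YAML alone.

## The synthetic generator

`synthesize_corpus()` writes raw DSV files (manufacturer-style junk
header, a name row, then time, channels, and eight per-pin voltage
columns), matching behavioral tables, and the complete ground-truth
schedule. Defaults emulate the reference session: 10 blocks × 80 trials at
1000 Hz; fixation 216/217 ms (97%) with a uniform 214–250 ms tail;
stimulus codes drawn uniformly from {1, 2, 4, 8} (target × position);
response times log-normal (median 450 ms, log-sd 0.25, floored at 150 ms);
90% correct responses (code 32, else 64); the response code held 500 ms;
ITIs uniform on 1000–1500 ms; a 500-ms code-0 lead-in per block. Channels
are a sum of slow sway sinusoids (0.1/0.25/0.4 Hz at 0.8/0.4/0.2 N·m,
random phases per block), white noise (sd 0.3 N·m), and optional 50-Hz
line noise (off by default). These magnitudes were chosen once as
plausible for standing-sway plate moments; none of the pipeline's checks
depend on them beyond signal-vs-noise sanity.

Generation is deterministic: every block draws from its own RNG stream
derived from (seed, block), so extending a session never alters existing
blocks, and identical (config, seed) give byte-identical files. Ground
truth is always written beside the raw data; validation compares pipeline
output to the schedule, never to quantities re-derived from the signal.

A variance effect can be planted for recovery studies: within a window
locked to the response onset (default [−150, 0) ms) the white-noise sd of
one channel is multiplied by `effect_multiplier` for a condition subset
(default: left-position stimuli, codes {1, 4}). Recovery of the planted
sd-ratio is assessed with sway amplitudes set to zero and filtering
disabled: both slow sway (which contributes drift variance within a bin)
and low-pass filtering (which correlates samples across the window edge)
bias the within-bin sd ratio away from the planted value by construction,
and the recovery check isolates the binning arithmetic. On the default
session size (~400 trials per condition) the pre-response ratio estimates
the planted 0.5 to about ±0.006 (3 Monte-Carlo SEs) while the
post-response bin shows no effect.

What the generator does *not* emulate: physiological sway dynamics
(intermittent postural control, drift nonstationarity), amplifier drift,
missing or duplicated samples, and hardware trigger jitter. Passing the
package's checks therefore demonstrates correctness of the processing
arithmetic under clean level-held triggers, not robustness to acquisition
faults; the glitch filter (`suppress_glitches()`) covers only the common
transient-code-at-transition artifact, merging sub-threshold runs into the
preceding event.

## Design choices in open territory

- **File identity** comes from the first case-sensitive `subj`/`block` tag
  in the basename; leading zeros are ignored. Only positive examples of
  the naming scheme exist, so multiple-match and case behavior are our
  choices, documented in `parse_data_filename()`.
- **No auto-detection**: delimiter, header length, and column layout are
  explicit in `recording_format_spec()`; manufacturer headers are too
  idiosyncratic to sniff safely. Decimal separators must be `.`.
- **Code 0 is a legal event** (the ITI), not an error; trigger onset is
  the first sample at which a new code is observed, and all time-locking
  references onsets.
- **Bin edge convention**: half-open bins with $t = 0$ in the post-event
  bin. The alternative (closed pre-bin) would double-count the anchor
  sample; whichever convention an original analysis used, the package's
  choice is explicit and tested.
- **Problem sizes in the test-suite**: unit tests run on 1–2 block
  sessions of 4–10 trials; end-to-end validation uses the full
  10 × 80-trial session, 30-s sinusoidal probes for the frequency-response
  checks, and 100 randomly sampled trials for the brute-force
  bin-statistic comparison.

## Limitations

- The package processes one subject per raw file set as named; multi-plate
  or multi-subject simultaneous recordings are out of scope.
- No artifact-based automatic trial rejection and no center-of-pressure
  formula are built in: CoP and similar derived quantities are one
  `add_derived_variable()` call, but their definitions vary by plate and
  mounting and are deliberately left to the user.
- Downstream inference (ANOVA, mixed models) is out of scope; the output
  table is designed to drop directly into `aov()`/`lmer()`-style analyses.
- Filtering quality at the very start and end of a block is limited by the
  mirrored-prefix scheme's boundary behavior discussed above.
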