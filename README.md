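# fptrials

Event-related processing of raw force-plate time series in R.

Force plates record ground-reaction forces (Fx, Fy, Fz in N) and moments
(Mx, My, Mz in N·m) at ~1000 Hz while a participant stands and performs a
cognitive task. Block-level sway summaries average away trial-locked
cognitive-motor interactions; an event-related analysis instead needs
every trial cut out of the continuous recording and summarized in short
time bins aligned to stimulus or response onset. fptrials does exactly
that, for researchers in posturography and cognitive-motor interaction:

1. **Read** plain-text DSV exports (any delimiter, explicit header count),
   with subject/block identity taken from the `subj<NNN>`/`block<NNN>`
   file-name contract, and **decode** parallel-port pin voltages into
   integer trigger codes (`code = Σ 2^pin` over high pins).
2. **Filter** each channel with a fourth-order low-pass Butterworth,
   cut-off 10 Hz, applied forward and backward (zero phase, magnitude
   response |H(f)|²) with the first *n* = 2000 samples prepended in
   reverse order before each pass and discarded after, so filter
   transients never touch the data.
3. **Segment** the recording into trials at start-trigger onsets (level-
   held code 128 = fixation cross), attach within-trial events, and
   resolve condition labels from trigger codes.
4. **Baseline-correct** each trial by subtracting the mean of the
   fixation interval [0, 215] ms (216 samples at 1000 Hz).
5. **Summarize** each trial in half-open bins locked to the response
   onset (codes 32/64) — default [−150, 0) and [0, 150) ms — with the
   mean, sample standard deviation, and range (max − min) of Mx and My,
   yielding one row per trial ready for `aov()` or mixed models.
6. **Merge** with behavioral tables keyed by (subject, block, trial).

A seeded synthetic-recording generator (`synthesize_corpus()`) emulates a
full session — 10 blocks × 80 trials of fixation → stimulus {1,2,4,8} →
response {32,64} → ITI over sway-plus-noise channels — and writes the
ground-truth schedule beside the raw files, so the entire pipeline is
verifiable end to end without laboratory data.

## Worked example

```r
library(fptrials)

# a small synthetic session with known ground truth
cfg    <- synthetic_config(n_blocks = 2, n_trials_per_block = 10)
dir    <- file.path(tempdir(), "demo")
corpus <- synthesize_corpus(cfg, seed = 7, dir = dir)

# the default pipeline: filter -> segment -> baseline -> bin statistics
pc    <- default_pipeline_config(dir, file.path(dir, "out"),
                                 exp_dir = dir, segmentation.n_trials = 10L)
stats <- run_pipeline(pc)
#> fp_subj001_block001.txt: 10 trial(s), 0 incomplete, 0 without lock event
#> fp_subj001_block002.txt: 10 trial(s), 0 incomplete, 0 without lock event

stats[1:4, c("subject", "block", "trial", "stimulus", "correctness",
             "Mx_m150_0_sd", "Mx_0_150_sd")]
#>   subject block trial      stimulus correctness Mx_m150_0_sd Mx_0_150_sd
#> 1       1     1     1 target2_right     correct   0.06080759  0.09197282
#> 2       1     1     2  target1_left     correct   0.05495159  0.03618177
#> 3       1     1     3  target2_left     correct   0.04826593  0.04639445
#> 4       1     1     4  target2_left     correct   0.06126278  0.04274357
```

Each row is one trial. `Mx_m150_0_sd` is the standard deviation of the
(filtered, baseline-corrected) mediolateral moment in N·m over the 150 ms
*before* the response onset — the sway-variability measure of interest —
and `Mx_0_150_sd` the same for the 150 ms after. Column names encode
variable, bin (`m150_0` = [−150, 0) ms), and statistic. The run also
writes `trial_stats.csv`, the fully resolved `effective_config.yaml`, and
a log next to the outputs; because behavioral inputs were given, the
merged table is attached:

```r
attr(stats, "merged")[1:3, c("subject", "block", "trial", "rt_ms",
                             "correct", "Mx_m150_0_sd")]
#>   subject block trial rt_ms correct Mx_m150_0_sd
#> 1       1     1     1   531    TRUE   0.06080759
#> 2       1     1     2   419    TRUE   0.05495159
#> 3       1     1     3   667    TRUE   0.04826593
```

The designed filter itself is inspectable:

```r
co <- design_lowpass_butterworth(filter_spec(sampling_rate = 1000))
filter_gain(co, c(0, 10, 50), 1000)
#> [1] 1.00000000 0.70710678 0.00154996   # DC, half-power at cut-off, stopband
```

A command-line front end over the same functions ships in
`inst/cli/fptrials.R` (`process`, `generate`, `prep-exp`, `combine`), e.g.
`Rscript $(Rscript -e 'cat(system.file("cli/fptrials.R", package = "fptrials"))') generate --out raw/ --seed 1`.

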