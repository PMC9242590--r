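---
title: "Analyzing social touch in group-housed mice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing social touch in group-housed mice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethotouch)
```

## The problem

Automated tracking systems for group-housed mice (of which the Live Mouse
Tracker, LMT, is the best-known example) deliver per-frame body points —
nose, mass centre, tail base — for every animal in a cage, and from those
points an ethogram of social events: contacts of different kinds, isolated
versus in-contact locomotion, approaches, escapes. Studies of affective
touch use this machinery to ask how a manipulation (a genotype impairing
C-low-threshold mechanoreceptors, or their chemogenetic activation with
CNO) changes social behavior inside a stable group of four: two control
and two manipulated mice housed together.

`ethotouch` re-implements this analysis chain as a reusable, tested
pipeline, and pairs it with a seeded agent-based cage simulator so that
every stage can be exercised — and its statistical behavior measured —
without any recorded data.

## The simulator

Each mouse follows a correlated random walk: heading increments are
Gaussian with standard deviation scaled by `(1 - persistence)`, speeds
alternate between movement bouts (mean 8 s) and pauses (mean 4 s), walls
reflect, and free mice steer away from cage-mates closer than the
avoidance radius (9 cm), keeping chance body contacts below 1% of frames.
Social episodes are the only mechanism that produces deliberate contact: a
Poisson process per mouse (default 2.5 episodes/min) schedules episodes in
which the initiator approaches a body point of a partner chosen uniformly
among cage-mates — the choice that underlies the 1/3 same-genotype vs 2/3
different-genotype chance baseline in a 2 + 2 cage — holds contact for an
exponential duration (mean 2.5 s, at least 1.5 s), then turns away. A busy
initiator queues further episodes and serves them when free; episodes that
wait longer than 120 s are dropped, so the realized rate tracks the
scheduled rate well below saturation.

The injection effect multiplies the experimental genotype's episode rate
by `1 + amplitude * w(t)`, where `w` plateaus at 1 from onset through the
peak window (default 90 min) and decays linearly to 0 at return-to-baseline
(default 150 min, i.e. 2.5 h); the multiplier is exactly 1 afterwards.

Ground truth is logged by the annotator's own criterion: an episode's
recorded span runs from the first to the last frame at which the two body
polylines are within the contact threshold. This makes the log a fair
oracle for the event annotator (at default geometry at least 80% of
episodes are recovered with Jaccard overlap of 0.5 or better) without
sharing any code with it.

Reproducibility is structural: every mouse draws from its own substream,
seeded by hashing its id with the root seed. Sessions are bit-identical
across runs, identical under identity-table row permutations, and, with
avoidance disabled, unchanged when a mouse is added to the cage.

What the simulator does **not** emulate: body shape beyond a three-point
polyline (so mask-based traits such as rearing are out of scope),
occlusions and identity swaps, circadian structure within a session,
ultrasonic or olfactory channels, and any absolute calibration of contact
rates — only the direction and transience of effects are meaningful, not
absolute counts. Tests passing on simulated data therefore validate the
pipeline's arithmetic and statistical behavior, not the biological realism
of any particular threshold.

## Event annotation

All intervals are half-open `[start_frame, end_frame)`; durations are
`(end - start) / frame_rate`. Contacts are runs of frames where the
minimum distance between the two 2-segment body polylines is at most
`contact_dist` (default 2 cm), after bridging interruptions up to
`merge_gap_frames` (2) and dropping runs shorter than `min_event_frames`
(3). Segment-segment distances use the clamped parametric form in compiled
code; the test suite checks them against an independent endpoint-based
oracle.

Contact types are non-exclusive per frame, as in the LMT's overlapping
ethogram: nose-nose (noses within `nose_dist`, 1.5 cm), directional
nose-anogenital (nose within `nose_dist` of the partner's tail base),
side-by-side (centres within `contact_dist`, body axes within 45°), and
side-by-side-opposite (axes within 45° of antiparallel). A degenerate body
(nose at the tail base) suppresses the side classes only.

The four locomotion states (moving/stopped × alone/in-contact, with
moving defined by a 5-frame smoothed centre speed above 1.75 cm/s) are
assembled as raw runs, without gap bridging or minimum-length filtering.
This is a deliberate deviation from the contact rules: the states must
partition each mouse's detected time exactly — a conservation property the
tests assert to the frame — and any filtering would break it.

Approach requires the focal mouse to be moving with decreasing,
cone-restricted (±60°) bearing to a specific partner, ending at contact
onset; escape requires moving with increasing distance within 1 s after a
contact ends. The stretch-attend posture (SAP) proxy combines body
elongation above the mouse's own session 0.9-quantile with near-immobility
(below half the speed threshold); sessions under 1000 frames cannot
support the quantile and return an empty set with a warning.

The numeric thresholds are plausible LMT-scale values, configurable and
echoed into every run manifest; no quantitative agreement with the
original LMT executable is claimed.

## Trait tables and the LMT index

Events aggregate into per-mouse × trait × bin counts and durations.
Undirected pairwise traits credit both members; directional ano-genital
contacts credit the giver, with `total_contact_received` crediting the
receiver. An event is counted in the bin containing its start; durations
split fractionally across bins, which makes cumulative checkpoint series
monotone by construction.

Three bin modes exist. `dark_phase_sum` totals per dark phase (plus a
grand total), matching multi-night designs where analysis is restricted to
the active phase. `checkpoint_cumulative` accumulates from the injection
anchor to each checkpoint; the internal grid is
{30, 60, 90, 120, 150, 210, 270, 330, 390} min, while reports display the
conventional subset without 120. `checkpoint_interval` uses increments
between consecutive checkpoints; negative checkpoints denote pre-injection
baseline windows such as one hour before injection.

The LMT index divides each mouse's value by the mean of its cage's two
control mice for the same trait, bin and measure. Two identities follow
algebraically and are enforced by tests: the two control indexes average
exactly to 1, and rescaling every mouse's values by a common factor leaves
all indexes unchanged. A zero control mean leaves the index undefined
(`NA` with a warning) rather than zero or infinite. Mice with no events
enter as zeros rather than being dropped, so the control mean is always a
mean of two animals.

Percent differences between conditions are reported as
`100 * (a - b) / b` on indexes, alongside the absolute index difference:
published percent changes of this kind are ambiguous between the two
conventions (a ratio change cannot be below −100% on non-negative
indexes, yet such values appear in print), so both are emitted and
neither is asserted as canonical.

## Group dynamics

For dyads, the chance that a focal mouse interacts with a same-genotype
partner is `(n_same - 1) / (N - 1)` under uniform partner choice — 1/3 in
a 2 + 2 cage — and the observed counterpart is the per-mouse share of
dyadic contact events with each partner genotype, averaged within focal
genotype per checkpoint window. Event-count weighting is the default,
duration weighting an option, since the published analyses do not state
their weighting. Condition differences (`p_cno - p_saline`) are contrasted
against the pre-injection baseline window (default one hour before
injection).

A triad is a maximal run of frames during which a fixed trio forms a
connected subgraph of the contact graph — a chain suffices, a triangle is
not required. Frames where all four mice form one component suspend triad
scoring rather than counting ambiguous sub-trios. The creator is the
member whose joining completed connectivity (the pre-existing pair defines
the base composition); the breaker is the member whose departure first
disconnects the trio. When the boundary is ambiguous — simultaneous edge
changes, suspension boundaries, session edges — the member that moved most
in the preceding second is chosen, then the lexicographically smallest id:
deterministic and documented, if arbitrary. Detection is validated
frame-exactly against a graph-library connected-components oracle.

## Statistics

The statistical layer is self-contained and written from defining
formulas: Pearson chi-square on contingency tables (no continuity
correction by default, Yates optional), Welch/pooled/paired t tests,
Holm–Šidák step-down adjustment (`1 - (1 - p_(i))^(m - i + 1)` with a
running maximum), and a seeded permutation test for mean differences with
p = `(1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)`, or the exact enumerated
proportion on small samples. Repeated-measures ANOVA machinery is
deliberately out of scope; condition contrasts use the permutation test
with Holm–Šidák correction across checkpoints instead. Tests verify the
implementations against closed forms, base R's `chisq.test`/`t.test` as
independent cross-checks, exhaustive enumeration, and null calibration
(rejection rates at the nominal 5% level within [0.03, 0.07] over 2000
replicates).

## Detecting a transient effect: design choices

The effect-recovery check simulates five 2 + 2 cages in a crossover
design (one saline, one cno session per cage; 450 min at 10 frames/s,
injection at 60 min) with amplitude +0.5 active 0–90 min. Detection uses
the cumulative contact index at 30, 60 and 90 min — cumulated values are
the convention for checkpoint index time courses — contrasted between
conditions across the ten experimental mice by permutation test at each
of the three confirmatory checkpoints (a pre-specified confirmatory set,
so each is reported at its nominal level; the Holm–Šidák-adjusted values
are also computed and reported alongside).

Transience needs a different currency: a cumulative sum retains the early
excess at every later checkpoint by construction, so "back to baseline"
is assessed on interval increments. Because a single null p-value is
uniform — it would fall below 0.2 one run in five no matter how truly
absent the effect — the claim is made on the post-return family
({210, 270, 330, 390} min, after the 150-min return-to-baseline) with
step-down adjustment, whose adjusted p at 390 min concentrates near 1
under the joint null. This mirrors how figure-legend statistics correct
across time points, and it makes "no difference at 390 min" a stable,
falsifiable statement.

Problem sizes throughout (10 frames/s rather than the 30 frames/s
simulator default, five cages, twenty seed batches, 2000-replicate null
calibrations) were chosen once; the same sizes are used by the test suite
and the acceptance script.

Two properties of this design temper its power and are worth knowing
before interpreting the contrasts. First, the within-cage normalization
absorbs much of a genotype-specific boost: in a closed arena the control
cage-mates are partners in two-thirds of the extra contacts, so their
counts — the index denominator — rise too, and a 30–40% increase in raw
contact counts translates into only a 6–16 point index increase. Second,
the earliest checkpoint accumulates the fewest events and is therefore
the noisiest; with ten experimental mice the 90-min contrast is reliably
significant while the 30-min contrast is not always, so claims that
require every early checkpoint to clear significance individually will
fail in a minority of replicate batches.

## Worked example

```{r example, eval = FALSE}
library(ethotouch)

out <- run_pipeline(default_config(seed = 3), out_dir = "demo_run")
out$index_contrast
#> # A tibble: 4 x 7
#>   bin_label mean_cno mean_saline  delta ratio_pct     p p_adjusted
#>   <chr>        <dbl>       <dbl>  <dbl>     <dbl> <dbl>      <dbl>
#> 1 T15           1.09       0.961 0.133      13.9  0.331      0.794
#> 2 T30           1.04       0.963 0.0726      7.54 0.342      0.794
#> 3 T45           1.07       1.01  0.0601      5.97 0.326      0.794
#> 4 T60           1.05       1.02  0.0322      3.17 0.342      0.794
```

A single demonstration cage shows the expected direction (experimental
indexes higher after cno than saline) without significance — two
experimental mice per group cannot power the contrast; the five-cage
experiment in `checkpoint_index_experiment()` does.

## Known limitations

Three body points cannot express rearing or grooming postures; contact
typing near the threshold is sensitive to the configured distances; the
triad creator/breaker attribution inside merged or simultaneous edge
changes is a convention, not an observation; and the simulator's absolute
event rates are not calibrated to any recorded data set, so only relative
and directional claims transfer.
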