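---
title: "Stitching fragmented multi-worm tracks into per-animal trails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitching fragmented multi-worm tracks into per-animal trails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormtrails)
```

## The problem and the model

A real-time multi-worm tracker segments each video frame into blobs
(connected clusters of foreground pixels) and chains blobs into tracks, but
it cannot keep identities through collisions, body splits, or dropped
detections — and it stores no video, so appearance-based re-identification
is off the table. The observable record of a recording is therefore a large
set of short tracks plus the tracker's own parent/child links, and the task
is combinatorial: decide which tracks belong to the same animal using only
geometry and timing.

`wormtrails` represents this as a directed acyclic network. Each track is a
node; an arc (u, v) asserts that v could continue u. The tracker's links
provide the initial arcs; corrections then edit the network:

* **collision untangling** duplicates a merged two-worm node into two
  copies and rewires them according to pixel-overlap voting;
* **gap inference** adds arcs between sinks and later sources under strict
  time/distance caps;
* **pruning** removes sub-second parentless/childless debris;
* **consolidation** contracts split-rejoin motifs.

The phases run in exactly that order — collisions first, because untangling
changes the degree structure every later phase keys on — and the whole
sequence repeats until a pass makes no change (at most `maxPasses`, default
10; non-convergence is reported as a flag, never an error). Maximal chains
(internal in/out degree 1) of the final network are emitted as trails.

The modelling assumptions are minimal but real: animals move continuously
(so a small Δt × Δd product is evidence of identity), a body barely moves
during the instants before and after a contact (so boundary-mask overlap is
evidence of which worm went where), and transient fragmentation is short
(sub-second debris, split-rejoin motifs under a few seconds). Recordings
that violate these — very slow frame rates, dense heaps of animals,
long-lasting occlusions — will degrade gracefully into *unresolved*
structure rather than wrong identities, because every ambiguous decision is
refused.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `bodyLengthPx` | 50 | px | spatial scale; collision flagging requires a neighbour path > 1 body length |
| `overlapThreshold` | 100 | px | required margin \|S₁ − S₂\| between the two pairings' summed overlaps |
| `maxGapFrames` | 50 | frames | strict Δt cap for gap inference (10 s at 5 fps) |
| `maxGapPx` | 50 | px | strict Δd cap for gap inference (~1 body length) |
| `pruneMaxS` | 1 | s | strict duration cap for orphan removal |
| `consolidateMaxS` | 3 | s | strict span cap for split-rejoin merging |
| `fps` | 5 | Hz | frame rate; never inferred, always declared in the recording header |

Two readings of the collision threshold are possible ("resolve when overlap
is at least 100 px" vs "resolve when one outcome is better by 100 px"); the
margin reading is the only one that makes the published behaviour — refusing
near-equal cases — fall out of the rule itself, so the package requires
`|S₁ − S₂| ≥ overlapThreshold`. Raising the margin trades resolved
collisions for accuracy; lowering it below ~50 px starts accepting
coin-flip geometry and is not recommended.

The motif span for consolidation is measured over the *intermediary window*
(earliest fragment start to latest fragment end): that interval is what the
segmentation error physically occupies. The alternative parent-start to
child-end convention is available via `span = "parent-child"` in
`findSplitRejoinMotifs()`.

Overlap voting compares a single boundary blob on each side (the parents'
last masks, the children's first). A multi-frame boundary window was
considered and deliberately not defaulted to: with slow-moving worms the
single-frame masks are the least-displaced evidence available, and widening
the window only blurs them.

## Numerical and tie-break choices

* All caps are strict inequalities ("less than"); boundary values 50
  frames / 50 px / 1 s / 3 s are rejected. The tests pin this at
  49/50/51.
* Gap candidates are ordered by score Δt × Δd, ties broken by smaller Δt,
  then sink id, then source id — determinism across platforms. Selection is
  greedy with one inferred arc out of a sink and into a source; an
  exhaustive re-scan of the same local rule is the test oracle. (A global
  minimum-total-cost assignment is *not* the semantics: the rule is the
  published local one, applied greedily.)
* Consolidation merges one motif at a time, earliest parent first, and
  re-scans after every merge: a merge can create a new, earlier motif, and
  one-at-a-time keeps overlapping motifs deterministic and auditable.
* Same-frame blobs merged during consolidation are combined by pixel-set
  union with the centroid recomputed as the pixel-mass centroid (the
  fragments are one body); maskless blobs fall back to an area-weighted
  mean.
* The duplicated collision node carries the merged two-worm mask on both
  copies — during contact the shape is genuinely unknown, and this mirrors
  the accepted imprecision of collision intervals. Blob conservation is
  therefore defined as coverage (no observation lost; duplication allowed
  only through collision copies) and is asserted in every end-to-end test.
* Pruned nodes are never deleted: they move to a side table that the
  conservation check and the coverage report both see.
* Degenerate inputs: empty graphs, single-blob (zero-duration) tracks,
  masks absent on some blobs, and already-simplified networks are all legal
  and covered by tests; collision cases with a missing boundary mask
  resolve to `unresolved` with a reason code rather than erroring.
* Speed analysis: centred running means with window shrinkage at series
  ends (no padding); gaps shorter than 1 s are linearly interpolated, longer
  gaps are excluded and invalidate any speed sample that straddles them; a
  smoothing window containing invalid frames shrinks to its valid portion.

## The simulator: what it emulates, and what it does not

`simulateRecording()` drives `nWorms` persistent random walkers (per-frame
heading correlation `headingPersistence`, default 0.9; per-worm speeds drawn
from a gamma with mean `speedMeanPxS` = 3 px/s) inside a reflecting arena of
1250 × 750 px — a 2.5 × 1.5 cm copper-frame field of view at 50 px/mm — and
renders each worm as a 50 × 5 px capsule mask, the simplest body shape that
supports exact overlap counting. An emulated segmenter then produces output
with precisely the upstream failure taxonomy:

* **collision merging** — masks touching within a 1 px dilation are emitted
  as one blob carrying both identities, with links into and out of the
  merged node;
* **split episodes** — a worm is emitted as two separated half-capsules for
  an exponential duration (mean 1 s), with links, creating split-rejoin
  motifs;
* **dropouts** — a worm is unobserved for an exponential duration (mean
  2 s) with *no* link across the gap: the false negatives gap inference
  must repair.

Default per-worm-frame rates (`pSplit` 0.004, `pDropout` 0.002) were chosen
once so that a three-hour, ten-worm recording would carry on the order of a
few thousand disruptions, the load a real recording of this kind exhibits.
The default duration is 120 s: the stitching problem is stationary in time,
so a two-minute window exercises every correction class at desk scale; the
acceptance experiments state their exact sizes below.

Ground truth maps every emitted blob to its true worm set, records every
dropout with its flanking nodes, and keeps the true trajectories.
`scoreAgainstTruth()` reproduces the manual-screen error taxonomy: a trail
is *id-switched* if it contains single-worm observations from two worms
outside collision intervals; a *collision trail* if more than half its
frames are multi-worm; it *contains an undetected collision* if it has
multi-worm frames that no audited collision case covered. Collision
resolution accuracy is correct/decided; gap recall is the fraction of
in-cap dropouts whose flanking nodes end up in one trail.

What passing these tests does **not** show about real data: real worms are
not capsules (overlap counts on real masks are noisier), real segmenters
drop and split worms with spatially correlated, contrast-dependent
patterns rather than independent per-frame coin flips, three-plus-worm
pileups are rarer here than on a crowded plate, and posture-level errors
(partial bodies, halo pixels) are not modelled at all. The simulator
validates the *network logic* under a faithful error taxonomy, not the
segmenter.

## Validation experiments and problem sizes

* **Collision accuracy** (`collisionAccuracyExperiment()`, also the
  acceptance script): ≥ 1000 two-worm crossing recordings from the
  `"collisions"` preset — two worms steered to cross near the arena centre
  at a random angle in [40°, 140°] with a small impact offset, 40 s at
  5 fps, ballistic headings — flagged, resolved at the 100 px margin, and
  scored against truth. About a third of crossings are refused (near-equal
  overlaps, exactly the partial-trade-places geometry); decided cases are
  correct in well over 99%.
* **Noiseless recovery**: 10 worms, 60 s, grid placement in a large arena,
  corruption off → exactly 10 trails at coverage 1.0 and zero id-switches.
* **Oracle equivalence**: 500 random gap instances (≤ 6 sinks/sources)
  against exhaustive re-scan selection, with an exhaustive 49/50/51
  boundary grid; 500 random DAGs (≤ 12 nodes) for prune and consolidate
  fixpoints against re-scan oracles.
* **Conservation and closed forms**: blob conservation on every end-to-end
  run; constant-velocity and stationary trajectories recovered to < 1% in
  the series interior.

## Downstream motility quantification

Trails feed a standard centroid-speed pipeline: linear interpolation of
sub-second gaps, exclusion of longer ones, a 1 s running average on
positions, speed as per-frame displacement × fps, a 60 s running average on
speed, per-minute binning pooled across worms (trails under one minute are
excluded as noise). Worms are classified active/inactive per observation
window — first 30 min, 30–90 min, 90–180 min — by whether they accumulate
more than 5 min with smoothed speed above `activeSpeedThreshold`. No
operational speed threshold for "active movement" is published for this
assay; the package default is 1 px/s (0.02 body lengths/s at a 50 px
body), a declared choice exposed as a parameter, not an inference of
anyone's intent.

## Known limitations

* Three-or-more-worm collisions are flagged but never auto-resolved; they
  are the main residual error source on crowded plates.
* The method is a faithful reimplementation of a heuristic pipeline, not a
  globally optimal linker; no min-cost-flow or appearance model is used,
  and none is planned — identity fidelity over coverage is the design
  point.
* Unresolved collisions deliberately fragment trails; dense recordings
  retain substantial fragmentation.
* The canonical JSON-lines dialect is the only supported input; converting
  native tracker formats is the caller's burden.
* Posture and skeleton metrics are out of scope; only centroid kinematics
  are computed.
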