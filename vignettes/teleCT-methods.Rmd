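---
title: "teleCT: rendering, streaming and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{teleCT: rendering, streaming and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teleCT)
```

## The problem and the architecture

Acute-stroke reading is time-critical: a remote expert must exclude
intraparenchymal hemorrhage and judge early ischemic change on NCCT, and
find occlusions on CTA, within minutes of acquisition. Shipping whole DICOM
studies to a remote device is slow and leaves identifiable data outside the
hospital. teleCT implements the alternative architecture: the server loads
and renders the volumes; a thin client sends interaction events and receives
rendered 8-bit frames plus state updates. Nothing identifying and no pixel
source data crosses the wire; the client's cache is volatile and cleared on
disconnect.

The package provides the full pipeline — DICOM ingestion, reformatting and
volume rendering, the block-delta frame codec, diff-based state
synchronization, an in-process session engine with a scriptable reference
client — plus a head-CT phantom generator and the diagnostic-accuracy
statistics used to evaluate readers against a reference read.

## Volume model and coordinate conventions

`ImageVolume` stores voxels as an R array indexed `[row, col, slice]`
(1-based, the natural R convention), a spacing triple in mm, the mm origin
of voxel (1,1,1), and a 3×3 orthonormal orientation matrix (columns: row
direction, column direction, slice normal; LPS patient space). Voxel
(i, j, k) sits at `origin + (i−1)·sp₁·R[,1] + (j−1)·sp₂·R[,2] +
(k−1)·sp₃·R[,3]`. Loading honours the acquisition orientation without
resampling: reformation happens downstream, so the load is lossless.

`loadSeries()` sorts slices by the projection of each file's image position
onto the slice normal (robust to file naming), applies the rescale
slope/intercept so voxels are HU, and enforces geometry: duplicate or
missing positions raise "inconsistent series", inter-slice steps deviating
more than `spacing_tolerance` (default 5%) from their median raise
"non-uniform spacing", and mixed matrix sizes raise "heterogeneous series".
With `anonymize = TRUE` (the default) only a whitelist of non-identifying
textual attributes survives the load. The built-in DICOM reader covers
uncompressed explicit and implicit VR little endian; compressed transfer
syntaxes are rejected with a clear error rather than silently mis-read.

## Window/level

The display mapping is the DICOM linear convention,

`out = clamp(((v − (c − 0.5)) / (w − 1) + 0.5) · 255, 0, 255)`,

rounded half-up, with `w = 1` degenerating to a binary threshold at the
centre. Values at or below `c − w/2` map to 0, values at or above `c + w/2`
to 255, and the mapping is monotone in voxel rank. Defaults per modality:
brain window 40/80 HU for NCCT, 150/600 HU for CTA. HU probing
(`huProbe()`) always runs on the raw volume, never on windowed 8-bit data —
a regression test asserts the two differ — because the clinically useful
dense-vessel check is a quantitative comparison of absolute HU between a
suspect vessel and its contralateral counterpart.

## Reformatting and view transforms

`extractSlice()` samples the volume trilinearly at each output pixel of a
`SlicePlane`; out-of-volume samples contribute a configurable background
(−1024 HU, air, by CT convention). Slabs thicker than zero take samples at
native slice-spacing steps along the plane normal, centred on the plane, and
combine them by arithmetic mean (average-intensity projection) by default —
3-mm reformations from 1-mm data average three samples — or by maximum
intensity via `projection = "max"`, which is the mode that keeps a
contrast-filled vessel conspicuous. Nearest-neighbour interpolation is
available for debugging.

`applyView()` composes the in-plane transform in the fixed order rotate
(about the viewport centre) → zoom → pan, resampling bilinearly into an
exactly viewport-sized output. Fixing the order makes recorded event
streams replayable bit-for-bit.

## Ray-cast rendering

Rendering is orthographic (sufficient for diagnostic 3-D overviews and much
easier to validate; perspective is deferred): one ray per pixel, trilinear
HU samples every `stepMm`, transfer-function lookup by linear interpolation
between control points, and front-to-back compositing

`C ← C + (1 − A)·a·g`, `A ← A + (1 − A)·a`,

with early termination at `A ≥ 0.99`. Per-sample opacity is corrected for
step size as `a' = 1 − (1 − a)^(Δs/Δs₀)` with a 1-mm reference, so renders
are comparable across step sizes; the test suite checks that halving the
step converges monotonically. The packaged presets (bone, soft tissue,
vessel, MIP) use conventional HU anchors — the bone ramp starts near
300 HU — as configuration defaults, with gray-scale output matching the
monochrome frame codec; there is no gradient shading in this version. The
renderer is validated against an independent scalar-loop oracle on 16³
volumes (agreement within one gray level) and against analytic geometry
(sphere silhouette area within 2% of πr²).

## The block-delta frame codec

The encoder keeps the last frame sent, pre-compression. Each new frame is
compared 8×8-block-wise, bit-exactly — any differing pixel marks its block —
and only changed blocks are JPEG-encoded and transmitted, each as an
independent grayscale baseline JPEG (independence buys per-block
testability and random-access decode at the cost of per-block header
overhead). Quality is 25 while the user drags and 100 for static frames;
for one frame pair the q=25 payload is never larger than the q=100 payload.
Edge blocks are zero-padded to 8×8 before encoding and cropped on decode.

Because change detection compares pre-compression frames, the client canvas
can drift within JPEG error of the last-written content; keyframes (first
frame, viewport resize, forced reset, and every 120 frames by default)
resynchronize the canvas to within the q=100 round-trip tolerance, measured
at ≤ 2 gray levels on smooth CT-like content. The wire format is
length-prefixed big-endian binary, documented field-by-field in
`inst/extdata/wire_format.md`.

One consequence of per-block independence worth stating: for a *constant*
full keyframe the aggregate payload is dominated by per-block JPEG headers,
so the frame-level compression ratio does not reach what a single
whole-frame JPEG of the same content achieves (far beyond 12:1). The 12:1
figure enters the package only as the configurable guideline bound that
`compressionRatio()` checks static frames against, warning when compression
exceeds it.

## State synchronization

Session state is a tree of typed leaves (number, string, boolean) addressed
by slash-separated paths, with a revision counter. `computeDiff()` emits the
minimal diff (never an upsert that repeats an unchanged value);
`applyDiff()` rejects diffs whose base revision does not match ("stale
diff"), after which a client requests the full-state resync diff, which
applies to any tree. Diffs serialize to XML (schema in
`inst/extdata/state_diff.xsd`) and, equivalently, to JSON for the wire.
Conflict policy is deliberately simple: the server serializes mutations in
arrival order, last writer wins per path; with every rebroadcast diff
delivered, all clients converge to the server tree byte-for-byte. There are
no operational transforms and no cross-server transactions; multiple
servers are modelled as independent state trees.

## The session engine

`teleServer()` runs in-process with an explicit wire layer: every exchanged
message — catalog JSON, packed frames, serialized diffs, probe text, event
text — is appended to a wire log, and reference clients reconstruct their
canvas and state tree exclusively from those bytes. This keeps the full
protocol observable and lets `assertConfidential()` check the
confidentiality contract over an entire session: only the allowed message
types appear, frame bytes parse as the documented format, no message embeds
DICOM content, and no textual message carries identifying keys. The
transport is in-process rather than a network socket; the protocol and
message boundaries are exactly those a socket transport would carry.

Sessions default to a 320×480 portrait viewport (40×60 = 2400 blocks).
Interactive events mutate the state tree, re-render server-side, and stream
the changed blocks with the interactive quality; probe events return
textual HU statistics and leave the frame untouched; `disconnectSession()`
releases the volume and codec server-side and makes attached clients blank
their canvas and purge their volatile cache, idempotently. The
2-D side-by-side mode renders two viewports (current and next slice) from
one shared state tree.

## Phantom generator

The phantoms are geometric, not anatomical: tests need controllable,
exactly-known ground truth rather than realism. The background is an
elliptic head — skull shell at 1000 HU, brain parenchyma at 35 HU, two
ventricles at 8 HU, air at −1000 HU — into which sphere/ellipsoid/tube
inserts are stamped at configured HU: hemorrhage 70, ischemia 27
(parenchyma − 8), dense vessel 60, contrast vessel 250, occlusion gap 45.
These layer values are CT-convention configuration defaults. Gaussian noise
is added last, the volume is rounded to integer HU (so DICOM round trips
are exact), and every stochastic step runs under the spec's seed, making
phantoms bit-reproducible. Insert masks are recorded exactly, and
case-level labels are derived from the insert list, so masks and labels
cannot disagree.

Spacing defaults mirror routine acute-stroke acquisitions: 512×512 over a
220-mm field of view (0.4297 mm in-plane) with 5-mm NCCT and 0.6-mm CTA
slices. What the phantoms do *not* emulate — beam hardening, streaks,
anatomy-shaped lesions, ASPECTS-region geometry — bounds what passing tests
show about real data: they validate the engine's geometry, codec and
statistics, not clinical detectability.

`simulateReaderResponses()` turns case truth into reader calls with chosen
sensitivity and specificity, seeded; at the CTA operating point
(sensitivity 0.944, specificity 1.0, 18 positive / 47 negative cases) the
generating sensitivity is recovered within binomial error over many
replicates.

## Reader evaluation

`contingency()` cross-classifies calls against truth; truth is an input
vector (in the motivating study design it is the first reader's workstation
read), a choice kept as data rather than code. `diagnosticMetrics()` reports
sensitivity, specificity and accuracy as percentages at full precision and
truncated. The printed-precision convention is truncation, not rounding:
103/105 = 98.095…% prints as 98.09 and 100·100/105 = 95.238…% as 95.23;
published tables reproduce only under this convention, and
`reproduceStudyTables()` regenerates all 24 metric cells of the packaged
two-reader counts exactly at each cell's printed precision. Cohen's kappa
is the unweighted two-category statistic; it is undefined when both raters
are constant in the same category. The ASPECTS discrepancy rule flags
|s₁ − s₂| > 1. Interrater kappas that cannot be recomputed from published
marginal counts (the dense-vessel and parenchymal-change values require the
unpublished reader-by-reader cross-tabulation) are deliberately out of
scope of the reproduction suite.

## Numerical choices and degenerate inputs

- 8-bit output rounds half-up (`floor(x + 0.5)`); window width 1 is a
  threshold; zoom must be positive; probe rectangles clipped to the slice,
  empty intersections are errors.
- Trilinear/bilinear sampling clamps indices at the grid edge and returns
  the background for points outside; orientation matrices are validated
  orthonormal to 1e-6; slice-sorting ties are errors, not silent choices.
- Diff application is strict (unknown delete paths are errors) so protocol
  bugs surface immediately rather than as divergent replicas.
- Numbers in serialized diffs are formatted at 17 significant digits, so
  doubles round-trip exactly through XML and JSON.

## Problem sizes used by the test and acceptance runs

The suite exercises the full stack at reduced sizes chosen to keep runs
quick while leaving every code path intact: phantoms of 48–64² × 8–16
voxels at the native spacings, 96×64 session viewports alongside the
320×480 codec checks, 16³ volumes against the scalar ray-marching oracle,
1000 random tree pairs and 500 serialization fuzz cases for state sync, and
10,000 replicates for reader-response recovery. The phantom geometry and
insert HU values are identical at any grid size, so the reduced grids probe
the same arithmetic as full 512×512 series.

## Known limitations

Compressed DICOM transfer syntaxes are not read; multi-frame enhanced CT,
curvilinear reformatting, perspective and shaded rendering, video codecs,
adaptive quality control, operational transforms and state persistence are
all out of scope. The in-process transport carries the exact protocol but
not network timing, so frame-rate behaviour over real links is outside what
this package can measure.
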