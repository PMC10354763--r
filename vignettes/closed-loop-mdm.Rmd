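---
title: "Closed-loop droplet control on a simulated MDM platform: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop droplet control on a simulated MDM platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droploop)
```

## Scope and intent

`droploop` rebuilds an image-feedback control system for magnetic digital
microfluidics without any hardware: the camera is a renderer, the
electromagnet and stage are a physics-lite simulator, and the neural object
detector is a classical pixel detector behind a pluggable interface. The
value of the package is that the *control logic* — success criteria, retry
policies, assay choreography — runs against interfaces a hardware adapter
could equally implement, and every closed-loop behavior is testable
offline. Nothing here claims to reproduce wet-lab numbers (detector mAP of
a trained network, absorbance curves, limits of detection); those depend on
private data, trained weights and reagents and are deliberately out of
scope.

## The engagement model

The simulator reduces magnet–particle–droplet physics to threshold speeds,
all linear in the particle volume $V_p$ (µl):

* **Disengagement**: the magnet carries a cluster only up to
  $v_{mag} = k_{mag} V_p \, g$, where $g$ is the power gain (1 at
  24 V/0.8 A, 1.5 at 36 V/1.2 A). Faster than that, nothing moves — the
  classic silent transport failure.
* **Retention**: `extraction_speed()` reports
  $v_{exit} = k_{exit} V_p / g$, multiplied by `set_factor` (0.5) when the
  droplet is anchored on a surface energy trap. The invariant
  $k_{mag} > k_{exit}$ keeps an extraction-feasible window open at every
  load and power.
* **Free-droplet escape**: a droplet that is *not* anchored follows its
  cluster, so actually pulling the cluster across its boundary requires
  beating droplet drag as well. The boundary-crossing threshold for a free
  droplet is $k_{drag} + k_{exit} V_p / g$ with $k_{drag} = 6$ mm/s.

The third rule is the one place the package had to make a genuinely open
design choice. A single linear threshold $k_{exit} V_p / g$ applied to free
droplets cannot simultaneously let a 0.5 µl load transport a droplet at the
default 8.33 mm/s *and* make a 1 µl load resist extraction at that speed —
both behaviors the platform demonstrably exhibits (operating conditions are
chosen to favor transport; extraction difficulty is what the rectification
demo relies on). Separating "retention relative to a held droplet" from
"escape from a droplet that is free to follow" resolves the tension with
one extra constant: with the defaults, 0.5 µl transports at 8.33 mm/s
(escape at 10 mm/s), a 1 µl extraction attempt at 12.5 mm/s fails (escape
at 14 mm/s) and the retry at 18.75 mm/s succeeds just under the 20 mm/s
disengagement ceiling, and anchoring collapses the threshold to 4 mm/s.
All constants are configuration, not code.

Residual particles after extraction are modeled as a fixed 2% of cluster
volume left in the droplet — small enough that the renderer draws nothing
and the detector never reports them, matching the observation that
left-over particles do not disturb subsequent operations.

Droplets are spherical caps at a fixed 120° contact angle (hydrophobic
Teflon); only the circular footprint matters, so a 10 µl droplet has a
1.22 mm footprint radius. There is no fluid dynamics, evaporation,
hysteresis or deformation; the simulator is deliberately deterministic
(identical commands reproduce identical trajectories bit for bit), which
makes the controller's replay property testable.

## Imaging and the synthetic dataset

The camera maps the 40 × 40 mm field of view at 10 px/mm onto 400 × 400 px
frames; every pixel threshold in the control layer (10 px arrival
tolerance, 20 px overshoot, 3 px merge growth) lives in this space. The
mm-to-pixel scale of the original rig is unknown; 10 px/mm is declared, not
inferred.

Illumination maps to a background gray of
$40 + 180(\mathrm{lux}-25)/975$ — an arbitrary monotone choice, documented
here precisely because only its monotonicity matters. Transparent droplets
are drawn as a faint rim 25 intensity units above background (the hard,
low-contrast case the real system struggles with); reagent droplets are
filled with their RGB color; clusters are near-black mounds. The generator
emulates the six training-image categories (P/D ratio sweeps, aspect-ratio
distortion, particles in/out of droplets, the 25–1000 lux range, Carba NP
reds-to-yellows, BCA greens-to-violets) with seed-deterministic sampling.
Reagent palettes are sampled along *hue arcs* at fixed saturation rather
than straight lines in RGB: linear RGB interpolation between green and
violet passes through gray, which no real indicator chemistry does and
which would make the colored-droplet detection floor meaningless.

What a green test on this generator establishes: the detector contract,
the evaluation arithmetic and the closed loop's behavior under a faithful
camera. What it does not establish: robustness to reflections, refraction
patterns, motion blur, shadows or any optical effect the renderer does not
model. The acceptance floor (recall ≥ 0.9 colored / ≥ 0.8 transparent at
IoU 0.5) mirrors the direction of the real finding — colored droplets are
easier — without claiming its magnitudes.

## Detection and evaluation

The classical detector thresholds three channels: dark unsaturated blobs
(particles), saturated regions (colored droplets) and bright low-chroma
rims (transparent droplets), using run-length connected-component labeling
with union-find. It is intentionally simple; the package treats *any*
function `frame -> detections` as a detector.

Evaluation follows the COCO convention: detections sorted by descending
confidence (stable under ties), greedily matched within their frame to the
unmatched truth of highest IoU at or above the threshold, ties to the lower
truth index, duplicates counted as false positives; AP by 101-point
interpolated precision; mAP averaged over the full class × threshold grid
(0.50:0.05:0.95). Classes with no ground-truth instances are excluded from
the mean. Whether class averaging happens before or after threshold
averaging is numerically irrelevant under full-grid averaging — stated as
a convention. Boxes are half-open pixel intervals with continuous areas.
An independent pixel-counting/naive-loop oracle in the test suite pins the
arithmetic on every fixture with ≤ 5 boxes per frame.

## The closed loop

Each operation is a state machine over two interfaces: actuation
(`move_to`, `set_magnet`, `set_power`, `wait`, `home`) and detection
(`capture`). The controller never reads simulator state; a corrupted
detector (dropout, jitter, or a frozen frame) degrades the loop to a clean
`failed` result, never to an action on ground truth.

Decisions worth recording:

* **Retry schedule.** The platform only prescribes directions ("a lower
  speed", "a higher moving speed"). The geometric factors 0.6/1.5 with a
  budget of 5 retries guarantee crossing any feasibility threshold the
  monotone engagement model admits; the budget itself is an addition — the
  original flowcharts loop forever, which is not acceptable in unattended
  software.
* **"Back to the previous state"** is realized as returning the control
  point to the *currently detected* particle centroid, not the original
  start: that is what the flowchart's loop arrow does, and it is the only
  choice that works when a failed attempt leaves the scene half-moved.
* **Overshoot** (20 px along +y, then back) applies to transport and
  merge, not extraction.
* **Arrival** is judged on the detected droplet *box center* (the original
  criterion does not distinguish box from droplet center; box center is
  what a detector actually provides), inclusively at 10 px.
* **Disengagement detection** is purely the failed arrival check after a
  motion settles (0.5 s) — no continuous monitoring, as in the original
  design.
* A failed *extraction* attempt below the escape threshold drags droplet
  and particles along together; this is the correct signature (boxes still
  overlap somewhere) and the retry starts from wherever the particles now
  are.

## Assay choreographies

Both assays drive only control-module operations. BCA: three areas, each a
20 µl working-reagent droplet with 1.5 µl particles merged into a 2 µl
protein droplet, five mixing loops, 10 min incubation (magnet homed and
off), then SET-assisted extraction — areas 2–3 merge and mix while area 1
incubates, and each extraction is gated on its own incubation clock. The
BCA contract ends at particle extraction; absorbance at 480 nm is wet-lab
territory. Carba NP: control pair (no imipenem) and test pair (imipenem),
10 µl + 10 µl merges, one hour incubation during which the simulated
chemistry linearly recolors a droplet containing both a CPE lysate and
imipenem from red toward yellow, extraction, then colorimetric readout.

Chemistry is exactly that recolor rule — no pH or kinetics model. The
hue thresholds (positive 20–90°, negative within 20° of 0°, saturation
floor 0.2) quantify a qualitative red-versus-yellow/orange rule; the
original color-space figure is not numerically extractable, so the bounds
are configurable defaults. Color is read as the mean RGB over the central
50%-area sub-box, which excludes rim highlights. The HOME position is the
field-of-view top-left corner (unstated in the source; configurable).

## Numerical and degenerate-input choices

* Inclusive comparisons throughout the success criteria (exactly 10 px is
  arrived; exactly 3 px growth is merged; touching boxes are disjoint).
* Nearest-candidate association ties break to the lower index,
  documented and tested from both orderings.
* Magnet–cluster coupling uses a 3 mm capture radius (the pole piece is a
  3 mm hemisphere); clusters outside it never move.
* The simulator integrates at 0.1 s steps; the control point arrives at
  its target exactly (the last step is truncated), so determinism is not
  at the mercy of step-count rounding. Actuator lag (a first-order delay,
  ~1 s on the real hardware) defaults to 0 in tests.
* Merging is applied to a fixed point after every step, so chain contacts
  collapse deterministically; the merged droplet keeps the larger parent's
  id, takes the volume-weighted centroid and color (transparent parents
  dilute nothing visually), ORs reagent flags, and re-derives anchoring
  from trap geometry.
* A disengaged magnet never re-engages by proximity: every operation
  explicitly returns the control point to the detected particles first.

## Known limitations

The simulator cannot fail in ways it does not model: no splitting,
satellite droplets, contact-line pinning, partial merges or detector
hallucinations from optical artifacts. The rectification guarantees are
theorems of the monotone threshold model, not of fluid physics; on
hardware the same loops are heuristics. The classical detector is a stand-
in — its perfect recall on synthetic frames says nothing about a trained
network on real video, and the package intentionally reports no mAP
numbers for comparison with the original system.
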