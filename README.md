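# droploop

Closed-loop, image-feedback control for **magnetic digital microfluidics
(MDM)** — reimplemented hardware-free so the entire control stack can be
developed, tested and benchmarked on a laptop.

## The problem

MDM platforms move droplets on an open hydrophobic substrate by dragging
embedded magnetic particle clusters with an electromagnet underneath. Run
open-loop, the four fundamental operations fail silently:

* **Transport** — if the commanded speed exceeds the *disengagement
  threshold* for the particle load, the magnet outruns the particles and
  the droplet stays behind.
* **Particle extraction** — pulling the cluster out of a droplet
  (solid/liquid separation) fails if the speed is *not high enough* to beat
  surface-tension retention; a surface energy trap (SET) that anchors the
  droplet makes extraction much easier.
* **Merging** — two droplets must actually coalesce, confirmed by bounding
  box growth.
* **Mixing** — repeated transport along a cross-shaped path.

A camera plus a two-class object detector (droplets, particles) closes the
loop: after every motion the scene is re-detected, success is judged in
pixel space, and failures are *rectified* by returning the control point to
the particles and retrying — slower for transport, faster for extraction.

`droploop` provides:

1. a deterministic physics-lite simulator with the engagement-regime model
   `v_disengage = k_mag·Vp·g` (disengagement) and escape thresholds
   `k_exit·Vp·s/g` (anchored) / `k_drag + k_exit·Vp/g` (free droplet);
2. a renderer producing camera-like frames with exact ground-truth boxes
   across six image categories (P/D ratios, aspect ratios, particles moving
   in/out, 25–1000 lux illumination, Carba NP and BCA reagent colors);
3. a classical pluggable detector plus COCO-style evaluation (IoU, per-class
   AP with 101-point interpolation, mAP over IoU 0.50:0.05:0.95);
4. the four closed-loop operations as state machines with success criteria
   of 10 px arrival tolerance (inclusive), box disjointness, and ≥ 3 px
   box growth in both dimensions, with a 20 px +y overshoot and geometric
   retry schedules (×0.6 down / ×1.5 up, max 5 retries);
5. scripted in-vitro-diagnostic choreographies: triplicate BCA protein
   quantification and the Carba NP carbapenemase test with HSV-hue
   colorimetric calls (yellow/orange 20–90° → positive, red ±20° →
   negative, control must stay red for validity).

## Worked example

```r
library(droploop)

# a 10 ul droplet with 0.3 ul of particles: too light for the default
# 8.33 mm/s -> the magnet disengages, the loop retries slower and succeeds
st <- platform_state(
  droplets = list(droplet_state("d1", c(10, 20), 10)),
  clusters = list(particle_cluster_state("p1", c(NA, NA), 0.3, "d1")))
world <- sim_world(st, engagement_model())
eyes  <- perfect_eyes(world)
res <- transport(list(c(300, 200)), operation_config(), world, eyes)
print(res)
#> <operation_result> transport: success after 1 retry
#>   droplet delivered to 1 destination(s)
sapply(res$attempts, `[[`, "speed")
#> [1] 8.330 4.998

# Carba NP on a carbapenemase-producing strain
rep <- run_carba_np(strain_profile = list(cpe = TRUE))
print(rep)
#> <assay_report> CarbaNP: 2/2 area(s) complete
#>   control: rgb(220,40,50) -> negative
#>   test: rgb(235,190,40) -> positive
#>   valid: TRUE
```

The first attempt at 8.33 mm/s exceeds the 6 mm/s disengagement threshold
of a 0.3 µl load, so nothing moves; the retry at 8.33 × 0.6 = 5.0 mm/s
lands the droplet within the 10 px tolerance. In the assay, the hour-long
incubation turns the imipenem-containing test reaction from red
(hue ≈ 357°) to yellow (hue ≈ 51°) while the control stays red, so the
call is *positive* and the run is valid.

## Command line

```sh
Rscript -e 'droploop::run_cli()' generate --n_frames 769 --seed 1 --out_dir out/
Rscript -e 'droploop::run_cli()' assay --assay carba-np --cpe TRUE --out_dir out/
```

Subcommands: `simulate`, `generate`, `evaluate`, `assay`. Exit codes:
0 success, 1 operation failure (retries exhausted), 2 configuration error.
Images are written as PPM, annotations as COCO JSON, logs as TSV.

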