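---
title: "Measuring abdominal aortic calcification severity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring abdominal aortic calcification severity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacscore)
```

## The measurement model

`aacscore` grades calcific atherosclerotic disease of the distal
abdominal aorta on contrast-enhanced CT. The scored region is the
segment between the origin of the inferior mesenteric artery (IMA) and
the aortic bifurcation into the common iliac arteries — a segment
chosen for reproducibility, because both landmarks are unambiguous on
CT angiography and the vessel runs with minimal tortuosity there.

The quantity at the core of the package is, per aortic wall
(anterior and posterior), the **calcified fraction of the segment's
longitudinal length**:

$$ f_\text{wall} \;=\; \frac{\big|\bigcup_i [z^{(i)}_\text{lo},\, z^{(i)}_\text{hi})\big|}{z_\text{bif} - z_\text{ima}} \in [0, 1], $$

where the intervals are the longitudinal extents of the calcified
voxels attributed to that wall. Fractions are discretised by the
severity rubric

* 0 — no calcification at all ($f = 0$ exactly),
* 1 — $0 < f < \tfrac13$,
* 2 — $\tfrac13 \le f \le \tfrac23$,
* 3 — $f > \tfrac23$,

and the two wall sub-scores are summed into the 0–6 severity score.
The rubric phrase "between one-third and two-thirds" is read as
*inclusive* at both boundaries, with "less than" and "more than"
strict; `wall_subscore()` states this once and the tests pin both
boundaries. Any nonzero fraction scores at least 1: "no calcification"
means exactly zero. For noisy real data a `min_detectable_fraction`
floor exists (fractions at or below it count as clean), but it
defaults to 0 and is off in everything the package itself validates.

A voxel is *calcified* when its HU lies in the detection band
[450, 3070], both bounds inclusive (the protocol states the thresholds
without an open/closed convention; inclusivity is the package's stated
choice, exercised at exactly 450 and 3070 in tests). The 450 HU floor
is far above contrast-opacified blood (~300 HU), which is what makes
the measurement possible on angiographic studies without subtracting
the lumen.

A calcified voxel is *attributed to a wall* when its centre

1. lies longitudinally within $[z_\text{ima}, z_\text{bif}]$;
2. lies within 10 mm of the centreline along x — a 20 mm midline slab
   mirroring the 20 mm sagittal MIP on which the score is read
   visually. This deliberately reproduces the reading practice,
   including its known blind spot for strongly eccentric lateral
   disease; the tool measures what the visual protocol measures rather
   than "fixing" it;
3. lies radially within the wall band
   $[r_\text{lumen} - \delta,\; r_\text{lumen} + t_\text{wall} + \delta]$,
   with tolerance $\delta$ equal to one maximal in-plane voxel
   spacing, so partial-volume voxels at the wall edge still count;
4. is on the requested side: anterior means y above the centreline,
   posterior below. The 180° split is the simplest convention
   consistent with "anterior and posterior walls"; phantom plaques may
   be narrower sectors, but attribution never is. The two walls
   partition the voxels — nothing is counted twice.

Each contributing voxel covers its half-open longitudinal extent
$[z_\text{lo}, z_\text{hi})$; extents are unioned (no gap bridging —
the score counts calcified *length*, not lesions, so two plaques
separated by any gap contribute separately), clipped to the segment,
and divided by the segment length. Whether human raters judge the
fraction on the projected MIP image or across the slab volumetrically
is not specified by the protocol; the slab-volumetric reading is
implemented, and on the noise-free phantom the two are equivalent
because every plaque is within the slab.

## The display reformat

`sagittal_mip()` reproduces the viewing reconstruction: a sagittal
slab maximum-intensity projection, slab defined in millimetres and
converted to voxel columns by half-open rounding
$[\lfloor \text{lo}/dx \rfloor, \lceil \text{hi}/dx \rceil)$, so a
20 mm slab at 1 mm spacing covers exactly 20 columns and voxel counts
are reproducible. The protocol centres the slab "on the middle of the
aorta" without defining *middle*; the CLI's `--center-x auto` uses the
mean centreline x over the segment. `apply_window()` is the standard
linear window/level map (defaults: bone window, width 2500 HU, level
200 HU — "window length" in the source protocol is read as window
level, the standard radiology usage), with rounding **half away from
zero** so PNG exports are bit-identical across platforms.

## The reference calcium score

`agatston_score()` provides the comparison measure: per axial slice
inside the segment, 8-connected lesions of the detection mask
restricted to the wall band (both walls, no midline restriction),
lesion area in mm² times a peak-density weight (1/2/3/4 for peak HU in
[130, 200) / [200, 300) / [300, 400) / ≥ 400), scaled by
slice-spacing/3 mm and summed; lesions under 1 mm² are discarded;
`volume_score` is the retained plaque volume and `lesion_count` uses
26-connectivity in 3-D. Two notes. First, with the 450 HU floor every
retained lesion necessarily carries weight 4 — the code asserts rather
than assumes this, so lowering the floor (e.g. to the conventional
130 HU) reactivates the lower weight bands. Second, workstation
implementations are known to bleed into confluent calcification
beyond the segment landmarks when disease is extensive; this
implementation instead clips strictly to
$[z_\text{ima}, z_\text{bif}]$ — a deliberate, documented deviation
that removes that artefact, at the cost of not reproducing workstation
numbers (which are proprietary anyway; correlation with the rubric
score, not equality, is the only claim the package touches).

## Agreement statistics

`icc()` implements the two-way ANOVA intraclass correlation in the
Shrout–Fleiss / McGraw–Wong formulary, rows = subjects, columns =
raters, with three models: ICC(2,1) (two-way random, absolute
agreement, single measures — the default, since a published "ICC"
without a model most plausibly means agreement of single ratings),
ICC(2,k) for the k-rater average, and ICC(3,1) for consistency.
Mean squares come from `stats::aov`; the test suite recomputes them
from definitional sums of squares and requires agreement to 1e-10.
Confidence bounds use the standard F-based constructions (the
Spearman–Brown step-up for the average-measures model). An
all-identical matrix has undefined ICC and returns a flagged `NA`
rather than crashing.

`spearman_rank()` computes rho as the Pearson correlation of average
(tie-adjusted) ranks. The two-sided p-value is **exact by full
enumeration of the $n!$ rank permutations for $n \le 9$** — correct in
the presence of ties, which the classical exact tables are not — and
uses the t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ beyond
that. The enumeration cutoff at 9 keeps the exact path under ~0.4 M
permutations.

`simulate_raters()` exercises the machinery: each rater reports the
true 0–6 score, perturbed by ±1 with probability `error_prob`
(direction equiprobable) and clipped to [0, 6]. The study-style
analysis — ICC across raters, Spearman of the per-subject *arithmetic
mean* rater score (possibly fractional) against a calcium score — is
packaged as `agreement_stats()`. The published validation statistics
for this score (ICC 0.972, rho ≈ 0.85–0.89) derive from 75 unpublished
patient scans and three human raters, so the package makes no attempt
to reproduce those numbers; the agreement code is instead validated by
the oracle equivalences and by the property that mean simulated ICC
rises monotonically to exactly 1 as `error_prob` falls through
{0.4, 0.2, 0.1, 0}.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds the study conditions synthetically: a
contrast-filled lumen (300 HU) of radius 9 mm inside a 2 mm soft-tissue
wall (50 HU) on a 40 HU background, default grid 64×64×80 voxels at
1.5×1.5×1 mm (a typical reconstructed CTA resolution; the source
protocol reports no scanner parameters, so these are chosen defaults,
not inferred ones), segment 60 mm, plaques as angular wall sectors at
700 HU by default, and additive Gaussian HU noise (σ = 10 HU)
generated from the spec's seed. Voxels are floating HU with no integer
quantisation, which keeps the analytic oracles exact. Ground-truth
fractions are computed from the plaque intervals analytically, never
from voxels, so phantom and pipeline are genuinely independent routes
to the same number; with zero noise, every voxel at or above 450 HU
provably lies inside a declared plaque.

The default tube is straight, matching the minimal tortuosity of the
scored segment; an optional sinusoidal bow exists for robustness
experiments only. The phantom does **not** emulate organ backgrounds,
bone, beam hardening, motion, or DICOM semantics — so green tests
demonstrate the correctness of the measurement and scoring logic under
controlled geometry, not robustness to real-scan segmentation or
artefact burden. Geometry (centreline, radii, landmarks) is always an
*input*; automatic aorta segmentation and landmark detection are out
of scope.

`random_phantom_spec()` defines the sampled study conditions: per wall
it draws either a clean wall (probability 0.2) or a target fraction
uniform over the rubric-safe regions at least 0.05 away from the 1/3
and 2/3 boundaries (and at least 0.05 above 0), splits it over one or
two disjoint plaques, and — a deliberate design choice — snaps all
plaque intervals to the voxel grid. Snapping makes the analytic
fraction exactly recoverable from a noise-free rasterisation, so score
recovery tests are decided by the pipeline's correctness, not by
sub-voxel jitter; the safe margin is pre-shrunk by 0.6 dz/L before
snapping so the post-snap fraction still honours the 0.05 buffer. At
σ = 10 HU the tissue contrasts sit 15–25 standard deviations from the
450 HU threshold, so noise never flips a detection — by construction,
scoring is exact under the default conditions, and the 30-phantom
recovery suite (seeds 1–30) requires 30/30 exact totals.

## Numerical conventions and degenerate inputs

* All lengths in mm; all longitudinal intervals half-open
  $[z_\text{lo}, z_\text{hi})$; fraction denominators use
  $z_\text{bif} - z_\text{ima}$ exactly; fractions clipped to [0, 1].
* Canonical orientation (x left→right, y posterior→anterior,
  z inferior→superior) is asserted on NIfTI load; axes are permuted
  and flipped into it from the file affine, and obliquity beyond 5° is
  an error, not a resample.
* Empty masks are results (fraction 0, Agatston 0), not errors;
  invalid specs, geometry outside the volume, unknown config keys and
  out-of-range fractions are errors that name the violated field.
* Batch runs catch per-patient failures into an `error` column and
  continue; the CSV dialect is fixed (UTF-8, LF, integer scores,
  six-decimal fractions) so reruns are byte-identical.
* Test problem sizes: module tests use a 40×40×48 phantom with the
  same spacing and proportions as the default; the recovery suite runs
  the full 64×64×80 default across 30 seeds. Both sizes are the
  package's own choices of smallest grids that keep every geometric
  regime (multi-plaque, both walls, boundary-adjacent fractions)
  represented.

## Known limitations

Midline-slab reading under-measures strongly eccentric lateral
disease, by design fidelity to the visual protocol. The Agatston
module reproduces the standard public definition, not any vendor's.
The ICC model behind the published headline value is not identifiable
from the publication; the default here is declared, configurable, and
makes no claim to match an unstated choice. Real-scan ingestion
assumes HU-calibrated, near-axis-aligned NIfTI volumes and
externally supplied geometry.
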