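# aacscore

Semi-quantitative scoring of abdominal aortic calcification (AAC) from
CT angiography.

## The problem

Vascular calcification of the abdominal aorta is a marker of
cardiovascular morbidity, but unlike coronary calcium — where Agatston
scoring is the accepted standard — there is no widely used quantitative
grading for the aorta, and radiologists typically fall back on
subjective "mild / moderate / severe" descriptions. `aacscore`
implements a simple, reproducible alternative aimed at radiologists and
imaging researchers: a six-point severity score for the aortic segment
between the inferior mesenteric artery (IMA) origin and the bifurcation
into the common iliac arteries, computed automatically from a
HU-calibrated CT volume plus a segment geometry.

## The score

For each of the anterior and posterior aortic walls, the package
measures the **calcified fraction** `f` of the segment's longitudinal
length: calcified voxels are those in the 450–3070 HU detection band
that lie in the wall band of a 20 mm midline slab (mirroring how the
score is read visually on a 20 mm sagittal maximum-intensity
projection in bone windows, 2500/200 HU); the union of their
longitudinal extents is divided by the segment length
`z_bif − z_ima`. Each wall then receives a sub-score

| sub-score | calcified fraction of wall length |
|-----------|-----------------------------------|
| 0 | exactly none |
| 1 | less than one third |
| 2 | one third to two thirds (inclusive) |
| 3 | more than two thirds |

and the total severity score is the sum, 0–6, with 6 indicating severe
disease of both walls. Alongside the rubric the package computes a
standard Agatston-style calcium score over the same segment (per-slice
8-connected lesions, area × peak-density weight, slice spacing
normalised to 3 mm) for correlation, and provides the agreement
statistics used to validate such scores: two-way ANOVA intraclass
correlation (three model variants, F-based 95% CIs) and Spearman rank
correlation with exact permutation p-values for n ≤ 9, ties included.

Because no scan data accompany the scoring protocol, the package ships
a synthetic phantom generator: a contrast-opacified tube (lumen 300 HU,
safely below the detection floor) with a soft-tissue wall, calcified
plaques of known wall, extent and intensity, Gaussian HU noise, and
analytic ground truth for every derived quantity.

## Worked example

```r
library(aacscore)

spec <- random_phantom_spec(21)     # a randomly diseased phantom
ph   <- generate_phantom(spec)
ph$truth
#> <ground_truth> anterior 0.8833 (score 3), posterior 0.0000 (score 0), total 3

score_volume(ph$volume, ph$geometry)
#> <atheroma_score> anterior 3 + posterior 0 = total 3 (of 6)

mask <- detect_calcification(ph$volume)        # 450-3070 HU band
agatston_score(ph$volume, mask, ph$geometry)
#> <calcium_score_result> Agatston 2538.0, volume 1903.5 mm^3, 2 lesion(s)
```

The phantom's anterior wall is 88% calcified over the segment, so the
rubric assigns the anterior wall 3, the clean posterior wall 0, and a
total of 3 of 6 — and the pipeline recovers exactly the analytic
ground-truth scores. The Agatston result says the same disease is worth
2538 Agatston units (1903.5 mm³ of plaque in two discrete lesions).

Agreement statistics on simulated raters:

```r
m <- simulate_raters(rep(0:6, length.out = 75), n_raters = 3,
                     error_prob = 0.1, seed = 7)
icc(m)
#> $icc 0.980  $ci_low 0.969  $ci_high 0.988
#> $icc_model "two_way_random_absolute_single"
```

A command-line interface is installed as `aacscore` with subcommands
`phantom`, `mip`, `coverage`, `score`, `agatston`, `agree` and `run`;
see `?aac_cli`.

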