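---
title: "Automated photo-identification of dolphin dorsal fins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated photo-identification of dolphin dorsal fins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finprint)
```

## The problem

Photo-identification (photo-ID) recognises individual animals from
photographs of stable natural marks. Risso's dolphins (*Grampus griseus*)
are particularly well suited to it: they accumulate long-lasting white
scratches and scars on the dorsal fin throughout life, so the fin acts as a
fingerprint. Manual photo-ID — an expert leafing through a catalogue — does
not scale to the thousands of photographs a multi-year vessel survey
produces. `finprint` implements a fully automated pipeline: given a cropped
fin photograph, it decides which catalogued individual the fin belongs to,
flags unreliable decisions, and feeds the resulting sighting records into
simple site-fidelity analytics.

This vignette documents the model, the tunable parameters, the synthetic
data the package is tested on, the numerical conventions, and the design
choices that were genuinely open.

## Pipeline

A query photograph `I` passes through five stages.

**1. Fin segmentation.** `I` is converted from sRGB to CIE-Lab (D65 white
point, via `grDevices::convertColor`). A grey fin against blue water is
nearly achromatic while the sea sits far down the blue-yellow (b\*) axis, so
a single threshold on an opponent channel separates the two classes. The
channel (a\* or b\*) is chosen per image as the one whose Otsu split attains
the larger between-class variance; `segmentation_config(channel =)` can
force either. Otsu's threshold is computed over a 256-bin histogram of the
channel. The split polarity is fixed by the image border: the class holding
the majority of the 1-pixel border is called sea (cropped fin photographs
have water at their edges, the fin interior). The binary mask is cleaned by
a morphological opening-then-closing with a disc of radius
`max(1, round(0.005 * min(H, W)))` pixels and reduced to its largest
8-connected component, which must be unique and non-empty.

**2. Sharpness.** Image quality is scored as the standard deviation of the
response to the 3x3 Laplacian kernel `[[0,1,0],[1,-4,1],[0,1,0]]`, computed
on the CIE-Lab lightness plane rescaled to `[0, 255]` with reflect padding,
and evaluated over the fin foreground only (the score is meant to measure
blur *of the fin*, not of the background; `sharpness_scope = "image"` gives
the whole-frame variant). A constant region scores exactly 0 and Gaussian
blur strictly lowers the score. Because L\* is mildly non-linear in RGB, the
score is only approximately invariant to a uniform intensity shift (within
a few percent in practice).

**3. Keypoint detection.** Scale- and rotation-invariant keypoints are
detected and described by a pluggable backend (any object with a
`detect(image, mask)` function); keypoints falling outside the fin mask are
always deleted afterwards. The built-in `"cdog"` backend works in a
*canonical fin frame*: the mask's centroid, second-moment major axis
(direction disambiguated by the sign of the third moment along the axis)
and root-area fix a similarity transform, and the image is warped so the
fin is centred, axis-horizontal, and of fixed size (root-area 130 px on a
288 px canvas). In that frame a difference-of-Gaussians ladder
(`sigma = 1.2 * 2^(i/3)`, 9 levels — fine enough to respond to
few-pixel-wide scratch marks) yields extrema that are strict 3x3x3 maxima
or minima above a contrast threshold (0.01 on the `[0,1]` grey scale).
Responses closer than about twice their scale to the mask boundary are
discarded: they are driven by the fin/sea silhouette rather than by marks
on the fin, and they would make even an unmarked fin appear feature-rich.
Each keypoint receives a dominant gradient orientation (36-bin histogram,
Gaussian-weighted, parabolic peak interpolation) and a 128-dimensional
SIFT-style descriptor (4x4 spatial cells x 8 orientation bins over a
rotated patch of half-width 6 sigma, L2-normalised, clipped at 0.2,
renormalised). Keypoint positions and scales are mapped back to the
original image frame; **orientations are reported in the canonical frame**,
i.e. relative to the fin's own axis. The strongest 150 keypoints are kept.

**4. Admission filter.** An image takes part in enrollment or
identification only if it is at least 200 px wide *and* 200 px tall, has at
least 5 keypoints inside the fin, and (optionally) reaches a sharpness
floor `sigma_s` (`quality_config()`; all thresholds inclusive, defaults
200/200/5/0). Failing images are returned as structured rejections naming
every violated rule — never as forced guesses.

**5. Matching and decision.** The query's feature set is compared with
every enrolled fin model (one model per dolphin side). Matching is
mutual-nearest-neighbour in descriptor space under the L2 norm, hence
one-to-one; an optional Lowe ratio test is available but off by default.
For each model `i` three quantities are kept: the raw match count `k_i`;
the trimmed median distance `d*_i` — the median of the match distances
lying inside the closed 25th-75th percentile interval
(linear-interpolation percentiles) of all `k_i` distances; and `k*_i`, the
number of matches whose rounded orientation difference
`round(o_query - o_model)` is zero, the difference being wrapped to
`(-180, 180]` degrees first (R's round-half-to-even). The predicted
identity is `argmax_i k*_i`; ties are broken by minimum `d*_i`; a double
tie falls back to enrollment order and raises an `ambiguous_tie` warning;
a winning `k* <= 4` raises `low_support`. A query matching no model at all
(`k_i = 0` everywhere) is rejected rather than guessed.

### Why orientations live in the fin frame

The equal-orientation filter keeps only matches whose absolute orientations
agree, which presumes the query and the model fin are seen in the same
pose. Rotating the photograph rotates every keypoint orientation with it,
so orientations measured in the *camera* frame would make the filter delete
every correct match of a rotated query. Measuring orientations relative to
the fin's own principal axis removes the camera pose from the comparison:
an in-plane rotation of the photograph rotates mask and keypoints together
and the relative orientations are unchanged up to estimation noise. This is
what makes the identification outcome stable under in-plane rotations of
tens of degrees and under rescaling, while keeping the filter fully
effective at rejecting coincidental matches, whose orientation differences
spread over the whole circle. The same canonicalisation normalises scale,
so the descriptor comparison is also size-independent as long as the image
survives the 200-px admission gate.

## Enrollment and the catalogue

The catalogue stores, per photograph: the dolphin's name, the full image
path, the cropped fin path, the observation date (ISO 8601), the GPS
position (signed decimal degrees WGS84), an acquisition-campaign codename,
and optionally the fin side. Sighting records (date, position, depth in
metres, group size, identified dolphins) ride along in a companion table.
Files are flat JSON or CSV — deliberately serverless, so a catalogue is a
directory that round-trips bit-for-bit and diffs cleanly under version
control.

`build_fin_models()` enrolls, for every (dolphin, side) pair, the admitted
image with the highest sharpness, breaking ties by lexicographically
smallest path (the selection rule had to be fixed somehow; sharpest-first
matches the admission logic). The model count is therefore
`m = d + b`, with `d` enrolled dolphins and `b` dolphins contributing both
sides. Dolphins with no admitted image are reported as un-enrollable, never
silently dropped.

## Sighting analytics

Three small analyses support site-fidelity questions:

* the bipartite **dolphin-date graph** (edge iff a dolphin was photographed
  on a date) and its connected components — disjoint components are closed
  sighting communities;
* the **co-sighting graph**: dolphins linked iff they share a sighting
  date, edge weight = number of shared dates (rendered dashed when 1, solid
  otherwise), nodes classed `shallow_only` / `deep_only` / `both` by the
  depth stratum of their sightings. The stratum boundary defaults to 800 m;
  a sighting at exactly the boundary is classed deep (the boundary had to
  fall on one side; "deep starts at 800 m" is the convention here);
* the **sighting frequency**: per dolphin and stratum, the number of its
  sightings in the stratum divided by the stratum's sighting total,
  restricted to individuals sighted more than once overall (a single
  sighting carries no fidelity information). Frequencies of the two strata
  are compared with a right-tailed Wilcoxon rank-sum test
  (`wilcoxon_rank_sum_right`): exact via the null distribution of the
  Mann-Whitney statistic when the combined sample is at most 12 and
  tie-free, otherwise midranks with a tie-corrected, continuity-corrected
  normal approximation; a zero-variance degenerate case returns p = 0.5.

## Synthetic data: what it emulates, what it does not

Real fin imagery of this kind is typically available only on request, so
the package ships a generator that every other module is tested against.
An `identity_spec` is a dorsal-fin-like polygon (quadratic Bezier leading
and trailing edges, 1-3 trailing-edge notches, per-identity jitter) plus
8 near-white scar strokes whose endpoints both lie on the fin surface —
all a pure function of the identity's seed. `generate_fin_image()` applies
rotation and scale analytically to the polygon before rasterising, so the
returned ground-truth mask is the exact rendered support; Gaussian blur and
pixel noise (sd 2 by default) are applied to the image only. Defaults —
400x400 canvas (clearing the 200-px gate), fin grey `(128,128,128)`, sea
blue `(20,60,140)`, far apart on b\* — encode the colour-separability
assumption the segmentation relies on. `generate_gallery()` mirrors the
enrollment/test split of a real campaign: one clean model render per
identity, queries re-rendered with perturbed rotation (±15° by default),
scale (0.9-1.1) and blur (cycling a given set), never sharing the model's
parameters. `generate_catalogue()` emulates a multi-year survey: per-date
Bernoulli resighting (default 0.25, at least one sighting each), dates
assigned to depth strata, GPS inside a fixed Gulf-of-Taranto-like bounding
box.

The generator deliberately omits: water texture, reflections and
over-exposure; out-of-plane (3-D) fin pose, so the rotation-invariance
claims are tested through in-plane proxies only; occlusion and multiple
fins per frame; and photographic colour casts. Passing tests on synthetic
scenes therefore demonstrate the pipeline's *logic* (segmentation given
colour separability, invariances, decision rule, gating) — not field
accuracy on real imagery, which depends on exactly the nuisances the
generator leaves out.

## Numerical conventions and edge cases

* Coordinates are 0-based; `x` is the column (rightward), `y` the row
  (downward). Percentiles and quantiles use the linear-interpolation
  convention (R type 7). Rounding is R's round-half-to-even.
* Otsu on a constant channel, an all-sea image, an empty post-cleaning
  mask, an empty model list, and an evaluation with zero admitted queries
  are all hard errors, not silent defaults.
* Sharpness ties in enrollment break by image path; `which`-style argmax
  ties in matching break by first index; both keep every run reproducible.
* `D_i` stores *descriptor-space* L2 distances. The phrase "relative
  distance" could equally mean image-plane distance between matched
  coordinates; that reading is available as
  `match_features(distance_space = "image")` but descriptor distance is the
  default, since it measures match quality independent of fin pose.
* All randomness flows through explicit integer seeds; derived sub-seeds
  stay below 2^31.

## Evaluation protocol

`evaluate()` scores labelled queries; accuracy is counted over *admitted*
queries only (rejected ones are excluded from the denominator, mirroring
the restriction to reliable test images; a penalised accuracy counting
rejections as errors is reported alongside). `accuracy_by_sharpness()`
sweeps a sharpness floor `sigma_s` — by default the 1, 10, 25, 50, 75 and
90-percentiles of the admitted queries' sharpness — using strict
`sharpness > sigma_s` filtering; thresholds retaining nothing are reported
with `NA` accuracy rather than dropped. On mixed-blur synthetic sets the
curve rises with the threshold, because errors concentrate in the blurred
queries. The test suite checks the package at these problem sizes: a
20-identity gallery, 40 clean rotated queries, and a 200-query mixed-blur
sweep (blur sigma 0/1/2/4) — small enough to run routinely, large enough
for the accuracy statements to be meaningful.

## Known limitations

* The canonical pose relies on the mask's second and third moments; a fin
  segmented badly enough to corrupt its moments will mis-canonicalise and
  the match will fail (it usually then fails the feature gate and is
  rejected rather than misidentified).
* In-plane invariance only: out-of-plane rotation changes the visible scar
  pattern itself and is out of scope.
* The left and right fin sides are independent models; no symmetry transfer
  is attempted.
* The detector is tuned for mark-carrying fins; an individual with very few
  scars will produce few keypoints and be rejected by the feature gate —
  consistent with how such individuals are treated in manual catalogues.
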