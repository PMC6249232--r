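# finprint

Automated photo-identification of individual Risso's dolphins (*Grampus
griseus*) from cropped dorsal-fin photographs, with the catalogue data model
and sighting analytics that go with a multi-year photo-ID campaign.

Risso's dolphins accumulate long-lasting white scars on the dorsal fin, so
the fin works as a natural fingerprint. `finprint` automates the match
against a catalogue of known individuals:

1. **Segmentation** — sRGB → CIE-Lab (D65); Otsu's threshold on the opponent
   channel (a\* or b\*) with the larger between-class variance; polarity
   fixed by the image border (sea touches the edges); morphological
   opening/closing; largest 8-connected component.
2. **Sharpness** — the standard deviation of the 3×3 Laplacian response
   over the fin foreground; used to gate blurred images and to stratify
   accuracy.
3. **Features** — scale/rotation-invariant keypoints restricted to the fin,
   from a pluggable backend. The built-in `cdog` backend detects
   difference-of-Gaussians extrema in a canonical fin frame (pose fixed from
   the mask's moments) and describes them with 128-d gradient-histogram
   descriptors; orientations are reported relative to the fin axis.
4. **Admission filter** — at least 200 px width, 200 px height and 5
   keypoints inside the fin (plus an optional sharpness floor σ_s); failing
   images are rejected with the violated rules named.
5. **Decision** — mutual-nearest-neighbour matching (one-to-one, L2) against
   each enrolled fin model *i* gives the match count `k_i`, the trimmed
   median descriptor distance `d*_i` (median inside the closed 25th–75th
   percentile interval of the match distances) and `k*_i`, the matches with
   `round(o_query − o_model) = 0` after wrapping to (−180°, 180°]. The
   prediction is `argmax_i k*_i`, ties broken by minimum `d*_i`, with
   warnings for `k* ≤ 4` (`low_support`) and unresolved ties
   (`ambiguous_tie`).

A synthetic fin generator (grey fin polygon on blue sea, per-identity scar
strokes, controllable rotation/scale/blur/noise, exact ground-truth masks)
stands in for field imagery, which is typically request-only. Sighting
analytics include the bipartite dolphin–date graph and its connected
components, the co-sighting graph with depth-stratum node classes
(shallow/deep split at 800 m), per-stratum sighting frequencies (individuals
sighted more than once), and a right-tailed Wilcoxon rank-sum comparison of
the two strata.

## Worked example

```r
library(finprint)

# a 20-identity synthetic gallery: clean model renders + rotated queries
gal <- generate_gallery(20, q_per_identity = 2, blur_levels = 0, seed = 42)

models <- lapply(gal$models, function(m) {
  mask <- extract_fin_mask(m$image)
  fin_model(m$label, "left", m$image,
            detect_features(m$image, mask),
            sharpness = sharpness(m$image, mask))
})

q <- gal$queries[[1]]
identify(q$image, models)
#> <prediction: SYN-001 (left)  k*=29 d*=0.0219>

res <- evaluate(models, gal$queries)
res
#> <evaluation: accuracy 100.0% on 40/40 admitted queries>

head(accuracy_by_sharpness(res), 3)
#>    sigma_s accuracy n_retained
#> 1 23.52366        1         39
#> 2 24.20034        1         36
#> 3 24.92372        1         30
```

`identify()` reports the winning identity with its evidence: `k*` is the
number of equally oriented descriptor matches against that model and `d*`
the trimmed median descriptor distance (0 would mean a pixel-identical
enrolled image). `evaluate()` scores labelled queries, counting accuracy
over admitted queries only; `accuracy_by_sharpness()` sweeps the sharpness
floor σ_s and shows how accuracy rises when blurred queries are excluded.

The command-line interface wires the same functions end to end:

```sh
inst/cli/finprint simulate --identities 20 --queries 3 --blur 0,1,2,4 --seed 7 --out simdata/
inst/cli/finprint enroll   --catalogue simdata/models_catalogue.json --out gallery/
inst/cli/finprint identify --gallery gallery/ --images q1.png q2.png --report out.csv
inst/cli/finprint stats    --catalogue c.json --sightings s.json --out reports/ --depth-split 800
inst/cli/finprint evaluate --gallery gallery/ --queries simdata/queries --labels simdata/labels.csv --out eval/
```

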