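# herdtrack

Multi-object tracking and behavior analytics for barn-camera livestock
video, in R.

Surveillance cameras over a cattle pen produce per-frame detector output:
bounding boxes with confidence scores and one of seven behavior classes
(feeding, drinking, standing, lying, walking, climbing, fighting).
`herdtrack` links those detections into persistent animal identities and
turns the resulting trajectories into the quantities a welfare or
husbandry study needs: per-animal behavior time budgets and herd-level
behavior incidence over time. It is aimed at researchers who already run
a detector (and optionally a re-identification embedding model) and need
the tracking, evaluation and analytics stages to be reproducible and
scriptable.

## The tracker

`herdtrack` implements a confidence-tiered, two-round
tracking-by-detection cascade in the BoT-SORT family:

- Detections are split by confidence into a high tier
  (conf ≥ θ<sub>high</sub> = 0.5), a medium tier
  (θ<sub>med</sub> = 0.3 ≤ conf < θ<sub>high</sub>), and a discarded tier
  (conf < θ<sub>med</sub>).
- Each track carries a constant-velocity Kalman filter over the state
  (c<sub>x</sub>, c<sub>y</sub>, w, h, v<sub>cx</sub>, v<sub>cy</sub>,
  v<sub>w</sub>, v<sub>h</sub>), with noise scaled to box size. Predicted
  boxes may be adjusted by an injected camera-motion transform.
- Round 1 matches high-tier detections to tracks with a fused cost:
  motion cost 1 − DIoU (distance-IoU, which penalises the squared center
  distance normalised by the enclosing-box diagonal,
  DIoU = IoU − ρ²/C²) combined with the cosine distance between
  appearance embeddings under a gated minimum rule. Round 2 matches the
  remaining detections with the motion cost alone. Assignments are
  optimal (Jonker–Volgenant).
- Tracks unmatched for more than 30 frames are deleted. When a lost
  track is re-acquired, per-coordinate cubic splines are fitted over
  observations bracketing the gap, evaluated at the missed frames, and
  the resulting *virtual observations* are replayed through the Kalman
  filter so the state sheds the error accumulated while coasting.

The package also provides the standard MOT evaluation suite (HOTA, MOTA,
MOTP, IDF1, MT/ML ratios, identity switches) with a pooled multi-sequence
report, MOTChallenge txt readers/writers, and a seeded synthetic
barn-scene simulator that makes the entire pipeline testable without
field video.

## A worked example

```r
library(herdtrack)

# simulate a sparse daytime pen: 8 animals, 25 fps, seeded
cfg <- scene_preset("sparse_day")
cfg$n_frames <- 250L
scene <- simulate_scene(cfg, seed = 42)

# track the corrupted detections with the default configuration
tracks <- track_detections(scene$detections, tracker_config(),
                           embeddings = scene$embeddings)
glance(tracks)
#> # A tibble: 1 × 5
#>   n_tracks births deletions discarded n_frames
#>      <int>  <int>     <int>     <int>    <int>
#> 1        8      8         0        13      250

# evaluate against the simulator's ground truth
mot_evaluate(scene$gt, tracks[!tracks$virtual,
                              c("frame", "id", "left", "top",
                                "width", "height")])
#> # A tibble: 1 × 12
#>    HOTA  DetA  AssA  MOTA  MOTP  IDF1   MTR   MLR   IDS    FP    FN    GT
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <int> <int> <int> <int>
#> 1  94.7  94.6  94.7  95.7  96.9  97.8   100     0     0     0    86  2000

# behavior analytics: seconds per behavior for each animal
time_budget(tracks, fps = 25)
#> # A tibble: 8 × 12
#>      id feeding drinking standing lying walking climbing fighting   gap total
#>   <int>   <dbl>    <dbl>    <dbl> <dbl>   <dbl>    <dbl>    <dbl> <dbl> <dbl>
#> 1     1    0         0       0.6   9.16    0           0     0     0.24    10
#> 2     2    5.08      0       2.32  1.96    0           0     0     0.64    10
#> 3     3    1.12      0       1.68  7       0           0     0     0.2     10
#> # … 5 more rows and first_frame, last_frame columns
```

The run above says: all 8 simulated animals were tracked (8 births, no
deletions), and 13 clutter detections fell below θ<sub>med</sub> and were
discarded. Against ground truth the tracker keeps every identity
(IDS = 0, IDF1 = 97.8), emits no box without a ground-truth counterpart
(FP = 0) and loses 86 of 2000 ground-truth boxes to occlusion dropouts
(FN), for MOTA 95.7%; HOTA 94.7% summarises detection and association
quality jointly. The time budget converts each track's smoothed behavior
labels into seconds per class over its 10-second span, with lost-track
gap time reported separately rather than attributed to a behavior.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/herdtrack simulate --preset sparse_day --seed 42 --out scene/
Rscript inst/cli/herdtrack track --det scene/det/det.txt \
    --emb scene/det/embeddings.txt --out tracks.txt
Rscript inst/cli/herdtrack eval --gt scene/gt/gt.txt --pred tracks.txt --out report
Rscript inst/cli/herdtrack behavior --tracks tracks.txt --out analytics/
```

Every command writes a JSON manifest (config snapshot, input hashes,
seed, version) so a run can be reproduced exactly.

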