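# pairtrack

Multi-animal tracking by identification: contrastive representation learning
on image pairs mined from video structure, without any identity labels.

## The problem

Tracking N visually similar animals in a video is easy between crossings —
follow each blob from frame to frame — and hard across them: whenever two
animals touch or occlude each other, frame-to-frame linking loses who is who.
`pairtrack` resolves crossings by *identification*: it learns, from the video
alone, an appearance representation in which images of the same animal lie
close together and images of different animals lie far apart, then uses that
representation to assign a consistent identity to every detection.

The supervision is free and comes from the video's own structure:

- all detections between two crossings (a **fragment**) show the same animal
  — a source of *positive* image pairs;
- two fragments that overlap in time (**coexist**) must show different
  animals — a source of *negative* pairs.

## The model

Write `e(x) ∈ R^M` for the embedding of an image crop `x` (here an MLP,
`M = 8`). Training minimises the double-margin contrastive loss over mined
pairs at distance `d = ||e(x1) − e(x2)||`:

    L(x1, x2) = max(0, d − d_pos)²     for positive pairs   (d_pos = 1)
    L(x1, x2) = max(0, d_neg − d)²     for negative pairs   (d_neg = 10)

Each batch holds 400 positive and 400 negative pairs (1600 images). Every
`eval_every` batches the embedded images are clustered with k-means (`k = N`)
and the clustering quality is measured with the mean Silhouette score;
training stops once it reaches **0.91** on two consecutive evaluations, the
level at which per-image identification error falls below 1%. Poorly
separated clusters receive priority in subsequent pair sampling.

Identities are then assigned per fragment (each fragment takes the cluster
with the highest mean assignment probability, with exclusivity among
coexisting fragments enforced by maximum-weight matching), trajectories are
assembled per frame, impossible jumps at fragment handoffs are corrected, and
positions during crossings are linearly interpolated.

The pipeline needs no global fragments (moments where all N animals are
visible at once); accuracy degrades only when **fragment connectivity** — the
mean fraction of other animals each fragment coexists with — drops below 0.5,
at which point a warning is raised.

## Worked example

```r
library(pairtrack)

# a ground-truthed synthetic video: 4 textured discs in a circular arena
dataset <- generate_dataset(generator_config(
  n_animals = 4, n_frames = 600, arena_radius = 150, seed = 5))

fit <- track(dataset, seed = 2)
print(fit)
#> Multi-animal tracking by contrastive identity learning
#>   4 animals, 600 frames, 12 fragments (connectivity 1.278)
#>   training: 200 batches, stop: silhouette_reached
#>   mean silhouette: 0.9472   estimated accuracy: 1.0000

summary(fit)          # per-run metrics: connectivity, coverage, silhouette...
positions <- fitted(fit)   # N x T x 2 array, NA where missing
plot(fit)             # trajectories, one colour per identity

# evaluate against the generator's ground truth
gt <- ground_truth_trajectories(dataset)
idf1(fit$trajectories, gt, match_radius = dataset$gen$body_radius,
     include_crossings = FALSE)
#> IDF1 = 1.0000 (IDTP 2317, IDFP 0, IDFN 0)
```

The command-line interface (`inst/cli/pairtrack`) wraps the same pipeline:
`pairtrack generate`, `pairtrack track`, `pairtrack evaluate` and
`pairtrack occlusion-sweep` operate on dataset/session directories described
in a YAML config. Exit codes: 0 success, 2 invalid config/input, 3
insufficient connectivity, 4 data inconsistency.

## Stress-testing without global fragments

`occlusion_experiment()` masks an angular sector of the arena before tracking
and reports, per angle: fragment connectivity, whether any global fragment
survives, and IDF1 restricted to ground truth outside the mask (and farther
than `exclusion_margin` pixels from its boundary). Global fragments vanish
long before connectivity falls below 0.5; identification stays accurate until
it does.

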