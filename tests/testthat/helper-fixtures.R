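# Shared fixtures, rendered lazily and cached for the whole test run so that
# expensive full-frame renders are not repeated across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A standard dorsal pose at a known angle/position, plus its localization.
fx_dorsal <- function() {
  fixture("dorsal", function() {
    spec <- larva_spec(axis_angle = 37, head_center = c(480, 650))
    pose <- render_pose(spec, rng_seed = 101)
    loc <- multipose:::localize_pose(pose$brightfield, pose$fluorescence)
    list(spec = spec, pose = pose, loc = loc)
  })
}

# A lateral pose (one eye over the brain region).
fx_lateral <- function() {
  fixture("lateral", function() {
    spec <- larva_spec(orientation = "lateral_down", axis_angle = 202,
                       head_center = c(540, 700))
    render_pose(spec, rng_seed = 102)
  })
}

# Healthy eye-masked crops and a template built from them.
fx_crops <- function() {
  fixture("crops", function() {
    lapply(1:3, function(s) {
      pose <- render_pose(larva_spec(axis_angle = 67 * s), rng_seed = 200 + s)
      loc <- multipose:::localize_pose(pose$brightfield, pose$fluorescence)
      stopifnot(loc$ok)
      mask_eyes(loc$crop$image, loc$crop$eye_mask)
    })
  })
}

fx_template <- function() {
  fixture("template", function() build_template(fx_crops()))
}

# Render + localize one larva at a random angle/position under `seed`;
# returns errors against ground truth (NULL on localization failure).
localize_random_dorsal <- function(seed, ablation = 0) {
  set.seed(seed)
  spec <- larva_spec(axis_angle = runif(1, 0, 360),
                     head_center = c(520, 696) + runif(2, -60, 60),
                     ablation_fraction = ablation)
  pose <- render_pose(spec, rng_seed = seed)
  loc <- multipose:::localize_pose(pose$brightfield, pose$fluorescence)
  if (!loc$ok) return(NULL)
  gt <- pose$ground_truth
  dims <- dim(pose$brightfield)
  bc_gt <- transform_points(gt$brain_center, loc$angle, dims)
  eyes_gt <- transform_points(gt$eye_centroids, loc$angle, dims, scale = 0.5)
  eyes_gt <- eyes_gt[order(eyes_gt[, 2]), ]
  # return only the error summaries: keeping renders alive across hundreds
  # of larvae would hold gigabytes
  list(brain_err = sqrt(sum((bc_gt - loc$brain_center_full)^2)),
       eye_err = max(sqrt(rowSums((eyes_gt - loc$eyes)^2))))
}
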