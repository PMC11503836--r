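# Shared fixtures and oracles, all built in code at test time.

# A noise-free, occlusion-free scene: detections equal ground truth with
# confidence 1. Used for identity end-to-end properties.
clean_scene_config <- function(n_animals = 10L, n_frames = 100L) {
  scene_config(n_animals = n_animals, n_frames = n_frames,
               occlusion_rate = 0, overlap_dropout = 1.01,
               overlap_partial = 1.01, jitter_center_sd = 0,
               jitter_size_sd = 0, conf_visible_mean = 1,
               conf_visible_sd = 0, false_positive_rate = 0, miss_rate = 0)
}

# Walking-heavy scenes with forced 5-15-frame occlusion events: animals
# follow curved paths, so occlusion recovery exercises the motion model.
curved_occlusion_config <- function(n_animals = 10L, n_frames = 200L) {
  P <- matrix(0, 7, 7)
  w0 <- c(0.05, 0.02, 0.1, 0.05, 0.65, 0.08, 0.05)
  for (i in 1:7) {
    w <- w0
    w[i] <- 0
    P[i, ] <- 0.1 * w / sum(w)
    P[i, i] <- 0.9
  }
  scene_config(n_animals = n_animals, n_frames = n_frames,
               behavior_transition = P, dwell_min = 5L, accel_sd = 0.5,
               occlusion_rate = 0.02, occlusion_duration = c(5L, 15L),
               false_positive_rate = 0.1, miss_rate = 0.02)
}

# Exhaustive-permutation assignment oracle: minimum total cost over all
# complete one-to-one assignments of a square matrix.
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# Integer-grid rasterization IoU oracle: count covered unit pixels.
raster_iou <- function(a, b) {
  cells <- function(box) {
    xs <- seq(box[1], box[1] + box[3] - 1L)
    ys <- seq(box[2], box[2] + box[4] - 1L)
    as.vector(outer(xs, ys, function(x, y) paste(x, y)))
  }
  ca <- cells(a)
  cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

random_int_box <- function() {
  c(sample(0:40, 1), sample(0:40, 1), sample(1:25, 1), sample(1:25, 1))
}

# tracker output in the column layout the evaluator expects
pred_boxes <- function(tracks) {
  tracks[!tracks$virtual, c("frame", "id", "left", "top", "width", "height")]
}

run_reference_evaluator <- function(gt, pred) {
  gt_file <- tempfile(fileext = ".txt")
  pred_file <- tempfile(fileext = ".txt")
  write_mot(gt, gt_file)
  write_mot(pred, pred_file)
  script <- testthat::test_path("ref_eval.py")
  out <- suppressWarnings(
    system2("python", c(script, gt_file, pred_file), stdout = TRUE)
  )
  unlink(c(gt_file, pred_file))
  if (!is.null(attr(out, "status"))) return(NULL)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

python_available <- function() {
  nzchar(Sys.which("python"))
}
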