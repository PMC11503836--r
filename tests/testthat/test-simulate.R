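test_that("scene configs are validated field by field", {
  expect_s3_class(scene_config(), "scene_config")
  bad_P <- diag(7)
  bad_P[1, 1] <- 0.5
  expect_error(scene_config(behavior_transition = bad_P), "stochastic")
  expect_error(scene_config(miss_rate = 1.5), "miss_rate")
  expect_error(scene_config(occlusion_duration = c(4L, 2L)),
               "occlusion_duration")
  expect_error(scene_config(n_animals = 0), "n_animals")
})

test_that("a noise-free scene reproduces the ground truth exactly", {
  cfg <- clean_scene_config(n_animals = 5L, n_frames = 30L)
  sc <- simulate_scene(cfg, seed = 1)
  expect_equal(nrow(sc$detections), 5L * 30L)
  expect_true(all(sc$detections$conf == 1))
  expect_equal(sc$detections[, c("frame", "left", "top", "width", "height")],
               sc$gt[, c("frame", "left", "top", "width", "height")],
               tolerance = 1e-12)
  expect_equal(nrow(sc$events), 0L)
})

test_that("scenes are reproducible from the seed, down to the files", {
  cfg <- scene_preset("sparse_day")
  cfg$n_frames <- 40L
  s1 <- simulate_scene(cfg, seed = 9)
  s2 <- simulate_scene(cfg, seed = 9)
  expect_identical(s1$gt, s2$gt)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$embeddings, s2$embeddings)
  d1 <- tempfile(); d2 <- tempfile()
  write_scene(s1, d1); write_scene(s2, d2)
  for (f in c("gt/gt.txt", "det/det.txt", "det/embeddings.txt")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  s3 <- simulate_scene(cfg, seed = 10)
  expect_false(identical(s1$detections, s2$detections) &&
                 identical(s1$detections, s3$detections))
  unlink(c(d1, d2), recursive = TRUE)
  expect_error(simulate_scene(scene_config()), "seed")
})

test_that("trajectories are continuous and boxes stay in the arena", {
  cfg <- curved_occlusion_config(n_animals = 6L, n_frames = 120L)
  sc <- simulate_scene(cfg, seed = 4)
  gt <- dplyr::mutate(sc$gt, cx = left + width / 2, cy = top + height / 2)
  for (i in unique(gt$id)) {
    g <- gt[gt$id == i, ]
    step <- sqrt(diff(g$cx)^2 + diff(g$cy)^2)
    expect_true(all(step <= cfg$speed_cap + 1e-9))
  }
  expect_true(all(gt$left >= -1e-9))
  expect_true(all(gt$top >= -1e-9))
  expect_true(all(gt$left + gt$width <= cfg$arena_width + 1e-9))
  expect_true(all(gt$top + gt$height <= cfg$arena_height + 1e-9))
})

test_that("detection count under a pure miss rate is binomial", {
  m <- 0.15
  cfg <- scene_config(n_animals = 8L, n_frames = 200L, occlusion_rate = 0,
                      overlap_dropout = 1.01, overlap_partial = 1.01,
                      false_positive_rate = 0, miss_rate = m,
                      jitter_center_sd = 0, jitter_size_sd = 0)
  sc <- simulate_scene(cfg, seed = 5)
  n <- 8 * 200
  expected <- n * (1 - m)
  sd3 <- 3 * sqrt(n * m * (1 - m))
  expect_gt(nrow(sc$detections), expected - sd3)
  expect_lt(nrow(sc$detections), expected + sd3)
})

test_that("occlusion events suppress detections while active", {
  cfg <- scene_config(n_animals = 4L, n_frames = 120L, occlusion_rate = 0.02,
                      overlap_dropout = 1.01, overlap_partial = 1.01,
                      false_positive_rate = 0, miss_rate = 0)
  sc <- simulate_scene(cfg, seed = 7)
  ev <- sc$events[sc$events$type == "occlusion", ]
  expect_gt(nrow(ev), 0L)
  for (k in seq_len(nrow(ev))) {
    during <- sc$detections$frame >= ev$frame_start[k] &
      sc$detections$frame <= min(ev$frame_end[k], cfg$n_frames)
    # the occluded animal is undetected, so its gt boxes in the window
    # outnumber detections (detections carry id -1; count by overlap)
    gt_boxes <- sc$gt[sc$gt$id == ev$id[k] &
                        sc$gt$frame >= ev$frame_start[k] &
                        sc$gt$frame <= ev$frame_end[k], ]
    det_during <- sc$detections[during, ]
    if (nrow(gt_boxes) && nrow(det_during)) {
      overlaps <- vapply(seq_len(nrow(gt_boxes)), function(i) {
        same_frame <- det_during[det_during$frame == gt_boxes$frame[i], ]
        if (nrow(same_frame) == 0L) return(0)
        max(box_iou(as.matrix(gt_boxes[i, c("left", "top", "width",
                                            "height")]),
                    as.matrix(same_frame[, c("left", "top", "width",
                                             "height")])))
      }, numeric(1))
      expect_true(all(overlaps < 0.999))
    }
  }
})

test_that("presets encode the intended density and confidence regimes", {
  sparse <- scene_preset("sparse_day")
  dense <- scene_preset("dense_occluded")
  night <- scene_preset("night_low_conf")
  expect_error(scene_preset("foggy"))
  expect_equal(sparse$n_animals, 8L)
  expect_equal(dense$n_animals, 25L)
  expect_lt(night$conf_visible_mean, sparse$conf_visible_mean)
  # presets are pure data: no seed inside
  expect_null(sparse$seed)
  # the dense preset yields more crowding: per animal, the largest
  # overlap with any other animal (mean over animals and frames)
  mean_crowding <- function(cfg, seed) {
    cfg$n_frames <- 20L
    sc <- simulate_scene(cfg, seed = seed)
    g <- sc$gt
    mean(vapply(split(g, g$frame), function(gf) {
      b <- as.matrix(gf[, c("left", "top", "width", "height")])
      s <- 1 - pairwise_cost(b, b, kind = "iou")
      diag(s) <- 0
      mean(apply(s, 1, max))
    }, numeric(1)))
  }
  expect_gt(mean_crowding(dense, 3), mean_crowding(sparse, 3))
  # night preset shifts confidence mass toward the medium tier
  night$n_frames <- 40L
  sn <- simulate_scene(night, seed = 3)
  cfg_day <- scene_preset("sparse_day")
  cfg_day$n_frames <- 40L
  sd_ <- simulate_scene(cfg_day, seed = 3)
  frac_med <- function(s) mean(s$detections$conf < 0.5 &
                                 s$detections$conf >= 0.3)
  expect_gt(frac_med(sn), frac_med(sd_))
})

test_that("behavior labels converge to the chain's stationary distribution", {
  # fast-mixing chain, dwell minimum 1, one animal over 10^4 frames
  P <- matrix(0, 7, 7)
  for (i in 1:7) {
    P[i, ] <- 0.5 / 6
    P[i, i] <- 0.5
  }
  # stationary distribution of this symmetric chain is uniform
  cfg <- scene_config(n_animals = 1L, n_frames = 10000L,
                      behavior_transition = P, dwell_min = 1L,
                      occlusion_rate = 0, false_positive_rate = 0,
                      miss_rate = 0)
  sc <- simulate_scene(cfg, seed = 11)
  freq <- as.numeric(table(factor(sc$gt$class_id, levels = 1:7))) / 1e4
  pi_ <- rep(1 / 7, 7)
  # effective sample size for a chain with self-transition 0.5
  n_eff <- 1e4 * (1 - 0.5) / (1 + 0.5)
  tol <- 3 * sqrt(pi_ * (1 - pi_) / n_eff)
  expect_true(all(abs(freq - pi_) <= tol))
})

test_that("embedding self-similarity is high and cross-identity low", {
  cfg <- clean_scene_config(n_animals = 6L, n_frames = 50L)
  sc <- simulate_scene(cfg, seed = 13)
  det_ids <- sc$gt$id # clean scene: detections mirror gt rows
  same <- sc$embeddings[det_ids == 1, , drop = FALSE]
  other <- sc$embeddings[det_ids == 2, , drop = FALSE]
  self_sim <- mean(same[-1, ] %*% same[1, ])
  cross_sim <- mean(other %*% same[1, ])
  expect_gt(self_sim, 0.8)
  expect_lt(abs(cross_sim), 0.5)
})
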