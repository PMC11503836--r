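det_row <- function(frame, left, top = 50, w = 40, h = 30, conf = 0.9,
                    class_id = 3L) {
  tibble::tibble(frame = frame, left = left, top = top, width = w,
                 height = h, conf = conf, class_id = class_id)
}

test_that("configuration defaults match the tiered-cascade design", {
  cfg <- tracker_config()
  expect_equal(cfg$theta_high, 0.5)
  expect_equal(cfg$theta_med, 0.3)
  expect_equal(cfg$max_lost, 30L)
  expect_equal(cfg$fps, 25)
  expect_equal(cfg$motion, "diou")
  expect_true(cfg$reupdate)
  expect_error(tracker_config(theta_med = 0.6), "theta")
  expect_error(tracker_config(max_lost = 0), "max_lost")
})

test_that("confidence tiers partition detections exhaustively", {
  d <- det_row(1, left = c(0, 100, 200), conf = c(0.9, 0.4, 0.2))
  tiers <- classify_confidence(d, tracker_config())
  expect_equal(tiers$high$conf, 0.9)
  expect_equal(tiers$medium$conf, 0.4)
  expect_equal(tiers$discarded, 1L)
  # boundary: exactly theta_high is high tier
  t2 <- classify_confidence(det_row(1, 0, conf = 0.5), tracker_config())
  expect_equal(nrow(t2$high), 1L)
  t3 <- classify_confidence(det_row(1, 0, conf = numeric(0))[0, ],
                            tracker_config())
  expect_equal(nrow(t3$high) + nrow(t3$medium) + t3$discarded, 0L)
})

test_that("track birth, discard and deletion follow the lifecycle rules", {
  # one high-confidence detection births exactly one activated track
  tr <- track_detections(det_row(1, 0, conf = 0.9))
  expect_equal(nrow(tr), 1L)
  expect_equal(glance(tr)$births, 1L)
  # below theta_med: discarded, no track
  tr2 <- track_detections(det_row(1, 0, conf = 0.2))
  expect_equal(nrow(tr2), 0L)
  expect_equal(glance(tr2)$discarded, 1L)
  # medium confidence never creates or updates a fresh track
  tr3 <- track_detections(det_row(1, 0, conf = 0.4))
  expect_equal(nrow(tr3), 0L)

  # a track unmatched for 31 consecutive frames is deleted
  tk <- new_tracker(tracker_config())
  tracker_step(tk, 1, det_row(1, 0))
  for (f in 2:32) tracker_step(tk, f, det_row(f, 0)[0, ])
  expect_equal(tk$tracks[[1]]$status, "deleted")
  expect_equal(tk$tracks[[1]]$fsu, 31L)
  # at exactly 30 missed frames it is still lost, not deleted
  tk2 <- new_tracker(tracker_config())
  tracker_step(tk2, 1, det_row(1, 0))
  for (f in 2:31) tracker_step(tk2, f, det_row(f, 0)[0, ])
  expect_equal(tk2$tracks[[1]]$status, "lost")
})

test_that("step enforces monotone frames; run rejects unsorted streams", {
  tk <- new_tracker(tracker_config())
  tracker_step(tk, 5, det_row(5, 0))
  expect_error(tracker_step(tk, 5, det_row(5, 0)), "not after")
  expect_error(tracker_step(tk, 3, det_row(3, 0)), "not after")
  unsorted <- dplyr::bind_rows(det_row(2, 0), det_row(1, 0))
  expect_error(track_detections(unsorted), "sorted")
})

test_that("track ids increase with creation order and are never reused", {
  d <- dplyr::bind_rows(
    det_row(1, 0), det_row(1, 300),
    det_row(2, 0), det_row(2, 300), det_row(2, 600)
  )
  tr <- track_detections(d)
  first_seen <- tapply(tr$frame, tr$id, min)
  expect_true(all(diff(as.integer(names(sort(first_seen)))) > 0))
  expect_equal(dplyr::n_distinct(tr$id), 3L)
})

test_that("each detection feeds at most one track per frame", {
  set.seed(4)
  cfg <- clean_scene_config(n_animals = 6L, n_frames = 40L)
  sc <- simulate_scene(cfg, seed = 2)
  tr <- track_detections(sc$detections)
  per_frame <- dplyr::count(tr[!tr$virtual, ], frame, id)
  expect_true(all(per_frame$n == 1))
  real <- tr[!tr$virtual, ]
  expect_true(all(dplyr::count(real, frame)$n <= 6))
})

test_that("runs are deterministic bit for bit", {
  cfg <- curved_occlusion_config(n_animals = 6L, n_frames = 60L)
  sc <- simulate_scene(cfg, seed = 8)
  t1 <- track_detections(sc$detections, embeddings = sc$embeddings)
  t2 <- track_detections(sc$detections, embeddings = sc$embeddings)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(nrow(track_detections(det_row(1, 0)[0, ])), 0L)
})

test_that("perfect detections are tracked without identity errors", {
  sc <- simulate_scene(clean_scene_config(n_animals = 8L, n_frames = 120L),
                       seed = 6)
  tr <- track_detections(sc$detections)
  r <- mot_evaluate(sc$gt, pred_boxes(tr))
  expect_equal(r$IDS, 0L)
  expect_equal(r$MOTA, 100)
})

test_that("re-acquisition after a forced gap re-uses the same identity", {
  # a single target occluded for 8 frames on a straight path
  frames <- c(1:20, 29:40)
  d <- det_row(frames, left = 4 * frames)
  tr <- track_detections(d, tracker_config())
  expect_equal(dplyr::n_distinct(tr$id), 1L)
  # virtual rows fill the gap and are flagged
  virt <- tr[tr$virtual, ]
  expect_equal(virt$frame, 21:28)
  expect_true(all(is.na(virt$conf)))
  # with re-update off there are no virtual rows
  tr2 <- track_detections(d, tracker_config(reupdate = FALSE))
  expect_equal(sum(tr2$virtual), 0L)
  expect_equal(dplyr::n_distinct(tr2$id), 1L)
})

test_that("virtual rows only ever appear inside gaps", {
  cfg <- curved_occlusion_config(n_animals = 6L, n_frames = 80L)
  sc <- simulate_scene(cfg, seed = 12)
  tr <- track_detections(sc$detections)
  for (tid in unique(tr$id)) {
    h <- tr[tr$id == tid, ]
    expect_true(all(diff(h$frame) > 0)) # strictly increasing history
    if (any(h$virtual)) {
      # every virtual run is bracketed by real observations
      expect_false(h$virtual[1])
      expect_false(h$virtual[nrow(h)])
    }
  }
})

test_that("camera transform shifts predictions coherently", {
  # constant camera pan: detections shift 5 px right each frame while the
  # animal is static in the world; CMC cancels the shift
  frames <- 1:30
  d <- det_row(frames, left = 100 + 5 * frames)
  cmc <- function(f) cbind(matrix(c(1, 0, 0, 1), 2), c(5, 0))
  tr <- track_detections(d, tracker_config(), cmc = cmc)
  expect_equal(dplyr::n_distinct(tr$id), 1L)
  # without CMC the same stream still tracks (velocity absorbs the pan)
  tr2 <- track_detections(d, tracker_config())
  expect_equal(dplyr::n_distinct(tr2$id), 1L)
})

test_that("with re-update off and iou motion the baseline pipeline remains", {
  cfg <- clean_scene_config(n_animals = 5L, n_frames = 50L)
  sc <- simulate_scene(cfg, seed = 3)
  base <- tracker_config(reupdate = FALSE, motion = "iou")
  tr <- track_detections(sc$detections, base)
  expect_equal(sum(tr$virtual), 0L)
  r <- mot_evaluate(sc$gt, pred_boxes(tr))
  expect_equal(r$IDS, 0L)
  expect_equal(r$MOTA, 100)
})

test_that("glance and tidy summarise a run", {
  d <- dplyr::arrange(
    dplyr::bind_rows(det_row(1:10, left = 0),
                     det_row(1:10, left = 300, class_id = 5L)),
    .data$frame
  )
  tr <- track_detections(d)
  g <- glance(tr)
  expect_equal(g$n_tracks, 2L)
  expect_equal(g$births, 2L)
  expect_equal(g$n_frames, 10L)
  td <- tidy(tr)
  expect_equal(sort(td$behavior), c("standing", "walking"))
  p <- ggplot2::autoplot(tr)
  expect_s3_class(p, "ggplot")
})
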