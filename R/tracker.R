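# The per-frame tracking pipeline: confidence tiering, Kalman prediction
# with an optional camera-motion hook, two matching rounds (fused DIoU +
# appearance, then motion-only), track lifecycle management, and the
# spline re-update when a lost track is re-acquired.

#' Tracker configuration
#'
#' All thresholds and switches of the tracking pipeline. Defaults follow
#' the confidence-tiered cascade: detections with confidence in
#' \[theta_high, 1\] are high tier, \[theta_med, theta_high) medium tier,
#' and below theta_med discarded; unmatched tracks are deleted once they
#' have been lost for more than `max_lost` frames.
#'
#' @param theta_high High-confidence threshold (default 0.5).
#' @param theta_med Medium-confidence threshold (default 0.3); detections
#'   below it are discarded.
#' @param theta_low Label for the discarded tier (reporting only).
#' @param new_track_threshold Minimum confidence for an unmatched high-tier
#'   detection to start a new track (default 0.6).
#' @param max_lost Frames a track may remain unmatched before deletion
#'   (default 30).
#' @param motion Overlap measure for motion costs: `"diou"` (default),
#'   `"iou"`, `"giou"`, or `"biou"`.
#' @param biou_buffer Buffer factor when `motion = "biou"`.
#' @param reupdate Enable the cubic-spline virtual-observation re-update on
#'   re-acquisition of a lost track (default `TRUE`).
#' @param reupdate_pre_frames Number of pre-loss observations used as spline
#'   support (default 3; plus the re-detection itself).
#' @param reupdate_noise_inflation Measurement-noise multiplier for virtual
#'   observations (default 1).
#' @param spline_boundary Spline boundary kind, `"notaknot"` or `"natural"`.
#' @param use_appearance Use embedding costs in round 1 when available.
#' @param appearance_gate,proximity_gate,motion_gate Gates of [fuse_costs()].
#' @param fusion `"min"` (default) or `"weighted"` cost fusion.
#' @param fusion_lambda Motion weight for weighted fusion.
#' @param round1_threshold Acceptance threshold on the fused round-1 cost
#'   (default 0.8).
#' @param round2_threshold Acceptance threshold on the motion-only round-2
#'   cost (default 0.5).
#' @param round2_pool `"medium_and_unmatched_high"` (default) or
#'   `"unmatched_high"` (literal second-round pool).
#' @param round1_candidates `"activated_and_lost"` (default; lost tracks can
#'   be re-identified in round 1) or `"activated"`.
#' @param ema_alpha Exponential moving-average weight for the track's
#'   appearance feature (default 0.9; frozen while lost).
#' @param duplicate_iou Overlap at or above which an activated and a lost
#'   track are considered duplicates of one target; the younger is dropped
#'   (default 0.85).
#' @param fps Video frame rate in frames per second (default 25).
#' @param std_weight_position,std_weight_velocity Kalman noise weights.
#' @return A validated list of class `tracker_config`.
#' @export
tracker_config <- function(theta_high = 0.5, theta_med = 0.3,
                           theta_low = 0.1, new_track_threshold = 0.6,
                           max_lost = 30L,
                           motion = c("diou", "iou", "giou", "biou"),
                           biou_buffer = 0.3,
                           reupdate = TRUE, reupdate_pre_frames = 3L,
                           reupdate_noise_inflation = 1,
                           spline_boundary = c("notaknot", "natural"),
                           use_appearance = TRUE,
                           appearance_gate = 0.25, proximity_gate = 0.5,
                           motion_gate = 1.0,
                           fusion = c("min", "weighted"), fusion_lambda = 0.98,
                           round1_threshold = 0.8, round2_threshold = 0.5,
                           round2_pool = c("medium_and_unmatched_high",
                                           "unmatched_high"),
                           round1_candidates = c("activated_and_lost",
                                                 "activated"),
                           ema_alpha = 0.9, duplicate_iou = 0.85, fps = 25,
                           std_weight_position = 1 / 20,
                           std_weight_velocity = 1 / 160) {
  cfg <- list(
    theta_high = theta_high, theta_med = theta_med, theta_low = theta_low,
    new_track_threshold = new_track_threshold, max_lost = as.integer(max_lost),
    motion = match.arg(motion), biou_buffer = biou_buffer,
    reupdate = isTRUE(reupdate),
    reupdate_pre_frames = as.integer(reupdate_pre_frames),
    reupdate_noise_inflation = reupdate_noise_inflation,
    spline_boundary = match.arg(spline_boundary),
    use_appearance = isTRUE(use_appearance),
    appearance_gate = appearance_gate, proximity_gate = proximity_gate,
    motion_gate = motion_gate, fusion = match.arg(fusion),
    fusion_lambda = fusion_lambda,
    round1_threshold = round1_threshold, round2_threshold = round2_threshold,
    round2_pool = match.arg(round2_pool),
    round1_candidates = match.arg(round1_candidates),
    ema_alpha = ema_alpha, duplicate_iou = duplicate_iou, fps = fps,
    std_weight_position = std_weight_position,
    std_weight_velocity = std_weight_velocity
  )
  if (!(cfg$theta_low >= 0 && cfg$theta_low <= cfg$theta_med &&
        cfg$theta_med < cfg$theta_high && cfg$theta_high <= 1)) {
    stop("need 0 <= theta_low <= theta_med < theta_high <= 1", call. = FALSE)
  }
  if (cfg$max_lost < 1L) stop("max_lost must be >= 1", call. = FALSE)
  if (cfg$fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (cfg$ema_alpha < 0 || cfg$ema_alpha > 1) {
    stop("ema_alpha must be in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "tracker_config")
}

#' Partition detections into confidence tiers
#'
#' High tier: confidence in \[theta_high, 1\]; medium: \[theta_med,
#' theta_high); below theta_med: discarded. The partition is exhaustive
#' and disjoint.
#'
#' @param detections Tibble with a `conf` column.
#' @param config A [tracker_config()].
#' @return List with elements `high`, `medium` (tibbles) and `discarded`
#'   (count).
#' @export
classify_confidence <- function(detections, config = tracker_config()) {
  detections <- tibble::as_tibble(detections)
  hi <- detections$conf >= config$theta_high
  med <- detections$conf >= config$theta_med & !hi
  list(high = detections[hi, , drop = FALSE],
       medium = detections[med, , drop = FALSE],
       discarded = sum(!hi & !med))
}

#' Create a fresh tracker state
#'
#' @param config A [tracker_config()].
#' @return An environment of class `herd_tracker` holding the track set and
#'   run counters; advance it with [tracker_step()].
#' @export
new_tracker <- function(config = tracker_config()) {
  tr <- new.env(parent = emptyenv())
  tr$config <- config
  tr$model <- kalman_model(std_weight_position = config$std_weight_position,
                           std_weight_velocity = config$std_weight_velocity)
  tr$tracks <- list()
  tr$next_id <- 1L
  tr$last_frame <- 0L
  tr$births <- 0L
  tr$deletions <- 0L
  tr$discarded <- 0L
  class(tr) <- "herd_tracker"
  tr
}

state_box <- function(state) {
  m <- state$mean
  c(m[1] - m[3] / 2, m[2] - m[4] / 2, m[3], m[4])
}

det_measurement <- function(det) {
  c(det$left + det$width / 2, det$top + det$height / 2, det$width, det$height)
}

# history rows are stored as flat numeric vectors for speed:
# (frame, left, top, width, height, conf, class_id, virtual)
push_history <- function(track, frame, box, conf, class_id, virtual) {
  track$history[[length(track$history) + 1L]] <-
    c(frame, box, conf, class_id, as.numeric(virtual))
  track
}

new_track <- function(tracker, frame, det, emb) {
  z <- det_measurement(det)
  st <- kf_initiate(tracker$model, z)
  track <- list(
    id = tracker$next_id, state = st, status = "activated", fsu = 0L,
    last_real_state = st, last_real_frame = frame,
    recent_obs = matrix(c(frame, z), nrow = 1L),
    feature = emb, last_class = det$class_id, history = list()
  )
  track <- push_history(track, frame, state_box(st), det$conf, det$class_id,
                        FALSE)
  tracker$next_id <- tracker$next_id + 1L
  tracker$births <- tracker$births + 1L
  track
}

# Re-acquisition of a track that missed >= 1 frame: synthesise virtual
# observations over the gap (cubic spline when >= 4 support points are
# available, otherwise linear interpolation), replay them through the
# filter from the last real posterior, and only then fold in the real
# re-detection. Virtual frames are recorded in the history with the class
# label of the nearest real observation.
reupdate_track <- function(tracker, track, frame, z, det) {
  cfg <- tracker$config
  gap <- seq(track$last_real_frame + 1L, frame - 1L)
  # spread the pre-loss support over the recent-observation window rather
  # than taking consecutive frames: a cubic through closely spaced noisy
  # knots amplifies detection jitter into large mid-gap swings, while a
  # longer knot baseline keeps the interpolant's derivatives conditioned
  obs <- track$recent_obs
  k <- cfg$reupdate_pre_frames
  pick <- if (nrow(obs) <= k) {
    seq_len(nrow(obs))
  } else {
    unique(round(seq(1L, nrow(obs), length.out = k)))
  }
  pre <- obs[pick, , drop = FALSE]
  support <- rbind(pre, c(frame, z))
  colnames(support) <- c("frame", "cx", "cy", "w", "h")
  support_df <- tibble::as_tibble(as.data.frame(support))
  virtual <- if (nrow(support) >= 4L) {
    sp <- fit_gap_spline(support_df, boundary = cfg$spline_boundary)
    virtual_observations(sp, gap)
  } else {
    # linear fallback between the last pre-loss and the re-detection
    t0 <- support[nrow(support) - 1L, ]
    t1 <- support[nrow(support), ]
    frac <- (gap - t0[1]) / (t1[1] - t0[1])
    tibble::tibble(frame = gap,
                   cx = t0[2] + frac * (t1[2] - t0[2]),
                   cy = t0[3] + frac * (t1[3] - t0[3]),
                   w = t0[4] + frac * (t1[4] - t0[4]),
                   h = t0[5] + frac * (t1[5] - t0[5]))
  }
  # cubic overshoot over a long gap can drive interpolated sizes through
  # zero; box sizes are physical, so floor them at 1 px
  virtual$w <- pmax(virtual$w, 1)
  virtual$h <- pmax(virtual$h, 1)
  st <- replay_gap(tracker$model, track$last_real_state, virtual,
                   noise_scale = cfg$reupdate_noise_inflation)
  # record the virtual frames (flagged; class from the nearest real obs)
  mid <- (track$last_real_frame + frame) / 2
  for (i in seq_len(nrow(virtual))) {
    cls <- if (virtual$frame[i] <= mid) track$last_class else det$class_id
    vbox <- c(virtual$cx[i] - virtual$w[i] / 2,
              virtual$cy[i] - virtual$h[i] / 2, virtual$w[i], virtual$h[i])
    track <- push_history(track, virtual$frame[i], vbox, NA_real_, cls, TRUE)
  }
  new_state <- kf_predict(tracker$model, st)
  # the replayed mean carries the virtual trajectory, but interpolated
  # pseudo-measurements add no real information: keep the coasted
  # (predict-only) covariance so the true re-detection still dominates
  new_state$cov <- track$state$cov
  track$state <- new_state
  track
}

handle_match <- function(tracker, track, frame, det, emb) {
  cfg <- tracker$config
  z <- det_measurement(det)
  if (cfg$reupdate && track$fsu > 0L && frame - track$last_real_frame > 1L) {
    track <- reupdate_track(tracker, track, frame, z, det)
  }
  track$state <- kf_update(tracker$model, track$state, z)
  track$status <- "activated"
  track$fsu <- 0L
  track$last_real_state <- track$state
  track$last_real_frame <- frame
  track$recent_obs <- utils::tail(rbind(track$recent_obs, c(frame, z)), 15L)
  track$last_class <- det$class_id
  if (!is.null(emb)) {
    if (is.null(track$feature)) {
      track$feature <- emb
    } else {
      f <- cfg$ema_alpha * track$feature + (1 - cfg$ema_alpha) * emb
      track$feature <- f / sqrt(sum(f^2))
    }
  }
  push_history(track, frame, state_box(track$state), det$conf, det$class_id,
               FALSE)
}

motion_cost_for <- function(tracker, track_idx, dets) {
  cfg <- tracker$config
  if (length(track_idx) == 0L || nrow(dets) == 0L) {
    return(matrix(numeric(0), nrow = length(track_idx), ncol = nrow(dets)))
  }
  tb <- t(vapply(tracker$tracks[track_idx],
                 function(tk) state_box(tk$state), numeric(4)))
  db <- cbind(dets$left, dets$top, dets$width, dets$height)
  pairwise_cost(tb, db, kind = cfg$motion, buffer_scale = cfg$biou_buffer)
}

#' Advance the tracker by one frame
#'
#' Executes the full per-frame pipeline: (1) confidence tiering; (2) Kalman
#' prediction for all live tracks; (3) optional camera-motion compensation
#' of the predicted means; (4) round 1, high-tier detections against the
#' candidate tracks with fused motion + appearance cost; (5) round 2,
#' remaining detections against remaining tracks with motion-only cost;
#' (6) aging of unmatched tracks; (7) track births from unmatched
#' high-tier detections; (8) deletion of long-lost tracks.
#'
#' @param tracker A [new_tracker()] environment (modified in place).
#' @param frame Frame index, strictly greater than the previous call's.
#' @param detections Tibble of this frame's detections with columns
#'   `left, top, width, height, conf, class_id`.
#' @param embeddings Optional numeric matrix, one row per detection row.
#' @param cmc Optional 2 x 3 affine camera-motion matrix applied to
#'   predicted means.
#' @return Invisibly, a tibble of this frame's activated-track records.
#' @export
tracker_step <- function(tracker, frame, detections, embeddings = NULL,
                         cmc = NULL) {
  cfg <- tracker$config
  if (frame <= tracker$last_frame) {
    stop(sprintf("frame %s is not after previous frame %s",
                 frame, tracker$last_frame), call. = FALSE)
  }
  detections <- tibble::as_tibble(detections)
  if (!is.null(embeddings)) {
    embeddings <- as.matrix(embeddings)
    if (nrow(embeddings) != nrow(detections)) {
      stop(sprintf("frame %s: embedding rows (%d) != detections (%d)",
                   frame, nrow(embeddings), nrow(detections)), call. = FALSE)
    }
  }
  det_idx <- seq_len(nrow(detections))
  tiers <- classify_confidence(detections, cfg)
  tracker$discarded <- tracker$discarded + tiers$discarded
  hi_idx <- det_idx[detections$conf >= cfg$theta_high]
  med_idx <- det_idx[detections$conf >= cfg$theta_med &
                       detections$conf < cfg$theta_high]

  # predict all live tracks; lost tracks coast predict-only
  live <- which(vapply(tracker$tracks, function(tk) tk$status != "deleted",
                       logical(1)))
  for (i in live) {
    st <- kf_predict(tracker$model, tracker$tracks[[i]]$state)
    # boxes are physical: a coasting track whose size velocity drives
    # w or h through zero is floored at 1 px with the shrink stopped
    if (st$mean[3] < 1 || st$mean[4] < 1) {
      st$mean[3:4] <- pmax(st$mean[3:4], 1)
      st$mean[7:8] <- 0
    }
    if (!is.null(cmc)) st <- apply_cmc(st, cmc)
    tracker$tracks[[i]]$state <- st
  }

  statuses <- vapply(tracker$tracks, function(tk) tk$status, character(1))
  r1_tracks <- if (cfg$round1_candidates == "activated_and_lost") {
    which(statuses != "deleted")
  } else {
    which(statuses == "activated")
  }

  matched_tracks <- integer(0)
  matched_dets <- integer(0)

  # round 1: high-tier detections, fused DIoU + appearance cost
  d1 <- detections[hi_idx, , drop = FALSE]
  cm <- motion_cost_for(tracker, r1_tracks, d1)
  ca <- NULL
  if (cfg$use_appearance && !is.null(embeddings) && length(r1_tracks) &&
      nrow(d1)) {
    feats <- t(vapply(tracker$tracks[r1_tracks], function(tk) {
      if (is.null(tk$feature)) rep(NA_real_, ncol(embeddings)) else tk$feature
    }, numeric(ncol(embeddings))))
    ca <- appearance_cost_matrix(feats, embeddings[hi_idx, , drop = FALSE])
  }
  fused <- fuse_costs(cm, ca, appearance_gate = cfg$appearance_gate,
                      proximity_gate = cfg$proximity_gate,
                      motion_gate = cfg$motion_gate, method = cfg$fusion,
                      lambda = cfg$fusion_lambda)
  a1 <- solve_assignment(fused, cfg$round1_threshold)
  for (k in seq_len(nrow(a1$matches))) {
    ti <- r1_tracks[a1$matches$track[k]]
    dj <- hi_idx[a1$matches$det[k]]
    emb <- if (!is.null(embeddings)) embeddings[dj, ] else NULL
    tracker$tracks[[ti]] <- handle_match(tracker, tracker$tracks[[ti]], frame,
                                         detections[dj, ], emb)
    matched_tracks <- c(matched_tracks, ti)
    matched_dets <- c(matched_dets, dj)
  }

  # round 2: leftover detections vs leftover tracks, motion-only cost
  r2_dets <- if (cfg$round2_pool == "medium_and_unmatched_high") {
    c(med_idx, setdiff(hi_idx, matched_dets))
  } else {
    setdiff(hi_idx, matched_dets)
  }
  r2_dets <- sort(r2_dets)
  r2_tracks <- setdiff(which(statuses != "deleted"), matched_tracks)
  d2 <- detections[r2_dets, , drop = FALSE]
  cm2 <- motion_cost_for(tracker, r2_tracks, d2)
  cm2[cm2 > cfg$motion_gate] <- Inf
  a2 <- solve_assignment(cm2, cfg$round2_threshold)
  for (k in seq_len(nrow(a2$matches))) {
    ti <- r2_tracks[a2$matches$track[k]]
    dj <- r2_dets[a2$matches$det[k]]
    emb <- if (!is.null(embeddings)) embeddings[dj, ] else NULL
    tracker$tracks[[ti]] <- handle_match(tracker, tracker$tracks[[ti]], frame,
                                         detections[dj, ], emb)
    matched_tracks <- c(matched_tracks, ti)
    matched_dets <- c(matched_dets, dj)
  }

  # age unmatched tracks; delete the long-lost
  for (i in setdiff(live, matched_tracks)) {
    tk <- tracker$tracks[[i]]
    tk$fsu <- tk$fsu + 1L
    tk$status <- if (tk$fsu > cfg$max_lost) "deleted" else "lost"
    if (tk$status == "deleted") tracker$deletions <- tracker$deletions + 1L
    tracker$tracks[[i]] <- tk
  }

  # births from unmatched high-tier detections
  for (dj in setdiff(hi_idx, matched_dets)) {
    if (detections$conf[dj] >= cfg$new_track_threshold) {
      emb <- if (!is.null(embeddings)) embeddings[dj, ] else NULL
      tracker$tracks[[length(tracker$tracks) + 1L]] <-
        new_track(tracker, frame, detections[dj, ], emb)
    }
  }

  # duplicate suppression (base-algorithm behavior): a lost track whose box
  # nearly coincides with an activated track is the same target twice; the
  # younger of the pair is dropped
  statuses <- vapply(tracker$tracks, function(tk) tk$status, character(1))
  act <- which(statuses == "activated")
  lost <- which(statuses == "lost")
  if (length(act) && length(lost)) {
    ab <- t(vapply(tracker$tracks[act], function(tk) state_box(tk$state),
                   numeric(4)))
    lb <- t(vapply(tracker$tracks[lost], function(tk) state_box(tk$state),
                   numeric(4)))
    ov <- 1 - pairwise_cost(ab, lb, kind = "iou")
    dup <- which(ov >= cfg$duplicate_iou, arr.ind = TRUE)
    for (r in seq_len(nrow(dup))) {
      i <- act[dup[r, 1]]; j <- lost[dup[r, 2]]
      drop <- if (tracker$tracks[[i]]$id < tracker$tracks[[j]]$id) j else i
      if (tracker$tracks[[drop]]$status != "deleted") {
        tracker$tracks[[drop]]$status <- "deleted"
        tracker$deletions <- tracker$deletions + 1L
      }
    }
  }

  tracker$last_frame <- frame
  out <- lapply(tracker$tracks, function(tk) {
    h <- tk$history
    if (length(h) == 0L) return(NULL)
    last <- h[[length(h)]]
    if (last[1] == frame && last[8] == 0) c(tk$id, last) else NULL
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  invisible(history_to_tibble(out))
}

apply_cmc <- function(state, cmc) {
  A <- cmc[, 1:2, drop = FALSE]
  b <- cmc[, 3]
  m <- state$mean
  m[1:2] <- drop(A %*% m[1:2]) + b
  m[5:6] <- drop(A %*% m[5:6])
  T8 <- diag(8)
  T8[1:2, 1:2] <- A
  T8[5:6, 5:6] <- A
  new_kalman_state(m, T8 %*% state$cov %*% t(T8))
}

history_to_tibble <- function(m) {
  if (is.null(m) || nrow(m) == 0L) {
    return(tibble::tibble(frame = integer(0), id = integer(0),
                          left = numeric(0), top = numeric(0),
                          width = numeric(0), height = numeric(0),
                          conf = numeric(0), class_id = integer(0),
                          virtual = logical(0)))
  }
  tibble::tibble(frame = as.integer(m[, 2]), id = as.integer(m[, 1]),
                 left = m[, 3], top = m[, 4], width = m[, 5],
                 height = m[, 6], conf = m[, 7],
                 class_id = as.integer(m[, 8]), virtual = m[, 9] > 0)
}

#' Run the tracker over a full detection stream
#'
#' Folds [tracker_step()] over every frame from the first to the last frame
#' present in `detections` (frames with no detections still age the
#' tracks). Deterministic: identical inputs produce identical output.
#'
#' @param detections Tibble with columns `frame, left, top, width, height,
#'   conf, class_id`, sorted by ascending frame.
#' @param config A [tracker_config()].
#' @param embeddings Optional appearance-embedding matrix, one row per
#'   detection row (same order).
#' @param cmc Optional camera-motion hook: a function of the frame index
#'   returning a 2 x 3 affine matrix, or `NULL` for identity.
#' @return A `herd_tracks` tibble: one row per track per frame with
#'   columns `frame, id, left, top, width, height, conf, class_id,
#'   virtual`. Spline-synthesised gap rows are flagged `virtual = TRUE`.
#'   Run counters are available via [glance()].
#' @export
#' @examples
#' dets <- tibble::tibble(frame = 1:5, left = 10 * (1:5), top = 50,
#'                        width = 40, height = 30, conf = 0.9, class_id = 3L)
#' tracks <- track_detections(dets)
#' glance(tracks)
track_detections <- function(detections, config = tracker_config(),
                             embeddings = NULL, cmc = NULL) {
  detections <- tibble::as_tibble(detections)
  if (nrow(detections) == 0L) {
    out <- history_to_tibble(NULL)
    attr(out, "run_summary") <- list(births = 0L, deletions = 0L,
                                     discarded = 0L, n_frames = 0L)
    attr(out, "config") <- config
    class(out) <- c("herd_tracks", class(out))
    return(out)
  }
  if (is.unsorted(detections$frame)) {
    stop("detections must be sorted by ascending frame", call. = FALSE)
  }
  if (!is.null(embeddings)) {
    embeddings <- as.matrix(embeddings)
    if (nrow(embeddings) != nrow(detections)) {
      stop("embeddings must have one row per detection", call. = FALSE)
    }
  }
  tracker <- new_tracker(config)
  frames <- seq(min(detections$frame), max(detections$frame))
  rows_by_frame <- split(seq_len(nrow(detections)), detections$frame)
  for (f in frames) {
    idx <- rows_by_frame[[as.character(f)]]
    d <- detections[idx, , drop = FALSE]
    e <- if (!is.null(embeddings) && length(idx)) {
      embeddings[idx, , drop = FALSE]
    } else if (!is.null(embeddings)) {
      embeddings[0, , drop = FALSE]
    } else NULL
    m <- if (!is.null(cmc)) cmc(f) else NULL
    tracker_step(tracker, f, d, embeddings = e, cmc = m)
  }
  rows <- lapply(tracker$tracks, function(tk) {
    if (length(tk$history) == 0L) return(NULL)
    cbind(tk$id, do.call(rbind, tk$history))
  })
  m <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- history_to_tibble(m)
  out <- dplyr::arrange(out, .data$frame, .data$id)
  attr(out, "run_summary") <- list(
    births = tracker$births, deletions = tracker$deletions,
    discarded = tracker$discarded, n_frames = length(frames)
  )
  attr(out, "config") <- config
  class(out) <- c("herd_tracks", class(out))
  out
}

#' @export
tidy.herd_tracks <- function(x, ...) {
  labels <- behavior_classes()
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$id),
    first_frame = min(.data$frame),
    last_frame = max(.data$frame),
    n_real = sum(!.data$virtual),
    n_virtual = sum(.data$virtual),
    modal_class = {
      tab <- table(.data$class_id[!.data$virtual])
      as.integer(names(tab)[which.max(tab)])
    },
    .groups = "drop"
  ) |>
    dplyr::mutate(behavior = unname(labels[as.character(.data$modal_class)]))
}

#' @export
glance.herd_tracks <- function(x, ...) {
  s <- attr(x, "run_summary")
  tibble::tibble(
    n_tracks = dplyr::n_distinct(x$id), births = s$births,
    deletions = s$deletions, discarded = s$discarded, n_frames = s$n_frames
  )
}

#' Plot track trajectories
#'
#' Box-center paths over the image plane (y axis reversed to match image
#' coordinates), one colour per identity; virtual gap-fill points are drawn
#' hollow.
#'
#' @param object A `herd_tracks` table from [track_detections()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.herd_tracks <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      cx = .data$left + .data$width / 2,
                      cy = .data$top + .data$height / 2)
  ggplot2::ggplot(df, ggplot2::aes(.data$cx, .data$cy,
                                   colour = factor(.data$id),
                                   group = .data$id)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$virtual),
                        shape = 1, size = 1.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "track") +
    ggplot2::theme_minimal()
}
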