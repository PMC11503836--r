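# Seeded synthetic barn-scene generator. Emulates the factors that drive
# tracking difficulty in barn surveillance footage: herd density, scheduled
# and geometry-induced occlusion, detector jitter, confidence degradation
# under partial occlusion, clutter false positives and missed detections,
# with behavior labels drawn from a seven-class Markov chain.

default_behavior_transition <- function(self = c(0.97, 0.93, 0.96, 0.985,
                                                 0.94, 0.90, 0.90),
                                        attract = c(0.18, 0.04, 0.35, 0.25,
                                                    0.14, 0.02, 0.02)) {
  P <- matrix(0, 7, 7)
  for (i in 1:7) {
    w <- attract
    w[i] <- 0
    P[i, ] <- (1 - self[i]) * w / sum(w)
    P[i, i] <- self[i]
  }
  P
}

#' Synthetic barn-scene configuration
#'
#' All knobs of the scene generator. Defaults describe a mid-density
#' daytime pen filmed at 25 fps in a 1280 x 720 px frame: animals move
#' with smooth random accelerations capped at `speed_cap` px/frame when in
#' a locomotor behavior state and stand still otherwise; behaviors follow
#' a Markov chain over the seven-class ethogram with a minimum dwell time;
#' detections are ground-truth boxes with Gaussian jitter, confidence tied
#' to visibility, clutter false positives and random misses.
#'
#' @param n_animals Number of animals.
#' @param n_frames Number of frames.
#' @param fps Frame rate, frames per second (default 25).
#' @param arena_width,arena_height Arena size in pixels.
#' @param box_width_range,box_height_range Per-animal box size ranges (px).
#' @param accel_sd Std of per-frame random acceleration (px/frame^2).
#' @param speed_cap Maximum speed (px/frame).
#' @param behavior_transition 7 x 7 Markov transition matrix (rows sum
#'   to 1).
#' @param dwell_min Minimum frames spent in a behavior before a switch.
#' @param occlusion_rate Per-animal, per-frame probability of starting a
#'   scheduled occlusion event.
#' @param occlusion_duration Inclusive range (frames) of event durations.
#' @param overlap_dropout Fraction of a box covered by animals in front
#'   above which its detection is dropped.
#' @param overlap_partial Coverage above which the detection survives but
#'   with degraded (medium-tier) confidence.
#' @param jitter_center_sd,jitter_size_sd Detection noise stds (px).
#' @param conf_visible_mean,conf_visible_sd Confidence model for fully
#'   visible detections.
#' @param conf_partial_mean,conf_partial_sd Confidence model under partial
#'   occlusion.
#' @param conf_fp_mean,conf_fp_sd Confidence model for clutter false
#'   positives (mass mostly below the medium-tier threshold).
#' @param false_positive_rate Expected clutter boxes per frame (Poisson).
#' @param miss_rate Per-detection random miss probability.
#' @param embedding_dim Appearance embedding dimension.
#' @param embedding_noise Isotropic embedding noise (cosine self-similarity
#'   about 0.9 at the default).
#' @param seed Scene seed (may also be given to [simulate_scene()]).
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(n_animals = 10L, n_frames = 500L, fps = 25,
                         arena_width = 1280, arena_height = 720,
                         box_width_range = c(70, 120),
                         box_height_range = c(50, 90),
                         accel_sd = 0.4, speed_cap = 4,
                         behavior_transition = default_behavior_transition(),
                         dwell_min = 25L,
                         occlusion_rate = 0.002,
                         occlusion_duration = c(5L, 15L),
                         overlap_dropout = 0.65, overlap_partial = 0.35,
                         jitter_center_sd = 1, jitter_size_sd = 0.8,
                         conf_visible_mean = 0.85, conf_visible_sd = 0.06,
                         conf_partial_mean = 0.4, conf_partial_sd = 0.05,
                         conf_fp_mean = 0.2, conf_fp_sd = 0.08,
                         false_positive_rate = 0.1, miss_rate = 0.02,
                         embedding_dim = 16L, embedding_noise = 0.12,
                         seed = NULL) {
  cfg <- as.list(environment())
  P <- cfg$behavior_transition
  if (!is.matrix(P) || !all(dim(P) == c(7, 7)) ||
      any(abs(rowSums(P) - 1) > 1e-9) || any(P < 0)) {
    stop("behavior_transition must be a 7 x 7 stochastic matrix (rows sum to 1)",
         call. = FALSE)
  }
  rates <- c(occlusion_rate, miss_rate)
  probs_ok <- all(rates >= 0 & rates <= 1)
  bad <- character(0)
  if (n_animals < 1) bad <- c(bad, "n_animals")
  if (n_frames < 1) bad <- c(bad, "n_frames")
  if (fps <= 0) bad <- c(bad, "fps")
  if (!probs_ok) bad <- c(bad, "occlusion_rate/miss_rate")
  if (false_positive_rate < 0) bad <- c(bad, "false_positive_rate")
  if (any(occlusion_duration < 1) ||
      occlusion_duration[1] > occlusion_duration[2]) {
    bad <- c(bad, "occlusion_duration")
  }
  if (dwell_min < 1) bad <- c(bad, "dwell_min")
  if (length(bad)) {
    stop("invalid scene config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "scene_config")
}

#' Scene presets for the main barn-surveillance regimes
#'
#' Pure-data configurations (no seed inside): `sparse_day` is a light
#' herd with rare occlusion; `dense_occluded` packs 25 animals with
#' frequent long occlusion events and heavy pairwise overlap;
#' `night_low_conf` shifts the detector confidence mass toward the medium
#' tier, as under low light.
#'
#' @param name One of `"sparse_day"`, `"dense_occluded"`,
#'   `"night_low_conf"`.
#' @return A [scene_config()].
#' @export
scene_preset <- function(name = c("sparse_day", "dense_occluded",
                                  "night_low_conf")) {
  name <- match.arg(name)
  switch(name,
    sparse_day = scene_config(n_animals = 8L, occlusion_rate = 0.001,
                              false_positive_rate = 0.05),
    dense_occluded = scene_config(n_animals = 25L, arena_width = 960,
                                  arena_height = 600, accel_sd = 0.6,
                                  occlusion_rate = 0.01,
                                  occlusion_duration = c(5L, 15L),
                                  false_positive_rate = 0.3,
                                  miss_rate = 0.05),
    night_low_conf = scene_config(n_animals = 10L,
                                  conf_visible_mean = 0.55,
                                  conf_visible_sd = 0.1,
                                  occlusion_rate = 0.004,
                                  false_positive_rate = 0.2)
  )
}

# Behaviors 5 (walking), 6 (climbing) and 7 (fighting) move; the rest are
# stationary postures.
moving_classes <- c(5L, 6L, 7L)

#' Simulate a synthetic barn scene
#'
#' Deterministic given the seed. Ground-truth trajectories are continuous
#' (per-frame displacement bounded by the speed cap), behavior labels
#' follow the configured Markov chain with its dwell minimum, and the
#' detection set is the ground truth corrupted by jitter, occlusion
#' dropout, random misses and clutter false positives.
#'
#' @param config A [scene_config()] or [scene_preset()].
#' @param seed Integer seed; overrides `config$seed`.
#' @return A `synthetic_scene` list: `gt` and `detections` tibbles (MOT
#'   column layout), `embeddings` matrix aligned with the detection rows,
#'   `events` log tibble, and the `config` used.
#' @export
simulate_scene <- function(config = scene_config(), seed = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("a seed is required (config$seed or seed argument)",
                          call. = FALSE)
  config$seed <- as.integer(seed)
  withr::with_seed(config$seed, simulate_scene_impl(config))
}

simulate_scene_impl <- function(cfg) {
  n <- cfg$n_animals
  nf <- cfg$n_frames
  W <- cfg$arena_width; H <- cfg$arena_height
  bw <- runif(n, cfg$box_width_range[1], cfg$box_width_range[2])
  bh <- runif(n, cfg$box_height_range[1], cfg$box_height_range[2])
  # keep centers inside margins so boxes rarely need clipping
  x <- runif(n, bw / 2, W - bw / 2)
  y <- runif(n, bh / 2, H - bh / 2)
  vx <- numeric(n); vy <- numeric(n)
  beh <- sample.int(7L, n, replace = TRUE,
                    prob = c(0.18, 0.04, 0.35, 0.25, 0.14, 0.02, 0.02))
  dwell <- rep(0L, n)
  occ_until <- rep(0L, n)
  dirs <- matrix(rnorm(n * cfg$embedding_dim), n)
  dirs <- dirs / sqrt(rowSums(dirs^2))

  gt_rows <- vector("list", nf)
  det_rows <- vector("list", nf)
  emb_rows <- vector("list", nf)
  ev_rows <- list()

  for (f in seq_len(nf)) {
    # behavior chain with dwell minimum
    for (i in seq_len(n)) {
      dwell[i] <- dwell[i] + 1L
      if (dwell[i] >= cfg$dwell_min) {
        nxt <- sample.int(7L, 1L, prob = cfg$behavior_transition[beh[i], ])
        if (nxt != beh[i]) {
          beh[i] <- nxt
          dwell[i] <- 0L
          if (nxt %in% moving_classes) {
            ang <- runif(1, 0, 2 * pi)
            sp <- runif(1, 0.5, cfg$speed_cap)
            vx[i] <- sp * cos(ang); vy[i] <- sp * sin(ang)
          }
        }
      }
    }
    moving <- beh %in% moving_classes
    vx[moving] <- vx[moving] + rnorm(sum(moving), 0, cfg$accel_sd)
    vy[moving] <- vy[moving] + rnorm(sum(moving), 0, cfg$accel_sd)
    vx[!moving] <- 0; vy[!moving] <- 0
    sp <- sqrt(vx^2 + vy^2)
    over <- sp > cfg$speed_cap
    vx[over] <- vx[over] * cfg$speed_cap / sp[over]
    vy[over] <- vy[over] * cfg$speed_cap / sp[over]
    x <- x + vx; y <- y + vy
    # reflect at the walls
    lo_x <- x < bw / 2; hi_x <- x > W - bw / 2
    x[lo_x] <- bw[lo_x] - x[lo_x]; x[hi_x] <- 2 * (W - bw[hi_x] / 2) - x[hi_x]
    vx[lo_x | hi_x] <- -vx[lo_x | hi_x]
    lo_y <- y < bh / 2; hi_y <- y > H - bh / 2
    y[lo_y] <- bh[lo_y] - y[lo_y]; y[hi_y] <- 2 * (H - bh[hi_y] / 2) - y[hi_y]
    vy[lo_y | hi_y] <- -vy[lo_y | hi_y]
    x <- pmin(pmax(x, bw / 2), W - bw / 2)
    y <- pmin(pmax(y, bh / 2), H - bh / 2)

    left <- x - bw / 2; top <- y - bh / 2
    gt_rows[[f]] <- cbind(f, seq_len(n), left, top, bw, bh, beh)

    # scheduled occlusion events
    start <- runif(n) < cfg$occlusion_rate & occ_until < f
    if (any(start)) {
      dur <- sample(seq(cfg$occlusion_duration[1], cfg$occlusion_duration[2]),
                    sum(start), replace = TRUE)
      occ_until[start] <- f + dur - 1L
      ev_rows[[length(ev_rows) + 1L]] <-
        tibble::tibble(type = "occlusion", id = which(start),
                       frame_start = f, frame_end = f + dur - 1L)
    }
    occluded <- occ_until >= f

    # geometry-induced occlusion: coverage by any animal in front
    # (depth order fixed by identity: lower id is nearer the camera)
    cover <- numeric(n)
    if (n > 1L) {
      boxes <- cbind(left, top, bw, bh)
      for (i in 2:n) {
        front <- boxes[seq_len(i - 1L), , drop = FALSE]
        iw <- pmax(0, pmin(front[, 1] + front[, 3], left[i] + bw[i]) -
                     pmax(front[, 1], left[i]))
        ih <- pmax(0, pmin(front[, 2] + front[, 4], top[i] + bh[i]) -
                     pmax(front[, 2], top[i]))
        cover[i] <- max(iw * ih) / (bw[i] * bh[i])
      }
    }
    dropped <- occluded | cover >= cfg$overlap_dropout
    partial <- !dropped & cover >= cfg$overlap_partial
    missed <- runif(n) < cfg$miss_rate
    detected <- !dropped & !missed

    if (any(detected)) {
      di <- which(detected)
      dl <- left[di] + rnorm(length(di), 0, cfg$jitter_center_sd)
      dt_ <- top[di] + rnorm(length(di), 0, cfg$jitter_center_sd)
      dw <- pmax(4, bw[di] + rnorm(length(di), 0, cfg$jitter_size_sd))
      dh <- pmax(4, bh[di] + rnorm(length(di), 0, cfg$jitter_size_sd))
      conf <- ifelse(partial[di],
                     rnorm(length(di), cfg$conf_partial_mean,
                           cfg$conf_partial_sd),
                     rnorm(length(di), cfg$conf_visible_mean,
                           cfg$conf_visible_sd))
      conf <- pmin(pmax(conf, 0.01), 1)
      det_rows[[f]] <- cbind(f, -1, dl, dt_, dw, dh, conf, beh[di])
      noise <- matrix(rnorm(length(di) * cfg$embedding_dim,
                            0, cfg$embedding_noise), length(di))
      e <- dirs[di, , drop = FALSE] + noise
      emb_rows[[f]] <- e / sqrt(rowSums(e^2))
    }

    n_fp <- rpois(1, cfg$false_positive_rate)
    if (n_fp > 0) {
      fw <- runif(n_fp, cfg$box_width_range[1], cfg$box_width_range[2])
      fh <- runif(n_fp, cfg$box_height_range[1], cfg$box_height_range[2])
      fl <- runif(n_fp, 0, W - fw)
      ft <- runif(n_fp, 0, H - fh)
      fconf <- pmin(pmax(rnorm(n_fp, cfg$conf_fp_mean, cfg$conf_fp_sd),
                         0.01), 1)
      fcls <- sample.int(7L, n_fp, replace = TRUE)
      det_rows[[f]] <- rbind(det_rows[[f]],
                             cbind(f, -1, fl, ft, fw, fh, fconf, fcls))
      e <- matrix(rnorm(n_fp * cfg$embedding_dim), n_fp)
      emb_rows[[f]] <- rbind(emb_rows[[f]], e / sqrt(rowSums(e^2)))
      ev_rows[[length(ev_rows) + 1L]] <-
        tibble::tibble(type = "false_positive", id = NA_integer_,
                       frame_start = f, frame_end = f)
    }
  }

  gm <- do.call(rbind, gt_rows)
  gt <- tibble::tibble(frame = as.integer(gm[, 1]), id = as.integer(gm[, 2]),
                       left = gm[, 3], top = gm[, 4], width = gm[, 5],
                       height = gm[, 6], conf = 1,
                       class_id = as.integer(gm[, 7]), visibility = 1)
  dm <- do.call(rbind, det_rows)
  if (is.null(dm)) dm <- matrix(numeric(0), 0, 8)
  detections <- tibble::tibble(frame = as.integer(dm[, 1]),
                               id = as.integer(dm[, 2]),
                               left = dm[, 3], top = dm[, 4],
                               width = dm[, 5], height = dm[, 6],
                               conf = dm[, 7], class_id = as.integer(dm[, 8]),
                               visibility = -1)
  emb <- do.call(rbind, emb_rows)
  events <- if (length(ev_rows)) dplyr::bind_rows(ev_rows) else {
    tibble::tibble(type = character(0), id = integer(0),
                   frame_start = integer(0), frame_end = integer(0))
  }
  structure(list(gt = gt, detections = detections, embeddings = emb,
                 events = events, config = cfg),
            class = "synthetic_scene")
}

#' Write a synthetic scene as a MOTChallenge-style sequence directory
#'
#' Creates `gt/gt.txt`, `det/det.txt`, `det/embeddings.txt`, `events.csv`
#' and `config.yaml` under `dir`. Byte-identical for identical scenes.
#'
#' @param scene A `synthetic_scene` from [simulate_scene()].
#' @param dir Output sequence directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(file.path(dir, "gt"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "det"), recursive = TRUE, showWarnings = FALSE)
  write_mot(scene$gt, file.path(dir, "gt", "gt.txt"))
  write_mot(scene$detections, file.path(dir, "det", "det.txt"))
  if (!is.null(scene$embeddings)) {
    write_embeddings(scene$embeddings, file.path(dir, "det", "embeddings.txt"))
  }
  ev <- scene$events
  ev_lines <- c("type,id,frame_start,frame_end",
                sprintf("%s,%s,%d,%d", ev$type,
                        ifelse(is.na(ev$id), "", ev$id),
                        ev$frame_start, ev$frame_end))
  con <- file(file.path(dir, "events.csv"), open = "wb")
  writeLines(ev_lines, con)
  close(con)
  cfg <- scene$config
  cfg$behavior_transition <- as.numeric(cfg$behavior_transition)
  write_run_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
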