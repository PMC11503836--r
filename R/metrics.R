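# Sequence-level tracking evaluation: CLEAR metrics (MOTA, MOTP, FP, FN,
# IDS, MT/ML), identity metrics (IDF1) and HOTA. Ground truth and
# predictions are tibbles with columns frame, id, left, top, width, height
# (class_id optional). Evaluation is class-agnostic by default.

check_mot_set <- function(x, arg) {
  x <- tibble::as_tibble(x)
  req <- c("frame", "id", "left", "top", "width", "height")
  if (!all(req %in% names(x))) {
    stop(sprintf("`%s` needs columns %s", arg, paste(req, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(x[, c("frame", "id")])) {
    stop(sprintf("`%s` has more than one box for an identity in a frame",
                 arg), call. = FALSE)
  }
  x
}

frame_iou_matrix <- function(g, p, class_aware = FALSE) {
  if (nrow(g) == 0L || nrow(p) == 0L) {
    return(matrix(numeric(0), nrow(g), nrow(p)))
  }
  sim <- 1 - pairwise_cost(g[, c("left", "top", "width", "height")],
                           p[, c("left", "top", "width", "height")],
                           kind = "iou")
  if (class_aware && "class_id" %in% names(g) && "class_id" %in% names(p)) {
    sim[outer(g$class_id, p$class_id, "!=")] <- 0
  }
  sim
}

#' Frame-by-frame correspondence between ground truth and predictions
#'
#' CLEAR-protocol matching: per frame, a previous (gt, pred) pairing is
#' kept whenever both are present and still overlap at or above the
#' threshold; the remainder is matched by a minimum-cost (1 - IoU)
#' assignment restricted to pairs with IoU >= threshold.
#'
#' @param gt,pred Tibbles with columns `frame, id, left, top, width,
#'   height`.
#' @param iou_threshold Minimum IoU for a valid correspondence (default
#'   0.5).
#' @param class_aware Restrict matches to equal `class_id` (default FALSE).
#' @return Tibble of matches: `frame, gt_id, pred_id, iou`.
#' @export
match_frames <- function(gt, pred, iou_threshold = 0.5,
                         class_aware = FALSE) {
  gt <- check_mot_set(gt, "gt")
  pred <- check_mot_set(pred, "pred")
  frames <- sort(unique(c(gt$frame, pred$frame)))
  gt_split <- split(gt, gt$frame)
  pred_split <- split(pred, pred$frame)
  prev <- list() # persisting map gt_id -> pred_id
  acc <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- as.character(frames[fi])
    g <- gt_split[[f]]
    p <- pred_split[[f]]
    if (is.null(g)) g <- gt[0, ]
    if (is.null(p)) p <- pred[0, ]
    sim <- frame_iou_matrix(g, p, class_aware)
    keep_g <- integer(0); keep_p <- integer(0)
    for (gi in seq_len(nrow(g))) {
      pid <- prev[[as.character(g$id[gi])]]
      if (!is.null(pid)) {
        pj <- match(pid, p$id)
        if (!is.na(pj) && !(pj %in% keep_p) && sim[gi, pj] >= iou_threshold) {
          keep_g <- c(keep_g, gi); keep_p <- c(keep_p, pj)
        }
      }
    }
    rem_g <- setdiff(seq_len(nrow(g)), keep_g)
    rem_p <- setdiff(seq_len(nrow(p)), keep_p)
    if (length(rem_g) && length(rem_p)) {
      cost <- 1 - sim[rem_g, rem_p, drop = FALSE]
      cost[cost > 1 - iou_threshold] <- Inf
      a <- solve_assignment(cost, accept_threshold = 1 - iou_threshold)
      keep_g <- c(keep_g, rem_g[a$matches$track])
      keep_p <- c(keep_p, rem_p[a$matches$det])
    }
    if (length(keep_g)) {
      acc[[fi]] <- tibble::tibble(frame = frames[fi], gt_id = g$id[keep_g],
                                  pred_id = p$id[keep_p],
                                  iou = sim[cbind(keep_g, keep_p)])
      for (k in seq_along(keep_g)) {
        prev[[as.character(g$id[keep_g[k]])]] <- p$id[keep_p[k]]
      }
    }
  }
  out <- dplyr::bind_rows(acc)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(frame = integer(0), gt_id = integer(0),
                          pred_id = integer(0), iou = numeric(0))
  }
  out
}

clear_counts <- function(gt, pred, iou_threshold = 0.5,
                         class_aware = FALSE) {
  m <- match_frames(gt, pred, iou_threshold, class_aware)
  total_gt <- nrow(gt)
  total_pred <- nrow(pred)
  n_match <- nrow(m)
  # identity switches: a gt identity's matched prediction id differs from
  # its most recent previous match
  ids <- 0L
  if (n_match > 0L) {
    m <- dplyr::arrange(m, .data$gt_id, .data$frame)
    ids <- sum(unlist(lapply(split(m$pred_id, m$gt_id), function(p) {
      if (length(p) < 2L) 0L else sum(p[-1] != p[-length(p)])
    })))
  }
  # mostly tracked / mostly lost over each identity's alive span
  per_id <- dplyr::summarise(dplyr::group_by(gt, .data$id),
                             alive = dplyr::n(), .groups = "drop")
  tracked <- table(m$gt_id)
  ratio <- as.numeric(tracked[as.character(per_id$id)])
  ratio[is.na(ratio)] <- 0
  ratio <- ratio / per_id$alive
  list(total_gt = total_gt, total_pred = total_pred, n_match = n_match,
       fp = total_pred - n_match, fn = total_gt - n_match, ids = ids,
       sum_iou = sum(m$iou), mt = sum(ratio >= 0.8), ml = sum(ratio < 0.2),
       n_ids = nrow(per_id), matches = m)
}

#' CLEAR tracking metrics
#'
#' MOTA aggregates misses, false positives and identity switches against
#' the ground-truth count: `MOTA = 1 - (FN + FP + IDS) / GT`, as a
#' percentage. MOTP is the mean IoU of the matched pairs (as a
#' percentage). MTR/MLR are the fractions of ground-truth identities
#' matched in at least 80% / under 20% of their alive frames.
#'
#' @inheritParams match_frames
#' @return One-row tibble: `MOTA, MOTP, FP, FN, IDS, MTR, MLR, GT`.
#' @export
clear_metrics <- function(gt, pred, iou_threshold = 0.5,
                          class_aware = FALSE) {
  gt <- check_mot_set(gt, "gt")
  pred <- check_mot_set(pred, "pred")
  cc <- clear_counts(gt, pred, iou_threshold, class_aware)
  if (cc$total_gt == 0L) {
    stop("MOTA undefined: ground truth contains no boxes", call. = FALSE)
  }
  tibble::tibble(
    MOTA = 100 * (1 - (cc$fn + cc$fp + cc$ids) / cc$total_gt),
    MOTP = if (cc$n_match > 0) 100 * cc$sum_iou / cc$n_match else NA_real_,
    FP = cc$fp, FN = cc$fn, IDS = cc$ids,
    MTR = 100 * cc$mt / cc$n_ids, MLR = 100 * cc$ml / cc$n_ids,
    GT = cc$total_gt
  )
}

idf1_counts <- function(gt, pred, iou_threshold = 0.5,
                        class_aware = FALSE) {
  gt_ids <- sort(unique(gt$id))
  pred_ids <- sort(unique(pred$id))
  pair <- matrix(0, length(gt_ids), length(pred_ids),
                 dimnames = list(gt_ids, pred_ids))
  frames <- sort(unique(c(gt$frame, pred$frame)))
  gt_split <- split(gt, gt$frame)
  pred_split <- split(pred, pred$frame)
  for (f in as.character(frames)) {
    g <- gt_split[[f]]; p <- pred_split[[f]]
    if (is.null(g) || is.null(p)) next
    sim <- frame_iou_matrix(g, p, class_aware)
    hit <- which(sim >= iou_threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      gi <- match(g$id[hit[, 1]], gt_ids)
      pj <- match(p$id[hit[, 2]], pred_ids)
      for (k in seq_along(gi)) pair[gi[k], pj[k]] <- pair[gi[k], pj[k]] + 1
    }
  }
  idtp <- 0
  if (length(gt_ids) && length(pred_ids)) {
    n <- max(dim(pair))
    cost <- matrix(0, n, n)
    cost[seq_len(nrow(pair)), seq_len(ncol(pair))] <- -pair
    a <- solve_assignment(cost, accept_threshold = Inf)
    sel <- a$matches[a$matches$track <= nrow(pair) &
                       a$matches$det <= ncol(pair), ]
    idtp <- sum(pair[cbind(sel$track, sel$det)])
  }
  list(idtp = idtp, idfp = nrow(pred) - idtp, idfn = nrow(gt) - idtp)
}

#' Identity F1 score
#'
#' Pairs ground-truth and predicted identities globally (each gt identity
#' with at most one predicted identity) so as to maximise the number of
#' overlap-matched detections, then scores
#' `IDF1 = 2 IDTP / (2 IDTP + IDFP + IDFN)` as a percentage.
#'
#' @inheritParams match_frames
#' @return One-row tibble: `IDF1, IDTP, IDFP, IDFN`.
#' @export
idf1_metrics <- function(gt, pred, iou_threshold = 0.5,
                         class_aware = FALSE) {
  gt <- check_mot_set(gt, "gt")
  pred <- check_mot_set(pred, "pred")
  ic <- idf1_counts(gt, pred, iou_threshold, class_aware)
  denom <- 2 * ic$idtp + ic$idfp + ic$idfn
  tibble::tibble(IDF1 = if (denom > 0) 100 * 2 * ic$idtp / denom else 0,
                 IDTP = ic$idtp, IDFP = ic$idfp, IDFN = ic$idfn)
}

# HOTA accumulators per localisation threshold alpha. Follows the published
# two-pass scheme: a soft potential-match count defines a global alignment
# score; each frame is then matched once by maximising alignment x
# similarity; per alpha, matches with similarity >= alpha are the TPs and
# the association accuracy averages TPA / (TPA + FNA + FPA) over them.
hota_accumulate <- function(gt, pred, class_aware = FALSE) {
  alphas <- seq(0.05, 0.95, by = 0.05)
  gt_ids <- sort(unique(gt$id))
  pred_ids <- sort(unique(pred$id))
  ng <- length(gt_ids); np <- length(pred_ids)
  gt_count <- as.numeric(table(factor(gt$id, levels = gt_ids)))
  pred_count <- as.numeric(table(factor(pred$id, levels = pred_ids)))
  frames <- sort(unique(c(gt$frame, pred$frame)))
  gt_split <- split(gt, gt$frame)
  pred_split <- split(pred, pred$frame)

  pot <- matrix(0, ng, np)
  sims <- vector("list", length(frames))
  gidx <- vector("list", length(frames))
  pidx <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- as.character(frames[fi])
    g <- gt_split[[f]]; p <- pred_split[[f]]
    gi <- if (is.null(g)) integer(0) else match(g$id, gt_ids)
    pj <- if (is.null(p)) integer(0) else match(p$id, pred_ids)
    gidx[[fi]] <- gi; pidx[[fi]] <- pj
    if (length(gi) == 0L || length(pj) == 0L) next
    sim <- frame_iou_matrix(g, p, class_aware)
    sims[[fi]] <- sim
    denom <- outer(rowSums(sim), colSums(sim), "+") - sim
    soft <- ifelse(denom > .Machine$double.eps, sim / denom, 0)
    pot[gi, pj] <- pot[gi, pj] + soft
  }
  galign <- pot / (outer(gt_count, pred_count, "+") - pot)

  tp <- numeric(length(alphas))
  ass_cnt <- lapply(alphas, function(a) matrix(0, ng, np))
  eps <- .Machine$double.eps
  for (fi in seq_along(frames)) {
    sim <- sims[[fi]]
    if (is.null(sim)) next
    gi <- gidx[[fi]]; pj <- pidx[[fi]]
    score <- galign[gi, pj, drop = FALSE] * sim
    n <- max(dim(score))
    cost <- matrix(0, n, n)
    cost[seq_along(gi), seq_along(pj)] <- -score
    a <- solve_assignment(cost, accept_threshold = Inf)
    sel <- a$matches[a$matches$track <= length(gi) &
                       a$matches$det <= length(pj), ]
    if (nrow(sel) == 0L) next
    s <- sim[cbind(sel$track, sel$det)]
    for (ai in seq_along(alphas)) {
      ok <- s >= alphas[ai] - eps
      if (any(ok)) {
        tp[ai] <- tp[ai] + sum(ok)
        rows <- gi[sel$track[ok]]; cols <- pj[sel$det[ok]]
        for (k in seq_along(rows)) {
          ass_cnt[[ai]][rows[k], cols[k]] <- ass_cnt[[ai]][rows[k], cols[k]] + 1
        }
      }
    }
  }
  total_gt <- nrow(gt); total_pred <- nrow(pred)
  ass_sum <- vapply(seq_along(alphas), function(ai) {
    m <- ass_cnt[[ai]]
    denom <- outer(gt_count, pred_count, "+") - m
    sum(m * ifelse(denom > 0, m / denom, 0))
  }, numeric(1))
  tibble::tibble(alpha = alphas, tp = tp, fn = total_gt - tp,
                 fp = total_pred - tp, ass_sum = ass_sum)
}

hota_from_acc <- function(acc) {
  by_alpha <- dplyr::summarise(dplyr::group_by(acc, .data$alpha),
                               tp = sum(.data$tp), fn = sum(.data$fn),
                               fp = sum(.data$fp),
                               ass_sum = sum(.data$ass_sum),
                               .groups = "drop")
  det_a <- with(by_alpha, ifelse(tp + fn + fp > 0, tp / (tp + fn + fp), 0))
  ass_a <- with(by_alpha, ifelse(tp > 0, ass_sum / tp, 0))
  tibble::tibble(HOTA = 100 * mean(sqrt(det_a * ass_a)),
                 DetA = 100 * mean(det_a), AssA = 100 * mean(ass_a))
}

#' Higher-order tracking accuracy
#'
#' HOTA is the geometric mean of detection accuracy and association
#' accuracy, averaged over localisation thresholds alpha in 0.05, 0.10,
#' ..., 0.95, as a percentage.
#'
#' @inheritParams match_frames
#' @return One-row tibble: `HOTA, DetA, AssA`.
#' @export
hota_metrics <- function(gt, pred, class_aware = FALSE) {
  gt <- check_mot_set(gt, "gt")
  pred <- check_mot_set(pred, "pred")
  hota_from_acc(hota_accumulate(gt, pred, class_aware))
}

mot_accumulate <- function(gt, pred, iou_threshold = 0.5,
                           class_aware = FALSE) {
  gt <- check_mot_set(gt, "gt")
  pred <- check_mot_set(pred, "pred")
  cc <- clear_counts(gt, pred, iou_threshold, class_aware)
  ic <- idf1_counts(gt, pred, iou_threshold, class_aware)
  list(clear = cc[setdiff(names(cc), "matches")], idf1 = ic,
       hota = hota_accumulate(gt, pred, class_aware))
}

format_report_row <- function(acc) {
  cc <- acc$clear; ic <- acc$idf1
  if (cc$total_gt == 0L) {
    stop("MOTA undefined: ground truth contains no boxes", call. = FALSE)
  }
  denom <- 2 * ic$idtp + ic$idfp + ic$idfn
  dplyr::bind_cols(
    hota_from_acc(acc$hota),
    tibble::tibble(
      MOTA = 100 * (1 - (cc$fn + cc$fp + cc$ids) / cc$total_gt),
      MOTP = if (cc$n_match > 0) 100 * cc$sum_iou / cc$n_match else NA_real_,
      IDF1 = if (denom > 0) 100 * 2 * ic$idtp / denom else 0,
      MTR = 100 * cc$mt / cc$n_ids, MLR = 100 * cc$ml / cc$n_ids,
      IDS = cc$ids, FP = cc$fp, FN = cc$fn, GT = cc$total_gt
    )
  )
}

pool_accumulators <- function(accs) {
  cc_names <- names(accs[[1]]$clear)
  cc <- lapply(setNames(cc_names, cc_names), function(nm) {
    sum(vapply(accs, function(a) a$clear[[nm]], numeric(1)))
  })
  ic_names <- c("idtp", "idfp", "idfn")
  ic <- lapply(setNames(ic_names, ic_names), function(nm) {
    sum(vapply(accs, function(a) a$idf1[[nm]], numeric(1)))
  })
  list(clear = cc, idf1 = ic,
       hota = dplyr::bind_rows(lapply(accs, function(a) a$hota)))
}

#' Evaluate tracker output against ground truth
#'
#' Computes the full metric report (HOTA, DetA, AssA, MOTA, MOTP, IDF1,
#' MTR, MLR, IDS, FP, FN) for one sequence given as tibbles.
#'
#' @inheritParams match_frames
#' @return One-row tibble of metrics, ratios as percentages.
#' @export
#' @examples
#' gt <- tibble::tibble(frame = 1:5, id = 1L, left = 0, top = 0,
#'                      width = 10, height = 10)
#' mot_evaluate(gt, dplyr::mutate(gt, id = 7L)) # perfect up to relabeling
mot_evaluate <- function(gt, pred, iou_threshold = 0.5,
                         class_aware = FALSE) {
  format_report_row(mot_accumulate(gt, pred, iou_threshold, class_aware))
}

#' Evaluate a set of sequences from MOTChallenge files
#'
#' Reads paired ground-truth and prediction files, evaluates each sequence
#' and appends a pooled `Overall` row in which counts are summed and ratio
#' metrics recomputed from the pooled counts (HOTA pooled over all
#' sequences' TPs).
#'
#' @param gt_paths,pred_paths Character vectors of paired file paths.
#' @param names Sequence names (defaults to gt file directory or base
#'   names).
#' @inheritParams match_frames
#' @return Tibble with a `Seq` column, one row per sequence plus
#'   `Overall`.
#' @export
evaluate_sequences <- function(gt_paths, pred_paths, names = NULL,
                               iou_threshold = 0.5, class_aware = FALSE) {
  if (length(gt_paths) != length(pred_paths)) {
    stop("gt and prediction path lists differ in length", call. = FALSE)
  }
  for (p in c(gt_paths, pred_paths)) {
    if (!file.exists(p)) stop("missing sequence file: ", p, call. = FALSE)
  }
  if (is.null(names)) {
    names <- basename(dirname(dirname(gt_paths)))
    bad <- names %in% c("", ".")
    names[bad] <- basename(gt_paths)[bad]
    if (anyDuplicated(names)) names <- make.unique(names)
  }
  accs <- purrr::map2(gt_paths, pred_paths, function(g, p) {
    mot_accumulate(read_mot(g, role = "ground_truth"),
                   read_mot(p, role = "tracks"),
                   iou_threshold, class_aware)
  })
  rows <- dplyr::bind_rows(purrr::map(accs, format_report_row))
  pooled <- format_report_row(pool_accumulators(accs))
  dplyr::bind_cols(tibble::tibble(Seq = c(names, "Overall")),
                   dplyr::bind_rows(rows, pooled))
}

#' Write a metric report as CSV and aligned text
#'
#' @param report Tibble from [evaluate_sequences()] or [mot_evaluate()].
#' @param csv_path,txt_path Output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, txt_path = NULL) {
  cols <- intersect(c("Seq", "HOTA", "MOTA", "MOTP", "IDF1", "MTR", "MLR",
                      "IDS", "DetA", "AssA", "FP", "FN", "GT"),
                    names(report))
  out <- report[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, 1))
  if (!is.null(csv_path)) {
    utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(txt_path)) {
    txt <- utils::capture.output(print(as.data.frame(out), row.names = FALSE))
    writeLines(txt, txt_path)
  }
  invisible(report)
}
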