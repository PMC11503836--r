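# Post-tracking behavior analytics: per-individual time budgets over the
# seven-class ethogram and herd-level behavior incidence per time bin.
# Class labels are majority-vote smoothed before any duration is counted,
# so single-frame classifier flicker does not fragment the budgets.

#' Majority-vote smoothing of a per-frame class sequence
#'
#' Each frame's label becomes the majority class in a centered window
#' (truncated at the sequence ends). Ties keep the previously emitted
#' label; `window = 1` is the identity.
#'
#' @param classes Integer vector of class ids in frame order.
#' @param window Odd window width >= 1 (default 9 frames).
#' @return Integer vector of smoothed class ids, same length.
#' @export
smooth_labels <- function(classes, window = 9L) {
  if (length(window) != 1L || is.na(window) || window < 1L ||
      window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  }
  n <- length(classes)
  if (n == 0L || window == 1L) return(classes)
  half <- (window - 1L) %/% 2L
  out <- classes
  prev <- classes[1]
  for (t in seq_len(n)) {
    lo <- max(1L, t - half)
    hi <- min(n, t + half)
    tab <- table(classes[lo:hi])
    best <- as.integer(names(tab)[tab == max(tab)])
    out[t] <- if (length(best) == 1L) {
      best
    } else if (prev %in% best) {
      prev
    } else {
      best[1]
    }
    prev <- out[t]
  }
  out
}

budget_prep <- function(tracks, include_virtual, smooth_window) {
  df <- tibble::as_tibble(tracks)
  if (!all(c("frame", "id", "class_id") %in% names(df))) {
    stop("tracks need columns frame, id, class_id", call. = FALSE)
  }
  if (!include_virtual && "virtual" %in% names(df)) {
    df <- df[!df$virtual, , drop = FALSE]
  }
  df <- dplyr::arrange(df, .data$id, .data$frame)
  dplyr::mutate(dplyr::group_by(df, .data$id),
                class_smooth = smooth_labels(.data$class_id, smooth_window)) |>
    dplyr::ungroup()
}

#' Per-individual behavior time budgets
#'
#' For each tracked identity, the seconds spent in each behavior class
#' (smoothed frame counts divided by the frame rate). Frames missing
#' inside the track's span - lost-track gaps - are reported as `gap`
#' seconds, not attributed to any behavior. Spline-synthesised virtual
#' frames are excluded by default.
#'
#' @param tracks A `herd_tracks` table (or any tibble with `frame, id,
#'   class_id` and optionally `virtual`).
#' @param fps Frame rate (default 25).
#' @param smooth_window Label-smoothing window (default 9; see
#'   [smooth_labels()]).
#' @param include_virtual Count virtual gap-fill frames toward budgets.
#' @return Tibble: one row per identity with one column per behavior
#'   (seconds), plus `gap`, `total` (span seconds) and `first_frame`,
#'   `last_frame`.
#' @export
time_budget <- function(tracks, fps = 25, smooth_window = 9L,
                        include_virtual = FALSE) {
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  labels <- behavior_classes()
  df <- budget_prep(tracks, include_virtual, smooth_window)
  if (nrow(df) == 0L) {
    out <- tibble::tibble(id = integer(0))
    for (l in labels) out[[l]] <- numeric(0)
    out$gap <- numeric(0); out$total <- numeric(0)
    out$first_frame <- integer(0); out$last_frame <- integer(0)
    return(out)
  }
  spans <- dplyr::summarise(
    dplyr::group_by(df, .data$id),
    n_obs = dplyr::n(),
    first_frame = min(.data$frame),
    last_frame = max(.data$frame),
    .groups = "drop"
  )
  counts <- dplyr::count(df, .data$id, .data$class_smooth)
  wide <- tidyr::pivot_wider(counts, names_from = "class_smooth",
                             values_from = "n", values_fill = 0L)
  for (k in as.character(1:7)) if (!k %in% names(wide)) wide[[k]] <- 0L
  out <- dplyr::left_join(spans, wide, by = "id")
  for (k in 1:7) out[[labels[k]]] <- out[[as.character(k)]] / fps
  out$gap <- (out$last_frame - out$first_frame + 1 - out$n_obs) / fps
  out$total <- (out$last_frame - out$first_frame + 1) / fps
  out[, c("id", unname(labels), "gap", "total", "first_frame", "last_frame")]
}

#' Herd-level behavior summary per time bin
#'
#' Bins the sequence into `bin_seconds` windows; within each bin every
#' present individual is assigned its modal smoothed behavior, and the
#' summary reports the count and percentage of individuals per behavior
#' (percentages sum to 100 over present individuals). A frame-weighted
#' incidence percentage (`pct_frames`, over all present frames in the
#' bin) is included alongside.
#'
#' @inheritParams time_budget
#' @param bin_seconds Bin width in seconds (default 60).
#' @return Tibble: `bin, t_start, class_id, behavior, n_individuals,
#'   pct_individuals, pct_frames`.
#' @export
herd_summary <- function(tracks, bin_seconds = 60, fps = 25,
                         smooth_window = 9L, include_virtual = FALSE) {
  if (bin_seconds <= 0) stop("bin_seconds must be > 0", call. = FALSE)
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  labels <- behavior_classes()
  df <- budget_prep(tracks, include_virtual, smooth_window)
  df$bin <- (df$frame - 1L) %/% as.integer(round(bin_seconds * fps)) + 1L
  modal <- dplyr::summarise(
    dplyr::group_by(df, .data$bin, .data$id),
    class_id = {
      tab <- table(.data$class_smooth)
      as.integer(names(tab)[which.max(tab)])
    },
    .groups = "drop_last"
  )
  per_bin <- dplyr::summarise(
    dplyr::group_by(modal, .data$bin, .data$class_id),
    n_individuals = dplyr::n(), .groups = "drop_last"
  ) |>
    dplyr::mutate(pct_individuals = 100 * .data$n_individuals /
                    sum(.data$n_individuals)) |>
    dplyr::ungroup()
  frame_w <- dplyr::summarise(
    dplyr::group_by(df, .data$bin, class_id = .data$class_smooth),
    nf = dplyr::n(), .groups = "drop_last"
  ) |>
    dplyr::mutate(pct_frames = 100 * .data$nf / sum(.data$nf)) |>
    dplyr::ungroup()
  out <- dplyr::left_join(per_bin,
                          frame_w[, c("bin", "class_id", "pct_frames")],
                          by = c("bin", "class_id"))
  out$behavior <- unname(labels[as.character(out$class_id)])
  out$t_start <- (out$bin - 1L) * bin_seconds
  out[, c("bin", "t_start", "class_id", "behavior", "n_individuals",
          "pct_individuals", "pct_frames")]
}

#' Plot per-individual time budgets
#'
#' Stacked horizontal bars of seconds per behavior for each identity.
#'
#' @param budget Output of [time_budget()].
#' @return A ggplot object.
#' @export
plot_time_budget <- function(budget) {
  labels <- unname(behavior_classes())
  long <- tidyr::pivot_longer(budget, dplyr::all_of(labels),
                              names_to = "behavior", values_to = "seconds")
  long <- long[long$seconds > 0, ]
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$id), y = .data$seconds,
                                     fill = .data$behavior)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "track", y = "seconds", fill = "behavior") +
    ggplot2::theme_minimal()
}

#' Plot herd behavior incidence over time
#'
#' @param summary Output of [herd_summary()].
#' @param what `"individuals"` (percentage of individuals per behavior)
#'   or `"frames"` (frame-weighted incidence).
#' @return A ggplot object.
#' @export
plot_herd_summary <- function(summary, what = c("individuals", "frames")) {
  what <- match.arg(what)
  y <- if (what == "individuals") "pct_individuals" else "pct_frames"
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$t_start,
                                        y = .data[[y]],
                                        fill = .data$behavior)) +
    ggplot2::geom_col(width = diff(range(summary$t_start))[1] /
                        max(1, dplyr::n_distinct(summary$bin)) * 0.9) +
    ggplot2::labs(x = "time (s)", y = "% of herd", fill = "behavior") +
    ggplot2::theme_minimal()
}
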