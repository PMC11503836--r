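# Axis-aligned boxes in MOTChallenge convention: top-left origin, y grows
# downward, stored as (left, top, width, height) floats. Every conversion
# and overlap measure in the package goes through this file so a single
# coordinate convention holds everywhere.

# Accepts a length-4 numeric, an n x 4 matrix, or a data frame with
# left/top/width/height columns; returns an n x 4 matrix. Zero or negative
# sizes are rejected here rather than propagated as NaN downstream.
as_box_matrix <- function(x, arg = "box") {
  if (is.data.frame(x)) {
    req <- c("left", "top", "width", "height")
    if (!all(req %in% names(x))) {
      stop(sprintf("`%s` must have columns left, top, width, height", arg),
           call. = FALSE)
    }
    x <- cbind(x$left, x$top, x$width, x$height)
  } else if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 4L) {
      stop(sprintf("`%s` must be a length-4 numeric (left, top, width, height)",
                   arg), call. = FALSE)
    }
    x <- matrix(x, nrow = 1L)
  } else if (is.matrix(x)) {
    if (ncol(x) != 4L) stop(sprintf("`%s` must have 4 columns", arg),
                            call. = FALSE)
    storage.mode(x) <- "double"
  } else {
    stop(sprintf("`%s` is not a valid box representation", arg), call. = FALSE)
  }
  if (nrow(x) > 0L && (anyNA(x) || any(x[, 3] <= 0) || any(x[, 4] <= 0))) {
    stop(sprintf("invalid box in `%s`: width and height must be > 0", arg),
         call. = FALSE)
  }
  colnames(x) <- c("left", "top", "width", "height")
  x
}

#' Convert boxes between top-left and center form
#'
#' `box_center()` maps (left, top, width, height) to the center form
#' (cx, cy, w, h) used as the Kalman measurement; `box_from_center()` is the
#' exact inverse.
#'
#' @param box,center A length-4 numeric, an n x 4 matrix, or a data frame
#'   with the respective columns.
#' @return A tibble with columns `cx, cy, w, h` (resp. `left, top, width,
#'   height`), one row per box.
#' @export
#' @examples
#' box_center(c(0, 0, 10, 10)) # cx = 5, cy = 5
box_center <- function(box) {
  b <- as_box_matrix(box)
  tibble::tibble(
    cx = unname(b[, 1] + b[, 3] / 2),
    cy = unname(b[, 2] + b[, 4] / 2),
    w = unname(b[, 3]),
    h = unname(b[, 4])
  )
}

#' @rdname box_center
#' @export
box_from_center <- function(center) {
  if (is.data.frame(center)) {
    req <- c("cx", "cy", "w", "h")
    if (!all(req %in% names(center))) {
      stop("`center` must have columns cx, cy, w, h", call. = FALSE)
    }
    m <- cbind(center$cx, center$cy, center$w, center$h)
  } else if (is.numeric(center) && is.null(dim(center))) {
    if (length(center) != 4L) stop("`center` must be length 4", call. = FALSE)
    m <- matrix(center, nrow = 1L)
  } else {
    m <- as.matrix(center)
  }
  if (nrow(m) > 0L && (anyNA(m) || any(m[, 3] <= 0) || any(m[, 4] <= 0))) {
    stop("invalid center-form box: w and h must be > 0", call. = FALSE)
  }
  tibble::tibble(
    left = unname(m[, 1] - m[, 3] / 2),
    top = unname(m[, 2] - m[, 4] / 2),
    width = unname(m[, 3]),
    height = unname(m[, 4])
  )
}

# Elementwise similarity cores on box matrices (rows recycled to a common
# length). Each returns a numeric vector.
box_pair_core <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  if (nrow(a) != nrow(b)) {
    stop("box arguments must have equal length (or length 1)", call. = FALSE)
  }
  list(a = a, b = b)
}

iou_core <- function(a, b) {
  r1 <- a[, 1] + a[, 3]; b1 <- a[, 2] + a[, 4]
  r2 <- b[, 1] + b[, 3]; b2 <- b[, 2] + b[, 4]
  iw <- pmax(0, pmin(r1, r2) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(b1, b2) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  union <- a[, 3] * a[, 4] + b[, 3] * b[, 4] - inter
  unname(inter / union)
}

#' Box overlap and distance-penalised overlap measures
#'
#' Pairwise (elementwise) similarity between boxes. `box_iou()` is
#' intersection-over-union in \[0, 1\]. `box_diou()` subtracts the squared
#' center distance normalised by the squared diagonal of the smallest
#' enclosing rectangle, giving a similarity in (-1, 1\] that still
#' discriminates between non-overlapping candidates by center proximity.
#' `box_giou()` subtracts the fraction of the enclosing rectangle not covered
#' by the union. `box_biou()` is the IoU of the two boxes after each is
#' buffered (expanded) by `buffer_scale` times its own width and height.
#'
#' @param a,b Boxes (length-4 numeric, n x 4 matrix, or data frame with
#'   left/top/width/height). Recycled to a common length.
#' @param buffer_scale Non-negative expansion factor for `box_biou()`;
#'   0 reduces to plain IoU. Default 0.3.
#' @return Numeric vector of similarities.
#' @export
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 10, 10)) # 1/3
#' box_diou(c(0, 0, 10, 10), c(10, 0, 10, 10)) # -0.2
box_iou <- function(a, b) {
  p <- box_pair_core(as_box_matrix(a, "a"), as_box_matrix(b, "b"))
  iou_core(p$a, p$b)
}

#' @rdname box_iou
#' @export
box_diou <- function(a, b) {
  p <- box_pair_core(as_box_matrix(a, "a"), as_box_matrix(b, "b"))
  a <- p$a; b <- p$b
  iou <- iou_core(a, b)
  cxa <- a[, 1] + a[, 3] / 2; cya <- a[, 2] + a[, 4] / 2
  cxb <- b[, 1] + b[, 3] / 2; cyb <- b[, 2] + b[, 4] / 2
  rho2 <- (cxa - cxb)^2 + (cya - cyb)^2
  ew <- pmax(a[, 1] + a[, 3], b[, 1] + b[, 3]) - pmin(a[, 1], b[, 1])
  eh <- pmax(a[, 2] + a[, 4], b[, 2] + b[, 4]) - pmin(a[, 2], b[, 2])
  c2 <- ew^2 + eh^2
  unname(iou - rho2 / c2)
}

#' @rdname box_iou
#' @export
box_giou <- function(a, b) {
  p <- box_pair_core(as_box_matrix(a, "a"), as_box_matrix(b, "b"))
  a <- p$a; b <- p$b
  iou <- iou_core(a, b)
  ew <- pmax(a[, 1] + a[, 3], b[, 1] + b[, 3]) - pmin(a[, 1], b[, 1])
  eh <- pmax(a[, 2] + a[, 4], b[, 2] + b[, 4]) - pmin(a[, 2], b[, 2])
  enc <- ew * eh
  r1 <- a[, 1] + a[, 3]; bb1 <- a[, 2] + a[, 4]
  r2 <- b[, 1] + b[, 3]; bb2 <- b[, 2] + b[, 4]
  iw <- pmax(0, pmin(r1, r2) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(bb1, bb2) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  union <- a[, 3] * a[, 4] + b[, 3] * b[, 4] - inter
  unname(iou - (enc - union) / enc)
}

#' @rdname box_iou
#' @export
box_biou <- function(a, b, buffer_scale = 0.3) {
  if (!is.numeric(buffer_scale) || length(buffer_scale) != 1L ||
      is.na(buffer_scale) || buffer_scale < 0) {
    stop("`buffer_scale` must be a single non-negative number", call. = FALSE)
  }
  buffer_box <- function(m) {
    cbind(m[, 1] - buffer_scale * m[, 3] / 2,
          m[, 2] - buffer_scale * m[, 4] / 2,
          m[, 3] * (1 + buffer_scale),
          m[, 4] * (1 + buffer_scale))
  }
  p <- box_pair_core(as_box_matrix(a, "a"), as_box_matrix(b, "b"))
  iou_core(buffer_box(p$a), buffer_box(p$b))
}

#' Pairwise association cost matrix between track and detection boxes
#'
#' Builds the motion cost matrix used by the matching rounds: entry (i, j)
#' is `1 - similarity(track_i, det_j)` under the chosen overlap measure.
#'
#' @param track_boxes,det_boxes Box collections (n x 4 matrix or data frame
#'   with left/top/width/height). Either may be empty.
#' @param kind One of `"diou"` (default), `"iou"`, `"giou"`, `"biou"`.
#' @param buffer_scale Buffer factor for `kind = "biou"`.
#' @return A numeric matrix of shape (#tracks, #detections).
#' @export
pairwise_cost <- function(track_boxes, det_boxes,
                          kind = c("diou", "iou", "giou", "biou"),
                          buffer_scale = 0.3) {
  kind <- match.arg(kind)
  tb <- as_box_matrix(track_boxes, "track_boxes")
  db <- as_box_matrix(det_boxes, "det_boxes")
  n <- nrow(tb); m <- nrow(db)
  if (n == 0L || m == 0L) return(matrix(numeric(0), nrow = n, ncol = m))
  ai <- rep(seq_len(n), times = m)
  bj <- rep(seq_len(m), each = n)
  sim <- switch(kind,
    iou = box_iou(tb[ai, , drop = FALSE], db[bj, , drop = FALSE]),
    diou = box_diou(tb[ai, , drop = FALSE], db[bj, , drop = FALSE]),
    giou = box_giou(tb[ai, , drop = FALSE], db[bj, , drop = FALSE]),
    biou = box_biou(tb[ai, , drop = FALSE], db[bj, , drop = FALSE],
                    buffer_scale = buffer_scale)
  )
  matrix(1 - sim, nrow = n, ncol = m)
}
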