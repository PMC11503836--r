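# Virtual-trajectory re-update. When a lost track is re-acquired after an
# occlusion gap, the observations bracketing the gap are interpolated with
# one cubic spline per measurement coordinate (cx, cy, w, h); the spline is
# evaluated at the missed frames to synthesise virtual observations, and
# those are replayed through the Kalman filter so the state at re-match no
# longer carries the error accumulated while coasting.

# Cubic spline coefficients via the second-derivative (moment) formulation.
# Boundary kinds: "notaknot" (third derivative continuous across the first
# and last interior knot; reproduces cubic polynomials exactly) and
# "natural" (zero second derivative at the ends).
spline_moments <- function(t, y, boundary) {
  n <- length(t)
  h <- diff(t)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  if (boundary == "natural") {
    A[1, 1] <- 1
    A[n, n] <- 1
  } else { # not-a-knot: M continuous in third derivative at t[2], t[n-1]
    A[1, 1] <- h[2]
    A[1, 2] <- -(h[1] + h[2])
    A[1, 3] <- h[1]
    A[n, n - 2] <- h[n - 1]
    A[n, n - 1] <- -(h[n - 2] + h[n - 1])
    A[n, n] <- h[n - 2]
  }
  solve(A, rhs)
}

spline_coefs_1d <- function(t, y, boundary) {
  M <- spline_moments(t, y, boundary)
  n <- length(t)
  h <- diff(t)
  i <- seq_len(n - 1)
  cbind(
    a = y[i],
    b = (y[i + 1] - y[i]) / h - h * (2 * M[i] + M[i + 1]) / 6,
    c = M[i] / 2,
    d = (M[i + 1] - M[i]) / (6 * h)
  )
}

#' Bundle the observations that bracket an occlusion gap
#'
#' @param pre Data frame of observations before the loss: columns `frame`
#'   plus measurement coordinates (typically `cx, cy, w, h`).
#' @param post Data frame of observations after re-detection, same columns.
#' @return A `gap_support` object: the row-bound support table, checked for
#'   strictly increasing frames with all `post` frames after all `pre`
#'   frames.
#' @export
gap_support <- function(pre, post) {
  pre <- tibble::as_tibble(pre)
  post <- tibble::as_tibble(post)
  if (!("frame" %in% names(pre)) || !("frame" %in% names(post))) {
    stop("support tables need a `frame` column", call. = FALSE)
  }
  if (nrow(pre) == 0L || nrow(post) == 0L) {
    stop("need at least one observation on each side of the gap",
         call. = FALSE)
  }
  if (max(pre$frame) >= min(post$frame)) {
    stop("post-redetection frames must all follow pre-loss frames",
         call. = FALSE)
  }
  support <- dplyr::bind_rows(pre, post)
  if (any(diff(support$frame) <= 0)) {
    stop("support frames must be strictly increasing", call. = FALSE)
  }
  gstart <- max(pre$frame) + 1L
  gend <- min(post$frame) - 1L
  structure(list(support = support,
                 gap = if (gend >= gstart) seq(gstart, gend) else integer(0)),
            class = "gap_support")
}

#' Fit per-coordinate cubic splines over gap support observations
#'
#' One independent interpolating cubic spline is fitted per measurement
#' coordinate, passing exactly through every support point with continuous
#' first and second derivatives at interior knots.
#'
#' @param support A [gap_support()] object, or a data frame with a `frame`
#'   column and one or more numeric value columns.
#' @param boundary `"notaknot"` (default; reproduces polynomials up to
#'   degree 3) or `"natural"` (zero end curvature).
#' @return A `trajectory_spline`: knot frames and an (intervals x 4 x
#'   coordinates) coefficient array for the local polynomials
#'   `a + b u + c u^2 + d u^3`, `u = t - t_i`.
#' @export
fit_gap_spline <- function(support, boundary = c("notaknot", "natural")) {
  boundary <- match.arg(boundary)
  if (inherits(support, "gap_support")) support <- support$support
  support <- tibble::as_tibble(support)
  if (!("frame" %in% names(support))) {
    stop("`support` needs a `frame` column", call. = FALSE)
  }
  t <- as.numeric(support$frame)
  if (anyDuplicated(t)) stop("duplicate support frames", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("support frames must be strictly increasing", call. = FALSE)
  }
  if (length(t) < 4L) {
    stop("insufficient support: cubic spline needs at least 4 points",
         call. = FALSE)
  }
  coords <- setdiff(names(support), "frame")
  if (length(coords) == 0L) stop("no value columns in support", call. = FALSE)
  coef <- array(NA_real_, dim = c(length(t) - 1L, 4L, length(coords)),
                dimnames = list(NULL, c("a", "b", "c", "d"), coords))
  for (k in seq_along(coords)) {
    coef[, , k] <- spline_coefs_1d(t, support[[coords[k]]], boundary)
  }
  structure(list(knots = t, coef = coef, coords = coords,
                 boundary = boundary),
            class = "trajectory_spline")
}

#' Evaluate a trajectory spline at missed frames
#'
#' Synthesises one virtual observation per requested frame by evaluating
#' the fitted spline. Requests outside the knot span are refused
#' (interpolation only, never extrapolation).
#'
#' @param spline A `trajectory_spline` from [fit_gap_spline()].
#' @param frames Frame indices inside the knot span (may be empty).
#' @return A tibble with column `frame` plus one column per coordinate, in
#'   frame order.
#' @export
virtual_observations <- function(spline, frames) {
  stopifnot(inherits(spline, "trajectory_spline"))
  frames <- as.numeric(frames)
  if (length(frames) == 0L) {
    out <- c(list(frame = numeric(0)),
             setNames(rep(list(numeric(0)), length(spline$coords)),
                      spline$coords))
    return(tibble::as_tibble(out))
  }
  kn <- spline$knots
  if (any(frames < kn[1]) || any(frames > kn[length(kn)])) {
    stop("frames outside the spline's knot span (extrapolation refused)",
         call. = FALSE)
  }
  frames <- sort(frames)
  iv <- findInterval(frames, kn, rightmost.closed = TRUE)
  iv <- pmin(pmax(iv, 1L), length(kn) - 1L)
  u <- frames - kn[iv]
  vals <- lapply(seq_along(spline$coords), function(k) {
    cf <- spline$coef[, , k, drop = FALSE]
    cf[iv, 1, 1] + cf[iv, 2, 1] * u + cf[iv, 3, 1] * u^2 + cf[iv, 4, 1] * u^3
  })
  tibble::as_tibble(c(list(frame = frames), setNames(vals, spline$coords)))
}

#' Replay virtual observations through the Kalman filter
#'
#' Starting from the posterior state at the last real update before a gap,
#' runs one predict/update cycle per virtual observation, in frame order.
#' An empty sequence returns the input state unchanged.
#'
#' @param model A [kalman_model()].
#' @param state_at_loss Posterior `kalman_state` at the last real update.
#' @param virtual Tibble of virtual observations with columns
#'   `cx, cy, w, h` (from [virtual_observations()]), in frame order.
#' @param noise_scale Inflation factor for the virtual measurement noise
#'   relative to real observations (default 1).
#' @return The posterior `kalman_state` after the last virtual frame.
#' @export
replay_gap <- function(model, state_at_loss, virtual, noise_scale = 1) {
  state <- state_at_loss
  if (is.null(virtual) || nrow(virtual) == 0L) return(state)
  for (i in seq_len(nrow(virtual))) {
    z <- c(virtual$cx[i], virtual$cy[i], virtual$w[i], virtual$h[i])
    state <- kf_predict(model, state)
    state <- kf_update(model, state, z, noise_scale = noise_scale)
  }
  state
}
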