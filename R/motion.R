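# Constant-velocity Kalman filter over box center and size. State is the
# 8-vector (cx, cy, w, h, vcx, vcy, vw, vh) in pixels and pixels/frame;
# the measurement is z = (cx, cy, w, h). Process and measurement noise
# standard deviations scale with the current box size (SORT-family
# convention), so large animals tolerate proportionally larger jitter.

#' Constant-velocity Kalman model for box tracking
#'
#' Builds the linear-Gaussian model used by the tracker: an 8-dimensional
#' constant-velocity transition over (cx, cy, w, h) plus velocities, and an
#' observation matrix selecting the first four components. Noise standard
#' deviations are proportional to the current box width/height with the
#' given weights. Explicit `Q` and `R` matrices may be supplied instead
#' (used for reduced-dimension filters in validation).
#'
#' @param dt Frame interval (state units are per frame; default 1).
#' @param std_weight_position Position noise std as a fraction of box size.
#' @param std_weight_velocity Velocity noise std as a fraction of box size.
#' @param F,H,Q,R Optional explicit transition, observation, process-noise
#'   and measurement-noise matrices overriding the box convention.
#' @return An object of class `kalman_model`.
#' @export
kalman_model <- function(dt = 1, std_weight_position = 1 / 20,
                         std_weight_velocity = 1 / 160,
                         F = NULL, H = NULL, Q = NULL, R = NULL) {
  if (is.null(F)) {
    F <- diag(8)
    F[cbind(1:4, 5:8)] <- dt
  }
  if (is.null(H)) {
    if (nrow(F) != 8L) {
      stop("`H` must be supplied for a non-standard state dimension",
           call. = FALSE)
    }
    H <- cbind(diag(4), matrix(0, 4, 4))
  }
  structure(
    list(F = F, H = H, Q = Q, R = R,
         swp = std_weight_position, swv = std_weight_velocity),
    class = "kalman_model"
  )
}

new_kalman_state <- function(mean, cov) {
  structure(list(mean = as.numeric(mean), cov = cov), class = "kalman_state")
}

# Size-scaled noise; w, h taken from the current state mean.
process_noise <- function(model, mean) {
  if (!is.null(model$Q)) return(model$Q)
  w <- mean[3]; h <- mean[4]
  std <- c(model$swp * c(w, h, w, h), model$swv * c(w, h, w, h))
  diag(std^2)
}

measurement_noise <- function(model, mean, scale = 1) {
  if (!is.null(model$R)) return(model$R * scale)
  w <- mean[3]; h <- mean[4]
  std <- model$swp * c(w, h, w, h)
  diag(std^2) * scale
}

#' Kalman filter primitives: initiate, predict, update
#'
#' `kf_initiate()` starts a state at a measurement with zero velocity and a
#' covariance scaled by the measured box size. `kf_predict()` propagates
#' mean and covariance one frame (`mean <- F mean`,
#' `P <- F P F' + Q`). `kf_update()` corrects with a measurement via the
#' Kalman gain `K = P H' (H P H' + R)^-1`, using the standard symmetric
#' covariance update `P <- (I - K H) P`.
#'
#' @param model A [kalman_model()].
#' @param state A `kalman_state` as returned by these functions.
#' @param z Measurement vector (cx, cy, w, h) with positive w, h (or the
#'   model's observation dimension when explicit matrices are used).
#' @param R Optional explicit measurement-noise matrix for this update.
#' @param noise_scale Multiplier on the default measurement noise (used to
#'   inflate the noise of virtual observations).
#' @return A `kalman_state` with elements `mean` and `cov`.
#' @export
kf_initiate <- function(model, z) {
  z <- as.numeric(z)
  if (length(z) != 4L || anyNA(z) || z[3] <= 0 || z[4] <= 0) {
    stop("invalid measurement: need (cx, cy, w, h) with w, h > 0",
         call. = FALSE)
  }
  mean <- c(z, rep(0, 4))
  w <- z[3]; h <- z[4]
  std <- c(2 * model$swp * c(w, h, w, h), 10 * model$swv * c(w, h, w, h))
  new_kalman_state(mean, diag(std^2))
}

#' @rdname kf_initiate
#' @export
kf_predict <- function(model, state) {
  F <- model$F
  Q <- process_noise(model, state$mean)
  mean <- drop(F %*% state$mean)
  cov <- F %*% state$cov %*% t(F) + Q
  new_kalman_state(mean, (cov + t(cov)) / 2)
}

#' @rdname kf_initiate
#' @export
kf_update <- function(model, state, z, R = NULL, noise_scale = 1) {
  H <- model$H
  z <- as.numeric(z)
  if (length(z) != nrow(H) || anyNA(z)) {
    stop("measurement has wrong dimension", call. = FALSE)
  }
  if (nrow(H) == 4L && is.null(model$R) && (z[3] <= 0 || z[4] <= 0)) {
    stop("invalid measurement: w, h must be > 0", call. = FALSE)
  }
  if (is.null(R)) R <- measurement_noise(model, state$mean, noise_scale)
  P <- state$cov
  S <- H %*% P %*% t(H) + R
  K <- tryCatch(
    t(solve(S, H %*% P)),
    error = function(e) stop("innovation covariance is singular: ",
                             conditionMessage(e), call. = FALSE)
  )
  innov <- z - drop(H %*% state$mean)
  mean <- state$mean + drop(K %*% innov)
  P_post <- (diag(nrow(P)) - K %*% H) %*% P
  new_kalman_state(mean, (P_post + t(P_post)) / 2)
}
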