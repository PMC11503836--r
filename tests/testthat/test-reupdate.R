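poly_support <- function(f, frames = c(0, 1, 4, 5)) {
  tibble::tibble(frame = frames, x = f(frames))
}

test_that("interpolating spline passes through every support point", {
  set.seed(5)
  frames <- c(0, 2, 3, 7, 9)
  sup <- tibble::tibble(frame = frames, cx = rnorm(5, 100, 20),
                        cy = rnorm(5, 50, 10), w = runif(5, 10, 20),
                        h = runif(5, 10, 20))
  for (bk in c("notaknot", "natural")) {
    sp <- fit_gap_spline(sup, boundary = bk)
    at_knots <- virtual_observations(sp, frames)
    expect_equal(as.data.frame(at_knots), as.data.frame(sup),
                 tolerance = 1e-10)
  }
})

test_that("first and second derivatives are continuous at interior knots", {
  set.seed(8)
  sup <- tibble::tibble(frame = c(0, 1, 3, 6, 8), x = rnorm(5))
  for (bk in c("notaknot", "natural")) {
    sp <- fit_gap_spline(sup, boundary = bk)
    cf <- sp$coef[, , 1]
    h <- diff(sp$knots)
    for (i in 1:3) {
      d1_left <- cf[i, 2] + 2 * cf[i, 3] * h[i] + 3 * cf[i, 4] * h[i]^2
      d2_left <- 2 * cf[i, 3] + 6 * cf[i, 4] * h[i]
      expect_equal(d1_left, cf[i + 1, 2], tolerance = 1e-6)
      expect_equal(d2_left, 2 * cf[i + 1, 3], tolerance = 1e-6)
    }
  }
})

test_that("not-a-knot reproduces polynomials up to degree 3 at gap frames", {
  polys <- list(function(t) rep(7, length(t)),
                function(t) 3 + 2 * t,
                function(t) 1 - t + 0.5 * t^2,
                function(t) t^3 - 2 * t)
  for (f in polys) {
    sp <- fit_gap_spline(poly_support(f), boundary = "notaknot")
    at <- seq(0, 5, by = 0.5)
    v <- virtual_observations(sp, at)
    expect_equal(v$x, f(at), tolerance = 1e-8)
  }
  # the cubic case pinned to its printed value
  v2 <- virtual_observations(
    fit_gap_spline(poly_support(function(t) t^3 - 2 * t)), 2)
  expect_equal(v2$x, 4, tolerance = 1e-8)
})

test_that("degree <= 1 is reproduced under every boundary kind", {
  f <- function(t) 3 + 2 * t
  for (bk in c("notaknot", "natural")) {
    v <- virtual_observations(fit_gap_spline(poly_support(f), boundary = bk),
                              c(2, 2.5, 3))
    expect_equal(v$x, f(c(2, 2.5, 3)), tolerance = 1e-8)
  }
})

test_that("spline oracle: natural boundary agrees with stats::spline", {
  set.seed(21)
  t <- c(0, 1, 3, 4, 6)
  y <- rnorm(5)
  sp <- fit_gap_spline(tibble::tibble(frame = t, x = y),
                       boundary = "natural")
  at <- seq(0, 6, by = 0.25)
  ref <- stats::spline(t, y, xout = at, method = "natural")$y
  expect_equal(virtual_observations(sp, at)$x, ref, tolerance = 1e-9)
})

test_that("support preconditions are enforced", {
  expect_error(fit_gap_spline(tibble::tibble(frame = c(0, 1, 2), x = 1:3)),
               "insufficient support")
  expect_error(fit_gap_spline(tibble::tibble(frame = c(0, 1, 1, 2),
                                             x = 1:4)), "duplicate")
  expect_error(gap_support(tibble::tibble(frame = c(1, 2), cx = 1:2),
                           tibble::tibble(frame = 2, cx = 3)),
               "must all follow")
  sup <- gap_support(tibble::tibble(frame = 1:3, cx = 1:3),
                     tibble::tibble(frame = 9, cx = 9))
  expect_equal(sup$gap, 4:8)
})

test_that("virtual observations refuse extrapolation, keep frame order", {
  sp <- fit_gap_spline(poly_support(function(t) t))
  expect_error(virtual_observations(sp, 6), "span")
  expect_equal(nrow(virtual_observations(sp, numeric(0))), 0L)
  v <- virtual_observations(sp, c(3, 2))
  expect_equal(v$frame, c(2, 3))
  # knot frame returns the knot observation exactly
  expect_equal(virtual_observations(sp, 4)$x, 4)
})

test_that("replay of an empty virtual sequence is the identity", {
  m <- kalman_model()
  s <- kf_initiate(m, c(10, 10, 5, 5))
  out <- replay_gap(m, s, tibble::tibble(frame = numeric(0),
                                         cx = numeric(0), cy = numeric(0),
                                         w = numeric(0), h = numeric(0)))
  expect_identical(out, s)
})

test_that("replay across a gap recovers a noiseless constant-velocity path", {
  # noiseless filter limit (no process noise, exact measurements): the
  # replayed chain must land on the true path to numerical precision
  m <- kalman_model(Q = matrix(0, 8, 8), R = diag(1e-12, 4))
  path <- function(t) c(10 + 2 * t, 5 + 1 * t, 12, 12)
  s <- kf_initiate(m, path(1))
  for (t in 2:5) {
    s <- kf_predict(m, s)
    s <- kf_update(m, s, path(t))
  }
  sup <- tibble::tibble(frame = c(3, 4, 5, 10))
  z <- t(vapply(sup$frame, path, numeric(4)))
  sup$cx <- z[, 1]; sup$cy <- z[, 2]; sup$w <- z[, 3]; sup$h <- z[, 4]
  v <- virtual_observations(fit_gap_spline(sup), 6:9)
  out <- replay_gap(m, s, v)
  pred <- kf_predict(m, out)
  expect_lt(sqrt(sum((pred$mean[1:2] - path(10)[1:2])^2)), 1e-6)
})

test_that("replay is deterministic bit for bit", {
  m <- kalman_model()
  s <- kf_initiate(m, c(0, 0, 10, 10))
  v <- tibble::tibble(frame = 1:3, cx = c(1, 2.5, 3.7),
                      cy = c(0.5, 1, 1.5), w = 10, h = 10)
  expect_identical(replay_gap(m, s, v), replay_gap(m, s, v))
})

test_that("replay beats predict-only coasting across curved-path gaps", {
  # monotone-benefit property: over random quadratic trajectories with
  # 5-frame gaps, the state after replaying virtual observations (and
  # folding in the re-detection) sits closer to the true path than the
  # predict-only coasted state does
  set.seed(31)
  m <- kalman_model()
  errs <- matrix(NA_real_, 25, 2)
  for (trial in 1:25) {
    a <- runif(2, -0.08, 0.08)
    v0 <- runif(2, -3, 3)
    p0 <- runif(2, 200, 800)
    path <- function(t) c(p0 + v0 * t + a * t^2, 80, 60)
    s <- kf_initiate(m, path(1))
    for (t in 2:10) {
      s <- kf_predict(m, s)
      s <- kf_update(m, s, path(t))
    }
    gap <- 11:15
    coast <- s
    for (t in c(gap, 16)) coast <- kf_predict(m, coast)
    sup <- tibble::tibble(frame = c(8, 9, 10, 16))
    z <- t(vapply(sup$frame, path, numeric(4)))
    sup$cx <- z[, 1]; sup$cy <- z[, 2]; sup$w <- z[, 3]; sup$h <- z[, 4]
    re <- replay_gap(m, s, virtual_observations(fit_gap_spline(sup), gap))
    re <- kf_predict(m, re)
    re <- kf_update(m, re, path(16))
    errs[trial, ] <- c(sqrt(sum((coast$mean[1:2] - path(16)[1:2])^2)),
                       sqrt(sum((re$mean[1:2] - path(16)[1:2])^2)))
  }
  expect_lt(mean(errs[, 2]), mean(errs[, 1]))
  expect_true(all(errs[, 2] < errs[, 1] + 1e-9))
})
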